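#' Desk-scale experiment preset
#'
#' The fixed small-scale study conditions used throughout the package's
#' tests and reproduction script: 2 classes x 6 slides of 256 x 256
#' pixels, signal occupying 10% of each slide, 64-pixel patches at
#' overlap 32 (about 600 patches), a compact encoder, 10 pretraining
#' epochs at batch 16 and a 25-epoch linear probe. These sizes are the
#' package's desk-scale operating point; the structure (alpha, schedule,
#' optimisers, augmentations) is identical to the full-scale recipe.
#'
#' @param positive_fraction signal fraction of each slide.
#' @param data_seed seed of the fixed synthetic dataset.
#' @return list with \code{spec}, \code{grid} and size constants used by
#'   [run_probe_condition()].
#' @export
desk_preset <- function(positive_fraction = 0.1, data_seed = 7) {
  list(spec = synthetic_spec(n_classes = 2, slides_per_class = 6,
                             slide_size = c(256, 256),
                             positive_fraction = positive_fraction,
                             seed = data_seed),
       grid = patch_grid_spec(64, 32, 5),
       batch_size = 16, pretrain_epochs = 10, warmup_epochs = 1,
       base_lr = 0.01,
       ## 64-px patches need a milder crop range than full-scale 224-px
       ## inputs, or the two views of a patch rarely share content
       policy = augmentation_policy(output_size = 64,
                                    crop_scale_range = c(0.2, 1)),
       probe_epochs = 25, probe_batch = 64,
       model = list(pool_grid = 8, encoder_hidden = 64, rep_dim = 32,
                    proj_hidden = 64, proj_dim = 32))
}

#' Build the desk-scale patch dataset
#'
#' @param preset a [desk_preset()].
#' @export
desk_dataset <- function(preset = desk_preset()) {
  make_patch_dataset(preset$spec, preset$grid)
}

#' Pretrain + linear probe for one condition
#'
#' Runs the full pipeline once: self-supervised pretraining on the train
#' split (with or without the class-preserving permutation), then a
#' linear probe trained on the frozen encoder and evaluated on the test
#' split at patch and slide level.
#'
#' @param dataset a patch dataset with train/test splits (see
#'   [desk_dataset()]).
#' @param framework \code{"byol"}, \code{"simclr"} or \code{"vicreg"}.
#' @param histoperm permute the second labeled view?
#' @param seed run seed (reseeds model init, partitions, augmentations
#'   and the probe).
#' @param preset a [desk_preset()] supplying the sizes.
#' @return list with \code{patch} and \code{slide} \code{metrics_report}s,
#'   plus \code{pretrain} and \code{probe} artefacts.
#' @export
run_probe_condition <- function(dataset, framework, histoperm, seed,
                                preset = desk_preset()) {
  train <- dataset_split(dataset, "train")
  test <- dataset_split(dataset, "test")
  cfg <- do.call(pretrain_config, c(
    list(epochs = preset$pretrain_epochs,
         warmup_epochs = preset$warmup_epochs,
         base_lr = preset$base_lr,
         batch_size = preset$batch_size, alpha = 0.75,
         histoperm = histoperm, framework = framework, seed = seed,
         policy = preset$policy),
    preset$model))
  pt <- pretrain(train, cfg)
  probe <- linear_eval(pt$state, train, test,
                       linear_eval_config(epochs = preset$probe_epochs,
                                          batch_size = preset$probe_batch,
                                          seed = derive_seed(seed,
                                                             "probe")))
  list(patch = metrics_report(probe$predictions, "patch"),
       slide = metrics_report(probe$predictions, "slide"),
       pretrain = pt, probe = probe)
}

#' Directional comparison: permuted pipeline vs vanilla baseline
#'
#' For every framework x seed cell, pretrains with the class-preserving
#' permutation (alpha = 0.75) and without it (vanilla pipeline), probes
#' both encoders, and tabulates patch-level accuracy. Mirrors the
#' repeated-run design of the full-scale study at desk scale.
#'
#' @param dataset patch dataset (default: the fixed desk-scale dataset).
#' @param frameworks character vector of frameworks to run.
#' @param seeds integer run seeds (3 by default).
#' @param preset a [desk_preset()].
#' @param quiet suppress progress messages?
#' @return list with \code{cells} (data.frame framework, seed, condition,
#'   accuracy, f1, auc), \code{summary} (per-condition mean patch
#'   accuracy), \code{delta} (permuted minus vanilla mean accuracy) and
#'   \code{wins} (cells where the permuted run is strictly better).
#' @export
directional_experiment <- function(dataset = NULL,
                                   frameworks = c("byol", "simclr",
                                                  "vicreg"),
                                   seeds = c(11, 12, 13),
                                   preset = desk_preset(),
                                   quiet = FALSE) {
  if (is.null(dataset)) dataset <- desk_dataset(preset)
  cells <- list()
  for (fw in frameworks) {
    for (sd in seeds) {
      for (cond in c("histoperm", "baseline")) {
        if (!quiet) {
          message(sprintf("[%s] seed %d, %s", fw, sd, cond))
        }
        res <- run_probe_condition(dataset, fw, cond == "histoperm",
                                   sd, preset)
        m <- res$patch$metrics
        cells[[length(cells) + 1]] <- data.frame(
          framework = fw, seed = sd, condition = cond,
          accuracy = m[["accuracy"]], f1 = m[["f1"]], auc = m[["auc"]])
      }
    }
  }
  cells <- do.call(rbind, cells)
  mean_acc <- tapply(cells$accuracy, cells$condition, mean)
  wide <- merge(
    cells[cells$condition == "histoperm",
          c("framework", "seed", "accuracy")],
    cells[cells$condition == "baseline",
          c("framework", "seed", "accuracy")],
    by = c("framework", "seed"), suffixes = c("_histoperm", "_baseline"))
  list(cells = cells,
       summary = mean_acc,
       delta = unname(mean_acc[["histoperm"]] - mean_acc[["baseline"]]),
       wins = sum(wide$accuracy_histoperm > wide$accuracy_baseline),
       n_cells = nrow(wide))
}
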