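toy_preds <- function() {
  data.frame(slide_id = c("s1", "s1", "s2", "s2"),
             x = 0L, y = c(0L, 16L, 0L, 16L),
             true_label = c("A", "A", "B", "B"),
             prob_A = c(0.9, 0.6, 0.3, 0.8),
             prob_B = c(0.1, 0.4, 0.7, 0.2),
             stringsAsFactors = FALSE)
}

test_that("slide aggregation is the unweighted mean with a lowest-index
           tie-break", {
  one <- toy_preds()[1, ]
  agg <- aggregate_slide(one)
  expect_equal(agg$prob_A, 0.9)
  expect_equal(agg$predicted_label, "A")

  tie <- data.frame(slide_id = "s", true_label = "A",
                    prob_A = c(0.8, 0.2), prob_B = c(0.2, 0.8))
  agg <- aggregate_slide(tie)
  expect_equal(agg$prob_A, 0.5)
  expect_equal(agg$prob_B, 0.5)
  expect_equal(agg$predicted_label, "A") # tie -> lowest class index
  expect_equal(agg$prob_A + agg$prob_B, 1)

  expect_error(aggregate_slide(toy_preds()), "single slide")
  expect_error(aggregate_slide(toy_preds()[0, ]), "no patches")

  # permutation invariance over a slide's patches
  s1 <- toy_preds()[1:2, ]
  expect_equal(aggregate_slide(s1[2:1, ])$prob_A,
               aggregate_slide(s1)$prob_A)
})

test_that("metrics match a by-hand confusion-matrix and rank
           computation on the 4-item toy set", {
  p <- toy_preds()
  m <- compute_metrics(p$true_label, p[, c("prob_A", "prob_B")])
  # argmax predictions: A, A, B, A -> 3/4 correct
  expect_equal(unname(m["accuracy"]), 0.75)
  # F1(A): tp=2 fp=1 fn=0 -> 0.8; F1(B): tp=1 fp=0 fn=1 -> 2/3
  expect_equal(unname(m["f1"]), (0.8 + 2 / 3) / 2)
  # rank AUC: both one-vs-rest AUCs are 0.75
  expect_equal(unname(m["auc"]), 0.75)
})

test_that("metrics hit their boundary values", {
  perfect <- data.frame(true_label = c("A", "B"),
                        prob_A = c(1, 0), prob_B = c(0, 1))
  expect_equal(unname(compute_metrics(perfect$true_label,
                                      perfect[, 2:3])),
               c(1, 1, 1))
  wrong <- data.frame(true_label = c("A", "B"),
                      prob_A = c(0.1, 0.9), prob_B = c(0.9, 0.1))
  m <- compute_metrics(wrong$true_label, wrong[, 2:3])
  expect_equal(unname(m["accuracy"]), 0)
  # single-class truth: AUC undefined, other metrics still reported in
  # the error message
  expect_error(compute_metrics(c("A", "A"), perfect[, 2:3]),
               "AUC undefined")
})

test_that("metrics agree with an independent reference implementation
           on random prediction sets", {
  set.seed(99)
  for (k in 1:100) {
    n <- sample(10:40, 1)
    truth <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("A", "B")
    pa <- stats::runif(n)
    probs <- data.frame(prob_A = pa, prob_B = 1 - pa)
    m <- compute_metrics(truth, probs)
    ref_auc <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(truth == "A", pa, quiet = TRUE,
                          direction = "<",
                          levels = c(FALSE, TRUE)))))
    expect_equal(unname(m["auc"]), ref_auc, tolerance = 1e-9)
    # accuracy from an explicit confusion table
    pred <- ifelse(pa >= 0.5, "A", "B")
    expect_equal(unname(m["accuracy"]), mean(pred == truth),
                 tolerance = 1e-9)
  }
})

test_that("run summaries report mean and sample standard deviation", {
  mk <- function(acc) {
    structure(list(level = "patch",
                   metrics = c(accuracy = acc, f1 = acc, auc = acc)),
              class = "metrics_report")
  }
  s <- summarize_runs(list(mk(0.8), mk(0.9), mk(1.0)))
  expect_equal(unname(s$mean["accuracy"]), 0.9)
  expect_equal(unname(s$std["accuracy"]), stats::sd(c(0.8, 0.9, 1.0)))
  expect_true(all(s$mean >= apply(s$per_run, 2, min) &
                    s$mean <= apply(s$per_run, 2, max)))

  same <- summarize_runs(list(mk(0.7), mk(0.7), mk(0.7)))
  expect_equal(unname(same$std), c(0, 0, 0))

  single <- summarize_runs(list(mk(0.6)))
  expect_equal(unname(single$mean["f1"]), 0.6)
  expect_equal(unname(single$std["f1"]), 0)

  slide <- structure(list(level = "slide", metrics = mk(0.5)$metrics),
                     class = "metrics_report")
  expect_error(summarize_runs(list(mk(0.5), slide)), "levels")
})

test_that("condition comparisons are signed and antisymmetric", {
  mk <- function(acc) summarize_runs(list(structure(
    list(level = "patch", metrics = c(accuracy = acc, f1 = acc,
                                      auc = acc)),
    class = "metrics_report")))
  a <- mk(0.9); b <- mk(0.8)
  expect_equal(compare_conditions(a, a)$delta, c(0, 0, 0))
  d_ab <- compare_conditions(a, b)$delta
  d_ba <- compare_conditions(b, a)$delta
  expect_equal(d_ab, -d_ba)
  expect_equal(d_ab, rep(0.1, 3), tolerance = 1e-12)
  slide_a <- a; slide_a$level <- "slide"
  expect_error(compare_conditions(a, slide_a), "levels")
})

test_that("patch predictions aggregate to slide reports end to end", {
  p <- toy_preds()
  slides <- aggregate_slides(p)
  expect_equal(nrow(slides), 2)
  rep_slide <- metrics_report(p, "slide")
  expect_true(all(rep_slide$metrics >= 0 & rep_slide$metrics <= 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(summarize_runs(list(rep_slide)), path)
  back <- jsonlite::read_json(path)
  expect_equal(back$level, "slide")
  expect_equal(back$mean$accuracy, unname(rep_slide$metrics["accuracy"]))
})
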