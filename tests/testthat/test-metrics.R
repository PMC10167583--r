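test_that("the headline 2x2 reproduces the printed metric set", {
  rep <- diagnostic_metrics(printed_cm(), seed = 1)
  est <- function(m) report_metric(rep, m)[["estimate"]]
  expect_equal(round(100 * est("sensitivity"), 1), 89.9)
  expect_equal(round(100 * est("specificity"), 1), 99.8)
  expect_equal(round(100 * est("ppv"), 1), 91.1)
  expect_equal(round(100 * est("npv"), 1), 99.8)
  expect_equal(round(est("lr_pos")), 483)
  expect_equal(round(est("lr_neg"), 2), 0.10)
  expect_equal(round(est("auc"), 2), 0.95)
  expect_equal(round(est("kappa"), 2), 0.90)
  # printed F1 interval 0.90-0.91 contains the computed value (~0.905)
  expect_gte(est("f1"), 0.90)
  expect_lte(est("f1"), 0.91)
  expect_equal(round(100 * est("prevalence"), 1), 2.1)
})

test_that("perfect and chance-level tables behave as expected", {
  perfect <- diagnostic_metrics(vte_confusion(10, 0, 0, 90))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(report_metric(perfect, m)[["estimate"]], 1)
  }
  expect_equal(report_metric(perfect, "kappa")[["estimate"]], 1)
  # no false positives: LR+ undefined, flagged rather than thrown
  expect_true(is.na(report_metric(perfect, "lr_pos")[["estimate"]]))
  expect_match(perfect$note[perfect$metric == "lr_pos"], "undefined")
  # 100% sensitivity: LR- is 0 with a bootstrap interval anchored near 0
  expect_equal(report_metric(perfect, "lr_neg")[["estimate"]], 0)
  expect_lt(report_metric(perfect, "lr_neg")[["lower"]], 0.005)

  chance <- diagnostic_metrics(vte_confusion(25, 25, 25, 25))
  expect_equal(report_metric(chance, "sensitivity")[["estimate"]], 0.5)
  expect_equal(report_metric(chance, "specificity")[["estimate"]], 0.5)
  expect_equal(report_metric(chance, "auc")[["estimate"]], 0.5)
  expect_equal(report_metric(chance, "kappa")[["estimate"]], 0)
})

test_that("algebraic identities hold exactly for arbitrary tables", {
  set.seed(9)
  for (i in 1:20) {
    cm <- vte_confusion(sample(1:200, 1), sample(1:50, 1),
                        sample(1:50, 1), sample(1:5000, 1))
    rep <- diagnostic_metrics(cm, boot_reps = 2000)
    sens <- report_metric(rep, "sensitivity")[["estimate"]]
    spec <- report_metric(rep, "specificity")[["estimate"]]
    expect_equal(sens * (cm$tp + cm$fn), cm$tp)
    expect_equal(report_metric(rep, "auc")[["estimate"]], (sens + spec) / 2)
    expect_equal(report_metric(rep, "lr_pos")[["estimate"]] * (1 - spec), sens)
    # CI sandwich: lower <= point <= upper wherever defined
    defined <- !is.na(rep$estimate) & !is.na(rep$lower)
    expect_true(all(rep$lower[defined] <= rep$estimate[defined] + 1e-12))
    expect_true(all(rep$estimate[defined] <= rep$upper[defined] + 1e-12))
  }
})

test_that("proportion intervals match independent oracles", {
  # exact interval against binom.test
  for (k in c(0, 3, 50, 97, 100)) {
    got <- proportion_ci(k, 100)
    ref <- stats::binom.test(k, 100)$conf.int
    expect_equal(unname(got), as.numeric(ref), tolerance = 1e-8)
  }
  expect_equal(proportion_ci(0, 10)[["lower"]], 0)
  expect_equal(proportion_ci(10, 10)[["upper"]], 1)

  # Wilson interval against numeric inversion of the score test:
  # p0 is inside the interval iff |phat - p0| <= z * sqrt(p0 (1-p0) / n)
  z <- stats::qnorm(0.975)
  score_ok <- function(k, n, p0) {
    abs(k / n - p0) <= z * sqrt(p0 * (1 - p0) / n) + 1e-12
  }
  for (k in c(5, 50, 95)) {
    got <- proportion_ci(k, 100, method = "wilson")
    grid <- seq(0.0005, 0.9995, by = 0.0005)
    inside <- grid[vapply(grid, function(p0) score_ok(k, 100, p0), logical(1))]
    expect_lt(abs(got[["lower"]] - min(inside)), 0.001)  # grid resolution
    expect_lt(abs(got[["upper"]] - max(inside)), 0.001)
  }
  # symmetric about 0.5 for k = n/2
  w <- proportion_ci(50, 100, method = "wilson")
  expect_equal(w[["upper"]] - 0.5, 0.5 - w[["lower"]], tolerance = 1e-12)
  expect_error(proportion_ci(5, 0), "positive")
})

test_that("log-method LR intervals reproduce the printed bounds", {
  cm <- printed_cm()
  pos <- lr_ci(cm, "pos")
  expect_equal(round(pos[["lower"]]), 370)
  expect_equal(round(pos[["upper"]]), 630)  # 629.5 at full precision
  neg <- lr_ci(cm, "neg")
  expect_equal(round(neg[["lower"]], 2), 0.08)
  expect_equal(round(neg[["upper"]], 2), 0.13)
  expect_error(lr_ci(vte_confusion(10, 0, 0, 90), "pos"), "bootstrap_lr_ci")
})

test_that("bootstrap LR interval is seeded, near the log-method, 0-anchored", {
  cm <- printed_cm()
  b1 <- bootstrap_lr_ci(cm, "neg", reps = 4000, seed = 7)
  b2 <- bootstrap_lr_ci(cm, "neg", reps = 4000, seed = 7)
  expect_identical(b1, b2)
  logm <- lr_ci(cm, "neg")
  expect_lt(abs(b1[["lower"]] - logm[["lower"]]), 0.02)
  expect_lt(abs(b1[["upper"]] - logm[["upper"]]), 0.02)
  # 100% sensitivity: defined, lower bound 0 at reported precision,
  # upper bound strictly positive
  sens100 <- bootstrap_lr_ci(vte_confusion(50, 8, 0, 2000), "neg",
                             reps = 2000, seed = 3)
  expect_lt(sens100[["lower"]], 0.005)
  expect_gt(sens100[["upper"]], 0)
  expect_error(bootstrap_lr_ci(cm, "neg", reps = 100), "at least 1000")
})

test_that("kappa has the printed value, swap invariance, and a null near 0", {
  kp <- kappa_ci(printed_cm())
  expect_equal(round(kp$kappa, 2), 0.90)
  expect_equal(round(kp$lower, 2), 0.89)
  expect_equal(round(kp$upper, 2), 0.92)

  set.seed(11)
  for (i in 1:10) {
    cm <- vte_confusion(sample(1:100, 1), sample(1:100, 1),
                        sample(1:100, 1), sample(1:100, 1))
    swapped <- vte_confusion(cm$tn, cm$fn, cm$fp, cm$tp)
    expect_equal(kappa_ci(cm)$kappa, kappa_ci(swapped)$kappa)
  }

  perfect <- kappa_ci(vte_confusion(40, 0, 0, 60))
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$upper, 1)
  expect_match(kappa_ci(vte_confusion(0, 0, 0, 50))$note, "degenerate")

  # independent labels at n = 10^4: kappa ~ 0 within Monte-Carlo error
  set.seed(12)
  a <- stats::runif(10000) < 0.3
  b <- stats::runif(10000) < 0.3
  cm0 <- vte_confusion(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
  expect_lt(abs(kappa_ci(cm0)$kappa), 0.03)
})

test_that("confusion_matrix aligns ids and rejects mismatches", {
  pred <- data.frame(patient_id = c("a", "b", "c"),
                     vte_any = c(TRUE, FALSE, TRUE))
  ref <- data.frame(patient_id = c("c", "a", "b"),
                    vte_any = c(FALSE, TRUE, FALSE))
  cm <- confusion_matrix(pred, ref)
  expect_equal(unlist(cm), c(tp = 1, fp = 1, fn = 0, tn = 1))
  expect_error(confusion_matrix(pred, ref[1:2, ]), "mismatch")
  expect_error(vte_confusion(-1, 0, 0, 5), "non-negative")
  expect_error(vte_confusion(0, 0, 0, 0), "n > 0")
})
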