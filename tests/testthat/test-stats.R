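test_that("paired t-test matches the closed form on the worked examples", {
  # symmetric differences: t = 0, p = 1
  r <- paired_t_test(tibble::tibble(pms_tumor = c(1, 2), pms_healthy = c(2, 1)))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r2 <- paired_t_test(tibble::tibble(pms_tumor = c(1, 2, 3),
                                     pms_healthy = c(2, 4, 9)))
  expect_equal(r2$t, -3 * sqrt(3) / sqrt(7), tolerance = 1e-12)
  expect_equal(r2$df, 2)
  expect_equal(r2$p, 2 * pt(-abs(r2$t), 2), tolerance = 1e-12)
  expect_equal(r2$mean_diff, -3)
})

test_that("paired t-test agrees with the closed-form oracle on random data", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    x <- rnorm(n, mean = runif(1, -2, 2))
    y <- rnorm(n, mean = runif(1, -2, 2))
    got <- paired_t_test(tibble::tibble(pms_tumor = x, pms_healthy = y))
    want <- brute_paired_t(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    # two-sided symmetry: swapping the arms negates t, preserves p
    rev <- paired_t_test(tibble::tibble(pms_tumor = y, pms_healthy = x))
    expect_equal(rev$t, -got$t, tolerance = 1e-10)
    expect_equal(rev$p, got$p, tolerance = 1e-10)
  }
})

test_that("degenerate difference variance is flagged, not fatal", {
  same <- tibble::tibble(pms_tumor = c(1, 2, 3), pms_healthy = c(1, 2, 3))
  r <- paired_t_test(same)
  expect_true(r$degenerate)
  expect_equal(c(r$t, r$p), c(0, 1))

  shifted <- tibble::tibble(pms_tumor = c(2, 3, 4), pms_healthy = c(1, 2, 3))
  r2 <- paired_t_test(shifted)
  expect_true(r2$degenerate)
  expect_equal(r2$p, 0)
  expect_error(paired_t_test(tibble::tibble(pms_tumor = 1, pms_healthy = 2)),
               "at least 2")
})

test_that("ROC handles the separable and reversed worked examples", {
  expect_equal(roc_curve(c(0.1, 0.2), c(1.0, 1.1))$auc, 1)
  expect_equal(roc_curve(c(1.0, 1.1), c(0.1, 0.2))$auc, 0)
  r <- roc_curve(c(0.4, 0.5, 0.7, 1.1), c(1.0, 1.3, 0.9, 1.6))
  expect_equal(r$auc, 14 / 16)
})

test_that("trapezoidal AUC equals the Mann-Whitney pair count, ties included", {
  set.seed(17)
  for (i in 1:200) {
    nc <- sample(2:15, 1)
    nh <- sample(2:15, 1)
    # coarse grid forces ties within and across groups
    cancer <- sample(seq(0, 2, by = 0.25), nc, replace = TRUE)
    healthy <- sample(seq(0, 2, by = 0.25), nh, replace = TRUE)
    r <- roc_curve(cancer, healthy)
    expect_equal(r$auc, brute_auc(cancer, healthy), tolerance = 1e-12)
  }
})

test_that("AUC and operating points are invariant to monotone transforms", {
  set.seed(5)
  cancer <- runif(12, 0, 1)
  healthy <- runif(9, 0.3, 1.4)
  base <- roc_curve(cancer, healthy)
  for (f in list(function(x) x^3, function(x) exp(x), function(x) 5 * x + 2)) {
    tr <- roc_curve(f(cancer), f(healthy))
    expect_equal(tr$auc, base$auc, tolerance = 1e-12)
    expect_equal(sort(unique(round(tr$curve$sens, 12))),
                 sort(unique(round(base$curve$sens, 12))))
    expect_equal(tr$youden_sens, base$youden_sens)
    expect_equal(tr$youden_spec, base$youden_spec)
  }
})

test_that("AUC agrees with pROC on random score sets", {
  set.seed(23)
  for (i in 1:20) {
    cancer <- sample(seq(0, 3, by = 0.5), sample(3:10, 1), replace = TRUE)
    healthy <- sample(seq(0, 3, by = 0.5), sample(3:10, 1), replace = TRUE)
    ours <- roc_curve(cancer, healthy)$auc
    ref <- suppressMessages(
      pROC::auc(pROC::roc(controls = healthy, cases = cancer, direction = ">"))
    )
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("the Youden threshold lands on the gap midpoint under separation", {
  r <- roc_curve(c(0.1, 0.2), c(1.0, 1.1))
  expect_equal(r$youden_threshold, 0.6)
  expect_equal(c(r$youden_sens, r$youden_spec), c(1, 1))

  single <- roc_curve(0.5, 1.0)
  expect_equal(single$youden_threshold, 0.75)
  expect_equal(c(single$youden_sens, single$youden_spec), c(1, 1))
})

test_that("the Youden point of the overlapping example matches brute force", {
  cancer <- c(0.4, 0.5, 0.7, 1.1)
  healthy <- c(1.0, 1.3, 0.9, 1.6)
  r <- roc_curve(cancer, healthy)
  # brute force over all candidate cutoffs
  cand <- c(-Inf, sort(unique(c(cancer, healthy))), Inf)
  best <- -Inf; best_t <- NA
  for (t in cand) {
    j <- mean(cancer < t) + mean(healthy >= t) - 1
    if (j > best) { best <- j; best_t <- t }
  }
  yt <- youden_threshold(r)
  expect_equal(yt$sens + yt$spec - 1, best, tolerance = 1e-12)
  expect_equal(yt$threshold, 0.8)
  expect_equal(yt$sens, 0.75)
  expect_equal(yt$spec, 1.0)
})

test_that("cohort_report summarises groups, test, ROC and confusion table", {
  set.seed(2)
  pairs <- tibble::tibble(pms_tumor = runif(30, 0.3, 0.7),
                          pms_healthy = runif(30, 0.9, 1.8))
  rep <- cohort_report(pairs)
  g <- glance(rep)
  expect_equal(g$auc, 1)
  expect_equal(c(g$youden_sens, g$youden_spec), c(1, 1))
  expect_lt(g$p, 1e-6)
  expect_gt(g$youden_threshold, max(pairs$pms_tumor))
  expect_lt(g$youden_threshold, min(pairs$pms_healthy))
  correct <- dplyr::filter(rep$confusion, .data$actual == .data$predicted)
  expect_equal(sum(correct$n), 60)
})

test_that("exchangeable arms give an AUC of one half", {
  scores <- c(0.4, 0.8, 1.1, 1.6, 0.55)
  rep <- cohort_report(tibble::tibble(pms_tumor = scores, pms_healthy = scores))
  expect_equal(rep$roc$auc, 0.5)
})
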