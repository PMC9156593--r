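test_that("voxel metrics hit the degenerate extremes", {
  d <- c(6, 6, 6)
  a <- array(FALSE, d); a[2:3, 2:3, 2:3] <- TRUE
  same <- voxel_metrics(a, a)
  expect_equal(same$precision, 1); expect_equal(same$sensitivity, 1)
  expect_equal(same$dice, 1)
  b <- array(FALSE, d); b[5, 5, 5] <- TRUE
  disjoint <- voxel_metrics(a, b)
  expect_equal(disjoint$precision, 0); expect_equal(disjoint$sensitivity, 0)
  expect_equal(disjoint$dice, 0)
})

test_that("the published precision and sensitivity imply Dice 0.61", {
  # counts realizing precision 0.69 and sensitivity 0.54 exactly
  tp <- 69 * 54; fp <- 69 * 54 / 0.69 - tp; fn <- 69 * 54 / 0.54 - tp
  dice <- 2 * tp / (2 * tp + fp + fn)
  expect_equal(round(dice, 2), 0.61)
  expect_equal(dice, 2 * 0.69 * 0.54 / (0.69 + 0.54), tolerance = 1e-12)
})

test_that("Dice from pooled counts equals the harmonic-mean identity", {
  set.seed(6)
  for (rep in 1:10) {
    pred <- lapply(1:3, function(i) array(runif(5^3) > 0.6, c(5, 5, 5)))
    truth <- lapply(1:3, function(i) array(runif(5^3) > 0.6, c(5, 5, 5)))
    vm <- voxel_metrics(pred, truth)
    if (!is.na(vm$dice) && !is.na(vm$precision) && !is.na(vm$sensitivity) &&
        (vm$precision + vm$sensitivity) > 0) {
      expect_equal(vm$dice,
                   2 * vm$precision * vm$sensitivity /
                     (vm$precision + vm$sensitivity), tolerance = 1e-12)
    }
  }
})

test_that("undefined ratios are reported as missing, never zero", {
  d <- c(4, 4, 4)
  none <- voxel_metrics(array(FALSE, d), array(FALSE, d))
  expect_true(is.na(none$precision))
  expect_true(is.na(none$sensitivity))
  expect_true(is.na(none$dice))
  expect_equal(none$tn, 64)
  expect_error(voxel_metrics(array(FALSE, d), array(FALSE, d),
                             array(FALSE, d)), "valid mask")
})

test_that("the published confusion matrix gives accuracy 0.88", {
  cm <- case_metrics(43, 5, 45, 7)
  expect_equal(cm$accuracy, 0.88)
  expect_equal(case_metrics(1, 0, 1, 0)$accuracy, 1)
  expect_equal(case_metrics(0, 1, 0, 1)$accuracy, 0)
  expect_error(case_metrics(0, 0, 0, 0), "no cases")
  expect_error(case_metrics(-1, 0, 1, 0), "non-negative")
})

test_that("perfectly separated volumes give AUC 1 at the top-left corner", {
  roc <- roc_volume_threshold(c(30, 40, 50, 1, 2, 3),
                              c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(roc$auc, 1)
  expect_equal(unname(roc$optimal_point), c(0, 1))
  expect_gte(roc$optimal_threshold, 3)
  expect_lt(roc$optimal_threshold, 30)
})

test_that("volume-independent labels give AUC near one half", {
  set.seed(9)
  v <- runif(2000, 0, 100)
  l <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  expect_lt(abs(roc_volume_threshold(v, l)$auc - 0.5), 0.05)
})

test_that("trapezoidal AUC equals the pairwise concordance oracle", {
  set.seed(10)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    v <- round(runif(n, 0, 10), 1)   # ties likely
    l <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    roc <- roc_volume_threshold(v, l)
    expect_equal(roc$auc, concordance_auc(v, l), tolerance = 1e-12)
  }
})

test_that("single-class inputs are rejected", {
  expect_error(roc_volume_threshold(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("stroke/control character labels are accepted", {
  roc <- roc_volume_threshold(c(30, 1), c("stroke", "control"))
  expect_equal(roc$auc, 1)
})

test_that("a constant statistic gives a zero-width interval", {
  df <- data.frame(x = 1:20)
  ci <- bootstrap_ci(df, function(d) 7, reps = 200, seed = 1)
  expect_equal(as.numeric(ci), c(7, 7))
})

test_that("bootstrap intervals are deterministic under a fixed seed", {
  df <- data.frame(x = rnorm(30), g = rep(c("a", "b"), 15))
  a <- bootstrap_ci(df, function(d) mean(d$x), reps = 500, seed = 9,
                    strata = df$g)
  b <- bootstrap_ci(df, function(d) mean(d$x), reps = 500, seed = 9,
                    strata = df$g)
  expect_identical(a, b)
})

test_that("the bootstrap interval width matches normal theory for a mean", {
  set.seed(42)
  df <- data.frame(x = rnorm(50))
  ci <- bootstrap_ci(df, function(d) mean(d$x), reps = 1e4, seed = 3)
  width <- ci["hi"] - ci["lo"]
  analytic <- 2 * 1.96 / sqrt(50)
  expect_lt(abs(width - analytic) / analytic, 0.15)
})

test_that("stratified resampling keeps class sizes and flags mass skipping", {
  df <- data.frame(x = c(rep(1, 5), rep(2, 10)),
                   g = c(rep("s", 5), rep("n", 10)))
  # statistic errors unless both strata appear at original sizes
  ci <- bootstrap_ci(df, function(d) {
    stopifnot(sum(d$g == "s") == 5, sum(d$g == "n") == 10)
    mean(d$x)
  }, reps = 300, seed = 2, strata = df$g)
  expect_equal(attr(ci, "skipped"), 0)
  expect_error(bootstrap_ci(df, function(d) stop("boom"), reps = 100,
                            seed = 1), "resamples")
})

test_that("bootstrap intervals usually contain the point estimate", {
  set.seed(11)
  hits <- vapply(1:40, function(i) {
    df <- data.frame(x = rnorm(25, sd = runif(1, 0.5, 2)))
    ci <- bootstrap_ci(df, function(d) mean(d$x), reps = 400, seed = i)
    mean(df$x) >= ci["lo"] && mean(df$x) <= ci["hi"]
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("identical volume vectors agree perfectly", {
  v <- c(10, 20, 30, 40, 25)
  ag <- volume_agreement(v, v, seed = 1, reps = 500)
  expect_equal(ag$pearson_r, 1)
  expect_equal(ag$relative_difference_pct, 0)
})

test_that("doubling the reference volumes doubles the slope", {
  v <- c(10, 20, 30, 40)
  ag <- volume_agreement(v, 2 * v, seed = 1, ci = FALSE)
  expect_equal(ag$slope_through_origin, 2)
  expect_equal(ag$relative_difference_pct, 100)
})

test_that("the through-origin slope matches the closed form", {
  ag <- volume_agreement(c(1, 2, 3), c(2, 3, 5), seed = 1, ci = FALSE)
  expect_equal(ag$slope_through_origin, 23 / 14)
})

test_that("Pearson r is invariant to positive affine rescaling", {
  set.seed(12)
  x <- runif(20, 5, 50); y <- x + rnorm(20, sd = 4)
  r1 <- volume_agreement(x, y, seed = 1, reps = 200)$pearson_r
  r2 <- volume_agreement(2.5 * x + 3, y, seed = 1, reps = 200)$pearson_r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("degenerate volume vectors are rejected", {
  expect_error(volume_agreement(c(1, 1, 1), c(1, 2, 3), seed = 1),
               "degenerate")
  expect_error(volume_agreement(1:2, 1:2, seed = 1), "at least 3")
  expect_error(volume_agreement(1:4, 1:3, seed = 1), "paired")
})
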