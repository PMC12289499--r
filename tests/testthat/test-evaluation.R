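test_that("DeLong AUC equals brute-force pair counting", {
  for (s in 1:12) {
    withr::with_seed(s, {
      n <- sample(6:30, 1)
      scores <- round(rnorm(n), 1)  # rounding forces ties
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    })
    expect_equal(auc_delong(scores, labels)$auc,
                 auc_bruteforce(scores, labels), tolerance = 1e-12)
  }
  # worked instance and tie conventions
  expect_equal(auc_delong(c(3, 1, 2, 4), c(0, 1, 0, 1))$auc, 0.5)
  expect_equal(auc_delong(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  a <- auc_delong(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(a$auc, 1)
  expect_equal(a$variance, 0)
  expect_error(auc_delong(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("DeLong variance and paired comparison match pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(21, {
    n <- 50
    l <- rbinom(n, 1, 0.5)
    s1 <- rnorm(n) + l
    s2 <- 0.6 * s1 + rnorm(n)
  })
  a <- auc_delong(s1, l)
  r <- pROC::roc(l, s1, quiet = TRUE, direction = "<")
  expect_equal(a$variance, pROC::var(r), tolerance = 1e-12)
  d <- delong_compare(s1, l, s2, paired = TRUE)
  rt <- pROC::roc.test(r, pROC::roc(l, s2, quiet = TRUE, direction = "<"),
                       method = "delong")
  expect_equal(d$p_value, rt$p.value, tolerance = 1e-10)
  # self-comparison is exactly null
  self <- delong_compare(s1, l, s1, paired = TRUE)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)
})

test_that("unpaired DeLong gate has nominal type-I error", {
  rej <- purrr::map_lgl(1:400, function(s) {
    withr::with_seed(1000 + s, {
      la <- rep(c(0, 1), each = 20); lb <- rep(c(0, 1), each = 20)
      sa <- rnorm(40) + la; sb <- rnorm(40) + lb
    })
    delong_compare(sa, la, sb, lb, paired = FALSE)$p_value < 0.05
  })
  # 3 Monte-Carlo SDs around 5%: sqrt(.05*.95/400) ~ 0.011
  expect_lt(abs(mean(rej) - 0.05), 0.033)
})

test_that("permutation p matches exhaustive enumeration at 3 vs 3", {
  v <- c(1.2, 3.4, 0.1, 2.2, 5.1, 4.0)
  l <- c(0, 0, 0, 1, 1, 1)
  p_mc <- permutation_test_scores(v, l, n_permutations = 19999, seed = 3)
  expect_lt(abs(p_mc - perm_p_exhaustive_3v3(v)), 0.02)
  # identical group value multisets give p = 1
  expect_equal(permutation_test_scores(rep(c(1, 2), 6), rep(c(0, 1), each = 6),
                                       999, seed = 1), 1)
  # saturation at the add-one floor for a huge shift
  v2 <- c(rnorm(60), rnorm(60) + 3)
  l2 <- rep(c(0, 1), each = 60)
  expect_equal(permutation_test_scores(v2, l2, 999, seed = 2), 1 / 1000)
  expect_error(permutation_test_scores(v, l, 0), "n_permutations")
})

test_that("permutation p-values are super-uniform under the null", {
  ps <- purrr::map_dbl(1:200, function(s) {
    withr::with_seed(500 + s, {
      v <- rnorm(30); l <- rep(c(0, 1), 15)
    })
    permutation_test_scores(v, l, 199, seed = s)
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("Youden cutoff equals the exhaustive sweep", {
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- sample(10:50, 1)
      scores <- round(rnorm(n), 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    })
    expect_equal(youden_cutoff(scores, labels)$youden_j,
                 youden_bruteforce(scores, labels), tolerance = 1e-12)
  }
  # separated groups: J = 1 with the cutoff between them
  yc <- youden_cutoff(c(1, 2, 3, 8, 9, 10), c(0, 0, 0, 1, 1, 1))
  expect_equal(yc$youden_j, 1)
  expect_gt(yc$cutoff, 3); expect_lt(yc$cutoff, 8)
  # constant scores are degenerate
  yc0 <- youden_cutoff(rep(2, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(yc0$youden_j, 0)
  expect_true(yc0$degenerate)
  # ties in J break toward the higher-specificity cutoff
  yc2 <- youden_cutoff(c(1, 2, 3, 4), c(0, 1, 0, 1))
  sens <- sum(c(1, 2, 3, 4) >= yc2$cutoff & c(0, 1, 0, 1) == 1) / 2
  expect_equal(yc2$specificity, 1)
})

test_that("confusion metrics reproduce the worked ridge-train column", {
  m <- confusion_metrics(tp = 20, fn = 19, fp = 4, tn = 35)
  expect_equal(round(m$sensitivity, 3), 0.513)
  expect_equal(round(m$specificity, 3), 0.897)
  expect_equal(round(m$accuracy, 3), 0.705)
  expect_equal(round(m$kappa, 3), 0.410)
  expect_equal(m$error_rate, 1 - m$accuracy)
  expect_equal(m$recall, m$sensitivity)
})

test_that("undefined rates are NA and kappa = 2*acc - 1 on balanced matrices", {
  m <- confusion_metrics(tp = 3, fn = 2, fp = 0, tn = 0)
  expect_true(is.na(m$specificity))
  expect_true(is.na(confusion_metrics(2, 0, 3, 0)$npv))
  withr::with_seed(4, {
    for (i in 1:100) {
      k <- sample(5:50, 1)
      tp <- sample(0:k, 1); fp <- sample(0:k, 1)
      m <- confusion_metrics(tp, k - tp, fp, k - fp)
      expect_equal(m$kappa, 2 * m$accuracy - 1, tolerance = 1e-12)
    }
  })
})

test_that("Hosmer-Lemeshow matches hand arithmetic and its chi-square mean", {
  # hand toy, g = 3: statistic computed from the grouped (O-E) table
  p <- c(0.1, 0.15, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.85, 0.9)
  y <- c(0, 0, 1, 0, 1, 1, 1, 1, 0, 1)
  grp <- list(1:4, 5:7, 8:10)
  stat_hand <- sum(vapply(grp, function(ix) {
    e <- sum(p[ix]); o <- sum(y[ix]); n_g <- length(ix)
    (o - e)^2 / (e * (1 - e / n_g))
  }, numeric(1)))
  res <- hosmer_lemeshow(p, y, g = 3)
  expect_equal(res$statistic, stat_hand, tolerance = 1e-10)
  expect_equal(res$df, 1)
  # mean of the statistic under a correctly specified fitted model is ~ g-2
  stats_hl <- purrr::map_dbl(1:150, function(s) {
    withr::with_seed(3000 + s, {
      x <- rnorm(500)
      y <- rbinom(500, 1, stats::plogis(-0.3 + 0.8 * x))
    })
    pr <- fitted(glm(y ~ x, family = binomial()))
    hosmer_lemeshow(pr, y)$statistic
  })
  se <- sd(stats_hl) / sqrt(length(stats_hl))
  expect_lt(abs(mean(stats_hl) - 8), 3 * se)
  expect_error(hosmer_lemeshow(c(0, 0.5, 1), c(0, 1, 1)), "strictly in")
})

test_that("calibration bins aggregate correctly and conserve counts", {
  p <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1, 1, 1)
  b <- calibration_bins(p, y, n_bins = 2)
  expect_equal(nrow(b), 2)
  expect_equal(sum(b$n), 10)
  expect_equal(b$mean_predicted[1], mean(p[1:5]))
  expect_equal(b$observed_rate[2], mean(y[6:10]))
  expect_error(calibration_bins(p[c(1, 2, 3)], c(0, 1, 0), n_bins = 5),
               "fewer samples")
})

test_that("decision curves obey the net-benefit algebra", {
  withr::with_seed(6, {
    y <- rbinom(200, 1, 0.4)
    p <- stats::plogis(rnorm(200) + y)
  })
  dc <- decision_curve(p, y)
  expect_true(all(dc$treat_none == 0))
  prev <- mean(y)
  # treat-all crosses zero exactly at t = prevalence
  ta <- prev - (1 - prev) * prev / (1 - prev)
  expect_equal(ta, 0)
  # 8-sample hand case at t = 0.25
  p8 <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9)
  y8 <- c(0, 0, 1, 0, 1, 0, 1, 1)
  dc8 <- decision_curve(p8, y8, thresholds = 0.25)
  # predictions >= 0.25: samples 3..8 -> TP = 4, FP = 2
  expect_equal(dc8$net_benefit, 4 / 8 - 2 / 8 * 0.25 / 0.75, tolerance = 1e-12)
  # a perfect classifier attains NB = prevalence everywhere
  dcp <- decision_curve(ifelse(y == 1, 0.999, 0.001), y)
  expect_true(all(abs(dcp$net_benefit - prev) < 1e-12))
})

test_that("roc_points traces a valid curve with the trapezoidal AUC", {
  withr::with_seed(8, {
    s <- rnorm(60); l <- rbinom(60, 1, 0.5)
  })
  rc <- roc_points(s, l)
  expect_true(all(diff(rc$sensitivity) <= 1e-12))   # non-increasing in cutoff
  fpr <- 1 - rc$specificity
  auc_trap <- -sum(diff(fpr) * (head(rc$sensitivity, -1) + tail(rc$sensitivity, -1)) / 2)
  expect_equal(auc_trap, rc$auc[1], tolerance = 1e-10)
})
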