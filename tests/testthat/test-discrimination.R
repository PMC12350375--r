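# ROC/AUROC, DeLong, risk calibration, NRI/IDI, bootstrap, operating
# points.  The DeLong and AUROC implementations are checked against
# straight-from-definition oracles in helper-fixtures.R.

test_that("auroc matches pair counting on the worked examples", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(c(5, 5, 5, 5), c(0, 1, 0, 1)), 0.5)
  # labels (0,1,0,1): pairs (2>1), (2<3), (4>1), (4>3) -> 3/4
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "event")
})

test_that("auroc equals brute-force pair counting on random fixtures", {
  set.seed(101)
  for (i in 1:200) {
    n <- 30
    scores <- sample(0:10, n, replace = TRUE)  # heavy ties on purpose
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(auroc(scores, labels), auroc_oracle(scores, labels))
  }
})

test_that("auroc complement and monotone-transform invariances hold", {
  set.seed(55)
  for (i in 1:20) {
    scores <- rnorm(40)          # tie-free
    labels <- runif(40) < 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(auroc(scores, labels) + auroc(-scores, labels), 1)
    expect_equal(auroc(exp(2 * scores + 1), labels),
                 auroc(scores, labels))
  }
})

test_that("delong_compare is exact against the definition oracle", {
  set.seed(77)
  for (i in 1:50) {
    n <- 12 + sample(0:20, 1)
    y <- c(TRUE, TRUE, FALSE, FALSE, runif(n - 4) < 0.4)
    s1 <- sample(0:8, n, replace = TRUE)
    s2 <- s1 + sample(0:4, n, replace = TRUE)
    dl <- delong_compare(s2, s1, y)
    or <- delong_oracle(s2, s1, y)
    expect_equal(dl$auc_new, or$auc_new)
    expect_equal(dl$auc_old, or$auc_old)
    expect_equal(dl$var_new, or$var_new)
    expect_equal(dl$var_old, or$var_old)
    expect_equal(dl$cov, or$cov)
    if (is.finite(or$z)) {
      expect_equal(dl$z, or$z)
      expect_equal(dl$p, or$p)
    }
  }
})

test_that("delong_compare degenerate and symmetry contracts", {
  set.seed(12)
  s <- rnorm(30)
  y <- rep(c(TRUE, FALSE), 15)
  self <- delong_compare(s, s, y)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)

  s2 <- s + rnorm(30, sd = 0.5)
  ab <- delong_compare(s2, s, y)
  ba <- delong_compare(s, s2, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_true(ab$p >= 0 && ab$p <= 1)
})

test_that("fit_score_risk recovers known logistic parameters", {
  set.seed(31)
  n <- 5000
  s <- runif(n, 0, 10)
  y <- runif(n) < plogis(-2 + 0.4 * s)
  fit <- fit_score_risk(s, y)
  expect_lt(abs(fit$intercept - (-2)), 0.1)
  expect_lt(abs(fit$slope - 0.4), 0.1)
  expect_true(all(diff(fit$risk[order(s)]) >= -1e-12))

  # null case: slope near zero, risks near prevalence
  y0 <- runif(n) < 0.3
  fit0 <- fit_score_risk(s, y0)
  expect_lt(abs(fit0$slope), 0.05)
  expect_lt(max(abs(fit0$risk - mean(y0))), 0.1)

  # complete separation is refused
  expect_error(fit_score_risk(c(1, 1, 2, 2, 3, 3),
                              c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)),
               "separation")
})

test_that("continuous NRI follows its definition on forced cases", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  r <- c(0.3, 0.4, 0.2, 0.1)
  expect_equal(continuous_nri(r, r, y)$nri, 0)
  # everyone up: events contribute +1, nonevents -1
  up <- continuous_nri(r, r + 0.1, y)
  expect_equal(up$nri_events, 1)
  expect_equal(up$nri_nonevents, -1)
  expect_equal(up$nri, 0)
  # perfect reclassification: events up, nonevents down
  perfect <- continuous_nri(r, c(0.4, 0.5, 0.1, 0.05), y)
  expect_equal(perfect$nri, 2)
  # hand arithmetic on a 10-patient fixture
  y10 <- c(rep(TRUE, 4), rep(FALSE, 6))
  old <- c(0.5, 0.5, 0.5, 0.5, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3)
  new <- c(0.6, 0.6, 0.4, 0.5, 0.2, 0.2, 0.2, 0.4, 0.3, 0.3)
  # events: 2 up, 1 down, 1 tie -> 2/4 - 1/4 = 0.25
  # nonevents: 3 down, 1 up, 2 ties -> 3/6 - 1/6 = 1/3
  res <- continuous_nri(old, new, y10)
  expect_equal(res$nri_events, 0.25)
  expect_equal(res$nri_nonevents, 1 / 3)
  expect_equal(res$nri, 0.25 + 1 / 3)
})

test_that("IDI is the change in discrimination slope", {
  y <- c(rep(TRUE, 4), rep(FALSE, 6))
  old <- c(0.5, 0.5, 0.5, 0.5, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3)
  new <- c(0.6, 0.6, 0.4, 0.5, 0.2, 0.2, 0.2, 0.4, 0.3, 0.3)
  expect_equal(idi(old, old, y), 0)
  # slopes by direct mean arithmetic
  slope_new <- mean(new[y]) - mean(new[!y])
  slope_old <- mean(old[y]) - mean(old[!y])
  expect_equal(idi(old, new, y), slope_new - slope_old)
  # risk equal to the labels vs constant prevalence: slope 1 vs 0
  expect_equal(idi(rep(mean(y), 10), as.numeric(y), y), 1)
})

test_that("bootstrap percentile interval honours its contracts", {
  x <- rnorm(50)
  const <- bootstrap_ci(x, function(d) 42, b = 200, seed = 1)
  expect_equal(const$lower, 42)
  expect_equal(const$upper, 42)

  a <- bootstrap_ci(x, mean, b = 300, seed = 9)
  b <- bootstrap_ci(x, mean, b = 300, seed = 9)
  expect_identical(a, b)

  # width close to the closed form 2 * 1.96 / sqrt(200)
  set.seed(2)
  z <- rnorm(200)
  ci <- bootstrap_ci(z, mean, b = 1000, seed = 3)
  width <- ci$upper - ci$lower
  expect_lt(abs(width - 2 * 1.96 / sqrt(200)), 0.2 * 2 * 1.96 / sqrt(200))

  expect_error(bootstrap_ci(x, mean, b = 50, seed = 1), "at least 100")
  expect_error(bootstrap_ci(x, function(d) stop("boom"), b = 100, seed = 1),
               "failed")
})

test_that("single-class resamples are redrawn when labels are supplied", {
  d <- data.frame(y = c(TRUE, rep(FALSE, 9)))
  ci <- bootstrap_ci(d, function(dd) mean(dd$y), b = 100, seed = 4,
                     labels = d$y)
  expect_gt(ci$lower, 0)   # every resample kept the lone event
  expect_gte(ci$redrawn, 0)
})

test_that("operating point maximises Youden's J with the tie rule", {
  # perfectly separating score
  op <- operating_point(c(1, 1, 2, 2), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_equal(op$threshold, 2)

  # 2x2 with a=9 b=1 c=1 d=9 at threshold 1
  scores <- c(rep(1, 9), 0, 1, rep(0, 9))
  labels <- c(rep(TRUE, 10), rep(FALSE, 10))
  op <- operating_point(scores, labels)
  expect_equal(op$threshold, 1)
  expect_equal(op$sensitivity, 0.9)
  expect_equal(op$specificity, 0.9)
  expect_equal(op$ppv, 0.9)
  expect_equal(op$npv, 0.9)
  expect_equal(op$plr, 9)
  expect_equal(op$nlr, 1 / 9, tolerance = 1e-12)

  # all-ties score: J = 0 everywhere, lowest threshold returned
  op <- operating_point(rep(3, 10), c(rep(TRUE, 4), rep(FALSE, 6)))
  expect_equal(op$threshold, 3)
  expect_equal(op$sensitivity + op$specificity - 1, 0)
})

test_that("reclassification wraps NRI/IDI with bootstrap intervals", {
  set.seed(8)
  g <- generate_cohort(generator_params(n = 600, seed = 8))$cohort
  sc <- score_cohort(g)
  y <- horizon_label(sc$time_days, sc$event, 28)
  keep <- !is.na(y)
  rc <- reclassification(sc$alc_sofa_total[keep], sc$sofa_total[keep],
                         y[keep], b = 100, seed = 10)
  expect_equal(rc$nri, rc$nri_events + rc$nri_nonevents)
  expect_true(rc$nri >= -2 && rc$nri <= 2)
  expect_true(rc$idi >= -1 && rc$idi <= 1)
  expect_equal(rc$b_replicates, 100)
  expect_lt(rc$ci_nri[1], rc$ci_nri[2])
})
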