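# Component scorers: printed-cutoff boundary suite, monotonicity sweeps,
# and whole-grid compositions.

test_that("respiratory component scores per the grid with the support cap", {
  expect_identical(score_respiratory(450, FALSE), 0L)
  expect_identical(score_respiratory(400, FALSE), 0L)
  expect_identical(score_respiratory(399.9, FALSE), 1L)
  expect_identical(score_respiratory(300, FALSE), 1L)
  expect_identical(score_respiratory(299.9, FALSE), 2L)
  expect_identical(score_respiratory(200, TRUE), 2L)
  expect_identical(score_respiratory(199.9, TRUE), 3L)
  expect_identical(score_respiratory(150, TRUE), 3L)
  expect_identical(score_respiratory(100, TRUE), 3L)
  expect_identical(score_respiratory(99.9, TRUE), 4L)
  expect_identical(score_respiratory(90, TRUE), 4L)
  # without respiratory support the score caps at 2
  expect_identical(score_respiratory(150, FALSE), 2L)
  expect_identical(score_respiratory(90, FALSE), 2L)
  expect_identical(score_respiratory(NA, FALSE), 0L)
  expect_error(score_respiratory(0, FALSE), "pf_ratio")
  expect_error(score_respiratory(-5, TRUE), "pf_ratio")
})

test_that("coagulation component scores on platelet cutoffs", {
  cases <- rbind(
    c(200, 0), c(150, 0), c(149.9, 1), c(100, 1), c(99.9, 2),
    c(50, 2), c(49.9, 3), c(45, 3), c(20, 3), c(19.9, 4), c(5, 4)
  )
  expect_identical(score_coagulation(cases[, 1]), as.integer(cases[, 2]))
  expect_identical(score_coagulation(NA), 0L)
  expect_error(score_coagulation(-1), "platelets")
})

test_that("hepatic component uses right-open bilirubin bands", {
  cases <- rbind(
    c(0.8, 0), c(1.19, 0), c(1.2, 1), c(1.9, 1), c(1.95, 1),
    c(2.0, 2), c(3.0, 2), c(5.9, 2), c(5.95, 2), c(6.0, 3),
    c(11.9, 3), c(11.95, 3), c(12.0, 4), c(15, 4)
  )
  expect_identical(score_hepatic(cases[, 1]), as.integer(cases[, 2]))
  expect_identical(score_hepatic(NA), 0L)
  expect_error(score_hepatic(-0.1), "bilirubin")
})

test_that("cardiovascular component: highest category wins, dose boundaries", {
  expect_identical(score_cardiovascular(85), 0L)
  expect_identical(score_cardiovascular(70), 0L)
  expect_identical(score_cardiovascular(69.9), 1L)
  expect_identical(score_cardiovascular(65), 1L)
  # dobutamine at any dose scores 2 even with low MAP
  expect_identical(score_cardiovascular(60, dobutamine = 2,
                                        dobutamine_ge_1h = TRUE), 2L)
  # dopamine band closure: exactly 5.0 scores 2, above 5 scores 3
  expect_identical(score_cardiovascular(80, dopamine = 5.0,
                                        dopamine_ge_1h = TRUE), 2L)
  expect_identical(score_cardiovascular(80, dopamine = 5.1,
                                        dopamine_ge_1h = TRUE), 3L)
  expect_identical(score_cardiovascular(80, dopamine = 15,
                                        dopamine_ge_1h = TRUE), 3L)
  expect_identical(score_cardiovascular(80, dopamine = 15.1,
                                        dopamine_ge_1h = TRUE), 4L)
  # epinephrine / norepinephrine 0.1 boundary
  expect_identical(score_cardiovascular(70, epinephrine = 0.1,
                                        epinephrine_ge_1h = TRUE), 3L)
  expect_identical(score_cardiovascular(70, epinephrine = 0.11,
                                        epinephrine_ge_1h = TRUE), 4L)
  expect_identical(score_cardiovascular(70, norepinephrine = 0.05,
                                        norepinephrine_ge_1h = TRUE), 3L)
  expect_identical(score_cardiovascular(70, norepinephrine = 0.3,
                                        norepinephrine_ge_1h = TRUE), 4L)
  # agents given for under an hour do not count
  expect_identical(score_cardiovascular(65, norepinephrine = 0.3,
                                        norepinephrine_ge_1h = FALSE), 1L)
  # missing duration flag treated as qualifying
  expect_identical(score_cardiovascular(70, norepinephrine = 0.3), 4L)
  expect_identical(score_cardiovascular(NA), 0L)
  expect_error(score_cardiovascular(70, dopamine = -1), "dose")
})

test_that("CNS component scores GCS bands", {
  expect_identical(score_cns(c(15, 14, 13, 12, 10, 9, 6, 5, 3)),
                   c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_identical(score_cns(NA), 0L)
  expect_error(score_cns(2), "gcs")
  expect_error(score_cns(16), "gcs")
})

test_that("renal component takes the worse of creatinine and urine output", {
  cr <- rbind(
    c(1.0, 0), c(1.19, 0), c(1.2, 1), c(1.95, 1), c(2.0, 2),
    c(3.4, 2), c(3.45, 2), c(3.5, 3), c(4.95, 3), c(5.0, 4), c(6.0, 4)
  )
  expect_identical(score_renal(cr[, 1], rep(2000, nrow(cr))),
                   as.integer(cr[, 2]))
  # urine output bands
  expect_identical(score_renal(1.0, 500), 0L)
  expect_identical(score_renal(1.0, 499), 3L)
  expect_identical(score_renal(1.5, 400), 3L)   # urine dominates creat 1
  expect_identical(score_renal(1.0, 199), 4L)
  expect_identical(score_renal(6.0, NA), 4L)
  expect_identical(score_renal(NA, NA), 0L)
  expect_error(score_renal(-1, 100), "creatinine")
})

test_that("ALC score reproduces the printed bins and the 1.0 closure", {
  expect_identical(score_alc(1.5), 0L)
  expect_identical(score_alc(1.0), 0L)   # lymphopenia is strictly below 1.0
  expect_identical(score_alc(0.99), 1L)
  expect_identical(score_alc(0.9), 1L)
  expect_identical(score_alc(0.78), 1L)
  expect_identical(score_alc(0.77), 2L)
  expect_identical(score_alc(0.6), 2L)
  expect_identical(score_alc(0.58), 2L)
  expect_identical(score_alc(0.57), 3L)
  expect_identical(score_alc(0.36), 3L)
  expect_identical(score_alc(0.35), 4L)
  expect_identical(score_alc(0.2), 4L)
  expect_identical(score_alc(0), 4L)
  expect_error(score_alc(NA), "excluded")
  expect_error(score_alc(-0.1), "alc")
})

test_that("every component scorer is monotone on a fine sweep", {
  nondecr <- function(x) all(diff(x) >= 0)
  # non-increasing in the better direction = non-decreasing in worst
  expect_true(nondecr(rev(score_respiratory(seq(50, 500, by = 0.5), TRUE))))
  expect_true(nondecr(rev(score_coagulation(seq(0, 400, by = 0.5)))))
  expect_true(nondecr(score_hepatic(seq(0, 25, by = 0.01))))
  expect_true(nondecr(score_renal(seq(0, 10, by = 0.01), 2000)))
  expect_true(nondecr(rev(score_cns(3:15))))
  expect_true(nondecr(rev(score_alc(seq(0, 3, by = 0.001)))))
  doses <- seq(0, 20, by = 0.01)
  expect_true(nondecr(score_cardiovascular(rep(80, length(doses)),
                                           dopamine = doses)))
})

test_that("compute_sofa equals the sum of independently called scorers", {
  set.seed(7)
  g <- generate_cohort(generator_params(n = 300, seed = 7))$cohort
  br <- compute_sofa(g)
  manual <- score_respiratory(g$pf_ratio, g$respiratory_support) +
    score_coagulation(g$platelets) + score_hepatic(g$bilirubin) +
    score_cardiovascular(g$map, g$dopamine, g$dobutamine, g$epinephrine,
                         g$norepinephrine) +
    score_cns(g$gcs) + score_renal(g$creatinine, g$urine_output_24h)
  expect_identical(br$sofa_total, as.integer(manual))
  expect_true(all(br$sofa_total >= 0 & br$sofa_total <= 24))
})

test_that("worked grid examples: all-normal, all-worst, single derangement", {
  normal <- compute_alc_sofa(make_patient())
  expect_identical(normal$sofa_total, 0L)
  expect_identical(normal$alc_sofa_total, 0L)

  worst <- compute_alc_sofa(worst_patient())
  expect_identical(worst$sofa_total, 24L)
  expect_identical(worst$alc_score, 4L)
  expect_identical(worst$alc_sofa_total, 28L)

  bili_only <- compute_alc_sofa(make_patient(bilirubin = 3.0))
  expect_identical(bili_only$sofa_total, 2L)

  # SOFA 6 with ALC 0.6 (bin 2) gives a combined 8
  mid <- compute_alc_sofa(make_patient(bilirubin = 3.0, gcs = 12,
                                       platelets = 90, alc = 0.6))
  expect_identical(mid$sofa_total, 6L)
  expect_identical(mid$alc_sofa_total, 8L)
})

test_that("missing components contribute 0 with a flag; strict mode errors", {
  p <- make_patient(bilirubin = NA)
  br <- compute_sofa(p)
  expect_identical(br$hepatic, 0L)
  expect_match(br$flags, "hepatic missing")
  expect_error(compute_sofa(p, strict_missing = TRUE), "strict_missing")
  expect_error(compute_alc_sofa(make_patient(alc = NA)), "alc")
})

test_that("combined total always dominates the organ total", {
  g <- generate_cohort(generator_params(n = 500, seed = 21))$cohort
  br <- compute_alc_sofa(g)
  expect_true(all(br$alc_sofa_total >= br$sofa_total))
  expect_true(all(br$alc_sofa_total <= 28))
  expect_identical(br$alc_sofa_total, as.integer(br$sofa_total + br$alc_score))
})
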