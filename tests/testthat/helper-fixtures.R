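# Fixture builders and independent oracles shared across the suite.

# A single-patient cohort row with all-normal defaults; override any field.
make_patient <- function(...) {
  base <- list(
    patient_id = "p1", age = 60, sex = "male",
    pf_ratio = 450, respiratory_support = FALSE,
    platelets = 250, bilirubin = 0.5, map = 85,
    dopamine = 0, dobutamine = 0, epinephrine = 0, norepinephrine = 0,
    any_other_vasopressor = FALSE,
    dopamine_ge_1h = NA, dobutamine_ge_1h = NA,
    epinephrine_ge_1h = NA, norepinephrine_ge_1h = NA,
    gcs = 15, creatinine = 0.8, urine_output_24h = 2000,
    alc = 1.5, icu_los_hours = 72, repeat_admission = FALSE,
    time_days = 90, event = FALSE
  )
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(base, stringsAsFactors = FALSE)
}

make_cohort <- function(n = 10, ...) {
  rows <- lapply(seq_len(n), function(i) {
    p <- make_patient(...)
    p$patient_id <- sprintf("p%03d", i)
    p
  })
  do.call(rbind, rows)
}

# The all-worst-category patient: every organ system in its top band and
# profound lymphopenia.
worst_patient <- function() {
  make_patient(
    pf_ratio = 80, respiratory_support = TRUE, platelets = 10,
    bilirubin = 15, map = 60, norepinephrine = 0.5,
    norepinephrine_ge_1h = TRUE, gcs = 3, creatinine = 6.0,
    urine_output_24h = 100, alc = 0.1
  )
}

# --- independent oracles -------------------------------------------------

# AUROC by brute-force enumeration of all (event, nonevent) pairs.
auroc_oracle <- function(scores, labels) {
  ev <- scores[as.logical(labels)]
  ne <- scores[!as.logical(labels)]
  total <- 0
  for (x in ev) for (y in ne) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(ev) * length(ne))
}

# DeLong comparison straight from the definition: explicit psi-matrices,
# per-patient placement values, empirical covariances of the structural
# components.
delong_oracle <- function(s_new, s_old, labels) {
  y <- as.logical(labels)
  psi <- function(s) outer(s[y], s[!y],
                           function(a, b) (a > b) + 0.5 * (a == b))
  P1 <- psi(s_new)
  P2 <- psi(s_old)
  m <- sum(y)
  n <- sum(!y)
  a1 <- mean(P1)
  a2 <- mean(P2)
  v10_1 <- rowMeans(P1); v01_1 <- colMeans(P1)
  v10_2 <- rowMeans(P2); v01_2 <- colMeans(P2)
  var1 <- var(v10_1) / m + var(v01_1) / n
  var2 <- var(v10_2) / m + var(v01_2) / n
  cv <- cov(v10_1, v10_2) / m + cov(v01_1, v01_2) / n
  z <- (a1 - a2) / sqrt(var1 + var2 - 2 * cv)
  list(auc_new = a1, auc_old = a2, var_new = var1, var_old = var2,
       cov = cv, z = z, p = 2 * pnorm(-abs(z)))
}

# Simulate exponential survival with a known log-hazard coefficient.
sim_cox_data <- function(n, beta, baseline = 0.01, censor = 90,
                         x = NULL) {
  if (is.null(x)) x <- rnorm(n)
  t <- rexp(n, baseline * exp(beta * x))
  data.frame(x = x, times = pmin(t, censor), events = t <= censor)
}
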