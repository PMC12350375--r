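# Kaplan-Meier estimation, the log-rank test, score-class survival curves,
# horizon mortality, and the univariate -> multivariate Cox screening
# procedure.  The product-limit estimator and the log-rank statistic are
# implemented from their definitions (the survival package serves as an
# independent oracle in the test suite); the Cox partial-likelihood
# optimisation itself is delegated to survival::coxph with Breslow tie
# handling -- the contract is the partial-likelihood optimum, not a
# bespoke optimiser.

#' Kaplan-Meier product-limit estimate
#'
#' `S(t)` is the product over distinct event times `t_i <= t` of
#' `(1 - d_i / n_i)`.  Patients censored at an event time are counted as
#' still at risk at that time (the standard convention).
#'
#' @param times Follow-up times in days (>= 0).
#' @param events Logical event indicator aligned with `times`.
#' @return A list of class `km_curve`: `time` (sorted distinct event
#'   times), `n_risk`, `n_event` (integers per time), and `surv` (the
#'   product-limit estimates).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0) stop("empty input", call. = FALSE)
  if (any(is.na(times)) || any(is.na(events))) {
    stop("times/events must not contain NA", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  events <- as.logical(events)
  et <- sort(unique(times[events]))
  n_risk <- vapply(et, function(t) sum(times >= t), integer(1))
  n_event <- vapply(et, function(t) sum(events & times == t), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = et, n_risk = n_risk, n_event = n_event,
                 surv = surv), class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Step-function evaluation: `S(t) = 1` before the first event time.
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param t Times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(x) {
    i <- sum(curve$time <= x)
    if (i == 0) 1 else curve$surv[i]
  }, numeric(1))
}

#' Log-rank test across survival groups
#'
#' The standard observed-minus-expected chi-square statistic over pooled
#' event times, using the full hypergeometric covariance matrix on the
#' first `G - 1` groups; `df = G - 1`.
#'
#' @param groups A list with one element per group, each a list (or data
#'   frame) with components `times` and `events`.
#' @return A list: `chi2`, `df`, `p`.
#' @export
logrank_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  times <- unlist(lapply(groups, function(g) g$times))
  events <- unlist(lapply(groups, function(g) as.logical(g$events)))
  grp <- rep(seq_along(groups),
             vapply(groups, function(g) length(g$times), integer(1)))
  if (any(vapply(groups, function(g) length(g$times) == 0, logical(1)))) {
    stop("all groups must be nonempty", call. = FALSE)
  }
  if (!any(events)) stop("no events in any group", call. = FALSE)
  G <- length(groups)
  et <- sort(unique(times[events]))
  o <- numeric(G)
  e <- numeric(G)
  V <- matrix(0, G - 1, G - 1)
  for (t in et) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    d_j <- sum(events & times == t)
    n_gj <- vapply(seq_len(G), function(g) sum(at_risk & grp == g),
                   numeric(1))
    d_gj <- vapply(seq_len(G), function(g) sum(events & times == t & grp == g),
                   numeric(1))
    o <- o + d_gj
    e <- e + d_j * n_gj / n_j
    if (n_j > 1) {
      f <- d_j * (n_j - d_j) / (n_j - 1)
      p_g <- n_gj / n_j
      vt <- f * (diag(p_g[-G], G - 1) - outer(p_g[-G], p_g[-G]))
      V <- V + vt
    }
  }
  d <- (o - e)[-G]
  chi2 <- tryCatch(drop(t(d) %*% solve(V, d)), error = function(err) {
    drop(t(d) %*% MASS_ginv(V) %*% d)
  })
  list(chi2 = chi2, df = G - 1, p = pchisq(chi2, df = G - 1,
                                           lower.tail = FALSE))
}

# Moore-Penrose pseudoinverse via SVD; avoids a MASS dependency for the
# rare singular covariance case (e.g. a group with no event overlap).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Survival curves by combined-score class
#'
#' Partitions the combined 0-28 score into 5-point classes
#' (`[0,5), [5,10), [10,15), [15,20), [20,28]`), estimates a Kaplan-Meier
#' curve per nonempty class, and tests the classes with the log-rank test.
#' Empty classes are dropped and listed.
#'
#' @param score Combined score per patient (0-28).
#' @param times,events Survival outcome aligned with `score`.
#' @param class_width Width of the score classes (default 5).
#' @return A list: `classes` (labels in score order), `curves` (named list
#'   of `km_curve`), `logrank` (from [logrank_test()], or `NULL` with a
#'   single class), `dropped` (empty class labels), and `class_of`
#'   (factor assignment per patient).
#' @export
class_curves <- function(score, times, events, class_width = 5) {
  stopifnot(class_width > 0)
  breaks <- unique(c(seq(0, 28 - class_width, by = class_width), 28))
  labs <- paste0(utils::head(breaks, -1), "-",
                 c(utils::head(breaks[-1], -1) - 1, 28))
  # right-open classes; include.lowest closes the top band at 28
  cls <- cut(score, breaks = breaks, right = FALSE, labels = labs,
             include.lowest = TRUE)
  present <- levels(cls)[levels(cls) %in% unique(as.character(cls))]
  dropped <- setdiff(levels(cls), present)
  curves <- lapply(present, function(l) {
    sel <- cls == l
    km_estimate(times[sel], events[sel])
  })
  names(curves) <- present
  lr <- NULL
  if (length(present) >= 2) {
    lr <- logrank_test(lapply(present, function(l) {
      sel <- cls == l
      list(times = times[sel], events = events[sel])
    }))
  }
  list(classes = present, curves = curves, logrank = lr,
       dropped = dropped, class_of = cls)
}

#' Mortality proportion at a horizon
#'
#' Among patients whose label at the horizon is determined (died within,
#' or followed beyond, the horizon), the fraction that died.  Patients
#' censored before the horizon are excluded and counted.
#'
#' @param times,events Survival outcome.
#' @param horizon Horizon in days (> 0).
#' @return A list: `proportion`, `n_dead`, `n_labeled`, `n_unlabeled`.
#' @export
mortality_at <- function(times, events, horizon) {
  lab <- horizon_label(times, events, horizon)
  labeled <- !is.na(lab)
  if (!any(labeled)) stop("no patient has a defined label at this horizon",
                          call. = FALSE)
  list(proportion = mean(lab[labeled]),
       n_dead = sum(lab[labeled]),
       n_labeled = sum(labeled),
       n_unlabeled = sum(!labeled))
}

#' Univariate-to-multivariate Cox screening
#'
#' Stage 1 fits a univariate Cox proportional-hazards model (Breslow tie
#' handling) for each candidate covariate; stage 2 refits jointly on the
#' covariates whose univariate Wald p-value is below `entry_p` (a single
#' joint fit, no stepwise removal).  Constant covariates are skipped with
#' a log entry.
#'
#' @param data Data frame containing the covariate columns.
#' @param covariates Character vector of column names (numeric or binary).
#' @param times,events Survival outcome aligned with `data`.
#' @param entry_p Univariate p-value threshold for entering the joint fit.
#' @return A list of class `cox_screen`: `univariate` (data frame with
#'   `covariate`, `hr`, `lo`, `hi`, `p`), `entered` (covariates passing
#'   the entry rule), `multivariate` (same layout, or `NULL` when nothing
#'   enters), and `skipped` (constant covariates).
#' @export
cox_screen <- function(data, covariates, times, events, entry_p = 0.05) {
  stopifnot(all(covariates %in% names(data)))
  surv_obj <- survival::Surv(times, as.integer(events))
  skipped <- character(0)
  uni <- list()
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.logical(x)) x <- as.numeric(x)
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2) {
      skipped <- c(skipped, cv)
      next
    }
    fit <- tryCatch(
      survival::coxph(surv_obj[ok] ~ x[ok], ties = "breslow"),
      error = function(e) stop("Cox fit failed for covariate '", cv, "': ",
                               conditionMessage(e), call. = FALSE),
      warning = function(w) suppressWarnings(
        survival::coxph(surv_obj[ok] ~ x[ok], ties = "breslow"))
    )
    sm <- summary(fit)
    uni[[cv]] <- data.frame(
      covariate = cv,
      hr = unname(sm$conf.int[1, "exp(coef)"]),
      lo = unname(sm$conf.int[1, "lower .95"]),
      hi = unname(sm$conf.int[1, "upper .95"]),
      p = unname(sm$coefficients[1, "Pr(>|z|)"]),
      stringsAsFactors = FALSE
    )
  }
  univariate <- do.call(rbind, uni)
  rownames(univariate) <- NULL
  entered <- univariate$covariate[univariate$p < entry_p]
  multivariate <- NULL
  if (length(entered) > 0) {
    X <- data[, entered, drop = FALSE]
    for (cv in entered) if (is.logical(X[[cv]])) X[[cv]] <- as.numeric(X[[cv]])
    cc <- complete.cases(X)
    fit <- survival::coxph(surv_obj[cc] ~ .,
                           data = X[cc, , drop = FALSE], ties = "breslow")
    sm <- summary(fit)
    multivariate <- data.frame(
      covariate = rownames(sm$coefficients),
      hr = unname(sm$conf.int[, "exp(coef)"]),
      lo = unname(sm$conf.int[, "lower .95"]),
      hi = unname(sm$conf.int[, "upper .95"]),
      p = unname(sm$coefficients[, "Pr(>|z|)"]),
      stringsAsFactors = FALSE
    )
    rownames(multivariate) <- NULL
  }
  structure(list(univariate = univariate, entered = entered,
                 multivariate = multivariate, skipped = skipped),
            class = "cox_screen")
}

#' Tidy a set of survival curves for export
#'
#' Flattens per-class Kaplan-Meier curves into a long data frame suitable
#' for CSV export and downstream plotting.
#'
#' @param curves Named list of `km_curve` objects.
#' @return Data frame with columns `class`, `time`, `surv`, `n_risk`,
#'   `n_event`.
#' @export
km_tidy <- function(curves) {
  do.call(rbind, lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    data.frame(class = nm, time = cv$time, surv = cv$surv,
               n_risk = cv$n_risk, n_event = cv$n_event,
               stringsAsFactors = FALSE)
  }))
}
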