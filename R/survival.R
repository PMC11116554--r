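#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()]; censored observations at an event time are
#' processed after the events at that time (the standard convention).
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Data frame step table: time, n_risk, n_event, n_censor, surv
#'   (survival immediately after `time`); S(0) = 1 is implicit.
#' @export
km_estimate <- function(times, events) {
  .check_surv(times, events, min_events = 0)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             n_censor = sf$n.censor, surv = sf$surv)
}

.check_surv <- function(times, events, min_events = 1) {
  stopifnot(length(times) == length(events), length(times) >= 1)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("survival times must be positive and finite")
  if (!all(events %in% c(0, 1))) stop("event flags must be 0/1")
  if (sum(events) < min_events) stop("need at least ", min_events, " event(s)")
  invisible(TRUE)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' summed over event times, via [survival::survdiff()]; p from chi-square
#' with 1 degree of freedom.
#'
#' @inheritParams km_estimate
#' @param group Binary group labels per subject.
#' @return List: `chisq`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  .check_surv(times, events)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("log-rank test needs exactly 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Fit a Cox proportional-hazards model
#'
#' Efron tie correction by default, Newton-Raphson convergence tolerance
#' 1e-9 with at most 50 iterations, Wald confidence intervals. Divergence
#' (monotone partial likelihood / perfect separation) and non-convergence
#' raise errors rather than returning an unusable fit.
#'
#' @inheritParams km_estimate
#' @param X Covariate vector, matrix, or data frame (one column per
#'   covariate; factors allowed in a data frame).
#' @param ties Tie-handling method (default "efron").
#' @param ci_level Wald confidence level (default 0.95).
#' @return Object of class `cox_fit`: `beta`, `hr`, `se`, `p`, `ci_lower`,
#'   `ci_upper`, `loglik` (at the solution), `loglik_null`, `n`, `n_events`,
#'   `ci_level`, and the underlying `fit`.
#' @export
coxph_fit <- function(X, times, events, ties = "efron", ci_level = 0.95) {
  .check_surv(times, events)
  df <- as.data.frame(X, stringsAsFactors = TRUE)
  if (is.null(colnames(X)) && ncol(df) == 1L) names(df) <- "x"
  num_cols <- vapply(df, is.numeric, TRUE)
  if (any(vapply(df[num_cols], function(v) stats::sd(v) == 0, TRUE)))
    stop("constant covariate in X")
  df$.time <- times
  df$.event <- events
  covars <- setdiff(names(df), c(".time", ".event"))
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covars), collapse = " + ")))
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    }
  )
  if (!is.null(warn) && grepl("infinite|converge", warn))
    stop("Cox fit diverged or failed to converge: ", warn,
         "\nfinal coefficients: ",
         paste(format(stats::coef(fit), digits = 4), collapse = ", "))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  structure(
    list(beta = beta, hr = exp(beta), se = se,
         p = 2 * stats::pnorm(-abs(beta / se)),
         ci_lower = exp(beta - z * se), ci_upper = exp(beta + z * se),
         loglik = fit$loglik[2], loglik_null = fit$loglik[1],
         n = fit$n, n_events = fit$nevent, ci_level = ci_level, fit = fit),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties): n =", x$n,
      ", events =", x$n_events, "\n")
  tab <- data.frame(beta = x$beta, HR = x$hr,
                    lower = x$ci_lower, upper = x$ci_upper, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Proportional-hazards assumption check
#'
#' Score test of association between scaled Schoenfeld residuals and the
#' Kaplan-Meier transform of event time, via [survival::cox.zph()].
#'
#' @param fit A `cox_fit` from [coxph_fit()].
#' @param times,events Ignored if supplied; kept for interface symmetry (the
#'   fit already carries its data).
#' @return Named numeric vector of per-covariate p-values.
#' @export
ph_assumption_test <- function(fit, times = NULL, events = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 3) stop("need at least 3 events for the PH check")
  zp <- survival::cox.zph(fit$fit, transform = "km")
  p <- zp$table[, "p"]
  p[setdiff(names(p), "GLOBAL")]
}

#' Concordance index of a risk score
#'
#' Harrell's C over censoring-comparable pairs: a pair is usable when the
#' two follow-up times differ and the shorter one ended in an event;
#' concordant when the shorter time has the higher risk, risk ties count
#' 1/2. Confidence intervals by a Noether-type normal approximation at each
#' requested level (defaults 95% and 85%; the 85% interval approximates a 5%
#' error rate when comparing two C-indices by CI overlap).
#'
#' @param risk Per-sample risk score (higher = higher hazard).
#' @inheritParams km_estimate
#' @param ci_levels Confidence levels (default `c(0.95, 0.85)`).
#' @return List: `c_index`, `n_pairs`, `se`, and `ci` (matrix level x
#'   c(lower, upper)).
#' @export
concordance_index <- function(risk, times, events,
                              ci_levels = c(0.95, 0.85)) {
  .check_surv(times, events, min_events = 1)
  stopifnot(length(risk) == length(times), all(is.finite(risk)))
  n <- length(risk)
  dt <- outer(times, times, "-")       # dt[i,j] = t_i - t_j
  usable <- dt < 0 & matrix(events == 1, n, n)  # i fails first
  dr <- outer(risk, risk, "-")
  conc <- sum(dr[usable] > 0) + 0.5 * sum(dr[usable] == 0)
  n_pairs <- sum(usable)
  if (n_pairs == 0) stop("no usable pairs under censoring")
  cidx <- conc / n_pairs
  se <- sqrt(cidx * (1 - cidx) / n_pairs)
  ci <- t(vapply(ci_levels, function(lv) {
    z <- stats::qnorm(1 - (1 - lv) / 2)
    c(lower = max(0, cidx - z * se), upper = min(1, cidx + z * se))
  }, c(lower = 0, upper = 0)))
  rownames(ci) <- paste0(ci_levels * 100, "%")
  list(c_index = cidx, n_pairs = n_pairs, se = se, ci = ci)
}

#' Nested two-group vs four-group risk models
#'
#' Compares a Cox model on a single dichotomous clinical factor against the
#' model on the four combinations of that factor with a binary subtype
#' indicator (three indicator covariates against a designated high-risk
#' reference combination). The comparison is a likelihood-ratio chi-square
#' with 2 degrees of freedom; pairwise hazard ratios against the reference
#' combination are reported from the four-group fit.
#'
#' @param clinical_factor Binary clinical factor per subject.
#' @param subtype Binary subtype indicator per subject.
#' @inheritParams km_estimate
#' @param reference Level of `interaction(clinical_factor, subtype, sep =
#'   " ")` used as the reference (high-risk) combination; default the last
#'   factor level combined with the first subtype level.
#' @return List: `fit2`, `fit4` (both `cox_fit`), `lr_chisq`, `df`, `p`,
#'   `reference`.
#' @export
risk_group_model <- function(clinical_factor, subtype, times, events,
                             reference = NULL) {
  .check_surv(times, events)
  f <- as.factor(clinical_factor)
  s <- as.factor(subtype)
  stopifnot(nlevels(f) == 2L, nlevels(s) == 2L)
  combo <- factor(paste(as.character(f), as.character(s)))
  if (nlevels(combo) < 4L) {
    missing_cells <- setdiff(
      as.vector(outer(levels(f), levels(s), paste)), levels(combo))
    stop("empty combination cell(s): ",
         paste(missing_cells, collapse = ", "))
  }
  if (is.null(reference))
    reference <- paste(levels(f)[2], levels(s)[1])
  if (!reference %in% levels(combo))
    stop("reference '", reference, "' is not a combination level")
  combo <- stats::relevel(combo, ref = reference)
  fit2 <- coxph_fit(data.frame(factor = f), times, events)
  fit4 <- coxph_fit(data.frame(combo = combo), times, events)
  lr <- 2 * (fit4$loglik - fit2$loglik)
  list(fit2 = fit2, fit4 = fit4, lr_chisq = lr, df = 2,
       p = stats::pchisq(lr, df = 2, lower.tail = FALSE),
       reference = reference)
}

# deterministic backward elimination minimizing AIC (penalty 2/parameter)
.backward_aic <- function(df, covars, k = 2) {
  current <- covars
  fit_aic <- function(vars) {
    if (length(vars) == 0L) return(Inf)
    f <- coxph_fit(df[, vars, drop = FALSE], df$.time, df$.event)
    -2 * f$loglik + k * length(f$beta)
  }
  best <- fit_aic(current)
  repeat {
    if (length(current) <= 1L) break
    cand <- vapply(current, function(v) fit_aic(setdiff(current, v)), 0)
    if (min(cand) < best) {
      best <- min(cand)
      current <- setdiff(current, names(cand)[which.min(cand)])
    } else break
  }
  current
}

#' Multivariable risk-modeling workflow
#'
#' The full train/test protocol: an event-stratified random 7:3 train-test
#' split; a univariable Cox screen on the training set keeping candidates
#' with Wald p < `screen_p` (default 0.2); backward elimination minimizing
#' AIC (penalty 2 per parameter); the final model fitted on the training
#' set; the linear predictor computed on the test set, centered and scaled;
#' a univariable Cox fit of that standardized risk score on the test set
#' (HR, CI, p); and the test-set concordance index with 95% and 85%
#' confidence intervals.
#'
#' @param table Data frame with columns `<endpoint>_time`,
#'   `<endpoint>_event`, and the candidate covariates.
#' @param candidates Character vector of candidate covariate columns.
#' @param endpoint Endpoint name prefix (e.g. "OS").
#' @param seed Integer RNG seed for the split.
#' @param screen_p Univariable screening threshold (default 0.2).
#' @param train_frac Training fraction (default 0.7).
#' @return List: `selected`, `screened`, `risk_hr`, `risk_ci`, `risk_p`,
#'   `c_index` (from [concordance_index()]), `train_fit`, `null_model`
#'   (TRUE when the screen left no covariates; then the model fields are
#'   NULL and this is the documented null result, not an error).
#' @export
multivariable_workflow <- function(table, candidates, endpoint, seed = 1,
                                   screen_p = 0.2, train_frac = 0.7) {
  tc <- paste0(endpoint, "_time"); ec <- paste0(endpoint, "_event")
  if (!all(c(tc, ec) %in% names(table)))
    stop("endpoint columns ", tc, "/", ec, " not found")
  stopifnot(length(candidates) >= 2, all(candidates %in% names(table)))
  df <- table[stats::complete.cases(table[, c(tc, ec, candidates)]), ]
  df$.time <- df[[tc]]; df$.event <- df[[ec]]
  .check_surv(df$.time, df$.event)

  set.seed(as.integer(seed))
  train <- logical(nrow(df))
  for (ev in unique(df$.event)) {       # stratify the split on the event flag
    idx <- which(df$.event == ev)
    n_tr <- round(train_frac * length(idx))
    train[sample(idx, n_tr)] <- TRUE
  }
  dtr <- df[train, ]; dte <- df[!train, ]

  screened <- character(0)
  for (v in candidates) {
    p <- tryCatch(coxph_fit(dtr[, v, drop = FALSE], dtr$.time,
                            dtr$.event)$p[1],
                  error = function(e) NA_real_)
    if (!is.na(p) && p < screen_p) screened <- c(screened, v)
  }
  if (length(screened) == 0L)
    return(list(selected = character(0), screened = screened,
                risk_hr = NULL, risk_ci = NULL, risk_p = NULL,
                c_index = NULL, train_fit = NULL, null_model = TRUE))

  selected <- .backward_aic(dtr, screened)
  train_fit <- coxph_fit(dtr[, selected, drop = FALSE], dtr$.time, dtr$.event)
  lp_test <- as.numeric(as.matrix(dte[, selected, drop = FALSE]) %*%
                          train_fit$beta)
  if (stats::sd(lp_test) == 0)
    return(list(selected = selected, screened = screened, risk_hr = NULL,
                risk_ci = NULL, risk_p = NULL, c_index = NULL,
                train_fit = train_fit, null_model = TRUE))
  risk <- as.numeric(scale(lp_test))
  rf <- coxph_fit(data.frame(risk = risk), dte$.time, dte$.event)
  ci <- concordance_index(risk, dte$.time, dte$.event)
  list(selected = selected, screened = screened,
       risk_hr = unname(rf$hr[1]),
       risk_ci = c(unname(rf$ci_lower[1]), unname(rf$ci_upper[1])),
       risk_p = unname(rf$p[1]), c_index = ci, train_fit = train_fit,
       null_model = FALSE)
}

#' Sliding-threshold survival scan of a continuous marker
#'
#' For each fraction f on the grid, the top group is the floor(f * n)
#' largest marker values and the bottom group the floor(f * n) smallest
#' (marker ties broken by stable sample order); the middle samples are
#' excluded, and a univariable Cox model of top vs bottom yields HR, CI and
#' p at that threshold.
#'
#' @param marker Finite per-sample continuous marker values.
#' @inheritParams km_estimate
#' @param fractions Fraction grid (default 0.05 to 0.50 in steps of 0.01).
#' @return Object of class `scan_result`: data frame with fraction, n_top,
#'   n_bottom, hr, ci_lower, ci_upper, p (NA rows where the Cox fit failed,
#'   e.g. no events in the two groups).
#' @export
sliding_threshold_scan <- function(marker, times, events,
                                   fractions = seq(0.05, 0.50, by = 0.01)) {
  .check_surv(times, events)
  stopifnot(all(is.finite(marker)), length(marker) == length(times))
  if (any(fractions > 0.5)) stop("fractions above 0.5 overlap top and bottom")
  n <- length(marker)
  if (floor(min(fractions) * n) < 2)
    stop("smallest fraction selects fewer than 2 samples per group")
  ord_inc <- order(marker)                       # stable: ties by sample order
  ord_dec <- order(-marker)
  rows <- lapply(fractions, function(f) {
    m <- floor(f * n)
    bottom <- ord_inc[seq_len(m)]
    top <- ord_dec[seq_len(m)]
    idx <- c(top, bottom)
    grp <- rep(c(1, 0), each = m)                # 1 = top
    fit <- tryCatch(
      coxph_fit(data.frame(top = grp), times[idx], events[idx]),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(fraction = f, n_top = m, n_bottom = m,
                        hr = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p = NA_real_))
    data.frame(fraction = f, n_top = m, n_bottom = m,
               hr = unname(fit$hr[1]), ci_lower = unname(fit$ci_lower[1]),
               ci_upper = unname(fit$ci_upper[1]), p = unname(fit$p[1]))
  })
  structure(do.call(rbind, rows), class = c("scan_result", "data.frame"))
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Sliding-threshold scan over", nrow(x), "fractions\n")
  ok <- !is.na(x$p)
  if (any(ok)) {
    best <- which.min(x$p)
    cat(sprintf("Minimum p = %.4g at fraction %.2f (HR = %.3f)\n",
                x$p[best], x$fraction[best], x$hr[best]))
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
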