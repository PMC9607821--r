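# Outcome models under the conditional-measures adjustment rules, predictor
# models for conditional wealth, and the fixed-effects <-> conditional
# reparameterization identities.

# Plain OLS on an explicit design matrix with classical (or HC1) standard
# errors and Wald 95% CIs (estimate +/- 1.96 SE, matching the reporting
# convention of the framework).
ols_table <- function(D, y, robust = FALSE) {
  n <- nrow(D)
  p <- ncol(D)
  q <- qr(D)
  if (q$rank < p) stop("rank-deficient design")
  beta <- qr.coef(q, y)
  fit <- drop(D %*% beta)
  e <- y - fit
  XtXinv <- chol2inv(qr.R(q))
  if (robust) {
    meat <- crossprod(D * e)
    V <- XtXinv %*% meat %*% XtXinv * n / (n - p)  # HC1
  } else {
    V <- XtXinv * sum(e^2) / (n - p)
  }
  se <- sqrt(diag(V))
  tab <- data.frame(term = colnames(D), estimate = as.numeric(beta),
                    se = se, lower = beta - 1.96 * se,
                    upper = beta + 1.96 * se, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, fitted = fit, residuals = e, n = n)
}

new_outcome_fit <- function(ols, parameterization, adjustment, robust,
                            se_type = if (robust) "HC1" else "classical") {
  structure(
    list(parameterization = parameterization, coefficients = ols$table,
         n = ols$n, fitted = ols$fitted, residuals = ols$residuals,
         adjustment = adjustment, se_type = se_type),
    class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(sprintf("outcome_fit [%s] (n = %d, %s SEs)\n",
              x$parameterization, x$n, x$se_type))
  print.data.frame(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Build the adjustment set for a conditional-wealth outcome model
#'
#' Outcome models for conditional wealth adjust for the first (anchor)
#' measure of wealth, all past conditional measures, and declared life-course
#' covariates — but never for any raw wealth measure other than the anchor,
#' because later raw measures are exact linear combinations of the anchor and
#' the conditional measures.
#'
#' @param model a [fit_conditional()] result.
#' @param covariates character vector of covariate names to include.
#' @param target_wave latest wave whose conditional measure enters (default:
#'   last fitted wave).
#' @return character vector: anchor term `w_<first wave>`, conditional terms
#'   `c_<wave>`, then covariates.
#' @export
build_adjustment_set <- function(model, covariates = character(),
                                 target_wave = NULL) {
  stopifnot(inherits(model, "conditional_wealth_model"))
  waves <- model$wave_labels
  if (is.null(target_wave)) target_wave <- waves[length(waves)]
  target_wave <- as.character(target_wave)
  ti <- match(target_wave, waves)
  if (is.na(ti) || ti < 2L) stop("target wave must be a fitted wave (>= 2)")
  raw <- paste0("w_", waves[-1])
  offending <- intersect(covariates, c(raw, waves[-1]))
  if (length(offending))
    stop("adjust for the anchor measure, conditional measures and covariates, ",
         "but not for any other raw wealth measure; offending: ",
         paste(offending, collapse = ", "))
  c(paste0("w_", waves[1]), paste0("c_", waves[2:ti]), covariates)
}

#' Outcome regression in the conditional parameterization
#'
#' Ordinary least squares of the outcome on the anchor wealth measure, all
#' conditional wealth measures, and covariates — the parameterization in
#' which each conditional coefficient reads as the change in outcome per unit
#' of relative wealth mobility over its interval.
#'
#' @param y numeric outcome per household.
#' @param W households x waves wealth matrix.
#' @param model optional [fit_conditional()] result on `W`; fitted afresh
#'   when omitted.
#' @param X optional data frame of covariates (rows aligned with `W`).
#' @param covariates columns of `X` to adjust for (default all).
#' @param robust use heteroskedasticity-robust (HC1) SEs instead of
#'   classical.
#' @param bootstrap if > 0, number of household-resampling bootstrap
#'   replicates used for SEs; the conditional decomposition is re-estimated
#'   inside each replicate, so the SEs account for the two-stage estimation.
#' @param seed RNG seed for the bootstrap.
#' @return an `outcome_fit` with coefficient table (estimate, SE, Wald 95%
#'   CI per term).
#' @export
fit_outcome_conditional <- function(y, W, model = NULL, X = NULL,
                                    covariates = if (is.null(X)) character()
                                                 else names(X),
                                    robust = FALSE, bootstrap = 0,
                                    seed = NULL) {
  W <- check_wealth_matrix(W)
  if (is.null(model)) model <- fit_conditional(W)
  stopifnot(length(y) == nrow(W))
  adj <- build_adjustment_set(model, covariates)
  D <- cbind(`(Intercept)` = 1, W[, 1, drop = FALSE], model$conditional)
  colnames(D)[2] <- paste0("w_", model$wave_labels[1])
  if (length(covariates)) {
    X <- as.data.frame(X)
    stopifnot(nrow(X) == nrow(W))
    D <- cbind(D, as.matrix(X[, covariates, drop = FALSE]))
  }
  ols <- ols_table(D, y, robust)
  fit <- new_outcome_fit(ols, "conditional", adj, robust)
  if (bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    est <- matrix(NA_real_, bootstrap, ncol(D))
    for (b in seq_len(bootstrap)) {
      idx <- sample.int(nrow(W), replace = TRUE)
      mb <- fit_conditional(W[idx, , drop = FALSE])
      Db <- D[idx, , drop = FALSE]
      Db[, colnames(mb$conditional)] <- mb$conditional
      Db[, 2] <- W[idx, 1]
      cf <- tryCatch(qr.coef(qr(Db), y[idx]), error = function(e) NULL)
      if (!is.null(cf)) est[b, ] <- cf
    }
    bse <- apply(est, 2, stats::sd, na.rm = TRUE)
    fit$coefficients$se <- bse
    fit$coefficients$lower <- fit$coefficients$estimate - 1.96 * bse
    fit$coefficients$upper <- fit$coefficients$estimate + 1.96 * bse
    fit$se_type <- sprintf("household bootstrap (%d reps)", bootstrap)
  }
  fit
}

#' Outcome regression on raw repeated wealth measures
#'
#' The fixed-effects-style parameterization: OLS of the outcome on every raw
#' wealth measure plus covariates. Numerically equivalent (same fitted
#' values, same coefficient on the latest measure) to the conditional
#' parameterization of [fit_outcome_conditional()].
#'
#' @inheritParams fit_outcome_conditional
#' @export
fit_outcome_fixed <- function(y, W, X = NULL,
                              covariates = if (is.null(X)) character()
                                           else names(X),
                              robust = FALSE) {
  W <- check_wealth_matrix(W)
  stopifnot(length(y) == nrow(W))
  D <- cbind(`(Intercept)` = 1, W)
  colnames(D)[-1] <- paste0("w_", colnames(W))
  if (length(covariates)) {
    X <- as.data.frame(X)
    stopifnot(nrow(X) == nrow(W))
    D <- cbind(D, as.matrix(X[, covariates, drop = FALSE]))
  }
  ols <- ols_table(D, y, robust)
  new_outcome_fit(ols, "fixed-effects",
                  c(colnames(D)[-1]), robust)
}

#' Verify the fixed-effects / conditional reparameterization identities
#'
#' Because each conditional measure is an exact linear combination of the raw
#' wealth history, the two outcome parameterizations span the same column
#' space. This check verifies (i) the coefficient on the latest raw wealth
#' measure equals the coefficient on the latest conditional measure; (ii) the
#' anchor-coefficient mapping `a'_1 = sum_t a_t * pi_t`, where `pi_t` is the
#' coefficient of the anchor in the linear expansion of wave `t`'s fitted
#' wealth history (for two waves, `a'_1 = a_1 + a_2 * b_1`); and (iii)
#' identical fitted values and residuals.
#'
#' @param fit_fixed an `outcome_fit` from [fit_outcome_fixed()].
#' @param fit_conditional an `outcome_fit` from [fit_outcome_conditional()].
#' @param model the [fit_conditional()] result behind `fit_conditional`.
#' @param tol,tol_fitted tolerances for coefficient and fitted-value
#'   agreement.
#' @return list with the three discrepancies and an overall `pass` flag.
#' @export
check_equivalence <- function(fit_fixed, fit_conditional, model,
                              tol = 1e-8, tol_fitted = 1e-10) {
  stopifnot(inherits(fit_fixed, "outcome_fit"),
            inherits(fit_conditional, "outcome_fit"),
            inherits(model, "conditional_wealth_model"))
  if (fit_fixed$n != fit_conditional$n) stop("mismatched samples")
  waves <- model$wave_labels
  T_ <- length(waves)
  cf_f <- stats::setNames(fit_fixed$coefficients$estimate,
                          fit_fixed$coefficients$term)
  cf_c <- stats::setNames(fit_conditional$coefficients$estimate,
                          fit_conditional$coefficients$term)
  last_diff <- abs(cf_f[paste0("w_", waves[T_])] -
                     cf_c[paste0("c_", waves[T_])])
  # pi_t: coefficient of the anchor when wave t's wealth is expanded in
  # (anchor, conditional measures): pi_1 = 1, pi_t = sum_{s<t} b_{t,s} pi_s
  pi <- numeric(T_)
  pi[1] <- 1
  for (t in 2:T_) {
    b <- model$coefficients[[waves[t]]]
    pi[t] <- sum(b[waves[seq_len(t - 1L)]] * pi[seq_len(t - 1L)])
  }
  a_fixed <- cf_f[paste0("w_", waves)]
  anchor_expected <- sum(a_fixed * pi)
  anchor_diff <- abs(anchor_expected - cf_c[paste0("w_", waves[1])])
  fitted_diff <- max(abs(fit_fixed$fitted - fit_conditional$fitted))
  list(latest_coef_diff = unname(last_diff),
       anchor_mapping_diff = unname(anchor_diff),
       fitted_diff = fitted_diff,
       pass = last_diff < tol && anchor_diff < tol &&
         fitted_diff < tol_fitted)
}

#' Predictors of conditional wealth at a wave
#'
#' Regresses one wave's conditional wealth on declared covariates to
#' quantify the "absorbed effect" of those predictors on relative wealth
#' mobility. The anchor measure must not be included: conditional wealth is
#' uncorrelated with it by construction, and adjusting for it is
#' inappropriate when modeling predictors of conditional measures.
#'
#' @param model a [fit_conditional()] result.
#' @param X data frame of covariates aligned with the fitted households.
#' @param wave wave label whose conditional measure is modeled.
#' @param covariates columns of `X` to use (default all).
#' @param robust use HC1 SEs.
#' @return a `predictor_fit`: wave, coefficient table, residuals `u`.
#' @export
predict_conditional <- function(model, X, wave,
                                covariates = names(X), robust = FALSE) {
  stopifnot(inherits(model, "conditional_wealth_model"))
  waves <- model$wave_labels
  wave <- as.character(wave)
  cn <- paste0("c_", wave)
  if (!cn %in% colnames(model$conditional))
    stop("unknown or unfitted wave: ", wave)
  offending <- intersect(covariates, c(paste0("w_", waves), waves))
  if (length(offending))
    stop("do not adjust for the anchor (or any raw wealth) measure when ",
         "modeling predictors of conditional wealth; offending: ",
         paste(offending, collapse = ", "))
  X <- as.data.frame(X)
  stopifnot(nrow(X) == model$n)
  D <- cbind(`(Intercept)` = 1,
             as.matrix(X[, covariates, drop = FALSE]))
  ols <- ols_table(D, model$conditional[, cn], robust)
  structure(list(wave = wave, coefficients = ols$table,
                 residuals = ols$residuals, n = ols$n),
            class = "predictor_fit")
}

#' @export
print.predictor_fit <- function(x, ...) {
  cat(sprintf("predictors of conditional wealth at wave %s (n = %d)\n",
              x$wave, x$n))
  print.data.frame(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Table of conditional-wealth predictors across waves
#'
#' Convenience wrapper running [predict_conditional()] at every fitted wave,
#' returning one long data frame (wave, term, estimate, se, lower, upper).
#'
#' @inheritParams predict_conditional
#' @param covariate_map optional named list, wave label -> covariate columns
#'   entered for that wave; default all columns at every wave.
#' @export
predictor_table <- function(model, X, covariate_map = NULL, robust = FALSE) {
  waves <- model$wave_labels[-1]
  out <- lapply(waves, function(w) {
    cols <- if (is.null(covariate_map)) names(X) else covariate_map[[w]]
    pf <- predict_conditional(model, X, w, covariates = cols, robust = robust)
    cbind(wave = w, pf$coefficients)
  })
  do.call(rbind, out)
}

#' Group-stratified outcome fits
#'
#' Repeats the conditional-parameterization outcome regression independently
#' within each group (e.g. by sex). The conditional decomposition is taken
#' from the pooled cohort, matching the practice of constructing the index
#' and conditional measures once and stratifying only the outcome model. No
#' interaction tests are performed.
#'
#' @inheritParams fit_outcome_conditional
#' @param group factor-like vector of group labels per household.
#' @return named list of `outcome_fit`, one per group level.
#' @export
stratified_fit <- function(y, W, model = NULL, X = NULL,
                           covariates = if (is.null(X)) character()
                                        else names(X),
                           group, robust = FALSE) {
  W <- check_wealth_matrix(W)
  if (is.null(model)) model <- fit_conditional(W)
  group <- as.factor(group)
  stopifnot(length(group) == nrow(W))
  p <- 2L + ncol(model$conditional) + length(covariates)
  out <- list()
  for (g in levels(group)) {
    idx <- which(group == g)
    if (length(idx) <= p)
      stop("group '", g, "' too small for the design (n = ",
           length(idx), ", parameters = ", p, ")")
    sub_model <- model
    sub_model$conditional <- model$conditional[idx, , drop = FALSE]
    sub_model$n <- length(idx)
    out[[g]] <- fit_outcome_conditional(
      y[idx], W[idx, , drop = FALSE], model = sub_model,
      X = if (is.null(X)) NULL else as.data.frame(X)[idx, , drop = FALSE],
      covariates = covariates, robust = robust)
  }
  out
}
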