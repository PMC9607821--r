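# Conditional wealth: per-wave decomposition of harmonized wealth into the
# component predicted by all prior waves (and optionally covariates) and the
# unexplained residual, kept in harmonized-wealth units.

# Shared fitting engine.  `covariate_map` maps wave label -> covariate column
# names entered at stage 1 for that wave (adjusted variant only).
fit_conditional_engine <- function(W, X = NULL, covariate_map = NULL,
                                   adjusted = FALSE) {
  W <- check_wealth_matrix(W)
  n <- nrow(W)
  T_ <- ncol(W)
  waves <- colnames(W)
  if (T_ < 2L) stop("need at least 2 waves")
  if (adjusted) {
    stopifnot(is.data.frame(X) || is.matrix(X))
    X <- as.data.frame(X)
    if (nrow(X) != n) stop("covariates not aligned with households")
    if (is.null(covariate_map))
      covariate_map <- stats::setNames(
        rep(list(names(X)), T_ - 1L), waves[-1])
  }
  coefs <- fitted <- resid <- vector("list", T_ - 1L)
  sigma2 <- share <- numeric(T_ - 1L)
  used_cov <- vector("list", T_ - 1L)
  for (j in seq_len(T_ - 1L)) {
    t <- j + 1L
    prior <- W[, seq_len(t - 1L), drop = FALSE]
    if (n <= t) stop("need n > number of prior waves + 1 at every wave")
    # collinear prior waves mean a canalized wealth history: refuse to fit
    sv <- svd(scale(prior, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
    if (min(sv) <= 0 || max(sv) / min(sv) > 1e8)
      stop("canalized/collinear wealth history at wave ", waves[t])
    D <- cbind(`(Intercept)` = 1, prior)
    cov_cols <- character(0)
    if (adjusted) {
      cov_cols <- intersect(covariate_map[[waves[t]]], names(X))
      if (length(cov_cols)) {
        Xc <- as.matrix(X[, cov_cols, drop = FALSE])
        q <- qr(cbind(D, Xc))
        if (q$rank < ncol(D) + length(cov_cols)) {
          keep_idx <- q$pivot[seq_len(q$rank)]
          dropped <- cov_cols[setdiff(seq_along(cov_cols),
                                      keep_idx[keep_idx > ncol(D)] - ncol(D))]
          warning("dropping covariate(s) collinear with prior wealth at wave ",
                  waves[t], ": ", paste(dropped, collapse = ", "))
          cov_cols <- setdiff(cov_cols, dropped)
          Xc <- as.matrix(X[, cov_cols, drop = FALSE])
        }
        if (length(cov_cols)) D <- cbind(D, Xc)
      }
    }
    fit <- stats::lm.fit(D, W[, t])
    coefs[[j]] <- fit$coefficients
    fitted[[j]] <- fit$fitted.values
    resid[[j]] <- fit$residuals
    sigma2[j] <- sample_var(fit$residuals)
    share[j] <- sample_var(fit$residuals) / sample_var(W[, t])
    used_cov[[j]] <- cov_cols
  }
  C <- do.call(cbind, resid)
  colnames(C) <- paste0("c_", waves[-1])
  rownames(C) <- rownames(W)
  Fhat <- do.call(cbind, fitted)
  colnames(Fhat) <- waves[-1]
  spearman <- vapply(seq_len(T_ - 1L), function(j)
    stats::cor(W[, j], W[, j + 1L], method = "spearman"), numeric(1))
  names(spearman) <- paste(waves[-T_], waves[-1], sep = "-")
  structure(
    list(wave_labels = waves, n = n,
         coefficients = stats::setNames(coefs, waves[-1]),
         conditional = C, fitted = Fhat,
         sigma2 = stats::setNames(sigma2, waves[-1]),
         unexplained = stats::setNames(share, waves[-1]),
         successive_spearman = spearman,
         adjusted = adjusted,
         covariates_used = stats::setNames(used_cov, waves[-1])),
    class = "conditional_wealth_model")
}

#' Decompose wealth into explained and conditional components
#'
#' For each wave `t >= 2`, regresses wealth on all prior waves by ordinary
#' least squares. The residual is conditional wealth: the component of the
#' wave's wealth unexplained by the household's wealth history, with zero
#' mean and zero correlation with every earlier wave. Residuals stay in
#' harmonized-wealth units and are never re-standardized, so a unit of
#' conditional wealth is comparable across waves.
#'
#' @param W numeric households x waves wealth matrix, columns named by wave,
#'   in calendar order.
#' @return an object of class `conditional_wealth_model` with per-wave
#'   `coefficients`, the `conditional` residual matrix (columns `c_<wave>`),
#'   `fitted` values, residual variances `sigma2`, `unexplained` variance
#'   shares, and `successive_spearman` rank correlations.
#' @examples
#' W <- cbind(`1` = c(0, 1, 2, 3), `2` = c(1, 1, 3, 3))
#' fit_conditional(W)$coefficients
#' @export
fit_conditional <- function(W) {
  fit_conditional_engine(W)
}

#' Conditional wealth with stage-1 covariate adjustment
#'
#' The adjusted variant enters declared covariates alongside prior wealth in
#' each stage-1 regression, so the resulting conditional wealth is
#' uncorrelated with both the wealth history and the covariates. Covariates
#' collinear with prior wealth are dropped with a warning.
#'
#' @inheritParams fit_conditional
#' @param X data frame of household-level covariates, rows aligned with `W`.
#' @param covariate_map optional named list, wave label -> character vector
#'   of covariate columns to enter at that wave; default enters all columns
#'   at every wave.
#' @return a `conditional_wealth_model` with `adjusted = TRUE`.
#' @export
fit_conditional_adjusted <- function(W, X, covariate_map = NULL) {
  fit_conditional_engine(W, X, covariate_map, adjusted = TRUE)
}

#' @export
print.conditional_wealth_model <- function(x, ...) {
  cat(sprintf("conditional_wealth_model (%s): %d households, waves %s\n",
              if (x$adjusted) "covariate-adjusted" else "wealth-history only",
              x$n, paste(x$wave_labels, collapse = ", ")))
  df <- data.frame(wave = names(x$unexplained),
                   sd_conditional = sqrt(x$sigma2),
                   unexplained_share = x$unexplained)
  print.data.frame(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Unexplained variance share at a wave
#'
#' The proportion of a wave's wealth variance carried by conditional wealth:
#' the share of variance unexplained by the wealth history, which quantifies
#' the extent of positional mobility over the preceding interval.
#'
#' @param model a [fit_conditional()] result.
#' @param t wave label (`t >= 2`).
#' @return fraction in `[0, 1]`.
#' @export
unexplained_share <- function(model, t) {
  stopifnot(inherits(model, "conditional_wealth_model"))
  t <- as.character(t)
  if (!t %in% names(model$unexplained)) stop("unknown or unfitted wave: ", t)
  unname(model$unexplained[t])
}

#' Interval-selection (canalization) diagnostics
#'
#' High rank correlation between successive waves means wealth rank is nearly
#' deterministic over the interval, which collapses conditional-wealth
#' variance and makes the interval a poor choice for mobility analysis.
#' Intervals with successive Spearman correlation above `threshold` are
#' flagged.
#'
#' @param W numeric households x waves wealth matrix.
#' @param threshold flag intervals whose successive-wave Spearman rank
#'   correlation exceeds this value (default 0.9).
#' @return data frame with one row per successive interval: `interval`,
#'   `spearman`, `unexplained_share`, `flagged`.
#' @export
canalization_diagnostics <- function(W, threshold = 0.9) {
  W <- check_wealth_matrix(W)
  model <- tryCatch(fit_conditional(W), error = function(e) NULL)
  waves <- colnames(W)
  k <- ncol(W) - 1L
  sp <- vapply(seq_len(k), function(j)
    stats::cor(W[, j], W[, j + 1L], method = "spearman"), numeric(1))
  data.frame(
    interval = paste(waves[-ncol(W)], waves[-1], sep = "-"),
    spearman = sp,
    unexplained_share = if (is.null(model)) rep(NA_real_, k)
                        else as.numeric(model$unexplained),
    flagged = sp > threshold,
    stringsAsFactors = FALSE)
}
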