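# Two-step polychoric correlation machinery: thresholds from the ordinal
# margins, then the latent correlation by maximizing the bivariate-normal
# cell-probability likelihood with thresholds held fixed.

#' Estimate latent-normal thresholds from ordinal level counts
#'
#' Thresholds are the inverse standard-normal quantiles of the cumulative
#' level proportions: the first step of two-step polychoric estimation. Empty
#' interior levels receive a 0.5 continuity correction so thresholds stay
#' strictly increasing.
#'
#' @param counts non-negative level counts in level order (length >= 2).
#' @return numeric vector of `length(counts) - 1` strictly increasing
#'   thresholds, with attribute `corrected` set to `TRUE` when the continuity
#'   correction was applied.
#' @examples
#' estimate_thresholds(c(50, 50))    # 0: a median split
#' estimate_thresholds(c(25, 50, 25))
#' @export
estimate_thresholds <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L)
    stop("constant item: fewer than 2 levels")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (sum(counts > 0) < 2L)
    stop("constant item: all mass in one level")
  corrected <- any(counts == 0)
  if (corrected) counts[counts == 0] <- 0.5
  cum <- cumsum(counts) / sum(counts)
  th <- stats::qnorm(cum[-length(cum)])
  attr(th, "corrected") <- corrected
  th
}

#' Polychoric correlation from a two-way contingency table
#'
#' Two-step maximum-likelihood estimate of the correlation of the latent
#' bivariate normal underlying a cross-tabulation of two ordinal variables.
#' Thresholds are fixed from the table margins; the correlation maximizes the
#' multinomial likelihood of the bivariate-normal cell probabilities. Empty
#' cells receive a 0.5 continuity correction (flagged). Estimates within
#' 1e-4 of the boundary are clamped to +/-(1 - 1e-6) and flagged.
#'
#' @param tab numeric matrix of counts with at least 2 rows and 2 columns.
#' @return a list of class `polychoric_fit`: `rho`, `loglik`,
#'   `row_thresholds`, `col_thresholds`, `n`, and logical flags `boundary`
#'   and `corrected`.
#' @examples
#' tab <- matrix(c(40, 10, 10, 40), 2)
#' estimate_polychoric(tab)$rho
#' @export
estimate_polychoric <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(!is.finite(tab)) || any(tab < 0))
    stop("counts must be finite and non-negative")
  if (sum(rowSums(tab) > 0) < 2L || sum(colSums(tab) > 0) < 2L)
    stop("degenerate margins: a variable is constant")
  corrected <- any(tab == 0)
  work <- tab
  if (corrected) work[work == 0] <- 0.5
  a <- estimate_thresholds(rowSums(work))
  b <- estimate_thresholds(colSums(work))
  nll <- function(rho) -cell_loglik(work, a, b, rho)
  eps <- 1e-6
  opt <- stats::optimise(nll, interval = c(-1 + eps, 1 - eps), tol = 1e-7)
  rho <- opt$minimum
  boundary <- (1 - abs(rho)) < 1e-4
  if (boundary) rho <- sign(rho) * (1 - eps)
  structure(
    list(rho = rho, loglik = -opt$objective,
         row_thresholds = as.numeric(a), col_thresholds = as.numeric(b),
         n = sum(tab), boundary = boundary, corrected = corrected),
    class = "polychoric_fit")
}

#' @export
print.polychoric_fit <- function(x, ...) {
  cat(sprintf("polychoric correlation: %.4f (n = %g)%s%s\n", x$rho, x$n,
              if (x$boundary) " [boundary]" else "",
              if (x$corrected) " [0.5 continuity correction]" else ""))
  invisible(x)
}

# Multinomial log-likelihood of a table under a bivariate normal with
# row/column thresholds a, b and correlation rho.  Cell probabilities come
# from CDF differences over the (extended) threshold grid.
cell_loglik <- function(tab, a, b, rho) {
  P <- cell_probs(a, b, rho)
  sum(tab * log(pmax(P, 1e-12)))
}

cell_probs <- function(a, b, rho) {
  aa <- c(-Inf, a, Inf)
  bb <- c(-Inf, b, Inf)
  grid <- pbinorm(rep(aa, times = length(bb)), rep(bb, each = length(aa)), rho)
  Fm <- matrix(grid, length(aa), length(bb))
  P <- Fm[-1, -1, drop = FALSE] - Fm[-nrow(Fm), -1, drop = FALSE] -
    Fm[-1, -ncol(Fm), drop = FALSE] +
    Fm[-nrow(Fm), -ncol(Fm), drop = FALSE]
  pmax(P, 0)
}
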