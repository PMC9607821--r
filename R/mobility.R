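# Distributional-change metrics for a closed cohort scored on a
# temporally-harmonized wealth index: mean change, individual change,
# inequality-share change, and rank change.

check_wealth_matrix <- function(W) {
  if (!is.matrix(W) || !is.numeric(W))
    stop("`W` must be a numeric households x waves matrix")
  if (is.null(colnames(W))) colnames(W) <- as.character(seq_len(ncol(W)))
  W
}

wave_index <- function(W, t) {
  t <- as.character(t)
  i <- match(t, colnames(W))
  if (is.na(i)) stop("unknown wave label: ", t)
  i
}

#' Change in mean wealth between two waves
#'
#' @param W numeric households x waves wealth matrix (index units), columns
#'   named by wave label.
#' @param t1,t2 wave labels.
#' @return `mean(W[, t2]) - mean(W[, t1])`.
#' @export
mean_wealth_change <- function(W, t1, t2) {
  W <- check_wealth_matrix(W)
  mean(W[, wave_index(W, t2)]) - mean(W[, wave_index(W, t1)])
}

#' Change in individual wealth between two waves
#'
#' @inheritParams mean_wealth_change
#' @return per-household vector `W[, t2] - W[, t1]`.
#' @export
individual_wealth_change <- function(W, t1, t2) {
  W <- check_wealth_matrix(W)
  W[, wave_index(W, t2)] - W[, wave_index(W, t1)]
}

# Square root of each wave's share of the total across-wave wealth variance
# (the McKenzie partition of temporal variance).
inequality_shares <- function(W) {
  W <- check_wealth_matrix(W)
  v <- apply(W, 2, sample_var)
  tot <- sum(v)
  if (tot <= 0) stop("zero total variance across waves")
  sqrt(v / tot)
}

#' Change in asset-based inequality between two waves
#'
#' Inequality at a wave is measured as the square root of that wave's share
#' of the total across-wave wealth variance; the change is the difference of
#' these shares. Shares are invariant to a common rescaling of the index.
#'
#' @inheritParams mean_wealth_change
#' @return scalar change in the inequality share from `t1` to `t2`.
#' @export
inequality_share_change <- function(W, t1, t2) {
  W <- check_wealth_matrix(W)
  if (ncol(W) < 2L) stop("need at least 2 waves")
  s <- inequality_shares(W)
  unname(s[wave_index(W, t2)] - s[wave_index(W, t1)])
}

#' Change in relative position (rank) between two waves
#'
#' Ranks within each wave use average ranks for ties, so rank changes sum to
#' zero exactly over a closed cohort.
#'
#' @inheritParams mean_wealth_change
#' @return per-household vector of rank changes.
#' @export
rank_change <- function(W, t1, t2) {
  W <- check_wealth_matrix(W)
  rank(W[, wave_index(W, t2)], ties.method = "average") -
    rank(W[, wave_index(W, t1)], ties.method = "average")
}

#' Wave-level mobility summary
#'
#' Per-wave means, standard deviations and inequality shares, with successive
#' changes in mean wealth and inequality share — the wave-level summary table
#' for a harmonized wealth matrix. Variances use the unbiased (n-1)
#' denominator throughout.
#'
#' @param W numeric households x waves wealth matrix.
#' @return a `mobility_summary` object: a data frame with one row per wave
#'   (`wave`, `mean`, `sd`, `inequality_share`, `mean_change`,
#'   `inequality_change`), plus attribute `n` (number of households).
#' @export
mobility_summary <- function(W) {
  W <- check_wealth_matrix(W)
  s <- inequality_shares(W)
  mu <- colMeans(W)
  out <- data.frame(
    wave = colnames(W),
    mean = as.numeric(mu),
    sd = as.numeric(apply(W, 2, stats::sd)),
    inequality_share = as.numeric(s),
    mean_change = c(NA, diff(mu)),
    inequality_change = c(NA, diff(s)),
    stringsAsFactors = FALSE)
  attr(out, "n") <- nrow(W)
  class(out) <- c("mobility_summary", "data.frame")
  out
}

#' @export
print.mobility_summary <- function(x, ...) {
  cat(sprintf("Wave-level wealth summary (n = %d households)\n", attr(x, "n")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
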