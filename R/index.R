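# Temporally-harmonized asset index: polychoric correlations among ordinal
# items pooled over household-waves, first principal component, and a single
# scoring rule applied to every household-wave.

#' Drop rare and constant items from an asset panel
#'
#' Rare assets can distort index estimation, so items whose minority pooled
#' category falls below `min_prevalence` are removed before the polychoric
#' PCA. Items constant in the pooled data are always removed.
#'
#' @param panel an [asset_panel()].
#' @param min_prevalence minimum pooled share of the smallest category, in
#'   `[0, 0.5)`.
#' @return list with the filtered `panel` and a `report` data frame (one row
#'   per item: `item`, `min_share`, `dropped`, `reason`).
#' @export
filter_items <- function(panel, min_prevalence = 0.01) {
  stopifnot(inherits(panel, "asset_panel"))
  if (min_prevalence < 0 || min_prevalence >= 0.5)
    stop("`min_prevalence` must be in [0, 0.5)")
  items <- names(panel$n_levels)
  min_share <- numeric(length(items))
  reason <- character(length(items))
  dropped <- logical(length(items))
  for (k in seq_along(items)) {
    v <- panel$values[, , k]
    cnt <- tabulate(v + 1L, nbins = panel$n_levels[k])
    if (sum(cnt > 0) < 2L) {
      dropped[k] <- TRUE
      reason[k] <- "constant item"
      min_share[k] <- NA_real_
    } else {
      min_share[k] <- min(cnt[cnt > 0]) / sum(cnt)
      if (min_share[k] < min_prevalence) {
        dropped[k] <- TRUE
        reason[k] <- sprintf("minority prevalence %.4f < %.4f",
                             min_share[k], min_prevalence)
      }
    }
  }
  report <- data.frame(item = items, min_share = min_share,
                       dropped = dropped, reason = reason,
                       stringsAsFactors = FALSE)
  if (all(dropped)) stop("no usable items after prevalence filtering")
  keep <- items[!dropped]
  out <- panel
  if (any(dropped)) {
    out <- asset_panel(panel$values[, , keep, drop = FALSE],
                       panel$n_levels[keep])
  }
  list(panel = out, report = report)
}

#' Build a temporally-harmonized wealth index
#'
#' Pools all household-wave rows, estimates the pairwise polychoric
#' correlation matrix of the surviving items, extracts the first principal
#' component, and fixes the standardization constants so that pooled scores
#' have mean 0 and unit variance. The eigenvector is oriented so the index
#' increases with asset ownership (positive correlation with the pooled sum
#' of standardized codes).
#'
#' @param panel an [asset_panel()].
#' @param min_prevalence passed to [filter_items()].
#' @param pairwise if `TRUE`, estimate each polychoric correlation from
#'   pairwise-complete rows (with nearest-PSD repair if needed); the default
#'   uses pooled rows complete on every item.
#' @return an object of class `harmonized_index`: `loadings`,
#'   `thresholds` (per item), `polychoric_matrix`, `eigenvalues`,
#'   `item_centers`, `item_scales`, `score_center`, `score_scale`,
#'   `orientation` (+1/-1), `items_dropped`, `psd_repaired`, `n_pooled`.
#' @seealso [score_households()] for scoring arbitrary panels on the index.
#' @export
build_harmonized_index <- function(panel, min_prevalence = 0.01,
                                   pairwise = FALSE) {
  flt <- filter_items(panel, min_prevalence)
  panel <- flt$panel
  items <- names(panel$n_levels)
  K <- length(items)
  if (K < 2L) stop("need at least 2 items to build an index")
  M <- pooled_codes(panel)
  complete <- stats::complete.cases(M)
  if (!pairwise) {
    M <- M[complete, , drop = FALSE]
    if (nrow(M) < K + 1L) stop("too few complete pooled rows")
  }
  thresholds <- vector("list", K)
  names(thresholds) <- items
  centers <- scales <- numeric(K)
  for (k in seq_len(K)) {
    v <- M[, k]
    cnt <- tabulate(v + 1L, nbins = panel$n_levels[k])
    thresholds[[k]] <- estimate_thresholds(cnt)
    centers[k] <- mean(v, na.rm = TRUE)
    scales[k] <- stats::sd(v, na.rm = TRUE)
  }
  R <- diag(1, K)
  for (j in seq_len(K - 1L)) {
    for (k in (j + 1L):K) {
      ok <- !is.na(M[, j]) & !is.na(M[, k])
      tab <- table(factor(M[ok, j], levels = 0:(panel$n_levels[j] - 1L)),
                   factor(M[ok, k], levels = 0:(panel$n_levels[k] - 1L)))
      R[j, k] <- R[k, j] <- estimate_polychoric(tab)$rho
    }
  }
  eig <- eigen(R, symmetric = TRUE)
  psd_repaired <- FALSE
  if (min(eig$values) < -1e-8) {
    # nearest-PSD repair by eigenvalue clipping, then rescale to unit diagonal
    lam <- pmax(eig$values, 1e-8)
    R <- eig$vectors %*% diag(lam) %*% t(eig$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    eig <- eigen(R, symmetric = TRUE)
    psd_repaired <- TRUE
  }
  loadings <- eig$vectors[, 1]
  names(loadings) <- items
  Z <- sweep(sweep(M, 2, centers), 2, scales, "/")
  raw <- as.numeric(Z %*% loadings)
  flip <- stats::cor(raw, rowSums(Z), use = "complete.obs") < 0
  orientation <- if (isTRUE(flip)) -1 else 1
  loadings <- loadings * orientation
  raw <- raw * orientation
  structure(
    list(loadings = loadings,
         thresholds = thresholds,
         polychoric_matrix = R,
         eigenvalues = eig$values,
         item_centers = stats::setNames(centers, items),
         item_scales = stats::setNames(scales, items),
         score_center = mean(raw, na.rm = TRUE),
         score_scale = stats::sd(raw, na.rm = TRUE),
         orientation = orientation,
         n_levels = panel$n_levels,
         items_dropped = flt$report[flt$report$dropped, , drop = FALSE],
         psd_repaired = psd_repaired,
         n_pooled = sum(!is.na(raw))),
    class = "harmonized_index")
}

#' @export
print.harmonized_index <- function(x, ...) {
  cat(sprintf("harmonized_index: %d items, %d pooled household-waves\n",
              length(x$loadings), x$n_pooled))
  cat(sprintf("  first-component share of variance: %.3f\n",
              x$eigenvalues[1] / sum(x$eigenvalues)))
  if (nrow(x$items_dropped))
    cat("  dropped:", paste(x$items_dropped$item, collapse = ", "), "\n")
  if (x$psd_repaired)
    cat("  note: polychoric matrix repaired to nearest PSD\n")
  invisible(x)
}

#' Score household-waves on a harmonized index
#'
#' Applies the index scoring rule to an asset panel: each item contributes
#' its loading times the standardized ordinal code (centered and scaled by
#' the pooled training moments), and the summed score is standardized by the
#' training `score_center` / `score_scale`. Household-waves with any missing
#' item score `NA`.
#'
#' @param index a [build_harmonized_index()] result.
#' @param panel an [asset_panel()] whose items include the index items.
#' @return a numeric households x waves matrix of wealth scores in index
#'   units (pooled mean 0, variance 1 on the training panel).
#' @export
score_households <- function(index, panel) {
  stopifnot(inherits(index, "harmonized_index"), inherits(panel, "asset_panel"))
  items <- names(index$loadings)
  miss <- setdiff(items, names(panel$n_levels))
  if (length(miss))
    stop("panel lacks index item(s): ", paste(miss, collapse = ", "))
  d <- dim(panel$values)
  M <- pooled_codes(panel)[, items, drop = FALSE]
  for (k in seq_along(items)) {
    bad <- M[, k] >= index$n_levels[items[k]]
    if (any(bad, na.rm = TRUE))
      stop(sprintf("item '%s' has level codes unseen at index construction",
                   items[k]))
  }
  Z <- sweep(sweep(M, 2, index$item_centers[items]), 2,
             index$item_scales[items], "/")
  raw <- as.numeric(Z %*% index$loadings)
  sc <- (raw - index$score_center) / index$score_scale
  W <- matrix(sc, d[1], d[2],
              dimnames = list(panel$household_ids, panel$wave_labels))
  W
}
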