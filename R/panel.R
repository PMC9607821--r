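#' Asset panel: households x waves x ordinal items
#'
#' An `asset_panel` holds the ordinal asset, housing and utility codes of a
#' closed cohort over its study waves: a three-dimensional integer array
#' (household x wave x item) of 0-based consecutive level codes, with `NA`
#' marking missing cells, plus an item catalog recording the number of ordered
#' levels per item.
#'
#' @param values integer array with `dim = c(n_households, n_waves, n_items)`
#'   and dimnames giving household identifiers, wave labels (in calendar
#'   order) and item names. Codes are 0-based consecutive integers.
#' @param n_levels optional named integer vector of level counts per item;
#'   inferred as `max(code) + 1` when omitted.
#' @return an object of class `asset_panel`.
#' @examples
#' arr <- array(rbinom(2 * 3 * 4, 1, 0.5), c(2, 3, 4),
#'              dimnames = list(c("h1", "h2"), c("1983", "1991", "1994"),
#'                              paste0("item", 1:4)))
#' asset_panel(arr)
#' @export
asset_panel <- function(values, n_levels = NULL) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-d array (household x wave x item)")
  dn <- dimnames(values)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    stop("`values` must carry complete dimnames")
  storage.mode(values) <- "integer"
  if (any(values < 0L, na.rm = TRUE))
    stop("level codes must be non-negative (0-based)")
  items <- dn[[3]]
  if (is.null(n_levels)) {
    n_levels <- apply(values, 3, function(v) {
      m <- suppressWarnings(max(v, na.rm = TRUE))
      if (!is.finite(m)) 1L else as.integer(m) + 1L
    })
    names(n_levels) <- items
  } else {
    n_levels <- as.integer(n_levels[items])
    names(n_levels) <- items
    for (k in seq_along(items)) {
      bad <- values[, , k] >= n_levels[k]
      if (any(bad, na.rm = TRUE))
        stop(sprintf("item '%s' has codes outside its declared level range",
                     items[k]))
    }
  }
  structure(
    list(values = values,
         household_ids = dn[[1]],
         wave_labels = dn[[2]],
         n_levels = n_levels),
    class = "asset_panel")
}

#' @export
print.asset_panel <- function(x, ...) {
  cat(sprintf("asset_panel: %d households x %d waves x %d items\n",
              length(x$household_ids), length(x$wave_labels),
              length(x$n_levels)))
  cat("  waves:", paste(x$wave_labels, collapse = ", "), "\n")
  nm <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.2f%%)\n", nm,
              100 * nm / length(x$values)))
  invisible(x)
}

#' @export
dim.asset_panel <- function(x) dim(x$values)

#' Subset an asset panel by wave
#'
#' @param panel an [asset_panel()].
#' @param waves character vector of wave labels to retain (calendar order is
#'   preserved).
#' @return an `asset_panel` restricted to the requested waves.
#' @export
panel_waves <- function(panel, waves) {
  stopifnot(inherits(panel, "asset_panel"))
  miss <- setdiff(waves, panel$wave_labels)
  if (length(miss))
    stop("unknown wave label(s): ", paste(miss, collapse = ", "))
  keep <- panel$wave_labels[panel$wave_labels %in% waves]
  asset_panel(panel$values[, keep, , drop = FALSE], panel$n_levels)
}

# Pooled household-wave matrix: (n * T) x K, household varying fastest.
pooled_codes <- function(panel) {
  d <- dim(panel$values)
  m <- matrix(panel$values, d[1] * d[2], d[3])
  colnames(m) <- names(panel$n_levels)
  rownames(m) <- paste(rep(panel$household_ids, times = d[2]),
                       rep(panel$wave_labels, each = d[1]), sep = ".")
  m
}
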