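# CSV dialects for asset panels and the complete-case filter.
#
# Canonical dialect is long CSV with columns household_id, wave, item,
# level_code (one row per observed cell).  The wide dialect is a convenience
# view with one row per household and one column per item-wave, named
# `<item>__<wave>`.  Wave labels are treated as labels ordered by the
# declared (or sorted) order, never parsed as dates.

#' Read an asset panel from CSV
#'
#' @param path CSV file path.
#' @param dialect `"long"` (columns `household_id`, `wave`, `item`,
#'   `level_code`) or `"wide"` (`household_id` plus `<item>__<wave>`
#'   columns).
#' @param waves optional character vector fixing the wave order; default is
#'   the sorted unique labels.
#' @param n_levels optional named integer vector of level counts per item
#'   (an item catalog override); inferred from the data when omitted.
#' @return an [asset_panel()] with a `report` attribute (rows read, cells
#'   missing).
#' @export
read_panel <- function(path, dialect = c("long", "wide"), waves = NULL,
                       n_levels = NULL) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (dialect == "wide") df <- wide_to_long(df)
  need <- c("household_id", "wave", "item", "level_code")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df$household_id <- as.character(df$household_id)
  df$wave <- as.character(df$wave)
  df$item <- as.character(df$item)
  if (!is.numeric(df$level_code) ||
      any(is.finite(df$level_code) & df$level_code != round(df$level_code)))
    stop("level codes must be integers")
  key <- paste(df$household_id, df$wave, df$item, sep = "|")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate household-wave-item row: ", key[which(dup)[1]])
  hh <- unique(df$household_id)
  if (is.null(waves)) waves <- sort(unique(df$wave))
  items <- sort(unique(df$item))
  vals <- array(NA_integer_, c(length(hh), length(waves), length(items)),
                dimnames = list(hh, waves, items))
  vals[cbind(match(df$household_id, hh), match(df$wave, waves),
             match(df$item, items))] <- as.integer(df$level_code)
  panel <- asset_panel(vals, n_levels)
  attr(panel, "report") <- list(rows_read = nrow(df),
                                cells_missing = sum(is.na(vals)))
  panel
}

#' Write an asset panel to CSV
#'
#' @param panel an [asset_panel()].
#' @param path output path.
#' @param dialect `"long"` or `"wide"`.
#' @param header optional comment line (e.g. a run fingerprint) written
#'   before the CSV body, prefixed with `#`.
#' @export
write_panel <- function(panel, path, dialect = c("long", "wide"),
                        header = NULL) {
  dialect <- match.arg(dialect)
  df <- panel_to_long(panel)
  if (dialect == "wide") {
    df$col <- paste(df$item, df$wave, sep = "__")
    wide <- stats::reshape(df[, c("household_id", "col", "level_code")],
                           idvar = "household_id", timevar = "col",
                           direction = "wide")
    names(wide) <- sub("^level_code\\.", "", names(wide))
    df <- wide[match(panel$household_ids, wide$household_id), , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Long-format view of an asset panel
#'
#' @param panel an [asset_panel()].
#' @param drop_missing omit missing cells (default `TRUE`).
#' @return data frame with columns `household_id`, `wave`, `item`,
#'   `level_code`.
#' @export
panel_to_long <- function(panel, drop_missing = TRUE) {
  stopifnot(inherits(panel, "asset_panel"))
  d <- dim(panel$values)
  df <- data.frame(
    household_id = rep(panel$household_ids, times = d[2] * d[3]),
    wave = rep(rep(panel$wave_labels, each = d[1]), times = d[3]),
    item = rep(names(panel$n_levels), each = d[1] * d[2]),
    level_code = as.integer(panel$values),
    stringsAsFactors = FALSE)
  if (drop_missing) df <- df[!is.na(df$level_code), , drop = FALSE]
  rownames(df) <- NULL
  df
}

wide_to_long <- function(df) {
  if (!"household_id" %in% names(df)) stop("missing column(s): household_id")
  cols <- setdiff(names(df), "household_id")
  bad <- cols[!grepl("__", cols)]
  if (length(bad))
    stop("wide columns must be named <item>__<wave>; offending: ",
         paste(bad, collapse = ", "))
  parts <- strsplit(cols, "__", fixed = TRUE)
  out <- data.frame(
    household_id = rep(as.character(df$household_id), times = length(cols)),
    wave = rep(vapply(parts, `[`, "", 2), each = nrow(df)),
    item = rep(vapply(parts, `[`, "", 1), each = nrow(df)),
    level_code = unlist(df[cols], use.names = FALSE),
    stringsAsFactors = FALSE)
  out[!is.na(out$level_code), , drop = FALSE]
}

#' Restrict inputs to complete cases
#'
#' Removes households with any missing asset cell at any wave, any missing
#' covariate, or a missing outcome, and reports the count removed per
#' reason (a household is counted once, at the first applicable reason in
#' the order wealth, covariate, outcome).
#'
#' @param panel an [asset_panel()].
#' @param covariates optional data frame with a `household_id` column.
#' @param outcome optional numeric vector aligned with the panel households
#'   (NA = missing).
#' @return list with filtered `panel`, `covariates`, `outcome`, the retained
#'   `household_ids`, and a `report` data frame (`reason`, `n`).
#' @export
apply_complete_case <- function(panel, covariates = NULL, outcome = NULL) {
  stopifnot(inherits(panel, "asset_panel"))
  n <- length(panel$household_ids)
  wealth_miss <- apply(panel$values, 1, anyNA)
  cov_miss <- rep(FALSE, n)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if ("household_id" %in% names(covariates)) {
      idx <- match(panel$household_ids, covariates$household_id)
      covariates <- covariates[idx, , drop = FALSE]
      cov_miss <- is.na(idx) | apply(is.na(covariates), 1, any)
    } else {
      stopifnot(nrow(covariates) == n)
      cov_miss <- apply(is.na(covariates), 1, any)
    }
  }
  out_miss <- rep(FALSE, n)
  if (!is.null(outcome)) {
    stopifnot(length(outcome) == n)
    out_miss <- is.na(outcome)
  }
  reason <- rep(NA_character_, n)
  reason[out_miss] <- "outcome_missing"
  reason[cov_miss] <- "covariate_missing"
  reason[wealth_miss] <- "wealth_missing"   # highest priority overwrites
  keep <- is.na(reason)
  if (!any(keep)) stop("no households left after complete-case restriction")
  report <- data.frame(
    reason = c("wealth_missing", "covariate_missing", "outcome_missing"),
    n = c(sum(reason == "wealth_missing", na.rm = TRUE),
          sum(reason == "covariate_missing", na.rm = TRUE),
          sum(reason == "outcome_missing", na.rm = TRUE)),
    stringsAsFactors = FALSE)
  ids <- panel$household_ids[keep]
  list(
    panel = asset_panel(panel$values[keep, , , drop = FALSE], panel$n_levels),
    covariates = if (is.null(covariates)) NULL
                 else covariates[keep, , drop = FALSE],
    outcome = if (is.null(outcome)) NULL else outcome[keep],
    household_ids = ids,
    report = report)
}
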