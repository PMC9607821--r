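# End-to-end orchestration: read -> complete-case filter -> harmonized index
# -> scores -> mobility -> conditional decomposition -> predictor and outcome
# fits, with JSON/CSV artifacts and a structured run log.

#' Pipeline configuration
#'
#' Collects every input and tuning choice of [run_pipeline()]. Inputs can be
#' file paths (CSV) or in-memory objects; a [synthetic_config()] may be
#' supplied as `panel` to simulate the cohort inside the pipeline.
#'
#' @param panel an [asset_panel()], a path to a panel CSV, or a
#'   [synthetic_config()].
#' @param covariates data frame (with `household_id`) or CSV path.
#' @param outcome numeric vector, or name of a column of `covariates`
#'   holding the outcome, or a CSV path with columns `household_id`,
#'   `outcome`.
#' @param dialect panel CSV dialect, `"long"` or `"wide"`.
#' @param waves optional declared wave order.
#' @param min_prevalence item prevalence filter (see [filter_items()]).
#' @param complete_case restrict to complete cases (default `TRUE`).
#' @param adjusted_conditional use [fit_conditional_adjusted()] at stage 1.
#' @param outcome_covariates covariate columns adjusted for in outcome
#'   models.
#' @param predictor_covariate_map optional named list, wave ->
#'   covariate columns, for the conditional-wealth predictor table.
#' @param stratify_by optional covariate column for stratified outcome fits.
#' @param row_filter optional function of the covariate table returning a
#'   logical keep-vector (e.g. to exclude rows unsuitable for the outcome
#'   model); applied before fitting outcome models only.
#' @param bootstrap bootstrap replicates for outcome-model SEs (0 = none).
#' @param robust use HC1 SEs in outcome and predictor models.
#' @param seed integer seed recorded in the run log and used for the
#'   bootstrap and any simulation.
#' @param out_dir optional output directory; when set, all artifacts are
#'   written there.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(panel, covariates = NULL, outcome = NULL,
                            dialect = "long", waves = NULL,
                            min_prevalence = 0.01, complete_case = TRUE,
                            adjusted_conditional = FALSE,
                            outcome_covariates = NULL,
                            predictor_covariate_map = NULL,
                            stratify_by = NULL, row_filter = NULL,
                            bootstrap = 0, robust = FALSE,
                            seed = 1L, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

config_fingerprint <- function(config) {
  drop <- c("panel", "covariates", "outcome", "row_filter", "out_dir")
  keep <- config[setdiff(names(config), drop)]
  fnv1a_hash(paste(utils::capture.output(utils::str(keep)), collapse = "\n"))
}

#' Run the full conditional-wealth pipeline
#'
#' Executes every stage on one cohort and returns (and optionally writes)
#' the artifact bundle: harmonized index, wealth scores, wave-level mobility
#' summary, conditional decomposition with canalization diagnostics,
#' predictors of conditional wealth per wave, and outcome fits in both
#' parameterizations (plus stratified fits if requested). Errors carry the
#' name of the failing stage. Outputs are stamped with the configuration
#' fingerprint and seed, so identical config and seed reproduce identical
#' artifacts.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `pipeline_result` with elements `panel`, `index`,
#'   `scores`, `mobility`, `conditional`, `diagnostics`, `predictors`,
#'   `fit_conditional`, `fit_fixed`, `equivalence`, `stratified`,
#'   `exclusions`, and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  fingerprint <- config_fingerprint(config)
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
    log[[name]] <<- list(stage = name,
                         seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  inputs <- stage("read", {
    panel <- config$panel
    covariates <- config$covariates
    outcome <- config$outcome
    if (inherits(panel, "synthetic_config")) {
      cohort <- simulate_cohort(panel)
      panel <- cohort$asset_panel
      if (is.null(covariates)) covariates <- cohort$covariates
      if (is.null(outcome)) outcome <- cohort$outcome
    } else if (is.character(panel)) {
      panel <- read_panel(panel, config$dialect, waves = config$waves)
    }
    if (is.character(covariates))
      covariates <- utils::read.csv(covariates, stringsAsFactors = FALSE,
                                    comment.char = "#")
    if (is.character(outcome) && length(outcome) == 1) {
      if (file.exists(outcome)) {
        odf <- utils::read.csv(outcome, stringsAsFactors = FALSE,
                               comment.char = "#")
        outcome <- odf$outcome[match(panel$household_ids, odf$household_id)]
      } else if (!is.null(covariates) && outcome %in% names(covariates)) {
        outcome <- covariates[[outcome]]
      } else stop("outcome column or file not found: ", outcome)
    }
    list(panel = panel, covariates = covariates, outcome = outcome)
  })

  filtered <- stage("complete_case", {
    if (config$complete_case)
      apply_complete_case(inputs$panel, inputs$covariates, inputs$outcome)
    else
      list(panel = inputs$panel, covariates = inputs$covariates,
           outcome = inputs$outcome, household_ids = inputs$panel$household_ids,
           report = NULL)
  })

  index <- stage("index",
                 build_harmonized_index(filtered$panel, config$min_prevalence))
  W <- stage("scores", score_households(index, filtered$panel))
  mobility <- stage("mobility", mobility_summary(W))
  cond <- stage("conditional", {
    if (config$adjusted_conditional) {
      cc <- config$outcome_covariates
      if (is.null(cc))
        cc <- setdiff(names(filtered$covariates), "household_id")
      fit_conditional_adjusted(W, filtered$covariates[, cc, drop = FALSE])
    } else fit_conditional(W)
  })
  diagnostics <- stage("diagnostics", canalization_diagnostics(W))

  predictors <- NULL
  fits <- list(conditional = NULL, fixed = NULL, equivalence = NULL,
               stratified = NULL)
  if (!is.null(filtered$covariates)) {
    covs <- config$outcome_covariates
    if (is.null(covs))
      covs <- setdiff(names(filtered$covariates), "household_id")
    predictors <- stage("predictors", {
      pm <- config$predictor_covariate_map
      predictor_table(cond, filtered$covariates,
                      covariate_map = if (is.null(pm)) stats::setNames(
                        rep(list(covs), length(cond$wave_labels) - 1L),
                        cond$wave_labels[-1]) else pm,
                      robust = config$robust)
    })
    if (!is.null(filtered$outcome)) {
      keep <- rep(TRUE, nrow(W))
      if (!is.null(config$row_filter))
        keep <- config$row_filter(filtered$covariates)
      yk <- filtered$outcome[keep]
      Wk <- W[keep, , drop = FALSE]
      Xk <- filtered$covariates[keep, , drop = FALSE]
      condk <- if (all(keep)) cond else fit_conditional(Wk)
      fits$conditional <- stage("fit_outcome_conditional",
        fit_outcome_conditional(yk, Wk, model = condk, X = Xk,
                                covariates = covs, robust = config$robust,
                                bootstrap = config$bootstrap,
                                seed = config$seed))
      fits$fixed <- stage("fit_outcome_fixed",
        fit_outcome_fixed(yk, Wk, X = Xk, covariates = covs,
                          robust = config$robust))
      fits$equivalence <- stage("equivalence",
        check_equivalence(fits$fixed, fits$conditional, condk))
      if (!is.null(config$stratify_by)) {
        fits$stratified <- stage("stratified",
          stratified_fit(yk, Wk, model = condk, X = Xk,
                         covariates = setdiff(covs, config$stratify_by),
                         group = Xk[[config$stratify_by]],
                         robust = config$robust))
      }
    }
  }

  result <- structure(
    list(panel = filtered$panel, index = index, scores = W,
         mobility = mobility, conditional = cond, diagnostics = diagnostics,
         predictors = predictors, fit_conditional = fits$conditional,
         fit_fixed = fits$fixed, equivalence = fits$equivalence,
         stratified = fits$stratified, exclusions = filtered$report,
         log = list(fingerprint = fingerprint, seed = config$seed,
                    package_version = as.character(
                      utils::packageVersion("condwealth")),
                    stages = unname(log))),
    class = "pipeline_result")
  if (!is.null(config$out_dir))
    stage("write", write_pipeline_outputs(result, config))
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (fingerprint", x$log$fingerprint,
      "seed", x$log$seed, ")\n")
  print(x$mobility)
  if (!is.null(x$fit_conditional)) print(x$fit_conditional)
  invisible(x)
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- result$log$fingerprint
  stamp <- sprintf("condwealth run %s seed %d", fp, config$seed)
  p <- function(f) file.path(config$out_dir, f)
  wjson <- function(x, f)
    jsonlite::write_json(c(list(fingerprint = fp, seed = config$seed), x),
                         p(f), auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  wcsv <- function(df, f) {
    con <- file(p(f), "w")
    on.exit(close(con))
    writeLines(paste0("# ", stamp), con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  idx <- result$index
  wjson(list(loadings = as.list(idx$loadings),
             thresholds = idx$thresholds,
             item_centers = as.list(idx$item_centers),
             item_scales = as.list(idx$item_scales),
             score_center = idx$score_center,
             score_scale = idx$score_scale,
             orientation = idx$orientation,
             eigenvalues = idx$eigenvalues,
             items_dropped = idx$items_dropped$item), "index.json")
  W <- result$scores
  wcsv(data.frame(household_id = rep(rownames(W), ncol(W)),
                  wave = rep(colnames(W), each = nrow(W)),
                  wealth = as.numeric(W)), "scores.csv")
  wcsv(as.data.frame(result$mobility), "mobility.csv")
  C <- result$conditional$conditional
  wcsv(data.frame(household_id = rep(rownames(W), ncol(C)),
                  wave = rep(sub("^c_", "", colnames(C)), each = nrow(C)),
                  conditional_wealth = as.numeric(C)), "conditional.csv")
  wjson(list(unexplained = as.list(result$conditional$unexplained),
             sigma2 = as.list(result$conditional$sigma2),
             successive_spearman =
               as.list(result$conditional$successive_spearman),
             diagnostics = result$diagnostics), "conditional_report.json")
  if (!is.null(result$predictors)) wcsv(result$predictors, "predictors.csv")
  if (!is.null(result$fit_conditional)) {
    fits <- list(conditional = result$fit_conditional$coefficients,
                 fixed = result$fit_fixed$coefficients,
                 equivalence = result$equivalence[
                   c("latest_coef_diff", "anchor_mapping_diff",
                     "fitted_diff", "pass")])
    if (!is.null(result$stratified))
      fits$stratified <- lapply(result$stratified, `[[`, "coefficients")
    wjson(fits, "fits.json")
  }
  wjson(result$log, "runlog.json")
  invisible(config$out_dir)
}
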