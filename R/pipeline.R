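# End-to-end orchestration: simulate or load a cohort, compute FC,
# fingerprint, ICC reliability, PCA Idiff sweep, optional residualization,
# and write a JSON report plus TSV matrices.

#' Build a pipeline configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"tsv"` (read a
#'   cohort directory of `<subject>_run-<r>_timeseries.tsv` files)
#' @param out_dir output directory for the report bundle
#' @param cohort a [cohort_spec()] (simulate mode)
#' @param tsv_dir cohort directory (tsv mode)
#' @param topk_max top-K curve extent
#' @param pca run the PCA Idiff sweep
#' @param pca_range component counts for the sweep (default full range)
#' @param icc_pct percentile for ICC thresholding
#' @param residual_direction `NULL`, `"spine_given_brain"`,
#'   `"brain_given_spine"`, or `"both"` (requires a combined parcellation)
#' @param sort_matrix reorder the identifiability matrix by diagonal before
#'   writing
#' @param seed seed (simulate mode; overrides the spec's seed when given)
#' @param verbose log stage progress to stderr
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(mode = c("simulate", "tsv"),
                            out_dir,
                            cohort = cohort_spec(),
                            tsv_dir = NULL,
                            topk_max = 5L,
                            pca = TRUE,
                            pca_range = NULL,
                            icc_pct = 95,
                            residual_direction = NULL,
                            sort_matrix = TRUE,
                            seed = NULL,
                            verbose = TRUE) {
  mode <- match.arg(mode)
  if (mode == "tsv" && is.null(tsv_dir)) stop("tsv mode requires `tsv_dir`")
  if (mode == "simulate") {
    stopifnot(inherits(cohort, "cohort_spec"))
    if (!is.null(seed)) cohort$seed <- as.integer(seed)
  }
  if (!is.null(residual_direction)) {
    residual_direction <- match.arg(residual_direction,
                                    c("spine_given_brain", "brain_given_spine",
                                      "both"))
  }
  structure(
    list(mode = mode, out_dir = out_dir, cohort = cohort, tsv_dir = tsv_dir,
         topk_max = as.integer(topk_max), pca = isTRUE(pca),
         pca_range = pca_range, icc_pct = icc_pct,
         residual_direction = residual_direction,
         sort_matrix = isTRUE(sort_matrix), verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

.log_stage <- function(config, ...) {
  if (config$verbose) message("[spineprint] ", ...)
}

# Collapse an identifiability_result to plain-list report form.
.result_report <- function(res) {
  list(
    n_subjects = res$n_subjects,
    Iself = res$Iself, Iothers = res$Iothers, Idiff = res$Idiff,
    var_self = res$var_self, var_others = res$var_others,
    cohens_d = res$cohens_d,
    success_count = res$success_count,
    accuracy = res$accuracy, accuracy_label = res$accuracy_label,
    topk = as.list(res$topk),
    chance_level = res$chance$percent, chance_label = res$chance$label
  )
}

#' Run the full fingerprinting pipeline
#'
#' Stages: acquire runs (simulate or TSV), FC + vectorization, fingerprint
#' statistics, edge ICC(1,1) map with percentile thresholding and nodal
#' strength, optional PCA Idiff sweep, optional brain/spine residual
#' fingerprints. Deterministic given the configuration (and its seed).
#' Writes `report.json`, the identifiability and ICC matrices as TSV, and a
#' `run.log` with the package version and configuration digest.
#'
#' @param config a [pipeline_config()]
#' @return the report, invisibly (a nested list mirroring `report.json`)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  .log_stage(config, "stage input: mode=", config$mode)
  runs <- tryCatch({
    if (config$mode == "simulate") {
      cohort <- generate_cohort(config$cohort)
      write_cohort(cohort, file.path(config$out_dir, "cohort"))
      cohort$runs
    } else {
      read_cohort(config$tsv_dir)
    }
  }, error = function(e) stop("stage 'input' failed: ", conditionMessage(e)))

  .log_stage(config, "stage fc: ", length(runs), " subjects")
  vectors <- tryCatch(
    list(run1 = fc_vectors_of_runs(lapply(runs, `[[`, 1L)),
         run2 = fc_vectors_of_runs(lapply(runs, `[[`, 2L))),
    error = function(e) stop("stage 'fc' failed: ", conditionMessage(e))
  )

  .log_stage(config, "stage fingerprint")
  res <- fingerprint(vectors$run1, vectors$run2,
                     k_max = min(config$topk_max, length(runs)))
  if (config$sort_matrix) res <- sort_by_diagonal(res)
  write_matrix_tsv(res$I, file.path(config$out_dir, "identifiability.tsv"))

  .log_stage(config, "stage icc")
  icc <- icc_matrix(vectors$run1, vectors$run2)
  thr <- threshold_percentile(icc$values, pct = config$icc_pct)
  strength <- nodal_strength(thr$filtered)
  write_matrix_tsv(icc$values, file.path(config$out_dir, "icc.tsv"))
  write_matrix_tsv(thr$filtered,
                   file.path(config$out_dir, "icc_thresholded.tsv"))

  report <- list(
    package = "spineprint",
    version = as.character(utils::packageVersion("spineprint")),
    mode = config$mode,
    n_subjects = length(runs),
    n_rois = length(vectors$run1[[1L]]$roi_names),
    n_edges = length(vectors$run1[[1L]]$values),
    fingerprint = .result_report(res),
    subject_order = res$subject_order,
    icc = list(
      mean = mean(icc$values[upper.tri(icc$values)], na.rm = TRUE),
      max = max(icc$values[upper.tri(icc$values)], na.rm = TRUE),
      threshold_pct = config$icc_pct,
      threshold_value = thr$threshold,
      nodal_strength = as.list(strength)
    )
  )

  if (config$pca) {
    .log_stage(config, "stage pca-sweep")
    sweep <- tryCatch(
      idiff_sweep(vectors$run1, vectors$run2, m_range = config$pca_range),
      error = function(e) stop("stage 'pca' failed: ", conditionMessage(e))
    )
    utils::write.table(
      data.frame(m = sweep$m_values, idiff = sweep$idiff_by_m),
      file.path(config$out_dir, "pca_sweep.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    report$pca <- list(m_star = sweep$m_star,
                       idiff_at_m_star = sweep$idiff_at_m_star,
                       idiff_full_rank = sweep$idiff_full_rank)
  }

  if (!is.null(config$residual_direction)) {
    dirs <- if (config$residual_direction == "both") {
      c("spine_given_brain", "brain_given_spine")
    } else config$residual_direction
    report$residual <- list()
    for (d in dirs) {
      .log_stage(config, "stage residualize: ", d)
      rres <- tryCatch(
        residual_fingerprint(runs, direction = d,
                             k_max = min(config$topk_max, length(runs))),
        error = function(e) stop("stage 'residualize (", d, ")' failed: ",
                                 conditionMessage(e))
      )
      report$residual[[d]] <- .result_report(rres)
    }
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_string <- paste(
    config$mode, config$topk_max, config$icc_pct,
    if (config$mode == "simulate") config$cohort$seed else config$tsv_dir,
    collapse = "|")
  cfg_digest <- sum(utf8ToInt(cfg_string) * seq_along(utf8ToInt(cfg_string)))
  writeLines(
    c(paste0("spineprint ", utils::packageVersion("spineprint")),
      paste0("mode: ", config$mode),
      paste0("config-digest: ", cfg_digest),
      paste0("subjects: ", length(runs)),
      paste0("rois: ", report$n_rois)),
    file.path(config$out_dir, "run.log")
  )
  .log_stage(config, "done: report at ",
             file.path(config$out_dir, "report.json"))
  invisible(report)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; simulate-mode cohort
#' parameters live under a `cohort:` mapping (`n_subjects`, `levels`,
#' `n_brain_rois`, `n_timepoints`, `k_factors`, `lambda_subject`,
#' `sigma_run`, `sigma_obs`, `coupling`, `seed`).
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading config files requires the yaml package")
  }
  y <- yaml::read_yaml(path)
  cohort <- cohort_spec()
  if (!is.null(y$cohort)) {
    cs <- y$cohort
    parc <- build_spinal_parcellation(cs$levels %||% c("C4", "C5", "C6"))
    if (!is.null(cs$n_brain_rois) && cs$n_brain_rois > 0) {
      parc <- combine_parcellations(build_brain_parcellation(cs$n_brain_rois),
                                    parc)
    }
    cohort <- cohort_spec(
      n_subjects = cs$n_subjects %||% 15L, parcellation = parc,
      n_timepoints = cs$n_timepoints %||% 300L,
      k_factors = cs$k_factors %||% 5L,
      lambda_subject = cs$lambda_subject %||% 1,
      sigma_run = cs$sigma_run %||% 0.3,
      sigma_obs = cs$sigma_obs %||% 1,
      coupling = cs$coupling %||% 0,
      seed = cs$seed %||% 1L
    )
  }
  pipeline_config(
    mode = y$mode %||% "simulate", out_dir = y$out_dir %||% "spineprint-out",
    cohort = cohort, tsv_dir = y$tsv_dir,
    topk_max = y$topk_max %||% 5L, pca = y$pca %||% TRUE,
    pca_range = y$pca_range, icc_pct = y$icc_pct %||% 95,
    residual_direction = y$residual_direction,
    sort_matrix = y$sort_matrix %||% TRUE, seed = y$seed,
    verbose = y$verbose %||% TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
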