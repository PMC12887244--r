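# Plain-text I/O: parcelled time series and matrices as TSV, cohort
# manifests and reports as JSON, optional NIfTI readers for voxel data.

#' Write a parcelled run as TSV
#'
#' Layout: first row = ROI names, each subsequent row = one time point.
#' The conventional file name is `<subject>_run-<r>_timeseries.tsv`.
#'
#' @param run a [parcelled_run()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_timeseries_tsv <- function(run, path) {
  stopifnot(inherits(run, "parcelled_run"))
  utils::write.table(
    format(run$data, digits = 17, trim = TRUE, scientific = TRUE),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = colnames(run$data)
  )
  invisible(path)
}

#' Read a parcelled run from TSV
#'
#' Validates a rectangular, all-finite numeric table with unique ROI names.
#' Subject and run default to the `<subject>_run-<r>_timeseries.tsv` file
#' name convention when not given.
#'
#' @param path TSV file (header = ROI names, rows = time points)
#' @param parcellation optional `parcellation`; when absent, a generic brain
#'   parcellation is inferred for spinal-unaware tables, or a spinal one when
#'   every name matches `<level>_<region>_<side>`
#' @param subject_id,run optional metadata overrides
#' @return a `parcelled_run`
#' @export
read_timeseries_tsv <- function(path, parcellation = NULL,
                                subject_id = NULL, run = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || !nzchar(lines[[1L]])) stop("empty time-series file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (anyDuplicated(header)) {
    stop("duplicate ROI name(s) in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  body <- lines[-1L][nzchar(lines[-1L])]
  if (!length(body)) stop("time-series file has a header but no rows: ", path)
  rows <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != length(header))) {
    stop("ragged row(s) at line(s): ",
         paste(which(widths != length(header)) + 1L, collapse = ", "))
  }
  data <- suppressWarnings(
    matrix(as.numeric(unlist(rows, use.names = FALSE)),
           nrow = length(rows), ncol = length(header), byrow = TRUE)
  )
  if (anyNA(data) || !all(is.finite(data))) {
    stop("non-numeric or non-finite cell(s) in ", path)
  }
  colnames(data) <- header
  if (is.null(parcellation)) parcellation <- infer_parcellation(header)
  fn <- basename(path)
  if (is.null(subject_id)) {
    subject_id <- sub("_run-.*$", "", fn)
    if (identical(subject_id, fn)) subject_id <- sub("\\.tsv$", "", fn)
  }
  if (is.null(run)) {
    m <- regmatches(fn, regexpr("run-([0-9]+)", fn))
    run <- if (length(m)) as.integer(sub("run-", "", m)) else 1L
  }
  parcelled_run(data, parcellation, subject_id, run)
}

# Rebuild a parcellation from ROI names: spinal names follow
# <level>_<region>_<side>; anything else becomes a brain label.
infer_parcellation <- function(names) {
  parts <- strsplit(names, "_", fixed = TRUE)
  is_spinal <- vapply(parts, function(p) {
    length(p) == 3L && p[[1L]] %in% spinal_levels() &&
      p[[2L]] %in% c(.gm_regions, .wm_regions) && p[[3L]] %in% c("L", "R")
  }, logical(1))
  labels <- do.call(rbind, lapply(seq_along(names), function(i) {
    if (is_spinal[i]) {
      p <- parts[[i]]
      tissue <- if (p[[2L]] %in% .gm_regions) "GM" else "WM"
      data.frame(name = names[i], level = p[[1L]], tissue = tissue,
                 region = p[[2L]], side = p[[3L]], stringsAsFactors = FALSE)
    } else {
      data.frame(name = names[i], level = "brain", tissue = "brain",
                 region = "brain", side = NA_character_,
                 stringsAsFactors = FALSE)
    }
  }))
  .new_parcellation(labels,
                    n_levels = length(unique(labels$level[is_spinal])))
}

#' Write a named square matrix (FC, identifiability, ICC) as TSV
#' @param mat square matrix with dimnames
#' @param path output file
#' @return `path`, invisibly
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(roi = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("roi", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square matrix written by [write_matrix_tsv()]
#' @param path TSV file
#' @return numeric matrix with dimnames
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Write an FC vector as a two-column TSV (`edge`, `value`)
#' @param v an `fc_vector`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fc_vector_tsv <- function(v, path) {
  stopifnot(inherits(v, "fc_vector"))
  utils::write.table(
    data.frame(edge = v$edge_names,
               value = format(v$values, digits = 17, trim = TRUE,
                              scientific = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a synthetic cohort to a directory of TSV files plus a JSON manifest
#'
#' One `<subject>_run-<r>_timeseries.tsv` per run; `manifest.json` records
#' the generative [cohort_spec()] for provenance.
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pair in cohort$runs) {
    for (run in pair) {
      write_timeseries_tsv(
        run, file.path(dir, sprintf("%s_run-%d_timeseries.tsv",
                                    run$subject_id, run$run))
      )
    }
  }
  spec <- cohort$spec
  manifest <- list(
    n_subjects = spec$n_subjects, n_timepoints = spec$n_timepoints,
    k_factors = spec$k_factors, lambda_subject = spec$lambda_subject,
    sigma_run = spec$sigma_run, sigma_obs = spec$sigma_obs,
    coupling = spec$coupling, seed = spec$seed,
    n_rois = spec$parcellation$N,
    spinal_levels = unique(spec$parcellation$labels$level[
      spec$parcellation$labels$tissue != "brain"]),
    n_brain_rois = sum(spec$parcellation$labels$tissue == "brain")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()] (or hand-prepared)
#'
#' @param dir directory containing `<subject>_run-<r>_timeseries.tsv` files
#' @param parcellation optional shared `parcellation`
#' @return list of per-subject `list(run1, run2)` pairs
#' @export
read_cohort <- function(dir, parcellation = NULL) {
  files <- list.files(dir, pattern = "_run-[12]_timeseries\\.tsv$",
                      full.names = TRUE)
  if (!length(files)) stop("no *_run-<r>_timeseries.tsv files in ", dir)
  runs <- lapply(files, read_timeseries_tsv, parcellation = parcellation)
  ids <- vapply(runs, function(r) r$subject_id, character(1))
  out <- lapply(split(runs, ids), function(pair) {
    pair[order(vapply(pair, function(r) r$run, integer(1)))]
  })
  bad <- vapply(out, function(p) length(p) != 2L, logical(1))
  if (any(bad)) {
    stop("subject(s) without exactly two runs: ",
         paste(names(out)[bad], collapse = ", "))
  }
  out[order(names(out))]
}

#' Read a voxel run from NIfTI files plus a TSV ROI lookup
#'
#' Requires the RNifti package. The lookup TSV needs columns `label_int`,
#' `name`, `level`, `tissue`, `region`, `side`.
#'
#' @param func_path 4D functional NIfTI (.nii or .nii.gz)
#' @param roi_path 3D integer-label NIfTI
#' @param lookup_path TSV lookup file
#' @return a [voxel_run()]
#' @export
read_voxel_run_nifti <- function(func_path, roi_path, lookup_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI requires the RNifti package")
  }
  image <- array(as.numeric(RNifti::readNifti(func_path)),
                 dim = dim(RNifti::readNifti(func_path)))
  roi <- RNifti::readNifti(roi_path)
  roi_volume <- array(as.integer(round(roi)), dim = dim(roi))
  lookup <- utils::read.delim(lookup_path, stringsAsFactors = FALSE)
  voxel_run(image, roi_volume, lookup)
}
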