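# Functional-connectivity matrices and their vectorized (edge) forms.

#' Pearson functional-connectivity matrix of a parcelled run
#'
#' Correlates every ROI pair over time. The result is symmetric with unit
#' diagonal. Constant (zero-variance) ROI columns are rejected by name, since
#' their correlation is undefined.
#'
#' @param run a [parcelled_run()] with `T >= 3`
#' @return object of class `fc_matrix` with fields `values` (N x N),
#'   `parcellation`, `subject_id`, `run`
#' @export
compute_fc <- function(run) {
  stopifnot(inherits(run, "parcelled_run"))
  x <- run$data
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant (zero-variance) ROI column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  values <- stats::cor(x)
  values <- (values + t(values)) / 2
  diag(values) <- 1
  structure(
    list(values = values, parcellation = run$parcellation,
         subject_id = run$subject_id, run = run$run),
    class = "fc_matrix"
  )
}

# Strict-upper-triangle edge index in row-major order: (1,2),(1,3),...,(2,3),...
edge_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(row = i, col = j)
}

#' Vectorize a functional-connectivity matrix
#'
#' Unfolds the strict upper triangle into a length `M = N(N-1)/2` vector in
#' row-major edge order. The inverse mapping is [devectorize_fc()].
#'
#' @param fc an `fc_matrix` (or a plain symmetric matrix)
#' @param tol maximum allowed asymmetry
#' @return object of class `fc_vector` with fields `values`, `edge_index`
#'   (M x 2), `edge_names` (`"roiA|roiB"`), `roi_names`, `subject_id`, `run`
#' @export
vectorize_fc <- function(fc, tol = 1e-10) {
  if (inherits(fc, "fc_matrix")) {
    m <- fc$values
    subject_id <- fc$subject_id
    run <- fc$run
  } else {
    m <- as.matrix(fc)
    subject_id <- NA_character_
    run <- NA_integer_
  }
  if (nrow(m) != ncol(m)) stop("FC matrix must be square")
  if (max(abs(m - t(m))) > tol) {
    stop("FC matrix asymmetric beyond tolerance ", format(tol))
  }
  n <- nrow(m)
  idx <- edge_index(n)
  roi_names <- colnames(m)
  if (is.null(roi_names)) roi_names <- sprintf("roi_%03d", seq_len(n))
  structure(
    list(values = m[idx], edge_index = idx,
         edge_names = paste(roi_names[idx[, 1L]], roi_names[idx[, 2L]], sep = "|"),
         roi_names = roi_names, subject_id = subject_id, run = run),
    class = "fc_vector"
  )
}

#' Rebuild the symmetric matrix from an `fc_vector`
#'
#' @param v an `fc_vector`
#' @param diag_value value placed on the diagonal (1 for correlations)
#' @return N x N symmetric matrix with ROI dimnames
#' @export
devectorize_fc <- function(v, diag_value = 1) {
  stopifnot(inherits(v, "fc_vector"))
  n <- length(v$roi_names)
  m <- matrix(diag_value, n, n, dimnames = list(v$roi_names, v$roi_names))
  m[v$edge_index] <- v$values
  m[v$edge_index[, c(2L, 1L)]] <- v$values
  diag(m) <- diag_value
  m
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("FC matrix %s run-%s: %d x %d\n", x$subject_id,
              x$run, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.fc_vector <- function(x, ...) {
  cat(sprintf("FC vector: %d edges (%d ROIs)\n",
              length(x$values), length(x$roi_names)))
  invisible(x)
}

# All runs of a cohort-like list -> per-run fc_vectors, checking edge
# compatibility. `runs` is a list of parcelled_run.
fc_vectors_of_runs <- function(runs, fisher_z = FALSE) {
  vs <- lapply(runs, function(r) {
    v <- vectorize_fc(compute_fc(r))
    if (fisher_z) v$values <- atanh(pmin(pmax(v$values, -1 + 1e-15), 1 - 1e-15))
    v
  })
  check_edge_compatibility(vs)
  vs
}

check_edge_compatibility <- function(vectors) {
  ref <- vectors[[1L]]$edge_names
  for (k in seq_along(vectors)) {
    cur <- vectors[[k]]$edge_names
    if (length(cur) != length(ref) || any(cur != ref)) {
      first <- which(cur != ref)[1L]
      if (is.na(first)) first <- min(length(cur), length(ref)) + 1L
      stop("edge index mismatch at position ", first, ": '",
           if (first <= length(ref)) ref[first] else "<absent>", "' vs '",
           if (first <= length(cur)) cur[first] else "<absent>", "'")
    }
  }
  invisible(TRUE)
}
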