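# Edge-wise ICC(1,1) test-retest reliability maps, cross-level averaging,
# percentile thresholding and nodal strength.

#' One-way random-effects intraclass correlation ICC(1,1)
#'
#' For an Ns x k table (subjects x repeated measurements) the one-way random
#' ANOVA gives the between-subject mean square MSR (df `Ns - 1`) and the
#' within-subject mean square MSW (df `Ns (k - 1)`), and
#' `ICC(1,1) = (MSR - MSW) / (MSR + (k - 1) MSW)`. For k = 2 the value lies in
#' [-1, 1]; negative values are retained. A zero denominator yields `NA`.
#'
#' @param measurements Ns x k numeric matrix, `Ns >= 2`, finite
#' @return ICC value (or `NA` when undefined)
#' @export
icc_1_1 <- function(measurements) {
  x <- as.matrix(measurements)
  ns <- nrow(x)
  k <- ncol(x)
  if (ns < 2L) stop("need at least 2 subjects")
  if (k < 2L) stop("need at least 2 measurements per subject")
  if (!all(is.finite(x))) stop("non-finite measurement values")
  row_means <- rowMeans(x)
  grand <- mean(x)
  msr <- k * sum((row_means - grand)^2) / (ns - 1)
  msw <- sum((x - row_means)^2) / (ns * (k - 1))
  denom <- msr + (k - 1) * msw
  if (denom == 0) return(NA_real_)
  (msr - msw) / denom
}

#' Edge-wise ICC(1,1) map from two run sets
#'
#' Applies [icc_1_1()] independently to every edge, using each subject's
#' run-1 and run-2 FC values as the two repeated measurements, and maps the
#' resulting vector back to the symmetric N x N layout (diagonal `NA`).
#'
#' @param run1_vectors,run2_vectors lists of `fc_vector` (one per subject,
#'   matched order and edge index)
#' @return object of class `icc_map`: `values` (N x N), `MSR_map`, `MSW_map`,
#'   `k = 2`, `roi_names`, `parcellation` (when available)
#' @export
icc_matrix <- function(run1_vectors, run2_vectors) {
  ns <- length(run1_vectors)
  if (ns < 2L || length(run2_vectors) != ns) {
    stop("need the same number (>= 2) of run-1 and run-2 vectors")
  }
  check_edge_compatibility(c(run1_vectors, run2_vectors))
  m_edges <- length(run1_vectors[[1L]]$values)
  x1 <- vapply(run1_vectors, function(v) v$values, numeric(m_edges))
  x2 <- vapply(run2_vectors, function(v) v$values, numeric(m_edges))
  # Vectorized one-way ANOVA across edges, k = 2.
  pair_mean <- (x1 + x2) / 2
  grand <- rowMeans(cbind(x1, x2))
  msr <- 2 * rowSums((pair_mean - grand)^2) / (ns - 1)
  msw <- rowSums((x1 - pair_mean)^2 + (x2 - pair_mean)^2) / ns
  denom <- msr + msw
  icc <- ifelse(denom == 0, NA_real_, (msr - msw) / denom)
  ref <- run1_vectors[[1L]]
  to_mat <- function(vals) {
    n <- length(ref$roi_names)
    m <- matrix(NA_real_, n, n, dimnames = list(ref$roi_names, ref$roi_names))
    m[ref$edge_index] <- vals
    m[ref$edge_index[, c(2L, 1L)]] <- vals
    m
  }
  structure(
    list(values = to_mat(icc), MSR_map = to_mat(msr), MSW_map = to_mat(msw),
         k = 2L, roi_names = ref$roi_names),
    class = "icc_map"
  )
}

#' @export
print.icc_map <- function(x, ...) {
  v <- x$values[upper.tri(x$values)]
  cat(sprintf("ICC(1,1) map: %d ROIs, %d edges; mean %.3f, max %.3f\n",
              nrow(x$values), sum(!is.na(v)), mean(v, na.rm = TRUE),
              max(v, na.rm = TRUE)))
  invisible(x)
}

# Match rows of a spinal parcellation's labels to the canonical cross-section
# positions for one level; returns indices in canonical order.
.level_indices <- function(labels, level, scheme) {
  key <- paste(scheme$region, scheme$side)
  at_level <- which(labels$level == level)
  lab_key <- paste(labels$region[at_level], labels$side[at_level])
  pos <- match(key, lab_key)
  if (anyNA(pos)) {
    stop("level ", level, " lacks canonical cross-section ROI(s): ",
         paste(key[is.na(pos)], collapse = ", "))
  }
  at_level[pos]
}

#' Average within-level 14 x 14 cross-sectional ICC blocks
#'
#' From each spinal ICC map, the within-level 14 x 14 diagonal blocks are
#' extracted in canonical cross-section order and averaged elementwise across
#' all levels and all maps; undefined (`NA`) entries are excluded from each
#' elementwise mean. Between-level edges do not contribute.
#'
#' @param icc_maps list of `icc_map` objects built on spinal parcellations
#' @param parcellations matching list of `parcellation` objects (one per map)
#' @return 14 x 14 matrix with `region_side` dimnames
#' @export
average_level_blocks <- function(icc_maps, parcellations) {
  if (inherits(icc_maps, "icc_map")) icc_maps <- list(icc_maps)
  if (inherits(parcellations, "parcellation")) parcellations <- list(parcellations)
  stopifnot(length(icc_maps) == length(parcellations))
  scheme <- cross_section_scheme()
  acc <- matrix(0, 14L, 14L)
  cnt <- matrix(0L, 14L, 14L)
  for (m in seq_along(icc_maps)) {
    parc <- parcellations[[m]]
    labels <- parc$labels
    spinal_levels_here <- unique(labels$level[labels$level != "brain"])
    if (!length(spinal_levels_here)) stop("parcellation has no spinal levels")
    for (lv in spinal_levels_here) {
      idx <- .level_indices(labels, lv, scheme)
      block <- icc_maps[[m]]$values[idx, idx, drop = FALSE]
      ok <- !is.na(block)
      acc[ok] <- acc[ok] + block[ok]
      cnt <- cnt + ok
    }
  }
  out <- ifelse(cnt > 0, acc / cnt, NA_real_)
  nm <- paste(scheme$region, scheme$side, sep = "_")
  dimnames(out) <- list(nm, nm)
  out
}

#' Threshold a symmetric edge map at a percentile
#'
#' The threshold is the given percentile of the defined strict-upper-triangle
#' entries (each edge counted once); entries below it are set to zero, entries
#' at or above it are retained. `NA` entries stay `NA`.
#'
#' @param mat symmetric N x N matrix (e.g. an ICC map's `values`)
#' @param pct percentile in (0, 100), default 95
#' @return list: `threshold`, `filtered` (symmetric N x N)
#' @export
threshold_percentile <- function(mat, pct = 95) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == ncol(mat))
  if (!(pct > 0 && pct < 100)) stop("`pct` must be in (0, 100)")
  vals <- mat[upper.tri(mat)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("all edges undefined; nothing to threshold")
  thr <- stats::quantile(vals, pct / 100, names = FALSE, type = 7)
  filtered <- mat
  filtered[!is.na(mat) & mat < thr] <- 0
  diag(filtered) <- diag(mat)
  list(threshold = thr, filtered = filtered)
}

#' Nodal strength of a (filtered) edge map
#'
#' Per-ROI reduction of the symmetric edge matrix across one axis, excluding
#' the diagonal; `"sum"` (default) sums retained edge values, `"mean"`
#' averages them.
#'
#' @param mat symmetric N x N matrix
#' @param reduce `"sum"` or `"mean"`
#' @return named length-N vector
#' @export
nodal_strength <- function(mat, reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == ncol(mat))
  diag(mat) <- NA_real_
  out <- apply(mat, 1L, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) return(0)
    if (reduce == "sum") sum(r) else mean(r)
  })
  names(out) <- rownames(mat)
  out
}
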