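# ROI label schemes for the cervical spinal cord cross-section and the brain,
# robust-mean parcel extraction from voxel data, and tSNR.

#' Recognized cervical spinal level tags
#' @export
spinal_levels <- function() paste0("C", 2:8)

# Canonical cross-section: gray matter (dorsal horn, intermediate zone,
# ventral horn) then white matter (corticospinal tract, fasciculus cuneatus,
# fasciculus gracilis, spinal lemniscus), each bilateral L then R.
.gm_regions <- c("dh", "iz", "vh")
.wm_regions <- c("cst", "fc", "fg", "sl")

#' Canonical 14-region spinal cross-section scheme
#'
#' Returns the ordered region/side/tissue layout used within every spinal
#' level: 6 bilateral gray-matter ROIs (dorsal horn `dh`, intermediate zone
#' `iz`, ventral horn `vh`) followed by 8 bilateral white-matter ROIs
#' (corticospinal tract `cst`, fasciculus cuneatus `fc`, fasciculus gracilis
#' `fg`, spinal lemniscus `sl`), each left then right.
#'
#' @return data.frame with columns `region`, `side`, `tissue` (14 rows)
#' @export
cross_section_scheme <- function() {
  regions <- c(.gm_regions, .wm_regions)
  tissue <- c(rep("GM", length(.gm_regions)), rep("WM", length(.wm_regions)))
  data.frame(
    region = rep(regions, each = 2L),
    side = rep(c("L", "R"), times = length(regions)),
    tissue = rep(tissue, each = 2L),
    stringsAsFactors = FALSE
  )
}

.new_parcellation <- function(labels, n_levels) {
  stopifnot(!anyDuplicated(labels$name))
  structure(
    list(labels = labels, n_levels = n_levels, N = nrow(labels)),
    class = "parcellation"
  )
}

#' Build a spinal cord parcellation from a list of levels
#'
#' Each level contributes the canonical 14 cross-sectional ROIs (see
#' [cross_section_scheme()]), so `N = 14 * length(levels)`: C4-C6 gives 42
#' ROIs, C4-C8 gives 70, C2-C8 gives 98. ROI names are `<level>_<region>_<side>`.
#'
#' @param levels character vector of level tags, subset of `C2`..`C8`,
#'   no duplicates; order is preserved
#' @param scheme optional permutation of [cross_section_scheme()] to change
#'   the within-level ROI order
#' @return object of class `parcellation`
#' @export
build_spinal_parcellation <- function(levels, scheme = cross_section_scheme()) {
  if (length(levels) == 0L) stop("`levels` must be non-empty")
  bad <- setdiff(levels, spinal_levels())
  if (length(bad)) {
    stop("unknown spinal level tag(s): ", paste(bad, collapse = ", "),
         " (expected C2..C8)")
  }
  if (anyDuplicated(levels)) stop("duplicate spinal level tags")
  stopifnot(is.data.frame(scheme), nrow(scheme) == 14L,
            all(c("region", "side", "tissue") %in% names(scheme)))
  labels <- do.call(rbind, lapply(levels, function(lv) {
    data.frame(
      name = paste(lv, scheme$region, scheme$side, sep = "_"),
      level = lv, tissue = scheme$tissue, region = scheme$region,
      side = scheme$side, stringsAsFactors = FALSE
    )
  }))
  .new_parcellation(labels, n_levels = length(levels))
}

#' Build a brain parcellation
#'
#' Default size 119 mirrors a 100-region cortical atlas complemented by 19
#' subcortical areas. Brain ROIs carry no level/side structure.
#'
#' @param n number of brain ROIs
#' @param names optional ROI names (length `n`, unique)
#' @return object of class `parcellation`
#' @export
build_brain_parcellation <- function(n = 119L, names = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer")
  if (is.null(names)) names <- sprintf("brain_%03d", seq_len(n))
  if (length(names) != n || anyDuplicated(names)) {
    stop("`names` must be ", n, " unique strings")
  }
  labels <- data.frame(
    name = names, level = "brain", tissue = "brain", region = "brain",
    side = NA_character_, stringsAsFactors = FALSE
  )
  .new_parcellation(labels, n_levels = 0L)
}

#' Concatenate two parcellations (e.g. brain block + spine block)
#' @param a,b parcellation objects; ROI names must not collide
#' @return combined `parcellation`
#' @export
combine_parcellations <- function(a, b) {
  stopifnot(inherits(a, "parcellation"), inherits(b, "parcellation"))
  labels <- rbind(a$labels, b$labels)
  if (anyDuplicated(labels$name)) stop("ROI names collide across parcellations")
  .new_parcellation(labels, n_levels = a$n_levels + b$n_levels)
}

#' @export
print.parcellation <- function(x, ...) {
  cat("Parcellation:", x$N, "ROIs")
  if (x$n_levels > 0L) cat(" (", x$n_levels, " spinal level(s))", sep = "")
  cat("\n")
  invisible(x)
}

# Indices of the brain and spinal blocks of a (possibly combined) parcellation.
parcel_blocks <- function(parcellation) {
  is_brain <- parcellation$labels$tissue == "brain"
  list(brain = which(is_brain), spine = which(!is_brain))
}

#' A parcelled run: one subject/run time-series table
#'
#' @param data T x N numeric matrix (rows = time points, columns = ROIs)
#' @param parcellation matching `parcellation` (N columns)
#' @param subject_id subject identifier
#' @param run run index, 1 or 2
#' @return object of class `parcelled_run`
#' @export
parcelled_run <- function(data, parcellation, subject_id, run) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  stopifnot(inherits(parcellation, "parcellation"))
  if (ncol(data) != parcellation$N) {
    stop("data has ", ncol(data), " columns but parcellation has ",
         parcellation$N, " ROIs")
  }
  if (nrow(data) < 3L) stop("need at least 3 time points, got ", nrow(data))
  if (!all(is.finite(data))) stop("non-finite values in time series")
  run <- as.integer(run)
  if (!run %in% c(1L, 2L)) stop("`run` must be 1 or 2")
  colnames(data) <- parcellation$labels$name
  structure(
    list(subject_id = as.character(subject_id), run = run,
         data = data, parcellation = parcellation),
    class = "parcelled_run"
  )
}

#' @export
print.parcelled_run <- function(x, ...) {
  cat(sprintf("ParcelledRun %s run-%d: %d time points x %d ROIs\n",
              x$subject_id, x$run, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' A voxel-level run: 4D signal, integer ROI labels, and a lookup table
#'
#' @param image X x Y x Z x T numeric array
#' @param roi_volume X x Y x Z integer array of ROI labels (0 = background)
#' @param lookup data.frame with columns `label_int`, `name`, `level`,
#'   `tissue`, `region`, `side`; every listed ROI must own at least one voxel
#' @return object of class `voxel_run`
#' @export
voxel_run <- function(image, roi_volume, lookup) {
  stopifnot(length(dim(image)) == 4L, length(dim(roi_volume)) == 3L)
  if (!identical(dim(image)[1:3], dim(roi_volume)[1:3])) {
    stop("image and roi_volume spatial dimensions differ")
  }
  req <- c("label_int", "name", "level", "tissue", "region", "side")
  if (!all(req %in% names(lookup))) {
    stop("lookup must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(lookup$label_int) || anyDuplicated(lookup$name)) {
    stop("duplicate label_int or name in lookup")
  }
  present <- unique(as.vector(roi_volume))
  missing <- setdiff(lookup$label_int, present)
  if (length(missing)) {
    stop("ROI(s) with no voxels in roi_volume: ",
         paste(lookup$name[lookup$label_int %in% missing], collapse = ", "))
  }
  structure(list(image = image, roi_volume = roi_volume,
                 lookup = lookup[order(lookup$label_int), , drop = FALSE]),
            class = "voxel_run")
}

# Trimmed mean of one voxel-value vector: keep values within the
# [lower, upper] percentile band (linear-interpolation quantiles); fall back
# to the plain mean when trimming would discard everything.
.robust_mean <- function(v, lower_pct, upper_pct) {
  if (length(v) == 1L) return(v)
  q <- stats::quantile(v, c(lower_pct, upper_pct) / 100, names = FALSE, type = 7)
  keep <- v >= q[1] & v <= q[2]
  if (!any(keep)) return(mean(v))
  mean(v[keep])
}

#' Extract robust-mean parcel time series from voxel data
#'
#' For each ROI and each time point, voxel values are averaged with a robust
#' mean that keeps only values lying between the `lower_pct` and `upper_pct`
#' percentiles of that ROI's voxel-value distribution at that time point.
#' Single-voxel ROIs (or any trim that would empty the set) fall back to the
#' plain mean.
#'
#' @param voxrun a [voxel_run()]
#' @param lower_pct,upper_pct trim percentiles, `0 <= lower < upper <= 100`
#' @param subject_id,run metadata for the resulting [parcelled_run()]
#' @return a `parcelled_run` whose ROI order follows the lookup table
#' @export
robust_parcel_mean <- function(voxrun, lower_pct = 5, upper_pct = 95,
                               subject_id = "unknown", run = 1L) {
  stopifnot(inherits(voxrun, "voxel_run"))
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100)) {
    stop("require 0 <= lower_pct < upper_pct <= 100")
  }
  dims <- dim(voxrun$image)
  T_len <- dims[4]
  flat <- matrix(voxrun$image, nrow = prod(dims[1:3]), ncol = T_len)
  roi_flat <- as.vector(voxrun$roi_volume)
  lk <- voxrun$lookup
  out <- matrix(NA_real_, nrow = T_len, ncol = nrow(lk))
  for (j in seq_len(nrow(lk))) {
    vox <- which(roi_flat == lk$label_int[j])
    if (!length(vox)) stop("ROI has no voxels: ", lk$name[j])
    block <- flat[vox, , drop = FALSE]
    out[, j] <- apply(block, 2L, .robust_mean, lower_pct, upper_pct)
  }
  parc <- .new_parcellation(
    lk[, c("name", "level", "tissue", "region", "side")],
    n_levels = length(unique(lk$level[lk$level != "brain"]))
  )
  parcelled_run(out, parc, subject_id, run)
}

#' Voxelwise temporal signal-to-noise ratio
#'
#' tSNR is the temporal mean divided by the temporal standard deviation
#' (population denominator). Voxels with zero temporal variance yield `NA`.
#'
#' @param x a [voxel_run()] or an X x Y x Z x T array
#' @return X x Y x Z array of tSNR values
#' @export
compute_tsnr <- function(x) {
  image <- if (inherits(x, "voxel_run")) x$image else x
  stopifnot(length(dim(image)) == 4L)
  dims <- dim(image)
  if (dims[4] < 2L) stop("need at least 2 time points")
  flat <- matrix(image, nrow = prod(dims[1:3]), ncol = dims[4])
  mu <- rowMeans(flat)
  sd_pop <- sqrt(rowMeans((flat - mu)^2))
  tsnr <- ifelse(sd_pop > 0, mu / sd_pop, NA_real_)
  array(tsnr, dim = dims[1:3])
}
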