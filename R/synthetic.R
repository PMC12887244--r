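# Seeded synthetic two-run cohorts of parcelled time series with controllable
# subject distinctiveness (lambda_subject), run-level covariance perturbation
# (sigma_run), observation noise (sigma_obs) and optional brain->spine shared
# signal (coupling).

# Deterministic substream seed for (entity, purpose) counters, so that adding
# subjects never changes earlier subjects' draws. Doubles are exact here
# (values stay far below 2^53); result fits in a 32-bit seed.
.subseed <- function(seed, entity, purpose) {
  s <- (as.double(seed) %% 2147483647) * 69621 +
    as.double(entity) * 131071 + as.double(purpose) * 7919 + 1
  as.integer(s %% 2147483647)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic two-run cohort
#'
#' The generative model is a Gaussian latent-factor construction: subject i
#' has loading matrix `A_i = A_group + lambda_subject * B_i` (entries standard
#' normal) and target covariance `C_i = A_i A_i' + sigma_obs^2 I`, positive
#' definite by construction. Each run perturbs `C_i` by a symmetrized random
#' matrix scaled by `sigma_run` (eigenvalues floored at 1e-6 of the leading
#' eigenvalue), then draws `T` time points from the corresponding zero-mean
#' multivariate normal. With a combined brain+spine parcellation and
#' `coupling > 0`, a shared latent signal with subject-specific loadings
#' drives the brain block and, weighted by `coupling`, the spine block — so
#' regressing brain out of spine removes identifiable spinal variance.
#'
#' @param n_subjects number of subjects (two runs each)
#' @param parcellation [build_spinal_parcellation()] output, optionally
#'   combined with a brain block
#' @param n_timepoints time points per run (a warning is issued when
#'   `n_timepoints <= N`)
#' @param k_factors latent dimension of the loading matrices
#' @param lambda_subject subject-effect scale, >= 0; 0 makes all subjects
#'   exchangeable
#' @param sigma_run run-level covariance perturbation scale, >= 0
#' @param sigma_obs observation-noise scale, > 0
#' @param coupling brain->spine shared-signal weight in [0, 1]
#' @param seed integer seed; fully determines the cohort
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_subjects = 15L,
                        parcellation = build_spinal_parcellation(c("C4", "C5", "C6")),
                        n_timepoints = 300L,
                        k_factors = 5L,
                        lambda_subject = 1,
                        sigma_run = 0.3,
                        sigma_obs = 1,
                        coupling = 0,
                        seed = 1L) {
  stopifnot(inherits(parcellation, "parcellation"))
  n_subjects <- as.integer(n_subjects)
  n_timepoints <- as.integer(n_timepoints)
  k_factors <- as.integer(k_factors)
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (n_timepoints < 3L) stop("need at least 3 time points")
  if (k_factors < 1L) stop("k_factors must be >= 1")
  if (!is.finite(lambda_subject) || lambda_subject < 0) stop("lambda_subject must be finite and >= 0")
  if (!is.finite(sigma_run) || sigma_run < 0) stop("sigma_run must be finite and >= 0")
  if (!is.finite(sigma_obs) || sigma_obs <= 0) stop("sigma_obs must be finite and > 0")
  if (!is.finite(coupling) || coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  if (n_timepoints <= parcellation$N) {
    warning("n_timepoints <= number of ROIs; FC estimates will be rank-deficient")
  }
  structure(
    list(n_subjects = n_subjects, parcellation = parcellation,
         n_timepoints = n_timepoints, k_factors = k_factors,
         lambda_subject = lambda_subject, sigma_run = sigma_run,
         sigma_obs = sigma_obs, coupling = coupling,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Per-subject target covariance matrices
#'
#' `C_i = A_i A_i' + sigma_obs^2 I` with `A_i = A_group + lambda_subject *
#' B_i`; `A_group` is drawn once per cohort, `B_i` from each subject's own
#' substream. All outputs are symmetric positive definite.
#'
#' @param spec a [cohort_spec()]
#' @return list of N x N covariance matrices, one per subject
#' @export
generate_subject_covariances <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$parcellation$N
  k <- spec$k_factors
  blocks <- parcel_blocks(spec$parcellation)
  # Brain and spine blocks get independent latent factors so the base
  # covariance is block-diagonal: cross-block dependence enters only through
  # the explicit coupling latent in generate_cohort().
  block_idx <- Filter(length, blocks)
  if (!length(block_idx)) block_idx <- list(all = seq_len(n))
  a_group <- lapply(seq_along(block_idx), function(b) {
    .with_seed(.subseed(spec$seed, 0L, 30L + b),
               matrix(stats::rnorm(length(block_idx[[b]]) * k),
                      length(block_idx[[b]]), k))
  })
  lapply(seq_len(spec$n_subjects), function(i) {
    cov <- matrix(0, n, n)
    for (b in seq_along(block_idx)) {
      idx <- block_idx[[b]]
      b_i <- .with_seed(.subseed(spec$seed, i, 30L + b),
                        matrix(stats::rnorm(length(idx) * k), length(idx), k))
      a_i <- a_group[[b]] + spec$lambda_subject * b_i
      cov[idx, idx] <- tcrossprod(a_i)
    }
    cov <- cov + spec$sigma_obs^2 * diag(n)
    (cov + t(cov)) / 2
  })
}

#' Draw one run's time series from a perturbed subject covariance
#'
#' The run covariance is `C + sigma_run * (S + S')/2` with `S` standard
#' normal, projected to the nearest positive-definite matrix by flooring
#' eigenvalues at 1e-6 of the leading eigenvalue; `T` rows are then drawn from
#' the zero-mean multivariate normal with that covariance.
#'
#' @param cov N x N subject covariance
#' @param n_timepoints number of rows to draw
#' @param sigma_run perturbation scale
#' @param seed substream seed for this draw
#' @return T x N numeric matrix
#' @export
sample_run_timeseries <- function(cov, n_timepoints, sigma_run, seed) {
  n <- nrow(cov)
  .with_seed(seed, {
    cov_r <- cov
    if (sigma_run > 0) {
      s <- matrix(stats::rnorm(n * n), n, n)
      cov_r <- cov + sigma_run * (s + t(s)) / 2
    }
    e <- eigen(cov_r, symmetric = TRUE)
    floor_val <- 1e-6 * max(e$values)
    vals <- pmax(e$values, floor_val)
    z <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n)
    z %*% t(e$vectors %*% diag(sqrt(vals), n))
  })
}

#' Generate a full synthetic two-run cohort
#'
#' Composes [generate_subject_covariances()] and [sample_run_timeseries()]
#' per subject/run. When the parcellation contains both brain and spine
#' blocks and `coupling > 0`, a per-run latent signal with subject-specific
#' loadings is added to the brain block and, scaled by `coupling`, to the
#' spine block.
#'
#' @param spec a [cohort_spec()]
#' @return object of class `synthetic_cohort`: `runs` (list of subjects, each
#'   a list of two [parcelled_run()]), `true_covariances`, `spec`
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  covs <- generate_subject_covariances(spec)
  blocks <- parcel_blocks(spec$parcellation)
  couple <- spec$coupling > 0 && length(blocks$brain) > 0 && length(blocks$spine) > 0
  n <- spec$parcellation$N
  k <- spec$k_factors
  if (couple) {
    g_group_br <- .with_seed(.subseed(spec$seed, 0L, 2L),
                             matrix(stats::rnorm(length(blocks$brain) * k),
                                    length(blocks$brain), k))
    g_group_sp <- .with_seed(.subseed(spec$seed, 0L, 3L),
                             matrix(stats::rnorm(length(blocks$spine) * k),
                                    length(blocks$spine), k))
  }
  runs <- lapply(seq_len(spec$n_subjects), function(i) {
    sid <- sprintf("sub-%02d", i)
    if (couple) {
      h_br <- .with_seed(.subseed(spec$seed, i, 2L),
                         matrix(stats::rnorm(length(blocks$brain) * k),
                                length(blocks$brain), k))
      h_sp <- .with_seed(.subseed(spec$seed, i, 3L),
                         matrix(stats::rnorm(length(blocks$spine) * k),
                                length(blocks$spine), k))
      g_br <- g_group_br + spec$lambda_subject * h_br
      g_sp <- g_group_sp + spec$lambda_subject * h_sp
    }
    lapply(1:2, function(r) {
      x <- sample_run_timeseries(covs[[i]], spec$n_timepoints, spec$sigma_run,
                                 .subseed(spec$seed, i, 10L + r))
      if (couple) {
        latent <- .with_seed(.subseed(spec$seed, i, 20L + r),
                             matrix(stats::rnorm(spec$n_timepoints * k),
                                    spec$n_timepoints, k))
        x[, blocks$brain] <- x[, blocks$brain] + latent %*% t(g_br)
        x[, blocks$spine] <- x[, blocks$spine] + spec$coupling * latent %*% t(g_sp)
      }
      parcelled_run(x, spec$parcellation, sid, r)
    })
  })
  names(runs) <- sprintf("sub-%02d", seq_len(spec$n_subjects))
  structure(list(runs = runs, true_covariances = covs, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d subjects x 2 runs, %d ROIs, ",
                     "%d time points (seed %d)\n"),
              x$spec$n_subjects, x$spec$parcellation$N,
              x$spec$n_timepoints, x$spec$seed))
  invisible(x)
}

# Split a cohort into the two ordered run lists used by the fingerprint stage.
cohort_run_lists <- function(cohort) {
  list(run1 = lapply(cohort$runs, `[[`, 1L),
       run2 = lapply(cohort$runs, `[[`, 2L))
}

#' Fingerprint a cohort of parcelled runs end to end
#'
#' Computes FC, vectorizes, and runs the fingerprint analysis on a
#' [generate_cohort()] result (or any list of per-subject two-run lists),
#' optionally restricted to the brain or spine block.
#'
#' @param cohort a `synthetic_cohort` or list of `list(run1, run2)` pairs
#' @param block `"all"`, `"brain"` or `"spine"`
#' @param k_max top-K curve extent
#' @return an `identifiability_result`
#' @export
fingerprint_cohort <- function(cohort, block = c("all", "brain", "spine"),
                               k_max = 5L) {
  block <- match.arg(block)
  runs <- if (inherits(cohort, "synthetic_cohort")) cohort$runs else cohort
  if (block != "all") {
    runs <- lapply(runs, function(pair) lapply(pair, subset_block, block))
  }
  rl <- list(run1 = lapply(runs, `[[`, 1L), run2 = lapply(runs, `[[`, 2L))
  fingerprint(fc_vectors_of_runs(rl$run1), fc_vectors_of_runs(rl$run2),
              k_max = k_max)
}

# Restrict a parcelled run to its brain or spine block.
subset_block <- function(run, block = c("brain", "spine")) {
  block <- match.arg(block)
  idx <- parcel_blocks(run$parcellation)[[block]]
  if (!length(idx)) stop("parcellation has no ", block, " block")
  labels <- run$parcellation$labels[idx, , drop = FALSE]
  sub_parc <- .new_parcellation(
    labels,
    n_levels = length(unique(labels$level[labels$level != "brain"]))
  )
  parcelled_run(run$data[, idx, drop = FALSE], sub_parc,
                run$subject_id, run$run)
}
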