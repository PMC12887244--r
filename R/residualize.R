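# Linear removal of shared variance between brain and spinal time series,
# and fingerprinting of the residuals.

#' Least-squares residualization of one time-series block on another
#'
#' Columns of `Y` (targets) and `X` (predictors) share the time axis and are
#' demeaned; `beta` is the minimum-norm least-squares solution of
#' `Y ~ X beta`, computed by SVD pseudoinverse so rank-deficient predictor
#' sets remain well defined. Fitted values have the column means of `Y` added
#' back, so `Y = fitted + residuals` holds exactly; each residual column is
#' orthogonal to every demeaned predictor column. A warning is issued when
#' the predictor count reaches the number of time points (perfect-fit
#' regime: residuals are numerically zero and carry no signal).
#'
#' @param Y T x N_target matrix (dependent block)
#' @param X T x N_pred matrix (predictor block), same `T`
#' @param direction optional tag, e.g. `"spine_given_brain"`
#' @return object of class `regression_result`: `beta` (N_pred x N_target),
#'   `fitted`, `residuals`, `direction`
#' @export
fit_linear_model <- function(Y, X, direction = NA_character_) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) {
    stop("Y has ", nrow(Y), " time points but X has ", nrow(X))
  }
  if (nrow(Y) < 2L) stop("need at least 2 time points")
  if (ncol(X) >= nrow(X)) {
    warning("predictor count (", ncol(X), ") >= time points (", nrow(X),
            "): perfect-fit regime, residuals will vanish")
  }
  y_mean <- colMeans(Y)
  x_mean <- colMeans(X)
  yc <- sweep(Y, 2L, y_mean)
  xc <- sweep(X, 2L, x_mean)
  sv <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * max(sv$d, 0)
  d_inv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  beta <- sv$v %*% (d_inv * crossprod(sv$u, yc))
  fitted_c <- xc %*% beta
  residuals <- yc - fitted_c
  fitted <- sweep(fitted_c, 2L, y_mean, `+`)
  dimnames(beta) <- list(colnames(X), colnames(Y))
  dimnames(residuals) <- dimnames(Y)
  structure(
    list(beta = beta, fitted = fitted, residuals = residuals,
         direction = direction),
    class = "regression_result"
  )
}

#' Residualize one block of a combined brain+spine run on the other
#'
#' @param run a [parcelled_run()] whose parcellation contains both blocks
#' @param direction `"spine_given_brain"` (brain regressed out of spine) or
#'   `"brain_given_spine"`
#' @return a `parcelled_run` of residual time series restricted to the target
#'   block
#' @export
residualize_run <- function(run,
                            direction = c("spine_given_brain",
                                          "brain_given_spine")) {
  direction <- match.arg(direction)
  stopifnot(inherits(run, "parcelled_run"))
  blocks <- parcel_blocks(run$parcellation)
  if (!length(blocks$brain) || !length(blocks$spine)) {
    stop("run must contain both a brain and a spine block")
  }
  target <- if (direction == "spine_given_brain") "spine" else "brain"
  predictor <- if (target == "spine") "brain" else "spine"
  fit <- fit_linear_model(run$data[, blocks[[target]], drop = FALSE],
                          run$data[, blocks[[predictor]], drop = FALSE],
                          direction = direction)
  if (max(abs(fit$residuals)) < 1e-10) {
    stop("residuals are numerically zero (degenerate predictor block); ",
         "no residual signal to fingerprint")
  }
  target_run <- subset_block(run, target)
  parcelled_run(fit$residuals, target_run$parcellation,
                run$subject_id, run$run)
}

#' Fingerprint the residual block of a combined cohort
#'
#' For every subject and run independently, the target block is regressed on
#' the predictor block ([fit_linear_model()]), FC is computed on the
#' residual time series, and the fingerprint analysis is run on the residual
#' FC profiles — quantifying the identifiable variance not linearly explained
#' by the other block.
#'
#' @param cohort a `synthetic_cohort` or list of per-subject `list(run1,
#'   run2)` pairs with combined parcellations
#' @param direction `"spine_given_brain"` or `"brain_given_spine"`
#' @param k_max top-K curve extent
#' @return an `identifiability_result`
#' @export
residual_fingerprint <- function(cohort,
                                 direction = c("spine_given_brain",
                                               "brain_given_spine"),
                                 k_max = 5L) {
  direction <- match.arg(direction)
  runs <- if (inherits(cohort, "synthetic_cohort")) cohort$runs else cohort
  resid_runs <- lapply(runs, function(pair) {
    lapply(pair, residualize_run, direction = direction)
  })
  fingerprint_cohort(resid_runs, block = "all", k_max = k_max)
}
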