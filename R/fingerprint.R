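# Identifiability matrix and fingerprint statistics: Iself, Iothers, Idiff,
# Cohen's d, identification accuracy, top-K accuracy.

#' Identifiability matrix between run-1 and run-2 FC profiles
#'
#' `I[i, j]` is the Pearson correlation between subject i's run-1 vectorized
#' FC profile and subject j's run-2 profile; rows index run 1, columns run 2.
#' The matrix is asymmetric because runs 1 and 2 are ordered sets.
#'
#' @param run1_vectors,run2_vectors lists of `fc_vector`, equal length
#'   (`Ns >= 2`), identical edge indices throughout
#' @param subject_ids optional subject identifiers (taken from the run-1
#'   vectors when present)
#' @return Ns x Ns matrix with subject dimnames
#' @export
identifiability_matrix <- function(run1_vectors, run2_vectors,
                                   subject_ids = NULL) {
  ns <- length(run1_vectors)
  if (ns < 2L || length(run2_vectors) != ns) {
    stop("need the same number (>= 2) of run-1 and run-2 vectors")
  }
  check_edge_compatibility(c(run1_vectors, run2_vectors))
  if (is.null(subject_ids)) {
    subject_ids <- vapply(run1_vectors, function(v) v$subject_id, character(1))
    if (anyNA(subject_ids) || anyDuplicated(subject_ids)) {
      subject_ids <- sprintf("sub-%02d", seq_len(ns))
    }
  }
  v1 <- vapply(run1_vectors, function(v) v$values,
               numeric(length(run1_vectors[[1L]]$values)))
  v2 <- vapply(run2_vectors, function(v) v$values,
               numeric(length(run2_vectors[[1L]]$values)))
  I <- stats::cor(v1, v2)
  dimnames(I) <- list(run1 = subject_ids, run2 = subject_ids)
  I
}

.check_square <- function(I) {
  I <- as.matrix(I)
  if (nrow(I) != ncol(I)) stop("identifiability matrix must be square")
  if (nrow(I) < 2L) stop("need at least 2 subjects")
  I
}

#' Iself, Iothers and the identifiability differential Idiff
#'
#' `Iself` is the mean of the diagonal (within-subject similarity), `Iothers`
#' the mean of all off-diagonal entries (both triangles, since the matrix is
#' asymmetric), and `Idiff = Iself - Iothers`.
#'
#' @param I identifiability matrix
#' @return named list: `Iself`, `Iothers`, `Idiff`
#' @export
idiff <- function(I) {
  I <- .check_square(I)
  d <- diag(I)
  off <- I[row(I) != col(I)]
  list(Iself = mean(d), Iothers = mean(off), Idiff = mean(d) - mean(off))
}

#' Cohen's d between self- and other-similarity distributions
#'
#' `d = (Iself - Iothers) / sqrt((var_self + var_others) / 2)` with sample
#' variances (denominator n-1) over the diagonal and off-diagonal entries.
#' Returns `NA` with a warning when both variances are zero.
#'
#' @param I identifiability matrix (`Ns >= 2`)
#' @return effect size in standard-deviation units
#' @export
cohens_d <- function(I) {
  I <- .check_square(I)
  d <- diag(I)
  off <- I[row(I) != col(I)]
  v_self <- stats::var(d)
  v_others <- stats::var(off)
  pooled <- (v_self + v_others) / 2
  if (pooled == 0) {
    warning("zero variance in both similarity sets; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(d) - mean(off)) / sqrt(pooled)
}

#' Identification success rate
#'
#' A subject is correctly identified when the strict maximum of their row of
#' the identifiability matrix lies on the diagonal. An exact tie involving the
#' diagonal counts as a failure (with a warning), keeping the count
#' deterministic.
#'
#' @param I identifiability matrix
#' @return list: `success_count`, `accuracy` (percent, unrounded),
#'   `accuracy_label` (rounded to one decimal, e.g. `"66.7%"`)
#' @export
success_rate <- function(I) {
  I <- .check_square(I)
  ns <- nrow(I)
  tied <- FALSE
  wins <- vapply(seq_len(ns), function(i) {
    self <- I[i, i]
    best_other <- max(I[i, -i])
    if (self == best_other) tied <<- TRUE
    self > best_other
  }, logical(1))
  if (tied) warning("exact tie at a row maximum; counted as failure")
  count <- sum(wins)
  acc <- 100 * count / ns
  list(success_count = count, accuracy = acc,
       accuracy_label = paste0(formatC(round(acc, 1), format = "f", digits = 1), "%"))
}

#' Top-K identification accuracy curve
#'
#' For each K, the percentage of subjects whose diagonal entry ranks within
#' the K largest values of their row (descending order, ties broken by lower
#' column index). `K = 1` equals the success rate; `K = Ns` is always 100.
#'
#' @param I identifiability matrix
#' @param k_max largest K to report, `1 <= k_max <= Ns`
#' @return named numeric vector, `topk["k"]` in percent
#' @export
topk_accuracy <- function(I, k_max = 5L) {
  I <- .check_square(I)
  ns <- nrow(I)
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max > ns) stop("`k_max` must be in 1..Ns")
  self_rank <- vapply(seq_len(ns), function(i) {
    ord <- order(-I[i, ], seq_len(ns))
    which(ord == i)
  }, integer(1))
  out <- vapply(seq_len(k_max), function(k) 100 * mean(self_rank <= k), numeric(1))
  names(out) <- as.character(seq_len(k_max))
  out
}

#' Chance-level identification accuracy
#'
#' Under random assignment each of the Ns subjects is identified with
#' probability 1/Ns, so chance accuracy is 100/Ns percent.
#'
#' @param ns number of subjects
#' @param digits rounding for the reported label (one decimal by convention)
#' @return list: `percent` (unrounded), `label` (e.g. `"5.6%"`)
#' @export
chance_level <- function(ns, digits = 1) {
  stopifnot(ns >= 1)
  p <- 100 / ns
  list(percent = p,
       label = paste0(formatC(round(p, digits), format = "f", digits = digits), "%"))
}

#' Full fingerprint analysis of two ordered run sets
#'
#' Convenience wrapper assembling the identifiability matrix and every derived
#' statistic into one result object.
#'
#' @param run1_vectors,run2_vectors lists of `fc_vector`
#' @param k_max top-K curve extent (capped at Ns)
#' @param subject_ids optional subject identifiers
#' @param symmetric if `TRUE`, statistics are averaged over the run1->run2 and
#'   run2->run1 directions (default `FALSE`: row-wise run1->run2 only)
#' @return object of class `identifiability_result`
#' @export
fingerprint <- function(run1_vectors, run2_vectors, k_max = 5L,
                        subject_ids = NULL, symmetric = FALSE) {
  I <- identifiability_matrix(run1_vectors, run2_vectors, subject_ids)
  res <- fingerprint_from_matrix(I, k_max = k_max)
  if (symmetric) {
    res2 <- fingerprint_from_matrix(t(I), k_max = k_max)
    res$accuracy <- (res$accuracy + res2$accuracy) / 2
    res$success_count <- (res$success_count + res2$success_count) / 2
    res$topk <- (res$topk + res2$topk) / 2
    res$symmetric <- TRUE
  }
  res
}

#' Fingerprint statistics from a precomputed identifiability matrix
#' @param I identifiability matrix
#' @param k_max top-K curve extent (capped at Ns)
#' @return object of class `identifiability_result`
#' @export
fingerprint_from_matrix <- function(I, k_max = 5L) {
  I <- .check_square(I)
  ns <- nrow(I)
  k_max <- min(as.integer(k_max), ns)
  ids <- rownames(I)
  if (is.null(ids)) ids <- sprintf("sub-%02d", seq_len(ns))
  stats_id <- idiff(I)
  sr <- success_rate(I)
  structure(
    list(I = I, n_subjects = ns, subject_order = ids,
         Iself = stats_id$Iself, Iothers = stats_id$Iothers,
         Idiff = stats_id$Idiff,
         var_self = stats::var(diag(I)),
         var_others = stats::var(I[row(I) != col(I)]),
         cohens_d = cohens_d(I),
         success_count = sr$success_count, accuracy = sr$accuracy,
         accuracy_label = sr$accuracy_label,
         topk = topk_accuracy(I, k_max),
         chance = chance_level(ns), symmetric = FALSE),
    class = "identifiability_result"
  )
}

#' Reorder an identifiability result by decreasing self-similarity
#'
#' Rows and columns are permuted jointly so the diagonal is in descending
#' order; all summary statistics are invariant under this relabeling.
#'
#' @param result an `identifiability_result`
#' @return reordered `identifiability_result`
#' @export
sort_by_diagonal <- function(result) {
  stopifnot(inherits(result, "identifiability_result"))
  ord <- order(-diag(result$I), seq_len(result$n_subjects))
  result$I <- result$I[ord, ord, drop = FALSE]
  result$subject_order <- result$subject_order[ord]
  result
}

#' @export
print.identifiability_result <- function(x, ...) {
  cat(sprintf("Identifiability over %d subjects\n", x$n_subjects))
  cat(sprintf("  Iself  = %.4f   Iothers = %.4f   Idiff = %.4f\n",
              x$Iself, x$Iothers, x$Idiff))
  cat(sprintf("  Cohen's d = %.2f\n", x$cohens_d))
  cat(sprintf("  accuracy = %s (%g/%d correct, chance %s)\n",
              x$accuracy_label, x$success_count, x$n_subjects, x$chance$label))
  cat("  top-K: ",
      paste(sprintf("K=%s: %.1f%%", names(x$topk), x$topk), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
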