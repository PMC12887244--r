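# Independent brute-force oracles, deliberately written from first principles
# (no calls into the package's own implementations).

# Pearson correlation from the definition: covariance over sd product.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Iself / Iothers / Idiff by explicit loops.
oracle_idiff <- function(I) {
  ns <- nrow(I)
  self <- sum(sapply(seq_len(ns), function(i) I[i, i])) / ns
  off <- c()
  for (i in seq_len(ns)) for (j in seq_len(ns)) if (i != j) off <- c(off, I[i, j])
  list(Iself = self, Iothers = mean(off), Idiff = self - mean(off))
}

# Cohen's d via the two-sample pooled-SD formula, sample variances.
oracle_cohens_d <- function(I) {
  ns <- nrow(I)
  self <- sapply(seq_len(ns), function(i) I[i, i])
  off <- c()
  for (i in seq_len(ns)) for (j in seq_len(ns)) if (i != j) off <- c(off, I[i, j])
  v1 <- sum((self - mean(self))^2) / (length(self) - 1)
  v2 <- sum((off - mean(off))^2) / (length(off) - 1)
  (mean(self) - mean(off)) / sqrt((v1 + v2) / 2)
}

# One-way random ANOVA from raw sums of squares.
oracle_icc_1_1 <- function(x) {
  ns <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  ss_between <- k * sum((rowMeans(x) - grand)^2)
  ss_within <- sum((x - rowMeans(x))^2)
  msr <- ss_between / (ns - 1)
  msw <- ss_within / (ns * (k - 1))
  (msr - msw) / (msr + (k - 1) * msw)
}

# Least-squares coefficients from the normal equations (full-rank X only).
oracle_beta_normal_equations <- function(Y, X) {
  xc <- sweep(X, 2, colMeans(X))
  yc <- sweep(Y, 2, colMeans(Y))
  solve(t(xc) %*% xc, t(xc) %*% yc)
}

# Robust mean by literal percentile filtering of one value vector.
oracle_trimmed_mean <- function(v, lower, upper) {
  q_lo <- quantile(v, lower / 100, type = 7, names = FALSE)
  q_hi <- quantile(v, upper / 100, type = 7, names = FALSE)
  kept <- v[v >= q_lo & v <= q_hi]
  if (!length(kept)) kept <- v
  mean(kept)
}

# Random asymmetric similarity matrix with distinct entries.
random_similarity_matrix <- function(ns) {
  matrix(runif(ns * ns, -1, 1), ns, ns)
}

# Hand-built fc_vector from a plain numeric vector and ROI count.
make_fc_vector <- function(values, n_roi, subject_id = "sub", run = 1L) {
  m <- diag(n_roi)
  idx <- spineprint:::edge_index(n_roi)
  m[idx] <- values
  m[idx[, c(2, 1)]] <- values
  colnames(m) <- rownames(m) <- sprintf("r%02d", seq_len(n_roi))
  v <- vectorize_fc(m)
  v$subject_id <- subject_id
  v$run <- run
  v
}
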