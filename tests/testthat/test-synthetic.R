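small_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 4L,
                   parcellation = build_spinal_parcellation("C4"),
                   n_timepoints = 60L, k_factors = 3L, lambda_subject = 1,
                   sigma_run = 0.2, sigma_obs = 1, coupling = 0, seed = 101L)
  defaults[names(args)] <- args
  do.call(cohort_spec, defaults)
}

test_that("identical specs give bitwise-identical cohorts", {
  c1 <- generate_cohort(small_spec())
  c2 <- generate_cohort(small_spec())
  expect_identical(lapply(c1$runs, function(p) lapply(p, `[[`, "data")),
                   lapply(c2$runs, function(p) lapply(p, `[[`, "data")))
  expect_identical(c1$true_covariances, c2$true_covariances)
})

test_that("adding subjects leaves earlier subjects' data unchanged", {
  c4 <- generate_cohort(small_spec(n_subjects = 4L))
  c6 <- generate_cohort(small_spec(n_subjects = 6L))
  for (i in 1:4) {
    expect_identical(c4$runs[[i]][[1]]$data, c6$runs[[i]][[1]]$data)
    expect_identical(c4$runs[[i]][[2]]$data, c6$runs[[i]][[2]]$data)
  }
})

test_that("subject covariances are symmetric positive definite", {
  covs <- generate_subject_covariances(small_spec(lambda_subject = 2))
  for (cv in covs) {
    expect_equal(cv, t(cv))
    expect_gt(min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("lambda_subject = 0 collapses all subjects onto one covariance", {
  covs <- generate_subject_covariances(small_spec(lambda_subject = 0))
  for (i in 2:length(covs)) expect_identical(covs[[i]], covs[[1]])
})

test_that("run draws have the requested shape", {
  cov <- diag(2)
  x <- sample_run_timeseries(cov, 3L, 0, seed = 5L)
  expect_equal(dim(x), c(3L, 2L))
})

test_that("sample covariance converges to the target as T grows", {
  spec <- small_spec(n_subjects = 2L)
  cov <- generate_subject_covariances(spec)[[1]]
  err <- function(T_len) {
    x <- sample_run_timeseries(cov, T_len, 0, seed = 77L)
    emp <- crossprod(x) / T_len
    norm(emp - cov, "F") / norm(cov, "F")
  }
  e_small <- err(150L)
  e_large <- err(6000L)
  expect_lt(e_large, e_small)
  expect_lt(e_large, 0.1)
})

test_that("within-subject runs are more FC-similar than across subjects", {
  co <- generate_cohort(small_spec(n_subjects = 6L, n_timepoints = 200L,
                                   lambda_subject = 3, sigma_run = 0.05))
  res <- fingerprint_cohort(co)
  expect_gt(res$Iself, res$Iothers)
  expect_gt(res$Idiff, 0.3)
})

test_that("degenerate spec parameters are rejected, short runs warned", {
  expect_error(small_spec(lambda_subject = -1), "lambda_subject")
  expect_error(small_spec(sigma_obs = 0), "sigma_obs")
  expect_error(small_spec(coupling = 1.5), "coupling")
  expect_warning(small_spec(n_timepoints = 10L), "rank-deficient")
})

test_that("coupling only enters cohorts with both brain and spine blocks", {
  parc <- combine_parcellations(build_brain_parcellation(8),
                                build_spinal_parcellation("C4"))
  spec <- small_spec(parcellation = parc, coupling = 0.5)
  co <- generate_cohort(spec)
  expect_equal(ncol(co$runs[[1]][[1]]$data), 22L)
  # coupled and uncoupled cohorts differ in the data, same dimensions
  co0 <- generate_cohort(small_spec(parcellation = parc, coupling = 0))
  expect_false(identical(co$runs[[1]][[1]]$data, co0$runs[[1]][[1]]$data))
})
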