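test_that("ICC(1,1) reproduces the hand-worked ANOVA cases", {
  expect_equal(icc_1_1(rbind(c(1, 1), c(2, 2), c(3, 3))), 1)
  expect_equal(icc_1_1(rbind(c(1, 2), c(2, 1))), -1)
  expect_error(icc_1_1(rbind(c(1, 2))), "2 subjects")
})

test_that("ICC(1,1) matches the sums-of-squares oracle on random tables", {
  set.seed(23)
  for (rep in 1:50) {
    x <- matrix(rnorm(6 * 2), 6, 2)
    expect_equal(icc_1_1(x), oracle_icc_1_1(x), tolerance = 1e-12)
  }
})

test_that("ICC(1,1) for k = 2 stays within [-1, 1] and ignores affine shifts", {
  set.seed(29)
  for (rep in 1:40) {
    x <- matrix(rnorm(sample(3:12, 1) * 2, sd = runif(1, 0.1, 5)), ncol = 2)
    v <- icc_1_1(x)
    expect_gte(v, -1)
    expect_lte(v, 1)
    expect_equal(icc_1_1(x * 2.5 + 7), v, tolerance = 1e-10)
  }
})

test_that("edge-wise ICC map agrees with per-edge icc_1_1 and is symmetric", {
  set.seed(31)
  ns <- 5
  v1 <- lapply(1:ns, function(i) make_fc_vector(runif(6, -1, 1), 4, paste0("s", i)))
  v2 <- lapply(1:ns, function(i) make_fc_vector(runif(6, -1, 1), 4, paste0("s", i), 2L))
  map <- icc_matrix(v1, v2)
  expect_equal(map$values, t(map$values))
  expect_true(all(is.na(diag(map$values))))
  for (e in 1:6) {
    tbl <- cbind(sapply(v1, function(v) v$values[e]),
                 sapply(v2, function(v) v$values[e]))
    idx <- v1[[1]]$edge_index[e, ]
    expect_equal(map$values[idx[1], idx[2]], icc_1_1(tbl), tolerance = 1e-12)
  }
})

test_that("perfect test-retest agreement gives ICC 1 on every edge", {
  set.seed(37)
  vs <- lapply(1:5, function(i) make_fc_vector(runif(10, -1, 1), 5, paste0("s", i)))
  map <- icc_matrix(vs, vs)
  off <- map$values[upper.tri(map$values)]
  expect_equal(off, rep(1, length(off)), tolerance = 1e-12)
})

test_that("subject-exchangeable noise gives mean edge ICC near zero", {
  set.seed(41)
  mean_icc <- replicate(30, {
    v1 <- lapply(1:8, function(i) make_fc_vector(rnorm(15), 6, paste0("s", i)))
    v2 <- lapply(1:8, function(i) make_fc_vector(rnorm(15), 6, paste0("s", i), 2L))
    m <- icc_matrix(v1, v2)$values
    mean(m[upper.tri(m)])
  })
  expect_lt(abs(mean(mean_icc)), 3 * sd(mean_icc) / sqrt(30) + 0.02)
})

test_that("level-block averaging matches elementwise arithmetic", {
  parc <- build_spinal_parcellation(c("C4", "C5"))
  set.seed(43)
  base <- matrix(runif(14 * 14), 14, 14)
  block <- (base + t(base)) / 2
  diag(block) <- NA
  vals <- matrix(NA_real_, 28, 28)
  vals[1:14, 1:14] <- block
  vals[15:28, 15:28] <- block
  map <- structure(list(values = vals, k = 2L,
                        roi_names = parc$labels$name), class = "icc_map")
  avg <- average_level_blocks(map, parc)
  expect_equal(unname(avg), unname(block))

  # blocks B and -B cancel
  vals2 <- vals
  vals2[15:28, 15:28] <- -block
  map2 <- structure(list(values = vals2, k = 2L,
                         roi_names = parc$labels$name), class = "icc_map")
  expect_equal(unname(average_level_blocks(map2, parc)),
               unname(block * 0))

  # three hand-made maps across two objects average elementwise
  b2 <- block * 0.5
  vals3 <- vals
  vals3[15:28, 15:28] <- b2
  map3 <- structure(list(values = vals3, k = 2L,
                         roi_names = parc$labels$name), class = "icc_map")
  got <- average_level_blocks(list(map, map3), list(parc, parc))
  expect_equal(unname(got), unname((block + block + block + b2) / 4))
})

test_that("percentile thresholding retains exactly the top edges", {
  set.seed(47)
  n <- 8   # 28 edges
  s <- matrix(runif(n * n), n, n)
  m <- (s + t(s)) / 2
  diag(m) <- NA
  out <- threshold_percentile(m, pct = 95)
  edges <- m[upper.tri(m)]
  expect_equal(out$threshold,
               quantile(edges, 0.95, type = 7, names = FALSE))
  kept <- out$filtered[upper.tri(out$filtered)]
  expect_identical(kept != 0, edges >= out$threshold)
  expect_equal(out$filtered, t(out$filtered))

  # degenerate cases
  cm <- matrix(0.4, 5, 5)
  expect_true(all(threshold_percentile(cm)$filtered == 0.4))
  zm <- matrix(0, 5, 5)
  expect_true(all(threshold_percentile(zm)$filtered == 0))
})

test_that("nodal strength sums retained edges per ROI", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(nodal_strength(z), c(a = 0, b = 0, c = 0, d = 0))
  e <- z
  e["b", "d"] <- e["d", "b"] <- 0.7
  expect_equal(nodal_strength(e), c(a = 0, b = 0.7, c = 0, d = 0.7))
  set.seed(53)
  s <- matrix(runif(36), 6, 6)
  m <- (s + t(s)) / 2
  strength <- nodal_strength(m)
  manual <- sapply(1:6, function(i) sum(m[i, -i]))
  expect_equal(unname(strength), manual)
  expect_equal(unname(nodal_strength(m, reduce = "mean")), manual / 5)
})
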