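test_that("identifiability matrix matches a direct Pearson oracle", {
  v1 <- list(make_fc_vector(c(0.1, 0.5, 0.3), 3, "a"),
             make_fc_vector(c(0.9, -0.2, 0.4), 3, "b"))
  v2 <- list(make_fc_vector(c(0.2, 0.4, 0.35), 3, "a", 2L),
             make_fc_vector(c(0.8, -0.1, 0.5), 3, "b", 2L))
  I <- identifiability_matrix(v1, v2)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(I[i, j], oracle_pearson(v1[[i]]$values, v2[[j]]$values),
                 tolerance = 1e-12)
  }
  expect_equal(rownames(I), c("a", "b"))
})

test_that("identical run sets give a unit diagonal", {
  set.seed(2)
  vs <- lapply(1:4, function(i) make_fc_vector(runif(10), 5, paste0("s", i)))
  I <- identifiability_matrix(vs, vs)
  expect_equal(unname(diag(I)), rep(1, 4), tolerance = 1e-12)
})

test_that("idiff reproduces the hand-worked examples", {
  expect_equal(idiff(diag(4)), list(Iself = 1, Iothers = 0, Idiff = 1))
  expect_equal(idiff(matrix(0.3, 3, 3))$Idiff, 0)
  got <- idiff(matrix(c(0.9, 0.3, 0.5, 0.7), 2, 2))
  expect_equal(got$Iself, 0.8)
  expect_equal(got$Iothers, 0.4)
  expect_equal(got$Idiff, 0.4)
  expect_error(idiff(matrix(1, 2, 3)), "square")
})

test_that("Cohen's d matches hand arithmetic and flags degenerate input", {
  I <- matrix(c(0.9, 0.3, 0.5, 0.7), 2, 2)
  expect_equal(cohens_d(I), 0.4 / sqrt(0.02), tolerance = 1e-12)
  expect_warning(d <- cohens_d(matrix(0.5, 3, 3)), "undefined")
  expect_true(is.na(d))
})

test_that("success rate counts strict diagonal maxima; ties fail", {
  I <- diag(3) + 0.1
  expect_equal(success_rate(I)$accuracy, 100)
  I2 <- matrix(c(0.9, 0.1, 0.2,
                 0.8, 0.5, 0.1,
                 0.1, 0.2, 0.7), 3, 3, byrow = TRUE)
  sr <- success_rate(I2)   # row 2's max (0.8) is off-diagonal
  expect_equal(sr$success_count, 2L)
  expect_equal(sr$accuracy, 200 / 3)
  expect_equal(sr$accuracy_label, "66.7%")
  I3 <- matrix(c(0.5, 0.5, 0.1, 0.4), 2, 2, byrow = TRUE)
  expect_warning(sr3 <- success_rate(I3), "tie")
  expect_equal(sr3$success_count, 1L)
})

test_that("top-K accuracy is monotone, anchored at success rate and 100%", {
  set.seed(9)
  for (rep in 1:25) {
    I <- random_similarity_matrix(sample(3:10, 1))
    tk <- topk_accuracy(I, k_max = nrow(I))
    expect_equal(unname(tk["1"]), success_rate(I)$accuracy)
    expect_equal(unname(tk[as.character(nrow(I))]), 100)
    expect_true(all(diff(tk) >= 0))
  }
})

test_that("a self rank of two enters exactly at K = 2", {
  I <- matrix(c(0.6, 0.9, 0.05,
                0.1, 0.8, 0.2,
                0.0, 0.1, 0.9), 3, 3, byrow = TRUE)
  tk <- topk_accuracy(I, 3)
  expect_equal(unname(tk["1"]), 200 / 3)
  expect_equal(unname(tk["2"]), 100)
})

test_that("fingerprint statistics are invariant under subject relabeling", {
  set.seed(13)
  for (rep in 1:20) {
    ns <- sample(3:9, 1)
    I <- random_similarity_matrix(ns)
    perm <- sample(ns)
    Ip <- I[perm, perm]
    expect_equal(idiff(Ip)$Idiff, idiff(I)$Idiff, tolerance = 1e-14)
    expect_equal(cohens_d(Ip), cohens_d(I), tolerance = 1e-12)
    expect_equal(success_rate(Ip)$accuracy, success_rate(I)$accuracy)
    expect_equal(unname(topk_accuracy(Ip, ns)), unname(topk_accuracy(I, ns)))
  }
})

test_that("sorting by diagonal reorders the matrix but not the statistics", {
  set.seed(17)
  I <- random_similarity_matrix(6)
  dimnames(I) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  res <- fingerprint_from_matrix(I)
  sorted <- sort_by_diagonal(res)
  expect_true(all(diff(diag(sorted$I)) <= 0))
  expect_equal(sorted$Idiff, res$Idiff, tolerance = 1e-15)
  expect_equal(sorted$accuracy, res$accuracy)
  expect_equal(sort(sorted$subject_order), sort(res$subject_order))
  already <- sort_by_diagonal(sorted)
  expect_equal(already$I, sorted$I)
})

test_that("chance level follows the 100/Ns convention with one-decimal labels", {
  expect_equal(chance_level(18)$label, "5.6%")
  expect_equal(chance_level(43)$label, "2.3%")
  expect_equal(chance_level(18)$percent, 100 / 18)
})
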