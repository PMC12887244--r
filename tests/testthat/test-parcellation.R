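test_that("spinal parcellation sizes follow 14 ROIs per level", {
  expect_equal(build_spinal_parcellation(c("C4", "C5", "C6"))$N, 42L)
  expect_equal(build_spinal_parcellation(paste0("C", 4:8))$N, 70L)
  expect_equal(build_spinal_parcellation(paste0("C", 2:8))$N, 98L)
  # property over random level subsets
  set.seed(42)
  for (rep in 1:20) {
    levels <- sample(spinal_levels(), sample(1:7, 1))
    p <- build_spinal_parcellation(levels)
    expect_equal(p$N, 14L * length(levels))
    expect_equal(p$n_levels, length(levels))
    expect_false(anyDuplicated(p$labels$name) > 0)
  }
})

test_that("cross-section ordering and tissue pairing are canonical", {
  p <- build_spinal_parcellation("C4")
  expect_equal(p$labels$name[1:6],
               c("C4_dh_L", "C4_dh_R", "C4_iz_L", "C4_iz_R",
                 "C4_vh_L", "C4_vh_R"))
  expect_equal(p$labels$name[7:14],
               c("C4_cst_L", "C4_cst_R", "C4_fc_L", "C4_fc_R",
                 "C4_fg_L", "C4_fg_R", "C4_sl_L", "C4_sl_R"))
  expect_true(all(p$labels$tissue[p$labels$region %in% c("dh", "vh", "iz")] == "GM"))
  expect_true(all(p$labels$tissue[p$labels$region %in% c("cst", "fc", "fg", "sl")] == "WM"))
  expect_true(all(p$labels$side %in% c("L", "R")))
})

test_that("invalid level lists are rejected", {
  expect_error(build_spinal_parcellation(character(0)), "non-empty")
  expect_error(build_spinal_parcellation("C9"), "unknown")
  expect_error(build_spinal_parcellation(c("C4", "C4")), "duplicate")
})

test_that("brain parcellation defaults to 119 ROIs and combines with spine", {
  br <- build_brain_parcellation()
  expect_equal(br$N, 119L)
  expect_true(all(br$labels$tissue == "brain"))
  both <- combine_parcellations(br, build_spinal_parcellation(c("C4", "C5", "C6")))
  expect_equal(both$N, 161L)
  blocks <- spineprint:::parcel_blocks(both)
  expect_length(blocks$brain, 119L)
  expect_length(blocks$spine, 42L)
})

# Small voxel fixture: two ROIs in a 3x3x1 slab.
make_voxrun <- function(values_by_roi, T_len) {
  n_vox <- sum(lengths(values_by_roi) > 0)
  roi_vol <- array(0L, dim = c(3, 3, 1))
  image <- array(0, dim = c(3, 3, 1, T_len))
  lookup <- data.frame(label_int = integer(), name = character(),
                       level = character(), tissue = character(),
                       region = character(), side = character())
  vox <- 1L
  for (k in seq_along(values_by_roi)) {
    vals <- values_by_roi[[k]]  # n_vox x T matrix
    for (r in seq_len(nrow(vals))) {
      roi_vol[vox] <- k
      image[((vox - 1) %% 3) + 1, ((vox - 1) %/% 3) + 1, 1, ] <- vals[r, ]
      vox <- vox + 1L
    }
    lookup <- rbind(lookup, data.frame(
      label_int = k, name = paste0("roi", k), level = "C4", tissue = "GM",
      region = "dh", side = c("L", "R")[k]))
  }
  voxel_run(image, roi_vol, lookup)
}

test_that("robust parcel mean trims by within-timepoint percentiles", {
  # 10 identical voxels -> parcel equals that value
  vr <- make_voxrun(list(matrix(7, nrow = 9, ncol = 4)), 4)
  pr <- robust_parcel_mean(vr)
  expect_equal(unname(pr$data[, 1]), rep(7, 4))

  # single-voxel ROI -> series passes through untouched
  series <- c(1, 5, -2, 8)
  vr1 <- make_voxrun(list(matrix(series, nrow = 1)), 4)
  expect_equal(unname(robust_parcel_mean(vr1)$data[, 1]), series)

  # 9 voxels with values 1..9 at t=1: matches the enumeration oracle
  vals <- matrix(rep(1:9, 3), nrow = 9)
  vr9 <- make_voxrun(list(vals), 3)
  expect_equal(unname(robust_parcel_mean(vr9)$data[1, 1]),
               oracle_trimmed_mean(1:9, 5, 95))
})

test_that("robust mean is permutation invariant and bounded by voxel range", {
  set.seed(7)
  vals <- matrix(rnorm(9 * 5), nrow = 9)
  vr <- make_voxrun(list(vals), 5)
  pr <- robust_parcel_mean(vr)
  vr_perm <- make_voxrun(list(vals[sample(9), , drop = FALSE]), 5)
  expect_equal(robust_parcel_mean(vr_perm)$data, pr$data)
  for (t in 1:5) {
    expect_gte(pr$data[t, 1], min(vals[, t]))
    expect_lte(pr$data[t, 1], max(vals[, t]))
  }
})

test_that("voxel runs with empty ROIs are rejected by name", {
  image <- array(rnorm(3 * 3 * 1 * 4), dim = c(3, 3, 1, 4))
  roi_vol <- array(0L, dim = c(3, 3, 1))
  roi_vol[1] <- 1L
  lookup <- data.frame(label_int = 1:2, name = c("ok", "ghost"),
                       level = "C4", tissue = "GM", region = "dh",
                       side = c("L", "R"))
  expect_error(voxel_run(image, roi_vol, lookup), "ghost")
})

test_that("tSNR is mean over population sd, NA for flat voxels", {
  img <- array(0, dim = c(2, 1, 1, 2))
  img[1, 1, 1, ] <- c(9, 11)   # mean 10, population sd 1
  img[2, 1, 1, ] <- c(4, 4)    # zero variance
  ts <- compute_tsnr(img)
  expect_equal(ts[1, 1, 1], 10)
  expect_true(is.na(ts[2, 1, 1]))
})

test_that("tSNR is invariant under positive scaling, sign-flips under negation", {
  set.seed(11)
  img <- array(rnorm(4 * 4 * 2 * 20, mean = 5), dim = c(4, 4, 2, 20))
  base <- compute_tsnr(img)
  expect_equal(compute_tsnr(img * 3.7), base, tolerance = 1e-12)
  expect_equal(compute_tsnr(-img), -base, tolerance = 1e-12)
})
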