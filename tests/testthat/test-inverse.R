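# shared forward setup (built once per file)
mon <- build_montage(32, 92)
sp <- build_source_space(15)
lf <- compute_lead_field(mon, sp)
K_avg <- apply_reference(lf, "average")$gain

test_that("sLORETA localizes noiseless single dipoles exactly (sample)", {
  op <- build_sloreta_operator(lf, alpha_frac = 0)
  set.seed(4)
  for (j in sample(n_voxels(sp), 40)) {
    m <- rnorm(3)
    a <- K_avg[, 3 * (j - 1) + 1:3] %*% m
    img <- source_band_power(op, tcrossprod(a) + 0i)
    expect_equal(which.max(img$values), j)
  }
})

test_that("regularized operator is finite with SPD blocks", {
  op <- build_sloreta_operator(lf, alpha_frac = 1 / 100)
  expect_true(all(is.finite(op$T)))
  ev <- apply(op$blocks, 3, function(S)
    min(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
  expect_true(all(ev > 0))
  expect_error(build_sloreta_operator(lf, -1), ">= 0")
})

test_that("standardized power is invariant to lead-field scaling", {
  lf2 <- lf
  lf2$gain <- 5 * lf$gain
  op1 <- build_sloreta_operator(lf, 0.01)
  op2 <- build_sloreta_operator(lf2, 0.01)
  expect_equal(op2$T, op1$T / 5, tolerance = 1e-8)
  ## data generated by the scaled forward model: power cancels the scale
  a <- K_avg[, 301:303] %*% c(1, 1, 0.2)
  p1 <- source_band_power(op1, tcrossprod(a) + 0i)$values
  p2 <- source_band_power(op2, tcrossprod(5 * a) + 0i)$values
  expect_equal(p2, p1, tolerance = 1e-8)
})

test_that("source power is linear and additive over uncorrelated sources", {
  op <- build_sloreta_operator(lf, 0.01)
  a1 <- K_avg[, 31:33] %*% c(1, 0, 1)
  a2 <- K_avg[, 601:603] %*% c(0, 1, -1)
  C1 <- tcrossprod(a1) + 0i
  C2 <- tcrossprod(a2) + 0i
  z <- source_band_power(op, matrix(0i, 32, 32))$values
  expect_equal(z, rep(0, n_voxels(sp)))
  p1 <- source_band_power(op, C1)$values
  p12 <- source_band_power(op, C1 + C2)$values
  p2 <- source_band_power(op, C2)$values
  expect_equal(p12, p1 + p2, tolerance = 1e-9 * max(p12))
  p1c <- source_band_power(op, 3.7 * C1)$values
  expect_equal(p1c, 3.7 * p1, tolerance = 1e-9 * max(p1c))
})

test_that("two separated uncorrelated sources give two local maxima", {
  op <- build_sloreta_operator(lf, alpha_frac = 0)
  ant <- which(sp$region_label == "MF_SF")[5]
  post <- which(sp$region_label == "PCC_precuneus")[5]
  mk <- function(j) {
    u <- sp$voxel_centers[j, ] / sqrt(sum(sp$voxel_centers[j, ]^2))
    K_avg[, 3 * (j - 1) + 1:3] %*% u
  }
  C <- tcrossprod(mk(ant)) + tcrossprod(mk(post)) + 0i
  img <- source_band_power(op, C)$values
  ## each true source is within one voxel of a local argmax in its half
  half_ant <- sp$voxel_centers[, 2] > 0
  best_ant <- which(half_ant)[which.max(img[half_ant])]
  best_post <- which(!half_ant)[which.max(img[!half_ant])]
  d_ant <- sqrt(sum((sp$voxel_centers[best_ant, ] -
                     sp$voxel_centers[ant, ])^2))
  d_post <- sqrt(sum((sp$voxel_centers[best_post, ] -
                      sp$voxel_centers[post, ])^2))
  expect_lte(d_ant, sp$spacing + 1e-9)
  expect_lte(d_post, sp$spacing + 1e-9)
})

test_that("images are invariant to the data reference", {
  op <- build_sloreta_operator(lf, 0.01)
  set.seed(5)
  x <- matrix(rnorm(32 * 40 * 510), 32)
  rec_avg <- new_recording(apply_reference(x, "average"), 300,
                           channel_names = mon$channel_names)
  rec_lm <- new_recording(apply_reference(x, "linked_mastoids", mon),
                          300, channel_names = mon$channel_names)
  c_avg <- band_cross_spectra(segment_epochs(rec_avg),
                              dmn_constants$bands["alpha"])$alpha
  c_lm <- band_cross_spectra(segment_epochs(rec_lm),
                             dmn_constants$bands["alpha"])$alpha
  p_avg <- source_band_power(op, c_avg)$values
  p_lm <- source_band_power(op, c_lm)$values
  expect_equal(p_lm, p_avg, tolerance = 1e-8)
})

test_that("stronger regularization blurs a single-source image", {
  a <- K_avg[, 901:903] %*% c(1, 0.5, 1)
  C <- tcrossprod(a) + 0i
  ## blurring is monotone from the operating regularization upward
  ## (at vanishing alpha the standardized ratio plateaus instead)
  ratios <- vapply(c(0.01, 0.1, 1, 10), function(al) {
    p <- source_band_power(build_sloreta_operator(lf, al), C)$values
    max(p) / mean(p)
  }, 0)
  expect_true(all(diff(ratios) <= 1e-9))
})

test_that("invalid cross-spectra are rejected", {
  op <- build_sloreta_operator(lf, 0.01)
  expect_error(source_band_power(op, matrix(0i, 5, 5)), "mismatch")
  bad <- diag(32) + 0i
  bad[1, 2] <- 5
  expect_error(source_band_power(op, bad), "Hermitian")
  npsd <- diag(c(-5, rep(1, 31))) + 0i
  expect_error(source_band_power(op, npsd), "positive semidefinite")
})

test_that("per-epoch images average to the cross-spectral image", {
  op <- build_sloreta_operator(lf, 0.01)
  set.seed(6)
  x <- matrix(rnorm(32 * 20 * 510), 32)
  rec <- new_recording(x, 300, channel_names = mon$channel_names)
  es <- segment_epochs(rec, 1.7, 0)
  per_epoch <- source_band_power_epochs(op, es,
                                        dmn_constants$bands["alpha"])$alpha
  expect_equal(dim(per_epoch), c(20, n_voxels(sp)))
  Ca <- band_cross_spectra(es, dmn_constants$bands["alpha"])$alpha
  whole <- source_band_power(op, Ca)$values
  expect_equal(colMeans(per_epoch), whole,
               tolerance = 1e-8, ignore_attr = TRUE)
})
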