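test_that("image stacks validate their inputs", {
  imgs <- list(matrix(rnorm(20), 4), matrix(rnorm(15), 3))
  st <- new_image_stack(imgs)
  expect_equal(st$subject_index, rep(1:2, c(4, 3)))
  expect_error(new_image_stack(list(matrix(rnorm(5), 1))), ">= 2 rows")
  bad <- list(cbind(1, rnorm(2)), cbind(1, rnorm(2)))
  expect_error(new_image_stack(bad), "constant")
})

test_that("MDL recovers exact rank and degrades gracefully", {
  set.seed(10)
  ## noiseless rank-2 data: infinite eigenvalue gap
  A <- matrix(rnorm(40), 20, 2)
  S <- matrix(rnorm(2 * 300), 2)
  expect_equal(estimate_order_mdl(A %*% S), 2L)
  ## pure iid noise: no structure
  expect_lte(estimate_order_mdl(matrix(rnorm(30 * 2000), 30)), 2L)
  ## degenerate covariance: warning path
  expect_warning(k0 <- estimate_order_mdl(matrix(0, 5, 50)),
                 "degenerate")
  expect_equal(k0, 1L)
})

test_that("group ICA recovers planted patterns and subject amplitudes", {
  pl <- make_planted_stack(nsub = 30, rows = 40, seed = 11)
  dec <- fit_group_ica(pl$stack, 3, seed = 1)
  m <- match_sources(dec$group_maps, pl$S)
  expect_gte(m$min_cor, 0.95)
  ## amari index against the planted patterns
  expect_lte(amari_index(m$cor_matrix), 0.1)
  ## cross-check with an independent FastICA oracle
  fast <- fastica_oracle(pl$stack$X, 3, seed = 2)
  mf <- match_sources(fast, pl$S)
  expect_gte(mf$min_cor, 0.9)
  dec <- back_reconstruct(dec, pl$stack)
  for (k in 1:3) {
    sums <- intensity_scores(dec, which(m$perm == k))
    expect_gte(cor(sums, pl$amp[, k]), 0.8)
  }
})

test_that("group ICA is deterministic and block-permutation invariant", {
  pl <- make_planted_stack(nsub = 12, rows = 20, V = 300, seed = 12)
  d1 <- fit_group_ica(pl$stack, 3, seed = 7)
  d2 <- fit_group_ica(pl$stack, 3, seed = 7)
  expect_identical(d1$group_maps, d2$group_maps)
  ## permute subject blocks
  ord <- c(5:12, 1:4)
  imgs <- lapply(ord, function(i)
    pl$stack$X[pl$stack$subject_index == i, , drop = FALSE])
  stp <- new_image_stack(imgs)
  d3 <- fit_group_ica(stp, 3, seed = 7)
  m <- match_sources(d3$group_maps, d1$group_maps)
  expect_gte(m$min_cor, 1 - 1e-6)
})

test_that("group maps are z-scored, skew-positive and variance-ordered", {
  pl <- make_planted_stack(nsub = 12, rows = 20, V = 300, seed = 13)
  dec <- fit_group_ica(pl$stack, 3, seed = 1)
  expect_equal(rowMeans(dec$group_maps), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply(dec$group_maps, 1, sd), rep(1, 3),
               tolerance = 1e-8)
  expect_true(all(rowMeans(dec$group_maps^3) >= -1e-12))
  expect_true(all(diff(dec$explained_variance) <= 1e-12))
  expect_error(fit_group_ica(pl$stack, 1000), "exceeds")
})

test_that("back-reconstruction reflects presence and absence", {
  set.seed(14)
  V <- 400; rows <- 30
  S <- matrix(0, 2, V)
  S[1, 1:80] <- rexp(80); S[2, 201:280] <- rexp(80)
  S <- S / apply(S, 1, sd)
  nsub <- 20
  amp <- cbind(rlnorm(nsub, 0, 0.4), rlnorm(nsub, 0, 0.4))
  amp[1, 2] <- 0                         # subject 1 lacks component 2
  imgs <- lapply(1:nsub, function(i) {
    A <- matrix(rnorm(rows * 2), rows) %*% diag(amp[i, ])
    A %*% S + matrix(rnorm(rows * V, sd = 0.3), rows)
  })
  st <- new_image_stack(imgs)
  dec <- back_reconstruct(fit_group_ica(st, 2, seed = 1), st)
  m <- match_sources(dec$group_maps, S)
  k2 <- which(m$perm == 2)
  cor_absent <- cor(dec$subject_maps[1, k2, ], dec$group_maps[k2, ])
  expect_lte(abs(cor_absent), 0.2)
  ## planted group amplitudes 0.5 / 1 / 2: mean sums strictly increase
  grp_amp <- rep(c(0.5, 1, 2), length.out = nsub)
  imgs2 <- lapply(1:nsub, function(i) {
    A <- matrix(rnorm(rows * 2), rows) %*% diag(c(amp[i, 1], grp_amp[i]))
    A %*% S + matrix(rnorm(rows * V, sd = 0.3), rows)
  })
  st2 <- new_image_stack(imgs2)
  dec2 <- back_reconstruct(fit_group_ica(st2, 2, seed = 1), st2)
  m2 <- match_sources(dec2$group_maps, S)
  sums <- intensity_scores(dec2, which(m2$perm == 2))
  means <- tapply(sums, grp_amp, mean)
  expect_true(all(diff(means) > 0))
  expect_error(back_reconstruct(structure(list(subject_reducers = NULL),
                                          class = "dmn_group_decomp"),
                                st2),
               "missing reduction")
})

test_that("a single-subject stack reproduces the group map", {
  set.seed(15)
  V <- 300
  S <- matrix(0, 2, V)
  S[1, 1:50] <- rexp(50); S[2, 151:200] <- rexp(50)
  A <- matrix(rnorm(40 * 2), 40)
  st <- new_image_stack(list(A %*% S +
                             matrix(rnorm(40 * V, sd = 0.05), 40)))
  dec <- back_reconstruct(fit_group_ica(st, 2, seed = 1), st)
  for (k in 1:2)
    expect_gte(abs(cor(dec$subject_maps[1, k, ], dec$group_maps[k, ])),
               0.99)
})

test_that("significance maps recover a planted cube and filter clusters", {
  space <- box_space(8, 8, 8)
  V <- n_voxels(space)
  cube <- which(space$grid_index[, 1] %in% 4:6 &
                space$grid_index[, 2] %in% 4:6 &
                space$grid_index[, 3] %in% 4:6)
  set.seed(16)
  n <- 60
  maps <- matrix(rnorm(n * V), n)
  maps[, cube] <- maps[, cube] + 2       # Cohen's d = 2
  sig <- component_significance(maps, space, q = 0.05, min_cluster = 8)
  expect_true(all(sig$surviving_mask[cube]))
  expect_lte(sum(sig$surviving_mask[-cube]), 5)
  ## a significant 7-voxel cluster must be removed at min_cluster 8
  seven <- which(space$grid_index[, 1] == 1 &
                 space$grid_index[, 2] == 1)[1:7]
  maps2 <- matrix(rnorm(n * V), n)
  maps2[, seven] <- maps2[, seven] + 3
  sig2 <- component_significance(maps2, space, min_cluster = 8)
  expect_false(any(sig2$surviving_mask[seven]))
  sig3 <- component_significance(maps2, space, min_cluster = 7)
  expect_true(all(sig3$surviving_mask[seven]))
  ## zero-variance voxels are excluded, not tested
  maps3 <- maps2
  maps3[, 1] <- 1
  sig4 <- component_significance(maps3, space)
  expect_true(sig4$excluded[1])
  expect_true(is.na(sig4$tmap[1]))
  expect_error(component_significance(maps2[1:2, ], space), ">= 3")
})

test_that("all-noise maps rarely survive the FDR + cluster filter", {
  space <- box_space(6, 6, 6)
  set.seed(17)
  surv <- vapply(1:30, function(i) {
    maps <- matrix(rnorm(40 * n_voxels(space)), 40)
    sum(component_significance(maps, space)$surviving_mask)
  }, 0)
  expect_lte(mean(surv), 0.5)
})
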