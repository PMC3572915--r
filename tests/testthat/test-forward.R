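test_that("montages have the right sizes, radii and landmarks", {
  for (nch in c(19, 32, 64)) {
    mon <- build_montage(nch, 92)
    expect_length(mon$channel_names, nch)
    expect_false(anyDuplicated(mon$channel_names) > 0)
    expect_equal(sqrt(rowSums(mon$positions^2)),
                 rep(92, nch), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(mon$mastoid_proxies %in% mon$channel_names))
  }
  expect_equal(unname(build_montage(19, 92)$positions["Cz", ]),
               c(0, 0, 92))
  expect_error(build_montage(20, 92), "unsupported")
  expect_error(build_montage(32, -1), "positive")
})

test_that("mastoid proxies are the lowest posterior-lateral electrodes", {
  mon <- build_montage(32, 92)
  pos <- mon$positions
  lowest <- names(sort(pos[, "z"]))[1:4]
  expect_true(all(mon$mastoid_proxies %in% lowest))
  expect_true(all(pos[mon$mastoid_proxies, "y"] < 0))
})

test_that("source grid is clipped, labelled and monotone in spacing", {
  sp <- build_source_space(15)
  r <- sqrt(rowSums(sp$voxel_centers^2))
  rb <- dmn_constants$head_model$radii_mm[["brain"]]
  expect_true(all(r >= 0.55 * rb - 1e-9 & r <= 0.95 * rb + 1e-9))
  expect_true(all(sp$voxel_centers[, 3] >= dmn_constants$grid_clip$z_min_mm))
  counts <- table(sp$region_label)
  expect_true(all(counts[setdiff(dmn_constants$region_levels,
                                 "other_cortex")] > 0))
  expect_gt(n_voxels(sp), 100)
  expect_lt(n_voxels(sp), 1000)
  sp5 <- build_source_space(5)
  expect_gt(n_voxels(sp5), n_voxels(sp))
  expect_gt(n_voxels(sp5), 1000)
  expect_lt(n_voxels(sp5), 10000)
  expect_error(build_source_space(60), "empty region")
  expect_error(build_source_space(2), ">= 5")
})

test_that("anterior and posterior label sets are disjoint and non-empty", {
  sp <- build_source_space(15)
  ant <- which(sp$region_label %in% dmn_constants$anterior_labels)
  post <- which(sp$region_label %in% dmn_constants$posterior_labels)
  expect_gt(length(ant), 0)
  expect_gt(length(post), 0)
  expect_length(intersect(ant, post), 0)
  expect_true(all(sp$voxel_centers[ant, "y"] > 0))
  expect_true(all(sp$voxel_centers[post, "y"] < 0))
})

test_that("layered-sphere surface factors match the homogeneous closed form", {
  rn <- dmn_constants$head_model$radii_mm /
    dmn_constants$head_model$radii_mm[["scalp"]]
  eqc <- c(scalp = 0.33, skull = 0.33, brain = 0.33)
  S <- dmnalpha:::.sphere_surface_factors(rn, eqc, 40)
  n <- 1:40
  ## insulated homogeneous sphere: per-degree surface factor
  ## (2n+1)/n relative to the infinite-medium coefficient
  expected <- (2 * n + 1) / n * rn[["brain"]]^(n + 1)
  expect_equal(S, expected, tolerance = 1e-12)
})

test_that("central radial dipole produces a cosine scalp profile", {
  mon <- build_montage(32, 92)
  sp <- build_source_space(15)
  spc <- sp
  spc$voxel_centers <- matrix(c(0, 0, 1e-9), 1, 3)
  spc$grid_index <- matrix(0L, 1, 3)
  lf <- compute_lead_field(mon, spc, order = 60)
  lf_avg <- apply_reference(lf, "average")
  g <- lf_avg$gain[, 3]                  # z-oriented central dipole
  cosg <- mon$positions[, 3] / 92
  cosg <- cosg - mean(cosg)              # average-referenced cosine
  expect_gt(abs(cor(g, cosg)), 1 - 1e-10)
  ## axis-aligned electrode (Cz) carries the maximum potential
  expect_equal(unname(which.max(g)),
               which(mon$channel_names == "Cz"))
})

test_that("lead field is linear in dipole moment and reference-consistent", {
  mon <- build_montage(32, 92)
  sp <- build_source_space(15)
  spv <- sp
  spv$voxel_centers <- sp$voxel_centers[c(10, 100), ]
  spv$grid_index <- sp$grid_index[c(10, 100), ]
  lf <- compute_lead_field(mon, spv, order = 80)
  m <- c(0.3, -1.2, 0.5)
  v1 <- lf$gain[, 1:3] %*% m
  v2 <- lf$gain[, 1:3] %*% (2 * m)
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  K <- apply_reference(lf, "average")$gain
  expect_lt(max(abs(colSums(K))), 1e-12 * max(abs(K)))
})

test_that("swapping electrodes permutes lead-field rows exactly", {
  mon <- build_montage(19, 92)
  sp <- build_source_space(15)
  spv <- sp
  spv$voxel_centers <- sp$voxel_centers[5:8, ]
  spv$grid_index <- sp$grid_index[5:8, ]
  mon2 <- mon
  sw <- c(2, 1, 3:19)
  mon2$positions <- mon$positions[sw, ]
  mon2$channel_names <- mon$channel_names[sw]
  mon2$reference_scheme <- "average"
  mon$reference_scheme <- "average"
  k1 <- compute_lead_field(mon, spv, order = 60)$gain
  k2 <- compute_lead_field(mon2, spv, order = 60)$gain
  expect_equal(k2, k1[sw, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("referenced potentials are equivariant under joint rotation", {
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mon <- build_montage(19, 92)
  mon$reference_scheme <- "average"
  sp <- build_source_space(15)
  spv <- sp
  spv$voxel_centers <- sp$voxel_centers[21:23, ]
  spv$grid_index <- sp$grid_index[21:23, ]
  monR <- mon
  monR$positions <- mon$positions %*% t(R)
  spR <- spv
  spR$voxel_centers <- spv$voxel_centers %*% t(R)
  K <- compute_lead_field(mon, spv, order = 80)$gain
  KR <- compute_lead_field(monR, spR, order = 80)$gain
  m <- c(1, -0.5, 2)
  for (j in 1:3) {
    cols <- 3 * (j - 1) + 1:3
    v <- K[, cols] %*% m
    vR <- KR[, cols] %*% (R %*% m)
    expect_equal(vR, v, tolerance = 1e-8 * max(abs(v)))
  }
})

test_that("series truncation error is below 1e-6 of the column norm", {
  mon <- build_montage(32, 92)
  sp <- build_source_space(15)
  spv <- sp
  ## include the shallowest voxel (worst-case convergence)
  r <- sqrt(rowSums(sp$voxel_centers^2))
  pick <- c(which.max(r), 1, 50)
  spv$voxel_centers <- sp$voxel_centers[pick, ]
  spv$grid_index <- sp$grid_index[pick, ]
  k1 <- compute_lead_field(mon, spv)$gain
  k2 <- compute_lead_field(mon, spv, order = 230)$gain
  expect_lt(max(abs(k1 - k2)), 1e-6 * min(sqrt(colSums(k1^2))))
})

test_that("sources outside the brain shell are rejected", {
  mon <- build_montage(32, 92)
  sp <- build_source_space(15)
  spv <- sp
  spv$voxel_centers <- matrix(c(0, 0, 85), 1, 3)
  spv$grid_index <- matrix(0L, 1, 3)
  expect_error(compute_lead_field(mon, spv), "outside")
})

test_that("re-referencing is idempotent and kills common offsets", {
  mon <- build_montage(32, 92)
  x <- matrix(rnorm(32 * 100), 32)
  const <- matrix(5, 32, 100)
  expect_equal(apply_reference(const, "average"),
               matrix(0, 32, 100))
  a1 <- apply_reference(x, "average")
  expect_equal(apply_reference(a1, "average"), a1)
  l1 <- apply_reference(x, "linked_mastoids", mon)
  expect_equal(apply_reference(l1, "linked_mastoids", mon), l1)
  ## zero mastoid rows: linked-mastoid referencing changes nothing
  idx <- match(mon$mastoid_proxies, mon$channel_names)
  x0 <- x
  x0[idx, ] <- 0
  expect_equal(apply_reference(x0, "linked_mastoids", mon), x0)
  mon19 <- build_montage(19, 92)
  mon19$mastoid_proxies <- c("nope1", "nope2")
  expect_error(apply_reference(x[1:19, ], "linked_mastoids", mon19),
               "absent")
})
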