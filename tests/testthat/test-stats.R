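test_that("Cronbach's alpha matches closed forms", {
  set.seed(30)
  x <- rnorm(100)
  identical_items <- cbind(x, x, x, x)
  expect_equal(cronbach_alpha(identical_items), 1)
  ## Spearman-Brown for k parallel items with correlation rho
  k <- 6; rho <- 0.4; n <- 2000
  f <- rnorm(n)
  items <- sapply(1:k, function(i)
    sqrt(rho) * f + sqrt(1 - rho) * rnorm(n))
  expect_equal(cronbach_alpha(items), spearman_brown(k, rho),
               tolerance = 0.02)
})

test_that("varimax PCA assigns planted factor items correctly", {
  set.seed(31)
  n <- 200
  f1 <- rnorm(n); f2 <- rnorm(n)
  lam <- 0.75
  latent <- cbind(sapply(1:5, function(i) lam * f1 +
                           sqrt(1 - lam^2) * rnorm(n)),
                  sapply(1:5, function(i) lam * f2 +
                           sqrt(1 - lam^2) * rnorm(n)))
  items <- matrix(findInterval(latent, c(-1.5, -0.5, 0.5, 1.5)) + 1L, n)
  ss <- construct_scales(items, n_factors = 2)
  ## each factor collects exactly its planted block of items
  expect_true(setequal(ss$scales$factor1$items,
                       if (1 %in% ss$scales$factor1$items) 1:5 else 6:10))
  expect_true(setequal(c(ss$scales$factor1$items,
                         ss$scales$factor2$items), 1:10))
  expect_gt(ss$scales$factor1$alpha, 0.6)
})

test_that("reverse-scored items are detected and scored correctly", {
  set.seed(32)
  n <- 300
  f <- rnorm(n)
  latent <- cbind(0.8 * f + 0.6 * rnorm(n),
                  -0.8 * f + 0.6 * rnorm(n),
                  0.8 * f + 0.6 * rnorm(n),
                  rnorm(n), rnorm(n), rnorm(n))
  items <- matrix(findInterval(latent, c(-1.5, -0.5, 0.5, 1.5)) + 1L, n)
  ss <- suppressWarnings(construct_scales(items, n_factors = 2))
  s1 <- ss$scales[[which(vapply(ss$scales, function(s)
    1 %in% s$items, TRUE))[1]]]
  expect_true(2 %in% s1$items)
  expect_true(s1$reversed[match(2, s1$items)])
  ## scores correlate positively with the factor despite reversal
  expect_gt(cor(s1$scores, f), 0.6)
})

test_that("moderation coefficients match an lm() oracle exactly", {
  set.seed(33)
  n <- 60
  x <- rnorm(n); m <- rnorm(n)
  y <- 0.7 * x * m + rnorm(n, sd = 0.7)
  res <- hierarchical_moderation(y, x, m)
  zy <- as.numeric(scale(y)); zx <- as.numeric(scale(x))
  zm <- as.numeric(scale(m))
  ref2 <- lm(zy ~ zx + zm + I(zx * zm))
  expect_equal(res$step2$B, unname(coef(ref2)), tolerance = 1e-10)
  expect_equal(res$step2$SE,
               unname(sqrt(diag(vcov(ref2)))), tolerance = 1e-10)
  expect_equal(res$step2$df[1], n - 4)
  ref1 <- lm(zy ~ zx + zm)
  expect_equal(res$step1$B, unname(coef(ref1)), tolerance = 1e-10)
  expect_equal(res$delta_r2,
               summary(ref2)$r.squared - summary(ref1)$r.squared,
               tolerance = 1e-10)
  ## z-scoring invariance under affine transforms of the raw inputs
  res2 <- hierarchical_moderation(3 * y - 2, -0.5 * x + 1, 10 * m + 5)
  expect_equal(abs(res2$step2$B), abs(res$step2$B), tolerance = 1e-10)
  expect_equal(res2$step2$p, res$step2$p, tolerance = 1e-8)
})

test_that("degenerate regressions are guarded", {
  set.seed(34)
  x <- rnorm(20)
  res <- hierarchical_moderation(x, x, rnorm(20))
  expect_equal(res$step1$B[res$step1$term == "x"], 1, tolerance = 1e-8)
  expect_equal(res$step1$p[res$step1$term == "x"], 0)
  expect_error(hierarchical_moderation(rnorm(20), x, x), "collinear")
  expect_error(hierarchical_moderation(rnorm(5), rnorm(5), rnorm(5)),
               "n >= 10")
  expect_error(hierarchical_moderation(rep(1, 20), rnorm(20), rnorm(20)),
               "zero-variance")
})

test_that("simple slopes follow the closed form", {
  set.seed(35)
  n <- 80
  x <- rnorm(n); m <- rnorm(n)
  y <- 0.3 * x + 0.7 * x * m + rnorm(n)
  res <- hierarchical_moderation(y, x, m)
  ss <- simple_slopes(res, c(0.5, -0.5))
  b <- res$step2$B
  names(b) <- res$step2$term
  expect_equal(ss$slope, c(b[["x"]] + 0.5 * b[["x_m"]],
                           b[["x"]] - 0.5 * b[["x_m"]]))
  ## no interaction: equal slopes at any moderator value
  y2 <- 0.5 * x + rnorm(n)
  res2 <- hierarchical_moderation(y2, x, m)
  ss2 <- simple_slopes(res2, c(2, -2))
  expect_equal(diff(ss2$slope),
               -4 * res2$step2$B[res2$step2$term == "x_m"],
               tolerance = 1e-12, ignore_attr = TRUE)
  ## planted model: slope signs recovered at +/-0.5 SD
  signs <- replicate(20, {
    xx <- rnorm(60); mm <- rnorm(60)
    yy <- 0.7 * xx * mm + rnorm(60, sd = 0.7)
    s <- simple_slopes(hierarchical_moderation(yy, xx, mm))
    c(s$slope[s$at > 0] > 0, s$slope[s$at < 0] < 0)
  })
  expect_gte(mean(signs), 0.95)
})

test_that("subgroup correlations split at +/-0.5 SD by strict inequality", {
  set.seed(36)
  n <- 60
  m <- rnorm(n)
  pdmn <- rnorm(n); admn <- rnorm(n)
  y <- 0.8 * pdmn * (m > 0.5) + 0.8 * admn * (m < -0.5) + 0.3 * rnorm(n)
  sg <- subgroup_correlations(y, m, list(PDMN = pdmn, ADMN = admn))
  expect_equal(nrow(sg), 4)
  zm <- as.numeric(scale(m))
  expect_equal(sg$n[sg$group == "high"][1], sum(zm > 0.5))
  expect_gt(sg$r[sg$group == "high" & sg$score == "PDMN"], 0.5)
  expect_gt(sg$r[sg$group == "low" & sg$score == "ADMN"], 0.5)
  ## constant outcome within a subgroup flags NA
  ycst <- y
  ycst[zm > 0.5] <- 1
  expect_warning(sg2 <- subgroup_correlations(ycst, m,
                                              list(PDMN = pdmn)),
                 "constant")
  expect_true(is.na(sg2$r[sg2$group == "high"]))
  expect_error(subgroup_correlations(y, m, list(PDMN = pdmn),
                                     threshold_sd = 3), "fewer than 3")
})
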