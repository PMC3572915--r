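# Independent oracles used across tests.

# brute-force sliding-window count
count_windows <- function(n_samples, win, step) {
  k <- 0L
  s <- 1L
  while (s + win - 1L <= n_samples) {
    k <- k + 1L
    s <- s + step
  }
  k
}

# Spearman-Brown closed form for k parallel items with correlation rho
spearman_brown <- function(k, rho) k * rho / (1 + (k - 1) * rho)

# Small FastICA (symmetric, tanh contrast) as an ICA cross-check oracle,
# independent of the package's Infomax implementation.
fastica_oracle <- function(X, n_comp, seed = 1, max_iter = 200,
                           tol = 1e-8) {
  set.seed(seed)
  Xc <- X - rowMeans(X)
  cv <- tcrossprod(Xc) / ncol(Xc)
  e <- eigen(cv, symmetric = TRUE)
  Kw <- t(e$vectors[, 1:n_comp]) / sqrt(e$values[1:n_comp])
  Z <- Kw %*% Xc
  W <- matrix(rnorm(n_comp^2), n_comp)
  sym_dec <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_dec(W)
  for (i in seq_len(max_iter)) {
    WX <- W %*% Z
    g <- tanh(WX)
    gp <- 1 - g^2
    W1 <- g %*% t(Z) / ncol(Z) - diag(rowMeans(gp)) %*% W
    W1 <- sym_dec(W1)
    d <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (d < tol) break
  }
  W %*% Z
}

# exhaustive best permutation matching estimated to true sources by
# absolute correlation; returns min matched |cor| and the permutation
match_sources <- function(S_est, S_true) {
  k <- nrow(S_true)
  cm <- abs(stats::cor(t(S_est), t(S_true)))
  perms <- .permutations(k)
  scores <- apply(perms, 1, function(p) min(cm[cbind(seq_len(k), p)]))
  best <- which.max(scores)
  list(min_cor = scores[best], perm = perms[best, ], cor_matrix = cm)
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- .permutations(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    m <- cbind(i, sub + (sub >= i))
    out <- rbind(out, m)
  }
  out
}

# Amari index between two square mixing-like matrices (0 = perfect)
amari_index <- function(P) {
  k <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (r + c) / (2 * k * (k - 1))
}

# minimal rectangular-grid source space for cluster/significance tests
box_space <- function(nx = 8, ny = 8, nz = 8, spacing = 10) {
  g <- as.matrix(expand.grid(ix = seq_len(nx), iy = seq_len(ny),
                             iz = seq_len(nz)))
  structure(list(voxel_centers = g * spacing, spacing = spacing,
                 grid_index = g,
                 region_label = factor(rep("other_cortex", nrow(g)),
                                       levels = dmn_constants$region_levels),
                 shell_radii = dmn_constants$head_model$radii_mm),
            class = "dmn_source_space")
}

# planted-pattern group stack used by ICA recovery tests: 3 sparse
# exponential patterns, per-subject amplitudes, Gaussian noise
make_planted_stack <- function(nsub = 60, rows = 40, V = 500,
                               noise_sd = 0.3, amp_sdlog = 0.4,
                               seed = 1) {
  set.seed(seed)
  b <- floor(V / 8)
  S <- matrix(0, 3, V)
  S[1, 1:b] <- rexp(b)
  S[2, (3 * b + 1):(4 * b)] <- rexp(b)
  S[3, (6 * b + 1):(7 * b)] <- rexp(b)
  S <- S / apply(S, 1, sd)
  amp <- matrix(rlnorm(nsub * 3, 0, amp_sdlog), nsub)
  imgs <- lapply(seq_len(nsub), function(i) {
    A <- matrix(rnorm(rows * 3), rows) %*% diag(amp[i, ])
    A %*% S + matrix(rnorm(rows * V, sd = noise_sd), rows)
  })
  list(stack = new_image_stack(imgs), S = S, amp = amp)
}
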