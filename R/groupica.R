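## Group spatial ICA over concatenated per-epoch source images.
##
## Subject-wise row reduction (PCA over epochs), concatenation, group
## PCA, then Infomax spatial ICA; subject maps are recovered by GICA
## back-reconstruction through the stored reduction operators.

#' Assemble a group image stack
#'
#' @param images List of per-subject matrices (rows = epochs, columns =
#'   voxels), one per subject.
#' @param band Band label carried along for bookkeeping.
#' @return Object of class `dmn_image_stack`: `X` (rows x voxels),
#'   `subject_index` per row, `subjects`, `band`.
#' @export
new_image_stack <- function(images, band = NA_character_) {
  if (is.null(names(images)))
    names(images) <- sprintf("S%02d", seq_along(images))
  nr <- vapply(images, nrow, 0L)
  if (any(nr < 2)) stop("every subject must contribute >= 2 rows")
  X <- do.call(rbind, images)
  cv <- apply(X, 2, function(v) max(v) - min(v))
  if (any(cv == 0)) stop("constant voxel column(s) in stack: ",
                         paste(utils::head(which(cv == 0)), collapse = ","))
  structure(list(X = X,
                 subject_index = rep(seq_along(images), nr),
                 subjects = names(images), band = band),
            class = "dmn_image_stack")
}

#' Estimate the number of components by minimum description length
#'
#' Classic MDL (Wax & Kailath) over the eigenvalues of the row covariance
#' of the stack, treating voxels as samples: the description length of a
#' k-source model is the log-likelihood of equal residual eigenvalues
#' plus a `0.5 k (2p - k) log N` parameter penalty; the order is its
#' argmin.
#'
#' @param stack A `dmn_image_stack` or a plain rows x voxels matrix.
#' @return Integer estimated order in `[1, rows - 1]`.
#' @export
estimate_order_mdl <- function(stack) {
  X <- if (inherits(stack, "dmn_image_stack")) stack$X else stack
  p <- nrow(X)
  N <- ncol(X)
  Xc <- X - rowMeans(X)
  lam <- eigen(tcrossprod(Xc) / N, symmetric = TRUE,
               only.values = TRUE)$values
  lam <- pmax(lam, 0)
  if (max(lam) <= 0 || (max(lam) - min(lam)) < 1e-12 * max(lam)) {
    warning("degenerate covariance: all eigenvalues equal; order = 1")
    return(1L)
  }
  floor_ <- 1e-12 * max(lam)
  lam <- pmax(lam, floor_)
  mdl <- numeric(p)                      # index k+1 for order k
  for (k in 0:(p - 1)) {
    tail_ <- lam[(k + 1):p]
    m <- p - k
    llr <- sum(log(tail_)) / m - log(sum(tail_) / m)
    mdl[k + 1] <- -N * m * llr + 0.5 * k * (2 * p - k) * log(N)
  }
  max(1L, which.min(mdl) - 1L)
}

# deterministic sign fix for right singular vectors: largest-magnitude
# coordinate positive (first index on ties)
.fix_svd_signs <- function(sv) {
  s <- vapply(seq_len(ncol(sv$v)), function(i) {
    v <- sv$v[, i]
    sign(v[which.max(abs(v))])
  }, 0)
  s[s == 0] <- 1
  sv$v <- sweep(sv$v, 2, s, "*")
  sv$u <- sweep(sv$u, 2, s, "*")
  sv
}

# Infomax ICA (natural gradient, logistic nonlinearity) on whitened
# rows-as-components data Y (k x N).  Deterministic given the RNG state.
.infomax <- function(Y, max_iter = 500, tol = 1e-7, lrate = NULL) {
  k <- nrow(Y); N <- ncol(Y)
  if (is.null(lrate)) lrate <- 0.015 / log(k + 2)
  W <- diag(k)
  block <- max(8L, floor(sqrt(N / 3)))
  wold <- W
  change <- Inf
  for (it in seq_len(max_iter)) {
    perm <- sample.int(N)
    t0 <- 1L
    while (t0 <= N - block + 1L) {
      idx <- perm[t0:(t0 + block - 1L)]
      u <- W %*% Y[, idx, drop = FALSE]
      y <- 1 / (1 + exp(-u))
      W <- W + lrate * ((diag(k) * block + (1 - 2 * y) %*% t(u)) %*% W) /
        block
      if (max(abs(W)) > 1e8) stop("ICA weights blew up; reduce lrate")
      t0 <- t0 + block
    }
    change <- sum((W - wold)^2) / sum(W^2)
    if (it > 1 && change > oldchange * 1.1) lrate <- lrate * 0.9
    oldchange <- max(change, 1e-300)
    wold <- W
    if (change < tol) break
  }
  if (change >= tol)
    stop("Infomax ICA did not converge in ", max_iter,
         " iterations (last relative change ", signif(change, 3), ")")
  list(W = W, iterations = it, change = change)
}

#' Fit a group spatial ICA
#'
#' Two-stage reduction (per-subject PCA over rows to `r1 = round(1.5 *
#' n_components)`, concatenation, group PCA to `n_components`), then
#' Infomax spatial ICA on the whitened group data.  Component maps are
#' z-scored over voxels, sign-aligned to positive skewness, and ordered
#' by decreasing explained variance; the run is deterministic given
#' `seed`.
#'
#' @param stack A `dmn_image_stack`.
#' @param n_components Number of components (default 20).
#' @param seed Integer seed for the ICA iteration order.
#' @param ev_floor Warn if the retained per-subject PCA subspace
#'   explains less than this fraction of variance (default 0.8).
#' @return Object of class `dmn_group_decomp` with `group_maps`
#'   (components x voxels, z-scored), reduction operators, and
#'   convergence metadata.  Subject maps are filled by
#'   [back_reconstruct].
#' @export
fit_group_ica <- function(stack, n_components = 20, seed = 1,
                          ev_floor = 0.8) {
  stopifnot(inherits(stack, "dmn_image_stack"))
  X <- stack$X
  nsub <- length(stack$subjects)
  if (n_components > min(nrow(X), ncol(X)))
    stop("n_components exceeds stack rank bound")
  r1 <- max(n_components, round(1.5 * n_components))
  minrows <- min(tabulate(stack$subject_index, nsub))
  r1 <- min(r1, minrows, ncol(X))
  Zs <- vector("list", nsub)
  Us <- vector("list", nsub)
  ev1 <- numeric(nsub)
  for (i in seq_len(nsub)) {
    Xi <- X[stack$subject_index == i, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))     # remove subject mean image
    sv <- .fix_svd_signs(svd(Xi, nu = r1, nv = r1))
    Zs[[i]] <- sv$d[seq_len(r1)] * t(sv$v[, seq_len(r1), drop = FALSE])
    Us[[i]] <- sv$u
    ev1[i] <- sum(sv$d[seq_len(r1)]^2) / sum(sv$d^2)
  }
  if (mean(ev1) < ev_floor)
    warning(sprintf(
      "first-stage PCA retains %.2f of variance (< floor %.2f)",
      mean(ev1), ev_floor))
  Z <- do.call(rbind, Zs)
  svg <- .fix_svd_signs(svd(Z, nu = n_components, nv = n_components))
  dg <- svg$d[seq_len(n_components)]
  Y <- t(svg$v[, seq_len(n_components), drop = FALSE]) * sqrt(ncol(Z))
  ## Y rows are whitened spatial PCs (unit variance over voxels)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  fit <- .infomax(Y)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  S <- fit$W %*% Y                       # components x voxels
  A <- solve(fit$W)                      # mixing in whitened PC space
  ## mixing back in concatenated space: G = U_g diag(d) A / sqrt(V)
  G <- svg$u[, seq_len(n_components), drop = FALSE] %*%
    (dg * A) / sqrt(ncol(Z))
  ## order by explained variance (mixing column energy x map variance)
  sdS <- apply(S, 1, stats::sd)
  evar <- colSums(G^2) * sdS^2
  ord <- order(evar, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  G <- G[, ord, drop = FALSE]
  evar <- evar[ord]
  ## sign alignment: positive skewness, ties by positive maximum entry
  zmaps <- t(scale(t(S)))
  sk <- rowMeans(zmaps^3)
  sgn <- ifelse(abs(sk) < 1e-12,
                ifelse(max(zmaps) >= abs(min(zmaps)), 1, -1),
                sign(sk))
  zmaps <- zmaps * sgn
  G <- sweep(G, 2, sgn, "*")
  structure(list(group_maps = zmaps,
                 n_components = n_components,
                 mixing_concat = G,
                 subject_reducers = Us,
                 subject_index = stack$subject_index,
                 subjects = stack$subjects,
                 r1 = r1,
                 explained_variance = evar,
                 ev_stage1 = ev1,
                 band = stack$band,
                 seed = seed,
                 ica_iterations = fit$iterations,
                 sign_convention_applied = TRUE,
                 subject_maps = NULL),
            class = "dmn_group_decomp")
}

#' @export
print.dmn_group_decomp <- function(x, ...) {
  cat("Group spatial ICA:", x$n_components, "components,",
      length(x$subjects), "subjects,", ncol(x$group_maps), "voxels;",
      "Infomax iterations:", x$ica_iterations, "\n")
  invisible(x)
}

#' Back-reconstruct per-subject component maps
#'
#' GICA back-reconstruction: the concatenated mixing matrix is
#' partitioned into subject blocks `G_i`; each subject's maps are
#' `pinv(G_i) Z_i` with `Z_i` that subject's reduced data.  The
#' map/time-course scale indeterminacy is resolved by normalizing each
#' subject time course to unit RMS, so a subject's expression strength
#' of a component lives in that subject's map; maps are then
#' standardized with component-pooled mean and SD across subjects,
#' which preserves between-subject intensity differences (a strongly
#' expressing subject has large positive standardized values in the
#' component's support, a non-expressing subject a near-flat map).
#'
#' @param decomp A fitted `dmn_group_decomp`.
#' @param stack The `dmn_image_stack` the fit was computed from.
#' @return The decomposition with `subject_maps` (subjects x components
#'   x voxels, pooled-standardized) and `subject_loadings` (unit-RMS
#'   time courses per subject) filled.
#' @export
back_reconstruct <- function(decomp, stack) {
  stopifnot(inherits(decomp, "dmn_group_decomp"),
            inherits(stack, "dmn_image_stack"))
  if (is.null(decomp$subject_reducers))
    stop("missing reduction operators")
  nsub <- length(decomp$subjects)
  nc <- decomp$n_components
  V <- ncol(decomp$group_maps)
  r1 <- decomp$r1
  maps <- array(0, dim = c(nsub, nc, V))
  loadings <- vector("list", nsub)
  for (i in seq_len(nsub)) {
    Xi <- stack$X[stack$subject_index == i, , drop = FALSE]
    Xi <- sweep(Xi, 2, colMeans(Xi))
    Zi <- crossprod(decomp$subject_reducers[[i]], Xi)  # r1 x V
    Gi <- decomp$mixing_concat[((i - 1) * r1 + 1):(i * r1), ,
                               drop = FALSE]
    Si <- MASS::ginv(Gi) %*% Zi
    tc <- decomp$subject_reducers[[i]] %*% Gi          # rows_i x nc
    tc_rms <- sqrt(colMeans(tc^2))
    tc_rms[tc_rms < 1e-300] <- 1
    maps[i, , ] <- (Si - rowMeans(Si)) * tc_rms
    loadings[[i]] <- sweep(tc, 2, tc_rms, "/")
  }
  ## component-pooled standardization across subjects and voxels
  for (k in seq_len(nc)) {
    mk <- maps[, k, , drop = FALSE]
    maps[, k, ] <- (mk - mean(mk)) / stats::sd(mk)
  }
  decomp$subject_maps <- maps
  decomp$subject_loadings <- loadings
  decomp
}

#' Voxelwise one-sample significance map with FDR and cluster filtering
#'
#' One-sample t-test across subjects at every voxel, Benjamini-Hochberg
#' FDR over voxels, then removal of surviving clusters (face adjacency,
#' 6-connectivity) smaller than `min_cluster` voxels.
#'
#' @param subject_maps Subjects x voxels matrix for one component (or a
#'   `dmn_group_decomp` plus `component`).
#' @param space The `dmn_source_space` defining grid adjacency.
#' @param q FDR threshold (default 0.05).
#' @param min_cluster Minimum surviving cluster size (default 8).
#' @param component Component index when `subject_maps` is a
#'   decomposition.
#' @return Object of class `dmn_significance_map`: `tmap`, `p`, `padj`,
#'   `surviving_mask`, `excluded` (zero-variance voxels), `q_threshold`,
#'   `min_cluster`.
#' @export
component_significance <- function(subject_maps, space, q = 0.05,
                                   min_cluster = 8, component = NULL) {
  if (inherits(subject_maps, "dmn_group_decomp")) {
    if (is.null(subject_maps$subject_maps))
      stop("subject maps not back-reconstructed")
    stopifnot(!is.null(component))
    subject_maps <- subject_maps$subject_maps[, component, ]
  }
  n <- nrow(subject_maps)
  if (n < 3) stop("need >= 3 subjects for a one-sample t-test")
  V <- ncol(subject_maps)
  mu <- colMeans(subject_maps)
  sdv <- apply(subject_maps, 2, stats::sd)
  excluded <- sdv == 0
  tmap <- rep(NA_real_, V)
  tmap[!excluded] <- mu[!excluded] / (sdv[!excluded] / sqrt(n))
  p <- rep(NA_real_, V)
  p[!excluded] <- 2 * stats::pt(-abs(tmap[!excluded]), df = n - 1)
  padj <- rep(NA_real_, V)
  padj[!excluded] <- stats::p.adjust(p[!excluded], method = "BH")
  mask <- !is.na(padj) & padj <= q
  if (any(mask)) {
    edges <- voxel_adjacency(space)
    keep <- mask[edges[, 1]] & mask[edges[, 2]]
    sub <- which(mask)
    relabel <- match(seq_len(V), sub)
    gr <- igraph::graph_from_edgelist(
      cbind(relabel[edges[keep, 1]], relabel[edges[keep, 2]]),
      directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, length(sub) -
                                            igraph::vcount(gr)))
    comp <- igraph::components(gr)
    small <- which(comp$csize[comp$membership] < min_cluster)
    mask[sub[small]] <- FALSE
  }
  structure(list(component_id = component, tmap = tmap, p = p,
                 padj = padj, surviving_mask = mask,
                 excluded = excluded, q_threshold = q,
                 min_cluster = min_cluster, n_subjects = n),
            class = "dmn_significance_map")
}
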