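## sLORETA standardized inverse imaging.
##
## The minimum-norm inverse T = K' (K K' + a H)^+ (H the average-reference
## centering projector) yields current-density estimates that sLORETA
## standardizes by the 3x3 diagonal blocks of the model resolution matrix
## T K.  For a noiseless single dipole and a = 0 the standardized power
## peaks exactly at the true voxel.

# Moore-Penrose pseudoinverse of a symmetric PSD matrix
.sym_pinv <- function(M, rtol = 1e-12) {
  e <- eigen(M, symmetric = TRUE)
  pos <- e$values > rtol * max(e$values)
  if (!any(pos)) stop("singular system: no usable eigenvalues")
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

# inverse principal square root of a symmetric positive definite matrix
.spd_inv_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("standardization block not positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Build the sLORETA inverse operator
#'
#' Computes `T = K' (K K' + a H)^+` on the average-reference-projected
#' lead field, with `H` the centering projector and
#' `a = alpha_frac * trace(K K') / n_channels` (so `alpha_frac` is a
#' dimensionless regularization fraction; default 1/100).  The 3x3
#' diagonal blocks of the resolution matrix `T K` standardize each
#' voxel's estimate; the pre-standardized rows `Tstd = S^{-1/2} T` are
#' stored so that standardized power is a plain quadratic form.
#'
#' @param K A `dmn_lead_field` (any reference; it is average-reference
#'   projected internally).
#' @param alpha_frac Regularization fraction (>= 0, default 0.01).
#' @return Object of class `dmn_inverse`: `T` ((3V) x channels), `Tstd`
#'   ((3V) x channels), `blocks` (3 x 3 x V resolution blocks), `alpha`,
#'   `alpha_frac`, `n_voxels`.
#' @export
build_sloreta_operator <- function(K, alpha_frac = 1 / 100) {
  stopifnot(inherits(K, "dmn_lead_field"))
  if (alpha_frac < 0) stop("alpha_frac must be >= 0")
  G <- apply_reference(K$gain, "average", K$montage)
  nch <- nrow(G)
  H <- diag(nch) - matrix(1 / nch, nch, nch)
  GG <- tcrossprod(G)
  alpha <- alpha_frac * sum(diag(GG)) / nch
  Tm <- crossprod(G, .sym_pinv(GG + alpha * H))
  V <- K$n_voxels
  blocks <- array(0, dim = c(3, 3, V))
  Tstd <- matrix(0, nrow(Tm), ncol(Tm))
  for (j in seq_len(V)) {
    rows <- 3L * (j - 1L) + 1:3
    S <- Tm[rows, , drop = FALSE] %*% G[, rows, drop = FALSE]
    blocks[, , j] <- (S + t(S)) / 2
    Tstd[rows, ] <- .spd_inv_sqrt(blocks[, , j]) %*%
      Tm[rows, , drop = FALSE]
  }
  structure(list(T = Tm, Tstd = Tstd, blocks = blocks, alpha = alpha,
                 alpha_frac = alpha_frac, n_voxels = V,
                 n_channels = nch,
                 channel_names = K$montage$channel_names),
            class = "dmn_inverse")
}

#' @export
print.dmn_inverse <- function(x, ...) {
  cat("sLORETA operator:", x$n_voxels, "voxels x", x$n_channels,
      "channels, alpha_frac =", x$alpha_frac, "\n")
  invisible(x)
}

# double-center a cross-spectral matrix: H C H, H = I - 11'/n
.center_csd <- function(C) {
  n <- nrow(C)
  rm_ <- rowMeans(C); cm_ <- colMeans(C); gm <- mean(C)
  C - matrix(rm_, n, n) - matrix(cm_, n, n, byrow = TRUE) + gm
}

#' Standardized source power image from a band cross-spectrum
#'
#' Per voxel j the standardized power is
#' `Re trace(S_jj^{-1} T_j C T_j^H)` over the three orientations.  Small
#' negative values from floating-point Hermitian averaging are clipped
#' to zero.
#'
#' @param op A `dmn_inverse` operator.
#' @param C A `dmn_cross_spectrum` or a plain Hermitian channels x
#'   channels matrix.
#' @return Object of class `dmn_source_image`: `values` (non-negative,
#'   one per voxel), `band`, `subject_id`.
#' @export
source_band_power <- function(op, C) {
  band <- NA_character_; subject_id <- NA_character_
  if (inherits(C, "dmn_cross_spectrum")) {
    band <- C$band; subject_id <- C$subject_id; C <- C$matrix
  }
  if (nrow(C) != op$n_channels)
    stop("channel count mismatch between operator and cross-spectrum")
  herm_err <- max(abs(C - Conj(t(C))))
  if (herm_err > 1e-8 * max(1e-300, max(abs(C))))
    stop("input matrix is not Hermitian")
  ev <- eigen((C + Conj(t(C))) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  tol <- 1e-9 * max(abs(sum(Re(diag(C)))), .Machine$double.eps)
  if (min(ev) < -tol)
    stop("input cross-spectrum is not positive semidefinite")
  Cc <- .center_csd(C)
  G <- op$Tstd %*% Cc
  q <- Re(rowSums(G * op$Tstd))          # diag(Tstd C Tstd'), Tstd real
  vals <- colSums(matrix(q, nrow = 3))
  mx <- max(vals, 0)
  vals[vals < 0 & vals > -1e-9 * max(mx, 1)] <- 0
  vals[vals < 0] <- 0
  structure(list(values = vals, band = band, subject_id = subject_id,
                 n_voxels = op$n_voxels),
            class = "dmn_source_image")
}

#' Per-epoch standardized band power images
#'
#' Computes one standardized source image per epoch from that epoch's
#' tapered Fourier coefficients in the band, the per-epoch analogue of
#' [source_band_power] used to build the group-ICA image stack.
#'
#' @param op A `dmn_inverse` operator.
#' @param es A `dmn_epochs` object.
#' @param bands Named list of band edges (Hz).
#' @return Named list (per band) of n_epochs x n_voxels matrices.
#' @export
source_band_power_epochs <- function(op, es,
                                     bands = dmn_constants$bands) {
  stopifnot(inherits(es, "dmn_epochs"))
  if (dim(es$epochs)[2] != op$n_channels)
    stop("channel count mismatch between operator and epochs")
  sp <- .epoch_spectra(es)
  ne <- dim(sp$coef)[1]
  nch <- dim(sp$coef)[2]
  out <- list()
  for (b in names(bands)) {
    bins <- .band_bins(sp$freqs, bands[[b]])
    if (!length(bins)) stop("band ", b, " has no frequency bins")
    ## stack all epoch x bin Fourier vectors as columns, centre
    ## (average reference), propagate through Tstd, accumulate |y|^2
    X <- sp$coef[, , bins, drop = FALSE]
    dim(X) <- c(ne, nch * length(bins))
    X <- matrix(t(X), nrow = nch)        # nch x (bins*ne), epoch-major
    X <- sweep(X, 2, colMeans(Re(X)) + 1i * colMeans(Im(X)), "-")
    Yr <- op$Tstd %*% Re(X)
    Yi <- op$Tstd %*% Im(X)
    P <- Yr^2 + Yi^2                     # 3V x (bins*ne)
    P3 <- rowsum(P, rep(seq_len(op$n_voxels), each = 3))
    grp <- rep(seq_len(ne), each = length(bins))
    img <- t(rowsum(t(P3), grp)) / length(bins) * sp$scale
    out[[b]] <- t(img)                   # epochs x voxels
  }
  out
}

#' Export a source image (or any per-voxel vector) as NIfTI
#'
#' @param values A `dmn_source_image` or numeric per-voxel vector.
#' @param space The `dmn_source_space` the values live on.
#' @param path Output `.nii` / `.nii.gz` path (off-grid voxels zero).
#' @return `path`, invisibly.
#' @export
write_source_nifti <- function(values, space, path) {
  if (inherits(values, "dmn_source_image")) values <- values$values
  stopifnot(length(values) == n_voxels(space))
  vol <- .embed_volume(space, values)
  img <- RNifti::asNifti(vol, pixdim = rep(space$spacing, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}
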