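## Three-shell spherical-head EEG lead field.
##
## The scalp potential of a current dipole inside a set of concentric
## conducting shells has the classic Legendre-series solution: expand the
## infinite-medium dipole potential about the sphere centre, then match
## potential and radial current density at every conductivity interface
## and impose zero radial current at the scalp surface.  Per spherical
## degree n this is a small linear system; its solution gives a surface
## gain factor per degree, and the potential at an electrode follows by
## summing the series in the angle between electrode and dipole.

# Per-degree surface factors for the layered sphere.
#
# Radii are normalised by the scalp radius.  Unknowns are scaled per
# region (A1*r1^n, A2*r2^n, B2*r1^-(n+1), A3, B3*r2^-(n+1)) so the per-n
# 5x5 systems stay well conditioned at high degree.  The source term is
# normalised to unit primary potential at the brain-shell radius; the
# caller multiplies by (b/r1)^(n-1) * r1^-2 for a dipole at normalised
# radius b.  Returned: S_n = surface potential per unit source at r1.
.sphere_surface_factors <- function(radii_norm, cond, order) {
  r1 <- radii_norm[["brain"]]
  r2 <- radii_norm[["skull"]]
  s1 <- cond[["brain"]]; s2 <- cond[["skull"]]; s3 <- cond[["scalp"]]
  S <- numeric(order)
  for (n in seq_len(order)) {
    q12 <- (r1 / r2)^n
    q12b <- (r1 / r2)^(n + 1)
    r2n <- r2^n
    r2n1 <- r2^(n + 1)
    np1 <- n + 1
    ## unknowns: u1 = A1 r1^n, u2 = A2 r2^n, v2 = B2 r1^-(n+1),
    ##           u3 = A3,      v3 = B3 r2^-(n+1)
    A <- matrix(0, 5, 5)
    b <- numeric(5)
    # continuity at r1
    A[1, ] <- c(1, -q12, -1, 0, 0); b[1] <- -1
    # radial current at r1 (times r1)
    A[2, ] <- c(s1 * n, -s2 * n * q12, s2 * np1, 0, 0); b[2] <- s1 * np1
    # continuity at r2
    A[3, ] <- c(0, 1, q12b, -r2n, -1); b[3] <- 0
    # radial current at r2 (times r2)
    A[4, ] <- c(0, s2 * n, -s2 * np1 * q12b, -s3 * n * r2n, s3 * np1)
    b[4] <- 0
    # insulating scalp surface at radius 1
    A[5, ] <- c(0, 0, 0, n, -np1 * r2n1); b[5] <- 0
    x <- solve(A, b)
    S[n] <- x[4] + x[5] * r2n1
  }
  S
}

# Legendre P_n(x) and associated P_n^1(x) = sqrt(1-x^2) P_n'(x) for
# n = 1..order; x a vector.  Returns list of order x length(x) matrices.
.legendre_tables <- function(x, order) {
  m <- length(x)
  P <- matrix(0, order, m)
  P1 <- matrix(0, order, m)
  sx <- sqrt(pmax(0, 1 - x^2))
  P[1, ] <- x
  if (order >= 2) P[2, ] <- 0.5 * (3 * x^2 - 1)
  P1[1, ] <- sx
  if (order >= 2) P1[2, ] <- 3 * x * sx
  if (order >= 3) {
    pm2 <- rep(1, m); pm1 <- x             # P_0, P_1
    for (n in 2:order) {
      pn <- ((2 * n - 1) * x * pm1 - (n - 1) * pm2) / n
      P[n, ] <- pn
      pm2 <- pm1; pm1 <- pn
    }
    for (n in 2:(order - 1)) {
      # n P^1_{n+1} = (2n+1) x P^1_n - (n+1) P^1_{n-1}, seed P^1_0 = 0
      prev <- if (n == 1) 0 else P1[n - 1, ]
      P1[n + 1, ] <- ((2 * n + 1) * x * P1[n, ] - (n + 1) * prev) / n
    }
  }
  list(P = P, P1 = P1)
}

#' Compute the three-shell spherical lead field
#'
#' Gain matrix mapping unit dipole moments (A m) at every source-space
#' voxel, for the three Cartesian orientations, to referenced scalp
#' potentials (V) at the montage electrodes.  Columns are ordered
#' voxel-major, orientation-minor (x, y, z).  The returned potentials are
#' referenced according to `montage$reference_scheme`.
#'
#' @param montage A `dmn_montage` whose head radius equals the scalp
#'   shell radius of `model`.
#' @param space A `dmn_source_space` built inside the brain shell.
#' @param model Head-model parameters: list with `radii_mm` (named
#'   scalp/skull/brain) and `conductivities` (S/m); defaults to the
#'   standard three-shell values in [dmn_constants].
#' @param order Series truncation degree.  The default satisfies a
#'   truncation error below 1e-6 of each gain-column norm for sources up
#'   to 95% of the brain-shell radius.
#' @return Object of class `dmn_lead_field`: `gain` (channels x 3V),
#'   `head_model`, `montage`, `space_spacing`, `reference_scheme`.
#' @export
compute_lead_field <- function(montage, space,
                               model = dmn_constants$head_model,
                               order = model$series_order) {
  r <- model$radii_mm
  if (abs(montage$head_radius_mm - r[["scalp"]]) > 1e-9 * r[["scalp"]])
    stop("montage head radius does not match the scalp shell radius")
  rad <- sqrt(rowSums(space$voxel_centers^2))
  if (any(rad >= r[["brain"]]))
    stop("source voxel outside the inner (brain) shell")
  if (order < 10) stop("series order too small to converge")
  R <- r[["scalp"]]
  radii_norm <- r / R
  S <- .sphere_surface_factors(radii_norm, model$conductivities, order)
  r1 <- radii_norm[["brain"]]
  ns <- seq_len(order)
  elec <- montage$positions / R          # unit electrode directions
  nch <- nrow(elec)
  V <- nrow(space$voxel_centers)
  K <- matrix(0, nch, 3L * V)
  sigma1 <- model$conductivities[["brain"]]
  R_m <- R / 1000                        # metres
  pref <- 1 / (4 * pi * sigma1 * R_m^2)
  for (j in seq_len(V)) {
    pos <- space$voxel_centers[j, ] / R  # normalised dipole position
    b <- sqrt(sum(pos^2))
    if (b < 1e-12) {
      zhat <- c(0, 0, 1)                 # degenerate: centre dipole
      b <- 0
    } else zhat <- pos / b
    cosg <- drop(elec %*% zhat)
    cosg <- pmax(-1, pmin(1, cosg))
    leg <- .legendre_tables(cosg, order)
    # per-degree weights: S_n * (b/r1)^(n-1) / r1^2
    w <- S * (b / r1)^(ns - 1) / r1^2
    F1 <- drop(crossprod(leg$P, w * ns))   # radial sum per electrode
    F2 <- drop(crossprod(leg$P1, w))       # tangential sum per electrode
    # tangential unit vector at each electrode, in the dipole frame
    tvec <- elec - outer(cosg, zhat)
    tn <- sqrt(rowSums(tvec^2))
    ok <- tn > 1e-12
    tvec[ok, ] <- tvec[ok, ] / tn[ok]
    tvec[!ok, ] <- 0
    cols <- 3L * (j - 1L) + 1:3
    # potential for unit moment along axis k: pref*(zhat_k F1 + t_k F2)
    K[, cols] <- pref * (outer(F1, zhat) + F2 * tvec)
  }
  rownames(K) <- montage$channel_names
  K <- apply_reference(K, montage$reference_scheme, montage)
  structure(list(gain = K,
                 head_model = model[c("radii_mm", "conductivities")],
                 series_order = order,
                 montage = montage,
                 space_spacing = space$spacing,
                 n_voxels = V,
                 reference_scheme = montage$reference_scheme),
            class = "dmn_lead_field")
}

#' @export
print.dmn_lead_field <- function(x, ...) {
  cat("Three-shell spherical lead field:", nrow(x$gain), "channels x",
      ncol(x$gain), "columns (", x$n_voxels, "voxels x 3 ),",
      "reference:", x$reference_scheme, "\n")
  invisible(x)
}
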