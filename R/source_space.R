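#' Build the labelled cortical source grid
#'
#' Constructs a cubic voxel grid clipped to a spherical cortical shell
#' (between 55% and 95% of the brain-shell radius, upper hemisphere plus
#' a band extending 20 mm below the equator) and labels every voxel with
#' one of six angular-sector region labels: `MF_SF` (medial/superior
#' frontal), `ACC` (anterior cingulate), `PPC` (posterior parietal),
#' `OPJ` (occipito-parietal junction), `PCC_precuneus` (posterior
#' cingulate / precuneus) and `other_cortex`.  The sector bounds are
#' fixed in [dmn_constants].
#'
#' @param spacing_mm Grid step in millimetres (>= 5).
#' @param shell_radii Named numeric vector with `scalp`, `skull`, `brain`
#'   radii in mm (defaults to the standard three-shell model).
#' @return An object of class `dmn_source_space`: `voxel_centers`
#'   (V x 3, mm), `spacing`, `region_label` (factor), `grid_index`
#'   (V x 3 integer grid coordinates), `shell_radii`.
#' @examples
#' sp <- build_source_space(15)
#' table(sp$region_label)
#' @export
build_source_space <- function(spacing_mm = 15,
                               shell_radii = dmn_constants$head_model$radii_mm) {
  if (!is.numeric(spacing_mm) || spacing_mm < 5)
    stop("spacing_mm must be >= 5 mm")
  r <- shell_radii
  if (!(r[["brain"]] < r[["skull"]] && r[["skull"]] < r[["scalp"]]))
    stop("shell radii must satisfy brain < skull < scalp")
  rb <- r[["brain"]]
  clip <- dmn_constants$grid_clip
  kmax <- floor(rb / spacing_mm)
  ax <- (-kmax):kmax
  g <- as.matrix(expand.grid(ix = ax, iy = ax, iz = ax))
  xyz <- g * spacing_mm
  rad <- sqrt(rowSums(xyz^2))
  keep <- rad >= clip$r_frac[["lo"]] * rb &
          rad <= clip$r_frac[["hi"]] * rb &
          xyz[, 3] >= clip$z_min_mm
  xyz <- xyz[keep, , drop = FALSE]
  g <- g[keep, , drop = FALSE]
  lab <- .label_sectors(xyz)
  lev <- dmn_constants$region_levels
  counts <- table(factor(lab, levels = lev))
  required <- setdiff(lev, "other_cortex")
  if (any(counts[required] == 0))
    stop("spacing too coarse: empty region label(s): ",
         paste(required[counts[required] == 0], collapse = ", "))
  colnames(xyz) <- c("x", "y", "z")
  colnames(g) <- c("ix", "iy", "iz")
  structure(list(voxel_centers = xyz,
                 spacing = spacing_mm,
                 region_label = factor(lab, levels = lev),
                 grid_index = g,
                 shell_radii = r,
                 constants_version = dmn_constants$constants_version),
            class = "dmn_source_space")
}

# first-match sector labelling on unit directions
.label_sectors <- function(xyz) {
  u <- xyz / sqrt(rowSums(xyz^2))
  s <- dmn_constants$sectors
  lab <- rep("other_cortex", nrow(u))
  ux <- abs(u[, 1]); uy <- u[, 2]; uz <- u[, 3]
  pick <- function(cond, name) {
    hit <- cond & lab == "other_cortex"
    lab[hit] <<- name
  }
  pick(uy >= s$MF_SF$y_min & ux <= s$MF_SF$x_abs_max &
       uz >= s$MF_SF$z_min, "MF_SF")
  pick(uy >= s$ACC$y_min & ux <= s$ACC$x_abs_max &
       uz < s$ACC$z_max, "ACC")
  pick(uy <= s$PCC_precuneus$y_max & ux <= s$PCC_precuneus$x_abs_max,
       "PCC_precuneus")
  pick(uy <= s$PPC$y_max & uz >= s$PPC$z_min, "PPC")
  pick(uy <= s$OPJ$y_max & uz < s$OPJ$z_max, "OPJ")
  lab
}

#' @export
print.dmn_source_space <- function(x, ...) {
  cat("Cortical source grid:", nrow(x$voxel_centers), "voxels at",
      x$spacing, "mm spacing\n")
  print(table(x$region_label))
  invisible(x)
}

#' Number of voxels in a source space
#' @param space A `dmn_source_space`.
#' @return Integer voxel count.
#' @export
n_voxels <- function(space) nrow(space$voxel_centers)

#' Face-adjacency (6-connectivity) edge list of the voxel grid
#'
#' @param space A `dmn_source_space` (or any list with an integer
#'   `grid_index` matrix).
#' @return Two-column integer matrix of voxel index pairs sharing a face.
#' @keywords internal
voxel_adjacency <- function(space) {
  g <- space$grid_index
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  idx <- seq_len(nrow(g))
  lookup <- stats::setNames(idx, key(g))
  edges <- NULL
  for (d in 1:3) {
    gn <- g
    gn[, d] <- gn[, d] + 1L
    j <- lookup[key(gn)]
    ok <- !is.na(j)
    if (any(ok)) edges <- rbind(edges, cbind(idx[ok], unname(j[ok])))
  }
  if (is.null(edges)) matrix(integer(0), 0, 2) else edges
}

#' Serialize a montage or source space to JSON
#' @param x A `dmn_montage` or `dmn_source_space`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(x, path) {
  obj <- unclass(x)
  obj$.class <- class(x)[1]
  jsonlite::write_json(obj, path, digits = NA, pretty = TRUE,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Export the source-space label volume as NIfTI
#'
#' Embeds the voxel grid in a dense integer volume (0 off-grid, region
#' label codes 1..6 on-grid) for visualization.
#'
#' @param space A `dmn_source_space`.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_labels_nifti <- function(space, path) {
  vol <- .embed_volume(space, as.integer(space$region_label))
  img <- RNifti::asNifti(vol, pixdim = rep(space$spacing, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# embed per-voxel values into a dense 3-D array on the grid
.embed_volume <- function(space, values, fill = 0) {
  g <- space$grid_index
  off <- apply(g, 2, min)
  dims <- apply(g, 2, max) - off + 1L
  vol <- array(fill, dim = dims)
  vol[cbind(g[, 1] - off[1] + 1L, g[, 2] - off[2] + 1L,
            g[, 3] - off[3] + 1L)] <- values
  vol
}
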