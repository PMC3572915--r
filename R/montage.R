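## Idealised spherical 10-20 / 10-10 electrode geometry.
##
## Electrodes are placed on a sphere using the classic arc construction:
## the vertex (Cz) at inclination 0, the nasion-inion and ear-to-ear arcs
## divided in 10% / 20% steps (18 / 36 degrees), and intermediate sites
## obtained by great-circle interpolation between a lateral ring electrode
## and the corresponding midline electrode of the same coronal row.

# unit vector from inclination (degrees from +z) and azimuth (degrees from
# +y = anterior, positive toward +x = right)
.ang_pos <- function(incl, az) {
  ti <- incl * pi / 180
  ta <- az * pi / 180
  c(sin(ti) * sin(ta), sin(ti) * cos(ta), cos(ti))
}

# great-circle interpolation from unit vector a to b, fraction t
.slerp <- function(a, b, t) {
  om <- acos(max(-1, min(1, sum(a * b))))
  if (om < 1e-12) return(a)
  (sin((1 - t) * om) * a + sin(t * om) * b) / sin(om)
}

# electrode definitions: either c(incl, az) or list(from, to, frac)
.electrode_defs <- function() {
  defs <- list(
    ## midline
    Fpz = c(72, 0), AFz = c(54, 0), Fz = c(36, 0), FCz = c(18, 0),
    Cz = c(0, 0), CPz = c(18, 180), Pz = c(36, 180), POz = c(54, 180),
    Oz = c(72, 180),
    ## 10% lateral ring (inclination 72)
    Fp1 = c(72, -18), Fp2 = c(72, 18),
    AF7 = c(72, -36), AF8 = c(72, 36),
    F7 = c(72, -54), F8 = c(72, 54),
    FT7 = c(72, -72), FT8 = c(72, 72),
    T7 = c(72, -90), T8 = c(72, 90),
    TP7 = c(72, -108), TP8 = c(72, 108),
    P7 = c(72, -126), P8 = c(72, 126),
    PO7 = c(72, -144), PO8 = c(72, 144),
    O1 = c(72, -162), O2 = c(72, 162),
    ## lowest ring (inclination 90, through the pre-auricular points)
    FT9 = c(90, -72), FT10 = c(90, 72),
    TP9 = c(90, -108), TP10 = c(90, 108),
    ## interpolated rows (lateral ring electrode -> midline electrode)
    AF3 = list("AF7", "AFz", 0.5), AF4 = list("AF8", "AFz", 0.5),
    F5 = list("F7", "Fz", 0.25), F3 = list("F7", "Fz", 0.5),
    F1 = list("F7", "Fz", 0.75),
    F6 = list("F8", "Fz", 0.25), F4 = list("F8", "Fz", 0.5),
    F2 = list("F8", "Fz", 0.75),
    FC5 = list("FT7", "FCz", 0.25), FC3 = list("FT7", "FCz", 0.5),
    FC1 = list("FT7", "FCz", 0.75),
    FC6 = list("FT8", "FCz", 0.25), FC4 = list("FT8", "FCz", 0.5),
    FC2 = list("FT8", "FCz", 0.75),
    C5 = list("T7", "Cz", 0.25), C3 = list("T7", "Cz", 0.5),
    C1 = list("T7", "Cz", 0.75),
    C6 = list("T8", "Cz", 0.25), C4 = list("T8", "Cz", 0.5),
    C2 = list("T8", "Cz", 0.75),
    CP5 = list("TP7", "CPz", 0.25), CP3 = list("TP7", "CPz", 0.5),
    CP1 = list("TP7", "CPz", 0.75),
    CP6 = list("TP8", "CPz", 0.25), CP4 = list("TP8", "CPz", 0.5),
    CP2 = list("TP8", "CPz", 0.75),
    P5 = list("P7", "Pz", 0.25), P3 = list("P7", "Pz", 0.5),
    P1 = list("P7", "Pz", 0.75),
    P6 = list("P8", "Pz", 0.25), P4 = list("P8", "Pz", 0.5),
    P2 = list("P8", "Pz", 0.75),
    PO3 = list("PO7", "POz", 0.5), PO4 = list("PO8", "POz", 0.5)
  )
  defs
}

.channel_sets <- list(
  `19` = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
           "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2"),
  `32` = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT9", "FC5",
           "FC1", "FC2", "FC6", "FT10", "T7", "C3", "Cz", "C4", "T8",
           "TP9", "CP5", "CP1", "CP2", "CP6", "TP10", "P7", "P3", "Pz",
           "P4", "P8", "O1", "Oz", "O2"),
  `64` = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT9", "FC5",
           "FC1", "FC2", "FC6", "FT10", "T7", "C3", "Cz", "C4", "T8",
           "TP9", "CP5", "CP1", "CP2", "CP6", "TP10", "P7", "P3", "Pz",
           "P4", "P8", "O1", "Oz", "O2",
           "AF7", "AF3", "AFz", "AF4", "AF8", "F5", "F1", "F2",
           "F6", "FT7", "FC3", "FCz", "FC4", "FT8", "C5", "C1", "C2",
           "C6", "TP7", "CP3", "CPz", "CP4", "TP8", "P5", "P1", "P2",
           "P6", "PO7", "PO3", "POz", "PO4", "PO8")
)

# lowest posterior-lateral pair, used as the linked-mastoid proxies
.mastoid_proxies <- list(`19` = c("P7", "P8"),
                         `32` = c("TP9", "TP10"),
                         `64` = c("TP9", "TP10"))

#' Build an idealised 10-20 / 10-10 electrode montage on a sphere
#'
#' Returns standard electrode positions projected onto the outer (scalp)
#' shell of the spherical head model.  The 19-channel set is the classic
#' 10-20 montage; the 32- and 64-channel sets add standard intermediate
#' 10-10 sites.  The two lowest posterior-lateral electrodes are flagged
#' as proxies for the linked-mastoid reference.
#'
#' @param n_channels One of 19, 32 or 64.
#' @param head_radius_mm Scalp (outer-shell) radius in millimetres.
#' @param reference_scheme `"linked_mastoids"` (default) or `"average"`.
#' @return An object of class `dmn_montage`: a list with `channel_names`,
#'   `positions` (channels x 3 matrix, mm, rows on the scalp sphere),
#'   `reference_scheme`, `mastoid_proxies` and `head_radius_mm`.
#' @examples
#' mon <- build_montage(32, 92)
#' mon$channel_names[1:5]
#' @export
build_montage <- function(n_channels, head_radius_mm = 92,
                          reference_scheme = c("linked_mastoids",
                                               "average")) {
  reference_scheme <- match.arg(reference_scheme)
  key <- as.character(n_channels)
  if (!key %in% names(.channel_sets))
    stop("unsupported channel count: ", n_channels,
         " (supported: 19, 32, 64)")
  if (!is.numeric(head_radius_mm) || head_radius_mm <= 0)
    stop("head_radius_mm must be positive")
  defs <- .electrode_defs()
  resolve <- function(name) {
    d <- defs[[name]]
    if (is.list(d)) .slerp(resolve(d[[1]]), resolve(d[[2]]), d[[3]])
    else .ang_pos(d[1], d[2])
  }
  labels <- .channel_sets[[key]]
  pos <- t(vapply(labels, resolve, numeric(3))) * head_radius_mm
  colnames(pos) <- c("x", "y", "z")
  structure(list(channel_names = labels,
                 positions = pos,
                 reference_scheme = reference_scheme,
                 mastoid_proxies = .mastoid_proxies[[key]],
                 head_radius_mm = head_radius_mm),
            class = "dmn_montage")
}

#' @export
print.dmn_montage <- function(x, ...) {
  cat("Spherical 10-20 montage:", length(x$channel_names), "channels,",
      "scalp radius", x$head_radius_mm, "mm\n")
  cat("Reference:", x$reference_scheme,
      "(mastoid proxies:", paste(x$mastoid_proxies, collapse = ", "),
      ")\n")
  invisible(x)
}

#' Re-reference channel data or a lead field
#'
#' Applies the linked-mastoid or average reference to a channels x time
#' data matrix or to a lead field (whose rows are channels).  Both
#' operations subtract a common signal from every channel and are
#' idempotent; converting between references is exact because a reference
#' change only ever removes a channel-common component.
#'
#' @param lead_or_data A `dmn_lead_field` object or a numeric matrix with
#'   channels in rows.
#' @param scheme `"linked_mastoids"` or `"average"`.
#' @param montage The montage the rows refer to (required for
#'   `"linked_mastoids"`, used for channel bookkeeping otherwise).
#' @return Same type as the input, re-referenced.
#' @export
apply_reference <- function(lead_or_data,
                            scheme = c("linked_mastoids", "average"),
                            montage = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(lead_or_data, "dmn_lead_field")) {
    lf <- lead_or_data
    if (is.null(montage)) montage <- lf$montage
    lf$gain <- apply_reference(lf$gain, scheme, montage)
    lf$reference_scheme <- scheme
    return(lf)
  }
  x <- lead_or_data
  if (!is.matrix(x)) stop("data must be a channels x time matrix")
  if (scheme == "average") {
    ref <- colMeans(x)
  } else {
    if (is.null(montage))
      stop("montage required for the linked-mastoid reference")
    idx <- match(montage$mastoid_proxies, montage$channel_names)
    if (anyNA(idx))
      stop("mastoid proxy channels absent from montage")
    if (nrow(x) != length(montage$channel_names))
      stop("row count does not match montage channel count")
    ref <- colMeans(x[idx, , drop = FALSE])
  }
  sweep(x, 2, ref, "-")
}
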