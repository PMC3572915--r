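#' Versioned geometric and spectral constants
#'
#' All numeric conventions that downstream stages depend on live here so
#' that they are fixed in one place: three-shell head-model defaults,
#' the angular-sector bounds that carve the cortical source shell into
#' labelled regions, and the frequency-band edges.
#'
#' Coordinates are right-handed: +x right, +y anterior (nose), +z superior,
#' origin at the sphere centre; all lengths in millimetres.
#'
#' @format A list with elements `head_model`, `sectors`, `bands`,
#'   `grid_clip`, `constants_version`.
#' @export
dmn_constants <- list(
  constants_version = "1.0",

  ## Three-shell spherical head model: scalp / skull / brain radii (mm)
  ## and conductivities (S/m).  Standard literature values.
  head_model = list(
    radii_mm = c(scalp = 92, skull = 85, brain = 81),
    conductivities = c(scalp = 0.33, skull = 0.0042, brain = 0.33),
    series_order = 150L
  ),

  ## Cortical source shell: voxels kept between these fractions of the
  ## brain-shell radius, upper hemisphere plus a band below the equator.
  grid_clip = list(
    r_frac = c(lo = 0.55, hi = 0.95),
    z_min_mm = -20
  ),

  ## Angular-sector labelling rules, applied to the unit direction
  ## u = v/|v| of each voxel, in the precedence order given here (first
  ## match wins).  Anterior sectors emulate medial/superior frontal and
  ## anterior cingulate territory; posterior sectors emulate posterior
  ## parietal cortex, the occipito-parietal junction and the posterior
  ## cingulate/precuneus.
  sectors = list(
    MF_SF = list(y_min = 0.35, x_abs_max = 0.50, z_min = 0.15),
    ACC = list(y_min = 0.35, x_abs_max = 0.50, z_max = 0.15),
    PCC_precuneus = list(y_max = -0.20, x_abs_max = 0.30),
    PPC = list(y_max = -0.35, z_min = 0.35),
    OPJ = list(y_max = -0.35, z_max = 0.35)
  ),
  region_levels = c("MF_SF", "ACC", "PPC", "OPJ", "PCC_precuneus",
                    "other_cortex"),
  anterior_labels = c("MF_SF", "ACC"),
  posterior_labels = c("PPC", "OPJ", "PCC_precuneus"),

  ## Frequency-band edges in Hz; bins are included half-open [low, high).
  bands = list(
    delta = c(2, 4), theta = c(4, 8), alpha = c(8, 12),
    beta = c(12, 30), gamma = c(30, 45)
  )
)
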