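## Synthetic resting-EEG cohort with known ground truth.
##
## Two coherent alpha-band cortical patches (anterior medial-frontal and
## posterior parietal/midline) with subject-varying amplitudes are
## projected through the three-shell lead field, on top of 1/f background
## sources and sensor noise.  A questionnaire table with a planted
## four-factor item structure and a planted amplitude x moderator
## interaction on one outcome item accompanies the EEG.

#' Cohort configuration
#'
#' Defaults define the reference study conditions: 60 subjects, 32
#' channels at 300 Hz, 3 minutes of eyes-closed data, 10 Hz alpha
#' patches on the anterior and posterior DMN sectors, lognormal
#' subject amplitudes, and an outcome generated as
#' `beta1 * PA + beta2 * m + beta3 * PA * m + eps` with
#' `PA = z(a_P) - z(a_A)`.
#'
#' @param n_subjects Number of subjects (>= 4; default 60).
#' @param fs Sampling rate, Hz (default 300).
#' @param duration_s Eyes-closed duration per subject, seconds
#'   (default 180, which at 50% epoch overlap yields per-subject epoch
#'   counts near the top of the 85-210 range typical of resting
#'   eyes-closed protocols).
#' @param n_channels Montage size (default 32).
#' @param spacing_mm Source-grid spacing (default 15).
#' @param anterior_labels,posterior_labels Region labels carrying the
#'   planted patches.
#' @param patch_radius_mm Optional radius (mm) restricting each patch
#'   around its label-set centroid (default `Inf` = all label voxels).
#' @param alpha_center_hz,alpha_bw_hz Centre and bandwidth of the
#'   planted narrowband alpha sources (default 10 and 2 Hz).
#' @param amp_dispersion Lognormal sdlog of the subject amplitudes
#'   (default 0.35).
#' @param snr Ratio of planted-patch scalp alpha RMS (at unit amplitude)
#'   to the alpha-band RMS of the combined background + sensor noise
#'   (default 3).
#' @param n_background Number of 1/f background sources (default 12).
#' @param bg_exponent Spectral exponent of the background (default 1).
#' @param bg_rms_uv Scalp RMS per background source, microvolts
#'   (default 1).
#' @param sensor_noise_uv Sensor white-noise SD, microvolts (default 1).
#' @param beta1,beta2,beta3 Outcome model coefficients (defaults 0, 0,
#'   0.7).
#' @param eps_sd Outcome noise SD (default 0.7).
#' @param item_loading Loading of questionnaire items on their factor
#'   (default 0.7).
#' @param moderator_reliability Reliability of the observed moderator
#'   scale (default 0.8).
#' @param seed Master seed.
#' @return A validated `dmn_cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 60, fs = 300, duration_s = 180,
                          n_channels = 32, spacing_mm = 15,
                          anterior_labels = dmn_constants$anterior_labels,
                          posterior_labels = dmn_constants$posterior_labels,
                          patch_radius_mm = Inf,
                          alpha_center_hz = 10, alpha_bw_hz = 2,
                          amp_dispersion = 0.35, snr = 3,
                          n_background = 12, bg_exponent = 1,
                          bg_rms_uv = 1, sensor_noise_uv = 1,
                          beta1 = 0, beta2 = 0, beta3 = 0.7,
                          eps_sd = 0.7, item_loading = 0.7,
                          moderator_reliability = 0.8, seed = 1) {
  cfg <- as.list(environment())
  if (n_subjects < 4) stop("n_subjects must be >= 4")
  if (any(c(amp_dispersion, snr, bg_rms_uv, sensor_noise_uv,
            eps_sd) < 0)) stop("dispersions and SDs must be >= 0")
  if (length(intersect(anterior_labels, posterior_labels)))
    stop("anterior and posterior patch labels must be disjoint")
  class(cfg) <- "dmn_cohort_config"
  cfg
}

# 31-bit polynomial rolling hash of the deparsed config, as hex
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Precompute the forward geometry for a cohort configuration
#'
#' Montage, source space, lead field, patch voxel sets and patch scalp
#' topographies (radial dipole orientations, averaged over the patch).
#'
#' @param cfg A `dmn_cohort_config`.
#' @return List with `montage`, `space`, `lead_field`, `topo_A`,
#'   `topo_P`, `patch_A`, `patch_P`, `signal_scale_uv`.
#' @export
cohort_geometry <- function(cfg) {
  mon <- build_montage(cfg$n_channels,
                       dmn_constants$head_model$radii_mm[["scalp"]])
  sp <- build_source_space(cfg$spacing_mm)
  lf <- compute_lead_field(mon, sp)
  patch <- function(labels) {
    idx <- which(sp$region_label %in% labels)
    if (!length(idx)) stop("empty patch for labels ",
                           paste(labels, collapse = "/"))
    if (is.finite(cfg$patch_radius_mm)) {
      ctr <- colMeans(sp$voxel_centers[idx, , drop = FALSE])
      d <- sqrt(rowSums(sweep(sp$voxel_centers[idx, , drop = FALSE],
                              2, ctr)^2))
      idx <- idx[d <= cfg$patch_radius_mm]
      if (!length(idx)) stop("patch radius excludes all voxels")
    }
    idx
  }
  topo <- function(idx) {
    cols <- vapply(idx, function(j) {
      u <- sp$voxel_centers[j, ] / sqrt(sum(sp$voxel_centers[j, ]^2))
      drop(lf$gain[, 3 * (j - 1) + 1:3] %*% u)
    }, numeric(nrow(mon$positions)))
    rowMeans(cols)
  }
  pa <- patch(cfg$anterior_labels)
  pp <- patch(cfg$posterior_labels)
  ## alpha-band RMS of the configured noise floor (per channel, uV):
  ## white sensor noise spread over [0, fs/2]; background 1/f sources
  ## spread over [1, fs/2] with the configured exponent.
  bw <- diff(dmn_constants$bands$alpha)
  sens_alpha <- cfg$sensor_noise_uv * sqrt(bw / (cfg$fs / 2))
  f_alpha <- if (cfg$bg_exponent == 1) {
    log(dmn_constants$bands$alpha[2] / dmn_constants$bands$alpha[1]) /
      log((cfg$fs / 2) / 1)
  } else {
    e <- 1 - cfg$bg_exponent
    (dmn_constants$bands$alpha[2]^e - dmn_constants$bands$alpha[1]^e) /
      ((cfg$fs / 2)^e - 1)
  }
  bg_alpha <- cfg$bg_rms_uv * sqrt(max(f_alpha, 0) * cfg$n_background)
  noise_alpha_rms <- sqrt(sens_alpha^2 + bg_alpha^2)
  list(montage = mon, space = sp, lead_field = lf,
       patch_A = pa, patch_P = pp,
       topo_A = topo(pa), topo_P = topo(pp),
       signal_scale_uv = cfg$snr * noise_alpha_rms)
}

# unit-RMS narrowband Gaussian noise via FFT masking
.narrowband <- function(n, fs, f0, bw) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                   # two-sided frequency axis
  X[f < f0 - bw / 2 | f > f0 + bw / 2] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# unit-RMS 1/f^expo noise (power spectrum), flat below 1 Hz
.pink <- function(n, fs, expo) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  g <- pmax(f, 1)^(-expo / 2)
  g[1] <- 0                              # no DC
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Simulate one subject's eyes-closed recording
#'
#' A pure function of (config, amplitudes, seed): coherent narrowband
#' alpha time courses on the anterior and posterior patches (amplitudes
#' `a_A`, `a_P`), 1/f background sources at random voxels, projection
#' through the lead field, linked-mastoid referencing and sensor noise.
#'
#' @param cfg A `dmn_cohort_config`.
#' @param subject_i Subject index (used for the id).
#' @param seed Integer seed for this subject's signals.
#' @param a_A,a_P Patch amplitudes (default 1).
#' @param geometry Optional precomputed [cohort_geometry] (built on the
#'   fly otherwise).
#' @return A `dmn_recording` (microvolts, linked-mastoid referenced).
#' @export
simulate_subject_recording <- function(cfg, subject_i, seed,
                                       a_A = 1, a_P = 1,
                                       geometry = NULL) {
  if (is.null(geometry)) geometry <- cohort_geometry(cfg)
  g <- geometry
  n <- round(cfg$duration_s * cfg$fs)
  nch <- nrow(g$montage$positions)
  set.seed(seed)
  sA <- .narrowband(n, cfg$fs, cfg$alpha_center_hz, cfg$alpha_bw_hz)
  sP <- .narrowband(n, cfg$fs, cfg$alpha_center_hz, cfg$alpha_bw_hz)
  ## scale topographies to the calibrated scalp RMS at unit amplitude
  tA <- g$topo_A / sqrt(mean(g$topo_A^2)) * g$signal_scale_uv
  tP <- g$topo_P / sqrt(mean(g$topo_P^2)) * g$signal_scale_uv
  X <- outer(tA, a_A * sA) + outer(tP, a_P * sP)
  V <- n_voxels(g$space)
  if (cfg$n_background > 0) {
    vox <- sample.int(V, cfg$n_background, replace = TRUE)
    for (k in seq_len(cfg$n_background)) {
      orient <- stats::rnorm(3)
      orient <- orient / sqrt(sum(orient^2))
      topo <- drop(g$lead_field$gain[, 3 * (vox[k] - 1) + 1:3] %*%
                     orient)
      rms <- sqrt(mean(topo^2))
      if (rms < 1e-30) next
      X <- X + outer(topo / rms * cfg$bg_rms_uv,
                     .pink(n, cfg$fs, cfg$bg_exponent))
    }
  }
  if (cfg$sensor_noise_uv > 0)
    X <- X + matrix(stats::rnorm(nch * n, sd = cfg$sensor_noise_uv),
                    nch, n)
  X <- apply_reference(X, "linked_mastoids", g$montage)
  rownames(X) <- g$montage$channel_names
  new_recording(X, cfg$fs, subject_id = sprintf("S%02d", subject_i),
                condition = "eyes_closed")
}

# Likert discretization at fixed latent thresholds
.likert <- function(z) {
  findInterval(z, c(-1.5, -0.5, 0.5, 1.5)) + 1L
}

#' Simulate a full cohort with ground truth
#'
#' Draws the latent moderator and patch amplitudes, generates the
#' outcome by the planted linear-interaction law, builds the 35-item
#' questionnaire (4 planted factors; item 1 is the self-referential
#' positive-expectations outcome item), and optionally the per-subject
#' EEG recordings.
#'
#' @param cfg A `dmn_cohort_config`.
#' @param keep_recordings Generate and keep the EEG (default TRUE; set
#'   FALSE to obtain only ground truth, questionnaire and per-subject
#'   seeds for streaming generation).
#' @param geometry Optional precomputed [cohort_geometry].
#' @return Object of class `dmn_cohort`: `truth` (data.frame),
#'   `items` (subjects x 35), `questionnaire` (data.frame with scale
#'   columns and items), `recordings` (list or NULL), `subject_seeds`,
#'   `config`, `config_hash`, `geometry`.
#' @export
simulate_cohort <- function(cfg, keep_recordings = TRUE,
                            geometry = NULL) {
  stopifnot(inherits(cfg, "dmn_cohort_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_subjects
  subject_seeds <- sample.int(2^31 - 2, ns)
  m <- stats::rnorm(ns)
  a_A <- exp(cfg$amp_dispersion * stats::rnorm(ns))
  a_P <- exp(cfg$amp_dispersion * stats::rnorm(ns))
  PA <- as.numeric(scale(a_P)) - as.numeric(scale(a_A))
  zPA <- as.numeric(scale(PA))
  eps <- stats::rnorm(ns, sd = cfg$eps_sd)
  srpe <- cfg$beta1 * zPA + cfg$beta2 * m + cfg$beta3 * zPA * m + eps
  zsrpe <- as.numeric(scale(srpe))
  ## 4-factor item structure: SRT (9, item 1 = SRPE), NE (9),
  ## arousal (9), ATT (8)
  w <- 0.5
  F_SRT <- w * zsrpe + sqrt(1 - w^2) * stats::rnorm(ns)
  Fs <- cbind(SRT = F_SRT, NE = stats::rnorm(ns),
              arousal = stats::rnorm(ns), ATT = stats::rnorm(ns))
  fac_of_item <- rep(1:4, times = c(9, 9, 9, 8))
  lam <- cfg$item_loading
  items <- matrix(0L, ns, 35)
  for (j in 1:35) {
    latent <- if (j == 1) zsrpe
              else lam * Fs[, fac_of_item[j]] +
                   sqrt(1 - lam^2) * stats::rnorm(ns)
    items[, j] <- .likert(latent)
  }
  if (all(items == items[1, 1]))
    stop("degenerate discretization: all responses identical")
  colnames(items) <- sprintf("item%02d", 1:35)
  rel <- cfg$moderator_reliability
  assert_obs <- sqrt(rel) * m + sqrt(1 - rel) * stats::rnorm(ns)
  sociab <- 0.4 * m + sqrt(1 - 0.16) * stats::rnorm(ns)
  activ <- 0.4 * m + sqrt(1 - 0.16) * stats::rnorm(ns)
  ids <- sprintf("S%02d", seq_len(ns))
  truth <- data.frame(subject = ids, a_A = a_A, a_P = a_P,
                      PA_true = zPA, moderator_true = m,
                      srpe_cont = srpe, srpe_item = items[, 1],
                      seed = subject_seeds,
                      beta1 = cfg$beta1, beta2 = cfg$beta2,
                      beta3 = cfg$beta3, stringsAsFactors = FALSE)
  questionnaire <- data.frame(subject = ids,
                              assertiveness = assert_obs,
                              sociability = sociab, activity = activ,
                              stringsAsFactors = FALSE)
  questionnaire <- cbind(questionnaire, as.data.frame(items))
  recordings <- NULL
  if (keep_recordings) {
    if (is.null(geometry)) geometry <- cohort_geometry(cfg)
    recordings <- lapply(seq_len(ns), function(i)
      simulate_subject_recording(cfg, i, subject_seeds[i],
                                 a_A[i], a_P[i], geometry))
    names(recordings) <- ids
  }
  structure(list(truth = truth, items = items,
                 questionnaire = questionnaire,
                 recordings = recordings,
                 subject_seeds = subject_seeds,
                 config = cfg, config_hash = config_hash(cfg),
                 geometry = geometry),
            class = "dmn_cohort")
}

#' Write a cohort as a fixture directory
#'
#' EEG recordings as EDF, questionnaire and ground truth as TSV, plus a
#' JSON manifest carrying the master seed, per-subject seeds and the
#' config hash.
#'
#' @param bundle A `dmn_cohort` (with recordings).
#' @param directory Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
write_fixture_set <- function(bundle, directory) {
  stopifnot(inherits(bundle, "dmn_cohort"))
  if (is.null(bundle$recordings))
    stop("bundle has no recordings; rerun simulate_cohort with ",
         "keep_recordings = TRUE")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  eeg_files <- character(0)
  for (id in names(bundle$recordings)) {
    f <- file.path(directory, paste0(id, ".edf"))
    write_edf(bundle$recordings[[id]], f)
    eeg_files[id] <- basename(f)
  }
  utils::write.table(bundle$questionnaire,
                     file.path(directory, "questionnaire.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth,
                     file.path(directory, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(config_hash = bundle$config_hash,
                   master_seed = bundle$config$seed,
                   subject_seeds = bundle$subject_seeds,
                   n_subjects = bundle$config$n_subjects,
                   fs = bundle$config$fs,
                   eeg_files = as.list(eeg_files),
                   questionnaire = "questionnaire.tsv",
                   ground_truth = "ground_truth.tsv")
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
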