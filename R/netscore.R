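## Anterior / posterior DMN templates, component matching and
## per-subject intensity scores.

#' Build the anterior and posterior DMN template masks
#'
#' The anterior template (ADMN) covers the medial/superior frontal and
#' anterior cingulate sectors; the posterior template (PDMN) covers the
#' posterior parietal, occipito-parietal junction and posterior
#' cingulate/precuneus sectors.  The masks are disjoint by construction.
#'
#' @param space A `dmn_source_space` with all required labels non-empty.
#' @return Named list of two `dmn_template` objects (`ADMN`, `PDMN`),
#'   each with a binary `mask` and the `region_labels` included.
#' @export
build_dmn_templates <- function(space) {
  stopifnot(inherits(space, "dmn_source_space"))
  mk <- function(name, labels) {
    have <- table(space$region_label)[labels]
    if (anyNA(have) || any(have == 0))
      stop("empty required label(s) for ", name, " template: ",
           paste(labels[is.na(have) | have == 0], collapse = ", "))
    mask <- space$region_label %in% labels
    structure(list(name = name, mask = mask, region_labels = labels),
              class = "dmn_template")
  }
  list(ADMN = mk("ADMN", dmn_constants$anterior_labels),
       PDMN = mk("PDMN", dmn_constants$posterior_labels))
}

#' Rank components by spatial correlation with a template
#'
#' Pearson correlation between each z-scored group map and the 0/1
#' template mask over all voxels; components are ranked by descending
#' correlation (ties broken by lower component id) and the top-ranked
#' one selected.
#'
#' @param decomp A `dmn_group_decomp`.
#' @param template A `dmn_template`.
#' @param eligible Optional logical/integer subset of components allowed
#'   for selection (e.g. those with non-empty significance masks).
#' @return Object of class `dmn_match`: `template_name`, `ranking`
#'   (data.frame component_id / correlation), `selected_component`.
#' @export
match_components <- function(decomp, template, eligible = NULL) {
  stopifnot(inherits(decomp, "dmn_group_decomp"),
            inherits(template, "dmn_template"))
  if (length(template$mask) != ncol(decomp$group_maps))
    stop("template and decomposition use different source spaces")
  ids <- seq_len(decomp$n_components)
  if (!is.null(eligible)) {
    el <- if (is.logical(eligible)) which(eligible) else eligible
    ids <- intersect(ids, el)
    if (!length(ids)) stop("no eligible components")
  }
  m <- as.numeric(template$mask)
  cors <- vapply(ids, function(i) {
    g <- decomp$group_maps[i, ]
    if (stats::sd(g) == 0) {
      warning("component ", i, " has zero variance; skipped")
      return(NA_real_)
    }
    stats::cor(g, m)
  }, 0)
  ok <- !is.na(cors)
  ord <- order(-cors[ok], ids[ok])
  ranking <- data.frame(component_id = ids[ok][ord],
                        correlation = cors[ok][ord])
  if (!nrow(ranking)) stop("no component with defined correlation")
  structure(list(template_name = template$name, ranking = ranking,
                 selected_component = ranking$component_id[1]),
            class = "dmn_match")
}

#' Per-subject component intensity scores
#'
#' For each subject, the sum of strictly positive values of that
#' subject's z-scored map of the selected component (optionally
#' restricted to a significance mask).
#'
#' @param decomp A back-reconstructed `dmn_group_decomp`.
#' @param match A `dmn_match` (or a component index).
#' @param mask Optional logical voxel mask restricting the summation.
#' @return Numeric vector of non-negative raw sums, one per subject.
#' @export
intensity_scores <- function(decomp, match, mask = NULL) {
  stopifnot(inherits(decomp, "dmn_group_decomp"))
  if (is.null(decomp$subject_maps))
    stop("subject maps not back-reconstructed")
  comp <- if (inherits(match, "dmn_match")) match$selected_component
          else as.integer(match)
  M <- decomp$subject_maps[, comp, , drop = TRUE]
  if (is.null(dim(M))) M <- matrix(M, nrow = 1)
  if (!is.null(mask)) M <- M[, mask, drop = FALSE]
  rowSums(M * (M > 0))
}

#' Combine anterior and posterior scores into the P/ADMN measure
#'
#' Both raw intensity scores are z-scored across subjects and the
#' anterior score is subtracted from the posterior one, yielding an axis
#' running from anterior-dominant (negative) to posterior-dominant
#' (positive) network activity.
#'
#' @param admn_raw,pdmn_raw Per-subject raw positive-voxel sums.
#' @param band Band label for bookkeeping.
#' @param subject_ids Optional subject identifiers.
#' @return A data.frame (`dmn_score_table`) with columns `subject`,
#'   `ADMN_IC`, `PDMN_IC`, `z_ADMN`, `z_PDMN`, `P_ADMN`, `band`.
#' @export
combined_score <- function(admn_raw, pdmn_raw, band = NA_character_,
                           subject_ids = NULL) {
  n <- length(admn_raw)
  if (length(pdmn_raw) != n) stop("score vectors differ in length")
  if (n < 2) stop("need >= 2 subjects to z-score")
  if (stats::sd(admn_raw) == 0 || stats::sd(pdmn_raw) == 0)
    stop("zero-variance score column; z-scores undefined")
  if (is.null(subject_ids)) subject_ids <- sprintf("S%02d", seq_len(n))
  zA <- as.numeric(scale(admn_raw))
  zP <- as.numeric(scale(pdmn_raw))
  out <- data.frame(subject = subject_ids, ADMN_IC = admn_raw,
                    PDMN_IC = pdmn_raw, z_ADMN = zA, z_PDMN = zP,
                    P_ADMN = zP - zA, band = band,
                    stringsAsFactors = FALSE)
  class(out) <- c("dmn_score_table", "data.frame")
  out
}

#' Write a subject score table as TSV
#' @param table A `dmn_score_table` (or data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a template mask as NIfTI
#' @param template A `dmn_template`.
#' @param space The source space it was built on.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_template_nifti <- function(template, space, path) {
  write_source_nifti(as.numeric(template$mask), space, path)
}
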