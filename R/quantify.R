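#' Normalize channel intensities by the spot's mean PanCK intensity
#'
#' Every channel of every cell is divided by the mean raw PanCK intensity of
#' the spot's reference cells. Two reference sets are supported:
#' \describe{
#'   \item{panck}{all PanCK-positive cells of the spot (the literal
#'     definition; the default).}
#'   \item{tumor}{PanCK-positive final-malignant cells only (requires a
#'     `label_final` column). This is what the scoring pipeline uses: the
#'     normalization factor then cannot be moved by admixed benign glands,
#'     so marker summaries are invariant to tumor purity.}
#' }
#' Adds one `<marker>_norm` column per `<marker>_raw` column (and
#' `DAPI_norm`). Normalizing an already-normalized table again with the same
#' reference is a no-op.
#'
#' @inheritParams nearest_myoepithelial_distance
#' @param reference `"panck"` or `"tumor"`.
#' @return The cell table with `_norm` columns added.
#' @export
normalize_intensities <- function(cells, reference = c("panck", "tumor")) {
  reference <- match.arg(reference)
  cells <- as_cell_table(cells)
  need_cols(cells, c("spot_id", "PanCK_pos", "PanCK_raw"))
  if (reference == "tumor") need_cols(cells, "label_final")
  raw_cols <- grep("_raw$", names(cells), value = TRUE)
  for (rc in raw_cols)
    cells[[sub("_raw$", "_norm", rc)]] <- NA_real_
  for (sid in unique(cells$spot_id)) {
    i <- cells$spot_id == sid
    ref <- i & cells$PanCK_pos
    if (reference == "tumor")
      ref <- ref & !is.na(cells$label_final) &
        cells$label_final == "malignant"
    if (!any(ref))
      stop(sprintf("spot '%s' has no %s reference cells for normalization",
                   sid,
                   if (reference == "tumor") "PanCK+ malignant" else "PanCK+"))
    f <- mean(cells$PanCK_raw[ref])
    for (rc in raw_cols)
      cells[[sub("_raw$", "_norm", rc)]][i] <- cells[[rc]][i] / f
  }
  cells
}

#' Default per-marker positivity thresholds (normalized units)
#'
#' The threshold for each marker is the geometric mean of the positive and
#' negative log-normal component medians of the configured intensity model —
#' the midpoint of the bimodal valley on the log scale — divided by the
#' expected mean PanCK intensity of PanCK-positive cells, so that it applies
#' to PanCK-normalized intensities. Real-data use requires user-supplied
#' thresholds; these defaults match the generator only.
#'
#' @param config an [sim_config()] object.
#' @param markers marker subset (default: the nine prognosis markers).
#' @return named numeric vector of thresholds.
#' @export
default_positivity_thresholds <- function(config,
                                          markers = PROGNOSIS_MARKERS) {
  pk <- config$intensity_model$markers$PanCK$pos
  panck_mean <- clamped_lnorm_mean(pk[["meanlog"]], pk[["sdlog"]])
  th <- vapply(markers, function(m) {
    par <- config$intensity_model$markers[[m]]
    exp((par$pos[["meanlog"]] + par$neg[["meanlog"]]) / 2) / panck_mean
  }, numeric(1))
  stats::setNames(th, markers)
}

#' Call per-cell marker positivity by thresholding normalized intensity
#'
#' @param cells cell table with `<marker>_norm` columns (see
#'   [normalize_intensities()]).
#' @param marker single marker name.
#' @param threshold positivity threshold in normalized units; a cell is
#'   positive iff its normalized intensity is >= threshold.
#' @return logical vector along the rows of `cells`.
#' @export
call_positivity <- function(cells, marker, threshold) {
  cells <- as_cell_table(cells)
  col <- paste0(marker, "_norm")
  if (!col %in% names(cells))
    stop(sprintf("unknown marker '%s' (no column '%s')", marker, col))
  cells[[col]] >= threshold
}

#' Per-patient positive fraction and positive-cell mean intensity
#'
#' Both quantities are computed over final-malignant cells only (the tumor
#' denominator): `positive_fraction` = positive tumor cells / all tumor
#' cells; `mean_pos_intensity` = mean normalized intensity over positive
#' tumor cells, 0 when no tumor cell is positive (declared convention).
#' Patients without any final-malignant cell are excluded and reported in
#' `attr(, "excluded")`.
#'
#' @param cells annotated, normalized cell table (`label_final` and `_norm`
#'   columns present).
#' @param markers marker names to summarize.
#' @param thresholds named positivity thresholds (normalized units).
#' @return data.frame, one row per analyzed patient x marker: `patient_id`,
#'   `marker`, `n_tumor_cells`, `positive_fraction`, `mean_pos_intensity`.
#' @export
summarize_markers <- function(cells, markers, thresholds) {
  cells <- as_cell_table(cells)
  need_cols(cells, c("patient_id", "label_final"))
  miss <- setdiff(markers, names(thresholds))
  if (length(miss))
    stop("missing thresholds for: ", paste(miss, collapse = ", "))
  pats <- unique(cells$patient_id)
  tum <- !is.na(cells$label_final) & cells$label_final == "malignant"
  excluded <- character(0)
  rows <- list()
  for (p in pats) {
    it <- tum & cells$patient_id == p
    n_t <- sum(it)
    if (n_t == 0L) {
      excluded <- c(excluded, p)
      next
    }
    for (m in markers) {
      pos <- call_positivity(cells, m, thresholds[[m]]) & it
      n_pos <- sum(pos)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p, marker = m, n_tumor_cells = n_t,
        positive_fraction = n_pos / n_t,
        mean_pos_intensity = if (n_pos > 0)
          mean(cells[[paste0(m, "_norm")]][pos]) else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no patient with final-malignant cells; nothing to summarize")
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Min-max scale cohort values to a fixed range
#'
#' `v -> lo + (hi - lo) * (v - min) / (max - min)` with min/max taken over
#' the supplied (analyzed) cohort. A constant vector maps everything to `lo`
#' with a warning (degenerate cohort).
#'
#' @param values numeric vector of per-patient values.
#' @param lo,hi output range (default 0-50, the two halves of the mfIHC
#'   score).
#' @return scaled numeric vector.
#' @export
minmax_to_range <- function(values, lo = 0, hi = 50) {
  rng <- range(values)
  if (diff(rng) == 0) {
    warning("constant values: min-max scaling maps all patients to the ",
            "range minimum")
    return(rep(lo, length(values)))
  }
  # ratio first, so the cohort maximum lands on `hi` exactly
  lo + (hi - lo) * ((values - rng[1]) / diff(rng))
}

#' mfIHC scores for a patient-by-marker summary table
#'
#' The mfIHC score of a patient for a marker is the sum of the min-max
#' scaled (0-50) positive-cell fraction and the min-max scaled (0-50)
#' positive-cell mean intensity, both scaled within the analyzed cohort per
#' marker; scores therefore lie in [0, 100] and the cohort argmax of either
#' component attains 50 on it.
#'
#' @param summary output of [summarize_markers()].
#' @return The summary with `prop_component`, `int_component` and
#'   `mfihc_score` columns added, plus `labeling_index`
#'   (= 100 x positive fraction, reported for Ki67/TOP2A-style use).
#' @export
mfihc_scores <- function(summary) {
  need_cols(summary, c("patient_id", "marker", "positive_fraction",
                       "mean_pos_intensity"))
  summary$prop_component <- NA_real_
  summary$int_component <- NA_real_
  for (m in unique(summary$marker)) {
    i <- summary$marker == m
    summary$prop_component[i] <- minmax_to_range(summary$positive_fraction[i])
    summary$int_component[i] <- minmax_to_range(summary$mean_pos_intensity[i])
  }
  summary$mfihc_score <- summary$prop_component + summary$int_component
  summary$labeling_index <- 100 * summary$positive_fraction
  summary
}

#' Labeling index of a proliferation marker
#'
#' Percentage of final-malignant cells positive for the marker
#' (100 x positive fraction); conventionally reported for Ki67 and TOP2A.
#'
#' @inheritParams summarize_markers
#' @param marker single marker name.
#' @param threshold positivity threshold (normalized units).
#' @return data.frame `patient_id`, `labeling_index`.
#' @export
labeling_index <- function(cells, marker, threshold) {
  s <- summarize_markers(cells, marker,
                         stats::setNames(threshold, marker))
  data.frame(patient_id = s$patient_id,
             labeling_index = 100 * s$positive_fraction,
             stringsAsFactors = FALSE)
}

#' Patients-by-markers matrix of mfIHC scores
#'
#' Wide matrix used for correlation and clustering: one row per patient, one
#' column per marker, entries the mfIHC score except for Ki67 and TOP2A
#' where the labeling index is used.
#'
#' @param scores output of [mfihc_scores()].
#' @return numeric matrix with patient ids as rownames.
#' @export
marker_matrix <- function(scores) {
  need_cols(scores, c("patient_id", "marker", "mfihc_score",
                      "labeling_index"))
  scores$value <- ifelse(scores$marker %in% c("Ki67", "TOP2A"),
                         scores$labeling_index, scores$mfihc_score)
  pats <- unique(scores$patient_id)
  mks <- unique(scores$marker)
  m <- matrix(NA_real_, length(pats), length(mks),
              dimnames = list(pats, mks))
  m[cbind(match(scores$patient_id, pats), match(scores$marker, mks))] <-
    scores$value
  if (anyNA(m)) stop("incomplete patient x marker grid")
  m
}
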