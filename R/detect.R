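#' Nearest myoepithelial-cell distance per epithelial cell
#'
#' For every PanCK-positive cell of every spot, the Euclidean distance (um) to
#' the nearest Myosin-positive cell of the same spot. Computed with a
#' grid-bucket spatial index that is exact (equal to the brute-force
#' all-pairs minimum). Spots without any Myosin-positive cell yield `Inf`.
#'
#' @param cells cell table with columns `spot_id`, `cell_id`, `x_um`, `y_um`,
#'   `PanCK_pos`, `Myosin_pos` (an `mfihc_spot`/`mfihc_cohort` is accepted).
#' @return data.frame: `cell_id`, `spot_id`, `nearest_myo_dist_um`, ordered
#'   as the epithelial cells appear in the input. Zero epithelial cells give
#'   an empty result, not an error.
#' @export
nearest_myoepithelial_distance <- function(cells) {
  cells <- as_cell_table(cells)
  need_cols(cells, c("spot_id", "cell_id", "x_um", "y_um",
                     "PanCK_pos", "Myosin_pos"))
  out <- lapply(split(cells, cells$spot_id), function(sp) {
    epi <- sp[sp$PanCK_pos, , drop = FALSE]
    if (nrow(epi) == 0L) return(NULL)
    myo <- sp[sp$Myosin_pos, , drop = FALSE]
    d <- nn_dist(epi$x_um, epi$y_um, myo$x_um, myo$y_um)
    data.frame(cell_id = epi$cell_id, spot_id = epi$spot_id,
               nearest_myo_dist_um = d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(cell_id = character(0), spot_id = character(0),
                      nearest_myo_dist_um = numeric(0))
  rownames(out) <- NULL
  out
}

#' Classify epithelial cells by the 25 um myoepithelial distance rule
#'
#' Cells within `threshold_um` of a myoepithelial cell are benign; all others
#' (including cells in spots without myoepithelium, distance `Inf`) are
#' malignant. The boundary is inclusive: exactly 25 um is benign.
#'
#' @param distances output of [nearest_myoepithelial_distance()], or a
#'   numeric vector of distances.
#' @param threshold_um positive distance threshold (default 25).
#' @return For a data.frame input, the same data.frame plus a
#'   `label_distance` column; for a numeric vector, a character vector of
#'   labels `"benign"`/`"malignant"`.
#' @export
classify_cells_by_distance <- function(distances, threshold_um = 25) {
  stopifnot(is.numeric(threshold_um), length(threshold_um) == 1L,
            threshold_um > 0)
  if (is.data.frame(distances)) {
    distances$label_distance <-
      classify_cells_by_distance(distances$nearest_myo_dist_um, threshold_um)
    return(distances)
  }
  ifelse(distances <= threshold_um, "benign", "malignant")
}

#' Group epithelial cells into glands by single-linkage connectivity
#'
#' Glands are the connected components of the graph joining PanCK-positive
#' cells of the same spot at pairwise distance <= `linkage_radius_um`
#' (single-linkage clustering cut at that height). Every epithelial cell
#' belongs to exactly one gland.
#'
#' @inheritParams nearest_myoepithelial_distance
#' @param linkage_radius_um positive linkage radius (default 20).
#' @return data.frame: `cell_id`, `spot_id`, `gland_id` (unique across
#'   spots). Zero epithelial cells give an empty result.
#' @export
detect_glands <- function(cells, linkage_radius_um = 20) {
  stopifnot(linkage_radius_um > 0)
  cells <- as_cell_table(cells)
  need_cols(cells, c("spot_id", "cell_id", "x_um", "y_um", "PanCK_pos"))
  out <- lapply(split(cells, cells$spot_id), function(sp) {
    epi <- sp[sp$PanCK_pos, , drop = FALSE]
    n <- nrow(epi)
    if (n == 0L) return(NULL)
    comp <- if (n == 1L) 1L else {
      hc <- stats::hclust(stats::dist(cbind(epi$x_um, epi$y_um)),
                          method = "single")
      stats::cutree(hc, h = linkage_radius_um)
    }
    data.frame(cell_id = epi$cell_id, spot_id = epi$spot_id,
               gland_id = sprintf("%s_g%03d", epi$spot_id, comp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(cell_id = character(0), spot_id = character(0),
                      gland_id = character(0))
  rownames(out) <- NULL
  out
}

#' Classify glands by myoepithelial coverage
#'
#' A gland's coverage is the fraction of its member cells whose nearest
#' myoepithelial cell lies within `threshold_um`. Glands with coverage at or
#' above `coverage_threshold` are benign (ties resolve to benign, the
#' conservative direction for excluding cells from tumor scoring).
#'
#' @param glands output of [detect_glands()].
#' @param distances output of [nearest_myoepithelial_distance()] on the same
#'   cells.
#' @param threshold_um distance defining "covered" (default 25).
#' @param coverage_threshold minimum benign coverage fraction (default 0.5).
#' @return data.frame, one row per gland: `gland_id`, `spot_id`, `n_cells`,
#'   `myoepithelial_coverage`, `label_gland`.
#' @export
classify_gland <- function(glands, distances, threshold_um = 25,
                           coverage_threshold = 0.5) {
  m <- merge(glands, distances[, c("cell_id", "nearest_myo_dist_um")],
             by = "cell_id", sort = FALSE)
  if (nrow(m) != nrow(glands))
    stop("distances do not cover all gland member cells")
  cov <- tapply(m$nearest_myo_dist_um <= threshold_um, m$gland_id, mean)
  nc <- tapply(m$cell_id, m$gland_id, length)
  sid <- tapply(m$spot_id, m$gland_id, `[`, 1L)
  out <- data.frame(gland_id = names(cov),
                    spot_id = as.character(sid),
                    n_cells = as.integer(nc),
                    myoepithelial_coverage = as.numeric(cov),
                    stringsAsFactors = FALSE)
  out$label_gland <- ifelse(out$myoepithelial_coverage >= coverage_threshold,
                            "benign", "malignant")
  rownames(out) <- NULL
  out
}

#' Combine the distance-rule and gland-rule classifications
#'
#' Fuses the per-cell distance labels (approach 1) with the per-gland labels
#' (approach 2) into a final per-cell call. Modes:
#' \describe{
#'   \item{benign-if-either}{(default) benign when either approach says
#'     benign — maximal exclusion of benign glands from tumor scoring.}
#'   \item{benign-if-both}{benign only when both agree.}
#'   \item{cell-priority}{the distance label wins.}
#'   \item{gland-priority}{the gland label wins.}
#' }
#'
#' @param cell_labels data.frame with `cell_id`, `label_distance`.
#' @param glands data.frame with `cell_id`, `gland_id`.
#' @param gland_labels data.frame with `gland_id`, `label_gland`.
#' @param mode combination rule, see above.
#' @return data.frame `cell_id`, `label_distance`, `label_gland`,
#'   `label_final`, with the chosen mode in `attr(, "mode")`.
#' @export
combine_approaches <- function(cell_labels, glands, gland_labels,
                               mode = c("benign-if-either", "benign-if-both",
                                        "cell-priority", "gland-priority")) {
  mode <- match.arg(mode)
  if (!setequal(cell_labels$cell_id, glands$cell_id))
    stop("cell_labels and glands cover different cell ids")
  m <- merge(cell_labels[, c("cell_id", "label_distance")],
             glands[, c("cell_id", "gland_id")], by = "cell_id", sort = FALSE)
  m <- merge(m, gland_labels[, c("gland_id", "label_gland")],
             by = "gland_id", sort = FALSE)
  m <- m[match(cell_labels$cell_id, m$cell_id), ]
  cb <- m$label_distance == "benign"
  gb <- m$label_gland == "benign"
  final <- switch(mode,
    "benign-if-either" = cb | gb,
    "benign-if-both"   = cb & gb,
    "cell-priority"    = cb,
    "gland-priority"   = gb)
  out <- data.frame(cell_id = m$cell_id,
                    label_distance = m$label_distance,
                    label_gland = m$label_gland,
                    label_final = ifelse(final, "benign", "malignant"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

# Wilson score 95% interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Classification performance with Wilson confidence intervals
#'
#' Accuracy, sensitivity and specificity (positive class = malignant) with
#' 95% Wilson score intervals, at cell or gland level. Inputs are label
#' vectors (`"benign"`/`"malignant"`), aligned element-wise.
#'
#' @param pred,truth character vectors of equal positive length.
#' @param unit `"cell"` or `"gland"`; recorded in the result only.
#' @return An object of class `mfihc_metrics`: list with `unit`, `n`,
#'   `confusion` (2x2 table), and `accuracy`, `sensitivity`, `specificity`
#'   each a vector `(estimate, lower, upper)`.
#' @export
evaluate_classification <- function(pred, truth, unit = c("gland", "cell")) {
  unit <- match.arg(unit)
  if (length(pred) == 0L || length(pred) != length(truth))
    stop("pred and truth must be non-empty and aligned")
  lv <- c("benign", "malignant")
  pred <- factor(pred, levels = lv)
  truth <- factor(truth, levels = lv)
  if (anyNA(pred) || anyNA(truth)) stop("labels must be 'benign'/'malignant'")
  cm <- table(truth = truth, pred = pred)
  tp <- cm["malignant", "malignant"]; fn <- cm["malignant", "benign"]
  tn <- cm["benign", "benign"];       fp <- cm["benign", "malignant"]
  met <- function(k, n) {
    ci <- wilson_ci(k, n)
    c(estimate = if (n > 0) k / n else NA_real_, ci)
  }
  structure(list(unit = unit, n = length(pred), confusion = cm,
                 accuracy = met(tp + tn, length(pred)),
                 sensitivity = met(tp, tp + fn),
                 specificity = met(tn, tn + fp)),
            class = "mfihc_metrics")
}

#' @export
print.mfihc_metrics <- function(x, ...) {
  cat(sprintf("Classification metrics (%s level, n = %d)\n", x$unit, x$n))
  for (m in c("accuracy", "sensitivity", "specificity")) {
    v <- x[[m]]
    cat(sprintf("  %-11s %.3f (95%% CI %.3f-%.3f)\n", m,
                v[["estimate"]], v[["lower"]], v[["upper"]]))
  }
  invisible(x)
}

#' Annotate a cell table with all detection outputs
#'
#' Convenience wrapper running the full detection chain and attaching the
#' columns `nearest_myo_dist_um`, `label_distance`, `gland_id`,
#' `label_gland`, `label_final` to the epithelial rows of the table
#' (non-epithelial rows get `NA`).
#'
#' @inheritParams nearest_myoepithelial_distance
#' @param threshold_um distance-rule threshold (default 25).
#' @param linkage_radius_um gland linkage radius (default 20).
#' @param coverage_threshold benign gland coverage threshold (default 0.5).
#' @param mode combination rule, see [combine_approaches()].
#' @return The cell table with the five detection columns added; the
#'   combination mode in `attr(, "detection_mode")`.
#' @export
annotate_cells <- function(cells, threshold_um = 25, linkage_radius_um = 20,
                           coverage_threshold = 0.5,
                           mode = "benign-if-either") {
  cells <- as_cell_table(cells)
  d <- nearest_myoepithelial_distance(cells)
  d <- classify_cells_by_distance(d, threshold_um)
  g <- detect_glands(cells, linkage_radius_um)
  gl <- classify_gland(g, d, threshold_um, coverage_threshold)
  comb <- combine_approaches(d, g, gl, mode)
  idx <- match(cells$cell_id, comb$cell_id)
  cells$nearest_myo_dist_um <- d$nearest_myo_dist_um[match(cells$cell_id,
                                                           d$cell_id)]
  cells$label_distance <- comb$label_distance[idx]
  cells$gland_id <- g$gland_id[match(cells$cell_id, g$cell_id)]
  cells$label_gland <- comb$label_gland[idx]
  cells$label_final <- comb$label_final[idx]
  attr(cells, "detection_mode") <- attr(comb, "mode")
  cells
}

#' Gland-level predicted and ground-truth labels
#'
#' Aggregates an annotated cell table (see [annotate_cells()]) to one row per
#' detected gland: the predicted label is the majority of the member cells'
#' `label_final` and the truth label the majority of their
#' `compartment_truth` (malignant iff most members are malignant
#' epithelium); ties resolve to benign in both cases.
#'
#' @param cells annotated cell table containing `gland_id`, `label_final`,
#'   `compartment_truth`.
#' @return data.frame: `gland_id`, `n_cells`, `pred`, `truth`.
#' @export
gland_level_labels <- function(cells) {
  cells <- as_cell_table(cells)
  need_cols(cells, c("gland_id", "label_final", "compartment_truth"))
  epi <- cells[!is.na(cells$gland_id), , drop = FALSE]
  frac_pred <- tapply(epi$label_final == "malignant", epi$gland_id, mean)
  frac_true <- tapply(epi$compartment_truth == "malignant_epithelial",
                      epi$gland_id, mean)
  n <- tapply(epi$gland_id, epi$gland_id, length)
  data.frame(gland_id = names(frac_pred),
             n_cells = as.integer(n),
             pred = ifelse(frac_pred > 0.5, "malignant", "benign"),
             truth = ifelse(frac_true > 0.5, "malignant", "benign"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# coerce package objects to their cell table
as_cell_table <- function(x) {
  if (inherits(x, "mfihc_spot")) return(x$cells)
  if (inherits(x, "mfihc_cohort")) return(x$cells)
  stopifnot(is.data.frame(x))
  x
}

need_cols <- function(df, cols) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("cell table is missing required column(s): ",
         paste(miss, collapse = ", "))
  invisible(df)
}
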