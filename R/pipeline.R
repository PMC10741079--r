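#' Write / read cell tables and patient tables as CSV
#'
#' `read_cells_csv` validates the schema and raises an error naming every
#' missing required column.
#'
#' @param cells,patients data.frames to write.
#' @param path CSV file path.
#' @param required required columns for validation.
#' @return the read data.frame (readers); the path, invisibly (writers).
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(as_cell_table(cells), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path,
                           required = c("spot_id", "patient_id", "cell_id",
                                        "x_um", "y_um", "PanCK_pos",
                                        "Myosin_pos")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("input cell table violates the schema; missing column(s): ",
         paste(miss, collapse = ", "))
  for (cc in grep("_pos$|_pos_truth$", names(df), value = TRUE))
    df[[cc]] <- as.logical(df[[cc]])
  df
}

#' @rdname write_cells_csv
#' @export
write_patients_csv <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_patients_csv <- function(path,
                              required = c("patient_id", "time_months",
                                           "event")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("input patient table violates the schema; missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(x, file = f, control = c("keepNA", "keepInteger", "showAttributes"))
  unname(tools::md5sum(f))
}

#' Run the full analysis chain on a synthetic cohort
#'
#' Simulation -> benign/malignant detection -> tumor-restricted marker
#' scoring -> dichotomization -> five-marker prognosis score -> survival
#' statistics -> correlation and clustering, with exclusion bookkeeping and
#' a reproducibility manifest. All randomness derives from `seed`.
#'
#' @param config an [sim_config()] object.
#' @param n_patients cohort size (needs >= 10 analyzable patients for the
#'   automatic cutpoints).
#' @param seed root seed.
#' @param out_dir optional directory; when given, all result tables are
#'   persisted as CSV plus a JSON manifest with MD5 checksums.
#' @param mode combination rule for [combine_approaches()].
#' @param threshold_um,linkage_radius_um,coverage_threshold detection
#'   parameters.
#' @param thresholds named positivity thresholds; defaults derived from the
#'   configured intensity model.
#' @param cutpoints optional named list of manual cutpoint overrides
#'   (mfIHC-score units) per marker.
#' @param k_clusters clusters for [hierarchical_cluster()] (default 3).
#' @return An object of class `mfihc_result`; see Details in the vignette.
#' @export
run_pipeline <- function(config, n_patients = 60, seed = config$seed,
                         out_dir = NULL, mode = "benign-if-either",
                         threshold_um = 25, linkage_radius_um = 20,
                         coverage_threshold = 0.5, thresholds = NULL,
                         cutpoints = NULL, k_clusters = 3) {
  cohort <- simulate_cohort(config, n_patients, seed = seed)
  cells <- annotate_cells(cohort$cells, threshold_um = threshold_um,
                          linkage_radius_um = linkage_radius_um,
                          coverage_threshold = coverage_threshold,
                          mode = mode)
  # exclusion: spots without representative cancer cells cannot be scored
  tum_by_pat <- tapply(!is.na(cells$label_final) &
                         cells$label_final == "malignant" & cells$PanCK_pos,
                       cells$patient_id, sum)
  excl_ids <- names(tum_by_pat)[tum_by_pat == 0]
  excluded <- data.frame(patient_id = as.character(excl_ids),
                         reason = rep("no representative cancer cells",
                                      length(excl_ids)),
                         stringsAsFactors = FALSE)
  analyzed <- setdiff(cohort$patients$patient_id, excluded$patient_id)
  cells_a <- cells[cells$patient_id %in% analyzed, , drop = FALSE]
  cells_a <- normalize_intensities(cells_a, reference = "tumor")
  if (is.null(thresholds))
    thresholds <- default_positivity_thresholds(config)
  summ <- summarize_markers(cells_a, PROGNOSIS_MARKERS, thresholds)
  scores <- mfihc_scores(summ)

  # dichotomization (automatic unless overridden) and five-marker score
  cuts <- list()
  flags <- data.frame(patient_id = unique(scores$patient_id),
                      stringsAsFactors = FALSE)
  for (m in PROGNOSIS_MARKERS) {
    sm <- scores[scores$marker == m, ]
    sm <- sm[match(flags$patient_id, sm$patient_id), ]
    cuts[[m]] <- highest_slope_threshold(sm$mfihc_score,
                                         override = cutpoints[[m]],
                                         marker = m)
    flags[[paste0(m, "_high")]] <- cuts[[m]]$high
  }
  flags$five_marker_score <- five_marker_score(flags)

  pat <- cohort$patients[match(flags$patient_id,
                               cohort$patients$patient_id), ]
  surv_tab <- cbind(flags,
                    pat[c("pT", "pN", "M", "grade", "time_months", "event")])

  score_group <- factor(surv_tab$five_marker_score, levels = 0:5)
  km <- kaplan_meier(surv_tab$time_months, surv_tab$event,
                     droplevels(score_group))
  lr <- tryCatch(
    logrank_test(surv_tab$time_months, surv_tab$event,
                 droplevels(score_group)),
    error = function(e) NULL)
  X <- data.frame(pT2 = as.integer(surv_tab$pT == "pT2"),
                  pT34 = as.integer(surv_tab$pT == "pT3-4"),
                  pNpos = as.integer(surv_tab$pN == "pN+"),
                  grade2 = as.integer(surv_tab$grade == "2"),
                  grade3 = as.integer(surv_tab$grade == "3"),
                  five_marker_score = surv_tab$five_marker_score)
  cox <- tryCatch(cox_ph(surv_tab$time_months, surv_tab$event, X),
                  error = function(e) NULL)

  mm <- marker_matrix(scores)
  sp <- spearman_matrix(mm)
  clusters <- if (nrow(mm) >= k_clusters)
    hierarchical_cluster(mm, k = k_clusters) else NULL
  if (!is.null(clusters))
    surv_tab$cluster <- as.character(clusters[surv_tab$patient_id])

  manifest <- list(
    package = "mfihc",
    version = as.character(utils::packageVersion("mfihc")),
    config_md5 = md5_of_object(unclass(config)),
    seed = as.integer(seed),
    modes = list(combination = mode, threshold_um = threshold_um,
                 linkage_radius_um = linkage_radius_um,
                 coverage_threshold = coverage_threshold,
                 ci_method = "wilson",
                 cutpoints = lapply(cuts, function(cp)
                   list(cutpoint = cp$cutpoint, method = cp$method))),
    n_input = as.integer(n_patients),
    n_analyzed = length(analyzed),
    n_excluded = nrow(excluded),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  res <- structure(list(config = config, cohort = cohort, cells = cells_a,
                        scores = scores, cutpoints = cuts,
                        patients = surv_tab, km = km, logrank = lr,
                        cox = cox, spearman = sp, clusters = clusters,
                        exclusions = excluded, manifest = manifest),
                   class = "mfihc_result")
  if (!is.null(out_dir)) res <- persist_result(res, out_dir)
  res
}

persist_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  write_cells_csv(res$cells, fp("cells.csv"))
  write_patients_csv(res$patients, fp("patients.csv"))
  utils::write.csv(res$scores, fp("scores.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$spearman), fp("spearman.csv"))
  utils::write.csv(res$exclusions, fp("exclusions.csv"), row.names = FALSE)
  files <- c("cells.csv", "patients.csv", "scores.csv", "spearman.csv",
             "exclusions.csv")
  sums <- tools::md5sum(vapply(files, fp, character(1)))
  res$manifest$files <- as.list(stats::setNames(unname(sums), files))
  jsonlite::write_json(res$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res
}

#' @export
print.mfihc_result <- function(x, ...) {
  cat("mfIHC pipeline result\n")
  cat(sprintf("  patients: %d analyzed, %d excluded (of %d)\n",
              x$manifest$n_analyzed, x$manifest$n_excluded,
              x$manifest$n_input))
  cat(sprintf("  combination rule: %s; distance threshold %g um\n",
              x$manifest$modes$combination, x$manifest$modes$threshold_um))
  tab <- table(x$patients$five_marker_score)
  cat("  five-marker score:",
      paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank across score groups: p = %.4g\n",
                x$logrank$p_value))
  invisible(x)
}

#' @export
summary.mfihc_result <- function(object, ...) {
  print(object)
  cat("\nPer-marker cutpoints:\n")
  for (m in names(object$cutpoints)) {
    cp <- object$cutpoints[[m]]
    cat(sprintf("  %-6s %6.2f (%s)\n", m, cp$cutpoint, cp$method))
  }
  if (!is.null(object$cox)) {
    cat("\nMultivariate Cox model:\n")
    print(object$cox)
  }
  if (!is.null(object$clusters)) {
    cat("\nCluster sizes:\n")
    print(table(object$clusters))
  }
  invisible(object)
}

#' Kaplan-Meier plot of the five-marker prognosis score groups
#'
#' @param x an `mfihc_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mfihc_result <- function(x, ...) {
  g <- droplevels(factor(x$patients$five_marker_score, levels = 0:5))
  fit <- survival::survfit(
    survival::Surv(x$patients$time_months, x$patients$event) ~ g)
  cols <- grDevices::hcl.colors(nlevels(g), "Zissou 1")
  graphics::plot(fit, col = cols, lwd = 2, xlab = "months",
                 ylab = "overall survival", ...)
  graphics::legend("bottomleft", legend = paste("score", levels(g)),
                   col = cols, lwd = 2, bty = "n")
  invisible(x)
}
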