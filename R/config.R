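#' Marker panel used throughout the package
#'
#' Eleven markers plus the DAPI counterstain: the nine prognosis markers
#' (PR, ER, AR, GATA3, TROP2, HER2, PDL1, Ki67, TOP2A) and the two lineage
#' markers PanCK (epithelial) and Myosin (myoepithelial). `PD-L1` is spelled
#' `PDL1` so marker names are syntactic R column names.
#' @export
MARKER_PANEL <- c("PR", "ER", "AR", "GATA3", "TROP2", "HER2", "PDL1",
                  "Ki67", "TOP2A", "Myosin", "PanCK")

#' Nine prognosis markers (panel minus the lineage markers)
#' @export
PROGNOSIS_MARKERS <- setdiff(MARKER_PANEL, c("Myosin", "PanCK"))

#' Markers entering the five-marker prognosis score
#' @export
SCORE_MARKERS <- c("PR", "ER", "AR", "GATA3", "PDL1")

default_intensity_model <- function() {
  pos <- c(meanlog = log(150), sdlog = 0.25)
  neg <- c(meanlog = log(12), sdlog = 0.40)
  m <- lapply(stats::setNames(PROGNOSIS_MARKERS, PROGNOSIS_MARKERS),
              function(x) list(pos = pos, neg = neg))
  m$PanCK  <- list(pos = c(meanlog = log(120), sdlog = 0.30),
                   neg = c(meanlog = log(8),   sdlog = 0.50))
  m$Myosin <- list(pos = c(meanlog = log(140), sdlog = 0.30),
                   neg = c(meanlog = log(8),   sdlog = 0.50))
  m$DAPI   <- list(pos = c(meanlog = log(180), sdlog = 0.15),
                   neg = c(meanlog = log(180), sdlog = 0.15))
  # positive-cell fractions: per marker, for patient-high / patient-low tumors
  # and for benign epithelium (normal glands are hormone-receptor rich)
  pf <- function(high, low, benign) c(high = high, low = low, benign = benign)
  frac <- list(
    PR    = pf(0.65, 0.08, 0.80), ER    = pf(0.65, 0.08, 0.80),
    AR    = pf(0.65, 0.08, 0.75), GATA3 = pf(0.70, 0.10, 0.85),
    TROP2 = pf(0.70, 0.10, 0.60), HER2  = pf(0.60, 0.03, 0.02),
    PDL1  = pf(0.40, 0.03, 0.02), Ki67  = pf(0.30, 0.03, 0.03),
    TOP2A = pf(0.25, 0.02, 0.02))
  list(markers = m, pos_frac = frac,
       # patient-high tumors are also brighter on the log scale
       intensity_high_shift = 0.30,
       patient_intensity_sd = 0.10)
}

default_correlation_model <- function() {
  list(
    hormone_loading    = 0.80,  # PR/ER/AR/GATA3 share one latent factor
    prolif_loading     = 0.80,  # Ki67/TOP2A share another
    hormone_prevalence = 0.60,
    prolif_prevalence  = 0.30,
    her2_prevalence    = 0.15,
    trop2_prevalence   = 0.70,
    pdl1_prevalence    = 0.25,
    her2_top2a_coamp   = 0.40,  # P(TOP2A high | HER2 high) boost
    # clinical latent: aggressive phenotype loads negatively on the hormone
    # factor and positively on the proliferation factor
    clinical_hormone_coef = -0.6,
    clinical_prolif_coef  =  0.7,
    clinical_noise_sd     =  0.6,
    grade_breaks = c(0.123, 0.647),   # cumulative P(grade 1), P(grade <= 2)
    pt_breaks    = c(0.50, 0.915),    # cumulative P(pT1), P(pT <= 2)
    pn_intercept = -0.30, pn_coef = 0.50,
    m_intercept  = -2.60, m_coef  = 0.30)
}

default_survival_model <- function() {
  list(
    baseline_hazard = 0.010,          # events per month, exponential baseline
    log_hr = c(PR = -0.45, ER = -0.35, AR = -0.45, GATA3 = -0.35,
               TROP2 = 0, HER2 = 0, PDL1 = -0.35, Ki67 = 0, TOP2A = 0),
    censor_rate = 0.012,              # random right-censoring hazard
    admin_censor_months = 120)        # administrative end of follow-up
}

#' Simulation configuration for synthetic TMA spots and cohorts
#'
#' Defines the geometry of a 0.6 mm tissue-microarray spot (benign glands as
#' epithelial annuli wrapped in a myoepithelial cell ring; malignant nests as
#' compact clusters kept clear of any myoepithelium), the per-marker bimodal
#' intensity model on the 0-255 measurement scale, the patient-level
#' correlation structure (a hormone block PR/ER/AR/GATA3, a proliferation
#' block Ki67/TOP2A, and HER2-TOP2A coamplification), and a proportional-
#' hazards survival model tied to marker-high status.
#'
#' @param spot_diameter_um spot diameter in micrometres (default 600).
#' @param n_benign_glands,n_malignant_nests structures per spot.
#' @param gland_radius_um outer radius of the benign epithelial annulus.
#' @param lumen_fraction inner radius of the annulus as a fraction of
#'   `gland_radius_um` (the gland lumen is acellular).
#' @param ring_offset_um radial offset of the myoepithelial ring beyond the
#'   epithelial annulus (<= 10 by design so the 25 um rule holds).
#' @param ring_spacing_um arc spacing between adjacent myoepithelial cells.
#' @param ring_jitter_um radial jitter of ring cells.
#' @param nest_sd_um,nest_max_radius_um Gaussian spread and hard truncation
#'   radius of malignant nests.
#' @param clearance_um minimum distance between any malignant cell and any
#'   myoepithelial cell (default 50).
#' @param cell_density named vector, cells per mm^2: `epithelial` (within
#'   gland annuli and nest discs), `stroma`, `immune` (over the whole spot).
#' @param marker_panel ordered marker names; see [MARKER_PANEL].
#' @param intensity_model,correlation_model,survival_model list structures as
#'   produced by the unexported defaults; see the methods vignette.
#' @param seed integer root seed recorded with the configuration.
#' @return An object of class `mfihc_config`.
#' @export
sim_config <- function(spot_diameter_um = 600,
                       n_benign_glands = 3,
                       n_malignant_nests = 3,
                       gland_radius_um = 40,
                       lumen_fraction = 0.6,
                       ring_offset_um = 5,
                       ring_spacing_um = 8,
                       ring_jitter_um = 1.5,
                       nest_sd_um = 18,
                       nest_max_radius_um = 40,
                       clearance_um = 50,
                       cell_density = c(epithelial = 10000, stroma = 800,
                                        immune = 300),
                       marker_panel = MARKER_PANEL,
                       intensity_model = default_intensity_model(),
                       correlation_model = default_correlation_model(),
                       survival_model = default_survival_model(),
                       seed = 1L) {
  cfg <- list(spot_diameter_um = spot_diameter_um,
              n_benign_glands = n_benign_glands,
              n_malignant_nests = n_malignant_nests,
              gland_radius_um = gland_radius_um,
              lumen_fraction = lumen_fraction,
              ring_offset_um = ring_offset_um,
              ring_spacing_um = ring_spacing_um,
              ring_jitter_um = ring_jitter_um,
              nest_sd_um = nest_sd_um,
              nest_max_radius_um = nest_max_radius_um,
              clearance_um = clearance_um,
              cell_density = cell_density,
              marker_panel = marker_panel,
              intensity_model = intensity_model,
              correlation_model = correlation_model,
              survival_model = survival_model,
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "mfihc_config"
  cfg
}

validate_config <- function(cfg) {
  lens <- c("spot_diameter_um", "gland_radius_um", "ring_spacing_um",
            "nest_sd_um", "nest_max_radius_um", "clearance_um")
  for (f in lens) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop(sprintf("config field '%s' must be a positive length", f))
  }
  if (cfg$ring_offset_um < 0 || cfg$ring_jitter_um < 0)
    stop("ring_offset_um and ring_jitter_um must be >= 0")
  if (cfg$lumen_fraction < 0 || cfg$lumen_fraction >= 1)
    stop("lumen_fraction must lie in [0, 1)")
  if (cfg$n_benign_glands < 0 || cfg$n_malignant_nests < 0)
    stop("structure counts must be >= 0")
  co <- cfg$correlation_model$her2_top2a_coamp
  if (co < 0 || co > 1) stop("her2_top2a_coamp must lie in [0, 1]")
  if (any(cfg$cell_density < 0)) stop("cell densities must be >= 0")
  miss <- setdiff(c("epithelial", "stroma", "immune"),
                  names(cfg$cell_density))
  if (length(miss))
    stop("cell_density must name: ", paste(miss, collapse = ", "))
  invisible(cfg)
}

#' @export
print.mfihc_config <- function(x, ...) {
  cat("mfIHC simulation configuration\n")
  cat(sprintf("  spot: %g um diameter; %d benign gland(s), %d malignant nest(s)\n",
              x$spot_diameter_um, x$n_benign_glands, x$n_malignant_nests))
  cat(sprintf("  gland radius %g um (lumen %.0f%%), ring offset %g um, clearance %g um\n",
              x$gland_radius_um, 100 * x$lumen_fraction, x$ring_offset_um,
              x$clearance_um))
  cat(sprintf("  panel: %s + DAPI\n", paste(x$marker_panel, collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' Only scalar and vector fields are serialized; the three model sub-lists are
#' rebuilt from defaults and patched with any overrides present in the file.
#' @param cfg an `mfihc_config`.
#' @param path file path.
#' @return `read_config` returns an `mfihc_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mfihc_config"))
  # yaml drops names of named atomic vectors; store them as maps
  to_map <- function(x) {
    if (is.list(x)) lapply(x, to_map)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  yaml::write_yaml(to_map(unclass(cfg)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- sim_config()
  # lists of named scalars read back from YAML become numeric vectors again
  restore <- function(x) {
    if (is.list(x)) {
      if (length(x) &&
          all(vapply(x, function(e) is.numeric(e) && length(e) == 1,
                     logical(1))) && !is.null(names(x))) {
        unlist(x)
      } else lapply(x, restore)
    } else x
  }
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (nm == "cell_density") v <- unlist(v)
    if (nm %in% c("intensity_model", "correlation_model",
                  "survival_model")) {
      v <- utils::modifyList(unclass(base)[[nm]], lapply(v, restore))
    }
    base[[nm]] <- v
  }
  validate_config(base)
  class(base) <- "mfihc_config"
  base
}
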