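#' Simulate patient-level profiles (marker status, clinical, survival)
#'
#' Draws the patient-level layer of the generator without any cells: latent
#' hormone and proliferation factors, per-marker high/low status, per-marker
#' positive-cell fractions, clinical covariates (pT, pN, M, grade) coupled to
#' the latent factors, and right-censored survival times from an exponential
#' proportional-hazards model whose log-hazard shifts are the configured
#' per-marker-high multipliers.
#'
#' @param config an [sim_config()] object.
#' @param n_patients number of patients (>= 1).
#' @param seed integer seed.
#' @return data.frame, one row per patient, with columns `patient_id`,
#'   `hormone_f`, `prolif_f`, `<marker>_high` (logical, per prognosis
#'   marker), `<marker>_frac` (tumor positive-cell fraction), `pT`, `pN`,
#'   `M`, `grade`, `time_months`, `event`.
#' @export
simulate_patient_profiles <- function(config, n_patients, seed = config$seed) {
  stopifnot(inherits(config, "mfihc_config"), n_patients >= 1)
  cm <- config$correlation_model
  sm <- config$survival_model
  if (sm$baseline_hazard <= 0) stop("baseline hazard must be positive")
  with_seed(derive_seed(seed, 1L), {
    n <- as.integer(n_patients)
    H <- stats::rnorm(n)   # hormone factor
    P <- stats::rnorm(n)   # proliferation factor
    lat <- function(f, loading) {
      loading * f + sqrt(1 - loading^2) * stats::rnorm(n)
    }
    lat_m <- list()
    for (m in c("PR", "ER", "AR", "GATA3")) {
      lat_m[[m]] <- lat(H, cm$hormone_loading)
    }
    for (m in c("Ki67", "TOP2A")) {
      lat_m[[m]] <- lat(P, cm$prolif_loading)
    }
    lat_m$TROP2 <- stats::rnorm(n)
    lat_m$PDL1 <- stats::rnorm(n)
    thr <- c(PR = cm$hormone_prevalence, ER = cm$hormone_prevalence,
             AR = cm$hormone_prevalence, GATA3 = cm$hormone_prevalence,
             Ki67 = cm$prolif_prevalence, TOP2A = cm$prolif_prevalence,
             TROP2 = cm$trop2_prevalence, PDL1 = cm$pdl1_prevalence)
    high <- lapply(stats::setNames(names(lat_m), names(lat_m)), function(m) {
      lat_m[[m]] > stats::qnorm(1 - thr[[m]])
    })
    high$HER2 <- stats::runif(n) < cm$her2_prevalence
    # HER2 amplicon carries TOP2A in a configurable fraction of cases
    coamp <- high$HER2 & (stats::runif(n) < cm$her2_top2a_coamp)
    high$TOP2A <- high$TOP2A | coamp

    # positive-cell fraction per patient: Beta noise around a sigmoid of the
    # marker latent, so expression varies continuously across the cohort
    # (HER2 is amplification-driven and stays two-state)
    pf <- config$intensity_model$pos_frac
    frac <- lapply(PROGNOSIS_MARKERS, function(m) {
      lo <- pf[[m]][["low"]]
      hi <- pf[[m]][["high"]]
      mu <- if (m == "HER2") {
        ifelse(high$HER2, hi, lo)
      } else {
        v <- lo + (hi - lo) *
          stats::pnorm((lat_m[[m]] - stats::qnorm(1 - thr[[m]])) / 0.5)
        if (m == "TOP2A") v[coamp] <- hi
        v
      }
      conc <- 60
      stats::rbeta(n, mu * conc, (1 - mu) * conc)
    })
    names(frac) <- PROGNOSIS_MARKERS

    # clinical covariates from an aggressiveness latent
    agg_sd <- sqrt(cm$clinical_hormone_coef^2 + cm$clinical_prolif_coef^2 +
                     cm$clinical_noise_sd^2)
    agg <- function() {
      cm$clinical_hormone_coef * H + cm$clinical_prolif_coef * P +
        stats::rnorm(n, 0, cm$clinical_noise_sd)
    }
    grade <- cut(agg(), c(-Inf, stats::qnorm(cm$grade_breaks, 0, agg_sd), Inf),
                 labels = c("1", "2", "3"))
    pT <- cut(agg(), c(-Inf, stats::qnorm(cm$pt_breaks, 0, agg_sd), Inf),
              labels = c("pT1", "pT2", "pT3-4"))
    pN <- ifelse(stats::runif(n) <
                   stats::plogis(cm$pn_intercept + cm$pn_coef * agg() / agg_sd),
                 "pN+", "pN-")
    M <- ifelse(stats::runif(n) <
                  stats::plogis(cm$m_intercept + cm$m_coef * agg() / agg_sd),
                "M+", "M-")

    # proportional-hazards survival with exponential baseline
    lp <- rep(0, n)
    for (m in names(sm$log_hr)) {
      if (m %in% names(high)) lp <- lp + sm$log_hr[[m]] * high[[m]]
    }
    t_event <- stats::rexp(n, sm$baseline_hazard) / exp(lp)
    t_cens <- if (sm$censor_rate > 0) stats::rexp(n, sm$censor_rate)
              else rep(Inf, n)
    t_cens <- pmin(t_cens, sm$admin_censor_months)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                      hormone_f = H, prolif_f = P,
                      stringsAsFactors = FALSE)
    for (m in PROGNOSIS_MARKERS) out[[paste0(m, "_high")]] <- high[[m]]
    for (m in PROGNOSIS_MARKERS) out[[paste0(m, "_frac")]] <- frac[[m]]
    out$pT <- as.character(pT)
    out$pN <- pN
    out$M <- M
    out$grade <- as.character(grade)
    out$time_months <- time
    out$event <- event
    out
  })
}

# place n_gland + n_nest structure centres inside the spot disc by rejection
# sampling; errors out when the requested structures cannot be packed
place_structures <- function(config) {
  R <- config$spot_diameter_um / 2
  g_fp <- config$gland_radius_um + config$ring_offset_um + config$ring_jitter_um
  n_fp <- config$nest_max_radius_um
  sep_margin <- 25   # keeps epithelium of distinct structures un-linkable
  kinds <- c(rep("gland", config$n_benign_glands),
             rep("nest", config$n_malignant_nests))
  fp <- ifelse(kinds == "gland", g_fp, n_fp)
  cx <- cy <- numeric(0)
  for (i in seq_along(kinds)) {
    placed <- FALSE
    for (att in seq_len(2000L)) {
      p <- runif_disc(1, R - fp[i] - 2, R, R)
      ok <- TRUE
      if (length(cx)) {
        d <- sqrt((cx - p[1])^2 + (cy - p[2])^2)
        need <- fp[seq_along(cx)] + fp[i] + sep_margin
        mixed <- kinds[seq_along(cx)] != kinds[i]
        need[mixed] <- pmax(need[mixed],
                            g_fp + n_fp + config$clearance_um)
        ok <- all(d >= need)
      }
      if (ok) {
        cx <- c(cx, p[1])
        cy <- c(cy, p[2])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(paste0("cannot pack %d benign gland(s) and %d malignant ",
                          "nest(s) into a %g um spot with clearance %g um"),
                   config$n_benign_glands, config$n_malignant_nests,
                   config$spot_diameter_um, config$clearance_um))
    }
  }
  data.frame(kind = kinds, cx = cx, cy = cy, fp = fp,
             stringsAsFactors = FALSE)
}

# geometry layer: positions + compartment truth for one spot
spot_geometry <- function(config) {
  R <- config$spot_diameter_um / 2
  st <- place_structures(config)
  xs <- ys <- numeric(0)
  comp <- character(0)
  struct <- integer(0)
  add <- function(x, y, k, s) {
    xs <<- c(xs, x); ys <<- c(ys, y)
    comp <<- c(comp, rep(k, length(x)))
    struct <<- c(struct, rep(s, length(x)))
  }
  dens <- config$cell_density
  for (i in seq_len(nrow(st))) {
    if (st$kind[i] == "gland") {
      r_out <- config$gland_radius_um
      r_in <- config$lumen_fraction * r_out
      area_mm2 <- pi * (r_out^2 - r_in^2) / 1e6
      n_epi <- max(3L, stats::rpois(1, dens[["epithelial"]] * area_mm2))
      rr <- sqrt(stats::runif(n_epi, r_in^2, r_out^2))
      aa <- stats::runif(n_epi, 0, 2 * pi)
      add(st$cx[i] + rr * cos(aa), st$cy[i] + rr * sin(aa),
          "benign_epithelial", i)
      ring_r <- r_out + config$ring_offset_um
      n_ring <- max(8L, round(2 * pi * ring_r / config$ring_spacing_um))
      phase <- stats::runif(1, 0, 2 * pi)
      aa <- phase + 2 * pi * seq_len(n_ring) / n_ring
      rr <- ring_r + stats::runif(n_ring, -config$ring_jitter_um,
                                  config$ring_jitter_um)
      add(st$cx[i] + rr * cos(aa), st$cy[i] + rr * sin(aa),
          "myoepithelial", i)
    } else {
      area_mm2 <- pi * config$nest_max_radius_um^2 / 1e6
      n_mal <- max(5L, stats::rpois(1, dens[["epithelial"]] * area_mm2))
      px <- py <- numeric(0)
      while (length(px) < n_mal) {
        k <- n_mal - length(px)
        dx <- stats::rnorm(2 * k, 0, config$nest_sd_um)
        dy <- stats::rnorm(2 * k, 0, config$nest_sd_um)
        keep <- which(dx^2 + dy^2 <= config$nest_max_radius_um^2)
        keep <- keep[seq_len(min(k, length(keep)))]
        px <- c(px, dx[keep]); py <- c(py, dy[keep])
      }
      add(st$cx[i] + px, st$cy[i] + py, "malignant_epithelial", i)
    }
  }
  spot_area_mm2 <- pi * R^2 / 1e6
  for (k in c("stroma", "immune")) {
    nk <- stats::rpois(1, dens[[k]] * spot_area_mm2)
    if (nk > 0) {
      p <- runif_disc(nk, R - 1, R, R)
      add(p[, 1], p[, 2], k, NA_integer_)
    }
  }
  list(cells = data.frame(x_um = xs, y_um = ys, compartment_truth = comp,
                          structure_id = struct, stringsAsFactors = FALSE),
       structures = st)
}

# intensity layer: draws raw channel intensities + per-marker truth flags
draw_intensities <- function(cells, config, patient) {
  im <- config$intensity_model
  n <- nrow(cells)
  epi <- cells$compartment_truth %in% c("benign_epithelial",
                                        "malignant_epithelial")
  mal <- cells$compartment_truth == "malignant_epithelial"
  myo <- cells$compartment_truth == "myoepithelial"
  cells$PanCK_pos <- epi
  cells$Myosin_pos <- myo
  shift <- config$intensity_model$intensity_high_shift
  pat_jit <- stats::rnorm(1, 0, im$patient_intensity_sd)
  for (m in config$marker_panel) {
    par <- im$markers[[m]]
    pos <- logical(n)
    if (m == "PanCK") pos <- epi
    else if (m == "Myosin") pos <- myo
    else {
      frac_mal <- patient[[paste0(m, "_frac")]]
      frac_ben <- im$pos_frac[[m]][["benign"]]
      u <- stats::runif(n)
      pos[mal] <- u[mal] < frac_mal
      ben <- cells$compartment_truth == "benign_epithelial"
      pos[ben] <- u[ben] < frac_ben
    }
    mlog <- rep(par$neg[["meanlog"]], n)
    slog <- rep(par$neg[["sdlog"]], n)
    mlog[pos] <- par$pos[["meanlog"]]
    slog[pos] <- par$pos[["sdlog"]]
    if (!m %in% c("PanCK", "Myosin")) {
      is_high <- isTRUE(patient[[paste0(m, "_high")]])
      mlog[pos & mal] <- mlog[pos & mal] + pat_jit +
        if (is_high) shift else 0
    }
    cells[[paste0(m, "_raw")]] <- rclnorm(n, mlog, slog)
    cells[[paste0(m, "_pos_truth")]] <- pos
  }
  dap <- im$markers$DAPI
  cells$DAPI_raw <- rclnorm(n, dap$pos[["meanlog"]], dap$pos[["sdlog"]])
  cells
}

#' Simulate one synthetic TMA spot
#'
#' Generates the cell table of a single 0.6 mm tissue spot: benign glands
#' (epithelial annulus enclosed by a myoepithelial cell ring within
#' `ring_offset_um`), malignant nests placed at least `clearance_um` away
#' from every myoepithelial cell, and stromal/immune background, each cell
#' carrying raw channel intensities on [0, 255] and ground-truth labels.
#'
#' @param config an [sim_config()] object.
#' @param seed integer seed; identical `(config, seed)` gives identical output.
#' @param patient optional single-row data.frame from
#'   [simulate_patient_profiles()]; when missing, a one-patient profile is
#'   drawn from the same seed.
#' @param spot_id,patient_id identifiers stamped on the cell table.
#' @return An object of class `mfihc_spot`: a list with elements `cells`
#'   (data.frame), `clinical`, `survival`, `structures`, `config`.
#' @export
simulate_spot <- function(config, seed = config$seed, patient = NULL,
                          spot_id = "S0001",
                          patient_id = if (!is.null(patient))
                            patient$patient_id else "P0001") {
  stopifnot(inherits(config, "mfihc_config"))
  if (is.null(patient)) {
    patient <- simulate_patient_profiles(config, 1L, seed = seed)
    patient$patient_id <- patient_id
  }
  with_seed(derive_seed(seed, 2L), {
    geo <- spot_geometry(config)
    cells <- draw_intensities(geo$cells, config, patient)
    n <- nrow(cells)
    cells <- cbind(data.frame(spot_id = rep(spot_id, n),
                              patient_id = rep(patient_id, n),
                              cell_id = sprintf("%s_c%05d", spot_id,
                                                seq_len(n)),
                              stringsAsFactors = FALSE),
                   cells)
    structure(list(cells = cells,
                   clinical = patient[c("pT", "pN", "M", "grade")],
                   survival = list(time_months = patient$time_months,
                                   event = patient$event),
                   structures = geo$structures,
                   config = config),
              class = "mfihc_spot")
  })
}

#' @export
print.mfihc_spot <- function(x, ...) {
  tab <- table(x$cells$compartment_truth)
  cat(sprintf("mfIHC synthetic spot '%s': %d cells\n",
              x$cells$spot_id[1], nrow(x$cells)))
  print(tab)
  invisible(x)
}

#' Simulate a synthetic TMA cohort
#'
#' One spot per patient, with patient-level marker status, clinical
#' covariates and survival drawn by [simulate_patient_profiles()].
#'
#' @inheritParams simulate_patient_profiles
#' @return An object of class `mfihc_cohort`: list with `patients`
#'   (profile data.frame), `spots` (list of `mfihc_spot`), `cells`
#'   (row-bound cell table of all spots), `config`.
#' @export
simulate_cohort <- function(config, n_patients, seed = config$seed) {
  patients <- simulate_patient_profiles(config, n_patients, seed = seed)
  spots <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    spots[[i]] <- simulate_spot(config,
                                seed = derive_seed(seed, 100L + i),
                                patient = patients[i, , drop = FALSE],
                                spot_id = sprintf("S%04d", i),
                                patient_id = patients$patient_id[i])
  }
  cells <- do.call(rbind, lapply(spots, `[[`, "cells"))
  rownames(cells) <- NULL
  structure(list(patients = patients, spots = spots, cells = cells,
                 config = config),
            class = "mfihc_cohort")
}

#' @export
print.mfihc_cohort <- function(x, ...) {
  cat(sprintf("mfIHC synthetic cohort: %d patients, %d cells\n",
              nrow(x$patients), nrow(x$cells)))
  cat(sprintf("  events: %d of %d (%.0f%% censored)\n",
              sum(x$patients$event), nrow(x$patients),
              100 * mean(1 - x$patients$event)))
  invisible(x)
}

#' Add benign glands and stroma to an existing spot
#'
#' Used to probe tumor-purity invariance: extra benign content is placed with
#' the same clearance constraints against the existing structures, so the
#' original malignant cells, their intensities and their classification are
#' untouched; new rows are appended after the original ones.
#'
#' @param spot an `mfihc_spot`.
#' @param n_glands extra benign glands to add.
#' @param extra_stroma_per_mm2 extra stromal cell density.
#' @param seed integer seed.
#' @return The augmented `mfihc_spot`.
#' @export
add_benign_content <- function(spot, n_glands = 1,
                               extra_stroma_per_mm2 = 300, seed = 1L) {
  stopifnot(inherits(spot, "mfihc_spot"))
  config <- spot$config
  cfg2 <- config
  cfg2$n_benign_glands <- n_glands
  cfg2$n_malignant_nests <- 0L
  cfg2$cell_density[["stroma"]] <- extra_stroma_per_mm2
  cfg2$cell_density[["immune"]] <- 0
  with_seed(derive_seed(seed, 3L), {
    R <- config$spot_diameter_um / 2
    g_fp <- config$gland_radius_um + config$ring_offset_um +
      config$ring_jitter_um
    old <- spot$structures
    # place new glands against the union of old and new structures
    cx <- old$cx; cy <- old$cy; fp <- old$fp; kinds <- old$kind
    new_centers <- NULL
    for (i in seq_len(n_glands)) {
      placed <- FALSE
      for (att in seq_len(4000L)) {
        p <- runif_disc(1, R - g_fp - 2, R, R)
        d <- sqrt((cx - p[1])^2 + (cy - p[2])^2)
        need <- fp + g_fp + 25
        mixed <- kinds == "nest"
        need[mixed] <- pmax(need[mixed],
                            g_fp + config$nest_max_radius_um +
                              config$clearance_um)
        if (all(d >= need)) {
          cx <- c(cx, p[1]); cy <- c(cy, p[2])
          fp <- c(fp, g_fp); kinds <- c(kinds, "gland")
          new_centers <- rbind(new_centers, p)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("cannot pack additional benign gland into the spot")
    }
    # build gland + stroma cells at the accepted centres
    geo <- spot_geometry_at(cfg2, new_centers)
    patient <- data.frame(patient_id = spot$cells$patient_id[1])
    for (m in PROGNOSIS_MARKERS) {
      patient[[paste0(m, "_frac")]] <- 0
      patient[[paste0(m, "_high")]] <- FALSE
    }
    extra <- draw_intensities(geo, cfg2, patient)
    n0 <- nrow(spot$cells)
    extra <- cbind(data.frame(spot_id = spot$cells$spot_id[1],
                              patient_id = spot$cells$patient_id[1],
                              cell_id = sprintf("%s_x%05d",
                                                spot$cells$spot_id[1],
                                                seq_len(nrow(extra))),
                              stringsAsFactors = FALSE),
                   extra)
    spot$cells <- rbind(spot$cells[, names(extra)], extra)
    spot$structures <- data.frame(kind = kinds, cx = cx, cy = cy, fp = fp,
                                  stringsAsFactors = FALSE)
    spot
  })
}

# gland + stroma geometry at fixed centres (helper for add_benign_content)
spot_geometry_at <- function(config, centers) {
  xs <- ys <- numeric(0)
  comp <- character(0)
  dens <- config$cell_density
  if (!is.null(centers)) {
    for (i in seq_len(nrow(centers))) {
      r_out <- config$gland_radius_um
      r_in <- config$lumen_fraction * r_out
      area_mm2 <- pi * (r_out^2 - r_in^2) / 1e6
      n_epi <- max(3L, stats::rpois(1, dens[["epithelial"]] * area_mm2))
      rr <- sqrt(stats::runif(n_epi, r_in^2, r_out^2))
      aa <- stats::runif(n_epi, 0, 2 * pi)
      xs <- c(xs, centers[i, 1] + rr * cos(aa))
      ys <- c(ys, centers[i, 2] + rr * sin(aa))
      comp <- c(comp, rep("benign_epithelial", n_epi))
      ring_r <- r_out + config$ring_offset_um
      n_ring <- max(8L, round(2 * pi * ring_r / config$ring_spacing_um))
      phase <- stats::runif(1, 0, 2 * pi)
      aa <- phase + 2 * pi * seq_len(n_ring) / n_ring
      rr <- ring_r + stats::runif(n_ring, -config$ring_jitter_um,
                                  config$ring_jitter_um)
      xs <- c(xs, centers[i, 1] + rr * cos(aa))
      ys <- c(ys, centers[i, 2] + rr * sin(aa))
      comp <- c(comp, rep("myoepithelial", n_ring))
    }
  }
  R <- config$spot_diameter_um / 2
  nk <- stats::rpois(1, dens[["stroma"]] * pi * R^2 / 1e6)
  if (nk > 0) {
    p <- runif_disc(nk, R - 1, R, R)
    xs <- c(xs, p[, 1]); ys <- c(ys, p[, 2])
    comp <- c(comp, rep("stroma", nk))
  }
  data.frame(x_um = xs, y_um = ys, compartment_truth = comp,
             structure_id = NA_integer_, stringsAsFactors = FALSE)
}
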