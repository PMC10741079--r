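make_quant_cells <- function() {
  # 4 PanCK+ tumor cells (PanCK raw mean 100), 1 myo, 1 stroma
  df <- make_cells(x = c(0, 10, 20, 30, 100, 200),
                   y = rep(0, 6),
                   panck = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                   myosin = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  df$PanCK_raw <- c(80, 90, 110, 120, 5, 6)
  df$PR_raw <- c(50, 100, 150, 200, 10, 10)
  df$label_final <- c(rep("malignant", 4), NA, NA)
  df
}

test_that("normalization is the direct PanCK ratio and scale invariant", {
  df <- make_quant_cells()
  nm <- normalize_intensities(df)
  expect_equal(nm$PR_norm[1], 0.5)               # 50 / 100
  expect_equal(mean(nm$PanCK_norm[nm$PanCK_pos]), 1.0)  # self-normalization
  df2 <- df
  for (cc in grep("_raw$", names(df2), value = TRUE))
    df2[[cc]] <- df2[[cc]] * 7.3
  nm2 <- normalize_intensities(df2)
  expect_equal(nm2$PR_norm, nm$PR_norm)
  # idempotence: renormalizing normalized values changes nothing
  df3 <- df
  df3$PanCK_raw <- nm$PanCK_norm
  df3$PR_raw <- nm$PR_norm
  nm3 <- normalize_intensities(df3)
  expect_equal(nm3$PR_norm, nm$PR_norm, tolerance = 1e-9)
})

test_that("tumor-reference normalization ignores benign PanCK+ cells", {
  df <- make_quant_cells()
  extra <- df[1, ]
  extra$cell_id <- "S1_b999"
  extra$PanCK_raw <- 250
  extra$label_final <- "benign"
  both <- rbind(df, extra)
  nm <- normalize_intensities(both, reference = "tumor")
  expect_equal(nm$PR_norm[1:4],
               normalize_intensities(df, reference = "tumor")$PR_norm[1:4])
  # the all-PanCK reference does move, by definition
  nm_all <- normalize_intensities(both, reference = "panck")
  expect_false(isTRUE(all.equal(nm_all$PR_norm[1], nm$PR_norm[1])))
})

test_that("missing reference cells raise an error naming the spot", {
  df <- make_quant_cells()
  df$PanCK_pos <- FALSE
  expect_error(normalize_intensities(df), "S1")
  df2 <- make_quant_cells()
  df2$label_final <- NA
  expect_error(normalize_intensities(df2, reference = "tumor"), "S1")
})

test_that("positivity thresholds reproduce generator truth on tumor cells", {
  cfg <- sim_config()
  sp <- simulate_spot(cfg, seed = 31)
  cells <- annotate_cells(sp)
  cells <- normalize_intensities(cells, reference = "tumor")
  th <- default_positivity_thresholds(cfg)
  tum <- cells$compartment_truth == "malignant_epithelial"
  agree <- vapply(PROGNOSIS_MARKERS, function(m) {
    mean(call_positivity(cells, m, th[[m]])[tum] ==
           cells[[paste0(m, "_pos_truth")]][tum])
  }, numeric(1))
  expect_true(all(agree >= 0.99))
  expect_error(call_positivity(cells, "NOTAMARKER", 1), "unknown marker")
  expect_true(all(call_positivity(cells, "PR", 0)))
  expect_false(any(call_positivity(cells, "PR", 1e9)))
})

test_that("marker summaries equal a brute-force recomputation", {
  cfg <- sim_config()
  sp <- simulate_spot(cfg, seed = 8)
  cells <- normalize_intensities(annotate_cells(sp), reference = "tumor")
  th <- default_positivity_thresholds(cfg)
  s <- summarize_markers(cells, c("PR", "Ki67"), th)
  for (m in c("PR", "Ki67")) {
    tum <- which(!is.na(cells$label_final) & cells$label_final == "malignant")
    v <- cells[[paste0(m, "_norm")]][tum]
    pos <- v >= th[[m]]
    row <- s[s$marker == m, ]
    expect_equal(row$n_tumor_cells, length(tum))
    expect_equal(row$positive_fraction, sum(pos) / length(pos))
    expect_equal(row$mean_pos_intensity,
                 if (any(pos)) mean(v[pos]) else 0)
  }
})

test_that("fraction arithmetic and the empty-positive convention hold", {
  df <- make_quant_cells()
  # 10 tumor cells, 4 positive at threshold 1.0 on PR_norm
  df <- df[rep(1, 10), ]
  df$cell_id <- sprintf("c%02d", 1:10)
  df$PR_raw <- c(rep(200, 4), rep(10, 6))
  df$PanCK_raw <- 100
  df$label_final <- "malignant"
  nm <- normalize_intensities(df)
  s <- summarize_markers(nm, "PR", c(PR = 1.0))
  expect_equal(s$positive_fraction, 0.4)
  s0 <- summarize_markers(nm, "PR", c(PR = 1e9))
  expect_equal(s0$positive_fraction, 0)
  expect_equal(s0$mean_pos_intensity, 0)
  # a patient without tumor cells is excluded, not an error
  df$patient_id <- rep(c("P1", "P2"), each = 5)
  df$label_final[df$patient_id == "P2"] <- "benign"
  s2 <- summarize_markers(normalize_intensities(df), "PR", c(PR = 1.0))
  expect_identical(attr(s2, "excluded"), "P2")
  expect_identical(unique(s2$patient_id), "P1")
})

test_that("min-max scaling maps cohort extremes onto the score range", {
  expect_equal(minmax_to_range(c(0, 5, 10)), c(0, 25, 50))
  v <- c(3.2, 9.1, 4.4, 7.7)
  sc <- minmax_to_range(v)
  expect_equal(sc[which.max(v)], 50)
  expect_equal(sc[which.min(v)], 0)
  expect_warning(out <- minmax_to_range(rep(4, 5)), "constant")
  expect_equal(out, rep(0, 5))
})

test_that("mfIHC scores match a hand-computed five-patient cohort", {
  s <- data.frame(patient_id = paste0("P", 1:5), marker = "PR",
                  n_tumor_cells = 100,
                  positive_fraction = c(0.1, 0.2, 0.4, 0.5, 0.9),
                  mean_pos_intensity = c(1, 2, 3, 4, 5))
  out <- mfihc_scores(s)
  # by hand: prop = 50*(f-0.1)/0.8 ; int = 50*(i-1)/4
  expect_equal(out$prop_component, c(0, 6.25, 18.75, 25, 50))
  expect_equal(out$int_component, c(0, 12.5, 25, 37.5, 50))
  expect_equal(out$mfihc_score, c(0, 18.75, 43.75, 62.5, 100))
  expect_true(all(out$mfihc_score >= 0 & out$mfihc_score <= 100))
})

test_that("labeling index is one hundred times the positive fraction", {
  cfg <- sim_config()
  sp <- simulate_spot(cfg, seed = 19)
  cells <- normalize_intensities(annotate_cells(sp), reference = "tumor")
  th <- default_positivity_thresholds(cfg)
  li <- labeling_index(cells, "Ki67", th[["Ki67"]])
  s <- summarize_markers(cells, "Ki67", th)
  expect_equal(li$labeling_index, 100 * s$positive_fraction)
})
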