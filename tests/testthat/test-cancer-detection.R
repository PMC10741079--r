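test_that("distances follow hand geometry and the empty-reference sentinel", {
  cells <- make_cells(x = c(0, 3, 10), y = c(0, 4, 0),
                      panck = c(TRUE, FALSE, FALSE),
                      myosin = c(FALSE, TRUE, TRUE))
  d <- nearest_myoepithelial_distance(cells)
  expect_equal(d$nearest_myo_dist_um, 5)
  no_myo <- make_cells(x = c(1, 2), y = c(1, 2),
                       panck = c(TRUE, TRUE), myosin = c(FALSE, FALSE))
  d2 <- nearest_myoepithelial_distance(no_myo)
  expect_identical(d2$nearest_myo_dist_um, c(Inf, Inf))
  expect_identical(classify_cells_by_distance(d2)$label_distance,
                   c("malignant", "malignant"))
  # zero epithelial cells: empty result, not an error
  none <- make_cells(x = 1, y = 1, panck = FALSE, myosin = TRUE)
  expect_identical(nrow(nearest_myoepithelial_distance(none)), 0L)
})

test_that("grid-index distances equal the brute-force minimum", {
  set.seed(101)
  n <- 500
  cells <- make_cells(x = runif(n, 0, 600), y = runif(n, 0, 600),
                      panck = runif(n) < 0.5, myosin = runif(n) < 0.2)
  cells$PanCK_pos <- cells$PanCK_pos & !cells$Myosin_pos
  d <- nearest_myoepithelial_distance(cells)
  epi <- cells[cells$PanCK_pos, ]
  myo <- cells[cells$Myosin_pos, ]
  expect_equal(d$nearest_myo_dist_um[match(epi$cell_id, d$cell_id)],
               bf_nn(epi$x_um, epi$y_um, myo$x_um, myo$y_um))
})

test_that("the 25 um boundary is inclusive and thresholding is monotone", {
  expect_identical(classify_cells_by_distance(25.0), "benign")
  expect_identical(classify_cells_by_distance(25.000001), "malignant")
  expect_identical(classify_cells_by_distance(Inf), "malignant")
  set.seed(7)
  d <- runif(200, 0, 100)
  prev <- rep(FALSE, 200)
  for (th in c(5, 15, 25, 60, 101)) {
    ben <- classify_cells_by_distance(d, th) == "benign"
    expect_true(all(ben | !prev))   # benign set only grows
    prev <- ben
  }
  expect_error(classify_cells_by_distance(d, 0))
})

test_that("distances are invariant under rigid motion", {
  set.seed(11)
  n <- 120
  cells <- make_cells(x = runif(n, 0, 600), y = runif(n, 0, 600),
                      panck = runif(n) < 0.6, myosin = runif(n) < 0.3)
  d0 <- nearest_myoepithelial_distance(cells)$nearest_myo_dist_um
  th <- pi / 5
  xr <- cells$x_um * cos(th) - cells$y_um * sin(th) + 500
  yr <- cells$x_um * sin(th) + cells$y_um * cos(th) - 120
  rot <- cells
  rot$x_um <- xr
  rot$y_um <- yr
  expect_equal(nearest_myoepithelial_distance(rot)$nearest_myo_dist_um, d0,
               tolerance = 1e-9)
})

test_that("gland components equal the transitive-closure oracle", {
  set.seed(23)
  n <- 150
  cells <- make_cells(x = runif(n, 0, 300), y = runif(n, 0, 300),
                      panck = rep(TRUE, n), myosin = rep(FALSE, n))
  g <- detect_glands(cells, linkage_radius_um = 15)
  oracle <- bf_components(cells$x_um, cells$y_um, 15)
  expect_true(same_partition(g$gland_id[match(cells$cell_id, g$cell_id)],
                             oracle))
  # two clusters separated by 3x the linkage radius
  two <- make_cells(x = c(0, 5, 10, 70, 75), y = rep(0, 5),
                    panck = rep(TRUE, 5), myosin = rep(FALSE, 5))
  expect_identical(length(unique(detect_glands(two, 20)$gland_id)), 2L)
  # zero epithelial cells
  none <- make_cells(x = 1, y = 1, panck = FALSE, myosin = TRUE)
  expect_identical(nrow(detect_glands(none, 20)), 0L)
})

test_that("gland labels follow the coverage rule with benign ties", {
  cells <- make_cells(x = c(0, 40, 200, 1), y = c(0, 0, 200, 0),
                      panck = c(TRUE, TRUE, TRUE, FALSE),
                      myosin = c(FALSE, FALSE, FALSE, TRUE))
  d <- nearest_myoepithelial_distance(cells)
  g <- detect_glands(cells, linkage_radius_um = 50)
  gl <- classify_gland(g, d)
  gl <- gl[order(gl$gland_id), ]
  # gland 1: cells at 1 um and 39 um from the myo cell -> coverage 0.5 -> tie
  expect_equal(gl$myoepithelial_coverage, c(0.5, 0))
  expect_identical(gl$label_gland, c("benign", "malignant"))
  gl2 <- classify_gland(g, d, coverage_threshold = 0.51)
  expect_identical(sort(gl2$label_gland), c("malignant", "malignant"))
})

test_that("combination rules reproduce their 2x2 truth tables", {
  labs <- expand.grid(cell = c("benign", "malignant"),
                      gland = c("benign", "malignant"),
                      stringsAsFactors = FALSE)
  expected <- list(
    "benign-if-either" = c("benign", "benign", "benign", "malignant"),
    "benign-if-both"   = c("benign", "malignant", "malignant", "malignant"),
    "cell-priority"    = c("benign", "malignant", "benign", "malignant"),
    "gland-priority"   = c("benign", "benign", "malignant", "malignant"))
  for (mode in names(expected)) {
    got <- vapply(seq_len(nrow(labs)), function(i) {
      cl <- data.frame(cell_id = "c1", label_distance = labs$cell[i])
      g <- data.frame(cell_id = "c1", gland_id = "g1")
      gl <- data.frame(gland_id = "g1", label_gland = labs$gland[i])
      combine_approaches(cl, g, gl, mode)$label_final
    }, character(1))
    expect_identical(got, expected[[mode]])
  }
  expect_error(combine_approaches(
    data.frame(cell_id = "c1", label_distance = "benign"),
    data.frame(cell_id = "c2", gland_id = "g1"),
    data.frame(gland_id = "g1", label_gland = "benign")),
    "different cell ids")
})

test_that("metrics and Wilson intervals match the closed form", {
  pred <- c(rep("malignant", 90), rep("benign", 10),   # truth malignant
            rep("benign", 95), rep("malignant", 5))    # truth benign
  truth <- c(rep("malignant", 100), rep("benign", 100))
  m <- evaluate_classification(pred, truth, unit = "cell")
  expect_equal(m$sensitivity[["estimate"]], 0.90)
  expect_equal(m$specificity[["estimate"]], 0.95)
  wilson <- function(k, n) {
    z <- qnorm(0.975)
    p <- k / n
    c((p + z^2 / (2 * n)) / (1 + z^2 / n) -
        z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n),
      (p + z^2 / (2 * n)) / (1 + z^2 / n) +
        z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n))
  }
  expect_equal(unname(m$sensitivity[c("lower", "upper")]), wilson(90, 100))
  expect_equal(unname(m$accuracy[["estimate"]]), 185 / 200)
  # arithmetic of the headline form: 984 correct of 1000
  perfect <- evaluate_classification(
    c(rep("malignant", 492), rep("benign", 492), rep("malignant", 16)),
    c(rep("malignant", 492), rep("benign", 492), rep("benign", 16)))
  expect_equal(perfect$accuracy[["estimate"]], 0.984)
  all_right <- evaluate_classification(c("benign", "malignant"),
                                       c("benign", "malignant"))
  expect_equal(all_right$accuracy[["estimate"]], 1)
  expect_equal(all_right$accuracy[["upper"]], 1)
  expect_error(evaluate_classification(character(0), character(0)))
})
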