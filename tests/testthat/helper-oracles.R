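# independent brute-force oracles used across test files

# O(n^2) all-pairs nearest-neighbour distance
bf_nn <- function(qx, qy, rx, ry) {
  if (length(rx) == 0L) return(rep(Inf, length(qx)))
  vapply(seq_along(qx), function(i) {
    sqrt(min((rx - qx[i])^2 + (ry - qy[i])^2))
  }, numeric(1))
}

# connected components of the distance-threshold graph by transitive closure
# (boolean matrix powering)
bf_components <- function(x, y, radius) {
  n <- length(x)
  A <- as.matrix(stats::dist(cbind(x, y))) <= radius
  diag(A) <- TRUE
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  match(apply(A, 1, function(r) paste(which(r), collapse = ",")),
        unique(apply(A, 1, function(r) paste(which(r), collapse = ","))))
}

# are two partitions identical up to label permutation?
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# hand product-limit estimator (no package code)
bf_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    d <- sum(times == ut[i] & events == 1)
    r <- sum(times >= ut[i])
    s <- s * (1 - d / r)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# hand two-group log-rank statistic (observed minus expected form)
bf_logrank <- function(times, events, group) {
  g <- unique(group)
  stopifnot(length(g) == 2L)
  ut <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ut) {
    d <- sum(times == t & events == 1)
    n <- sum(times >= t)
    n1 <- sum(times >= t & group == g[1])
    d1 <- sum(times == t & events == 1 & group == g[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# minimal cell table builder for hand-constructed geometries
make_cells <- function(x, y, panck, myosin, spot = "S1", patient = "P1") {
  n <- length(x)
  data.frame(spot_id = rep(spot, n), patient_id = rep(patient, n),
             cell_id = sprintf("%s_c%03d", spot, seq_len(n)),
             x_um = x, y_um = y,
             compartment_truth = ifelse(myosin, "myoepithelial",
                                        ifelse(panck, "malignant_epithelial",
                                               "stroma")),
             PanCK_pos = panck, Myosin_pos = myosin,
             stringsAsFactors = FALSE)
}
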