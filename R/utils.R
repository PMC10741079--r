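# internal helpers: seeding, clamping, spatial index

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic stage seed derived from a root seed; stays below 2^31 - 1
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483629)
}

# log-normal draw clamped to [lo, hi]; the measurement contract is 0-255
rclnorm <- function(n, meanlog, sdlog, lo = 0, hi = 255) {
  clamp(stats::rlnorm(n, meanlog, sdlog), lo, hi)
}

# expected value of min(X, hi) for X ~ lognormal(meanlog, sdlog)
clamped_lnorm_mean <- function(meanlog, sdlog, hi = 255) {
  # E[X; X <= hi] = exp(mu + s^2/2) * Phi((log hi - mu - s^2)/s)
  exp(meanlog + sdlog^2 / 2) *
    stats::pnorm((log(hi) - meanlog - sdlog^2) / sdlog) +
    hi * (1 - stats::plnorm(hi, meanlog, sdlog))
}

#' Nearest-neighbour distances via a grid-bucket index
#'
#' For each query point the Euclidean distance to the nearest reference point.
#' Uses a uniform-grid ring search; exact (equal to the brute-force minimum).
#' Returns +Inf when the reference set is empty.
#' @noRd
nn_dist <- function(qx, qy, rx, ry) {
  nq <- length(qx)
  nr <- length(rx)
  if (nq == 0L) return(numeric(0))
  if (nr == 0L) return(rep(Inf, nq))
  if (nr <= 32L) {
    # direct scan: a grid index cannot pay off on a handful of points
    return(vapply(seq_len(nq), function(i) {
      sqrt(min((rx - qx[i])^2 + (ry - qy[i])^2))
    }, numeric(1)))
  }
  # bucket width from the joint extent so far-away queries terminate fast
  span <- max(diff(range(rx, qx)), diff(range(ry, qy)), 1e-9)
  h <- span / max(1, floor(sqrt(nr)))
  bx <- floor(rx / h)
  by <- floor(ry / h)
  buckets <- split(seq_len(nr), paste(bx, by))
  qbx <- floor(qx / h)
  qby <- floor(qy / h)
  out <- numeric(nq)
  for (i in seq_len(nq)) {
    best <- Inf
    ring <- 0L
    repeat {
      ii <- (qbx[i] - ring):(qbx[i] + ring)
      jj <- (qby[i] - ring):(qby[i] + ring)
      for (ix in ii) {
        for (iy in jj) {
          if (max(abs(ix - qbx[i]), abs(iy - qby[i])) < ring) next
          b <- buckets[[paste(ix, iy)]]
          if (!is.null(b)) {
            d2 <- (rx[b] - qx[i])^2 + (ry[b] - qy[i])^2
            best <- min(best, sqrt(min(d2)))
          }
        }
      }
      # any unscanned point sits in a bucket with Chebyshev offset > ring,
      # hence at Euclidean distance >= ring * h
      if (best <= ring * h) break
      ring <- ring + 1L
    }
    out[i] <- best
  }
  out
}

# uniform draw inside a disc of radius R centred at (cx, cy)
runif_disc <- function(n, R, cx = 0, cy = 0) {
  r <- R * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(x = cx + r * cos(a), y = cy + r * sin(a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
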