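# Independent brute-force oracles, deliberately coded with different
# algorithms than the package implementation.

# Otsu by exhaustive double loop over all 256 cuts, minimizing the pooled
# intra-class variance directly.
oracle_otsu <- function(histogram) {
  levels <- 0:255
  best_t <- NA_integer_
  best_v <- Inf
  for (t in 0:255) {
    in0 <- levels <= t
    n0 <- sum(histogram[in0]); n1 <- sum(histogram[!in0])
    if (n0 == 0 || n1 == 0) next
    m0 <- sum(histogram[in0] * levels[in0]) / n0
    m1 <- sum(histogram[!in0] * levels[!in0]) / n1
    v0 <- sum(histogram[in0] * (levels[in0] - m0)^2) / n0
    v1 <- sum(histogram[!in0] * (levels[!in0] - m1)^2) / n1
    v <- (n0 * v0 + n1 * v1) / (n0 + n1)
    if (v < best_v - 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# Heatmap assembly by a per-cell loop over every rectangle.
oracle_heatmap_values <- function(predictions, canvas_size, cell_size) {
  nx <- ceiling(canvas_size[1] / cell_size)
  ny <- ceiling(canvas_size[2] / cell_size)
  H <- matrix(NA_real_, ny, nx)
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    xc <- (c - 0.5) * cell_size
    yc <- (r - 0.5) * cell_size
    best <- NA_real_
    for (i in seq_len(nrow(predictions))) {
      p <- predictions[i, ]
      if (xc >= p$x && xc < p$x + p$w && yc >= p$y && yc < p$y + p$h)
        best <- max(best, p$prob, na.rm = TRUE)
    }
    H[r, c] <- best
  }
  H
}

# Connected-component labeling by iterative label propagation (minimum
# neighbor label until fixpoint) -- a different algorithm than the package's
# flood fill.
oracle_label_8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  lab[m] <- seq_len(sum(m))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!m[r, c]) next
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc || !m[rr, cc]) next
        if (lab[rr, cc] < lab[r, c]) {
          lab[r, c] <- lab[rr, cc]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # renumber 1..k in first-appearance order
  ids <- unique(lab[lab > 0])
  out <- matrix(0L, nr, nc)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

# Region properties by direct per-pixel loops.
oracle_region_props <- function(lab, values, k) {
  nr <- nrow(lab); nc <- ncol(lab)
  rows <- c(); cols <- c()
  for (r in seq_len(nr)) for (c in seq_len(nc)) if (lab[r, c] == k) {
    rows <- c(rows, r); cols <- c(cols, c)
  }
  area <- length(rows)
  per <- 0
  for (i in seq_along(rows)) {
    r <- rows[i]; c <- cols[i]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || lab[rr, cc] != k)
        per <- per + 1
    }
  }
  mr <- sum(rows) / area; mc <- sum(cols) / area
  mu20 <- sum((cols - mc)^2) / area
  mu02 <- sum((rows - mr)^2) / area
  mu11 <- sum((cols - mc) * (rows - mr)) / area
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- max((mu20 + mu02) / 2 - common, 0)
  vals <- values[cbind(rows, cols)]
  list(area = area, perimeter = per,
       eccentricity = if (l1 <= 0) 0 else sqrt(1 - l2 / l1),
       extent = area / ((max(rows) - min(rows) + 1) * (max(cols) - min(cols) + 1)),
       major_axis = 4 * sqrt(l1),
       mean_prob = mean(vals))
}

oracle_stats5 <- function(x) {
  if (length(x) == 0) return(c(0, 0, 0, 0, 0))
  m <- sum(x) / length(x)
  m2 <- sum((x - m)^2) / length(x)
  if (m2 == 0) return(c(max(x), m, 0, 0, 0))
  m3 <- sum((x - m)^3) / length(x)
  m4 <- sum((x - m)^4) / length(x)
  c(max(x), m, m2, m3 / m2^(3 / 2), m4 / m2^2)
}

# Full 44-feature oracle, independently coded from the heatmap values matrix
# (NA = no data) and a logical tissue matrix.
oracle_features44 <- function(values, tissue) {
  ok <- tissue & !is.na(values)
  p <- values[ok]
  n <- sum(ok)
  f <- numeric(44)
  bin90 <- ok & !is.na(values) & values >= 0.90
  bin50 <- ok & !is.na(values) & values >= 0.50
  bin90[is.na(bin90)] <- FALSE
  bin50[is.na(bin50)] <- FALSE
  lab90 <- oracle_label_8(bin90)
  lab50 <- oracle_label_8(bin50)
  props <- function(lab) {
    k <- max(lab)
    if (k == 0) return(NULL)
    do.call(rbind, lapply(seq_len(k), function(i)
      as.data.frame(oracle_region_props(lab, values, i))))
  }
  p90 <- props(lab90)
  p50 <- props(lab50)
  f[1] <- if (is.null(p90)) 0 else sum(p90$area >= 0.05 * n)
  f[2] <- if (is.null(p90)) 0 else sum(p90$area) / n
  if (!is.null(p50)) {
    i <- which.max(p50$area)
    f[3] <- p50$area[i]
    f[4] <- p50$major_axis[i]
  }
  f[5] <- sum(p >= 0.90) / n
  f[6] <- if (any(p >= 0.90)) mean(p[p >= 0.90]) else 0
  f[7:11] <- oracle_stats5(if (is.null(p90)) numeric(0) else p90$area)
  f[12:16] <- oracle_stats5(if (is.null(p90)) numeric(0) else p90$perimeter)
  f[17:21] <- oracle_stats5(if (is.null(p90)) numeric(0) else p90$eccentricity)
  f[22:26] <- oracle_stats5(if (is.null(p50)) numeric(0) else p50$extent)
  m <- mean(p)
  f[27] <- m
  f[28] <- sum((p - m)^2) / n
  f[29] <- sqrt(f[28])
  f[30] <- stats::median(p)
  mode_counts <- vapply(1:100, function(j)
    sum(p > (j - 1) / 100 & p <= j / 100) + if (j == 1) sum(p == 0) else 0L, 0)
  f[31] <- (which.max(mode_counts) - 1) / 100
  f[32] <- min(p); f[33] <- max(p); f[34] <- max(p) - min(p); f[35] <- sum(p)
  f[36] <- m
  lo <- c(0.999, 0.99, 0.95, 0.9, 0.8, 0.7, 0.6, 0.5)
  hi <- c(Inf, 0.999, 0.99, 0.95, 0.9, 0.8, 0.7, 0.6)
  for (b in 1:8) f[36 + b] <- sum(p > lo[b] & p <= hi[b]) / n
  f
}

angle_deg <- function(a, b) {
  acos(pmin(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), 1)) * 180 / pi
}

# Pooled per-channel earth-mover (L1 between empirical CDFs on the 0..255
# gray grid) distance between two lists of RGB rasters.
pooled_emd <- function(xs, ys) {
  mean(sapply(1:3, function(k) {
    px <- unlist(lapply(xs, function(x) as.vector(x[, , k])))
    py <- unlist(lapply(ys, function(y) as.vector(y[, , k])))
    cx <- cumsum(tabulate(floor(px) + 1, 256) / length(px))
    cy <- cumsum(tabulate(floor(py) + 1, 256) / length(py))
    sum(abs(cx - cy))
  }))
}
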