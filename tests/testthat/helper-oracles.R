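# Fixtures and independent oracles shared across tests. Everything is built
# in code at test time; oracles are deliberately naive implementations kept
# separate from the package's own code paths.

# Rasterised ball mask: voxel centres within `radius` mm of the grid centre.
rasterize_ball <- function(shape, spacing = c(1, 1, 1), radius,
                           center = NULL) {
  ctr <- if (is.null(center)) (shape - 1) / 2 * spacing else center
  x <- (seq_len(shape[1]) - 1) * spacing[1]
  y <- (seq_len(shape[2]) - 1) * spacing[2]
  z <- (seq_len(shape[3]) - 1) * spacing[3]
  d2 <- outer(outer((x - ctr[1])^2, (y - ctr[2])^2, `+`), (z - ctr[3])^2, `+`)
  array(d2 <= radius^2, dim = shape)
}

# Brute-force SE radius straight from the definition.
se_radius_oracle <- function(mask, spacing = c(1, 1, 1)) {
  (3 * sum(mask) * prod(spacing) / (4 * pi))^(1 / 3)
}

# Brute-force Euclidean distance transform (O(n * features)).
edt_oracle <- function(mask, spacing) {
  shp <- dim(mask)
  feat <- which(mask, arr.ind = TRUE)
  out <- array(Inf, shp)
  for (i in seq_len(shp[1])) for (j in seq_len(shp[2])) for (k in seq_len(shp[3])) {
    dd <- ((feat[, 1] - i) * spacing[1])^2 +
      ((feat[, 2] - j) * spacing[2])^2 +
      ((feat[, 3] - k) * spacing[3])^2
    out[i, j, k] <- sqrt(min(dd))
  }
  out
}

# Brute-force two-group log-rank statistic from first principles: walk the
# pooled distinct event times, build the 2x2 risk-set table at each, and
# accumulate observed-minus-expected and hypergeometric variance.
logrank_oracle <- function(time_a, event_a, time_b, event_b) {
  times <- sort(unique(c(time_a[event_a], time_b[event_b])))
  U <- 0
  V <- 0
  for (t in times) {
    n1 <- sum(time_a >= t)
    n2 <- sum(time_b >= t)
    d1 <- sum(time_a == t & event_a)
    d2 <- sum(time_b == t & event_b)
    n <- n1 + n2
    d <- d1 + d2
    if (n < 2 || d == 0) next
    U <- U + d1 - d * n1 / n
    V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) U^2 / V else 0
  list(chi_square = chi, p_value = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# Logistic growth closed form for the D = 0 limit.
logistic_closed_form <- function(c0, rho, t) {
  c0 * exp(rho * t) / (1 - c0 + c0 * exp(rho * t))
}

# Connectivity check by iterative 6-neighbour dilation from one seed voxel.
mask_connected <- function(mask) {
  seedv <- which(mask)[1]
  comp <- array(FALSE, dim(mask))
  comp[seedv] <- TRUE
  repeat {
    grown <- (!daysgained:::erode_layer(!comp)) & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  sum(comp) == sum(mask)
}

default_thresholds <- detection_thresholds()
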