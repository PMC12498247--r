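# Independent reference implementations used as oracles.  These are kept as
# plain loops, deliberately separate from the package's vectorized code.

# nearest-target equidistant selection, written as literal loops
oracle_select <- function(values, energies, n = 10, include_lowest = TRUE) {
  m <- length(values)
  if (m <= n) return(seq_len(m))
  targets <- min(values) + (seq_len(n) - 1) * (max(values) - min(values)) / (n - 1)
  selected <- integer(0)
  for (t in targets) {
    best <- NA_integer_
    for (i in seq_len(m)) {
      if (i %in% selected) next
      if (is.na(best)) { best <- i; next }
      di <- abs(values[i] - t); db <- abs(values[best] - t)
      if (di < db ||
          (di == db && energies[i] < energies[best]) ||
          (di == db && energies[i] == energies[best] && i < best)) {
        best <- i
      }
    }
    selected <- c(selected, best)
  }
  if (include_lowest) {
    lowest <- which(energies == min(energies))[1]
    if (!(lowest %in% selected)) selected <- c(selected, lowest)
  }
  selected
}

# loop-based five-statistic aggregation
oracle_aggregate <- function(mat, weights, energies) {
  out <- list()
  lowest <- which(energies == min(energies))[1]
  for (f in colnames(mat)) {
    v <- mat[, f]
    b <- 0
    for (i in seq_along(v)) b <- b + weights[i] * v[i]
    out[[f]] <- c(boltzmann = b, min = min(v), max = max(v),
                  mean = sum(v) / length(v), lowest = v[lowest])
  }
  out
}

# textbook regression metrics
oracle_metrics <- function(y, yhat) {
  n <- length(y)
  sse <- 0; sab <- 0
  for (i in seq_len(n)) {
    sse <- sse + (y[i] - yhat[i])^2
    sab <- sab + abs(y[i] - yhat[i])
  }
  sst <- sum((y - mean(y))^2)
  c(r2 = 1 - sse / sst, mae = sab / n, rmse = sqrt(sse / n))
}

# a random blob of atoms around the origin, for sphere-descriptor tests
random_cluster <- function(n = 6, seed = 1, spread = 1.5,
                           elems = c("C", "N", "O", "H", "S")) {
  withr::with_seed(seed, {
    conformer(
      tibble::tibble(
        element = sample(elems, n, replace = TRUE),
        x = rnorm(n, sd = spread), y = rnorm(n, sd = spread),
        z = rnorm(n, sd = spread)
      ),
      energy = 0, id = "cluster"
    )
  })
}

# apply a rigid rotation + translation to a conformer
transform_conformer <- function(cf, angles = c(0.3, 1.1, -0.7),
                                shift = c(1, -2, 0.5)) {
  rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]), 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                 sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  m <- coords(cf) %*% t(rz %*% ry %*% rx)
  m <- sweep(m, 2, shift, "+")
  cf$atoms$x <- m[, 1]; cf$atoms$y <- m[, 2]; cf$atoms$z <- m[, 3]
  cf
}
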