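# Internal numerical geometry engines shared by the descriptor functions:
# quasi-uniform direction sets, sphere-occupancy fractions on a cubic grid or
# by Monte Carlo, and union-of-spheres volumes.

# n quasi-uniform unit vectors (Fibonacci spiral lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# run expr with a private RNG state so seeded numerics never disturb the
# caller's random stream
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# fraction of a probe sphere (radius R, centred at the origin) covered by the
# union of spheres at `centers` (matrix n x 3) with `radii`
probe_sphere_fraction <- function(centers, radii, R,
                                  method = c("grid", "mc"),
                                  spacing = 0.05, n_mc = 1e5, seed = 2025) {
  method <- match.arg(method)
  if (R <= 0) abort("Probe radius must be positive.")
  if (is.null(centers) || nrow(centers) == 0) return(0)
  r2 <- radii^2
  if (method == "grid") {
    g <- seq(-R + spacing / 2, R - spacing / 2, by = spacing)
    gx <- rep(g, times = length(g))
    gy <- rep(g, each = length(g))
    xy2 <- gx^2 + gy^2
    tot <- 0; occ <- 0
    for (z in g) {
      inside <- xy2 + z^2 <= R^2
      if (!any(inside)) next
      x <- gx[inside]; y <- gy[inside]
      tot <- tot + length(x)
      covered <- rep(FALSE, length(x))
      for (k in seq_len(nrow(centers))) {
        dz <- z - centers[k, 3]
        if (abs(dz) > radii[k]) next
        covered <- covered |
          ((x - centers[k, 1])^2 + (y - centers[k, 2])^2 + dz^2 <= r2[k])
      }
      occ <- occ + sum(covered)
    }
    if (tot == 0) return(0)
    occ / tot
  } else {
    with_private_seed(seed, {
      u <- runif(n_mc)
      rad <- R * u^(1 / 3)
      dir <- matrix(rnorm(3 * n_mc), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      pts <- dir * rad
      covered <- rep(FALSE, n_mc)
      for (k in seq_len(nrow(centers))) {
        covered <- covered |
          ((pts[, 1] - centers[k, 1])^2 + (pts[, 2] - centers[k, 2])^2 +
             (pts[, 3] - centers[k, 3])^2 <= r2[k])
      }
      mean(covered)
    })
  }
}

# volume (A^3) of the union of spheres
sphere_union_volume <- function(centers, radii,
                                method = c("grid", "mc"),
                                spacing = 0.1, n_mc = 2e5, seed = 2025) {
  method <- match.arg(method)
  if (is.null(centers) || nrow(centers) == 0) return(0)
  lo <- apply(centers - radii, 2, min)
  hi <- apply(centers + radii, 2, max)
  r2 <- radii^2
  if (method == "grid") {
    gx <- seq(lo[1] + spacing / 2, hi[1], by = spacing)
    gy <- seq(lo[2] + spacing / 2, hi[2], by = spacing)
    gz <- seq(lo[3] + spacing / 2, hi[3], by = spacing)
    px <- rep(gx, times = length(gy))
    py <- rep(gy, each = length(gx))
    occ <- 0
    for (z in gz) {
      covered <- rep(FALSE, length(px))
      for (k in seq_len(nrow(centers))) {
        dz <- z - centers[k, 3]
        if (abs(dz) > radii[k]) next
        covered <- covered |
          ((px - centers[k, 1])^2 + (py - centers[k, 2])^2 + dz^2 <= r2[k])
      }
      occ <- occ + sum(covered)
    }
    occ * spacing^3
  } else {
    box <- prod(hi - lo)
    with_private_seed(seed, {
      pts <- cbind(runif(n_mc, lo[1], hi[1]),
                   runif(n_mc, lo[2], hi[2]),
                   runif(n_mc, lo[3], hi[3]))
      covered <- rep(FALSE, n_mc)
      for (k in seq_len(nrow(centers))) {
        covered <- covered |
          ((pts[, 1] - centers[k, 1])^2 + (pts[, 2] - centers[k, 2])^2 +
             (pts[, 3] - centers[k, 3])^2 <= r2[k])
      }
      mean(covered) * box
    })
  }
}

# solid angle (steradians) subtended at the origin by the union of spheres,
# by quasi-uniform ray sampling.  clamp = TRUE treats spheres containing the
# apex as covering the whole sky; clamp = FALSE errors in that case.
union_solid_angle <- function(centers, radii, n_rays = 1e5, clamp = TRUE) {
  if (is.null(centers) || nrow(centers) == 0) return(0)
  d2 <- rowSums(centers^2)
  if (any(d2 <= radii^2)) {
    if (!clamp)
      abort("An included sphere contains the apex; enable clamping or exclude it.")
    return(4 * pi)
  }
  u <- fibonacci_sphere(n_rays)
  hit <- rep(FALSE, n_rays)
  for (k in seq_len(nrow(centers))) {
    b <- u %*% centers[k, ]
    disc <- b^2 - (d2[k] - radii[k]^2)
    ok <- disc >= 0
    # forward intersection: largest root positive
    hit <- hit | (ok & (b + sqrt(pmax(disc, 0)) > 0))
  }
  4 * pi * mean(hit)
}
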