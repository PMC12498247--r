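test_that("core-atom detection finds Pd, the P pair and the nearest Cl pair", {
  cf <- make_complex(95)
  core <- detect_core_atoms(cf)
  expect_equal(core$pd, 1)
  expect_equal(core$p_pair, c(2, 3))
  expect_equal(core$cl_pair, c(4, 5))

  # remote third chloride (counter-ion): the two closest to Pd win
  cf3 <- cf
  cf3$atoms <- dplyr::bind_rows(cf3$atoms,
                                tibble::tibble(element = "Cl", x = 9, y = 9,
                                               z = 9))
  expect_equal(detect_core_atoms(cf3)$cl_pair, c(4, 5))

  free_ligand <- conformer(dplyr::filter(cf$atoms, element != "Pd"))
  expect_error(detect_core_atoms(free_ligand), "no Pd")
})

test_that("bite angle matches the vector-geometry oracle", {
  atoms <- tibble::tibble(element = c("Pd", "P", "P"),
                          x = c(0, 2.3, 0), y = c(0, 0, 2.3), z = 0)
  expect_equal(bite_angle(conformer(atoms), 1, 2, 3), 90)
  atoms$x <- c(0, 2.3, -2.3); atoms$y <- 0
  expect_equal(bite_angle(conformer(atoms), 1, 2, 3), 180)

  withr::with_seed(42, {
    for (i in 1:10) {
      xyz <- matrix(rnorm(9, sd = 2), 3, 3)
      cf <- conformer(tibble::tibble(element = c("Pd", "P", "P"),
                                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
      v1 <- xyz[2, ] - xyz[1, ]; v2 <- xyz[3, ] - xyz[1, ]
      expected <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      expect_equal(bite_angle(cf, 1, 2, 3), expected, tolerance = 1e-12)
    }
  })
  atoms$x <- c(0, 0, 1); atoms$y <- 0
  expect_error(bite_angle(conformer(atoms), 1, 2, 3), "zero-length")
})

test_that("bond lengths are Euclidean distances", {
  cf <- conformer(tibble::tibble(element = c("Pd", "Cl"),
                                 x = 0, y = 0, z = c(0, 2.3)))
  expect_equal(bond_length(cf, 1, 2), 2.3)
  expect_equal(bond_length(cf, 1, 1), 0)
  withr::with_seed(7, {
    xyz <- matrix(rnorm(6), 2, 3)
    cf2 <- conformer(tibble::tibble(element = c("C", "C"), x = xyz[, 1],
                                    y = xyz[, 2], z = xyz[, 3]))
    expect_equal(bond_length(cf2, 1, 2), sqrt(sum((xyz[1, ] - xyz[2, ])^2)),
                 tolerance = 1e-12)
  })
})

test_that("buried volume matches the analytic sphere ratio and saturates", {
  # one atom centred on the probe centre: %Vbur = (r_atom/R)^3 * 100
  cf <- conformer(tibble::tibble(element = c("Pd", "H"), x = 0, y = 0, z = 0))
  v <- buried_volume(cf, center = 1, radius = 3.5,
                     radii = radius_table(overrides = c(H = 1.0)),
                     exclude = 1)
  expect_equal(v, (1 / 3.5)^3 * 100, tolerance = 0.05)
  # full occlusion
  v100 <- buried_volume(cf, center = 1, radius = 1.2,
                        radii = radius_table(overrides = c(H = 4.0)),
                        exclude = 1, spacing = 0.1)
  expect_equal(v100, 100)
  expect_warning(
    v0 <- buried_volume(cf, center = 1, radius = 3, exclude = 1:2),
    "No atoms")
  expect_equal(v0, 0)
  expect_error(buried_volume(cf, center = 1, radius = -1), "positive")
})

test_that("grid and Monte Carlo buried-volume estimates agree", {
  cl <- random_cluster(n = 6, seed = 3)
  g <- buried_volume(cl, center = 1, radius = 3.5, exclude = 1,
                     spacing = 0.08)
  m <- buried_volume(cl, center = 1, radius = 3.5, exclude = 1,
                     method = "mc", n_mc = 1e6)
  expect_lt(abs(g - m), 0.5)
})

test_that("buried volume stays in [0,100] and shrinks with the probe radius", {
  for (s in 1:5) {
    # spheres kept near the probe centre so occupancy genuinely dilutes
    cl <- random_cluster(n = 8, seed = s, spread = 0.6)
    vals <- vapply(2:7, function(r)
      buried_volume(cl, center = 1, radius = r, exclude = 1, spacing = 0.1),
      numeric(1))
    expect_true(all(vals >= 0 & vals <= 100))
    expect_true(all(diff(vals) <= 0.2))   # grid-level tolerance
  }
})

test_that("equivalent cone angle matches the single-sphere closed form", {
  cf <- conformer(tibble::tibble(element = c("Pd", "H"),
                                 x = c(0, 0), y = c(0, 0), z = c(0, 2)))
  theta <- equivalent_cone_angle(cf, apex = 1, included = 2,
                                 radii = radius_table(overrides = c(H = 1.0)))
  expect_lt(abs(theta - 60), 0.1)
  expect_equal(equivalent_cone_angle(cf, apex = 1, included = integer(0)), 0)
})

test_that("cone angles of disjoint caps add in solid angle", {
  cf <- conformer(tibble::tibble(
    element = c("Pd", "H", "H"),
    x = c(0, 0, 3), y = 0, z = c(0, 3, 0)))
  rt <- radius_table(overrides = c(H = 1.0))
  omega_single <- 2 * pi * (1 - cos(asin(1 / 3)))
  expected <- 2 * acos(1 - 2 * omega_single / (2 * pi)) * 180 / pi
  theta <- equivalent_cone_angle(cf, apex = 1, included = c(2, 3), radii = rt)
  expect_lt(abs(theta - expected), 0.5)
})

test_that("an atom overlapping the apex errors when clamping is off", {
  cf <- conformer(tibble::tibble(element = c("Pd", "C"),
                                 x = c(0, 0.5), y = 0, z = 0))
  expect_error(
    equivalent_cone_angle(cf, apex = 1, included = 2, clamp = FALSE),
    "apex")
  expect_equal(
    equivalent_cone_angle(cf, apex = 1, included = 2, clamp = TRUE), 360)
})

test_that("SASA matches closed forms for isolated and engulfed atoms", {
  one <- conformer(tibble::tibble(element = "N", x = 0, y = 0, z = 0))
  a <- sasa(one, radii = radius_table(overrides = c(N = 1.5)))
  expect_equal(unname(a[1]), 4 * pi * 2.9^2, tolerance = 1e-9)

  pair <- conformer(tibble::tibble(element = c("H", "S"),
                                   x = c(0, 0.2), y = 0, z = 0))
  a2 <- sasa(pair, radii = radius_table(overrides = c(H = 0.4, S = 3.0)))
  expect_equal(unname(a2[1]), 0)
  expect_error(sasa(one, n_points = 50), "at least 100")
})

test_that("diatomic SASA matches the two-sphere cap formula within 2%", {
  d <- 2.1; probe <- 1.4
  r1 <- 1.5; r2 <- 1.2
  cf <- conformer(tibble::tibble(element = c("C", "O"),
                                 x = c(0, d), y = 0, z = 0))
  a <- sasa(cf, radii = radius_table(overrides = c(C = r1, O = r2)),
            probe = probe)
  R1 <- r1 + probe; R2 <- r2 + probe
  cap <- function(Ra, Rb) {
    xa <- (d^2 + Ra^2 - Rb^2) / (2 * d)     # plane of intersection
    2 * pi * Ra * (Ra - xa)                  # buried cap area on sphere a
  }
  expect_equal(unname(a[1]), 4 * pi * R1^2 - cap(R1, R2), tolerance = 0.02)
  expect_equal(unname(a[2]), 4 * pi * R2^2 - cap(R2, R1), tolerance = 0.02)
})

test_that("molecular volume handles single spheres, unions and overlaps", {
  one <- conformer(tibble::tibble(element = "C", x = 0, y = 0, z = 0))
  rt2 <- radius_table(overrides = c(C = 2.0))
  expect_equal(molecular_volume(one, radii = rt2, spacing = 0.05),
               4 * pi * 8 / 3, tolerance = 0.01)

  two_same <- conformer(tibble::tibble(element = c("C", "C"),
                                       x = 0, y = 0, z = 0))
  expect_equal(molecular_volume(two_same, radii = rt2, spacing = 0.1),
               molecular_volume(one, radii = rt2, spacing = 0.1))

  d <- 2.5; r1 <- 2.0; r2 <- 1.4
  pair <- conformer(tibble::tibble(element = c("C", "O"),
                                   x = c(0, d), y = 0, z = 0))
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * r2 - 3 * r2^2 + 2 * d * r1 + 6 * r1 * r2 - 3 * r1^2) /
    (12 * d)
  expected <- 4 * pi * (r1^3 + r2^3) / 3 - lens
  got <- molecular_volume(pair, radii = radius_table(overrides = c(C = r1, O = r2)),
                          spacing = 0.05)
  expect_equal(got, expected, tolerance = 0.01)
})

test_that("cone angle and SASA are invariant under rigid motion", {
  cf <- make_complex(97)
  cf2 <- transform_conformer(cf)
  expect_lt(abs(equivalent_cone_angle(cf2, n_rays = 5e4) -
                  equivalent_cone_angle(cf, n_rays = 5e4)), 0.5)
  # total surface: tight relative agreement; the small exposed Pd patch is
  # resolved with a denser point set
  expect_equal(sum(sasa(cf2)), sum(sasa(cf)), tolerance = 0.005)
  expect_lt(abs(unname(sasa(cf2, n_points = 8000)[1]) -
                  unname(sasa(cf, n_points = 8000)[1])), 0.3)
})

test_that("descriptors do not depend on atom-list order", {
  cf <- make_complex(101, pattern = substituent_pattern(
    p1 = c("C", "C", "H"), p2 = c("N", "O", "H")))
  perm <- withr::with_seed(4, sample(nrow(cf$atoms)))
  shuffled <- conformer(cf$atoms[perm, ], energy = cf$energy)
  expect_equal(bite_angle(shuffled), bite_angle(cf), tolerance = 1e-10)
  expect_equal(
    buried_volume(shuffled, spacing = 0.1),
    buried_volume(cf, spacing = 0.1), tolerance = 1e-9)
  expect_equal(equivalent_cone_angle(shuffled, n_rays = 2e4),
               equivalent_cone_angle(cf, n_rays = 2e4), tolerance = 1e-9)
})

test_that("donor roles follow branch buried volume with the index tie rule", {
  sym <- make_complex(96)
  da <- assign_donor_roles(sym, spacing = 0.1)
  expect_equal(da$vbur_small, da$vbur_large, tolerance = 1e-9)
  expect_equal(da$p_small, 2)   # tie broken by lower atom index

  # small-substituent donor vs bulky donor
  asym_pat <- substituent_pattern(p1 = c("H", "H", "H"),
                                  p2 = c("Br", "Br", "Br"))
  asym <- make_complex(96, pattern = asym_pat)
  da2 <- assign_donor_roles(asym, spacing = 0.1)
  expect_equal(da2$p_small, 2)
  expect_lt(da2$vbur_small, da2$vbur_large)

  # swapping the two branches swaps the roles
  swapped <- make_complex(96, pattern = substituent_pattern(
    p1 = c("Br", "Br", "Br"), p2 = c("H", "H", "H")))
  da3 <- assign_donor_roles(swapped, spacing = 0.1)
  expect_equal(da3$p_small, 3)
  expect_equal(da3$vbur_small, da2$vbur_small, tolerance = 1e-9)
})

test_that("describe_ensemble produces one valid record per conformer", {
  ens <- make_ensemble(ensemble_spec(n_conformers = 17, seed = 21))
  rec <- describe_ensemble(ens, vbur_radii = c(2, 3, 4), spacing = 0.15,
                           volume_spacing = 0.2, n_rays = 2e4,
                           sasa_points = 240)
  expect_equal(nrow(rec), 17)
  expect_true(all(c("conformer_id", "bite_angle", "pd_p_avg", "pd_p_min",
                    "pd_p_max", "pd_cl_avg", "vbur_r2", "vbur_r3", "vbur_r4",
                    "cone_angle", "sasa_pd", "mol_volume") %in% names(rec)))
  expect_true(all(rec$bite_angle > 0 & rec$bite_angle <= 180))
  vb <- as.matrix(rec[paste0("vbur_r", c(2, 3, 4))])
  expect_true(all(vb >= 0 & vb <= 100))
  expect_true(all(rec$pd_p_avg > 0 & rec$pd_cl_avg > 0))
  expect_true(all(rec$cone_angle > 0 & rec$cone_angle < 360))
  # two Pd-P bonds average correctly
  expect_equal(rec$pd_p_avg, (rec$pd_p_min + rec$pd_p_max) / 2)
})

test_that("describe_ensemble copies properties through and flags gaps", {
  ens <- make_ensemble(ensemble_spec(n_conformers = 3, seed = 2))
  ens$conformers[[1]]$properties <- c(NPA_Pd = 0.4)
  ens$conformers[[2]]$properties <- c(NPA_Pd = 0.5)
  ens$conformers[[3]]$properties <- c(NPA_Pd = 0.6, homo = -5)
  expect_warning(
    rec <- describe_ensemble(ens, features = c("geometry", "properties")),
    "homo")
  expect_equal(rec$NPA_Pd, c(0.4, 0.5, 0.6))
  expect_true(is.na(rec$homo[1]))
})
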