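# Per-residue interaction energies: oracle equivalence, additivity,
# symmetry, ensemble statistics.

test_that("a two-bead subsystem matches the closed-form pair energies", {
  r <- 6.5
  sub <- two_bead_subsystem(q = c(0.8, -0.5), rmin2 = c(2.0, 2.2),
                            eps = c(0.12, 0.2), gbr = c(1.8, 2.1), r = r)
  tab <- interaction_energy(sub, gamma = 0)   # isolate MM + GB
  tot <- energy_totals(tab)
  expect_equal(unname(tot["E_vdW"]), lj_pair(2.0, 0.12, 2.2, 0.2, r), tolerance = 1e-12)
  expect_equal(unname(tot["E_ele"]), coulomb_pair(0.8, -0.5, r), tolerance = 1e-12)
  # GB interaction = complex total minus the two isolated Born self terms
  rad <- born_radii(sub$atoms)
  gb_complex <- oracle_gb_total(sub$atoms, rad)
  self <- function(q, gbr) -0.5 * (1 - 1 / 80) * KE * q^2 / (gbr - 0.09)
  expect_equal(unname(tot["E_GB"]),
               gb_complex - self(0.8, 1.8) - self(-0.5, 2.1), tolerance = 1e-9)
  # no burial at this separation with gamma restored
  tab2 <- interaction_energy(sub)
  expect_equal(unname(energy_totals(tab2)["E_SA"]),
               0.0072 * (sum(sasa(sub$atoms)) -
                           sasa(sub$atoms[1, ]) - sasa(sub$atoms[2, ])),
               tolerance = 1e-12)
})

test_that("zero charges and well depths give identically zero MM and GB terms", {
  pipe <- toy_pipeline(seed = 9, n_res = 3, atoms_per_res = 2)
  sub <- make_subsystem(pipe$ring, "lateral", 1)
  par0 <- transform(pipe$toy$params, charge = 0, eps = 0)
  sub$atoms <- parameterize(sub$atoms, par0)
  tab <- interaction_energy(sub, gamma = 0, sasa_points = 120)
  expect_equal(sum(abs(tab$E_vdW)), 0)
  expect_equal(sum(abs(tab$E_ele)), 0)
  expect_equal(sum(abs(tab$E_GB)), 0, tolerance = 1e-12)
  expect_equal(sum(abs(tab$E_total)), 0, tolerance = 1e-12)
})

test_that("cross-molecular components equal a scalar brute-force evaluation to 1e-9", {
  pipe <- toy_pipeline(seed = 13, n_res = 4, atoms_per_res = 3,
                       e_site = "none")  # 48 atoms per subsystem
  for (kind in c("lateral", "longitudinal")) {
    sub <- make_subsystem(pipe$ring, kind, 2)
    sub$atoms <- parameterize(sub$atoms, pipe$toy$params)
    expect_lte(nrow(sub$atoms), 50)
    tab <- interaction_energy(sub, sasa_points = 120)
    tot <- energy_totals(tab)
    mm <- oracle_mm(sub$atoms)
    expect_equal(unname(tot["E_vdW"]), mm$vdw, tolerance = 1e-9)
    expect_equal(unname(tot["E_ele"]), mm$ele, tolerance = 1e-9)
    # GB: independent scalar radii + scalar double loop, complex minus parts
    iR <- sub$atoms$role == "R"
    gb_or <- oracle_gb_total(sub$atoms, oracle_born_radii(sub$atoms)) -
      oracle_gb_total(sub$atoms[iR, ], oracle_born_radii(sub$atoms[iR, ])) -
      oracle_gb_total(sub$atoms[!iR, ], oracle_born_radii(sub$atoms[!iR, ]))
    expect_equal(unname(tot["E_GB"]), gb_or, tolerance = 1e-9)
  }
})

test_that("per-residue contributions sum to the subsystem totals for every component", {
  pipe <- toy_pipeline(seed = 21, e_site = "GDP")
  for (kind in c("lateral", "lateral_seam", "longitudinal")) {
    sub <- make_subsystem(pipe$ring, kind, 5)
    sub$atoms <- parameterize(sub$atoms, pipe$toy$params)
    tab <- interaction_energy(sub, sasa_points = 120)
    tot <- energy_totals(tab)
    for (cc in c("E_vdW", "E_ele", "E_GB", "E_SA", "E_total")) {
      expect_equal(sum(tab[[cc]]), unname(tot[cc]),
                   tolerance = 1e-6 * max(1, abs(tot[cc])))
    }
    expect_equal(unname(tot["E_total"]),
                 unname(tot["E_vdW"] + tot["E_ele"] + tot["E_GB"] + tot["E_SA"]),
                 tolerance = 1e-9)
  }
})

test_that("interaction energy is invariant under rigid transformation", {
  pipe <- toy_pipeline(seed = 31, n_res = 3, atoms_per_res = 2)
  sub <- make_subsystem(pipe$ring, "longitudinal", 4)
  sub$atoms <- parameterize(sub$atoms, pipe$toy$params)
  base <- energy_totals(interaction_energy(sub, sasa_points = 240))
  # translation: exact for every component
  sub_t <- sub
  sub_t$atoms$x <- sub$atoms$x + 17.3
  sub_t$atoms$y <- sub$atoms$y - 6.1
  sub_t$atoms$z <- sub$atoms$z + 101
  tot_t <- energy_totals(interaction_energy(sub_t, sasa_points = 240))
  expect_equal(unname(tot_t["E_total"]), unname(base["E_total"]), tolerance = 1e-6)
  # rotation: exact for MM and GB; SASA is sampled on a fixed point grid,
  # so the non-polar term is only equal to sampling accuracy
  th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(sub$atoms[, c("x", "y", "z")]) %*% R
  sub_r <- sub
  sub_r$atoms$x <- xyz[, 1]; sub_r$atoms$y <- xyz[, 2]; sub_r$atoms$z <- xyz[, 3]
  tot_r <- energy_totals(interaction_energy(sub_r, sasa_points = 240))
  for (cc in c("E_vdW", "E_ele", "E_GB")) {
    expect_equal(unname(tot_r[cc]), unname(base[cc]), tolerance = 1e-6)
  }
  expect_equal(unname(tot_r["E_SA"]), unname(base["E_SA"]), tolerance = 0.02)
})

test_that("swapping receptor and ligand preserves the total; MM shares are symmetric", {
  pipe <- toy_pipeline(seed = 8)
  sub <- make_subsystem(pipe$ring, "lateral", 6)
  sub$atoms <- parameterize(sub$atoms, pipe$toy$params)
  tab <- interaction_energy(sub, sasa_points = 120)
  swapped <- sub
  swapped$atoms$role <- ifelse(sub$atoms$role == "R", "L", "R")
  swapped$atoms$index <- NULL
  swapped$atoms$index <- mtring:::continuous_residue_index(swapped$atoms)
  tab_s <- interaction_energy(swapped, sasa_points = 120)
  expect_equal(unname(energy_totals(tab_s)["E_total"]),
               unname(energy_totals(tab)["E_total"]), tolerance = 1e-9)
  # per-molecule MM shares are exactly half the cross sums on both sides
  mm_share <- function(t, role, cc) sum(t[[cc]][t$role == role])
  for (cc in c("E_vdW", "E_ele")) {
    expect_equal(mm_share(tab, "R", cc), mm_share(tab, "L", cc), tolerance = 1e-9)
    expect_equal(mm_share(tab_s, "R", cc), mm_share(tab, "R", cc), tolerance = 1e-9)
  }
})

test_that("ensemble averaging: mean, population SD, and SD recovery", {
  pipe <- toy_pipeline(seed = 5, n_res = 3, atoms_per_res = 2)
  sub <- make_subsystem(pipe$ring, "lateral", 1)
  sub$atoms <- parameterize(sub$atoms, pipe$toy$params)
  tab <- interaction_energy(sub, sasa_points = 120)
  # identical frames: SD zero, mean equals the frame
  avg <- ensemble_average(list(tab, tab, tab))
  expect_equal(avg$E_total, tab$E_total)
  expect_equal(sum(abs(avg$sd_E_total)), 0)
  expect_equal(unname(attr(avg, "totals_sd")["E_total"]), 0)
  # two frames with totals -10 and -20 have mean -15
  mk <- function(total) {
    t <- data.frame(role = "R", subunit = "alpha", resno = 1:2, resname = "RES",
                    E_vdW = c(total / 2, total / 2), E_ele = 0, E_GB = 0, E_SA = 0)
    as_energy_table(t)
  }
  two <- ensemble_average(list(mk(-10), mk(-20)))
  expect_equal(unname(energy_totals(two)["E_total"]), -15)
  expect_equal(unname(attr(two, "totals_sd")["E_total"]), 5)  # population SD
  # 200 seeded Gaussian frames: recovered SD within 15% of the generating sigma
  frames <- make_mock_frames(tab, n_frames = 200, sigma = 0.5, seed = 77)
  avg200 <- ensemble_average(frames)
  n_res <- nrow(tab)
  # each of 4 components perturbed i.i.d. per residue: total variance 4*n*sigma^2
  expect_equal(unname(attr(avg200, "totals_sd")["E_total"]),
               sqrt(4 * n_res) * 0.5, tolerance = 0.15)
  expect_error(ensemble_average(list(tab)), "at least 2")
  bad <- tab[-1, ]
  expect_error(ensemble_average(list(tab, as_energy_table(as.data.frame(bad)))),
               "inconsistent residue sets")
})
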