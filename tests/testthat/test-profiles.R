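# Spatial coordinates and binned energy profiles.

test_that("radial coordinates measure distance from the lumen reference", {
  # ring of beads whose residue COMs sit exactly 30 A outside the lumen ref
  mk_atoms <- function(rad, n = 26) {
    phi <- 2 * pi * seq_len(n) / n
    data.frame(atom = "X", resname = "RES", resno = seq_len(n),
               subunit = rep(c("alpha", "beta"), n / 2),
               dimer = rep(1:13, each = n / 13), role = "R",
               x = rad * cos(phi), y = rad * sin(phi), z = seq_len(n),
               element = "C", mass = 12, stringsAsFactors = FALSE)
  }
  shell <- mk_atoms(112)
  rc <- radial_coordinates(shell, ring = shell, r_lumen = 82)
  expect_equal(rc$coord, rep(30, 26), tolerance = 1e-9)
  # residue on the reference surface maps to zero
  rc0 <- radial_coordinates(mk_atoms(82), ring = mk_atoms(82), r_lumen = 82)
  expect_equal(rc0$coord, rep(0, 26), tolerance = 1e-9)
  # rigid xy translation leaves coordinates unchanged after the axis refit
  shifted <- shell
  shifted$x <- shell$x + 40; shifted$y <- shell$y - 15
  rc_s <- radial_coordinates(shifted, ring = shifted, r_lumen = 82)
  expect_equal(rc_s$coord, rc$coord, tolerance = 1e-9)
  expect_error(radial_coordinates(shell[0, ], ring = shell), "zero atoms")
})

test_that("the lumen reference reproduces the center-of-mass convention on a toy ring", {
  pipe <- toy_pipeline(seed = 1, n_res = 5, atoms_per_res = 3)
  rl <- lumen_radius(pipe$ring)
  com_r <- sqrt(sum(center_of_mass(pipe$ring[pipe$ring$dimer == 1, ])[1:2]^2))
  x_com <- com_r - rl
  # dimer COM sits a wall half-thickness outside the inner surface
  expect_gt(x_com, 10)
  expect_lt(x_com, 40)
})

test_that("tangential coordinates are measured from the lateral interface plane", {
  pipe <- toy_pipeline(seed = 2)
  sub <- make_subsystem(pipe$ring, "longitudinal", 3)
  tc <- tangential_coordinates(sub, pipe$ring)        # adjacent = dimer 4
  expect_equal(attr(tc, "adjacent"), 4L)
  # independent recomputation: project residue COMs on the tangential axis
  ax <- ring_axis(pipe$ring)
  rec <- sub$atoms[sub$atoms$role == "R", ]
  com <- center_of_mass(rec)
  phi <- atan2(com[2] - ax[2], com[1] - ax[1])
  tvec <- c(-sin(phi), cos(phi))
  adj_com <- center_of_mass(pipe$ring[pipe$ring$dimer == 4, ])
  for (i in seq_len(min(5, nrow(tc)))) {
    sel <- sub$atoms$role == tc$role[i] & sub$atoms$subunit == tc$subunit[i] &
      sub$atoms$resno == tc$resno[i]
    rcom <- center_of_mass(sub$atoms[sel, ])
    proj <- sum(rcom[1:2] * tvec)
    # distances along the axis are preserved between residues
    if (i > 1) {
      sel1 <- sub$atoms$role == tc$role[1] & sub$atoms$subunit == tc$subunit[1] &
        sub$atoms$resno == tc$resno[1]
      p1 <- sum(center_of_mass(sub$atoms[sel1, ])[1:2] * tvec)
      expect_equal(abs(tc$coord[i] - tc$coord[1]), abs(proj - p1), tolerance = 1e-9)
    }
  }
  # the adjacent dimer's own COM lies on the non-positive side
  origin_proj <- sum(adj_com[1:2] * tvec)
  sgn_adj <- sign(mean(tc$coord))
  expect_gt(mean(tc$coord), 0)   # subsystem residues sit on the positive side
  expect_error(tangential_coordinates(sub, pipe$ring, adjacent = 99),
               "no adjacent dimer")
})

test_that("binning is half-open, conservative, and refinement-consistent", {
  coords <- data.frame(role = "R", subunit = "alpha", resno = 1:2,
                       resname = "RES", coord = c(2.999, 3.000))
  tab <- as_energy_table(data.frame(role = "R", subunit = "alpha", resno = 1:2,
                                    resname = "RES", E_vdW = c(-5, -7),
                                    E_ele = 0, E_GB = 0, E_SA = 0))
  p <- binned_profile(coords, tab, width = 3)
  expect_equal(p$E_total[p$bin_lower == 0], -5)
  expect_equal(p$E_total[p$bin_lower == 3], -7)
  expect_error(binned_profile(coords, tab, width = -3), "width")
  # uniform residues: ten bins of -3 each
  coords30 <- data.frame(role = "R", subunit = "alpha", resno = 1:30,
                         resname = "RES", coord = seq(0.5, 29.5, 1))
  tab30 <- as_energy_table(data.frame(role = "R", subunit = "alpha",
                                      resno = 1:30, resname = "RES",
                                      E_vdW = -1, E_ele = 0, E_GB = 0, E_SA = 0))
  p30 <- binned_profile(coords30, tab30, width = 3)
  expect_equal(nrow(p30), 10)
  expect_equal(p30$E_total, rep(-3, 10))
  # seeded random placement: conservation and brute-force bin sums
  set.seed(12)
  n <- 100
  coords_r <- data.frame(role = "R", subunit = "alpha", resno = 1:n,
                         resname = "RES", coord = runif(n, 0, 60))
  tab_r <- as_energy_table(data.frame(role = "R", subunit = "alpha",
                                      resno = 1:n, resname = "RES",
                                      E_vdW = rnorm(n, -2), E_ele = rnorm(n),
                                      E_GB = rnorm(n, -0.5), E_SA = rnorm(n, 0, 0.1)))
  p_r <- binned_profile(coords_r, tab_r, width = 3)
  for (cc in c("E_vdW", "E_ele", "E_GB", "E_SA", "E_total")) {
    expect_equal(sum(p_r[[cc]]), sum(tab_r[[cc]]), tolerance = 1e-9)
  }
  for (b in sample(seq_len(nrow(p_r)), 5)) {
    sel <- coords_r$coord >= p_r$bin_lower[b] & coords_r$coord < p_r$bin_upper[b]
    expect_equal(p_r$E_total[b], sum(tab_r$E_total[sel]), tolerance = 1e-12)
  }
  # refining to width 1.5 and re-merging adjacent bins reproduces width 3
  p_half <- binned_profile(coords_r, tab_r, width = 1.5)
  merged <- tapply(p_half$E_total, floor(p_half$bin_lower / 3), sum)
  expect_equal(as.numeric(merged), p_r$E_total, tolerance = 1e-12)
})

test_that("inner/outer split conserves the total and recovers planted fractions", {
  mock <- make_mock_tables(n_subsystems = 13, n_residues = 24, seed = 8,
                           kind = "longitudinal", outer_fraction = 0.80)
  rt <- ring_aggregate(mock$tables, "longitudinal")
  p <- binned_profile(mock$coords, rt, width = 3)
  sp <- inner_outer_split(p, threshold = 30)
  expect_equal(sp$inner + sp$outer, sp$total, tolerance = 1e-12)
  expect_equal(sp$fraction, 0.80, tolerance = 1e-9)   # exact planted truth
  # threshold below every bin puts everything outside
  sp_all <- inner_outer_split(p, threshold = min(p$bin_lower) - 1)
  expect_equal(sp_all$inner, 0)
  expect_equal(sp_all$outer, sp_all$total)
  expect_equal(sp_all$fraction, 1)
})

test_that("radial profiles of an axisymmetric ring are rotation invariant", {
  pipe <- toy_pipeline(seed = 10, n_res = 3, atoms_per_res = 2)
  rc <- radial_coordinates(pipe$ring, pipe$ring)
  rot <- pipe$ring
  th <- 2 * pi / 13
  x <- rot$x * cos(th) - rot$y * sin(th)
  rot$y <- rot$x * sin(th) + rot$y * cos(th)
  rot$x <- x
  rc_rot <- radial_coordinates(rot, rot)
  expect_equal(sort(rc_rot$coord), sort(rc$coord), tolerance = 1e-9)
})
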