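# Shared fixtures and independent oracles. Oracles are coded as plain
# scalar loops / closed forms, independent of the package's vectorized
# implementations.

KE <- 332.0636

toy_pipeline <- function(seed = 1L, n_res = 4L, atoms_per_res = 2L,
                         e_site = "GDP", nucleotide = e_site) {
  if (nucleotide == "none") nucleotide <- "GDP"
  toy <- make_toy_dimer(n_res = n_res, atoms_per_res = atoms_per_res,
                        seed = seed, e_site = e_site)
  spec <- lattice_spec(nucleotide = nucleotide)
  ring <- build_ring(spec, toy$dimer)
  list(toy = toy, spec = spec, ring = ring)
}

scored_subsystem <- function(pipe, kind, k = 1L, sasa_points = 240L) {
  sub <- make_subsystem(pipe$ring, kind, k)
  sub$atoms <- parameterize(sub$atoms, pipe$toy$params)
  list(sub = sub, table = interaction_energy(sub, sasa_points = sasa_points))
}

# Minimal hand-built subsystem: one bead per molecule at separation r on z.
two_bead_subsystem <- function(q = c(1, -1), rmin2 = c(2, 2), eps = c(0.1, 0.1),
                               gbr = c(1.8, 1.8), r = 5) {
  atoms <- data.frame(
    atom = c("X1", "X1"), resname = c("RA", "RB"), resno = c(1L, 1L),
    subunit = c("alpha", "alpha"), dimer = c(1L, 1L),
    x = c(0, 0), y = c(0, 0), z = c(0, r), element = "C",
    mass = 12.011, charge = q, rmin2 = rmin2, eps = eps, gbr = gbr,
    screen = 0.8, role = c("R", "L"), index = c(1L, 2L),
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, kind = "longitudinal", k = 1L,
                 spec = lattice_spec()), class = "mt_subsystem")
}

# --- independent oracles -------------------------------------------------

# Scalar-loop cross-molecular MM sums.
oracle_mm <- function(atoms) {
  iR <- which(atoms$role == "R"); iL <- which(atoms$role == "L")
  vdw <- 0; ele <- 0
  for (i in iR) for (j in iL) {
    r <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                (atoms$z[i] - atoms$z[j])^2)
    ele <- ele + KE * atoms$charge[i] * atoms$charge[j] / r
    rm <- atoms$rmin2[i] + atoms$rmin2[j]
    ep <- sqrt(atoms$eps[i] * atoms$eps[j])
    vdw <- vdw + ep * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  list(vdw = vdw, ele = ele)
}

# Scalar OBC-II effective radii + GB total, written as explicit loops.
oracle_born_radii <- function(atoms) {
  n <- nrow(atoms)
  offset <- 0.09
  out <- numeric(n)
  for (i in seq_len(n)) {
    rho <- atoms$gbr[i] - offset
    I <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      r <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                  (atoms$z[i] - atoms$z[j])^2)
      sj <- atoms$screen[j] * (atoms$gbr[j] - offset)
      if (r + sj <= rho) next
      U <- r + sj
      L <- max(rho, abs(r - sj))
      Iij <- 0.5 * (1 / L - 1 / U + 0.25 * (r - sj^2 / r) * (1 / U^2 - 1 / L^2) +
                      0.5 * log(L / U) / r)
      if (sj - r - rho > 0) Iij <- Iij + (1 / rho - 1 / L)
      I <- I + Iij
    }
    psi <- rho * I
    out[i] <- 1 / (1 / rho - tanh(1.0 * psi - 0.8 * psi^2 + 4.85 * psi^3) / atoms$gbr[i])
  }
  out
}

oracle_gb_total <- function(atoms, radii, eps_in = 1, eps_out = 80) {
  n <- nrow(atoms)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- (atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
      (atoms$z[i] - atoms$z[j])^2
    f <- sqrt(r2 + radii[i] * radii[j] * exp(-r2 / (4 * radii[i] * radii[j])))
    tot <- tot - 0.5 * (1 / eps_in - 1 / eps_out) * KE *
      atoms$charge[i] * atoms$charge[j] / f
  }
  tot
}

# Analytic SASA of two intersecting spheres (radii already probe-expanded):
# each sphere loses the cap cut off by the radical plane.
lens_sasa <- function(a, b, d) {
  if (d >= a + b) return(c(4 * pi * a^2, 4 * pi * b^2))
  xa <- (d^2 + a^2 - b^2) / (2 * d)
  xb <- d - xa
  c(4 * pi * a^2 - 2 * pi * a * (a - xa),
    4 * pi * b^2 - 2 * pi * b * (b - xb))
}

# Grid integration of the HCT descreening integral:
# I = (1/4pi) * int over (sphere j of radius sj at distance d) \ (r < rho)
#     of dV / r^4, measured from atom i at the origin.
oracle_descreen_integral <- function(d, sj, rho, n_grid = 120L) {
  h <- 2 * sj / n_grid
  g <- seq(-sj + h / 2, sj - h / 2, length.out = n_grid)
  tot <- 0
  for (x in g) for (y in g) {
    rxy2 <- x^2 + y^2
    if (rxy2 > sj^2) next
    zs <- g[g^2 <= sj^2 - rxy2]
    r2 <- rxy2 + (zs + d)^2
    r2 <- r2[r2 >= rho^2]
    tot <- tot + sum(h^3 / r2^2)
  }
  tot / (4 * pi)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
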