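# Nonbonded energy primitives: Coulomb, Lennard-Jones 12-6, generalized
# Born (OBC-II effective radii, Still pairwise function) and Shrake-Rupley
# solvent-accessible surface area.

#' Coulomb pair energy
#'
#' `k_e * q_i * q_j / (eps_in * r)` with
#' `k_e = 332.0636 kcal A / (mol e^2)`.
#'
#' @param q_i,q_j partial charges in units of e.
#' @param r_ij separation in angstroms (> 0).
#' @param eps_in solute dielectric constant (default 1).
#' @return energy in kcal/mol.
#' @export
coulomb_pair <- function(q_i, q_j, r_ij, eps_in = 1) {
  if (any(r_ij <= 0)) stop("singularity error: r_ij must be > 0")
  KE_COULOMB * q_i * q_j / (eps_in * r_ij)
}

#' Lennard-Jones 12-6 pair energy
#'
#' `eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` with the combination rules
#' `rmin_ij = rmin2_i + rmin2_j` (half-radii summed) and
#' `eps_ij = sqrt(eps_i * eps_j)`.
#'
#' @param rmin2_i,rmin2_j r_min/2 for each atom, angstroms.
#' @param eps_i,eps_j well depths, kcal/mol.
#' @param r_ij separation, angstroms (> 0).
#' @return energy in kcal/mol (equals `-eps_ij` at `r = rmin_ij`).
#' @export
lj_pair <- function(rmin2_i, eps_i, rmin2_j, eps_j, r_ij) {
  if (any(r_ij <= 0)) stop("singularity error: r_ij must be > 0")
  rmin <- rmin2_i + rmin2_j
  epsij <- sqrt(eps_i * eps_j)
  s6 <- (rmin / r_ij)^6
  epsij * (s6 * s6 - 2 * s6)
}

# OBC-II generalized Born constants.
.obc <- list(alpha = 1.0, beta = 0.8, gamma = 4.85, offset = 0.09)

#' Effective Born radii (OBC-II)
#'
#' Computes per-atom effective Born radii with the pairwise-descreening
#' (HCT) integral rescaled through the OBC-II tanh correction
#' (alpha = 1.0, beta = 0.8, gamma = 4.85, intrinsic-radius offset 0.09 A).
#' An isolated atom's effective radius equals its intrinsic radius minus
#' the offset; burial by neighbors increases it.
#'
#' @param atoms atom table carrying `gbr` (intrinsic radius, A) and
#'   `screen` columns plus coordinates.
#' @return numeric vector of effective Born radii, angstroms.
#' @export
born_radii <- function(atoms) {
  if (!has_parameters(atoms)) stop("atoms are not parameterized")
  if (any(atoms$gbr <= 0)) stop("GB radii must be positive")
  n <- nrow(atoms)
  rho <- atoms$gbr - .obc$offset         # offset (reduced) intrinsic radii
  if (any(rho <= 0)) stop("GB radius smaller than the OBC offset")
  if (n == 1L) return(rho)
  xyz <- xyz_matrix(atoms)
  r <- dist_cross(xyz, xyz)
  off <- r[upper.tri(r)]
  if (any(off < 1e-6)) stop("numerical-overlap error: coincident atoms in GB radii")
  s <- atoms$screen * rho                # scaled descreening radii
  rho_i <- matrix(rho, n, n)             # row atom being descreened
  s_j <- matrix(s, n, n, byrow = TRUE)   # column atom doing the descreening
  U <- r + s_j
  D <- abs(r - s_j)
  L <- pmax(rho_i, D)
  I <- 0.5 * (1 / L - 1 / U +
                0.25 * (r - s_j^2 / r) * (1 / U^2 - 1 / L^2) +
                0.5 * log(L / U) / r)
  # Atom i engulfed by neighbor j's descreening sphere
  eng <- (s_j - r - rho_i) > 0
  I[eng] <- I[eng] + (1 / rho_i[eng] - 1 / L[eng])
  I[U <= rho_i] <- 0                     # neighbor entirely inside atom i
  diag(I) <- 0
  Ii <- rowSums(I)
  psi <- rho * Ii
  tanh_term <- tanh(.obc$alpha * psi - .obc$beta * psi^2 + .obc$gamma * psi^3)
  reff <- 1 / (1 / rho - tanh_term / atoms$gbr)
  if (any(!is.finite(reff) | reff <= 0)) stop("numerical-overlap error: non-physical Born radii")
  reff
}

#' Generalized Born polar solvation energy
#'
#' `-1/2 (1/eps_in - 1/eps_out) k_e sum_ij q_i q_j / f_GB(r_ij, R_i, R_j)`
#' with the Still function
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`; the i = j terms
#' are the Born self energies (`f_GB(0) = R_i`). Per-atom shares assign
#' each self term fully to its atom and half of every pair term to each
#' partner.
#'
#' @param atoms parameterized atom table (charges in e).
#' @param radii effective Born radii from [born_radii()] (same atom order).
#' @param eps_in,eps_out solute and solvent dielectric constants
#'   (defaults 1 and 80).
#' @return list with `total` (kcal/mol) and `per_atom` shares summing to it.
#' @export
gb_energy <- function(atoms, radii = born_radii(atoms), eps_in = 1, eps_out = 80) {
  if (eps_in <= 0 || eps_out <= 0) stop("dielectric constants must be positive")
  n <- nrow(atoms)
  stopifnot(length(radii) == n)
  q <- atoms$charge
  xyz <- xyz_matrix(atoms)
  r2 <- dist_cross(xyz, xyz)^2
  RR <- outer(radii, radii)
  fgb <- sqrt(r2 + RR * exp(-r2 / (4 * RR)))
  qq <- outer(q, q)
  pref <- -0.5 * (1 / eps_in - 1 / eps_out) * KE_COULOMB
  terms <- pref * qq / fgb
  # row i of the ordered double sum = full self term + half of each
  # unordered pair term (the other half lands on the partner's row)
  per_atom <- rowSums(terms)
  list(total = sum(per_atom), per_atom = per_atom)
}

# Deterministic unit-sphere point set (golden-spiral / Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA from test points on each atom's solvent-expanded sphere
#' (radius `gbr + probe`); a point is accessible when outside every
#' neighbor's expanded sphere. The non-polar solvation energy is
#' `gamma * total_SASA + beta`.
#'
#' @param atoms parameterized atom table; `gbr` is used as the atomic
#'   radius.
#' @param probe probe radius, angstroms (default 1.4; must be >= 0).
#' @param n_points test points per atom (default 960).
#' @return numeric vector of per-atom areas in A^2.
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  if (probe < 0) stop("probe_radius must be >= 0")
  n <- nrow(atoms)
  pts <- sphere_points(n_points)
  xyz <- xyz_matrix(atoms)
  rad <- atoms$gbr + probe
  d <- dist_cross(xyz, xyz)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rad[i] + rad & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 >= rad[j]^2
      if (!any(acc)) break
    }
    areas[i] <- 4 * pi * rad[i]^2 * mean(acc)
  }
  areas
}

#' @rdname sasa
#' @param sasa_areas per-atom areas (A^2).
#' @param gamma surface tension, kcal/(mol A^2) (default 0.0072).
#' @param beta additive constant, kcal/mol (default 0).
#' @export
nonpolar_energy <- function(sasa_areas, gamma = 0.0072, beta = 0) {
  gamma * sum(sasa_areas) + beta
}
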