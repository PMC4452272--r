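# Internal helpers shared across modules.

# Coulomb constant in kcal * A / (mol * e^2)
KE_COULOMB <- 332.0636

# Minimal element -> atomic mass table; toy generators only emit these.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, MG = 24.305, NA. = 22.990, CL = 35.45
)

atom_masses <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .element_masses[key]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Rotate coordinates about the z axis
#'
#' @param xyz numeric matrix with columns x, y, z.
#' @param angle rotation angle in radians (counter-clockwise looking down +z).
#' @return rotated matrix of the same shape.
#' @keywords internal
rotate_z <- function(xyz, angle) {
  ca <- cos(angle); sa <- sin(angle)
  out <- xyz
  out[, 1] <- ca * xyz[, 1] - sa * xyz[, 2]
  out[, 2] <- sa * xyz[, 1] + ca * xyz[, 2]
  out
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

xyz_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Mass-weighted center of mass
#'
#' @param atoms an atom table with columns x, y, z and mass.
#' @return numeric length-3 vector (x, y, z) in angstroms.
#' @export
center_of_mass <- function(atoms) {
  stopifnot(nrow(atoms) > 0L)
  w <- atoms$mass / sum(atoms$mass)
  c(sum(atoms$x * w), sum(atoms$y * w), sum(atoms$z * w))
}

# Pairwise distance matrix between two coordinate sets (plain O(n*m)).
dist_cross <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Returns the rotation matrix and translation that best superpose `mobile`
#' onto `fixed` in the least-squares sense, plus the residual RMSD.
#'
#' @param mobile,fixed n x 3 coordinate matrices with matching rows.
#' @return list with elements `R` (3x3 rotation), `t` (translation applied
#'   after rotation), and `rmsd`.
#' @export
kabsch <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed), ncol(mobile) == 3L, ncol(fixed) == 3L)
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  P <- sweep(mobile, 2, cm); Q <- sweep(fixed, 2, cf)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(R = R, t = cf - as.numeric(R %*% cm), rmsd = rmsd)
}

# Format numbers for deterministic text output (full double precision).
fmt_num <- function(x) formatC(x, format = "g", digits = 17)

`%||%` <- function(a, b) if (is.null(a)) b else a
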