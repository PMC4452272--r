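# Radial and tangential energy profiles across the longitudinal
# inter-dimer interface.

#' Ring axis and lumen reference
#'
#' The microtubule axis is refit per frame: direction fixed to z (the
#' lattice convention), center = mean x/y of the dimer centers of mass, so
#' ovalized frames are measured about their own centroid. The lumen
#' reference radius is a low quantile (default 1st percentile) of all
#' atomic distances from the axis, a robust estimate of the inner surface.
#'
#' @param ring an `mt_structure` ring.
#' @return `ring_axis()`: numeric c(x, y) center. `lumen_radius()`: radius
#'   in angstroms.
#' @export
ring_axis <- function(ring) {
  coms <- dimer_coms(ring)
  c(mean(coms[, 1]), mean(coms[, 2]))
}

#' @rdname ring_axis
#' @param prob quantile of atomic axis distances used as the lumen surface.
#' @export
lumen_radius <- function(ring, prob = 0.01) {
  ax <- ring_axis(ring)
  d <- sqrt((ring$x - ax[1])^2 + (ring$y - ax[2])^2)
  unname(stats::quantile(d, prob))
}

dimer_coms <- function(ring) {
  ks <- sort(unique(ring$dimer))
  t(vapply(ks, function(k) center_of_mass(ring[ring$dimer == k, ]), numeric(3)))
}

# Mass-weighted residue centers of a subsystem/ring atom table; residues
# are keyed on (dimer, role, subunit, resno) so ring atoms do not collapse
# across dimers.
residue_coms <- function(atoms) {
  if (nrow(atoms) == 0L) stop("residue with zero atoms")
  role <- atoms$role %||% rep("R", nrow(atoms))
  dimer <- atoms$dimer %||% rep(1L, nrow(atoms))
  key <- paste(dimer, role, atoms$subunit, atoms$resno, sep = ":")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  w <- atoms$mass
  sw <- tapply(w, grp, sum)
  cx <- tapply(atoms$x * w, grp, sum) / sw
  cy <- tapply(atoms$y * w, grp, sum) / sw
  cz <- tapply(atoms$z * w, grp, sum) / sw
  out <- data.frame(
    dimer = dimer[first], role = role[first],
    subunit = atoms$subunit[first], resno = atoms$resno[first],
    resname = atoms$resname[first],
    x = as.numeric(cx), y = as.numeric(cy), z = as.numeric(cz),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$x)) stop("residue with zero atoms")
  out
}

#' Radial residue coordinates
#'
#' Distance of each residue's mass-weighted center from the microtubule
#' lumen: (distance from the refit axis) minus the lumen reference radius.
#' Residues falling inside the lumen reference are clamped to 0 and
#' flagged in attribute `"clamped"`. On this scale the tubulin center of
#' mass sits near x = 30 A.
#'
#' @param atoms atom table of the residues to measure (e.g. the receptor
#'   half of a longitudinal subsystem, or a whole ring).
#' @param ring the ring used to fit the axis and lumen reference; defaults
#'   to `atoms`.
#' @param r_lumen lumen reference radius; computed with [lumen_radius()]
#'   when omitted.
#' @return data frame of residue keys with coordinate column `coord` (A);
#'   attributes `r_lumen` and `clamped`.
#' @export
radial_coordinates <- function(atoms, ring = atoms, r_lumen = NULL) {
  if (is.null(r_lumen)) r_lumen <- lumen_radius(ring)
  ax <- ring_axis(ring)
  res <- residue_coms(atoms)
  x <- sqrt((res$x - ax[1])^2 + (res$y - ax[2])^2) - r_lumen
  clamped <- x < 0
  x[clamped] <- 0
  res$coord <- x
  structure(res[, c("dimer", "role", "subunit", "resno", "resname", "coord")],
            r_lumen = r_lumen, clamped = which(clamped))
}

#' Tangential residue coordinates
#'
#' Signed distance of each residue center along the local tangential
#' direction (perpendicular to both the axis and the radial direction at
#' the subsystem's protofilament azimuth), measured from the lateral
#' interface with a designated adjacent dimer: the origin is the plane
#' through the midpoint of the closest receptor/adjacent-dimer atom pair,
#' normal to the tangential unit vector, and the coordinate increases away
#' from the adjacent dimer so that the subsystem's residues are positive
#' and its center of mass sits near x = 30 A (x < 30: intermediate domain;
#' x > 30: nucleotide-binding domain).
#'
#' @param sub a longitudinal `mt_subsystem`.
#' @param ring the ring the subsystem came from.
#' @param adjacent index of the designated laterally adjacent dimer
#'   (default `k + 1`, wrapping around the ring).
#' @return data frame of residue keys with `coord` (A) and attribute
#'   `origin` (the interface offset along the tangential axis).
#' @export
tangential_coordinates <- function(sub, ring, adjacent = NULL) {
  stopifnot(inherits(sub, "mt_subsystem"))
  spec <- sub$spec
  if (is.null(adjacent)) adjacent <- if (sub$k < spec$n_pf) sub$k + 1L else 1L
  adj <- ring[ring$dimer == adjacent, , drop = FALSE]
  if (nrow(adj) == 0L) stop("no adjacent dimer designated")
  ax <- ring_axis(ring)
  rec <- sub$atoms[sub$atoms$role == "R", , drop = FALSE]
  com <- center_of_mass(rec)
  phi <- atan2(com[2] - ax[2], com[1] - ax[1])
  tangent <- c(-sin(phi), cos(phi), 0)
  # contact midpoint of the closest receptor/adjacent atom pair
  d <- dist_cross(xyz_matrix(rec), xyz_matrix(adj))
  ij <- arrayInd(which.min(d), dim(d))
  mid <- (as.numeric(xyz_matrix(rec)[ij[1], ]) + as.numeric(xyz_matrix(adj)[ij[2], ])) / 2
  origin <- sum(mid[1:2] * tangent[1:2])
  # sign: positive away from the adjacent dimer
  adj_side <- sum(center_of_mass(adj)[1:2] * tangent[1:2]) - origin
  sgn <- if (adj_side > 0) -1 else 1
  res <- residue_coms(sub$atoms)
  res$coord <- sgn * (res$x * tangent[1] + res$y * tangent[2] - origin)
  structure(res[, c("dimer", "role", "subunit", "resno", "resname", "coord")],
            origin = origin, adjacent = adjacent)
}

#' Bin per-residue energies along a spatial coordinate
#'
#' Sums each energy component over half-open coordinate bins
#' `[i*width, (i+1)*width)`; the bin grid is anchored at 0 and extends to
#' negative coordinates when present. Binning conserves energy: the bin
#' sums of every component add up to the table totals.
#'
#' @param coords data frame from [radial_coordinates()] or
#'   [tangential_coordinates()] (residue keys + `coord`).
#' @param table an `energy_table` (or `ring_energy_table`) over the same
#'   residues.
#' @param width bin width in angstroms (default 3, must be > 0).
#' @return a `profile` data frame: `bin_lower`, `bin_upper`, component
#'   sums `E_vdW`, `E_ele`, `E_GB`, `E_SA`, the grouping `E_ele_GB`, and
#'   `E_total`; empty interior bins are present with zeros.
#' @export
binned_profile <- function(coords, table, width = 3) {
  if (width <= 0) stop("negative width: bin width must be > 0")
  key_c <- paste(coords$role, coords$subunit, coords$resno, sep = ":")
  key_t <- paste(table$role, table$subunit, table$resno, sep = ":")
  i <- match(key_t, key_c)
  if (anyNA(i)) stop("coords and table cover different residues")
  x <- coords$coord[i]
  bin <- floor(x / width)
  rng <- range(bin)
  bins <- seq.int(rng[1], rng[2])
  comp <- c("E_vdW", "E_ele", "E_GB", "E_SA", "E_total")
  out <- data.frame(bin_lower = bins * width, bin_upper = (bins + 1) * width)
  for (cc in comp) {
    s <- tapply(table[[cc]], factor(bin, levels = bins), sum)
    v <- as.numeric(s)
    v[is.na(v)] <- 0
    out[[cc]] <- v
  }
  out$E_ele_GB <- out$E_ele + out$E_GB
  structure(out[, c("bin_lower", "bin_upper", "E_vdW", "E_ele", "E_GB",
                    "E_SA", "E_ele_GB", "E_total")],
            width = width, class = c("profile", "data.frame"))
}

#' Split a profile at a threshold into inner and outer sums
#'
#' Bins whose lower edge is at or above the threshold count as outer. With
#' the default threshold at the tubulin center of mass (x ~ 30 A), the
#' outer fraction measures how much of the longitudinal interaction energy
#' lies outward of the center of mass - the lever arm of the
#' outward-curling torque.
#'
#' @param profile a `profile` from [binned_profile()].
#' @param threshold coordinate threshold in angstroms (default 30).
#' @param component which component to split (default `"E_total"`).
#' @return list with `inner`, `outer`, `total` and `fraction`
#'   (= outer / total).
#' @export
inner_outer_split <- function(profile, threshold = 30, component = "E_total") {
  outer_sel <- profile$bin_lower >= threshold
  inner <- sum(profile[[component]][!outer_sel])
  outer <- sum(profile[[component]][outer_sel])
  total <- inner + outer
  list(inner = inner, outer = outer, total = total,
       fraction = if (total != 0) outer / total else NA_real_)
}
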