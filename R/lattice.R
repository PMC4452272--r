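# Idealized microtubule lattice: ring construction and two-dimer subsystems.

#' Lattice specification for an idealized microtubule ring
#'
#' Describes an `n_pf`-protofilament, `helix_start`-start helical lattice of
#' tubulin-like dimers. The axial dimer repeat depends on the nucleotide in
#' the exchangeable site: 81.20 A for the GDP state and 83.38 A for the GTP
#' state; the monomer rise is half of the repeat. For the canonical 13_3
#' B-lattice, going once around the ring rises three monomer lengths, so the
#' closing (seam) contact is one monomer out of axial register, which is
#' where alpha-tubulin meets beta-tubulin laterally.
#'
#' @param n_pf number of protofilaments (dimers per ring), >= 3.
#' @param helix_start helix start number in monomers of rise per turn, >= 1.
#' @param nucleotide `"GDP"` or `"GTP"`; selects the default dimer repeat.
#' @param dimer_repeat axial dimer repeat c in angstroms; overrides the
#'   nucleotide default when given. The monomer rise is `dimer_repeat / 2`.
#' @param ring_radius distance from the microtubule axis to a dimer center
#'   of mass, angstroms.
#' @return an object of class `lattice_spec` (a validated list with fields
#'   `n_pf`, `helix_start`, `nucleotide`, `dimer_repeat`, `monomer_rise`,
#'   `ring_radius`, and the periodic `box` c(Lx, Ly, Lz)).
#' @examples
#' spec <- lattice_spec()            # 13_3 GDP lattice, repeat 81.20 A
#' spec$monomer_rise                 # 40.60
#' @export
lattice_spec <- function(n_pf = 13L, helix_start = 3L,
                         nucleotide = c("GDP", "GTP"),
                         dimer_repeat = NULL, ring_radius = 105) {
  nucleotide <- match.arg(nucleotide)
  if (is.null(dimer_repeat)) {
    dimer_repeat <- if (nucleotide == "GDP") 81.20 else 83.38
  }
  spec <- structure(list(
    n_pf = as.integer(n_pf),
    helix_start = as.integer(helix_start),
    nucleotide = nucleotide,
    dimer_repeat = as.numeric(dimer_repeat),
    monomer_rise = as.numeric(dimer_repeat) / 2,
    ring_radius = as.numeric(ring_radius),
    box = c(293.85, 293.85, as.numeric(dimer_repeat))
  ), class = "lattice_spec")
  validate_lattice_spec(spec)
  spec
}

#' @rdname lattice_spec
#' @param spec object to validate.
#' @export
validate_lattice_spec <- function(spec) {
  if (!inherits(spec, "lattice_spec")) stop("not a lattice_spec")
  if (is.na(spec$n_pf) || spec$n_pf < 1L) stop("spec error: n_pf must be >= 1")
  if (spec$n_pf > 1L && spec$n_pf < 3L) stop("spec error: n_pf must be >= 3 (or 1 for a single protofilament)")
  if (is.na(spec$helix_start) || spec$helix_start < 1L) stop("spec error: helix_start must be >= 1")
  if (!is.finite(spec$dimer_repeat) || spec$dimer_repeat <= 0) stop("spec error: dimer_repeat must be positive")
  if (!is.finite(spec$ring_radius) || spec$ring_radius <= 0) stop("spec error: ring_radius must be positive")
  if (abs(spec$dimer_repeat - 2 * spec$monomer_rise) > 1e-9) stop("spec error: dimer_repeat must equal 2 * monomer_rise")
  invisible(spec)
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf(
    "lattice_spec: %d_%d lattice, %s state, dimer repeat %.2f A (monomer rise %.2f A), ring radius %.1f A\n",
    x$n_pf, x$helix_start, x$nucleotide, x$dimer_repeat, x$monomer_rise, x$ring_radius))
  invisible(x)
}

#' Rigid transform between lattice neighbors
#'
#' The lateral step carries dimer k onto dimer k+1: a rotation of
#' `2*pi/n_pf` about the axis plus an axial rise of
#' `helix_start * monomer_rise / n_pf`, so that `n_pf` lateral steps
#' accumulate exactly one full turn and `helix_start` monomer rises (helix
#' closure). The longitudinal step is a pure axial translation by the dimer
#' repeat.
#'
#' @param spec a [lattice_spec()].
#' @param step_kind `"lateral"` or `"longitudinal"`.
#' @return list with `angle` (radians) and `rise` (angstroms).
#' @examples
#' neighbor_transform(lattice_spec(), "lateral")$rise   # 3 * 40.60 / 13
#' @export
neighbor_transform <- function(spec, step_kind = c("lateral", "longitudinal")) {
  validate_lattice_spec(spec)
  step_kind <- match.arg(step_kind)
  if (step_kind == "lateral") {
    list(angle = 2 * pi / spec$n_pf,
         rise = spec$helix_start * spec$monomer_rise / spec$n_pf)
  } else {
    list(angle = 0, rise = spec$dimer_repeat)
  }
}

#' Build an idealized microtubule ring from a dimer template
#'
#' Places `n_pf` copies of the template dimer on the helical lattice: dimer
#' k is the template rotated by `(k-1) * 2*pi/n_pf` about z and raised by
#' `(k-1)` lateral rises. The template must be centered near the origin
#' with its alpha->beta axis along +z; it is first translated radially to
#' `ring_radius` along +x (so dimer 1 sits at azimuth 0).
#'
#' @param spec a [lattice_spec()].
#' @param template a dimer atom table (see [make_toy_dimer()] or
#'   [read_dimer_pdb()]) with a `subunit` column labeling `"alpha"` and
#'   `"beta"` atoms.
#' @return an `mt_structure` data frame of all ring atoms with a `dimer`
#'   column (1..n_pf); the spec is attached as attribute `"spec"`.
#' @export
build_ring <- function(spec, template) {
  validate_lattice_spec(spec)
  template <- as_mt_structure(template)
  subs <- unique(template$subunit)
  if (!all(c("alpha", "beta") %in% subs)) {
    stop("labeling error: template must label both 'alpha' and 'beta' subunits")
  }
  tr <- neighbor_transform(spec, "lateral")
  xyz0 <- xyz_matrix(template)
  xyz0[, 1] <- xyz0[, 1] + spec$ring_radius
  pieces <- vector("list", spec$n_pf)
  for (k in seq_len(spec$n_pf)) {
    xyz <- rotate_z(xyz0, (k - 1) * tr$angle)
    xyz[, 3] <- xyz[, 3] + (k - 1) * tr$rise
    d <- template
    d$x <- xyz[, 1]; d$y <- xyz[, 2]; d$z <- xyz[, 3]
    d$dimer <- k
    pieces[[k]] <- d
  }
  ring <- do.call(rbind, pieces)
  rownames(ring) <- NULL
  structure(ring, spec = spec, class = c("mt_structure", "data.frame"))
}

as_mt_structure <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("atom", "resname", "resno", "subunit", "x", "y", "z")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(x$element)) x$element <- "C"
  if (is.null(x$mass)) x$mass <- atom_masses(x$element)
  if (is.null(x$dimer)) x$dimer <- 1L
  class(x) <- unique(c("mt_structure", class(x)))
  x
}

#' Extract a two-dimer subsystem from a ring
#'
#' Subsystems follow the receptor/ligand convention used for lateral and
#' longitudinal interface scoring:
#' * `lateral`, k in 1..n_pf-1: receptor = dimer k (its M-loop face points
#'   toward the interface), ligand = dimer k+1.
#' * `lateral_seam`: receptor = dimer n_pf, ligand = the periodic image of
#'   dimer 1 carried one full turn around the helix plus one additional
#'   monomer rise, so the ligand's alpha subunit faces the receptor's beta
#'   subunit (the B-lattice seam flip).
#' * `longitudinal`, k in 1..n_pf: receptor = dimer k, ligand = its +z
#'   periodic image (a pure translation by the dimer repeat); the
#'   receptor's alpha-tubulin faces the interface.
#'
#' Residues are renumbered continuously over receptor-alpha, receptor-beta,
#' ligand-alpha, ligand-beta (column `index`).
#'
#' @param ring an `mt_structure` ring built by [build_ring()].
#' @param kind `"lateral"`, `"lateral_seam"` or `"longitudinal"`.
#' @param k subsystem index; ignored for the seam.
#' @return an `mt_subsystem`: list with `atoms` (atom table with `role`
#'   "R"/"L" and continuous residue `index`), `kind`, `k`, `spec`.
#' @export
make_subsystem <- function(ring, kind = c("lateral", "lateral_seam", "longitudinal"),
                           k = 1L) {
  kind <- match.arg(kind)
  spec <- attr(ring, "spec")
  if (is.null(spec)) stop("ring has no lattice spec attached")
  n <- spec$n_pf
  if (kind == "lateral") {
    if (n < 2L) stop("k out of range: a single-protofilament ring has no lateral subsystems")
    if (k < 1L || k > n - 1L) stop(sprintf("k out of range: lateral k must be in 1..%d", n - 1L))
    rec <- ring[ring$dimer == k, , drop = FALSE]
    lig <- ring[ring$dimer == k + 1L, , drop = FALSE]
  } else if (kind == "lateral_seam") {
    off <- spec$helix_start * spec$monomer_rise - spec$dimer_repeat
    if (abs(off - spec$monomer_rise) > 1e-9) {
      stop("seam requested but helical closure is inconsistent: ",
           "helix_start * monomer_rise - dimer_repeat must equal one monomer rise")
    }
    k <- n
    rec <- ring[ring$dimer == n, , drop = FALSE]
    lig <- ring[ring$dimer == 1L, , drop = FALSE]
    # One full turn of the helix (identity rotation, rise = helix_start
    # monomers) plus one extra monomer rise: 3h + h = 2c for the 13_3
    # lattice, i.e. the image two boxes up. The extra monomer puts the
    # ligand's alpha against the receptor's beta.
    lig$z <- lig$z + spec$helix_start * spec$monomer_rise + spec$monomer_rise
  } else {
    if (k < 1L || k > n) stop(sprintf("k out of range: longitudinal k must be in 1..%d", n))
    rec <- ring[ring$dimer == k, , drop = FALSE]
    lig <- rec
    lig$z <- lig$z + spec$dimer_repeat
  }
  if (nrow(rec) == 0L || nrow(lig) == 0L) stop("missing dimer labels in ring")
  rec$role <- "R"; lig$role <- "L"
  atoms <- rbind(rec, lig)
  rownames(atoms) <- NULL
  atoms$index <- continuous_residue_index(atoms)
  structure(list(atoms = atoms, kind = kind, k = as.integer(k), spec = spec),
            class = "mt_subsystem")
}

# Continuous residue numbering over receptor-alpha, receptor-beta,
# ligand-alpha, ligand-beta; each residue gets one index.
continuous_residue_index <- function(atoms) {
  ord <- order(match(atoms$role, c("R", "L")),
               match(atoms$subunit, c("alpha", "beta")),
               atoms$resno)
  key <- paste(atoms$role, atoms$subunit, atoms$resno, sep = ":")
  first <- !duplicated(key[ord])
  idx_sorted <- cumsum(first)
  idx <- integer(nrow(atoms))
  idx[ord] <- idx_sorted
  idx
}

#' @export
print.mt_subsystem <- function(x, ...) {
  cat(sprintf("mt_subsystem: kind=%s k=%d, %d atoms, %d residues\n",
              x$kind, x$k, nrow(x$atoms), max(x$atoms$index)))
  invisible(x)
}

#' Enumerate all subsystems of one interface class
#'
#' @param ring a ring structure.
#' @param class `"lateral"` (12 laterals plus the seam, for a 13-pf ring) or
#'   `"longitudinal"` (13 subsystems).
#' @return list of `mt_subsystem` objects, seam last for the lateral class.
#' @export
enumerate_subsystems <- function(ring, class = c("lateral", "longitudinal")) {
  class <- match.arg(class)
  spec <- attr(ring, "spec")
  if (class == "lateral") {
    subs <- lapply(seq_len(spec$n_pf - 1L), function(k) make_subsystem(ring, "lateral", k))
    c(subs, list(make_subsystem(ring, "lateral_seam")))
  } else {
    lapply(seq_len(spec$n_pf), function(k) make_subsystem(ring, "longitudinal", k))
  }
}
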