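# Trajectory geometry observables: perpendicular ring diameters and
# backbone RMSD.

#' Perpendicular microtubule ring diameters
#'
#' `Dx` is the distance between the center of mass of dimer 4 and the
#' joint (mass-weighted) center of mass of dimers 10 and 11; `Dy` between
#' dimer 1 and dimers 7 and 8. Only the projection onto the x-y plane is
#' taken, which is what gives the cylinder diameter; both are therefore
#' invariant under axial translation.
#'
#' @param ring an `mt_structure` ring with 13 labeled dimers.
#' @return named numeric vector `c(Dx = , Dy = )` in angstroms.
#' @export
diameters <- function(ring) {
  ks <- unique(ring$dimer)
  need <- c(1L, 4L, 7L, 8L, 10L, 11L)
  if (!all(need %in% ks)) stop("missing dimer labels: need dimers 1, 4, 7, 8, 10, 11")
  com_of <- function(sel) center_of_mass(ring[ring$dimer %in% sel, , drop = FALSE])
  dx <- com_of(4L) - com_of(c(10L, 11L))
  dy <- com_of(1L) - com_of(c(7L, 8L))
  c(Dx = sqrt(sum(dx[1:2]^2)), Dy = sqrt(sum(dy[1:2]^2)))
}

#' Backbone RMSD between a frame and a reference
#'
#' Root-mean-square deviation over a matched atom selection, by default
#' after optimal rigid-body superposition (Kabsch). The backbone selection
#' keeps atoms named N, CA, C, O of protein residues; set
#' `selection = "all"` to use every atom, or pass a logical mask.
#'
#' @param frame,reference atom tables with identical atom ordering.
#' @param selection `"backbone"`, `"all"`, or a logical vector over atoms.
#' @param fit superpose before measuring (default TRUE); with
#'   `fit = FALSE` the raw deviation in the lab frame is returned.
#' @return RMSD in angstroms.
#' @export
backbone_rmsd <- function(frame, reference, selection = "backbone", fit = TRUE) {
  if (nrow(frame) != nrow(reference)) stop("selection mismatch: atom counts differ")
  sel <- if (is.logical(selection)) {
    selection
  } else if (identical(selection, "backbone")) {
    bb <- frame$atom %in% c("N", "CA", "C", "O")
    if (!any(bb)) rep(TRUE, nrow(frame)) else bb   # bead models have no N/CA/C/O
  } else if (identical(selection, "all")) {
    rep(TRUE, nrow(frame))
  } else {
    stop("unknown selection")
  }
  if (length(sel) != nrow(frame)) stop("selection mismatch")
  P <- xyz_matrix(frame)[sel, , drop = FALSE]
  Q <- xyz_matrix(reference)[sel, , drop = FALSE]
  if (fit) kabsch(P, Q)$rmsd else sqrt(mean(rowSums((P - Q)^2)))
}

#' Diameter and RMSD series over a trajectory
#'
#' @param frames list of ring structures (see [make_ring_trajectory()]).
#' @param reference reference frame for RMSD (default the first frame).
#' @param fit superpose before RMSD.
#' @return data frame with columns `frame`, `Dx`, `Dy`, `rmsd`.
#' @export
geometry_series <- function(frames, reference = frames[[1L]], fit = TRUE) {
  out <- data.frame(frame = seq_along(frames))
  dd <- t(vapply(frames, diameters, numeric(2)))
  out$Dx <- dd[, "Dx"]; out$Dy <- dd[, "Dy"]
  out$rmsd <- vapply(frames, backbone_rmsd, numeric(1),
                     reference = reference, fit = fit)
  out
}
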