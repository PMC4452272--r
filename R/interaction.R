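# Per-residue MM/GBSA-style interaction energies for two-dimer subsystems
# under the single-trajectory convention.

#' Per-residue interaction energy of a subsystem
#'
#' Scores one receptor/ligand dimer pair with the single-trajectory
#' MM/GBSA-style decomposition: every component is
#' `E(complex) - E(receptor) - E(ligand)` on identical coordinates.
#' The molecular-mechanics terms (Lennard-Jones and Coulomb) reduce to the
#' cross-molecular pair sums, half-assigned to each pair partner, so the
#' receptor and ligand shares of those terms are symmetric. The
#' generalized Born and surface-area terms are per-atom differences
#' (complex minus isolated molecule), which is how the two molecules'
#' totals can differ through solvation alone.
#'
#' @param sub an `mt_subsystem` whose atoms are parameterized (see
#'   [parameterize()]).
#' @param eps_in,eps_out solute / solvent dielectric constants (1 and 80).
#' @param gamma,beta non-polar solvation coefficients,
#'   `E_SA = gamma * SASA + beta` (defaults 0.0072 kcal/(mol A^2) and 0).
#' @param probe SASA probe radius, angstroms.
#' @param sasa_points Shrake-Rupley points per atom.
#' @return an `energy_table`: data frame with one row per residue (columns
#'   `index`, `resname`, `role`, `subunit`, `resno`, `E_vdW`, `E_ele`,
#'   `E_GB`, `E_SA`, `E_total`) and attributes `totals` (named component
#'   totals including `E_vdW_SA` and `E_ele_GB`), `role_totals`, `kind`,
#'   `k`.
#' @export
interaction_energy <- function(sub, eps_in = 1, eps_out = 80,
                               gamma = 0.0072, beta = 0,
                               probe = 1.4, sasa_points = 960L) {
  stopifnot(inherits(sub, "mt_subsystem"))
  atoms <- sub$atoms
  if (!has_parameters(atoms)) {
    stop("parameterization error: subsystem atoms carry no parameters; run parameterize()")
  }
  iR <- which(atoms$role == "R")
  iL <- which(atoms$role == "L")
  xyz <- xyz_matrix(atoms)
  r <- dist_cross(xyz[iR, , drop = FALSE], xyz[iL, , drop = FALSE])
  if (any(r <= 0)) stop("singularity error: coincident receptor/ligand atoms")

  # Cross-molecular MM terms, half to each partner atom.
  qq <- outer(atoms$charge[iR], atoms$charge[iL])
  ele <- KE_COULOMB * qq / (eps_in * r)
  rmin <- outer(atoms$rmin2[iR], atoms$rmin2[iL], "+")
  epsij <- sqrt(outer(atoms$eps[iR], atoms$eps[iL]))
  s6 <- (rmin / r)^6
  vdw <- epsij * (s6 * s6 - 2 * s6)
  n <- nrow(atoms)
  at_vdw <- numeric(n); at_ele <- numeric(n)
  at_vdw[iR] <- 0.5 * rowSums(vdw); at_vdw[iL] <- 0.5 * colSums(vdw)
  at_ele[iR] <- 0.5 * rowSums(ele); at_ele[iL] <- 0.5 * colSums(ele)

  # Solvation terms: complex minus isolated molecules, per atom.
  gb_c <- gb_energy(atoms, born_radii(atoms), eps_in, eps_out)$per_atom
  gb_r <- gb_energy(atoms[iR, ], born_radii(atoms[iR, ]), eps_in, eps_out)$per_atom
  gb_l <- gb_energy(atoms[iL, ], born_radii(atoms[iL, ]), eps_in, eps_out)$per_atom
  at_gb <- numeric(n)
  at_gb[iR] <- gb_c[iR] - gb_r
  at_gb[iL] <- gb_c[iL] - gb_l

  sa_c <- sasa(atoms, probe, sasa_points)
  sa_r <- sasa(atoms[iR, ], probe, sasa_points)
  sa_l <- sasa(atoms[iL, ], probe, sasa_points)
  dsa <- numeric(n)
  dsa[iR] <- sa_c[iR] - sa_r
  dsa[iL] <- sa_c[iL] - sa_l
  # gamma * dSASA; the additive constant enters once per molecule, so the
  # interaction picks up -beta, spread evenly to preserve additivity.
  at_sa <- gamma * dsa - beta / n

  rollup_energy_table(atoms, at_vdw, at_ele, at_gb, at_sa,
                      kind = sub$kind, k = sub$k)
}

rollup_energy_table <- function(atoms, at_vdw, at_ele, at_gb, at_sa, kind, k) {
  key <- paste(atoms$role, atoms$subunit, atoms$resno, sep = ":")
  first <- !duplicated(key)
  tab <- data.frame(
    index = atoms$index[first],
    resname = atoms$resname[first],
    role = atoms$role[first],
    subunit = atoms$subunit[first],
    resno = atoms$resno[first],
    stringsAsFactors = FALSE
  )
  grp <- match(key, key[first])
  tab$E_vdW <- as.numeric(tapply(at_vdw, grp, sum))
  tab$E_ele <- as.numeric(tapply(at_ele, grp, sum))
  tab$E_GB <- as.numeric(tapply(at_gb, grp, sum))
  tab$E_SA <- as.numeric(tapply(at_sa, grp, sum))
  tab$E_total <- tab$E_vdW + tab$E_ele + tab$E_GB + tab$E_SA
  tab <- tab[order(tab$index), ]
  rownames(tab) <- NULL
  as_energy_table(tab, kind = kind, k = k)
}

#' Construct / validate an energy table
#'
#' @param tab data frame with residue keys and component columns.
#' @param kind,k subsystem interface kind and index (optional metadata).
#' @return the table with class `energy_table` and component totals in
#'   attribute `totals` (`E_total = E_vdW + E_ele + E_GB + E_SA` per row).
#' @export
as_energy_table <- function(tab, kind = NA_character_, k = NA_integer_) {
  need <- c("role", "subunit", "resno", "E_vdW", "E_ele", "E_GB", "E_SA")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("energy table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(tab$resname)) tab$resname <- "RES"
  if (is.null(tab$index)) {
    ord <- order(match(tab$role, c("R", "L")),
                 match(tab$subunit, c("alpha", "beta")), tab$resno)
    idx <- integer(nrow(tab))
    idx[ord] <- seq_len(nrow(tab))
    tab$index <- idx
  }
  tab$E_total <- tab$E_vdW + tab$E_ele + tab$E_GB + tab$E_SA
  totals <- c(
    E_vdW = sum(tab$E_vdW), E_ele = sum(tab$E_ele),
    E_GB = sum(tab$E_GB), E_SA = sum(tab$E_SA)
  )
  totals <- c(totals,
              E_vdW_SA = unname(totals["E_vdW"] + totals["E_SA"]),
              E_ele_GB = unname(totals["E_ele"] + totals["E_GB"]),
              E_total = unname(sum(totals[1:4])))
  role_totals <- c(R = sum(tab$E_total[tab$role == "R"]),
                   L = sum(tab$E_total[tab$role == "L"]))
  structure(tab, totals = totals, role_totals = role_totals,
            kind = kind, k = k,
            class = unique(c("energy_table", class(tab))))
}

#' Component totals of an energy table
#' @param tab an `energy_table`.
#' @return named numeric vector of totals (kcal/mol).
#' @export
energy_totals <- function(tab) attr(tab, "totals")

#' Ensemble mean and spread of per-frame energy tables
#'
#' Averages per-residue interaction tables over trajectory frames. The
#' spread of each total is the population standard deviation of the
#' per-frame totals (not the sum of per-residue SDs).
#'
#' @param tables list of >= 2 `energy_table`s over identical residue sets.
#' @return an `energy_table` of means with extra `sd_*` columns and
#'   attributes `totals` (means) and `totals_sd`.
#' @export
ensemble_average <- function(tables) {
  if (length(tables) < 2L) stop("need at least 2 frames")
  ref <- tables[[1L]]
  key0 <- paste(ref$role, ref$subunit, ref$resno, sep = ":")
  comp <- c("E_vdW", "E_ele", "E_GB", "E_SA", "E_total")
  mats <- lapply(comp, function(cc) {
    sapply(tables, function(t) {
      key <- paste(t$role, t$subunit, t$resno, sep = ":")
      if (length(key) != length(key0) || !setequal(key, key0)) {
        stop("inconsistent residue sets across frames")
      }
      t[[cc]][match(key0, key)]
    })
  })
  names(mats) <- comp
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- ref[, c("index", "resname", "role", "subunit", "resno")]
  for (cc in comp) {
    out[[cc]] <- rowMeans(mats[[cc]])
    out[[paste0("sd_", cc)]] <- apply(mats[[cc]], 1L, pop_sd)
  }
  frame_totals <- sapply(comp, function(cc) colSums(mats[[cc]]))
  totals <- colMeans(frame_totals)
  totals_sd <- apply(frame_totals, 2L, pop_sd)
  out <- as_energy_table(out, kind = attr(ref, "kind"), k = attr(ref, "k"))
  attr(out, "totals_sd") <- totals_sd
  attr(out, "n_frames") <- length(tables)
  out
}
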