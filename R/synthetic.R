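# Seeded synthetic-data generators: toy parameterized dimers, ovalized
# ring trajectories, and mock per-residue energy tables with planted
# ground truth. All generators are pure functions of (spec, seed).

#' Generate a toy parameterized tubulin-like dimer
#'
#' Builds a bead-residue dimer with two labeled subunits ("alpha" below,
#' "beta" above, alpha->beta along +z), a compact scaffold sized like a
#' tubulin dimer (~80 A tall, ~45 A wide), seeded partial charges adjusted
#' to an exact net protein charge (tubulin-like: net negative), and a
#' bespoke minimal nonbonded parameter preset (Lennard-Jones, GB radius
#' and screening per atom). Optionally the nucleotide cofactors are added
#' as named residues assigned to their host subunit: GTP + Mg at the
#' alpha-tubulin N-site and, at the beta-tubulin E-site, either GDP alone
#' or GTP + Mg, so that cofactors appear as first-class rows in
#' per-residue energy tables.
#'
#' @param n_res residues per subunit (default 5, must be >= 1).
#' @param atoms_per_res beads per residue (default 3).
#' @param seed RNG seed; the output is reproducible given the seed.
#' @param net_charge exact net charge of the protein beads, e.
#' @param e_site `"none"`, `"GDP"` or `"GTP"`: exchangeable-site content
#'   (`"GTP"` brings a Mg ion with it; the N-site GTP + Mg are always
#'   present unless `"none"`).
#' @param height,width dimer axial and lateral extent, angstroms.
#' @return list with `dimer` (parameterized `mt_structure` atom table) and
#'   `params` (the matching parameter table keyed on atom and residue
#'   name).
#' @export
make_toy_dimer <- function(n_res = 5L, atoms_per_res = 3L, seed = 1L,
                           net_charge = -4, e_site = c("none", "GDP", "GTP"),
                           height = 80, width = 45) {
  e_site <- match.arg(e_site)
  if (n_res < 1L) stop("zero residues: n_res must be >= 1")
  if (atoms_per_res < 1L) stop("atoms_per_res must be >= 1")
  with_seed(seed, {
    mk_subunit <- function(subunit, z0, z1, tag) {
      rows <- list()
      edge <- 7   # z margin keeping inter-dimer contacts near LJ range
      # terminal residue of each monomer sits on the dimer axis, standing in
      # for the longitudinal contact surface (alpha: bottom, beta: top)
      rfac <- rep(1, n_res)
      if (subunit == "alpha") rfac[1L] <- 0 else rfac[n_res] <- 0
      for (j in seq_len(n_res)) {
        t <- if (n_res == 1L) 0.5 else (j - 1) / (n_res - 1)
        ang <- 2.399963229728653 * (j - 1)   # golden angle: even azimuth cover
        ctr <- c(0.5 * width * rfac[j] * cos(ang), 0.5 * width * rfac[j] * sin(ang),
                 z0 + edge + (z1 - z0 - 2 * edge) * t) + rnorm(3, 0, 1.5)
        for (a in seq_len(atoms_per_res)) {
          th <- 2 * pi * (a - 1) / atoms_per_res
          off <- c(1.8 * cos(th), 1.8 * sin(th), 1.2 * ((a %% 2) - 0.5)) +
            rnorm(3, 0, 0.3)
          rows[[length(rows) + 1L]] <- data.frame(
            atom = sprintf("C%d", a), resname = sprintf("%s%02d", tag, j),
            resno = j, subunit = subunit,
            x = ctr[1] + off[1], y = ctr[2] + off[2], z = ctr[3] + off[3],
            element = "C", stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    }
    atoms <- rbind(mk_subunit("alpha", -height / 2, 0, "A"),
                   mk_subunit("beta", 0, height / 2, "B"))
    np <- nrow(atoms)
    q <- rnorm(np, 0, 0.35)
    q <- q + (net_charge - sum(q)) / np       # exact net charge
    atoms$charge <- q
    # coarse-grained beads (one bead ~ several heavy atoms), so radii are
    # a few angstroms and neighboring dimers make genuine vdW/SASA contact
    atoms$rmin2 <- runif(np, 8.0, 9.0)
    atoms$eps <- runif(np, 0.15, 0.35)
    atoms$gbr <- atoms$rmin2 - 0.4
    atoms$screen <- 0.80

    if (e_site != "none") {
      cof <- function(resname, subunit, resno, center, n_beads, q_each, elem) {
        k <- seq_len(n_beads)
        data.frame(
          atom = sprintf("%s%d", substr(resname, 1, 1), k), resname = resname,
          resno = resno, subunit = subunit,
          x = center[1] + 1.5 * cos(2 * pi * k / n_beads),
          y = center[2] + 1.5 * sin(2 * pi * k / n_beads),
          z = center[3] + 0.6 * ((k %% 2) - 0.5),
          element = elem, charge = q_each,
          rmin2 = if (elem == "MG") 1.6 else 4.0,
          eps = if (elem == "MG") 0.88 else 0.20,
          gbr = if (elem == "MG") 1.45 else 3.6,
          screen = 0.80, stringsAsFactors = FALSE)
      }
      # N-site: intra-dimer interface (z ~ 0), lumen-facing (-x) side.
      inner_x <- -0.35 * width
      extra <- list(cof("GTP", "alpha", n_res + 1L, c(inner_x, 0, -3), 5L, -0.8, "C"),
                    cof("MG", "alpha", n_res + 2L, c(inner_x, 2.5, -3), 1L, 2.0, "MG"))
      # E-site: top of beta, at the longitudinal inter-dimer interface.
      e_ctr <- c(inner_x, 0, height / 2 - 4)
      if (e_site == "GDP") {
        extra <- c(extra, list(cof("GDP", "beta", n_res + 1L, e_ctr, 4L, -0.75, "C")))
      } else {
        extra <- c(extra, list(cof("GTP", "beta", n_res + 1L, e_ctr, 5L, -0.8, "C"),
                               cof("MG", "beta", n_res + 2L, e_ctr + c(0, 2.5, 0), 1L, 2.0, "MG")))
      }
      atoms <- rbind(atoms, do.call(rbind, extra))
    }
    atoms$mass <- atom_masses(atoms$element)
    atoms$dimer <- 1L
    rownames(atoms) <- NULL
    key <- paste(atoms$atom, atoms$resname, sep = "|")
    params <- atoms[!duplicated(key),
                    c("atom", "resname", "charge", "rmin2", "eps", "gbr", "screen")]
    rownames(params) <- NULL
    list(dimer = structure(atoms, class = c("mt_structure", "data.frame")),
         params = params)
  })
}

#' Generate a synthetic ring trajectory with ovalization and jitter
#'
#' Frame t applies an elliptical in-plane distortion that moves the dimer
#' center-of-mass radius to `R + e_t` along x and `R - e_t` along y, with
#' `e_t = delta * sin(2 * pi * t / n_frames)`, emulating the spontaneous
#' circular-to-oval breathing of simulated rings, plus isotropic Gaussian
#' jitter of width `sigma` on every coordinate.
#'
#' @param spec a [lattice_spec()].
#' @param dimer a template dimer atom table.
#' @param n_frames number of frames (>= 1).
#' @param delta ovalization amplitude, angstroms.
#' @param sigma per-coordinate jitter, angstroms (>= 0).
#' @param seed RNG seed.
#' @return list of `mt_structure` ring frames.
#' @export
make_ring_trajectory <- function(spec, dimer, n_frames = 10L, delta = 0,
                                 sigma = 0, seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  ring <- build_ring(spec, dimer)
  R <- spec$ring_radius
  with_seed(seed, {
    lapply(seq_len(n_frames), function(t) {
      e <- delta * sin(2 * pi * t / n_frames)
      fr <- ring
      fr$x <- ring$x * (1 + e / R)
      fr$y <- ring$y * (1 - e / R)
      if (sigma > 0) {
        n <- nrow(fr)
        fr$x <- fr$x + rnorm(n, 0, sigma)
        fr$y <- fr$y + rnorm(n, 0, sigma)
        fr$z <- fr$z + rnorm(n, 0, sigma)
      }
      fr
    })
  })
}

#' Mock per-residue energy tables with planted ground truth
#'
#' Generates one `energy_table` per subsystem together with shared residue
#' coordinates and a ground-truth record, for exercising the aggregation
#' and profiling machinery against known answers. Planting options:
#'
#' * `cells`: named ring-level ligand/receptor-by-subunit totals
#'   (`L.beta`, `R.beta`, `L.alpha`, `R.alpha`); each subsystem's
#'   (role, subunit) group is rescaled so the ring aggregate reproduces
#'   the cells exactly.
#' * `outer_fraction`: fraction of each table's total energy carried by
#'   residues at coordinate >= 30 A; planted by an energy-conserving
#'   transfer inside every (role, subunit) group, so planted cells are
#'   preserved.
#' * `per_subsystem_totals`: length-`n_subsystems` vector of interface
#'   totals (e.g. a weak seam); applied last by whole-table rescaling,
#'   which overrides the cell split of the ring aggregate.
#'
#' @param n_subsystems number of subsystems (13 for a full ring).
#' @param n_residues residues per subsystem (split over 2 roles x 2
#'   subunits; rounded up to a multiple of 4).
#' @param seed RNG seed.
#' @param kind interface class label for the tables (`"lateral"` tables
#'   get the last subsystem flagged as the seam).
#' @param cells,outer_fraction,per_subsystem_totals planting options as
#'   above (`NULL` to skip). `outer_fraction` must lie in `[0, 1]`.
#' @param sd_frac if > 0, attach `sd_*` columns equal to `sd_frac * |E|`.
#' @return list with `tables` (list of `energy_table`s), `coords`
#'   (residue coordinate data frame shared by all subsystems),
#'   `domain_map` (a toy map labeling the leading third of each subunit's
#'   residues as M-loop and the next third as H3 helix), and `truth`
#'   (named list recording every planted quantity).
#' @export
make_mock_tables <- function(n_subsystems = 13L, n_residues = 40L, seed = 1L,
                             kind = c("lateral", "longitudinal"),
                             cells = NULL, outer_fraction = NULL,
                             per_subsystem_totals = NULL, sd_frac = 0) {
  kind <- match.arg(kind)
  if (!is.null(outer_fraction) &&
      (outer_fraction < 0 || outer_fraction > 1)) {
    stop("fraction outside [0,1]")
  }
  if (!is.null(per_subsystem_totals) && length(per_subsystem_totals) != n_subsystems) {
    stop("per_subsystem_totals must have length n_subsystems")
  }
  m <- ceiling(n_residues / 4)
  groups <- expand.grid(role = c("R", "L"), subunit = c("alpha", "beta"),
                        stringsAsFactors = FALSE)
  with_seed(seed, {
    skel <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
      data.frame(role = groups$role[g], subunit = groups$subunit[g],
                 resno = seq_len(m), resname = "RES", stringsAsFactors = FALSE)
    }))
    nr <- nrow(skel)
    # shared coordinates: half inner [0, 27), half outer [30, 57)
    outer_res <- rep(c(FALSE, TRUE), length.out = m)[skel$resno]
    coord <- ifelse(outer_res, 30 + runif(nr) * 27, runif(nr) * 27)
    coords <- data.frame(skel, coord = coord, stringsAsFactors = FALSE)

    tables <- lapply(seq_len(n_subsystems), function(s) {
      t <- skel
      t$E_vdW <- rnorm(nr, -2.5, 0.8)
      t$E_ele <- rnorm(nr, 0.6, 0.5)
      t$E_GB <- rnorm(nr, -0.8, 0.4)
      t$E_SA <- rnorm(nr, -0.15, 0.05)
      t$E_total <- t$E_vdW + t$E_ele + t$E_GB + t$E_SA

      scale_rows <- function(t, sel, f) {
        for (cc in c("E_vdW", "E_ele", "E_GB", "E_SA", "E_total")) {
          t[[cc]][sel] <- t[[cc]][sel] * f
        }
        t
      }
      if (!is.null(cells)) {
        for (g in seq_len(nrow(groups))) {
          nm <- paste(groups$role[g], groups$subunit[g], sep = ".")
          sel <- t$role == groups$role[g] & t$subunit == groups$subunit[g]
          target <- cells[[nm]] / n_subsystems
          t <- scale_rows(t, sel, target / sum(t$E_total[sel]))
        }
      }
      if (!is.null(outer_fraction)) {
        f <- outer_fraction
        for (g in seq_len(nrow(groups))) {
          sel <- t$role == groups$role[g] & t$subunit == groups$subunit[g]
          Tg <- sum(t$E_total[sel])
          So <- sum(t$E_total[sel & outer_res])
          Si <- Tg - So
          t <- scale_rows(t, sel & outer_res, f * Tg / So)
          t <- scale_rows(t, sel & !outer_res, (1 - f) * Tg / Si)
        }
      }
      if (!is.null(per_subsystem_totals)) {
        t <- scale_rows(t, rep(TRUE, nr), per_subsystem_totals[s] / sum(t$E_total))
      }
      if (sd_frac > 0) {
        for (cc in c("E_vdW", "E_ele", "E_GB", "E_SA", "E_total")) {
          t[[paste0("sd_", cc)]] <- sd_frac * abs(t[[cc]])
        }
      }
      sub_kind <- if (kind == "lateral" && s == n_subsystems) "lateral_seam" else kind
      as_energy_table(t, kind = sub_kind, k = as.integer(s))
    })

    third <- max(1L, ceiling(m / 3))
    dmap <- structure(list(
      alpha = list(`M-loop` = list(c(1L, third)),
                   `H3 helix` = list(c(third + 1L, min(m, 2L * third)))),
      beta = list(`M-loop` = list(c(1L, third)),
                  `H3 helix` = list(c(third + 1L, min(m, 2L * third))))
    ), class = "domain_map")

    truth <- list(
      n_subsystems = n_subsystems, n_residues_per_subsystem = nr, seed = seed,
      ring_total = sum(vapply(tables, function(t) unname(energy_totals(t)["E_total"]), 1)),
      per_subsystem_totals = vapply(tables, function(t) unname(energy_totals(t)["E_total"]), 1)
    )
    if (!is.null(cells)) truth$cells <- unlist(cells)
    if (!is.null(outer_fraction)) truth$outer_fraction <- outer_fraction
    list(tables = tables, coords = coords, domain_map = dmap, truth = truth)
  })
}

#' Perturb an energy table into mock trajectory frames
#'
#' Adds i.i.d. Gaussian noise to every component of every residue (the
#' total is recomputed as the component sum), giving per-frame tables for
#' ensemble statistics.
#'
#' @param table an `energy_table` of means.
#' @param n_frames number of frames.
#' @param sigma per-residue, per-component noise SD.
#' @param seed RNG seed.
#' @return list of `energy_table`s.
#' @export
make_mock_frames <- function(table, n_frames = 200L, sigma = 0.5, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      t <- as.data.frame(table)[, c("index", "resname", "role", "subunit", "resno",
                                    "E_vdW", "E_ele", "E_GB", "E_SA")]
      for (cc in c("E_vdW", "E_ele", "E_GB", "E_SA")) {
        t[[cc]] <- t[[cc]] + rnorm(nrow(t), 0, sigma)
      }
      as_energy_table(t, kind = attr(table, "kind"), k = attr(table, "k"))
    })
  })
}

#' Write / read a ground-truth sidecar file
#'
#' Flat key = value text with full double precision, so that planted
#' ground truth round-trips bit-exactly through export and import. Vector
#' entries are comma-separated.
#'
#' @param truth named list of numeric scalars/vectors (and strings).
#' @param file path.
#' @return `read_truth()` returns the named list (numbers as doubles).
#' @export
write_truth <- function(truth, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(truth)) {
    v <- truth[[nm]]
    txt <- if (is.numeric(v)) paste(vapply(v, fmt_num, ""), collapse = ",")
    else paste(as.character(v), collapse = ",")
    writeLines(sprintf("%s = %s", nm, txt), con)
  }
  invisible(file)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  lines <- readLines(file)
  out <- list()
  for (ln in lines[nzchar(lines)]) {
    kv <- strsplit(ln, " = ", fixed = TRUE)[[1L]]
    parts <- strsplit(kv[2L], ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(parts))
    out[[kv[1L]]] <- if (anyNA(num)) parts else num
  }
  out
}
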