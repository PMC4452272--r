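# Readers and writers: PDB structures, per-residue energy tables in the
# supplementary-dataset text layout, run configuration, profiles.

#' Read a dimer template from PDB
#'
#' Uses bio3d to parse the file; chains are mapped to subunits through
#' `chain_map` (e.g. `c(A = "alpha", B = "beta")`). The structure is
#' re-centered so its center of mass sits at the origin (templates are
#' placed on the lattice by [build_ring()]).
#'
#' @param file PDB path.
#' @param chain_map named character vector chain id -> subunit label.
#' @param recenter move the center of mass to the origin (default TRUE).
#' @return an `mt_structure` atom table.
#' @export
read_dimer_pdb <- function(file, chain_map = c(A = "alpha", B = "beta"),
                           recenter = TRUE) {
  pdb <- bio3d::read.pdb(file)
  a <- pdb$atom
  sub <- unname(chain_map[a$chain])
  if (anyNA(sub)) stop("labeling error: chains ", paste(setdiff(unique(a$chain), names(chain_map)), collapse = ","),
                       " not covered by chain_map")
  atoms <- data.frame(
    atom = a$elety, resname = a$resid, resno = a$resno, subunit = sub,
    x = a$x, y = a$y, z = a$z,
    element = ifelse(is.na(a$elesy) | a$elesy == "", substr(a$elety, 1, 1), a$elesy),
    stringsAsFactors = FALSE
  )
  atoms$mass <- atom_masses(atoms$element)
  atoms$dimer <- 1L
  if (recenter) {
    com <- center_of_mass(atoms)
    atoms$x <- atoms$x - com[1]; atoms$y <- atoms$y - com[2]; atoms$z <- atoms$z - com[3]
  }
  structure(atoms, class = c("mt_structure", "data.frame"))
}

#' Write a structure (dimer, ring or subsystem atoms) as PDB
#'
#' The dimer index goes into the chain field (A = dimer 1 ... M = dimer
#' 13) and into the segment id; subsystem roles ("R"/"L") go to chains R
#' and L.
#'
#' @param atoms an `mt_structure` atom table (or `$atoms` of a subsystem).
#' @param file output path.
#' @export
write_structure_pdb <- function(atoms, file) {
  chain <- if (!is.null(atoms$role)) atoms$role else LETTERS[atoms$dimer %||% 1L]
  resno <- atoms$resno
  if (!is.null(atoms$index)) resno <- atoms$index
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(xyz_matrix(atoms))),
                   resno = resno, resid = atoms$resname, chain = chain,
                   elety = atoms$atom, elesy = atoms$element,
                   segid = sprintf("D%02d", atoms$dimer %||% 1L))
  invisible(file)
}

#' Write / read a per-residue energy table
#'
#' Plain tab-separated text, one residue per line, in the supplementary
#' dataset layout: residue index, residue name, E_vdW, E_ele, E_GB, E_SA,
#' E_total, followed by the entity key columns role, subunit, resno (and
#' any `sd_*` columns). Header comment lines start with `#` and carry
#' provenance (e.g. the run-config hash).
#'
#' @param table an `energy_table` or `ring_energy_table`.
#' @param file output path.
#' @param header character vector of comment lines.
#' @return `read_energy_table()` returns an `energy_table`.
#' @export
write_energy_table <- function(table, file, header = NULL) {
  df <- as.data.frame(table)
  lead <- c("index", "resname", "E_vdW", "E_ele", "E_GB", "E_SA", "E_total")
  if (is.null(df$index)) df$index <- seq_len(nrow(df))
  rest <- setdiff(names(df), lead)
  df <- df[, c(lead, rest)]
  con <- file(file, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  for (i in seq_len(nrow(df))) {
    vals <- vapply(df[i, ], function(v) if (is.numeric(v)) fmt_num(v) else as.character(v), "")
    writeLines(paste(vals, collapse = "\t"), con)
  }
  invisible(file)
}

#' @rdname write_energy_table
#' @export
read_energy_table <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  as_energy_table(df)
}

#' Write a profile as delimited text
#'
#' Columns bin_lower, bin_upper, E_vdW, E_ele_GB, E_SA, E_total (the
#' component grouping used for interface energy profiles).
#'
#' @param profile a `profile` from [binned_profile()].
#' @param file output path.
#' @param header comment lines.
#' @export
write_profile <- function(profile, file, header = NULL) {
  df <- as.data.frame(profile)[, c("bin_lower", "bin_upper",
                                   "E_vdW", "E_ele_GB", "E_SA", "E_total")]
  con <- file(file, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  for (i in seq_len(nrow(df))) {
    writeLines(paste(vapply(df[i, ], fmt_num, ""), collapse = "\t"), con)
  }
  invisible(file)
}

#' Run configuration
#'
#' A validated bundle of lattice spec, scoring settings, profile settings,
#' paths and seed, serialized into every output header for provenance.
#'
#' @param file YAML path for `read_run_config()`.
#' @param config a run-config list.
#' @return `run_config()` returns a validated `run_config` list with a
#'   `hash` field; `config_hash()` the md5 of the canonical serialization.
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  do.call(run_config, cfg)
}

#' @rdname read_run_config
#' @param n_pf,helix_start,nucleotide,dimer_repeat,ring_radius lattice
#'   fields, see [lattice_spec()].
#' @param eps_in,eps_out,gamma,beta,probe,sasa_points scoring settings,
#'   see [interaction_energy()].
#' @param bin_width,lumen_quantile,com_threshold profile settings.
#' @param seed integer seed for the synthetic generators.
#' @param outdir output directory.
#' @export
run_config <- function(n_pf = 13L, helix_start = 3L, nucleotide = "GDP",
                       dimer_repeat = NULL, ring_radius = 105,
                       eps_in = 1, eps_out = 80, gamma = 0.0072, beta = 0,
                       probe = 1.4, sasa_points = 960L,
                       bin_width = 3, lumen_quantile = 0.01, com_threshold = 30,
                       seed = 1L, outdir = ".") {
  spec <- lattice_spec(n_pf, helix_start, nucleotide, dimer_repeat, ring_radius)
  for (nm in c("eps_in", "eps_out")) {
    if (get(nm) <= 0) stop(sprintf("validation failure: field %s must be positive", nm))
  }
  if (bin_width <= 0) stop("validation failure: field bin_width must be positive")
  if (lumen_quantile < 0 || lumen_quantile > 1) {
    stop("validation failure: field lumen_quantile must be in [0,1]")
  }
  cfg <- list(spec = spec, eps_in = eps_in, eps_out = eps_out, gamma = gamma,
              beta = beta, probe = probe, sasa_points = as.integer(sasa_points),
              bin_width = bin_width, lumen_quantile = lumen_quantile,
              com_threshold = com_threshold, seed = as.integer(seed),
              outdir = outdir)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$hash <- NULL
  cfg$outdir <- NULL
  flat <- unlist(cfg)
  canon <- paste(names(flat), vapply(flat, function(v)
    if (is.numeric(v)) fmt_num(v) else as.character(v), ""),
    sep = "=", collapse = ";")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canon, tmp)
  unname(tools::md5sum(tmp))
}

config_header <- function(config) {
  sprintf("config_hash=%s seed=%d lattice=%d_%d %s repeat=%.2fA",
          config$hash, config$seed, config$spec$n_pf, config$spec$helix_start,
          config$spec$nucleotide, config$spec$dimer_repeat)
}
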