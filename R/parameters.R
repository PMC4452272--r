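# Per-atom nonbonded parameter tables and their application to structures.

#' Read / write a nonbonded parameter table
#'
#' Parameter tables are tab-separated text with one row per (atom name,
#' residue name) pair and columns `atom`, `resname`, `charge` (e),
#' `rmin2` (Lennard-Jones r_min/2, A), `eps` (well depth, kcal/mol),
#' `gbr` (intrinsic generalized Born radius, A) and `screen`
#' (dimensionless GB screening factor). Lines starting with `#` are
#' comments.
#'
#' @param file path to the table.
#' @return data frame with the columns above.
#' @export
read_param_table <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("atom", "resname", "charge", "rmin2", "eps", "gbr", "screen")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("parameter table lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_param_table
#' @param params parameter data frame.
#' @param header optional character vector of comment lines (written with
#'   a leading `# `).
#' @export
write_param_table <- function(params, file, header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste(c("atom", "resname", "charge", "rmin2", "eps", "gbr", "screen"),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(params))) {
    writeLines(paste(c(params$atom[i], params$resname[i],
                       fmt_num(params$charge[i]), fmt_num(params$rmin2[i]),
                       fmt_num(params$eps[i]), fmt_num(params$gbr[i]),
                       fmt_num(params$screen[i])), collapse = "\t"), con)
  }
  invisible(file)
}

#' Attach nonbonded parameters to a structure
#'
#' Joins a parameter table onto an atom table by (atom name, residue name).
#' Every atom must match exactly one table row; unmatched atoms raise a
#' parameterization error listing them.
#'
#' @param atoms an `mt_structure` atom table or subsystem atom table.
#' @param params parameter data frame as from [read_param_table()].
#' @return the atom table with columns `charge`, `rmin2`, `eps`, `gbr`,
#'   `screen` filled in.
#' @export
parameterize <- function(atoms, params) {
  key_a <- paste(atoms$atom, atoms$resname, sep = "|")
  key_p <- paste(params$atom, params$resname, sep = "|")
  if (anyDuplicated(key_p)) stop("parameter table has duplicate (atom, resname) rows")
  idx <- match(key_a, key_p)
  if (anyNA(idx)) {
    bad <- unique(key_a[is.na(idx)])
    stop("parameterization error: no parameters for atoms: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L) else "")
  }
  for (col in c("charge", "rmin2", "eps", "gbr", "screen")) {
    atoms[[col]] <- params[[col]][idx]
  }
  atoms
}

has_parameters <- function(atoms) {
  all(c("charge", "rmin2", "eps", "gbr", "screen") %in% names(atoms))
}
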