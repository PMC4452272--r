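# Roll-up of per-subsystem residue tables to per-ring contributions:
# E_x = eps_x(R13 L'1) + sum_{k=1..12} eps_x(Rk Lk+1)   (lateral, seam included)
# E_x = sum_{k=1..13} eps_x(Rk L'k)                     (longitudinal)

#' Aggregate 13 subsystem tables into a per-ring energy table
#'
#' Sums the energetic contribution of every entity (residue, keyed on role,
#' subunit and residue number) over the subsystems of one interface class:
#' 12 laterals plus the seam, or 13 longitudinals. Residue sets may differ
#' between subsystems; missing entities contribute zero.
#'
#' @param tables list of `energy_table`s, one per subsystem (length
#'   `n_pf`, seam table last for the lateral class).
#' @param class `"lateral"` or `"longitudinal"`.
#' @param domain_map optional domain map (see [read_domain_map()]) used to
#'   label each residue with a domain; unmapped residues are labeled
#'   `"unassigned"`.
#' @return a `ring_energy_table`: per-entity summed components (with
#'   quadrature-propagated `sd_*` columns when the inputs carry them), plus
#'   attributes `per_subsystem` (data frame of per-subsystem totals, seam
#'   flagged), `totals`, and `class`.
#' @export
ring_aggregate <- function(tables, class = c("lateral", "longitudinal"),
                           domain_map = NULL) {
  class <- match.arg(class)
  if (!length(tables) || !all(vapply(tables, inherits, TRUE, "energy_table"))) {
    stop("missing subsystem table: need a list of energy_table objects")
  }
  comp <- c("E_vdW", "E_ele", "E_GB", "E_SA", "E_total")
  has_sd <- all(vapply(tables, function(t) all(paste0("sd_", comp) %in% names(t)), TRUE))
  keys <- unique(unlist(lapply(tables, function(t)
    paste(t$role, t$subunit, t$resno, sep = ":"))))
  acc <- matrix(0, length(keys), length(comp), dimnames = list(keys, comp))
  var_acc <- if (has_sd) acc else NULL
  meta <- NULL
  for (t in tables) {
    key <- paste(t$role, t$subunit, t$resno, sep = ":")
    i <- match(key, keys)
    for (cc in comp) acc[i, cc] <- acc[i, cc] + t[[cc]]
    if (has_sd) for (cc in comp) var_acc[i, cc] <- var_acc[i, cc] + t[[paste0("sd_", cc)]]^2
    m <- t[, c("role", "subunit", "resno", "resname")]
    meta <- if (is.null(meta)) m[!duplicated(key), ] else {
      new <- !(key %in% paste(meta$role, meta$subunit, meta$resno, sep = ":"))
      rbind(meta, m[new & !duplicated(key), ])
    }
  }
  mi <- match(keys, paste(meta$role, meta$subunit, meta$resno, sep = ":"))
  out <- data.frame(meta[mi, c("role", "subunit", "resno", "resname")],
                    acc, row.names = NULL, stringsAsFactors = FALSE)
  if (has_sd) for (cc in comp) out[[paste0("sd_", cc)]] <- sqrt(var_acc[, cc])
  out$domain <- if (!is.null(domain_map)) assign_domains(out, domain_map) else NA_character_
  out <- out[order(match(out$role, c("R", "L")),
                   match(out$subunit, c("alpha", "beta")), out$resno), ]
  rownames(out) <- NULL

  per_sub <- data.frame(
    k = vapply(tables, function(t) as.integer(attr(t, "k") %||% NA_integer_), 1L),
    kind = vapply(tables, function(t) as.character(attr(t, "kind") %||% NA_character_), ""),
    E_total = vapply(tables, function(t) unname(energy_totals(t)["E_total"]), 1),
    stringsAsFactors = FALSE
  )
  if (has_sd) {
    per_sub$sd_E_total <- vapply(tables, function(t)
      unname(attr(t, "totals_sd")["E_total"]), 1)
  }
  per_sub$is_seam <- per_sub$kind == "lateral_seam"
  totals <- colSums(acc)
  totals <- c(totals, E_vdW_SA = unname(totals["E_vdW"] + totals["E_SA"]),
              E_ele_GB = unname(totals["E_ele"] + totals["E_GB"]))
  structure(out, per_subsystem = per_sub, totals = totals, class_kind = class,
            class = c("ring_energy_table", "data.frame"))
}

#' @export
print.ring_energy_table <- function(x, ...) {
  tot <- attr(x, "totals")
  cat(sprintf("ring_energy_table (%s): %d entities, E_total = %.3f kcal/mol per ring\n",
              attr(x, "class_kind"), nrow(x), tot["E_total"]))
  invisible(x)
}

#' Domain-level aggregation of a ring energy table
#'
#' @param ring_table a `ring_energy_table` whose `domain` column is filled
#'   (pass a `domain_map` to [ring_aggregate()]), or any data frame with
#'   `domain` and component columns.
#' @param by grouping columns (default domain within subunit and role).
#' @return data frame of component sums per group.
#' @export
domain_table <- function(ring_table, by = c("role", "subunit", "domain")) {
  comp <- intersect(c("E_vdW", "E_ele", "E_GB", "E_SA", "E_total"), names(ring_table))
  dom <- ring_table$domain
  dom[is.na(dom)] <- "unassigned"
  grp <- interaction(as.data.frame(ring_table)[, by, drop = FALSE], drop = TRUE, sep = "/")
  out <- data.frame(group = levels(grp), stringsAsFactors = FALSE)
  for (cc in comp) out[[cc]] <- as.numeric(tapply(ring_table[[cc]], grp, sum))
  out
}

#' Ligand/receptor by subunit contribution matrix
#'
#' Builds the 2x2 matrix of per-ring contributions of each subunit in each
#' role (ligand L or receptor R), with row, column and grand margins. Cell
#' "L beta", for example, is the contribution of the beta subunit of the
#' dimer acting as ligand, summed over the ring.
#'
#' @param x a `ring_energy_table`, or a named numeric vector of the four
#'   cells with names `"L.beta"`, `"R.beta"`, `"L.alpha"`, `"R.alpha"`.
#' @param component which component to tabulate (default `"E_total"`).
#' @return a `subunit_matrix`: 3x3 numeric matrix with rows beta, alpha,
#'   total and columns L, R, total (kcal/mol per ring); when the input
#'   carries `sd_*` columns, a quadrature-propagated SD matrix is attached
#'   as attribute `"sd"`.
#' @export
subunit_matrix <- function(x, component = "E_total") {
  if (is.numeric(x) && !is.null(names(x))) {
    need <- c("L.beta", "R.beta", "L.alpha", "R.alpha")
    if (!all(need %in% names(x))) stop("role labels absent: need ", paste(need, collapse = ", "))
    cells <- matrix(x[need], 2, 2, byrow = TRUE,
                    dimnames = list(c("beta", "alpha"), c("L", "R")))
    sdc <- NULL
  } else {
    if (!all(c("role", "subunit") %in% names(x))) stop("role labels absent")
    cells <- matrix(0, 2, 2, dimnames = list(c("beta", "alpha"), c("L", "R")))
    sd_col <- paste0("sd_", component)
    sdc <- if (sd_col %in% names(x)) cells else NULL
    for (su in rownames(cells)) for (ro in colnames(cells)) {
      sel <- x$subunit == su & x$role == ro
      cells[su, ro] <- sum(x[[component]][sel])
      if (!is.null(sdc)) sdc[su, ro] <- sqrt(sum(x[[sd_col]][sel]^2))
    }
  }
  m <- rbind(cbind(cells, total = rowSums(cells)),
             total = c(colSums(cells), sum(cells)))
  if (!is.null(sdc)) {
    sm <- rbind(cbind(sdc, total = sqrt(rowSums(sdc^2))),
                total = c(sqrt(colSums(sdc^2)), sqrt(sum(sdc^2))))
    attr(m, "sd") <- sm
  }
  class(m) <- c("subunit_matrix", class(m))
  m
}

#' @export
print.subunit_matrix <- function(x, ...) {
  cat("subunit contribution matrix (kcal/mol per ring):\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Entity-wise difference between two models
#'
#' Component-wise `A - B` on matching entities; by convention A is the
#' GTP-state model and B the GDP-state model, so negative totals mean the
#' GTP state is more stable. Entities present in only one table are kept
#' (outer join) with a zero fill on the other side and flagged in the
#' `matched` column.
#'
#' @param table_a,table_b `ring_energy_table`s (or energy tables) sharing
#'   at least one entity.
#' @return data frame of per-entity component differences with attribute
#'   `totals` (difference of totals).
#' @export
model_difference <- function(table_a, table_b) {
  key_a <- paste(table_a$role, table_a$subunit, table_a$resno, sep = ":")
  key_b <- paste(table_b$role, table_b$subunit, table_b$resno, sep = ":")
  if (!length(intersect(key_a, key_b))) stop("entirely disjoint entity sets")
  keys <- union(key_a, key_b)
  comp <- intersect(c("E_vdW", "E_ele", "E_GB", "E_SA", "E_total"),
                    intersect(names(table_a), names(table_b)))
  ia <- match(keys, key_a); ib <- match(keys, key_b)
  meta_src <- ifelse(is.na(ia), ib + nrow(table_a), ia)
  meta <- rbind(as.data.frame(table_a)[, c("role", "subunit", "resno", "resname")],
                as.data.frame(table_b)[, c("role", "subunit", "resno", "resname")])
  out <- meta[meta_src, ]
  rownames(out) <- NULL
  for (cc in comp) {
    va <- ifelse(is.na(ia), 0, table_a[[cc]][ia])
    vb <- ifelse(is.na(ib), 0, table_b[[cc]][ib])
    out[[cc]] <- va - vb
  }
  out$matched <- !is.na(ia) & !is.na(ib)
  tot <- vapply(comp, function(cc) sum(out[[cc]]), 1)
  structure(out, totals = tot)
}

#' Ring energy diagram and weakest-interface report
#'
#' Orders the 13 per-subsystem interface energies around the ring, flags
#' the seam, and reports the weakest interface: the one of smallest energy
#' magnitude |E|. Ties (within `tol`) are reported as a tie set.
#'
#' @param per_subsystem data frame with columns `k`, `E_total` and
#'   optionally `is_seam` (as produced by [ring_aggregate()]), or a plain
#'   numeric vector of 13 totals (seam assumed last for a lateral class).
#' @param n_pf expected interface count (default 13).
#' @param tol magnitude tolerance for ties, kcal/mol.
#' @return list with `diagram` (ordered data frame), `weakest` (row
#'   indices of minimum |E|), `weakest_is_seam`, `tie` (logical).
#' @export
ring_diagram <- function(per_subsystem, n_pf = 13L, tol = 1e-9) {
  if (is.numeric(per_subsystem)) {
    per_subsystem <- data.frame(k = seq_along(per_subsystem),
                                E_total = as.numeric(per_subsystem),
                                is_seam = seq_along(per_subsystem) == length(per_subsystem))
  }
  if (nrow(per_subsystem) != n_pf) {
    stop(sprintf("wrong count: expected %d interface energies, got %d",
                 n_pf, nrow(per_subsystem)))
  }
  if (is.null(per_subsystem$is_seam)) per_subsystem$is_seam <- FALSE
  d <- per_subsystem[order(per_subsystem$k), ]
  rownames(d) <- NULL
  mag <- abs(d$E_total)
  wk <- which(mag <= min(mag) + tol)
  list(diagram = d, weakest = wk,
       weakest_is_seam = any(d$is_seam[wk]),
       tie = length(wk) > 1L)
}
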