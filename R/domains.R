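# Domain maps: (subunit, residue-number ranges) -> domain label, plus
# residue-name overrides for cofactors. The map is data, not code: it is
# read from an editable YAML config and the shipped default follows the
# standard tubulin secondary-structure nomenclature.

#' Read a domain map
#'
#' The YAML layout has one block per subunit mapping domain labels to lists
#' of inclusive residue-number ranges, plus an optional `resnames` block
#' mapping residue names (e.g. cofactors) directly to labels:
#' ```yaml
#' alpha:
#'   M-loop: [[272, 288]]
#'   H3 helix: [[108, 128]]
#' beta: { ... }
#' resnames: { GTP: cofactor, GDP: cofactor, MG: Mg2+ }
#' ```
#' Ranges must not overlap within a subunit; every residue maps to at most
#' one domain and unmapped residues aggregate under `"unassigned"`.
#'
#' @param file path to a YAML domain map; the default map bundled with the
#'   package is used when omitted.
#' @return a `domain_map` list.
#' @export
read_domain_map <- function(file = system.file("extdata", "tubulin_domains.yaml",
                                               package = "mtring")) {
  m <- yaml::read_yaml(file)
  validate_domain_map(m)
  structure(m, class = "domain_map")
}

validate_domain_map <- function(m) {
  for (su in intersect(names(m), c("alpha", "beta"))) {
    covered <- integer(0)
    for (dom in names(m[[su]])) {
      for (rg in m[[su]][[dom]]) {
        if (length(rg) != 2L || rg[1] > rg[2]) {
          stop(sprintf("bad range for %s/%s", su, dom))
        }
        span <- seq.int(rg[1], rg[2])
        if (length(intersect(span, covered))) {
          stop(sprintf("overlapping domain ranges in subunit %s at %s", su, dom))
        }
        covered <- c(covered, span)
      }
    }
  }
  invisible(m)
}

#' Assign domain labels to residues
#'
#' @param residues data frame with columns `subunit`, `resno` and
#'   optionally `resname` (residue-name overrides win over ranges).
#' @param map a `domain_map` from [read_domain_map()].
#' @return character vector of domain labels (`"unassigned"` when no rule
#'   matches).
#' @export
assign_domains <- function(residues, map) {
  out <- rep("unassigned", nrow(residues))
  for (su in intersect(names(map), c("alpha", "beta"))) {
    for (dom in names(map[[su]])) {
      for (rg in map[[su]][[dom]]) {
        hit <- residues$subunit == su & residues$resno >= rg[1] & residues$resno <= rg[2]
        out[hit] <- dom
      }
    }
  }
  if (!is.null(map$resnames) && !is.null(residues$resname)) {
    hit <- residues$resname %in% names(map$resnames)
    out[hit] <- unlist(map$resnames)[residues$resname[hit]]
  }
  out
}
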