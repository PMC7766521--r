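## The H/D thermodynamic binding cycle, affinity-unit conversions, ligand
## speciation, and per-residue decomposition bookkeeping.
##
## Sign conventions used throughout:
##   E_BIND = E_INTER - E_HYDR            (per isotope state)
##   dd(E_X) = E_X(D) - E_X(H)            (deuteration-induced change)
##   dd(E_BIND) = dd(E_INTER) - dd(E_HYDR)
## so a negative dd(E_BIND) means deuteration strengthens binding.

#' Thermodynamic parameters for affinity conversions
#'
#' @param temperature Kelvin (default 298.15)
#' @param gas_constant kcal/(mol K) (default 1.98720425e-3)
#' @return object of class `affinity_params`
#' @export
affinity_params <- function(temperature = 298.15,
                            gas_constant = 1.98720425e-3) {
  stopifnot(temperature > 0, gas_constant > 0)
  structure(list(temperature = temperature, gas_constant = gas_constant),
            class = "affinity_params")
}

#' Supermolecule complexation energy
#'
#' `E_complex - E_partA - E_partB`: the association energy of forming a
#' complex from its two parts, each energy in kcal/mol from any external
#' engine (or the package's surrogate score for demonstrations).
#'
#' @param e_complex,e_part_a,e_part_b component energies, kcal/mol
#' @return kcal/mol
#' @export
complexation_energy <- function(e_complex, e_part_a, e_part_b) {
  stopifnot(is.finite(e_complex), is.finite(e_part_a), is.finite(e_part_b))
  e_complex - e_part_a - e_part_b
}

#' Assemble the H/D thermodynamic binding cycle
#'
#' Takes the hydration and receptor-interaction energies for the protiated
#' (H) and deuterated (D) states and fills the full cycle: per-isotope
#' binding energies `E_BIND = E_INTER - E_HYDR`, and D-minus-H differences
#' `dd_hydr`, `dd_inter`, `dd_bind = dd_inter - dd_hydr`. A negative
#' `dd_bind` means increased affinity upon deuteration.
#'
#' @param hydr_H,hydr_D,inter_H,inter_D component energies, kcal/mol
#' @return object of class `CycleResult`: list with `hydr_H`, `hydr_D`,
#'   `inter_H`, `inter_D`, `bind_H`, `bind_D`, `dd_hydr`, `dd_inter`,
#'   `dd_bind`
#' @examples
#' cy <- assemble_cycle(hydr_H = -71.63, hydr_D = -71.20,
#'                      inter_H = -82.31, inter_D = -82.73)
#' cy$dd_bind
#' @export
assemble_cycle <- function(hydr_H, hydr_D, inter_H, inter_D) {
  comps <- list(hydr_H = hydr_H, hydr_D = hydr_D,
                inter_H = inter_H, inter_D = inter_D)
  for (nm in names(comps))
    if (is.null(comps[[nm]]) || length(comps[[nm]]) != 1L ||
        !is.finite(comps[[nm]]))
      stop("missing or non-finite cycle component: ", nm)
  bind_H <- inter_H - hydr_H
  bind_D <- inter_D - hydr_D
  structure(list(hydr_H = hydr_H, hydr_D = hydr_D,
                 inter_H = inter_H, inter_D = inter_D,
                 bind_H = bind_H, bind_D = bind_D,
                 dd_hydr = hydr_D - hydr_H,
                 dd_inter = inter_D - inter_H,
                 dd_bind = bind_D - bind_H),
            class = "CycleResult")
}

#' @export
print.CycleResult <- function(x, ...) {
  m <- matrix(c(x$hydr_H, x$inter_H, x$bind_H,
                x$hydr_D, x$inter_D, x$bind_D), nrow = 2L, byrow = TRUE,
              dimnames = list(c("H", "D"), c("E_HYDR", "E_INTER", "E_BIND")))
  print(round(m, 2))
  cat(sprintf("ddE_HYDR = %+.2f  ddE_INTER = %+.2f  ddE_BIND = %+.2f kcal/mol\n",
              x$dd_hydr, x$dd_inter, x$dd_bind))
  invisible(x)
}

#' Write a cycle report as delimited text
#' @param cycle a `CycleResult`
#' @param path output path (tab-separated; two-decimal report precision)
#' @return invisibly, `path`
#' @export
write_cycle_report <- function(cycle, path) {
  df <- data.frame(quantity = c("E_HYDR_H", "E_INTER_H", "E_BIND_H",
                                "E_HYDR_D", "E_INTER_D", "E_BIND_D",
                                "ddE_HYDR", "ddE_INTER", "ddE_BIND"),
                   kcal_mol = sprintf("%.2f", unlist(cycle[c(
                     "hydr_H", "inter_H", "bind_H",
                     "hydr_D", "inter_D", "bind_D",
                     "dd_hydr", "dd_inter", "dd_bind")])))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cycle component energies from delimited text
#'
#' Expects a header `component<TAB>isotope<TAB>energy_kcal_mol` with
#' components `hydr`/`inter` and isotopes `H`/`D`, and assembles the cycle.
#'
#' @param path TSV path
#' @return a `CycleResult`
#' @export
read_cycle_components <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("component", "isotope", "energy_kcal_mol")
  if (!all(need %in% names(df)))
    stop("component table needs columns: ", paste(need, collapse = ", "))
  pick <- function(comp, iso) {
    v <- df$energy_kcal_mol[df$component == comp & df$isotope == iso]
    if (length(v) != 1L)
      stop("missing cycle component: ", comp, " (", iso, ")")
    v
  }
  assemble_cycle(hydr_H = pick("hydr", "H"), hydr_D = pick("hydr", "D"),
                 inter_H = pick("inter", "H"), inter_D = pick("inter", "D"))
}

#' Binding free energy from pKi
#'
#' `dG = -RT ln(10) pKi` kcal/mol: pKi 4.3 at 298.15 K gives -5.87
#' (-5.9 at two significant figures).
#'
#' @param pki numeric pKi value(s)
#' @param params an [affinity_params]
#' @return kcal/mol
#' @export
dg_from_pki <- function(pki, params = affinity_params()) {
  -params$gas_constant * params$temperature * log(10) * pki
}

#' Relative binding free-energy shift from a pIC50 change
#'
#' The relative Cheng-Prusoff form: `ddG = -RT ln(10) (p2 - p1)`, so an
#' affinity increase (larger pIC50) maps to a negative ddG.
#'
#' @param p1,p2 pIC50 before and after (e.g. control and D2O)
#' @param params an [affinity_params]
#' @return kcal/mol
#' @export
ddg_from_pic50 <- function(p1, p2, params = affinity_params()) {
  -params$gas_constant * params$temperature * log(10) * (p2 - p1)
}

#' Monocation fraction under an independent-site protonation model
#'
#' The fraction of ligand with the aliphatic amine protonated AND the ring
#' imidazole neutral:
#' `f = 1/(1 + 10^(pH - pKa_amine)) * 1/(1 + 10^(pKa_ring - pH))`.
#' For histamine (pKa 6.0 ring, 9.7 amine) at pH 7.4 this gives 0.957,
#' i.e. 96 percent to the nearest percent.
#'
#' @param pH solution pH
#' @param pKa_ring imidazole pKa (default 6.0)
#' @param pKa_amine aliphatic amine pKa (default 9.7)
#' @return fraction in (0, 1)
#' @export
monocation_fraction <- function(pH, pKa_ring = 6.0, pKa_amine = 9.7) {
  1 / (1 + 10^(pH - pKa_amine)) * 1 / (1 + 10^(pKa_ring - pH))
}

#' Per-residue decomposition table
#'
#' @param residues character residue labels (e.g. `"Asp98"`)
#' @param contributions kcal/mol per residue
#' @param total total binding free energy, kcal/mol
#' @return object of class `DecompositionTable`
#' @export
decomposition_table <- function(residues, contributions, total) {
  stopifnot(length(residues) == length(contributions))
  df <- data.frame(residue = as.character(residues),
                   contribution = as.numeric(contributions),
                   stringsAsFactors = FALSE)
  attr(df, "total") <- total
  class(df) <- c("DecompositionTable", "data.frame")
  df
}

#' Read a per-residue decomposition table from delimited text
#'
#' Expects columns `residue` and `contribution_kcal_mol`; the total binding
#' free energy is taken from a `# total_kcal_mol:` header comment or the
#' `total` argument.
#'
#' @param path TSV path
#' @param total total binding free energy (overrides the file header)
#' @return a `DecompositionTable`
#' @export
read_decomposition <- function(path, total = NULL) {
  if (is.null(total)) {
    hdr <- grep("^#\\s*total_kcal_mol:", readLines(path, n = 5L), value = TRUE)
    if (length(hdr))
      total <- as.numeric(sub("^#\\s*total_kcal_mol:\\s*", "", hdr[1L]))
  }
  if (is.null(total)) stop("total binding energy not given and not in file")
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  decomposition_table(df$residue, df$contribution_kcal_mol, total)
}

#' Partition a decomposition table into favorable/unfavorable residues
#'
#' Favorable rows contribute at most `favorable` kcal/mol (inclusive);
#' unfavorable rows at least `unfavorable` (inclusive); the thresholds'
#' sign gap guarantees disjoint sets. Percentages are of the table total.
#'
#' @param tbl a `DecompositionTable`
#' @param favorable threshold, kcal/mol (default -0.06)
#' @param unfavorable threshold, kcal/mol (default +0.02)
#' @return list with `favorable` and `unfavorable` data.frames (sorted by
#'   contribution, with `percent_of_total`), `n_favorable`,
#'   `n_unfavorable`, `total`
#' @export
decompose_filter <- function(tbl, favorable = -0.06, unfavorable = 0.02) {
  stopifnot(inherits(tbl, "DecompositionTable"),
            favorable < 0, unfavorable > 0)
  total <- attr(tbl, "total")
  if (is.null(total) || total == 0)
    stop("percentages require a non-zero total binding energy")
  augment <- function(rows) {
    rows <- rows[order(rows$contribution), , drop = FALSE]
    rows$percent_of_total <- 100 * rows$contribution / total
    rownames(rows) <- NULL
    rows
  }
  fav <- augment(tbl[tbl$contribution <= favorable, , drop = FALSE])
  unf <- augment(tbl[tbl$contribution >= unfavorable, , drop = FALSE])
  list(favorable = fav, unfavorable = unf,
       n_favorable = nrow(fav), n_unfavorable = nrow(unf), total = total)
}
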