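## Exchangeable-site identification, the empirical bond-contraction
## transform emulating deuteration, and binding-site cluster / solvent-shell
## extraction.

#' Rule for identifying exchangeable (acidic) hydrogens
#'
#' Every hydrogen within `max_bond` of an N, O or S heavy atom is treated
#' as exchangeable: in D2O such protons swap with solvent deuterium
#' (threonine, the least acidic of the relevant side chains, is known to
#' exchange all of its hydroxyl protons).
#'
#' @param donor_elements subset of `c("N", "O", "S")`
#' @param max_bond maximum X-H bond length for detection, Angstrom
#'   (default 1.2)
#' @return object of class `exchange_rule`
#' @export
exchange_rule <- function(donor_elements = c("N", "O", "S"), max_bond = 1.2) {
  donor_elements <- match.arg(donor_elements, c("N", "O", "S"),
                              several.ok = TRUE)
  stopifnot(length(donor_elements) >= 1L, max_bond > 0)
  structure(list(donor_elements = donor_elements, max_bond = max_bond),
            class = "exchange_rule")
}

#' Find exchangeable X-H bonds
#'
#' Pairs every hydrogen with its nearest N/O/S heavy atom within the rule's
#' bond length; each hydrogen appears at most once. The output is sorted by
#' heavy-atom index (then hydrogen index) and is therefore invariant to the
#' input atom order up to that sorting.
#'
#' @param s a [Structure]
#' @param rule an [exchange_rule]
#' @return data.frame with columns `X` (heavy-atom index) and `H`
#' @examples
#' h <- build_histamine()
#' nrow(find_exchangeable(h))  # four N-H bonds on the monocation
#' @export
find_exchangeable <- function(s, rule = exchange_rule()) {
  stopifnot(inherits(s, "Structure"))
  hs <- which(s$atoms$element == "H")
  xs <- which(s$atoms$element %in% rule$donor_elements)
  if (!length(hs) || !length(xs))
    return(data.frame(X = integer(), H = integer()))
  out_x <- integer(0); out_h <- integer(0)
  xm <- s$coords[xs, , drop = FALSE]
  for (h in hs) {
    p <- s$coords[h, ]
    d <- sqrt((xm[, 1L] - p[1L])^2 + (xm[, 2L] - p[2L])^2 +
              (xm[, 3L] - p[3L])^2)
    within <- which(d <= rule$max_bond)
    if (!length(within)) next
    dmin <- min(d[within])
    near <- within[d[within] - dmin < 1e-6]
    if (length(near) > 1L)
      stop("malformed input: hydrogen ", h, " is equidistant (within 1e-6 A)",
           " to ", length(near), " candidate donors")
    out_x <- c(out_x, xs[near]); out_h <- c(out_h, h)
  }
  o <- order(out_x, out_h)
  data.frame(X = out_x[o], H = out_h[o])
}

#' Apply the empirical deuteration geometry transform
#'
#' Emulates the dominant nuclear quantum effect of H -> D substitution
#' (the Ubbelohde contraction) by moving each listed hydrogen along its
#' X -> H bond vector so that the new bond length is `(1 - fraction)` times
#' the original; heavy atoms are untouched. The default fraction 0.023
#' follows the neutron-diffraction result that deuteration reduces the
#' attraction in acidic N-D bonds by 2.3 percent. A constraint list
#' (atom index pair + target length) is emitted for downstream engines
#' that re-optimize with the deuterated bonds frozen.
#'
#' @param s a [Structure]
#' @param bonds data.frame/matrix of (X, H) index pairs, e.g. from
#'   [find_exchangeable]
#' @param fraction fractional shortening in \[0, 1)
#' @return object of class `DeuterationResult`: list with `structure`
#'   (transformed [Structure]), `constraints` (data.frame `X`, `H`,
#'   `length`), `fraction`
#' @export
apply_deuteration <- function(s, bonds = find_exchangeable(s),
                              fraction = 0.023) {
  stopifnot(inherits(s, "Structure"), fraction >= 0, fraction < 1)
  bonds <- as.data.frame(bonds)
  names(bonds)[1:2] <- c("X", "H")
  xyz <- s$coords
  lens <- numeric(nrow(bonds))
  for (i in seq_len(nrow(bonds))) {
    xi <- bonds$X[i]; hi <- bonds$H[i]
    v <- xyz[hi, ] - s$coords[xi, ]
    l0 <- vnorm(v)
    if (l0 < 1e-9) stop("zero-length bond between atoms ", xi, " and ", hi)
    xyz[hi, ] <- s$coords[xi, ] + (1 - fraction) * v
    lens[i] <- (1 - fraction) * l0
  }
  s$coords <- xyz
  structure(list(structure = s,
                 constraints = data.frame(X = bonds$X, H = bonds$H,
                                          length = lens),
                 fraction = fraction),
            class = "DeuterationResult")
}

#' @export
print.DeuterationResult <- function(x, ...) {
  cat("DeuterationResult:", nrow(x$constraints), "X-H bond(s) shortened by",
      x$fraction * 100, "percent\n")
  invisible(x)
}

#' Write a deuteration constraint list as delimited text
#'
#' Engine-agnostic triples: atom serial of the heavy atom, of the hydrogen,
#' and the frozen bond length in Angstrom.
#'
#' @param result a `DeuterationResult`
#' @param path output path (tab-separated)
#' @return invisibly, `path`
#' @export
write_constraints <- function(result, path) {
  utils::write.table(
    data.frame(serial_X = result$constraints$X,
               serial_H = result$constraints$H,
               length_A = sprintf("%.6f", result$constraints$length)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the binding-site residue cluster
#'
#' Keeps exactly the residues whose numbers fall in any of the given
#' inclusive ranges, plus the ligand residue(s), with coordinates
#' untouched. Idempotent for fixed ranges.
#'
#' @param complex a [Structure]
#' @param ranges list of length-2 vectors `c(first, last)` of residue
#'   numbers (e.g. `list(c(98, 103), c(186, 190), c(250, 254))`)
#' @param ligand_resname residue name(s) identifying the ligand
#'   (default `"HSM"`)
#' @return a [Structure]
#' @export
extract_cluster <- function(complex,
                            ranges = list(c(98, 103), c(186, 190), c(250, 254)),
                            ligand_resname = HISTAMINE_RESNAME) {
  stopifnot(inherits(complex, "Structure"), length(ranges) >= 1L)
  keep <- complex$atoms$resname %in% ligand_resname
  in_range <- rep(FALSE, nrow(complex$atoms))
  for (r in ranges) {
    stopifnot(length(r) == 2L)
    in_range <- in_range | (complex$atoms$resno >= r[1L] &
                            complex$atoms$resno <= r[2L] &
                            !keep)
  }
  if (!any(in_range))
    stop("no residues fall in the requested range(s)")
  sel <- keep | in_range
  Structure(complex$atoms[sel, , drop = FALSE],
            complex$coords[sel, , drop = FALSE])
}

#' Solvent-shell selection specification
#'
#' @param n_waters number of waters to retain (default 36)
#' @param cutoff maximum water-O to solute heavy-atom distance, Angstrom
#'   (default 4)
#' @param residue_ranges optional residue ranges passed through to cluster
#'   extraction in pipeline use
#' @return object of class `shell_spec`
#' @export
shell_spec <- function(n_waters = 36L, cutoff = 4.0, residue_ranges = NULL) {
  stopifnot(n_waters >= 0, cutoff > 0)
  structure(list(n_waters = as.integer(n_waters), cutoff = cutoff,
                 residue_ranges = residue_ranges), class = "shell_spec")
}

#' Select the nearest solvent shell around a solute
#'
#' Waters (residue name HOH/WAT/...) are ranked by the minimum distance
#' from their oxygen to any solute heavy atom; the nearest `n_waters` with
#' distance within `cutoff` are retained as whole molecules. Exact rank
#' ties are resolved towards the lower residue number. When fewer waters
#' than requested lie inside the cutoff, all of them are returned and the
#' result carries attribute `"shell_incomplete" = TRUE` with a warning.
#'
#' @param s a [Structure] containing the solute and waters
#' @param solute_sel integer indices of the solute atoms
#' @param spec a [shell_spec]
#' @return a [Structure] with the solute-shell waters appended to the
#'   non-water atoms in `solute_sel`'s structure order
#' @export
select_water_shell <- function(s, solute_sel, spec = shell_spec()) {
  stopifnot(inherits(s, "Structure"))
  is_water <- s$atoms$resname %in% standard_water_names
  if (!any(is_water)) stop("structure contains no waters (HOH/WAT)")
  solute_sel <- as.integer(solute_sel)
  heavy <- solute_sel[s$atoms$element[solute_sel] != "H"]
  hx <- s$coords[heavy, , drop = FALSE]
  ow <- which(is_water & s$atoms$name %in% c("O", "OW", "OH2"))
  wat_resno <- s$atoms$resno[ow]
  dmin <- vapply(seq_along(ow), function(i) {
    p <- s$coords[ow[i], ]
    min(sqrt((hx[, 1L] - p[1L])^2 + (hx[, 2L] - p[2L])^2 +
             (hx[, 3L] - p[3L])^2))
  }, numeric(1L))
  inside <- dmin <= spec$cutoff
  o <- order(dmin[inside], wat_resno[inside])
  chosen <- wat_resno[inside][o]
  incomplete <- length(chosen) < spec$n_waters
  if (incomplete)
    warning("only ", length(chosen), " of ", spec$n_waters,
            " requested waters lie within ", spec$cutoff, " A")
  chosen <- utils::head(chosen, spec$n_waters)
  keep <- !is_water | (s$atoms$resno %in% chosen)
  out <- Structure(s$atoms[keep, , drop = FALSE],
                   s$coords[keep, , drop = FALSE])
  attr(out, "shell_incomplete") <- incomplete
  attr(out, "shell_distances") <- stats::setNames(dmin, wat_resno)
  out
}
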