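## Conformer analytics: per-frame gauche/trans classification from the
## ethylamino torsion, population estimates with Wilson intervals, and
## k-medoids clustering in (|torsion|, N1-N2 distance) feature space.

#' Conformer classification thresholds
#'
#' Frames with |torsion| at most `gauche_max_abs_torsion` are gauche, at
#' least `trans_min_abs_torsion` trans, and intermediate otherwise, giving
#' an explicit band for the mixed structures rather than a forced binary.
#'
#' @param gauche_max_abs_torsion degrees (default 90)
#' @param trans_min_abs_torsion degrees (default 120)
#' @param hbond_flag_distance N1-N2 distance below which an intramolecular
#'   hydrogen bond is even considered, Angstrom (default 3.5)
#' @return object of class `conformer_thresholds`
#' @export
conformer_thresholds <- function(gauche_max_abs_torsion = 90,
                                 trans_min_abs_torsion = 120,
                                 hbond_flag_distance = 3.5) {
  if (gauche_max_abs_torsion >= trans_min_abs_torsion)
    stop("gauche_max_abs_torsion must be below trans_min_abs_torsion")
  structure(list(gauche_max_abs_torsion = gauche_max_abs_torsion,
                 trans_min_abs_torsion = trans_min_abs_torsion,
                 hbond_flag_distance = hbond_flag_distance),
            class = "conformer_thresholds")
}

#' Classify one conformation from its internal coordinates
#'
#' A pure function of the two geometric order parameters: the N1-N2
#' distance (Angstrom) and the ethylamino torsion (degrees; only the
#' magnitude is used, so the dihedral sign convention is immaterial).
#'
#' @param d_N1N2 N1..N2 distance, Angstrom (> 0)
#' @param torsion side-chain torsion, degrees
#' @param thresholds a [conformer_thresholds]
#' @return `"gauche"`, `"trans"` or `"intermediate"`
#' @examples
#' classify_conformer(4.54, 158.8)
#' classify_conformer(3.01, 62.1)
#' @export
classify_conformer <- function(d_N1N2, torsion,
                               thresholds = conformer_thresholds()) {
  if (any(d_N1N2 <= 0)) stop("d_N1N2 must be positive")
  at <- abs(torsion)
  ifelse(at <= thresholds$gauche_max_abs_torsion, "gauche",
         ifelse(at >= thresholds$trans_min_abs_torsion, "trans",
                "intermediate"))
}

#' Per-frame conformer series over a trajectory
#'
#' Measures the N1-N2 distance and the side-chain torsion for every frame,
#' classifies each frame, and flags frames where an intramolecular
#' N2-H...N1 hydrogen bond is geometrically present (N1-N2 distance within
#' the flag distance AND an N2 hydrogen pointing at N1 under `criteria`).
#'
#' @param traj a [Trajectory]
#' @param n1,n2 site strings resolving the ring imino and the aliphatic
#'   amine nitrogens (see [resolve_site])
#' @param torsion_atoms four site strings defining the classified torsion
#' @param thresholds a [conformer_thresholds]
#' @param criteria an [hbond_criteria] for the intramolecular flag
#' @return data.frame of class `ConformerSeries`: columns `frame`, `label`,
#'   `torsion` (signed degrees), `abs_torsion`, `d_N1N2`, `intra_hbond`
#' @export
conformer_series <- function(traj, n1 = "N1", n2 = "N2",
                             torsion_atoms = c("CG", "CB", "CA", "N2"),
                             thresholds = conformer_thresholds(),
                             criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "Trajectory"))
  topo <- traj$topology
  i1 <- resolve_site(topo, n1)
  i2 <- resolve_site(topo, n2)
  it <- vapply(torsion_atoms, function(a) resolve_site(topo, a), 1L)
  hs <- which(topo$atoms$element == "H")
  d2h <- sqrt(colSums((t(topo$coords[hs, , drop = FALSE]) - topo$coords[i2, ])^2))
  n2_h <- hs[d2h > 1e-6 & d2h <= 1.2]
  nf <- length(traj$frames)
  tor <- numeric(nf); d <- numeric(nf); flag <- logical(nf)
  for (f in seq_len(nf)) {
    xyz <- traj$frames[[f]]
    tor[f] <- measure(xyz, "dihedral", it)
    d[f] <- measure(xyz, "distance", c(i1, i2))
    if (d[f] <= thresholds$hbond_flag_distance && length(n2_h)) {
      ev <- detect_hbonds(xyz, cbind(i2, n2_h), i1, criteria)
      flag[f] <- nrow(ev) > 0L
    }
  }
  out <- data.frame(frame = seq_len(nf),
                    label = classify_conformer(d, tor, thresholds),
                    torsion = tor, abs_torsion = abs(tor), d_N1N2 = d,
                    intra_hbond = flag, stringsAsFactors = FALSE)
  class(out) <- c("ConformerSeries", "data.frame")
  out
}

wilson_halfwidth <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
}

#' Conformer state populations with Wilson confidence intervals
#'
#' @param series a `ConformerSeries` (or any data.frame with a `label`
#'   column), or a character vector of labels
#' @param conf confidence level for the Wilson interval (default 0.95)
#' @return data.frame of class `PopulationEstimate`: `label`, `count`,
#'   `fraction`, `ci_halfwidth`; attribute `n_frames`
#' @export
estimate_populations <- function(series, conf = 0.95) {
  labels <- if (is.character(series)) series else series$label
  n <- length(labels)
  if (n == 0L) stop("empty conformer series")
  lv <- c("gauche", "trans", "intermediate")
  lv <- c(intersect(lv, unique(labels)), setdiff(unique(labels), lv))
  counts <- as.integer(table(factor(labels, levels = lv)))
  p <- counts / n
  out <- data.frame(label = lv, count = counts, fraction = p,
                    ci_halfwidth = wilson_halfwidth(p, n, conf),
                    stringsAsFactors = FALSE)
  attr(out, "n_frames") <- n
  class(out) <- c("PopulationEstimate", "data.frame")
  out
}

## circular distance between two angles in degrees
ang_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' k-medoids clustering of conformer geometries
#'
#' Clusters frames in (|torsion|, N1-N2 distance) space. The torsion axis
#' uses circular angular distance; both axes are scaled by their sample
#' standard deviation. Medoid initialization is deterministic (global
#' medoid first, then farthest-point additions) and the medoid update
#' breaks ties by the lowest frame index, so the result is reproducible
#' bit-exactly; the `seed` argument is accepted for interface stability.
#'
#' @param series a `ConformerSeries` (needs `abs_torsion` and `d_N1N2`)
#' @param k number of clusters (1 <= k <= number of distinct points)
#' @param seed unused; kept for call-site compatibility
#' @return list of class `ConformerClusters`: `assignment` (frame ->
#'   cluster), `medoids` (frame indices), `populations` (fractions),
#'   `sizes`
#' @export
cluster_conformers <- function(series, k, seed = 1L) {
  stopifnot(k >= 1)
  x <- series$abs_torsion
  y <- series$d_N1N2
  n <- length(x)
  if (k > n) stop("k exceeds number of frames")
  if (k > nrow(unique(cbind(x, y)))) stop("k exceeds number of distinct points")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || sx < 1e-12) sx <- 1
  if (!is.finite(sy) || sy < 1e-12) sy <- 1
  D <- outer(x, x, ang_dist)^2 / sx^2 +
       outer(y, y, function(a, b) (a - b)^2) / sy^2
  D <- sqrt(D)
  ## deterministic maxmin initialization
  med <- which.min(rowSums(D))          # ties: which.min takes lowest index
  while (length(med) < k) {
    dmin <- apply(D[, med, drop = FALSE], 1L, min)
    med <- c(med, which.max(dmin))
  }
  assign <- apply(D[, med, drop = FALSE], 1L, which.min)
  for (iter in 1:100) {
    new_med <- vapply(seq_len(k), function(c) {
      members <- which(assign == c)
      if (!length(members)) return(med[c])
      members[which.min(rowSums(D[members, members, drop = FALSE]))]
    }, 1L)
    new_assign <- apply(D[, new_med, drop = FALSE], 1L, which.min)
    if (identical(new_med, med) && identical(new_assign, assign)) break
    med <- new_med; assign <- new_assign
  }
  sizes <- as.integer(table(factor(assign, levels = seq_len(k))))
  structure(list(assignment = assign, medoids = med,
                 populations = sizes / n, sizes = sizes),
            class = "ConformerClusters")
}

#' Write a conformer series as delimited text
#' @param series a `ConformerSeries`
#' @param path output path (tab-separated)
#' @return invisibly, `path`
#' @export
write_conformer_series <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
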