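## Solvation-structure analytics: radial distribution functions with
## finite-system edge handling, coordination numbers, geometric hydrogen-bond
## detection and contact occupancy/persistence statistics.

#' Geometric hydrogen-bond criteria
#'
#' The common geometric convention: donor-acceptor heavy-atom distance at
#' most `distance` Angstrom and donor-H...acceptor angle (at the hydrogen)
#' at least `angle` degrees. Both boundaries are inclusive.
#'
#' @param distance maximum D..A heavy-atom distance, Angstrom (default 3.5)
#' @param angle minimum D-H..A angle, degrees (default 135)
#' @return object of class `hbond_criteria`
#' @export
hbond_criteria <- function(distance = 3.5, angle = 135) {
  stopifnot(distance > 0, angle > 0, angle <= 180)
  structure(list(distance = distance, angle = angle), class = "hbond_criteria")
}

## region constructors -------------------------------------------------------

#' Rectangular analysis region
#' @param lo,hi length-3 numeric corners (Angstrom)
#' @return region object for [compute_rdf]
#' @export
rdf_region_box <- function(lo, hi) {
  stopifnot(length(lo) == 3L, length(hi) == 3L, all(hi > lo))
  structure(list(type = "box", lo = lo, hi = hi), class = "rdf_region")
}

#' Spherical (droplet) analysis region
#' @param center length-3 numeric (Angstrom)
#' @param radius sphere radius (Angstrom)
#' @return region object for [compute_rdf]
#' @export
rdf_region_sphere <- function(center, radius) {
  stopifnot(length(center) == 3L, radius > 0)
  structure(list(type = "sphere", center = center, radius = radius),
            class = "rdf_region")
}

## auto region: union of `probe`-radius spheres around the target atoms;
## volume by seeded Monte Carlo, then summarized as an effective sphere for
## the edge-distance bookkeeping
resolve_region <- function(region, target_xyz, seed) {
  if (is.null(region)) region <- structure(list(type = "auto", probe = 3.0),
                                           class = "rdf_region")
  if (region$type == "box") {
    region$volume <- prod(region$hi - region$lo)
    return(region)
  }
  if (region$type == "sphere") {
    region$volume <- 4 / 3 * pi * region$radius^3
    return(region)
  }
  probe <- region$probe
  lo <- apply(target_xyz, 2L, min) - probe
  hi <- apply(target_xyz, 2L, max) + probe
  vbox <- prod(hi - lo)
  nmc <- 1e5
  frac <- with_seed(seed, {
    pts <- cbind(stats::runif(nmc, lo[1L], hi[1L]),
                 stats::runif(nmc, lo[2L], hi[2L]),
                 stats::runif(nmc, lo[3L], hi[3L]))
    inside <- rep(FALSE, nmc)
    for (i in seq_len(nrow(target_xyz))) {
      di <- (pts[, 1L] - target_xyz[i, 1L])^2 +
            (pts[, 2L] - target_xyz[i, 2L])^2 +
            (pts[, 3L] - target_xyz[i, 3L])^2
      inside <- inside | di <= probe^2
    }
    mean(inside)
  })
  region$volume <- frac * vbox
  region$center <- colMeans(target_xyz)
  region$radius_eff <- (3 * region$volume / (4 * pi))^(1 / 3)
  region
}

region_boundary_dist <- function(region, p) {
  switch(region$type,
    box = min(p - region$lo, region$hi - p),
    sphere = region$radius - vnorm(p - region$center),
    auto = region$radius_eff - vnorm(p - region$center))
}

#' Radial distribution function g(r)
#'
#' Pair-distance histogram between a center selection and a target
#' selection, normalized by the target bulk density so that the ideal-gas
#' limit is 1. The system is a finite (non-periodic) box or droplet; to stay
#' unbiased near the boundary, a center contributes to a distance bin only
#' when the whole spherical shell around it fits inside the region
#' (per-bin valid-center exclusion). Bins with no valid center are `NA`.
#'
#' @param traj a [Trajectory] or single [Structure]
#' @param centers,targets integer atom-index vectors (non-empty)
#' @param r_max histogram range, Angstrom (default 10)
#' @param dr bin width, Angstrom (default 0.05)
#' @param region an [rdf_region_box]/[rdf_region_sphere], or `NULL` for an
#'   automatic droplet envelope (union of 3 Angstrom spheres around the
#'   targets, volume by seeded Monte Carlo with 1e5 samples)
#' @param seed seed for the Monte Carlo volume estimate
#' @return object of class `RDFProfile`: list with `edges`, `r` (bin
#'   midpoints), `g`, `counts`, `n_valid`, `density` (targets/A^3),
#'   `n_frames`
#' @export
compute_rdf <- function(traj, centers, targets, r_max = 10, dr = 0.05,
                        region = NULL, seed = 1L) {
  if (inherits(traj, "Structure")) traj <- Trajectory(traj, list(traj$coords))
  stopifnot(inherits(traj, "Trajectory"), dr > 0, r_max > dr)
  if (length(traj$frames) == 0L) stop("trajectory has zero frames")
  centers <- as.integer(centers); targets <- as.integer(targets)
  if (!length(centers) || !length(targets))
    stop("empty center or target selection")
  edges <- seq(0, r_max, by = dr)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  n_valid <- numeric(nb)
  region <- resolve_region(region, traj$frames[[1L]][targets, , drop = FALSE],
                           seed)
  for (f in traj$frames) {
    tx <- f[targets, , drop = FALSE]
    for (ci in centers) {
      p <- f[ci, ]
      keep <- targets != ci
      d <- sqrt((tx[keep, 1L] - p[1L])^2 + (tx[keep, 2L] - p[2L])^2 +
                (tx[keep, 3L] - p[3L])^2)
      bd <- region_boundary_dist(region, p)
      bmax <- min(nb, floor(bd / dr + 1e-12))
      if (bmax < 1L) next
      n_valid[seq_len(bmax)] <- n_valid[seq_len(bmax)] + 1
      d <- d[d < edges[bmax + 1L] & d >= 0]
      if (length(d)) {
        b <- findInterval(d, edges, rightmost.closed = TRUE)
        tb <- tabulate(b, nbins = nb)
        counts <- counts + tb
      }
    }
  }
  rho <- length(targets) / region$volume
  vshell <- 4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  g <- counts / (n_valid * rho * vshell)
  g[n_valid == 0] <- NA_real_
  structure(list(edges = edges, r = (edges[-1L] + edges[-length(edges)]) / 2,
                 g = g, counts = counts, n_valid = n_valid, density = rho,
                 n_frames = length(traj$frames), region = region),
            class = "RDFProfile")
}

#' @export
print.RDFProfile <- function(x, ...) {
  cat("RDFProfile:", length(x$g), "bins to", max(x$edges), "A, density",
      signif(x$density, 4), "targets/A^3,", x$n_frames, "frame(s)\n")
  invisible(x)
}

#' Running coordination number from an RDF
#'
#' N(r_cut) = rho * integral_0^r_cut g(r) 4 pi r^2 dr, integrated by the
#' trapezoid rule on the profile's bin midpoints; equals the direct mean
#' neighbor count within `r_cut` up to discretization error.
#'
#' @param p an `RDFProfile`
#' @param r_cut integration cutoff, Angstrom (must not exceed the profile
#'   range)
#' @return numeric scalar, mean number of target neighbors within `r_cut`
#' @export
coordination_number <- function(p, r_cut) {
  stopifnot(inherits(p, "RDFProfile"))
  if (r_cut > max(p$edges) + 1e-9) stop("r_cut exceeds profile range")
  if (r_cut <= 0) return(0)
  keep <- p$r <= r_cut
  g <- p$g[keep]; r <- p$r[keep]
  if (anyNA(g)) stop("g(r) undefined (no valid centers) below r_cut")
  r <- c(0, r); y <- c(0, p$density * g * 4 * pi * r[-1L]^2)
  if (r_cut > max(r)) {
    gl <- g[length(g)]
    r <- c(r, r_cut); y <- c(y, p$density * gl * 4 * pi * r_cut^2)
  }
  sum(diff(r) * (y[-1L] + y[-length(y)]) / 2)
}

## donors detected from the structure: every H within 1.2 A of an N/O/S
auto_donors <- function(s) {
  pairs <- find_exchangeable(s, exchange_rule())
  data.frame(D = pairs$X, H = pairs$H)
}

#' Detect hydrogen bonds in one frame
#'
#' An event is recorded for every (donor D-H, acceptor A) combination with
#' d(D, A) at most the criteria distance and the D-H..A angle (at the
#' hydrogen) at least the criteria angle; both boundaries inclusive.
#' Self pairs (A equal to D or to H) are excluded. The result is a pure
#' function of the frame coordinates.
#'
#' @param s a [Structure] (or bare coordinate matrix)
#' @param donors two-column matrix or data.frame of (D, H) atom indices;
#'   every H must lie within 1.2 Angstrom of its D
#' @param acceptors integer vector of acceptor heavy-atom indices
#' @param criteria an [hbond_criteria]
#' @return data.frame with columns `donor`, `h`, `acceptor`, `d_DA`
#'   (Angstrom), `angle` (degrees); zero rows when nothing is bonded
#' @export
detect_hbonds <- function(s, donors, acceptors, criteria = hbond_criteria()) {
  xyz <- if (inherits(s, "Structure")) s$coords else as.matrix(s)
  donors <- as.matrix(as.data.frame(donors))
  if (ncol(donors) != 2L) stop("donors must have two columns (D, H)")
  acceptors <- as.integer(acceptors)
  out <- list()
  for (i in seq_len(nrow(donors))) {
    di <- unname(as.integer(donors[i, 1L]))
    hi <- unname(as.integer(donors[i, 2L]))
    dvec <- xyz[di, ]; hvec <- xyz[hi, ]
    if (vnorm(hvec - dvec) > 1.2)
      stop("topology error: hydrogen ", hi, " is not bonded to donor ", di,
           " (d > 1.2 A)")
    acc <- acceptors[acceptors != di & acceptors != hi]
    if (!length(acc)) next
    ax <- xyz[acc, , drop = FALSE]
    dda <- sqrt((ax[, 1L] - dvec[1L])^2 + (ax[, 2L] - dvec[2L])^2 +
                (ax[, 3L] - dvec[3L])^2)
    hd <- dvec - hvec
    ha1 <- ax[, 1L] - hvec[1L]; ha2 <- ax[, 2L] - hvec[2L]; ha3 <- ax[, 3L] - hvec[3L]
    nha <- sqrt(ha1^2 + ha2^2 + ha3^2)
    cth <- (ha1 * hd[1L] + ha2 * hd[2L] + ha3 * hd[3L]) / (nha * vnorm(hd))
    ang <- acos(pmax(-1, pmin(1, cth))) * 180 / pi
    hit <- which(dda <= criteria$distance & ang >= criteria$angle)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(donor = di, h = hi,
                                            acceptor = unname(acc[hit]),
                                            d_DA = unname(dda[hit]),
                                            angle = unname(ang[hit]))
  }
  if (!length(out))
    return(data.frame(donor = integer(), h = integer(), acceptor = integer(),
                      d_DA = numeric(), angle = numeric()))
  do.call(rbind, out)
}

atom_label <- function(s, i) {
  paste0(s$atoms$resname[i], s$atoms$resno[i], ":", s$atoms$name[i])
}

#' Hydrogen-bond occupancy and persistence statistics over a trajectory
#'
#' For every (donor heavy atom, acceptor) pair observed bonded in at least
#' one frame (or listed in `pairs`), reports the occupancy (bonded-frame
#' fraction), and the mean heavy-atom distance over the bonded frames.
#' Per donor heavy atom, reports the mean number of simultaneous hydrogen
#' bonds per frame (zero frames included in the mean).
#'
#' @param traj a [Trajectory]
#' @param donors two-column (D, H) index matrix; defaults to every H bonded
#'   to an N/O/S heavy atom in the topology
#' @param acceptors acceptor heavy-atom indices; defaults to all N/O/S
#' @param criteria an [hbond_criteria]
#' @param pairs optional two-column (donor, acceptor) matrix restricting the
#'   report to those contacts (reported even at zero occupancy)
#' @return object of class `OccupancyStats`: list with `pairs` (data.frame
#'   `donor`, `acceptor`, labels, `occupancy`, `mean_dist`) and `donors`
#'   (data.frame `donor`, label, `mean_count`), plus `n_frames`
#' @export
occupancy_stats <- function(traj, donors = NULL, acceptors = NULL,
                            criteria = hbond_criteria(), pairs = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  nf <- length(traj$frames)
  if (nf == 0L) stop("empty trajectory")
  topo <- traj$topology
  if (is.null(donors)) donors <- auto_donors(topo)
  donors <- as.matrix(as.data.frame(donors))
  if (is.null(acceptors))
    acceptors <- which(topo$atoms$element %in% c("N", "O", "S"))
  key <- character(0)
  cnt <- numeric(0); dsum <- numeric(0)
  dheavy <- unique(donors[, 1L])
  dcount <- stats::setNames(numeric(length(dheavy)), dheavy)
  for (f in seq_len(nf)) {
    ev <- detect_hbonds(traj$frames[[f]], donors, acceptors, criteria)
    if (nrow(ev)) {
      ## a donor-acceptor pair counts once per frame even if two hydrogens
      ## of the same donor qualify
      pairkey <- paste(ev$donor, ev$acceptor)
      first <- !duplicated(pairkey)
      for (j in which(first)) {
        k <- pairkey[j]
        at <- match(k, key)
        if (is.na(at)) {
          key <- c(key, k); cnt <- c(cnt, 0); dsum <- c(dsum, 0)
          at <- length(key)
        }
        cnt[at] <- cnt[at] + 1
        dsum[at] <- dsum[at] + ev$d_DA[j]
      }
      tb <- table(factor(ev$donor[first], levels = dheavy))
      dcount <- dcount + as.numeric(tb)
    }
  }
  if (!is.null(pairs)) {
    pairs <- as.matrix(as.data.frame(pairs))
    want <- paste(pairs[, 1L], pairs[, 2L])
    add <- setdiff(want, key)
    if (length(add)) {
      key <- c(key, add); cnt <- c(cnt, numeric(length(add)))
      dsum <- c(dsum, numeric(length(add)))
    }
    sel <- match(want, key)
    key <- key[sel]; cnt <- cnt[sel]; dsum <- dsum[sel]
  }
  ij <- do.call(rbind, lapply(strsplit(key, " "), as.integer))
  pairs_df <- if (length(key)) {
    data.frame(donor = ij[, 1L], acceptor = ij[, 2L],
               donor_label = atom_label(topo, ij[, 1L]),
               acceptor_label = atom_label(topo, ij[, 2L]),
               occupancy = cnt / nf,
               mean_dist = ifelse(cnt > 0, dsum / pmax(cnt, 1), NA_real_),
               stringsAsFactors = FALSE)
  } else {
    data.frame(donor = integer(), acceptor = integer(),
               donor_label = character(), acceptor_label = character(),
               occupancy = numeric(), mean_dist = numeric())
  }
  donors_df <- data.frame(donor = as.integer(names(dcount)),
                          donor_label = atom_label(topo, as.integer(names(dcount))),
                          mean_count = as.numeric(dcount) / nf,
                          stringsAsFactors = FALSE)
  structure(list(pairs = pairs_df, donors = donors_df, n_frames = nf),
            class = "OccupancyStats")
}

#' @export
print.OccupancyStats <- function(x, ...) {
  cat("OccupancyStats over", x$n_frames, "frames:",
      nrow(x$pairs), "contact pair(s)\n")
  if (nrow(x$pairs)) print(x$pairs[, c("donor_label", "acceptor_label",
                                       "occupancy", "mean_dist")])
  invisible(x)
}
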