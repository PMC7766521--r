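## Synthetic generators emulating the statistical structure of the MD systems
## (solvated histamine, binding-pocket cluster, conformer/occupancy schedules)
## so that every downstream analysis stage is testable without MD or QM runs.

HISTAMINE_RESNAME <- "HSM"
## ring-CB rotamer fixed so that the requested CG-CB-CA-N2 torsion reproduces
## the gauche/trans N1..N2 distance regimes (3.0 A at 62 deg, 4.4 A at 159 deg)
HISTAMINE_CHI1 <- -60

#' Rigid three-site water template
#'
#' O-H 0.9572 Angstrom, H-O-H 104.52 degrees (standard rigid 3-site geometry),
#' oxygen at the origin with the H-O-H bisector along +x.
#' @return a [Structure] of one `HOH` residue
#' @export
water_template <- function() {
  half <- 104.52 / 2 * pi / 180
  xyz <- rbind(c(0, 0, 0),
               0.9572 * c(cos(half), sin(half), 0),
               0.9572 * c(cos(half), -sin(half), 0))
  atoms <- data.frame(name = c("O", "H1", "H2"), resname = "HOH",
                      resno = 1L, chain = "W", stringsAsFactors = FALSE)
  Structure(atoms, xyz)
}

## place a rigid water with O at `o` and the H-O-H bisector along unit
## vector `away` (H atoms point towards `away`); `perp` fixes the molecular
## plane.
place_water <- function(o, away, perp, resno) {
  away <- unitv(away)
  p <- perp - sum(perp * away) * away
  if (vnorm(p) < 1e-8) {
    ref <- if (abs(away[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p <- ref - sum(ref * away) * away
  }
  p <- unitv(p)
  half <- 104.52 / 2 * pi / 180
  h1 <- o + 0.9572 * (cos(half) * away + sin(half) * p)
  h2 <- o + 0.9572 * (cos(half) * away - sin(half) * p)
  atoms <- data.frame(name = c("O", "H1", "H2"), resname = "HOH",
                      resno = as.integer(resno), chain = "W",
                      stringsAsFactors = FALSE)
  Structure(atoms, rbind(o, h1, h2))
}

append_structures <- function(a, b) {
  Structure(rbind(a$atoms, b$atoms), rbind(a$coords, b$coords))
}

#' Idealized histamine monocation builder
#'
#' Constructs histamine from an internal-coordinate template (standard bond
#' lengths and angles, planar imidazole ring) with the ethylamino side-chain
#' torsion CG-CB-CA-N2 set exactly to `side_torsion`. Nitrogen atoms are
#' named by their functional roles: `N1` (ring imino nitrogen, hydrogen-bond
#' acceptor), `N2` (aliphatic amine, protonated in the monocation), `N3`
#' (ring amino nitrogen). The tautomer argument selects which ring nitrogen
#' carries the ring hydrogen: `"Ntau"` (tele, on N3; the dominant form in
#' water) or `"Npi"` (pros, on N1).
#'
#' @param tau_tautomer `"Ntau"` or `"Npi"`
#' @param protonated logical; `TRUE` gives the +1 cation with three N2-H
#'   bonds (18 atoms), `FALSE` the neutral amine (17 atoms)
#' @param side_torsion ethylamino torsion in degrees, in (-180, 180]
#' @return a [Structure] (residue `HSM`)
#' @examples
#' h <- build_histamine(side_torsion = 62.1)
#' measure(h, "distance", c(resolve_site(h, "N1"), resolve_site(h, "N2")))
#' @export
build_histamine <- function(tau_tautomer = c("Ntau", "Npi"), protonated = TRUE,
                            side_torsion = 158.8) {
  tau_tautomer <- match.arg(tau_tautomer)
  if (!(side_torsion > -180 && side_torsion <= 180) || !is.finite(side_torsion))
    stop("side_torsion must lie in (-180, 180]")
  rr <- 1.37 / (2 * sin(pi / 5))
  ringang <- (0:4) * 72 * pi / 180
  ring <- lapply(ringang, function(a) rr * c(cos(a), sin(a), 0))
  names(ring) <- c("CG", "N1", "CE1", "N3", "CD2")
  CG <- ring$CG; N1 <- ring$N1; CE1 <- ring$CE1; N3 <- ring$N3; CD2 <- ring$CD2
  CB <- CG + 1.50 * unitv(CG)
  CA <- place_internal(N1, CG, CB, 1.53, 114, HISTAMINE_CHI1)
  N2 <- place_internal(CG, CB, CA, 1.49, 111, side_torsion)
  HE1 <- CE1 + 1.08 * unitv(CE1)
  HD2 <- CD2 + 1.08 * unitv(CD2)
  ring_h_pos <- if (tau_tautomer == "Ntau") N3 + 1.01 * unitv(N3) else N1 + 1.01 * unitv(N1)
  ring_h_name <- if (tau_tautomer == "Ntau") "HN3" else "HN1"
  HB1 <- place_internal(N1, CG, CB, 1.09, 109.5, HISTAMINE_CHI1 + 120)
  HB2 <- place_internal(N1, CG, CB, 1.09, 109.5, HISTAMINE_CHI1 - 120)
  HA1 <- place_internal(CG, CB, CA, 1.09, 109.5, side_torsion + 120)
  HA2 <- place_internal(CG, CB, CA, 1.09, 109.5, side_torsion - 120)
  hn2_phi <- if (protonated) c(60, 180, -60) else c(60, 180)
  hn2 <- lapply(hn2_phi, function(p) place_internal(CB, CA, N2, 1.01, 109.5, p))
  nm <- c("CG", "N1", "CE1", "N3", "CD2", "CB", "CA", "N2",
          "HE1", "HD2", ring_h_name, "HB1", "HB2", "HA1", "HA2",
          paste0("HN2", seq_along(hn2)))
  xyz <- rbind(CG, N1, CE1, N3, CD2, CB, CA, N2, HE1, HD2, ring_h_pos,
               HB1, HB2, HA1, HA2, do.call(rbind, hn2))
  atoms <- data.frame(name = nm, resname = HISTAMINE_RESNAME, resno = 1L,
                      chain = "A", stringsAsFactors = FALSE)
  Structure(atoms, xyz)
}

## atoms that swing with the CG-CB-CA-N2 torsion (everything bonded to CA
## off the CB-CA axis, with the amine hydrogens)
histamine_rotating_names <- c("N2", "HA1", "HA2", "HN21", "HN22", "HN23")

#' Set the histamine side-chain torsion of a conformation in place
#'
#' Rotates the terminal amine group (and the CA hydrogens) about the CB-CA
#' axis so that the CG-CB-CA-N2 torsion equals `target` exactly.
#'
#' @param s a [Structure] carrying histamine atom names (CG, CB, CA, N2)
#' @param target torsion in degrees
#' @return the modified [Structure]
#' @export
set_side_torsion <- function(s, target) {
  i_cg <- resolve_site(s, paste0(HISTAMINE_RESNAME, "1:CG"))
  i_cb <- resolve_site(s, paste0(HISTAMINE_RESNAME, "1:CB"))
  i_ca <- resolve_site(s, paste0(HISTAMINE_RESNAME, "1:CA"))
  i_n2 <- resolve_site(s, paste0(HISTAMINE_RESNAME, "1:N2"))
  cur <- measure(s, "dihedral", c(i_cg, i_cb, i_ca, i_n2))
  delta <- (target - cur) * pi / 180
  rot <- which(s$atoms$resname == HISTAMINE_RESNAME &
               s$atoms$name %in% histamine_rotating_names)
  axis <- s$coords[i_ca, ] - s$coords[i_cb, ]
  new <- s$coords
  new[rot, ] <- rotate_about_axis(s$coords[rot, , drop = FALSE],
                                  s$coords[i_ca, ], axis, delta)
  chk <- measure(new, "dihedral", c(i_cg, i_cb, i_ca, i_n2))
  if (abs(((chk - target + 180) %% 360) - 180) > 1e-6) {
    new <- s$coords
    new[rot, ] <- rotate_about_axis(s$coords[rot, , drop = FALSE],
                                    s$coords[i_ca, ], axis, -delta)
  }
  s$coords <- new
  s
}

#' Specification for a synthetic solvent shell or box
#'
#' @param n_water number of waters to place (>= 0)
#' @param geometry `"sphere"` (droplet around the solute centroid) or `"box"`
#' @param radius sphere radius in Angstrom; derived from `bulk_density` when
#'   `NULL`
#' @param edge box edge in Angstrom; derived from `bulk_density` when `NULL`
#' @param bulk_density waters per cubic Angstrom (default 0.0334, liquid water)
#' @param placed_contacts list of `list(site = <site string>, dist = <A>)`
#'   entries pinning one water oxygen at an exact distance from a solute site
#' @return object of class `solvation_spec`
#' @export
solvation_spec <- function(n_water, geometry = c("sphere", "box"),
                           radius = NULL, edge = NULL, bulk_density = 0.0334,
                           placed_contacts = list()) {
  geometry <- match.arg(geometry)
  stopifnot(n_water >= 0, bulk_density > 0)
  if (length(placed_contacts) > n_water)
    stop("more placed contacts than waters")
  structure(list(n_water = as.integer(n_water), geometry = geometry,
                 radius = radius, edge = edge, bulk_density = bulk_density,
                 placed_contacts = placed_contacts),
            class = "solvation_spec")
}

#' Solvate a solute with rigid 3-site waters
#'
#' Placed contacts are satisfied exactly (oxygen on the donor-H direction of
#' the named site, or on the outward radial direction for acceptor-only
#' sites); remaining waters are drawn uniformly over the region, rejecting
#' any heavy-atom pair closer than 2.4 Angstrom.
#'
#' @param solute a [Structure]
#' @param spec a [solvation_spec]
#' @param seed integer seed (placement is bit-reproducible given spec + seed)
#' @return a [Structure] with the solute followed by `HOH` residues; the
#'   attribute `"contact_waters"` maps placed-contact sites to water residue
#'   numbers
#' @export
solvate <- function(solute, spec, seed = 1L) {
  stopifnot(inherits(solute, "Structure"), inherits(spec, "solvation_spec"))
  if (spec$n_water == 0L) return(solute)
  center <- colMeans(solute$coords)
  radius <- spec$radius %||% (3 * spec$n_water / (4 * pi * spec$bulk_density))^(1 / 3)
  edge <- spec$edge %||% (spec$n_water / spec$bulk_density)^(1 / 3)
  heavy <- solute$coords[solute$atoms$element != "H", , drop = FALSE]
  out <- solute
  next_resno <- max(solute$atoms$resno) + 1L
  contact_log <- data.frame(site = character(), resno = integer(),
                            dist = numeric(), stringsAsFactors = FALSE)
  used_h <- integer(0)
  with_seed(seed, {
    for (pc in spec$placed_contacts) {
      i <- resolve_site(solute, pc$site)
      p <- solute$coords[i, ]
      hs <- which(solute$atoms$element == "H")
      dh <- sqrt(colSums((t(solute$coords[hs, , drop = FALSE]) - p)^2))
      ## contacts sharing a donor site consume successive hydrogens
      hnear <- setdiff(hs[dh > 1e-6 & dh <= 1.2], used_h)
      if (length(hnear)) {
        used_h <- c(used_h, hnear[1L])
        u <- unitv(solute$coords[hnear[1L], ] - p)
        o <- p + pc$dist * u
        w <- place_water(o, u, stats::rnorm(3L), next_resno)   # acceptor water
      } else {
        u <- if (vnorm(p - center) > 1e-6) unitv(p - center) else c(1, 0, 0)
        o <- p + pc$dist * u
        w <- place_water(o, -u, stats::rnorm(3L), next_resno)  # donor water
      }
      out <- append_structures(out, w)
      heavy <- rbind(heavy, o)
      contact_log <- rbind(contact_log,
                           data.frame(site = pc$site, resno = next_resno,
                                      dist = pc$dist, stringsAsFactors = FALSE))
      next_resno <- next_resno + 1L
    }
    n_bulk <- spec$n_water - length(spec$placed_contacts)
    tries <- 0L; max_tries <- max(2000L, 500L * n_bulk)
    placed <- 0L
    while (placed < n_bulk) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("packing error: placed ", placed, " of ", n_bulk,
             " bulk waters after ", max_tries, " attempts")
      o <- if (spec$geometry == "sphere") {
        center + radius * stats::runif(1L)^(1 / 3) *
          unitv(stats::rnorm(3L))
      } else {
        center + stats::runif(3L, -edge / 2, edge / 2)
      }
      if (min(sqrt(colSums((t(heavy) - o)^2))) < 2.4) next
      w <- place_water(o, unitv(stats::rnorm(3L)), stats::rnorm(3L), next_resno)
      out <- append_structures(out, w)
      heavy <- rbind(heavy, o)
      next_resno <- next_resno + 1L
      placed <- placed + 1L
    }
  })
  attr(out, "contact_waters") <- contact_log
  out
}

#' Specification for a synthetic trajectory
#'
#' @param n_frames number of frames (>= 1)
#' @param state_populations named fractions over `c("gauche", "trans")`
#'   summing to 1, or `NULL` to leave the side-chain torsion untouched
#' @param jitter_sigma Gaussian positional noise applied to every atom, in
#'   Angstrom
#' @param hbond_occupancy list of `list(donor = <site>, acceptor = <site>,
#'   occupancy = <fraction>)` contact schedules; the acceptor's water
#'   molecule (or the acceptor atom, for non-water sites) is toggled between
#'   a bonded (2.8 A) and a broken (5.0 A) position with the requested
#'   marginal frequency
#' @param seed integer seed; all draws flow from this one generator
#' @return object of class `trajectory_spec`
#' @export
trajectory_spec <- function(n_frames, state_populations = c(trans = 0.73, gauche = 0.27),
                            jitter_sigma = 0.01, hbond_occupancy = list(),
                            seed = 1L) {
  stopifnot(n_frames >= 1, jitter_sigma >= 0)
  if (!is.null(state_populations)) {
    if (is.null(names(state_populations)) ||
        !all(names(state_populations) %in% c("gauche", "trans")))
      stop("state_populations labels must be in {gauche, trans}")
    if (any(state_populations < 0 | state_populations > 1) ||
        abs(sum(state_populations) - 1) > 1e-9)
      stop("state_populations must be fractions in [0,1] summing to 1")
  }
  for (e in hbond_occupancy)
    if (is.null(e$donor) || is.null(e$acceptor) || is.null(e$occupancy) ||
        e$occupancy < 0 || e$occupancy > 1)
      stop("each hbond_occupancy entry needs donor, acceptor, occupancy in [0,1]")
  structure(list(n_frames = as.integer(n_frames),
                 state_populations = state_populations,
                 jitter_sigma = jitter_sigma,
                 hbond_occupancy = hbond_occupancy,
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

## torsion sampling windows straddling the representative gauche (62.1) and
## trans (158.8) geometries
GAUCHE_RANGE <- c(40, 90)
TRANS_RANGE <- c(140, 180)

#' Generate a synthetic trajectory with prescribed statistics
#'
#' Frames are drawn i.i.d.: a conformer state per frame from
#' `state_populations` (gauche torsions uniform in 40-90 degrees, trans in
#' 140-180), hydrogen-bond contacts realized as independent Bernoulli draws
#' at the requested marginal occupancy, then Gaussian positional jitter on
#' all atoms. The drawn state labels, torsions and contact schedule are kept
#' as attributes (`"states"`, `"torsions"`, `"occupancy_schedule"`) so that
#' estimator-recovery tests can compare against the generating truth.
#'
#' @param base a [Structure]; must carry the histamine site names when
#'   `state_populations` is used, and the named donor/acceptor sites for
#'   each contact schedule
#' @param spec a [trajectory_spec]
#' @return a [Trajectory]
#' @export
synth_trajectory <- function(base, spec) {
  stopifnot(inherits(base, "Structure"), inherits(spec, "trajectory_spec"))
  pops <- spec$state_populations
  contacts <- lapply(spec$hbond_occupancy, function(e) {
    di <- tryCatch(resolve_site(base, e$donor),
                   error = function(err) stop("unknown site name: ", e$donor))
    ai <- tryCatch(resolve_site(base, e$acceptor),
                   error = function(err) stop("unknown site name: ", e$acceptor))
    list(donor = di, acceptor = ai, occupancy = e$occupancy)
  })
  ## assign one donor hydrogen per contact; contacts sharing a donor heavy
  ## atom consume successive hydrogens
  used <- integer(0)
  for (k in seq_along(contacts)) {
    di <- contacts[[k]]$donor
    p <- base$coords[di, ]
    hs <- which(base$atoms$element == "H")
    dh <- sqrt(colSums((t(base$coords[hs, , drop = FALSE]) - p)^2))
    cand <- setdiff(hs[dh > 1e-6 & dh <= 1.2], used)
    if (!length(cand))
      stop("donor site ", base$atoms$name[di], " has no free hydrogen")
    contacts[[k]]$h <- cand[1L]
    used <- c(used, cand[1L])
    ## mobile set: whole water residue, or the lone acceptor atom
    ai <- contacts[[k]]$acceptor
    contacts[[k]]$mobile <-
      if (base$atoms$resname[ai] %in% standard_water_names)
        which(base$atoms$resno == base$atoms$resno[ai] &
              base$atoms$chain == base$atoms$chain[ai])
      else ai
  }
  n <- spec$n_frames
  na <- nrow(base$coords)
  with_seed(spec$seed, {
    states <- if (is.null(pops)) rep(NA_character_, n)
              else sample(names(pops), n, replace = TRUE, prob = pops)
    torsions <- rep(NA_real_, n)
    if (!is.null(pops)) {
      g <- states == "gauche"
      torsions[g] <- stats::runif(sum(g), GAUCHE_RANGE[1L], GAUCHE_RANGE[2L])
      torsions[!g] <- stats::runif(sum(!g), TRANS_RANGE[1L], TRANS_RANGE[2L])
    }
    sched <- matrix(FALSE, n, length(contacts))
    for (k in seq_along(contacts))
      sched[, k] <- stats::runif(n) < contacts[[k]]$occupancy
    frames <- vector("list", n)
    work <- base
    for (f in seq_len(n)) {
      work$coords <- base$coords
      if (!is.null(pops)) work <- set_side_torsion(work, torsions[f])
      for (k in seq_along(contacts)) {
        ct <- contacts[[k]]
        u <- unitv(work$coords[ct$h, ] - work$coords[ct$donor, ])
        d <- if (sched[f, k]) 2.8 else 5.0
        target <- work$coords[ct$donor, ] + d * u
        shift <- target - work$coords[ct$acceptor, ]
        work$coords[ct$mobile, ] <-
          sweep(work$coords[ct$mobile, , drop = FALSE], 2L, shift, "+")
      }
      frames[[f]] <- work$coords +
        matrix(stats::rnorm(3L * na, 0, spec$jitter_sigma), na, 3L)
    }
  })
  traj <- Trajectory(base, frames)
  attr(traj, "states") <- states
  attr(traj, "torsions") <- torsions
  if (length(contacts)) {
    colnames(sched) <- vapply(spec$hbond_occupancy, function(e)
      paste(e$donor, e$acceptor, sep = "->"), "")
    attr(traj, "occupancy_schedule") <- sched
  }
  traj
}

## ---- binding-pocket cluster model ---------------------------------------

pocket_residues <- data.frame(
  resno = c(98L, 99L, 100L, 101L, 102L, 103L,
            186L, 187L, 188L, 189L, 190L,
            250L, 251L, 252L, 253L, 254L),
  resname = c("ASP", "VAL", "MET", "LEU", "CYS", "THR",
              "ASP", "GLY", "LEU", "VAL", "THR",
              "TYR", "PHE", "THR", "ALA", "PHE"),
  stringsAsFactors = FALSE)

sidechain_stub_names <- list(
  ASP = c("CB", "CG", "OD1", "OD2"),
  VAL = c("CB", "CG1", "CG2"),
  MET = c("CB", "CG", "SD", "CE"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  CYS = c("CB", "SG", "HG"),
  THR = c("CB", "OG1", "HG1", "CG2"),
  GLY = character(0),
  TYR = c("CB", "CG", "OH", "HH"),
  PHE = c("CB", "CG", "CD1"),
  ALA = c("CB"))

## lay out a residue stub as a mildly zig-zagged chain of heavy atoms
## starting at `anchor` and growing along `dir`; hydrogen names bind to the
## immediately preceding heavy atom at bonded distance (1.15 A off sulfur,
## 0.96 A otherwise) so exchangeable-site detection sees real X-H bonds
residue_chain <- function(names, resname, resno, anchor, dir, perp,
                          spacing = 1.45) {
  dir <- unitv(dir)
  p <- perp - sum(perp * dir) * dir
  if (vnorm(p) < 1e-8) {
    ref <- if (abs(dir[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p <- ref - sum(ref * dir) * dir
  }
  p <- unitv(p)
  xyz <- matrix(0, length(names), 3L)
  step <- 0L
  prev_heavy <- anchor
  prev_name <- ""
  for (i in seq_along(names)) {
    if (startsWith(names[i], "H") && i > 1L) {
      blen <- if (startsWith(prev_name, "S")) 1.15 else 0.96
      xyz[i, ] <- prev_heavy + blen * unitv(p + 0.35 * dir)
    } else {
      xyz[i, ] <- anchor + step * spacing * dir + 0.6 * (step %% 2L) * p
      prev_heavy <- xyz[i, ]
      prev_name <- names[i]
      step <- step + 1L
    }
  }
  atoms <- data.frame(name = names, resname = resname, resno = as.integer(resno),
                      chain = "R", stringsAsFactors = FALSE)
  Structure(atoms, xyz)
}

#' Toy 16-residue binding-pocket complex
#'
#' Builds a synthetic cluster model of the receptor binding site around a
#' histamine-like ligand: residues Asp98, Val99, Met100, Leu101, Cys102,
#' Thr103, Asp186, Gly187, Leu188, Val189, Thr190, Tyr250, Phe251, Thr252,
#' Ala253 and Phe254 as idealized side-chain stubs (minimal backbone plus
#' the functionally relevant side-chain atoms). The anionic anchor geometry
#' is built in exactly: one Asp98 carboxylate oxygen accepts an N2-H
#' hydrogen bond at 2.8 Angstrom, Tyr250's hydroxyl donates to the other
#' carboxylate oxygen, and Thr190's hydroxyl donates to the Asp186 backbone
#' carbonyl at 2.76 Angstrom. Remaining residues are scattered on a shell
#' with clash exclusion. Purely synthetic; not a homology model.
#'
#' @param ligand a [Structure] built by [build_histamine] (or any structure
#'   carrying the histamine site names)
#' @param seed integer seed for the scattered placements
#' @return a [Structure]: ligand atoms first, then 16 receptor residues on
#'   chain `"R"`
#' @export
make_pocket_complex <- function(ligand, seed = 1L) {
  stopifnot(inherits(ligand, "Structure"))
  cen <- colMeans(ligand$coords)
  n2 <- ligand$coords[resolve_site(ligand, "N2"), ]
  h21 <- ligand$coords[resolve_site(ligand, "HN21"), ]
  n3 <- ligand$coords[resolve_site(ligand, "N3"), ]
  out <- ligand

  u <- unitv(h21 - n2)
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  pq <- unitv(ref - sum(ref * u) * u)

  ## Asp98: OD1 accepts from N2-H at exactly 2.8 A; OD2 offered to Tyr250
  od1 <- n2 + 2.8 * u
  cg98 <- od1 + 1.30 * unitv(u + 0.35 * pq)
  w <- unitv(u + 1.3 * pq)
  od2 <- cg98 + 1.30 * w
  asp98_rest <- residue_chain(c("CB", "CA", "N", "C", "O"), "ASP", 98L,
                              cg98 + 1.50 * u, u, pq)
  asp98 <- Structure(
    rbind(data.frame(name = c("OD1", "CG", "OD2"), resname = "ASP",
                     resno = 98L, chain = "R", stringsAsFactors = FALSE),
          asp98_rest$atoms[, c("name", "resname", "resno", "chain")]),
    rbind(od1, cg98, od2, asp98_rest$coords))
  out <- append_structures(out, asp98)

  ## Tyr250: hydroxyl donates to Asp98 OD2 (O..O 2.8, H on the axis)
  wout <- unitv(od2 - cen)
  oh <- od2 + 2.8 * wout
  hh <- oh + 0.96 * unitv(od2 - oh)
  tyr_rest <- residue_chain(c("CG", "CB", "CA", "N", "C", "O"), "TYR", 250L,
                            oh + 1.40 * wout, wout, pq)
  tyr250 <- Structure(
    rbind(data.frame(name = c("OH", "HH"), resname = "TYR", resno = 250L,
                     chain = "R", stringsAsFactors = FALSE),
          tyr_rest$atoms[, c("name", "resname", "resno", "chain")]),
    rbind(oh, hh, tyr_rest$coords))
  out <- append_structures(out, tyr250)

  ## Thr190 hydroxyl donating to the Asp186 backbone carbonyl (2.76 A)
  v <- unitv(unitv(n3 - cen) + 0.8 * cross3(u, pq))
  og1 <- cen + 5.5 * v
  hg1 <- og1 + 0.96 * v
  o186 <- og1 + 2.76 * v
  q190 <- unitv(cross3(v, pq))
  thr_rest <- residue_chain(c("CB", "CG2", "CA", "N", "C", "O"), "THR", 190L,
                            og1 + 1.43 * q190, q190 + 0.3 * v, u)
  thr190 <- Structure(
    rbind(data.frame(name = c("OG1", "HG1"), resname = "THR", resno = 190L,
                     chain = "R", stringsAsFactors = FALSE),
          thr_rest$atoms[, c("name", "resname", "resno", "chain")]),
    rbind(og1, hg1, thr_rest$coords))
  out <- append_structures(out, thr190)
  asp186_rest <- residue_chain(c("C", "CA", "N", "CB", "CG", "OD1", "OD2"),
                               "ASP", 186L, o186 + 1.23 * v, v, pq)
  asp186 <- Structure(
    rbind(data.frame(name = "O", resname = "ASP", resno = 186L, chain = "R",
                     stringsAsFactors = FALSE),
          asp186_rest$atoms[, c("name", "resname", "resno", "chain")]),
    rbind(matrix(o186, 1L), asp186_rest$coords))
  out <- append_structures(out, asp186)

  ## remaining residues scattered on a 7 A shell with clash exclusion
  rest <- pocket_residues[!pocket_residues$resno %in% c(98L, 186L, 190L, 250L), ]
  with_seed(seed, {
    for (i in seq_len(nrow(rest))) {
      rn <- rest$resname[i]; rno <- rest$resno[i]
      names_i <- c("N", "CA", "C", "O", sidechain_stub_names[[rn]])
      ok <- FALSE
      for (try in 1:500) {
        dir <- unitv(stats::rnorm(3L))
        anchor <- cen + 7.0 * dir
        cand <- residue_chain(names_i, rn, rno, anchor, dir, stats::rnorm(3L))
        dmin <- min(as.matrix(stats::dist(rbind(out$coords, cand$coords)))[
          seq_len(nrow(out$coords)), nrow(out$coords) + seq_len(nrow(cand$coords))])
        if (dmin >= 2.2) { ok <- TRUE; break }
      }
      if (!ok) stop("packing error: could not place residue ", rn, rno)
      out <- append_structures(out, cand)
    }
  })
  out
}

## reference X-H bond lengths (Angstrom) used by the surrogate's isotope
## sensitivity; matching the generators' construction values
XH_REFERENCE <- c(N = 1.01, O = 0.96, S = 1.15)

#' Deterministic surrogate interaction score
#'
#' A stand-in energy for demonstration and end-to-end pipeline runs: the sum
#' over all detected hydrogen bonds of a Gaussian distance well,
#' `-5 * exp(-((d - 2.9)/0.3)^2)` kcal/mol per bond. The well is evaluated
#' at the effective donor-acceptor distance
#' `d = d(D, A) + (l_ref(D) - d(D, H))`: a donor bond contracted below its
#' reference length (as after the deuteration transform) acts as an
#' elongated effective heteroatom separation, which is the Ubbelohde
#' response the surrogate is meant to exhibit. For bonds at their reference
#' length the correction vanishes and the well is the plain heavy-atom
#' distance well. This is a geometric score internal to this package -- it
#' is NOT a quantum-chemical or force-field energy, and pipeline reports
#' label it as a surrogate.
#'
#' @param s a [Structure]
#' @param criteria hydrogen-bond geometry criteria ([hbond_criteria])
#' @return numeric scalar, kcal/mol (0 when no hydrogen bond is present)
#' @export
surrogate_energy <- function(s, criteria = hbond_criteria()) {
  stopifnot(inherits(s, "Structure"))
  don <- auto_donors(s)
  acc <- which(s$atoms$element %in% c("N", "O", "S"))
  if (nrow(don) == 0L || length(acc) == 0L) return(0)
  ev <- detect_hbonds(s, donors = don, acceptors = acc, criteria = criteria)
  if (nrow(ev) == 0L) return(0)
  dxh <- sqrt(rowSums((s$coords[ev$donor, , drop = FALSE] -
                       s$coords[ev$h, , drop = FALSE])^2))
  lref <- XH_REFERENCE[s$atoms$element[ev$donor]]
  deff <- ev$d_DA + (lref - dxh)
  sum(-5 * exp(-((deff - 2.9) / 0.3)^2))
}
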