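## shared fixtures, all generated in code

## uniform ideal-gas trajectory in a cubic box
gas_trajectory <- function(n = 800, box = 30, n_frames = 3, seed = 42) {
  atoms <- data.frame(name = "N", resname = "GAS", resno = seq_len(n),
                      chain = "A", stringsAsFactors = FALSE)
  frames <- deutbind:::with_seed(seed, lapply(seq_len(n_frames), function(i)
    matrix(stats::runif(3 * n, 0, box), n, 3)))
  Trajectory(Structure(atoms, frames[[1]]), frames)
}

## histamine in a small droplet with three pinned N2 contacts
solvated_fixture <- function(n_water = 8, radius = 7, seed = 3) {
  h <- build_histamine(side_torsion = 158.8)
  contacts <- list(list(site = "N2", dist = 2.8),
                   list(site = "N2", dist = 2.8),
                   list(site = "N2", dist = 2.8))
  solvate(h, solvation_spec(n_water, "sphere", radius = radius,
                            placed_contacts = contacts), seed = seed)
}

## four points with a known dihedral built by explicit rotation about the
## central bond (independent of the package's internal-coordinate builder)
dihedral_fixture <- function(phi_deg) {
  p1 <- c(-1, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  p4_ref <- c(2, 1, 0)                       # phi = 0 (cis) reference
  phi <- phi_deg * pi / 180
  R <- matrix(c(1, 0, 0,
                0, cos(phi), -sin(phi),
                0, sin(phi), cos(phi)), 3, 3, byrow = TRUE)
  ## a right-hand rotation of the far substituent by +phi about the
  ## central-bond direction (+x here) yields a dihedral of +phi in the
  ## standard convention (checked against Biopython and bio3d)
  p4 <- as.numeric(R %*% (p4_ref - p3)) + p3
  rbind(p1, p2, p3, p4)
}

random_rigid_motion <- function(xyz, seed = 1) {
  deutbind:::with_seed(seed, {
    ax <- deutbind:::unitv(stats::rnorm(3))
    th <- stats::runif(1, 0, 2 * pi)
    shift <- stats::rnorm(3, sd = 10)
  })
  R <- deutbind:::rotation_matrix(ax, th)
  sweep(xyz %*% t(R), 2, shift, "+")
}
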