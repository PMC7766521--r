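test_that("histamine builder hits the requested torsion and conformer regimes", {
  tors_of <- function(s) measure(s, "dihedral",
    c(resolve_site(s, "CG"), resolve_site(s, "CB"),
      resolve_site(s, "CA"), resolve_site(s, "N2")))
  d_of <- function(s) measure(s, "distance",
    c(resolve_site(s, "N1"), resolve_site(s, "N2")))

  trans <- build_histamine(side_torsion = 158.8)
  expect_equal(tors_of(trans), 158.8, tolerance = 1e-6)
  expect_gt(d_of(trans), 4)

  gauche <- build_histamine(side_torsion = 62.1)
  expect_equal(tors_of(gauche), 62.1, tolerance = 1e-6)
  expect_lt(d_of(gauche), 3.6)

  ## protonation state and formula: C5H10N3+ has 18 atoms, neutral 17
  expect_equal(nrow(trans$atoms), 18)
  expect_equal(sum(trans$atoms$element == "C"), 5)
  expect_equal(sum(trans$atoms$element == "N"), 3)
  expect_equal(sum(trans$atoms$element == "H"), 10)
  expect_equal(nrow(build_histamine(protonated = FALSE)$atoms), 17)

  ## exactly four detectable N-H bonds on the monocation
  fx <- find_exchangeable(trans)
  expect_equal(nrow(fx), 4)
  expect_true(all(trans$atoms$element[fx$X] == "N"))

  ## Npi tautomer puts the ring hydrogen on N1
  npi <- build_histamine("Npi")
  expect_equal(sum(npi$atoms$name == "HN1"), 1)
  expect_error(build_histamine(side_torsion = 200), "-180")
})

test_that("set_side_torsion rotates only the terminal group, exactly", {
  h <- build_histamine(side_torsion = 158.8)
  h2 <- set_side_torsion(h, -47.25)
  tors <- measure(h2, "dihedral",
                  c(resolve_site(h2, "CG"), resolve_site(h2, "CB"),
                    resolve_site(h2, "CA"), resolve_site(h2, "N2")))
  expect_equal(tors, -47.25, tolerance = 1e-9)
  fixed <- !(h$atoms$name %in% deutbind:::histamine_rotating_names)
  expect_identical(h2$coords[fixed, ], h$coords[fixed, ])
})

test_that("solvate packs rigid waters inside the region without clashes", {
  h <- build_histamine()
  s <- solvate(h, solvation_spec(36, "sphere", radius = 6), seed = 1)
  expect_equal(sum(s$atoms$resname == "HOH") / 3, 36)
  cen <- colMeans(h$coords)
  ow <- select_atoms(s, resname = "HOH", name = "O")
  expect_true(all(sqrt(colSums((t(s$coords[ow, ]) - cen)^2)) <= 6))

  ## rigid 3-site geometry
  for (rn in s$atoms$resno[ow][1:5]) {
    at <- select_atoms(s, resno = rn, resname = "HOH")
    expect_equal(measure(s, "distance", at[1:2]), 0.9572, tolerance = 1e-9)
    expect_equal(measure(s, "distance", at[c(1, 3)]), 0.9572, tolerance = 1e-9)
    expect_equal(measure(s, "angle", at[c(2, 1, 3)]), 104.52, tolerance = 1e-6)
  }

  ## no water oxygen within 2.4 A of any other heavy atom
  heavy <- which(s$atoms$element != "H")
  solute_heavy <- heavy[heavy <= nrow(h$atoms)]
  for (o in ow) {
    others <- setdiff(c(solute_heavy, ow), o)
    d <- sqrt(colSums((t(s$coords[others, ]) - s$coords[o, ])^2))
    expect_gte(min(d), 2.4)
  }
})

test_that("solvate honours placed contacts, the empty case, and the seed", {
  h <- build_histamine()
  spec <- solvation_spec(5, "sphere", radius = 7,
                         placed_contacts = list(list(site = "N2", dist = 2.8)))
  s <- solvate(h, spec, seed = 2)
  cw <- attr(s, "contact_waters")
  o <- select_atoms(s, resno = cw$resno[1], name = "O")
  expect_equal(measure(s, "distance", c(resolve_site(s, "N2"), o)), 2.8,
               tolerance = 0.05)

  expect_identical(solvate(h, solvation_spec(0, "sphere", radius = 5)), h)
  expect_identical(solvate(h, spec, seed = 2)$coords, s$coords)
  expect_false(identical(solvate(h, spec, seed = 3)$coords, s$coords))
  expect_error(solvation_spec(1, placed_contacts = list(list(), list())),
               "more placed contacts")
  ## impossible packing densities fail loudly
  expect_error(solvate(h, solvation_spec(250, "sphere", radius = 5), seed = 1),
               "packing")
})

test_that("synthetic trajectories realize populations, occupancy and jitter", {
  s <- solvated_fixture(n_water = 8, seed = 3)
  cw <- attr(s, "contact_waters")
  spec <- trajectory_spec(
    800, state_populations = c(trans = 0.73, gauche = 0.27),
    jitter_sigma = 0.01,
    hbond_occupancy = list(
      list(donor = "N2", acceptor = paste0("HOH", cw$resno[1], ":O"),
           occupancy = 0.92)),
    seed = 11)
  traj <- synth_trajectory(s, spec)
  expect_equal(length(traj$frames), 800)

  states <- attr(traj, "states")
  expect_lt(abs(mean(states == "trans") - 0.73), 0.05)
  tors <- attr(traj, "torsions")
  expect_true(all(tors[states == "gauche"] >= 40 &
                  tors[states == "gauche"] <= 90))
  expect_true(all(tors[states == "trans"] >= 140 &
                  tors[states == "trans"] <= 180))

  ## realized contact geometry follows the drawn schedule exactly
  sched <- attr(traj, "occupancy_schedule")[, 1]
  n2 <- resolve_site(s, "N2")
  o <- select_atoms(s, resno = cw$resno[1], name = "O")
  d <- vapply(traj$frames, function(f) measure(f, "distance", c(n2, o)),
              numeric(1))
  expect_true(all(abs(d[sched] - 2.8) < 0.1))
  expect_true(all(abs(d[!sched] - 5.0) < 0.1))
  expect_lt(abs(mean(sched) - 0.92), 0.03)

  ## bit-reproducible given (spec, seed); different under another seed
  traj2 <- synth_trajectory(s, spec)
  expect_identical(traj$frames, traj2$frames)
  spec2 <- spec; spec2$seed <- 12L
  expect_false(identical(synth_trajectory(s, spec2)$frames, traj$frames))

  expect_error(synth_trajectory(s, trajectory_spec(
    5, hbond_occupancy = list(list(donor = "NOPE", acceptor = "N2",
                                   occupancy = 0.5)))),
    "unknown site")
  expect_error(trajectory_spec(10, c(trans = 0.6, gauche = 0.3)),
               "summing to 1")
  expect_error(trajectory_spec(10, c(cis = 1)), "gauche")
})

test_that("pure-state trajectories classify as generated", {
  h <- build_histamine()
  traj <- synth_trajectory(h, trajectory_spec(
    40, state_populations = c(gauche = 1.0), seed = 5))
  ser <- conformer_series(traj)
  expect_true(all(ser$label == "gauche"))
})

test_that("the pocket complex realizes the designed anchor geometry", {
  h <- build_histamine(side_torsion = 158.8)
  p <- make_pocket_complex(h, seed = 1)

  rec <- unique(p$atoms$resno[p$atoms$chain == "R"])
  expect_equal(length(rec), 16)
  expect_setequal(rec, c(98:103, 186:190, 250:254))

  d <- measure(p, "distance", c(resolve_site(p, "ASP98:OD1"),
                                resolve_site(p, "N2")))
  expect_equal(d, 2.8, tolerance = 0.1)

  ## Tyr250 hydroxyl donates to the second Asp98 carboxylate oxygen
  ev <- detect_hbonds(p, deutbind:::auto_donors(p),
                      which(p$atoms$element %in% c("N", "O", "S")))
  lab <- function(i) paste0(p$atoms$resname[i], p$atoms$resno[i], ":",
                            p$atoms$name[i])
  found <- paste(lab(ev$donor), lab(ev$acceptor))
  expect_true("TYR250:OH ASP98:OD2" %in% found)
  expect_true("THR190:OG1 ASP186:O" %in% found)
  expect_true("HSM1:N2 ASP98:OD1" %in% found)
})

test_that("the surrogate score has the designed well and isotope response", {
  ## no hydrogen bonds -> exactly zero
  expect_equal(surrogate_energy(build_histamine()), 0)

  ## single ideal bond at the well minimum -> exactly -5
  one <- Structure(data.frame(name = c("N", "H1", "O"),
                              resname = c("AMM", "AMM", "HOH"),
                              resno = c(1, 1, 2), chain = "A"),
                   rbind(c(0, 0, 0), c(1.01, 0, 0), c(2.9, 0, 0)))
  expect_equal(surrogate_energy(one), -5)

  ## deuteration changes the score through the Ubbelohde response
  p <- make_pocket_complex(build_histamine(), seed = 1)
  eH <- surrogate_energy(p)
  eD <- surrogate_energy(apply_deuteration(p)$structure)
  expect_lt(eH, 0)
  expect_gt(abs(eD - eH), 1e-3)
})
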