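test_that("hydrogen-bond detection applies inclusive geometric criteria", {
  ## O-H...O linear at 2.8 A
  lin <- Structure(data.frame(name = c("O", "H1", "O"),
                              resname = c("HOH", "HOH", "HOH"),
                              resno = c(1, 1, 2), chain = "W"),
                   rbind(c(0, 0, 0), c(0.9572, 0, 0), c(2.8, 0, 0)))
  ev <- detect_hbonds(lin, cbind(1, 2), 3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$d_DA, 2.8)
  expect_equal(ev$angle, 180)

  ## beyond the distance criterion
  far <- lin; far$coords[3, 1] <- 4.0
  expect_equal(nrow(detect_hbonds(far, cbind(1, 2), 3)), 0)

  ## boundaries are closed: criteria set to exactly the measured geometry
  ## still yield the event
  th <- 45 * pi / 180
  brd <- lin
  hx <- brd$coords[2, ]
  dir <- c(cos(th), sin(th), 0)   # from H, 135 deg away from H->D (-x)
  ## acceptor on that ray, exactly at d(D, A) = 3.5 (quadratic root)
  hd <- sum(hx * dir)
  tpos <- -hd + sqrt(hd^2 - sum(hx^2) + 3.5^2)
  brd$coords[3, ] <- hx + tpos * dir
  d_meas <- measure(brd$coords, "distance", c(1, 3))
  a_meas <- measure(brd$coords, "angle", c(1, 2, 3))
  expect_equal(d_meas, 3.5, tolerance = 1e-12)
  expect_equal(a_meas, 135, tolerance = 1e-9)
  ev2 <- detect_hbonds(brd, cbind(1, 2), 3,
                       hbond_criteria(distance = d_meas, angle = a_meas))
  expect_equal(nrow(ev2), 1)

  ## a slightly sharper angle or longer distance fails
  expect_equal(nrow(detect_hbonds(brd, cbind(1, 2), 3,
                                  hbond_criteria(distance = d_meas - 1e-9,
                                                 angle = a_meas))), 0)
  expect_equal(nrow(detect_hbonds(brd, cbind(1, 2), 3,
                                  hbond_criteria(distance = d_meas,
                                                 angle = a_meas + 1e-6))),
               0)

  ## misassigned hydrogen is a topology error; self-pairs excluded
  expect_error(detect_hbonds(lin, cbind(3, 2), 1), "topology error")
  expect_equal(nrow(detect_hbonds(lin, cbind(1, 2), c(1, 2))), 0)
})

test_that("detection is a pure per-frame function, invariant to rigid motion", {
  s <- solvated_fixture(n_water = 6)
  don <- deutbind:::auto_donors(s)
  acc <- which(s$atoms$element %in% c("N", "O", "S"))
  ev <- detect_hbonds(s, don, acc)
  moved <- random_rigid_motion(s$coords, seed = 9)
  ev2 <- detect_hbonds(moved, don, acc)
  expect_equal(ev$donor, ev2$donor)
  expect_equal(ev$acceptor, ev2$acceptor)
  expect_equal(ev$d_DA, ev2$d_DA, tolerance = 1e-9)
  ## acos is ill-conditioned at 180 degrees; a few 1e-7 degrees of noise
  expect_equal(ev$angle, ev2$angle, tolerance = 1e-5)
})

test_that("the uniform-gas RDF is flat at 1 within sampling error", {
  traj <- gas_trajectory(n = 800, box = 30, n_frames = 3, seed = 42)
  p <- compute_rdf(traj, 1:800, 1:800, r_max = 8, dr = 0.25,
                   region = rdf_region_box(c(0, 0, 0), c(30, 30, 30)))
  keep <- p$r >= 2
  expect_lt(abs(mean(p$g[keep]) - 1), 0.05)
  ## per-bin: 5 sigma with the pair-sharing variance inflation (each pair
  ## feeds two centers)
  vshell <- 4 / 3 * pi * diff(p$edges^3)
  sigma <- sqrt(2 * pmax(p$counts, 1)) / (p$n_valid * p$density * vshell)
  expect_true(all(abs(p$g[keep] - 1) < 5 * sigma[keep]))
})

test_that("RDF input validation catches empty selections", {
  traj <- gas_trajectory(n = 50, n_frames = 1)
  expect_error(compute_rdf(traj, integer(0), 1:50), "empty")
  expect_error(compute_rdf(traj, 1:50, integer(0)), "empty")
})

test_that("a placed contact shows up as the RDF peak at its distance", {
  h <- build_histamine(side_torsion = 158.8)
  s <- solvate(h, solvation_spec(12, "sphere", radius = 12,
                                 placed_contacts = list(
                                   list(site = "N2", dist = 2.8))),
               seed = 4)
  wo <- select_atoms(s, resname = "HOH", name = "O")
  n2 <- resolve_site(s, "N2")
  p <- compute_rdf(s, n2, wo, r_max = 8, dr = 0.1,
                   region = rdf_region_sphere(colMeans(h$coords), 13.4))
  expect_equal(p$r[which.max(p$g)], 2.85, tolerance = 0.1)
  ## coordination number just past the peak counts that single water
  expect_equal(coordination_number(p, 3.2), 1.0, tolerance = 0.05)
  expect_equal(coordination_number(p, 0), 0)
})

test_that("coordination numbers integrate to the closed form and match counting", {
  traj <- gas_trajectory(n = 640, box = 40, n_frames = 4, seed = 8)
  p <- compute_rdf(traj, 1:640, 1:640, r_max = 6, dr = 0.1,
                   region = rdf_region_box(c(0, 0, 0), c(40, 40, 40)))
  rho <- 640 / 40^3
  expect_equal(p$density, rho)
  expect_equal(coordination_number(p, 5), 4 / 3 * pi * 125 * rho,
               tolerance = 0.05)

  ## integration equals direct enumeration among interior centers
  direct <- local({
    tot <- 0; nval <- 0
    for (f in traj$frames) {
      bd <- pmin(f[, 1], 40 - f[, 1], f[, 2], 40 - f[, 2],
                 f[, 3], 40 - f[, 3])
      ctr <- which(bd >= 5)
      D <- as.matrix(dist(f))
      tot <- tot + sum(D[ctr, ] > 0 & D[ctr, ] <= 5)
      nval <- nval + length(ctr)
    }
    tot / nval
  })
  expect_equal(coordination_number(p, 5), direct, tolerance = 0.02)
  expect_error(coordination_number(p, 99), "exceeds")
})

test_that("the automatic droplet envelope normalizes a droplet RDF sanely", {
  s <- solvated_fixture(n_water = 15, radius = 8)
  wo <- select_atoms(s, resname = "HOH", name = "O")
  p <- compute_rdf(s, resolve_site(s, "N2"), wo, r_max = 6, dr = 0.2)
  expect_equal(p$region$type, "auto")
  expect_gt(p$region$volume, 0)
  expect_true(all(p$g[!is.na(p$g)] >= 0))
  ## seeded Monte Carlo volume is reproducible
  p2 <- compute_rdf(s, resolve_site(s, "N2"), wo, r_max = 6, dr = 0.2)
  expect_identical(p$region$volume, p2$region$volume)
})

test_that("occupancy statistics count contacts and simultaneous bonds", {
  ## three waters permanently placed around N2: mean simultaneous count 3
  s <- solvated_fixture(n_water = 3, seed = 3)
  traj <- Trajectory(s, list(s$coords, s$coords))
  st <- occupancy_stats(traj)
  n2row <- st$donors[st$donors$donor_label == "HSM1:N2", ]
  expect_equal(n2row$mean_count, 3.0)
  expect_true(all(st$pairs$occupancy >= 0 & st$pairs$occupancy <= 1))
  expect_true(all(st$pairs$mean_dist <= 3.5))

  ## scheduled occupancy is recovered from the frames
  cw <- attr(s, "contact_waters")
  traj2 <- synth_trajectory(s, trajectory_spec(
    600, state_populations = NULL, jitter_sigma = 0.01,
    hbond_occupancy = list(
      list(donor = "N2", acceptor = paste0("HOH", cw$resno[1], ":O"),
           occupancy = 0.92)),
    seed = 13))
  st2 <- occupancy_stats(traj2)
  o1 <- which(s$atoms$resno == cw$resno[1] & s$atoms$name == "O")
  row <- st2$pairs[st2$pairs$acceptor == o1 & st2$pairs$donor ==
                     resolve_site(s, "N2"), ]
  expect_equal(row$occupancy, mean(attr(traj2, "occupancy_schedule")[, 1]),
               tolerance = 1e-9)
  expect_lt(abs(row$occupancy - 0.92), 0.03)

  ## dropping m frames moves any occupancy by at most m/n
  sub <- Trajectory(traj2$topology, traj2$frames[1:500])
  stsub <- occupancy_stats(sub)
  rsub <- stsub$pairs[stsub$pairs$acceptor == o1 &
                        stsub$pairs$donor == resolve_site(s, "N2"), ]
  expect_lte(abs(rsub$occupancy - row$occupancy), 100 / 500 + 1e-9)
})

test_that("the two-then-three contact schedule averages 2.2 bonds", {
  s <- solvated_fixture(n_water = 6, seed = 3)
  cw <- attr(s, "contact_waters")
  occ <- list(
    list(donor = "N2", acceptor = paste0("HOH", cw$resno[1], ":O"),
         occupancy = 1.0),
    list(donor = "N2", acceptor = paste0("HOH", cw$resno[2], ":O"),
         occupancy = 1.0),
    list(donor = "N2", acceptor = paste0("HOH", cw$resno[3], ":O"),
         occupancy = 0.2))
  traj <- synth_trajectory(s, trajectory_spec(
    700, state_populations = NULL, jitter_sigma = 0.01,
    hbond_occupancy = occ, seed = 17))
  st <- occupancy_stats(traj)
  n2 <- st$donors[st$donors$donor_label == "HSM1:N2", ]
  expect_lt(abs(n2$mean_count - 2.2), 0.05)
})
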