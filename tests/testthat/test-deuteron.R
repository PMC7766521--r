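test_that("exchangeable-site detection pairs hydrogens with N/O/S donors", {
  h <- build_histamine()
  fx <- find_exchangeable(h)
  expect_equal(nrow(fx), 4)
  expect_true(all(h$atoms$element[fx$X] == "N"))
  ## three amine + one ring N-H
  expect_equal(sum(h$atoms$name[fx$X] == "N2"), 3)
  expect_equal(sum(h$atoms$name[fx$X] == "N3"), 1)

  w <- water_template()
  expect_equal(nrow(find_exchangeable(w)), 2)

  p <- make_pocket_complex(h, seed = 1)
  lab <- paste0(p$atoms$resname, p$atoms$resno, ":", p$atoms$name)
  got <- lab[find_exchangeable(p)$X]
  for (want in c("THR103:OG1", "THR190:OG1", "TYR250:OH", "THR252:OG1",
                 "CYS102:SG"))
    expect_true(want %in% got, label = want)

  ## element subsets narrow the search
  expect_true(all(p$atoms$element[
    find_exchangeable(p, exchange_rule("S"))$X] == "S"))
})

test_that("exchangeable detection is order-invariant and rejects ties", {
  h <- build_histamine()
  perm <- deutbind:::with_seed(4, sample(nrow(h$atoms)))
  hp <- Structure(h$atoms[perm, ], h$coords[perm, ])
  key <- function(s, fx) sort(paste(s$atoms$name[fx$X], s$atoms$name[fx$H]))
  expect_equal(key(hp, find_exchangeable(hp)), key(h, find_exchangeable(h)))

  tie <- Structure(data.frame(name = c("O1", "H1", "O2"),
                              resname = "X", resno = 1, chain = "A",
                              element = c("O", "H", "O")),
                   rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)))
  expect_error(find_exchangeable(tie), "equidistant")
})

test_that("the deuteration transform contracts bonds exactly and only them", {
  h <- build_histamine()
  fx <- find_exchangeable(h)
  res <- apply_deuteration(h, fx, fraction = 0.023)

  l0 <- sqrt(rowSums((h$coords[fx$H, ] - h$coords[fx$X, ])^2))
  l1 <- sqrt(rowSums((res$structure$coords[fx$H, ] -
                      res$structure$coords[fx$X, ])^2))
  expect_equal(l1 / l0, rep(0.977, 4), tolerance = 1e-9)
  expect_equal(res$constraints$length, l1, tolerance = 1e-12)

  ## arithmetic: 1.010 * 0.977 = 0.98677
  nh <- Structure(data.frame(name = c("N", "HN"), resname = "X", resno = 1,
                             chain = "A"),
                  rbind(c(0, 0, 0), c(1.010, 0, 0)))
  r1 <- apply_deuteration(nh, data.frame(X = 1, H = 2))
  expect_equal(r1$constraints$length, 0.98677, tolerance = 1e-9)

  ## heavy atoms bit-identical; untouched hydrogens too
  heavy <- which(h$atoms$element != "H")
  expect_identical(res$structure$coords[heavy, ], h$coords[heavy, ])
  untouched <- setdiff(which(h$atoms$element == "H"), fx$H)
  expect_identical(res$structure$coords[untouched, ], h$coords[untouched, ])

  ## direction preserved
  u0 <- (h$coords[fx$H[1], ] - h$coords[fx$X[1], ]) / l0[1]
  u1 <- (res$structure$coords[fx$H[1], ] -
         res$structure$coords[fx$X[1], ]) / l1[1]
  expect_equal(sum(u0 * u1), 1, tolerance = 1e-12)

  ## identity at fraction zero
  expect_identical(apply_deuteration(h, fx, 0)$structure$coords, h$coords)
  expect_error(apply_deuteration(h, fx, 1), "fraction")
})

test_that("sequential contractions compose multiplicatively", {
  h <- build_histamine()
  fx <- find_exchangeable(h)
  f1 <- 0.023; f2 <- 0.04
  twice <- apply_deuteration(apply_deuteration(h, fx, f1)$structure, fx, f2)
  once <- apply_deuteration(h, fx, 1 - (1 - f1) * (1 - f2))
  expect_equal(twice$structure$coords, once$structure$coords,
               tolerance = 1e-9)

  degen <- Structure(data.frame(name = c("O", "HO"), resname = "X",
                                resno = 1, chain = "A",
                                element = c("O", "H")),
                     rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(apply_deuteration(degen, data.frame(X = 1, H = 2)),
               "zero-length")
})

test_that("cluster extraction keeps exactly the ranged residues plus ligand", {
  h <- build_histamine()
  p <- make_pocket_complex(h, seed = 1)
  cl <- extract_cluster(p, list(c(98, 103), c(186, 190), c(250, 254)))
  rec <- unique(cl$atoms$resno[cl$atoms$chain == "R"])
  expect_equal(length(rec), 16)
  expect_true(any(cl$atoms$resname == "HSM"))

  ## idempotent
  expect_identical(extract_cluster(cl, list(c(98, 103), c(186, 190),
                                            c(250, 254))), cl)

  only98 <- extract_cluster(p, list(c(98, 98)))
  expect_setequal(unique(only98$atoms$resname), c("HSM", "ASP"))
  expect_setequal(unique(only98$atoms$resno[only98$atoms$chain == "R"]), 98)

  expect_error(extract_cluster(p, list(c(900, 999))), "no residues")
})

test_that("water-shell selection ranks by distance with deterministic ties", {
  ## deterministic fixture: a point solute with waters on concentric shells
  solute <- Structure(data.frame(name = "N", resname = "LIG", resno = 1,
                                 chain = "A"), matrix(0, 1, 3))
  dirs <- deutbind:::with_seed(5, t(vapply(1:50, function(i)
    deutbind:::unitv(stats::rnorm(3)), numeric(3))))
  radii <- c(seq(2.6, 3.96, length.out = 40), seq(4.5, 8, length.out = 10))
  s <- solute
  for (i in 1:50)
    s <- deutbind:::append_structures(
      s, deutbind:::place_water(radii[i] * dirs[i, ], dirs[i, ],
                                c(0, 0, 1), i + 1))

  shell <- select_water_shell(s, 1, shell_spec(36, 4.0))
  kept <- unique(shell$atoms$resno[shell$atoms$resname == "HOH"])
  expect_equal(length(kept), 36)
  ## every retained water is at least as close as every excluded in-cutoff one
  d <- attr(shell, "shell_distances")
  excl <- setdiff(as.integer(names(d))[d <= 4], kept)
  expect_lte(max(d[as.character(kept)]), min(d[as.character(excl)]))
  expect_false(attr(shell, "shell_incomplete"))

  ## fewer available than requested: all returned, with a warning
  expect_warning(sh2 <- select_water_shell(s, 1, shell_spec(45, 4.0)),
                 "40 of 45")
  expect_equal(sum(sh2$atoms$name == "O"), 40)
  expect_true(attr(sh2, "shell_incomplete"))

  ## exact tie at the n-th rank resolves to the lower residue number
  tie <- solute
  tie <- deutbind:::append_structures(
    tie, deutbind:::place_water(c(3, 0, 0), c(1, 0, 0), c(0, 0, 1), 10))
  tie <- deutbind:::append_structures(
    tie, deutbind:::place_water(c(-3, 0, 0), c(-1, 0, 0), c(0, 0, 1), 11))
  one <- select_water_shell(tie, 1, shell_spec(1, 4.0))
  expect_equal(unique(one$atoms$resno[one$atoms$resname == "HOH"]), 10)

  expect_error(select_water_shell(solute, 1, shell_spec(5, 4)), "no waters")
})

test_that("constraint lists serialize as engine-agnostic triples", {
  h <- build_histamine()
  res <- apply_deuteration(h)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_constraints(res, tf)
  back <- read.delim(tf)
  expect_named(back, c("serial_X", "serial_H", "length_A"))
  expect_equal(nrow(back), 4)
  expect_equal(back$length_A, res$constraints$length, tolerance = 1e-6)
})
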