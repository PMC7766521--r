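## Config-driven orchestration: generate -> analyze conformers/hydration ->
## deuterate -> extract -> cycle -> report, with one global seed and a
## manifest recording inputs, parameters and output checksums.

resolve_config_path <- function(path, config_dir) {
  if (file.exists(path)) return(path)
  cand <- file.path(config_dir, path)
  if (file.exists(cand)) return(cand)
  cand <- system.file("extdata", path, package = "deutbind")
  if (nzchar(cand) && file.exists(cand)) return(cand)
  stop("referenced file not found: ", path)
}

#' Run the full analysis pipeline from a configuration file
#'
#' Stages, in dependency order: build the ligand; solvate it with three
#' pinned N2 contacts; generate the aqueous trajectory with the configured
#' conformer populations and contact occupancies; conformer series and
#' populations; N2-water RDF and contact occupancy statistics; build the
#' binding-pocket complex, extract the residue cluster and the solvent
#' shell; apply the deuteration transform and emit the constraint list;
#' surrogate association score of the pocket complex; assemble the H/D
#' binding cycle from the configured component-energy table; partition the
#' per-residue decomposition; affinity conversions. Every stage writes its
#' outputs under `out_dir` and is logged; a `manifest.json` records the
#' configuration, seed and MD5 checksum of every output, so a rerun with
#' the same configuration is bit-identical.
#'
#' @param config path to a YAML configuration (see the bundled
#'   `demo_config.yaml`) or an equivalent named list
#' @param out_dir output directory (created if needed)
#' @param seed optional override of the config seed
#' @param quiet suppress progress messages
#' @return invisibly, a list with the main in-memory results (`ligand`,
#'   `trajectory` (not written), `populations`, `rdf`, `occupancy`,
#'   `cluster`, `deuterated`, `cycle`, `decomposition`, `affinity`,
#'   `manifest`)
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, quiet = FALSE) {
  config_dir <- "."
  if (is.character(config)) {
    config_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[deutbind] ", ...)
  outputs <- character(0)
  put <- function(name) {
    p <- file.path(out_dir, name)
    outputs <<- c(outputs, p)
    p
  }

  ## -- generate -------------------------------------------------------------
  lg <- config$ligand %||% list()
  say("stage simulate: building ligand and solvated system")
  ligand <- build_histamine(tau_tautomer = lg$tautomer %||% "Ntau",
                            protonated = lg$protonated %||% TRUE,
                            side_torsion = lg$side_torsion %||% 158.8)
  write_structure(ligand, put("ligand.pdb"))
  sv <- config$solvation %||% list()
  cdist <- sv$contact_distance %||% 2.8
  occ <- (config$aqueous %||% list())$n2_contact_occupancies %||% c(1, 1, 0.2)
  contacts <- replicate(length(occ),
                        list(site = "N2", dist = cdist), simplify = FALSE)
  solv <- solvate(ligand,
                  solvation_spec(n_water = sv$n_water %||% 40L,
                                 geometry = "sphere",
                                 radius = sv$radius %||% 8.0,
                                 placed_contacts = contacts),
                  seed = seed)
  write_structure(solv, put("solvated.pdb"))
  cw <- attr(solv, "contact_waters")
  aq <- config$aqueous %||% list()
  sched <- lapply(seq_along(occ), function(k)
    list(donor = "N2", acceptor = paste0("HOH", cw$resno[k], ":O"),
         occupancy = occ[k]))
  pops <- unlist(aq$populations %||% list(trans = 0.73, gauche = 0.27))
  traj <- synth_trajectory(solv,
                           trajectory_spec(n_frames = aq$n_frames %||% 300L,
                                           state_populations = pops,
                                           jitter_sigma = aq$jitter_sigma %||% 0.01,
                                           hbond_occupancy = sched,
                                           seed = seed))
  preview <- Trajectory(traj$topology,
                        traj$frames[seq_len(min(5L, length(traj$frames)))])
  write_trajectory(preview, put("trajectory_preview.pdb"))

  ## -- conformers -----------------------------------------------------------
  say("stage conformers: classification and populations")
  cf <- config$conformer %||% list()
  thr <- conformer_thresholds(cf$gauche_max %||% 90, cf$trans_min %||% 120)
  hb <- config$hbond %||% list()
  crit <- hbond_criteria(hb$distance %||% 3.5, hb$angle %||% 135)
  series <- conformer_series(traj, thresholds = thr, criteria = crit)
  write_conformer_series(series, put("conformer_series.tsv"))
  pop <- estimate_populations(series)
  utils::write.table(pop, put("conformer_populations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## -- hydration ------------------------------------------------------------
  say("stage hydration: RDF and contact occupancy")
  rd <- config$rdf %||% list()
  wat_o <- select_atoms(solv, resname = standard_water_names, name = "O")
  n2 <- resolve_site(solv, "N2")
  rdf <- compute_rdf(traj, centers = n2, targets = wat_o,
                     r_max = rd$r_max %||% 7.0, dr = rd$dr %||% 0.1,
                     region = rdf_region_sphere(colMeans(ligand$coords),
                                                (sv$radius %||% 8.0) + 1.4),
                     seed = seed)
  utils::write.table(data.frame(r = rdf$r, g = rdf$g),
                     put("rdf_n2_water.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  occ_stats <- occupancy_stats(traj, criteria = crit)
  utils::write.table(occ_stats$pairs, put("occupancy_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(occ_stats$donors, put("occupancy_donors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- pocket, cluster, shell, deuteration ---------------------------------
  say("stage deuterate: pocket cluster and bond contraction")
  pocket <- make_pocket_complex(ligand, seed = seed)
  write_structure(pocket, put("pocket_complex.pdb"))
  ranges <- lapply(config$cluster_ranges %||%
                     list(c(98, 103), c(186, 190), c(250, 254)), as.numeric)
  cluster <- extract_cluster(pocket, ranges)
  sh <- config$shell %||% list()
  shell <- suppressWarnings(
    select_water_shell(solv, seq_len(nrow(ligand$atoms)),
                       shell_spec(sh$n_waters %||% 36L, sh$cutoff %||% 4.0)))
  write_structure(shell, put("water_shell.pdb"))
  frac <- (config$deuteration %||% list())$fraction %||% 0.023
  deut <- apply_deuteration(cluster, fraction = frac)
  write_structure(deut$structure, put("cluster_deuterated.pdb"))
  write_constraints(deut, put("deuteration_constraints.tsv"))

  ## surrogate association score (geometric demo score, not QM)
  lig_idx <- which(pocket$atoms$resname == HISTAMINE_RESNAME)
  pocket_only <- Structure(pocket$atoms[-lig_idx, , drop = FALSE],
                           pocket$coords[-lig_idx, , drop = FALSE])
  assoc <- complexation_energy(surrogate_energy(pocket, crit),
                               surrogate_energy(pocket_only, crit),
                               surrogate_energy(ligand, crit))
  utils::write.table(
    data.frame(quantity = "surrogate_association_kcal_mol",
               value = sprintf("%.4f", assoc),
               note = "geometric surrogate score, not a QM energy"),
    put("surrogate_association.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  ## -- cycle and decomposition ---------------------------------------------
  say("stage cycle: H/D thermodynamic cycle")
  comp_path <- resolve_config_path(config$energies %||% "cycle_components.tsv",
                                   config_dir)
  cycle <- read_cycle_components(comp_path)
  write_cycle_report(cycle, put("cycle_report.tsv"))
  dc <- config$decomposition %||% list()
  dec_path <- resolve_config_path(dc$table %||% "mmgbsa_per_residue.tsv",
                                  config_dir)
  dec <- decompose_filter(read_decomposition(dec_path, total = dc$total),
                          favorable = dc$favorable_threshold %||% -0.06,
                          unfavorable = dc$unfavorable_threshold %||% 0.02)
  utils::write.table(dec$favorable, put("decomposition_favorable.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dec$unfavorable, put("decomposition_unfavorable.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- affinity conversions -------------------------------------------------
  af <- config$affinity %||% list()
  params <- affinity_params(af$temperature %||% 298.15)
  affin <- data.frame(
    quantity = c("dG_from_pKi_kcal_mol", "ddG_from_pIC50_kcal_mol",
                 "monocation_percent"),
    value = sprintf("%.4f", c(
      dg_from_pki(af$pki %||% 4.3, params),
      ddg_from_pic50(af$pic50_control %||% 7.25, af$pic50_d2o %||% 7.80,
                     params),
      100 * monocation_fraction(af$pH %||% 7.4, af$pKa_ring %||% 6.0,
                                af$pKa_amine %||% 9.7))))
  utils::write.table(affin, put("affinity.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## -- manifest -------------------------------------------------------------
  manifest <- list(seed = seed, config = config,
                   outputs = as.list(stats::setNames(
                     as.character(tools::md5sum(outputs)),
                     basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", length(outputs), " outputs in ", out_dir)
  invisible(list(ligand = ligand, trajectory = traj, populations = pop,
                 rdf = rdf, occupancy = occ_stats, cluster = cluster,
                 deuterated = deut, cycle = cycle, decomposition = dec,
                 affinity = affin, manifest = manifest))
}

#' Path to the bundled demonstration configuration
#' @return file path of `demo_config.yaml`
#' @export
demo_config <- function() {
  system.file("extdata", "demo_config.yaml", package = "deutbind")
}
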