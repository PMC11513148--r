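# Orchestration: a validated config drives simulate -> analyze -> report.
# Stages communicate only through files under the run's output directory, so
# any stage can be re-run in isolation against the persisted inputs.

.config_error <- function(msg) abort(msg, class = "qcprof_config_error")
.data_error <- function(msg) abort(msg, class = "qcprof_data_error")

.check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    .config_error(sprintf("Unknown key(s) in %s: %s", where,
                          paste(unknown, collapse = ", ")))
  }
}

.defaults <- list(
  silac = list(ratio_min = 0.3, p_max = 0.05, min_peptides = 2L,
               min_replicates = 2L, aggregate = "median",
               background_policy = "pooled"),
  tmd = list(l_thresholds = c(16L, 18L), count_threshold = 10L),
  lipids = list(q = 0.01, delta_min = 6L, family = "class", groups = NULL),
  thickness = list(bin_size = 2, window_start = 0.6, bulk_radius = 25)
)

#' Validate and default a pipeline configuration
#'
#' Accepts a YAML file path, a YAML string, or an R list. Unknown keys are
#' rejected at every level; thresholds are range-checked; defaults are
#' filled in (significance at -log2 >= 0.3 and p <= 0.05, FDR Q = 0.01,
#' 2-angstrom thickness bins, final-40% averaging window).
#'
#' @param config Path, YAML text, or list.
#' @return A fully defaulted `qcprof_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
              else yaml::yaml.load(config)
  }
  if (!is.list(config)) .config_error("Config must be a YAML mapping or a list.")
  .check_keys(config, c("seed", "out_dir", "stages", "inputs", "simulate",
                        "silac", "tmd", "lipids", "thickness"), "config")
  cfg <- config
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$stages <- cfg$stages %||% "simulate"
  bad_stage <- setdiff(cfg$stages, c("simulate", "silac", "tmd", "lipids", "thickness"))
  if (length(bad_stage)) {
    .config_error(sprintf("Unknown stage(s): %s", paste(bad_stage, collapse = ", ")))
  }
  cfg$inputs <- cfg$inputs %||% list()
  .check_keys(cfg$inputs, c("silac_a", "silac_b", "membrane_list", "fasta_a",
                            "topology_a", "fasta_b", "topology_b",
                            "lipid_table", "frames_a", "frames_b"), "inputs")
  for (blk in names(.defaults)) {
    .check_keys(cfg[[blk]] %||% list(), names(.defaults[[blk]]), blk)
    cfg[[blk]] <- utils::modifyList(.defaults[[blk]], cfg[[blk]] %||% list())
  }
  s <- cfg$silac
  if (s$ratio_min < 0) .config_error("silac.ratio_min must be >= 0.")
  if (s$p_max <= 0 || s$p_max > 1) .config_error("silac.p_max must be in (0, 1].")
  if (cfg$lipids$q <= 0 || cfg$lipids$q >= 1) .config_error("lipids.q must be in (0, 1).")
  if (cfg$thickness$bin_size <= 0) .config_error("thickness.bin_size must be > 0.")
  if (cfg$thickness$window_start < 0 || cfg$thickness$window_start >= 1) {
    .config_error("thickness.window_start must be in [0, 1).")
  }
  if (!is.null(cfg$simulate)) {
    .check_keys(cfg$simulate, c("proteome_a", "proteome_b", "silac_a", "silac_b",
                                "bilayer_a", "bilayer_b", "lipidome"), "simulate")
    spec_fun <- list(proteome_a = proteome_spec, proteome_b = proteome_spec,
                     silac_a = silac_spec, silac_b = silac_spec,
                     bilayer_a = bilayer_spec, bilayer_b = bilayer_spec,
                     lipidome = NULL)
    for (nm in setdiff(names(cfg$simulate), "lipidome")) {
      .check_keys(cfg$simulate[[nm]], names(formals(spec_fun[[nm]])),
                  paste0("simulate.", nm))
    }
    if (!is.null(cfg$simulate$lipidome)) {
      .check_keys(cfg$simulate$lipidome,
                  c("species", "effects", "n_replicates", "noise_cv", "seed"),
                  "simulate.lipidome")
    }
  }
  structure(cfg, class = "qcprof_config")
}

.simulate_lipidome_from_cfg <- function(blk, seed) {
  sp <- bind_rows(lapply(blk$species, function(s) {
    tibble(class = s$class, chain1 = s$chain1 %||% NA_character_,
           chain2 = s$chain2 %||% NA_character_, baseline = s$baseline)
  }))
  eff <- lapply(blk$effects, function(e) unlist(e))
  spec <- lipidome_spec(select(sp, -"baseline"), sp$baseline, eff,
                        n_replicates_per_group = blk$n_replicates %||% 4L,
                        noise_cv = blk$noise_cv %||% 0.1,
                        seed = blk$seed %||% seed)
  generate_lipidome(spec)
}

#' Run the pipeline described by a configuration
#'
#' Executes the selected stages in dependency order (`simulate` first, then
#' the analyses), writing every product — generator files, volcano/overlap
#' tables, TMD signatures, lipid comparisons, thickness maps — plus the
#' resolved config and a run report under `out_dir`. With identical config
#' and seed the outputs are byte-identical across runs.
#'
#' @param config Anything [validate_config()] accepts.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return The run report (list), invisibly; also written as `report.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- validate_config(config)
  out <- out_dir %||% cfg$out_dir
  if (is.null(out)) .config_error("An output directory is required (out_dir).")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  inputs <- cfg$inputs
  report <- list(seed = cfg$seed, stages = list())

  if ("simulate" %in% cfg$stages && !is.null(cfg$simulate)) {
    sim_dir <- file.path(out, "sim")
    dir.create(sim_dir, showWarnings = FALSE)
    sim_summary <- list()
    for (nm in c("proteome_a", "proteome_b")) {
      blk <- cfg$simulate[[nm]]
      if (is.null(blk)) next
      blk$seed <- blk$seed %||% cfg$seed
      prot <- generate_proteome(do.call(proteome_spec, blk))
      tag <- sub("proteome_", "", nm)
      fa <- file.path(sim_dir, paste0("proteome_", tag, ".fasta"))
      gff <- file.path(sim_dir, paste0("topology_", tag, ".gff3"))
      write_fasta(prot$sequences, fa)
      write_topology(prot$topology, gff, "gff3")
      inputs[[paste0("fasta_", tag)]] <- inputs[[paste0("fasta_", tag)]] %||% fa
      inputs[[paste0("topology_", tag)]] <- inputs[[paste0("topology_", tag)]] %||% gff
      sim_summary[[nm]] <- list(n_proteins = nrow(prot$proteins),
                                n_tmds = nrow(prot$tmds))
    }
    for (nm in c("silac_a", "silac_b")) {
      blk <- cfg$simulate[[nm]]
      if (is.null(blk)) next
      blk$seed <- blk$seed %||% (cfg$seed + match(nm, c("silac_a", "silac_b")))
      eff <- unlist(blk$effect_map %||% list()) %||% numeric(0)
      blk$effect_map <- eff
      tab <- generate_silac_table(do.call(silac_spec, blk))
      path <- file.path(sim_dir, paste0(nm, ".tsv"))
      readr::write_tsv(tab, path)
      inputs[[nm]] <- inputs[[nm]] %||% path
      sim_summary[[nm]] <- list(n_rows = nrow(tab),
                                planted = names(eff))
    }
    for (nm in c("bilayer_a", "bilayer_b")) {
      blk <- cfg$simulate[[nm]]
      if (is.null(blk)) next
      blk$seed <- blk$seed %||% cfg$seed
      frames <- generate_bilayer_trajectory(do.call(bilayer_spec, blk))
      path <- file.path(sim_dir, paste0(nm, ".xyz"))
      write_frames_xyz(frames, path)
      inputs[[sub("bilayer", "frames", nm)]] <-
        inputs[[sub("bilayer", "frames", nm)]] %||% path
      sim_summary[[nm]] <- list(n_frames = max(frames$frame))
    }
    if (!is.null(cfg$simulate$lipidome)) {
      tab <- .simulate_lipidome_from_cfg(cfg$simulate$lipidome, cfg$seed)
      path <- file.path(sim_dir, "lipidome.tsv")
      readr::write_tsv(tab, path)
      inputs$lipid_table <- inputs$lipid_table %||% path
      sim_summary$lipidome <- list(n_rows = nrow(tab))
    }
    report$stages$simulate <- sim_summary
  }

  if ("silac" %in% cfg$stages) {
    if (is.null(inputs$silac_a)) .data_error("silac stage needs inputs.silac_a.")
    membrane <- if (!is.null(inputs$membrane_list)) {
      readr::read_lines(inputs$membrane_list)
    } else character(0)
    s <- cfg$silac
    run_one <- function(path) {
      rec <- readr::read_tsv(path, show_col_types = FALSE)
      run_silac_contrast(rec, membrane, s$min_peptides, s$min_replicates,
                         s$ratio_min, s$p_max, s$aggregate, s$background_policy)
    }
    res_a <- run_one(inputs$silac_a)
    readr::write_tsv(res_a, file.path(out, "volcano_a.tsv"))
    silac_summary <- list(
      n_quantified_a = nrow(res_a),
      significant_a = sort(res_a$protein_id[res_a$significant]))
    if (!is.null(inputs$silac_b)) {
      res_b <- run_one(inputs$silac_b)
      readr::write_tsv(res_b, file.path(out, "volcano_b.tsv"))
      ov <- overlap_contrasts(res_a, res_b,
                              membrane_only = length(membrane) > 0)
      readr::write_tsv(ov, file.path(out, "overlap.tsv"))
      silac_summary$significant_b <- sort(res_b$protein_id[res_b$significant])
      silac_summary$overlap_both <- sort(ov$protein_id[ov$class == "both"])
      silac_summary$overlap_counts <- as.list(table(ov$class))
    }
    report$stages$silac <- silac_summary
  }

  if ("tmd" %in% cfg$stages) {
    if (is.null(inputs$topology_a)) .data_error("tmd stage needs inputs.topology_a.")
    run_set <- function(topo_path, fasta_path, tag) {
      ann <- parse_topology(topo_path)
      seqs <- if (!is.null(fasta_path)) read_fasta(fasta_path)
      tmds <- extract_tmds(ann, seqs)
      readr::write_tsv(tmds, file.path(out, sprintf("tmds_%s.tsv", tag)))
      sig <- signature_stats(tmds, cfg$tmd$l_thresholds, cfg$tmd$count_threshold,
                             all_protein_ids = unique(ann$protein_id))
      jsonlite::write_json(sig[c("n_tmds", "n_proteins", "n_proteins_no_tmd",
                                 "median", "q1", "q3", "frac_tmds_le",
                                 "frac_proteins_shortest_le",
                                 "frac_proteins_count_gt")],
                           file.path(out, sprintf("signature_%s.json", tag)),
                           auto_unbox = TRUE, digits = NA)
      sig
    }
    sig_a <- run_set(inputs$topology_a, inputs$fasta_a, "a")
    tmd_summary <- list(a = list(n_tmds = sig_a$n_tmds, median = sig_a$median,
                                 frac_tmds_le = as.list(sig_a$frac_tmds_le)))
    if (!is.null(inputs$topology_b)) {
      sig_b <- run_set(inputs$topology_b, inputs$fasta_b, "b")
      cmpx <- compare_signatures(sig_a, sig_b)
      jsonlite::write_json(cmpx, file.path(out, "signature_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
      tmd_summary$b <- list(n_tmds = sig_b$n_tmds, median = sig_b$median)
      tmd_summary$delta_median <- cmpx$delta_median
    }
    report$stages$tmd <- tmd_summary
  }

  if ("lipids" %in% cfg$stages) {
    if (is.null(inputs$lipid_table)) .data_error("lipids stage needs inputs.lipid_table.")
    tab <- normalize_per_class(readr::read_tsv(inputs$lipid_table,
                                               show_col_types = FALSE))
    groups <- cfg$lipids$groups %||% head(unique(tab$group), 2L)
    cmpx <- compare_groups(tab, groups, cfg$lipids$q, cfg$lipids$family)
    asym <- classify_asymmetry(cmpx$chain1, cmpx$chain2, cfg$lipids$delta_min)
    cmpx <- dplyr::bind_cols(cmpx, asym)
    readr::write_tsv(cmpx, file.path(out, "lipid_comparison.tsv"))
    report$stages$lipids <- list(
      groups = groups, n_species = nrow(cmpx),
      discoveries = lipid_species_key(cmpx[cmpx$discovery, ]))
  }

  if ("thickness" %in% cfg$stages) {
    if (is.null(inputs$frames_a)) .data_error("thickness stage needs inputs.frames_a.")
    th <- cfg$thickness
    run_frames <- function(path, tag) {
      frames <- if (grepl("\\.pdb$", path)) read_frames_pdb(path)
                else read_frames_xyz(path)
      frames <- assign_leaflets(frames)
      m <- thickness_map(frames, th$bin_size, c(th$window_start, 1))
      readr::write_tsv(as_tibble(m$thickness, .name_repair = "unique_quiet"),
                       file.path(out, sprintf("thickness_map_%s.tsv", tag)),
                       col_names = FALSE)
      list(map = m, summary = thinning_summary(m, th$bulk_radius))
    }
    a <- run_frames(inputs$frames_a, "a")
    thick_summary <- list(a = a$summary[c("bulk", "min", "max_thinning")])
    if (!is.null(inputs$frames_b)) {
      b <- run_frames(inputs$frames_b, "b")
      dm <- difference_map(a$map, b$map, th$bulk_radius)
      thick_summary$b <- b$summary[c("bulk", "min", "max_thinning")]
      thick_summary$delta_max_thinning <- dm$delta_max_thinning
    }
    jsonlite::write_json(thick_summary, file.path(out, "thinning_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$thickness <- thick_summary
  }

  resolved <- file.path(out, "resolved_config.yaml")
  yaml::write_yaml(unclass(cfg), resolved)
  report$config_hash <- unname(tools::md5sum(resolved))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "list")
  invisible(report)
}
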