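PIPELINE_STAGES <- c("simulate", "preprocess", "segment", "dmr",
                     "occupancy", "landscape", "cluster")

STAGE_DEPS <- list(
  simulate = character(),
  preprocess = "simulate",
  segment = "simulate",
  dmr = "simulate",
  occupancy = "simulate",
  landscape = c("segment", "occupancy"),
  cluster = "occupancy"
)

#' Pipeline configuration
#'
#' Builds (or reads from a YAML file) the structured configuration driving
#' [run_stage()]. Every per-module parameter block is validated through the
#' module's own constructor and the fully resolved parameters are printed
#' into each stage manifest, so no defaults stay hidden.
#'
#' @param path Optional YAML file with the same structure as the arguments.
#' @param outdir Output directory for all stages.
#' @param seed Global seed.
#' @param sim Named list of [sim_config()] overrides.
#' @param seg,dm Named lists of [seg_params()] / [dm_params()] overrides.
#' @param occupancy List with `target_depth` (and optional `n_density_bins`).
#' @param landscape List with `body_bins`, `flank`, `flank_bin`.
#' @param cluster List with `k_groups`, `k_deg`, `tss_flank`, `tss_bin`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, outdir = "pipeline_out", seed = 1L,
                            sim = list(), seg = list(), dm = list(),
                            occupancy = list(), landscape = list(),
                            cluster = list()) {
  cfg <- list(outdir = outdir, seed = seed, sim = sim, seg = seg, dm = dm,
              occupancy = occupancy, landscape = landscape,
              cluster = cluster)
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("config file '%s' does not exist", path),
            class = "canyonscape_config_error")
    }
    user <- yaml::read_yaml(path)
    blocks <- c("sim", "seg", "dm", "occupancy", "landscape", "cluster")
    for (nm in names(user)) {
      cfg[[nm]] <- if (nm %in% blocks) {
        utils::modifyList(cfg[[nm]] %||% list(), as.list(user[[nm]]))
      } else {
        user[[nm]]
      }
    }
  }
  cfg$sim$seed <- cfg$sim$seed %||% cfg$seed
  # validate every block through its constructor; fail early and loudly
  cfg$sim_resolved <- do.call(sim_config, cfg$sim)
  cfg$seg_resolved <- do.call(seg_params, cfg$seg)
  cfg$dm_resolved <- do.call(dm_params, cfg$dm)
  cfg$occupancy <- utils::modifyList(
    list(target_depth = 1e6, n_density_bins = 20), cfg$occupancy)
  cfg$landscape <- utils::modifyList(
    list(body_bins = 100, flank = 5000, flank_bin = 50), cfg$landscape)
  cfg$cluster <- utils::modifyList(
    list(k_groups = 5, k_deg = 7, tss_flank = 5000, tss_bin = 50),
    cfg$cluster)
  structure(cfg, class = "pipeline_config")
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (synthetic inputs with ground truth), `preprocess`
#' (read-level filters and pileup), `segment` (UMR/canyon calling per
#' condition), `dmr` (WT vs Dnmt3aKO differential methylation),
#' `occupancy` (normalization, windows, differential occupancy),
#' `landscape` (meta-profiles, density stratification, crossing point),
#' `cluster` (TSS groups and DEG clusters), or `all` in dependency order.
#' Outputs are written atomically; each stage writes a `manifest.json`
#' recording parameters, seed, input/output checksums, and summary
#' statistics. Re-running a stage whose inputs are unchanged is a no-op
#' unless `force = TRUE`.
#'
#' @param name Stage name or `"all"`.
#' @param config A [pipeline_config()].
#' @param force Re-run even when inputs are unchanged.
#' @return The stage manifest(s), invisibly.
#' @export
run_stage <- function(name, config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (name == "all") {
    res <- purrr::map(PIPELINE_STAGES, run_stage, config = config,
                      force = force)
    return(invisible(setNames(res, PIPELINE_STAGES)))
  }
  if (!name %in% PIPELINE_STAGES) {
    abort(sprintf("unknown stage '%s'; stages: %s, all", name,
                  paste(PIPELINE_STAGES, collapse = ", ")),
          class = "canyonscape_config_error")
  }
  for (dep in STAGE_DEPS[[name]]) {
    if (!file.exists(stage_manifest_path(config, dep))) {
      abort(sprintf("stage '%s' requires stage '%s'; run it first",
                    name, dep),
            class = "canyonscape_dependency_error")
    }
  }
  inputs <- stage_inputs(name, config)
  mpath <- stage_manifest_path(config, name)
  if (!force && file.exists(mpath)) {
    old <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    cur <- tools::md5sum(inputs)
    old_in <- unlist(old$inputs)
    same <- length(cur) == length(old_in) &&
      (length(cur) == 0 ||
         (setequal(names(cur), names(old_in)) &&
            all(cur[sort(names(cur))] == old_in[sort(names(cur))])))
    if (same) {
      rlang::inform(sprintf("stage '%s' up to date; skipping", name))
      return(invisible(old))
    }
  }
  dir.create(stage_dir(config, name), recursive = TRUE, showWarnings = FALSE)
  stats <- switch(name,
                  simulate = stage_simulate(config),
                  preprocess = stage_preprocess(config),
                  segment = stage_segment(config),
                  dmr = stage_dmr(config),
                  occupancy = stage_occupancy(config),
                  landscape = stage_landscape(config),
                  cluster = stage_cluster(config))
  manifest <- list(
    stage = name,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    tool_version = as.character(utils::packageVersion("canyonscape")),
    seed = config$seed,
    params = stage_params(name, config),
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(stage_outputs(config, name))),
    stats = stats
  )
  atomic_write_json(manifest, mpath)
  invisible(manifest)
}

stage_dir <- function(config, name) file.path(config$outdir, name)
stage_manifest_path <- function(config, name) {
  file.path(stage_dir(config, name), "manifest.json")
}
stage_outputs <- function(config, name) {
  f <- list.files(stage_dir(config, name), full.names = TRUE)
  sort(f[!grepl("manifest\\.json$", f)])
}
stage_inputs <- function(name, config) {
  out <- unlist(purrr::map(STAGE_DEPS[[name]], stage_outputs, config = config))
  if (is.null(out)) character(0) else out
}

stage_params <- function(name, config) {
  switch(name,
         simulate = unclass(config$sim_resolved),
         preprocess = list(mbias_n_bases = 3, clonal_p_cutoff = 1e-5),
         segment = unclass(config$seg_resolved),
         dmr = unclass(config$dm_resolved),
         occupancy = config$occupancy,
         landscape = config$landscape,
         cluster = config$cluster)
}

atomic_write_json <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

atomic_write <- function(writer, obj, path) {
  tmp <- paste0(path, ".tmp")
  writer(obj, tmp)
  file.rename(tmp, path)
  invisible(path)
}

# ---- stage bodies -----------------------------------------------------------

stage_simulate <- function(config) {
  dir <- stage_dir(config, "simulate")
  cfg <- config$sim_resolved
  genome <- simulate_genome(cfg)

  atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
               genome$chrom_sizes, file.path(dir, "chrom_sizes.tsv"))
  atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
               genome$cpg, file.path(dir, "cpg.tsv"))
  atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
               genome$genes, file.path(dir, "genes.tsv"))
  atomic_write(write_bed, genome$satellite, file.path(dir, "satellite.bed"))
  atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
               genome$regions, file.path(dir, "truth_regions.tsv"))

  for (cond in c("WT", "Dnmt3aKO")) {
    m <- simulate_methylome(genome, cfg, condition = cond)
    atomic_write(write_cpg_table, m$track,
                 file.path(dir, sprintf("methylome_%s.tsv", cond)))
    atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
                 m$regions,
                 file.path(dir, sprintf("truth_hypo_%s.tsv", cond)))
  }
  specs <- list(c("TET1", "WT"), c("DNMT3A1", "WT"), c("DNMT3A2", "WT"),
                c("DNMT3B1", "WT"), c("DNMT3A1", "Tet1KO"), c("input", "WT"))
  spikes <- purrr::map(specs, function(s) {
    occ <- simulate_occupancy(genome, s[1], cfg, condition = s[2])
    atomic_write(write_bedgraph, occ$track,
                 file.path(dir, sprintf("occ_%s_%s.bedgraph", s[1], s[2])))
    if (nrow(occ$peaks) > 0 && s[1] == "TET1") {
      atomic_write(write_bed, occ$peaks, file.path(dir, "tet1_peaks.bed"))
    }
    occ$spike
  })
  atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
               dplyr::bind_rows(spikes), file.path(dir, "spike_counts.tsv"))

  expr <- simulate_expression(genome, cfg)
  atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
               expr$expression, file.path(dir, "expression.tsv"))
  atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
               expr$truth, file.path(dir, "truth_genes.tsv"))

  list(n_cpgs = nrow(genome$cpg), n_regions = nrow(genome$regions),
       n_genes = nrow(genome$genes))
}

stage_preprocess <- function(config) {
  sim <- stage_dir(config, "simulate")
  dir <- stage_dir(config, "preprocess")
  sizes <- readr::read_tsv(file.path(sim, "chrom_sizes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  track <- read_cpg_table(file.path(sim, "methylome_WT.tsv"))
  calls <- simulate_read_calls(track)
  calls <- mbias_trim(calls, n_bases = 3)
  cf <- clonal_filter(calls, genome_length = sum(sizes$length))
  calls <- mate_overlap_dedup(cf$calls)
  pile <- pileup_methylome(calls)
  atomic_write(write_cpg_table, pile, file.path(dir, "methylome_WT.tsv"))
  list(max_dup = cf$max_dup, n_sites = nrow(pile))
}

stage_segment <- function(config) {
  sim <- stage_dir(config, "simulate")
  dir <- stage_dir(config, "segment")
  stats <- list()
  for (cond in c("WT", "Dnmt3aKO")) {
    track <- read_cpg_table(file.path(sim, sprintf("methylome_%s.tsv", cond)))
    regions <- call_meth_regions(track, config$seg_resolved)
    bed <- dplyr::mutate(regions, name = .data$klass,
                         score = round(1000 * (1 - .data$mean_ratio)),
                         strand = ".")
    atomic_write(write_bed, bed,
                 file.path(dir, sprintf("regions_%s.bed", cond)))
    stats[[cond]] <- list(n_umr = sum(regions$klass == "UMR"),
                          n_canyon = sum(regions$klass == "CANYON"))
  }
  stats
}

stage_dmr <- function(config) {
  sim <- stage_dir(config, "simulate")
  dir <- stage_dir(config, "dmr")
  a <- read_cpg_table(file.path(sim, "methylome_WT.tsv"))
  b <- read_cpg_table(file.path(sim, "methylome_Dnmt3aKO.tsv"))
  dmcs <- call_dmcs(a, b, config$dm_resolved, seed = config$seed)
  dmrs <- merge_dmrs(dmcs, config$dm_resolved)
  atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
               dmcs[dmcs$is_dmc, ], file.path(dir, "dmcs.tsv"))
  atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
               dmrs, file.path(dir, "dmrs.tsv"))
  cnt <- dmr_summary(dmrs)
  list(n_dmc = sum(dmcs$is_dmc),
       n_dmr_hypo = sum(cnt$n[cnt$direction == "hypo"]),
       n_dmr_hyper = sum(cnt$n[cnt$direction == "hyper"]))
}

stage_occupancy <- function(config) {
  sim <- stage_dir(config, "simulate")
  dir <- stage_dir(config, "occupancy")
  input <- read_bedgraph(file.path(sim, "occ_input_WT.bedgraph"))
  depth <- config$occupancy$target_depth
  for (f in c("TET1_WT", "DNMT3A1_WT", "DNMT3A2_WT", "DNMT3B1_WT",
              "DNMT3A1_Tet1KO")) {
    tr <- read_bedgraph(file.path(sim, sprintf("occ_%s.bedgraph", f)))
    norm <- normalize_track(tr, input, target_depth = depth)
    atomic_write(write_bedgraph, norm,
                 file.path(dir, sprintf("norm_%s.bedgraph", f)))
  }
  sizes <- readr::read_tsv(file.path(sim, "chrom_sizes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  cpg <- readr::read_tsv(file.path(sim, "cpg.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  wgbs <- read_cpg_table(file.path(sim, "methylome_WT.tsv"))
  sat <- read_bed(file.path(sim, "satellite.bed"))
  wins <- build_windows(sizes, cpg, wgbs_track = wgbs, input_track = input,
                        satellite = sat)
  atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
               wins, file.path(dir, "windows.tsv"))
  a <- read_bedgraph(file.path(dir, "norm_DNMT3A1_Tet1KO.bedgraph"))
  r <- read_bedgraph(file.path(dir, "norm_DNMT3A1_WT.bedgraph"))
  diffocc <- differential_occupancy(a, r)
  atomic_write(function(o, p) {
    readr::write_tsv(o, p, col_names = FALSE, progress = FALSE)
  }, diffocc, file.path(dir, "diff_DNMT3A1_Tet1KO_vs_WT.tsv"))
  list(n_windows = nrow(wins), n_included = sum(wins$included))
}

stage_landscape <- function(config) {
  seg <- stage_dir(config, "segment")
  occ <- stage_dir(config, "occupancy")
  dir <- stage_dir(config, "landscape")
  regions <- read_bed(file.path(seg, "regions_WT.bed"))
  canyons <- regions[regions$name == "CANYON", , drop = FALSE]
  tet1 <- read_bedgraph(file.path(occ, "norm_TET1_WT.bedgraph"))
  a1 <- read_bedgraph(file.path(occ, "norm_DNMT3A1_WT.bedgraph"))
  lp <- config$landscape
  stats <- list(n_canyons = nrow(canyons))
  if (nrow(canyons) > 0) {
    for (nm in c("TET1", "DNMT3A1")) {
      tr <- if (nm == "TET1") tet1 else a1
      prof <- scaled_region_profile(tr, canyons, body_bins = lp$body_bins,
                                    flank = lp$flank,
                                    flank_bin = lp$flank_bin)
      atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
                   tibble::as_tibble(prof),
                   file.path(dir, sprintf("canyon_profile_%s.tsv", nm)))
    }
  }
  wins <- readr::read_tsv(file.path(occ, "windows.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  dp <- density_profile(list(TET1 = tet1, DNMT3A1 = a1), wins,
                        n_bins = config$occupancy$n_density_bins)
  atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
               tibble::as_tibble(dp), file.path(dir, "density_profile.tsv"))
  stats$crossing_density <- crossing_point(dp, "TET1", "DNMT3A1")
  stats
}

stage_cluster <- function(config) {
  sim <- stage_dir(config, "simulate")
  occ <- stage_dir(config, "occupancy")
  dir <- stage_dir(config, "cluster")
  genes <- readr::read_tsv(file.path(sim, "genes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  cp <- config$cluster
  mats <- purrr::map(c(DNMT3A1 = "DNMT3A1_WT", DNMT3A2 = "DNMT3A2_WT",
                       DNMT3B1 = "DNMT3B1_WT"), function(f) {
    tss_matrix(read_bedgraph(file.path(occ, sprintf("norm_%s.bedgraph", f))),
               genes, flank = cp$tss_flank, bin = cp$tss_bin)
  })
  groups <- kmeans_tss_groups(mats, k = cp$k_groups, seed = config$seed)
  atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
               groups$assignment, file.path(dir, "tss_groups.tsv"))
  expr <- readr::read_tsv(file.path(sim, "expression.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  stats <- list(group_sizes = as.list(table(groups$assignment$group)))
  if (sum(expr$de) >= cp$k_deg) {
    deg <- deg_clusters(expr, k = cp$k_deg, seed = config$seed)
    atomic_write(function(o, p) readr::write_tsv(o, p, progress = FALSE),
                 deg$assignment, file.path(dir, "deg_clusters.tsv"))
    stats$cluster_sizes <- as.list(table(deg$assignment$cluster))
  }
  stats
}
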