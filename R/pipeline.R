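#' Pipeline orchestration
#'
#' `run_pipeline()` executes the full analysis on a synthetic community:
#' simulate -> triage -> link -> populations -> abundance -> defensome ->
#' meta, writing one sub-directory of TSV outputs per stage plus a
#' `manifest.json` recording the configuration hash, output checksums,
#' package version and seed.  Identical configuration (including the seed)
#' reproduces byte-identical outputs; the manifest deliberately carries no
#' wall-clock timestamps so the whole output directory is comparable.
#'
#' @name cli_orchestrator
NULL

#' Default pipeline configuration
#'
#' Every analysis threshold is a named key with the pipeline's default
#' value: homology identity 0.70 over >= 2500 bases, spacers > 6 bp, k-mer
#' channel k = 25 with >= 10 shared, ANI population threshold 95 with
#' 500 bp fragments and minimum aligned fractions 0.8 (virus) / 0.5
#' (host), PADS identity >= 30 at E < 1e-10, PFAM E < 1e-3 with bit
#' score >= 30, KEGG E < 1e-5, and adjusted-p gate 0.05.
#'
#' @param seed integer seed driving every stochastic stage.
#' @return a nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    community = list(n_hosts = 10L, n_phages = 20L, host_len = 24000L,
                     phage_len = 10000L, mutation_rate = 0.10, n_closed = 5L,
                     n_provirus = 2L, n_samples = 2L),
    linkage = list(min_identity = 0.70, min_len = 2500L, min_spacer_len = 7L,
                   k = 25L, min_shared = 10L),
    populations = list(ani_threshold = 95, frag_len = 500L,
                       min_fraction_virus = 0.8, min_fraction_host = 0.5),
    defensome = list(pads_min_identity = 30, pads_max_evalue = 1e-10,
                     pfam_max_evalue = 1e-3, pfam_min_bitscore = 30,
                     kegg_max_evalue = 1e-5),
    da = list(n_genes = 200L, n_per_group = 8L, prop_da = 0.1, log2fc = 1.5,
              dispersion = 0.1, n_locations = 2L, padj_threshold = 0.05,
              meta_p_threshold = 0.05, positive_is = "seawater")
  )
}

#' Validate a pipeline configuration
#'
#' @param config configuration list (or path to a YAML file with the same
#'   structure).
#' @return the validated configuration list, invisibly on success; aborts
#'   with class `bioflink_config_error` naming the offending field.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "bioflink_config_error")
    }
    config <- modifyList(default_config(), yaml::read_yaml(config))
  }
  need <- function(block, field, check, what) {
    val <- config[[block]][[field]]
    if (is.null(val) || !check(val)) {
      abort(sprintf("invalid config field `%s.%s` (%s)", block, field, what),
            class = "bioflink_config_error")
    }
  }
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    abort("invalid config field `seed` (integer required)",
          class = "bioflink_config_error")
  }
  pos <- function(x) is.numeric(x) && length(x) == 1L && x > 0
  frac <- function(x) is.numeric(x) && length(x) == 1L && x > 0 && x <= 1
  need("community", "n_hosts", pos, "positive integer")
  need("community", "n_phages", pos, "positive integer")
  need("community", "phage_len", function(x) pos(x) && x >= 5000, ">= 5000 bases")
  need("community", "mutation_rate",
       function(x) is.numeric(x) && x >= 0 && x <= 0.3, "in [0, 0.3]")
  need("linkage", "min_identity", frac, "fraction in (0, 1]")
  need("linkage", "min_len", pos, "positive bases")
  need("linkage", "k", pos, "positive integer")
  need("populations", "ani_threshold",
       function(x) is.numeric(x) && x > 0 && x <= 100, "percent in (0, 100]")
  need("da", "n_per_group", function(x) pos(x) && x >= 2, ">= 2 samples per group")
  need("da", "padj_threshold", frac, "fraction in (0, 1]")
  invisible(config)
}

ts_write <- function(x, dir, name) {
  readr::write_tsv(x, file.path(dir, name))
}

md5_of_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline
#'
#' @param config configuration list ([default_config()]) or path to a YAML
#'   file overriding parts of it.
#' @param out_dir output directory; one sub-directory per stage.
#' @param stages stages to run, in pipeline order (default: all).
#' @param quiet suppress progress messages.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate", "triage", "link", "populations",
                                    "abundance", "defensome", "meta"),
                         quiet = FALSE) {
  config <- validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(config$seed)
  st <- function(name) {
    d <- file.path(out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }

  # -- simulate -------------------------------------------------------------
  say("[simulate] generating synthetic community (seed %d)", seed)
  cc <- config$community
  comm <- generate_community(community_spec(
    n_hosts = cc$n_hosts, n_phages = cc$n_phages, host_len = cc$host_len,
    phage_len = cc$phage_len, mutation_rate = cc$mutation_rate,
    n_closed = cc$n_closed, n_provirus = cc$n_provirus,
    n_samples = cc$n_samples, seed = seed))
  hits <- simulate_defensome_hits(seed = seed + 1L)
  dd <- config$da
  damat <- simulate_defence_counts(
    n_genes = dd$n_genes, n_per_group = dd$n_per_group, prop_da = dd$prop_da,
    log2fc = dd$log2fc, dispersion = dd$dispersion,
    n_locations = dd$n_locations, seed = seed + 2L)
  if ("simulate" %in% stages) {
    d <- st("simulate")
    write_community(comm, d)
    ts_write(hits$pads_hits, d, "pads_hits.tsv")
    ts_write(hits$pfam_hits, d, "pfam_hits.tsv")
    ts_write(hits$kegg_hits, d, "kegg_hits.tsv")
    ts_write(damat$counts, d, "defence_counts.tsv")
    ts_write(damat$samples, d, "defence_samples.tsv")
  }

  # -- triage ---------------------------------------------------------------
  say("[triage] provirus flags and closed-genome calls")
  flags <- flag_proviruses(comm$provirus_calls, comm$bins,
                           known_scaffolds = comm$scaffolds$id)
  phage_scafs <- filter(comm$scaffolds, .data$entity == "phage")
  closed <- call_closed_genomes(phage_scafs, flags)
  units <- comm$units |>
    mutate(kind = if_else(.data$unit_id %in% closed$unit_id,
                          "closed_genome", "fragment"))
  if ("triage" %in% stages) {
    d <- st("triage")
    ts_write(flags, d, "provirus_flags.tsv")
    ts_write(closed, d, "closed_genomes.tsv")
    ts_write(units, d, "units.tsv")
  }

  # -- link -----------------------------------------------------------------
  links <- NULL
  pairs <- NULL
  if (any(c("link", "populations", "abundance") %in% stages)) {
    say("[link] four-channel virus-host linkage")
    lk <- config$linkage
    links <- link_virus_hosts(units, comm$bins, comm$scaffolds, comm$genes,
                              min_identity = lk$min_identity,
                              min_len = lk$min_len, k = lk$k,
                              min_shared = lk$min_shared,
                              min_spacer_len = lk$min_spacer_len)
    pairs <- integrate_pairs(links)
    if ("link" %in% stages) {
      d <- st("link")
      ts_write(links, d, "links.tsv")
      ts_write(pairs, d, "pairs.tsv")
    }
  }

  # -- populations ----------------------------------------------------------
  if ("populations" %in% stages) {
    say("[populations] fragment ANI and 95%% clustering")
    pp <- config$populations
    vseqs <- comm$scaffolds |>
      semi_join(units, by = c(id = "scaffold_id")) |>
      select("id", "seq")
    ani <- ani_matrix(vseqs, frag_len = pp$frag_len,
                      min_fraction = pp$min_fraction_virus,
                      prefilter_min_kmers = 100L)
    vpops <- cluster_populations(ani, vseqs$id, threshold = pp$ani_threshold)
    net <- pair_network_components(pairs, virus_pops = vpops)
    d <- st("populations")
    ts_write(ani, d, "ani.tsv")
    ts_write(vpops, d, "virus_populations.tsv")
    ts_write(net$membership, d, "network_groups.tsv")
    ts_write(tibble(n_groups = net$n_groups, n_multi = net$n_multi),
             d, "network_summary.tsv")
  }

  # -- abundance ------------------------------------------------------------
  if ("abundance" %in% stages) {
    say("[abundance] unit depths, VPR, RPKM")
    vdepth <- mean_depth(comm$depth,
                         select(units, "unit_id", "scaffold_id"))
    hdepth <- mean_depth(comm$depth,
                         select(comm$bins, unit_id = "bin_id", "scaffold_id"))
    vpr <- virus_host_ratio(pairs, vdepth, hdepth, units = units)
    rp <- rpkm(damat$counts, damat$gene_meta)
    rel <- relative_abundance(rp, damat$samples)
    d <- st("abundance")
    ts_write(vdepth, d, "virus_depth.tsv")
    ts_write(hdepth, d, "host_depth.tsv")
    ts_write(vpr, d, "vpr.tsv")
    ts_write(rp, d, "rpkm.tsv")
    ts_write(rel, d, "relative_abundance.tsv")
  }

  # -- defensome ------------------------------------------------------------
  if ("defensome" %in% stages) {
    say("[defensome] defence / counter-defence / AMG calls")
    dcfg <- load_defence_config()
    acfg <- load_amg_config()
    df <- config$defensome
    def_calls <- call_defence_genes(hits$pads_hits, hits$pfam_hits,
                                    dcfg$domain_map,
                                    min_identity = df$pads_min_identity,
                                    max_pads_evalue = df$pads_max_evalue,
                                    min_pfam_bitscore = df$pfam_min_bitscore,
                                    max_pfam_evalue = df$pfam_max_evalue)
    amgs <- call_amgs(hits$kegg_hits, hits$pfam_hits, acfg,
                      hits$gene_positions,
                      max_kegg_evalue = df$kegg_max_evalue,
                      max_pfam_evalue = df$pfam_max_evalue,
                      min_pfam_bitscore = df$pfam_min_bitscore)
    viral_genes <- hits$truth$gene_id[hits$truth$entity == "virus"]
    counter <- call_counter_defence(hits$pads_hits, hits$pfam_hits,
                                    dcfg$domain_map, viral_genes,
                                    min_identity = df$pads_min_identity,
                                    max_pads_evalue = df$pads_max_evalue,
                                    min_pfam_bitscore = df$pfam_min_bitscore,
                                    max_pfam_evalue = df$pfam_max_evalue)
    containers <- def_calls |>
      inner_join(hits$gene_positions, by = "gene_id") |>
      select(container_id = "scaffold_id", "system", "component")
    systems <- system_completeness(containers, dcfg$required)
    d <- st("defensome")
    ts_write(def_calls, d, "defence_genes.tsv")
    ts_write(counter, d, "counter_defence.tsv")
    ts_write(amgs, d, "amgs.tsv")
    ts_write(systems, d, "systems.tsv")
  }

  # -- meta -----------------------------------------------------------------
  if ("meta" %in% stages) {
    say("[meta] differential abundance and random-effects meta-analysis")
    da_all <- differential_abundance_all(damat$counts, damat$samples,
                                         positive_is = dd$positive_is)
    sel <- select_significant(da_all, gene_systems = damat$gene_meta,
                              padj_threshold = dd$padj_threshold,
                              meta_p_threshold = dd$meta_p_threshold,
                              positive_is = dd$positive_is)
    d <- st("meta")
    ts_write(da_all, d, "da.tsv")
    ts_write(sel$genes, d, "meta_significant.tsv")
    ts_write(sel$by_system, d, "enrichment_by_system.tsv")
  }

  # -- manifest -------------------------------------------------------------
  outputs <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  outputs <- outputs[outputs != "manifest.json"]
  checksums <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(checksums) <- outputs
  manifest <- list(
    config_hash = md5_of_object(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("bioflink")),
    stages = stages,
    checksums = checksums
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("[done] outputs in %s", out_dir)
  invisible(out_dir)
}
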