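#' Defence, counter-defence and auxiliary metabolic gene calling
#'
#' Rule-based calling from tabular database hits (DIAMOND/HMMER/KofamScan
#' style output tables are the interface; the search engines themselves are
#' not run here).  A prokaryotic defence gene needs a PADS hit passing the
#' identity/E-value gate *and* a confirming PFAM conserved domain for the
#' same system.  Viral counter-defence genes use the same conjunction
#' restricted to restriction-modification (RM) accessions.  AMGs need
#' passing KEGG and PFAM hits plus membership of a curated accession set.
#' System completeness requires every required component of a system to be
#' present in the container (contig or bin).
#'
#' @name defensome_calls
NULL

known_defence_systems <- c("RM", "CRISPR-Cas", "TA", "BREX", "DISARM", "ABI",
                           "Zorya", "Hachiman", "Gabija", "Septu", "Thoeris",
                           "Lamassu", "Druantia", "Wadjet", "Kiwa", "Shedu")

#' Load defence-system and AMG configuration
#'
#' Reads the YAML maps shipped with the package (or user-supplied
#' replacements): the system -> component -> PFAM accession map used as
#' conserved-domain confirmation, and the AMG accession set with pathway
#' labels.
#'
#' @param path YAML file; default: the configuration shipped in
#'   `inst/extdata`.
#' @return `load_defence_config()`: list with `domain_map` (tibble
#'   `system`, `component`, `accession`, `rm_type`) and `required`
#'   (tibble `system`, `component`).
#' @export
load_defence_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "defence_systems.yaml",
                                package = "bioflink")
  cfg <- yaml::read_yaml(path)
  rows <- list()
  for (sys_name in names(cfg$systems)) {
    if (!sys_name %in% known_defence_systems) {
      abort(sprintf("unknown defence system in config: %s", sys_name),
            class = "bioflink_config_error")
    }
    comps <- cfg$systems[[sys_name]]$components
    for (comp in names(comps)) {
      rows[[length(rows) + 1L]] <- tibble(
        system = sys_name, component = comp,
        accession = unlist(comps[[comp]])
      )
    }
  }
  domain_map <- bind_rows(rows)
  rm_types <- cfg$rm_types %||% list()
  domain_map$rm_type <- unlist(rm_types)[domain_map$accession]
  list(domain_map = domain_map,
       required = distinct(domain_map, .data$system, .data$component))
}

#' @rdname load_defence_config
#' @return `load_amg_config()`: tibble `accession`, `gene`, `pathway`.
#' @export
load_amg_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "amg_accessions.yaml",
                                package = "bioflink")
  cfg <- yaml::read_yaml(path)
  bind_rows(lapply(names(cfg$amgs), function(a) {
    tibble(accession = a, gene = cfg$amgs[[a]]$gene,
           pathway = cfg$amgs[[a]]$pathway)
  }))
}

#' Call prokaryotic defence genes
#'
#' A gene is called for a system when it has a PADS hit for that system
#' with identity >= `min_identity` and E-value < `max_pads_evalue`, *and* a
#' PFAM hit with E-value < `max_pfam_evalue` and bit score >=
#' `min_pfam_bitscore` whose accession is a conserved domain of the same
#' system in `domain_map`.
#'
#' @param pads_hits tibble `gene_id`, `system`, `identity` (percent),
#'   `evalue` (one row per hit; `system` is the PADS annotation).
#' @param pfam_hits tibble `gene_id`, `accession`, `evalue`, `bitscore`.
#' @param domain_map conserved-domain map
#'   (`load_defence_config()$domain_map`).
#' @param min_identity,max_pads_evalue,min_pfam_bitscore,max_pfam_evalue
#'   thresholds; defaults 30 (percent), 1e-10, 30, 1e-3.
#' @return tibble `gene_id`, `system`, `component`, `accession` (the
#'   confirming PFAM domain), one row per called gene-system combination.
#' @export
call_defence_genes <- function(pads_hits, pfam_hits, domain_map,
                               min_identity = 30, max_pads_evalue = 1e-10,
                               min_pfam_bitscore = 30, max_pfam_evalue = 1e-3) {
  bad <- setdiff(unique(domain_map$system), known_defence_systems)
  if (length(bad) > 0L) {
    abort(sprintf("unknown defence system in domain map: %s",
                  paste(bad, collapse = ", ")),
          class = "bioflink_config_error")
  }
  pads_pass <- pads_hits |>
    filter(.data$identity >= min_identity, .data$evalue < max_pads_evalue) |>
    distinct(.data$gene_id, .data$system)
  pfam_pass <- pfam_hits |>
    filter(.data$evalue < max_pfam_evalue, .data$bitscore >= min_pfam_bitscore) |>
    distinct(.data$gene_id, .data$accession) |>
    inner_join(domain_map, by = "accession",
               relationship = "many-to-many")
  pads_pass |>
    inner_join(pfam_pass, by = c("gene_id", "system"),
               relationship = "many-to-many") |>
    distinct(.data$gene_id, .data$system, .data$component, .data$accession) |>
    arrange(.data$gene_id, .data$system, .data$component)
}

#' Call viral counter-defence (RM) genes
#'
#' The defence-gene conjunction restricted to RM-system accessions, applied
#' to viral genes only.
#'
#' @inheritParams call_defence_genes
#' @param viral_genes character vector of gene ids that belong to viral
#'   units; hits on other genes are ignored.
#' @return tibble `gene_id`, `system` (`"RM"`), `component`, `accession`,
#'   `rm_type` (types I/II/III where the domain map annotates one).
#' @export
call_counter_defence <- function(pads_hits, pfam_hits, domain_map, viral_genes,
                                 min_identity = 30, max_pads_evalue = 1e-10,
                                 min_pfam_bitscore = 30, max_pfam_evalue = 1e-3) {
  rm_map <- filter(domain_map, .data$system == "RM")
  calls <- call_defence_genes(
    filter(pads_hits, .data$gene_id %in% viral_genes),
    filter(pfam_hits, .data$gene_id %in% viral_genes),
    rm_map, min_identity, max_pads_evalue, min_pfam_bitscore, max_pfam_evalue)
  left_join(calls, distinct(rm_map, .data$accession, .data$rm_type),
            by = "accession")
}

#' Call auxiliary metabolic genes
#'
#' AMG when all hold: a KEGG hit with E-value < `max_kegg_evalue` and score
#' above the per-family threshold carried in the hit table; a PFAM hit with
#' E-value < `max_pfam_evalue` and bit score > `min_pfam_bitscore`; and the
#' KEGG or PFAM accession is in the curated AMG set.  Genes sitting first
#' or last on their scaffold are flagged `edge_gene` (positional screening
#' as a flag, not a hard filter — terminal genes on a fragment may belong
#' to flanking host sequence).
#'
#' @param kegg_hits tibble `gene_id`, `accession`, `evalue`, `score`,
#'   `threshold` (KofamScan-style per-family score threshold).
#' @param pfam_hits tibble `gene_id`, `accession`, `evalue`, `bitscore`.
#' @param amg_config AMG accession tibble ([load_amg_config()]).
#' @param gene_positions tibble `gene_id`, `scaffold_id`, `start`; used for
#'   the edge-gene flag.
#' @param max_kegg_evalue,max_pfam_evalue,min_pfam_bitscore thresholds;
#'   defaults 1e-5, 1e-3, 30.
#' @return tibble `gene_id`, `accession`, `gene`, `pathway`, `edge_gene`.
#' @export
call_amgs <- function(kegg_hits, pfam_hits, amg_config, gene_positions,
                      max_kegg_evalue = 1e-5, max_pfam_evalue = 1e-3,
                      min_pfam_bitscore = 30) {
  kegg_pass <- kegg_hits |>
    filter(.data$evalue < max_kegg_evalue, .data$score > .data$threshold) |>
    distinct(.data$gene_id, kegg_accession = .data$accession)
  pfam_pass <- pfam_hits |>
    filter(.data$evalue < max_pfam_evalue, .data$bitscore > min_pfam_bitscore) |>
    distinct(.data$gene_id, pfam_accession = .data$accession)
  both <- inner_join(kegg_pass, pfam_pass, by = "gene_id",
                     relationship = "many-to-many")
  hit <- both |>
    mutate(accession = if_else(.data$kegg_accession %in% amg_config$accession,
                               .data$kegg_accession,
                               .data$pfam_accession)) |>
    filter(.data$accession %in% amg_config$accession) |>
    distinct(.data$gene_id, .data$accession) |>
    inner_join(amg_config, by = "accession")
  edges <- gene_positions |>
    group_by(.data$scaffold_id) |>
    mutate(edge_gene = .data$start == min(.data$start) |
             .data$start == max(.data$start)) |>
    ungroup() |>
    select("gene_id", "edge_gene")
  hit |>
    left_join(edges, by = "gene_id") |>
    mutate(edge_gene = dplyr::coalesce(.data$edge_gene, FALSE)) |>
    arrange(.data$gene_id)
}

#' Defence-system completeness per container
#'
#' A system is complete in a container (contig or bin) when every required
#' component of the system has at least one called gene there.
#'
#' @param gene_calls tibble `container_id`, `system`, `component` (called
#'   defence genes mapped to their containers).
#' @param required required-component tibble
#'   (`load_defence_config()$required`).
#' @return tibble `container_id`, `system`, `n_components_present`,
#'   `n_components_required`, `complete`.
#' @export
system_completeness <- function(gene_calls, required) {
  n_req <- count(required, .data$system, name = "n_components_required")
  gene_calls |>
    distinct(.data$container_id, .data$system, .data$component) |>
    count(.data$container_id, .data$system, name = "n_components_present") |>
    inner_join(n_req, by = "system") |>
    mutate(complete = .data$n_components_present >= .data$n_components_required) |>
    arrange(.data$container_id, .data$system)
}

#' Simulate database hit tables with planted defence/AMG truth
#'
#' Fabricates the PADS/PFAM/KEGG hit tables the calling rules consume:
#' planted true positives pass every gate, and decoys violate exactly one
#' gate each (PADS identity, PADS E-value, PFAM bit score, missing PFAM
#' confirmation, accession outside the AMG set), so precision and recall of
#' the rule conjunctions can be checked exactly.
#'
#' @param n_defence planted true defence genes (cycled over the configured
#'   systems/components).
#' @param n_decoy decoy genes per decoy class.
#' @param n_amg planted true AMGs (cycled over the configured accessions).
#' @param n_counter planted viral counter-defence (RM) genes.
#' @param config defence config ([load_defence_config()]).
#' @param amg_config AMG config ([load_amg_config()]).
#' @param seed RNG seed.
#' @return list with `pads_hits`, `pfam_hits`, `kegg_hits`,
#'   `gene_positions`, and `truth` (tibble `gene_id`, `role`, `entity`).
#' @export
simulate_defensome_hits <- function(n_defence = 20L, n_decoy = 5L, n_amg = 6L,
                                    n_counter = 4L,
                                    config = load_defence_config(),
                                    amg_config = load_amg_config(),
                                    seed = 1L) {
  set.seed(seed)
  dm <- config$domain_map
  rm_rows <- filter(dm, .data$system == "RM")
  pads <- list(); pfam <- list(); kegg <- list(); truth <- list()
  gid <- function(prefix, i) sprintf("%s_%03d", prefix, i)

  for (i in seq_len(n_defence)) {
    row <- dm[((i - 1L) %% nrow(dm)) + 1L, ]
    g <- gid("def", i)
    pads[[length(pads) + 1L]] <- tibble(gene_id = g, system = row$system,
                                        identity = runif(1, 35, 80),
                                        evalue = 10^runif(1, -50, -15))
    pfam[[length(pfam) + 1L]] <- tibble(gene_id = g, accession = row$accession,
                                        evalue = 10^runif(1, -30, -5),
                                        bitscore = runif(1, 50, 200))
    truth[[length(truth) + 1L]] <- tibble(gene_id = g, role = "defence",
                                          entity = "prokaryote",
                                          system = row$system,
                                          component = row$component)
  }
  for (i in seq_len(n_counter)) {
    row <- rm_rows[((i - 1L) %% nrow(rm_rows)) + 1L, ]
    g <- gid("cd", i)
    pads[[length(pads) + 1L]] <- tibble(gene_id = g, system = "RM",
                                        identity = runif(1, 35, 80),
                                        evalue = 10^runif(1, -50, -15))
    pfam[[length(pfam) + 1L]] <- tibble(gene_id = g, accession = row$accession,
                                        evalue = 10^runif(1, -30, -5),
                                        bitscore = runif(1, 50, 200))
    truth[[length(truth) + 1L]] <- tibble(gene_id = g, role = "counter_defence",
                                          entity = "virus",
                                          system = "RM", component = row$component)
  }
  # decoys: one violated gate each
  for (i in seq_len(n_decoy)) {
    row <- dm[((i - 1L) %% nrow(dm)) + 1L, ]
    g <- gid("decoy_lowid", i)
    pads[[length(pads) + 1L]] <- tibble(gene_id = g, system = row$system,
                                        identity = runif(1, 5, 29),
                                        evalue = 1e-30)
    pfam[[length(pfam) + 1L]] <- tibble(gene_id = g, accession = row$accession,
                                        evalue = 1e-10, bitscore = 100)
    g <- gid("decoy_evalue", i)
    pads[[length(pads) + 1L]] <- tibble(gene_id = g, system = row$system,
                                        identity = 60, evalue = 1e-5)
    pfam[[length(pfam) + 1L]] <- tibble(gene_id = g, accession = row$accession,
                                        evalue = 1e-10, bitscore = 100)
    g <- gid("decoy_bits", i)
    pads[[length(pads) + 1L]] <- tibble(gene_id = g, system = row$system,
                                        identity = 60, evalue = 1e-30)
    pfam[[length(pfam) + 1L]] <- tibble(gene_id = g, accession = row$accession,
                                        evalue = 1e-10, bitscore = 25)
    g <- gid("decoy_nodomain", i)
    pads[[length(pads) + 1L]] <- tibble(gene_id = g, system = row$system,
                                        identity = 60, evalue = 1e-30)
    for (nm in c("decoy_lowid", "decoy_evalue", "decoy_bits", "decoy_nodomain")) {
      truth[[length(truth) + 1L]] <- tibble(gene_id = gid(nm, i), role = "decoy",
                                            entity = "prokaryote",
                                            system = NA_character_,
                                            component = NA_character_)
    }
  }
  # AMGs: true ones pass everything; decoys carry an accession outside the set
  amg_acc <- amg_config$accession[!startsWith(amg_config$accession, "PF")]
  for (i in seq_len(n_amg)) {
    g <- gid("amg", i)
    acc <- amg_acc[((i - 1L) %% length(amg_acc)) + 1L]
    kegg[[length(kegg) + 1L]] <- tibble(gene_id = g, accession = acc,
                                        evalue = 1e-20, score = 300,
                                        threshold = 100)
    pfam[[length(pfam) + 1L]] <- tibble(gene_id = g, accession = "PF99999",
                                        evalue = 1e-10, bitscore = 120)
    truth[[length(truth) + 1L]] <- tibble(gene_id = g, role = "amg",
                                          entity = "virus",
                                          system = NA_character_,
                                          component = NA_character_)
    g <- gid("amg_decoy", i)
    kegg[[length(kegg) + 1L]] <- tibble(gene_id = g, accession = "K99999",
                                        evalue = 1e-20, score = 300,
                                        threshold = 100)
    pfam[[length(pfam) + 1L]] <- tibble(gene_id = g, accession = "PF99998",
                                        evalue = 1e-10, bitscore = 120)
    truth[[length(truth) + 1L]] <- tibble(gene_id = g, role = "decoy",
                                          entity = "virus",
                                          system = NA_character_,
                                          component = NA_character_)
  }
  truth <- bind_rows(truth)
  # genes spread over scaffolds, three per scaffold, so interior flags vary
  gene_positions <- truth |>
    mutate(scaffold_id = sprintf("scf_%03d", (row_number() - 1L) %/% 3L + 1L),
           start = ((row_number() - 1L) %% 3L) * 1000L) |>
    select("gene_id", "scaffold_id", "start")
  list(pads_hits = bind_rows(pads), pfam_hits = bind_rows(pfam),
       kegg_hits = bind_rows(kegg), gene_positions = gene_positions,
       truth = truth)
}
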