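#' Fragment-based ANI and population clustering
#'
#' Average nucleotide identity is computed FastANI-style: the query genome
#' is cut into consecutive 500 bp fragments, each fragment is aligned to the
#' target with the seed-and-extend aligner, and the ANI is the mean identity
#' of fragments whose best alignment covers at least 80% of the fragment.
#' The result is reported only when at least `min_fraction` of the query
#' fragments aligned (0.8 for viruses, 0.5 for the larger, patchier host
#' bins).  ANI is not assumed symmetric; clustering uses the larger of the
#' two directed values.  Populations are single-linkage components
#' at >= 95% ANI.
#'
#' @name population_ani
NULL

#' Fragment-based average nucleotide identity
#'
#' @param query,target DNA strings or one-row sequence tibbles (use the
#'   concatenated bin sequence for multi-scaffold genomes).
#' @param frag_len fragment length in bases (default 500).
#' @param min_fraction minimum fraction of query fragments that must align
#'   for a result to be reported (default 0.8; use 0.5 for host bins).
#' @param min_frag_covered a fragment counts as aligned when its best
#'   alignment spans at least this fraction of the fragment (default 0.8).
#' @return one-row tibble `query_id`, `target_id`, `ani` (percent),
#'   `aligned_fraction`; or `NULL` when too few fragments align.
#' @export
fragment_ani <- function(query, target, frag_len = 500L, min_fraction = 0.8,
                         min_frag_covered = 0.8) {
  q <- as_seq_string(query, "query")
  t <- as_seq_string(target, "target")
  qid <- if (is.data.frame(query) && "id" %in% names(query)) query$id[[1L]] else "query"
  tid <- if (is.data.frame(target) && "id" %in% names(target)) target$id[[1L]] else "target"
  n <- nchar(q)
  if (n < frag_len || nchar(t) < frag_len) {
    abort("genomes must be at least `frag_len` long")
  }
  n_frag <- n %/% frag_len
  min_cov <- as.integer(ceiling(min_frag_covered * frag_len))
  idents <- rep(NA_real_, n_frag)
  for (i in seq_len(n_frag)) {
    frag <- substr(q, (i - 1L) * frag_len + 1L, i * frag_len)
    aln <- local_align(frag, t, seed_k = 13L, min_identity = 0.3,
                       min_len = min_cov)
    if (nrow(aln) > 0L) {
      best <- slice_max(mutate(aln, score = .data$identity * .data$aln_len),
                        .data$score, n = 1L, with_ties = FALSE)
      idents[i] <- best$identity
    }
  }
  aligned <- !is.na(idents)
  af <- sum(aligned) / n_frag
  if (af < min_fraction) return(NULL)
  tibble(query_id = qid, target_id = tid,
         ani = 100 * mean(idents[aligned]), aligned_fraction = af)
}

#' All-vs-all directed fragment ANI
#'
#' @param seqs sequence tibble (`id`, `seq`); multi-scaffold genomes should
#'   be pre-concatenated per genome.
#' @inheritParams fragment_ani
#' @param prefilter_min_kmers skip genome pairs sharing fewer than this many
#'   distinct canonical 25-mers before running fragment alignment (0 = no
#'   prefilter, the default).  Genomes near the 95% population threshold
#'   share thousands of exact 25-mers, so a low bar (e.g. 100) discards only
#'   pairs that could never cluster together.
#' @return tibble of reported directed comparisons (`query_id`,
#'   `target_id`, `ani`, `aligned_fraction`).
#' @export
ani_matrix <- function(seqs, frag_len = 500L, min_fraction = 0.8,
                       min_frag_covered = 0.8, prefilter_min_kmers = 0L) {
  ksets <- if (prefilter_min_kmers > 0L) {
    lapply(seqs$seq, canonical_kmers, k = 25L)
  } else NULL
  out <- list()
  for (i in seq_len(nrow(seqs))) {
    for (j in seq_len(nrow(seqs))) {
      if (i == j) next
      if (!is.null(ksets) &&
          length(intersect(ksets[[i]], ksets[[j]])) < prefilter_min_kmers) next
      r <- fragment_ani(seqs[i, ], seqs[j, ], frag_len = frag_len,
                        min_fraction = min_fraction,
                        min_frag_covered = min_frag_covered)
      if (!is.null(r)) out[[length(out) + 1L]] <- r
    }
  }
  if (length(out) == 0L) {
    return(tibble(query_id = character(), target_id = character(),
                  ani = double(), aligned_fraction = double()))
  }
  bind_rows(out)
}

#' Cluster genomes into populations at an ANI threshold
#'
#' Single-linkage components over undirected edges with
#' `max(ani(a,b), ani(b,a)) >= threshold`.  Population ids are deterministic
#' (`pop_001`, ... ordered by smallest member id) and invariant to input
#' order.
#'
#' @param ani_tbl directed ANI tibble ([ani_matrix()] output).
#' @param ids character vector of all genome ids (singletons included).
#' @param threshold ANI percent threshold (default 95).
#' @return tibble `member_id`, `population_id`.
#' @export
cluster_populations <- function(ani_tbl, ids, threshold = 95) {
  ids <- sort(unique(ids))
  edges <- if (nrow(ani_tbl) == 0L) {
    tibble(a = character(), b = character(), ani = double())
  } else {
    ani_tbl |>
      mutate(a = pmin(.data$query_id, .data$target_id),
             b = pmax(.data$query_id, .data$target_id)) |>
      group_by(.data$a, .data$b) |>
      summarise(ani = max(.data$ani), .groups = "drop") |>
      filter(.data$ani >= threshold, .data$a != .data$b)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE) |>
    igraph::add_vertices(length(ids), name = ids)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, rbind(match(edges$a, ids), match(edges$b, ids)))
  }
  comp <- igraph::components(g)
  memb <- tibble(member_id = ids, comp = as.integer(comp$membership))
  pop_order <- memb |>
    group_by(.data$comp) |>
    summarise(first_member = min(.data$member_id), .groups = "drop") |>
    arrange(.data$first_member) |>
    mutate(population_id = sprintf("pop_%03d", row_number()))
  memb |>
    left_join(pop_order, by = "comp") |>
    select("member_id", "population_id") |>
    arrange(.data$member_id)
}

#' Shared virus-host pair populations across samples
#'
#' A (virus population, host population) combination is shared when two or
#' more samples each contain a pair whose members belong to those
#' populations.
#'
#' @param pairs_by_sample tibble `virus_unit_id`, `host_bin_id`,
#'   `sample_id`.
#' @param virus_pops,host_pops population tibbles (`member_id`,
#'   `population_id`); unassigned members become singleton populations.
#' @return tibble `virus_population`, `host_population`, `n_samples`,
#'   `samples` (comma-collapsed, sorted); empty when nothing is shared.
#' @export
shared_pairs <- function(pairs_by_sample, virus_pops, host_pops) {
  pop_or_self <- function(ids, pops) {
    m <- pops$population_id[match(ids, pops$member_id)]
    dplyr::coalesce(m, ids)
  }
  pairs_by_sample |>
    mutate(virus_population = pop_or_self(.data$virus_unit_id, virus_pops),
           host_population = pop_or_self(.data$host_bin_id, host_pops)) |>
    distinct(.data$virus_population, .data$host_population, .data$sample_id) |>
    group_by(.data$virus_population, .data$host_population) |>
    summarise(n_samples = dplyr::n_distinct(.data$sample_id),
              samples = paste(sort(unique(.data$sample_id)), collapse = ","),
              .groups = "drop") |>
    filter(.data$n_samples >= 2L) |>
    arrange(.data$virus_population, .data$host_population)
}
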