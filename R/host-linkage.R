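#' Virus-host linkage
#'
#' Four independent evidence channels connect a viral unit to a prokaryotic
#' bin; a pair exists when any channel fires (logical OR):
#'
#' * `homology`: a local alignment between a viral and a host scaffold with
#'   identity >= 70% over >= 2.5 kb;
#' * `crispr`: a CRISPR spacer (> 6 bp) from a host array matches a viral
#'   sequence exactly on either strand;
#' * `trna`: an identical full-length tRNA gene is annotated on both;
#' * `kmer`: virus and host share at least `min_shared` distinct canonical
#'   25-mers (alignment-free channel).
#'
#' @name host_linkage
NULL

#' Detect CRISPR arrays (CRT-style, exact repeats)
#'
#' Finds maximal arrays of at least `min_repeats` exact copies of a repeat
#' (length within `repeat_len_range`) separated by spacers whose lengths lie
#' in `spacer_len_range`.  Repeats are anchored on duplicated
#' `min(repeat_len_range)`-mers, extended to the maximal common repeat, and
#' claimed greedily left-to-right with a longest-repeat-first tie-break.
#' Exact copies only: this is conservative relative to fuzzy-repeat CRT.
#'
#' @param scaffold DNA string or one-row sequence tibble.
#' @param repeat_len_range,spacer_len_range admissible length ranges
#'   (defaults 19-48 for both).
#' @param min_repeats minimum repeat copies (default 3).
#' @return tibble with one row per array: `scaffold_id`, `array_id`,
#'   `repeat_seq`, `n_copies`, `positions` (list of 0-based repeat starts),
#'   `spacers` (list of spacer strings).  Zero rows when none found.
#' @export
detect_crispr_arrays <- function(scaffold,
                                 repeat_len_range = c(19L, 48L),
                                 spacer_len_range = c(19L, 48L),
                                 min_repeats = 3L) {
  s <- as_seq_string(scaffold, "scaffold")
  sid <- if (is.data.frame(scaffold) && "id" %in% names(scaffold)) scaffold$id[[1L]] else "scaffold"
  n <- nchar(s)
  k0 <- repeat_len_range[1L]
  empty <- tibble(scaffold_id = character(), array_id = integer(),
                  repeat_seq = character(), n_copies = integer(),
                  positions = list(), spacers = list())
  if (n < min_repeats * k0) return(empty)
  kmers <- substring(s, 1:(n - k0 + 1L), k0:n)
  occ_by_kmer <- split(seq_len(n - k0 + 1L), kmers)
  occ_by_kmer <- occ_by_kmer[lengths(occ_by_kmer) >= min_repeats &
                               !grepl("N", names(occ_by_kmer), fixed = TRUE)]
  gap_min <- repeat_len_range[1L] + spacer_len_range[1L]
  gap_max <- repeat_len_range[2L] + spacer_len_range[2L]

  cands <- list()
  seen <- character()
  for (pos in occ_by_kmer) {
    pos <- sort(pos)
    run_id <- cumsum(c(1L, !(diff(pos) >= gap_min & diff(pos) <= gap_max)))
    for (run in split(pos, run_id)) {
      if (length(run) < min_repeats) next
      # maximal common extension of all copies, left then right
      left <- 0L
      while (run[1L] - left - 1L >= 1L) {
        ch <- substr(s, run[1L] - left - 1L, run[1L] - left - 1L)
        if (all(substring(s, run - left - 1L, run - left - 1L) == ch) &&
            (k0 + left + 1L) <= repeat_len_range[2L] &&
            run[1L] - left - 1L >= 1L) left <- left + 1L else break
      }
      starts <- run - left
      L <- k0 + left
      gaps <- diff(starts)
      # maximal equality extension; a tandem repeat extends past the gap and
      # is then rejected by the spacer-length check rather than truncated
      while (L < repeat_len_range[2L] && max(starts) + L <= n) {
        ch <- substr(s, starts[1L] + L, starts[1L] + L)
        if (all(substring(s, starts + L, starts + L) == ch)) L <- L + 1L else break
      }
      spacer_lens <- gaps - L
      if (any(spacer_lens < spacer_len_range[1L] | spacer_lens > spacer_len_range[2L])) next
      key <- paste(starts[1L], L, length(starts))
      if (key %in% seen) next
      seen <- c(seen, key)
      cands[[length(cands) + 1L]] <- list(starts = starts, L = L)
    }
  }
  if (length(cands) == 0L) return(empty)
  # greedy left-to-right claim, longest repeat first on ties
  ord <- order(vapply(cands, function(c) c$starts[1L], integer(1)),
               -vapply(cands, function(c) c$L, integer(1)))
  claimed <- matrix(numeric(0), ncol = 2L)
  out <- list()
  for (i in ord) {
    cand <- cands[[i]]
    span <- c(cand$starts[1L], max(cand$starts) + cand$L)
    if (nrow(claimed) > 0L &&
        any(span[1L] < claimed[, 2L] & claimed[, 1L] < span[2L])) next
    claimed <- rbind(claimed, span)
    spacers <- substring(s, head(cand$starts, -1L) + cand$L, cand$starts[-1L] - 1L)
    out[[length(out) + 1L]] <- tibble(
      scaffold_id = sid, array_id = length(out) + 1L,
      repeat_seq = substr(s, cand$starts[1L], cand$starts[1L] + cand$L - 1L),
      n_copies = length(cand$starts),
      positions = list(as.integer(cand$starts - 1L)),
      spacers = list(spacers)
    )
  }
  bind_rows(out)
}

# all distinct canonical k-mers of a set of sequences (N-containing skipped)
canonical_kmers <- function(seqs, k = 25L) {
  out <- character(0)
  for (s in toupper(seqs)) {
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, 1:(n - k + 1L), k:n)
    km <- km[!grepl("N", km, fixed = TRUE)]
    if (length(km) == 0L) next
    rc <- dna_revcomp(km)
    out <- c(out, unique(pmin(km, rc)))
  }
  unique(out)
}

#' Evidence channels
#'
#' Each `link_by_*()` function tests one channel for a single virus-host
#' combination and returns either a one-row evidence tibble
#' (`virus_unit_id`, `host_bin_id`, `channel`, plus channel statistics) or
#' `NULL`.
#'
#' @param arrays CRISPR arrays from the host bin's scaffolds
#'   ([detect_crispr_arrays()] output).
#' @param virus_seqs sequence tibble of the viral unit's scaffolds.
#' @param virus_unit_id,host_bin_id identifiers stamped into the result.
#' @param min_spacer_len spacers must be strictly longer than 6 bp
#'   (default 7 = shortest admissible length).
#' @return one-row tibble or `NULL`.
#' @export
link_by_spacers <- function(arrays, virus_seqs, virus_unit_id = "virus",
                            host_bin_id = "host", min_spacer_len = 7L) {
  if (nrow(arrays) == 0L) return(NULL)
  spacers <- unique(unlist(arrays$spacers))
  spacers <- spacers[nchar(spacers) >= min_spacer_len & !grepl("N", spacers, fixed = TRUE)]
  if (length(spacers) == 0L) return(NULL)
  n_hit <- 0L
  for (sp in spacers) {
    hit <- FALSE
    for (i in seq_len(nrow(virus_seqs))) {
      if (nrow(find_exact_matches(sp, virus_seqs$seq[i], both_strands = TRUE)) > 0L) {
        hit <- TRUE
        break
      }
    }
    if (hit) n_hit <- n_hit + 1L
  }
  if (n_hit == 0L) return(NULL)
  tibble(virus_unit_id = virus_unit_id, host_bin_id = host_bin_id,
         channel = "crispr", n_spacer_hits = n_hit)
}

#' @rdname link_by_spacers
#' @param host_seqs sequence tibble of the host bin's scaffolds.
#' @param min_identity,min_len homology thresholds (defaults 0.70 and
#'   2500 bases).
#' @export
link_by_homology <- function(virus_seqs, host_seqs, virus_unit_id = "virus",
                             host_bin_id = "host", min_identity = 0.70,
                             min_len = 2500L) {
  best <- NULL
  for (i in seq_len(nrow(virus_seqs))) {
    for (j in seq_len(nrow(host_seqs))) {
      aln <- local_align(virus_seqs[i, ], host_seqs[j, ],
                         min_identity = min_identity, min_len = min_len)
      if (nrow(aln) > 0L) {
        top <- slice_max(aln, .data$aln_len, n = 1L, with_ties = FALSE)
        if (is.null(best) || top$aln_len > best$aln_len) best <- top
      }
    }
  }
  if (is.null(best)) return(NULL)
  tibble(virus_unit_id = virus_unit_id, host_bin_id = host_bin_id,
         channel = "homology", identity = best$identity, aln_len = best$aln_len)
}

#' @rdname link_by_spacers
#' @param virus_genes,host_genes gene tibbles with `is_trna` and `seq`
#'   columns; only tRNA rows are used and matching is exact over the full
#'   length, on either strand.
#' @export
link_by_trna <- function(virus_genes, host_genes, virus_unit_id = "virus",
                         host_bin_id = "host") {
  vt <- filter(virus_genes, .data$is_trna)
  ht <- filter(host_genes, .data$is_trna)
  if (nrow(vt) == 0L || nrow(ht) == 0L) return(NULL)
  hset <- unique(c(toupper(ht$seq), dna_revcomp(ht$seq)))
  n_hit <- sum(toupper(vt$seq) %in% hset)
  if (n_hit == 0L) return(NULL)
  tibble(virus_unit_id = virus_unit_id, host_bin_id = host_bin_id,
         channel = "trna", n_trna_hits = n_hit)
}

#' @rdname link_by_spacers
#' @param k k-mer length (default 25).
#' @param min_shared minimum number of distinct shared canonical k-mers for
#'   a link (default 10).
#' @export
link_by_kmers <- function(virus_seqs, host_seqs, virus_unit_id = "virus",
                          host_bin_id = "host", k = 25L, min_shared = 10L) {
  vk <- canonical_kmers(virus_seqs$seq, k = k)
  hk <- canonical_kmers(host_seqs$seq, k = k)
  n_shared <- length(intersect(vk, hk))
  if (n_shared < min_shared) return(NULL)
  tibble(virus_unit_id = virus_unit_id, host_bin_id = host_bin_id,
         channel = "kmer", n_shared_kmers = n_shared)
}

#' Run all four linkage channels over a community
#'
#' Evaluates every viral unit against every host bin on all four channels
#' and returns the evidence links.  Self-matches are excluded: a unit whose
#' scaffold belongs to the host bin (an integrated provirus) is not linked
#' to that bin.  CRISPR arrays are detected once per host scaffold and
#' reused.
#'
#' @param units viral unit membership tibble (`unit_id`, `scaffold_id`).
#' @param bins host bin membership tibble (`bin_id`, `scaffold_id`).
#' @param scaffolds sequence tibble covering both.
#' @param genes gene tibble with `scaffold_id`, `is_trna`, `seq` (may be
#'   empty).
#' @param min_identity,min_len,k,min_shared,min_spacer_len channel
#'   thresholds (see [link_by_spacers()] and friends).
#' @return evidence-link tibble, one row per (virus, host, channel) that
#'   fired.
#' @export
link_virus_hosts <- function(units, bins, scaffolds, genes = NULL,
                             min_identity = 0.70, min_len = 2500L,
                             k = 25L, min_shared = 10L, min_spacer_len = 7L) {
  genes <- genes %||% tibble(scaffold_id = character(), is_trna = logical(),
                             seq = character())
  seq_of <- function(ids) filter(scaffolds, .data$id %in% ids)
  host_ids <- unique(bins$bin_id)
  unit_ids <- unique(units$unit_id)
  # per-host caches: scaffold sequences, CRISPR arrays, canonical k-mer sets
  host_cache <- lapply(setNames(host_ids, host_ids), function(h) {
    scafs <- seq_of(bins$scaffold_id[bins$bin_id == h])
    list(
      scaffold_ids = bins$scaffold_id[bins$bin_id == h],
      seqs = scafs,
      genes = filter(genes, .data$scaffold_id %in% scafs$id),
      arrays = bind_rows(lapply(seq_len(nrow(scafs)),
                                function(i) detect_crispr_arrays(scafs[i, ]))),
      kmers = canonical_kmers(scafs$seq, k = k)
    )
  })
  links <- list()
  for (u in unit_ids) {
    u_scafs <- units$scaffold_id[units$unit_id == u]
    vseqs <- seq_of(u_scafs)
    vgenes <- filter(genes, .data$scaffold_id %in% u_scafs)
    vkmers <- canonical_kmers(vseqs$seq, k = k)
    for (h in host_ids) {
      hc <- host_cache[[h]]
      if (any(u_scafs %in% hc$scaffold_ids)) next # provirus vs its own bin
      kmer_link <- if (length(intersect(vkmers, hc$kmers)) >= min_shared) {
        tibble(virus_unit_id = u, host_bin_id = h, channel = "kmer",
               n_shared_kmers = length(intersect(vkmers, hc$kmers)))
      } else NULL
      for (res in list(
        link_by_homology(vseqs, hc$seqs, u, h, min_identity, min_len),
        link_by_spacers(hc$arrays, vseqs, u, h, min_spacer_len),
        link_by_trna(vgenes, hc$genes, u, h),
        kmer_link
      )) {
        if (!is.null(res)) links[[length(links) + 1L]] <- res
      }
    }
  }
  if (length(links) == 0L) {
    return(tibble(virus_unit_id = character(), host_bin_id = character(),
                  channel = character()))
  }
  arrange(bind_rows(links), .data$virus_unit_id, .data$host_bin_id, .data$channel)
}

#' Integrate evidence links into virus-host pairs
#'
#' OR semantics: one pair per (virus, host) with at least one fired channel;
#' channels are deduplicated and sorted, ordering is deterministic by
#' (virus, host).
#'
#' @param links evidence-link tibble ([link_virus_hosts()] output).
#' @return tibble `virus_unit_id`, `host_bin_id`, `channels`
#'   (comma-collapsed sorted channel string), `n_channels`.
#' @export
integrate_pairs <- function(links) {
  if (nrow(links) == 0L) {
    return(tibble(virus_unit_id = character(), host_bin_id = character(),
                  channels = character(), n_channels = integer()))
  }
  links |>
    distinct(.data$virus_unit_id, .data$host_bin_id, .data$channel) |>
    group_by(.data$virus_unit_id, .data$host_bin_id) |>
    summarise(channels = paste(sort(unique(.data$channel)), collapse = ","),
              n_channels = dplyr::n_distinct(.data$channel), .groups = "drop") |>
    arrange(.data$virus_unit_id, .data$host_bin_id)
}

#' Connected components of the pair network
#'
#' Builds the bipartite graph whose nodes are virus populations and host
#' populations and whose edges are virus-host pairs (mapped through the
#' population assignments), and returns its connected components.
#'
#' @param pairs pair tibble ([integrate_pairs()] output).
#' @param virus_pops,host_pops population tibbles (`member_id`,
#'   `population_id`), e.g. from [cluster_populations()]; members missing
#'   from them become singleton populations named after themselves.
#' @return list with `membership` (tibble `node_id`, `entity`, `group`),
#'   `n_groups`, and `n_multi` (groups containing more than one virus or
#'   more than one host population).
#' @export
pair_network_components <- function(pairs, virus_pops = NULL, host_pops = NULL) {
  pop_of <- function(ids, pops, prefix) {
    if (is.null(pops) || nrow(pops) == 0L) return(paste0(prefix, ids))
    m <- pops$population_id[match(ids, pops$member_id)]
    paste0(prefix, dplyr::coalesce(m, ids))
  }
  if (nrow(pairs) == 0L) {
    return(list(membership = tibble(node_id = character(), entity = character(),
                                    group = integer()),
                n_groups = 0L, n_multi = 0L))
  }
  vnode <- pop_of(pairs$virus_unit_id, virus_pops, "V:")
  hnode <- pop_of(pairs$host_bin_id, host_pops, "H:")
  g <- igraph::graph_from_data_frame(
    unique(data.frame(from = vnode, to = hnode, stringsAsFactors = FALSE)),
    directed = FALSE)
  comp <- igraph::components(g)
  membership <- tibble(
    node_id = names(comp$membership),
    entity = if_else(startsWith(names(comp$membership), "V:"), "virus", "host"),
    group = as.integer(comp$membership)
  )
  multi <- membership |>
    count(.data$group, .data$entity) |>
    filter(.data$n > 1L) |>
    distinct(.data$group)
  list(membership = membership, n_groups = comp$no, n_multi = nrow(multi))
}
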