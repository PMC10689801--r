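#' Synthetic communities with planted ground truth
#'
#' Every downstream stage of the pipeline is exercised on synthetic
#' virus-prokaryote communities in which the evidence the pipeline looks for
#' is planted explicitly: homologous blocks copied from phage to host with a
#' controlled substitution rate, CRISPR arrays whose spacers are sampled from
#' phage genomes, identical tRNA genes, exact shared 25-mer blocks, direct
#' terminal repeats, integrated proviruses, per-sample depth profiles, and
#' negative-binomial defence-gene count tables with planted
#' biofilm/seawater fold changes.  The emitted tables use the same headers
#' the analysis stages consume, and a `truth` component records what was
#' planted so recall and precision can be measured exactly.
#'
#' Background sequence is i.i.d. uniform ACGT; GC bias, repeats and
#' sequencing error are deliberately not modelled.
#'
#' @name synthetic_community
NULL

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each base independently with probability `rate` (always to a
# different base, so `rate` is the expected per-base divergence)
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  bases <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(bases)) < rate)
  if (length(hit) > 0L) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    bases[hit] <- vapply(bases[hit], function(b) sample(alt[[b]], 1L), character(1))
  }
  paste(bases, collapse = "")
}

splice_in <- function(s, insert, at) {
  # insert `insert` so that it starts at 0-based position `at`
  paste0(substr(s, 1L, at), insert, substr(s, at + 1L, nchar(s)))
}

#' Specify a synthetic community
#'
#' @param n_hosts,n_phages numbers of prokaryotic host bins and phages.
#' @param host_len,phage_len genome lengths in bases (each host bin is split
#'   over `scaffolds_per_host` scaffolds; phages are single scaffolds and
#'   must be at least 5 kb, the minimum scaffold size the pipeline analyses).
#' @param link_plan tibble with columns `phage` (1..n_phages), `host`
#'   (1..n_hosts) and `channel` (one of `"homology"`, `"crispr"`, `"trna"`,
#'   `"kmer"`); one row per planted evidence channel.  Default:
#'   [default_link_plan()].
#' @param mutation_rate substitution rate applied to planted homologous
#'   blocks, in `[0, 0.3]` (default 0.10, i.e. ~90% identity).
#' @param n_closed number of phages given a clean 40 bp direct terminal
#'   repeat (these are the planted closed genomes).
#' @param n_provirus number of host bins receiving an integrated provirus
#'   scaffold (flagged in the provirus-call table).
#' @param n_samples metagenome samples for the depth profiles.
#' @param homology_len,kmer_block_len lengths (bases) of the blocks copied
#'   for the homology and shared-k-mer channels.
#' @param scaffolds_per_host scaffolds per host bin.
#' @param seed RNG seed; the whole community is a deterministic function of
#'   the spec including this seed.
#' @return a `bfl_community_spec` list.
#' @export
community_spec <- function(n_hosts = 10L, n_phages = 20L,
                           host_len = 24000L, phage_len = 10000L,
                           link_plan = NULL, mutation_rate = 0.10,
                           n_closed = 5L, n_provirus = 2L, n_samples = 2L,
                           homology_len = 3000L, kmer_block_len = 300L,
                           scaffolds_per_host = 3L, seed = 1L) {
  if (phage_len < 5000L) abort("`phage_len` must be >= 5000")
  if (mutation_rate < 0 || mutation_rate > 0.3) abort("`mutation_rate` must be in [0, 0.3]")
  link_plan <- link_plan %||% default_link_plan(n_phages, n_hosts)
  stopifnot(all(c("phage", "host", "channel") %in% names(link_plan)))
  if (!all(link_plan$channel %in% c("homology", "crispr", "trna", "kmer"))) {
    abort("link_plan channels must be homology/crispr/trna/kmer")
  }
  if (max(link_plan$phage) > n_phages || max(link_plan$host) > n_hosts) {
    abort("link_plan refers to phages/hosts outside the community")
  }
  if (homology_len + 200L > phage_len) abort("`homology_len` too large for `phage_len`")
  structure(list(
    n_hosts = as.integer(n_hosts), n_phages = as.integer(n_phages),
    host_len = as.integer(host_len), phage_len = as.integer(phage_len),
    link_plan = as_tibble(link_plan), mutation_rate = mutation_rate,
    n_closed = as.integer(n_closed), n_provirus = as.integer(n_provirus),
    n_samples = as.integer(n_samples), homology_len = as.integer(homology_len),
    kmer_block_len = as.integer(kmer_block_len),
    scaffolds_per_host = as.integer(scaffolds_per_host),
    seed = as.integer(seed)
  ), class = "bfl_community_spec")
}

#' Default planted link plan
#'
#' One phage-host pair per phage, cycling the four evidence channels, plus a
#' second channel on every other pair: with the default 20 phages and 10
#' hosts this plants 30 channel-links over 20 pairs, covering all four
#' channels.
#'
#' @inheritParams community_spec
#' @return tibble with `phage`, `host`, `channel`.
#' @export
default_link_plan <- function(n_phages = 20L, n_hosts = 10L) {
  channels <- c("homology", "crispr", "trna", "kmer")
  base <- tibble(
    phage = seq_len(n_phages),
    host = ((seq_len(n_phages) - 1L) %% n_hosts) + 1L,
    channel = channels[((seq_len(n_phages) - 1L) %% 4L) + 1L]
  )
  extra_idx <- seq(1L, n_phages, by = 2L)
  extra <- tibble(
    phage = extra_idx,
    host = base$host[extra_idx],
    channel = channels[((extra_idx + 1L) %% 4L) + 1L]
  )
  distinct(bind_rows(base, extra), .data$phage, .data$host, .data$channel)
}

#' Generate a synthetic community
#'
#' Materialises a [community_spec()] into sequence and annotation tables plus
#' the planted ground truth.  The same spec (including its seed) always
#' yields byte-identical output.
#'
#' @param spec a `bfl_community_spec`.
#' @return a `bfl_community` list with tibbles `scaffolds` (`id`,
#'   `sample_id`, `entity`, `seq`, `length`), `units` (viral unit membership:
#'   `unit_id`, `kind`, `scaffold_id`, `phylum`), `bins` (host bin
#'   membership with `completeness`/`contamination`), `provirus_calls`,
#'   `genes` (coordinates, `is_trna`, tRNA `seq`), `depth` (per scaffold and
#'   sample), and a `truth` list (`true_links`, `true_closed`,
#'   `planted_crisprs` with the planted spacers).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "bfl_community_spec"))
  set.seed(spec$seed)
  n_p <- spec$n_phages; n_h <- spec$n_hosts

  phage_ids <- sprintf("phage_%02d", seq_len(n_p))
  host_ids <- sprintf("host_%02d", seq_len(n_h))

  phage_seq <- setNames(vapply(seq_len(n_p), function(i) random_dna(spec$phage_len), character(1)), phage_ids)
  # hosts as lists of scaffold sequences
  per_scaf <- spec$host_len %/% spec$scaffolds_per_host
  host_seq <- setNames(lapply(seq_len(n_h), function(i) {
    setNames(
      vapply(seq_len(spec$scaffolds_per_host), function(j) random_dna(per_scaf), character(1)),
      sprintf("%s_scaf_%d", host_ids[i], seq_len(spec$scaffolds_per_host))
    )
  }), host_ids)

  # --- plant DTRs: prepend-free — rewrite phage as repeat + core + repeat
  closed_idx <- seq_len(min(spec$n_closed, n_p))
  dtr_len <- 40L
  for (i in closed_idx) {
    rep_seq <- random_dna(dtr_len)
    core <- substr(phage_seq[[i]], 1L, spec$phage_len - 2L * dtr_len)
    phage_seq[[i]] <- paste0(rep_seq, core, rep_seq)
  }

  # --- plant evidence channels
  # tRNA rows are processed first: they are the only channel that edits the
  # phage sequence, and all other channels copy material *from* the phage.
  # Host-side insertion points avoid previously planted features so one
  # channel can never split another's evidence.
  truth_links <- spec$link_plan
  genes <- list()
  gene_n <- 0L
  planted_crisprs <- list()
  occupied <- list() # host scaffold key -> matrix of half-open intervals
  insert_into_host <- function(key, hseq, block) {
    iv <- occupied[[key]]
    repeat {
      at <- sample.int(nchar(hseq) - 10L, 1L)
      if (is.null(iv) || all(at <= iv[, 1L] | at >= iv[, 2L])) break
    }
    if (!is.null(iv)) {
      shift <- iv[, 1L] >= at
      iv[shift, ] <- iv[shift, , drop = FALSE] + nchar(block)
    }
    occupied[[key]] <<- rbind(iv, c(at, at + nchar(block)))
    list(seq = splice_in(hseq, block, at), at = at)
  }
  plan <- spec$link_plan
  plan$scaf_j <- ((seq_len(nrow(plan)) - 1L) %% spec$scaffolds_per_host) + 1L
  plan <- plan[order(plan$channel != "trna"), , drop = FALSE]
  for (r in seq_len(nrow(plan))) {
    pi <- plan$phage[r]; hi <- plan$host[r]; ch <- plan$channel[r]
    hid <- host_ids[hi]
    scaf_j <- plan$scaf_j[r]
    key <- sprintf("%s/%d", hid, scaf_j)
    hseq <- host_seq[[hid]][[scaf_j]]
    pseq <- phage_seq[[pi]]
    plen <- nchar(pseq)
    if (ch == "homology") {
      from <- sample.int(plen - spec$homology_len, 1L)
      block <- mutate_seq(substr(pseq, from, from + spec$homology_len - 1L), spec$mutation_rate)
      hseq <- insert_into_host(key, hseq, block)$seq
    } else if (ch == "kmer") {
      from <- sample.int(plen - spec$kmer_block_len, 1L)
      block <- substr(pseq, from, from + spec$kmer_block_len - 1L)
      hseq <- insert_into_host(key, hseq, block)$seq
    } else if (ch == "crispr") {
      rep_len <- sample(25:35, 1L)
      repeat_seq <- random_dna(rep_len)
      n_spacer <- sample(3:8, 1L)
      sp_lens <- sample(25:40, n_spacer, replace = TRUE)
      from_phage <- sample.int(n_spacer, 1L)
      spacers <- vapply(seq_len(n_spacer), function(k) {
        if (k == from_phage) {
          fp <- sample.int(plen - sp_lens[k], 1L)
          substr(pseq, fp, fp + sp_lens[k] - 1L)
        } else random_dna(sp_lens[k])
      }, character(1))
      array_seq <- paste0(paste0(repeat_seq, spacers, collapse = ""), repeat_seq)
      hseq <- insert_into_host(key, hseq, array_seq)$seq
      planted_crisprs[[length(planted_crisprs) + 1L]] <- tibble(
        scaffold_id = names(host_seq[[hid]])[scaf_j], repeat_seq = repeat_seq,
        spacer = spacers, spacer_rank = seq_len(n_spacer),
        phage_spacer = seq_len(n_spacer) == from_phage, phage_id = phage_ids[pi]
      )
    } else if (ch == "trna") {
      trna <- random_dna(75L)
      # identical gene copied into both genomes, recorded as gene calls;
      # keep the phage-side insertion clear of any terminal repeat
      at_p <- sample.int(plen - 300L, 1L) + 100L
      phage_seq[[pi]] <- splice_in(pseq, trna, at_p)
      ins <- insert_into_host(key, hseq, trna)
      hseq <- ins$seq
      gene_n <- gene_n + 2L
      genes[[length(genes) + 1L]] <- tibble(
        gene_id = sprintf("trna_%04d", c(gene_n - 1L, gene_n)),
        scaffold_id = c(phage_ids[pi], names(host_seq[[hid]])[scaf_j]),
        start = c(at_p, ins$at), end = c(at_p + 75L, ins$at + 75L),
        strand = "+", product = "tRNA", is_trna = TRUE, seq = trna
      )
    }
    host_seq[[hid]][[scaf_j]] <- hseq
  }

  # --- proviruses: extra host-bin scaffold carrying a phage block
  provirus_rows <- list()
  if (spec$n_provirus > 0L) {
    for (i in seq_len(min(spec$n_provirus, n_h))) {
      donor <- ((i - 1L) %% n_p) + 1L
      block <- substr(phage_seq[[donor]], 1L, 4000L)
      scaf <- paste0(random_dna(3000L), block, random_dna(3000L))
      sid <- sprintf("%s_provirus_scaf", host_ids[i])
      host_seq[[host_ids[i]]][[sid]] <- scaf
      provirus_rows[[i]] <- tibble(scaffold_id = sid)
    }
  }
  provirus_calls <- if (length(provirus_rows)) bind_rows(provirus_rows) else
    tibble(scaffold_id = character())

  # --- assemble tables
  scaffolds <- bind_rows(
    tibble(id = phage_ids, sample_id = "synth_1", entity = "phage",
           seq = unname(unlist(phage_seq))),
    bind_rows(lapply(host_ids, function(h) {
      tibble(id = names(host_seq[[h]]), sample_id = "synth_1", entity = "host",
             seq = unname(unlist(host_seq[[h]])))
    }))
  )
  scaffolds$length <- nchar(scaffolds$seq)

  units <- tibble(
    unit_id = phage_ids,
    kind = if_else(seq_len(n_p) %in% closed_idx, "closed_genome", "fragment"),
    scaffold_id = phage_ids,
    phylum = "Uroviricota"
  )
  bins <- bind_rows(lapply(host_ids, function(h) {
    tibble(bin_id = h, scaffold_id = names(host_seq[[h]]),
           completeness = 80, contamination = 5)
  }))

  genes <- if (length(genes)) bind_rows(genes) else
    tibble(gene_id = character(), scaffold_id = character(), start = integer(),
           end = integer(), strand = character(), product = character(),
           is_trna = logical(), seq = character())
  if (nrow(genes) > 0L) {
    # re-anchor coordinates on the final scaffolds (later insertions upstream
    # of a planted gene shift it); the 75 bp tRNAs are unique in practice
    seq_lookup <- setNames(scaffolds$seq, scaffolds$id)
    pos <- vapply(seq_len(nrow(genes)), function(i) {
      as.integer(regexpr(genes$seq[i], seq_lookup[[genes$scaffold_id[i]]], fixed = TRUE))
    }, integer(1))
    genes$start <- pos - 1L
    genes$end <- genes$start + nchar(genes$seq)
  }

  # --- depth profiles: lognormal unit depths per sample
  depth <- bind_rows(lapply(seq_len(spec$n_samples), function(s) {
    pd <- rlnorm(n_p, log(50), 0.5)
    hd <- rlnorm(n_h, log(8), 0.4)
    bind_rows(
      tibble(scaffold_id = phage_ids, sample_id = sprintf("sample_%d", s),
             mean_depth = pd),
      bind_rows(lapply(seq_len(n_h), function(i) {
        tibble(scaffold_id = names(host_seq[[i]]),
               sample_id = sprintf("sample_%d", s), mean_depth = hd[i])
      }))
    )
  }))
  depth <- left_join(depth, select(scaffolds, scaffold_id = "id", "length"),
                     by = "scaffold_id")

  truth <- list(
    true_links = mutate(truth_links,
                        phage_id = phage_ids[.data$phage],
                        host_id = host_ids[.data$host])[, c("phage_id", "host_id", "channel")],
    true_closed = phage_ids[closed_idx],
    planted_crisprs = if (length(planted_crisprs)) bind_rows(planted_crisprs) else
      tibble(scaffold_id = character(), repeat_seq = character(), spacer = character(),
             spacer_rank = integer(), phage_spacer = logical(), phage_id = character())
  )

  structure(list(spec = spec, scaffolds = scaffolds, units = units, bins = bins,
                 provirus_calls = provirus_calls, genes = genes, depth = depth,
                 truth = truth), class = "bfl_community")
}

#' Simulate genome populations for ANI clustering
#'
#' Builds clusters of genomes around independent random ancestors mutated
#' apart by `between` divergence, each member then diverging by `within`.
#' With the 95% ANI population threshold, `within = 0.01` and
#' `between = 0.20` give a cleanly recoverable partition.
#'
#' @param sizes integer vector; one cluster per element, of that many members.
#' @param genome_len member genome length (bases).
#' @param within,between per-base substitution rates within and between
#'   clusters.
#' @param seed RNG seed.
#' @return list with `seqs` (sequence tibble) and `truth` (tibble `id`,
#'   `population`).
#' @export
simulate_population_set <- function(sizes = c(3L, 2L, 2L), genome_len = 10000L,
                                    within = 0.01, between = 0.20, seed = 1L) {
  set.seed(seed)
  base <- random_dna(genome_len)
  rows <- list()
  for (cl in seq_along(sizes)) {
    anc <- mutate_seq(base, between)
    for (m in seq_len(sizes[cl])) {
      rows[[length(rows) + 1L]] <- tibble(
        id = sprintf("pop%d_member%d", cl, m),
        seq = mutate_seq(anc, within),
        population = cl
      )
    }
  }
  tbl <- bind_rows(rows)
  tbl$length <- nchar(tbl$seq)
  list(seqs = select(tbl, "id", "seq", "length"),
       truth = select(tbl, "id", "population"))
}

#' Simulate defence-gene count tables with planted fold changes
#'
#' Negative-binomial counts for a biofilm-versus-seawater comparison at one
#' or more locations.  Positive planted `log2fc` means seawater-enriched
#' (the pipeline's default sign convention).  Library sizes are log-normal;
#' dispersion is gene-wise constant at `dispersion`.
#'
#' @param n_genes genes per location (shared gene ids across locations).
#' @param n_per_group samples per group per location.
#' @param prop_da fraction of genes with a planted effect.
#' @param log2fc planted log2 fold change magnitude (split evenly between
#'   seawater- and biofilm-enriched genes).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param n_locations number of locations (independent count tables).
#' @param base_mu_meanlog,base_mu_sdlog log-normal parameters of baseline
#'   gene means.
#' @param libsize_sdlog log-normal sd of sample library size factors.
#' @param seed RNG seed.
#' @return list with `counts` (tibble `gene_id` + one column per sample),
#'   `samples` (tibble `sample`, `location`, `type`), `gene_meta`
#'   (`gene_id`, `length`, `system`), and `truth` (`gene_id`,
#'   `planted_log2fc`).
#' @export
simulate_defence_counts <- function(n_genes = 200L, n_per_group = 8L,
                                    prop_da = 0.1, log2fc = 1.5,
                                    dispersion = 0.1, n_locations = 2L,
                                    base_mu_meanlog = log(200), base_mu_sdlog = 1,
                                    libsize_sdlog = 0.25, seed = 1L) {
  set.seed(seed)
  gene_id <- sprintf("defgene_%04d", seq_len(n_genes))
  n_da <- round(prop_da * n_genes)
  lfc <- numeric(n_genes)
  if (n_da > 0L) {
    da_idx <- seq_len(n_da)
    half <- ceiling(n_da / 2)
    lfc[da_idx[seq_len(half)]] <- log2fc              # seawater-enriched
    if (n_da > half) lfc[da_idx[(half + 1L):n_da]] <- -log2fc # biofilm-enriched
  }
  base_mu <- rlnorm(n_genes, base_mu_meanlog, base_mu_sdlog)
  systems <- c("RM", "CRISPR-Cas", "TA", "BREX", "DISARM", "Zorya", "Hachiman",
               "Gabija", "Septu", "Thoeris", "Lamassu", "Druantia", "Wadjet",
               "Kiwa", "Shedu", "ABI")
  gene_meta <- tibble(gene_id = gene_id,
                      length = sample(300:1500, n_genes, replace = TRUE),
                      system = sample(systems, n_genes, replace = TRUE))
  counts_cols <- list(gene_id = gene_id)
  samp_rows <- list()
  for (loc in seq_len(n_locations)) {
    for (type in c("biofilm", "seawater")) {
      for (j in seq_len(n_per_group)) {
        sname <- sprintf("loc%d_%s_%d", loc, type, j)
        sf <- rlnorm(1L, 0, libsize_sdlog)
        mu <- base_mu * sf * if (type == "seawater") 2^lfc else 1
        counts_cols[[sname]] <- rnbinom(n_genes, mu = mu, size = 1 / dispersion)
        samp_rows[[length(samp_rows) + 1L]] <- tibble(
          sample = sname, location = sprintf("loc%d", loc), type = type)
      }
    }
  }
  list(counts = as_tibble(counts_cols), samples = bind_rows(samp_rows),
       gene_meta = gene_meta,
       truth = tibble(gene_id = gene_id, planted_log2fc = lfc))
}

#' Write / read a community and its ground truth as plain-text files
#'
#' `write_community()` emits FASTA plus TSV tables with documented headers;
#' `write_truth()`/`read_truth()` round-trip the ground-truth tables
#' losslessly (empty truths give header-only files).
#'
#' @param community a `bfl_community`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly (`write_*`); a truth list (`read_truth`).
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "bfl_community"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(select(community$scaffolds, "id", "seq"), file.path(dir, "scaffolds.fasta"))
  tsv <- function(x, f) readr::write_tsv(x, file.path(dir, f))
  tsv(select(community$scaffolds, -"seq"), "scaffolds.tsv")
  tsv(community$units, "units.tsv")
  tsv(community$bins, "bins.tsv")
  tsv(community$provirus_calls, "provirus_calls.tsv")
  tsv(community$genes, "genes.tsv")
  tsv(community$depth, "depth.tsv")
  write_truth(community$truth, file.path(dir, "truth"))
  invisible(dir)
}

#' @rdname write_community
#' @param truth a truth list as found in `bfl_community$truth`.
#' @param path directory for the truth TSVs.
#' @export
write_truth <- function(truth, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(truth$true_links, file.path(path, "true_links.tsv"))
  readr::write_tsv(tibble(phage_id = truth$true_closed), file.path(path, "true_closed.tsv"))
  readr::write_tsv(truth$planted_crisprs, file.path(path, "planted_crisprs.tsv"))
  invisible(path)
}

#' @rdname write_community
#' @export
read_truth <- function(path) {
  rd <- function(f, types) readr::read_tsv(file.path(path, f), col_types = types)
  list(
    true_links = rd("true_links.tsv", "ccc"),
    true_closed = rd("true_closed.tsv", "c")$phage_id,
    planted_crisprs = rd("planted_crisprs.tsv", "cccilc")
  )
}
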