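seq_tbl <- function(id, seq) tibble::tibble(id = id, seq = seq)

test_that("a planted CRISPR array is recovered with byte-identical spacers", {
  set.seed(41)
  rep28 <- rand_dna(28)
  spacers <- replicate(3, rand_dna(32))
  array <- paste0(paste0(rep28, spacers, collapse = ""), rep28)
  scaf <- paste0(rand_dna(2000), array, rand_dna(2000))
  got <- detect_crispr_arrays(scaf)
  expect_equal(nrow(got), 1L)
  expect_equal(got$repeat_seq, rep28)
  expect_equal(got$n_copies, 4L)
  expect_equal(got$spacers[[1]], spacers)
})

test_that("tandem repeats without spacers do not form arrays", {
  scaf <- paste0(rand_dna(500), strrep(rand_dna(40), 5), rand_dna(500))
  set.seed(43)
  scaf <- paste0(rand_dna(500), strrep(rand_dna(40), 5), rand_dna(500))
  expect_equal(nrow(detect_crispr_arrays(scaf)), 0L)
})

test_that("generator-planted arrays are all recovered from host scaffolds", {
  comm <- generate_community(community_spec(seed = 55L))
  pc <- comm$truth$planted_crisprs
  for (sid in unique(pc$scaffold_id)) {
    scaf <- comm$scaffolds[comm$scaffolds$id == sid, ]
    got <- detect_crispr_arrays(scaf)
    expect_gte(nrow(got), 1L)
    planted <- pc$spacer[pc$scaffold_id == sid]
    expect_true(all(planted %in% unlist(got$spacers)),
                info = sprintf("scaffold %s", sid))
  }
})

test_that("spacer links require an exact match longer than 6 bp", {
  set.seed(47)
  phage <- seq_tbl("p1", rand_dna(8000))
  sp <- substr(phage$seq, 100, 131)
  arrays <- tibble::tibble(scaffold_id = "h", array_id = 1L, repeat_seq = "r",
                           n_copies = 3L, positions = list(c(0L)),
                           spacers = list(c(sp)))
  link <- link_by_spacers(arrays, phage, "p1", "h1")
  expect_equal(link$channel, "crispr")
  expect_equal(link$n_spacer_hits, 1L)

  # reverse-complement spacers count too
  arrays_rc <- arrays
  arrays_rc$spacers <- list(revcomp_chr(sp))
  expect_false(is.null(link_by_spacers(arrays_rc, phage, "p1", "h1")))

  # a 6 bp spacer never links, even when it matches exactly
  arrays6 <- arrays
  arrays6$spacers <- list(substr(phage$seq, 100, 105))
  expect_null(link_by_spacers(arrays6, phage, "p1", "h1"))

  # random spacers vs a random phage: no collisions in 100 trials
  hits <- 0L
  for (i in 1:100) {
    a <- arrays
    a$spacers <- list(rand_dna(30))
    if (!is.null(link_by_spacers(a, seq_tbl("p", rand_dna(10000)), "p", "h"))) {
      hits <- hits + 1L
    }
  }
  expect_equal(hits, 0L)
})

test_that("homology links enforce both identity and length thresholds", {
  set.seed(49)
  shared <- rand_dna(5000)
  virus <- seq_tbl("v", shared)
  host <- seq_tbl("h", paste0(rand_dna(1000), shared, rand_dna(1000)))
  link <- link_by_homology(virus, host, "v", "hb")
  expect_equal(link$channel, "homology")
  expect_equal(link$identity, 1.0)
  expect_gte(link$aln_len, 5000L)

  # 2.4 kb of perfect match is below the 2.5 kb threshold
  block <- rand_dna(2400)
  virus2 <- seq_tbl("v", paste0(rand_dna(2000), block, rand_dna(2000)))
  host2 <- seq_tbl("h", paste0(rand_dna(2000), block, rand_dna(2000)))
  expect_null(link_by_homology(virus2, host2, "v", "hb"))

  # planted 3 kb block at 10% divergence links
  donor <- rand_dna(9000)
  blk <- sub_mutate(substr(donor, 3000, 5999), 0.10)
  host3 <- seq_tbl("h", paste0(rand_dna(3000), blk, rand_dna(3000)))
  link3 <- link_by_homology(seq_tbl("v", donor), host3, "v", "hb")
  expect_false(is.null(link3))
  expect_gte(link3$aln_len, 2500L)
})

test_that("tRNA links require full-length exact identity on either strand", {
  trna <- rand_dna(75)
  set.seed(53)
  trna <- rand_dna(75)
  vg <- tibble::tibble(gene_id = "vt", scaffold_id = "v", is_trna = TRUE, seq = trna)
  hg <- tibble::tibble(gene_id = "ht", scaffold_id = "h", is_trna = TRUE, seq = trna)
  link <- link_by_trna(vg, hg, "v", "hb")
  expect_equal(link$n_trna_hits, 1L)

  hg_rc <- hg
  hg_rc$seq <- revcomp_chr(trna)
  expect_false(is.null(link_by_trna(vg, hg_rc, "v", "hb")))

  hg_mut <- hg
  substr(hg_mut$seq, 10, 10) <- if (substr(trna, 10, 10) == "A") "C" else "A"
  expect_null(link_by_trna(vg, hg_mut, "v", "hb"))
  expect_null(link_by_trna(vg[0, ], hg, "v", "hb"))
})

test_that("k-mer links follow the exact shared 25-mer arithmetic", {
  set.seed(59)
  block <- rand_dna(300)
  virus <- seq_tbl("v", paste0(rand_dna(4000), block, rand_dna(4000)))
  host <- seq_tbl("h", paste0(rand_dna(4000), block, rand_dna(4000)))
  link <- link_by_kmers(virus, host, "v", "hb")
  expect_gte(link$n_shared_kmers, 276L)  # 300 - 25 + 1

  expect_null(link_by_kmers(seq_tbl("v", rand_dna(10000)),
                            seq_tbl("h", rand_dna(10000)), "v", "hb"))
})

test_that("pair integration uses OR semantics and deduplicates channels", {
  links <- tibble::tibble(
    virus_unit_id = c("v1", "v2", "v2", "v2"),
    host_bin_id = c("h1", "h1", "h1", "h2"),
    channel = c("crispr", "homology", "kmer", "kmer"))
  pairs <- integrate_pairs(links)
  expect_equal(nrow(pairs), 3L)
  expect_equal(pairs$channels[pairs$virus_unit_id == "v1"], "crispr")
  expect_equal(pairs$channels[pairs$virus_unit_id == "v2" &
                                pairs$host_bin_id == "h1"], "homology,kmer")
  expect_equal(pairs$n_channels[pairs$virus_unit_id == "v2" &
                                  pairs$host_bin_id == "h1"], 2L)
  # removing a channel never creates a pair
  fewer <- integrate_pairs(links[links$channel != "kmer", ])
  expect_true(all(paste(fewer$virus_unit_id, fewer$host_bin_id) %in%
                    paste(pairs$virus_unit_id, pairs$host_bin_id)))
})

test_that("network components equal a union-find oracle on random bipartite graphs", {
  set.seed(61)
  for (rep in 1:20) {
    nv <- sample(3:10, 1); nh <- sample(3:10, 1)
    ne <- sample(2:15, 1)
    pairs <- tibble::tibble(
      virus_unit_id = sprintf("v%d", sample(nv, ne, TRUE)),
      host_bin_id = sprintf("h%d", sample(nh, ne, TRUE))) |>
      dplyr::distinct()
    got <- pair_network_components(pairs)
    nodes <- got$membership$node_id
    want <- oracle_components(nodes, paste0("V:", pairs$virus_unit_id),
                              paste0("H:", pairs$host_bin_id))
    # same partition: groups agree up to relabelling
    expect_equal(length(unique(got$membership$group)), length(unique(want)))
    expect_true(all(tapply(want, got$membership$group,
                           function(x) length(unique(x))) == 1L))
    expect_equal(got$n_groups, length(unique(want)))
  }
})

test_that("a provirus unit is never linked to its own host bin", {
  set.seed(67)
  shared <- rand_dna(6000)
  units <- tibble::tibble(unit_id = "prov", kind = "fragment", scaffold_id = "s1")
  bins <- tibble::tibble(bin_id = "hb", scaffold_id = c("s1", "s2"),
                         completeness = 80, contamination = 5)
  scaffolds <- tibble::tibble(id = c("s1", "s2"),
                              seq = c(shared, paste0(rand_dna(100), shared)))
  links <- link_virus_hosts(units, bins, scaffolds)
  expect_equal(nrow(links), 0L)
})
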