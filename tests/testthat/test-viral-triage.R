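bin_tbl <- function(...) {
  tibble::tibble(...)
}

test_that("provirus flagging is the conjunction of call and quality bin", {
  calls <- bin_tbl(scaffold_id = c("s1", "s2", "s4"))
  bins <- bin_tbl(scaffold_id = c("s1", "s3", "s4"),
                  bin_id = c("b1", "b1", "b2"),
                  completeness = c(80, 80, 40),
                  contamination = c(5, 5, 5))
  fl <- flag_proviruses(calls, bins)
  get <- function(id) fl$is_provirus[fl$scaffold_id == id]
  expect_true(get("s1"))    # call + good bin
  expect_false(get("s2"))   # call, unbinned
  expect_false(get("s3"))   # binned, no call
  expect_false(get("s4"))   # call, but bin below completeness 50
  expect_true(all(fl$reason[fl$is_provirus] == "checkv_provirus_call"))
})

test_that("provirus calls for unknown scaffolds are dropped with a warning", {
  calls <- bin_tbl(scaffold_id = c("s1", "ghost"))
  bins <- bin_tbl(scaffold_id = "s1", bin_id = "b1",
                  completeness = 80, contamination = 5)
  expect_warning(fl <- flag_proviruses(calls, bins, known_scaffolds = "s1"),
                 "ghost")
  expect_false("ghost" %in% fl$scaffold_id)
})

test_that("closed-genome calling enforces all six repeat criteria", {
  set.seed(33)
  mk <- function(rep_seq, mid) paste0(rep_seq, mid, rep_seq)
  clean <- mk(rand_dna(40), rand_dna(5000))
  lowc <- mk(strrep("A", 40), rand_dna(5000))
  with_n <- mk(paste0(rand_dna(30), "N", rand_dna(9)), rand_dna(5000))
  rep6 <- rand_dna(40)
  many <- paste0(rep6, rand_dna(1000), rep6, rand_dna(1000), rep6,
                 rand_dna(1000), rep6, rand_dna(1000), rep6,
                 rand_dna(1000), rep6)
  fat_rep <- rand_dna(600)
  fat <- paste0(fat_rep, rand_dna(3800), fat_rep)  # covers 24% > 20%
  provir <- mk(rand_dna(40), rand_dna(5000))
  no_dtr <- rand_dna(5080)
  scaffolds <- tibble::tibble(
    id = c("clean", "lowc", "with_n", "many", "fat", "provir", "no_dtr"),
    seq = c(clean, lowc, with_n, many, fat, provir, no_dtr))
  flags <- tibble::tibble(scaffold_id = "provir", is_provirus = TRUE)
  got <- call_closed_genomes(scaffolds, flags)
  expect_equal(got$unit_id, "clean")
  expect_equal(got$kind, "closed_genome")
})

test_that("majority-rule taxonomy follows summed bit scores with strict majority", {
  t1 <- tibble::tibble(phylum = c("Uroviricota", "Hofneiviricota"),
                       bitscore = c(300, 100))
  expect_equal(majority_rule_phylum(t1), "Uroviricota")
  t2 <- tibble::tibble(phylum = c("Uroviricota", "Hofneiviricota"),
                       bitscore = c(200, 200))
  expect_equal(majority_rule_phylum(t2), "unclassified")  # exact split
  expect_equal(majority_rule_phylum(t1[0, ]), "unclassified")
  expect_error(majority_rule_phylum(t1, fraction = 0), "fraction")
})

test_that("majority rule agrees with brute-force per-phylum summation", {
  set.seed(37)
  phyla <- c("Uroviricota", "Hofneiviricota", "Preplasmiviricota", "Phixviricota")
  for (i in 1:300) {
    n <- sample(1:12, 1)
    tab <- tibble::tibble(phylum = sample(phyla, n, TRUE),
                          bitscore = round(runif(n, 10, 500)))
    sums <- tapply(tab$bitscore, tab$phylum, sum)
    want <- if (max(sums) > 0.5 * sum(tab$bitscore)) {
      names(sums)[which.max(sums)]
    } else "unclassified"
    expect_equal(majority_rule_phylum(tab), want)
  }
})

test_that("purity filter discards mixed-phylum and multi-TerL bins, conserving scaffolds", {
  gene_tax <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    scaffold_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    phylum = c("Uroviricota", "Uroviricota", "Uroviricota", "Preplasmiviricota",
               "Uroviricota", "Uroviricota"),
    bitscore = c(100, 100, 100, 100, 100, 100))
  bins <- tibble::tibble(bin_id = c("A", "A", "B", "B", "C", "C"),
                         scaffold_id = c("a1", "a2", "b1", "b2", "c1", "c2"))
  # bin C carries two TerL genes
  res <- purity_filter(bins, gene_tax, terl_labels = c("g5", "g6"))
  expect_equal(sort(unique(res$kept$bin_id)), "A")
  expect_setequal(res$released, c("b1", "b2", "c1", "c2"))
  expect_setequal(c(res$kept$scaffold_id, res$released), bins$scaffold_id)
  expect_equal(length(c(res$kept$scaffold_id, res$released)), nrow(bins))
  expect_equal(unique(res$kept$phylum), "Uroviricota")
})

test_that("single-TerL single-phylum bins are kept", {
  gene_tax <- tibble::tibble(gene_id = c("g1", "g2"),
                             scaffold_id = c("a1", "a2"),
                             phylum = "Uroviricota", bitscore = 50)
  bins <- tibble::tibble(bin_id = "A", scaffold_id = c("a1", "a2"))
  res <- purity_filter(bins, gene_tax, terl_labels = "g1")
  expect_equal(nrow(res$kept), 2L)
  expect_length(res$released, 0L)
})

test_that("prokaryote-infecting phylum filter keeps the allow-list", {
  units <- tibble::tibble(unit_id = c("u1", "u2", "u3"),
                          phylum = c("Uroviricota", "Nucleocytoviricota",
                                     "unclassified"))
  expect_equal(filter_prok_viruses(units)$unit_id, "u1")
  expect_setequal(filter_prok_viruses(units, keep_unclassified = TRUE)$unit_id,
                  c("u1", "u3"))
})
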