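test_that("unit depth is the length-weighted mean over member scaffolds", {
  depth <- tibble::tibble(
    scaffold_id = c("s1", "s2"), sample_id = "smp",
    mean_depth = c(10, 2), length = c(1000L, 3000L))
  members <- tibble::tibble(unit_id = "u", scaffold_id = c("s1", "s2"))
  got <- mean_depth(depth, members)
  expect_equal(got$mean_depth, 4.0)

  single <- mean_depth(depth[1, ], members[1, ])
  expect_equal(single$mean_depth, 10)

  expect_error(mean_depth(depth, tibble::tibble(unit_id = "u", scaffold_id = "s9")),
               "s9")
})

test_that("unit depth equals a per-base oracle on random profiles", {
  set.seed(91)
  for (rep in 1:10) {
    lens <- sample(50:200, 3)
    per_base <- lapply(lens, function(L) runif(L, 0, 30))
    depth <- tibble::tibble(
      scaffold_id = paste0("s", 1:3), sample_id = "x",
      mean_depth = vapply(per_base, mean, numeric(1)), length = lens)
    members <- tibble::tibble(unit_id = "u", scaffold_id = paste0("s", 1:3))
    want <- mean(unlist(per_base))
    expect_equal(mean_depth(depth, members)$mean_depth, want, tolerance = 1e-12)
  }
})

test_that("virus-to-prokaryote ratios accumulate multiple phages", {
  vd <- tibble::tibble(unit_id = c("p1", "p2", "p3"), sample_id = "x",
                       mean_depth = c(50, 30, 20))
  hd <- tibble::tibble(unit_id = c("h1", "h2", "h3", "h0"), sample_id = "x",
                       mean_depth = c(5, 5, 0, 4))
  units <- tibble::tibble(unit_id = c("p1", "p2", "p3"),
                          kind = c("closed_genome", "bin", "bin"))
  pairs <- tibble::tibble(virus_unit_id = c("p1", "p2", "p3", "p1"),
                          host_bin_id = c("h1", "h2", "h2", "h3"))
  vpr <- virus_host_ratio(pairs, vd, hd, units)
  g <- function(h) vpr[vpr$host_bin_id == h, ]
  expect_equal(g("h1")$vpr, 10)            # 50 / 5
  expect_equal(g("h2")$vpr, 10)            # (30 + 20) / 5, accumulation
  expect_true(g("h3")$undefined)           # zero host depth
  expect_true(is.na(g("h3")$vpr))
  expect_equal(g("h0")$vpr, 0)             # no paired viruses

  # fragments are excluded from the ratio
  units_frag <- dplyr::mutate(units, kind = c("closed_genome", "fragment", "fragment"))
  vpr2 <- virus_host_ratio(pairs, vd, hd, units_frag)
  expect_equal(vpr2[vpr2$host_bin_id == "h2", ]$vpr, 0)

  # invariant under uniform depth scaling
  vpr3 <- virus_host_ratio(pairs,
                           dplyr::mutate(vd, mean_depth = mean_depth * 7),
                           dplyr::mutate(hd, mean_depth = mean_depth * 7), units)
  expect_equal(vpr3$vpr, vpr$vpr)
})

test_that("RPKM follows its definition and scaling law", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(100, 900))
  lens <- tibble::tibble(gene_id = c("g1", "g2"), length = c(1000L, 2000L))
  r <- rpkm(counts, lens, library_sizes = c(s1 = 1e6))
  expect_equal(r$s1[1], 100)
  expect_equal(r$s1[2], 450)
  r2 <- rpkm(counts, lens, library_sizes = c(s1 = 2e6))
  expect_equal(r2$s1, r$s1 / 2)
  expect_error(rpkm(counts, lens, library_sizes = c(s1 = 0)), "positive")
})

test_that("relative abundances sum to one within each location and type", {
  set.seed(93)
  counts <- tibble::tibble(gene_id = paste0("g", 1:20))
  samples <- tidyr::crossing(location = c("HK", "RS"),
                             type = c("biofilm", "seawater"),
                             rep = 1:3) |>
    dplyr::mutate(sample = sprintf("%s_%s_%d", location, type, rep))
  for (s in samples$sample) counts[[s]] <- rpois(20, 200)
  lens <- tibble::tibble(gene_id = counts$gene_id,
                         length = sample(300:1500, 20))
  rel <- relative_abundance(rpkm(counts, lens), samples)
  sums <- rel |>
    dplyr::group_by(location, type) |>
    dplyr::summarise(s = sum(rel_abundance), .groups = "drop")
  expect_equal(sums$s, rep(1, 4))
})

test_that("TPM sums to one million per repeat and the expression rule is disjunctive", {
  counts <- tibble::tibble(gene_id = paste0("g", 1:4),
                           r1 = c(10, 10, 10, 10),
                           r2 = c(5, 0, 8, 2),
                           r3 = c(1, 2, 3, 0))
  lens <- tibble::tibble(gene_id = counts$gene_id, length = rep(500L, 4))
  hits <- tibble::tibble(gene_id = "g2", n_transcripts = 1L)
  ex <- tpm_and_expressed(counts, lens, hits)
  expect_equal(ex$tpm_r1, rep(250000, 4))   # equal counts, equal lengths
  for (r in c("tpm_r1", "tpm_r2", "tpm_r3")) {
    expect_equal(sum(ex[[r]]), 1e6, tolerance = 1e-6)
  }
  g <- function(id) ex[ex$gene_id == id, ]
  expect_true(g("g1")$expressed)    # reads in all three repeats
  expect_true(g("g2")$expressed)    # transcript in one repeat despite a zero
  expect_false(g("g4")$expressed)   # reads in 2 of 3 repeats, no transcript
  expect_true(g("g3")$expressed)
})

test_that("the BAM adapter reproduces hand-computed per-scaffold depth", {
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:ctgA\tLN:100",
    "@SQ\tSN:ctgB\tLN:50",
    "r1\t0\tctgA\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r2\t0\tctgA\t6\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r3\t0\tctgB\t11\t60\t20M\t*\t0\t0\tACGTACGTACGTACGTACGT\t*")
  dir <- withr::local_tempdir()
  sam_path <- file.path(dir, "toy.sam")
  writeLines(sam, sam_path)
  bam_path <- Rsamtools::asBam(sam_path, file.path(dir, "toy"),
                               overwrite = TRUE, indexDestination = TRUE)
  depth <- depth_from_bam(bam_path, sample_id = "toy")
  expect_equal(depth$mean_depth[depth$scaffold_id == "ctgA"], 20 / 100)
  expect_equal(depth$mean_depth[depth$scaffold_id == "ctgB"], 20 / 50)
  expect_equal(depth$length, c(100L, 50L))
})
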