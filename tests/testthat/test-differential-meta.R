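test_that("DerSimonian-Laird matches the hand-computed two-study closed form", {
  eff <- tibble::tibble(gene_id = "g", location = c("a", "b"),
                        log2fc = c(1, 1), se = c(0.5, 0.5))
  r <- tidy(random_effects_meta(eff))
  expect_equal(r$pooled_log2fc, 1)
  expect_equal(r$tau2, 0)
  expect_equal(r$se_pooled, sqrt(1 / 8), tolerance = 1e-12)  # 0.353553
  expect_equal(r$ci_lo, 1 - 1.96 * sqrt(1 / 8), tolerance = 1e-4)

  # heterogeneous pair: hand-computed DL
  y <- c(2, 0); se <- c(0.5, 0.5)
  w <- 1 / se^2
  q <- sum(w * (y - weighted.mean(y, w))^2)
  tau2 <- max(0, (q - 1) / (sum(w) - sum(w^2) / sum(w)))
  wstar <- 1 / (se^2 + tau2)
  r2 <- tidy(random_effects_meta(tibble::tibble(
    gene_id = "g", location = c("a", "b"), log2fc = y, se = se)))
  expect_equal(r2$tau2, tau2, tolerance = 1e-12)
  expect_equal(r2$pooled_log2fc, sum(wstar * y) / sum(wstar), tolerance = 1e-12)
  expect_equal(r2$se_pooled, sqrt(1 / sum(wstar)), tolerance = 1e-12)
})

test_that("a single-location meta returns the input effect exactly", {
  r <- tidy(random_effects_meta(tibble::tibble(
    gene_id = "g", location = "a", log2fc = 1.2, se = 0.3)))
  expect_equal(r$pooled_log2fc, 1.2)
  expect_equal(r$se_pooled, 0.3)
  expect_equal(r$tau2, 0)
  expect_error(random_effects_meta(tibble::tibble(
    gene_id = character(), location = character(),
    log2fc = double(), se = double())), "no effects")
})

test_that("DerSimonian-Laird agrees with metafor on random inputs", {
  skip_if_not_installed("metafor")
  set.seed(103)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    y <- rnorm(k, 1, 0.8)
    se <- runif(k, 0.1, 0.6)
    ours <- tidy(random_effects_meta(tibble::tibble(
      gene_id = "g", location = paste0("l", 1:k), log2fc = y, se = se)))
    ref <- metafor::rma(yi = y, sei = se, method = "DL")
    expect_equal(ours$pooled_log2fc, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(ours$se_pooled, ref$se, tolerance = 1e-8)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(ours$q_stat, ref$QE, tolerance = 1e-8)
  }
})

test_that("BH adjustment equals the textbook step-up procedure", {
  set.seed(107)
  for (rep in 1:20) {
    p <- runif(sample(5:200, 1))
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("planted log2 fold changes are recovered within tolerance", {
  sim <- simulate_defence_counts(n_genes = 100L, n_per_group = 8L,
                                 prop_da = 0.2, log2fc = 1.5,
                                 dispersion = 0.1, n_locations = 1L,
                                 seed = 109L)
  da <- differential_abundance(sim$counts, sim$samples)
  r <- tidy(da)
  up <- sim$truth$gene_id[sim$truth$planted_log2fc == 1.5]
  dn <- sim$truth$gene_id[sim$truth$planted_log2fc == -1.5]
  expect_lt(abs(mean(r$log2fc[r$gene_id %in% up]) - 1.5), 0.4)
  expect_lt(abs(mean(r$log2fc[r$gene_id %in% dn]) + 1.5), 0.4)
  # planted genes are overwhelmingly detected at padj < 0.05
  expect_gt(mean(r$padj[r$gene_id %in% c(up, dn)] < 0.05), 0.9)
  # positive sign means seawater-enriched by default, and the flag flips it
  expect_gt(mean(r$log2fc[r$gene_id %in% up]), 0)
  flipped <- tidy(differential_abundance(sim$counts, sim$samples,
                                         positive_is = "biofilm"))
  expect_equal(flipped$log2fc, -r$log2fc, tolerance = 1e-8)
})

test_that("fold-change estimates are invariant to count doubling and ~match DESeq2", {
  sim <- simulate_defence_counts(n_genes = 60L, n_per_group = 6L,
                                 prop_da = 0.25, log2fc = 1.5,
                                 dispersion = 0.1, n_locations = 1L,
                                 seed = 113L)
  r1 <- tidy(differential_abundance(sim$counts, sim$samples))
  doubled <- sim$counts
  for (s in setdiff(names(doubled), "gene_id")) doubled[[s]] <- doubled[[s]] * 2L
  # size factors absorb the doubling; only the pseudocount in the dispersion
  # floor moves the estimates, and only in the third decimal
  r2 <- tidy(differential_abundance(doubled, sim$samples))
  expect_equal(r2$log2fc, r1$log2fc, tolerance = 0.02)

  skip_if_not_installed("DESeq2")
  mat <- as.matrix(sim$counts[, -1])
  rownames(mat) <- sim$counts$gene_id
  storage.mode(mat) <- "integer"
  coldata <- data.frame(type = factor(sim$samples$type,
                                      levels = c("biofilm", "seawater")))
  dds <- DESeq2::DESeqDataSetFromMatrix(mat, coldata, ~type)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  both <- dplyr::inner_join(
    r1, tibble::tibble(gene_id = rownames(res), ref_lfc = res$log2FoldChange),
    by = "gene_id")
  expect_gt(cor(both$log2fc, both$ref_lfc, use = "complete.obs"), 0.95)
})

test_that("all-zero genes are excluded with a note", {
  sim <- simulate_defence_counts(n_genes = 20L, n_per_group = 3L, prop_da = 0,
                                 n_locations = 1L, seed = 127L)
  counts <- sim$counts
  counts[counts$gene_id == counts$gene_id[1], -1] <- 0
  da <- differential_abundance(counts, sim$samples)
  expect_equal(da$excluded, counts$gene_id[1])
  expect_false(counts$gene_id[1] %in% tidy(da)$gene_id)
})

test_that("significance selection gates on DA padj then meta p", {
  da <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), each = 2),
    location = rep(c("a", "b"), 3),
    log2fc = c(2, 2.2, 0.05, -0.02, 1.5, 1.4),
    se = 0.2,
    p = c(1e-8, 1e-8, 0.9, 0.8, 1e-6, 1e-6),
    padj = c(1e-6, 1e-6, 0.95, 0.9, 0.06, 0.06))
  sel <- select_significant(da, gene_systems = tibble::tibble(
    gene_id = c("g1", "g2", "g3"), system = c("RM", "TA", "RM")))
  # g3 has padj 0.06 everywhere: excluded from the meta input
  expect_equal(sel$genes$gene_id, "g1")
  expect_equal(sel$genes$direction, "seawater-enriched")
  expect_equal(sel$by_system$system, "RM")
  expect_equal(sel$by_system$n_genes, 1L)
})

test_that("tidy, glance and autoplot work on fitted objects", {
  sim <- simulate_defence_counts(n_genes = 30L, n_per_group = 4L,
                                 prop_da = 0.2, n_locations = 1L, seed = 131L)
  da <- differential_abundance(sim$counts, sim$samples)
  expect_s3_class(tidy(da), "tbl_df")
  g <- glance(da)
  expect_equal(g$n_genes, 30L)
  expect_s3_class(autoplot(da), "ggplot")

  meta <- random_effects_meta(dplyr::select(tidy(da), gene_id, location,
                                            log2fc, se))
  expect_s3_class(tidy(meta), "tbl_df")
  expect_equal(glance(meta)$n_genes, 30L)
  expect_s3_class(autoplot(meta), "ggplot")
})
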