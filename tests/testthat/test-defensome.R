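cfg <- load_defence_config()
amg_cfg <- load_amg_config()

test_that("defence calling is the PADS x PFAM conjunction at the stated gates", {
  dm <- cfg$domain_map
  rm_acc <- dm$accession[dm$system == "RM"][1]
  pads <- tibble::tibble(
    gene_id = c("ok", "low_id", "bad_e", "weak_bits", "no_domain"),
    system = "RM",
    identity = c(45, 29, 60, 60, 60),
    evalue = c(1e-20, 1e-20, 1e-5, 1e-20, 1e-20))
  pfam <- tibble::tibble(
    gene_id = c("ok", "low_id", "bad_e", "weak_bits"),
    accession = rm_acc,
    evalue = 1e-10,
    bitscore = c(100, 100, 100, 25))
  calls <- call_defence_genes(pads, pfam, dm)
  expect_equal(calls$gene_id, "ok")
  expect_equal(calls$system, "RM")

  # boundary: identity exactly 30 and bitscore exactly 30 pass
  pads_b <- tibble::tibble(gene_id = "b", system = "RM", identity = 30,
                           evalue = 1e-11)
  pfam_b <- tibble::tibble(gene_id = "b", accession = rm_acc, evalue = 1e-4,
                           bitscore = 30)
  expect_equal(nrow(call_defence_genes(pads_b, pfam_b, dm)), 1L)
})

test_that("the PFAM domain must confirm the same system as the PADS hit", {
  dm <- cfg$domain_map
  ta_acc <- dm$accession[dm$system == "TA"][1]
  pads <- tibble::tibble(gene_id = "x", system = "RM", identity = 60,
                         evalue = 1e-30)
  pfam <- tibble::tibble(gene_id = "x", accession = ta_acc, evalue = 1e-10,
                         bitscore = 100)
  expect_equal(nrow(call_defence_genes(pads, pfam, dm)), 0L)
})

test_that("unknown systems in the domain map raise a config error", {
  bad <- tibble::tibble(system = "MagicShield", component = "c",
                        accession = "PF00001", rm_type = NA_character_)
  expect_error(call_defence_genes(tibble::tibble(), tibble::tibble(), bad),
               class = "bioflink_config_error")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines("systems:\n  MagicShield:\n    components:\n      c: [PF00001]", tmp)
  expect_error(load_defence_config(tmp), class = "bioflink_config_error")
})

test_that("counter-defence calls are restricted to viral genes and typed", {
  dm <- cfg$domain_map
  rm_row <- dm[dm$system == "RM", ][1, ]
  pads <- tibble::tibble(gene_id = c("viral_g", "host_g"), system = "RM",
                         identity = 60, evalue = 1e-30)
  pfam <- tibble::tibble(gene_id = c("viral_g", "host_g"),
                         accession = rm_row$accession,
                         evalue = 1e-10, bitscore = 100)
  calls <- call_counter_defence(pads, pfam, dm, viral_genes = "viral_g")
  expect_equal(calls$gene_id, "viral_g")
  expect_equal(calls$system, "RM")
  expect_false(is.na(calls$rm_type))
})

test_that("AMG calling requires both hits, set membership, and flags edge genes", {
  kegg <- tibble::tibble(
    gene_id = c("amg1", "amg_edge", "not_in_set", "weak_kegg"),
    accession = c("K00525", "K00525", "K99999", "K00525"),
    evalue = c(1e-20, 1e-20, 1e-20, 1e-20),
    score = c(300, 300, 300, 50),
    threshold = 100)
  pfam <- tibble::tibble(
    gene_id = c("amg1", "amg_edge", "not_in_set", "weak_kegg"),
    accession = "PF99999", evalue = 1e-10, bitscore = 120)
  pos <- tibble::tibble(
    gene_id = c("amg1", "up", "dn", "amg_edge", "other"),
    scaffold_id = c("sc1", "sc1", "sc1", "sc2", "sc2"),
    start = c(1000L, 0L, 2000L, 0L, 1000L))
  got <- call_amgs(kegg, pfam, amg_cfg, pos)
  expect_setequal(got$gene_id, c("amg1", "amg_edge"))
  expect_false(got$edge_gene[got$gene_id == "amg1"])    # internal gene
  expect_true(got$edge_gene[got$gene_id == "amg_edge"]) # first on scaffold
  expect_equal(got$gene[got$gene_id == "amg1"], "nrdA")
})

test_that("system completeness equals a brute-force set cover over components", {
  req <- cfg$required
  # hand case: TA complete with both components, CRISPR-Cas incomplete with cas1 only
  calls <- tibble::tibble(
    container_id = c("bin1", "bin1", "bin1"),
    system = c("TA", "TA", "CRISPR-Cas"),
    component = c("toxin", "antitoxin", "cas1"))
  got <- system_completeness(calls, req)
  expect_true(got$complete[got$system == "TA"])
  expect_false(got$complete[got$system == "CRISPR-Cas"])

  set.seed(97)
  for (rep in 1:50) {
    sub <- req[sample(nrow(req), sample(3:10, 1)), ]
    sub$container_id <- "c"
    got <- system_completeness(sub, req)
    for (i in seq_len(nrow(got))) {
      sys <- got$system[i]
      want <- all(req$component[req$system == sys] %in%
                    sub$component[sub$system == sys])
      expect_equal(got$complete[i], want)
    }
  }
})

test_that("calls are monotone in the thresholds", {
  sim <- simulate_defensome_hits(seed = 13L)
  strict <- call_defence_genes(sim$pads_hits, sim$pfam_hits, cfg$domain_map)
  relaxed <- call_defence_genes(sim$pads_hits, sim$pfam_hits, cfg$domain_map,
                                min_identity = 20, max_pads_evalue = 1e-3,
                                min_pfam_bitscore = 10, max_pfam_evalue = 1e-1)
  expect_true(all(strict$gene_id %in% relaxed$gene_id))
  expect_gte(nrow(relaxed), nrow(strict))
})

test_that("the hit simulator's planted truth is recovered exactly", {
  sim <- simulate_defensome_hits(n_defence = 15L, n_decoy = 4L, n_amg = 5L,
                                 seed = 99L)
  calls <- call_defence_genes(sim$pads_hits, sim$pfam_hits, cfg$domain_map)
  want <- sim$truth$gene_id[sim$truth$role %in% c("defence", "counter_defence")]
  expect_setequal(unique(calls$gene_id), want)

  amgs <- call_amgs(sim$kegg_hits, sim$pfam_hits, amg_cfg, sim$gene_positions)
  expect_setequal(amgs$gene_id, sim$truth$gene_id[sim$truth$role == "amg"])

  counter <- call_counter_defence(sim$pads_hits, sim$pfam_hits, cfg$domain_map,
                                  viral_genes = sim$truth$gene_id[sim$truth$entity == "virus"])
  expect_setequal(counter$gene_id,
                  sim$truth$gene_id[sim$truth$role == "counter_defence"])
})
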