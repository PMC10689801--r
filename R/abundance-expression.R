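#' Coverage, virus-to-prokaryote ratios, RPKM/TPM and expression calls
#'
#' Quantification stage.  The canonical depth input is a per-scaffold depth
#' table (`scaffold_id`, `sample_id`, `mean_depth`, `length`); an optional
#' BAM adapter ([depth_from_bam()]) computes the same table from alignments
#' when one is available.
#'
#' @name abundance_expression
NULL

#' Length-weighted mean depth of multi-scaffold units
#'
#' @param depth depth tibble (`scaffold_id`, `sample_id`, `mean_depth`,
#'   `length`).
#' @param members membership tibble mapping `unit_id` to `scaffold_id`
#'   (viral units or host bins alike).
#' @return tibble `unit_id`, `sample_id`, `mean_depth` (length-weighted
#'   mean over member scaffolds).
#' @export
mean_depth <- function(depth, members) {
  missing <- setdiff(members$scaffold_id, depth$scaffold_id)
  if (length(missing) > 0L) {
    abort(sprintf("no depth for scaffold(s): %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  members |>
    distinct(.data$unit_id, .data$scaffold_id) |>
    inner_join(depth, by = "scaffold_id", relationship = "many-to-many") |>
    group_by(.data$unit_id, .data$sample_id) |>
    summarise(mean_depth = sum(.data$mean_depth * .data$length) / sum(.data$length),
              .groups = "drop")
}

#' Virus-to-prokaryote ratio per host bin
#'
#' For each host, the summed mean depth of all its paired viruses divided by
#' the host's own mean depth (multiple viruses accumulate).  Only viral
#' units of kind `bin` or `closed_genome` are counted: fragments do not
#' represent whole viral populations.  Hosts with zero depth are flagged
#' (`undefined = TRUE`, `vpr = NA`); hosts with no paired viruses get 0.
#'
#' @param pairs pair tibble (`virus_unit_id`, `host_bin_id`).
#' @param virus_depth,host_depth unit-level depth tibbles ([mean_depth()]
#'   output, `unit_id`, `sample_id`, `mean_depth`).
#' @param units viral unit tibble with `unit_id`, `kind`; used to exclude
#'   fragments.  Pass `NULL` to skip the kind filter.
#' @return tibble `host_bin_id`, `sample_id`, `vpr`, `n_viruses`,
#'   `undefined`.
#' @export
virus_host_ratio <- function(pairs, virus_depth, host_depth, units = NULL) {
  if (!is.null(units)) {
    keep <- units$unit_id[units$kind %in% c("bin", "closed_genome")]
    pairs <- filter(pairs, .data$virus_unit_id %in% keep)
  }
  vsum <- pairs |>
    distinct(.data$virus_unit_id, .data$host_bin_id) |>
    inner_join(virus_depth, by = c(virus_unit_id = "unit_id"),
               relationship = "many-to-many") |>
    group_by(.data$host_bin_id, .data$sample_id) |>
    summarise(virus_depth = sum(.data$mean_depth),
              n_viruses = dplyr::n_distinct(.data$virus_unit_id),
              .groups = "drop")
  host_depth |>
    rename(host_bin_id = "unit_id", host_depth = "mean_depth") |>
    left_join(vsum, by = c("host_bin_id", "sample_id")) |>
    mutate(virus_depth = dplyr::coalesce(.data$virus_depth, 0),
           n_viruses = dplyr::coalesce(.data$n_viruses, 0L),
           undefined = .data$host_depth <= 0,
           vpr = if_else(.data$undefined, NA_real_,
                         .data$virus_depth / .data$host_depth)) |>
    select("host_bin_id", "sample_id", "vpr", "n_viruses", "undefined")
}

#' RPKM and relative abundance
#'
#' `rpkm()` computes reads per kilobase per million mapped reads:
#' `count / (length_kb * library_size_millions)`.  `relative_abundance()`
#' divides each gene's summed RPKM by the group total so relative
#' abundances sum to 1 within each (location, sample type) group.
#'
#' @param counts tibble with `gene_id` plus one numeric column per sample
#'   (non-negative counts).
#' @param gene_lengths tibble `gene_id`, `length` (bases).
#' @param library_sizes named numeric vector of mapped reads per sample;
#'   default: column sums of `counts`.
#' @return `rpkm()`: tibble shaped like `counts` but holding RPKM values.
#' @export
rpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  samples <- setdiff(names(counts), "gene_id")
  lens <- gene_lengths$length[match(counts$gene_id, gene_lengths$gene_id)]
  if (anyNA(lens)) abort("missing gene lengths")
  if (is.null(library_sizes)) {
    library_sizes <- vapply(counts[samples], sum, numeric(1))
  }
  if (any(library_sizes <= 0)) abort("library sizes must be positive")
  out <- counts
  for (s in samples) {
    out[[s]] <- counts[[s]] / ((lens / 1e3) * (library_sizes[[s]] / 1e6))
  }
  out
}

#' @rdname rpkm
#' @param rpkm_tbl output of `rpkm()`.
#' @param samples sample sheet (`sample`, `location`, `type`).
#' @return `relative_abundance()`: tibble `gene_id`, `location`, `type`,
#'   `rel_abundance` (sums to 1 within each location/type group).
#' @export
relative_abundance <- function(rpkm_tbl, samples) {
  long <- tidyr::pivot_longer(rpkm_tbl, -"gene_id",
                              names_to = "sample", values_to = "rpkm")
  long |>
    inner_join(samples, by = "sample") |>
    group_by(.data$gene_id, .data$location, .data$type) |>
    summarise(rpkm = sum(.data$rpkm), .groups = "drop") |>
    group_by(.data$location, .data$type) |>
    mutate(rel_abundance = .data$rpkm / sum(.data$rpkm)) |>
    ungroup() |>
    select("gene_id", "location", "type", "rel_abundance")
}

#' TPM and the binary expression rule
#'
#' Transcripts per million per repeat sample:
#' `tpm_g = (count_g / len_g) / sum_j(count_j / len_j) * 1e6`.  A gene is
#' called expressed when it has at least one mapped assembled transcript in
#' any repeat, or read counts greater than zero in *all* repeats.
#'
#' @param counts tibble `gene_id` plus one column per repeat sample.
#' @param gene_lengths tibble `gene_id`, `length`.
#' @param transcript_hits tibble `gene_id`, `n_transcripts` (assembled
#'   transcripts mapped to the gene at >= 95% identity over their full
#'   length); genes absent from it have zero hits.
#' @return tibble with `gene_id`, one `tpm_<repeat>` column per repeat,
#'   `n_transcript_hits`, `expressed`.
#' @export
tpm_and_expressed <- function(counts, gene_lengths, transcript_hits = NULL) {
  repeats <- setdiff(names(counts), "gene_id")
  lens <- gene_lengths$length[match(counts$gene_id, gene_lengths$gene_id)]
  if (anyNA(lens)) abort("missing gene lengths")
  out <- tibble(gene_id = counts$gene_id)
  for (r in repeats) {
    rate <- counts[[r]] / lens
    out[[paste0("tpm_", r)]] <- rate / sum(rate) * 1e6
  }
  hits <- if (is.null(transcript_hits)) integer(nrow(out)) else {
    h <- transcript_hits$n_transcripts[match(counts$gene_id, transcript_hits$gene_id)]
    as.integer(dplyr::coalesce(h, 0L))
  }
  all_repeats_covered <- Reduce(`&`, lapply(repeats, function(r) counts[[r]] > 0))
  out$n_transcript_hits <- hits
  out$expressed <- hits >= 1L | all_repeats_covered
  out
}

#' Per-scaffold depth from a BAM file
#'
#' Optional adapter producing the canonical depth table from a position-
#' sorted BAM: mean per-base coverage per reference sequence.  Requires the
#' Rsamtools package.
#'
#' @param bam_path path to an indexed BAM file.
#' @param sample_id sample label stamped into the result.
#' @return depth tibble (`scaffold_id`, `sample_id`, `mean_depth`,
#'   `length`).
#' @export
depth_from_bam <- function(bam_path, sample_id = "sample") {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("depth_from_bam() requires the Rsamtools package")
  }
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1L]]$targets
  p <- Rsamtools::PileupParam(max_depth = 1e6L, min_base_quality = 0L,
                              min_mapq = 0L, distinguish_strands = FALSE,
                              distinguish_nucleotides = FALSE)
  pu <- Rsamtools::pileup(bam_path, pileupParam = p)
  cov <- pu |>
    group_by(seqnames = as.character(.data$seqnames)) |>
    summarise(total = sum(.data$count), .groups = "drop")
  tibble(scaffold_id = names(hdr), length = as.integer(unname(hdr))) |>
    left_join(cov, by = c(scaffold_id = "seqnames")) |>
    mutate(sample_id = sample_id,
           mean_depth = dplyr::coalesce(.data$total, 0) / .data$length) |>
    select("scaffold_id", "sample_id", "mean_depth", "length")
}
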