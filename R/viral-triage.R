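#' Viral scaffold triage
#'
#' Classifies viral scaffolds into proviruses, closed genomes, bins and
#' fragments; assigns majority-rule phylum taxonomy from per-gene bit
#' scores; and enforces bin purity (single phylum, at most one terminase
#' large subunit gene).
#'
#' @name viral_triage
NULL

# phyla known to infect prokaryotes; used as the default allow-list
#' Default prokaryote-infecting virus phyla
#'
#' Allow-list used when restricting viral units to phyla whose members
#' infect bacteria and archaea.
#' @export
prok_virus_phyla <- c("Dividoviricota", "Duplornaviricota", "Hofneiviricota",
                      "Phixviricota", "Preplasmiviricota", "Uroviricota")

#' Flag proviral scaffolds
#'
#' A scaffold is a provirus when it carries an external provirus call (e.g.
#' a CheckV provirus classification supplied as a table) *and* belongs to a
#' quality prokaryotic bin (completeness >= `min_completeness`,
#' contamination <= `max_contamination`).  Both conditions are required:
#' an integrated phage only makes sense inside a credible host genome bin.
#'
#' @param provirus_calls tibble with column `scaffold_id` (scaffolds called
#'   as containing proviruses).
#' @param bin_membership tibble with `scaffold_id`, `bin_id`,
#'   `completeness`, `contamination`.
#' @param known_scaffolds optional character vector of scaffold ids present
#'   in the assembly; provirus calls for unknown scaffolds are dropped with
#'   a warning.
#' @param min_completeness,max_contamination bin quality gates (defaults 50
#'   and 10).
#' @return tibble `scaffold_id`, `is_provirus`, `reason`, `in_prok_bin`,
#'   one row per scaffold seen in either input.
#' @export
flag_proviruses <- function(provirus_calls, bin_membership,
                            known_scaffolds = NULL,
                            min_completeness = 50, max_contamination = 10) {
  calls <- distinct(provirus_calls, .data$scaffold_id)
  if (!is.null(known_scaffolds)) {
    unknown <- setdiff(calls$scaffold_id, known_scaffolds)
    if (length(unknown) > 0L) {
      warn(sprintf("dropping %d provirus call(s) for scaffolds absent from the assembly: %s",
                   length(unknown), paste(head(unknown, 5L), collapse = ", ")))
      calls <- filter(calls, !.data$scaffold_id %in% unknown)
    }
  }
  good_bins <- filter(bin_membership,
                      .data$completeness >= min_completeness,
                      .data$contamination <= max_contamination)
  all_ids <- union(calls$scaffold_id, bin_membership$scaffold_id)
  tibble(scaffold_id = all_ids) |>
    mutate(
      has_call = .data$scaffold_id %in% calls$scaffold_id,
      in_prok_bin = .data$scaffold_id %in% good_bins$scaffold_id,
      is_provirus = .data$has_call & .data$in_prok_bin,
      reason = if_else(.data$is_provirus, "checkv_provirus_call", "none")
    ) |>
    select("scaffold_id", "is_provirus", "reason", "in_prok_bin")
}

#' Call closed viral genomes from direct terminal repeats
#'
#' A scaffold is a closed (putatively complete) viral genome when all six
#' conditions hold: it has a DTR of at least `min_repeat_len`; it is not a
#' flagged provirus; the repeat is not low-complexity; the repeat contains
#' no `N`; the repeat occurs fewer than six times in the scaffold; and the
#' repeat occurrences cover less than 20% of the scaffold.
#'
#' @param scaffolds sequence tibble (`id`, `seq`, optionally `sample_id`).
#' @param provirus_flags output of [flag_proviruses()] (or any tibble with
#'   `scaffold_id`, `is_provirus`).
#' @param min_repeat_len minimum DTR length (default 20).
#' @param max_occurrences repeat-copy ceiling (a closed call requires
#'   strictly fewer; default 6).
#' @param max_covered_fraction ceiling on the scaffold fraction covered by
#'   repeat copies (strictly less; default 0.20).
#' @return tibble of closed-genome units: `unit_id`, `kind`
#'   (`"closed_genome"`), `scaffold_id`, `repeat_len`, `occurrences`,
#'   `covered_fraction`.
#' @export
call_closed_genomes <- function(scaffolds, provirus_flags,
                                min_repeat_len = 20L,
                                max_occurrences = 6L,
                                max_covered_fraction = 0.20) {
  provirus_ids <- provirus_flags$scaffold_id[provirus_flags$is_provirus]
  rows <- purrr::map(seq_len(nrow(scaffolds)), function(i) {
    sid <- scaffolds$id[i]
    tr <- detect_terminal_repeat(scaffolds$seq[i], min_repeat_len = min_repeat_len)
    if (is.null(tr)) return(NULL)
    ok <- !(sid %in% provirus_ids) &&
      !tr$low_complexity &&
      !tr$has_N &&
      tr$occurrences < max_occurrences &&
      tr$covered_fraction < max_covered_fraction
    if (!ok) return(NULL)
    tibble(unit_id = sid, kind = "closed_genome", scaffold_id = sid,
           repeat_len = tr$length, occurrences = tr$occurrences,
           covered_fraction = tr$covered_fraction)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(unit_id = character(), kind = character(),
                  scaffold_id = character(), repeat_len = integer(),
                  occurrences = integer(), covered_fraction = double())
  }
  out
}

#' Majority-rule phylum from per-gene taxonomy
#'
#' Assigns phylum `P` when the summed bit score of genes classified as `P`
#' strictly exceeds `fraction` of the total bit score (the `--fraction 0.5`
#' majority rule); otherwise `"unclassified"`.  An exact 50/50 split is
#' unclassified.
#'
#' @param gene_tax tibble with `phylum` and `bitscore` (one row per gene).
#' @param fraction majority fraction in `(0, 1]` (default 0.5).
#' @return a single phylum string, or `"unclassified"`.
#' @export
majority_rule_phylum <- function(gene_tax, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
  if (nrow(gene_tax) == 0L) return("unclassified")
  sums <- gene_tax |>
    filter(!is.na(.data$phylum)) |>
    group_by(.data$phylum) |>
    summarise(bits = sum(.data$bitscore), .groups = "drop")
  total <- sum(gene_tax$bitscore, na.rm = TRUE)
  if (nrow(sums) == 0L || total <= 0) return("unclassified")
  top <- slice_max(sums, .data$bits, n = 1L, with_ties = FALSE)
  if (top$bits > fraction * total) top$phylum else "unclassified"
}

#' Purity filter for candidate viral bins
#'
#' A candidate bin is kept only when its member scaffolds agree on a single
#' phylum (per-scaffold majority rule over gene bit scores) and it carries
#' at most one terminase large subunit (TerL) gene; TerL is single-copy in
#' phage genomes, so two copies indicate a mixed bin.  Scaffolds of
#' discarded bins are released into the fragment pool; no scaffold is lost
#' or duplicated.
#'
#' @param bins tibble with `bin_id`, `scaffold_id`.
#' @param gene_tax tibble with `gene_id`, `scaffold_id`, `phylum`,
#'   `bitscore`.
#' @param terl_labels character vector of `gene_id`s annotated as TerL.
#' @param fraction majority fraction for the per-scaffold phylum call.
#' @return list with `kept` (tibble `bin_id`, `scaffold_id`, `phylum`) and
#'   `released` (character vector of scaffold ids returned to the fragment
#'   pool).
#' @export
purity_filter <- function(bins, gene_tax, terl_labels, fraction = 0.5) {
  scaf_phylum <- gene_tax |>
    group_by(.data$scaffold_id) |>
    summarise(phylum = majority_rule_phylum(dplyr::pick("phylum", "bitscore"),
                                            fraction = fraction),
              .groups = "drop")
  terl_per_bin <- gene_tax |>
    filter(.data$gene_id %in% terl_labels) |>
    inner_join(bins, by = "scaffold_id") |>
    count(.data$bin_id, name = "n_terl")
  verdict <- bins |>
    left_join(scaf_phylum, by = "scaffold_id") |>
    mutate(phylum = dplyr::coalesce(.data$phylum, "unclassified")) |>
    group_by(.data$bin_id) |>
    summarise(n_phyla = dplyr::n_distinct(.data$phylum[.data$phylum != "unclassified"]),
              bin_phylum = if (dplyr::n_distinct(.data$phylum[.data$phylum != "unclassified"]) == 1L)
                unique(.data$phylum[.data$phylum != "unclassified"]) else "unclassified",
              .groups = "drop") |>
    left_join(terl_per_bin, by = "bin_id") |>
    mutate(n_terl = dplyr::coalesce(.data$n_terl, 0L),
           keep = .data$n_phyla <= 1L & .data$n_terl < 2L)
  kept_bins <- verdict$bin_id[verdict$keep]
  kept <- bins |>
    filter(.data$bin_id %in% kept_bins) |>
    left_join(select(verdict, "bin_id", phylum = "bin_phylum"), by = "bin_id")
  released <- bins$scaffold_id[!bins$bin_id %in% kept_bins]
  list(kept = as_tibble(kept), released = released)
}

#' Restrict viral units to prokaryote-infecting phyla
#'
#' Keeps units whose phylum is on the allow-list (or unclassified units if
#' `keep_unclassified`).
#'
#' @param units tibble with a `phylum` column.
#' @param allowed character vector of allowed phyla
#'   (default [prok_virus_phyla]).
#' @param keep_unclassified keep units without a phylum call (default
#'   `FALSE`).
#' @return filtered tibble.
#' @export
filter_prok_viruses <- function(units, allowed = prok_virus_phyla,
                                keep_unclassified = FALSE) {
  filter(units, .data$phylum %in% allowed |
           (keep_unclassified & .data$phylum == "unclassified"))
}
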