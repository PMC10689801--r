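#' Sequence primitives
#'
#' Shared low-level operations on assembled scaffolds: exact substring search
#' on both strands, seed-and-extend local alignment, and detection of direct
#' terminal repeats (DTRs).  Sequences travel through the package as tibbles
#' with columns `id`, `seq` and `length` (plus `sample_id` where relevant);
#' most primitives also accept a bare DNA string.
#'
#' Coordinates are 0-based half-open throughout; strands are `"+"`/`"-"`.
#'
#' @name seq_core
NULL

# coerce a string / one-row sequence tibble to a bare DNA string
as_seq_string <- function(x, arg = "sequence") {
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  if (is.data.frame(x)) {
    if (nrow(x) != 1L || !"seq" %in% names(x)) {
      abort(sprintf("`%s` must be a single DNA string or a one-row tibble with a `seq` column", arg))
    }
    return(toupper(x$seq[[1L]]))
  }
  abort(sprintf("`%s` must be a single DNA string or a one-row tibble with a `seq` column", arg))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (`A`/`C`/`G`/`T`/`N`,
#'   case-insensitive).
#' @return character vector of reverse complements, uppercase.
#' @export
#' @examples
#' dna_revcomp("AAAC")
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

#' Read and write FASTA as sequence tibbles
#'
#' Thin wrappers around Biostrings that present multi-record FASTA files as
#' tibbles with `id`, `seq`, `length`.  Lowercase input is uppercased; `N`s
#' are preserved.  Writing wraps sequence lines at 80 columns.
#'
#' @param path file path.
#' @return `read_fasta()`: a tibble with one row per record.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(
    id = sub("\\s.*$", "", names(ss)),
    seq = unname(toupper(as.character(ss))),
    length = Biostrings::width(ss)
  )
}

#' @rdname read_fasta
#' @param seqs tibble with columns `id` and `seq`.
#' @return `write_fasta()`: `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  ss <- Biostrings::DNAStringSet(toupper(seqs$seq))
  names(ss) <- seqs$id
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Exact substring search on both strands
#'
#' Finds every exact occurrence of `pattern` in `subject`, optionally also of
#' its reverse complement.  `N` in the subject never matches (patterns must
#' not contain `N`).  Used for CRISPR spacer protospacer search and tRNA
#' identity checks, where the match must be perfect.
#'
#' @param pattern a non-empty DNA string without `N`.
#' @param subject a DNA string or one-row sequence tibble.
#' @param both_strands search the reverse complement too (default `TRUE`).
#' @return tibble with `position` (0-based start on the forward subject
#'   strand, of the leftmost matched base) and `strand`, sorted by position.
#' @export
#' @examples
#' find_exact_matches("ACGT", "ACGTACGT", both_strands = FALSE)
find_exact_matches <- function(pattern, subject, both_strands = TRUE) {
  pattern <- toupper(pattern)
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L) {
    abort("`pattern` must be a non-empty DNA string")
  }
  subj <- as_seq_string(subject, "subject")
  if (grepl("N", pattern, fixed = TRUE)) {
    return(tibble(position = integer(), strand = character()))
  }
  s <- Biostrings::DNAString(subj)
  hit_starts <- function(p) {
    Biostrings::start(Biostrings::matchPattern(Biostrings::DNAString(p), s, fixed = TRUE)) - 1L
  }
  fwd <- hit_starts(pattern)
  out <- tibble(position = as.integer(fwd), strand = rep("+", length(fwd)))
  if (both_strands) {
    rc <- dna_revcomp(pattern)
    # a palindromic pattern matches both strands at the same site; report once
    if (!identical(rc, pattern)) {
      rev <- hit_starts(rc)
      out <- bind_rows(out, tibble(position = as.integer(rev), strand = rep("-", length(rev))))
    }
  }
  arrange(out, .data$position, .data$strand)
}

#' Seed-and-extend local alignment
#'
#' Gapless exact `seed_k`-mer anchors are chained into near-diagonal bands,
#' extended with an X-drop rule, and re-scored with a unit-cost banded
#' alignment.  Alignments are reported when they individually reach both
#' `min_identity` and `min_len`; overlapping alignments are resolved
#' greedily by score so the result is a set of maximal non-overlapping
#' local alignments.  The defaults (70% identity over at least 2.5 kb) are
#' the homology-channel linkage thresholds.
#'
#' @param query,target DNA strings or one-row sequence tibbles.
#' @param seed_k exact seed length (>= 11; default 13).
#' @param min_identity minimum fraction of matching columns, in `[0,1]`.
#' @param min_len minimum query span of a reported alignment, in bases.
#' @param both_strands align the reverse complement of the query too.
#' @return tibble of alignments: `query_id`, `target_id`, `q_start`, `q_end`,
#'   `t_start`, `t_end` (0-based half-open; query coordinates always refer to
#'   the forward query strand), `identity`, `aln_len` (`== q_end - q_start`),
#'   `strand`.  Zero rows when nothing qualifies.
#' @export
local_align <- function(query, target, seed_k = 13L, min_identity = 0.70,
                        min_len = 2500L, both_strands = TRUE) {
  if (seed_k < 11L) abort("`seed_k` must be >= 11")
  q <- as_seq_string(query, "query")
  t <- as_seq_string(target, "target")
  qid <- if (is.data.frame(query) && "id" %in% names(query)) query$id[[1L]] else "query"
  tid <- if (is.data.frame(target) && "id" %in% names(target)) target$id[[1L]] else "target"
  res <- .cpp_seed_align(q, t, if (both_strands) dna_revcomp(q) else "",
                         as.integer(seed_k), min_identity, as.integer(min_len),
                         both_strands)
  out <- as_tibble(res)
  out$query_id <- qid
  out$target_id <- tid
  select(out, "query_id", "target_id", "q_start", "q_end", "t_start", "t_end",
         "identity", "aln_len", "strand")
}

# TRUE when the repeat is >75% one base or a perfect 1-3-mer tandem
is_low_complexity <- function(rep_seq) {
  n <- nchar(rep_seq)
  bases <- strsplit(rep_seq, "", fixed = TRUE)[[1L]]
  if (max(table(factor(bases, levels = c("A", "C", "G", "T", "N")))) > 0.75 * n) {
    return(TRUE)
  }
  for (p in 1:3) {
    unit <- substr(rep_seq, 1L, p)
    tandem <- strtrim(strrep(unit, ceiling(n / p)), n)
    if (identical(tandem, rep_seq)) return(TRUE)
  }
  FALSE
}

#' Detect a direct terminal repeat (DTR)
#'
#' Finds the longest exact prefix of a scaffold that also occurs as its
#' suffix.  A DTR is the hallmark of a circularly permuted, putatively
#' complete phage genome; downstream closed-genome calling additionally
#' screens the repeat for `N`s, low complexity, copy number and the fraction
#' of the scaffold it covers.
#'
#' @param scaffold DNA string or one-row sequence tibble.
#' @param min_repeat_len minimum repeat length to report (>= 10; default 20).
#' @return one-row tibble with `seq`, `length`, `occurrences` (exact,
#'   possibly overlapping occurrences in the whole scaffold),
#'   `covered_fraction` (fraction of scaffold bases covered by the union of
#'   occurrences), `has_N`, `low_complexity`; or `NULL` when no terminal
#'   repeat of at least `min_repeat_len` exists.
#' @export
detect_terminal_repeat <- function(scaffold, min_repeat_len = 20L) {
  if (min_repeat_len < 10L) abort("`min_repeat_len` must be >= 10")
  s <- as_seq_string(scaffold, "scaffold")
  n <- nchar(s)
  if (n < 2L * min_repeat_len) return(NULL)
  seed <- substr(s, 1L, min_repeat_len)
  if (grepl("N", seed, fixed = TRUE)) return(NULL) # seed with gap: no exact anchor
  starts <- find_exact_matches(seed, s, both_strands = FALSE)$position
  starts <- starts[starts > 0L & starts <= n - min_repeat_len]
  if (length(starts) == 0L) return(NULL)
  # repeat of length L = n - p exists iff suffix at p equals prefix of length L
  best_len <- 0L
  for (p in sort(starts)) {
    L <- n - p
    if (L <= best_len || L < min_repeat_len) next
    if (substr(s, p + 1L, n) == substr(s, 1L, L)) best_len <- L
  }
  if (best_len < min_repeat_len) return(NULL)
  rep_seq <- substr(s, 1L, best_len)
  occ <- find_exact_matches(rep_seq, s, both_strands = FALSE)$position
  covered <- IRanges::reduce(IRanges::IRanges(start = occ + 1L, width = best_len))
  tibble(
    seq = rep_seq,
    length = best_len,
    occurrences = length(occ),
    covered_fraction = sum(IRanges::width(covered)) / n,
    has_N = grepl("N", rep_seq, fixed = TRUE),
    low_complexity = is_low_complexity(rep_seq)
  )
}
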