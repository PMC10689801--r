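#' Biofilm-versus-seawater differential abundance and meta-analysis
#'
#' Per-location differential abundance of defence genes between biofilm and
#' seawater samples (negative-binomial Wald test on median-of-ratios
#' normalised counts), followed by a DerSimonian-Laird random-effects
#' meta-analysis pooling the per-location log2 fold changes.
#'
#' Sign convention: positive log2 fold change means seawater-enriched (the
#' seawater group is the numerator); `positive_is = "biofilm"` flips it.
#'
#' @name differential_meta
NULL

# DESeq-style median-of-ratios size factors
median_of_ratios <- function(mat) {
  log_geo <- rowMeans(log(mat))
  use <- is.finite(log_geo)
  if (!any(use)) abort("no gene has positive counts in every sample; cannot normalise")
  sf <- apply(mat[use, , drop = FALSE], 2L, function(col) {
    exp(median(log(col[col > 0]) - log_geo[use][col > 0]))
  })
  sf / exp(mean(log(sf)))
}

#' Differential abundance of genes between biofilm and seawater
#'
#' For one location: median-of-ratios size factors; gene-wise NB dispersion
#' by method of moments on normalised counts (floored at `min_dispersion`);
#' a log-link negative-binomial GLM of counts on sample type with the size
#' factors as offsets; a Wald test on the type coefficient against a t
#' reference with `n - 2` degrees of freedom; Benjamini-Hochberg adjustment
#' across the genes of the location.  All-zero genes are excluded and
#' listed in the result.
#'
#' @param counts tibble `gene_id` plus one integer column per sample.
#' @param samples sample sheet (`sample`, `location`, `type` with levels
#'   `biofilm`/`seawater`).
#' @param location location to analyse; default: the single location
#'   present (an error if several).
#' @param positive_is which group a positive log2 fold change indicates
#'   (`"seawater"`, the default, or `"biofilm"`).
#' @param min_dispersion dispersion floor (default 1e-8).
#' @return a `bfl_da` object; [tidy()] gives the per-gene table
#'   (`gene_id`, `location`, `base_mean`, `log2fc`, `se`, `stat`, `p`,
#'   `padj`), [glance()] a one-row summary.
#' @export
differential_abundance <- function(counts, samples, location = NULL,
                                   positive_is = c("seawater", "biofilm"),
                                   min_dispersion = 1e-8) {
  positive_is <- match.arg(positive_is)
  locs <- unique(samples$location)
  if (is.null(location)) {
    if (length(locs) != 1L) abort("several locations present; pass `location`")
    location <- locs
  }
  sm <- filter(samples, .data$location == !!location)
  if (!all(sm$type %in% c("biofilm", "seawater"))) {
    abort("sample types must be biofilm/seawater")
  }
  if (min(table(sm$type)) < 2L) abort("need >= 2 samples per group")
  mat <- as.matrix(counts[, sm$sample, drop = FALSE])
  rownames(mat) <- counts$gene_id
  storage.mode(mat) <- "double"
  if (any(mat < 0)) abort("counts must be non-negative")

  all_zero <- rowSums(mat) == 0
  excluded <- rownames(mat)[all_zero]
  mat <- mat[!all_zero, , drop = FALSE]

  sf <- median_of_ratios(mat)
  norm <- sweep(mat, 2L, sf, "/")
  ref <- if (positive_is == "seawater") "biofilm" else "seawater"
  grp <- factor(sm$type, levels = c(ref, setdiff(c("biofilm", "seawater"), ref)))

  # method-of-moments dispersion on normalised counts, pooled within groups
  disp <- vapply(seq_len(nrow(norm)), function(i) {
    x <- split(norm[i, ], grp)
    m <- mean(vapply(x, mean, numeric(1)))
    v <- mean(vapply(x, var, numeric(1)))
    max((v - m) / (m + 0.5)^2, min_dispersion)
  }, numeric(1))

  off <- log(sf)
  fit_one <- function(y, alpha) {
    fam <- MASS::negative.binomial(theta = 1 / alpha, link = "log")
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ grp + offset(off), family = fam)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(c(NA_real_, NA_real_))
    co <- summary(fit)$coefficients
    if (nrow(co) < 2L) return(c(NA_real_, NA_real_))
    co[2L, 1:2]
  }
  est <- t(vapply(seq_len(nrow(mat)), function(i) fit_one(mat[i, ], disp[i]),
                  numeric(2)))
  df <- nrow(sm) - 2L
  results <- tibble(
    gene_id = rownames(mat),
    location = location,
    base_mean = rowMeans(norm),
    log2fc = est[, 1L] / log(2),
    se = est[, 2L] / log(2),
    stat = est[, 1L] / est[, 2L],
    p = 2 * pt(-abs(est[, 1L] / est[, 2L]), df = df)
  )
  results$padj <- p.adjust(results$p, method = "BH")
  structure(list(results = results, size_factors = setNames(sf, sm$sample),
                 dispersions = setNames(disp, rownames(mat)),
                 excluded = excluded, location = location,
                 positive_is = positive_is, df = df),
            class = "bfl_da")
}

#' Run the DA stage for every location
#'
#' @inheritParams differential_abundance
#' @return tibble of tidied per-gene results across locations.
#' @export
differential_abundance_all <- function(counts, samples,
                                       positive_is = c("seawater", "biofilm"),
                                       min_dispersion = 1e-8) {
  positive_is <- match.arg(positive_is)
  bind_rows(lapply(unique(samples$location), function(loc) {
    tidy(differential_abundance(counts, samples, location = loc,
                                positive_is = positive_is,
                                min_dispersion = min_dispersion))
  }))
}

# DerSimonian-Laird pooling of one gene's per-location effects
dl_pool <- function(y, se, alpha = 0.05) {
  k <- length(y)
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar)^2)
  tau2 <- if (k > 1L) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  wstar <- 1 / (se^2 + tau2)
  pooled <- sum(wstar * y) / sum(wstar)
  se_pooled <- sqrt(1 / sum(wstar))
  z <- pooled / se_pooled
  zcrit <- qnorm(1 - alpha / 2)
  tibble(k = k, pooled_log2fc = pooled, se_pooled = se_pooled,
         ci_lo = pooled - zcrit * se_pooled, ci_hi = pooled + zcrit * se_pooled,
         tau2 = tau2, q_stat = q, p = 2 * pnorm(-abs(z)))
}

#' Random-effects meta-analysis of per-location effects
#'
#' Classical DerSimonian-Laird: inverse-variance weights give the Q
#' statistic and the moment estimate of the between-location variance
#' tau^2; effects are re-weighted by `1 / (se^2 + tau2)` and pooled; the
#' pooled effect is tested with a z statistic.  With a single location the
#' input effect is returned exactly (tau^2 = 0).
#'
#' @param effects tibble `gene_id`, `location`, `log2fc`, `se` (per-gene,
#'   per-location effects; `se > 0`).
#' @param alpha confidence level for the interval (default 0.05 -> 95% CI).
#' @return a `bfl_meta` object; [tidy()] gives `gene_id`, `k`,
#'   `pooled_log2fc`, `se_pooled`, `ci_lo`, `ci_hi`, `tau2`, `q_stat`, `p`.
#' @export
random_effects_meta <- function(effects, alpha = 0.05) {
  if (nrow(effects) == 0L) abort("no effects to pool")
  if (any(!is.finite(effects$se) | effects$se <= 0)) {
    effects <- filter(effects, is.finite(.data$se), .data$se > 0,
                      is.finite(.data$log2fc))
    if (nrow(effects) == 0L) abort("no effects with finite positive se")
  }
  results <- effects |>
    group_by(.data$gene_id) |>
    dplyr::group_modify(~ dl_pool(.x$log2fc, .x$se, alpha = alpha)) |>
    ungroup() |>
    arrange(.data$gene_id)
  structure(list(results = results, alpha = alpha, n_input = nrow(effects)),
            class = "bfl_meta")
}

#' Select significant genes and roll up by defence system
#'
#' Genes enter the meta-analysis when their DA adjusted p-value is below
#' `padj_threshold` in at least one location; the enriched set is then the
#' genes with meta p below `meta_p_threshold`.  Direction follows the sign
#' convention of the DA stage (positive pooled effect = seawater-enriched
#' by default).
#'
#' @param da_results tidied DA results ([differential_abundance_all()]).
#' @param meta a `bfl_meta` over the selected genes, or `NULL` to fit it
#'   here from `da_results`.
#' @param gene_systems optional tibble `gene_id`, `system` for the
#'   system-level rollup.
#' @param padj_threshold,meta_p_threshold significance gates (default 0.05
#'   each).
#' @param positive_is direction labelling (must match the DA stage).
#' @return list with `genes` (enriched genes with direction) and
#'   `by_system` (counts per system and direction; empty without
#'   `gene_systems`).
#' @export
select_significant <- function(da_results, meta = NULL, gene_systems = NULL,
                               padj_threshold = 0.05, meta_p_threshold = 0.05,
                               positive_is = c("seawater", "biofilm")) {
  positive_is <- match.arg(positive_is)
  eligible <- da_results |>
    group_by(.data$gene_id) |>
    summarise(min_padj = min(.data$padj, na.rm = TRUE), .groups = "drop") |>
    filter(.data$min_padj < padj_threshold)
  if (is.null(meta)) {
    input <- da_results |>
      semi_join(eligible, by = "gene_id") |>
      select("gene_id", "location", "log2fc", "se")
    if (nrow(input) == 0L) {
      return(list(genes = tibble(gene_id = character(), pooled_log2fc = double(),
                                 p = double(), direction = character()),
                  by_system = tibble(system = character(), direction = character(),
                                     n_genes = integer())))
    }
    meta <- random_effects_meta(input)
  }
  genes <- tidy(meta) |>
    semi_join(eligible, by = "gene_id") |>
    filter(.data$p < meta_p_threshold) |>
    mutate(direction = if_else(.data$pooled_log2fc > 0,
                               paste0(positive_is, "-enriched"),
                               paste0(setdiff(c("seawater", "biofilm"), positive_is),
                                      "-enriched"))) |>
    select("gene_id", "pooled_log2fc", "se_pooled", "ci_lo", "ci_hi", "p",
           "direction")
  by_system <- if (!is.null(gene_systems)) {
    genes |>
      inner_join(gene_systems, by = "gene_id") |>
      count(.data$system, .data$direction, name = "n_genes") |>
      arrange(.data$system, .data$direction)
  } else {
    tibble(system = character(), direction = character(), n_genes = integer())
  }
  list(genes = genes, by_system = by_system)
}
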