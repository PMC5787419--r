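#' Overlap test between a query gene set and a reference gene set
#'
#' One-sided Fisher's exact test of the overlap between a query set (e.g. age
#' co-expressed genes of a tissue) and a reference set (e.g. curated aging
#' genes) over a background of a given size. The 2x2 table is
#' `a = |query ∩ reference|`, `b = |query| - a`, `c = |reference| - a`,
#' `d = background - |query| - |reference| + a`. The ratio column is
#' `100 * a / |reference|` (the share of reference genes recovered).
#'
#' The reference size is taken as given, without intersecting the reference
#' with the background; use [overlap_test_counts()] with your own intersected
#' counts for the alternative construction, and
#' [implied_reference_size()] to diagnose a reported p-value that does not
#' match its printed counts.
#'
#' @param query,reference Character vectors of gene symbols.
#' @param background_size Total number of background genes; must be at least
#'   the size of the union of the two sets.
#' @return One-row tibble: `n_query`, `n_reference`, `n_background`,
#'   `n_overlap`, `ratio_percent`, `odds_ratio`, `p_value`.
#' @export
overlap_test <- function(query, reference, background_size) {
  query <- unique(toupper(query))
  reference <- unique(toupper(reference))
  overlap_test_counts(
    n_query = length(query),
    n_reference = length(reference),
    n_background = background_size,
    n_overlap = length(intersect(query, reference))
  )
}

#' Overlap test from printed counts
#'
#' Pure-counts form of [overlap_test()], used to reconstruct published
#' overlap tables from their printed columns alone.
#'
#' @param n_query,n_reference,n_background,n_overlap The four counts.
#' @return Same one-row tibble as [overlap_test()].
#' @examples
#' overlap_test_counts(2563, 305, 16516, 155)
#' @export
overlap_test_counts <- function(n_query, n_reference, n_background, n_overlap) {
  counts <- c(n_query, n_reference, n_background, n_overlap)
  if (anyNA(counts) || any(counts < 0)) abort("counts must be non-negative")
  if (n_overlap > min(n_query, n_reference)) {
    abort("overlap cannot exceed either set size")
  }
  if (n_background < n_query + n_reference - n_overlap) {
    abort("background smaller than the union of the two sets")
  }
  ft <- fisher_one_sided(
    n_overlap, n_query - n_overlap, n_reference - n_overlap,
    n_background - n_query - n_reference + n_overlap
  )
  tibble(
    n_query = n_query,
    n_reference = n_reference,
    n_background = n_background,
    n_overlap = n_overlap,
    ratio_percent = 100 * n_overlap / n_reference,
    odds_ratio = ft$odds_ratio,
    p_value = ft$p_value
  )
}

#' Solve for the reference size implied by a reported overlap p-value
#'
#' Published overlap tables sometimes report a p-value computed with a
#' reference set intersected with the study background while printing the
#' full reference size. Given the other printed counts and the reported
#' p-value, this searches integer reference sizes in
#' `[n_overlap, max_reference]` for the one whose one-sided Fisher p-value is
#' closest to the report (on the log10 scale).
#'
#' @param n_query,n_background,n_overlap Printed counts.
#' @param p_reported The printed p-value.
#' @param max_reference Largest reference size to consider (e.g. the printed
#'   full reference size).
#' @return One-row tibble: `implied_reference`, `p_value` at that size,
#'   `log10_error` versus the report, and `consistent` (TRUE when the match
#'   is within 0.05 on log10, i.e. reproduces the report to ~3 significant
#'   figures).
#' @export
implied_reference_size <- function(n_query, n_background, n_overlap,
                                   p_reported, max_reference) {
  if (p_reported <= 0 || p_reported > 1) abort("p_reported must be in (0, 1]")
  sizes <- seq.int(n_overlap, max_reference)
  p <- vapply(sizes, function(k) {
    overlap_test_counts(n_query, k, n_background, n_overlap)$p_value
  }, numeric(1))
  err <- abs(log10(p) - log10(p_reported))
  i <- which.min(err)
  tibble(
    implied_reference = sizes[i],
    p_value = p[i],
    log10_error = err[i],
    consistent = err[i] <= 0.05
  )
}

#' Split age co-expressed genes by the direction of their age trend
#'
#' For each candidate gene, computes the Pearson correlation between its
#' (transformed) expression profile and the (transformed) scouting variable,
#' tests it two-sided against the exact t reference distribution with n - 2
#' degrees of freedom, and adjusts by Benjamini-Hochberg across the candidate
#' genes only. Genes surviving at FDR `fdr` are split by the sign of the
#' correlation: positive = up-regulated (elevated) with age, negative =
#' down-regulated (repressed).
#'
#' Genes whose co-expression is purely liquid (conditional correlation
#' changing with age but no marginal age trend) are expected to be excluded
#' here, so both sets can legitimately come back empty.
#'
#' @param study An [expression_study()] (transformed automatically if
#'   needed).
#' @param coexpressed Candidate symbols, typically from
#'   [age_coexpressed_genes()]; must be non-empty and present in the study.
#' @param fdr FDR threshold (default 0.1).
#' @return Object of class `age_directional_sets`: list with `up_genes`,
#'   `down_genes` and a per-gene `stats` tibble (`gene`, `correlation`,
#'   `p_raw`, `p_adjusted`, `direction`). `tidy()` returns the stats.
#' @export
age_directional_sets <- function(study, coexpressed, fdr = 0.1) {
  stopifnot(inherits(study, "expression_study"))
  coexpressed <- unique(toupper(coexpressed))
  if (!length(coexpressed)) abort("`coexpressed` must be a non-empty gene set")
  missing <- setdiff(coexpressed, study_genes(study))
  if (length(missing)) {
    abort(sprintf("candidate gene(s) absent from the study: %s", missing[1]))
  }
  if (!study$transformed) study <- transform_study(study)
  coexpressed <- sort(coexpressed)
  X <- study$values[coexpressed, , drop = FALSE]
  n <- ncol(X)
  r <- as.vector(suppressWarnings(cor(t(X), study$scouting)))
  p_raw <- pcc_p_two_sided(r, n)
  p_adjusted <- p.adjust(p_raw, method = "BH")
  keep <- !is.na(r) & p_adjusted <= fdr
  stats <- tibble(
    gene = coexpressed,
    correlation = r,
    p_raw = p_raw,
    p_adjusted = p_adjusted,
    direction = dplyr::case_when(
      keep & r > 0 ~ "up",
      keep & r < 0 ~ "down",
      .default = "none"
    )
  )
  structure(
    list(
      up_genes = stats$gene[stats$direction == "up"],
      down_genes = stats$gene[stats$direction == "down"],
      stats = stats,
      fdr = fdr
    ),
    class = "age_directional_sets"
  )
}

#' @export
print.age_directional_sets <- function(x, ...) {
  cat(sprintf(
    "<age_directional_sets> %d up-regulated, %d down-regulated with age (of %d candidates, FDR %.2g)\n",
    length(x$up_genes), length(x$down_genes), nrow(x$stats), x$fdr
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.age_directional_sets <- function(x, ...) x$stats

#' Rank perturbation signatures by aging-signature reversal
#'
#' The connectivity-map-style prioritisation: a perturbation reverses the
#' aging signature when its up-regulated genes overlap the age-repressed
#' (down) genes, or its down-regulated genes overlap the age-elevated (up)
#' genes. Each direction is tested separately with the one-sided Fisher's
#' exact test over the study gene universe and ranked by ascending raw
#' p-value (ties broken by overlap descending, then id). The two directions
#' are reported as separate rankings, not combined.
#'
#' @param sets An [age_directional_sets()] object (or a list with `up_genes`
#'   and `down_genes`).
#' @param signatures Signature tibble from [read_signatures()].
#' @param background_size Number of genes in the study universe.
#' @return Tibble `perturbation_id`, `direction` (`"up"` = test of the
#'   age-elevated genes against the signature's down genes, `"down"` = test
#'   of the age-repressed genes against the signature's up genes),
#'   `overlap`, `n_signature`, `p_value`, `rank`. A direction whose aging
#'   set is empty yields no rows for that direction, with a warning.
#' @export
rank_perturbations <- function(sets, signatures, background_size) {
  stopifnot(is.data.frame(signatures))
  required <- c("perturbation_id", "up_genes", "down_genes")
  if (!all(required %in% names(signatures))) {
    abort("`signatures` must have perturbation_id, up_genes and down_genes")
  }
  one_direction <- function(aging_set, signature_genes, direction) {
    if (!length(aging_set)) {
      warn(sprintf(
        "no %s-regulated aging genes; the %s-reversal ranking is empty",
        direction, direction
      ))
      return(tibble(
        perturbation_id = character(), direction = character(),
        overlap = integer(), n_signature = integer(),
        p_value = numeric(), rank = integer()
      ))
    }
    res <- tibble(
      perturbation_id = signatures$perturbation_id,
      direction = direction,
      overlap = map_int(signature_genes, function(g) {
        length(intersect(toupper(g), aging_set))
      }),
      n_signature = map_int(signature_genes, length)
    )
    res$p_value <- purrr::map2_dbl(res$overlap, res$n_signature, function(a, k) {
      overlap_test_counts(length(aging_set), k, background_size, a)$p_value
    })
    res |>
      arrange(.data$p_value, desc(.data$overlap), .data$perturbation_id) |>
      mutate(rank = row_number())
  }
  up <- toupper(if (is.list(sets)) sets$up_genes else character())
  down <- toupper(if (is.list(sets)) sets$down_genes else character())
  check_sizes <- lengths(signatures$up_genes) + lengths(signatures$down_genes)
  if (any(check_sizes > background_size)) {
    abort("a signature is larger than the background universe")
  }
  bind_rows(
    one_direction(up, signatures$down_genes, "up"),
    one_direction(down, signatures$up_genes, "down")
  )
}
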