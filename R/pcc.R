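#' Pearson co-expression screen of one module
#'
#' The conventional co-expression counterpart of [screen_module()]: Pearson
#' correlation for every pair of module genes on the transformed values,
#' two-sided significance from the exact t reference distribution with n - 2
#' degrees of freedom, and Benjamini-Hochberg adjustment within the module.
#'
#' Pairs involving a zero-variance gene get an undefined correlation and
#' p = 1 (reported via a message).
#'
#' @inheritParams screen_module
#' @param fdr Within-module FDR threshold (default 0.1).
#' @return A tibble `module_id`, `gene_a`, `gene_b`, `correlation`, `p_raw`,
#'   `p_adjusted`, `significant`, pairs in lexicographic order.
#' @export
pcc_screen_module <- function(study, module_genes, fdr = 0.1,
                              module_id = "module") {
  check_screen_inputs(study)
  genes <- sort(unique(toupper(module_genes)))
  missing <- setdiff(genes, study_genes(study))
  if (length(missing)) {
    abort(sprintf("module gene(s) absent from the study: %s", missing[1]))
  }
  if (length(genes) < 2) {
    warn(sprintf("module %s has fewer than 2 usable genes; nothing to screen",
      module_id))
    return(empty_pcc_records())
  }
  X <- study$values[genes, , drop = FALSE]
  n <- ncol(X)
  k <- length(genes)
  degenerate <- apply(X, 1, sd) == 0
  if (any(degenerate)) {
    inform(sprintf(
      "%d zero-variance gene(s) in module %s; their pairs get p = 1",
      sum(degenerate), module_id
    ))
  }
  C <- suppressWarnings(cor(t(X)))
  pair_idx <- t(utils::combn(k, 2))
  r <- C[pair_idx]
  r[degenerate[pair_idx[, 1]] | degenerate[pair_idx[, 2]]] <- NA_real_
  p_raw <- pcc_p_two_sided(r, n)
  p_adjusted <- p.adjust(p_raw, method = "BH")
  tibble(
    module_id = module_id,
    gene_a = genes[pair_idx[, 1]],
    gene_b = genes[pair_idx[, 2]],
    correlation = r,
    p_raw = p_raw,
    p_adjusted = p_adjusted,
    significant = p_adjusted <= fdr
  )
}

# Two-sided p for a Pearson correlation via t = r sqrt((n-2)/(1-r^2)),
# df = n - 2; |r| = 1 maps to p = 0, undefined r to p = 1.
pcc_p_two_sided <- function(r, n) {
  p <- rep(1, length(r))
  ok <- !is.na(r)
  rr <- pmin(pmax(r[ok], -1), 1)
  t_stat <- ifelse(abs(rr) == 1, Inf, rr * sqrt((n - 2) / (1 - rr^2)))
  p[ok] <- 2 * pt(-abs(t_stat), df = n - 2)
  pmin(p, 1)
}

empty_pcc_records <- function() {
  tibble(
    module_id = character(), gene_a = character(), gene_b = character(),
    correlation = numeric(), p_raw = numeric(), p_adjusted = numeric(),
    significant = logical()
  )
}

#' Run the Pearson co-expression screen over a module collection
#'
#' Applies [pcc_screen_module()] to every module (sorted id order), the same
#' process as [run_screen()] but with ordinary correlation instead of liquid
#' association; used to contrast age-associated co-expression with general
#' co-expression.
#'
#' @inheritParams run_screen
#' @return An object of class `aagci_pcc_screen` with `records`,
#'   `significant` and `manifest`; `tidy()`/`glance()` methods apply.
#' @export
run_pcc_screen <- function(study, collection, fdr = 0.1) {
  stopifnot(inherits(study, "expression_study"))
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!study$transformed) {
    inform("transforming study (inverse-normal) before screening")
    study <- transform_study(study)
  }
  manifest <- run_manifest(study, collection, fdr = fdr,
    method = "pearson_correlation")
  if (!length(collection$sets)) {
    warn("empty module collection; nothing to screen")
    records <- empty_pcc_records()
  } else {
    ids <- sort(names(collection$sets))
    records <- bind_rows(lapply(ids, function(id) {
      pcc_screen_module(study, collection$sets[[id]], fdr = fdr, module_id = id)
    }))
  }
  new_screen_result(records, manifest, class = "aagci_pcc_screen")
}

#' @export
print.aagci_pcc_screen <- function(x, ...) {
  cat(sprintf(
    "<aagci_pcc_screen> %d pair(s) in %d module(s); %d significant at FDR %.2g\n",
    nrow(x$records), x$manifest$n_modules, nrow(x$significant), x$manifest$fdr
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.aagci_pcc_screen <- function(x, ...) x$records

#' @exportS3Method generics::glance
glance.aagci_pcc_screen <- function(x, ...) {
  tibble(
    n_modules = x$manifest$n_modules,
    n_pairs = nrow(x$records),
    n_significant = nrow(x$significant),
    fdr = x$manifest$fdr
  )
}

#' Per-module consistency of the LA and PCC screens
#'
#' For each module, cross-tabulates all gene pairs by LA significance and PCC
#' significance, tests enrichment of the overlap with the one-sided (greater)
#' Fisher's exact test, and adjusts across modules by Benjamini-Hochberg. A
#' module is called consistent when the adjusted p-value is at most `alpha`.
#' Both screens must have run on identical module pair enumerations.
#'
#' @param la_records Records from [run_screen()] (object or tibble).
#' @param pcc_records Records from [run_pcc_screen()] (object or tibble).
#' @param alpha Across-module adjusted significance level (default 0.05).
#' @return Tibble `module_id`, `n_pairs`, `n_la`, `n_pcc`, `n_both`,
#'   `p_raw`, `p_adjusted`, `consistent`.
#' @export
la_pcc_consistency <- function(la_records, pcc_records, alpha = 0.05) {
  la <- if (inherits(la_records, "aagci_screen")) la_records$records else la_records
  pcc <- if (inherits(pcc_records, "aagci_pcc_screen")) pcc_records$records else pcc_records
  stopifnot(is.data.frame(la), is.data.frame(pcc))
  key <- c("module_id", "gene_a", "gene_b")
  joined <- dplyr::full_join(
    select(la, dplyr::all_of(key), la_sig = "significant"),
    select(pcc, dplyr::all_of(key), pcc_sig = "significant"),
    by = key
  )
  if (anyNA(joined$la_sig) || anyNA(joined$pcc_sig)) {
    abort("LA and PCC screens were not run on identical module pair enumerations")
  }
  out <- joined |>
    group_by(.data$module_id) |>
    summarise(
      n_pairs = n(),
      n_la = sum(.data$la_sig),
      n_pcc = sum(.data$pcc_sig),
      n_both = sum(.data$la_sig & .data$pcc_sig),
      .groups = "drop"
    ) |>
    mutate(
      p_raw = purrr::pmap_dbl(
        list(.data$n_both, .data$n_la, .data$n_pcc, .data$n_pairs),
        function(ab, a, b, np) {
          fisher_one_sided(ab, a - ab, b - ab, np - a - b + ab)$p_value
        }
      )
    ) |>
    mutate(
      p_adjusted = p.adjust(.data$p_raw, method = "BH"),
      consistent = .data$p_adjusted <= alpha
    ) |>
    arrange(.data$module_id)
  out
}
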