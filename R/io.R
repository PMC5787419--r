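#' Read an expression matrix and sample metadata into a study
#'
#' The matrix is TSV with a header row of sample ids and gene symbols in the
#' first column; the metadata is TSV with a `sample_id` column and a numeric
#' scouting column (default `age`). Samples are intersected between the two
#' files and returned in matrix order; metadata-only samples are dropped with
#' a warning. Genes with any missing expression value are dropped and counted
#' (the liquid-association score has no missing-data variant).
#'
#' @param matrix_path Path to the expression TSV.
#' @param metadata_path Path to the metadata TSV.
#' @param scouting_column Name of the numeric metadata column (default
#'   `"age"`).
#' @return An (untransformed) [expression_study()].
#' @export
read_expression <- function(matrix_path, metadata_path, scouting_column = "age") {
  expr <- readr::read_tsv(matrix_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(expr) < 2) abort(sprintf("%s has no sample columns", matrix_path))
  genes <- toupper(as.character(expr[[1]]))
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicated gene id in %s: %s",
      matrix_path, genes[duplicated(genes)][1]))
  }
  # non-numeric entries become NA here and are dropped below as missing
  values <- suppressWarnings(
    vapply(expr[-1], as.numeric, numeric(nrow(expr)))
  )
  if (nrow(expr) == 1) values <- matrix(values, nrow = 1,
    dimnames = list(NULL, names(expr)[-1]))
  rownames(values) <- genes

  meta <- readr::read_tsv(metadata_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!"sample_id" %in% names(meta)) {
    abort(sprintf("metadata %s must contain a `sample_id` column", metadata_path))
  }
  if (!scouting_column %in% names(meta)) {
    abort(sprintf("metadata %s has no column `%s`", metadata_path, scouting_column))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort(sprintf("duplicated sample id in metadata: %s",
      meta$sample_id[duplicated(meta$sample_id)][1]))
  }

  shared <- intersect(colnames(values), meta$sample_id)
  if (!length(shared)) abort("no overlapping samples between matrix and metadata")
  extra_meta <- setdiff(meta$sample_id, colnames(values))
  if (length(extra_meta)) {
    warn(sprintf(
      "%d metadata sample(s) absent from the matrix were dropped (e.g. %s)",
      length(extra_meta), extra_meta[1]
    ))
  }
  extra_mat <- setdiff(colnames(values), meta$sample_id)
  if (length(extra_mat)) {
    warn(sprintf(
      "%d matrix sample(s) absent from the metadata were dropped (e.g. %s)",
      length(extra_mat), extra_mat[1]
    ))
  }
  keep <- colnames(values) %in% shared # matrix order
  values <- values[, keep, drop = FALSE]

  scout_chr <- meta[[scouting_column]][match(colnames(values), meta$sample_id)]
  scouting <- suppressWarnings(as.numeric(scout_chr))
  if (anyNA(scouting)) {
    abort(sprintf(
      "non-numeric %s value for sample %s",
      scouting_column, colnames(values)[which(is.na(scouting))[1]]
    ))
  }

  incomplete <- rowSums(!is.finite(values)) > 0
  if (any(incomplete)) {
    inform(sprintf("dropped %d gene(s) with missing values", sum(incomplete)))
    values <- values[!incomplete, , drop = FALSE]
  }
  if (!nrow(values)) abort("no complete gene rows left after dropping missing values")

  expression_study(values, scouting, scouting_name = scouting_column)
}

#' Construct a gene-set collection
#'
#' Named modules (GO/KEGG-style): a map of module id to a deduplicated,
#' uppercased set of gene symbols, with an optional description per module.
#'
#' @param sets Named list of character vectors (module id -> symbols).
#' @param descriptions Optional named character vector of descriptions.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || (length(sets) && is.null(names(sets)))) {
    abort("`sets` must be a named list of symbol vectors")
  }
  if (anyDuplicated(names(sets))) {
    abort(sprintf("duplicated module id: %s", names(sets)[duplicated(names(sets))][1]))
  }
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    abort(sprintf("empty module after parsing: %s", names(sets)[empty][1]))
  }
  desc <- setNames(rep("", length(sets)), names(sets))
  if (!is.null(descriptions)) desc[names(descriptions)] <- descriptions
  structure(list(sets = sets, descriptions = desc), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection> %d module(s), sizes %s\n",
    length(x$sets),
    if (length(x$sets)) {
      paste0(min(lengths(x$sets)), "-", max(lengths(x$sets)))
    } else {
      "-"
    }
  ))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @exportS3Method tibble::as_tibble
as_tibble.gene_set_collection <- function(x, ...) {
  tibble(
    module_id = names(x$sets),
    description = unname(x$descriptions[names(x$sets)]),
    n_genes = unname(lengths(x$sets)),
    genes = unname(x$sets)
  )
}

#' Read gene sets in GMT format
#'
#' Each line is tab-separated: set id, description, then one or more gene
#' symbols. Symbols are uppercased and deduplicated per set.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()]; empty files yield an empty collection
#'   with a warning.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn(sprintf("empty GMT file: %s", path))
    return(gene_set_collection(setNames(list(), character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields in %s", short[1], path))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  descriptions <- setNames(vapply(fields, `[[`, character(1), 2), ids)
  sets <- setNames(lapply(fields, function(f) f[-(1:2)]), ids)
  gene_set_collection(sets, descriptions)
}

#' Write gene sets in GMT format
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
      collapse = "\t"
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter modules by usable size
#'
#' Intersects every module with the study's measured genes and keeps modules
#' whose usable size lies in `[min_size, max_size)`. The size filter applies
#' to the intersection because screening can only use measured genes; the
#' upper bound is strict ("fewer than 500 genes"), excluding overly general
#' functional terms. The intersected membership is what downstream screening
#' uses.
#'
#' @param collection A [gene_set_collection()].
#' @param study An [expression_study()].
#' @param max_size Exclusive upper size bound (default 500).
#' @param min_size Inclusive lower size bound (default 5; smaller modules make
#'   per-module FDR control and consistency testing vacuous).
#' @return The filtered collection with intersected memberships.
#' @export
filter_modules <- function(collection, study, max_size = 500, min_size = 5) {
  stopifnot(inherits(collection, "gene_set_collection"))
  stopifnot(inherits(study, "expression_study"))
  genes <- study_genes(study)
  sets <- lapply(collection$sets, function(g) intersect(g, genes))
  keep <- lengths(sets) >= min_size & lengths(sets) < max_size
  if (!any(keep)) {
    warn("no module survives the size filter")
    return(gene_set_collection(setNames(list(), character())))
  }
  gene_set_collection(sets[keep], collection$descriptions[names(sets)[keep]])
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Path to the list file; blank lines and `#` comments are
#'   skipped, symbols are uppercased and deduplicated.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(toupper(x))
}

#' Read an undirected PPI edge list
#'
#' Two-column TSV of gene symbols (`#` comments allowed). Self-loops are
#' dropped and duplicate/reversed edges collapsed, yielding a simple
#' undirected graph in which every node has degree >= 1.
#'
#' @param path Path to the edge-list TSV.
#' @return An [igraph::igraph] object with uppercased symbol names.
#' @export
read_ppi <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  edges <- readr::read_tsv(path,
    col_names = c("a", "b"), comment = "#",
    col_types = readr::cols(readr::col_character(), readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!nrow(edges)) abort(sprintf("no edges in %s", path))
  edges <- dplyr::mutate(edges, a = toupper(.data$a), b = toupper(.data$b))
  loops <- edges$a == edges$b
  if (any(loops)) {
    inform(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read paired up/down perturbation signatures from GMT
#'
#' Set ids must end in `_up` or `_down`; the prefix is the perturbation id and
#' the two sets with matching prefixes are paired. An unpaired set yields a
#' signature with an empty partner (with a warning). Up and down sets of one
#' perturbation must be disjoint.
#'
#' @param path Path to the signature GMT file.
#' @return A tibble with columns `perturbation_id`, `up_genes` (list),
#'   `down_genes` (list).
#' @export
read_signatures <- function(path) {
  collection <- read_gmt(path)
  ids <- names(collection$sets)
  is_up <- grepl("_up$", ids)
  is_down <- grepl("_down$", ids)
  bad <- ids[!(is_up | is_down)]
  if (length(bad)) {
    abort(sprintf("signature set id without _up/_down suffix: %s", bad[1]))
  }
  prefix <- sub("_(up|down)$", "", ids)
  perturbations <- sort(unique(prefix))
  up <- setNames(vector("list", length(perturbations)), perturbations)
  down <- up
  for (i in seq_along(ids)) {
    if (is_up[i]) up[[prefix[i]]] <- collection$sets[[i]]
    else down[[prefix[i]]] <- collection$sets[[i]]
  }
  unpaired <- vapply(perturbations, function(p) {
    is.null(up[[p]]) || is.null(down[[p]])
  }, logical(1))
  if (any(unpaired)) {
    warn(sprintf(
      "%d perturbation(s) have only one of the up/down sets (e.g. %s)",
      sum(unpaired), perturbations[unpaired][1]
    ))
  }
  up <- lapply(up, function(g) g %||% character())
  down <- lapply(down, function(g) g %||% character())
  overlap <- vapply(perturbations, function(p) {
    length(intersect(up[[p]], down[[p]])) > 0
  }, logical(1))
  if (any(overlap)) {
    abort(sprintf(
      "up and down sets overlap for perturbation %s",
      perturbations[overlap][1]
    ))
  }
  tibble(
    perturbation_id = perturbations,
    up_genes = unname(up),
    down_genes = unname(down)
  )
}
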