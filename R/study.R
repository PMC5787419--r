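#' Construct an expression study
#'
#' Bundles a gene x sample expression matrix with one scouting value (age, in
#' years) per sample. This is the container every screening stage consumes.
#'
#' @param values Numeric matrix, genes in rows (unique rownames = symbols,
#'   uppercased) and samples in columns (unique colnames).
#' @param scouting Numeric vector of scouting values, one per column of
#'   `values`, all finite.
#' @param scouting_name Name of the scouting variable (default `"age"`).
#' @param transformed Whether `values` and `scouting` are already
#'   inverse-normal transformed. Set by [transform_study()]; only set this
#'   yourself for data that is already standardised.
#' @return An object of class `expression_study`.
#' @seealso [transform_study()], [read_expression()]
#' @export
expression_study <- function(values, scouting, scouting_name = "age",
                             transformed = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene rownames and sample colnames")
  }
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) {
    abort(sprintf(
      "duplicated gene id: %s",
      rownames(values)[duplicated(rownames(values))][1]
    ))
  }
  if (anyDuplicated(colnames(values))) {
    abort(sprintf(
      "duplicated sample id: %s",
      colnames(values)[duplicated(colnames(values))][1]
    ))
  }
  if (any(!is.finite(values))) {
    abort("`values` contains missing or non-finite entries; drop or handle them upstream")
  }
  if (length(scouting) != ncol(values)) {
    abort("`scouting` must have one value per sample")
  }
  if (any(!is.finite(scouting))) {
    bad <- colnames(values)[which(!is.finite(scouting))[1]]
    abort(sprintf("non-finite scouting value for sample %s", bad))
  }
  structure(
    list(
      values = values,
      scouting = as.numeric(scouting),
      scouting_raw = as.numeric(scouting),
      scouting_name = scouting_name,
      transformed = isTRUE(transformed)
    ),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study> %d genes x %d samples; scouting = %s (range %.1f-%.1f)%s\n",
    nrow(x$values), ncol(x$values), x$scouting_name,
    min(x$scouting_raw), max(x$scouting_raw),
    if (x$transformed) "; inverse-normal transformed" else ""
  ))
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Gene symbols of a study
#' @param study An `expression_study`.
#' @return Character vector of gene symbols (row order of the matrix).
#' @export
study_genes <- function(study) rownames(study$values)

#' Sample identifiers of a study
#' @param study An `expression_study`.
#' @return Character vector of sample ids (column order of the matrix).
#' @export
study_samples <- function(study) colnames(study$values)

#' Inverse-normal transform a whole study
#'
#' Applies [inverse_normal_transform()] to every gene's expression profile
#' (across samples) and to the scouting variable. The untransformed scouting
#' values are retained (as `scouting_raw`) so that age-stratum diagnostics can
#' still cut on years.
#'
#' @param study An `expression_study`.
#' @return The study with `transformed = TRUE`. Transforming twice is a no-op
#'   beyond rank discreteness and is refused with a warning.
#' @export
transform_study <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (study$transformed) {
    warn("study is already transformed; returning it unchanged")
    return(study)
  }
  study$values <- t(apply(study$values, 1, inverse_normal_transform))
  study$scouting <- inverse_normal_transform(study$scouting_raw)
  study$transformed <- TRUE
  study
}

#' Restrict a study to a gene universe
#'
#' Keeps only the genes present in a reference universe (e.g. protein-coding
#' symbols), mirroring the restriction of measured genes to an annotated
#' background before module screening.
#'
#' @param study An `expression_study`.
#' @param universe Either a path to a one-symbol-per-line text file or a
#'   character vector of symbols.
#' @return The restricted study; the retained gene count is reported.
#' @export
restrict_to_universe <- function(study, universe) {
  stopifnot(inherits(study, "expression_study"))
  if (is.character(universe) && length(universe) == 1) {
    if (file.exists(universe)) {
      universe <- read_gene_list(universe)
    } else if (grepl("[/\\\\.]", universe)) {
      abort(sprintf("universe file not found: %s", universe))
    }
  }
  if (!is.character(universe) || !length(universe)) {
    abort("`universe` must be a file path or a non-empty character vector")
  }
  universe <- unique(toupper(universe))
  keep <- rownames(study$values) %in% universe
  if (!any(keep)) abort("no study gene is present in the universe")
  inform(sprintf(
    "universe restriction: %d of %d genes retained",
    sum(keep), nrow(study$values)
  ))
  study$values <- study$values[keep, , drop = FALSE]
  study
}
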