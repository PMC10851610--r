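#' Construct a reference population for rank normalization
#'
#' A reference population holds, per gene, the sorted expression values of a
#' fixed normalization cohort (in the published assay: 735 solid tumors of 35
#' histologies). A tumor's expression is located within this baseline to give
#' its percentile rank.
#'
#' @param values named list of numeric vectors, one per gene; values are
#'   sorted ascending internally. All genes must have the same number of
#'   values, all finite and non-negative.
#' @param n_histologies number of histologies represented (metadata only).
#' @param version free-text version label.
#' @return An object of class \code{ctab_reference} with elements
#'   \code{values}, \code{n_samples}, \code{n_histologies}, \code{version}.
#' @export
reference_population <- function(values, n_histologies = NA_integer_,
                                 version = "unversioned") {
  if (!is.list(values) || !length(values) || is.null(names(values)) ||
      any(!nzchar(names(values))))
    stop("'values' must be a non-empty named list of numeric vectors")
  if (anyDuplicated(names(values)))
    stop("duplicate gene names in reference")
  lens <- lengths(values)
  if (any(lens == 0L))
    stop("every gene needs at least one reference value")
  if (length(unique(lens)) != 1L)
    stop("all genes must have the same number of reference values")
  values <- lapply(values, function(v) {
    v <- as.numeric(v)
    if (any(!is.finite(v)) || any(v < 0))
      stop("reference values must be finite and non-negative")
    sort(v)
  })
  structure(list(values = values, n_samples = unname(lens[1L]),
                 n_histologies = n_histologies, version = version),
            class = "ctab_reference")
}

#' @export
print.ctab_reference <- function(x, ...) {
  cat("Reference population:", length(x$values), "genes x", x$n_samples,
      "samples")
  if (!is.na(x$n_histologies)) cat(" (", x$n_histologies, " histologies)",
                                   sep = "")
  cat("  [", x$version, "]\n", sep = "")
  invisible(x)
}

#' Percentile rank of expression values against a reference
#'
#' Converts raw expression values to integer percentile ranks in \[0, 100\]
#' against a sorted reference vector. Ties use the midrank convention:
#' \deqn{rank = round(100 (n_{<} + 0.5\, n_{=}) / n)}
#' where \eqn{n_{<}} and \eqn{n_{=}} count reference values below and equal to
#' the probe value, and rounding is half-up. Values outside the reference
#' range clamp to 0 or 100. The function is monotone non-decreasing in
#' \code{value}.
#'
#' @param value numeric vector of expression values (finite).
#' @param reference sorted ascending numeric vector of reference values.
#' @return integer vector of ranks in \[0, 100\], same length as \code{value}.
#' @export
#' @examples
#' percentile_rank(25, c(10, 20, 30, 40))  # 50
#' percentile_rank(20, c(10, 20, 20, 40))  # midrank over the ties: 50
percentile_rank <- function(value, reference) {
  if (!length(reference))
    stop("empty reference")
  if (anyNA(reference) || any(!is.finite(reference)))
    stop("reference values must be finite")
  if (is.unsorted(reference))
    stop("reference must be sorted ascending")
  if (!length(value) || anyNA(value) || any(!is.finite(value)))
    stop("'value' must be finite and non-missing")
  n <- length(reference)
  n_le <- findInterval(value, reference)
  n_lt <- findInterval(value, reference, left.open = TRUE)
  # integer numerator keeps exact halves exact, so half-up rounding is stable
  r <- floor(100 * (n_lt + n_le) / (2 * n) + 0.5)
  as.integer(pmin(pmax(r, 0), 100))
}

#' Rank-normalize an expression matrix against a reference population
#'
#' Applies [percentile_rank()] gene by gene. Every requested gene must be
#' present in the reference; absent genes raise an error naming them rather
#' than being silently dropped.
#'
#' @param expr numeric matrix or data frame, samples x genes, with unique
#'   column (gene) names and optional row (sample) names. Values must be
#'   non-negative.
#' @param reference a \code{ctab_reference}.
#' @param genes genes to rank; defaults to all columns of \code{expr}.
#' @return integer matrix of ranks in \[0, 100\], samples x genes.
#' @export
rank_matrix <- function(expr, reference, genes = NULL) {
  stopifnot(inherits(reference, "ctab_reference"))
  expr <- as.matrix(expr)
  if (is.null(colnames(expr)) || anyDuplicated(colnames(expr)))
    stop("'expr' needs unique column (gene) names")
  if (!is.null(rownames(expr)) && anyDuplicated(rownames(expr)))
    stop("'expr' sample ids must be unique")
  if (any(!is.finite(expr)) || any(expr < 0))
    stop("expression values must be finite and non-negative")
  if (is.null(genes)) genes <- colnames(expr)
  missing_expr <- setdiff(genes, colnames(expr))
  if (length(missing_expr))
    stop("genes not in expression matrix: ", paste(missing_expr, collapse = ", "))
  missing_ref <- setdiff(genes, names(reference$values))
  if (length(missing_ref))
    stop("genes missing from reference population: ",
         paste(missing_ref, collapse = ", "))
  out <- matrix(0L, nrow(expr), length(genes),
                dimnames = list(rownames(expr), genes))
  for (g in genes)
    out[, g] <- percentile_rank(expr[, g], reference$values[[g]])
  out
}
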