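#' Cancer testis antigen burden (CTAB) score
#'
#' Sums the integer percentile ranks of the panel genes, giving a score in
#' \[0, 100 x panel size\] (\[0, 1700\] for the default 17-gene panel). Every
#' panel gene must be present (after alias resolution); missing genes are a
#' hard error, not imputed, because the score is only defined for samples
#' with expression data for the full panel.
#'
#' @param ranks either a named numeric vector of one sample's ranks, or a
#'   samples x genes rank matrix as returned by [rank_matrix()]. Names /
#'   column names may use panel aliases (e.g. \code{NY-ESO-1}).
#' @param panel a [ctab_panel()]; default the canonical 17-gene panel.
#' @return integer score (vector of scores for a matrix input, named by
#'   sample id when row names are present).
#' @export
#' @examples
#' r <- setNames(rep(100L, 17), default_ctab_panel()$genes)
#' ctab_score(r)  # 1700
ctab_score <- function(ranks, panel = default_ctab_panel()) {
  stopifnot(inherits(panel, "ctab_panel"))
  if (is.matrix(ranks) || is.data.frame(ranks)) {
    m <- as.matrix(ranks)
    if (is.null(colnames(m))) stop("rank matrix needs gene column names")
    colnames(m) <- resolve_genes(panel, colnames(m))
    missing <- setdiff(panel$genes, colnames(m))
    if (length(missing))
      stop("panel genes missing from ranks: ", paste(missing, collapse = ", "))
    m <- m[, panel$genes, drop = FALSE]
    .check_ranks(m)
    return(as.integer(round(rowSums(m))) |> stats::setNames(rownames(m)))
  }
  if (is.null(names(ranks))) stop("rank vector needs gene names")
  names(ranks) <- resolve_genes(panel, names(ranks))
  missing <- setdiff(panel$genes, names(ranks))
  if (length(missing))
    stop("panel genes missing from ranks: ", paste(missing, collapse = ", "))
  v <- ranks[panel$genes]
  .check_ranks(v)
  as.integer(round(sum(v)))
}

.check_ranks <- function(x) {
  if (anyNA(x) || any(!is.finite(x)))
    stop("ranks must be finite and non-missing")
  if (any(x < 0 | x > 100))
    stop("ranks must lie in [0, 100]")
  invisible(TRUE)
}

#' Classify CTAB scores as high or low
#'
#' Scores greater than or equal to the cutoff are "high", below it "low".
#' The default cutoff of 170 is the discovery-cohort median applied as a
#' fixed threshold; the boundary is inclusive (170 -> "high").
#'
#' @param score non-negative integer score(s).
#' @param cutoff non-negative cutoff (default 170).
#' @return character vector of \code{"high"} / \code{"low"}.
#' @export
#' @examples
#' classify_ctab(c(169, 170, 1700))
classify_ctab <- function(score, cutoff = 170) {
  if (anyNA(score) || any(score < 0) || length(cutoff) != 1L ||
      is.na(cutoff) || cutoff < 0)
    stop("'score' and 'cutoff' must be non-negative")
  ifelse(score >= cutoff, "high", "low")
}

#' Score and classify a whole cohort
#'
#' Computes per-sample CTAB scores and high/low classes from a rank matrix,
#' with a cohort summary (median and quartiles), optionally stratified by a
#' grouping factor such as tumor type.
#'
#' @inheritParams ctab_score
#' @param cutoff high/low cutoff passed to [classify_ctab()].
#' @param groups optional per-sample labels (e.g. tumor type) of the same
#'   length as the number of rows of \code{ranks}, used for the per-group
#'   summary.
#' @return An object of class \code{ctab_result}: a list with
#'   \code{results} (data frame: sample_id, ctab, ctab_class), \code{median},
#'   \code{cutoff}, and \code{by_group} (data frame: group, n, median, q1,
#'   q3; \code{NULL} when \code{groups} is absent).
#' @export
cohort_ctab <- function(ranks, panel = default_ctab_panel(), cutoff = 170,
                        groups = NULL) {
  scores <- ctab_score(ranks, panel)
  ids <- if (!is.null(names(scores))) names(scores)
         else sprintf("S%04d", seq_along(scores))
  res <- data.frame(sample_id = ids, ctab = as.integer(scores),
                    ctab_class = classify_ctab(scores, cutoff),
                    stringsAsFactors = FALSE, row.names = NULL)
  by_group <- NULL
  if (!is.null(groups)) {
    if (length(groups) != length(scores))
      stop("'groups' must match the number of samples")
    sp <- split(res$ctab, groups)
    by_group <- data.frame(
      group = names(sp),
      n = lengths(sp),
      median = vapply(sp, stats::median, numeric(1)),
      q1 = vapply(sp, stats::quantile, numeric(1), probs = 0.25, names = FALSE),
      q3 = vapply(sp, stats::quantile, numeric(1), probs = 0.75, names = FALSE),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(results = res, median = stats::median(res$ctab),
                 cutoff = cutoff, by_group = by_group),
            class = "ctab_result")
}

#' @export
print.ctab_result <- function(x, ...) {
  cat("CTAB results:", nrow(x$results), "samples; median", x$median,
      "; cutoff", x$cutoff, "\n")
  cat("  high:", sum(x$results$ctab_class == "high"),
      " low:", sum(x$results$ctab_class == "low"), "\n")
  if (!is.null(x$by_group)) {
    cat("  per-group medians:\n")
    print(x$by_group, row.names = FALSE)
  }
  invisible(x)
}
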