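#' PD-L1 tumor proportion score groups
#'
#' Classifies TPS percentages into the standard IHC strata: negative
#' (TPS = 0\%), low (0\% < TPS < 50\%) and high (TPS >= 50\%).
#'
#' @param tps numeric vector of tumor proportion scores in \[0, 100\].
#' @return factor with levels negative, low, high.
#' @export
#' @examples
#' pdl1_group(c(0, 25, 50))
pdl1_group <- function(tps) {
  if (anyNA(tps) || any(tps < 0 | tps > 100))
    stop("TPS must lie in [0, 100]")
  factor(ifelse(tps == 0, "negative", ifelse(tps < 50, "low", "high")),
         levels = c("negative", "low", "high"))
}

#' Tumor mutational burden groups
#'
#' Dichotomizes TMB at the conventional 10 mut/Mb threshold:
#' low (< 10) vs high (>= 10).
#'
#' @param tmb numeric vector of non-synonymous mutations per megabase, >= 0.
#' @return factor with levels low, high.
#' @export
#' @examples
#' tmb_group(c(0, 9.9, 10))
tmb_group <- function(tmb) {
  if (anyNA(tmb) || any(tmb < 0))
    stop("TMB must be non-negative")
  factor(ifelse(tmb < 10, "low", "high"), levels = c("low", "high"))
}

#' Rank-based comparison of a continuous variable between groups
#'
#' Two groups are compared with the two-sided Wilcoxon rank-sum test (exact
#' when both groups have at most 50 untied observations, otherwise the
#' normal approximation with tie correction and no continuity correction);
#' three or more with the Kruskal-Wallis test. Being rank-based, the result
#' is invariant under strictly monotone transforms of \code{values}.
#'
#' @param values numeric vector (e.g. CTAB scores).
#' @param labels group labels, same length as \code{values}; pairs with a
#'   missing value or label are dropped.
#' @return list with \code{test} ("wilcoxon" or "kruskal-wallis"),
#'   \code{statistic}, \code{p_value}, and \code{group_sizes}.
#' @export
compare_groups <- function(values, labels) {
  if (length(values) != length(labels))
    stop("'values' and 'labels' must have the same length")
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- factor(labels[keep])
  labels <- droplevels(labels)
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least 2 non-empty groups")
  if (any(sizes < 2L))
    stop("every group needs at least 2 observations; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (length(sizes) == 2L) {
    sp <- split(values, labels)
    exact <- all(sizes <= 50L) && !anyDuplicated(values)
    ht <- suppressWarnings(stats::wilcox.test(sp[[1L]], sp[[2L]],
                                              exact = exact,
                                              correct = FALSE))
    test <- "wilcoxon"
  } else {
    ht <- stats::kruskal.test(values, labels)
    test <- "kruskal-wallis"
  }
  list(test = test, statistic = unname(ht$statistic),
       p_value = ht$p.value, group_sizes = as.integer(sizes) |>
         stats::setNames(names(sizes)))
}

#' Define a gene-expression signature
#'
#' Generic rank-aggregation signatures (e.g. configurable stand-ins for
#' published proliferation or tumor-immunogenicity signatures whose exact
#' gene lists are assay-specific).
#'
#' @param name signature name.
#' @param genes non-empty character vector of gene symbols.
#' @param aggregation \code{"sum"} or \code{"mean"} of percentile ranks.
#' @return object of class \code{ctab_signature}.
#' @export
signature_definition <- function(name, genes,
                                 aggregation = c("sum", "mean")) {
  if (!is.character(genes) || !length(genes) || anyNA(genes))
    stop("'genes' must be a non-empty character vector")
  aggregation <- match.arg(aggregation)
  structure(list(name = name, genes = genes, aggregation = aggregation),
            class = "ctab_signature")
}

#' Score a rank-aggregation signature
#'
#' Aggregates the percentile ranks of a signature's genes per sample. With
#' \code{aggregation = "sum"} over the 17-gene CTA panel this reproduces
#' [ctab_score()] exactly.
#'
#' @param ranks named rank vector (one sample) or samples x genes rank
#'   matrix.
#' @param signature a [signature_definition()].
#' @return numeric score(s).
#' @export
signature_score <- function(ranks, signature) {
  stopifnot(inherits(signature, "ctab_signature"))
  one <- !(is.matrix(ranks) || is.data.frame(ranks))
  m <- if (one) matrix(ranks, 1L, dimnames = list(NULL, names(ranks)))
       else as.matrix(ranks)
  missing <- setdiff(signature$genes, colnames(m))
  if (length(missing))
    stop("signature genes missing from ranks: ",
         paste(missing, collapse = ", "))
  m <- m[, signature$genes, drop = FALSE]
  out <- switch(signature$aggregation,
                sum = rowSums(m), mean = rowMeans(m))
  if (one) unname(out) else out
}

#' Pairwise Spearman correlations between continuous biomarkers
#'
#' Correlates every pair of columns (e.g. CTAB, PD-L1 TPS, TMB, signature
#' scores) using pairwise-complete observations. Pairs with fewer than 3
#' complete cases are reported as \code{NA}.
#'
#' @param table data frame or matrix of per-sample numeric biomarkers.
#' @return list of symmetric matrices \code{r}, \code{p} and \code{n}
#'   (complete cases per pair).
#' @export
biomarker_correlations <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("'table' must be numeric")
  k <- ncol(m)
  if (k < 2L) stop("need at least 2 biomarkers")
  if (is.null(colnames(m))) colnames(m) <- sprintf("V%d", seq_len(k))
  nm <- colnames(m)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  n <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    r[i, i] <- 1
    n[i, i] <- sum(!is.na(m[, i]))
  }
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      cc <- stats::complete.cases(m[, c(i, j)])
      n[i, j] <- n[j, i] <- sum(cc)
      if (sum(cc) < 3L) next
      x <- m[cc, i]; y <- m[cc, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      r[i, j] <- r[j, i] <- stats::cor(x, y, method = "spearman")
      p[i, j] <- p[j, i] <- .spearman_pair_p(x, y)
    }
  }
  list(r = r, p = p, n = n)
}
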