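# Pairwise Spearman correlation with p-values.
# For n > 30 samples p comes from the t approximation on the rank
# correlation; for n <= 30 each pair is delegated to cor.test(), which uses
# the exact null distribution of the rank statistic when there are no ties.

.spearman_pair_p <- function(x, y) {
  suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                   alternative = "two.sided")$p.value)
}

#' Pairwise Spearman correlation matrix with p-values
#'
#' Computes all pairwise two-sided Spearman correlations between the columns
#' of a samples x genes matrix (raw expression or percentile ranks - the
#' statistic is invariant under strictly monotone transforms). Genes with
#' zero variance have undefined correlations; their rows/columns are
#' reported as \code{NA} with a warning, never silently set to 0.
#'
#' @param x numeric matrix or data frame, samples x genes, at least 3
#'   samples and 2 genes.
#' @return list with elements \code{r} (correlations, diagonal 1), \code{p}
#'   (two-sided p-values, diagonal \code{NA}) and \code{n} (sample count).
#' @export
#' @examples
#' m <- cbind(a = 1:5, b = c(1, 3, 2, 5, 4))
#' spearman_matrix(m)$r
spearman_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 samples")
  if (ncol(x) < 2L) stop("need at least 2 genes")
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  n <- nrow(x)
  const <- apply(x, 2, function(v) stats::sd(v) == 0 || anyNA(v))
  rk <- apply(x, 2, rank)
  r <- suppressWarnings(stats::cor(rk))
  if (n > 30L) {
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    p <- matrix(NA_real_, ncol(x), ncol(x),
                dimnames = dimnames(r))
    for (i in seq_len(ncol(x) - 1L))
      for (j in seq(i + 1L, ncol(x)))
        p[i, j] <- p[j, i] <- .spearman_pair_p(x[, i], x[, j])
  }
  diag(r) <- 1
  diag(p) <- NA_real_
  if (any(const)) {
    warning("constant gene(s), correlations undefined: ",
            paste(colnames(x)[const], collapse = ", "))
    r[const, ] <- r[, const] <- NA_real_
    p[const, ] <- p[, const] <- NA_real_
  }
  list(r = r, p = p, n = n)
}

#' Build a significance-thresholded correlation network
#'
#' Edges connect gene pairs whose two-sided Spearman p-value is at most
#' \code{alpha} and whose absolute correlation is at least \code{edge_min}.
#' Edge weight is the absolute correlation; the sign is kept separately.
#' \code{edge_min = 0.2} is the grouping default; use \code{edge_min = 0}
#' to retain every significant edge for plotting.
#'
#' @param r symmetric Spearman correlation matrix (as from
#'   [spearman_matrix()]).
#' @param p matching symmetric p-value matrix.
#' @param alpha significance threshold in (0, 1), default 0.05.
#' @param edge_min minimum absolute correlation for an edge, default 0.2.
#' @return object of class \code{ctab_network}: list with \code{genes},
#'   \code{r}, \code{p}, \code{alpha}, \code{edge_min}, and \code{edges}
#'   (data frame gene_a, gene_b, r_s, p, weight, sign).
#' @export
build_network <- function(r, p, alpha = 0.05, edge_min = 0.2) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  r <- as.matrix(r); p <- as.matrix(p)
  if (!identical(dim(r), dim(p)) || nrow(r) != ncol(r))
    stop("'r' and 'p' must be square matrices of the same size")
  genes <- colnames(r)
  if (is.null(genes)) stop("correlation matrix needs gene names")
  idx <- which(upper.tri(r), arr.ind = TRUE)
  keep <- !is.na(p[idx]) & p[idx] <= alpha &
    !is.na(r[idx]) & abs(r[idx]) >= edge_min
  idx <- idx[keep, , drop = FALSE]
  edges <- data.frame(
    gene_a = genes[idx[, 1L]],
    gene_b = genes[idx[, 2L]],
    r_s = r[idx],
    p = p[idx],
    weight = abs(r[idx]),
    sign = ifelse(r[idx] >= 0, 1L, -1L),
    stringsAsFactors = FALSE)
  structure(list(genes = genes, r = r, p = p, alpha = alpha,
                 edge_min = edge_min, edges = edges),
            class = "ctab_network")
}

#' @export
print.ctab_network <- function(x, ...) {
  cat("Correlation network:", length(x$genes), "genes,", nrow(x$edges),
      "edges (p <=", x$alpha, ", |r_s| >=", x$edge_min, ")\n")
  invisible(x)
}

.positive_graph <- function(network) {
  pos <- network$edges[network$edges$sign > 0, c("gene_a", "gene_b", "weight"),
                       drop = FALSE]
  igraph::graph_from_data_frame(pos, directed = FALSE,
                                vertices = network$genes)
}

#' Identify co-expression groups
#'
#' Groups are the connected components of the positive-edge subgraph of the
#' network; genes with no qualifying positive edge form singleton groups.
#' Components are labeled 1, 2, ... in decreasing size order (ties broken by
#' the earliest member in the network's gene order), so the main
#' co-expressed block is always group 1.
#'
#' @param network a \code{ctab_network} built with a positive
#'   \code{edge_min}.
#' @return named integer vector: gene -> group label.
#' @export
identify_groups <- function(network) {
  stopifnot(inherits(network, "ctab_network"))
  comp <- igraph::components(.positive_graph(network))
  member <- comp$membership[network$genes]
  first_member <- vapply(seq_len(comp$no),
                         function(k) min(which(member == k)), integer(1))
  ord <- order(-comp$csize, first_member)
  relabel <- integer(comp$no)
  relabel[ord] <- seq_len(comp$no)
  stats::setNames(relabel[member], network$genes)
}

#' Summarize correlation structure per group
#'
#' For each group reports the mean Spearman correlation over its within-group
#' pairs (undefined for singletons, reported as \code{NA}), the mean over all
#' pairs with at least one end in the group, and the maximum over those
#' pairs.
#'
#' @param r symmetric Spearman correlation matrix.
#' @param groups named group labels as from [identify_groups()].
#' @return list with \code{groups} (data frame: group, size, mean_within,
#'   mean_all, max_any), \code{mean_all_pairs} (mean over every unordered
#'   gene pair) and \code{max_offdiag}.
#' @export
group_summary <- function(r, groups) {
  r <- as.matrix(r)
  genes <- names(groups)
  if (is.null(genes) || !all(genes %in% colnames(r)))
    stop("'groups' must be named with genes present in 'r'")
  r <- r[genes, genes]
  ut <- upper.tri(r)
  labs <- sort(unique(groups))
  rows <- lapply(labs, function(g) {
    ing <- groups == g
    within <- r[ing, ing, drop = FALSE]
    wvals <- within[upper.tri(within)]
    touch <- outer(ing, ing, "|") & ut
    data.frame(group = g, size = sum(ing),
               mean_within = if (length(wvals)) mean(wvals) else NA_real_,
               mean_all = mean(r[touch]),
               max_any = max(r[touch]))
  })
  list(groups = do.call(rbind, rows),
       mean_all_pairs = mean(r[ut]),
       max_offdiag = max(r[ut]))
}

#' Force-directed network layout
#'
#' Places genes in the plane with the Fruchterman-Reingold algorithm, edges
#' weighted by absolute correlation so that strongly correlated genes sit
#' closer together. Deterministic for a fixed seed.
#'
#' @param network a \code{ctab_network}.
#' @param seed integer seed controlling the layout's random initialization.
#' @return numeric matrix, genes x (x, y).
#' @export
layout_fr <- function(network, seed = 1L) {
  stopifnot(inherits(network, "ctab_network"))
  if (!length(network$genes)) stop("empty network")
  g <- igraph::graph_from_data_frame(
    network$edges[, c("gene_a", "gene_b", "weight"), drop = FALSE],
    directed = FALSE, vertices = network$genes)
  set.seed(seed)
  w <- if (nrow(network$edges)) igraph::E(g)$weight else NULL
  xy <- igraph::layout_with_fr(g, weights = w)
  dimnames(xy) <- list(network$genes, c("x", "y"))
  xy
}

#' Plot a correlation network
#'
#' Basic base-graphics rendering of the force-directed layout: red edges for
#' positive, blue for negative correlations, edge width proportional to
#' |r_s|, nodes colored by group when labels are supplied.
#'
#' @param x a \code{ctab_network}.
#' @param groups optional named group labels for node coloring.
#' @param seed layout seed passed to [layout_fr()].
#' @param ... further arguments passed to [graphics::plot()].
#' @return the layout matrix, invisibly.
#' @export
plot.ctab_network <- function(x, groups = NULL, seed = 1L, ...) {
  xy <- layout_fr(x, seed = seed)
  graphics::plot(xy, type = "n", xlab = "", ylab = "", axes = FALSE, ...)
  if (nrow(x$edges))
    graphics::segments(xy[x$edges$gene_a, 1], xy[x$edges$gene_a, 2],
                       xy[x$edges$gene_b, 1], xy[x$edges$gene_b, 2],
                       col = ifelse(x$edges$sign > 0, "firebrick",
                                    "steelblue"),
                       lwd = 0.5 + 3 * x$edges$weight)
  col <- if (is.null(groups)) "grey30" else as.integer(factor(groups[x$genes]))
  graphics::points(xy, pch = 21, bg = col, cex = 2)
  graphics::text(xy, labels = x$genes, pos = 3, cex = 0.7)
  invisible(xy)
}

#' Write the edge list of a network to TSV
#'
#' @param network a \code{ctab_network}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "ctab_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
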