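#' Define a CTA scoring panel
#'
#' A panel is an ordered set of unique gene symbols whose percentile ranks are
#' summed into the burden score, plus an optional alias map so that legacy
#' antigen names (e.g. \code{NY-ESO-1}) resolve to the panel symbol.
#'
#' @param genes character vector of unique gene symbols.
#' @param aliases named character vector mapping alias name to panel symbol.
#' @return An object of class \code{ctab_panel} with elements \code{genes} and
#'   \code{aliases}.
#' @seealso [default_ctab_panel()] for the canonical 17-gene CTA panel.
#' @export
#' @examples
#' p <- ctab_panel(c("MAGEA3", "CTAG1B"), aliases = c("NY-ESO-1" = "CTAG1B"))
#' p$genes
ctab_panel <- function(genes, aliases = character()) {
  if (!is.character(genes) || length(genes) < 1L || anyNA(genes))
    stop("'genes' must be a non-empty character vector")
  if (anyDuplicated(genes))
    stop("panel gene symbols must be unique")
  aliases <- as.character(aliases) |> stats::setNames(names(aliases))
  if (length(aliases)) {
    if (is.null(names(aliases)) || any(!nzchar(names(aliases))))
      stop("'aliases' must be a named character vector (alias -> panel symbol)")
    bad <- setdiff(aliases, genes)
    if (length(bad))
      stop("aliases resolve to symbols not in the panel: ",
           paste(bad, collapse = ", "))
  }
  structure(list(genes = genes, aliases = aliases), class = "ctab_panel")
}

#' The default 17-gene CTA panel
#'
#' The canonical cancer testis antigen panel used for CTAB: BAGE, CTAG1B
#' (alias NY-ESO-1), CTAG2 (alias LAGE-1A), GAGE1, GAGE10, GAGE12J, GAGE13,
#' GAGE2, MAGEA1, MAGEA10, MAGEA12, MAGEA3, MAGEA4, MAGEC2, MLANA, SSX2 and
#' XAGE1B. The maximum attainable score for this panel is 1700.
#'
#' @return A \code{ctab_panel} of 17 genes.
#' @export
#' @examples
#' length(default_ctab_panel()$genes)
default_ctab_panel <- function() {
  ctab_panel(
    c("BAGE", "CTAG1B", "CTAG2", "GAGE1", "GAGE10", "GAGE12J", "GAGE13",
      "GAGE2", "MAGEA1", "MAGEA10", "MAGEA12", "MAGEA3", "MAGEA4", "MAGEC2",
      "MLANA", "SSX2", "XAGE1B"),
    aliases = c("NY-ESO-1" = "CTAG1B", "LAGE-1A" = "CTAG2")
  )
}

#' Resolve gene names through a panel's alias map
#'
#' @param panel a \code{ctab_panel}.
#' @param genes character vector of gene names, possibly containing aliases.
#' @return character vector with aliases replaced by panel symbols.
#' @export
resolve_genes <- function(panel, genes) {
  stopifnot(inherits(panel, "ctab_panel"))
  hit <- genes %in% names(panel$aliases)
  genes[hit] <- unname(panel$aliases[genes[hit]])
  genes
}

#' @export
print.ctab_panel <- function(x, ...) {
  cat("CTA panel:", length(x$genes), "genes (max score",
      100L * length(x$genes), ")\n")
  cat(" ", paste(x$genes, collapse = ", "), "\n")
  if (length(x$aliases))
    cat("  aliases:", paste(names(x$aliases), "->", x$aliases,
                            collapse = "; "), "\n")
  invisible(x)
}
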