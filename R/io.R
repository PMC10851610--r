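# Plain-text interchange formats:
#   expression  - TSV, rows = samples, first column sample_id, then genes
#   clinical    - CSV with the ClinicalRecord columns
#   reference   - TSV, one row per gene: symbol then the sorted values
#   config      - YAML

#' Write / read an expression matrix as TSV
#'
#' @param expr samples x genes numeric matrix with sample row names.
#' @param path file path.
#' @return \code{path} invisibly (write) or the matrix (read).
#' @export
write_expression <- function(expr, path) {
  expr <- as.matrix(expr)
  df <- data.frame(sample_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write / read a clinical annotation table as CSV
#'
#' @param clinical data frame with columns sample_id, tumor_type, histology,
#'   pdl1_tps, tmb, arm, os_months, os_event, recist.
#' @param path file path.
#' @return \code{path} invisibly (write) or the data frame (read).
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a reference population as per-gene TSV
#'
#' One row per gene: the gene symbol followed by its sorted reference
#' values. Reading restores a [reference_population()] that reproduces
#' identical ranks for any probe matrix.
#'
#' @param reference a \code{ctab_reference}.
#' @param path file path.
#' @param n_histologies,version metadata for the restored object.
#' @return \code{path} invisibly (write) or a \code{ctab_reference} (read).
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "ctab_reference"))
  lines <- vapply(names(reference$values), function(g)
    paste(c(g, format(reference$values[[g]], digits = 17, trim = TRUE,
                      scientific = FALSE)), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path, n_histologies = NA_integer_,
                           version = "file") {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  values <- lapply(parts, function(p) as.numeric(p[-1L]))
  names(values) <- vapply(parts, `[[`, character(1), 1L)
  reference_population(values, n_histologies = n_histologies,
                       version = version)
}

#' Write / read a generator configuration as YAML
#'
#' @param config a [generator_config()].
#' @param path file path.
#' @return \code{path} invisibly (write) or a validated configuration
#'   (read).
#' @export
write_generator_config <- function(config, path) {
  validate_generator_config(config)
  x <- unclass(config)
  # named atomic vectors must become lists to serialize as YAML maps
  for (f in c("activation_prob_by_tumor_type", "tumor_type_freq",
              "arm_split", "os_median_months"))
    x[[f]] <- as.list(x[[f]])
  x$recist_probs <- list(strata = rownames(config$recist_probs),
                         categories = colnames(config$recist_probs),
                         probs = as.vector(t(config$recist_probs)))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  rp <- matrix(unlist(x$recist_probs$probs), ncol = 4L, byrow = TRUE,
               dimnames = list(unlist(x$recist_probs$strata),
                               unlist(x$recist_probs$categories)))
  generator_config(
    n_reference = x$n_reference, n_discovery = x$n_discovery,
    n_retrospective = x$n_retrospective,
    correlated_genes = unlist(x$correlated_genes),
    independent_genes = unlist(x$independent_genes),
    latent_loading = x$latent_loading,
    magnitude_loading = x$magnitude_loading,
    activation_prob_by_tumor_type =
      unlist(x$activation_prob_by_tumor_type),
    tumor_type_freq = unlist(x$tumor_type_freq),
    tmb_coupling = x$tmb_coupling, zero_inflation = x$zero_inflation,
    arm_split = unlist(x$arm_split),
    nonsquamous_fraction = x$nonsquamous_fraction,
    os_median_months = unlist(x$os_median_months),
    recist_probs = rp, followup_horizon = x$followup_horizon,
    cutoff = x$cutoff, seed = x$seed)
}

#' Write a whole synthetic cohort to a directory
#'
#' Writes \code{expression.tsv}, \code{clinical.csv} and \code{config.yaml}
#' into \code{dir}.
#'
#' @param cohort a \code{ctab_cohort}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ctab_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.csv"))
  write_generator_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
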