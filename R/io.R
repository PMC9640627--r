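# Readers and writers for the plain-text formats the pipeline touches:
# tab-separated expression / purity / survival tables and GMT gene sets.
# Readers validate the schema and report the file and offending entries.

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose header row holds sample identifiers; UTF-8, no quoting.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 3L) {
    stop(sprintf("%s: expected a gene-id column plus >= 2 samples", path),
         call. = FALSE)
  }
  genes <- as.character(df[[1L]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop(sprintf("%s: duplicate gene identifiers: %s", path,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)
    stop(sprintf("%s: missing/non-numeric values in rows: %s", path,
                 paste(utils::head(genes[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  validate_expression(m)
  m
}

#' @rdname read_expression_tsv
#' @param expr Numeric matrix (genes x samples).
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expression(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample tumour purity from TSV
#'
#' Expects columns `sample` and `purity`, with purity in `[0, 1]`.
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of purities.
#' @export
read_purity_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("sample", "purity") %in% names(df))) {
    stop(sprintf("%s: expected columns 'sample' and 'purity'", path),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample)) {
    stop(sprintf("%s: duplicate sample identifiers", path), call. = FALSE)
  }
  p <- as.numeric(df$purity)
  bad <- which(!is.finite(p) | p < 0 | p > 1)
  if (length(bad)) {
    stop(sprintf("%s: purity outside [0, 1] at rows %s (samples %s)", path,
                 paste(utils::head(bad, 5L), collapse = ", "),
                 paste(utils::head(df$sample[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  stats::setNames(p, df$sample)
}

#' @rdname read_purity_tsv
#' @param purity Named numeric vector in `[0, 1]`.
#' @export
write_purity_tsv <- function(purity, path) {
  stopifnot(is.numeric(purity), !is.null(names(purity)))
  utils::write.table(
    data.frame(sample = names(purity), purity = as.numeric(purity)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table from TSV
#'
#' Expects columns `sample`, `time` (strictly positive), and `event`
#' (0 = censored, 1 = death).
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `sample`, `time`, `event`.
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("sample", "time", "event") %in% names(df))) {
    stop(sprintf("%s: expected columns 'sample', 'time', 'event'", path),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample)) {
    stop(sprintf("%s: duplicate sample identifiers", path), call. = FALSE)
  }
  time <- as.numeric(df$time)
  event <- as.numeric(df$event)
  bad_t <- which(!is.finite(time) | time <= 0)
  if (length(bad_t)) {
    stop(sprintf("%s: non-positive follow-up time at rows %s (field 'time')",
                 path, paste(utils::head(bad_t, 5L), collapse = ", ")),
         call. = FALSE)
  }
  bad_e <- which(!(event %in% c(0, 1)))
  if (length(bad_e)) {
    stop(sprintf("%s: event status not in {0, 1} at rows %s (field 'event')",
                 path, paste(utils::head(bad_e, 5L), collapse = ", ")),
         call. = FALSE)
  }
  data.frame(sample = as.character(df$sample), time = time,
             event = as.integer(event), stringsAsFactors = FALSE)
}

#' @rdname read_survival_tsv
#' @param surv data.frame with columns `sample`, `time`, `event`.
#' @export
write_survival_tsv <- function(surv, path) {
  stopifnot(all(c("sample", "time", "event") %in% names(surv)))
  utils::write.table(surv[, c("sample", "time", "event")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write gene-set collections in GMT format
#'
#' Reading is delegated to [fgsea::gmtPathways()]; each GMT line is
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return For `read_gmt()`, a named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop(sprintf("%s: gene-set names must be present and unique", path),
         call. = FALSE)
  }
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) {
    stop(sprintf("%s: empty gene sets: %s", path,
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character gene vectors.
#' @param description Description field written to the second GMT column.
#' @export
write_gmt <- function(sets, path, description = "") {
  stopifnot(is.list(sets), !is.null(names(sets)), all(lengths(sets) > 0L))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Align expression, purity, and survival on shared samples
#'
#' All pipeline stages operate on the intersection of sample identifiers,
#' taken in expression-matrix order; the number of samples dropped from each
#' input is recorded.
#'
#' @param expr Expression matrix (genes x samples).
#' @param purity Named purity vector (optional, may be `NULL`).
#' @param surv Survival data.frame (optional, may be `NULL`).
#' @return List with aligned `expression`, `purity`, `survival`, the shared
#'   `samples`, and a named vector `n_dropped`.
#' @export
align_samples <- function(expr, purity = NULL, surv = NULL) {
  validate_expression(expr)
  common <- colnames(expr)
  if (!is.null(purity)) common <- common[common %in% names(purity)]
  if (!is.null(surv)) common <- common[common %in% surv$sample]
  if (length(common) < 2L) {
    stop("fewer than 2 samples shared across inputs", call. = FALSE)
  }
  list(expression = expr[, common, drop = FALSE],
       purity = if (is.null(purity)) NULL else purity[common],
       survival = if (is.null(surv)) NULL else
         surv[match(common, surv$sample), , drop = FALSE],
       samples = common,
       n_dropped = c(expression = ncol(expr) - length(common),
                     purity = if (is.null(purity)) 0L else
                       length(purity) - length(common),
                     survival = if (is.null(surv)) 0L else
                       nrow(surv) - length(common)))
}
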