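# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded calls do not perturb a session.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a pipeline seed
#'
#' All randomness in [run_pipeline()] flows from one integer seed; each stage
#' draws from its own stream seeded by this stable derivation so stages are
#' individually reproducible.
#'
#' @param seed Integer base seed.
#' @param stage Integer stage index (>= 1).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(stage), length(stage) == 1L)
  as.integer((as.numeric(seed) + 99991 * as.numeric(stage)) %% 2147483647)
}

# Single scalar checks used throughout the package.
assert_scalar <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE,
                          open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  }
  if (x < lo || x > hi || (open_hi && x >= hi)) {
    stop(sprintf("'%s' must be in [%s, %s%s", name, format(lo),
                 format(hi), if (open_hi) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

# Validate an expression matrix: numeric, unique dimnames, no missing values,
# at least `min_samples` columns.
validate_expression <- function(expr, min_samples = 2L) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) {
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(expr))) {
    stop("duplicate sample identifiers in expression matrix", call. = FALSE)
  }
  if (anyNA(expr)) {
    stop("expression matrix contains missing values", call. = FALSE)
  }
  if (ncol(expr) < min_samples) {
    stop(sprintf("need at least %d samples", min_samples), call. = FALSE)
  }
  invisible(expr)
}

#' Partition genes into mRNA and lncRNA by identifier prefix
#'
#' @param genes Character vector of gene identifiers.
#' @param lnc_pattern Regular expression marking lncRNA identifiers.
#' @return Named character vector with values `"mRNA"` or `"lncRNA"`.
#' @export
partition_from_prefix <- function(genes, lnc_pattern = "^lnc") {
  stopifnot(is.character(genes))
  part <- ifelse(grepl(lnc_pattern, genes, ignore.case = TRUE),
                 "lncRNA", "mRNA")
  names(part) <- genes
  part
}

# Row-standardize a matrix so tcrossprod() yields Pearson correlations.
row_standardize <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowSums(xc^2))
  list(z = xc / s, sd = s / sqrt(ncol(x) - 1))
}
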