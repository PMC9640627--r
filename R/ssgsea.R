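#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Scores each sample against each gene set with the weighted-ECDF difference
#' statistic: genes are ranked by expression within the sample (average ranks
#' on ties, highest expression receives the largest rank value), and the score
#' is the sum over the descending-ordered list of the difference between the
#' weighted in-set cumulative distribution (weights `rank^exponent`) and the
#' unweighted out-of-set cumulative distribution. Scores therefore depend only
#' on within-sample ranks and are invariant to strictly increasing transforms
#' of a sample's values.
#'
#' @param expr Numeric expression matrix (genes x samples, >= 2 samples).
#' @param sets Named list of character gene vectors (e.g. from [read_gmt()]).
#' @param exponent Rank weight `tau`; `0.25` by default.
#' @param normalize If `TRUE`, min--max normalize the whole score matrix to
#'   `[0, 1]` across the cohort.
#' @return Numeric matrix, gene sets x samples. Sets sharing fewer than 2
#'   genes with the matrix are skipped with a warning; a set covering every
#'   gene is an error (the out-of-set distribution is undefined).
#' @examples
#' expr <- matrix(rnorm(60), 10, 6,
#'                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' ssgsea_scores(expr, list(A = c("g1", "g2", "g3")))
#' @export
ssgsea_scores <- function(expr, sets, exponent = 0.25, normalize = FALSE) {
  validate_expression(expr)
  assert_scalar(exponent, "exponent", lo = 0)
  stopifnot(is.list(sets), !is.null(names(sets)))
  genes <- rownames(expr)
  n_genes <- length(genes)
  use <- list()
  for (nm in names(sets)) {
    ov <- intersect(sets[[nm]], genes)
    if (length(ov) >= n_genes) {
      stop(sprintf("gene set '%s' covers every gene in the matrix; ",
                   nm), "the out-of-set distribution is undefined",
           call. = FALSE)
    }
    if (length(ov) < 2L) {
      warning(sprintf(
        "gene set '%s' shares fewer than 2 genes with the matrix; skipped",
        nm), call. = FALSE)
      next
    }
    use[[nm]] <- ov
  }
  if (!length(use)) stop("no scorable gene sets", call. = FALSE)

  scores <- matrix(NA_real_, length(use), ncol(expr),
                   dimnames = list(names(use), colnames(expr)))
  memb <- lapply(use, function(ov) genes %in% ov)
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    rk <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    w <- rk[ord]^exponent
    for (i in seq_along(use)) {
      m <- memb[[i]][ord]
      hit <- cumsum(w * m)
      hit <- hit / hit[n_genes]
      miss <- cumsum(!m) / (n_genes - sum(m))
      scores[i, j] <- sum(hit - miss)
    }
  }
  if (normalize) {
    rng <- range(scores)
    if (rng[2] > rng[1]) {
      scores <- (scores - rng[1]) / (rng[2] - rng[1])
    }
  }
  scores
}
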