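#' First-order partial correlation adjusting for tumour purity
#'
#' Correlation between an lncRNA and an mRNA after removing the linear effect
#' of tumour purity:
#' `PCC = (Rlncm - Rlncp * Rmp) / (sqrt(1 - Rlncp^2) * sqrt(1 - Rmp^2))`,
#' where `Rlncm`, `Rlncp`, `Rmp` are the pairwise Pearson correlations. This
#' equals, as an algebraic identity, the Pearson correlation of the residuals
#' of each vector regressed on purity.
#'
#' @param lnc,m Numeric expression vectors of one lncRNA and one mRNA,
#'   aligned with `purity` (same sample order).
#' @param purity Numeric tumour-purity vector.
#' @return A `pair_association` list with the three Pearson correlations
#'   (`r_lnc_m`, `r_lnc_p`, `r_m_p`), the partial correlation `pcc`, and the
#'   sample count `n`. Extend with [partial_correlation_pvalue()] and
#'   [rank_index()].
#' @examples
#' partial_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5),
#'                     c(0.9, 0.8, 0.7, 0.9, 0.6))
#' @export
partial_correlation <- function(lnc, m, purity) {
  n <- length(lnc)
  if (length(m) != n || length(purity) != n) {
    stop("lnc, m, and purity must be aligned vectors of equal length",
         call. = FALSE)
  }
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  if (stats::sd(lnc) == 0 || stats::sd(m) == 0 || stats::sd(purity) == 0) {
    stop("constant vector: correlations undefined", call. = FALSE)
  }
  r_lm <- stats::cor(lnc, m)
  r_lp <- stats::cor(lnc, purity)
  r_mp <- stats::cor(m, purity)
  if (1 - r_lp^2 < 1e-12 || 1 - r_mp^2 < 1e-12) {
    stop("expression collinear with purity: partial correlation undefined",
         call. = FALSE)
  }
  pcc <- (r_lm - r_lp * r_mp) / (sqrt(1 - r_lp^2) * sqrt(1 - r_mp^2))
  structure(list(r_lnc_m = r_lm, r_lnc_p = r_lp, r_m_p = r_mp,
                 pcc = min(1, max(-1, pcc)), n = as.integer(n)),
            class = "pair_association")
}

#' P-value of a partial correlation via the normal approximation
#'
#' `P = 2 * pnorm(-|PCC * sqrt((n - 3) / (1 - PCC^2))|)`: a two-sided normal
#' tail on the score statistic, so `PCC = 0` gives `P = 1` and, at fixed
#' `PCC`, `P` decreases in `n`.
#'
#' @param assoc A `pair_association` from [partial_correlation()] (any list
#'   with `pcc` and `n`).
#' @return The association with `p_value` filled in. `|pcc| = 1` yields the
#'   limit `p_value = 0` with a warning.
#' @export
partial_correlation_pvalue <- function(assoc) {
  stopifnot(is.list(assoc), !is.null(assoc$pcc), !is.null(assoc$n))
  pcc <- assoc$pcc
  n <- assoc$n
  if (n <= 3L) stop("need n > 3 for the p-value", call. = FALSE)
  if (abs(pcc) >= 1) {
    warning("|pcc| = 1: p-value taken as the limit 0", call. = FALSE)
    assoc$p_value <- 0
    return(assoc)
  }
  z <- abs(pcc * sqrt((n - 3) / (1 - pcc^2)))
  assoc$p_value <- 2 * stats::pnorm(-z)
  assoc
}

#' Signed rank index from a partial-correlation p-value
#'
#' `RI = -ln(P) * sign(PCC)`: large positive for strong positive association,
#' large negative for strong negative association, 0 at `P = 1`. mRNAs are
#' ranked by descending RI before enrichment testing.
#'
#' @param assoc A `pair_association` with `pcc` and `p_value` filled.
#' @param ln_cap Cap on `|RI|` used when `p_value` underflows to 0
#'   (default 745, about `-ln` of the smallest subnormal double).
#' @return The association with `ri` filled in.
#' @export
rank_index <- function(assoc, ln_cap = 745) {
  stopifnot(is.list(assoc), !is.null(assoc$pcc), !is.null(assoc$p_value))
  p <- assoc$p_value
  if (p < 0 || p > 1) stop("p_value outside [0, 1]", call. = FALSE)
  if (p == 0) {
    warning(sprintf("p_value underflowed to 0; rank index capped at %g",
                    ln_cap), call. = FALSE)
    assoc$ri <- ln_cap * sign(assoc$pcc)
  } else {
    assoc$ri <- min(-log(p), ln_cap) * sign(assoc$pcc)
  }
  assoc
}

#' All-pairs purity-adjusted associations between lncRNAs and mRNAs
#'
#' Matrix-form computation of [partial_correlation()],
#' [partial_correlation_pvalue()], and [rank_index()] for every
#' (lncRNA, mRNA) pair: standardized expression blocks are multiplied once,
#' so the arithmetic cost is linear in samples x lncRNAs x mRNAs.
#'
#' @param expr Expression matrix (genes x samples).
#' @param purity Named purity vector covering the samples.
#' @param partition Named `"mRNA"`/`"lncRNA"` vector for the genes; defaults
#'   to the identifier-prefix rule of [partition_from_prefix()].
#' @param adjust_purity If `FALSE`, the purity correlations are set to zero so
#'   `pcc` reduces to the raw Pearson correlation (used to quantify what the
#'   adjustment removes); `purity` may then be `NULL`.
#' @param ln_cap Cap on `|RI|`, see [rank_index()].
#' @return List with matrices `pcc`, `p_value`, `ri` (lncRNAs x mRNAs),
#'   vectors `r_lnc_p` and `r_m_p`, the sample count `n`, and identifiers of
#'   constant genes dropped with a warning.
#' @export
pair_associations <- function(expr, purity,
                              partition = partition_from_prefix(rownames(expr)),
                              adjust_purity = TRUE, ln_cap = 745) {
  validate_expression(expr, min_samples = 4L)
  part <- partition[rownames(expr)]
  if (anyNA(part)) {
    stop("partition does not cover every gene in the matrix", call. = FALSE)
  }
  n <- ncol(expr)
  if (adjust_purity) {
    purity <- purity[colnames(expr)]
    if (anyNA(purity)) {
      stop("purity does not cover every expression sample", call. = FALSE)
    }
    if (stats::sd(purity) == 0) {
      stop("purity is constant: correlations undefined", call. = FALSE)
    }
  }

  keep_ok <- apply(expr, 1L, stats::sd) > 0
  if (any(!keep_ok)) {
    warning(sprintf("dropping %d constant gene(s): %s", sum(!keep_ok),
                    paste(utils::head(rownames(expr)[!keep_ok], 5L),
                          collapse = ", ")), call. = FALSE)
  }
  dropped <- rownames(expr)[!keep_ok]
  expr <- expr[keep_ok, , drop = FALSE]
  part <- part[keep_ok]

  lnc <- expr[part == "lncRNA", , drop = FALSE]
  mr <- expr[part == "mRNA", , drop = FALSE]
  if (nrow(lnc) == 0L || nrow(mr) == 0L) {
    stop("need at least one lncRNA and one mRNA with nonzero variance",
         call. = FALSE)
  }

  lz <- row_standardize(lnc)$z
  mz <- row_standardize(mr)$z
  r_lm <- tcrossprod(lz, mz)
  if (adjust_purity) {
    pz <- (purity - mean(purity)) / sqrt(sum((purity - mean(purity))^2))
    r_lp <- drop(lz %*% pz)
    r_mp <- drop(mz %*% pz)
    col_l <- which(1 - r_lp^2 < 1e-12)
    col_m <- which(1 - r_mp^2 < 1e-12)
    if (length(col_l) || length(col_m)) {
      stop(sprintf("gene(s) collinear with purity: %s",
                   paste(c(rownames(lnc)[col_l], rownames(mr)[col_m]),
                         collapse = ", ")), call. = FALSE)
    }
  } else {
    r_lp <- rep(0, nrow(lnc))
    r_mp <- rep(0, nrow(mr))
    names(r_lp) <- rownames(lnc)
    names(r_mp) <- rownames(mr)
  }
  pcc <- (r_lm - r_lp %o% r_mp) /
    (sqrt(1 - r_lp^2) %o% sqrt(1 - r_mp^2))
  pcc <- pmin(pmax(pcc, -1), 1)
  z <- abs(pcc) * sqrt((n - 3) / pmax(1 - pcc^2, 1e-300))
  p <- 2 * stats::pnorm(-z)
  ri <- sign(pcc) * pmin(-log(pmax(p, 4.9e-324)), ln_cap)
  list(pcc = pcc, p_value = p, ri = ri,
       r_lnc_p = stats::setNames(r_lp, rownames(lnc)),
       r_m_p = stats::setNames(r_mp, rownames(mr)),
       n = n, dropped = dropped)
}

#' Tidy table of pairwise associations
#'
#' @param pa Result of [pair_associations()].
#' @return Long data.frame with one row per (lncRNA, mRNA) pair.
#' @export
pair_association_table <- function(pa) {
  stopifnot(is.list(pa), is.matrix(pa$pcc))
  data.frame(
    lnc_id = rep(rownames(pa$pcc), times = ncol(pa$pcc)),
    mrna_id = rep(colnames(pa$pcc), each = nrow(pa$pcc)),
    pcc = as.vector(pa$pcc), p_value = as.vector(pa$p_value),
    ri = as.vector(pa$ri), n = pa$n, stringsAsFactors = FALSE)
}

#' Screen lncRNAs for association with a target gene set
#'
#' The central statistic: for each lncRNA, every mRNA receives a
#' purity-adjusted rank index (RI); mRNAs are sorted by descending RI and the
#' target set is tested for enrichment at either extreme of the ranking by
#' [preranked_es()] with a permutation p-value. Raw permutation p-values are
#' Benjamini--Hochberg adjusted across all screened lncRNAs (one family per
#' invocation) to give `Pi`, and direction and significance are combined into
#' the total enrichment score `TES = (1 - 2 * Pi) * sign(ES)`, which lies in
#' `[-1, 1]`. Candidates satisfy `|TES| > tes_threshold` and
#' `Pi < fdr_threshold`.
#'
#' @inheritParams pair_associations
#' @param target_set Character vector of mRNA identifiers (a nonempty proper
#'   subset of the screened mRNAs).
#' @param n_perm Permutations per lncRNA (>= 100).
#' @param tes_threshold Candidate gate on `|TES|` (default 0.95).
#' @param fdr_threshold Candidate gate on the adjusted p-value (default 0.05).
#' @param weight_exp Hit-weight exponent on `|RI|` in the running sum.
#' @param seed Optional integer seed for the permutation draws.
#' @return data.frame of class `lnc_screen` with columns `lnc_id`, `es`,
#'   `p_raw`, `p_adj`, `tes`, `is_candidate`, sorted by `|tes|` descending
#'   then `lnc_id`; screen parameters and dropped genes are attached as
#'   attributes. Constant lncRNAs are skipped with a warning.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_samples = 80, n_mrna = 60,
#'                                            n_lncrna = 8, seed = 3))
#' scr <- screen_lncrnas(cohort$expression, cohort$purity,
#'                       cohort$truth$pathway_genes, n_perm = 100, seed = 3)
#' head(scr)
#' @export
screen_lncrnas <- function(expr, purity, target_set,
                           partition = partition_from_prefix(rownames(expr)),
                           n_perm = 1000L, tes_threshold = 0.95,
                           fdr_threshold = 0.05, weight_exp = 1, seed = NULL,
                           adjust_purity = TRUE, ln_cap = 745) {
  assert_scalar(tes_threshold, "tes_threshold", lo = 0, hi = 1)
  assert_scalar(fdr_threshold, "fdr_threshold", lo = 0, hi = 1)
  assert_scalar(n_perm, "n_perm", lo = 100, integer = TRUE)
  part <- partition[rownames(expr)]
  mrna_ids <- rownames(expr)[part == "mRNA" & !is.na(part)]
  if (!length(target_set)) stop("target_set is empty", call. = FALSE)
  missing <- setdiff(target_set, mrna_ids)
  if (length(missing) == length(target_set)) {
    stop("no target-set gene is present among the mRNAs", call. = FALSE)
  }
  if (length(missing)) {
    warning(sprintf("%d target-set gene(s) absent from the mRNAs; ignored",
                    length(missing)), call. = FALSE)
    target_set <- setdiff(target_set, missing)
  }
  if (length(target_set) >= length(mrna_ids)) {
    stop("target_set must be a proper subset of the mRNAs", call. = FALSE)
  }

  pa <- pair_associations(expr, purity, partition = partition,
                          adjust_purity = adjust_purity, ln_cap = ln_cap)
  ri <- pa$ri
  target_set <- intersect(target_set, colnames(ri))
  if (length(target_set) < 1L) {
    stop("target_set lost to constant-gene filtering", call. = FALSE)
  }
  lnc_ids <- rownames(ri)
  n_mrna <- ncol(ri)
  k <- length(target_set)
  target_flag <- colnames(ri) %in% target_set

  with_seed(seed, {
    es <- numeric(length(lnc_ids))
    p_raw <- numeric(length(lnc_ids))
    for (i in seq_along(lnc_ids)) {
      s <- ri[i, ]
      ord <- order(s, decreasing = TRUE)
      absw <- abs(s[ord])^weight_exp
      pos_obs <- which(target_flag[ord])
      es[i] <- es_from_positions(absw, n_mrna, pos_obs)
      null_es <- vapply(seq_len(n_perm), function(b) {
        es_from_positions(absw, n_mrna, sample.int(n_mrna, k))
      }, numeric(1L))
      p_raw[i] <- (1 + sum(abs(null_es) >= abs(es[i]))) / (n_perm + 1)
    }
    p_adj <- stats::p.adjust(p_raw, method = "BH")
    tes <- (1 - 2 * p_adj) * sign(es)
    res <- data.frame(lnc_id = lnc_ids, es = es, p_raw = p_raw, p_adj = p_adj,
                      tes = tes,
                      is_candidate = abs(tes) > tes_threshold &
                        p_adj < fdr_threshold,
                      stringsAsFactors = FALSE)
    res <- res[order(-abs(res$tes), res$lnc_id), , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "params") <- list(n_perm = as.integer(n_perm),
                                tes_threshold = tes_threshold,
                                fdr_threshold = fdr_threshold,
                                weight_exp = weight_exp,
                                adjust_purity = adjust_purity,
                                target_size = k, n_samples = pa$n)
    attr(res, "dropped") <- pa$dropped
    class(res) <- c("lnc_screen", "data.frame")
    res
  })
}

#' Intersect candidate lncRNAs across cohort screens
#'
#' Multi-cohort mode: candidates are intersected by identifier equality.
#'
#' @param screens List of `lnc_screen` results.
#' @return Character vector of lncRNA identifiers flagged as candidates in
#'   every screen.
#' @export
intersect_candidates <- function(screens) {
  stopifnot(is.list(screens), length(screens) >= 1L)
  Reduce(intersect, lapply(screens, function(s) s$lnc_id[s$is_candidate]))
}
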