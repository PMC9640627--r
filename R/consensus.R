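#' Consensus clustering of samples on candidate-lncRNA expression
#'
#' Repeatedly subsamples the cohort, clusters each subsample, and aggregates
#' pairwise co-assignments into a per-k consensus matrix (co-clustering
#' counts normalized by co-selection counts). The number of clusters is
#' selected from the stability of those matrices: the empirical CDF of
#' consensus entries is summarized by its area, and the selected k is the
#' largest k whose relative area increase over k - 1 exceeds
#' `elbow_threshold` (k = `k_min` is always eligible as the baseline). Final
#' subtype labels come from average-linkage hierarchical clustering of
#' `1 - consensus` at the selected k.
#'
#' @param expr Expression matrix restricted to the clustering features
#'   (features x samples), typically candidate lncRNAs; >= 2 features and
#'   >= `3 * k_max` samples.
#' @param k_min,k_max Range of cluster numbers evaluated (default 2 to 10).
#' @param n_resamples Number of subsampling iterations per k (default 500).
#' @param sample_fraction Fraction of samples drawn (without replacement) per
#'   iteration (default 0.8).
#' @param seed Optional integer seed; same seed and inputs give an identical
#'   result.
#' @param standardize Standardize each feature (z-score across samples)
#'   before clustering; constant features are dropped with a warning.
#' @param method Base clusterer: `"kmeans"` (Euclidean k-means with 10 random
#'   restarts per resample, the default) or `"pam_chebyshev"` (partitioning
#'   around medoids on the Chebyshev/maximum metric).
#' @param elbow_threshold Relative CDF-area increase required to accept a
#'   larger k (default 0.15: splitting one stable cluster of sample fraction
#'   `f` in half adds a relative area of roughly `f^2 / (2 * A)`, up to about
#'   0.14 for realistic cluster sizes, so genuine extra structure must exceed
#'   that).
#' @return Object of class `consensus_result`: `k_values`, `consensus` (named
#'   list of symmetric sample x sample matrices with unit diagonal), `cdf`
#'   (grid x k matrix), `area`, `delta_area`, `selected_k`, `labels` (named
#'   integer subtype per sample), and the call parameters.
#' @export
consensus_cluster <- function(expr, k_min = 2L, k_max = 10L,
                              n_resamples = 500L, sample_fraction = 0.8,
                              seed = NULL, standardize = TRUE,
                              method = c("kmeans", "pam_chebyshev"),
                              elbow_threshold = 0.15) {
  method <- match.arg(method)
  validate_expression(expr)
  assert_scalar(k_min, "k_min", lo = 2, integer = TRUE)
  assert_scalar(k_max, "k_max", lo = k_min, integer = TRUE)
  assert_scalar(n_resamples, "n_resamples", lo = 1, integer = TRUE)
  assert_scalar(sample_fraction, "sample_fraction", lo = 0.1, hi = 1)
  assert_scalar(elbow_threshold, "elbow_threshold", lo = 0)
  if (nrow(expr) < 2L) {
    stop("need at least 2 features to cluster on", call. = FALSE)
  }
  n <- ncol(expr)
  if (n < 3L * k_max) {
    stop(sprintf("need at least 3 * k_max = %d samples (have %d)",
                 3L * k_max, n), call. = FALSE)
  }
  samples <- colnames(expr)
  x <- t(expr)
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping %d constant feature(s) before clustering",
                      sum(sds == 0)), call. = FALSE)
      x <- x[, sds > 0, drop = FALSE]
      if (ncol(x) < 2L) {
        stop("fewer than 2 non-constant features", call. = FALSE)
      }
      sds <- sds[sds > 0]
    }
    x <- scale(x)
  }

  m <- as.integer(ceiling(sample_fraction * n))
  ks <- seq.int(k_min, k_max)
  grid <- seq(0, 1, by = 0.01)

  cluster_once <- function(xs, k) {
    if (method == "kmeans") {
      stats::kmeans(xs, centers = k, nstart = 10L, iter.max = 50L)$cluster
    } else {
      d <- stats::dist(xs, method = "maximum")
      pam_chebyshev(d, k)
    }
  }

  with_seed(seed, {
    consensus <- vector("list", length(ks))
    names(consensus) <- paste0("k", ks)
    for (ki in seq_along(ks)) {
      k <- ks[ki]
      co <- matrix(0, n, n)
      sel <- matrix(0, n, n)
      for (b in seq_len(n_resamples)) {
        cl <- NULL
        for (try in seq_len(10L)) {
          idx <- sort.int(sample.int(n, m))
          cl <- tryCatch({
            cc <- cluster_once(x[idx, , drop = FALSE], k)
            if (length(unique(cc)) < k) NULL else cc
          }, error = function(e) NULL)
          if (!is.null(cl)) break
        }
        if (is.null(cl)) {
          stop(sprintf(
            "resampling produced an empty cluster 10 times in a row at k = %d",
            k), call. = FALSE)
        }
        z <- outer(cl, seq_len(k), "==") + 0
        co[idx, idx] <- co[idx, idx] + tcrossprod(z)
        sel[idx, idx] <- sel[idx, idx] + 1
      }
      cm <- co / pmax(sel, 1)
      diag(cm) <- 1
      dimnames(cm) <- list(samples, samples)
      consensus[[ki]] <- cm
    }

    cdf <- vapply(consensus, function(cm) {
      entries <- cm[upper.tri(cm)]
      stats::ecdf(entries)(grid)
    }, numeric(length(grid)))
    rownames(cdf) <- format(grid)
    area <- apply(cdf, 2L, function(f) sum(diff(grid) * f[-1L]))
    delta_area <- c(area[1L], diff(area) / area[-length(area)])
    names(delta_area) <- names(area)

    eligible <- c(TRUE, delta_area[-1L] > elbow_threshold)
    selected_k <- ks[max(which(eligible))]

    sel_cm <- consensus[[paste0("k", selected_k)]]
    hc <- stats::hclust(stats::as.dist(1 - sel_cm), method = "average")
    labels <- stats::cutree(hc, k = selected_k)
    names(labels) <- samples

    structure(
      list(k_values = ks, consensus = consensus, cdf = cdf, area = area,
           delta_area = delta_area, selected_k = selected_k, labels = labels,
           params = list(k_min = k_min, k_max = k_max,
                         n_resamples = as.integer(n_resamples),
                         sample_fraction = sample_fraction, method = method,
                         standardize = standardize,
                         elbow_threshold = elbow_threshold)),
      class = "consensus_result")
  })
}

# Minimal PAM (build + swap) on a precomputed dist; supports the Chebyshev
# backend without adding a dependency.
pam_chebyshev <- function(d, k) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  medoids <- integer(k)
  medoids[1L] <- which.min(rowSums(dm))
  for (i in seq_len(k - 1L)) {
    dmin <- apply(dm[, medoids[seq_len(i)], drop = FALSE], 1L, min)
    gain <- vapply(seq_len(n), function(j) sum(pmax(dmin - dm[, j], 0)),
                   numeric(1L))
    gain[medoids[seq_len(i)]] <- -Inf
    medoids[i + 1L] <- which.max(gain)
  }
  cost <- function(med) sum(apply(dm[, med, drop = FALSE], 1L, min))
  best <- cost(medoids)
  repeat {
    improved <- FALSE
    for (mi in seq_len(k)) {
      for (j in setdiff(seq_len(n), medoids)) {
        cand <- medoids
        cand[mi] <- j
        cc <- cost(cand)
        if (cc < best - 1e-12) {
          medoids <- cand
          best <- cc
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  apply(dm[, medoids, drop = FALSE], 1L, which.min)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k evaluated %d..%d, selected k = %d\n",
              min(x$k_values), max(x$k_values), x$selected_k))
  cat(sprintf("  %d samples, %d resamples at %.0f%% (%s)\n",
              length(x$labels), x$params$n_resamples,
              100 * x$params$sample_fraction, x$params$method))
  print(table(subtype = x$labels))
  invisible(x)
}

#' Compare pathway scores across subtypes
#'
#' Per-pathway Kruskal--Wallis test of score differences between subtype
#' labels, Benjamini--Hochberg adjusted across pathways. Subtypes with fewer
#' than 3 samples are excluded with a warning; a pathway with identical
#' values in all samples gets `p_value = 1` and is flagged degenerate.
#'
#' @param scores Pathway-score matrix (pathways x samples).
#' @param labels Named subtype labels covering the score samples.
#' @param fdr_threshold Significance gate on the adjusted p-value.
#' @return data.frame with `pathway`, `statistic`, `p_value`, `p_adj`,
#'   `significant`, `degenerate`; the fraction of significant pathways is
#'   attached as attribute `significant_fraction`.
#' @export
compare_scores_across_subtypes <- function(scores, labels,
                                           fdr_threshold = 0.05) {
  stopifnot(is.matrix(scores), !is.null(names(labels)))
  common <- intersect(colnames(scores), names(labels))
  if (length(common) < 6L) {
    stop("fewer than 6 samples shared between scores and labels",
         call. = FALSE)
  }
  lab <- labels[common]
  sizes <- table(lab)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning(sprintf("excluding subtype(s) with < 3 samples: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    common <- common[!(lab %in% small)]
    lab <- labels[common]
  }
  if (length(unique(lab)) < 2L) {
    stop("need at least 2 subtypes with >= 3 samples", call. = FALSE)
  }
  g <- factor(lab)
  rows <- lapply(rownames(scores), function(pw) {
    v <- scores[pw, common]
    if (stats::sd(v) == 0) {
      return(data.frame(pathway = pw, statistic = NA_real_, p_value = 1,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    kw <- stats::kruskal.test(v, g)
    data.frame(pathway = pw, statistic = unname(kw$statistic),
               p_value = kw$p.value, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_adj < fdr_threshold & !res$degenerate
  rownames(res) <- NULL
  attr(res, "significant_fraction") <- mean(res$significant)
  res
}
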