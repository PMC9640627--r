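# Small in-code fixtures shared across test files.

# A tiny named expression matrix with both partitions.
toy_expression <- function(n_mrna = 8, n_lnc = 3, n = 20, seed = 42) {
  withr::with_seed(seed, {
    genes <- c(sprintf("mRNA_%02d", seq_len(n_mrna)),
               sprintf("lncRNA_%02d", seq_len(n_lnc)))
    m <- matrix(rnorm((n_mrna + n_lnc) * n), n_mrna + n_lnc, n,
                dimnames = list(genes, sprintf("S%03d", seq_len(n))))
    m
  })
}

# Brute-force running-sum enrichment score: evaluates the deviation at every
# prefix of the ranked list directly from the definition (positive extreme
# wins an exact magnitude tie). Independent of the package's implementation.
brute_force_es <- function(stats, set, weight_exp = 1) {
  hits <- names(stats) %in% set
  n <- length(stats)
  nr <- sum(abs(stats[hits])^weight_exp)
  run <- 0
  hi <- -Inf
  lo <- Inf
  for (i in seq_len(n)) {
    if (hits[i]) {
      w <- if (nr > 0) abs(stats[i])^weight_exp / nr else 1 / sum(hits)
      run <- run + w
    } else {
      run <- run - 1 / (n - sum(hits))
    }
    hi <- max(hi, run)
    lo <- min(lo, run)
  }
  unname(if (abs(hi) >= abs(lo)) hi else lo)
}

# Exact two-group log-rank tabulation (observed - expected and hypergeometric
# variance at each distinct event time); independent of survival::survdiff.
brute_force_logrank <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d_tot * n1 / n_tot
    if (n_tot > 1) {
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  o_minus_e^2 / v
}

# Cox partial log-likelihood with Breslow tie handling for a single
# covariate; maximized by grid/optimize in tests as an independent oracle.
breslow_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[d]) -
      length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
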