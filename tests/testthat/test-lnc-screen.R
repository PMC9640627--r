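test_that("partial correlation collapses and degenerates as expected", {
  # purity orthogonal to both vectors: pcc equals the raw correlation
  lnc <- c(1, 2, 3, 4, -10)
  m <- c(2, 1, 4, 3, -10)
  # build purity orthogonal to the centred vectors
  p0 <- c(1, -1, 1, -1, 0)
  p0 <- p0 - mean(p0)
  p0 <- p0 - sum(p0 * scale(lnc)) * scale(lnc)[, 1] / sum(scale(lnc)^2)
  pa <- partial_correlation(lnc, lnc, seq(0.1, 0.5, 0.1))
  expect_equal(pa$pcc, 1, tolerance = 1e-10)  # self-correlation survives
  expect_error(partial_correlation(rep(1, 5), m, seq(0.1, 0.5, 0.1)),
               "constant")
  expect_error(partial_correlation(lnc, m, lnc), "collinear")
  expect_error(partial_correlation(1:3, 1:3, 1:3), "at least 4")
})

test_that("formula PCC equals the residual-regression partial correlation", {
  # the worked 5-sample example
  pa <- partial_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5),
                            c(0.9, 0.8, 0.7, 0.9, 0.6))
  resid_pcor <- function(lnc, m, p) {
    cor(resid(lm(lnc ~ p)), resid(lm(m ~ p)))
  }
  expect_equal(pa$pcc,
               resid_pcor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5),
                          c(0.9, 0.8, 0.7, 0.9, 0.6)),
               tolerance = 1e-12)
  # randomized identity + symmetry check
  withr::local_seed(66)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    lnc <- rnorm(n)
    m <- rnorm(n) + 0.3 * lnc
    p <- runif(n)
    a <- partial_correlation(lnc, m, p)
    b <- partial_correlation(m, lnc, p)
    expect_equal(a$pcc, resid_pcor(lnc, m, p), tolerance = 1e-10)
    expect_equal(a$pcc, b$pcc, tolerance = 1e-12)
  }
})

test_that("the normal-approximation p-value matches its closed form", {
  a <- list(pcc = 0.3, n = 100L)
  got <- partial_correlation_pvalue(a)$p_value
  expect_equal(got, 2 * pnorm(-abs(0.3 * sqrt(97 / (1 - 0.09)))),
               tolerance = 1e-10)
  # null center
  expect_equal(partial_correlation_pvalue(list(pcc = 0, n = 50L))$p_value, 1)
  # monotone decreasing in n at fixed pcc
  ps <- vapply(c(10, 20, 40, 80, 160), function(n) {
    partial_correlation_pvalue(list(pcc = 0.5, n = n))$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_warning(partial_correlation_pvalue(list(pcc = 1, n = 50L)),
                 "limit")
})

test_that("rank index is a signed log transform with boundary handling", {
  mk <- function(pcc, p) list(pcc = pcc, p_value = p)
  expect_equal(rank_index(mk(0.8, 1))$ri, 0)
  expect_equal(rank_index(mk(-0.8, 1))$ri, 0)
  expect_equal(rank_index(mk(0.5, 0.01))$ri, -log(0.01), tolerance = 1e-12)
  # antisymmetry at equal p-values
  expect_equal(rank_index(mk(0.4, 0.03))$ri, -rank_index(mk(-0.4, 0.03))$ri)
  expect_warning(out <- rank_index(mk(-0.9, 0)), "capped")
  expect_equal(out$ri, -745)
})

test_that("matrix pair associations agree with the scalar path", {
  co <- generate_cohort(synthetic_config(n_samples = 50, n_mrna = 12,
                                         n_lncrna = 4, pathway_set_size = 5,
                                         n_active_lnc = 2, seed = 14))
  pa <- pair_associations(co$expression, co$purity)
  for (i in c(1, 3)) {
    for (j in c(2, 7, 12)) {
      lid <- rownames(pa$pcc)[i]
      mid <- colnames(pa$pcc)[j]
      one <- partial_correlation(co$expression[lid, ],
                                 co$expression[mid, ], co$purity)
      one <- rank_index(partial_correlation_pvalue(one))
      expect_equal(pa$pcc[lid, mid], one$pcc, tolerance = 1e-12)
      expect_equal(pa$p_value[lid, mid], one$p_value, tolerance = 1e-12)
      expect_equal(pa$ri[lid, mid], one$ri, tolerance = 1e-10)
    }
  }
  tab <- pair_association_table(pa)
  expect_equal(nrow(tab), nrow(pa$pcc) * ncol(pa$pcc))
  # sign(ri) == sign(pcc) throughout
  expect_true(all(sign(pa$ri) == sign(pa$pcc) | pa$ri == 0))
})

test_that("TES combines direction and adjusted significance as specified", {
  co <- generate_cohort(synthetic_config(n_samples = 120, n_mrna = 80,
                                         n_lncrna = 12,
                                         pathway_set_size = 12, seed = 6))
  scr <- screen_lncrnas(co$expression, co$purity, co$truth$pathway_genes,
                        n_perm = 200, seed = 99)
  expect_equal(scr$tes, (1 - 2 * scr$p_adj) * sign(scr$es),
               tolerance = 1e-12)
  expect_true(all(abs(scr$tes) <= 1))
  expect_true(all(scr$p_raw >= 1 / 201 & scr$p_raw <= 1))
  # sorted by |tes| descending
  expect_true(all(diff(abs(scr$tes)) <= 1e-12))
  # candidate gates as stated
  expect_identical(scr$is_candidate,
                   abs(scr$tes) > 0.95 & scr$p_adj < 0.05)
  # determinism
  again <- screen_lncrnas(co$expression, co$purity, co$truth$pathway_genes,
                          n_perm = 200, seed = 99)
  expect_identical(as.data.frame(scr), as.data.frame(again))
})

test_that("candidate sets are monotone in the screening gates", {
  co <- generate_cohort(synthetic_config(n_samples = 150, n_mrna = 100,
                                         n_lncrna = 20,
                                         pathway_set_size = 15, seed = 35))
  strict <- screen_lncrnas(co$expression, co$purity,
                           co$truth$pathway_genes, n_perm = 200, seed = 1,
                           tes_threshold = 0.95, fdr_threshold = 0.05)
  loose <- screen_lncrnas(co$expression, co$purity,
                          co$truth$pathway_genes, n_perm = 200, seed = 1,
                          tes_threshold = 0.8, fdr_threshold = 0.2)
  expect_true(all(strict$lnc_id[strict$is_candidate] %in%
                    loose$lnc_id[loose$is_candidate]))
})

test_that("screen validates its target set and skips constant lncRNAs", {
  co <- generate_cohort(synthetic_config(n_samples = 60, n_mrna = 30,
                                         n_lncrna = 6, pathway_set_size = 8,
                                         seed = 3))
  mrna_ids <- rownames(co$expression)[co$partition == "mRNA"]
  expect_error(screen_lncrnas(co$expression, co$purity, character(0),
                              n_perm = 100), "empty")
  expect_error(screen_lncrnas(co$expression, co$purity, mrna_ids,
                              n_perm = 100), "proper subset")
  expect_error(screen_lncrnas(co$expression, co$purity, c("nope1", "nope2"),
                              n_perm = 100), "no target-set gene")
  co$expression["lncRNA_0003", ] <- 5
  expect_warning(
    scr <- screen_lncrnas(co$expression, co$purity,
                          co$truth$pathway_genes, n_perm = 100, seed = 2),
    "constant")
  expect_false("lncRNA_0003" %in% scr$lnc_id)
})

test_that("planted lncRNAs are recovered and inert ones mostly are not", {
  co <- generate_cohort(synthetic_config(seed = 801))
  scr <- screen_lncrnas(co$expression, co$purity, co$truth$pathway_genes,
                        n_perm = 500, seed = 802)
  cand <- scr$lnc_id[scr$is_candidate]
  expect_true(all(co$truth$active_lnc %in% cand))
  expect_lte(length(setdiff(cand, co$truth$active_lnc)), 6)  # ~10% of 55
  expect_identical(intersect_candidates(list(scr, scr)), sort(cand))
})
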