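test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(pathway_set_size = 500, n_mrna = 400),
               "pathway_set_size")
  expect_error(synthetic_config(n_active_lnc = 100, n_lncrna = 60),
               "n_active_lnc")
  expect_error(synthetic_config(effect_r = 1.2), "effect_r")
  expect_error(synthetic_config(censor_rate = 1), "censor_rate")
  expect_error(synthetic_config(effect_r = 0.9, purity_confounding = 0.6),
               "noise variance")
})

test_that("generation is bit-reproducible given the seed", {
  cfg <- synthetic_config(n_samples = 60, n_mrna = 40, n_lncrna = 8,
                          pathway_set_size = 10, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  other <- generate_cohort(synthetic_config(n_samples = 60, n_mrna = 40,
                                            n_lncrna = 8,
                                            pathway_set_size = 10,
                                            seed = 12))
  expect_false(identical(generate_cohort(cfg)$expression, other$expression))
})

test_that("cohort structure matches its declared contracts", {
  co <- generate_cohort(synthetic_config(n_samples = 80, n_mrna = 50,
                                         n_lncrna = 10, seed = 4))
  expect_true(all(co$truth$active_lnc %in%
                    rownames(co$expression)[co$partition == "lncRNA"]))
  expect_setequal(co$survival$sample, colnames(co$expression))
  expect_true(all(co$survival$time > 0))
  expect_true(all(co$survival$event %in% c(0L, 1L)))
  expect_true(all(co$purity >= 0 & co$purity <= 1))
  expect_false(anyNA(co$expression))
})

test_that("no planted signal means no lncRNA-activity correlation", {
  co <- generate_cohort(synthetic_config(n_samples = 400, effect_r = 0,
                                         n_active_lnc = 0, n_mrna = 60,
                                         n_lncrna = 30, seed = 21))
  cc <- cor(t(co$expression[co$partition == "lncRNA", ]),
            co$truth$activity)
  expect_lt(mean(abs(cc)), 3 / sqrt(400))
})

test_that("active-lncRNA correlation with activity is calibrated", {
  means <- vapply(1:50, function(s) {
    co <- generate_cohort(synthetic_config(n_samples = 500, effect_r = 0.6,
                                           n_mrna = 40, n_lncrna = 10,
                                           pathway_set_size = 10,
                                           seed = 1000 + s))
    mean(cor(t(co$expression[co$truth$active_lnc, ]), co$truth$activity))
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.6), 0.05)
})

test_that("censoring fraction tracks censor_rate at large n", {
  for (cr in c(0.2, 0.5)) {
    fr <- vapply(1:5, function(s) {
      co <- generate_cohort(synthetic_config(n_samples = 600, n_mrna = 10,
                                             n_lncrna = 2,
                                             pathway_set_size = 5,
                                             n_active_lnc = 1,
                                             censor_rate = cr,
                                             seed = 3000 + s))
      1 - mean(co$survival$event)
    }, numeric(1))
    expect_lt(max(abs(fr - cr)), 0.05)
  }
  co <- generate_cohort(synthetic_config(n_samples = 50, n_mrna = 10,
                                         n_lncrna = 2, pathway_set_size = 5,
                                         n_active_lnc = 1, censor_rate = 0,
                                         seed = 9))
  expect_true(all(co$survival$event == 1L))
})

test_that("purity confounding inflates raw correlations over partial ones", {
  inflated <- vapply(1:20, function(s) {
    co <- generate_cohort(synthetic_config(n_samples = 150, n_mrna = 60,
                                           n_lncrna = 10,
                                           pathway_set_size = 15,
                                           effect_r = 0,
                                           purity_confounding = 0.5,
                                           seed = 4000 + s))
    pa_adj <- pair_associations(co$expression, co$purity)
    pa_raw <- pair_associations(co$expression, NULL, adjust_purity = FALSE)
    mean(abs(pa_raw$pcc)) > mean(abs(pa_adj$pcc))
  }, logical(1))
  expect_true(all(inflated))
})

test_that("subtype shift separates centroids per active-lncRNA coordinate", {
  co <- generate_cohort(synthetic_config(n_samples = 300, subtype_shift = 3,
                                         n_mrna = 20, pathway_set_size = 5,
                                         n_lncrna = 10, seed = 17))
  cent <- co$truth$centroids
  pairs <- combn(nrow(cent), 2)
  mean_sep <- mean(abs(cent[pairs[1, ], ] - cent[pairs[2, ], ]))
  expect_equal(mean_sep, 3, tolerance = 1e-10)
  # empirical means of active lncRNAs differ across planted subtypes
  grp <- co$truth$subtype
  l1 <- co$expression[co$truth$active_lnc[1], ]
  gm <- tapply(l1, grp[names(l1)], mean)
  expect_gt(max(gm) - min(gm), 1)
})

test_that("cohort round-trips through its text formats", {
  co <- generate_cohort(synthetic_config(n_samples = 30, n_mrna = 15,
                                         n_lncrna = 5, pathway_set_size = 6,
                                         seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expr <- read_expression_tsv(paths[["expression"]])
  expect_equal(expr, co$expression, tolerance = 1e-12)
  expect_equal(read_purity_tsv(paths[["purity"]]), co$purity,
               tolerance = 1e-12)
  sv <- read_survival_tsv(paths[["survival"]])
  expect_equal(sv$event, co$survival$event)
  sets <- read_gmt(paths[["gmt"]])
  expect_identical(sets[["PLANTED_PATHWAY"]], co$truth$pathway_genes)
})
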