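toy_surv <- function() {
  # 8 samples, two groups, hand-specified times and censoring
  data.frame(sample = paste0("s", 1:8),
             time = c(1, 3, 5, 7, 2, 4, 4, 9),
             event = c(1, 1, 0, 1, 1, 1, 1, 0),
             stringsAsFactors = FALSE)
}

test_that("KM estimates match the product-limit definition by hand", {
  sv <- toy_surv()
  labels <- setNames(rep(c("A", "B"), each = 4), sv$sample)
  out <- survival_curves(sv, labels)
  a <- out$curves[out$curves$group == "A", ]
  # group A: times 1, 3, 7 events; 5 censored -> steps 3/4, 1/2, 0
  expect_equal(a$estimate[a$time == 1], 3 / 4)
  expect_equal(a$estimate[a$time == 3], 1 / 2)
  expect_equal(a$estimate[a$time == 7], 0)
  # nonincreasing from 1; first-step value (n-1)/n holds with no censoring
  expect_true(all(diff(a$estimate) <= 1e-12))
  b5 <- survival_curves(
    data.frame(sample = paste0("x", 1:5), time = c(2, 4, 6, 8, 10),
               event = 1L),
    setNames(rep("g", 5), paste0("x", 1:5)))
  expect_equal(b5$curves$estimate[1], 4 / 5)
  expect_true(is.na(b5$logrank_p))  # single group: no test
})

test_that("log-rank statistic matches the O-E/V tabulation", {
  sv <- toy_surv()
  labels <- setNames(rep(c("A", "B"), each = 4), sv$sample)
  out <- survival_curves(sv, labels)
  expect_equal(out$logrank_stat,
               brute_force_logrank(sv$time, sv$event, labels[sv$sample]),
               tolerance = 1e-10)
  # relabeling the groups changes nothing
  flipped <- setNames(ifelse(labels == "A", "B", "A"), names(labels))
  expect_equal(survival_curves(sv, flipped)$logrank_p, out$logrank_p)
})

test_that("identical survival in both groups gives a null log-rank test", {
  sv <- data.frame(sample = paste0("s", 1:8),
                   time = rep(c(1, 2, 3, 4), 2), event = 1L)
  labels <- setNames(rep(c("A", "B"), each = 4), sv$sample)
  out <- survival_curves(sv, labels)
  expect_equal(out$logrank_stat, 0, tolerance = 1e-12)
  expect_equal(out$logrank_p, 1, tolerance = 1e-12)
})

test_that("a single hazard-driving lncRNA is recovered by the risk model", {
  hits <- vapply(1:10, function(s) {
    co <- generate_cohort(synthetic_config(n_samples = 300, n_mrna = 20,
                                           pathway_set_size = 5,
                                           n_lncrna = 5, n_active_lnc = 1,
                                           hazard_beta = 1,
                                           seed = 6000 + s))
    rm <- fit_risk_model(co$expression[co$truth$active_lnc, , drop = FALSE],
                         co$survival)
    rm$beta[1] > 0 && rm$logrank_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null lncRNAs give calibrated log-rank p-values", {
  withr::local_seed(303)
  ps <- vapply(1:40, function(s) {
    co <- generate_cohort(synthetic_config(n_samples = 120, n_mrna = 20,
                                           pathway_set_size = 5,
                                           n_lncrna = 3, n_active_lnc = 0,
                                           hazard_beta = 0,
                                           seed = 7000 + s))
    fit_risk_model(co$expression[co$partition == "lncRNA", ],
                   co$survival)$logrank_p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps), 0.3)
})

test_that("risk model enforces contracts and handles degeneracy", {
  co <- generate_cohort(synthetic_config(n_samples = 100, n_mrna = 20,
                                         pathway_set_size = 5, n_lncrna = 4,
                                         n_active_lnc = 2, seed = 55))
  lnc <- co$expression[co$partition == "lncRNA", ]
  # collinear features are named
  dup <- rbind(lnc, doubled = 2 * lnc[1, ])
  expect_error(fit_risk_model(dup, co$survival), "collinear")
  # median split: groups differ by at most 1 on distinct scores
  rm <- fit_risk_model(lnc, co$survival)
  expect_lte(abs(sum(rm$groups == "high") - sum(rm$groups == "low")), 1)
  expect_true(all(rm$risk_scores[rm$groups == "high"] > rm$cut))
  expect_true(all(rm$risk_scores[rm$groups == "low"] <= rm$cut))
  # univariate mode returns one beta per lncRNA
  rmu <- fit_risk_model(lnc, co$survival, mode = "univariate")
  expect_named(rmu$beta, rownames(lnc))
  # a constant feature is caught as collinear with the baseline
  flat <- lnc
  flat[1, ] <- 1
  expect_error(fit_risk_model(flat, co$survival), "collinear")
})

test_that("fixed coefficients make the median split shift-invariant", {
  co <- generate_cohort(synthetic_config(n_samples = 80, n_mrna = 20,
                                         pathway_set_size = 5, n_lncrna = 3,
                                         n_active_lnc = 1, seed = 18))
  lnc <- co$expression[co$partition == "lncRNA", ]
  rm <- fit_risk_model(lnc, co$survival)
  shifted <- lnc
  shifted[2, ] <- shifted[2, ] + 7
  applied <- apply_risk_model(rm, shifted)
  expect_identical(setNames(applied$group, applied$sample),
                   setNames(unname(rm$groups[applied$sample]),
                            applied$sample))
  expect_equal(applied$score - rm$risk_scores[applied$sample],
               rep(rm$beta[2] * 7, nrow(applied)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("risk models survive a JSON round trip", {
  co <- generate_cohort(synthetic_config(n_samples = 60, n_mrna = 20,
                                         pathway_set_size = 5, n_lncrna = 3,
                                         n_active_lnc = 1, seed = 29))
  lnc <- co$expression[co$partition == "lncRNA", ]
  rm <- fit_risk_model(lnc, co$survival)
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(rm, path)
  back <- read_risk_model(path)
  expect_equal(back$beta, rm$beta, tolerance = 1e-12)
  expect_equal(back$cut, rm$cut, tolerance = 1e-12)
  applied <- apply_risk_model(back, lnc, co$survival)
  expect_equal(attr(applied, "logrank_p"), rm$logrank_p, tolerance = 1e-9)
})
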