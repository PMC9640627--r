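#' Configuration for a synthetic tumour expression cohort
#'
#' Defines a desk-scale bulk-expression cohort with planted structure: a
#' latent per-sample pathway activity, a block of pathway mRNAs coupled to it,
#' "active" lncRNAs correlated with it at a controlled effect size, tumour
#' purity acting as a shared confounder, optional sample subtypes separated in
#' active-lncRNA space, and overall survival whose hazard depends on the
#' pathway activity.
#'
#' Expression is generated on a continuous (log-like) scale with unit marginal
#' variance per gene; no attempt is made to mimic RNA-seq counts, library-size
#' effects, or batches.
#'
#' @param n_samples Number of samples.
#' @param n_mrna Number of mRNAs.
#' @param n_lncrna Number of lncRNAs.
#' @param pathway_set_size Number of mRNAs forming the planted pathway set
#'   (first `pathway_set_size` mRNA identifiers).
#' @param n_active_lnc Number of lncRNAs planted as pathway-associated (first
#'   `n_active_lnc` lncRNA identifiers).
#' @param effect_r Target marginal Pearson correlation, in `[0, 1]`, between
#'   each active lncRNA and the latent activity.
#' @param pathway_coherence Loading, in `[0, 1]`, of each pathway-set mRNA on
#'   the latent activity; also its marginal correlation with the activity.
#'   The default 0.2 (mean intra-set gene--gene correlation 0.04, the loose
#'   end of real pathway modules) keeps the module's coherent rank shift for
#'   a null lncRNA below the resolution of a gene-label permutation test at
#'   this set size; tighter modules make any such test anti-conservative for
#'   set enrichment, a known caveat of preranked GSEA.
#' @param purity_confounding Loading, in `[0, 1]`, of standardized tumour
#'   purity on pathway mRNAs and on every lncRNA. Background mRNAs receive
#'   heterogeneous loadings drawn uniformly from
#'   `[-purity_confounding, purity_confounding]`, so purity inflates raw
#'   lncRNA--mRNA correlations coherently for the pathway block only --
#'   exactly the artefact the purity-adjusted screen must remove.
#' @param n_subtypes Number of planted subtypes (>= 2; labels are always
#'   drawn, separation requires `subtype_shift > 0`).
#' @param subtype_shift Mean separation of subtype centroids per active
#'   lncRNA, in expression units: the average absolute difference between two
#'   subtype centroids along each active-lncRNA coordinate equals this value.
#'   Centroids form a randomly oriented regular simplex (all subtype pairs
#'   equally separated). `0` (default) plants labels without separation.
#' @param hazard_beta Log-hazard coefficient of the latent activity on
#'   survival.
#' @param censor_rate Expected fraction of censored samples, in `[0, 1)`.
#' @param baseline_hazard Exponential baseline hazard rate per time unit.
#' @param purity_shape Two Beta shape parameters for the purity distribution;
#'   the default Beta(5, 2) mimics high-purity tumour cohorts.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `synthetic_config`.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n_samples = 300L, n_mrna = 400L, n_lncrna = 60L,
                             pathway_set_size = 30L, n_active_lnc = 5L,
                             effect_r = 0.6, pathway_coherence = 0.2,
                             purity_confounding = 0.4,
                             n_subtypes = 3L, subtype_shift = 0,
                             hazard_beta = 0.7, censor_rate = 0.3,
                             baseline_hazard = 0.1, purity_shape = c(5, 2),
                             seed = 1L) {
  assert_scalar(n_samples, "n_samples", lo = 2, integer = TRUE)
  assert_scalar(n_mrna, "n_mrna", lo = 1, integer = TRUE)
  assert_scalar(n_lncrna, "n_lncrna", lo = 1, integer = TRUE)
  assert_scalar(pathway_set_size, "pathway_set_size", lo = 1, integer = TRUE)
  assert_scalar(n_active_lnc, "n_active_lnc", lo = 0, integer = TRUE)
  assert_scalar(effect_r, "effect_r", lo = 0, hi = 1)
  assert_scalar(pathway_coherence, "pathway_coherence", lo = 0, hi = 1)
  assert_scalar(purity_confounding, "purity_confounding", lo = 0, hi = 1)
  assert_scalar(n_subtypes, "n_subtypes", lo = 2, integer = TRUE)
  assert_scalar(subtype_shift, "subtype_shift", lo = 0)
  assert_scalar(hazard_beta, "hazard_beta")
  assert_scalar(censor_rate, "censor_rate", lo = 0, hi = 1, open_hi = TRUE)
  assert_scalar(baseline_hazard, "baseline_hazard", lo = 1e-12)
  assert_scalar(seed, "seed", integer = TRUE)
  if (pathway_set_size > n_mrna) {
    stop("pathway_set_size must not exceed n_mrna", call. = FALSE)
  }
  if (n_active_lnc > n_lncrna) {
    stop("n_active_lnc must not exceed n_lncrna", call. = FALSE)
  }
  if (!is.numeric(purity_shape) || length(purity_shape) != 2L ||
      any(purity_shape <= 0)) {
    stop("purity_shape must be two positive Beta shape parameters",
         call. = FALSE)
  }
  if (effect_r^2 + purity_confounding^2 >= 1 ||
      pathway_coherence^2 + purity_confounding^2 >= 1) {
    stop("implied noise variance is not positive: require ",
         "effect_r^2 + purity_confounding^2 < 1 and ",
         "pathway_coherence^2 + purity_confounding^2 < 1", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), n_mrna = as.integer(n_mrna),
         n_lncrna = as.integer(n_lncrna),
         pathway_set_size = as.integer(pathway_set_size),
         n_active_lnc = as.integer(n_active_lnc), effect_r = effect_r,
         pathway_coherence = pathway_coherence,
         purity_confounding = purity_confounding,
         n_subtypes = as.integer(n_subtypes), subtype_shift = subtype_shift,
         hazard_beta = hazard_beta, censor_rate = censor_rate,
         baseline_hazard = baseline_hazard, purity_shape = purity_shape,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

# Subtype centroids in active-lncRNA space: the vertices of a regular
# simplex (all pairwise centroid distances equal, so no subtype pair is
# accidentally close), randomly oriented, rescaled so the mean absolute
# between-centroid difference per coordinate equals `shift`. When fewer
# active lncRNAs than K - 1 are available, centred Gaussian centroids are
# used instead.
subtype_centroids <- function(n_subtypes, n_active, shift) {
  if (shift <= 0 || n_active == 0L) {
    return(matrix(0, n_subtypes, n_active))
  }
  k <- n_subtypes
  if (n_active >= k - 1L) {
    simplex <- svd(diag(k) - 1 / k)$u[, seq_len(k - 1L), drop = FALSE]
    basis <- qr.Q(qr(matrix(stats::rnorm(n_active * (k - 1L)),
                            n_active, k - 1L)))
    raw <- simplex %*% t(basis)
  } else {
    raw <- matrix(stats::rnorm(k * n_active), k, n_active)
    raw <- sweep(raw, 2L, colMeans(raw))
  }
  pairs <- utils::combn(k, 2L)
  d <- mean(abs(raw[pairs[1L, ], , drop = FALSE] -
                  raw[pairs[2L, ], , drop = FALSE]))
  if (d == 0) d <- 1
  raw * (shift / d)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws purity from a Beta law, a standard-normal latent pathway activity
#' `A`, unit-variance gene expression with the loadings described in
#' [synthetic_config()], subtype labels with optional centroid shifts on the
#' active lncRNAs, and survival times from an exponential proportional-hazards
#' model `h(t) = baseline_hazard * exp(hazard_beta * A)`. Censoring times are
#' uniform on `[0, cmax]` with `cmax` solved numerically so the expected
#' censored fraction equals `censor_rate` given the drawn activities.
#'
#' @param config A [synthetic_config()] object.
#' @return An object of class `synthetic_cohort`: a list with `expression`
#'   (genes x samples matrix), `partition` (named `"mRNA"`/`"lncRNA"` vector),
#'   `purity` (named vector in `[0, 1]`), `survival` (data.frame with columns
#'   `sample`, `time`, `event`), and `truth` (latent activity, subtype labels,
#'   active lncRNA and pathway gene identifiers, centroid matrix).
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_samples = 60, n_mrna = 50,
#'                                            n_lncrna = 10, seed = 7))
#' dim(cohort$expression)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("config must be created by synthetic_config()", call. = FALSE)
  }
  with_seed(config$seed, {
    n <- config$n_samples
    samples <- sprintf("S%04d", seq_len(n))
    mrna_ids <- sprintf("mRNA_%04d", seq_len(config$n_mrna))
    lnc_ids <- sprintf("lncRNA_%04d", seq_len(config$n_lncrna))
    pathway_genes <- mrna_ids[seq_len(config$pathway_set_size)]
    active_lnc <- lnc_ids[seq_len_zero(config$n_active_lnc)]

    purity <- stats::rbeta(n, config$purity_shape[1L], config$purity_shape[2L])
    names(purity) <- samples
    pz <- as.vector(scale(purity))
    activity <- stats::rnorm(n)

    r <- config$effect_r
    a <- config$pathway_coherence
    b <- config$purity_confounding
    sig <- sqrt(1 - r^2 - b^2)

    ## mRNA block: coherent pathway module + heterogeneous background
    n_path <- config$pathway_set_size
    n_bg <- config$n_mrna - n_path
    M <- matrix(NA_real_, config$n_mrna, n,
                dimnames = list(mrna_ids, samples))
    M[seq_len(n_path), ] <-
      matrix(a * activity + b * pz, n_path, n, byrow = TRUE) +
      sqrt(1 - a^2 - b^2) * matrix(stats::rnorm(n_path * n), n_path, n)
    if (n_bg > 0L) {
      load_bg <- stats::runif(n_bg, -b, b)
      M[n_path + seq_len(n_bg), ] <-
        load_bg %o% pz +
        sqrt(1 - load_bg^2) * matrix(stats::rnorm(n_bg * n), n_bg, n)
    }

    ## subtype labels and centroid shifts in active-lncRNA space
    subtype <- sample.int(config$n_subtypes, n, replace = TRUE)
    names(subtype) <- samples
    centroids <- subtype_centroids(config$n_subtypes, config$n_active_lnc,
                                   config$subtype_shift)

    ## lncRNA block: all share the purity loading; active ones add activity
    n_act <- config$n_active_lnc
    L <- matrix(NA_real_, config$n_lncrna, n,
                dimnames = list(lnc_ids, samples))
    if (n_act > 0L) {
      L[seq_len(n_act), ] <-
        matrix(r * activity + b * pz, n_act, n, byrow = TRUE) +
        sig * matrix(stats::rnorm(n_act * n), n_act, n) +
        t(centroids[subtype, , drop = FALSE])
    }
    n_inact <- config$n_lncrna - n_act
    if (n_inact > 0L) {
      L[n_act + seq_len(n_inact), ] <-
        matrix(b * pz, n_inact, n, byrow = TRUE) +
        sqrt(1 - b^2) * matrix(stats::rnorm(n_inact * n), n_inact, n)
    }

    ## survival: exponential baseline with proportional hazards on activity
    rate <- config$baseline_hazard * exp(config$hazard_beta * activity)
    event_time <- stats::rexp(n, rate = rate)
    if (config$censor_rate > 0) {
      cens_frac <- function(cm) mean((1 - exp(-rate * cm)) / (rate * cm))
      hi <- 1 / config$baseline_hazard
      while (cens_frac(hi) > config$censor_rate && hi < 1e12) hi <- hi * 2
      cmax <- stats::uniroot(function(cm) cens_frac(cm) - config$censor_rate,
                             c(1e-9, hi), tol = 1e-10)$root
      cens_time <- stats::runif(n, 0, cmax)
      time <- pmin(event_time, cens_time)
      event <- as.integer(event_time <= cens_time)
    } else {
      time <- event_time
      event <- rep(1L, n)
    }
    surv <- data.frame(sample = samples, time = time, event = event,
                       stringsAsFactors = FALSE)

    expression <- rbind(M, L)
    partition <- c(stats::setNames(rep("mRNA", config$n_mrna), mrna_ids),
                   stats::setNames(rep("lncRNA", config$n_lncrna), lnc_ids))
    structure(
      list(expression = expression, partition = partition, purity = purity,
           survival = surv,
           truth = list(activity = stats::setNames(activity, samples),
                        subtype = subtype, active_lnc = active_lnc,
                        pathway_genes = pathway_genes, centroids = centroids),
           config = config),
      class = "synthetic_cohort")
  })
}

seq_len_zero <- function(n) if (n > 0L) seq_len(n) else integer(0)

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "synthetic_cohort: %d samples, %d mRNAs (%d in pathway set), ",
    "%d lncRNAs (%d active)\n"),
    cfg$n_samples, cfg$n_mrna, cfg$pathway_set_size, cfg$n_lncrna,
    cfg$n_active_lnc))
  cat(sprintf("  effect_r = %.2f, purity_confounding = %.2f, %d subtypes ",
              cfg$effect_r, cfg$purity_confounding, cfg$n_subtypes))
  cat(sprintf("(shift %.2f), events: %d/%d\n", cfg$subtype_shift,
              sum(x$survival$event), cfg$n_samples))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `expression.tsv` (gene rows, sample header), `purity.tsv`
#' (`sample`, `purity`), `survival.tsv` (`sample`, `time`, `event`),
#' `truth.json`, and `pathway.gmt` holding the planted pathway gene set.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @param set_name Name for the planted gene set in the GMT file.
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir, set_name = "PLANTED_PATHWAY") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             purity = file.path(dir, "purity.tsv"),
             survival = file.path(dir, "survival.tsv"),
             truth = file.path(dir, "truth.json"),
             gmt = file.path(dir, "pathway.gmt"))
  write_expression_tsv(cohort$expression, paths[["expression"]])
  write_purity_tsv(cohort$purity, paths[["purity"]])
  write_survival_tsv(cohort$survival, paths[["survival"]])
  truth <- cohort$truth
  jsonlite::write_json(
    list(activity = as.list(truth$activity),
         subtype = as.list(truth$subtype),
         active_lnc = truth$active_lnc,
         pathway_genes = truth$pathway_genes),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  write_gmt(stats::setNames(list(truth$pathway_genes), set_name),
            paths[["gmt"]], description = "planted synthetic pathway set")
  invisible(paths)
}
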