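#' Pipeline configuration
#'
#' Bundles either a [synthetic_config()] block or paths to real inputs
#' (exactly one of the two) together with every stage parameter and the
#' single seed from which all stage seeds are derived (see [derive_seed()]).
#'
#' @param synthetic A [synthetic_config()] (or argument list for one), or
#'   `NULL`.
#' @param inputs Named list of file paths (`expression`, `purity`,
#'   `survival`, `gmt`), or `NULL`.
#' @param set_name Gene set (GMT entry) screened against; defaults to the
#'   first set in the collection.
#' @param ssgsea_exponent,ssgsea_normalize ssGSEA rank-weight exponent and
#'   cohort-level min--max normalization flag, see [ssgsea_scores()].
#' @param cox_alpha Significance level of the pathway survival screen.
#' @param n_perm,tes_threshold,fdr_threshold,weight_exp lncRNA screen
#'   parameters, see [screen_lncrnas()].
#' @param k_min,k_max,n_resamples,sample_fraction,elbow_threshold,standardize
#'   Consensus clustering parameters, see [consensus_cluster()].
#' @param risk_mode `"multivariate"` or `"univariate"`, see
#'   [fit_risk_model()].
#' @param seed Integer master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL, set_name = NULL,
                            ssgsea_exponent = 0.25, ssgsea_normalize = FALSE,
                            cox_alpha = 0.05, n_perm = 1000L,
                            tes_threshold = 0.95, fdr_threshold = 0.05,
                            weight_exp = 1, k_min = 2L, k_max = 10L,
                            n_resamples = 500L, sample_fraction = 0.8,
                            elbow_threshold = 0.15, standardize = TRUE,
                            risk_mode = c("multivariate", "univariate"),
                            seed = 1L) {
  risk_mode <- match.arg(risk_mode)
  if (is.null(synthetic) == is.null(inputs)) {
    stop("exactly one of 'synthetic' and 'inputs' must be supplied",
         call. = FALSE)
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    synthetic <- do.call(synthetic_config, synthetic)
  }
  if (!is.null(inputs)) {
    need <- c("expression", "purity", "survival", "gmt")
    if (!all(need %in% names(inputs))) {
      stop(sprintf("'inputs' must name paths: %s",
                   paste(need, collapse = ", ")), call. = FALSE)
    }
  }
  assert_scalar(cox_alpha, "cox_alpha", lo = 0, hi = 1)
  assert_scalar(seed, "seed", integer = TRUE)
  structure(list(synthetic = synthetic, inputs = inputs,
                 set_name = set_name, ssgsea_exponent = ssgsea_exponent,
                 ssgsea_normalize = ssgsea_normalize, cox_alpha = cox_alpha,
                 n_perm = as.integer(n_perm), tes_threshold = tes_threshold,
                 fdr_threshold = fdr_threshold, weight_exp = weight_exp,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_resamples = as.integer(n_resamples),
                 sample_fraction = sample_fraction,
                 elbow_threshold = elbow_threshold,
                 standardize = standardize, risk_mode = risk_mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; `synthetic` is
#' a mapping of [synthetic_config()] arguments, `inputs` a mapping of paths.
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(y), known)
  if (length(extra)) {
    stop(sprintf("%s: unknown configuration key(s): %s", path,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  do.call(pipeline_config, y)
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the full screening pipeline
#'
#' Executes the stage chain generate/load -> ssGSEA scoring -> pathway
#' survival screen -> lncRNA TES screen -> consensus subtyping -> risk model,
#' writing each stage's TSV/JSON outputs under `outdir` plus a
#' `manifest.json` (package version, seed, parameter echo, per-stage record
#' counts). Stages consume only declared inputs or files written by earlier
#' stages; a failure leaves completed stage outputs intact. With identical
#' configuration and seed, reruns are byte-identical.
#'
#' Subtyping runs on the candidate lncRNAs and is skipped (with a manifest
#' note) when fewer than two candidates emerge; the risk model likewise needs
#' at least one candidate. When fewer than `3 * k_max` samples are available,
#' `k_max` is lowered to `floor(n / 3)` and the reduction is recorded.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be created by pipeline_config()", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(package = "lncTES",
                   version = as.character(utils::packageVersion("lncTES")),
                   seed = seed,
                   parameters = config[setdiff(names(config),
                                               c("synthetic", "inputs"))],
                   stages = list(), notes = character(0))

  ## stage 1: generate or load, then align samples
  if (!is.null(config$synthetic)) {
    cfg <- config$synthetic
    cfg$seed <- derive_seed(seed, 1L)
    stage_msg("input", "generating synthetic cohort (seed %d)", cfg$seed)
    cohort <- generate_cohort(cfg)
    write_cohort(cohort, file.path(outdir, "cohort"))
    expr <- cohort$expression
    partition <- cohort$partition
    purity <- cohort$purity
    surv <- cohort$survival
    sets <- stats::setNames(list(cohort$truth$pathway_genes),
                            "PLANTED_PATHWAY")
    manifest$parameters$synthetic <- unclass(cfg)
  } else {
    stage_msg("input", "loading %s", config$inputs$expression)
    expr <- read_expression_tsv(config$inputs$expression)
    partition <- partition_from_prefix(rownames(expr))
    purity <- read_purity_tsv(config$inputs$purity)
    surv <- read_survival_tsv(config$inputs$survival)
    sets <- read_gmt(config$inputs$gmt)
  }
  set_name <- if (is.null(config$set_name)) names(sets)[1L] else
    config$set_name
  if (!set_name %in% names(sets)) {
    stop(sprintf("gene set '%s' not found in the collection", set_name),
         call. = FALSE)
  }
  al <- align_samples(expr, purity, surv)
  expr <- al$expression
  purity <- al$purity
  surv <- al$survival
  stage_msg("input", "%d genes x %d samples (%d dropped in alignment)",
            nrow(expr), ncol(expr), sum(al$n_dropped))
  manifest$stages$input <- list(
    n_genes = nrow(expr), n_mrna = sum(partition == "mRNA"),
    n_lncrna = sum(partition == "lncRNA"), n_samples = ncol(expr),
    n_dropped = as.list(al$n_dropped), gene_sets = length(sets),
    target_set = set_name)

  ## stage 2: ssGSEA pathway scores on the mRNA partition
  mrna <- expr[partition[rownames(expr)] == "mRNA", , drop = FALSE]
  scores <- ssgsea_scores(mrna, sets, exponent = config$ssgsea_exponent,
                          normalize = config$ssgsea_normalize)
  utils::write.table(
    data.frame(pathway = rownames(scores), scores, check.names = FALSE),
    file.path(outdir, "pathway_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  stage_msg("score", "scored %d gene set(s) on %d mRNAs", nrow(scores),
            nrow(mrna))
  manifest$stages$score <- list(n_sets_scored = nrow(scores))

  ## stage 3: pathway survival screen
  pscreen <- screen_pathways(scores, surv, alpha = config$cox_alpha)
  utils::write.table(pscreen, file.path(outdir, "pathway_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_msg("screen-pathways", "%d/%d significant at alpha = %g",
            sum(pscreen$significant), nrow(pscreen), config$cox_alpha)
  manifest$stages$screen_pathways <- list(
    n_fitted = nrow(pscreen), n_significant = sum(pscreen$significant))

  ## stage 4: lncRNA TES screen
  lscreen <- screen_lncrnas(expr, purity, sets[[set_name]],
                            partition = partition, n_perm = config$n_perm,
                            tes_threshold = config$tes_threshold,
                            fdr_threshold = config$fdr_threshold,
                            weight_exp = config$weight_exp,
                            seed = derive_seed(seed, 4L))
  utils::write.table(lscreen, file.path(outdir, "lnc_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  candidates <- lscreen$lnc_id[lscreen$is_candidate]
  stage_msg("screen-lnc", "%d candidate lncRNA(s) of %d screened",
            length(candidates), nrow(lscreen))
  manifest$stages$screen_lnc <- list(n_screened = nrow(lscreen),
                                     n_candidates = length(candidates))

  ## stage 5: consensus subtyping on candidate lncRNAs
  if (length(candidates) >= 2L) {
    k_max <- config$k_max
    if (ncol(expr) < 3L * k_max) {
      k_max <- max(config$k_min, floor(ncol(expr) / 3))
      manifest$notes <- c(manifest$notes, sprintf(
        "k_max lowered to %d for %d samples", k_max, ncol(expr)))
    }
    cons <- consensus_cluster(expr[candidates, , drop = FALSE],
                              k_min = config$k_min, k_max = k_max,
                              n_resamples = config$n_resamples,
                              sample_fraction = config$sample_fraction,
                              seed = derive_seed(seed, 5L),
                              standardize = config$standardize,
                              elbow_threshold = config$elbow_threshold)
    utils::write.table(
      data.frame(sample = names(cons$labels), subtype = cons$labels),
      file.path(outdir, "subtype_labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    for (kn in names(cons$consensus)) {
      utils::write.table(
        data.frame(sample = rownames(cons$consensus[[kn]]),
                   cons$consensus[[kn]], check.names = FALSE),
        file.path(outdir, sprintf("consensus_%s.tsv", kn)), sep = "\t",
        quote = FALSE, row.names = FALSE)
    }
    utils::write.table(
      data.frame(k = cons$k_values, area = cons$area,
                 delta_area = cons$delta_area,
                 selected = cons$k_values == cons$selected_k),
      file.path(outdir, "consensus_cdf_summary.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    stage_msg("subtype", "selected k = %d", cons$selected_k)

    comp <- compare_scores_across_subtypes(scores, cons$labels,
                                           fdr_threshold =
                                             config$fdr_threshold)
    utils::write.table(comp, file.path(outdir, "subtype_pathway_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ssurv <- survival_curves(surv, cons$labels)
    utils::write.table(ssurv$curves,
                       file.path(outdir, "subtype_survival.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$stages$subtype <- list(
      selected_k = cons$selected_k,
      cluster_sizes = as.list(as.integer(table(cons$labels))),
      n_pathways_significant = sum(comp$significant),
      logrank_p = ssurv$logrank_p)
  } else {
    manifest$notes <- c(manifest$notes,
                        "subtyping skipped: fewer than 2 candidate lncRNAs")
    stage_msg("subtype", "skipped (fewer than 2 candidates)")
  }

  ## stage 6: risk model on candidate lncRNAs
  risk_ok <- length(candidates) >= 1L
  if (risk_ok) {
    risk <- tryCatch(
      fit_risk_model(expr[candidates, , drop = FALSE], surv,
                     mode = config$risk_mode),
      error = function(e) {
        manifest$notes <<- c(manifest$notes,
                             paste("risk model failed:",
                                   conditionMessage(e)))
        NULL
      })
    if (!is.null(risk)) {
      utils::write.table(
        data.frame(sample = names(risk$risk_scores),
                   score = unname(risk$risk_scores),
                   group = if (is.null(risk$groups)) NA else
                     unname(risk$groups)),
        file.path(outdir, "risk_scores.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      write_risk_model(risk, file.path(outdir, "risk_model.json"))
      if (!is.null(risk$groups)) {
        km <- survival_curves(surv, risk$groups)
        utils::write.table(km$curves, file.path(outdir, "risk_km.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      stage_msg("risk", "log-rank p = %.3g between median-split groups",
                risk$logrank_p)
      manifest$stages$risk <- list(
        mode = risk$mode, n_lncrna = length(risk$lnc_ids),
        beta = as.list(risk$beta), cut = risk$cut,
        logrank_p = risk$logrank_p, flagged = risk$flagged)
    }
  } else {
    manifest$notes <- c(manifest$notes,
                        "risk model skipped: no candidate lncRNAs")
    stage_msg("risk", "skipped (no candidates)")
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
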