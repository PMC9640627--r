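#' Univariate Cox regression of one score against overall survival
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling) for a single
#' continuous covariate and reports the hazard ratio on the base-2 log scale:
#' `log2(HR) > 0` marks a risk factor, `log2(HR) < 0` a protective factor.
#'
#' @param score Named numeric vector (one score per sample).
#' @param surv Survival data.frame with columns `sample`, `time`, `event`.
#' @param feature_id Identifier echoed in the result.
#' @return One-row data.frame with `feature_id`, `log2_hr`, `p_value` (Wald),
#'   `n`, `n_events`, and `flagged` (`TRUE` when the fit hit a monotone
#'   likelihood / infinite-coefficient warning).
#' @export
fit_univariate_cox <- function(score, surv, feature_id = "score") {
  stopifnot(is.numeric(score), !is.null(names(score)),
            all(c("sample", "time", "event") %in% names(surv)))
  common <- intersect(names(score), surv$sample)
  if (length(common) < 10L) {
    stop("need at least 10 samples with both score and survival",
         call. = FALSE)
  }
  x <- score[common]
  sv <- surv[match(common, surv$sample), , drop = FALSE]
  if (sum(sv$event) < 3L) stop("need at least 3 events", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("zero-variance covariate: Cox fit undefined", call. = FALSE)
  }
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(sv$time, sv$event) ~ x,
                    ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)$coefficients
  data.frame(feature_id = feature_id,
             log2_hr = unname(sm[1L, "coef"]) / log(2),
             p_value = unname(sm[1L, "Pr(>|z|)"]),
             n = length(common), n_events = sum(sv$event),
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Screen pathway scores for survival association
#'
#' Runs [fit_univariate_cox()] on every row of a pathway-score matrix and
#' flags pathways with Wald `p < alpha`, labelled risk or protective by the
#' sign of `log2(HR)`. Per-pathway fit failures (e.g. constant rows) are
#' logged as warnings and excluded, not fatal.
#'
#' @param scores Pathway-score matrix (pathways x samples), e.g. from
#'   [ssgsea_scores()].
#' @param surv Survival data.frame with columns `sample`, `time`, `event`.
#' @param alpha Significance level for the Wald test (default 0.05).
#' @return data.frame with one row per successfully fitted pathway:
#'   `feature_id`, `log2_hr`, `p_value`, `n`, `n_events`, `flagged`,
#'   `significant`, `direction`.
#' @export
screen_pathways <- function(scores, surv, alpha = 0.05) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)))
  assert_scalar(alpha, "alpha", lo = 0, hi = 1)
  rows <- lapply(rownames(scores), function(pw) {
    tryCatch(fit_univariate_cox(scores[pw, ], surv, feature_id = pw),
             error = function(e) {
               warning(sprintf("pathway '%s' excluded: %s", pw,
                               conditionMessage(e)), call. = FALSE)
               NULL
             })
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) stop("no pathway could be fitted", call. = FALSE)
  res <- do.call(rbind, rows)
  res$significant <- res$p_value < alpha
  res$direction <- ifelse(res$log2_hr > 0, "risk", "protective")
  rownames(res) <- NULL
  res
}

#' Intersect significant features across cohort screens
#'
#' @param screens List of [screen_pathways()] results.
#' @return Character vector of feature identifiers significant in every
#'   screen.
#' @export
intersect_significant <- function(screens) {
  stopifnot(is.list(screens), length(screens) >= 1L)
  Reduce(intersect,
         lapply(screens, function(s) s$feature_id[s$significant]))
}
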