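#' Cox-based lncRNA risk score with median split
#'
#' Fits Cox proportional-hazards coefficients for a panel of key lncRNAs
#' (jointly in `"multivariate"` mode, the default, or one-at-a-time in
#' `"univariate"` mode; Breslow tie handling), computes each sample's risk
#' score `sum_i beta_i * EXP_i`, splits the cohort into high- and low-risk
#' groups at the median score (scores exactly at the median go to the
#' low-risk group), and tests the survival difference between groups with the
#' log-rank test.
#'
#' @param expr Expression matrix restricted to the key lncRNAs
#'   (lncRNAs x samples).
#' @param surv Survival data.frame with columns `sample`, `time`, `event`;
#'   >= 20 shared samples and >= 10 events required.
#' @param mode `"multivariate"` (joint fit) or `"univariate"` (per-lncRNA
#'   fits). In multivariate mode the expression rows must be linearly
#'   independent; collinear features are named in the error.
#' @return Object of class `risk_model`: `lnc_ids`, `beta`, `risk_scores`
#'   (named), `cut` (median), `groups` (`"high"`/`"low"`), `logrank_stat`,
#'   `logrank_p`, `mode`, and `flagged` (separation warning or degenerate
#'   constant scores, in which case no test is run).
#' @export
fit_risk_model <- function(expr, surv, mode = c("multivariate",
                                                "univariate")) {
  mode <- match.arg(mode)
  validate_expression(expr)
  stopifnot(all(c("sample", "time", "event") %in% names(surv)))
  common <- intersect(colnames(expr), surv$sample)
  if (length(common) < 20L) {
    stop("need at least 20 samples with expression and survival",
         call. = FALSE)
  }
  x <- expr[, common, drop = FALSE]
  sv <- surv[match(common, surv$sample), , drop = FALSE]
  if (sum(sv$event) < 10L) stop("need at least 10 events", call. = FALSE)

  lnc_ids <- rownames(x)
  flagged <- FALSE
  note_flag <- function(expr_call) {
    withCallingHandlers(expr_call, warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  }
  y <- survival::Surv(sv$time, sv$event)
  if (mode == "multivariate") {
    xt <- t(x)
    qrd <- qr(cbind(1, xt))
    if (qrd$rank < ncol(xt) + 1L) {
      keep <- qrd$pivot[seq_len(qrd$rank)]
      bad <- setdiff(seq_len(ncol(xt)) + 1L, keep) - 1L
      stop(sprintf("collinear lncRNA expression in multivariate mode: %s",
                   paste(lnc_ids[bad], collapse = ", ")), call. = FALSE)
    }
    df <- data.frame(xt, check.names = FALSE)
    fit <- note_flag(survival::coxph(y ~ ., data = df, ties = "breslow"))
    beta <- stats::setNames(stats::coef(fit), lnc_ids)
  } else {
    beta <- vapply(lnc_ids, function(id) {
      fit <- note_flag(survival::coxph(y ~ x[id, ], ties = "breslow"))
      unname(stats::coef(fit))
    }, numeric(1L))
  }

  scores <- drop(crossprod(x, beta))
  cut <- stats::median(scores)
  if (stats::sd(scores) == 0) {
    warning("risk scores are constant; median split is degenerate and no ",
            "log-rank test is run", call. = FALSE)
    return(structure(list(lnc_ids = lnc_ids, beta = beta,
                          risk_scores = scores, cut = cut, groups = NULL,
                          logrank_stat = NA_real_, logrank_p = NA_real_,
                          mode = mode, flagged = TRUE),
                     class = "risk_model"))
  }
  groups <- stats::setNames(ifelse(scores > cut, "high", "low"), common)
  sd_fit <- survival::survdiff(y ~ groups)
  logrank_p <- stats::pchisq(sd_fit$chisq, df = 1L, lower.tail = FALSE)
  structure(list(lnc_ids = lnc_ids, beta = beta, risk_scores = scores,
                 cut = cut, groups = groups,
                 logrank_stat = unname(sd_fit$chisq), logrank_p = logrank_p,
                 mode = mode, flagged = flagged),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("risk_model (%s Cox, Breslow ties): %d lncRNAs, %d samples\n",
              x$mode, length(x$lnc_ids), length(x$risk_scores)))
  print(round(x$beta, 4))
  if (!is.null(x$groups)) {
    cat(sprintf("  median cut %.4f; high/low = %d/%d; log-rank p = %.3g\n",
                x$cut, sum(x$groups == "high"), sum(x$groups == "low"),
                x$logrank_p))
  } else {
    cat("  degenerate constant risk scores; no split\n")
  }
  invisible(x)
}

#' Apply a fitted risk model to new expression data
#'
#' Computes risk scores with the stored coefficients and splits the new
#' cohort at its own median score (each cohort is split by its own median).
#'
#' @param model A `risk_model` (or list read by [read_risk_model()]).
#' @param expr Expression matrix containing the model's lncRNAs.
#' @param surv Optional survival data.frame; if given, a log-rank test
#'   between the new groups is reported.
#' @return data.frame with `sample`, `score`, `group`; when `surv` is given,
#'   `logrank_stat` and `logrank_p` are attached as attributes.
#' @export
apply_risk_model <- function(model, expr, surv = NULL) {
  stopifnot(!is.null(model$lnc_ids), !is.null(model$beta))
  missing <- setdiff(model$lnc_ids, rownames(expr))
  if (length(missing)) {
    stop(sprintf("expression lacks model lncRNA(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x <- expr[model$lnc_ids, , drop = FALSE]
  scores <- drop(crossprod(x, model$beta))
  cut <- stats::median(scores)
  res <- data.frame(sample = colnames(x), score = scores,
                    group = ifelse(scores > cut, "high", "low"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (!is.null(surv)) {
    sc <- survival_curves(surv, stats::setNames(res$group, res$sample))
    attr(res, "logrank_stat") <- sc$logrank_stat
    attr(res, "logrank_p") <- sc$logrank_p
  }
  res
}

#' Save or load a risk model as JSON
#'
#' @param model A `risk_model`.
#' @param path Output path.
#' @return `write_risk_model()` returns the path invisibly;
#'   `read_risk_model()` a list usable by [apply_risk_model()].
#' @export
write_risk_model <- function(model, path) {
  jsonlite::write_json(list(lnc_ids = model$lnc_ids,
                            beta = as.list(model$beta), cut = model$cut,
                            mode = model$mode),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$beta <- unlist(m$beta)
  m
}

#' Kaplan--Meier curves and log-rank test for labelled groups
#'
#' Product-limit survival estimates per group, plus the k-group log-rank
#' statistic and p-value when at least two groups have >= 3 samples. With a
#' single group only the estimate is returned.
#'
#' @param surv Survival data.frame with columns `sample`, `time`, `event`.
#' @param labels Named group labels covering (a subset of) the samples.
#' @return List with `curves` (data.frame: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `estimate`), `logrank_stat`, `logrank_df`,
#'   `logrank_p` (all `NA` when no test is run).
#' @export
survival_curves <- function(surv, labels) {
  stopifnot(all(c("sample", "time", "event") %in% names(surv)),
            !is.null(names(labels)))
  common <- intersect(surv$sample, names(labels))
  if (length(common) < 3L) stop("fewer than 3 labelled samples",
                                call. = FALSE)
  sv <- surv[match(common, surv$sample), , drop = FALSE]
  g <- factor(labels[common])
  y <- survival::Surv(sv$time, sv$event)
  fit <- survival::survfit(y ~ g)
  if (nlevels(g) > 1L) {
    strata_group <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  } else {
    strata_group <- rep(levels(g), length(fit$time))
  }
  curves <- data.frame(group = strata_group, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       n_censor = fit$n.censor, estimate = fit$surv,
                       stringsAsFactors = FALSE)
  big <- names(table(g))[table(g) >= 3L]
  if (length(big) >= 2L) {
    keep <- g %in% big
    sd_fit <- survival::survdiff(survival::Surv(sv$time[keep],
                                                sv$event[keep]) ~
                                   droplevels(g[keep]))
    df <- length(sd_fit$n) - 1L
    list(curves = curves, logrank_stat = unname(sd_fit$chisq),
         logrank_df = df,
         logrank_p = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE))
  } else {
    list(curves = curves, logrank_stat = NA_real_, logrank_df = NA_integer_,
         logrank_p = NA_real_)
  }
}
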