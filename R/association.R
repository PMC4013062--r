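#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} ( p_(j) * m / j )` capped at 1, mapped back to the
#' input order. Statistical significance in this pipeline is claimed at
#' `q < 0.05`. Input p-values must lie in (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of adjusted values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || length(p) == 0)
    abort("p must be a non-empty numeric vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    abort("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

covariate_names <- function(covariates = c("age_sex", "full")) {
  covariates <- match.arg(covariates)
  base <- c("age", "sex")
  if (covariates == "age_sex") return(base)
  c(base, "smoking", "height", "weight", "sbp", "dbp", "diabetes", "mi",
    "heart_failure", "htn_treatment")
}

# Shared engine for expression-as-outcome models: regress each feature on a
# binary exposure plus covariates. Primary fit is a linear mixed model with
# a Gaussian random intercept per pedigree (REML); if that fit errors or
# fails to converge the feature falls back to OLS with cluster-robust
# (pedigree) standard errors, recorded in `note`. Constant features are
# flagged with effect 0, p 1; singular designs yield a flagged failure row.
fit_expression_models <- function(expr, samples, exposure, covs,
                                  method = c("lmm", "ols")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr), length(exposure) == nrow(samples))
  missing_cov <- setdiff(covs, colnames(samples))
  if (length(missing_cov))
    abort("unknown covariate(s): %s", paste(missing_cov, collapse = ", "))
  idx <- match(samples$sample_id, colnames(expr))
  if (any(is.na(idx)))
    abort("sample '%s' absent from expression matrix",
          samples$sample_id[is.na(idx)][1])
  expr <- expr[, idx, drop = FALSE]

  dat <- samples[, c("pedigree_id", covs), drop = FALSE]
  dat$.exposure <- as.numeric(exposure)
  cc <- stats::complete.cases(dat)
  n_excluded <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  expr <- expr[, cc, drop = FALSE]
  dat$pedigree_id <- factor(dat$pedigree_id)
  if (length(unique(dat$.exposure)) < 2)
    abort("exposure is constant after complete-case filtering")
  message(sprintf("fitting %d features on %d samples (%d excluded, %s model)",
                  nrow(expr), nrow(dat), n_excluded, method))

  rhs <- paste(c(".exposure", covs), collapse = " + ")
  fe_formula <- stats::as.formula(paste(".y ~", rhs))
  constant <- apply(expr, 1, function(x) stats::sd(x) == 0)

  base_fit <- NULL
  if (method == "lmm") {
    lmm_formula <- stats::as.formula(paste(".y ~", rhs, "+ (1 | pedigree_id)"))
    first <- which(!constant)[1]
    if (is.na(first)) abort("all features are constant")
    dat$.y <- expr[first, ]
    base_fit <- tryCatch(
      suppressMessages(lme4::lmer(lmm_formula, data = dat, REML = TRUE)),
      error = function(e) NULL)
    if (is.null(base_fit)) {
      # degenerate clustering (e.g. singleton pedigrees): the mixed model is
      # unidentifiable, so every feature uses the cluster-robust OLS path
      message("mixed model unidentifiable for this design; using cluster-robust OLS")
      method <- "ols"
    }
  }

  ols_fit <- function(y) {
    d <- dat
    d$.y <- y
    fit <- stats::lm(fe_formula, data = d)
    b <- stats::coef(fit)[".exposure"]
    if (any(is.na(stats::coef(fit)))) {
      return(list(effect = NA_real_, se = NA_real_, p = NA_real_,
                  note = "singular"))
    }
    V <- sandwich::vcovCL(fit, cluster = d$pedigree_id)
    se <- sqrt(V[".exposure", ".exposure"])
    list(effect = unname(b), se = se,
         p = 2 * stats::pnorm(-abs(b / se)), note = "ols")
  }

  one_feature <- function(y) {
    if (method == "ols") return(ols_fit(y))
    fit <- tryCatch(
      suppressMessages(withCallingHandlers(
        lme4::refit(base_fit, newresp = y),
        warning = function(w) stop(conditionMessage(w), call. = FALSE))),
      error = function(e) NULL)
    if (is.null(fit)) {
      out <- ols_fit(y)
      out$note <- if (out$note == "ols") "ols_fallback" else out$note
      return(out)
    }
    b <- lme4::fixef(fit)[".exposure"]
    se <- sqrt(as.matrix(stats::vcov(fit))[".exposure", ".exposure"])
    list(effect = unname(b), se = se,
         p = 2 * stats::pnorm(-abs(b / se)), note = "lmm")
  }

  rows <- vector("list", nrow(expr))
  for (i in seq_len(nrow(expr))) {
    rows[[i]] <- if (constant[i]) {
      list(effect = 0, se = NA_real_, p = 1, note = "constant")
    } else {
      one_feature(expr[i, ])
    }
  }
  finish_results(rownames(expr), rows, n_used = nrow(dat),
                 n_excluded = n_excluded)
}

finish_results <- function(feature_ids, rows, n_used, n_excluded) {
  res <- data.frame(
    feature_id = feature_ids,
    effect = vapply(rows, function(r) r$effect, 0),
    se = vapply(rows, function(r) r$se, 0),
    p = vapply(rows, function(r) r$p, 0),
    q = NA_real_,
    n_used = n_used,
    note = vapply(rows, function(r) r$note, ""),
    stringsAsFactors = FALSE)
  ok <- is.finite(res$p)
  if (any(ok)) res$q[ok] <- bh_fdr(res$p[ok])
  n_fallback <- sum(res$note %in% c("ols_fallback", "singular", "nonconvergence"))
  if (n_fallback)
    message(sprintf("%d feature(s) used a fallback or were flagged", n_fallback))
  attr(res, "n_used") <- n_used
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Association of expression with prevalent AF
#'
#' Per feature, regresses log2 expression on a prevalent-AF indicator plus
#' covariates, with a Gaussian random intercept per pedigree to absorb
#' familial correlation (REML). The reported effect is the AF coefficient
#' (log2 expression difference, AF vs referent) with a two-sided Wald
#' p-value; `q` is the Benjamini-Hochberg adjusted value across all
#' features tested in the run. The referent group excludes incident-AF
#' samples by default (participants who never developed AF); set
#' `include_incident = TRUE` to count them as referents. Features whose
#' mixed fit fails fall back to OLS with pedigree-cluster-robust standard
#' errors (noted per feature).
#'
#' @param expr Expression matrix, features x samples (see
#'   [read_expression()]).
#' @param samples Phenotype table (see [read_phenotypes()]).
#' @param covariates `"age_sex"` (primary adjustment) or `"full"`
#'   (additional AF risk factors: smoking, height, weight, systolic and
#'   diastolic blood pressure, diabetes, myocardial infarction, heart
#'   failure, antihypertensive treatment).
#' @param include_incident Count incident-AF samples as referents?
#' @param method `"lmm"` (default) or `"ols"` (cluster-robust OLS for every
#'   feature).
#' @return `data.frame` with columns `feature_id`, `effect`, `se`, `p`,
#'   `q`, `n_used`, `note`.
#' @export
fit_prevalent <- function(expr, samples, covariates = c("age_sex", "full"),
                          include_incident = FALSE,
                          method = c("lmm", "ols")) {
  samples <- validate_phenotypes(samples)
  covs <- covariate_names(covariates)
  keep <- samples$af_group %in%
    c("prevalent", "none", if (include_incident) "incident")
  samples <- samples[keep, , drop = FALSE]
  n_case <- sum(samples$af_group == "prevalent")
  n_ref <- sum(samples$af_group != "prevalent")
  if (n_case < 2 || n_ref < 2)
    abort("need >=2 samples per AF group (cases %d, referents %d)",
          n_case, n_ref)
  fit_expression_models(expr, samples,
                        exposure = samples$af_group == "prevalent",
                        covs = covs, method = method)
}

#' Association of expression with medication use
#'
#' Same model family as [fit_prevalent()] with a dichotomous medication
#' flag (expression is the outcome, medication use the exposure); by
#' default adjusted for age and sex.
#'
#' @inheritParams fit_prevalent
#' @param medication Name of a binary medication column in `samples`
#'   (e.g. `"warfarin"`, `"beta_blocker"`, `"digoxin"`, `"ccb"`).
#' @param adjust Adjust for the covariate set (`TRUE`) or fit unadjusted
#'   (`FALSE`)?
#' @return As [fit_prevalent()].
#' @export
fit_medication <- function(expr, samples, medication,
                           covariates = c("age_sex", "full"),
                           adjust = TRUE, method = c("lmm", "ols")) {
  samples <- validate_phenotypes(samples)
  if (!medication %in% colnames(samples))
    abort("medication flag '%s' not present in the phenotype table", medication)
  flag <- samples[[medication]]
  if (!all(stats::na.omit(flag) %in% 0:1))
    abort("medication flag '%s' must be binary", medication)
  if (length(unique(stats::na.omit(flag))) < 2)
    abort("medication '%s' has no %s", medication,
          if (all(flag == 1, na.rm = TRUE)) "non-users" else "users")
  covs <- if (adjust) covariate_names(covariates) else character(0)
  keep <- !is.na(flag)
  fit_expression_models(expr[, , drop = FALSE], samples[keep, , drop = FALSE],
                        exposure = flag[keep], covs = covs, method = method)
}

#' Association of expression with incident AF (Cox model)
#'
#' Per feature, fits a Cox proportional hazards model of time to incident
#' AF on continuous log2 expression plus covariates, with robust sandwich
#' standard errors clustered by pedigree. Follow-up is censored at the last
#' follow-up time (administrative horizon in the synthetic cohort).
#' Prevalent-AF samples are excluded. The effect is the log hazard ratio
#' per log2-expression unit.
#'
#' @inheritParams fit_prevalent
#' @param min_events Minimum number of incident events required (default
#'   10); fewer is an error.
#' @return As [fit_prevalent()].
#' @export
fit_incident <- function(expr, samples, covariates = c("age_sex", "full"),
                         min_events = 10) {
  samples <- validate_phenotypes(samples)
  covs <- covariate_names(covariates)
  for (col in c("followup_time", "event"))
    if (!col %in% colnames(samples))
      abort("phenotype table lacks '%s', required for incident models", col)
  samples <- samples[samples$af_group != "prevalent", , drop = FALSE]
  dat <- samples[, c("pedigree_id", "followup_time", "event", covs),
                 drop = FALSE]
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  ids <- samples$sample_id[cc]
  n_events <- sum(dat$event)
  if (n_events < min_events)
    abort("insufficient events: %d observed, %d required", n_events,
          min_events)
  idx <- match(ids, colnames(expr))
  if (any(is.na(idx)))
    abort("sample '%s' absent from expression matrix", ids[is.na(idx)][1])
  expr <- expr[, idx, drop = FALSE]
  dat$pedigree_id <- factor(dat$pedigree_id)
  message(sprintf("incident-AF Cox models: %d samples, %d events, %d excluded",
                  nrow(dat), n_events, sum(!cc)))

  fml <- stats::as.formula(paste(
    "survival::Surv(followup_time, event) ~ .y +",
    paste(covs, collapse = " + ")))
  one_feature <- function(y) {
    if (stats::sd(y) == 0)
      return(list(effect = 0, se = NA_real_, p = 1, note = "constant"))
    d <- dat
    d$.y <- y
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(fml, data = d, cluster = pedigree_id, robust = TRUE),
        warning = function(w) stop(conditionMessage(w), call. = FALSE)),
      error = function(e) NULL)
    if (is.null(fit) || is.na(stats::coef(fit)[".y"]))
      return(list(effect = NA_real_, se = NA_real_, p = NA_real_,
                  note = "nonconvergence"))
    b <- stats::coef(fit)[".y"]
    se <- sqrt(fit$var[1, 1])  # robust (sandwich) variance
    list(effect = unname(b), se = se,
         p = 2 * stats::pnorm(-abs(b / se)), note = "cox")
  }
  rows <- lapply(seq_len(nrow(expr)), function(i) one_feature(expr[i, ]))
  finish_results(rownames(expr), rows, n_used = nrow(dat),
                 n_excluded = sum(!cc))
}
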