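#' Fit a longitudinal linear mixed model
#'
#' Restricted-maximum-likelihood mixed model with a random intercept per
#' participant, the requested fixed factors/interactions, and the two
#' standing covariates (age at first implantation and inter-implant delay).
#' Factors are coded with sum-to-zero contrasts so the Type-III tests in
#' [anova_table()] are well defined. Rows with missing response or covariate
#' values are dropped listwise and counted.
#'
#' @param data Index table (long or wide form) with a `participant_id`
#'   column.
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect terms, e.g.
#'   `c("time_bin * condition * hemisphere")`.
#' @param covariates Covariate columns, always included (default
#'   `c("age_ci1", "inter_implant_delay")`; use `character(0)` to omit).
#' @param random Grouping column for the random intercept.
#' @param reml Use REML (default `TRUE`).
#' @return A list of class `cib_lmm`: `model` (the `lmerModLmerTest` fit),
#'   `converged`, `singular`, `n_dropped`, `formula`, `variance_components`
#'   (intercept and residual variance with SDs).
#' @export
fit_lmm <- function(data, response, fixed,
                    covariates = c("age_ci1", "inter_implant_delay"),
                    random = "participant_id", reml = TRUE) {
  stopifnot(is.data.frame(data), response %in% names(data))
  miss_cov <- setdiff(covariates, names(data))
  if (length(miss_cov))
    stop("missing covariate column(s): ", paste(miss_cov, collapse = ", "))
  rhs <- paste(c(fixed, covariates), collapse = " + ")
  fml <- stats::as.formula(paste0(response, " ~ ", rhs,
                                  " + (1 | ", random, ")"))
  vars <- all.vars(fml)
  d <- data[stats::complete.cases(data[intersect(vars, names(data))]), ,
            drop = FALSE]
  n_dropped <- nrow(data) - nrow(d)
  if (length(unique(d[[random]])) < 2L)
    stop("need at least 2 participants with complete data")
  for (v in vars) {
    if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  }
  # factors left with a single level cannot be estimated: drop their terms
  fe_terms <- attr(stats::terms(stats::reformulate(c(fixed, covariates))),
                   "term.labels")
  degenerate <- vars[vapply(vars, function(v)
    is.factor(d[[v]]) && nlevels(droplevels(d[[v]])) < 2L, logical(1))]
  if (length(degenerate)) {
    warning("dropping single-level factor term(s): ",
            paste(degenerate, collapse = ", "))
    keep <- !vapply(fe_terms, function(tl)
      any(degenerate %in% all.vars(stats::reformulate(tl))), logical(1))
    fe_terms <- fe_terms[keep]
    if (!length(fe_terms)) stop("no estimable fixed effects remain")
    fml <- stats::as.formula(paste0(response, " ~ ",
                                    paste(fe_terms, collapse = " + "),
                                    " + (1 | ", random, ")"))
  }
  for (v in all.vars(fml)) {
    if (is.factor(d[[v]])) {
      d[[v]] <- droplevels(d[[v]])
      stats::contrasts(d[[v]]) <- stats::contr.sum(nlevels(d[[v]]))
    }
  }
  fit <- lmerTest::lmer(fml, data = d, REML = reml)
  vc <- as.data.frame(lme4::VarCorr(fit))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  # boundary (singular) fits are legitimate and flagged separately; only
  # genuine optimizer failures mark the fit as non-converged
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  conv <- length(msgs) == 0L
  structure(list(model = fit, converged = conv, singular = singular,
                 n_dropped = n_dropped, formula = fml, data = d,
                 response = response,
                 variance_components = data.frame(
                   term = c("intercept (participant)", "residual"),
                   variance = vc$vcov, sd = vc$sdcor)),
            class = "cib_lmm")
}

#' @export
print.cib_lmm <- function(x, ...) {
  cat("Linear mixed model:", deparse(x$formula), "\n")
  cat("converged:", x$converged, " singular:", x$singular,
      " rows dropped:", x$n_dropped, "\n")
  print(x$variance_components, row.names = FALSE)
  invisible(x)
}

#' Type-III F tests for the fixed effects
#'
#' F statistic, numerator/denominator degrees of freedom (Satterthwaite
#' approximation) and p value per fixed term, with a significance marker at
#' the 0.05 level.
#'
#' @param fit A `cib_lmm` from [fit_lmm()].
#' @return A `data.frame`: `term`, `F`, `df1`, `df2`, `p`, `signif`.
#' @export
anova_table <- function(fit) {
  stopifnot(inherits(fit, "cib_lmm"))
  if (!fit$converged)
    stop("model did not converge; refusing to report F tests")
  a <- stats::anova(fit$model, type = 3, ddf = "Satterthwaite")
  out <- data.frame(term = rownames(a), F = a[["F value"]],
                    df1 = a$NumDF, df2 = a$DenDF, p = a[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  out$signif <- ifelse(out$p < 0.05, "*", "")
  rownames(out) <- NULL
  out
}

#' Estimated marginal means
#'
#' Model-adjusted cell means for the requested factors, averaged over the
#' other factors with covariates held at their means.
#'
#' @param fit A `cib_lmm`.
#' @param factors Character vector of factor names (must be model factors,
#'   not covariates).
#' @param df_method Denominator-df method passed to emmeans
#'   (`"satterthwaite"` or `"kenward-roger"`).
#' @return A `data.frame` of EMMs with SEs and the emmeans grid object as
#'   attribute `"emmGrid"`.
#' @export
estimated_marginal_means <- function(fit, factors,
                                     df_method = "satterthwaite") {
  stopifnot(inherits(fit, "cib_lmm"))
  covs <- c("age_ci1", "inter_implant_delay")
  if (any(factors %in% covs))
    stop("usage error: EMM levels are defined for factors, not covariates")
  em <- emmeans::emmeans(fit$model, specs = factors,
                         lmer.df = df_method)
  out <- as.data.frame(em)
  attr(out, "emmGrid") <- em
  attr(out, "df_method") <- df_method
  out
}

#' Tukey-corrected pairwise contrasts of estimated marginal means
#'
#' All pairwise differences within the contrast family, with the Tukey
#' family-wise adjustment and Kenward-Roger denominator df (falling back to
#' Satterthwaite if the pbkrtest package is unavailable).
#'
#' @param emms An EMM table from [estimated_marginal_means()] or a `cib_lmm`
#'   (in which case `factors` selects the family).
#' @param factors Factor(s) defining the contrast family when a model is
#'   given.
#' @param by Optional conditioning factor(s).
#' @return A `data.frame`: `contrast`, `estimate`, `SE`, `df`, `t`,
#'   `p_adjusted`, with the df method as attribute `"df_method"`.
#' @export
pairwise_contrasts <- function(emms, factors = NULL, by = NULL) {
  df_method <- "kenward-roger"
  if (!requireNamespace("pbkrtest", quietly = TRUE))
    df_method <- "satterthwaite"
  if (inherits(emms, "cib_lmm")) {
    stopifnot(!is.null(factors))
    em <- emmeans::emmeans(emms$model, specs = factors, by = by,
                           lmer.df = df_method)
  } else {
    em <- attr(emms, "emmGrid")
    if (is.null(em)) stop("no emmGrid attached; pass the fit instead")
  }
  lv <- nrow(as.data.frame(em))
  if (lv < 2L) return(data.frame())
  pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey"))
  names(pr)[names(pr) == "t.ratio"] <- "t"
  names(pr)[names(pr) == "p.value"] <- "p_adjusted"
  attr(pr, "df_method") <- df_method
  pr
}

#' Ordinary least-squares predictor model
#'
#' Linear model relating an outcome (e.g. future bilateral speech
#' perception) to one or more predictors, covarying for age at first
#' implantation and inter-implant delay. Marginal F tests per term are from
#' single-term deletions.
#'
#' @param data Data frame of complete cases.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor columns.
#' @param covariates Covariates, included on the right-hand side.
#' @return A list of class `cib_lm`: `model`, `terms` (F table),
#'   `r_squared`.
#' @export
fit_predictor_model <- function(data, outcome, predictors,
                                covariates = c("age_ci1",
                                               "inter_implant_delay")) {
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)))
  covariates <- intersect(covariates, names(data))
  rhs <- paste(c(predictors, covariates), collapse = " + ")
  fml <- stats::as.formula(paste0(outcome, " ~ ", rhs))
  d <- data[stats::complete.cases(data[all.vars(fml)]), , drop = FALSE]
  n_terms <- length(predictors) + length(covariates)
  if (nrow(d) < n_terms + 2L)
    stop("insufficient complete cases for the predictor model")
  fit <- stats::lm(fml, data = d)
  alias <- stats::alias(fit)$Complete
  if (!is.null(alias))
    stop("rank deficiency: collinear column(s): ",
         paste(rownames(alias), collapse = ", "))
  dr <- stats::drop1(fit, test = "F")
  terms <- data.frame(term = rownames(dr)[-1], F = dr[["F value"]][-1],
                      p = dr[["Pr(>F)"]][-1], stringsAsFactors = FALSE)
  structure(list(model = fit, terms = terms,
                 r_squared = summary(fit)$r.squared,
                 n = nrow(d)),
            class = "cib_lm")
}
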