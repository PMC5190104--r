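## Survival statistics: optimal cut-point with Monte-Carlo correction,
## dichotomization at validated cut-offs, Kaplan-Meier/log-rank with FDR
## control, Cox regression (univariate and backward-elimination by AIC),
## and the composite prognostic index.

#' Default dichotomization cut-offs for the histopathologic features
#'
#' Training-set-derived thresholds used to split patients into low (group 1,
#' at or below) and high (group 2, above) groups: 287 tumor buds, 16
#' minimal-LVI events, 35 poorly differentiated clusters, 21% tumor:stroma
#' ratio and 35,647 um^2 summed PDC area.  `high_is_risk` records which
#' side carries the excess hazard -- the low tumor:stroma group is the
#' high-risk one, all other features are risk-high.
#'
#' @return data frame of class `CutoffConfig`: `feature`, `threshold`,
#'   `high_is_risk`.
#' @export
cutoff_config <- function() {
  structure(data.frame(
    feature = c("n_buds", "n_minimal_lvi", "n_pdc", "tumor_stroma_pct",
                "area_pdc_um2"),
    threshold = c(287, 16, 35, 21, 35647),
    high_is_risk = c(TRUE, TRUE, TRUE, FALSE, TRUE)),
    class = c("CutoffConfig", "data.frame"))
}

# Vectorized two-group log-rank chi-square for every candidate threshold:
# group 1 = {values <= t}.  Returns one chi-square per candidate (0 for
# degenerate splits with no variance).
logrank_scan <- function(values, time, event, candidates) {
  ord <- order(time)
  t_s <- time[ord]; d_s <- event[ord]; v_s <- values[ord]
  n <- length(t_s)
  Z <- outer(v_s, candidates, "<=") * 1
  # at-risk count in group 1 at each (sorted) time = reverse cumulative sum
  Zc <- apply(Z[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
  first <- !duplicated(t_s)
  grp <- cumsum(first)
  n_at <- (n:1)[first]
  n1 <- Zc[first, , drop = FALSE]
  d_u <- rowsum(d_s, grp)[, 1]
  o1 <- rowsum(d_s * Z, grp)
  p1 <- n1 / n_at
  e1 <- d_u * p1
  vv <- d_u * p1 * (1 - p1) * ifelse(n_at > 1, (n_at - d_u) / (n_at - 1), 0)
  num <- colSums(o1 - e1)^2
  den <- colSums(vv)
  ifelse(den > 0, num / den, 0)
}

#' Optimal survival cut-point with Monte-Carlo permutation correction
#'
#' Scans all candidate thresholds (midpoints between adjacent sorted unique
#' values, restricted to an inner quantile range to avoid degenerate tail
#' splits) and selects the threshold maximizing the two-group log-rank
#' chi-square.  Because the maximum over many candidate splits inflates the
#' naive log-rank p value, a corrected p is computed by Monte-Carlo
#' permutation: the fraction of `n_sim` feature-permuted datasets whose own
#' maximal chi-square reaches the observed one.
#'
#' @param values continuous feature per patient (non-constant).
#' @param time,event survival time and event indicator (>= 2 events).
#' @param cfg list: `n_sim` permutations (default 1000), `range` quantile
#'   pair restricting candidates (default `c(0.1, 0.9)`), `seed`.
#' @return list of class `CutpointResult`: `threshold`, `chisq`, `p_naive`,
#'   `p_corrected` (>= `p_naive`), `n_simulations`, `candidates`.
#' @export
optimal_cutpoint <- function(values, time, event, cfg = list()) {
  n_sim <- cfg$n_sim %||% 1000L
  rng <- cfg$range %||% c(0.1, 0.9)
  seed <- cfg$seed %||% 1L
  if (sum(event) < 2L) stop("need at least 2 events")
  u <- sort(unique(values))
  if (length(u) < 2L) stop("values are constant; no cut-point exists")
  mids <- (u[-1] + u[-length(u)]) / 2
  qs <- stats::quantile(values, rng, names = FALSE)
  cand <- mids[mids >= qs[1] & mids <= qs[2]]
  if (!length(cand)) cand <- mids
  chi <- logrank_scan(values, time, event, cand)
  i <- which.max(chi)
  obs <- chi[i]
  p_naive <- stats::pchisq(obs, df = 1L, lower.tail = FALSE)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_sim)) {
      vmax <- max(logrank_scan(sample(values), time, event, cand))
      if (vmax >= obs) cnt <- cnt + 1L
    }
    cnt
  })
  p_corr <- (exceed + 1L) / (n_sim + 1L)
  structure(list(threshold = cand[i], chisq = obs, p_naive = p_naive,
                 p_corrected = max(p_corr, p_naive),
                 n_simulations = n_sim, candidates = cand),
            class = "CutpointResult")
}

#' Dichotomize patients at validated cut-offs
#'
#' Splits each configured feature at its threshold: group 2 ("high") for
#' values strictly above the threshold, group 1 ("low") at or below.
#' Patients missing a feature get `NA` for that feature and are reported in
#' a message.
#'
#' @param patients data frame carrying the configured feature columns.
#' @param cutoffs a [cutoff_config()]-style data frame.
#' @return data frame with one factor column `<feature>_group` (levels
#'   `low`, `high`) per configured feature present in `patients`.
#' @export
dichotomize <- function(patients, cutoffs = cutoff_config()) {
  out <- data.frame(row.names = seq_len(nrow(patients)))
  for (i in seq_len(nrow(cutoffs))) {
    f <- cutoffs$feature[i]
    if (!f %in% names(patients)) next
    x <- patients[[f]]
    g <- factor(ifelse(x > cutoffs$threshold[i], "high", "low"),
                levels = c("low", "high"))
    if (anyNA(x))
      message("dichotomize: ", sum(is.na(x)), " patient(s) missing ", f)
    out[[paste0(f, "_group")]] <- g
  }
  out
}

#' Kaplan-Meier curves with log-rank test
#'
#' Product-limit survival estimates per group and the two-sided log-rank
#' test.  With a single group only the curves are returned.
#'
#' @param groups group label per patient.
#' @param time,event survival time and event indicator.
#' @return list of class `KMResult`: `fit` (a [survival::survfit] object),
#'   `chisq`, `df`, `p` (NA for a single group).
#' @export
km_logrank <- function(groups, time, event) {
  groups <- as.factor(droplevels(as.factor(groups)))
  df <- data.frame(time = time, event = event, g = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = df)
  if (nlevels(groups) < 2L)
    return(structure(list(fit = fit, chisq = NA_real_, df = 0L, p = NA_real_),
                     class = "KMResult"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  k <- length(sd$n) - 1L
  structure(list(fit = fit, chisq = sd$chisq, df = k,
                 p = stats::pchisq(sd$chisq, k, lower.tail = FALSE)),
            class = "KMResult")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment across a family of p values.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p values, elementwise >= the input, <= 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood hazard ratio with Wald 95% confidence interval and p
#' value for a single covariate (binary flag, ordinal code or continuous
#' value).  Ties are handled by the Efron method.  Monotone-separation
#' non-convergence is reported via `converged = FALSE` rather than NaN.
#'
#' @param x covariate per patient.
#' @param time,event survival time and event indicator (>= 2 events).
#' @return data frame of class `CoxResult`: `term`, `hr`, `ci_lower`,
#'   `ci_upper`, `p`, `converged`, with the model AIC as attribute `aic`.
#' @export
cox_univariate <- function(x, time, event) {
  if (sum(event) < 2L) stop("need at least 2 events")
  if (length(unique(x)) < 2L) stop("covariate is constant")
  df <- data.frame(time = time, event = event, x = x)
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(survival::Surv(time, event) ~ x, data = df,
                      ties = "efron"),
      warning = function(w) {
        if (grepl("converge|infinite", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit)) stop("coxph failed")
  s <- summary(fit)
  converged <- all(is.finite(s$coefficients[, "se(coef)"])) &&
    all(abs(s$coefficients[, "coef"]) < 15)
  res <- data.frame(term = rownames(s$coefficients),
                    hr = s$coefficients[, "exp(coef)"],
                    ci_lower = s$conf.int[, "lower .95"],
                    ci_upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    converged = converged, row.names = NULL)
  attr(res, "aic") <- stats::AIC(fit)
  class(res) <- c("CoxResult", "data.frame")
  res
}

#' Multivariate Cox regression with backward elimination by AIC
#'
#' Starts from the full model and iteratively removes the covariate whose
#' removal most decreases the Akaike Information Criterion, stopping when
#' no removal decreases it further (classical backward elimination, driven
#' by [MASS::stepAIC]).  Collinear covariates are dropped with a warning
#' before fitting.
#'
#' @param data data frame holding the covariates.
#' @param covariates character vector of covariate column names.
#' @param time,event survival time and event indicator.
#' @return list of class `CoxBackwardResult`: `retained` (character),
#'   `coefficients` (`CoxResult`-style data frame for the final model; NULL
#'   when everything is eliminated), `aic`, `trace` (the stepwise anova).
#' @export
cox_backward_aic <- function(data, covariates, time, event) {
  stopifnot(length(covariates) >= 2L, all(covariates %in% names(data)))
  df <- data.frame(data[, covariates, drop = FALSE])
  mm <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad_cols <- colnames(mm)[qrm$pivot[seq.int(qrm$rank + 1L, ncol(mm))]]
    bad <- covariates[vapply(covariates, function(cv)
      any(startsWith(bad_cols, cv)), TRUE)]
    warning("dropping collinear covariate(s): ", paste(bad, collapse = ", "))
    covariates <- setdiff(covariates, bad)
  }
  df <- cbind(data[, covariates, drop = FALSE],
              .time = time, .event = event)
  full <- survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .event) ~",
                            paste(covariates, collapse = " + "))),
    data = df, ties = "efron")
  step <- MASS::stepAIC(full, direction = "backward", trace = 0,
                        scope = list(lower = ~ 1))
  retained_terms <- attr(stats::terms(step), "term.labels")
  if (length(retained_terms) == 0L) {
    res <- structure(list(retained = character(0), coefficients = NULL,
                          aic = stats::AIC(step), trace = step$anova),
                     class = "CoxBackwardResult")
    return(res)
  }
  s <- summary(step)
  coefs <- data.frame(term = rownames(s$coefficients),
                      hr = s$coefficients[, "exp(coef)"],
                      ci_lower = s$conf.int[, "lower .95"],
                      ci_upper = s$conf.int[, "upper .95"],
                      p = s$coefficients[, "Pr(>|z|)"], row.names = NULL)
  structure(list(retained = retained_terms, coefficients = coefs,
                 aic = stats::AIC(step), trace = step$anova),
            class = "CoxBackwardResult")
}

#' Composite prognostic index
#'
#' Combines the three prognostic components -- summed PDC area above its
#' cut-off, pT4 stage, and poor differentiation -- into a score counting
#' the positive flags; patients with two or more flags form the high-risk
#' group.
#'
#' @param patient list or single-row data frame with `area_pdc_um2`,
#'   `pt_stage` (`"pT3"`/`"pT4"`) and `differentiation`
#'   (`"well"`/`"moderate"`/`"poor"`).
#' @param cutoffs a [cutoff_config()]; supplies the AreaPDC threshold.
#' @return list of class `PrognosticIndex`: `flags` (named logical),
#'   `score` (0--3), `group` (`"high"`/`"low"`).
#' @export
build_npi <- function(patient, cutoffs = cutoff_config()) {
  need <- c("area_pdc_um2", "pt_stage", "differentiation")
  miss <- need[!need %in% names(patient)]
  vals <- lapply(need, function(f) patient[[f]])
  if (length(miss) || any(vapply(vals, function(v) is.null(v) || is.na(v), TRUE)))
    stop("prognostic index undefined: missing component(s): ",
         paste(c(miss, need[vapply(vals, function(v) is.null(v) || is.na(v), TRUE)]),
               collapse = ", "))
  thr <- cutoffs$threshold[cutoffs$feature == "area_pdc_um2"]
  flags <- c(area_pdc_high = unname(patient[["area_pdc_um2"]] > thr),
             pt4 = unname(patient[["pt_stage"]] == "pT4"),
             poor_differentiation = unname(patient[["differentiation"]] == "poor"))
  score <- sum(flags)
  structure(list(flags = flags, score = score,
                 group = if (score >= 2L) "high" else "low"),
            class = "PrognosticIndex")
}
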