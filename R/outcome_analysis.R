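# Cohort filtering, endpoint construction, Kaplan-Meier / log-rank comparison
# of immune-defined groups, Cox modelling (delegated to the survival package)
# and the bootstrap variable-retention procedure.

#' @importFrom survival Surv coxph survfit survdiff cox.zph strata
NULL

EXCLUSION_REASONS <- c("stageIV", "not_R0", "preop_radiotherapy",
                       "synchronous", "missing_data", "none")

#' Apply cohort inclusion filters for an endpoint
#'
#' Five-year relapse-free survival (`RFS5`) includes stage I-III patients with
#' complete (R0) resection, excluding pre-operative radiotherapy and
#' synchronous primaries; `OS5` is the separate stage-IV overall-survival
#' analysis (same radiotherapy/synchronous exclusions). The first matching
#' exclusion reason, in the order stage / margin / radiotherapy / synchronous
#' / missing data, is recorded.
#'
#' @param clinical validated clinical data.frame.
#' @param endpoint `"RFS5"` or `"OS5"`.
#' @return data.frame `patient_id`, `endpoint`, `inclusion`,
#'   `exclusion_reason`.
#' @export
apply_cohort_filters <- function(clinical, endpoint = c("RFS5", "OS5")) {
  endpoint <- match.arg(endpoint)
  n <- nrow(clinical)
  reason <- rep("none", n)
  core_missing <- is.na(clinical$tnm_stage) | is.na(clinical$r_status) |
    is.na(clinical$followup_months)
  stage_fail <- if (endpoint == "RFS5") clinical$tnm_stage == "IV"
                else clinical$tnm_stage != "IV"
  checks <- list(
    stageIV = stage_fail,
    not_R0 = if (endpoint == "RFS5") clinical$r_status != "R0" else rep(FALSE, n),
    preop_radiotherapy = clinical$preop_radio %in% TRUE,
    synchronous = clinical$synchronous_primary %in% TRUE,
    missing_data = core_missing)
  for (nm in names(checks)) {
    hit <- checks[[nm]] & reason == "none"
    reason[hit] <- nm
  }
  data.frame(patient_id = clinical$patient_id, endpoint = endpoint,
             inclusion = reason == "none",
             exclusion_reason = factor(reason, levels = EXCLUSION_REASONS),
             stringsAsFactors = FALSE)
}

#' Construct the survival endpoint for each patient
#'
#' `RFS5`: time from surgery to recurrence or death from any cause, censored
#' administratively at 60 months; `OS5`: death from any cause only.
#'
#' @param clinical validated clinical data.frame.
#' @param endpoint `"RFS5"` or `"OS5"`.
#' @param horizon_months administrative censoring horizon (60).
#' @return data.frame `patient_id`, `time_months`, `event`.
#' @export
compute_endpoint <- function(clinical, endpoint = c("RFS5", "OS5"),
                             horizon_months = 60) {
  endpoint <- match.arg(endpoint)
  ev_time <- if (endpoint == "RFS5")
    pmin(clinical$relapse_months, clinical$death_months, na.rm = TRUE)
  else clinical$death_months
  ev_time[is.infinite(ev_time)] <- NA
  cens <- pmin(clinical$followup_months, horizon_months)
  has_event <- !is.na(ev_time) & ev_time <= cens
  time <- ifelse(has_event, ev_time, cens)
  if (any(time <= 0, na.rm = TRUE))
    stop("non-positive event/follow-up time at row ", which(time <= 0)[1])
  data.frame(patient_id = clinical$patient_id, time_months = time,
             event = has_event, stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Delegated to [survival::survfit()] (Greenwood variance); returns the step
#' function plus the survival probability at the horizon.
#'
#' @param times event/censoring times.
#' @param events logical/0-1 event indicators.
#' @param horizon_months time at which survival is reported (60).
#' @return list: `steps` (data.frame `time`, `n_risk`, `n_event`, `surv`,
#'   `std_err`), `s_horizon`, `n`, `n_events`.
#' @export
km_estimate <- function(times, events, horizon_months = 60) {
  stopifnot(length(times) >= 1, length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "log")
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      std_err = fit$std.err * fit$surv)  # Greenwood SE of S(t)
  s_h <- c(1, fit$surv)[findInterval(horizon_months, c(0, fit$time))]
  list(steps = steps, s_horizon = s_h, n = length(times),
       n_events = sum(as.integer(events)))
}

#' Log-rank test across groups
#'
#' @param times,events as in [km_estimate()].
#' @param group group factor (>= 2 non-empty groups).
#' @return list `statistic` (chi-square), `df`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2L || any(table(group) == 0L))
    stop("log-rank test needs >= 2 non-empty groups")
  sd_ <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  df <- length(sd_$n) - 1L
  list(statistic = sd_$chisq, df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Multivariable Cox proportional-hazards fit
#'
#' Complete cases only; Efron ties; optional stratification by cohort.
#' Reports per-covariate hazard ratios with 95% CIs and Wald p values, the
#' concordance index, AIC, and the proportional-hazards diagnostic
#' ([survival::cox.zph()]).
#'
#' @param data model data.frame containing `time_months`, `event`, the
#'   covariates and (optionally) the strata column.
#' @param covariates character vector of covariate column names.
#' @param strata_col optional column name to stratify by (e.g. the cohort).
#' @return list: `coefficients` (data.frame `term`, `hr`, `lower`, `upper`,
#'   `p`), `concordance`, `aic`, `ph_test`, `n`, `n_events`, `fit`.
#' @export
cox_fit <- function(data, covariates, strata_col = NULL) {
  need <- c("time_months", "event", covariates, strata_col)
  cc <- stats::complete.cases(data[, need, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  rhs <- paste(c(covariates,
                 if (!is.null(strata_col)) sprintf("strata(%s)", strata_col)),
               collapse = " + ")
  fml <- stats::as.formula(paste("Surv(time_months, as.integer(event)) ~", rhs))
  fit <- tryCatch(
    survival::coxph(fml, data = d, ties = "efron"),
    error = function(e) stop(sprintf(
      "Cox model failed to converge (n = %d, events = %d): %s",
      nrow(d), sum(d$event), conditionMessage(e))))
  sm <- summary(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      hr = sm$coefficients[, "exp(coef)"],
                      lower = sm$conf.int[, "lower .95"],
                      upper = sm$conf.int[, "upper .95"],
                      p = sm$coefficients[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  list(coefficients = coefs,
       concordance = unname(sm$concordance["C"]),
       aic = stats::AIC(fit),
       ph_test = if (!is.null(zph)) as.data.frame(zph$table) else NULL,
       n = nrow(d), n_events = sum(d$event), fit = fit)
}

#' Bootstrap backward-selection variable retention
#'
#' For each of `B` bootstrap replicates: resample patients with replacement,
#' run p-value-based backward elimination (drop the least significant
#' candidate while its p exceeds `alpha_stay`, default 0.157, the AIC-
#' equivalent stay criterion for one degree of freedom), and record the
#' surviving candidates. Variables retained in at least `retain_threshold` of
#' the replicates are kept. For factor candidates the term's smallest
#' coefficient p value is used.
#'
#' @param data model data.frame (as in [cox_fit()]).
#' @param candidates candidate covariate column names.
#' @param B bootstrap replicates (>= 50).
#' @param retain_threshold retention-frequency cutoff (0.30).
#' @param alpha_stay backward-elimination stay criterion.
#' @param strata_col optional strata column.
#' @param seed RNG seed.
#' @return list: `retention` (data.frame `term`, `frequency`, `retained`),
#'   `B`, `retain_threshold`.
#' @export
bootstrap_selection <- function(data, candidates, B = 1000L,
                                retain_threshold = 0.30, alpha_stay = 0.157,
                                strata_col = NULL, seed = 1L) {
  if (B < 50L) stop("B < 50 bootstrap replicates is not interpretable")
  need <- c("time_months", "event", candidates, strata_col)
  d0 <- data[stats::complete.cases(data[, need, drop = FALSE]), , drop = FALSE]
  set.seed(as.integer(seed))
  kept <- matrix(FALSE, B, length(candidates),
                 dimnames = list(NULL, candidates))
  for (b in seq_len(B)) {
    d <- d0[sample.int(nrow(d0), replace = TRUE), , drop = FALSE]
    active <- candidates
    repeat {
      fit <- tryCatch(cox_fit(d, active, strata_col), error = function(e) NULL)
      if (is.null(fit)) { active <- character(0); break }
      pv <- term_p_values(fit$coefficients, active, d)
      pv <- pv[!is.na(pv)]
      if (!length(pv) || max(pv) <= alpha_stay) break
      active <- setdiff(active, names(pv)[which.max(pv)])
      if (!length(active)) break
    }
    kept[b, active] <- TRUE
  }
  freq <- colMeans(kept)
  list(retention = data.frame(term = candidates, frequency = unname(freq),
                              retained = unname(freq >= retain_threshold),
                              stringsAsFactors = FALSE),
       B = as.integer(B), retain_threshold = retain_threshold)
}

# map coefficient-level p values back to candidate terms (factors contribute
# their smallest coefficient p)
term_p_values <- function(coefs, active, data) {
  vapply(active, function(a) {
    hit <- coefs$term == a | startsWith(coefs$term, a)
    if (!any(hit)) NA_real_ else min(coefs$p[hit])
  }, numeric(1))
}

#' Assemble the relapse-free-survival model frame
#'
#' Joins cohort filters, the constructed endpoint and the recoded model
#' covariates: `mean_cd25_high` is High vs Low/Negative combined,
#' `proximity_significant` is significant vs non-significant (spatially
#' excluded samples become missing), and pT 1 and 2 are combined as the
#' reference (`pT_34` factor), per the reference model's recoding.
#'
#' @param clinical clinical data.frame carrying the feature columns
#'   `ie_cd8_high`, `mean_cd25_class`, `proximity_class`.
#' @return data.frame ready for [cox_fit()] (included patients only).
#' @export
rfs_model_frame <- function(clinical) {
  flt <- apply_cohort_filters(clinical, "RFS5")
  ep <- compute_endpoint(clinical, "RFS5")
  d <- clinical
  d$time_months <- ep$time_months
  d$event <- ep$event
  d$mean_cd25_high <- as.integer(d$mean_cd25_class == "High")
  d$proximity_significant <- ifelse(d$proximity_class == "excluded", NA_integer_,
                                    as.integer(d$proximity_class == "significant"))
  d$ie_cd8_high <- as.integer(d$ie_cd8_high)
  d$pT_34 <- factor(ifelse(d$pT %in% c("1", "2"), "T1/2",
                           paste0("T", d$pT)), levels = c("T1/2", "T3", "T4"))
  d$pN_f <- factor(paste0("N", d$pN), levels = c("N0", "N1", "N2"))
  d$msi_f <- factor(d$msi, levels = c("MSS", "MSI"))
  d$age_c <- d$age - 72
  d[flt$inclusion, , drop = FALSE]
}
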