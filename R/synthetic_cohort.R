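# Synthetic tissue cores, marked point patterns with controllable CD8-Treg
# attraction, marker intensities calibrated to the printed distribution
# statistics of the target cohorts, and clinical tables with
# proportional-hazards survival. The generator's defaults ARE the study
# conditions every property and acceptance test runs under; see the methods
# vignette for the calibration rationale.

#' Synthetic cohort configuration
#'
#' Defaults emulate the target data: 1.0 mm circular cores, right-skewed
#' infiltration densities with correlated FOXP3 and triple-positive Treg
#' abundances, two-component log-normal marker intensities with a Gaussian-
#' copula CD25-FOXP3 dependence inside tp-Tregs, per-sample random effects on
#' the positive-component means (driving the across-sample spread of the
#' per-sample mean intensities), and an exponential proportional-hazards
#' survival model with the multivariable effect sizes of the reference
#' analysis.
#'
#' @param n_samples number of tissue cores.
#' @param core_diameter_mm core diameter (1.0 default; 0.6 alternative).
#' @param cell_density expected cells per mm2.
#' @param proportions expected category proportions (`CD8`, `FOXP3`, `tpTreg`,
#'   `other`), must sum to 1.
#' @param abundance_sd log-scale per-sample random-effect SDs for the category
#'   abundances (right-skews the density distributions).
#' @param abundance_cor correlation of the FOXP3 and tpTreg abundance effects.
#' @param abundance_cor_cd8 correlation of CD8 with each Treg abundance effect.
#' @param theta CD8-Treg attraction strength (0 = complete spatial
#'   randomness of labels, the permutation test's null).
#' @param sigma_um attraction interaction range in micrometres (about 1-2
#'   cell diameters).
#' @param intensity_model per-marker two-component log-normal parameters,
#'   `list(marker = list(neg = c(meanlog, sdlog), pos = c(meanlog, sdlog)))`.
#' @param rho_cell Gaussian-copula correlation of CD25 and FOXP3 intensities
#'   within tp-Treg cells.
#' @param sample_effect_sd named log-scale SDs of the per-sample additive
#'   effects on the tp-Treg positive components (`CD25`, `FOXP3`).
#' @param cd25_bimodal optional `list(delta =, prob =)` mixture shift on the
#'   per-sample CD25 effect, for exercising the bimodal-cutoff logic.
#' @param epithelial_area_frac fraction of the core area occupied by the
#'   central epithelial (cancer) region.
#' @param survival survival-model settings; see [synthetic_survival_defaults()].
#' @param seed master seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 500L,
                             core_diameter_mm = 1.0,
                             cell_density = 1500,
                             proportions = c(CD8 = 0.10, FOXP3 = 0.05,
                                             tpTreg = 0.05, other = 0.80),
                             abundance_sd = c(CD8 = 0.8, FOXP3 = 0.9,
                                              tpTreg = 0.9, other = 0.1),
                             abundance_cor = 0.45,
                             abundance_cor_cd8 = 0.45,
                             theta = 0,
                             sigma_um = 20,
                             intensity_model = default_intensity_model(),
                             rho_cell = 0.90,
                             sample_effect_sd = c(CD25 = 0.273, FOXP3 = 0.5096),
                             cd25_bimodal = NULL,
                             epithelial_area_frac = 0.40,
                             survival = synthetic_survival_defaults(),
                             seed = 20220601L) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8, all(proportions >= 0),
            cell_density > 0, core_diameter_mm > 0, theta >= 0, sigma_um > 0,
            rho_cell >= -1, rho_cell <= 1)
  structure(list(n_samples = as.integer(n_samples),
                 core_diameter_mm = core_diameter_mm,
                 cell_density = cell_density, proportions = proportions,
                 abundance_sd = abundance_sd, abundance_cor = abundance_cor,
                 abundance_cor_cd8 = abundance_cor_cd8,
                 theta = theta, sigma_um = sigma_um,
                 intensity_model = intensity_model, rho_cell = rho_cell,
                 sample_effect_sd = sample_effect_sd,
                 cd25_bimodal = cd25_bimodal,
                 epithelial_area_frac = epithelial_area_frac,
                 survival = survival, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_intensity_model <- function() {
  neg <- c(meanlog = -2.5, sdlog = 0.35)
  list(CD3   = list(neg = neg, pos = c(meanlog = 1.2, sdlog = 0.5)),
       CD8   = list(neg = neg, pos = c(meanlog = 1.2, sdlog = 0.5)),
       CD4   = list(neg = neg, pos = c(meanlog = 1.2, sdlog = 0.5)),
       CD25  = list(neg = neg, pos = c(meanlog = 1.441, sdlog = 0.8)),
       FOXP3 = list(neg = neg, pos = c(meanlog = 0.5955, sdlog = 0.8)))
}

#' Positivity thresholds matched to the default synthetic intensity model
#'
#' The thresholds sit in the valley between the background and positive
#' log-normal components of [default_intensity_model()].
#'
#' @param series_ids series to cover.
#' @return a [marker_thresholds].
#' @export
default_thresholds <- function(series_ids = c("S1", "S2")) {
  tau <- c(CD3 = 0.4, CD8 = 0.4, CD4 = 0.4, CD25 = 0.5, FOXP3 = 0.3)
  marker_thresholds(do.call(rbind, lapply(series_ids, function(s)
    data.frame(series_id = s, marker = names(tau), tau = unname(tau)))))
}

#' @rdname synthetic_config
#' @param baseline_hazard exponential baseline hazard per month.
#' @param effects named log-hazard-ratios for the model covariates.
#' @param prevalences marginal prevalences of the immune features.
#' @param horizon_months administrative censoring horizon.
#' @param dropout_max_months uniform drop-out censoring upper bound.
#' @export
synthetic_survival_defaults <- function(
    baseline_hazard = 0.0065,
    effects = c(ie_cd8_high = log(0.62),
                mean_cd25_high = log(1.35),
                proximity_significant = log(1.36),
                pT3 = log(1.50), pT4 = log(3.00),
                pN1 = log(1.54), pN2 = log(2.34),
                msi = log(0.72), age_per_year = log(1.04)),
    prevalences = c(ie_cd8_high = 0.50, mean_cd25_high = 0.14,
                    mean_cd25_negative = 0.20, proximity_significant = 0.18,
                    proximity_excluded = 0.05),
    horizon_months = 60,
    dropout_max_months = 120) {
  list(baseline_hazard = baseline_hazard, effects = effects,
       prevalences = prevalences, horizon_months = horizon_months,
       dropout_max_months = dropout_max_months)
}

# ---------------------------------------------------------------------------
# point patterns

#' Uniform (binomial) cell positions inside an outline
#'
#' Homogeneous Poisson positions conditional on the number of points:
#' rejection sampling from the bounding box.
#'
#' @param outline a [tissue_outline].
#' @param n number of points.
#' @param seed optional seed (uses the current RNG state when NULL).
#' @return data.frame `x`, `y` in micrometres.
#' @export
sample_positions <- function(outline, n, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  bx <- range(unlist(lapply(outline$rings, `[[`, "x")))
  by <- range(unlist(lapply(outline$rings, `[[`, "y")))
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 64L)
    px <- runif(m, bx[1], bx[2]); py <- runif(m, by[1], by[2])
    ok <- point_in_rings(px, py, outline$rings)
    xs <- c(xs, px[ok]); ys <- c(ys, py[ok])
  }
  data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Assign cell categories with CD8-Treg attraction
#'
#' CD8 labels are placed uniformly at random. Treg labels (tpTreg first, then
#' FOXP3) are placed by weighted sampling without replacement with weight
#' `exp(theta * exp(-d / sigma))`, `d` the distance to the nearest CD8 cell,
#' so `theta = 0` reduces exactly to uniform labelling (the permutation
#' test's null) while the category counts are preserved for any `theta`.
#'
#' @param coords data.frame `x`, `y`.
#' @param counts named integer vector (`CD8`, `FOXP3`, `tpTreg`, `other`)
#'   summing to `nrow(coords)`.
#' @param theta attraction strength (>= 0).
#' @param sigma_um interaction range.
#' @param seed optional seed.
#' @return factor of categories (levels `CD8`, `FOXP3`, `tpTreg`, `other`).
#' @export
assign_labels_with_attraction <- function(coords, counts, theta = 0,
                                          sigma_um = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(coords)
  if (sum(counts) != n) stop("category counts do not sum to the number of cells")
  lab <- rep("other", n)
  avail <- seq_len(n)
  cd8_idx <- if (counts[["CD8"]] > 0) sample(avail, counts[["CD8"]]) else integer(0)
  lab[cd8_idx] <- "CD8"
  avail <- setdiff(avail, cd8_idx)
  w <- rep(1, n)
  if (theta > 0 && length(cd8_idx) > 0 && length(avail) > 0) {
    d2 <- outer(coords$x[avail], coords$x[cd8_idx], "-")^2 +
          outer(coords$y[avail], coords$y[cd8_idx], "-")^2
    dmin <- sqrt(apply(d2, 1L, min))
    w[avail] <- exp(theta * exp(-dmin / sigma_um))
  }
  for (catg in c("tpTreg", "FOXP3")) {
    k <- counts[[catg]]
    if (k > 0) {
      pick <- if (theta > 0) sample(avail, k, prob = w[avail]) else sample(avail, k)
      lab[pick] <- catg
      avail <- setdiff(avail, pick)
    }
  }
  factor(lab, levels = c("CD8", "FOXP3", "tpTreg", "other"))
}

#' Draw per-cell marker intensities
#'
#' Positive markers of each category draw from the positive log-normal
#' component (with the per-sample additive effects on the tp-Treg CD25/FOXP3
#' means), negatives from the background component. Within tp-Tregs, CD25 and
#' FOXP3 come from a Gaussian copula with correlation `rho_cell`.
#'
#' @param categories category factor.
#' @param config a [synthetic_config].
#' @param sample_effects named numeric: additive log-scale effects for this
#'   sample (`CD25`, `FOXP3`).
#' @param seed optional seed.
#' @return data.frame of marker intensity columns (`CD3`, `CD8`, `CD4`,
#'   `CD25`, `FOXP3`).
#' @export
sample_intensities <- function(categories, config,
                               sample_effects = c(CD25 = 0, FOXP3 = 0),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  im <- config$intensity_model
  cat <- as.character(categories)
  n <- length(cat)
  draw <- function(comp, k, shift = 0)
    stats::rlnorm(k, meanlog = comp[["meanlog"]] + shift, sdlog = comp[["sdlog"]])
  out <- data.frame(matrix(0, n, 5, dimnames = list(NULL, names(im))))
  for (m in names(im)) out[[m]] <- draw(im[[m]]$neg, n)
  # T-lineage markers
  tcell <- cat != "other"
  out$CD3[tcell] <- draw(im$CD3$pos, sum(tcell))
  is_cd8 <- cat == "CD8"
  out$CD8[is_cd8] <- draw(im$CD8$pos, sum(is_cd8))
  is_f <- cat == "FOXP3"
  if (any(is_f)) {
    out$FOXP3[is_f] <- draw(im$FOXP3$pos, sum(is_f), sample_effects[["FOXP3"]])
    cd4pos <- is_f & (runif(n) < 0.7)
    out$CD4[cd4pos] <- draw(im$CD4$pos, sum(cd4pos))
  }
  is_tp <- cat == "tpTreg"
  if (any(is_tp)) {
    k <- sum(is_tp)
    out$CD4[is_tp] <- draw(im$CD4$pos, k)
    z1 <- rnorm(k)
    z2 <- config$rho_cell * z1 + sqrt(1 - config$rho_cell^2) * rnorm(k)
    out$CD25[is_tp] <- exp(im$CD25$pos[["meanlog"]] + sample_effects[["CD25"]] +
                             im$CD25$pos[["sdlog"]] * z1)
    out$FOXP3[is_tp] <- exp(im$FOXP3$pos[["meanlog"]] + sample_effects[["FOXP3"]] +
                              im$FOXP3$pos[["sdlog"]] * z2)
  }
  out
}

#' Generate one synthetic tissue core
#'
#' Deterministic given `(config$seed, index)`: the per-sample sub-seed comes
#' from [stream_seeds()].
#'
#' @param config a [synthetic_config].
#' @param index sample index in `1..n_samples`.
#' @param series_id series label stamped on the sample.
#' @return a [sample_cell_table] with outline, region labels, intensities and
#'   attribute `truth` (the generating categories and sample effects).
#' @export
generate_sample <- function(config, index, series_id = "S2") {
  seed_i <- stream_seeds(config$seed, max(config$n_samples, index))[index]
  set.seed(seed_i)
  outline <- core_outline(config$core_diameter_mm)
  area <- outline$area_mm2
  n <- rpois(1L, config$cell_density * area)
  # per-sample abundance random effects (log-normal, FOXP3/tpTreg correlated)
  sd_ <- config$abundance_sd
  z <- rnorm(4L)
  r_ft <- config$abundance_cor; r_c8 <- config$abundance_cor_cd8
  u_cd8 <- sd_[["CD8"]] * z[1]
  base_f <- r_c8 * z[1] + sqrt(1 - r_c8^2) * z[2]
  z3 <- r_ft * z[2] + sqrt(1 - r_ft^2) * z[3]
  base_t <- r_c8 * z[1] + sqrt(1 - r_c8^2) * z3
  u <- c(CD8 = u_cd8, FOXP3 = sd_[["FOXP3"]] * base_f,
         tpTreg = sd_[["tpTreg"]] * base_t, other = sd_[["other"]] * z[4])
  w <- config$proportions * exp(u - sd_[names(config$proportions)]^2 / 2)
  w <- w / sum(w)
  counts <- as.vector(stats::rmultinom(1L, n, w))
  names(counts) <- names(config$proportions)
  coords <- sample_positions(outline, n)
  labels <- assign_labels_with_attraction(coords, counts, config$theta,
                                          config$sigma_um)
  eff <- c(CD25 = rnorm(1L, 0, config$sample_effect_sd[["CD25"]]),
           FOXP3 = rnorm(1L, 0, config$sample_effect_sd[["FOXP3"]]))
  if (!is.null(config$cd25_bimodal) &&
      runif(1L) < config$cd25_bimodal$prob)
    eff[["CD25"]] <- eff[["CD25"]] + config$cd25_bimodal$delta
  intens <- sample_intensities(labels, config, eff)
  r_epi <- config$core_diameter_mm * 1000 / 2 * sqrt(config$epithelial_area_frac)
  region <- ifelse(coords$x^2 + coords$y^2 <= r_epi^2, "epithelial", "stromal")
  cells <- data.frame(cell_id = as.character(seq_len(n)),
                      x = coords$x, y = coords$y, region = region, intens,
                      stringsAsFactors = FALSE)
  tab <- sample_cell_table(sprintf("%s_core%04d", series_id, index), cells,
                           markers = names(config$intensity_model),
                           series_id = series_id,
                           core_diameter_mm = config$core_diameter_mm,
                           outline = outline)
  attr(tab, "truth") <- list(categories = labels, counts = counts,
                             sample_effects = eff, seed = seed_i)
  tab
}

#' Generate a synthetic cohort: samples and/or a clinical table
#'
#' The clinical table draws covariates from marginals shaped like the target
#' cohorts' characteristics and simulates relapse-free survival from an
#' exponential proportional-hazards model whose per-patient hazard uses the
#' configured log-HR effects on the immune features and clinicopathological
#' covariates. Immune feature indicators (`ie_cd8_high`, `mean_cd25_class`,
#' `proximity_class`) are drawn from their configured prevalences; with
#' `generate_cells = TRUE` each patient additionally gets a cell-level
#' [generate_sample()] table (intended for small-to-moderate cohorts).
#'
#' @param config a [synthetic_config].
#' @param generate_cells also generate per-patient cell tables.
#' @return list with `clinical` (data.frame; includes the simulated feature
#'   columns and true event fields) and `samples` (list or NULL).
#' @export
generate_cohort <- function(config, generate_cells = FALSE) {
  set.seed(config$seed)
  n <- config$n_samples
  sv <- config$survival
  prev <- sv$prevalences
  series <- sample(c("S1", "S2"), n, replace = TRUE)
  stage <- sample(STAGE_LEVELS, n, TRUE, prob = c(0.177, 0.389, 0.265, 0.169))
  pT <- sample(PT_LEVELS, n, TRUE, prob = c(0.045, 0.170, 0.687, 0.098))
  pN <- ifelse(stage %in% c("I", "II"), "0",
               sample(PN_LEVELS, n, TRUE, prob = c(0.2, 0.5, 0.3)))
  sex <- sample(SEX_LEVELS, n, TRUE, prob = c(0.519, 0.481))
  age <- pmin(pmax(round(rnorm(n, 72, 11)), 27), 97)
  location <- sample(LOC_LEVELS, n, TRUE, prob = c(0.402, 0.314, 0.261, 0.023))
  msi <- sample(MSI_LEVELS, n, TRUE, prob = c(0.145, 0.855))
  braf <- sample(MUT_LEVELS, n, TRUE, prob = c(0.854, 0.146))
  kras <- sample(MUT_LEVELS, n, TRUE, prob = c(0.69, 0.31))
  r_status <- ifelse(stage == "IV",
                     sample(R_LEVELS, n, TRUE, prob = c(0.20, 0.05, 0.75)),
                     sample(R_LEVELS, n, TRUE, prob = c(0.92, 0.04, 0.04)))
  preop_radio <- location == "rectum" & runif(n) < 0.25
  synchronous_primary <- location == "synchronous"
  adjuvant <- (stage == "III" & runif(n) < 0.5) | runif(n) < 0.05
  ie_cd8_high <- runif(n) < prev[["ie_cd8_high"]]
  u <- runif(n)
  mean_cd25_class <- ifelse(u < prev[["mean_cd25_high"]], "High",
                     ifelse(u < prev[["mean_cd25_high"]] + prev[["mean_cd25_negative"]],
                            "Negative", "Low"))
  v <- runif(n)
  proximity_class <- ifelse(v < prev[["proximity_excluded"]], "excluded",
                     ifelse(v < prev[["proximity_excluded"]] +
                              (1 - prev[["proximity_excluded"]]) * prev[["proximity_significant"]],
                            "significant", "non_significant"))
  eff <- sv$effects
  lp <- eff[["ie_cd8_high"]] * ie_cd8_high +
    eff[["mean_cd25_high"]] * (mean_cd25_class == "High") +
    eff[["proximity_significant"]] * (proximity_class == "significant") +
    eff[["pT3"]] * (pT == "3") + eff[["pT4"]] * (pT == "4") +
    eff[["pN1"]] * (pN == "1") + eff[["pN2"]] * (pN == "2") +
    eff[["msi"]] * (msi == "MSI") +
    eff[["age_per_year"]] * (age - 72)
  t_event <- rexp(n, rate = sv$baseline_hazard * exp(lp))
  dropout <- runif(n, 0, sv$dropout_max_months)
  observed <- t_event <= dropout
  is_relapse <- runif(n) < 0.70
  relapse_months <- ifelse(observed & is_relapse, t_event, NA_real_)
  death_months <- ifelse(observed & !is_relapse, t_event,
                         ifelse(observed & is_relapse,
                                t_event + rexp(n, 0.03), NA_real_))
  followup_months <- ifelse(observed, pmax(t_event, pmin(dropout, 120)), dropout)
  clinical <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)), series_id = series,
    age = age, sex = sex, tnm_stage = stage, pT = pT, pN = pN,
    r_status = r_status, location = location, msi = msi, braf = braf,
    kras = kras, adjuvant_chemo = adjuvant, preop_radio = preop_radio,
    synchronous_primary = synchronous_primary,
    followup_months = followup_months, relapse_months = relapse_months,
    death_months = death_months,
    ie_cd8_high = ie_cd8_high, mean_cd25_class = mean_cd25_class,
    proximity_class = proximity_class,
    stringsAsFactors = FALSE)
  samples <- NULL
  if (generate_cells)
    samples <- lapply(seq_len(n), function(i)
      generate_sample(config, i, series_id = series[i]))
  list(clinical = clinical, samples = samples)
}
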