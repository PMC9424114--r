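make_intensity_table <- function(values, marker = "CD25", series = "S1") {
  n <- length(values)
  df <- data.frame(cell_id = as.character(seq_len(n)), x = seq_len(n), y = 0,
                   region = "unassigned")
  df[[marker]] <- values
  sample_cell_table("s", df, markers = marker, series_id = series)
}

test_that("positivity uses the closed >= threshold and is monotone in tau", {
  tab <- make_intensity_table(c(5.0, 0, 4.999, 10))
  thr <- marker_thresholds(data.frame(series_id = "S1", marker = "CD25", tau = 5.0))
  calls <- call_positivity(tab, thr)
  expect_equal(calls$CD25, c(TRUE, FALSE, FALSE, TRUE))
  # monotone: raising tau never increases the positive count
  set.seed(3)
  vals <- rlnorm(500)
  n_pos <- vapply(sort(runif(20, 0, 4)), function(tau) {
    thr <- marker_thresholds(data.frame(series_id = "S1", marker = "CD25", tau = tau))
    sum(call_positivity(make_intensity_table(vals), thr)$CD25)
  }, integer(1))
  expect_true(all(diff(n_pos) <= 0))
})

test_that("positivity on a known mixture equals the per-cell oracle", {
  set.seed(42)
  member <- rbinom(1000, 1, 0.3) == 1
  vals <- ifelse(member, rlnorm(1000, 1.5, 0.4), rlnorm(1000, -1.5, 0.4))
  tau <- exp(0)  # midpoint between components on the log scale
  thr <- marker_thresholds(data.frame(series_id = "S1", marker = "CD25", tau = tau))
  calls <- call_positivity(make_intensity_table(vals), thr)
  oracle <- vapply(vals, function(v) v >= tau, logical(1))
  expect_equal(calls$CD25, oracle)
  expect_equal(sum(calls$CD25 & member), sum(oracle & member))
  expect_equal(sum(calls$CD25 & !member), sum(oracle & !member))
})

test_that("missing thresholds are a hard error naming the marker", {
  tab <- make_intensity_table(1:3)
  thr <- marker_thresholds(data.frame(series_id = "S9", marker = "CD25", tau = 1))
  expect_error(call_positivity(tab, thr), "no threshold for marker CD25 in series S1")
})

test_that("category assignment follows tpTreg > FOXP3 > CD8 > other over all 16 patterns", {
  grid <- expand.grid(CD4 = c(FALSE, TRUE), CD25 = c(FALSE, TRUE),
                      FOXP3 = c(FALSE, TRUE), CD8 = c(FALSE, TRUE))
  expected <- with(grid, ifelse(CD4 & CD25 & FOXP3, "tpTreg",
                         ifelse(FOXP3, "FOXP3", ifelse(CD8, "CD8", "other"))))
  got <- suppressMessages(assign_category(grid))
  expect_equal(as.character(got), expected)
  # partition: category counts sum to cell count
  expect_equal(sum(table(got)), nrow(grid))
  # conflicts: CD8+ cells co-positive for FOXP3 or the triple
  expect_equal(attr(got, "n_conflicts"),
               sum(grid$CD8 & (grid$FOXP3 | (grid$CD4 & grid$CD25 & grid$FOXP3))))
  expect_equal(as.character(got[grid$CD4 & grid$CD25 & grid$FOXP3 & !grid$CD8]),
               "tpTreg")
})

test_that("infiltration density arithmetic and the log2(x + 1) transform", {
  mk_tab <- function(n_pos, n_tot, diameter) {
    df <- data.frame(cell_id = as.character(seq_len(n_tot)), x = seq_len(n_tot),
                     y = 0, region = "unassigned",
                     CD8 = c(rep(5, n_pos), rep(0, n_tot - n_pos)))
    sample_cell_table("s", df, markers = "CD8", core_diameter_mm = diameter)
  }
  thr <- marker_thresholds(data.frame(series_id = "S1", marker = "CD8", tau = 1))
  # 0 positives in 1 mm2 -> density 0, log2 0
  t0 <- mk_tab(0, 5, 2 / sqrt(pi))  # pi/4 * d^2 = 1 mm2
  expect_equal(infiltration_density(t0, call_positivity(t0, thr), "CD8")$log2_density, 0)
  # 10 positives / 0.5 mm2 -> 20 cells/mm2, log2(21)
  t1 <- mk_tab(10, 12, sqrt(2 / pi))
  d1 <- infiltration_density(t1, call_positivity(t1, thr), "CD8")
  expect_equal(d1$density, 20, tolerance = 1e-12)
  expect_equal(d1$log2_density, log2(21), tolerance = 1e-12)
  # full 1.0 mm disc, 100 positives -> ~127.32 cells/mm2
  t2 <- mk_tab(100, 100, 1.0)
  d2 <- infiltration_density(t2, call_positivity(t2, thr), "CD8")
  expect_equal(d2$density, 100 / (pi / 4), tolerance = 1e-12)
  expect_equal(d2$log2_density, 7.0036, tolerance = 1e-4)
})

test_that("compartment densities need regions and mask areas; counts split by region", {
  df <- data.frame(cell_id = as.character(1:10), x = 1:10, y = 0,
                   region = rep(c("epithelial", "stromal"), each = 5),
                   CD8 = c(rep(5, 3), rep(0, 2), rep(5, 4), 0))
  tab <- sample_cell_table("s", df, markers = "CD8")
  thr <- marker_thresholds(data.frame(series_id = "S1", marker = "CD8", tau = 1))
  calls <- call_positivity(tab, thr)
  areas <- c(epithelial = 0.3, stromal = 0.5)
  ie <- infiltration_density(tab, calls, "CD8", "intraepithelial",
                             compartment_areas = areas)
  st <- infiltration_density(tab, calls, "CD8", "stromal", compartment_areas = areas)
  expect_equal(ie$n_pos, 3L); expect_equal(st$n_pos, 4L)
  expect_equal(ie$density, 10)
  expect_equal(ie$n_pos + st$n_pos,
               infiltration_density(tab, calls, "CD8")$n_pos)
  expect_error(infiltration_density(tab, calls, "CD8", "stromal"),
               "compartment areas")
  df$region <- "unassigned"
  tab2 <- sample_cell_table("s", df, markers = "CD8")
  expect_error(infiltration_density(tab2, calls, "CD8", "stromal",
                                    compartment_areas = areas), "region labels")
})

test_that("cancer fractions equal counting oracles", {
  df <- data.frame(cell_id = as.character(1:100), x = 1:100, y = 0,
                   region = c(rep("epithelial", 30), rep("stromal", 70)), CD8 = 0)
  tab <- sample_cell_table("s", df, markers = "CD8")
  cf <- cancer_fractions(tab, region_areas = c(epithelial = 0.2, stromal = 0.6))
  expect_equal(cf$cell_fraction, 0.30)
  expect_equal(cf$area_fraction, 0.25)
  set.seed(8)
  df$region <- sample(c("epithelial", "stromal"), 100, TRUE)
  tab2 <- sample_cell_table("s", df, markers = "CD8")
  expect_equal(cancer_fractions(tab2)$cell_fraction, mean(df$region == "epithelial"))
  df0 <- df[0, ]
  expect_error(cancer_fractions(sample_cell_table("s", df0, markers = "CD8")),
               "no cells")
})

test_that("median dichotomization is strict > with documented tie policy", {
  expect_equal(as.character(dichotomize(c(1, 2, 3, 4))), c("Low", "Low", "High", "High"))
  expect_warning(lab <- dichotomize(c(2, 2, 2)), "identical")
  expect_equal(as.character(lab), rep("Low", 3))
  set.seed(5)
  x <- rnorm(1001)
  lab <- dichotomize(x)
  expect_equal(as.character(lab), ifelse(x > median(x), "High", "Low"))
  # odd-length distinct sample: exactly floor(n/2) High
  expect_equal(sum(lab == "High"), 500L)
})

test_that("Treg subgrouping uses the nearest-rank 75th percentile with strict >", {
  mk <- function(cd25, foxp3, id = "s1") {
    n <- length(cd25)
    df <- data.frame(cell_id = as.character(seq_len(n)), x = seq_len(n),
                     y = rep(0, n), region = rep("unassigned", n),
                     CD3 = rep(5, n), CD8 = rep(0, n), CD4 = rep(5, n),
                     CD25 = cd25, FOXP3 = foxp3)
    sample_cell_table(id, df, markers = c("CD3", "CD8", "CD4", "CD25", "FOXP3"))
  }
  cats <- function(tab) assign_category(call_positivity(tab, default_thresholds()))
  # intensities 1..100 -> threshold 75 (nearest rank), High = 76..100
  tab <- mk(1:100, 1:100)
  prof <- treg_subgroup_profile(list(tab), list(cats(tab)))
  expect_equal(prof$thr_cd25, oracle_percentile(1:100, 0.75))
  expect_equal(prof$thr_cd25, 75)
  expect_equal(prof$n_hh, 25L)
  expect_equal(prof$n_ll, 75L)
  expect_equal(prof$n_hh + prof$n_hl + prof$n_lh + prof$n_ll, prof$n_tpTreg)
  # all-identical intensities: threshold equals them, High groups empty
  tab2 <- mk(rep(4, 9), rep(2, 9))
  prof2 <- treg_subgroup_profile(list(tab2), list(cats(tab2)))
  expect_equal(prof2$n_hh + prof2$n_hl + prof2$n_lh, 0L)
  expect_equal(prof2$mean_cd25, 4)
  # no tp-Tregs: zero profile with absent means
  tab3 <- mk(numeric(0), numeric(0))
  prof3 <- treg_subgroup_profile(list(tab3), list(cats(tab3)))
  expect_equal(prof3$n_tpTreg, 0L)
  expect_true(is.na(prof3$mean_cd25))
})

test_that("pooled marginal High fractions approach 25% from below on large pools", {
  set.seed(21)
  n <- 20000
  df <- data.frame(cell_id = as.character(1:n), x = 1:n, y = 0,
                   region = "unassigned", CD3 = 5, CD8 = 0, CD4 = 5,
                   CD25 = rlnorm(n, 1.4, 0.8), FOXP3 = rlnorm(n, 0.6, 0.8))
  tab <- sample_cell_table("big", df, markers = c("CD3", "CD8", "CD4", "CD25", "FOXP3"))
  prof <- treg_subgroup_profile(list(tab),
                                list(assign_category(call_positivity(tab, default_thresholds()))))
  hi_cd25 <- (prof$n_hh + prof$n_hl) / prof$n_tpTreg
  hi_fox <- (prof$n_hh + prof$n_lh) / prof$n_tpTreg
  expect_lte(hi_cd25, 0.25); expect_lte(hi_fox, 0.25)
  expect_equal(hi_cd25, 0.25, tolerance = 0.01)
  expect_equal(hi_fox, 0.25, tolerance = 0.01)
})

test_that("mean-CD25 classification: Negative, manual cutoff, and the KDE valley", {
  prof <- data.frame(sample_id = c("a", "b", "c"), series_id = "S1",
                     n_tpTreg = c(0L, 10L, 10L),
                     mean_cd25 = c(NA, 9.0, 6.9))
  out <- suppressMessages(classify_mean_cd25(prof, cutoff = 7.0))
  expect_equal(as.character(out$mean_cd25_class), c("Negative", "High", "Low"))
  # bimodal means: auto cutoff lands in the valley, vs a dense-grid KDE oracle
  set.seed(9)
  means <- c(rnorm(60, 5, 0.5), rnorm(60, 9, 0.5))
  prof2 <- data.frame(sample_id = as.character(1:120), series_id = "S1",
                      n_tpTreg = 10L, mean_cd25 = means)
  out2 <- suppressMessages(classify_mean_cd25(prof2, cutoff = "auto"))
  cut_auto <- out2$mean_cd25_cutoff[1]
  expect_equal(cut_auto, 7, tolerance = 0.5)
  bw <- stats::bw.nrd0(means)
  grid <- seq(6, 8, length.out = 4001)
  kde <- vapply(grid, function(g) mean(dnorm((g - means) / bw)) / bw, numeric(1))
  expect_equal(cut_auto, grid[which.min(kde)], tolerance = 0.05)
  # unimodal refuses; too few samples refuses
  prof3 <- data.frame(sample_id = as.character(1:60), series_id = "S1",
                      n_tpTreg = 10L, mean_cd25 = rnorm(60, 6, 0.3))
  expect_error(suppressMessages(classify_mean_cd25(prof3, "auto")), "unimodal")
  expect_error(suppressMessages(classify_mean_cd25(prof2[1:20, ], "auto")), ">= 30")
})
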