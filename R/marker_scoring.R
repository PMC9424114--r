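# Per-cell positivity calling, phenotype assignment, infiltration density
# scoring and triple-positive Treg profiling.
#
# Conventions used throughout (documented, uniform):
#   * positivity is intensity >= tau (closed threshold);
#   * every High/Low dichotomization is strict ">" against its cutoff, so
#     boundary values fall Low;
#   * percentiles are nearest-rank order statistics (see nearest_rank()).

#' Marker thresholds
#'
#' Positivity thresholds on mean fluorescence intensity, set per patient
#' series and stain. Thresholds are required inputs: they are never derived
#' silently from the data (see [suggest_thresholds()] for an explicit helper).
#'
#' @param df data.frame with columns `series_id`, `marker`, `tau` (and
#'   optionally `stain_id`).
#' @return object of class `marker_thresholds`.
#' @export
marker_thresholds <- function(df) {
  stopifnot(all(c("series_id", "marker", "tau") %in% names(df)))
  if (any(df$tau < 0)) stop("thresholds must be non-negative")
  if (is.null(df$stain_id)) df$stain_id <- "default"
  class(df) <- c("marker_thresholds", "data.frame")
  df
}

#' @rdname marker_thresholds
#' @param path YAML file: `series -> marker -> tau` (or
#'   `series -> stain -> marker -> tau`).
#' @export
read_thresholds <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- list()
  for (ser in names(y)) {
    node <- y[[ser]]
    if (all(vapply(node, is.list, logical(1)))) {
      for (st in names(node))
        for (m in names(node[[st]]))
          rows[[length(rows) + 1L]] <- data.frame(series_id = ser, stain_id = st,
                                                  marker = m, tau = node[[st]][[m]])
    } else {
      for (m in names(node))
        rows[[length(rows) + 1L]] <- data.frame(series_id = ser, stain_id = "default",
                                                marker = m, tau = node[[m]])
    }
  }
  marker_thresholds(do.call(rbind, rows))
}

#' Suggest positivity thresholds from an intensity mixture valley
#'
#' Fits a two-component normal mixture to log(intensity + 1) per marker and
#' proposes the density valley between the component means. The suggestion is
#' only ever applied explicitly by the user.
#'
#' @param table a [sample_cell_table] (or pooled cell data.frame).
#' @param markers markers to examine.
#' @return data.frame with a suggested `tau` per marker.
#' @export
suggest_thresholds <- function(table, markers = table$markers) {
  cells <- if (inherits(table, "sample_cell_table")) table$cells else table
  out <- lapply(markers, function(m) {
    lx <- log(cells[[m]] + 1)
    km <- stats::kmeans(lx, centers = 2L, nstart = 5L)
    lo <- which.min(km$centers); hi <- which.max(km$centers)
    grid <- seq(km$centers[lo], km$centers[hi], length.out = 512L)
    dens <- stats::density(lx, bw = "nrd0")
    valley <- grid[which.min(stats::approx(dens$x, dens$y, xout = grid)$y)]
    data.frame(marker = m, tau = exp(valley) - 1)
  })
  do.call(rbind, out)
}

#' Call per-cell marker positivity
#'
#' A cell is positive for a marker when its mean intensity is greater than or
#' equal to the series-specific threshold.
#'
#' @param table a [sample_cell_table].
#' @param thresholds a [marker_thresholds].
#' @param markers markers to call (default: all markers on the table).
#' @return data.frame of logical call columns, one per marker, one row per
#'   cell, with attribute `n_pos` (named positive counts).
#' @export
call_positivity <- function(table, thresholds, markers = table$markers) {
  stopifnot(inherits(table, "sample_cell_table"),
            inherits(thresholds, "marker_thresholds"))
  calls <- data.frame(row.names = seq_len(nrow(table$cells)))
  for (m in markers) {
    hit <- thresholds$series_id == table$series_id & thresholds$marker == m
    if (!any(hit))
      stop(sprintf("no threshold for marker %s in series %s", m, table$series_id))
    tau <- thresholds$tau[which(hit)[1]]
    calls[[m]] <- table$cells[[m]] >= tau
  }
  attr(calls, "n_pos") <- vapply(calls, sum, integer(1))
  attr(calls, "sample_id") <- table$sample_id
  calls
}

#' Assign each cell to one of four mutually exclusive categories
#'
#' Categories: `tpTreg` (CD4+/CD25+/FOXP3+), `FOXP3` (FOXP3+ not tp-Treg),
#' `CD8` (CD8+ and neither of the former), `other`. Precedence
#' tpTreg > FOXP3 > CD8 > other resolves rare co-positive cells; the number of
#' precedence conflicts (cells positive for CD8 and for FOXP3 or the triple)
#' is logged and returned as an attribute.
#'
#' @param calls call data.frame from [call_positivity()] with columns `CD4`,
#'   `CD25`, `FOXP3`, `CD8`.
#' @return factor of categories with levels `CD8`, `FOXP3`, `tpTreg`, `other`
#'   and attribute `n_conflicts`.
#' @export
assign_category <- function(calls) {
  need <- c("CD4", "CD25", "FOXP3", "CD8")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("calls missing marker(s): ", paste(miss, collapse = ", "))
  tp <- calls$CD4 & calls$CD25 & calls$FOXP3
  cat <- ifelse(tp, "tpTreg",
         ifelse(calls$FOXP3, "FOXP3",
         ifelse(calls$CD8, "CD8", "other")))
  n_conflicts <- sum(calls$CD8 & (calls$FOXP3 | tp))
  if (n_conflicts > 0)
    ts_log("assign_category", "%d precedence conflict(s) (CD8+ co-positive cells)",
           n_conflicts)
  structure(factor(cat, levels = c("CD8", "FOXP3", "tpTreg", "other")),
            n_conflicts = n_conflicts)
}

#' Infiltration density score
#'
#' Positive cells per square millimetre of tissue, with the log2(density + 1)
#' transform used for all downstream analysis (the +1 keeps samples with zero
#' positive cells).
#'
#' @param table a [sample_cell_table].
#' @param calls calls from [call_positivity()] (for `type = "marker"`) or a
#'   category factor from [assign_category()] (for `type = "category"`).
#' @param target marker name or category level.
#' @param compartment `"whole"`, `"intraepithelial"` or `"stromal"`.
#' @param type how to interpret `target`.
#' @param compartment_areas named numeric (mm2) with entries `epithelial` and
#'   `stromal`, required for compartment scores (they come from the tissue
#'   segmentation mask, not from cell counts).
#' @return one-row data.frame: `sample_id`, `target`, `compartment`, `n_pos`,
#'   `area_mm2`, `density`, `log2_density`.
#' @export
infiltration_density <- function(table, calls, target,
                                 compartment = c("whole", "intraepithelial", "stromal"),
                                 type = c("marker", "category"),
                                 compartment_areas = NULL) {
  compartment <- match.arg(compartment)
  type <- match.arg(type)
  stopifnot(inherits(table, "sample_cell_table"))
  pos <- if (type == "marker") {
    if (is.null(calls[[target]])) stop("no call column for marker ", target)
    calls[[target]]
  } else {
    as.character(calls) == target
  }
  if (compartment != "whole") {
    reg <- table$cells$region
    if (all(reg == "unassigned"))
      stop("compartment score requested but the table has no region labels")
    keep <- reg == if (compartment == "intraepithelial") "epithelial" else "stromal"
    pos <- pos & keep
    if (is.null(compartment_areas))
      stop("compartment score requires mask-derived compartment areas")
    area <- unname(compartment_areas[[
      if (compartment == "intraepithelial") "epithelial" else "stromal"]])
  } else {
    area <- if (!is.null(table$outline)) table$outline$area_mm2
            else pi / 4 * table$core_diameter_mm^2
  }
  if (is.null(area) || !is.finite(area) || area <= 0) stop("zero or missing tissue area")
  n_pos <- sum(pos)
  dens <- n_pos / area
  data.frame(sample_id = table$sample_id, target = target, compartment = compartment,
             n_pos = n_pos, area_mm2 = area, density = dens,
             log2_density = log2(dens + 1), stringsAsFactors = FALSE)
}

#' Cancer cell and area fractions
#'
#' Fraction of cells in the epithelial cancer region, and fraction of tissue
#' area occupied by it.
#'
#' @param table a [sample_cell_table] with region labels.
#' @param region_areas optional named numeric (mm2) with `epithelial` and
#'   `stromal` mask areas; when absent the area fraction is `NA`.
#' @return one-row data.frame `cell_fraction`, `area_fraction`.
#' @export
cancer_fractions <- function(table, region_areas = NULL) {
  cells <- table$cells
  if (nrow(cells) == 0L) stop("no cells in sample ", table$sample_id)
  cf <- mean(cells$region == "epithelial")
  af <- if (!is.null(region_areas)) {
    tot <- sum(unlist(region_areas))
    unname(region_areas[["epithelial"]]) / tot
  } else NA_real_
  data.frame(sample_id = table$sample_id, cell_fraction = cf, area_fraction = af)
}

#' Dichotomize scores into High/Low
#'
#' High iff score is strictly greater than the cutoff; with `cutoff =
#' "median"` the cutoff is the median across the supplied scores (so boundary
#' and all-tied inputs fall Low).
#'
#' @param scores numeric vector (log2 density scores).
#' @param cutoff numeric value or `"median"`.
#' @return factor with levels `Low`, `High` and attribute `cutoff`.
#' @export
dichotomize <- function(scores, cutoff = "median") {
  if (identical(cutoff, "median")) {
    if (length(scores) < 2L) stop("median dichotomization needs >= 2 samples")
    cutoff <- stats::median(scores)
    if (all(scores == scores[1]))
      warning("all scores identical; every sample labelled Low")
  }
  lab <- factor(ifelse(scores > cutoff, "High", "Low"), levels = c("Low", "High"))
  attr(lab, "cutoff") <- cutoff
  lab
}

#' Triple-positive Treg subpopulation profile
#'
#' Splits each sample's triple-positive Tregs into the 2x2 of CD25
#' {High, Low} x FOXP3 {High, Low}, using the nearest-rank 75th percentile of
#' the positive-cell intensities as the threshold for both markers (strict `>`
#' for High). The percentile population is pooled per series by default; the
#' per-sample alternative is available via `scope`.
#'
#' @param tables list of [sample_cell_table].
#' @param categories list of category factors (from [assign_category()]),
#'   parallel to `tables`.
#' @param scope `"pooled"` (per series, default) or `"per_sample"`.
#' @return data.frame, one row per sample: `n_tpTreg`, the four subgroup
#'   counts (`n_hh`, `n_hl`, `n_lh`, `n_ll`; CD25 first), the thresholds used,
#'   `mean_cd25` / `mean_foxp3` (NA when no tp-Tregs). Attribute
#'   `joint_high_fraction`: pooled fraction of CD25-High/FOXP3-High tp-Tregs.
#' @export
treg_subgroup_profile <- function(tables, categories, scope = c("pooled", "per_sample")) {
  scope <- match.arg(scope)
  stopifnot(length(tables) == length(categories))
  ser <- vapply(tables, `[[`, "", "series_id")
  tp_int <- lapply(seq_along(tables), function(i) {
    sel <- as.character(categories[[i]]) == "tpTreg"
    data.frame(cd25 = tables[[i]]$cells$CD25[sel], foxp3 = tables[[i]]$cells$FOXP3[sel])
  })
  thr <- list()
  for (s in unique(ser)) {
    pool <- do.call(rbind, tp_int[ser == s])
    thr[[s]] <- if (nrow(pool) > 0)
      c(cd25 = nearest_rank(pool$cd25, 0.75), foxp3 = nearest_rank(pool$foxp3, 0.75))
    else c(cd25 = NA_real_, foxp3 = NA_real_)
  }
  rows <- lapply(seq_along(tables), function(i) {
    ti <- tp_int[[i]]
    th <- if (scope == "pooled") thr[[ser[i]]]
          else if (nrow(ti) > 0) c(cd25 = nearest_rank(ti$cd25, 0.75),
                                   foxp3 = nearest_rank(ti$foxp3, 0.75))
          else c(cd25 = NA_real_, foxp3 = NA_real_)
    n <- nrow(ti)
    hi_c <- ti$cd25 > th[["cd25"]]; hi_f <- ti$foxp3 > th[["foxp3"]]
    data.frame(sample_id = tables[[i]]$sample_id, series_id = ser[i],
               n_tpTreg = n,
               n_hh = sum(hi_c & hi_f), n_hl = sum(hi_c & !hi_f),
               n_lh = sum(!hi_c & hi_f), n_ll = sum(!hi_c & !hi_f),
               thr_cd25 = th[["cd25"]], thr_foxp3 = th[["foxp3"]],
               mean_cd25 = if (n > 0) mean(ti$cd25) else NA_real_,
               mean_foxp3 = if (n > 0) mean(ti$foxp3) else NA_real_,
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  tot <- sum(prof$n_tpTreg)
  attr(prof, "joint_high_fraction") <- if (tot > 0) sum(prof$n_hh) / tot else NA_real_
  prof
}

#' Classify samples by mean CD25 expression in triple-positive Tregs
#'
#' Per-sample class: `High` iff the sample's mean CD25 across its tp-Tregs is
#' strictly above the series cutoff; `Negative` for samples with no tp-Tregs.
#' `cutoff = "auto"` places the cutoff at the deepest local minimum of a
#' Gaussian kernel density estimate (Silverman bandwidth) between the two
#' largest modes of the per-sample means, echoing the chosen value for manual
#' confirmation; it refuses unimodal densities and requires at least 30
#' samples with tp-Tregs.
#'
#' @param profiles data.frame from [treg_subgroup_profile()].
#' @param cutoff numeric value, or `"auto"`.
#' @return `profiles` with columns `mean_cd25_cutoff` and `mean_cd25_class`
#'   (factor `Negative`/`Low`/`High`).
#' @export
classify_mean_cd25 <- function(profiles, cutoff = "auto") {
  out <- profiles
  out$mean_cd25_cutoff <- NA_real_
  out$mean_cd25_class <- factor(rep("Negative", nrow(out)),
                                levels = c("Negative", "Low", "High"))
  for (s in unique(out$series_id)) {
    sel <- out$series_id == s
    means <- out$mean_cd25[sel & out$n_tpTreg > 0]
    cut_s <- if (identical(cutoff, "auto")) {
      if (length(means) < 30L)
        stop("auto cutoff requires >= 30 samples with tp-Tregs in series ", s)
      kde_valley_cutoff(means)
    } else cutoff
    ts_log("classify_mean_cd25", "series %s: mean-CD25 cutoff %.4f", s, cut_s)
    out$mean_cd25_cutoff[sel] <- cut_s
    cls <- ifelse(out$n_tpTreg[sel] == 0, "Negative",
                  ifelse(out$mean_cd25[sel] > cut_s, "High", "Low"))
    out$mean_cd25_class[sel] <- factor(cls, levels = levels(out$mean_cd25_class))
  }
  out
}

# Deepest KDE local minimum between the two largest modes; errors when the
# density has fewer than two modes.
kde_valley_cutoff <- function(x) {
  d <- stats::density(x, bw = "nrd0", n = 1024L)
  y <- d$y
  up <- which(diff(sign(diff(y))) < 0) + 1L   # local maxima
  if (length(up) < 2L)
    stop("mean-CD25 density is unimodal; supply a manual cutoff")
  top2 <- sort(up[order(y[up], decreasing = TRUE)][1:2])
  seg <- seq(top2[1], top2[2])
  mins <- which(diff(sign(diff(y[seg]))) > 0) + 1L
  idx <- if (length(mins)) seg[mins[which.min(y[seg][mins])]]
         else seg[which.min(y[seg])]
  d$x[idx]
}
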