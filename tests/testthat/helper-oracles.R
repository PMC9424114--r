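# Test-side oracles, independent of the package's tessellation path.

# Brute-force Delaunay adjacency by the empty-circumcircle criterion over all
# point triples. O(n^4); for small n only. Returns a sorted 2-column matrix of
# pairs (i < j).
brute_delaunay_pairs <- function(x, y) {
  n <- length(x)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 2L)) for (j in seq(i + 1L, n - 1L)) for (k in seq(j + 1L, n)) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    if (all((x[others] - ux)^2 + (y[others] - uy)^2 > r2 * (1 + 1e-12))) {
      adj[i, j] <- adj[j, k] <- adj[i, k] <- TRUE
    }
  }
  which(adj, arr.ind = TRUE)
}

# Nearest-rank percentile oracle: plain sort + index arithmetic, kept separate
# from the package's implementation on purpose.
oracle_percentile <- function(x, q) sort(x)[ceiling(q * length(x))]

# Hand-computed Kaplan-Meier product-limit for a small dataset: sequential
# risk-set computation.
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (r in seq_along(ut)) {
    at_risk <- sum(times >= ut[r])
    d <- sum(times == ut[r] & events == 1)
    s <- s * (1 - d / at_risk)
    out$surv[r] <- s
  }
  out
}

# Uniform points in a disc of given diameter (mm), centred at origin, um units.
runif_disc <- function(n, diameter_mm = 1.0) {
  r <- diameter_mm * 1000 / 2
  th <- runif(n, 0, 2 * pi)
  rr <- r * sqrt(runif(n))
  data.frame(x = rr * cos(th), y = rr * sin(th))
}

# Small synthetic cell table built directly (no generator): k cells with given
# categories placed at given coordinates, intensities set to make the default
# thresholds recover the categories exactly.
toy_cell_table <- function(coords, categories, sample_id = "toy",
                           series_id = "S1", outline = NULL) {
  n <- nrow(coords)
  lowv <- 0.01
  df <- data.frame(cell_id = as.character(seq_len(n)),
                   x = coords$x, y = coords$y, region = "unassigned",
                   CD3 = lowv, CD8 = lowv, CD4 = lowv, CD25 = lowv, FOXP3 = lowv)
  df$CD8[categories == "CD8"] <- 5
  df$CD3[categories != "other"] <- 5
  df$FOXP3[categories %in% c("FOXP3", "tpTreg")] <- 5
  df$CD4[categories == "tpTreg"] <- 5
  df$CD25[categories == "tpTreg"] <- 5
  sample_cell_table(sample_id, df, markers = c("CD3", "CD8", "CD4", "CD25", "FOXP3"),
                    series_id = series_id, outline = outline)
}

# 10-row toy clinical table covering every exclusion rule.
toy_clinical <- function() {
  data.frame(
    patient_id = sprintf("T%02d", 1:10),
    age = 70, sex = "female",
    tnm_stage = c("II", "IV", "II", "III", "I", "II", "III", "II", "IV", "I"),
    pT = "3", pN = "0",
    r_status = c("R0", "R0", "R1", "R2", "R0", "R0", "R0", "R0", "R2", "R0"),
    location = c("left", "right", "left", "left", "rectum", "rectum",
                 "synchronous", "left", "left", "right"),
    msi = "MSS", braf = "wt", kras = "wt",
    adjuvant_chemo = FALSE,
    preop_radio = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    synchronous_primary = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                            FALSE, FALSE, FALSE),
    followup_months = c(70, 40, 50, 30, 65, 80, 45, 55, 20, 75),
    relapse_months = c(NA, 12, NA, 8, NA, 24, NA, NA, NA, NA),
    death_months = c(NA, 30, 44, 20, NA, 40, NA, NA, 15, NA),
    stringsAsFactors = FALSE)
}
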