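test_that("degenerate tessellations: one node, two nodes, coincident nodes", {
  o <- core_outline(1.0)
  g1 <- voronoi_neighbor_graph(data.frame(x = 0, y = 0), o)
  expect_equal(nrow(g1$edges), 0L)
  g2 <- voronoi_neighbor_graph(data.frame(x = c(-100, 100), y = c(0, 0)), o)
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(unname(g2$edges[1, ]), c(1L, 2L))
  # exact duplicates get jittered (and logged), not dropped
  expect_message(
    g3 <- voronoi_neighbor_graph(data.frame(x = c(0, 0, 100), y = c(0, 0, 0)), o),
    "jittered 1 duplicate")
  expect_equal(g3$n, 3L)
  expect_equal(g3$n_jittered, 1L)
})

test_that("neighbor graphs are symmetric-by-construction, simple and planar", {
  set.seed(14)
  o <- core_outline(1.0)
  for (rep in 1:5) {
    pts <- runif_disc(80)
    g <- voronoi_neighbor_graph(pts, o)
    expect_true(all(g$edges[, 1] < g$edges[, 2]))          # no self-edges
    expect_equal(anyDuplicated(paste(g$edges[, 1], g$edges[, 2])), 0L)
    expect_lte(nrow(g$edges), 3L * g$n - 6L)               # planarity bound
    expect_true(all(g$shared_length > 1e-6))
  }
})

test_that("outline clipping breaks adjacency across holes", {
  # two columns of cells separated by a full-height slit in the tissue
  pts <- data.frame(x = c(rep(100, 5), rep(300, 5)), y = rep(seq(50, 450, 100), 2))
  outer <- list(x = c(0, 400, 400, 0), y = c(0, 0, 500, 500))
  slit <- list(x = c(150, 250, 250, 150), y = c(0, 0, 500, 500))
  o_slit <- tissue_outline(list(outer, slit))
  o_full <- tissue_outline(list(outer))
  g_full <- voronoi_neighbor_graph(pts, o_full)
  g_slit <- voronoi_neighbor_graph(pts, o_slit)
  crosses <- function(g) sum(g$edges[, 1] <= 5 & g$edges[, 2] > 5)
  expect_gt(crosses(g_full), 0L)
  expect_equal(crosses(g_slit), 0L)
})

test_that("interior Voronoi adjacency matches the brute-force Delaunay oracle", {
  set.seed(31)
  o <- core_outline(1.0)
  for (rep in 1:15) {
    pts <- runif_disc(25)
    g <- voronoi_neighbor_graph(pts, o)
    del <- brute_delaunay_pairs(pts$x, pts$y)
    del_keys <- paste(pmin(del[, 1], del[, 2]), pmax(del[, 1], del[, 2]))
    g_keys <- paste(g$edges[, 1], g$edges[, 2])
    # clipping can only destroy Delaunay adjacency, never create it
    expect_true(all(g_keys %in% del_keys))
    # pairs whose Voronoi segment is untouched by clipping must be present
    dd <- deldir::deldir(pts$x, pts$y, rw = c(-600, 600, -600, 600))
    sg <- dd$dirsgs
    interior <- (sg$x1^2 + sg$y1^2 < 500^2 * 0.998) &
      (sg$x2^2 + sg$y2^2 < 500^2 * 0.998) & !sg$bp1 & !sg$bp2
    keys_int <- paste(pmin(sg$ind1, sg$ind2), pmax(sg$ind1, sg$ind2))[interior]
    expect_true(all(keys_int %in% g_keys))
    expect_true(all(keys_int %in% del_keys))
  }
})

test_that("outline fallback buffers the convex hull and contains every cell", {
  set.seed(4)
  pts <- runif_disc(100)
  tab <- toy_cell_table(pts, rep("other", 100))
  expect_message(o <- build_outline(tab), "convex hull fallback")
  inside <- sp::point.in.polygon(pts$x, pts$y, o$rings[[1]]$x, o$rings[[1]]$y) > 0
  expect_true(all(inside))
  tab2 <- toy_cell_table(pts[1:2, ], rep("other", 2))
  expect_error(build_outline(tab2), "fewer than 3 cells")
  # mask present: used as-is, no fallback message
  tab3 <- toy_cell_table(pts, rep("other", 100), outline = core_outline(1.0))
  expect_silent(o3 <- build_outline(tab3))
  expect_identical(o3, tab3$outline)
})

test_that("neighbor counts equal an exhaustive adjacency-scan oracle", {
  set.seed(22)
  o <- core_outline(1.0)
  for (rep in 1:5) {
    pts <- runif_disc(50)
    cats <- factor(sample(c("CD8", "FOXP3", "tpTreg", "other"), 50, TRUE,
                          prob = c(0.3, 0.2, 0.2, 0.3)),
                   levels = c("CD8", "FOXP3", "tpTreg", "other"))
    g <- voronoi_neighbor_graph(pts, o, categories = cats)
    for (target in c("tpTreg", "FOXP3any")) {
      tset <- if (target == "tpTreg") cats == "tpTreg"
              else cats %in% c("FOXP3", "tpTreg")
      oracle <- sum(vapply(which(cats == "CD8"), function(i) {
        nb <- c(g$edges[g$edges[, 1] == i, 2], g$edges[g$edges[, 2] == i, 1])
        any(tset[nb])
      }, logical(1)))
      expect_equal(neighbor_count(g, target = target), oracle)
      expect_equal(neighbor_fraction(g, target = target),
                   oracle / sum(cats == "CD8"))
    }
  }
  g0 <- voronoi_neighbor_graph(runif_disc(10), o,
                               categories = factor(rep("FOXP3", 10),
                                                   levels = c("CD8", "FOXP3", "tpTreg", "other")))
  expect_equal(neighbor_count(g0), 0L)
  expect_error(neighbor_fraction(g0), "no CD8")
})

test_that("permutation-invariant two-cell configuration is never significant", {
  o <- core_outline(1.0)
  cats <- factor(c("CD8", "tpTreg"), levels = c("CD8", "FOXP3", "tpTreg", "other"))
  g <- voronoi_neighbor_graph(data.frame(x = c(-50, 50), y = c(0, 0)), o,
                              categories = cats)
  r <- permutation_proximity_test(g, "tpTreg", B = 100, seed = 1)
  expect_equal(r$k_obs, 1L)
  expect_true(all(r$perm_counts == 1L))
  expect_equal(r$q95, 1L)
  expect_equal(r$classification, "non_significant")
})

test_that("exclusion and empty-target rules precede any permutation work", {
  set.seed(2)
  pts <- runif_disc(40)
  o <- core_outline(1.0)
  mk <- function(labels) factor(labels, levels = c("CD8", "FOXP3", "tpTreg", "other"))
  no_cd8 <- mk(rep(c("FOXP3", "other"), 20))
  r1 <- classify_sample_proximity(voronoi_neighbor_graph(pts, o, categories = no_cd8))
  expect_equal(r1$classification, "excluded")
  no_target <- mk(rep(c("CD8", "other"), 20))
  r2 <- classify_sample_proximity(voronoi_neighbor_graph(pts, o, categories = no_target))
  expect_equal(r2$classification, "non_significant")
  expect_equal(r2$k_obs, 0L)
  expect_error(permutation_proximity_test(
    voronoi_neighbor_graph(pts, o, categories = no_target), B = 10), "B < 20")
})

test_that("the permuted-count multiset is invariant to row reordering", {
  set.seed(77)
  pts <- runif_disc(60)
  cats <- factor(sample(c("CD8", "FOXP3", "tpTreg", "other"), 60, TRUE),
                 levels = c("CD8", "FOXP3", "tpTreg", "other"))
  o <- core_outline(1.0)
  g1 <- voronoi_neighbor_graph(pts, o, categories = cats)
  ord <- sample.int(60)
  g2 <- voronoi_neighbor_graph(pts[ord, ], o, categories = cats[ord])
  r1 <- permutation_proximity_test(g1, "tpTreg", B = 200, seed = 5)
  r2 <- permutation_proximity_test(g2, "tpTreg", B = 200, seed = 5)
  expect_equal(r1$k_obs, r2$k_obs)
  expect_equal(r1$perm_counts, r2$perm_counts)
})

test_that("a strongly attracted sample is flagged significant", {
  cfg <- synthetic_config(n_samples = 1, theta = 5,
                          abundance_sd = c(CD8 = 0, FOXP3 = 0, tpTreg = 0, other = 0),
                          seed = 313)
  tab <- generate_sample(cfg, 1)
  cats <- suppressMessages(assign_category(call_positivity(tab, default_thresholds())))
  g <- voronoi_neighbor_graph(tab, categories = cats)
  r <- classify_sample_proximity(g, "tpTreg", B = 500, seed = 99, categories = cats)
  expect_equal(r$classification, "significant")
  expect_gt(r$k_obs, r$q95)
})

test_that("neighbor fraction tracks target abundance under the null more than the permutation call", {
  set.seed(55)
  cfg <- synthetic_config(n_samples = 40, theta = 0, seed = 888)
  seeds <- stream_seeds(889, 40)
  rows <- lapply(1:40, function(i) {
    tab <- generate_sample(cfg, i)
    cats <- suppressMessages(assign_category(call_positivity(tab, default_thresholds())))
    if (sum(cats == "CD8") == 0 || sum(cats == "tpTreg") == 0) return(NULL)
    g <- voronoi_neighbor_graph(tab, categories = cats)
    r <- classify_sample_proximity(g, "tpTreg", B = 200, seed = seeds[i],
                                   categories = cats)
    data.frame(frac = neighbor_fraction(g, target = "tpTreg"),
               n_target = sum(cats == "tpTreg"),
               sig = r$classification == "significant")
  })
  d <- do.call(rbind, rows)
  r_frac <- cor(d$frac, d$n_target)
  expect_gt(r_frac, 0.5)
  r_sig <- if (stats::sd(d$sig) == 0) 0 else cor(as.numeric(d$sig), d$n_target)
  expect_lt(abs(r_sig), r_frac)
})
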