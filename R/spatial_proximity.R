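# Voronoi neighbor graphs clipped to tissue, neighbor counting between
# phenotypes, and the Monte-Carlo permutation test for CD8-Treg proximity.
#
# Neighborhood definition: two cells are neighbors when their Voronoi regions,
# clipped to the tissue outline, share a boundary segment longer than
# eps = 1e-6 um. Clipping means holes and excluded regions break adjacency
# across them: cells separated by a necrotic gap are not physical neighbors.

#' @importFrom Matrix sparseMatrix
NULL

#' Build a tissue outline for a sample
#'
#' Uses the mask-derived outline when the table carries one; otherwise falls
#' back to the convex hull of the cell coordinates buffered outward by the
#' median nearest-neighbor distance (logged, since the fallback is a coarser
#' support than a segmentation mask).
#'
#' @param table a [sample_cell_table].
#' @return a [tissue_outline].
#' @export
build_outline <- function(table) {
  if (!is.null(table$outline)) return(table$outline)
  cells <- table$cells
  if (nrow(cells) < 3L)
    stop("cannot build an outline from fewer than 3 cells without a mask")
  ts_log("build_outline", "sample %s: no mask; buffered convex hull fallback",
         table$sample_id)
  hull <- grDevices::chull(cells$x, cells$y)
  buf <- stats::median(nn_dist(cells$x, cells$y))
  ring <- list(x = cells$x[hull], y = cells$y[hull])
  buffered <- polyclip::polyoffset(list(ring), buf, jointype = "round")
  tissue_outline(buffered)
}

# nearest-neighbor distances, O(n^2) vectorized (cores hold <= a few thousand
# cells)
nn_dist <- function(x, y) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  apply(d, 1L, min)
}

#' Voronoi neighbor graph clipped to a tissue outline
#'
#' Tessellates the cell coordinates (Delaunay/Voronoi via \pkg{deldir}), clips
#' every Voronoi edge to the outline, and connects two cells when the within-
#' tissue length of their shared boundary exceeds `eps`. Exact coordinate
#' duplicates are jittered by a seeded uniform offset below 0.01 um before
#' tessellation (logged); Voronoi regions are undefined for coincident sites
#' and the jitter is far below pixel scale.
#'
#' @param table a [sample_cell_table] (or data.frame with `x`, `y`).
#' @param outline a [tissue_outline]; defaults to [build_outline()].
#' @param categories optional category factor (from [assign_category()]) to
#'   attach to the graph nodes.
#' @param eps minimum shared boundary length in micrometres.
#' @param jitter_seed seed for the duplicate-resolving jitter.
#' @return object of class `neighbor_graph`: node coordinates, categories,
#'   undirected `edges` (2-column matrix, i < j), shared boundary lengths, and
#'   the outline.
#' @export
voronoi_neighbor_graph <- function(table, outline = NULL, categories = NULL,
                                   eps = 1e-6, jitter_seed = 1L) {
  cells <- if (inherits(table, "sample_cell_table")) table$cells else table
  if (is.null(outline))
    outline <- if (inherits(table, "sample_cell_table")) build_outline(table)
               else stop("an outline is required for plain coordinate input")
  n <- nrow(cells)
  x <- cells$x; y <- cells$y
  if (!is.null(categories)) stopifnot(length(categories) == n)
  if (n == 1L) {
    return(structure(list(n = 1L, x = x, y = y, categories = categories,
                          edges = matrix(integer(0), 0L, 2L),
                          shared_length = numeric(0), outline = outline,
                          n_jittered = 0L),
                     class = "neighbor_graph"))
  }
  key <- paste(x, y)
  dup <- duplicated(key)
  if (any(dup)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(jitter_seed)
    x[dup] <- x[dup] + runif(sum(dup), -0.005, 0.005)
    y[dup] <- y[dup] + runif(sum(dup), -0.005, 0.005)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    ts_log("voronoi_neighbor_graph", "jittered %d duplicate coordinate(s)", sum(dup))
    if (any(duplicated(paste(x, y)))) stop("cells remain coincident after jitter")
  }
  bb <- c(range(unlist(lapply(outline$rings, `[[`, "x"))),
          range(unlist(lapply(outline$rings, `[[`, "y"))))
  rw <- c(min(bb[1], min(x)) - 1, max(bb[2], max(x)) + 1,
          min(bb[3], min(y)) - 1, max(bb[4], max(y)) + 1)
  dd <- deldir::deldir(x, y, rw = rw, suppressMsge = TRUE)
  sg <- dd$dirsgs
  len <- segment_inside_length(sg$x1, sg$y1, sg$x2, sg$y2, outline)
  keep <- len > eps
  i <- pmin(sg$ind1, sg$ind2)[keep]
  j <- pmax(sg$ind1, sg$ind2)[keep]
  structure(list(n = n, x = x, y = y, categories = categories,
                 edges = cbind(i = i, j = j), shared_length = len[keep],
                 outline = outline, n_jittered = sum(dup)),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d nodes, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' @export
plot.neighbor_graph <- function(x, ...) {
  plot(x$x, x$y, asp = 1, pch = 16, cex = 0.5,
       col = if (is.null(x$categories)) 1 else as.integer(x$categories),
       xlab = "x (um)", ylab = "y (um)", ...)
  segments(x$x[x$edges[, 1]], x$y[x$edges[, 1]],
           x$x[x$edges[, 2]], x$y[x$edges[, 2]], col = "grey70")
  for (r in x$outline$rings)
    polygon(r$x, r$y, border = "red", col = NA)
  invisible(x)
}

# Length of each segment (x1,y1)-(x2,y2) that lies inside the outline
# (even-odd over rings). Exact: crossing parameters with every boundary edge,
# then midpoint parity per sub-interval. Segments that cross nothing are fully
# inside or fully outside according to their endpoints.
segment_inside_length <- function(x1, y1, x2, y2, outline) {
  ns <- length(x1)
  if (ns == 0L) return(numeric(0))
  rings <- outline$rings
  ex1 <- unlist(lapply(rings, `[[`, "x"))
  ey1 <- unlist(lapply(rings, `[[`, "y"))
  ex2 <- unlist(lapply(rings, function(r) c(r$x[-1], r$x[1])))
  ey2 <- unlist(lapply(rings, function(r) c(r$y[-1], r$y[1])))
  rx <- x2 - x1; ry <- y2 - y1
  seg_len <- sqrt(rx^2 + ry^2)
  cross_t <- vector("list", ns)
  for (e in seq_along(ex1)) {
    sx <- ex2[e] - ex1[e]; sy <- ey2[e] - ey1[e]
    denom <- rx * sy - ry * sx
    qpx <- ex1[e] - x1; qpy <- ey1[e] - y1
    t <- (qpx * sy - qpy * sx) / denom
    u <- (qpx * ry - qpy * rx) / denom
    hit <- which(is.finite(t) & t > 0 & t < 1 & u >= 0 & u <= 1)
    for (k in hit) cross_t[[k]] <- c(cross_t[[k]], t[k])
  }
  mid_in <- point_in_rings((x1 + x2) / 2, (y1 + y2) / 2, rings)
  out <- ifelse(mid_in, seg_len, 0)
  crossing <- which(lengths(cross_t) > 0)
  for (k in crossing) {
    ts <- sort(unique(c(0, cross_t[[k]], 1)))
    mids_t <- (ts[-1] + ts[-length(ts)]) / 2
    inside <- point_in_rings(x1[k] + mids_t * rx[k], y1[k] + mids_t * ry[k], rings)
    out[k] <- sum((diff(ts) * seg_len[k])[inside])
  }
  out
}

# ---------------------------------------------------------------------------
# neighbor counting

#' Count CD8+ cells with at least one target neighbor
#'
#' @param graph a [voronoi_neighbor_graph()] result with categories attached.
#' @param categories category factor; defaults to the graph's.
#' @param target `"tpTreg"` or `"FOXP3any"`. `FOXP3any` counts both `FOXP3`
#'   and `tpTreg` category cells as targets: a triple-positive Treg is FOXP3+
#'   by definition, and category precedence would otherwise hide it from the
#'   FOXP3 test.
#' @return integer in `[0, n_CD8]`.
#' @export
neighbor_count <- function(graph, categories = graph$categories,
                           target = c("tpTreg", "FOXP3any")) {
  target <- match.arg(target)
  stopifnot(!is.null(categories))
  cat <- as.character(categories)
  tset <- if (target == "tpTreg") cat == "tpTreg" else cat %in% c("FOXP3", "tpTreg")
  cd8 <- cat == "CD8"
  has_t <- logical(graph$n)
  e <- graph$edges
  if (nrow(e))
    has_t[c(e[, 1][tset[e[, 2]]], e[, 2][tset[e[, 1]]])] <- TRUE
  sum(cd8 & has_t)
}

#' Fraction of CD8+ cells with at least one target neighbor
#'
#' The abundance-sensitive alternative score; see the methods vignette for why
#' the permutation classification is preferred.
#'
#' @inheritParams neighbor_count
#' @export
neighbor_fraction <- function(graph, categories = graph$categories,
                              target = c("tpTreg", "FOXP3any")) {
  target <- match.arg(target)
  n_cd8 <- sum(as.character(categories) == "CD8")
  if (n_cd8 == 0L) stop("neighbor fraction undefined: sample has no CD8+ cells")
  neighbor_count(graph, categories, target) / n_cd8
}

# ---------------------------------------------------------------------------
# permutation test

#' Monte-Carlo permutation test for CD8-target spatial proximity
#'
#' Holds cell positions and the category multiset fixed, randomizes which cell
#' carries which category (B uniform label permutations from a seeded
#' generator), and recomputes the neighbor count on each permuted cell map.
#' The observed count is called significant when it strictly exceeds the
#' nearest-rank 95th percentile of the permuted counts (the 1900th of 2000
#' sorted values at the default B); ties at the critical value are
#' non-significant. Label assignments are drawn against a canonical node order
#' (by x, then y), so the permuted-count multiset does not depend on the row
#' order of the input table.
#'
#' @param graph a [voronoi_neighbor_graph()] with categories.
#' @param target `"tpTreg"` or `"FOXP3any"`.
#' @param B number of permutations (default 2000; at least 20).
#' @param seed RNG seed for this sample's permutation stream.
#' @param categories category factor; defaults to the graph's.
#' @return object of class `proximity_result`: `k_obs`, `B`, `perm_counts`,
#'   `q95`, `classification` (`significant`/`non_significant`), `n_cd8`,
#'   `n_target`, `seed`.
#' @export
permutation_proximity_test <- function(graph, target = c("tpTreg", "FOXP3any"),
                                       B = 2000L, seed = 1L,
                                       categories = graph$categories) {
  target <- match.arg(target)
  if (B < 20L) stop("B < 20 permutations makes the 95th percentile meaningless")
  stopifnot(!is.null(categories))
  cat <- as.character(categories)
  n_cd8 <- sum(cat == "CD8")
  if (n_cd8 == 0L) stop("permutation test requires at least one CD8+ cell")
  k_obs <- neighbor_count(graph, categories, target)
  n <- graph$n
  canon <- order(graph$x, graph$y)
  cat_sorted <- sort(cat)          # the fixed category multiset
  e <- graph$edges
  adj <- if (nrow(e))
    Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                         x = 1, dims = c(n, n))
  else Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, n))
  is_t_lab <- if (target == "tpTreg") cat_sorted == "tpTreg"
              else cat_sorted %in% c("FOXP3", "tpTreg")
  is_c_lab <- cat_sorted == "CD8"
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  perm_counts <- integer(B)
  tmat <- matrix(FALSE, n, B)
  cmat <- matrix(FALSE, n, B)
  for (b in seq_len(B)) {
    ord <- sample.int(n)           # labels cat_sorted[ord] on canonical nodes
    lab_t <- is_t_lab[ord]; lab_c <- is_c_lab[ord]
    tmat[canon, b] <- lab_t
    cmat[canon, b] <- lab_c
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  nt <- as.matrix(adj %*% tmat) > 0
  perm_counts <- colSums(nt & cmat)
  q95 <- nearest_rank(perm_counts, 0.95)
  structure(list(sample_id = attr(categories, "sample_id"), target = target,
                 k_obs = k_obs, B = as.integer(B), perm_counts = perm_counts,
                 q95 = q95,
                 classification = if (k_obs > q95) "significant" else "non_significant",
                 n_cd8 = n_cd8,
                 n_target = if (target == "tpTreg") sum(cat == "tpTreg")
                            else sum(cat %in% c("FOXP3", "tpTreg")),
                 seed = seed),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("<proximity_result> target %s: k_obs = %d, q95 = %d (B = %d) -> %s\n",
              x$target, x$k_obs, x$q95, x$B, x$classification))
  invisible(x)
}

#' Classify one sample's CD8-target spatial proximity
#'
#' Applies the exclusion/classification rules before any permutation work:
#' samples without CD8+ cells are `excluded` from spatial analysis; samples
#' without target cells are `non_significant`; all others get the
#' [permutation_proximity_test()] verdict.
#'
#' @inheritParams permutation_proximity_test
#' @return a `proximity_result` whose `classification` is one of
#'   `excluded`, `non_significant`, `significant`.
#' @export
classify_sample_proximity <- function(graph, target = c("tpTreg", "FOXP3any"),
                                      B = 2000L, seed = 1L,
                                      categories = graph$categories) {
  target <- match.arg(target)
  stopifnot(!is.null(categories))
  cat <- as.character(categories)
  n_cd8 <- sum(cat == "CD8")
  n_target <- if (target == "tpTreg") sum(cat == "tpTreg")
              else sum(cat %in% c("FOXP3", "tpTreg"))
  if (n_cd8 == 0L || n_target == 0L) {
    return(structure(list(sample_id = attr(categories, "sample_id"),
                          target = target,
                          k_obs = if (n_cd8 == 0L) NA_integer_ else 0L,
                          B = as.integer(B), perm_counts = integer(0),
                          q95 = NA_integer_,
                          classification = if (n_cd8 == 0L) "excluded"
                                           else "non_significant",
                          n_cd8 = n_cd8, n_target = n_target, seed = seed),
                     class = "proximity_result"))
  }
  permutation_proximity_test(graph, target, B, seed, categories)
}

#' Summarize proximity results as a table
#' @param results list of `proximity_result`.
#' @return data.frame, one row per sample.
#' @export
proximity_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = if (is.null(r$sample_id)) NA_character_ else r$sample_id,
               target = r$target, n_cd8 = r$n_cd8, n_target = r$n_target,
               k_obs = r$k_obs, B = r$B, q95 = r$q95,
               perm_mean = if (length(r$perm_counts)) mean(r$perm_counts) else NA_real_,
               perm_sd = if (length(r$perm_counts)) stats::sd(r$perm_counts) else NA_real_,
               classification = r$classification, seed = r$seed,
               stringsAsFactors = FALSE)
  }))
}
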