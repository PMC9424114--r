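#' @importFrom data.table fread fwrite
#' @importFrom stats sd median rnorm runif rexp rpois setNames
#' @importFrom grDevices chull contourLines
#' @importFrom graphics segments polygon
NULL

# Canonical coordinate convention: Cartesian micrometres, origin at the image
# top-left corner, y increasing downward (raster order). Masks and cell tables
# read through this module share it, so Voronoi clipping lines up.

REGION_LEVELS  <- c("epithelial", "stromal", "unassigned")
STAGE_LEVELS   <- c("I", "II", "III", "IV")
PT_LEVELS      <- c("1", "2", "3", "4")
PN_LEVELS      <- c("0", "1", "2")
R_LEVELS       <- c("R0", "R1", "R2")
LOC_LEVELS     <- c("right", "left", "rectum", "synchronous")
MSI_LEVELS     <- c("MSI", "MSS")
MUT_LEVELS     <- c("wt", "mut")
SEX_LEVELS     <- c("female", "male")
NA_TOKENS      <- c("", "NA", "NaN")

# ---------------------------------------------------------------------------
# sample_cell_table

#' Construct a sample cell table
#'
#' The shared per-core data model: one row per segmented cell with planar
#' coordinates in micrometres, a tissue-region label and one mean fluorescence
#' intensity column per marker.
#'
#' @param sample_id sample (tissue core) identifier.
#' @param cells data.frame with columns `cell_id`, `x`, `y`, `region` and one
#'   non-negative numeric column per marker.
#' @param markers character vector naming the marker intensity columns.
#' @param series_id patient-series identifier (thresholds are set per series).
#' @param core_diameter_mm diameter of the tissue core in mm.
#' @param pixel_scale_um micrometres per pixel of the source image.
#' @param outline optional [tissue_outline].
#' @return an object of class `sample_cell_table`.
#' @export
sample_cell_table <- function(sample_id, cells, markers,
                              series_id = "S1", core_diameter_mm = 1.0,
                              pixel_scale_um = 0.5, outline = NULL) {
  stopifnot(is.data.frame(cells), core_diameter_mm > 0)
  need <- c("cell_id", "x", "y", "region", markers)
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cell table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
    stop("non-finite cell coordinates")
  for (m in markers) {
    bad <- which(!is.finite(cells[[m]]) | cells[[m]] < 0)
    if (length(bad))
      stop(sprintf("negative or non-finite intensity for marker %s at row %d", m, bad[1]))
  }
  cells$region <- as.character(cells$region)
  cells$region[is.na(cells$region)] <- "unassigned"
  bad <- setdiff(unique(cells$region), REGION_LEVELS)
  if (length(bad)) stop("invalid region label(s): ", paste(bad, collapse = ", "))
  structure(
    list(sample_id = as.character(sample_id), series_id = as.character(series_id),
         core_diameter_mm = core_diameter_mm, pixel_scale_um = pixel_scale_um,
         cells = as.data.frame(cells), markers = markers, outline = outline),
    class = "sample_cell_table")
}

#' @export
print.sample_cell_table <- function(x, ...) {
  cat(sprintf("<sample_cell_table> %s (series %s): %d cells, markers: %s%s\n",
              x$sample_id, x$series_id, nrow(x$cells),
              paste(x$markers, collapse = ", "),
              if (is.null(x$outline)) "" else sprintf(", outline %.4f mm2", x$outline$area_mm2)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# tissue_outline

#' Construct a tissue outline from polygon rings
#'
#' @param rings list of rings, each `list(x =, y =)` in micrometres; holes are
#'   additional rings interpreted with even-odd parity.
#' @return object of class `tissue_outline` with derived `area_mm2`.
#' @export
tissue_outline <- function(rings) {
  stopifnot(length(rings) >= 1)
  rings <- lapply(rings, function(r) {
    stopifnot(length(r$x) >= 3, length(r$x) == length(r$y))
    n <- length(r$x)
    if (r$x[1] == r$x[n] && r$y[1] == r$y[n]) { r$x <- r$x[-n]; r$y <- r$y[-n] }
    list(x = as.numeric(r$x), y = as.numeric(r$y))
  })
  # rings must be simple (non-self-intersecting); holes are rings nested
  # inside others, under even-odd parity. Area = sum over rings of
  # (-1)^depth * |ring area|, depth = number of rings containing it.
  n_r <- length(rings)
  depth <- vapply(seq_len(n_r), function(i) {
    sum(vapply(seq_len(n_r)[-i], function(j)
      sp::point.in.polygon(rings[[i]]$x[1], rings[[i]]$y[1],
                           rings[[j]]$x, rings[[j]]$y) > 0, logical(1)))
  }, integer(1))
  area_um2 <- sum((-1)^depth * vapply(rings, function(r)
    abs(ring_signed_area(r)), numeric(1)))
  if (!is.finite(area_um2) || area_um2 <= 0) stop("tissue outline has zero area")
  structure(list(rings = rings, area_mm2 = area_um2 / 1e6), class = "tissue_outline")
}

#' @export
print.tissue_outline <- function(x, ...) {
  cat(sprintf("<tissue_outline> %d ring(s), area %.6f mm2\n", length(x$rings), x$area_mm2))
  invisible(x)
}

#' Circular tissue outline for a TMA core
#'
#' @param diameter_mm core diameter in mm (0.6 and 1.0 are the TMA formats
#'   the pipeline targets).
#' @param n_vertices polygon resolution.
#' @param center_um centre coordinates in micrometres.
#' @return a [tissue_outline].
#' @export
core_outline <- function(diameter_mm = 1.0, n_vertices = 128L,
                         center_um = c(0, 0)) {
  r <- diameter_mm * 1000 / 2
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-1L]
  tissue_outline(list(list(x = center_um[1] + r * cos(th),
                           y = center_um[2] + r * sin(th))))
}

# ---------------------------------------------------------------------------
# cell-table reader

#' Column dialect for per-cell export tables
#'
#' Maps the column names of an image-analysis export to the canonical fields.
#' The shipped default (`dialect_inform()`) follows the common per-cell export
#' layout of commercial multiplex-IHC analysis software, but every mapping is
#' user-overridable because export schemas differ between versions.
#'
#' @param sample_id,x,y,region source column names.
#' @param markers named character vector: canonical marker name -> source column.
#' @param series_id optional source column carrying the patient series.
#' @param cell_id optional source column with a cell identifier (row number
#'   when absent).
#' @param coord_unit `"um"` or `"px"`.
#' @param pixel_scale_um micrometres per pixel, used when `coord_unit = "px"`.
#' @param region_map named character vector mapping source region labels to
#'   `epithelial`/`stromal`/`unassigned`.
#' @return a `cell_dialect` list.
#' @export
cell_dialect <- function(sample_id = "sample_id", x = "x", y = "y",
                         region = NULL, markers, series_id = NULL,
                         cell_id = NULL, coord_unit = c("um", "px"),
                         pixel_scale_um = 0.5,
                         region_map = c(epithelial = "epithelial",
                                        stromal = "stromal",
                                        unassigned = "unassigned")) {
  coord_unit <- match.arg(coord_unit)
  stopifnot(length(markers) >= 1, !is.null(names(markers)))
  structure(list(sample_id = sample_id, x = x, y = y, region = region,
                 markers = markers, series_id = series_id, cell_id = cell_id,
                 coord_unit = coord_unit, pixel_scale_um = pixel_scale_um,
                 region_map = region_map), class = "cell_dialect")
}

#' @rdname cell_dialect
#' @export
dialect_inform <- function(pixel_scale_um = 0.5) {
  cell_dialect(
    sample_id = "Sample Name",
    x = "Cell X Position", y = "Cell Y Position",
    region = "Tissue Category",
    markers = c(CD3 = "Mean CD3", CD8 = "Mean CD8", CD4 = "Mean CD4",
                CD25 = "Mean CD25", FOXP3 = "Mean FOXP3"),
    cell_id = "Cell ID",
    coord_unit = "px", pixel_scale_um = pixel_scale_um,
    region_map = c(epithelial = "Tumor", stromal = "Stroma",
                   unassigned = "Other"))
}

#' Read a per-cell export table
#'
#' Reads a delimited per-cell table (TSV or CSV, auto-detected) and splits it
#' into one [sample_cell_table] per distinct sample id. Pixel coordinates are
#' converted to micrometres; row order within each sample is preserved;
#' unmapped columns are ignored with a logged warning.
#'
#' @param path file path.
#' @param dialect a [cell_dialect].
#' @param core_diameter_mm core diameter recorded on each table.
#' @return named list of [sample_cell_table].
#' @export
read_cell_table <- function(path, dialect, core_diameter_mm = 1.0) {
  stopifnot(inherits(dialect, "cell_dialect"))
  dt <- data.table::fread(path, na.strings = NA_TOKENS, data.table = FALSE,
                          check.names = FALSE)
  mandatory <- c(dialect$sample_id, dialect$x, dialect$y, unname(dialect$markers))
  miss <- setdiff(mandatory, names(dt))
  if (length(miss)) stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  mapped <- c(mandatory, dialect$region, dialect$series_id, dialect$cell_id)
  extra <- setdiff(names(dt), mapped)
  if (length(extra))
    ts_log("read_cell_table", "ignoring %d unmapped column(s): %s",
           length(extra), paste(extra, collapse = ", "))
  for (cc in c(dialect$x, dialect$y)) {
    v <- dt[[cc]]
    if (!is.numeric(v)) stop("non-numeric coordinate column: ", cc)
  }
  scale <- if (dialect$coord_unit == "px") dialect$pixel_scale_um else 1.0
  out <- data.frame(
    cell_id = if (!is.null(dialect$cell_id)) as.character(dt[[dialect$cell_id]])
              else as.character(seq_len(nrow(dt))),
    x = dt[[dialect$x]] * scale,
    y = dt[[dialect$y]] * scale,
    stringsAsFactors = FALSE)
  if (!is.null(dialect$region)) {
    src <- as.character(dt[[dialect$region]])
    lut <- setNames(names(dialect$region_map), unname(dialect$region_map))
    reg <- unname(lut[src])
    reg[is.na(reg)] <- "unassigned"
    out$region <- reg
  } else out$region <- "unassigned"
  for (m in names(dialect$markers)) {
    v <- dt[[dialect$markers[[m]]]]
    if (!is.numeric(v)) stop("non-numeric intensity column: ", dialect$markers[[m]])
    bad <- which(v < 0)
    if (length(bad)) stop(sprintf("negative intensity for %s at row %d", m, bad[1]))
    out[[m]] <- v
  }
  sid <- as.character(dt[[dialect$sample_id]])
  ser <- if (!is.null(dialect$series_id)) as.character(dt[[dialect$series_id]]) else "S1"
  tabs <- lapply(split(seq_len(nrow(out)), factor(sid, levels = unique(sid))), function(ix) {
    sample_cell_table(sid[ix[1]], out[ix, , drop = FALSE], names(dialect$markers),
                      series_id = ser[ix[1]], core_diameter_mm = core_diameter_mm,
                      pixel_scale_um = dialect$pixel_scale_um)
  })
  tabs
}

#' Write a sample cell table in the package's canonical dialect
#'
#' Round-trips through [read_cell_table()] with [canonical_dialect()].
#'
#' @param table a [sample_cell_table].
#' @param path output path (TSV).
#' @export
write_sample_table <- function(table, path) {
  stopifnot(inherits(table, "sample_cell_table"))
  df <- data.frame(sample_id = table$sample_id, series_id = table$series_id,
                   table$cells, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @param markers canonical marker names expected in the file.
#' @export
canonical_dialect <- function(markers = c("CD3", "CD8", "CD4", "CD25", "FOXP3")) {
  cell_dialect(sample_id = "sample_id", x = "x", y = "y", region = "region",
               markers = setNames(markers, markers), series_id = "series_id",
               cell_id = "cell_id", coord_unit = "um")
}

# ---------------------------------------------------------------------------
# tissue masks

#' Read a tissue mask or outline polygon
#'
#' Binary raster masks (PNG/TIFF, foreground = tissue) are traced into polygon
#' outlines at the half-level between foreground and background pixel centres,
#' preserving holes; WKT text files (`POLYGON`/`MULTIPOLYGON`) are parsed
#' directly. Vertices are scaled to micrometres; the derived area equals the
#' polygon area in square micrometres divided by 1e6.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`, or `.wkt`/`.txt`).
#' @param pixel_scale_um micrometres per pixel for raster masks; for WKT input
#'   the coordinates are taken to be micrometres already.
#' @return a [tissue_outline].
#' @export
read_tissue_mask <- function(path, pixel_scale_um = 0.5) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("wkt", "txt"))
    return(tissue_outline(parse_wkt(paste(readLines(path, warn = FALSE), collapse = " "))))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unreadable mask format: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mask_to_outline(img > 0.5, pixel_scale_um)
}

#' @rdname read_tissue_mask
#' @param mask logical or 0/1 matrix, `mask[row, col]`, TRUE = tissue.
#' @export
mask_to_outline <- function(mask, pixel_scale_um = 0.5) {
  mask <- (mask > 0) * 1
  if (!any(mask > 0)) stop("no tissue foreground")
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- mask
  # pixel (r, c) centre sits at ((c - 0.5) s, (r - 0.5) s); padding centres at
  # -0.5 s and (n + 0.5) s so the traced half-level boundary lands on pixel edges
  xc <- ((seq_len(nc + 2L) - 1L) - 0.5) * pixel_scale_um
  yc <- ((seq_len(nr + 2L) - 1L) - 0.5) * pixel_scale_um
  cl <- grDevices::contourLines(x = yc, y = xc, z = z, levels = 0.5)
  if (!length(cl)) stop("no tissue foreground")
  rings <- lapply(cl, function(g) list(x = g$y, y = g$x))
  tissue_outline(rings)
}

# Minimal WKT POLYGON/MULTIPOLYGON parser (no installed package provides WKT
# parsing in this stack). Inner rings are holes via even-odd parity.
parse_wkt <- function(txt) {
  txt <- trimws(txt)
  body <- sub("^\\s*(MULTIPOLYGON|POLYGON)\\s*", "", txt, ignore.case = TRUE)
  if (identical(body, txt)) stop("not a WKT POLYGON/MULTIPOLYGON: ", substr(txt, 1, 30))
  ring_txt <- regmatches(body, gregexpr("\\(([^()]+)\\)", body))[[1]]
  if (!length(ring_txt)) stop("no rings in WKT input")
  lapply(ring_txt, function(r) {
    r <- gsub("[()]", "", r)
    pts <- strsplit(trimws(strsplit(r, ",")[[1]]), "\\s+")
    xy <- vapply(pts, function(p) as.numeric(p[1:2]), numeric(2))
    list(x = xy[1, ], y = xy[2, ])
  })
}

#' Write an outline as WKT
#' @param outline a [tissue_outline].
#' @param path output path.
#' @export
write_outline_wkt <- function(outline, path) {
  ring <- function(r) sprintf("(%s)", paste(sprintf("%.6f %.6f", c(r$x, r$x[1]),
                                                    c(r$y, r$y[1])), collapse = ", "))
  txt <- sprintf("POLYGON %s", paste0("(", paste(vapply(outline$rings, ring, ""),
                                                 collapse = ", "), ")"))
  writeLines(txt, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# clinical tables

#' Read and validate a clinical table
#'
#' Delimited text with the documented header names; enum fields are validated
#' on read and NA tokens (`""`, `"NA"`, `"NaN"`) map to missing.
#'
#' @param path file path.
#' @return data.frame of validated clinical records.
#' @export
read_clinical_table <- function(path) {
  df <- data.table::fread(path, na.strings = NA_TOKENS, data.table = FALSE,
                          colClasses = list(character = "pT"))
  validate_clinical(df)
}

#' @rdname read_clinical_table
#' @param df data.frame of raw clinical rows.
#' @export
validate_clinical <- function(df) {
  need <- c("patient_id", "age", "sex", "tnm_stage", "pT", "pN", "r_status",
            "location", "msi", "braf", "kras", "adjuvant_chemo", "preop_radio",
            "synchronous_primary", "followup_months", "relapse_months",
            "death_months")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  chk <- function(col, levels, allow_na = FALSE) {
    v <- as.character(df[[col]])
    bad <- which(!(v %in% levels) & !(allow_na & is.na(v)))
    if (length(bad))
      stop(sprintf("invalid %s value '%s' at row %d", col, v[bad[1]], bad[1]))
    v
  }
  df$tnm_stage <- chk("tnm_stage", STAGE_LEVELS)
  df$pT        <- chk("pT", PT_LEVELS)
  df$pN        <- chk("pN", PN_LEVELS)
  df$r_status  <- chk("r_status", R_LEVELS)
  df$location  <- chk("location", LOC_LEVELS)
  df$msi       <- chk("msi", MSI_LEVELS, allow_na = TRUE)
  df$braf      <- chk("braf", MUT_LEVELS, allow_na = TRUE)
  df$kras      <- chk("kras", MUT_LEVELS, allow_na = TRUE)
  df$sex       <- chk("sex", SEX_LEVELS)
  for (col in c("adjuvant_chemo", "preop_radio", "synchronous_primary"))
    df[[col]] <- as.logical(df[[col]])
  if (any(df$followup_months < 0, na.rm = TRUE)) stop("negative follow-up time")
  df
}

#' @rdname read_clinical_table
#' @param clinical validated clinical data.frame.
#' @export
write_clinical_table <- function(clinical, path) {
  data.table::fwrite(clinical, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# score output + manifest

#' Write per-sample result records
#'
#' Delimited TSV with a stable column order and floats rendered with at least
#' six significant digits; an empty input yields a header-only file.
#'
#' @param records data.frame of per-sample results.
#' @param path output path.
#' @export
write_sample_scores <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 8)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read back a score table written by [write_sample_scores()]
#' @param path file path.
#' @export
read_sample_scores <- function(path) {
  data.table::fread(path, na.strings = NA_TOKENS, data.table = FALSE)
}

#' Write a JSON run manifest
#'
#' Records command, configuration hash, input digests, master seed and package
#' version, so a rerun with an equal manifest reproduces the outputs.
#'
#' @param path output path (JSON).
#' @param command pipeline subcommand.
#' @param config configuration list.
#' @param inputs character vector of input file paths (digested when present).
#' @param seed master seed.
#' @export
write_run_manifest <- function(path, command, config, inputs = character(0), seed = NA) {
  cfg_txt <- paste(deparse(config[order(names(config))]), collapse = "")
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs[file.exists(inputs)])) else list()
  man <- list(command = command,
              config_hash = unname(tools::md5sum(textConnection_md5(cfg_txt))),
              input_digests = digests,
              seed = seed,
              package_version = as.character(utils::packageVersion("tregspatial")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# md5 of a string via a temp file (tools::md5sum is file-based)
textConnection_md5 <- function(txt) {
  tf <- tempfile()
  writeLines(txt, tf)
  tf
}
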