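# Pipeline orchestration: validated YAML config, staged subcommands, run
# manifests, deterministic reruns.

PIPELINE_COMMANDS <- c("score", "spatial", "simulate", "cohort", "all")
CONFIG_KEYS <- c("synthetic", "thresholds", "spatial", "cohort", "seed")

#' Read and validate a pipeline configuration
#'
#' Single YAML file with per-stage sections (`synthetic`, `thresholds`,
#' `spatial`, `cohort`, `seed`). Unknown keys are errors: silent typos would
#' corrupt thresholds.
#'
#' @param path YAML file; NULL gives the default configuration.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  bad <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  syn_args <- cfg$synthetic
  if (!is.null(syn_args)) {
    okn <- names(formals(synthetic_config))
    badn <- setdiff(names(syn_args), okn)
    if (length(badn)) stop("unknown synthetic key(s): ", paste(badn, collapse = ", "))
    if (!is.null(syn_args$proportions)) syn_args$proportions <- unlist(syn_args$proportions)
  }
  sp <- cfg$spatial
  if (!is.null(sp)) {
    badn <- setdiff(names(sp), c("permutations", "target"))
    if (length(badn)) stop("unknown spatial key(s): ", paste(badn, collapse = ", "))
  }
  ch <- cfg$cohort
  if (!is.null(ch)) {
    badn <- setdiff(names(ch), "n_patients")
    if (length(badn)) stop("unknown cohort key(s): ", paste(badn, collapse = ", "))
  }
  list(synthetic = syn_args,
       thresholds = cfg$thresholds,
       spatial = list(permutations = sp$permutations %||% 2000L,
                      target = sp$target %||% "tpTreg"),
       cohort = list(n_patients = ch$n_patients %||% NULL),
       seed = cfg$seed %||% 20220601L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a pipeline stage
#'
#' Subcommands: `simulate` writes synthetic per-cell tables; `score` computes
#' densities and Treg profiles; `spatial` runs the Voronoi permutation test;
#' `cohort` builds endpoints and survival models on the synthetic clinical
#' table; `all` chains simulate, score, spatial and cohort on synthetic data.
#' Every run writes a JSON manifest; partial outputs are removed on failure.
#'
#' @param command one of `score`, `spatial`, `simulate`, `cohort`, `all`.
#' @param config config list from [read_pipeline_config()] (or NULL for
#'   defaults).
#' @param out_dir output directory (created).
#' @param seed master seed override.
#' @param permutations permutation-count override for the spatial stage.
#' @param input_dir directory of per-cell TSV tables for `score`/`spatial`
#'   when not chaining from `simulate`.
#' @param verbose emit progress messages.
#' @return (invisibly) named list of written files.
#' @export
run_pipeline <- function(command, config = NULL, out_dir = "tregspatial_out",
                         seed = NULL, permutations = NULL, input_dir = NULL,
                         verbose = TRUE) {
  command <- match.arg(command, PIPELINE_COMMANDS)
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config)) config <- read_pipeline_config(NULL)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(permutations)) config$spatial$permutations <- as.integer(permutations)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  run <- function() {
    outs <- list()
    syn_cfg <- do.call(synthetic_config,
                       c(config$synthetic %||% list(n_samples = 20L),
                         list(seed = config$seed)))
    thr <- if (is.null(config$thresholds)) default_thresholds()
           else if (is.character(config$thresholds)) read_thresholds(config$thresholds)
           else marker_thresholds(as.data.frame(config$thresholds))
    tables <- NULL
    if (command %in% c("simulate", "all")) {
      tables <- lapply(seq_len(syn_cfg$n_samples), function(i)
        generate_sample(syn_cfg, i))
      f <- file.path(out_dir, "cells.tsv")
      df <- do.call(rbind, lapply(tables, function(t)
        data.frame(sample_id = t$sample_id, series_id = t$series_id,
                   t$cells, check.names = FALSE)))
      data.table::fwrite(df, f, sep = "\t", na = "NA", quote = FALSE)
      written <<- c(written, f); outs$cells <- f
      if (verbose) ts_log("simulate", "%d samples, seed %d", length(tables), syn_cfg$seed)
    }
    if (command %in% c("score", "spatial")) {
      if (is.null(input_dir)) stop("score/spatial need input_dir with cell tables")
      files <- list.files(input_dir, pattern = "\\.tsv$", full.names = TRUE)
      if (!length(files)) stop("no .tsv cell tables in ", input_dir)
      tables <- unlist(lapply(files, read_cell_table,
                              dialect = canonical_dialect(names(syn_cfg$intensity_model))),
                       recursive = FALSE)
    }
    if (command %in% c("score", "all")) {
      calls <- lapply(tables, call_positivity, thresholds = thr)
      cats <- lapply(calls, assign_category)
      dens <- do.call(rbind, lapply(seq_along(tables), function(i) {
        rbind(infiltration_density(tables[[i]], calls[[i]], "CD8"),
              infiltration_density(tables[[i]], calls[[i]], "FOXP3"),
              infiltration_density(tables[[i]], cats[[i]], "tpTreg",
                                   type = "category"))
      }))
      prof <- treg_subgroup_profile(tables, cats)
      f1 <- file.path(out_dir, "densities.tsv")
      f2 <- file.path(out_dir, "treg_profiles.tsv")
      write_sample_scores(dens, f1); write_sample_scores(prof, f2)
      written <<- c(written, f1, f2); outs$densities <- f1; outs$treg_profiles <- f2
      if (verbose) ts_log("score", "%d samples scored", length(tables))
    }
    if (command %in% c("spatial", "all")) {
      calls <- lapply(tables, call_positivity, thresholds = thr)
      cats <- lapply(calls, assign_category)
      seeds <- stream_seeds(config$seed, length(tables))
      res <- lapply(seq_along(tables), function(i) {
        g <- voronoi_neighbor_graph(tables[[i]], categories = cats[[i]])
        r <- classify_sample_proximity(g, target = config$spatial$target,
                                       B = config$spatial$permutations,
                                       seed = seeds[i], categories = cats[[i]])
        r$sample_id <- tables[[i]]$sample_id
        r
      })
      f <- file.path(out_dir, "proximity.tsv")
      write_sample_scores(proximity_table(res), f)
      written <<- c(written, f); outs$proximity <- f
      if (verbose) ts_log("spatial", "%d samples classified (B = %d)",
                          length(res), config$spatial$permutations)
    }
    if (command %in% c("cohort", "all")) {
      # the survival cohort needs enough patients for the multivariable model,
      # independently of how many cell-level cores were simulated
      coh_cfg <- syn_cfg
      coh_cfg$n_samples <- as.integer(config$cohort$n_patients %||%
                                        max(syn_cfg$n_samples, 500L))
      coh <- generate_cohort(coh_cfg)
      mf <- rfs_model_frame(coh$clinical)
      fit <- cox_fit(mf, c("ie_cd8_high", "mean_cd25_high",
                           "proximity_significant", "pT_34", "pN_f",
                           "msi_f", "age_c"),
                     strata_col = "series_id")
      km_groups <- split(mf, mf$mean_cd25_class)
      km <- do.call(rbind, lapply(names(km_groups), function(gname) {
        g <- km_groups[[gname]]
        if (!nrow(g)) return(NULL)
        est <- km_estimate(g$time_months, g$event)
        data.frame(group = gname, n = est$n, events = est$n_events,
                   s60 = est$s_horizon)
      }))
      f1 <- file.path(out_dir, "endpoints.tsv")
      f2 <- file.path(out_dir, "cox_coefficients.tsv")
      f3 <- file.path(out_dir, "km_summary.tsv")
      write_sample_scores(mf[, c("patient_id", "time_months", "event")], f1)
      write_sample_scores(fit$coefficients, f2)
      write_sample_scores(km, f3)
      written <<- c(written, f1, f2, f3)
      outs$endpoints <- f1; outs$cox <- f2; outs$km <- f3
      if (verbose) ts_log("cohort", "n = %d, events = %d, c-index %.3f",
                          fit$n, fit$n_events, fit$concordance)
    }
    fman <- file.path(out_dir, "manifest.json")
    write_run_manifest(fman, command, config, inputs = character(0),
                       seed = config$seed)
    written <<- c(written, fman); outs$manifest <- fman
    outs
  }
  outs <- tryCatch(run(), error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(outs)
}
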