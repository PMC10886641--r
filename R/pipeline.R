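#' Read a pipeline run configuration
#'
#' A single YAML (or JSON) file drives every stage. Recognized blocks:
#' \itemize{
#'   \item `seed`: integer, recorded in every output and used for all
#'     randomness.
#'   \item `output_dir`: where CSV/JSON outputs and the manifest go.
#'   \item `calibration: pixels_per_micron`.
#'   \item `preprocess:` `rolling_ball_radius_px`, `median_radius_px`,
#'     `clahe_tile_px`, `clahe_clip`.
#'   \item `images:` `paths` (TIFF files) and `metadata` (CSV with cell_id,
#'     line, condition, age, sex) — or `synth: scenes:` with `groups`
#'     (line, condition, n_cells plus scene_spec overrides) and shared
#'     scene_spec fields.
#'   \item `synth: traces:` groups (group, n_traces, slope, ...) plus shared
#'     trace_spec fields; optional `fccp_frame` / `fccp_drop` switch the
#'     analysis to membrane-potential mode.
#'   \item `stats:` `design`, `control_group`, `family_size`, `metrics`.
#' }
#'
#' @param path YAML/JSON config file.
#' @return A list of class `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' Build a run configuration from a list
#'
#' @param cfg named list with the blocks of [read_config()].
#' @return A list of class `run_config` with defaults filled in.
#' @export
as_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "mitomorph_results"
  cal <- cfg$calibration %||% list()
  cfg$calibration <- list(pixels_per_micron =
                            cal$pixels_per_micron %||% 23.4)
  if (cfg$calibration$pixels_per_micron <= 0)
    stop("calibration pixels_per_micron must be > 0")
  pp <- cfg$preprocess %||% list()
  cfg$preprocess <- list(
    rolling_ball_radius_px = pp$rolling_ball_radius_px %||% 50,
    median_radius_px = pp$median_radius_px %||% 1,
    clahe_tile_px = pp$clahe_tile_px %||% 64,
    clahe_clip = pp$clahe_clip %||% 0.01)
  st <- cfg$stats %||% list()
  cfg$stats <- list(design = st$design %||% "one_way",
                    control_group = st$control_group %||% "Control",
                    family_size = st$family_size,
                    metrics = st$metrics)
  class(cfg) <- "run_config"
  cfg
}

log_line <- function(log_path, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 paste0(..., collapse = ""))
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  message(msg)
}

config_manifest <- function(cfg, outdir, stage, files) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null",
                         digits = NA)
  tmp <- tempfile(); writeLines(js, tmp)
  manifest <- list(stage = stage, seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(tmp)),
                   package = "mitomorph",
                   package_version =
                     as.character(utils::packageVersion("mitomorph")),
                   r_version = as.character(getRversion()),
                   outputs = files)
  unlink(tmp)
  path <- file.path(outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}

# expand the synth.scenes block into one row per cell with its scene args
synth_cell_plan <- function(cfg) {
  sc <- cfg$synth$scenes
  if (is.null(sc) || is.null(sc$groups))
    stop("config has no images and no synth: scenes: groups block")
  shared <- sc[setdiff(names(sc), "groups")]
  plan <- list()
  ci <- 0L
  for (g in sc$groups) {
    n_cells <- g$n_cells %||% 1L
    over <- g[setdiff(names(g),
                      c("line", "condition", "n_cells", "age", "sex"))]
    for (j in seq_len(n_cells)) {
      ci <- ci + 1L
      plan[[ci]] <- list(cell_id = sprintf("%s_%s_c%02d",
                                           g$line %||% "Control",
                                           g$condition %||% "normal", j),
                         line = g$line %||% "Control",
                         condition = g$condition %||% "normal",
                         age = g$age %||% NA, sex = g$sex %||% NA,
                         scene_args = utils::modifyList(shared, over))
    }
  }
  plan
}

#' Run the image-morphometry stage
#'
#' Processes every input micrograph (real TIFFs or synthesized scenes)
#' through the fixed chain — background subtraction, median filter, CLAHE,
#' Otsu, particle analysis, skeletonization, skeleton-graph analysis,
#' classification, per-cell aggregation — and writes `cells.csv` (one row
#' per cell), `objects.csv` (one row per object, for audit), a log, and a
#' manifest tying the outputs to the config hash and seed.
#'
#' Unreadable images are skipped with a logged reason; the stage fails only
#' if every input fails.
#'
#' @param config a `run_config` (or path to one).
#' @return Invisibly, a list with `cells` and `objects` data.frames and the
#'   written `paths`.
#' @export
run_morphology <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  stopifnot(inherits(cfg, "run_config"))
  outdir <- cfg$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "morphology.log")
  cat("", file = log_path)
  ppm <- cfg$calibration$pixels_per_micron
  cells <- list(); objects <- list()
  failed <- 0L; total <- 0L

  analyze_one <- function(img, meta) {
    res <- analyze_cell(img, cell_id = meta$cell_id,
                        preprocess = cfg$preprocess)
    cell <- res$cell
    cell$line <- meta$line; cell$condition <- meta$condition
    cell$age <- meta$age; cell$sex <- meta$sex
    cell$seed <- cfg$seed
    obj <- res$objects
    obj$branch_lengths_um <- NULL
    if (nrow(obj) > 0) obj <- cbind(cell_id = meta$cell_id, obj)
    list(cell = cell, obj = obj)
  }

  if (!is.null(cfg$images$paths)) {
    meta <- NULL
    if (!is.null(cfg$images$metadata))
      meta <- utils::read.csv(cfg$images$metadata, stringsAsFactors = FALSE)
    for (p in cfg$images$paths) {
      total <- total + 1L
      res <- tryCatch({
        img <- read_micrograph(p, pixels_per_micron = ppm)
        id <- tools::file_path_sans_ext(basename(p))
        m <- list(cell_id = id, line = "Control", condition = "normal",
                  age = NA, sex = NA)
        if (!is.null(meta) && id %in% meta$cell_id) {
          mr <- meta[meta$cell_id == id, ][1, ]
          m <- utils::modifyList(m, as.list(mr))
        }
        analyze_one(img, m)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- failed + 1L
        log_line(log_path, "SKIP ", p, ": ", conditionMessage(res))
      } else {
        cells[[length(cells) + 1]] <- res$cell
        objects[[length(objects) + 1]] <- res$obj
        log_line(log_path, "OK   ", p)
      }
    }
  } else {
    plan <- synth_cell_plan(cfg)
    for (i in seq_along(plan)) {
      pl <- plan[[i]]
      total <- total + 1L
      res <- tryCatch({
        args <- pl$scene_args
        args$pixels_per_micron <- args$pixels_per_micron %||% ppm
        args$seed <- (cfg$seed * 1000L + i) %% .Machine$integer.max
        scene <- generate_scene(do.call(scene_spec, args))
        analyze_one(scene$image, pl)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failed <- failed + 1L
        log_line(log_path, "SKIP ", pl$cell_id, ": ", conditionMessage(res))
      } else {
        cells[[length(cells) + 1]] <- res$cell
        objects[[length(objects) + 1]] <- res$obj
        log_line(log_path, "OK   ", pl$cell_id)
      }
    }
  }
  if (total == 0) stop("no input images: give images: paths or synth: scenes")
  if (failed == total) stop("all ", total, " inputs failed; see ", log_path)
  cells_df <- do.call(rbind, cells)
  objects_df <- do.call(rbind, objects)
  paths <- c(cells = file.path(outdir, "cells.csv"),
             objects = file.path(outdir, "objects.csv"),
             log = log_path)
  utils::write.csv(cells_df, paths[["cells"]], row.names = FALSE)
  utils::write.csv(objects_df, paths[["objects"]], row.names = FALSE)
  paths <- c(paths, manifest = config_manifest(cfg, outdir, "morphology",
                                               paths))
  log_line(log_path, sprintf("done: %d cells, %d skipped", nrow(cells_df),
                             failed))
  invisible(list(cells = cells_df, objects = objects_df, paths = paths))
}

#' Run the kinetics stage
#'
#' Generates (or reads) fluorescence traces, fits ROS rates by OLS, measures
#' TMRM/FCCP potential proxies when an FCCP frame is configured, and
#' normalizes everything to the pooled control group.
#'
#' @param config a `run_config` (or path).
#' @return Invisibly, list with `rates` (and `potentials` when applicable)
#'   and the written `paths`.
#' @export
run_traces <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  stopifnot(inherits(cfg, "run_config"))
  outdir <- cfg$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tr_cfg <- cfg$synth$traces
  traces <- list()
  if (!is.null(cfg$traces_csv)) {
    traces <- read_traces(cfg$traces_csv)
  } else if (!is.null(tr_cfg$groups)) {
    shared <- tr_cfg[setdiff(names(tr_cfg), "groups")]
    ti <- 0L
    for (g in tr_cfg$groups) {
      n <- g$n_traces %||% 1L
      over <- g[setdiff(names(g), c("group", "probe", "n_traces"))]
      for (j in seq_len(n)) {
        ti <- ti + 1L
        args <- utils::modifyList(shared, over)
        args$seed <- (cfg$seed * 2000L + ti) %% .Machine$integer.max
        traces[[ti]] <- generate_trace(
          do.call(trace_spec, args),
          trace_id = sprintf("%s_t%03d", g$group %||% "Control", j),
          probe = g$probe %||% "DCF", group = g$group %||% "Control")
      }
    }
  } else {
    stop("no traces: give traces_csv or synth: traces: groups")
  }
  ctl <- cfg$stats$control_group
  fccp <- tr_cfg$fccp_frame
  paths <- character(0)
  out <- list()
  if (is.null(fccp)) {
    rates <- do.call(rbind, lapply(traces, fit_rate))
    rates <- normalize_to_control(rates, ctl, value = "slope")
    paths["rates"] <- file.path(outdir, "rates.csv")
    utils::write.csv(rates, paths[["rates"]], row.names = FALSE)
    out$rates <- rates
  } else {
    pots <- do.call(rbind, lapply(traces, measure_potential,
                                  fccp_frame = fccp))
    pots <- normalize_to_control(pots, ctl, value = "delta_psi_proxy")
    paths["potentials"] <- file.path(outdir, "potentials.csv")
    utils::write.csv(pots, paths[["potentials"]], row.names = FALSE)
    out$potentials <- pots
  }
  paths["manifest"] <- config_manifest(cfg, outdir, "traces", paths)
  out$paths <- paths
  invisible(out)
}

#' Run the statistics stage
#'
#' For every configured metric: Shapiro-Wilk normality gate per line,
#' ANOVA + Tukey under the Bonferroni-adjusted alpha, and fold changes of
#' group means against the pooled control. Writes a tidy CSV of comparisons
#' and a JSON summary.
#'
#' @param config a `run_config` (or path).
#' @param cells per-cell data.frame (default: reads `cells.csv` from the
#'   configured output directory).
#' @return Invisibly, list of per-metric results plus `paths`.
#' @export
run_stats <- function(config, cells = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  stopifnot(inherits(cfg, "run_config"))
  outdir <- cfg$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cells)) {
    cp <- file.path(outdir, "cells.csv")
    if (!file.exists(cp))
      stop("no cells.csv in ", outdir, "; run run_morphology() first")
    cells <- utils::read.csv(cp, stringsAsFactors = FALSE)
  }
  ctl <- cfg$stats$control_group
  if (!any(cells$line %in% ctl))
    stop("control group `", paste(ctl, collapse = "`, `"),
         "` absent from the cell table; cannot normalize or compare")
  metrics <- cfg$stats$metrics %||%
    intersect(c("footprint_um2", "median_network_branch_len_um",
                "individual_to_network_ratio", "median_individual_len_um",
                "mean_junctions_per_network",
                "median_individual_aspect_ratio"),
              names(cells))
  results <- list()
  rows <- list()
  for (m in metrics) {
    ok <- is.finite(cells[[m]])
    d <- cells[ok, , drop = FALSE]
    res <- list()
    res$normality <- tryCatch(
      suppressWarnings(normality_gate(d, m)), error = function(e) e)
    res$comparison <- tryCatch(
      compare_groups(d, m, design = cfg$stats$design,
                     family_size = cfg$stats$family_size),
      error = function(e) e)
    gm <- tapply(d[[m]], d$line, mean)
    ref_mean <- mean(d[[m]][d$line %in% ctl])
    fc <- tryCatch(
      fold_change(c(stats::setNames(ref_mean, "pooled_control"), gm),
                  "pooled_control"),
      error = function(e) e)
    res$fold_change <- fc
    results[[m]] <- res
    if (!inherits(res$comparison, "error")) {
      pw <- res$comparison$pairwise
      rows[[m]] <- cbind(metric = m, test = "Tukey", pw,
                         adjusted_alpha = res$comparison$adjusted_alpha)
    }
  }
  paths <- c(comparisons = file.path(outdir, "comparisons.csv"),
             summary = file.path(outdir, "stats_summary.json"))
  comp_df <- do.call(rbind, rows)
  utils::write.csv(comp_df, paths[["comparisons"]], row.names = FALSE)
  summ <- lapply(results, function(res) {
    list(all_normal = if (inherits(res$normality, "error")) NA
         else isTRUE(attr(res$normality, "all_normal")),
         adjusted_alpha = if (inherits(res$comparison, "error")) NA
         else res$comparison$adjusted_alpha,
         omnibus_p = if (inherits(res$comparison, "error")) NA
         else res$comparison$anova$p_value[1],
         fold_change = if (inherits(res$fold_change, "error")) NA
         else stats::setNames(res$fold_change$fold_change,
                              res$fold_change$group))
  })
  jsonlite::write_json(summ, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA)
  paths["manifest"] <- config_manifest(cfg, outdir, "stats", paths)
  invisible(c(results, list(paths = paths)))
}

#' Run the full pipeline
#'
#' Morphology, kinetics (when a trace block is configured) and statistics,
#' with one manifest tying all outputs to the config hash and seed.
#'
#' @param config a `run_config` (or path).
#' @return Invisibly, list with `morphology`, `traces` (or NULL), `stats`
#'   and `paths`.
#' @export
run_full <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  stopifnot(inherits(cfg, "run_config"))
  morph <- tryCatch(
    run_morphology(cfg),
    error = function(e) stop("morphology stage failed: ",
                             conditionMessage(e), call. = FALSE))
  traces <- NULL
  if (!is.null(cfg$synth$traces) || !is.null(cfg$traces_csv))
    traces <- tryCatch(run_traces(cfg),
                       error = function(e) stop("traces stage failed: ",
                                                conditionMessage(e),
                                                call. = FALSE))
  stats_res <- tryCatch(run_stats(cfg, cells = morph$cells),
                        error = function(e) stop("stats stage failed: ",
                                                 conditionMessage(e),
                                                 call. = FALSE))
  paths <- c(morph$paths, traces$paths, stats_res$paths)
  paths["manifest"] <- config_manifest(cfg, cfg$output_dir, "full", paths)
  invisible(list(morphology = morph, traces = traces, stats = stats_res,
                 paths = paths))
}
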