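## content hash of an arbitrary R object (used for stage-cache invalidation)
obj_hash <- function(x) {
  f <- tempfile()
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  h <- unname(tools::md5sum(f))
  unlink(f)
  h
}

log_stage <- function(log_path, stage, status, t0, extra = list()) {
  rec <- c(list(stage = stage, status = status,
                seconds = round(as.numeric(Sys.time()) - t0, 3)), extra)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = log_path, append = TRUE)
}

## persistable form of a probability volume (brick files stay on disk)
prob_meta <- function(prob) {
  list(brick_size = prob$brick_size, n_levels = prob$n_levels,
       level_dims = prob$level_dims, dims = prob$dims,
       spacing = prob$spacing, dir = prob$dir,
       state = as.list(prob$state), stats = prob$stats)
}

prob_reopen <- function(meta, cache_budget = 64L) {
  e <- new.env(parent = emptyenv())
  e$store <- new_brick_store(meta$dir, meta$brick_size, cache_budget)
  e$brick_size <- meta$brick_size
  e$n_levels <- meta$n_levels
  e$level_dims <- meta$level_dims
  e$dims <- meta$dims
  e$spacing <- meta$spacing
  e$dir <- meta$dir
  e$state <- list2env(meta$state, parent = emptyenv())
  e$stats <- meta$stats
  class(e) <- "probability_volume"
  e
}

pyr_meta <- function(pyr) pyr[setdiff(names(pyr), "store")]

pyr_reopen <- function(meta, cache_budget = 64L) {
  meta$store <- new_brick_store(meta$dir, meta$brick_size, cache_budget)
  structure(meta, class = "octree_pyramid")
}

default_config <- function() {
  list(brick_size = 32L, cache_budget = 64L,
       rw = list(beta = 90, solver_tol = 1e-6, max_iter = 2000L),
       hierarchy = list(binary_threshold = 0.5, homogeneity_eps = 0.01,
                        reuse_eps = 0.01, upsample_mode = "trilinear"),
       postprocess = list(median_radius = 1L, keep_largest = TRUE,
                          fill_cavities = TRUE),
       graph = list(bulge_threshold = 3.0),
       quantify = list(bin_width_um = 2))
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Run the full segmentation-to-morphometry pipeline
#'
#' Wires the stages end to end: load or synthesize the volume, build the
#' octree pyramid, run the hierarchical random-walker segmentation,
#' post-process the binary mask, extract and prune the vessel graph, and
#' compute the morphometry report. Every stage's output is cached under
#' `out_dir` keyed by a hash of its inputs, so re-running with an
#' unchanged configuration skips all stages; editing only the seeds
#' re-runs the segmentation incrementally against the cached result while
#' the octree stage is reused.
#'
#' @param config a YAML file path or a nested list. Recognized keys:
#'   `input` (either `phantom` = arguments for [phantom_spec()], or
#'   `volume` = path + `spacing`), `seeds` (path to a seed CSV, or
#'   `n_fg_strokes`/`n_bg_strokes` to derive strokes from phantom ground
#'   truth), `brick_size`, `cache_budget`, `rw`, `hierarchy`,
#'   `postprocess`, `graph`, `quantify`.
#' @param out_dir artifact directory.
#' @return list with `report`, `graph`, `mask`, `stats` (per-stage cache
#'   status and brick counters) and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.jsonl")
  stage_status <- list()

  cached <- function(name, key, fun) {
    t0 <- as.numeric(Sys.time())
    hfile <- file.path(out_dir, paste0(name, ".hash"))
    rfile <- file.path(out_dir, paste0(name, ".rds"))
    h <- obj_hash(key)
    if (file.exists(hfile) && file.exists(rfile) &&
        identical(readLines(hfile, warn = FALSE), h)) {
      stage_status[[name]] <<- "cached"
      log_stage(log_path, name, "cached", t0)
      return(readRDS(rfile))
    }
    val <- fun()
    saveRDS(val, rfile)
    writeLines(h, hfile)
    stage_status[[name]] <<- "computed"
    log_stage(log_path, name, "computed", t0)
    val
  }

  ## ---- input volume ----
  in_key <- cfg$input
  vol <- cached("volume", in_key, function() {
    if (!is.null(cfg$input$phantom)) {
      spec <- do.call(phantom_spec, cfg$input$phantom)
      gt <- generate_tree(spec)
      list(grid = rasterize_phantom(gt), gt = gt)
    } else {
      list(grid = read_volume(cfg$input$volume$path,
                              spacing = cfg$input$volume$spacing), gt = NULL)
    }
  })
  grid <- vol$grid

  ## ---- seeds ----
  seeds <- if (!is.null(cfg$seeds$path)) read_seeds(cfg$seeds$path)
    else if (!is.null(vol$gt))
      make_seed_file(vol$gt,
                     n_fg_strokes = cfg$seeds$n_fg_strokes %||% 2L,
                     n_bg_strokes = cfg$seeds$n_bg_strokes %||% 2L)
    else stop("config must provide seeds$path or a phantom input")

  ## ---- octree ----
  grid_hash <- obj_hash(list(grid$intensities, grid$spacing, cfg$brick_size))
  pyr_dir <- file.path(out_dir, "octree")
  meta <- cached("octree", grid_hash, function() {
    unlink(pyr_dir, recursive = TRUE)
    pyr <- build_octree(grid, brick_size = cfg$brick_size,
                        cache_budget = cfg$cache_budget, dir = pyr_dir)
    pyr_meta(pyr)
  })
  pyr <- pyr_reopen(meta, cfg$cache_budget)

  ## ---- segmentation (incremental when only seeds changed) ----
  rwc <- do.call(rw_config, cfg$rw)
  hc <- do.call(hierarchy_config, cfg$hierarchy)
  seg_key <- list(grid_hash, seeds, cfg$rw, cfg$hierarchy, cfg$cache_budget)
  t0 <- as.numeric(Sys.time())
  hfile <- file.path(out_dir, "segment.hash")
  sfile <- file.path(out_dir, "segment.rds")
  h <- obj_hash(seg_key)
  prev <- NULL
  if (file.exists(hfile) && file.exists(sfile)) {
    if (identical(readLines(hfile, warn = FALSE), h)) {
      prev_meta <- readRDS(sfile)
      prob <- prob_reopen(prev_meta$prob, cfg$cache_budget)
      stage_status$segment <- "cached"
      log_stage(log_path, "segment", "cached", t0)
    } else {
      prev_meta <- readRDS(sfile)
      same_but_seeds <- identical(prev_meta$base_hash,
                                  obj_hash(list(grid_hash, cfg$rw,
                                                cfg$hierarchy, cfg$cache_budget)))
      prev <- if (same_but_seeds) prev_meta else NULL
    }
  }
  if (is.null(stage_status$segment)) {
    prob_dir <- file.path(out_dir, if (is.null(prev)) "prob_a" else
      setdiff(c("prob_a", "prob_b"), basename(prev$prob$dir))[1])
    unlink(prob_dir, recursive = TRUE)
    prob <- if (is.null(prev))
      run_hierarchical_rw(pyr, seeds, hc, rwc, cache_budget = cfg$cache_budget,
                          dir = prob_dir)
    else
      incremental_update(prob_reopen(prev$prob, cfg$cache_budget), pyr,
                         prev$seeds, seeds, hc, rwc,
                         cache_budget = cfg$cache_budget, dir = prob_dir)
    saveRDS(list(prob = prob_meta(prob), seeds = seeds,
                 base_hash = obj_hash(list(grid_hash, cfg$rw, cfg$hierarchy,
                                           cfg$cache_budget))), sfile)
    writeLines(h, hfile)
    stage_status$segment <- if (is.null(prev)) "computed" else "incremental"
    log_stage(log_path, "segment", stage_status$segment, t0,
              list(bricks = segmentation_stats(prob)))
  }

  ## ---- postprocess ----
  mask <- cached("postprocess", list(h, cfg$postprocess), function() {
    m <- threshold_segmentation(prob, hc)
    if (cfg$postprocess$median_radius >= 1)
      m <- median_smooth(m, cfg$postprocess$median_radius)
    remove_spurious_and_fill(
      m,
      min_fg_size = if (isTRUE(cfg$postprocess$keep_largest)) NULL
                    else cfg$postprocess$min_fg_size,
      brick_size = cfg$brick_size)
  })

  ## ---- vessel graph ----
  graph <- cached("graph", list(obj_hash(mask), cfg$graph), function() {
    skel <- skeletonize(mask)
    g <- extract_graph(skel, mask, grid$spacing)
    prune_graph(g, cfg$graph$bulge_threshold)
  })
  gdir <- file.path(out_dir, "graph")
  write_graph(graph, gdir)

  ## ---- morphometry ----
  report <- cached("quantify", list(obj_hash(mask), cfg$graph, cfg$quantify),
                   function() summarize_graph(graph,
                                              bin_width_um = cfg$quantify$bin_width_um))
  write_report(report, file.path(out_dir, "report.json"))

  list(report = report, graph = graph, mask = mask,
       stats = list(stages = stage_status,
                    bricks = segmentation_stats(prob),
                    pyramid_cache = brick_cache_stats(pyr)),
       paths = list(report = file.path(out_dir, "report.json"),
                    graph = gdir, log = log_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
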