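# End-to-end orchestration: volume (or phantom) -> postprocessing ->
# skeleton -> spatial graph -> topology report, with optional disector
# verification and segmentation evaluation, all file outputs gathered
# under one run directory with a manifest.

#' Default pipeline configuration
#'
#' @param ... overrides for any configuration field (see Details).
#' @details Fields: `phantom` (lattice phantom spec: `rows`, `cols`,
#'   `pitch_nm`, `orientation_deg`, `jitter_nm`, `removed_edges`,
#'   `radius_vx`, `occlusions`, `cavities`, `salt_noise_rate`) or `input`
#'   (path to a volume readable by [read_stack()]) with `spacing_nm`;
#'   `target_spacing_nm` (resample before analysis, `NULL` = keep);
#'   `subregions` (list of `list(origin, size)` in voxels, `NULL` = whole
#'   volume); `prune_to_fixpoint`; `dissolve_chains`; `disector` (`NULL`
#'   or list(`h_dis_um`, `frame`, `margin_px`, `sampling`, `step`));
#'   `evaluate` (compare degraded phantom against the clean phantom);
#'   `outdir`; `seed`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    phantom = list(rows = 5L, cols = 5L, pitch_nm = 1800,
                   orientation_deg = 30, jitter_nm = 0,
                   removed_edges = integer(), radius_vx = 2,
                   occlusions = list(), cavities = list(),
                   salt_noise_rate = 0),
    input = NULL, spacing_nm = c(150, 150, 150),
    target_spacing_nm = NULL, subregions = NULL,
    prune_to_fixpoint = TRUE, dissolve_chains = TRUE,
    disector = NULL, evaluate = FALSE,
    outdir = tempfile("acnrun"), seed = 1L)
  over <- list(...)
  for (k in names(over)) {
    if (k %in% c("phantom", "disector") && is.list(over[[k]]) &&
        !is.null(cfg[[k]])) {
      for (kk in names(over[[k]])) cfg[[k]][[kk]] <- over[[k]][[kk]]
    } else {
      cfg[[k]] <- over[[k]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes volume acquisition (phantom generation or file input),
#' postprocessing (hole filling, largest-component selection), per
#' subregion skeletonization, graph extraction, pruning and topology
#' analysis, plus the optional disector estimate and segmentation
#' evaluation. Writes DOT and VTK graphs, CSV reports, a JSON summary and
#' a manifest into `config$outdir`. Runs are deterministic given the seed:
#' repeating a run produces byte-identical summaries.
#'
#' @param config a [run_config()] (or plain list of overrides, or a path
#'   to a JSON config file).
#' @return Invisibly, a list with the generated objects (`volume`,
#'   `graphs`, `report`, `disector`, `segeval`, `paths`).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_ctx("config file not found: ", config)
    config <- do.call(run_config,
                      jsonlite::read_json(config, simplifyVector = TRUE))
  }
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  if (!is.null(config$input) && !file.exists(config$input))
    stop_ctx("input volume not found: ", config$input)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  clean_volume <- NULL
  if (is.null(config$input)) {
    ph <- config$phantom
    net <- make_lattice_network(ph$rows, ph$cols, pitch_nm = ph$pitch_nm,
                                removed_edges = ph$removed_edges,
                                orientation_deg = ph$orientation_deg,
                                jitter_nm = ph$jitter_nm,
                                seed = config$seed)
    phantom <- voxelize_network(net$spec, radius_vx = ph$radius_vx,
                                spacing_nm = config$spacing_nm)
    clean_volume <- phantom$volume
    deg <- degrade_segmentation(phantom, occlusions = ph$occlusions,
                                cavities = ph$cavities,
                                salt_noise_rate = ph$salt_noise_rate,
                                seed = config$seed)
    volume <- deg$volume
    truth <- phantom$truth
    events <- deg$events
  } else {
    volume <- read_stack(config$input, config$spacing_nm)
    truth <- NULL
    events <- NULL
  }
  if (!is.null(config$target_spacing_nm)) {
    mode <- if (is_binary_volume(volume)) "nearest" else "linear"
    volume <- resample_isotropic(volume, config$target_spacing_nm, mode)
  }
  volume <- fill_holes(volume, "full_3d")
  volume <- largest_component(volume)

  subs <- config$subregions
  sub_volumes <- if (is.null(subs)) list(volume) else
    lapply(subs, function(s)
      largest_component(extract_subregion(volume, s$origin, s$size)))

  graphs <- list()
  disector_results <- list()
  for (i in seq_along(sub_volumes)) {
    sv <- sub_volumes[[i]]
    sk <- skeletonize(sv)
    g <- build_graph(sk)
    g <- prune_degree_one(g, to_fixpoint = config$prune_to_fixpoint)
    if (isTRUE(config$dissolve_chains)) g <- dissolve_degree_two(g)
    graphs[[i]] <- g
    write_dot(g, file.path(outdir, sprintf("graph_%02d.dot", i)))
    write_vtk_polylines(g, file.path(outdir, sprintf("graph_%02d.vtk", i)))
    if (!is.null(config$disector)) {
      ds <- config$disector
      fr <- disector_frame(ds$frame %||% "full_slice",
                           ds$margin_px %||% 0L)
      disector_results[[i]] <- disector_estimate(
        sv, h_dis_um = ds$h_dis_um %||% 1, frame = fr,
        sampling = ds$sampling %||% "exhaustive",
        step = ds$step %||% 10L, seed = config$seed)
      write_disector_csv(disector_results[[i]],
                         file.path(outdir,
                                   sprintf("disector_%02d.csv", i)))
    }
  }
  vols <- vapply(sub_volumes, volume_mm3, numeric(1))
  report <- analyze_subregions(graphs, vols)
  write_topology_csv(report, file.path(outdir, "topology.csv"))

  segeval <- NULL
  if (isTRUE(config$evaluate) && !is.null(clean_volume)) {
    segeval <- evaluate_stack(clean_volume, volume)
    write_segeval_csv(segeval, file.path(outdir, "segeval.csv"))
  }

  summary <- list(
    seed = config$seed,
    n_subregions = length(graphs),
    per_subregion = report$per_subregion,
    summary = report$summary,
    truth = if (!is.null(truth)) unclass(truth)[c("n_nodes_true",
                                                  "n_edges_true",
                                                  "n_cycles_true")],
    events = events,
    disector = lapply(disector_results, function(d)
      unclass(d)[c("sum_islands", "sum_bridges", "chi_stereol", "n_par",
                   "a_frame_um2", "h_dis_um", "nv_stereol_per_mm3")]))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null", force = TRUE)
  cfg_file <- file.path(outdir, "config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(
    package = "acntopo",
    version = as.character(utils::packageVersion("acntopo")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    files = sort(setdiff(list.files(outdir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(volume = volume, graphs = graphs, report = report,
                 disector = disector_results, segeval = segeval,
                 truth = truth, events = events, outdir = outdir))
}

#' Compare topology reports between datasets
#'
#' Percentage deviation of dataset means for node, edge, loop counts and
#' loop density for each requested pair of datasets, mirroring group
#' comparison tables (reference first: pair `c("CO", "NOX")` reports the
#' deviation of NOX relative to CO).
#'
#' @param reports named list of `topology_report`s (from
#'   [analyze_subregions()] or [run_pipeline()]).
#' @param pairs list of length-2 character vectors
#'   `c(reference, comparison)`; defaults to all ordered pairs.
#' @return Data frame with columns `pair`, `quantity`, `reference_mean`,
#'   `comparison_mean`, `percent_change` (rounded to 2 decimals in the
#'   `display` column, full precision in `percent_change`).
#' @export
compare_groups <- function(reports, pairs = NULL) {
  if (length(reports) < 2L || is.null(names(reports)))
    stop_ctx("need a named list of at least two topology reports")
  if (is.null(pairs)) {
    nm <- names(reports)
    pairs <- list()
    for (a in nm) for (b in nm) if (a != b)
      pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  qty <- c("n_nodes", "n_edges", "n_scl_polygon", "nv_polygon_per_mm3")
  rows <- list()
  for (p in pairs) {
    if (!all(p %in% names(reports)))
      stop_ctx("unknown dataset key in pair: ", paste(p, collapse = "/"))
    ra <- reports[[p[1]]]$summary
    rb <- reports[[p[2]]]$summary
    for (q in qty) {
      a <- ra$mean[ra$quantity == q]
      b <- rb$mean[rb$quantity == q]
      pc <- percent_change(a, b)
      rows[[length(rows) + 1L]] <-
        data.frame(pair = paste(p, collapse = "/"), quantity = q,
                   reference_mean = a, comparison_mean = b,
                   percent_change = pc, display = round(pc, 2))
    }
  }
  do.call(rbind, rows)
}

#' Command-line interface
#'
#' Subcommands: `generate` (write a lattice phantom),
#' `run` (end-to-end pipeline), `preprocess` (fill holes + largest
#' component on a stack), `graph` (skeletonize + extract + prune a stack
#' to DOT/VTK), `analyze` (topology report from DOT graphs), `disector`
#' (stereological estimate on a stack), `evaluate` (segmentation metrics
#' for a gt/seg stack pair), `compare` (percentage deviations between
#' topology CSVs is not supported; compare runs via run summaries).
#' Invoke via `Rscript -e 'acntopo::acn_cli()' <subcommand> [--flag value]`
#' or the script in `inst/cli/`.
#'
#' @param args character vector of command-line arguments; defaults to
#'   the process arguments.
#' @return Invisibly, the subcommand's result object.
#' @export
acn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: acn <generate|run|preprocess|graph|analyze|disector|evaluate>",
    " generate  --rows N --cols N [--radius-vx R] [--out phantom.tif]",
    " run       [--config cfg.json] [--outdir DIR] [--seed N]",
    " preprocess --in stack.tif --out clean.tif [--spacing-nm S]",
    " graph     --in stack.tif --out graph.dot [--spacing-nm S]",
    " analyze   --dot g1.dot[,g2.dot...] --volume-mm3 V [--out report.csv]",
    " disector  --in stack.tif [--h-dis-um H] [--spacing-nm S]",
    " evaluate  --gt gt.tif --seg seg.tif [--spacing-nm S] [--out out.csv]",
    sep = "\n")
  if (!length(args)) {
    cat(usage, "\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  fl <- parse_flags(args[-1])
  num <- function(k, d = NULL) if (is.null(fl[[k]])) d
    else as.numeric(fl[[k]])
  chr <- function(k, d = NULL) fl[[k]] %||% d
  sp <- num("spacing-nm", 150)
  res <- switch(cmd,
    generate = {
      net <- make_lattice_network(num("rows", 5), num("cols", 5),
                                  pitch_nm = num("pitch-nm", 1800),
                                  orientation_deg = num("orientation-deg",
                                                        30))
      ph <- voxelize_network(net$spec, radius_vx = num("radius-vx", 2),
                             spacing_nm = sp)
      out <- chr("out", "phantom.tif")
      write_phantom(ph, out)
      message("wrote ", out, " (", ph$truth$n_cycles_true, " loops)")
      ph
    },
    run = {
      cfg <- if (!is.null(fl[["config"]])) fl[["config"]] else run_config()
      if (is.character(cfg)) cfg <- do.call(
        run_config, jsonlite::read_json(cfg, simplifyVector = TRUE))
      if (!is.null(fl[["outdir"]])) cfg$outdir <- fl[["outdir"]]
      if (!is.null(fl[["seed"]])) cfg$seed <- as.integer(fl[["seed"]])
      r <- run_pipeline(cfg)
      message("run complete: ", r$outdir)
      r
    },
    preprocess = {
      v <- read_stack(chr("in"), sp)
      v <- largest_component(fill_holes(v))
      write_stack(v, chr("out", "clean.tif"))
      v
    },
    graph = {
      v <- read_stack(chr("in"), sp)
      g <- dissolve_degree_two(prune_degree_one(build_graph(skeletonize(
        largest_component(fill_holes(v))))))
      out <- chr("out", "graph.dot")
      write_dot(g, out)
      write_vtk_polylines(g, sub("\\.dot$", ".vtk", out))
      message(nrow(g$nodes), " nodes, ", nrow(g$edges), " edges")
      g
    },
    analyze = {
      dots <- strsplit(chr("dot"), ",")[[1]]
      graphs <- lapply(dots, read_dot)
      rep <- analyze_subregions(graphs,
                                rep(num("volume-mm3"), length(graphs)))
      out <- chr("out", "report.csv")
      write_topology_csv(rep, out)
      print(rep)
      rep
    },
    disector = {
      v <- read_stack(chr("in"), sp)
      d <- disector_estimate(v, h_dis_um = num("h-dis-um", 1))
      print(d)
      d
    },
    evaluate = {
      m <- evaluate_stack(read_stack(chr("gt"), sp),
                          read_stack(chr("seg"), sp))
      write_segeval_csv(m, chr("out", "segeval.csv"))
      print(m)
      m
    },
    {
      cat(usage, "\n")
      stop_ctx("unknown subcommand: ", cmd)
    })
  invisible(res)
}

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_ctx("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}
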