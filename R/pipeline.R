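#' Validate a pipeline run configuration
#'
#' A run config bundles every knob of the full analysis: the input (paths to
#' a wiring table + metadata, or a synthetic spec), the teleportation
#' parameter, the Markov-time grid, ensemble size, selection thresholds, the
#' propagation scenarios, the screen mode and the master seed. `mode =
#' "screen"` uses the reduced settings (50 time points, ell = 20) suitable
#' for exhaustive ablation screens; `mode = "paper"` uses the full-resolution
#' settings (200 points, ell = 100).
#'
#' @param cfg a named list or a path to a YAML file.
#' @return validated config list (class `run_config`).
#' @export
run_config <- function(cfg = list()) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  defaults <- list(edge_path = NULL, metadata_path = NULL, synthetic = NULL,
                   tau = 0.85, t_min = 0.01, t_max = 1000,
                   mode = c("screen", "paper"), eps_plateau = 0.02,
                   dip_threshold = 0.05, strong_threshold = 1 + 2 / 3,
                   alpha = 0.95, scenarios = NULL, run_ablation = TRUE,
                   n_times = NULL, ell = NULL, seed = 1)
  cfg <- utils::modifyList(defaults, cfg)
  cfg$mode <- match.arg(cfg$mode, c("screen", "paper"))
  if (is.null(cfg$edge_path) && is.null(cfg$synthetic))
    stop("config needs either 'edge_path' or a 'synthetic' spec")
  if (!is.null(cfg$edge_path) && !file.exists(cfg$edge_path))
    stop("input file does not exist: ", cfg$edge_path)
  if (!is.null(cfg$metadata_path) && !file.exists(cfg$metadata_path))
    stop("input file does not exist: ", cfg$metadata_path)
  stopifnot(cfg$tau > 0, cfg$tau < 1, cfg$eps_plateau > 0,
            cfg$dip_threshold > 0, cfg$strong_threshold > 0)
  if (!is.null(cfg$synthetic) && !inherits(cfg$synthetic, "synthetic_spec"))
    cfg$synthetic <- do.call(synthetic_spec, cfg$synthetic)
  structure(cfg, class = "run_config")
}

#' Run the full flow-analysis pipeline
#'
#' Executes, in dependency order: (1) data loading or synthesis, (2) the
#' transition system and stationary distribution, (3) the Markov Stability
#' sweep with robust-partition selection, (4) the single-ablation screen with
#' outlier detection (optional), (5) flow-role extraction, (6) stimulus
#' propagation for each configured scenario. Each stage writes its outputs
#' under `out_dir` and the run finishes with a `manifest.json` recording the
#' configuration, seeds and per-stage outputs. Stages whose outputs already
#' exist are skipped when `resume = TRUE`.
#'
#' @param cfg a [run_config()] (or list/path coercible to one).
#' @param out_dir output directory.
#' @param resume skip stages whose output files already exist.
#' @return the manifest, invisibly.
#' @export
run_all <- function(cfg, out_dir, resume = FALSE) {
  cfg <- run_config(if (inherits(cfg, "run_config")) unclass(cfg) else cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_times <- cfg$n_times %||% if (cfg$mode == "paper") 200L else 50L
  ell <- cfg$ell %||% if (cfg$mode == "paper") 100L else 20L
  times <- geomspace(cfg$t_min, cfg$t_max, n_times)
  stage_files <- list()
  done <- function(stage, files) stage_files[[stage]] <<- files

  # stage 1: data
  if (!is.null(cfg$edge_path)) {
    conn <- largest_weak_component(
      read_wiring_table(cfg$edge_path, cfg$metadata_path))
    truth <- NULL
  } else {
    gen <- generate_connectome(cfg$synthetic)
    conn <- gen$connectome
    truth <- gen$truth
  }
  f <- file.path(out_dir, "connectome")
  write_connectome(conn, f)
  done("data", file.path(f, c("edges.tsv", "metadata.csv")))

  # stage 2: dynamics
  ts <- build_transition_system(conn, cfg$tau)
  f <- file.path(out_dir, "stationary.csv")
  utils::write.csv(data.frame(node = ts$nodes, pagerank = ts$pi,
                              sink = ts$sink_mask, row.names = NULL), f,
                   row.names = FALSE)
  done("dynamics", f)

  # stage 3: partitions
  f_sweep <- file.path(out_dir, "sweep.csv")
  f_assign <- file.path(out_dir, "assignments.csv")
  f_sel <- file.path(out_dir, "robust_partitions.json")
  sw <- markov_sweep(ts, times = times, ell = ell,
                     seed = derive_seed(cfg$seed, 3))
  sel <- select_robust_partitions(sw, eps_plateau = cfg$eps_plateau,
                                  dip_threshold = cfg$dip_threshold)
  utils::write.csv(data.frame(time = sw$times,
                              n_communities = sw$n_communities,
                              stability = sw$r, mean_vi = sw$mean_vi), f_sweep,
                   row.names = FALSE)
  utils::write.csv(data.frame(node = sw$nodes, sw$partitions), f_assign,
                   row.names = FALSE)
  jsonlite::write_json(lapply(sel, function(s)
    list(t_start = s$t_start, t_end = s$t_end, t_best = s$t_best,
         mean_vi = s$mean_vi, n_communities = s$n_communities,
         assignment = as.list(s$partition))), f_sel, auto_unbox = TRUE)
  done("partitions", c(f_sweep, f_assign, f_sel))

  # stage 4: single-ablation screen
  if (isTRUE(cfg$run_ablation)) {
    refs <- lapply(sel, `[[`, "partition")
    names(refs) <- paste0("P", seq_along(refs))
    f <- file.path(out_dir, "single_ablations.csv")
    if (!(resume && file.exists(f))) {
      scr <- single_screen(conn, tau = cfg$tau, times = times, ell = ell,
                           seed = derive_seed(cfg$seed, 4),
                           references = if (length(refs)) refs)
      tab <- data.frame(node = scr$nodes, row.names = NULL)
      if (!is.null(scr$cv)) {
        tab <- cbind(tab, as.data.frame(scr$cv))
        for (rf in colnames(scr$cv)) {
          flag <- scr$nodes %in% ipr_outliers(stats::setNames(scr$cv[, rf],
                                                              scr$nodes))
          tab[[paste0("ipr_outlier.", rf)]] <- flag
        }
      }
      utils::write.csv(tab, f, row.names = FALSE)
    }
    done("ablation", f)
  }

  # stage 5: flow roles
  f <- file.path(out_dir, "roles.csv")
  roles <- flow_roles(conn, alpha = cfg$alpha, tau = cfg$tau, times = times,
                      ell = ell, seed = derive_seed(cfg$seed, 5))
  utils::write.csv(data.frame(node = names(roles$labels),
                              role = roles$labels, row.names = NULL), f,
                   row.names = FALSE)
  done("roles", f)

  # stage 6: propagation
  scenarios <- cfg$scenarios
  if (is.null(scenarios)) {
    # default input: the highest-PageRank non-sink nodes (a generic stimulus)
    k <- min(4L, length(ts$nodes))
    scenarios <- list(default = ts$nodes[order(ts$pi,
                                               decreasing = TRUE)][seq_len(k)])
  }
  f <- file.path(out_dir, "propagation.csv")
  prop_rows <- lapply(names(scenarios), function(sc) {
    tr <- propagation_trace(ts, make_input(conn, scenarios[[sc]]),
                            strong_threshold = cfg$strong_threshold)
    data.frame(scenario = sc, node = ts$nodes, q_max = tr$q_max,
               peak_time = tr$peak_time,
               strong = ts$nodes %in% tr$strong_set, row.names = NULL)
  })
  utils::write.csv(do.call(rbind, prop_rows), f, row.names = FALSE)
  done("propagation", f)

  manifest <- list(
    package_version = as.character(utils::packageVersion("wormflow")),
    seed = cfg$seed, tau = cfg$tau, mode = cfg$mode,
    n_times = n_times, ell = ell,
    n_nodes = length(conn$nodes),
    planted_truth = !is.null(truth),
    stages = stage_files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
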