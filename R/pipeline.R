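#' Assemble a pipeline configuration
#'
#' Collects every stage toggle and tunable parameter of the end-to-end
#' workflow into one nested list that round-trips losslessly to YAML, so a
#' run can be reproduced from its recorded configuration alone. Every
#' parameter has a recorded default; [run_pipeline()] writes the fully
#' resolved configuration next to its outputs for provenance.
#'
#' @param out_dir Output directory for all stage tables and logs.
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param stages Character vector of stages to run, in order, among
#'   `"simulate"`, `"features"`, `"cluster"`, `"calcium"`, `"morphometry"`,
#'   `"behavior"`.
#' @param tracks List of track featurization parameters: `angle_threshold`
#'   (degrees), `min_step` (um).
#' @param cluster List: `k_max`, `n_restarts`, `standardize`.
#' @param calcium List: `threshold` (z units), `min_gap` (samples).
#' @param behavior List: `hp_cutoff` (Hz), `window` (s), `amp_threshold`
#'   (signal units), `normalize_window` (s).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "olcquant_run", seed = 1,
                            stages = c("simulate", "features", "cluster",
                                       "calcium", "morphometry", "behavior"),
                            tracks = list(), cluster = list(),
                            calcium = list(), behavior = list()) {
  check_number(seed, "seed", integerish = TRUE)
  known <- c("simulate", "features", "cluster", "calcium", "morphometry",
             "behavior")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  defaults <- list(
    tracks = list(angle_threshold = 90, min_step = 2),
    cluster = list(k_max = 8, n_restarts = 20, standardize = TRUE),
    calcium = list(threshold = 2, min_gap = 1),
    behavior = list(hp_cutoff = 5, window = 0.5, amp_threshold = 0.5,
                    normalize_window = 20)
  )
  merge_defaults <- function(user, def) utils::modifyList(def, user)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 tracks = merge_defaults(tracks, defaults$tracks),
                 cluster = merge_defaults(cluster, defaults$cluster),
                 calcium = merge_defaults(calcium, defaults$calcium),
                 behavior = merge_defaults(behavior, defaults$behavior)),
            class = "pipeline_config")
}

#' Read and write pipeline configurations as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(out_dir = raw$out_dir %||% "olcquant_run",
                  seed = raw$seed %||% 1,
                  stages = unlist(raw$stages),
                  tracks = raw$tracks %||% list(),
                  cluster = raw$cluster %||% list(),
                  calcium = raw$calcium %||% list(),
                  behavior = raw$behavior %||% list())
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the quantification pipeline end to end
#'
#' Executes the enabled stages in order — simulate (seeded synthetic tracks,
#' calcium cohort, sheath table, behavior cohort), track featurization,
#' migration clustering, calcium event calling, sheath morphometry, shiver
#' scoring — writing one CSV per output table under `config$out_dir`,
#' together with the fully resolved configuration
#' (`resolved_config.yaml`) and a stage-tagged run log (`run.log`).
#' Downstream stages read the simulate stage's CSVs, so pre-existing input
#' tables of the same names can be analyzed by omitting `"simulate"` from
#' the stages. Identical configuration and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages (they are always written to the
#'   log file). Default `FALSE`.
#' @return Invisibly, a named list of the tables each stage produced.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    writeLines(line, log_con)
    if (!quiet) message(line)
  }
  path_of <- function(name) file.path(config$out_dir, name)
  need <- function(stage, name) {
    p <- path_of(name)
    if (!file.exists(p)) {
      abort(sprintf("stage '%s': required input %s is missing (run the simulate stage or provide it)",
                    stage, name))
    }
    p
  }
  write_pipeline_config(config, path_of("resolved_config.yaml"))
  out <- list()

  if ("simulate" %in% config$stages) {
    say("simulate", "generating seeded synthetic datasets (seed %d)", config$seed)
    tr_sim <- generate_tracks(track_sim_config(seed = config$seed))
    write_tracks_csv(tr_sim$tracks, path_of("tracks.csv"))
    utils::write.csv(
      data.frame(track_id = vapply(tr_sim$tracks, function(t) t$track_id,
                                   character(1)),
                 true_cluster = tr_sim$labels),
      path_of("track_labels.csv"), row.names = FALSE)
    ca_sim <- generate_calcium_cohort(seed = config$seed + 10L)
    write_traces_csv(ca_sim$traces, path_of("traces.csv"))
    utils::write.csv(ca_sim$truth, path_of("trace_truth.csv"), row.names = FALSE)
    sheaths <- generate_sheaths(sheath_sim_config(seed = config$seed + 20L))
    utils::write.csv(sheaths, path_of("sheaths.csv"), row.names = FALSE)
    be_sim <- generate_shiver_cohort(seed = config$seed + 30L)
    be_df <- do.call(rbind, lapply(be_sim$traces, function(tr) {
      data.frame(animal_id = tr$animal_id, group = tr$group, t_s = tr$t_s,
                 signal = tr$signal, stringsAsFactors = FALSE)
    }))
    utils::write.csv(be_df, path_of("behavior.csv"), row.names = FALSE)
    utils::write.csv(be_sim$truth, path_of("behavior_truth.csv"),
                     row.names = FALSE)
    say("simulate", "wrote tracks.csv, traces.csv, sheaths.csv, behavior.csv (+ truth tables)")
    out$simulate <- list(tracks = tr_sim, calcium = ca_sim,
                         sheaths = sheaths, behavior = be_sim)
  }

  if ("features" %in% config$stages) {
    tracks <- read_tracks_csv(need("features", "tracks.csv"))
    feats <- featurize_tracks(tracks,
                              angle_threshold = config$tracks$angle_threshold,
                              min_step = config$tracks$min_step)
    utils::write.csv(feats, path_of("features.csv"), row.names = FALSE)
    say("features", "featurized %d tracks -> features.csv", nrow(feats))
    out$features <- feats
  }

  if ("cluster" %in% config$stages) {
    feats <- utils::read.csv(need("cluster", "features.csv"),
                             stringsAsFactors = FALSE)
    res <- elbow_select_k(feats, k_max = min(config$cluster$k_max, nrow(feats)),
                          seed = config$seed,
                          n_restarts = config$cluster$n_restarts,
                          standardize = config$cluster$standardize)
    utils::write.csv(data.frame(track_id = feats$track_id, cluster = res$labels),
                     path_of("cluster_labels.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(res$centroids), path_of("centroids.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(k = seq_along(res$wcss_curve),
                                wcss = as.numeric(res$wcss_curve)),
                     path_of("wcss.csv"), row.names = FALSE)
    say("cluster", "elbow selected k = %d (WCSS %.3f)", res$k, res$wcss)
    out$cluster <- res
  }

  if ("calcium" %in% config$stages) {
    traces <- read_traces_csv(need("calcium", "traces.csv"))
    results <- lapply(traces, detect_calcium_events,
                      threshold = config$calcium$threshold,
                      min_gap_samples = config$calcium$min_gap)
    events <- do.call(rbind, lapply(results, function(r) {
      if (!r$n_peaks) return(NULL)
      data.frame(cell_id = r$cell_id, animal_id = r$animal_id,
                 start = r$events$start, end = r$events$end,
                 peak_z = r$events$peak_z, stringsAsFactors = FALSE)
    }))
    if (is.null(events)) {
      events <- data.frame(cell_id = character(0), animal_id = character(0),
                           start = integer(0), end = integer(0),
                           peak_z = numeric(0))
    }
    utils::write.csv(events, path_of("calcium_events.csv"), row.names = FALSE)
    act <- percent_active(results)
    utils::write.csv(act$per_animal, path_of("calcium_per_animal.csv"),
                     row.names = FALSE)
    hm <- activity_heatmap(results)
    utils::write.csv(hm, path_of("calcium_heatmap.csv"))
    say("calcium", "%d/%d cells active; mean per-animal activity %.1f%%",
        sum(vapply(results, function(r) r$is_active, logical(1))),
        length(results), act$mean_percent)
    out$calcium <- list(results = results, percent_active = act)
  }

  if ("morphometry" %in% config$stages) {
    sheaths <- utils::read.csv(need("morphometry", "sheaths.csv"),
                               stringsAsFactors = FALSE)
    cmp_len <- group_compare(sheaths, "length")
    cmp_wid <- group_compare(sheaths, "width")
    summary <- rbind(cbind(field = "length", cmp_len$summary),
                     cbind(field = "width", cmp_wid$summary))
    utils::write.csv(summary, path_of("morphometry_summary.csv"),
                     row.names = FALSE)
    stab <- do.call(rbind, lapply(unique(sheaths$fish_id), function(f) {
      st <- stability_test(sheaths, "length", fish_id = f)
      data.frame(fish_id = f, F = st$statistic, p_value = st$p_value,
                 degenerate = st$degenerate, stringsAsFactors = FALSE)
    }))
    utils::write.csv(stab, path_of("morphometry_stability.csv"),
                     row.names = FALSE)
    say("morphometry", "length %.2f vs %.2f um (Welch p = %.3g)",
        cmp_len$summary$mean[1], cmp_len$summary$mean[2], cmp_len$p_value)
    out$morphometry <- list(length = cmp_len, width = cmp_wid,
                            stability = stab)
  }

  if ("behavior" %in% config$stages) {
    be <- utils::read.csv(need("behavior", "behavior.csv"),
                          stringsAsFactors = FALSE)
    scores <- lapply(split(be, be$animal_id), function(sub) {
      tr <- behavior_trace(sub$animal_id[1], sub$t_s, sub$signal,
                           group = sub$group[1])
      tr <- normalize_window(tr, config$behavior$normalize_window)
      detect_shiver(tr, hp_cutoff = config$behavior$hp_cutoff,
                    window = config$behavior$window,
                    amp_threshold = config$behavior$amp_threshold)
    })
    score_df <- do.call(rbind, lapply(scores, function(s) {
      data.frame(animal_id = s$animal_id, group = s$group,
                 shiver_fraction = s$shiver_fraction,
                 analyzed_duration = s$analyzed_duration,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(score_df, path_of("shiver_scores.csv"), row.names = FALSE)
    gsum <- group_behavior_summary(unname(scores))
    utils::write.csv(gsum$summary, path_of("behavior_group_summary.csv"),
                     row.names = FALSE)
    if (!is.null(gsum$pairwise)) {
      utils::write.csv(gsum$pairwise, path_of("behavior_pairwise.csv"),
                       row.names = FALSE)
    }
    say("behavior", "scored %d animals in %d group(s)", nrow(score_df),
        nrow(gsum$summary))
    out$behavior <- list(scores = scores, summary = gsum)
  }

  say("done", "outputs in %s", normalizePath(config$out_dir))
  invisible(out)
}
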