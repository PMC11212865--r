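#' Pipeline configuration with validated defaults
#'
#' Defaults mirror the reference analysis settings: 20–500 ms window,
#' 70 V/m activation threshold, resolution 1, 1000 Louvain runs, 1000
#' permutations, alpha 0.05.
#'
#' @param window analysis window in ms (length-2 numeric).
#' @param threshold E-field activation threshold in V/m.
#' @param gamma modularity resolution parameter.
#' @param n_runs Louvain runs for consensus clustering.
#' @param n_perm permutations for the channel-COS null.
#' @param alpha significance level.
#' @param seed base seed for every stochastic stage.
#' @param midline midline-site orientation rule.
#' @param correction pairwise correction method.
#' @param n_sites,n_channels,n_timepoints,n_communities,snr synthetic
#'   generator settings used when the pipeline simulates its input.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(window = c(20, 500), threshold = 70,
                            gamma = 1, n_runs = 1000L, n_perm = 1000L,
                            alpha = 0.05, seed = 1L,
                            midline = "left", correction = "tukey",
                            n_sites = 72L, n_channels = 95L,
                            n_timepoints = 481L, n_communities = 3L,
                            snr = 5) {
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("`window` must be an increasing length-2 vector (ms)",
         call. = FALSE)
  }
  stop_if_not_scalar_number(threshold, "threshold", positive = TRUE)
  stop_if_not_scalar_number(gamma, "gamma", positive = TRUE)
  if (n_runs < 2L) stop("`n_runs` must be >= 2", call. = FALSE)
  if (n_perm < 100L) stop("`n_perm` must be >= 100", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(window = window, threshold = threshold, gamma = gamma,
                 n_runs = as.integer(n_runs), n_perm = as.integer(n_perm),
                 alpha = alpha, seed = as.integer(seed),
                 midline = midline, correction = correction,
                 n_sites = as.integer(n_sites),
                 n_channels = as.integer(n_channels),
                 n_timepoints = as.integer(n_timepoints),
                 n_communities = as.integer(n_communities), snr = snr),
            class = "pipeline_config")
}

#' Run the full stimulus-response mapping pipeline
#'
#' Executes the stages end to end on either a supplied `tep_dataset` or a
#' freshly simulated one: simulate, features (both perspectives), cluster
#' (both perspectives, consensus), coil-orientation sensitivity (site
#' agreement/dissimilarity and channel permutation scan), ROI/degree
#' measures, and across-community comparisons. Stage outputs are written
#' under `out_dir` and summarized in a manifest with per-stage file
#' checksums.
#'
#' @param config a [pipeline_config()].
#' @param tep optional `tep_dataset`; simulated from `config` when absent.
#' @param out_dir output directory (a temporary directory by default).
#' @return list with the per-stage results and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), tep = NULL,
                         out_dir = tempfile("tepmap-run-")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  note <- function(stage, files) {
    sums <- tools::md5sum(files)
    manifest$stages[[stage]] <<- list(
      files = basename(files),
      md5 = unname(sums))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## 1 simulate (or ingest)
  tep <- run_stage("simulate", {
    if (is.null(tep)) {
      tep <- simulate_tep_dataset(
        n_sites = config$n_sites, n_channels = config$n_channels,
        n_timepoints = config$n_timepoints,
        n_communities = config$n_communities,
        snr = config$snr, seed = config$seed)
    }
    write_tep_dataset(tep, file.path(out_dir, "dataset"))
    tep
  })
  note("simulate", list.files(file.path(out_dir, "dataset"),
                              full.names = TRUE))

  ## 2 features
  feats <- run_stage("features", {
    ## clamp the configured window to the recorded axis
    win <- extract_window(tep,
                          max(config$window[1], min(tep$time)),
                          min(config$window[2], max(tep$time)))
    win <- regress_out_covariate(win)
    stim <- stimulation_feature_matrix(win)
    chan <- channel_feature_matrix(win)
    sim_stim <- similarity_matrix(stim)
    sim_chan <- similarity_matrix(chan)
    write_array(sim_stim, file.path(out_dir, "similarity_stimulation"))
    write_array(sim_chan, file.path(out_dir, "similarity_channel"))
    list(tep = win, stim = stim, chan = chan,
         sim_stim = sim_stim, sim_chan = sim_chan)
  })
  note("features", file.path(out_dir, paste0(
    "similarity_", rep(c("stimulation", "channel"), each = 2),
    c(".bin", ".json"))))

  ## 3 cluster, both perspectives
  parts <- run_stage("cluster", {
    p_stim <- consensus_communities(feats$sim_stim,
                                    n_runs = config$n_runs,
                                    gamma = config$gamma,
                                    seed = config$seed)
    p_chan <- consensus_communities(feats$sim_chan,
                                    n_runs = config$n_runs,
                                    gamma = config$gamma,
                                    seed = config$seed + 10000L)
    write_tsv(data.frame(node_id = names(p_stim$labels),
                         community = p_stim$labels),
              file.path(out_dir, "communities_stimulation.tsv"))
    write_tsv(data.frame(node_id = names(p_chan$labels),
                         community = p_chan$labels),
              file.path(out_dir, "communities_channel.tsv"))
    jsonlite::write_json(list(q_mean_stimulation = p_stim$q_mean,
                              q_mean_channel = p_chan$q_mean),
                         file.path(out_dir, "modularity.json"),
                         auto_unbox = TRUE, digits = NA)
    list(stimulation = p_stim, channel = p_chan)
  })
  note("cluster", file.path(out_dir, c("communities_stimulation.tsv",
                                       "communities_channel.tsv",
                                       "modularity.json")))

  ## 4 coil-orientation sensitivity, both perspectives
  cos <- run_stage("cos", {
    pairs <- orientation_pairs(feats$tep)
    agree <- cos_agreement(parts$stimulation$labels, pairs)
    diss <- orientation_dissimilarity(feats$stim, pairs)
    chan_scan <- channel_cos_scan(feats$tep, n_perm = config$n_perm,
                                  seed = config$seed,
                                  alpha = config$alpha,
                                  midline = config$midline)
    write_tsv(cbind(agree$per_site, dissimilarity = unname(diss)),
              file.path(out_dir, "cos_sites.tsv"))
    write_tsv(chan_scan, file.path(out_dir, "cos_channels.tsv"))
    list(agreement = agree, dissimilarity = diss, channels = chan_scan)
  })
  note("cos", file.path(out_dir, c("cos_sites.tsv", "cos_channels.tsv")))

  ## 5 ROI / degree measures
  measures <- run_stage("roi_measures", {
    maps <- simulate_efield_maps(feats$tep, seed = config$seed + 1L,
                                 threshold = config$threshold)
    rois <- lapply(maps, extract_roi, threshold = config$threshold)
    stack <- simulate_connectome_stack(
      feats$tep, truth_labels = feats$tep$truth_labels,
      seed = config$seed + 2L)
    metrics <- stack_degree_metrics(
      stack, roi_areas = vapply(rois, `[[`, numeric(1), "size"))
    roi_tab <- data.frame(
      condition_id = vapply(rois, `[[`, character(1), "condition_id"),
      roi_size = vapply(rois, `[[`, numeric(1), "size"),
      roi_mean_intensity = vapply(rois, `[[`, numeric(1),
                                  "mean_intensity"))
    write_tsv(roi_tab, file.path(out_dir, "roi_summary.tsv"))
    write_tsv(metrics, file.path(out_dir, "degree_metrics.tsv"))
    list(rois = roi_tab, metrics = metrics)
  })
  note("roi_measures", file.path(out_dir, c("roi_summary.tsv",
                                            "degree_metrics.tsv")))

  ## 6 across-community comparisons
  compare <- run_stage("compare", {
    res <- compare_across_communities(
      measures$metrics, parts$stimulation$labels,
      covariate = feats$tep$conditions$suds,
      alpha = config$alpha, method = config$correction)
    write_tsv(res, file.path(out_dir, "community_comparisons.tsv"))
    res
  })
  note("compare", file.path(out_dir, "community_comparisons.tsv"))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(tep = feats$tep, partitions = parts, cos = cos,
       measures = measures, comparisons = compare,
       manifest = manifest, out_dir = out_dir)
}
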