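#' Simulate a trial-averaged TMS-EEG mapping dataset
#'
#' Generates a `tep_dataset` with the statistical structure the downstream
#' analysis assumes: each stimulation site belongs to one of
#' `n_communities` planted response communities, each community has its own
#' spatiotemporal TEP template (a sum of damped-oscillation peaks with
#' dipole-like channel topographies and community-specific peak latencies),
#' and every site is stimulated with two coil orientations (N45 and P45).
#' The P45 response of a site equals its N45 response with the component
#' topographies partially rotated; the per-site `orientation_sensitivity`
#' scalar in \[0, 1\] controls how different the two orientations are, which
#' lets callers plant both low- and high-sensitivity sites. White Gaussian
#' noise is added per channel-timepoint with standard deviation
#' `template RMS / snr`.
#'
#' Subjective-distress (SUDS) covariate values are drawn uniformly in
#' \[0, 100\]; `suds_leakage` optionally scales each condition's amplitude
#' linearly in its SUDS value so that covariate regression has a real
#' effect to remove.
#'
#' @param n_sites number of stimulation sites; each contributes two
#'   conditions (orientations N45 and P45).
#' @param n_channels number of EEG channels (default 95).
#' @param n_timepoints number of samples in the analysis window
#'   (default 481, i.e. 20–500 ms at 1 kHz).
#' @param n_communities number of planted response communities.
#' @param snr signal-to-noise ratio, template RMS over noise SD. Use `Inf`
#'   for noise-free data.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @param orientation_sensitivity scalar or per-site vector in \[0, 1\]:
#'   0 makes the two orientations identical, 1 fully rotates the
#'   topography.
#' @param suds_leakage linear leakage of the SUDS covariate into TEP
#'   amplitude (0 = none).
#' @param n_validation_sites number of trailing sites flagged as the
#'   validation set; the rest form the discovery set.
#' @param t_start,fs window start (ms) and sampling rate (Hz).
#' @return An object of class `tep_dataset`: a list with `voltages`
#'   (conditions x channels x timepoints array, µV), `conditions`
#'   (data frame: condition_id, site_label, hemisphere, orientation, set,
#'   suds), `channels` (label, x, y, z in mm), `time` (ms) and
#'   `truth_labels` (planted community per condition).
#' @examples
#' tep <- simulate_tep_dataset(n_sites = 6, n_channels = 10,
#'                             n_timepoints = 50, n_communities = 2,
#'                             snr = 5, seed = 1)
#' dim(tep$voltages)
#' @export
simulate_tep_dataset <- function(n_sites,
                                 n_channels = 95L,
                                 n_timepoints = 481L,
                                 n_communities = 3L,
                                 snr = 5,
                                 seed = 1L,
                                 orientation_sensitivity = 0.2,
                                 suds_leakage = 0,
                                 n_validation_sites = 0L,
                                 t_start = 20,
                                 fs = 1000) {
  if (n_sites < 1 || n_channels < 1 || n_timepoints < 2 || n_communities < 1) {
    stop("all dimensions must be positive (and n_timepoints >= 2)",
         call. = FALSE)
  }
  if (n_communities > n_sites) {
    stop("`n_communities` cannot exceed `n_sites`", call. = FALSE)
  }
  if (!is.numeric(snr) || snr <= 0) {
    stop("`snr` must be positive", call. = FALSE)
  }
  if (any(orientation_sensitivity < 0) || any(orientation_sensitivity > 1)) {
    stop("`orientation_sensitivity` must lie in [0, 1]", call. = FALSE)
  }
  os <- rep_len(orientation_sensitivity, n_sites)

  time_ms <- t_start + (seq_len(n_timepoints) - 1L) * 1000 / fs
  chan_pos <- scalp_layout(n_channels)
  site_pos <- scalp_layout(n_sites, radius = 80)

  with_seed(seed, {
    site_comm <- sample(rep_len(seq_len(n_communities), n_sites))
    geoms <- lapply(seq_len(n_communities), community_geometry)
    templates <- lapply(geoms, build_template, chan_pos = chan_pos,
                        time_ms = time_ms)
    ## rotated-topography variants used to build the P45 orientation
    templates_rot <- lapply(geoms, build_template, chan_pos = chan_pos,
                            time_ms = time_ms, rotate = TRUE)

    n_cond <- 2L * n_sites
    suds <- round(stats::runif(n_cond, 0, 100), 1)
    voltages <- array(0, dim = c(n_cond, n_channels, n_timepoints))
    truth <- integer(n_cond)
    cond_meta <- vector("list", n_cond)
    k <- 0L
    for (s in seq_len(n_sites)) {
      cc <- site_comm[s]
      base <- templates[[cc]]
      rot <- templates_rot[[cc]]
      for (orient in c("N45", "P45")) {
        k <- k + 1L
        tmpl <- if (orient == "N45") base else {
          (1 - os[s]) * base + os[s] * rot
        }
        rms <- sqrt(mean(tmpl^2))
        noise_sd <- if (is.finite(snr)) rms / snr else 0
        amp <- 1 + suds_leakage * (suds[k] - 50) / 50
        noise <- if (noise_sd > 0) {
          matrix(stats::rnorm(n_channels * n_timepoints, sd = noise_sd),
                 n_channels, n_timepoints)
        } else 0
        voltages[k, , ] <- amp * tmpl + noise
        truth[k] <- cc
        cond_meta[[k]] <- data.frame(
          condition_id = sprintf("S%03d_%s", s, orient),
          site_label = sprintf("S%03d", s),
          hemisphere = hemisphere_of(site_pos[s, "x"]),
          orientation = orient,
          set = if (s > n_sites - n_validation_sites) "validation"
                else "discovery",
          suds = suds[k],
          stringsAsFactors = FALSE
        )
      }
    }
    conditions <- do.call(rbind, cond_meta)
    dimnames(voltages) <- list(conditions$condition_id,
                               chan_pos$label, NULL)
    structure(
      list(voltages = voltages,
           conditions = conditions,
           channels = chan_pos,
           time = time_ms,
           truth_labels = truth),
      class = "tep_dataset")
  })
}

#' @export
print.tep_dataset <- function(x, ...) {
  cat(sprintf("tep_dataset: %d conditions x %d channels x %d timepoints\n",
              dim(x$voltages)[1], dim(x$voltages)[2], dim(x$voltages)[3]))
  cat(sprintf("  window %.0f-%.0f ms; sets: %s\n",
              min(x$time), max(x$time),
              paste(sprintf("%s=%d", names(table(x$conditions$set)),
                            table(x$conditions$set)), collapse = ", ")))
  invisible(x)
}

## Deterministic sensor/site layout: Fibonacci spiral over the upper
## hemisphere of a sphere, giving a roughly even scalp coverage.
scalp_layout <- function(n, radius = 90) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - i / n)           # polar angle, 0 (vertex) .. pi/2-ish
  theta <- pi * (1 + sqrt(5)) * i  # golden-angle azimuth
  data.frame(label = sprintf("E%03d", seq_len(n)),
             x = radius * sin(phi) * cos(theta),
             y = radius * sin(phi) * sin(theta),
             z = radius * cos(phi),
             stringsAsFactors = FALSE)
}

hemisphere_of <- function(x, tol = 1) {
  ifelse(abs(x) < tol, "midline", ifelse(x < 0, "left", "right"))
}

## Dipole-like topography: difference of two Gaussians centred at nearby
## scalp positions, mimicking the sign-reversing field of a tangential
## source.
dipole_topography <- function(chan_pos, centre, axis, sigma = 45) {
  p <- as.matrix(chan_pos[, c("x", "y", "z")])
  c1 <- centre + 20 * axis
  c2 <- centre - 20 * axis
  d1 <- sqrt(rowSums(sweep(p, 2, c1)^2))
  d2 <- sqrt(rowSums(sweep(p, 2, c2)^2))
  topo <- exp(-d1^2 / (2 * sigma^2)) - exp(-d2^2 / (2 * sigma^2))
  topo / max(abs(topo))
}

## Draws one community's component geometry and time course from the
## active RNG: each community gets its own randomly placed dipoles with
## community-specific peak latencies and frequencies, keeping communities
## well separated in both space and time. `community` only offsets the
## latency bands so communities never share a peak time.
community_geometry <- function(community) {
  n_comp <- 3L
  phi <- stats::runif(n_comp, 0.15, 1.3)        # polar angle on the scalp
  theta <- stats::runif(n_comp, 0, 2 * pi)
  centres <- cbind(90 * sin(phi) * cos(theta),
                   90 * sin(phi) * sin(theta),
                   90 * cos(phi))
  tang <- stats::runif(n_comp, 0, 2 * pi)       # tangential dipole axis
  axes <- cbind(-sin(theta) * cos(tang) - cos(theta) * cos(phi) * sin(tang),
                cos(theta) * cos(tang) - sin(theta) * cos(phi) * sin(tang),
                sin(phi) * sin(tang))
  list(centres = centres, axes = axes,
       latencies = c(35, 100, 190) + (community - 1) * c(16, 32, 60) +
         stats::runif(n_comp, 0, 8),
       freqs = c(30, 11, 5) * stats::runif(n_comp, 0.85, 1.15),
       decays = c(18, 45, 90),
       amps = c(6, 4, 3))
}

## Community template: sum of damped-oscillation peaks with dipole-like
## topographies from `community_geometry()`. With `rotate = TRUE` the
## dipole geometry is rotated 90 degrees about the vertex axis, modelling
## the orthogonal coil orientation; the time course is unchanged.
build_template <- function(geom, chan_pos, time_ms, rotate = FALSE) {
  out <- matrix(0, nrow(chan_pos), length(time_ms))
  rot <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  for (p in seq_along(geom$latencies)) {
    centre <- geom$centres[p, ]
    axis <- geom$axes[p, ]
    if (rotate) {
      centre <- as.vector(rot %*% centre)
      axis <- as.vector(rot %*% axis)
    }
    topo <- dipole_topography(chan_pos, centre, axis, sigma = 35)
    dt <- time_ms - geom$latencies[p]
    wave <- ifelse(dt >= 0,
                   sin(2 * pi * geom$freqs[p] * dt / 1000) *
                     exp(-dt / geom$decays[p]),
                   0)
    out <- out + geom$amps[p] * (topo %o% wave)
  }
  out
}

#' Simulate vertex-wise electric-field maps with a planted supra-threshold ROI
#'
#' Each condition receives a map in which one contiguous block of vertices
#' (the planted stimulation region of interest) carries field values
#' strictly between the 70 V/m activation threshold and `peak_field`, while
#' all remaining vertices stay below threshold. Thresholding at 70 V/m
#' downstream therefore recovers the planted vertex set exactly.
#'
#' @param conditions a `tep_dataset`, a data frame with a `condition_id`
#'   column, or an integer count of conditions.
#' @param n_vertices vertices per map.
#' @param roi_size_range integer pair: inclusive range the planted ROI size
#'   is drawn from.
#' @param peak_field maximum field value (V/m); must exceed 70 or no ROI
#'   could form.
#' @param threshold activation threshold (V/m), default 70.
#' @param seed integer seed.
#' @return list of `efield_map` objects (fields `values`, `condition_id`),
#'   one per condition, each carrying the planted indices as attribute
#'   `roi_vertices`.
#' @export
simulate_efield_maps <- function(conditions,
                                 n_vertices = 1000L,
                                 roi_size_range = c(20L, 60L),
                                 peak_field = 120,
                                 threshold = 70,
                                 seed = 1L) {
  ids <- condition_ids(conditions)
  stop_if_not_scalar_number(peak_field, "peak_field")
  if (peak_field <= threshold) {
    stop(sprintf(
      "`peak_field` (%.1f) must exceed the %.0f V/m activation threshold",
      peak_field, threshold), call. = FALSE)
  }
  lo <- roi_size_range[1]
  hi <- roi_size_range[2]
  if (lo < 1 || hi < lo || hi > n_vertices) {
    stop("invalid `roi_size_range`", call. = FALSE)
  }
  with_seed(seed, {
    lapply(ids, function(id) {
      size <- if (lo == hi) lo else sample(lo:hi, 1L)
      start <- sample.int(n_vertices - size + 1L, 1L)
      idx <- start:(start + size - 1L)
      values <- stats::runif(n_vertices, 0, 0.7 * threshold)
      ## strictly above threshold, at most peak_field
      values[idx] <- threshold +
        (peak_field - threshold) * stats::runif(size, min = 1e-6)
      structure(list(values = values, condition_id = id),
                class = "efield_map", roi_vertices = idx)
    })
  })
}

#' Simulate stimulation-ROI to parcel connectivity stacks
#'
#' Produces one conditions x parcels matrix per modality: streamline tract
#' counts (`tracts`), resting-state fMRI correlation (`rsfmri`), and eight
#' resting-EEG power-envelope connectivity matrices
#' (`pec_<band>_<eyes>` for four frequency bands x two eyes conditions).
#' Rows are drawn from nonnegative distributions whose means can be
#' shifted per planted community via `community_effects`, so group
#' comparisons downstream have a known ground truth. Parcels are labelled
#' with 7 contiguous network blocks, emulating a 100-parcel / 7-network
#' cortical atlas.
#'
#' @param conditions a `tep_dataset`, data frame with `condition_id`, or
#'   integer count.
#' @param n_parcels number of atlas parcels (default 100).
#' @param community_effects optional named list: community label ->
#'   named numeric vector of per-modality additive mean shifts
#'   (e.g. `list("3" = c(tracts = 2))`). Unknown community or modality
#'   keys are an error.
#' @param truth_labels planted community per condition; taken from the
#'   `tep_dataset` when `conditions` is one.
#' @param seed integer seed.
#' @param bands,eyes PEC frequency-band and eyes-condition names.
#' @return object of class `connectome_stack`: list with `matrices` (named
#'   list of conditions x parcels matrices), `parcel_networks` (integer
#'   1–7 per parcel) and `parcel_areas`.
#' @export
simulate_connectome_stack <- function(conditions,
                                      n_parcels = 100L,
                                      community_effects = NULL,
                                      truth_labels = NULL,
                                      seed = 1L,
                                      bands = c("theta", "alpha",
                                                "beta", "gamma"),
                                      eyes = c("open", "closed")) {
  ids <- condition_ids(conditions)
  n_cond <- length(ids)
  if (is.null(truth_labels) && inherits(conditions, "tep_dataset")) {
    truth_labels <- conditions$truth_labels
  }
  if (is.null(truth_labels)) truth_labels <- rep(1L, n_cond)
  modalities <- c("tracts", "rsfmri",
                  as.vector(outer(bands, eyes,
                                  function(b, e) paste("pec", b, e,
                                                       sep = "_"))))
  shifts <- matrix(0, n_cond, length(modalities),
                   dimnames = list(NULL, modalities))
  if (!is.null(community_effects)) {
    known <- as.character(unique(truth_labels))
    for (comm in names(community_effects)) {
      if (!comm %in% known) {
        stop(sprintf("community_effects refers to unknown community '%s'",
                     comm), call. = FALSE)
      }
      eff <- community_effects[[comm]]
      bad <- setdiff(names(eff), modalities)
      if (length(bad)) {
        stop(sprintf("community_effects names unknown modality: %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      rows <- truth_labels == as.integer(comm)
      for (m in names(eff)) shifts[rows, m] <- shifts[rows, m] + eff[[m]]
    }
  }
  ## 7 contiguous network blocks covering all parcels
  block <- rep(seq_len(7L), each = ceiling(n_parcels / 7))[seq_len(n_parcels)]
  with_seed(seed, {
    mats <- lapply(modalities, function(m) {
      mu <- shifts[, m]
      vals <- if (m == "tracts") {
        ## Poisson counts, base rate 5 streamlines per parcel
        stats::rpois(n_cond * n_parcels, lambda = pmax(5 + mu, 0.01))
      } else {
        ## folded-normal connectivity values, base mean 0.5
        abs(stats::rnorm(n_cond * n_parcels, mean = 0.5 + mu, sd = 0.3))
      }
      matrix(vals, n_cond, n_parcels, dimnames = list(ids, NULL))
    })
    names(mats) <- modalities
    structure(list(matrices = mats,
                   parcel_networks = block,
                   parcel_areas = rep(1, n_parcels)),
              class = "connectome_stack")
  })
}

condition_ids <- function(conditions) {
  if (inherits(conditions, "tep_dataset")) {
    conditions$conditions$condition_id
  } else if (is.data.frame(conditions)) {
    if (!"condition_id" %in% names(conditions)) {
      stop("`conditions` data frame needs a `condition_id` column",
           call. = FALSE)
    }
    conditions$condition_id
  } else if (is.numeric(conditions) && length(conditions) == 1L) {
    sprintf("C%03d", seq_len(conditions))
  } else {
    stop("`conditions` must be a tep_dataset, data frame or count",
         call. = FALSE)
  }
}
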