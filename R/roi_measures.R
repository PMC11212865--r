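#' Extract the supra-threshold stimulation ROI from an E-field map
#'
#' The cortical region activated by a TMS pulse is approximated by the
#' vertices whose simulated electric-field magnitude strictly exceeds the
#' activation threshold (70 V/m by default).
#'
#' @param map an `efield_map` (from [simulate_efield_maps()]) or a plain
#'   numeric vector of vertex values in V/m.
#' @param threshold activation threshold in V/m (strict inequality).
#' @return object of class `efield_roi`: `condition_id`, `vertex_indices`,
#'   `size`, `mean_intensity`.
#' @export
extract_roi <- function(map, threshold = 70) {
  stop_if_not_scalar_number(threshold, "threshold", positive = TRUE)
  values <- if (inherits(map, "efield_map")) map$values else as.numeric(map)
  id <- if (inherits(map, "efield_map")) map$condition_id else NA_character_
  idx <- which(values > threshold)
  if (!length(idx)) {
    stop(sprintf("no vertex exceeds %g V/m for condition %s",
                 threshold, id), call. = FALSE)
  }
  structure(list(condition_id = id,
                 vertex_indices = idx,
                 size = length(idx),
                 mean_intensity = mean(values[idx])),
            class = "efield_roi")
}

#' Average a vertex-wise scalar map over a stimulation ROI
#'
#' Used for cortical thickness and myelin maps: the per-vertex values
#' inside the E-field-defined ROI are arithmetically averaged into one
#' value per stimulation condition.
#'
#' @param scalar_map numeric vector of per-vertex values.
#' @param roi an `efield_roi`.
#' @return scalar mean.
#' @export
roi_scalar_mean <- function(scalar_map, roi) {
  stopifnot(inherits(roi, "efield_roi"))
  if (max(roi$vertex_indices) > length(scalar_map) ||
      anyNA(scalar_map[roi$vertex_indices])) {
    stop("scalar map does not cover all ROI vertices", call. = FALSE)
  }
  mean(scalar_map[roi$vertex_indices])
}

#' Area-normalize tract counts between ROIs and parcels
#'
#' Streamline counts between stimulation ROIs and atlas parcels are
#' divided by the geometric mean of the two connected areas,
#' `count / sqrt(roi_area * parcel_area)`, removing the trivial dependence
#' of counts on ROI size.
#'
#' @param counts ROIs x parcels nonnegative count matrix.
#' @param roi_areas,parcel_areas positive areas per ROI / parcel.
#' @return normalized matrix of the same shape.
#' @export
normalize_tract_counts <- function(counts, roi_areas, parcel_areas) {
  counts <- as.matrix(counts)
  if (length(roi_areas) != nrow(counts) ||
      length(parcel_areas) != ncol(counts)) {
    stop("areas must match the count matrix dimensions", call. = FALSE)
  }
  if (any(roi_areas <= 0) || any(parcel_areas <= 0)) {
    stop("all areas must be positive", call. = FALSE)
  }
  counts / sqrt(outer(roi_areas, parcel_areas))
}

#' Global and network-relative degree of one ROI-to-parcel row
#'
#' The global degree is the sum of the connectivity measure from the
#' stimulation ROI across all atlas parcels; each of the 7 networks then
#' receives the fraction of that total carried by its parcels.
#'
#' @param row numeric vector of length n_parcels (one condition, one
#'   modality).
#' @param parcel_networks integer network id (1–7) per parcel.
#' @return list with `global` (sum) and `per_network` (named fractions
#'   summing to 1; `NA` with a warning when the total is 0).
#' @export
degree_metrics <- function(row, parcel_networks) {
  if (length(row) != length(parcel_networks)) {
    stop("`parcel_networks` must cover all parcels", call. = FALSE)
  }
  nets <- sort(unique(parcel_networks))
  global <- sum(row)
  per_net <- vapply(nets, function(k) sum(row[parcel_networks == k]),
                    numeric(1))
  if (global == 0) {
    warning("total degree is 0; network fractions undefined",
            call. = FALSE)
    frac <- rep(NA_real_, length(nets))
  } else {
    frac <- per_net / global
  }
  list(global = global,
       per_network = stats::setNames(frac, paste0("network", nets)))
}

#' Degree metrics for a whole connectome stack
#'
#' Applies [degree_metrics()] to every condition of every modality in a
#' `connectome_stack`, producing the long table of measures that feeds the
#' across-community comparisons. Tract counts are area-normalized first
#' when areas are supplied.
#'
#' @param stack a `connectome_stack`.
#' @param roi_areas optional ROI areas for tract-count normalization.
#' @return data frame: condition_id, modality, measure
#'   (`global` or `network<k>_fraction`), value.
#' @export
stack_degree_metrics <- function(stack, roi_areas = NULL) {
  stopifnot(inherits(stack, "connectome_stack"))
  rows <- list()
  for (mod in names(stack$matrices)) {
    m <- stack$matrices[[mod]]
    if (mod == "tracts" && !is.null(roi_areas)) {
      m <- normalize_tract_counts(m, roi_areas, stack$parcel_areas)
    }
    for (i in seq_len(nrow(m))) {
      dm <- degree_metrics(m[i, ], stack$parcel_networks)
      rows[[length(rows) + 1L]] <- data.frame(
        condition_id = rownames(m)[i],
        modality = mod,
        measure = c("global", paste0(names(dm$per_network), "_fraction")),
        value = c(dm$global, unname(dm$per_network)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
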