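#' Write a numeric array to a binary container with a JSON sidecar
#'
#' Values are stored as little-endian doubles in `<prefix>.bin`; the JSON
#' sidecar `<prefix>.json` records the dimensions and the row/column ids,
#' so arrays can be re-aligned by id on read.
#'
#' @param x numeric vector, matrix or array.
#' @param prefix path prefix (without extension).
#' @return the prefix, invisibly.
#' @export
write_array <- function(x, prefix) {
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  dn <- dimnames(x)
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  jsonlite::write_json(
    list(dims = dims, dimnames = dn, storage = "float64-little-colmajor"),
    paste0(prefix, ".json"), auto_unbox = FALSE, null = "null")
  invisible(prefix)
}

#' Read a numeric array written by [write_array()]
#'
#' @param prefix path prefix (without extension).
#' @return the array with dimensions and dimnames restored.
#' @export
read_array <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n, size = 8L, endian = "little")
  if (length(x) != n) stop("binary container is truncated", call. = FALSE)
  if (length(meta$dims) > 1L) dim(x) <- meta$dims
  if (!is.null(meta$dimnames)) {
    dimnames(x) <- lapply(meta$dimnames, function(d) {
      if (length(d)) d else NULL
    })
  }
  x
}

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a TEP dataset to disk
#'
#' Voltages go to the binary array container (`voltages.bin/.json`),
#' condition metadata to `conditions.tsv`, channel locations to
#' `channels.tsv`, the time axis and any ground-truth labels to
#' `dataset.json`.
#'
#' @param tep a `tep_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tep_dataset <- function(tep, dir) {
  stopifnot(inherits(tep, "tep_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_array(tep$voltages, file.path(dir, "voltages"))
  write_tsv(tep$conditions, file.path(dir, "conditions.tsv"))
  write_tsv(tep$channels, file.path(dir, "channels.tsv"))
  jsonlite::write_json(list(time = tep$time,
                            truth_labels = tep$truth_labels),
                       file.path(dir, "dataset.json"), null = "null",
                       digits = NA)
  invisible(dir)
}

#' Read a TEP dataset written by [write_tep_dataset()]
#'
#' Voltage rows are re-aligned to the order of `conditions.tsv` by
#' condition id, so a permuted metadata table still yields a consistent
#' dataset.
#'
#' @param dir directory containing the dataset files.
#' @return a `tep_dataset`.
#' @export
read_tep_dataset <- function(dir) {
  conditions <- read_tsv_checked(
    file.path(dir, "conditions.tsv"),
    c("condition_id", "site_label", "hemisphere", "orientation",
      "set", "suds"))
  channels <- read_tsv_checked(file.path(dir, "channels.tsv"),
                               c("label", "x", "y", "z"))
  voltages <- read_array(file.path(dir, "voltages"))
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  ids <- dimnames(voltages)[[1]]
  if (is.null(ids)) stop("voltages sidecar lacks condition ids",
                         call. = FALSE)
  ord <- match(conditions$condition_id, ids)
  if (anyNA(ord)) {
    stop("conditions.tsv refers to condition ids absent from the array",
         call. = FALSE)
  }
  truth <- meta$truth_labels
  structure(list(voltages = voltages[ord, , , drop = FALSE],
                 conditions = conditions,
                 channels = channels,
                 time = meta$time,
                 truth_labels = if (length(truth)) truth[ord] else NULL),
            class = "tep_dataset")
}

#' Read a parcel/network atlas table
#'
#' @param path TSV with columns `parcel_id`, `network_id` (1–7) and
#'   optionally `area`.
#' @return the validated data frame.
#' @export
read_parcel_table <- function(path) {
  df <- read_tsv_checked(path, c("parcel_id", "network_id"))
  if (!all(df$network_id %in% 1:7)) {
    stop("network_id values must lie in 1..7", call. = FALSE)
  }
  if (is.null(df$area)) df$area <- 1
  df
}
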