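# Scan/manifest/config IO.  Scans are stored as a gzipped CSV of HU values
# plus a JSON sidecar (case id, slice orders, pixel size, shape); manifests
# as plain CSV.  All writes are atomic (temp file + rename) so a killed run
# never leaves a half-written artifact.

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path, call. = FALSE)
  invisible(path)
}

atomic_save_rds <- function(obj, path) {
  atomic_write(path, function(tmp) saveRDS(obj, tmp))
}

# 32-bit FNV-1a over a character string; used to stamp artifacts with the
# configuration they were produced under (no hashing package in scope).
fnv1a32 <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # h * 16777619 mod 2^32, kept exact in doubles: 16777619 = 2^24 + 403
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Hash a configuration object
#'
#' A short stable hash recorded in every output artifact, so that stats or
#' checkpoints produced under one configuration refuse to load against
#' another.
#'
#' @param cfg any serializable configuration list.
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  fnv1a32(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}

#' Write / read a CT scan archive
#'
#' `write_scan` stores the HU array as a gzipped CSV (`<stem>.hu.csv.gz`,
#' one row per pixel-row, slices stacked bottom-to-top) plus a JSON sidecar
#' (`<stem>.json`) holding case id, slice orders, shape and pixel size.
#' `read_scan` restores the scan bit-exactly; volumes with more than 32
#' slices are rejected (scans hold up to 32 axial slices).
#'
#' @param scan a [ct_scan()].
#' @param stem file path without extension.
#' @return `read_scan` returns a [ct_scan()]; `write_scan` the stem,
#'   invisibly.
#' @export
write_scan <- function(scan, stem) {
  stopifnot(inherits(scan, "ct_scan"))
  sidecar <- list(case_id = scan$case_id,
                  slice_orders = scan$slice_orders,
                  shape = dim(scan$slices[[1]]),
                  n_slices = length(scan$slices),
                  pixel_size_mm = scan$pixel_size_mm,
                  format = "ctanomaly-scan-v1")
  atomic_write(paste0(stem, ".json"), function(tmp)
    jsonlite::write_json(sidecar, tmp, auto_unbox = TRUE, digits = NA))
  atomic_write(paste0(stem, ".hu.csv.gz"), function(tmp) {
    con <- gzfile(tmp, "w")
    on.exit(close(con))
    for (s in scan$slices)
      writeLines(apply(s, 1, function(row) paste(sprintf("%.17g", row), collapse = ",")), con)
  })
  invisible(stem)
}

#' @rdname write_scan
#' @export
read_scan <- function(stem) {
  side_path <- paste0(stem, ".json")
  data_path <- paste0(stem, ".hu.csv.gz")
  if (!file.exists(side_path)) stop("missing sidecar ", side_path, call. = FALSE)
  if (!file.exists(data_path)) stop("missing data file ", data_path, call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (!identical(side$format, "ctanomaly-scan-v1"))
    stop("unrecognized scan format in ", side_path, call. = FALSE)
  if (side$n_slices > 32)
    stop("volume holds ", side$n_slices, " slices; the format limit is 32",
         call. = FALSE)
  h <- side$shape[1]; w <- side$shape[2]
  lines <- readLines(gzfile(data_path))
  if (length(lines) != h * side$n_slices)
    stop("corrupt scan data: expected ", h * side$n_slices, " rows, found ",
         length(lines), call. = FALSE)
  vals <- strsplit(lines, ",", fixed = TRUE)
  slices <- vector("list", side$n_slices)
  for (k in seq_len(side$n_slices)) {
    rows <- vals[((k - 1) * h + 1):(k * h)]
    m <- do.call(rbind, lapply(rows, as.numeric))
    if (ncol(m) != w || anyNA(m)) stop("corrupt scan data in ", data_path, call. = FALSE)
    slices[[k]] <- m
  }
  ct_scan(side$case_id, slices, side$slice_orders, side$pixel_size_mm)
}

#' Write / read a cohort manifest
#'
#' CSV with header `case_id,category,is_emergency`.  The emergency flag must
#' equal `category %in% c("urgent", "immediate")`.
#'
#' @param manifest data frame with those columns.
#' @param path CSV path.
#' @return `read_manifest` returns the validated data frame.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("case_id", "category", "is_emergency") %in% names(manifest)))
  atomic_write(path, function(tmp)
    utils::write.csv(manifest[, c("case_id", "category", "is_emergency")],
                     tmp, row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "category", "is_emergency")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "), call. = FALSE)
  ok <- c("normal", "benign", "indeterminate", "urgent", "immediate")
  if (!all(m$category %in% ok))
    stop("unknown category values: ",
         paste(setdiff(unique(m$category), ok), collapse = ", "), call. = FALSE)
  m$is_emergency <- as.logical(m$is_emergency)
  if (!identical(m$is_emergency, m$category %in% c("urgent", "immediate")))
    stop("is_emergency must equal category %in% {urgent, immediate}", call. = FALSE)
  m
}

#' Default pipeline configuration
#'
#' Nested sections mirroring the backbone, training, inversion, scoring and
#' simulation settings, serialized as JSON.  Unknown keys in a config file
#' are rejected.
#'
#' @return nested named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    backbone = list(resolution = 64L, style_dim = 16L, d_fc_dim = 64L,
                    hu_window = c(-20, 120)),
    train = unclass(train_config()),
    inversion = unclass(inversion_config()),
    scoring = list(norm = "l1", n_calibration_scans = 1000L),
    triage = list(policy = "youden", sensitivity_level = 0.95),
    simulation = list(block_size = 23L, prevalence = 0.11,
                      reader_median_rt = 30, reader_sdlog = 0.28)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration file (JSON)
#'
#' @param path JSON file; keys must be a subset of [default_config()].
#' @return merged `pipeline_config`.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  merge1 <- function(base, user, prefix = "") {
    for (k in names(user)) {
      if (!k %in% names(base))
        stop("unknown config key: ", prefix, k, call. = FALSE)
      if (is.list(base[[k]]) && is.list(user[[k]]))
        base[[k]] <- merge1(base[[k]], user[[k]], paste0(prefix, k, "."))
      else base[[k]] <- user[[k]]
    }
    base
  }
  out <- merge1(unclass(base), user)
  class(out) <- "pipeline_config"
  out
}
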