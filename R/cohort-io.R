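## Canonical cohort bundle on disk:
##   metadata.csv                subject_id,age,sex,site (empty age = missing)
##   spectra_<channel>.csv       subject_id,f_<center>,... ascending bins
##   grid.json                   {"bin_centers_hz":[...],"resolution_hz":...,
##                                "channels":[...]}

#' Read a cohort bundle
#'
#' Loads and validates a cohort from the canonical CSV/JSON interchange: a
#' metadata table, one spectra matrix per channel and a grid descriptor.
#'
#' @param metadata_path CSV with columns `subject_id,age,sex,site`
#'   (sex coded `F`/`M`/`U`; empty age field means missing).
#' @param spectra_paths Named character vector of per-channel spectra CSV
#'   paths (names are channel names). If unnamed, names are taken from the
#'   grid descriptor's `channels` in order.
#' @param grid_descriptor_path JSON descriptor with `bin_centers_hz`,
#'   `resolution_hz` and `channels`.
#' @return A validated [eeg_cohort()]. Subjects listed in the metadata but
#'   absent from any spectra file are dropped with a warning.
#' @seealso [write_cohort()] for the inverse; the pair round-trips values
#'   bit-identically.
#' @export
read_cohort <- function(metadata_path, spectra_paths, grid_descriptor_path) {
  for (p in c(metadata_path, spectra_paths, grid_descriptor_path))
    if (!file.exists(p)) stop("file not found: ", p)
  gd <- jsonlite::read_json(grid_descriptor_path, simplifyVector = TRUE)
  grid <- frequency_grid(gd$bin_centers_hz, gd$resolution_hz)
  if (is.null(names(spectra_paths)) || any(names(spectra_paths) == "")) {
    if (length(spectra_paths) != length(gd$channels))
      stop("unnamed spectra_paths must match the descriptor's channel list")
    names(spectra_paths) <- gd$channels
  }
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character",
                                         age = "numeric",
                                         sex = "character",
                                         site = "character"))
  if (anyDuplicated(meta$subject_id))
    stop("duplicate subject_id in ", metadata_path)
  b <- length(grid$bin_centers)
  spectra <- lapply(names(spectra_paths), function(ch) {
    df <- utils::read.csv(spectra_paths[[ch]], stringsAsFactors = FALSE,
                          check.names = FALSE)
    if (names(df)[1L] != "subject_id")
      stop("channel ", ch, ": first column must be subject_id")
    if (ncol(df) - 1L != b)
      stop("channel ", ch, ": ", ncol(df) - 1L,
           " spectral columns do not match the ", b, "-bin grid")
    if (anyDuplicated(df$subject_id))
      stop("duplicate subject_id in spectra for channel ", ch)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyNA(m) || any(m < 0))
      stop("channel ", ch, ": negative or missing spectral value")
    rownames(m) <- as.character(df$subject_id)
    m
  })
  names(spectra) <- names(spectra_paths)
  present <- Reduce(intersect, lapply(spectra, rownames))
  keep <- meta$subject_id %in% present
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) in metadata lack spectra in ",
            "one or more channels and were dropped")
    meta <- meta[keep, , drop = FALSE]
  }
  if (!nrow(meta)) stop("no subject has spectra in every channel")
  spectra <- lapply(spectra, function(m) m[meta$subject_id, , drop = FALSE])
  eeg_cohort(meta, spectra, grid)
}

#' Write a cohort bundle
#'
#' Writes the canonical interchange bundle (`metadata.csv`,
#' `spectra_<channel>.csv`, `grid.json`) with full numeric precision, so a
#' read/write/read cycle reproduces the cohort bit-identically and repeated
#' writes are byte-identical.
#'
#' @param cohort An [eeg_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named list of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_path <- file.path(dir, "metadata.csv")
  lines <- c("subject_id,age,sex,site",
             paste(cohort$meta$subject_id, fmt_num(cohort$meta$age),
                   cohort$meta$sex, cohort$meta$site, sep = ","))
  writeLines(lines, meta_path)
  centers <- cohort$grid$bin_centers
  header <- paste(c("subject_id",
                    paste0("f_", format(centers, trim = TRUE))), collapse = ",")
  spec_paths <- character(0)
  for (ch in cohort$channels) {
    m <- cohort$spectra[[ch]]
    body <- vapply(seq_len(nrow(m)), function(i)
      paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = ","), "")
    p <- file.path(dir, paste0("spectra_", ch, ".csv"))
    writeLines(c(header, body), p)
    spec_paths[ch] <- p
  }
  grid_path <- file.path(dir, "grid.json")
  jsonlite::write_json(list(bin_centers_hz = centers,
                            resolution_hz = cohort$grid$resolution,
                            channels = cohort$channels),
                       grid_path, auto_unbox = TRUE, digits = I(17))
  invisible(list(metadata = meta_path, spectra = spec_paths,
                 grid = grid_path))
}

#' Read a cohort bundle from a directory
#'
#' Convenience wrapper around [read_cohort()] for a directory laid out as
#' written by [write_cohort()].
#'
#' @param dir Bundle directory.
#' @return An [eeg_cohort()].
#' @export
read_cohort_dir <- function(dir) {
  gd_path <- file.path(dir, "grid.json")
  gd <- jsonlite::read_json(gd_path, simplifyVector = TRUE)
  paths <- file.path(dir, paste0("spectra_", gd$channels, ".csv"))
  names(paths) <- gd$channels
  read_cohort(file.path(dir, "metadata.csv"), paths, gd_path)
}
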