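## Cohort container and spectral preprocessing.
##
## A cohort bundles a metadata table (subject_id, age, sex, site), one
## spectra matrix per channel (subjects x frequency bins) and a shared
## frequency grid. Spectra are non-negative weights over bin centers; once
## rescaled to unit mass they are treated as probability distributions over
## frequency.

GRID_ALIGN_TOL <- 1e-6  # Hz; absorbs decimal printing of 0.39-Hz grids

#' Frequency grid
#'
#' A strictly ascending, equally spaced grid of positive bin-center
#' frequencies in Hz. Bin values are interpreted as point masses at the bin
#' centers (not band integrals).
#'
#' @param bin_centers Numeric vector of bin-center frequencies in Hz.
#' @param resolution Optional bin spacing in Hz; inferred from
#'   `bin_centers` when omitted.
#' @return An object of class `frequency_grid` with elements `bin_centers`
#'   and `resolution`.
#' @examples
#' frequency_grid(seq(1.17, by = 0.39, length.out = 47))
#' @export
frequency_grid <- function(bin_centers, resolution = NULL) {
  bin_centers <- as.numeric(bin_centers)
  if (length(bin_centers) < 1L || anyNA(bin_centers))
    stop("bin_centers must be a non-empty numeric vector without NA")
  if (any(bin_centers <= 0))
    stop("all bin-center frequencies must be positive")
  if (length(bin_centers) > 1L) {
    d <- diff(bin_centers)
    if (any(d <= 0)) stop("bin_centers must be strictly ascending")
    if (max(d) - min(d) > GRID_ALIGN_TOL)
      stop("bin_centers must be equally spaced (within ", GRID_ALIGN_TOL, " Hz)")
    res <- stats::median(d)
  } else {
    res <- resolution %||% NA_real_
  }
  if (!is.null(resolution)) {
    if (length(bin_centers) > 1L && abs(resolution - res) > GRID_ALIGN_TOL)
      stop("stated resolution disagrees with bin spacing")
    res <- resolution
  }
  structure(list(bin_centers = bin_centers, resolution = as.numeric(res)),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("frequency_grid: %d bins, %.4g-%.4g Hz, resolution %.4g Hz\n",
              length(x$bin_centers), min(x$bin_centers), max(x$bin_centers),
              x$resolution))
  invisible(x)
}

#' @export
length.frequency_grid <- function(x) length(x$bin_centers)

grids_compatible <- function(a, b, tol = GRID_ALIGN_TOL) {
  if (abs(a$resolution - b$resolution) > tol) return(FALSE)
  n <- min(length(a$bin_centers), length(b$bin_centers))
  all(abs(a$bin_centers[seq_len(n)] - b$bin_centers[seq_len(n)]) <= tol)
}

#' Single-channel spectrum
#'
#' Non-negative weights over a frequency grid; after [rescale_unit_mass()]
#' the weights sum to one and the spectrum is a probability distribution.
#'
#' @param weights Non-negative numeric vector, one weight per grid bin.
#' @param grid A [frequency_grid()].
#' @return An object of class `channel_spectrum`.
#' @export
channel_spectrum <- function(weights, grid) {
  weights <- as.numeric(weights)
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  if (length(weights) != length(grid$bin_centers))
    stop("length(weights) must equal the number of grid bins")
  if (anyNA(weights) || any(weights < 0))
    stop("spectral weights must be non-negative and non-missing")
  structure(list(weights = weights, grid = grid), class = "channel_spectrum")
}

#' Rescale a spectrum to unit mass
#'
#' Divides the weights by their total so the spectrum sums to 1 and can be
#' treated as a probability distribution over frequency. Idempotent and
#' invariant to positive rescaling of the input.
#'
#' @param x A `channel_spectrum` or a numeric weight vector.
#' @return Same type as the input, with weights summing to 1.
#' @examples
#' rescale_unit_mass(c(2, 2, 4))  # 0.25 0.25 0.50
#' @export
rescale_unit_mass <- function(x) {
  w <- if (inherits(x, "channel_spectrum")) x$weights else as.numeric(x)
  if (anyNA(w) || any(w < 0)) stop("spectral weights must be non-negative")
  s <- sum(w)
  if (s <= 0) stop("cannot rescale an all-zero spectrum to unit mass")
  w <- w / s
  if (inherits(x, "channel_spectrum")) {
    x$weights <- w
    x
  } else w
}

#' EEG cohort
#'
#' Bundles subject metadata, per-channel spectra matrices and the shared
#' frequency grid. Every subject carries every listed channel on the same
#' grid; subject ids are unique.
#'
#' @param meta Data frame with columns `subject_id` (character, unique),
#'   `age` (years; `NA` when not recorded), `sex` (`"F"`, `"M"` or `"U"`),
#'   `site` (acquisition site/batch label).
#' @param spectra Named list, one `subjects x bins` numeric matrix per
#'   channel, rows ordered and named as `meta$subject_id`.
#' @param grid A [frequency_grid()] shared by all channels.
#' @return An object of class `eeg_cohort`.
#' @export
eeg_cohort <- function(meta, spectra, grid) {
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "site")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  meta$subject_id <- as.character(meta$subject_id)
  meta$site <- as.character(meta$site)
  meta$sex <- as.character(meta$sex)
  meta$age <- as.numeric(meta$age)
  if (anyDuplicated(meta$subject_id))
    stop("duplicate subject_id in metadata")
  bad_sex <- setdiff(unique(meta$sex), c("F", "M", "U"))
  if (length(bad_sex))
    stop("sex must be one of F, M, U; found: ", paste(bad_sex, collapse = ", "))
  if (any(!is.na(meta$age) & meta$age <= 0))
    stop("recorded ages must be positive")
  if (!length(spectra) || is.null(names(spectra)) || any(names(spectra) == ""))
    stop("spectra must be a named list (one matrix per channel)")
  if (anyDuplicated(names(spectra))) stop("duplicate channel names")
  n <- nrow(meta); b <- length(grid$bin_centers)
  for (ch in names(spectra)) {
    m <- spectra[[ch]]
    if (!is.matrix(m)) m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (nrow(m) != n)
      stop("channel ", ch, ": expected ", n, " subject rows, found ", nrow(m))
    if (ncol(m) != b)
      stop("channel ", ch, ": ", ncol(m), " spectral columns do not match the ",
           b, "-bin grid")
    if (anyNA(m) || any(m < 0))
      stop("channel ", ch, ": spectra must be non-negative and non-missing")
    rownames(m) <- meta$subject_id
    colnames(m) <- paste0("f_", format(grid$bin_centers, trim = TRUE))
    spectra[[ch]] <- m
  }
  structure(list(meta = meta, spectra = spectra, grid = grid,
                 channels = names(spectra)),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("eeg_cohort: %d subjects, %d channels, %d bins (%.4g-%.4g Hz), %d sites\n",
              nrow(x$meta), length(x$channels), length(x$grid$bin_centers),
              min(x$grid$bin_centers), max(x$grid$bin_centers),
              length(unique(x$meta$site))))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort An [eeg_cohort()].
#' @return Integer subject count.
#' @export
n_subjects <- function(cohort) nrow(cohort$meta)

#' Extract one channel's spectra matrix
#' @param cohort An [eeg_cohort()].
#' @param channel Channel name.
#' @return `subjects x bins` matrix, rows named by subject id.
#' @export
cohort_spectra <- function(cohort, channel) {
  if (!channel %in% cohort$channels)
    stop("unknown channel: ", channel)
  cohort$spectra[[channel]]
}

#' Extract one subject's spectrum on one channel
#' @inheritParams cohort_spectra
#' @param subject_id Subject identifier.
#' @return A [channel_spectrum()].
#' @export
get_spectrum <- function(cohort, subject_id, channel) {
  m <- cohort_spectra(cohort, channel)
  if (!subject_id %in% rownames(m)) stop("unknown subject_id: ", subject_id)
  channel_spectrum(m[subject_id, ], cohort$grid)
}

subset_cohort <- function(cohort, idx) {
  meta <- cohort$meta[idx, , drop = FALSE]
  rownames(meta) <- NULL
  spectra <- lapply(cohort$spectra, function(m) m[idx, , drop = FALSE])
  eeg_cohort(meta, spectra, cohort$grid)
}

#' Filter subjects by recorded age
#'
#' Keeps subjects whose recorded age lies in `[min_age, max_age]`,
#' preserving order. Subjects without a recorded age are dropped unless
#' `drop_missing_age = FALSE`.
#'
#' @param cohort An [eeg_cohort()].
#' @param min_age,max_age Age bounds in years (inclusive).
#' @param drop_missing_age Drop subjects with missing age? Default `TRUE`.
#' @return The filtered cohort.
#' @export
filter_subjects <- function(cohort, min_age = 5, max_age = 97,
                            drop_missing_age = TRUE) {
  if (min_age > max_age) stop("min_age must not exceed max_age")
  age <- cohort$meta$age
  keep <- !is.na(age) & age >= min_age & age <= max_age
  if (!drop_missing_age) keep <- keep | is.na(age)
  if (!any(keep)) warning("age filter removed every subject")
  subset_cohort(cohort, which(keep))
}

#' Drop channels from a cohort
#'
#' Removes the named channels (e.g. a reference electrode such as Cz) from
#' the cohort and every subject, preserving the order of the rest.
#'
#' @param cohort An [eeg_cohort()].
#' @param names Character vector of channel names to drop; must all exist.
#' @return The reduced cohort.
#' @export
exclude_channels <- function(cohort, names) {
  unknown <- setdiff(names, cohort$channels)
  if (length(unknown))
    stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(cohort$channels, names)
  if (!length(keep)) stop("cannot exclude every channel")
  cohort$spectra <- cohort$spectra[keep]
  cohort$channels <- keep
  cohort
}

#' Rescale every spectrum in a cohort to unit mass
#' @param cohort An [eeg_cohort()].
#' @return Cohort whose spectra each sum to 1.
#' @export
rescale_cohort <- function(cohort) {
  cohort$spectra <- lapply(cohort$spectra, function(m) {
    s <- rowSums(m)
    if (any(s <= 0)) stop("cannot rescale an all-zero spectrum to unit mass")
    m / s
  })
  cohort
}

#' Truncate cohorts to the lowest common cutoff frequency and merge
#'
#' Sites record spectra up to different maximum frequencies; for full
#' compatibility all spectra are truncated at the lowest maximum cutoff
#' across the inputs, then re-rescaled to unit mass. Grids must share
#' resolution and bin alignment.
#'
#' @param cohorts A single [eeg_cohort()] or a list of them (e.g. one per
#'   site).
#' @param max_hz Optional explicit cutoff in Hz overriding the automatic
#'   minimum.
#' @return One merged cohort on the common truncated grid, all spectra
#'   unit mass.
#' @export
truncate_common_grid <- function(cohorts, max_hz = NULL) {
  if (inherits(cohorts, "eeg_cohort")) cohorts <- list(cohorts)
  if (!length(cohorts)) stop("no cohorts supplied")
  ref <- cohorts[[1L]]$grid
  for (co in cohorts[-1L]) {
    if (!grids_compatible(ref, co$grid))
      stop("cohort grids are misaligned (resolution or bin offsets differ)")
  }
  cutoff <- min(vapply(cohorts, function(co) max(co$grid$bin_centers), 0))
  if (!is.null(max_hz)) cutoff <- min(cutoff, max_hz)
  keep_bins <- which(ref$bin_centers <= cutoff + GRID_ALIGN_TOL)
  if (!length(keep_bins)) stop("cutoff leaves no frequency bins")
  grid <- frequency_grid(ref$bin_centers[keep_bins])
  channels <- Reduce(intersect, lapply(cohorts, `[[`, "channels"))
  if (!length(channels)) stop("cohorts share no channels")
  meta <- do.call(rbind, lapply(cohorts, `[[`, "meta"))
  rownames(meta) <- NULL
  spectra <- lapply(channels, function(ch) {
    do.call(rbind, lapply(cohorts, function(co)
      co$spectra[[ch]][, keep_bins, drop = FALSE]))
  })
  names(spectra) <- channels
  rescale_cohort(eeg_cohort(meta, spectra, grid))
}

#' Per-bin variance normalisation across subjects
#'
#' Returns a feature view of one channel in which every frequency bin has
#' unit variance across subjects (values divided by the per-bin standard
#' deviation; no centering). This feeds the linear/kernel ridge baselines;
#' it does not alter the distribution view used by the MMD machinery.
#' Constant bins pass through unscaled with a warning.
#'
#' @param cohort An [eeg_cohort()].
#' @param channel Channel name.
#' @param scale Optional per-bin scale (standard deviations) from a
#'   reference set, e.g. the training subjects; when supplied it is applied
#'   as-is so held-out subjects can be projected without leakage.
#' @return Numeric matrix with attribute `"bin_scale"` holding the per-bin
#'   divisors.
#' @export
normalize_bins_across_subjects <- function(cohort, channel, scale = NULL) {
  m <- cohort_spectra(cohort, channel)
  if (is.null(scale)) {
    if (nrow(m) < 2L)
      stop("per-bin normalisation needs at least 2 subjects")
    scale <- apply(m, 2L, stats::sd)
    flat <- !is.finite(scale) | scale <= 0
    if (any(flat)) {
      warning(sum(flat), " constant bin(s) passed through unscaled")
      scale[flat] <- 1
    }
  } else if (length(scale) != ncol(m)) {
    stop("scale length must match the number of bins")
  }
  out <- sweep(m, 2L, scale, "/")
  attr(out, "bin_scale") <- scale
  out
}
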