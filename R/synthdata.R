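## Seeded synthetic EEG cohorts.
##
## Each spectrum is the field-standard decomposition: an aperiodic 1/f
## power law plus a Gaussian alpha-like oscillatory peak whose amplitude
## declines and whose center frequency slows with age. Sites impose a
## multiplicative spectral tilt and strongly differing age distributions
## (prior shift); sexes can age at different spectral rates. Spectra are
## multiplied by per-bin log-normal noise and rescaled to unit mass, so
## every generated spectrum is a valid probability distribution.

#' Standard 19-channel 10/20 montage
#' @return Character vector of channel names (Cz included).
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

## Alpha power is posterior-dominant: peak gain by scalp region.
channel_peak_gain <- function(channels) {
  posterior <- c("O1", "O2", "P3", "P4", "Pz", "T5", "T6")
  central <- c("C3", "C4", "Cz", "T3", "T4")
  gain <- ifelse(channels %in% posterior, 1.2,
                 ifelse(channels %in% central, 1.0, 0.8))
  names(gain) <- channels
  gain
}

#' Site specification for the synthetic generator
#'
#' @param name Site label.
#' @param n Number of subjects.
#' @param dist Age distribution: `"uniform"` on `[min, max]` or
#'   `"truncnorm"` with `mean`/`sd` truncated to `[min, max]`.
#' @param min,max Age range in years.
#' @param mean,sd Location/scale for `"truncnorm"`.
#' @param tilt Site-level multiplicative spectral tilt exponent: the whole
#'   raw spectrum is multiplied by `(f / f_mid)^tilt`, emulating
#'   instrumentation differences between acquisition setups.
#' @return A list site spec.
#' @export
synth_site <- function(name, n = 100L, dist = c("uniform", "truncnorm"),
                       min = 5, max = 90, mean = NA, sd = NA, tilt = 0) {
  dist <- match.arg(dist)
  if (min >= max) stop("site ", name, ": min age must be below max age")
  if (dist == "truncnorm" && (is.na(mean) || is.na(sd) || sd <= 0))
    stop("site ", name, ": truncnorm needs mean and positive sd")
  list(name = name, n = as.integer(n), dist = dist, min = min, max = max,
       mean = mean, sd = sd, tilt = tilt)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults define the reference study conditions: 4 sites of 100 subjects
#' with strongly differing age distributions and mild spectral tilts, a
#' 1/f aperiodic component, an alpha peak near 10.8 Hz whose center slows
#' and whose amplitude declines with age through a saturating map
#' (`u = age / (age + age_sat)`, steeper change in youth), per-subject
#' biological variability and multiplicative log-normal measurement noise.
#' Sexes age at the same spectral pace by default; `sex_slope_mult > 1`
#' switches on a faster male trajectory.
#'
#' @param n_per_site Default subject count for sites that do not set `n`.
#' @param sites List of [synth_site()] specs.
#' @param grid A [frequency_grid()]; default 47 bins, 1.17-19.11 Hz at
#'   0.39 Hz, matching standard quantitative-EEG spectral sampling.
#' @param channels Channel names; default the 10/20 montage.
#' @param chi Mean aperiodic exponent of the `b f^(-chi)` component (> 0);
#'   the realised exponent flattens with age by `chi_slope u(age)` and
#'   varies between subjects with sd `chi_sd`, mirroring the documented
#'   individual variability and age-related flattening of the EEG 1/f
#'   slope.
#' @param chi_slope Age-related flattening of the aperiodic exponent.
#' @param chi_sd Between-subject sd of the aperiodic exponent.
#' @param b Aperiodic scale (> 0).
#' @param peak_amp Oscillatory peak amplitude at age 0 (> 0).
#' @param amp_slope Fractional amplitude decline over the saturating age
#'   map, in [0, 1): amplitude is `peak_amp (1 - amp_slope u)`.
#' @param mu0 Peak center frequency at age 0, Hz.
#' @param mu_slope Peak slowing in Hz over the age map (subtracted).
#' @param sigma Peak width (Hz, > 0).
#' @param age_sat Saturation age (years) of the nonlinear map.
#' @param nonlinear Use the saturating age map? When `FALSE`, age enters
#'   linearly as `u = age / 100`.
#' @param sex_slope_mult Multiplier on the male spectral ageing pace: males'
#'   peak-slowing (`mu_slope`) and exponent-flattening (`chi_slope`) rates
#'   are scaled by this factor (`> 1`: male spectra track age more
#'   steeply, making male age more predictable). Default 1 (no sex
#'   effect); values far from 1 also make the pooled cohort harder to
#'   predict because the sexes then follow different spectrum-age maps.
#' @param noise_sd Log-sd of the per-bin multiplicative measurement noise.
#' @param subj_sd_mu Between-subject sd of the peak center (Hz).
#' @param subj_sd_amp Between-subject log-sd of the peak amplitude.
#' @param seed RNG seed; generation is fully reproducible.
#' @return A `synth_config` object (validated).
#' @export
synth_config <- function(n_per_site = 100L,
                         sites = NULL,
                         grid = frequency_grid(seq(1.17, by = 0.39,
                                                   length.out = 47)),
                         channels = default_montage(),
                         chi = 1, chi_slope = 0.3, chi_sd = 0.3, b = 1,
                         peak_amp = 0.5, amp_slope = 0.55,
                         mu0 = 10.8, mu_slope = 4.5, sigma = 0.9,
                         age_sat = 20, nonlinear = TRUE,
                         sex_slope_mult = 1,
                         noise_sd = 0.12, subj_sd_mu = 0.15,
                         subj_sd_amp = 0.15, seed = 1L) {
  sites <- sites %||% list(
    synth_site("site_A", n_per_site, "uniform", min = 5, max = 40,
               tilt = -0.10),
    synth_site("site_B", n_per_site, "truncnorm", min = 10, max = 70,
               mean = 35, sd = 15, tilt = -0.03),
    synth_site("site_C", n_per_site, "uniform", min = 30, max = 85,
               tilt = 0.03),
    synth_site("site_D", n_per_site, "uniform", min = 5, max = 90,
               tilt = 0.10))
  cfg <- structure(list(sites = sites, grid = grid, channels = channels,
                        chi = chi, chi_slope = chi_slope, chi_sd = chi_sd,
                        b = b, peak_amp = peak_amp,
                        amp_slope = amp_slope, mu0 = mu0,
                        mu_slope = mu_slope, sigma = sigma,
                        age_sat = age_sat, nonlinear = isTRUE(nonlinear),
                        sex_slope_mult = sex_slope_mult,
                        noise_sd = noise_sd, subj_sd_mu = subj_sd_mu,
                        subj_sd_amp = subj_sd_amp,
                        seed = as.integer(seed)),
                   class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

age_map <- function(age, cfg) {
  if (cfg$nonlinear) age / (age + cfg$age_sat) else age / 100
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (chi <= 0) stop("chi must be positive")
    if (b <= 0 || peak_amp <= 0 || sigma <= 0 || age_sat <= 0)
      stop("b, peak_amp, sigma and age_sat must be positive")
    if (noise_sd < 0 || subj_sd_mu < 0 || subj_sd_amp < 0 || chi_sd < 0)
      stop("noise levels must be non-negative")
    if (chi_slope < 0) stop("chi_slope must be non-negative")
    if (amp_slope < 0 || amp_slope >= 1)
      stop("amp_slope must lie in [0, 1)")
    if (sex_slope_mult <= 0) stop("sex_slope_mult must be positive")
  })
  rng <- range(cfg$grid$bin_centers)
  for (s in cfg$sites) {
    for (age in c(s$min, s$max)) {
      ## the steeper (male) slope is the binding case for the grid check
      mu <- cfg$mu0 -
        cfg$mu_slope * max(1, cfg$sex_slope_mult) * age_map(age, cfg)
      if (mu < rng[1L] || mu > rng[2L])
        stop("peak center ", signif(mu, 4), " Hz at age ", age,
             " (site ", s$name, ") falls outside the frequency grid")
    }
  }
  invisible(cfg)
}

draw_site_ages <- function(spec) {
  if (spec$dist == "uniform") {
    ages <- stats::runif(spec$n, spec$min, spec$max)
  } else {
    ages <- numeric(0)
    while (length(ages) < spec$n) {
      cand <- stats::rnorm(spec$n, spec$mean, spec$sd)
      ages <- c(ages, cand[cand >= spec$min & cand <= spec$max])
    }
    ages <- ages[seq_len(spec$n)]
  }
  round(ages, 1)  # ages reported to 0.1-year resolution
}

#' Simulate a synthetic EEG cohort
#'
#' Draws subjects site by site (ages from the site's distribution, sex
#' uniformly), builds each raw spectrum as
#' `[b f^(-chi) + A(age, sex) exp(-(f - mu(age))^2 / (2 sigma^2))] (f/f_mid)^tilt`,
#' multiplies by per-bin log-normal noise, and rescales to unit mass.
#' The peak center `mu(age) = mu0 - pace mu_slope u(age)` slows with age,
#' the amplitude `A(age) = peak_amp (1 - amp_slope u(age)) g_channel`
#' declines, and the aperiodic exponent flattens by `pace chi_slope u(age)`;
#' `pace` is `sex_slope_mult` for males and 1 for females, and `u` is
#' linear or saturating depending on the `nonlinear` flag.
#'
#' @param config A [synth_config()].
#' @return List with `cohort` (an [eeg_cohort()], spectra unit mass) and
#'   `truth` (data frame of every latent per-subject parameter).
#' @export
simulate_cohort <- function(config) {
  validate_synth_config(config)
  f <- config$grid$bin_centers
  f_mid <- stats::median(f)
  gain <- channel_peak_gain(config$channels)
  with_seed(config$seed, {
    meta_rows <- list(); truth_rows <- list(); spectra_rows <- list()
    sid <- 0L
    for (s in config$sites) {
      ages <- draw_site_ages(s)
      sexes <- sample(c("F", "M"), s$n, replace = TRUE)
      for (i in seq_len(s$n)) {
        sid <- sid + 1L
        id <- sprintf("S%04d", sid)
        u <- age_map(ages[i], config)
        pace <- if (sexes[i] == "M") config$sex_slope_mult else 1
        amp_i <- config$peak_amp * (1 - config$amp_slope * u) *
          exp(stats::rnorm(1, 0, config$subj_sd_amp))
        mu_i <- config$mu0 - config$mu_slope * pace * u +
          stats::rnorm(1, 0, config$subj_sd_mu)
        chi_i <- config$chi - config$chi_slope * pace * u +
          stats::rnorm(1, 0, config$chi_sd)
        base <- config$b * f^(-chi_i)
        peak <- exp(-(f - mu_i)^2 / (2 * config$sigma^2))
        chans <- vapply(config$channels, function(ch) {
          raw <- (base + gain[[ch]] * amp_i * peak) * (f / f_mid)^s$tilt
          if (config$noise_sd > 0)
            raw <- raw * exp(stats::rnorm(length(f), 0, config$noise_sd))
          raw / sum(raw)
        }, numeric(length(f)))
        spectra_rows[[sid]] <- chans  # bins x channels
        meta_rows[[sid]] <- data.frame(subject_id = id, age = ages[i],
                                       sex = sexes[i], site = s$name,
                                       stringsAsFactors = FALSE)
        truth_rows[[sid]] <- data.frame(
          subject_id = id, site = s$name, sex = sexes[i], age = ages[i],
          u = u, peak_amp = amp_i, peak_mu = mu_i, pace = pace,
          tilt = s$tilt, chi = chi_i, b = config$b,
          sigma = config$sigma, stringsAsFactors = FALSE)
      }
    }
    meta <- do.call(rbind, meta_rows)
    spectra <- lapply(seq_along(config$channels), function(ci) {
      t(vapply(spectra_rows, function(m) m[, ci], numeric(length(f))))
    })
    names(spectra) <- config$channels
    list(cohort = eeg_cohort(meta, spectra, config$grid),
         truth = do.call(rbind, truth_rows))
  })
}

#' Prior-shift scenario
#'
#' Replaces the site list of a configuration with two sites whose realised
#' age ranges are disjoint (a young-only and an old-only site) while the
#' spectral model stays shared. Leave-site-out prediction then faces a
#' maximal prior shift: the test site's age distribution is unseen during
#' training.
#'
#' @param config A [synth_config()] to derive from.
#' @param young,old Two-element age ranges for the two sites.
#' @param n Subjects per site (defaults to the first site's `n`).
#' @return A modified `synth_config` with sites `"young"` and `"old"`.
#' @export
make_prior_shift_scenario <- function(config, young = c(10, 30),
                                      old = c(60, 90), n = NULL) {
  n <- n %||% config$sites[[1L]]$n
  config$sites <- list(
    synth_site("young", n, "uniform", min = young[1L], max = young[2L],
               tilt = config$sites[[1L]]$tilt),
    synth_site("old", n, "uniform", min = old[1L], max = old[2L],
               tilt = config$sites[[length(config$sites)]]$tilt))
  validate_synth_config(config)
  config
}
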