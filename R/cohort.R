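#' Configuration for a synthetic multi-domain cohort
#'
#' Describes a two-group (ADHD vs TD) cohort with three measurement domains:
#' neuropsychological scores (NPS), blood fatty-acid percentages (BIO), and
#' block-design fNIRS recordings in two chromophores (OXY, DEOXY). The
#' defaults emulate the study conditions the pipeline was designed for:
#' 22 children per group, 18 NPS and 10 BIO features, a 32-channel montage,
#' and the standard 750 s N-back protocol of [make_schedule()].
#'
#' Tabular features are drawn per group from unit-variance normals whose
#' group means differ by the per-feature standardized effect size (Cohen's
#' d). fNIRS responses are boxcar task regressors convolved with a smooth
#' hemodynamic kernel peaking near 5 s, scaled by a per-group, per-condition
#' amplitude, on top of a linear drift and Gaussian noise. The default
#' amplitudes give TD children a load-dependent activation (stronger for
#' 2-back) and ADHD children an attenuated one, so the groups separate in
#' the task-evoked response rather than in the raw signal level.
#'
#' @param n_per_group Subjects per group (default 22).
#' @param n_nps_features,n_bio_features Tabular feature counts (18 / 10).
#' @param nps_effect_sizes,bio_effect_sizes Per-feature standardized mean
#'   differences (ADHD minus TD, in SD units). Defaults mix strong, weak and
#'   null features; the last two BIO features are null, mirroring markers
#'   that carry no group signal.
#' @param nirs_channels Number of fNIRS channels (default 32).
#' @param sampling_rate fNIRS sampling rate in Hz (default 5; must exceed
#'   twice the 0.3 Hz low-pass cutoff so the filter is representable).
#' @param response_amplitude Named list with `TD` and `ADHD` elements, each a
#'   named vector of hemodynamic response amplitudes (relative concentration
#'   change, mM·mm) for conditions `C`, `1B`, `2B`.
#' @param deoxy_ratio Scale applied to the OXY response to obtain the DEOXY
#'   response (default -0.3: anticorrelated, smaller amplitude).
#' @param noise_sd SD of the additive Gaussian sensor noise (mM·mm).
#' @param drift_slope Linear drift in mM·mm per second.
#' @param feature_correlation Equicorrelation of the tabular feature noise
#'   (0 = independent features).
#' @param seed Integer seed making the whole cohort reproducible.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 22L,
                          n_nps_features = 18L,
                          n_bio_features = 10L,
                          nps_effect_sizes = NULL,
                          bio_effect_sizes = NULL,
                          nirs_channels = 32L,
                          sampling_rate = 5,
                          response_amplitude = list(
                            TD   = c(C = 0.3, `1B` = 0.6, `2B` = 1.0),
                            ADHD = c(C = 0.3, `1B` = 0.4, `2B` = 0.5)),
                          deoxy_ratio = -0.3,
                          noise_sd = 0.5,
                          drift_slope = 0.001,
                          feature_correlation = 0,
                          seed = 1L) {
  if (is.null(nps_effect_sizes))
    nps_effect_sizes <- rep(c(0.8, 0.4, 0), length.out = n_nps_features)
  if (is.null(bio_effect_sizes)) {
    bio_effect_sizes <- rep(c(0.8, 0.5, 0.3), length.out = n_bio_features)
    if (n_bio_features >= 2)       # trailing null markers
      bio_effect_sizes[(n_bio_features - 1):n_bio_features] <- 0
  }
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_nps_features = as.integer(n_nps_features),
              n_bio_features = as.integer(n_bio_features),
              nps_effect_sizes = nps_effect_sizes,
              bio_effect_sizes = bio_effect_sizes,
              nirs_channels = as.integer(nirs_channels),
              sampling_rate = sampling_rate,
              response_amplitude = response_amplitude,
              deoxy_ratio = deoxy_ratio,
              noise_sd = noise_sd,
              drift_slope = drift_slope,
              feature_correlation = feature_correlation,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_per_group >= 2,
            cfg$n_nps_features >= 1, cfg$n_bio_features >= 1,
            cfg$nirs_channels >= 1)
  if (cfg$sampling_rate <= 2 * 0.3)
    stop("sampling_rate must exceed 0.6 Hz so the 0.3 Hz cutoff is below Nyquist")
  if (!all(is.finite(cfg$nps_effect_sizes)) || !all(is.finite(cfg$bio_effect_sizes)))
    stop("effect sizes must be finite")
  if (length(cfg$nps_effect_sizes) != cfg$n_nps_features ||
      length(cfg$bio_effect_sizes) != cfg$n_bio_features)
    stop("effect-size vectors must match the feature counts")
  if (cfg$feature_correlation < 0 || cfg$feature_correlation >= 1)
    stop("feature_correlation must be in [0, 1)")
  invisible(cfg)
}

#' Generate a tabular feature table for one domain
#'
#' Feature j is drawn independently per subject from a unit-variance normal
#' whose mean is 0 in the TD group and `effect_sizes[j]` in the ADHD group,
#' so `effect_sizes` are standardized mean differences. With
#' `feature_correlation = rho > 0`, features share an equicorrelated latent
#' factor while keeping unit marginal variance.
#'
#' @param config A [cohort_config()].
#' @param domain `"NPS"` or `"BIO"`.
#' @param seed Seed; defaults to `config$seed`. Pass `NULL` to draw from the
#'   current RNG state (used when a whole cohort is generated under one seed).
#' @return A [feature_table()] with `2 * n_per_group` rows, ADHD first.
#' @export
generate_feature_table <- function(config, domain = c("NPS", "BIO"),
                                   seed = config$seed) {
  domain <- match.arg(domain)
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  d <- switch(domain, NPS = config$nps_effect_sizes, BIO = config$bio_effect_sizes)
  p <- length(d)
  n <- config$n_per_group
  rho <- config$feature_correlation
  draw_group <- function(shift) {
    z <- matrix(stats::rnorm(n * p), n, p)
    if (rho > 0) {
      common <- stats::rnorm(n)
      z <- sqrt(rho) * common + sqrt(1 - rho) * z
    }
    sweep(z, 2, shift, `+`)
  }
  x <- rbind(draw_group(d), draw_group(rep(0, p)))
  labels <- rep(c("ADHD", "TD"), each = n)
  feature_table(x, labels, domain = domain,
                subject_id = paste0(tolower(domain), "_",
                                    sprintf("s%02d", seq_len(2 * n))))
}

#' Canonical hemodynamic impulse response
#'
#' A double-gamma kernel (positive lobe peaking near 5 s, small late
#' undershoot), sampled at `sampling_rate` over 0-30 s and normalized to
#' unit sum, so a sustained boxcar convolved with it plateaus at the boxcar
#' amplitude.
#'
#' @param sampling_rate Hz.
#' @return Numeric vector of kernel weights.
#' @export
hemodynamic_kernel <- function(sampling_rate) {
  t <- seq(0, 30, by = 1 / sampling_rate)
  h <- stats::dgamma(t, shape = 6, scale = 0.9) -
    0.35 * stats::dgamma(t, shape = 12, scale = 0.9)
  h / sum(h)
}

#' Generate one synthetic fNIRS recording
#'
#' The signal per channel is a per-channel gain times the condition-scaled
#' boxcar task regressor convolved with [hemodynamic_kernel()], plus a
#' linear drift and i.i.d. Gaussian noise. DEOXY recordings carry the OXY
#' response scaled by `config$deoxy_ratio` with their own independent noise.
#'
#' @param config A [cohort_config()].
#' @param group `"ADHD"` or `"TD"` (selects the amplitude map).
#' @param schedule A [make_schedule()] block schedule.
#' @param chromophore `"OXY"` or `"DEOXY"`.
#' @param subject_id Identifier stored on the recording.
#' @param seed Seed; `NULL` to draw from the current RNG state.
#' @return An object of class `nirs_recording`: list with `subject_id`,
#'   `chromophore`, `data` (channels x samples, mM·mm), `sampling_rate`,
#'   `events` (the schedule).
#' @export
generate_nirs_recording <- function(config, group = c("ADHD", "TD"),
                                    schedule = make_schedule(),
                                    chromophore = c("OXY", "DEOXY"),
                                    subject_id = "s01",
                                    seed = config$seed) {
  group <- match.arg(group)
  chromophore <- match.arg(chromophore)
  validate_cohort_config(config)
  stopifnot(inherits(schedule, "block_schedule"))
  if (config$sampling_rate <= 0) stop("sampling_rate must be positive")
  if (!is.null(seed)) set.seed(seed)

  fs <- config$sampling_rate
  n <- round(schedule_duration(schedule) * fs)
  t <- (seq_len(n) - 1) / fs
  amp <- config$response_amplitude[[group]]

  box <- numeric(n)
  tb <- task_blocks(schedule)
  for (i in seq_len(nrow(tb))) {
    on <- tb$stim_onset[i]
    idx <- which(t >= on & t < on + tb$stim_duration[i])
    box[idx] <- box[idx] + amp[[tb$condition[i]]]
  }
  h <- hemodynamic_kernel(fs)
  padded <- stats::filter(c(numeric(length(h) - 1), box), h, sides = 1)
  response <- as.numeric(padded[length(h) - 1 + seq_len(n)])
  if (chromophore == "DEOXY") response <- config$deoxy_ratio * response

  gain <- stats::runif(config$nirs_channels, 0.5, 1.5)
  data <- outer(gain, response) +
    matrix(rep(config$drift_slope * t, each = config$nirs_channels),
           config$nirs_channels, n) +
    matrix(stats::rnorm(config$nirs_channels * n, sd = config$noise_sd),
           config$nirs_channels, n)
  rownames(data) <- paste0("ch", seq_len(config$nirs_channels))

  nirs_recording(subject_id, chromophore, data, fs, schedule)
}

#' Construct an fNIRS recording object
#'
#' @param subject_id Subject identifier.
#' @param chromophore `"OXY"` or `"DEOXY"`.
#' @param data Channels x samples numeric matrix (mM·mm).
#' @param sampling_rate Hz.
#' @param events A [make_schedule()] block schedule.
#' @return An object of class `nirs_recording`.
#' @export
nirs_recording <- function(subject_id, chromophore, data, sampling_rate, events) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  stopifnot(inherits(events, "block_schedule"))
  structure(list(subject_id = subject_id,
                 chromophore = match.arg(chromophore, c("OXY", "DEOXY")),
                 data = data, sampling_rate = sampling_rate, events = events),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat("<nirs_recording>", x$subject_id, x$chromophore, "-",
      nrow(x$data), "channels x", ncol(x$data), "samples @",
      x$sampling_rate, "Hz\n")
  invisible(x)
}

#' Simulate a full multi-domain cohort
#'
#' One call generates, under a single seed, the NPS and BIO feature tables
#' and per-subject OXY/DEOXY fNIRS recordings for a balanced ADHD/TD cohort
#' sharing one subject roster, ready for the preprocessing and
#' classification stages.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort` with elements `config`, `schedule`,
#'   `subject_id`, `labels`, `nps`, `bio` (feature tables), and `nirs`
#'   (list with `OXY` and `DEOXY`, each a list of `nirs_recording`s in
#'   subject order).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  schedule <- make_schedule()
  n <- 2L * config$n_per_group
  subject_id <- sprintf("s%03d", seq_len(n))
  labels <- rep(c("ADHD", "TD"), each = config$n_per_group)

  nps <- generate_feature_table(config, "NPS", seed = NULL)
  bio <- generate_feature_table(config, "BIO", seed = NULL)
  nps$subject_id <- bio$subject_id <- subject_id
  rownames(nps$x) <- rownames(bio$x) <- subject_id

  nirs <- list(OXY = vector("list", n), DEOXY = vector("list", n))
  for (i in seq_len(n)) {
    for (chrom in c("OXY", "DEOXY")) {
      nirs[[chrom]][[i]] <- generate_nirs_recording(
        config, group = labels[i], schedule = schedule,
        chromophore = chrom, subject_id = subject_id[i], seed = NULL)
    }
    names(nirs$OXY)[i] <- names(nirs$DEOXY)[i] <- subject_id[i]
  }
  structure(list(config = config, schedule = schedule,
                 subject_id = subject_id, labels = labels,
                 nps = nps, bio = bio, nirs = nirs),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", length(x$subject_id), "subjects (",
      sum(x$labels == "ADHD"), "ADHD /", sum(x$labels == "TD"), "TD ),",
      "NPS:", ncol(x$nps$x), "features, BIO:", ncol(x$bio$x), "features,",
      "NIRS:", nrow(x$nirs$OXY[[1]]$data), "channels\n")
  invisible(x)
}
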