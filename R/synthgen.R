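#' Standard 32-channel montage used by the simulator
#'
#' Channel labels of the 10-20 montage covering premotor, motor,
#' somatosensory and occipital sites, in fixed order. The simulator appends
#' one EMG channel after these.
#'
#' @return Character vector of 32 channel labels.
#' @export
montage_channels <- function() {
  c("FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "P3", "P1", "Pz", "P2", "P4",
    "PO3", "POz", "PO4",
    "O1", "Oz", "O2")
}

#' Spatial gain map centred on the contralateral hand area (C3)
#'
#' Fixed per-channel weights in (0, 1] describing how strongly the simulated
#' ERD/ERS effect expresses at each electrode: a Gaussian fall-off over the
#' flattened 10-20 layout, peaking at 1 on C3. Shipped as a plain-text table
#' so the topography is reproducible without any head modelling.
#'
#' @return Named numeric vector of 32 weights, names matching
#'   [montage_channels()].
#' @export
c3_gain_map <- function() {
  path <- system.file("extdata", "c3_gain_map.csv", package = "kmibci")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$weight, tab$channel)[montage_channels()]
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort generator. Defaults follow
#' the kinesthetic motor-imagery (KMI) protocol the package analyses: 40
#' trials of 6 s rest (red cue), 2 s warning (orange), 4 s KMI (green) and a
#' jittered inter-trial interval of about 2 s, sampled at 256 Hz over the
#' 32-channel montage plus a silent EMG channel.
#'
#' @param n_subjects Number of subjects in a cohort.
#' @param n_trials Trials per session (>= 4 so 4-fold CV is feasible).
#' @param fs Sampling rate in Hz; must exceed twice the highest simulated
#'   oscillator frequency.
#' @param channel_labels Ordered channel names; default 32 EEG + "EMG".
#' @param t_rest,t_warn,t_kmi Durations (s) of the rest, warning and KMI
#'   phases of each trial.
#' @param iti_jitter Length-2 numeric, lower/upper bound (s) of the uniform
#'   inter-trial interval.
#' @param mu_freq,beta_freq Centre frequencies (Hz) of the mu and beta
#'   rhythms.
#' @param erd_depth_dist Quantile function on [0, 1] for the population
#'   distribution of ERD depth (fraction of oscillator amplitude suppressed
#'   during KMI at the gain-map peak). Default Beta(2, 2).
#' @param rebound_gain_dist Quantile function on [0, 1] for the post-KMI
#'   beta rebound gain. Default Beta(2, 4).
#' @param noise_scale Overall amplitude scale (1 = ~10 uV RMS background).
#' @param covariate_corr Named list mapping a covariate name (one of
#'   `"freq_manual"` / `"manual"`, `"freq_sport"`, `"freq_music"`,
#'   `"freq_spare1"`, `"freq_spare2"`, `"age"`, `"gender"`,
#'   `"education_years"`, `"miq_kin"`, `"miq_vis"`) to its latent Gaussian
#'   correlation with the ERD-depth latent, each in [-1, 1]. Covariates not
#'   named are independent of ERD depth.
#' @param envelope_jitter Trial-to-trial multiplicative jitter (SD, as a
#'   fraction) on the per-trial ERD depth.
#' @param seed Integer seed consumed by [generate_cohort()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 35, n_trials = 40, fs = 256,
                       channel_labels = c(montage_channels(), "EMG"),
                       t_rest = 6, t_warn = 2, t_kmi = 4,
                       iti_jitter = c(1.5, 2.5),
                       mu_freq = 10, beta_freq = 20,
                       erd_depth_dist = function(p) stats::qbeta(p, 2, 2),
                       rebound_gain_dist = function(p) stats::qbeta(p, 2, 4),
                       noise_scale = 1,
                       covariate_corr = list(),
                       envelope_jitter = 0.1,
                       seed = 1L) {
  stopifnot(n_subjects >= 1, is.numeric(fs), length(iti_jitter) == 2)
  if (n_trials < 4) stop("n_trials must be >= 4 for cross-validation feasibility")
  if (fs <= 2 * max(mu_freq, beta_freq))
    stop("fs must exceed twice the highest simulated frequency")
  if (iti_jitter[1] > iti_jitter[2]) stop("iti_jitter: lower bound exceeds upper bound")
  if (length(covariate_corr)) {
    cc <- unlist(covariate_corr)
    if (any(abs(cc) > 1)) stop("covariate_corr values must lie in [-1, 1]")
  }
  cfg <- list(n_subjects = n_subjects, n_trials = n_trials, fs = fs,
              channel_labels = channel_labels,
              t_rest = t_rest, t_warn = t_warn, t_kmi = t_kmi,
              iti_jitter = iti_jitter,
              mu_freq = mu_freq, beta_freq = beta_freq,
              erd_depth_dist = erd_depth_dist,
              rebound_gain_dist = rebound_gain_dist,
              noise_scale = noise_scale,
              covariate_corr = covariate_corr,
              envelope_jitter = envelope_jitter,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# canonical covariate names; "manual" accepted as an alias for freq_manual
.covariate_names <- c("age", "gender", "education_years",
                      "freq_manual", "freq_sport", "freq_music",
                      "freq_spare1", "freq_spare2")

.corr_for <- function(config, name) {
  cc <- config$covariate_corr
  if (name == "freq_manual" && !is.null(cc$manual) && is.null(cc$freq_manual))
    return(cc$manual)
  v <- cc[[name]]
  if (is.null(v)) 0 else v
}

# one latent correlated with z0, discretised to k equal-probability levels
.likert_from_latent <- function(z, k, lo) lo + pmin(k - 1, floor(k * stats::pnorm(z)))

.corr_latent <- function(z0, c, n = 1) c * z0 + sqrt(1 - c^2) * stats::rnorm(n)

#' Draw one subject profile
#'
#' Samples the subject's ground-truth ERD parameters and their questionnaire
#' answers and personal factors. Covariates declared in
#' `config$covariate_corr` are tied to the ERD-depth latent through a
#' Gaussian copula before being discretised to their Likert range, so the
#' latent correlation is attenuated (never inflated) in the observed scores.
#' Consumes the current R RNG stream.
#'
#' @param config A [sim_config()].
#' @return Object of class `subject_profile` with fields `erd_mu_depth`,
#'   `erd_beta_depth`, `rebound_gain`, `miq_answers` (named K1..K7, V1..V7),
#'   and `factors`. The underlying Gaussian latents are attached as
#'   attribute `"latents"` for diagnostic use.
#' @export
generate_profile <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  z0 <- stats::rnorm(1)                       # ERD-depth latent
  erd_mu <- config$erd_depth_dist(stats::pnorm(z0))
  z_b <- .corr_latent(z0, 0.7)                # beta depth tracks mu depth
  erd_beta <- config$erd_depth_dist(stats::pnorm(z_b))
  rebound <- config$rebound_gain_dist(stats::runif(1))

  latents <- c(erd = z0)
  fac <- list()
  for (nm in .covariate_names) {
    z <- .corr_latent(z0, .corr_for(config, nm))
    latents[nm] <- z
    fac[[nm]] <- switch(nm,
      age = max(18, round(25.83 + 10.42 * z)),
      gender = if (stats::pnorm(z) < 13 / 35) "F" else "M",
      education_years = max(0, round(3.29 + 3.06 * z)),
      .likert_from_latent(z, 6, 0L))
  }

  zk <- .corr_latent(z0, .corr_for(config, "miq_kin"), 7)
  zv <- .corr_latent(z0, .corr_for(config, "miq_vis"), 7)
  ans <- c(.likert_from_latent(zk, 7, 1L), .likert_from_latent(zv, 7, 1L))
  names(ans) <- c(paste0("K", 1:7), paste0("V", 1:7))

  prof <- list(erd_mu_depth = erd_mu, erd_beta_depth = erd_beta,
               rebound_gain = rebound, miq_answers = ans, factors = fac)
  class(prof) <- "subject_profile"
  attr(prof, "latents") <- latents
  prof
}

# 1/f ("pink") noise, one column per channel, unit RMS per column.
# Spectral shaping of white noise, synthesised directly as a
# Hermitian-symmetric Gaussian spectrum (one inverse FFT); the FFT length is
# padded to a highly composite size (mixed-radix FFTs of awkward lengths are
# quadratic), then truncated to n.
.pink_noise_mat <- function(nch, n, fs) {
  m <- stats::nextn(n, c(2, 3))
  half <- floor(m / 2)
  f <- seq_len(half - 1) * fs / m
  g <- 1 / sqrt(pmax(f, 1))                   # flat below 1 Hz
  sp <- matrix(0 + 0i, m, nch)
  z <- matrix(complex(real = stats::rnorm((half - 1) * nch),
                      imaginary = stats::rnorm((half - 1) * nch)),
              half - 1, nch)
  sp[2:half, ] <- z * g
  sp[m:(m - half + 2), ] <- Conj(sp[2:half, ])
  x <- Re(stats::mvfft(sp, inverse = TRUE))[seq_len(n), , drop = FALSE]
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

.pink_noise <- function(n, fs) drop(.pink_noise_mat(1L, n, fs))

# narrowband oscillator at f0 with ~half_bw envelope bandwidth, unit RMS:
# a slowly varying complex Gaussian envelope (sampled at ~4*half_bw Hz and
# linearly interpolated) modulating a carrier at f0
.narrowband <- function(n, fs, f0, half_bw = 1.5) {
  step <- max(1, floor(fs / (4 * half_bw)))
  ne <- ceiling(n / step) + 2
  ei <- (seq_len(n) - 1) / step + 1
  a_re <- stats::approx(seq_len(ne), stats::rnorm(ne), ei)$y
  a_im <- stats::approx(seq_len(ne), stats::rnorm(ne), ei)$y
  ph <- 2 * pi * f0 * (seq_len(n) - 1) / fs
  x <- a_re * cos(ph) - a_im * sin(ph)
  x / stats::sd(x)
}

#' Simulate one EEG session
#'
#' Builds a continuous multichannel recording following the trial protocol:
#' per trial a red rest cue, an orange warning, then a green cue during which
#' mu and beta oscillator envelopes are attenuated by `(1 - depth * w)` at
#' each channel (`w` the fixed C3-centred gain map, so attenuation is exactly
#' `1 - depth` at C3), followed by a 1-s beta rebound scaled by
#' `(1 + rebound_gain * w)`. The signal is the sum of per-channel 1/f noise,
#' a shared common-mode 1/f component (20% amplitude), the two band-limited
#' oscillators (a common source per band plus 30% independent per-channel
#' narrowband activity), and a near-silent white-noise EMG channel.
#' Consumes the current R RNG stream; fully reproducible given the RNG state.
#'
#' @param profile A [generate_profile()] result.
#' @param config A [sim_config()].
#' @param return_components If TRUE, attach the noiseless per-band oscillator
#'   tracks (channels x samples) as attribute `"components"` so band power
#'   can be audited without noise.
#' @return Object of class `eeg_session`: `signal` (channels x samples, uV),
#'   `fs`, `channel_labels`, `events` (data.frame `onset_s`, `code`).
#' @export
generate_session <- function(profile, config, return_components = FALSE) {
  stopifnot(inherits(profile, "subject_profile"), inherits(config, "sim_config"))
  fs <- config$fs
  trial_len <- config$t_rest + config$t_warn + config$t_kmi
  iti <- stats::runif(config$n_trials, config$iti_jitter[1], config$iti_jitter[2])
  red <- 1 + c(0, cumsum(trial_len + iti))[seq_len(config$n_trials)]
  orange <- red + config$t_rest
  green <- red + config$t_rest + config$t_warn
  total_s <- green[config$n_trials] + config$t_kmi + 2
  n <- ceiling(total_s * fs)
  tt <- (seq_len(n) - 1) / fs

  labels <- config$channel_labels
  eeg_idx <- which(labels != "EMG")
  n_eeg <- length(eeg_idx)
  gains <- c3_gain_map()
  w <- ifelse(labels[eeg_idx] %in% names(gains), gains[labels[eeg_idx]], 0)

  # per-trial multiplicative jitter on ERD depth, clamped to [0, 1]
  jit <- function(depth) pmin(1, pmax(0, depth * (1 + config$envelope_jitter * stats::rnorm(config$n_trials))))
  dep_mu <- jit(profile$erd_mu_depth)
  dep_beta <- jit(profile$erd_beta_depth)

  # time-course of the attenuation "drive": 0 outside KMI, per-trial depth inside;
  # rebound drive: 1 during the second after green offset
  drive_mu <- numeric(n); drive_beta <- numeric(n); drive_reb <- numeric(n)
  for (k in seq_len(config$n_trials)) {
    on <- floor(green[k] * fs) + 1
    off <- min(n, floor((green[k] + config$t_kmi) * fs))
    drive_mu[on:off] <- dep_mu[k]
    drive_beta[on:off] <- dep_beta[k]
    reb_end <- min(n, floor((green[k] + config$t_kmi + 1) * fs))
    if (off < reb_end) drive_reb[(off + 1):reb_end] <- 1
  }

  amp_mu <- 6 * config$noise_scale
  amp_beta <- 4 * config$noise_scale
  bg_rms <- 10 * config$noise_scale

  src_mu <- .narrowband(n, fs, config$mu_freq)
  src_beta <- .narrowband(n, fs, config$beta_freq)
  common <- .pink_noise(n, fs)

  signal <- matrix(0, length(labels), n)
  comp_mu <- if (return_components) matrix(0, length(labels), n) else NULL
  comp_beta <- if (return_components) matrix(0, length(labels), n) else NULL

  pink <- .pink_noise_mat(n_eeg, n, fs)       # samples x channels
  for (j in seq_along(eeg_idx)) {
    ch <- eeg_idx[j]
    env_mu <- 1 - drive_mu * w[j]
    env_beta <- (1 - drive_beta * w[j]) * (1 + profile$rebound_gain * w[j] * drive_reb)
    g <- 0.25 + 0.75 * w[j]                   # oscillators strongest over motor sites
    osc_mu <- amp_mu * g * env_mu * (src_mu + 0.3 * .narrowband(n, fs, config$mu_freq))
    osc_beta <- amp_beta * g * env_beta * (src_beta + 0.3 * .narrowband(n, fs, config$beta_freq))
    bg <- bg_rms * (pink[, j] + 0.2 * common)
    signal[ch, ] <- osc_mu + osc_beta + bg
    if (return_components) { comp_mu[ch, ] <- osc_mu; comp_beta[ch, ] <- osc_beta }
  }
  emg <- which(labels == "EMG")
  if (length(emg)) signal[emg, ] <- 0.5 * config$noise_scale * stats::rnorm(n)

  events <- data.frame(
    onset_s = round(c(rbind(red, orange, green)), 6),  # seconds from recording start
    code = rep(c("RED", "ORANGE", "GREEN"), config$n_trials),
    stringsAsFactors = FALSE)

  ses <- eeg_session(signal, fs, labels, events)
  if (return_components)
    attr(ses, "components") <- list(mu = comp_mu, beta = comp_beta)
  ses
}

#' Construct an EEG session object
#'
#' @param signal Channels x samples numeric matrix (uV).
#' @param fs Sampling rate (Hz).
#' @param channel_labels Character vector, one per row of `signal`.
#' @param events data.frame with columns `onset_s` (seconds, 0-based) and
#'   `code` in RED/ORANGE/GREEN, sorted by onset.
#' @return Object of class `eeg_session`.
#' @export
eeg_session <- function(signal, fs, channel_labels, events) {
  stopifnot(is.matrix(signal), nrow(signal) == length(channel_labels))
  if (is.unsorted(events$onset_s)) stop("events must be sorted by onset")
  bad <- setdiff(unique(events$code), c("RED", "ORANGE", "GREEN"))
  if (length(bad))
    stop("unknown event code(s) ", paste(bad, collapse = ", "),
         "; allowed codes are RED, ORANGE, GREEN")
  structure(list(signal = signal, fs = fs,
                 channel_labels = channel_labels, events = events),
            class = "eeg_session")
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("<eeg_session> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$events)))
  invisible(x)
}

.profile_record <- function(id, profile) {
  data.frame(subject_id = id, as.list(profile$miq_answers),
             as.list(profile$factors), stringsAsFactors = FALSE)
}

#' Draw a cohort of subject profiles (no EEG)
#'
#' Profile-level sampling used by calibration studies that do not need raw
#' signals. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `records` (one row per subject: questionnaire answers
#'   and personal factors) and `ground_truth` (hidden ERD parameters; for
#'   test and calibration use only, never an input to the analysis stages).
#' @export
generate_profiles <- function(config) {
  set.seed(config$seed)
  ids <- sprintf("S%02d", seq_len(config$n_subjects))
  recs <- vector("list", config$n_subjects)
  gt <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    p <- generate_profile(config)
    recs[[i]] <- .profile_record(ids[i], p)
    gt[[i]] <- data.frame(subject_id = ids[i],
                          erd_mu_depth = p$erd_mu_depth,
                          erd_beta_depth = p$erd_beta_depth,
                          rebound_gain = p$rebound_gain)
  }
  list(records = do.call(rbind, recs), ground_truth = do.call(rbind, gt))
}

#' Generate a full synthetic cohort
#'
#' One profile and one EEG session per subject, reproducible from
#' `config$seed`. Sessions can be kept in memory or streamed to disk as
#' EDF + events TSV (one pair per subject) to bound memory for large cohorts.
#'
#' @param config A [sim_config()].
#' @param out_dir If non-NULL, write each session to
#'   `<out_dir>/<subject_id>.edf` / `_events.tsv` instead of keeping it.
#' @return List with `sessions` (list of `eeg_session` or file paths),
#'   `records` (subject table) and `ground_truth` (hidden ERD parameters,
#'   kept separate from the analysis inputs).
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  ids <- sprintf("S%02d", seq_len(config$n_subjects))
  sessions <- vector("list", config$n_subjects)
  recs <- vector("list", config$n_subjects)
  gt <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    p <- generate_profile(config)
    s <- generate_session(p, config)
    recs[[i]] <- .profile_record(ids[i], p)
    gt[[i]] <- data.frame(subject_id = ids[i],
                          erd_mu_depth = p$erd_mu_depth,
                          erd_beta_depth = p$erd_beta_depth,
                          rebound_gain = p$rebound_gain)
    if (is.null(out_dir)) {
      sessions[[i]] <- s
    } else {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      edf <- file.path(out_dir, paste0(ids[i], ".edf"))
      tsv <- file.path(out_dir, paste0(ids[i], "_events.tsv"))
      write_edf(s, edf)
      write_events_tsv(s$events, tsv)
      sessions[[i]] <- c(edf = edf, events = tsv)
    }
  }
  names(sessions) <- ids
  list(sessions = sessions,
       records = do.call(rbind, recs),
       ground_truth = do.call(rbind, gt))
}

#' Ground-truth accuracy surrogate for large calibration studies
#'
#' Maps hidden ERD depth to a plausible decoding accuracy
#' (`0.5 + 0.45 * depth` plus Gaussian noise, clamped to [0.25, 1]): chance
#' at zero depth, near-ceiling at full suppression. Used by statistical
#' calibration suites that need hundreds of cohorts, where running the full
#' EEG decoding chain per subject is not a desk-scale computation; it is
#' never part of the analysis of real or simulated recordings.
#'
#' @param erd_depth Numeric vector of ground-truth ERD depths in [0, 1].
#' @param noise_sd SD of the additive accuracy noise.
#' @return Numeric vector of surrogate accuracies.
#' @export
surrogate_accuracy <- function(erd_depth, noise_sd = 0.06) {
  pmin(1, pmax(0.25, 0.5 + 0.45 * erd_depth + stats::rnorm(length(erd_depth), 0, noise_sd)))
}
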