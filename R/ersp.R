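#' Event-related spectral perturbation (ERSP) map
#'
#' Time-frequency decomposition of the trials around each GREEN (imagery)
#' cue with a sliding Hanning-tapered 256-point FFT (hop 32 samples), power
#' averaged over trials, expressed in dB relative to a per-frequency
#' baseline: \eqn{10 \log_{10}(P(f, t) / \bar P_{baseline}(f))}. The
#' baseline is the mean power over the 2-s window ending 2 s before the
#' GREEN cue — inside the preceding rest period. The map covers `t_range`
#' (default -1 s to +4 s around the cue) and 8-30 Hz.
#'
#' @param session An `eeg_session` (unfiltered; the FFT handles band
#'   selection).
#' @param channel Channel label (e.g. "C3").
#' @param t_range Length-2 numeric, window around the GREEN cue in seconds.
#' @param f_range Length-2 numeric, retained frequency band in Hz.
#' @param nfft FFT length in samples (default 256).
#' @param hop Hop between window centres in samples (default 32).
#' @param baseline Length-2 numeric, baseline window relative to the GREEN
#'   cue in seconds (default c(-4, -2)).
#' @return Object of class `ersp_map`: `values` (frequency x time, dB),
#'   `freqs` (Hz), `times` (s, window centres relative to the cue),
#'   `channel`, `n_trials`.
#' @export
compute_ersp <- function(session, channel = "C3",
                         t_range = c(-1, 4), f_range = c(8, 30),
                         nfft = 256, hop = 32, baseline = c(-4, -2)) {
  stopifnot(inherits(session, "eeg_session"))
  ch <- match(channel, session$channel_labels)
  if (is.na(ch)) stop("channel not found: ", channel)
  fs <- session$fs
  x <- session$signal[ch, ]
  onsets <- session$events$onset_s[session$events$code == "GREEN"]
  if (!length(onsets)) stop("no GREEN events in session")
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nfft) / (nfft + 1)))  # Hanning
  freqs <- (seq_len(nfft / 2 + 1) - 1) * fs / nfft
  fsel <- which(freqs >= f_range[1] & freqs <= f_range[2])

  # window-centre grid relative to the cue, identical across trials
  rel_centers <- seq(t_range[1], t_range[2], by = hop / fs)
  base_centers <- seq(baseline[1] + nfft / fs / 2, baseline[2] - nfft / fs / 2,
                      by = hop / fs)

  spec_at <- function(t0) {
    start <- floor(t0 * fs) - nfft / 2 + 1
    if (start < 1 || start + nfft - 1 > length(x)) return(NULL)
    seg <- x[start:(start + nfft - 1)] * win
    sp <- stats::fft(seg)[seq_len(nfft / 2 + 1)]
    (Mod(sp)^2)[fsel]
  }

  P <- matrix(0, length(fsel), length(rel_centers))
  Pb <- numeric(length(fsel))
  used <- 0L
  for (on in onsets) {
    trial <- lapply(on + rel_centers, spec_at)
    base <- lapply(on + base_centers, spec_at)
    if (any(vapply(trial, is.null, TRUE)) || any(vapply(base, is.null, TRUE))) next
    P <- P + do.call(cbind, trial)
    Pb <- Pb + rowMeans(do.call(cbind, base))
    used <- used + 1L
  }
  if (used == 0L) stop("no trial had complete analysis and baseline windows")
  P <- P / used
  Pb <- Pb / used
  structure(list(values = 10 * log10(P / Pb),
                 freqs = freqs[fsel], times = rel_centers,
                 channel = channel, n_trials = used),
            class = "ersp_map")
}

#' @export
print.ersp_map <- function(x, ...) {
  cat(sprintf("<ersp_map> %s: %d freqs (%g-%g Hz) x %d times (%g to %g s), %d trials\n",
              x$channel, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), min(x$times), max(x$times), x$n_trials))
  invisible(x)
}

#' Permutation group comparison of ERSP maps
#'
#' Per time-frequency cell, the observed between-group difference of subject
#' means is compared with its permutation null (subject group labels
#' shuffled `n_perm` times); two-sided p-values per cell are corrected with
#' Benjamini-Hochberg FDR over the full grid at level `alpha`.
#'
#' @param maps1,maps2 Lists of `ersp_map` objects (one per subject, same
#'   grid), >= 2 subjects per group.
#' @param n_perm Number of permutations (default 1000; < 100 warns). When the
#'   number of distinct group assignments is at most `n_perm`, all of them
#'   are enumerated instead (exact permutation test, invariant to group
#'   order).
#' @param alpha FDR level for the significance mask (default 0.05).
#' @param seed RNG seed for the permutation draws.
#' @return List: `difference` (mean1 - mean2, frequency x time),
#'   `p_values`, `mask` (logical, FDR-significant cells), `freqs`, `times`.
#' @export
group_compare_ersp <- function(maps1, maps2, n_perm = 1000, alpha = 0.05,
                               seed = 1L) {
  if (length(maps1) < 2 || length(maps2) < 2)
    stop("each group needs >= 2 subjects")
  if (n_perm < 100) warning("n_perm < 100 gives coarse p-values")
  flat <- function(maps) t(vapply(maps, function(m) as.vector(m$values),
                                  numeric(length(maps1[[1]]$values))))
  X <- rbind(flat(maps1), flat(maps2))
  n1 <- length(maps1); n <- nrow(X)
  obs <- colMeans(X[seq_len(n1), , drop = FALSE]) -
         colMeans(X[-seq_len(n1), , drop = FALSE])
  n2 <- n - n1
  if (choose(n, n1) <= n_perm) {
    # exact test: enumerate every group-1 assignment (includes the observed
    # one, and is invariant to which group is passed first)
    combos <- utils::combn(n, n1)
    I <- matrix(0, ncol(combos), n)
    I[cbind(rep(seq_len(ncol(combos)), each = n1), as.vector(combos))] <- 1
    S <- I %*% X
    tot <- matrix(colSums(X), ncol(combos), ncol(X), byrow = TRUE)
    D <- S / n1 - (tot - S) / n2
    # the first combination is the observed assignment (1..n1); comparing
    # against its own row keeps the arithmetic identical, so the observed
    # partition always counts itself and p >= 1/n_partitions
    p <- colMeans(sweep(abs(D), 2, abs(D[1, ]), ">=") * 1)
  } else {
    set.seed(seed)
    exceed <- numeric(length(obs))
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n, n1)
      d <- colMeans(X[idx, , drop = FALSE]) - colMeans(X[-idx, , drop = FALSE])
      exceed <- exceed + (abs(d) >= abs(obs))
    }
    p <- (1 + exceed) / (1 + n_perm)
  }
  mask <- stats::p.adjust(p, method = "BH") <= alpha
  dm <- dim(maps1[[1]]$values)
  list(difference = matrix(obs, dm[1], dm[2]),
       p_values = matrix(p, dm[1], dm[2]),
       mask = matrix(mask, dm[1], dm[2]),
       freqs = maps1[[1]]$freqs, times = maps1[[1]]$times)
}

#' Write an ERSP map (or mask) as CSV with axis sidecar
#'
#' @param map An `ersp_map` or a matrix with `freqs`/`times` supplied.
#' @param path Output CSV path; a `<path>.axes.json` sidecar records the
#'   frequency and time axes.
#' @return `path`, invisibly.
#' @export
write_ersp_csv <- function(map, path) {
  vals <- if (inherits(map, "ersp_map")) map$values else map$difference
  utils::write.table(vals, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(freqs = map$freqs, times = map$times),
                       paste0(path, ".axes.json"), digits = NA)
  invisible(path)
}
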