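# Magnitude-squared coherence between bipolar derivations, by Welch-averaged
# Fourier cross-spectra.

channel_index <- function(recording, label) {
  labels <- colnames(recording)
  hit <- which(toupper(labels) == toupper(label))
  if (length(hit) != 1) {
    stop("electrode '", label, "' not found in recording channels",
         call. = FALSE)
  }
  hit
}

#' Derive a bipolar signal from two adjacent electrodes
#'
#' The bipolar derivation is the sample-wise difference anode - cathode; it
#' attenuates the volume-conducted activity common to neighbouring scalp
#' sites before coherence is computed.
#'
#' @param recording Numeric matrix or data frame, one column per channel,
#'   with 10-20 electrode labels as column names (matched
#'   case-insensitively).
#' @param anode,cathode Electrode labels.
#' @return A numeric vector, `recording[, anode] - recording[, cathode]`.
#' @export
derive_bipolar <- function(recording, anode, cathode) {
  recording <- as.matrix(recording)
  a <- recording[, channel_index(recording, anode)]
  c_ <- recording[, channel_index(recording, cathode)]
  if (length(a) != length(c_)) stop("channels differ in length", call. = FALSE)
  as.numeric(a - c_)
}

hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))
}

#' Welch-averaged auto- and cross-spectra of two signals
#'
#' Splits both signals into Hann-tapered, demeaned segments with the given
#' overlap, averages one-sided auto-spectra and the complex cross-spectrum
#' over segments, and records the segment count `K` (the 256-s resting
#' interval at 2-s segments and 50% overlap gives K = 255 and 0.5-Hz
#' resolution). Spectra are density-scaled so the auto-spectrum integrates to
#' the signal variance.
#'
#' @param x,y Equal-length numeric signals.
#' @param fs Sampling rate (Hz).
#' @param segment_s Segment length in seconds.
#' @param overlap Fractional overlap between consecutive segments in
#'   `[0, 1)`.
#' @return An object of class `spectral_estimate`: list with `freq`, `sxx`,
#'   `syy`, `sxy` (complex), `k` (segments), `fs`, `segment_s`, `overlap`.
#' @export
estimate_spectra <- function(x, y, fs, segment_s = 2, overlap = 0.5) {
  if (length(x) != length(y)) stop("signals differ in length", call. = FALSE)
  L <- round(segment_s * fs)
  if (L < 2) stop("segment shorter than two samples", call. = FALSE)
  if (L > length(x)) {
    stop("segment (", L, " samples) longer than signal (", length(x), ")",
         call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)",
                                        call. = FALSE)
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, length(x) - L + 1, by = step)
  K <- length(starts)
  w <- hann_window(L)
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(L / 2) + 1

  sxx <- numeric(nf); syy <- numeric(nf)
  sxy <- complex(real = numeric(nf), imaginary = numeric(nf))
  for (s0 in starts) {
    xs <- x[s0:(s0 + L - 1)]; ys <- y[s0:(s0 + L - 1)]
    X <- fft(w * (xs - mean(xs)))[seq_len(nf)]
    Y <- fft(w * (ys - mean(ys)))[seq_len(nf)]
    sxx <- sxx + Re(X * Conj(X))
    syy <- syy + Re(Y * Conj(Y))
    sxy <- sxy + X * Conj(Y)
  }
  one_sided <- rep(2, nf)
  one_sided[1] <- 1
  if (L %% 2 == 0) one_sided[nf] <- 1
  structure(list(
    freq = seq(0, nf - 1) * fs / L,
    sxx = sxx * scale * one_sided / K,
    syy = syy * scale * one_sided / K,
    sxy = sxy * scale * one_sided / K,
    k = K, fs = fs, segment_s = segment_s, overlap = overlap
  ), class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat("<spectral_estimate> ", length(x$freq), " bins 0-",
      max(x$freq), " Hz, K = ", x$k, " segments\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.spectral_estimate <- function(x, ...) {
  tibble::tibble(freq = x$freq, sxx = x$sxx, syy = x$syy,
                 cross_mod = Mod(x$sxy), cross_phase = Arg(x$sxy))
}

#' Per-frequency magnitude-squared coherence
#'
#' `C(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f))`, in `[0, 1]` by Cauchy-Schwarz.
#' With a single segment the estimate is identically 1 regardless of the
#' signals, so at least two averaged segments are required.
#'
#' @param spec A `spectral_estimate`.
#' @return A tibble with columns `freq`, `coherence` (`NA` at zero-power
#'   bins).
#' @export
coherence_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectral_estimate"))
  if (spec$k < 2) {
    stop("coherence needs K >= 2 averaged segments: a single-segment ",
         "estimate is identically 1", call. = FALSE)
  }
  denom <- spec$sxx * spec$syy
  C <- ifelse(denom > 0, Mod(spec$sxy)^2 / denom, NA_real_)
  tibble::tibble(freq = spec$freq, coherence = pmin(pmax(C, 0), 1))
}

#' Band-averaged coherence
#'
#' Unweighted mean of `C(f)` over FFT bins with `f_lo <= f < f_hi`
#' (half-open, so a band edge shared by two bands is counted once).
#'
#' @param coh Tibble from [coherence_spectrum()] (columns `freq`,
#'   `coherence`).
#' @param bands Band definition tibble ([eeg_bands()] or subset).
#' @return A tibble with columns `band`, `f_lo`, `f_hi`, `n_bins`,
#'   `coherence`.
#' @export
band_average <- function(coh, bands = eeg_bands()) {
  purrr::map_dfr(seq_len(nrow(bands)), function(i) {
    sel <- coh$freq >= bands$f_lo[i] & coh$freq < bands$f_hi[i]
    if (!any(sel)) {
      stop("band ", bands$band[i], " [", bands$f_lo[i], ", ", bands$f_hi[i],
           ") contains no frequency bins", call. = FALSE)
    }
    tibble::tibble(band = bands$band[i], f_lo = bands$f_lo[i],
                   f_hi = bands$f_hi[i], n_bins = sum(sel),
                   coherence = mean(coh$coherence[sel]))
  })
}

#' Band coherence for all bipolar pairs of one recording
#'
#' Derives the bipolar signals of every pair definition, estimates Welch
#' spectra per pair, and band-averages the coherence, yielding the
#' per-visit phenotype rows (pairs x bands).
#'
#' @param recording Numeric matrix / data frame of labelled channels.
#' @param fs Sampling rate (Hz).
#' @param pairs Pair definitions ([coherence_pairs()]).
#' @param bands Band definitions ([eeg_bands()]).
#' @param segment_s,overlap Welch parameters, see [estimate_spectra()].
#' @return A tibble with columns `pair_id`, `region_class`, `band`,
#'   `coherence`, one row per pair x band.
#' @export
coherence_table <- function(recording, fs, pairs = coherence_pairs(),
                            bands = eeg_bands(), segment_s = 2,
                            overlap = 0.5) {
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    sig_a <- derive_bipolar(recording, pairs$a_anode[i], pairs$a_cathode[i])
    sig_b <- derive_bipolar(recording, pairs$b_anode[i], pairs$b_cathode[i])
    if (var(sig_a) == 0 || var(sig_b) == 0) {
      stop("pair ", pairs$pair_id[i], " (", pairs$a_anode[i], "-",
           pairs$a_cathode[i], " vs ", pairs$b_anode[i], "-",
           pairs$b_cathode[i], "): bipolar derivation has zero power",
           call. = FALSE)
    }
    spec <- estimate_spectra(sig_a, sig_b, fs, segment_s, overlap)
    ba <- band_average(coherence_spectrum(spec), bands)
    tibble::tibble(pair_id = pairs$pair_id[i],
                   region_class = pairs$region_class[i],
                   band = ba$band, coherence = ba$coherence)
  })
}
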