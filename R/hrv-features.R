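# The ten HR/HRV input features, in canonical order:
# mean RR, HR, SDNN, RMSSD, LF, HF, LF/HF, SD1, SD2, SD2/SD1.

.hrvFeatureNames <- c("rri_mean", "hr", "sdnn", "rmssd", "lf", "hf",
                      "lf_hf", "sd1", "sd2", "sd2_sd1")

#' Canonical HRV feature names
#'
#' The ten heart-rate / heart-rate-variability features, in the fixed order
#' used throughout the package: mean RR interval (ms), heart rate (bpm), SDNN
#' (ms), RMSSD (ms), LF power (ms^2), HF power (ms^2), LF/HF ratio, Poincare
#' SD1 (ms), SD2 (ms) and SD2/SD1 ratio.
#'
#' @return Character vector of length 10.
#' @export
hrvFeatureNames <- function() .hrvFeatureNames

asIntervals <- function(rri) {
  if (is(rri, "RRISeries")) rri@intervals else as.numeric(rri)
}

# Artefact guard: inputs are assumed clean (no ectopic-beat correction is
# performed), so intervals outside the physiological 300-2000 ms window are
# rejected rather than silently processed.
assertCleanRR <- function(x, minLength = 30L) {
  if (length(x) < minLength)
    stop(sprintf("RR series has %d intervals; need at least %d", length(x), minLength),
         call. = FALSE)
  bad <- which(x < 300 | x > 2000)
  if (length(bad))
    stop(sprintf(paste0("interval plausibility guard: %d interval(s) outside ",
                        "300-2000 ms (first at position %d: %.1f ms)"),
                 length(bad), bad[1], x[bad[1]]), call. = FALSE)
  invisible(TRUE)
}

#' Time-domain HRV features
#'
#' Mean RR interval, heart rate, SDNN and RMSSD. SDNN uses the sample (n-1)
#' standard deviation; RMSSD is the root mean square of successive interval
#' differences; HR = 60000 / mean RR.
#'
#' @param rri an [RRISeries-class] or numeric vector of RR intervals (ms),
#'   length >= 30.
#' @return Named numeric vector `rri_mean`, `hr`, `sdnn`, `rmssd`.
#' @examples
#' timeDomain(rep(1000, 240))
#' @export
timeDomain <- function(rri) {
  x <- asIntervals(rri)
  assertCleanRR(x)
  m <- mean(x)
  d <- diff(x)
  c(rri_mean = m, hr = 60000 / m, sdnn = stats::sd(x), rmssd = sqrt(mean(d^2)))
}

#' Poincare-plot HRV features
#'
#' Dispersion of the lag-1 Poincare scatter perpendicular to (SD1) and along
#' (SD2) the identity line: `sd1 = sqrt(var(diff(x)) / 2)` and
#' `sd2 = sqrt(2 * var(x) - sd1^2)`, both using the population (1/n) variance
#' so the identities `sd1 = rmssd / sqrt(2)` (for zero-mean successive
#' differences) and `2 * sdnn_pop^2 = sd1^2 + sd2^2` hold exactly. For a
#' constant series SD1 = SD2 = 0 and the ratio is returned as `NA` (never
#' infinity).
#'
#' @inheritParams timeDomain
#' @return Named numeric vector `sd1`, `sd2`, `sd2_sd1`.
#' @export
poincare <- function(rri) {
  x <- asIntervals(rri)
  assertCleanRR(x)
  varPop <- function(v) mean((v - mean(v))^2)
  d <- diff(x)
  sd1 <- sqrt(varPop(d) / 2)
  sd2 <- sqrt(max(0, 2 * varPop(x) - sd1^2))
  c(sd1 = sd1, sd2 = sd2, sd2_sd1 = if (sd1 > 0) sd2 / sd1 else NA_real_)
}

# Welch one-sided PSD: Hann windows, 50% overlap, per-segment mean removal.
# Calibrated so a sinusoid of amplitude A integrates to band power A^2 / 2.
welchPsd <- function(x, fs, segLen = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(segLen)) segLen <- min(256L, max(64L, floor(n / 2)))
  segLen <- min(segLen, n)
  step <- max(1L, floor(segLen * (1 - overlap)))
  starts <- seq(1L, n - segLen + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(segLen) / (segLen + 1)))
  U <- sum(w^2)
  nf <- floor(segLen / 2) + 1L
  dup <- 2:(nf - if (segLen %% 2 == 0) 1L else 0L)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segLen - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- abs(stats::fft(seg))^2 / (fs * U)
    half <- P[1:nf]
    half[dup] <- 2 * half[dup]
    acc <- acc + half
  }
  list(freq = (seq_len(nf) - 1) * fs / segLen, psd = acc / length(starts))
}

bandPower <- function(freq, psd, lo, hi) {
  df <- freq[2] - freq[1]
  sum(psd[freq >= lo & freq < hi]) * df
}

#' Frequency-domain HRV features
#'
#' LF and HF band powers (ms^2) of the RR tachogram, and their ratio. The
#' irregularly sampled tachogram is resampled at 4 Hz by cubic-spline
#' interpolation and analysed with a Welch periodogram (Hann windows of at
#' most half the record, 50% overlap). Bands follow the short-term HRV
#' standard: LF 0.04-0.15 Hz, HF 0.15-0.40 Hz. If the HF power is zero the
#' ratio is returned as `NA`.
#'
#' @inheritParams timeDomain
#' @param fs resampling frequency in Hz.
#' @param lfBand,hfBand frequency bands as `c(lo, hi)` in Hz.
#' @return Named numeric vector `lf`, `hf`, `lf_hf`.
#' @export
frequencyDomain <- function(rri, fs = 4, lfBand = c(0.04, 0.15),
                            hfBand = c(0.15, 0.40)) {
  x <- asIntervals(rri)
  assertCleanRR(x)
  tBeat <- cumsum(x) / 1000
  if (tBeat[length(tBeat)] - tBeat[1] < 120)
    stop("frequency-domain analysis needs at least 120 s of data", call. = FALSE)
  grid <- seq(tBeat[1], tBeat[length(tBeat)], by = 1 / fs)
  y <- stats::spline(tBeat, x, xout = grid)$y
  p <- welchPsd(y, fs)
  lf <- bandPower(p$freq, p$psd, lfBand[1], lfBand[2])
  hf <- bandPower(p$freq, p$psd, hfBand[1], hfBand[2])
  c(lf = lf, hf = hf, lf_hf = if (hf > 0) lf / hf else NA_real_)
}

#' The 10-element HRV feature vector
#'
#' Combines [timeDomain()], [frequencyDomain()] and [poincare()] into the
#' canonical 10-feature vector (see [hrvFeatureNames()]). Ratios with a zero
#' denominator are `NA`; all other entries are finite for valid input.
#'
#' @inheritParams timeDomain
#' @return Named numeric vector of length 10 in canonical order.
#' @examples
#' rri <- simulateRR(100, 20, 2, duration = 240, seed = 1)
#' hrvFeatures(rri)
#' @export
hrvFeatures <- function(rri) {
  td <- timeDomain(rri)
  fd <- frequencyDomain(rri)
  pc <- poincare(rri)
  out <- c(td, fd, pc)[.hrvFeatureNames]
  stopifnot(identical(names(out), .hrvFeatureNames))
  out
}

#' Extract HRV features for a whole cohort
#'
#' Runs [hrvFeatures()] on every RR series of a cohort and assembles the
#' results into a `SummarizedExperiment`: one assay `"hrv"` with the ten
#' features in rows and one column per subject-stage, with the observation
#' table (Borg, reaction time, speed, latent fatigue) as column data.
#'
#' @param cohort a [FatigueCohort-class].
#' @return A [SummarizedExperiment::SummarizedExperiment-class].
#' @examples
#' \donttest{
#' se <- cohortFeatures(simulateCohort(protocolConfig(seed = 1)))
#' dim(se)
#' }
#' @export
cohortFeatures <- function(cohort) {
  stopifnot(is(cohort, "FatigueCohort"))
  mat <- vapply(cohort@series, hrvFeatures, numeric(10))
  obs <- cohort@observations
  colnames(mat) <- sprintf("%s_stage%d", obs$subject, obs$stage)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(hrv = mat),
    colData = S4Vectors::DataFrame(obs, row.names = colnames(mat))
  )
}
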