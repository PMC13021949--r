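#' Construct an ECG record
#'
#' Container for one multichannel ECG: a lead-by-sample signal matrix in mV,
#' its sampling rate, lead names, diagnostic annotation codes with optional
#' likelihoods, and basic demographics used for matched-control sampling.
#'
#' @param signal numeric matrix, leads in rows, samples in columns, in mV.
#' @param fs sampling rate in Hz (> 0).
#' @param lead_names character vector naming the rows of `signal`; must be a
#'   subset of the canonical 12-lead set (case-insensitive), without
#'   duplicates. Order is preserved.
#' @param record_id,patient_id identifiers; `patient_id` defaults to
#'   `record_id` (one record per patient).
#' @param labels named numeric vector of diagnostic codes with likelihoods in
#'   \[0, 100\] (e.g. `c(IMI = 80, ASMI = 35)`), or `NULL`.
#' @param age age in years, or `NA`.
#' @param sex `"male"`, `"female"`, or `NA`.
#' @param validated logical; whether the annotation was validated by a human
#'   rater.
#' @return An object of class `"ecg_record"`.
#' @examples
#' sig <- matrix(sin(seq(0, 20 * pi, length.out = 1000)), nrow = 1)
#' rec <- ecg_record(sig, fs = 100, lead_names = "II", record_id = "r1",
#'                   labels = c(NORM = 100), age = 54, sex = "female")
#' rec
#' @export
ecg_record <- function(signal, fs, lead_names, record_id = "rec",
                       patient_id = record_id, labels = NULL,
                       age = NA_real_, sex = NA_character_, validated = TRUE) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("signal must be a numeric matrix (leads x samples)")
  lead_names <- normalize_lead_names(lead_names)
  if (nrow(signal) != length(lead_names))
    stop("signal has ", nrow(signal), " rows but ", length(lead_names),
         " lead names were given")
  if (anyDuplicated(lead_names))
    stop("duplicate lead names: ",
         paste(unique(lead_names[duplicated(lead_names)]), collapse = ", "))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  if (!all(is.finite(signal)))
    stop("signal contains non-finite samples")
  if (!is.null(labels)) {
    if (is.null(names(labels)) || any(!nzchar(names(labels))))
      stop("labels must be a named numeric vector (code = likelihood)")
  }
  if (!is.na(sex) && !sex %in% c("male", "female"))
    stop("sex must be 'male', 'female', or NA")
  rownames(signal) <- lead_names
  structure(list(record_id = as.character(record_id),
                 patient_id = as.character(patient_id),
                 signal = signal, fs = as.numeric(fs),
                 lead_names = lead_names, labels = labels,
                 age = as.numeric(age), sex = as.character(sex),
                 validated = isTRUE(validated)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> %d lead(s) x %d samples @ %g Hz (%.1f s)\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs))
  if (!is.null(x$labels))
    cat("  labels:", paste(sprintf("%s:%g", names(x$labels), x$labels),
                           collapse = " "), "\n")
  if (!is.na(x$age) || !is.na(x$sex))
    cat(sprintf("  age %s, sex %s\n", format(x$age), x$sex))
  invisible(x)
}

#' Polyphase resampling with anti-aliasing
#'
#' Rational-rate resampling by zero-insertion upsampling, windowed-sinc
#' low-pass filtering (Kaiser window, beta = 7, half-width 16 * max(p, q)
#' taps) and downsampling. The filter delay is compensated so the output is
#' aligned with the input time grid, and the input is extended by reflection
#' so edges are handled without zero-padding roll-off; a constant signal is
#' reproduced exactly (to machine precision for pure downsampling).
#'
#' @param x numeric vector.
#' @param p,q positive integers: output rate is `p / q` times the input rate.
#' @return numeric vector of length `ceiling(length(x) * p / q)`.
#' @keywords internal
resample_poly <- function(x, p, q) {
  p <- as.integer(p); q <- as.integer(q)
  if (is.na(p) || is.na(q) || p < 1 || q < 1)
    stop("p and q must be positive integers")
  d <- gcd(p, q); p <- p %/% d; q <- q %/% d
  if (p == 1 && q == 1) return(x)
  L <- length(x)
  maxpq <- max(p, q)
  half <- 16L * maxpq
  n <- -half:half
  fc <- 1 / (2 * maxpq)                       # cutoff at the upsampled rate
  h <- ifelse(n == 0, 2 * fc, sin(2 * pi * fc * n) / (pi * n))
  beta <- 7
  w <- besselI(beta * sqrt(pmax(0, 1 - (n / half)^2)), 0) / besselI(beta, 0)
  h <- h * w
  h <- p * h / sum(h)                         # unity DC gain after upsampling
  pad <- ceiling(half / p) + 1L
  if (pad + 1L > L)
    stop("signal too short (", L, " samples) to resample at ratio ",
         p, "/", q)
  xp <- c(x[(pad + 1L):2L], x, x[(L - 1L):(L - pad)])   # reflect, no edge dup
  xu <- numeric(length(xp) * p)
  xu[seq(1L, length(xu), by = p)] <- xp
  z <- stats::convolve(xu, rev(h), type = "open")
  start <- pad * p + half + 1L                # index of input sample 1 (t = 0)
  nout <- ceiling(L * p / q)
  z[start + (seq_len(nout) - 1L) * q]
}

#' Resample an ECG record to a new sampling rate
#'
#' Applies delay-compensated polyphase resampling with anti-aliasing to every
#' lead. The rate ratio must be rational; e.g. 500 Hz to 250 Hz uses
#' up-factor 1 and down-factor 2.
#'
#' @param record an [ecg_record].
#' @param target_fs target sampling rate in Hz.
#' @return an [ecg_record] at `target_fs`; lead count unchanged, sample count
#'   scaled by `target_fs / record$fs` (exact when the ratio is integer).
#'   `target_fs == record$fs` returns the record unchanged.
#' @examples
#' rec <- ecg_record(matrix(rnorm(12 * 5000), 12), 500, CANONICAL_LEADS)
#' low <- resample_record(rec, 250)
#' ncol(low$signal)  # 2500
#' @export
resample_record <- function(record, target_fs) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.numeric(target_fs) || length(target_fs) != 1 || target_fs <= 0)
    stop("target_fs must be a single positive number (Hz)")
  if (target_fs == record$fs) return(record)
  # rational ratio: scale both rates to integers (supports e.g. 62.5 Hz)
  sc <- 1
  while (sc <= 1e6 &&
         (abs(target_fs * sc - round(target_fs * sc)) > 1e-9 ||
          abs(record$fs * sc - round(record$fs * sc)) > 1e-9)) sc <- sc * 10
  pi_ <- round(target_fs * sc); qi <- round(record$fs * sc)
  if (abs(target_fs * sc - pi_) > 1e-9 || abs(record$fs * sc - qi) > 1e-9)
    stop("unsupported sampling-rate ratio ", target_fs, "/", record$fs,
         ": not a rational number at reasonable precision")
  d <- gcd(pi_, qi); p <- pi_ %/% d; q <- qi %/% d
  out <- t(apply(record$signal, 1, resample_poly, p = p, q = q))
  rec <- record
  rec$signal <- out
  rownames(rec$signal) <- rec$lead_names
  rec$fs <- target_fs
  rec
}
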