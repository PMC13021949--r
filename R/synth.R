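#' Per-lead projection scales for the synthetic beat template
#'
#' A fixed polarity/scale table mimicking the relative amplitudes of the
#' standard leads (aVR predominantly negative, mid-precordial leads largest).
#' Not a dipole model; chosen so the template's peak amplitude stays within
#' 0.5-2.5 mV on every lead.
#' @keywords internal
SYNTH_LEAD_SCALE <- c(I = 0.75, II = 1.00, III = 0.60, aVR = -0.85,
                      aVL = 0.50, aVF = 0.80, V1 = 0.60, V2 = 0.90,
                      V3 = 1.10, V4 = 1.20, V5 = 1.05, V6 = 0.85)

# Waveform component timing, as fractions of the beat (P-QRS-T morphology);
# widths in seconds. Documented constants, see the methods vignette.
SYNTH_WAVE <- list(
  p   = list(center = 0.20, sd = 0.020, amp = 0.15),
  q   = list(center_off = -0.030, sd = 0.010, amp = -0.15),
  r   = list(center = 0.35, sd = 0.012, amp = 1.20),
  s   = list(center_off = 0.030, sd = 0.010, amp = -0.25),
  t   = list(center = 0.62, sd = 0.050, amp = 0.35),
  st_window = c(0.04, 0.16)  # seconds after the R peak (J point to mid-ST)
)

#' Configuration of the synthetic 12-lead ECG cohort
#'
#' Defines class-specific, lead-localized perturbations emulating the
#' clinical lead-location associations of myocardial infarction: an
#' anteroseptal-like class perturbs V1-V3, an inferior-like class perturbs
#' II, III, aVF, and a control class perturbs nothing. Perturbations are an
#' ST-segment offset plus a pathological deflection (T-wave inversion) on
#' the affected leads only.
#'
#' @param classes named list; each element is a list with `leads` (character
#'   vector of perturbed leads, possibly empty), `st_offset` (mV) and
#'   `deflection` (mV, subtracted from the T wave).
#' @param n_per_class records per class.
#' @param fs sampling rate in Hz.
#' @param duration record length in seconds; `fs * duration` must be integer.
#' @param heart_rate_range bpm range, sampled uniformly per record.
#' @param noise_sd additive Gaussian noise, mV.
#' @param amplitude_jitter relative per-beat amplitude jitter (sd of a
#'   multiplicative factor).
#' @param age_mean,age_sd,age_range Gaussian age distribution, clamped.
#' @param p_female probability of sex `"female"`.
#' @param split_fractions named numeric (train/val/test), summing to 1.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return object of class `"synth_config"`.
#' @export
synth_config <- function(classes = list(
                           NORM = list(leads = character(),
                                       st_offset = 0, deflection = 0),
                           ASMI = list(leads = c("V1", "V2", "V3"),
                                       st_offset = 0.2, deflection = 0.3),
                           IMI  = list(leads = c("II", "III", "aVF"),
                                       st_offset = 0.2, deflection = 0.3)),
                         n_per_class = 60, fs = 250, duration = 10,
                         heart_rate_range = c(60, 100), noise_sd = 0.05,
                         amplitude_jitter = 0.10,
                         age_mean = 60, age_sd = 15, age_range = c(18, 95),
                         p_female = 0.5,
                         split_fractions = c(train = 0.6, val = 0.2,
                                             test = 0.2),
                         seed = 1L) {
  if (abs(fs * duration - round(fs * duration)) > 1e-9)
    stop_field("duration", "fs * duration must be an integer sample count")
  if (n_per_class < 1) stop_field("n_per_class", "must be >= 1")
  if (noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  for (nm in names(classes)) {
    cl <- classes[[nm]]
    if (length(cl$leads)) classes[[nm]]$leads <- normalize_lead_names(cl$leads)
  }
  if (abs(sum(split_fractions) - 1) > 1e-9)
    stop_field("split_fractions", "must sum to 1")
  structure(list(classes = classes, n_per_class = n_per_class, fs = fs,
                 duration = duration, heart_rate_range = heart_rate_range,
                 noise_sd = noise_sd, amplitude_jitter = amplitude_jitter,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 p_female = p_female, split_fractions = split_fractions,
                 seed = as.integer(seed)),
            class = "synth_config")
}

gauss_bump <- function(t, center, sd, amp) amp * exp(-0.5 * ((t - center) / sd)^2)

#' Generate a single-beat 12-lead waveform template
#'
#' Deterministic piecewise waveform with P-like, QRS-like (Q, R, S spikes)
#' and T-like Gaussian components, projected onto the 12 leads by a fixed
#' polarity/scale table. The R-peak sample index and the ST-window sample
#' indices (J point + 40 ms to + 160 ms) are attached as attributes.
#'
#' @param fs sampling rate in Hz.
#' @param heart_rate beats per minute, in \[30, 220\].
#' @return 12 x L numeric matrix (mV), one beat of duration `60/heart_rate`
#'   seconds, with attributes `r_peak` (index) and `st_window` (index range).
#' @export
generate_beat_template <- function(fs, heart_rate) {
  if (heart_rate < 30 || heart_rate > 220)
    stop("heart_rate out of physiological range [30, 220]: ", heart_rate)
  if (fs <= 0) stop("fs must be positive")
  beat_s <- 60 / heart_rate
  L <- max(2L, round(fs * beat_s))
  t <- (seq_len(L) - 1) / fs
  wv <- SYNTH_WAVE
  rc <- wv$r$center * beat_s
  base <- gauss_bump(t, wv$p$center * beat_s, wv$p$sd, wv$p$amp) +
    gauss_bump(t, rc + wv$q$center_off, wv$q$sd, wv$q$amp) +
    gauss_bump(t, rc, wv$r$sd, wv$r$amp) +
    gauss_bump(t, rc + wv$s$center_off, wv$s$sd, wv$s$amp) +
    gauss_bump(t, wv$t$center * beat_s, wv$t$sd, wv$t$amp)
  tpl <- outer(SYNTH_LEAD_SCALE, base)
  rownames(tpl) <- CANONICAL_LEADS[match(rownames(tpl), CANONICAL_LEADS)]
  tpl <- tpl[CANONICAL_LEADS, , drop = FALSE]
  r_peak <- which.max(abs(base))
  stw <- round((rc + wv$st_window) * fs) + 1L
  stw <- pmin(pmax(stw, 1L), L)
  attr(tpl, "r_peak") <- r_peak
  attr(tpl, "st_window") <- stw[1]:stw[2]
  attr(tpl, "t_center") <- wv$t$center * beat_s
  attr(tpl, "t_sd") <- wv$t$sd
  tpl
}

#' Generate one synthetic ECG record
#'
#' Tiles amplitude-jittered beats to the configured duration, applies the
#' class's ST-segment offset over each beat's ST window and subtracts a
#' T-wave deflection on the perturbed leads only, then adds Gaussian noise
#' and attaches sampled demographics and the class label. The ground-truth
#' perturbed-lead set is stored in attribute `truth_leads` for recovery
#' checks. Uses the current RNG state; seed externally for reproducibility.
#'
#' @param class_name name of the class in `config$classes`.
#' @param config a [synth_config].
#' @param record_id,patient_id identifiers.
#' @return an [ecg_record] with likelihood-100 label `class_name`.
#' @export
generate_record <- function(class_name, config, record_id = "syn",
                            patient_id = record_id) {
  spec <- config$classes[[class_name]]
  if (is.null(spec)) stop("unknown synthetic class: ", class_name)
  fs <- config$fs
  nsamp <- round(fs * config$duration)
  hr <- stats::runif(1, config$heart_rate_range[1], config$heart_rate_range[2])
  tpl <- generate_beat_template(fs, hr)
  L <- ncol(tpl)
  n_beats <- ceiling(nsamp / L)
  sig <- matrix(0, 12, nsamp, dimnames = list(CANONICAL_LEADS, NULL))
  pert <- matrix(0, 12, nsamp, dimnames = list(CANONICAL_LEADS, NULL))
  stw <- attr(tpl, "st_window")
  tc <- attr(tpl, "t_center"); tsd <- attr(tpl, "t_sd")
  tgrid <- (seq_len(L) - 1) / fs
  t_shape <- gauss_bump(tgrid, tc, tsd, 1)
  for (b in seq_len(n_beats)) {
    a <- 1 + stats::rnorm(1, 0, config$amplitude_jitter)
    lo <- (b - 1) * L + 1
    hi <- min(b * L, nsamp)
    k <- hi - lo + 1
    sig[, lo:hi] <- sig[, lo:hi] + a * tpl[, seq_len(k), drop = FALSE]
    if (length(spec$leads)) {
      st_idx <- stw[stw <= k]
      pert[spec$leads, lo - 1 + st_idx] <-
        pert[spec$leads, lo - 1 + st_idx] + spec$st_offset
      defl <- spec$deflection * t_shape[seq_len(k)]
      pert[spec$leads, lo:hi] <- pert[spec$leads, lo:hi] -
        rep(defl, each = length(spec$leads))
    }
  }
  sig <- sig + pert
  if (config$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(length(sig), 0, config$noise_sd),
                        nrow(sig))
  age <- min(max(stats::rnorm(1, config$age_mean, config$age_sd),
                 config$age_range[1]), config$age_range[2])
  sex <- if (stats::runif(1) < config$p_female) "female" else "male"
  rec <- ecg_record(sig, fs = fs, lead_names = CANONICAL_LEADS,
                    record_id = record_id, patient_id = patient_id,
                    labels = stats::setNames(100, class_name),
                    age = age, sex = sex, validated = TRUE)
  attr(rec, "truth_leads") <- spec$leads
  attr(rec, "heart_rate") <- hr
  rec
}

#' Generate a full synthetic cohort with manifest
#'
#' `n_per_class` records per class, each its own patient (so any split is
#' patient-disjoint by construction), with a stratified train/val/test split
#' assignment. Fully deterministic given `config$seed`.
#'
#' @param config a [synth_config].
#' @return list with `records` (list of [ecg_record]) and `manifest`
#'   (data frame: record_id, patient_id, class, truth_leads, age, sex,
#'   validated, split).
#' @examples
#' coh <- generate_cohort(synth_config(n_per_class = 2))
#' coh$manifest$class
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    records <- list()
    rows <- list()
    idx <- 0L
    for (cls in names(config$classes)) {
      n <- config$n_per_class
      frac <- config$split_fractions
      n_tr <- round(n * frac[["train"]])
      n_va <- round(n * frac[["val"]])
      splits <- c(rep("train", n_tr), rep("val", n_va),
                  rep("test", n - n_tr - n_va))
      for (j in seq_len(n)) {
        idx <- idx + 1L
        rid <- sprintf("syn%05d", idx)
        rec <- generate_record(cls, config, record_id = rid,
                               patient_id = sprintf("pat%05d", idx))
        records[[idx]] <- rec
        rows[[idx]] <- data.frame(
          record_id = rid, patient_id = rec$patient_id, class = cls,
          truth_leads = paste(attr(rec, "truth_leads"), collapse = "|"),
          age = rec$age, sex = rec$sex, validated = TRUE,
          split = splits[j], stringsAsFactors = FALSE)
      }
    }
    list(records = records, manifest = do.call(rbind, rows))
  })
}

#' Write a synthetic cohort to disk as WFDB records plus manifest
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in cohort$records) write_wfdb(rec, dir)
  man <- cohort$manifest
  codes <- vapply(cohort$records, function(r)
    paste(sprintf("%s:%g", names(r$labels), r$labels), collapse = "|"), "")
  out <- data.frame(record_id = man$record_id, patient_id = man$patient_id,
                    codes = codes, age = man$age, sex = man$sex,
                    validated = man$validated, split = man$split,
                    class = man$class, truth_leads = man$truth_leads,
                    stringsAsFactors = FALSE)
  utils::write.table(out, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
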