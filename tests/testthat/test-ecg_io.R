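test_that("WFDB write/read round-trips integer-quantized signals bit-identically", {
  rec <- quantized_record()
  dir <- withr::local_tempdir()
  write_wfdb(rec, dir)
  back <- read_record(file.path(dir, rec$record_id))
  expect_identical(back$signal, rec$signal)
  expect_identical(back$lead_names, rec$lead_names)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$record_id, rec$record_id)
})

test_that("a single-channel file with lead II reads back with that lead", {
  rec <- ecg_record(matrix(round(sin(1:100) * 1000) / 1000, 1), fs = 100,
                    lead_names = "II", record_id = "one")
  dir <- withr::local_tempdir()
  write_wfdb(rec, dir)
  back <- read_record(file.path(dir, "one"))
  expect_identical(back$lead_names, "II")
  expect_identical(back$signal, rec$signal)
})

test_that("samples equal raw integers times gain, against a hand parse of the header", {
  sig <- withr::with_seed(12, {
    matrix(round(stats::runif(2 * 40, -750, 750)) / 500, 2, 40)
  })
  rec <- ecg_record(sig, fs = 250, lead_names = c("I", "II"),
                    record_id = "gainfix")
  dir <- withr::local_tempdir()
  write_wfdb(rec, dir, gain = 500, baseline = 12)
  # independent hand parse
  hdr <- readLines(file.path(dir, "gainfix.hea"))
  rl <- strsplit(hdr[1], " ")[[1]]
  nsig <- as.integer(rl[2]); nsamp <- as.integer(rl[4])
  gain_field <- strsplit(hdr[2], " ")[[1]][3]
  expect_match(gain_field, "^500\\(12\\)/mV$")
  con <- file(file.path(dir, "gainfix.dat"), "rb")
  raw <- readBin(con, "integer", nsig * nsamp, size = 2, signed = TRUE,
                 endian = "little")
  close(con)
  hand <- (matrix(raw, nrow = nsig) - 12) / 500
  back <- read_record(file.path(dir, "gainfix"))
  expect_equal(back$signal, hand, ignore_attr = TRUE)
  expect_equal(back$signal, rec$signal, ignore_attr = TRUE)
})

test_that("reader fails informatively on missing or corrupt input", {
  expect_error(read_record(file.path(tempdir(), "nope_such_rec")),
               "nope_such_rec")
  dir <- withr::local_tempdir()
  writeLines("broken", file.path(dir, "bad.hea"))
  expect_error(read_record(file.path(dir, "bad")), "corrupt")
  rec <- quantized_record(n_leads = 1, n_samp = 10, record_id = "odd")
  write_wfdb(rec, dir)
  hdr <- readLines(file.path(dir, "odd.hea"))
  hdr[2] <- sub(" I$", " QQ7", hdr[2])
  writeLines(hdr, file.path(dir, "odd.hea"))
  expect_error(read_record(file.path(dir, "odd")), "QQ7")
})

test_that("resampling 500 Hz to 250 Hz halves the sample count and keeps leads", {
  rec <- quantized_record()
  out <- resample_record(rec, 250)
  expect_equal(ncol(out$signal), 2500)
  expect_equal(nrow(out$signal), 12)
  expect_equal(out$fs, 250)
})

test_that("resampling preserves a constant signal", {
  rec <- ecg_record(matrix(2.5, 1, 5000), fs = 500, lead_names = "V1")
  out <- resample_record(rec, 250)
  expect_lt(max(abs(out$signal - 2.5)), 1e-6)
})

test_that("resampled sine matches the analytically sampled sine", {
  t5 <- (0:4999) / 500
  rec <- ecg_record(matrix(sin(2 * pi * 10 * t5), 1), fs = 500,
                    lead_names = "I")
  out <- resample_record(rec, 250)
  ref <- sin(2 * pi * 10 * (0:2499) / 250)
  mid <- 51:2450
  expect_lt(max(abs(out$signal[1, mid] - ref[mid])), 1e-3)
})

test_that("resampling at the original rate is the identity; bad ratios error", {
  rec <- quantized_record(n_leads = 1, n_samp = 200, fs = 100)
  expect_identical(resample_record(rec, 100), rec)
  up <- resample_record(rec, 250)          # rational non-integer ratio 5/2
  expect_equal(ncol(up$signal), 500)
  expect_error(resample_record(rec, pi), "rational")
})

test_that("dominant-label assignment follows likelihood then class order", {
  mi <- label_scheme("mi_localization")
  rec1 <- quantized_record(n_leads = 1, n_samp = 10)
  rec1$labels <- c(NORM = 100)
  expect_equal(assign_dominant_label(rec1, mi), "NORM")
  rec2 <- rec1; rec2$labels <- c(IMI = 80, ASMI = 35)
  expect_equal(assign_dominant_label(rec2, mi), "IMI")
  rec3 <- rec1; rec3$labels <- c(XX = 100, YY = 50)
  expect_identical(assign_dominant_label(rec3, mi), NA_character_)
  # tie broken by the scheme's class order (IMI before ASMI)
  rec4 <- rec1; rec4$labels <- c(ASMI = 80, IMI = 80)
  expect_equal(assign_dominant_label(rec4, mi), "IMI")
  # superclass scheme folds MI subtypes into MI
  sup <- label_scheme("superclass")
  expect_equal(assign_dominant_label(rec2, sup), "MI")
})

test_that("every non-negative age falls in exactly one of the four bins", {
  ages <- c(0, 1, 29.99, 30, 44.9, 45, 59.99, 60, 61, 95, 120)
  bins <- age_bin(ages)
  expect_false(anyNA(bins))
  expect_equal(as.character(bins[ages < 30]), rep("<30", 3))
  expect_equal(as.character(bins[ages >= 30 & ages < 45]), rep("30-45", 2))
  expect_equal(as.character(bins[ages >= 45 & ages < 60]), rep("45-60", 2))
  expect_equal(as.character(bins[ages >= 60]), rep(">60", 4))
})

make_demo_rec <- function(id, age, sex) {
  r <- quantized_record(n_leads = 1, n_samp = 10, record_id = id)
  r$age <- age; r$sex <- sex
  r
}

test_that("matched-control sampling reproduces the case cell histogram", {
  expect_identical(match_controls(list(), list()), list())
  # single-cell match
  cases <- lapply(1:2, function(i) make_demo_rec(paste0("c", i), 35, "female"))
  pool <- lapply(1:10, function(i) make_demo_rec(paste0("p", i), 31 + i %% 10,
                                                 "female"))
  got <- match_controls(cases, pool, seed = 4)
  expect_length(got, 2)
  for (g in got) {
    expect_equal(g$sex, "female")
    expect_equal(as.character(age_bin(g$age)), "30-45")
  }
  # multi-cell histogram oracle
  withr::with_seed(21, {
    cases <- lapply(1:12, function(i)
      make_demo_rec(paste0("c", i), sample(c(25, 40, 50, 70), 1),
                    sample(c("male", "female"), 1)))
    pool <- lapply(1:40, function(i)
      make_demo_rec(paste0("q", i), stats::runif(1, 18, 90),
                    sample(c("male", "female"), 1)))
  })
  got <- suppressWarnings(match_controls(cases, pool, seed = 8))
  cell <- function(recs) table(paste(
    vapply(recs, `[[`, "", "sex"),
    as.character(age_bin(vapply(recs, `[[`, 0, "age")))))
  want <- cell(cases)
  have <- cell(got)
  pool_avail <- cell(pool)
  for (k in names(want)) {
    avail <- if (k %in% names(pool_avail)) pool_avail[[k]] else 0L
    expect_equal(if (k %in% names(have)) have[[k]] else 0L,
                 min(want[[k]], avail))
  }
})

test_that("matched controls are invariant to pool order for a fixed seed", {
  withr::with_seed(5, {
    cases <- lapply(1:6, function(i)
      make_demo_rec(paste0("c", i), sample(c(25, 50), 1), "male"))
    pool <- lapply(1:30, function(i)
      make_demo_rec(paste0("p", i), stats::runif(1, 18, 80), "male"))
  })
  a <- match_controls(cases, pool, seed = 3)
  b <- match_controls(cases, rev(pool), seed = 3)
  expect_identical(vapply(a, `[[`, "", "record_id"),
                   vapply(b, `[[`, "", "record_id"))
})

test_that("label tables round-trip records with codes and demographics", {
  recs <- list(quantized_record(n_leads = 1, n_samp = 10, record_id = "a1"),
               quantized_record(n_leads = 1, n_samp = 10, record_id = "a2"))
  recs[[2]]$labels <- c(IMI = 80, ASMI = 35)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_label_table(recs, path, split = c("train", "test"))
  back <- read_label_table(path)
  expect_equal(back$record_id, c("a1", "a2"))
  expect_equal(back$labels[[2]], c(IMI = 80, ASMI = 35))
  expect_equal(back$split, c("train", "test"))
})
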