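#' Assign ages to the four matching bins
#'
#' Bins are left-closed, right-open: \[0, 30), \[30, 45), \[45, 60),
#' \[60, Inf) — every non-negative age falls in exactly one bin.
#'
#' @param age numeric vector of ages in years.
#' @return factor with levels `"<30"`, `"30-45"`, `"45-60"`, `">60"`.
#' @export
age_bin <- function(age) {
  cut(age, breaks = c(0, 30, 45, 60, Inf), right = FALSE,
      labels = c("<30", "30-45", "45-60", ">60"), include.lowest = TRUE)
}

#' Sample demographically matched controls
#'
#' Selects control records from `pool` so that the joint sex-by-age-bin
#' frequency of the controls equals that of `cases`, sampling without
#' replacement. The pool is sorted by `record_id` before sampling, so the
#' result depends only on the pool's contents and the seed, not its order.
#' Cells with too few pool members are filled as far as possible with a
#' warning.
#'
#' @param cases list of [ecg_record]s (must carry `age` and `sex`).
#' @param pool list of candidate control [ecg_record]s.
#' @param seed integer seed controlling the sampling.
#' @return list of selected control records, at most `length(cases)` long.
#' @export
match_controls <- function(cases, pool, seed = 1L) {
  if (length(cases) == 0) return(list())
  cell_of <- function(recs) {
    age <- vapply(recs, `[[`, 0, "age")
    sex <- vapply(recs, `[[`, "", "sex")
    if (anyNA(age) || anyNA(sex) || any(sex == "NA"))
      stop("all records must carry age and sex for matched sampling")
    paste(sex, as.character(age_bin(age)), sep = "|")
  }
  case_cells <- cell_of(cases)
  ord <- order(vapply(pool, `[[`, "", "record_id"))
  pool <- pool[ord]
  pool_cells <- cell_of(pool)
  want <- table(case_cells)
  out <- list()
  withr::with_seed(as.integer(seed), {
    for (cell in sort(names(want))) {
      cand <- which(pool_cells == cell)
      k <- want[[cell]]
      if (length(cand) < k) {
        warning(sprintf(
          "cell %s: only %d pool record(s) for %d case(s); partial fill",
          cell, length(cand), k))
        k <- length(cand)
      }
      take <- if (k > 0) sort(cand[sample.int(length(cand), k)]) else integer()
      out <- c(out, pool[take])
    }
  })
  out
}
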