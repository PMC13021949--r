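#' Canonical 12-lead order
#'
#' The fixed lead order used everywhere in the package: six limb leads
#' followed by six precordial (chest) leads. Vertex ordering, lead subsets
#' and plots all follow this order.
#'
#' @format Character vector of length 12.
#' @export
CANONICAL_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                     "V1", "V2", "V3", "V4", "V5", "V6")

LIMB_LEADS  <- CANONICAL_LEADS[1:6]
CHEST_LEADS <- CANONICAL_LEADS[7:12]

#' Normalize a lead label to the canonical spelling
#'
#' Case-insensitive match against the canonical 12-lead set.
#'
#' @param x character vector of lead labels.
#' @return character vector of canonical lead names.
#' @keywords internal
normalize_lead_names <- function(x) {
  idx <- match(toupper(x), toupper(CANONICAL_LEADS))
  if (anyNA(idx)) {
    bad <- x[is.na(idx)]
    stop("unknown lead label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(CANONICAL_LEADS, collapse = ", "), ")")
  }
  CANONICAL_LEADS[idx]
}

# greatest common divisor (positive integers)
gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}
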