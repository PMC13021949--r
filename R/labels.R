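#' Define a labeling scheme for a classification task
#'
#' Maps raw diagnostic annotation codes to task classes. Two tasks are
#' supported: the five-class diagnostic superclass task (NORM, MI, STTC, CD,
#' HYP; MI subtype codes collapse into MI) and three-class myocardial
#' infarction localization (NORM plus inferior MI and either anteroseptal or
#' anterior MI, depending on the annotation vocabulary available).
#'
#' @param task `"superclass"` or `"mi_localization"`.
#' @param anterior_class for `mi_localization`: `"ASMI"` (anteroseptal, the
#'   fine-grained annotation) or `"AMI"` (broader anterior category used when
#'   anteroseptal annotations are unavailable).
#' @return object of class `"label_scheme"` with elements `task`, `classes`
#'   (ordered), and `code_to_class` (named character vector).
#' @examples
#' sc <- label_scheme("mi_localization")
#' sc$classes
#' @export
label_scheme <- function(task = c("superclass", "mi_localization"),
                         anterior_class = c("ASMI", "AMI")) {
  task <- match.arg(task)
  anterior_class <- match.arg(anterior_class)
  if (task == "superclass") {
    classes <- c("NORM", "MI", "STTC", "CD", "HYP")
    code_to_class <- c(NORM = "NORM", MI = "MI", STTC = "STTC", CD = "CD",
                       HYP = "HYP", IMI = "MI", ASMI = "MI", AMI = "MI")
  } else {
    classes <- c("NORM", "IMI", anterior_class)
    code_to_class <- stats::setNames(c("NORM", "IMI", anterior_class),
                                     c("NORM", "IMI", anterior_class))
  }
  structure(list(task = task, classes = classes,
                 code_to_class = code_to_class),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("<label_scheme %s> classes: %s\n", x$task,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Assign a single dominant diagnostic label
#'
#' Each ECG can carry several annotation codes with likelihoods; the
#' classifier needs exactly one class. The dominance rule: among the record's
#' codes that map to a task class, pick the class whose mapped code has the
#' highest likelihood; ties are broken by the fixed class order of the
#' scheme. Returns `NA` when no code maps to the task.
#'
#' @param record an [ecg_record] (its `labels` field is used).
#' @param scheme a [label_scheme].
#' @return single character class name, or `NA_character_`.
#' @export
assign_dominant_label <- function(record, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  labs <- if (inherits(record, "ecg_record")) record$labels else record
  if (is.null(labs) || length(labs) == 0) return(NA_character_)
  mapped <- scheme$code_to_class[names(labs)]
  keep <- !is.na(mapped)
  if (!any(keep)) return(NA_character_)
  cls <- mapped[keep]
  lik <- as.numeric(labs[keep])
  # best likelihood per class, then order by (likelihood desc, class order)
  best <- tapply(lik, cls, max)
  ord <- order(-best, match(names(best), scheme$classes))
  names(best)[ord][1]
}
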