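#' Select true-positive instances for a class
#'
#' Explanations are aggregated over true positives only — instances the
#' model classified correctly — since those reflect the learned decision
#' patterns.
#'
#' @param predictions,labels aligned character vectors.
#' @param target_class the class of interest.
#' @return integer indices with `label == prediction == target_class`
#'   (empty, with a warning, if none).
#' @export
select_true_positives <- function(predictions, labels, target_class) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must be aligned")
  idx <- which(predictions == target_class & labels == target_class)
  if (length(idx) == 0)
    warning("no true positives for class ", target_class)
  idx
}

#' Aggregate instance explanations to cohort-level lead importance
#'
#' Collapses the patch dimension and averages across instances:
#' `lead_node_importance[i]` is the mean over instances and patches of the
#' node importance of vertex (i, t); `lead_pair_edge_importance[i, j]` the
#' mean over instances and patches of the within-patch spatial edge
#' (i,t)-(j,t) mask value; `temporal_importance[i]` the mean over instances
#' and consecutive-patch pairs of the (i,t)-(i,t+1) edge mask value.
#' Temporal edges never enter the lead-pair matrix.
#'
#' @param explanations list of [explain_instance()] results.
#' @param graphs aligned list of the explained graphs (must share topology).
#' @param target_class class these instances belong to.
#' @return object of class `"cohort_importance"`: `class`, `n_instances`,
#'   `lead_node_importance` (named vector), `lead_pair_edge_importance`
#'   (symmetric lead x lead matrix, `NA` off the constructed spatial pairs),
#'   `temporal_importance` (named vector, `NA` when p = 1).
#' @export
aggregate_explanations <- function(explanations, graphs, target_class = "") {
  if (length(explanations) == 0) stop("no explanations to aggregate")
  if (length(explanations) != length(graphs))
    stop("explanations and graphs must be aligned")
  g1 <- graphs[[1]]
  for (g in graphs)
    if (!identical(g$edges[c("from", "to", "class")],
                   g1$edges[c("from", "to", "class")]) ||
        !identical(g$vertices$lead, g1$vertices$lead))
      stop("mismatched graph topologies across instances")
  leads <- g1$leads
  nL <- length(leads)
  node_mat <- vapply(explanations, node_importance, numeric(nrow(g1$A)))
  node_mean <- rowMeans(node_mat)            # per vertex, over instances
  lead_node <- stats::setNames(
    as.numeric(tapply(node_mean, g1$vertices$lead, mean)[leads]), leads)
  edge_imp <- vapply(explanations, function(e)
    (e$M_E + t(e$M_E))[cbind(g1$edges$from, g1$edges$to)] / 2,
    numeric(nrow(g1$edges)))
  edge_imp <- if (is.matrix(edge_imp)) rowMeans(edge_imp) else
    mean(edge_imp)
  lead_of <- g1$vertices$lead
  pair <- matrix(NA_real_, nL, nL, dimnames = list(leads, leads))
  sp <- g1$edges$class == "spatial"
  if (any(sp)) {
    la <- lead_of[g1$edges$from[sp]]
    lb <- lead_of[g1$edges$to[sp]]
    key <- paste(la, lb)
    m <- tapply(edge_imp[sp], key, mean)
    for (k in names(m)) {
      ab <- strsplit(k, " ")[[1]]
      pair[ab[1], ab[2]] <- m[[k]]
      pair[ab[2], ab[1]] <- m[[k]]
    }
  }
  temporal <- stats::setNames(rep(NA_real_, nL), leads)
  tp <- g1$edges$class == "temporal"
  if (any(tp)) {
    lt <- lead_of[g1$edges$from[tp]]
    tm <- tapply(edge_imp[tp], lt, mean)
    temporal[names(tm)] <- tm
  }
  structure(list(class = target_class, n_instances = length(explanations),
                 lead_node_importance = lead_node,
                 lead_pair_edge_importance = pair,
                 temporal_importance = temporal),
            class = "cohort_importance")
}

#' @export
print.cohort_importance <- function(x, ...) {
  cat(sprintf("<cohort_importance %s> averaged over %d instance(s)\n",
              x$class, x$n_instances))
  print(round(x$lead_node_importance, 3))
  invisible(x)
}

#' Patient-level temporal importance for one explanation
#'
#' The per-lead mean of the temporal-edge mask values of a single instance —
#' the patient-level adaptation of the cohort aggregation.
#'
#' @param expl an [explain_instance()] result.
#' @param graph the explained graph.
#' @return named numeric vector, one value per lead (`NA` when p = 1).
#' @export
patient_temporal_importance <- function(expl, graph) {
  agg <- aggregate_explanations(list(expl), list(graph))
  agg$temporal_importance
}

#' Write cohort importance as delimited text
#'
#' @param ci a [aggregate_explanations()] result.
#' @param dir output directory (lead table and lead-pair matrix as TSV).
#' @return Invisibly, `dir`.
#' @export
write_cohort_importance <- function(ci, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lead_tab <- data.frame(lead = names(ci$lead_node_importance),
                         node_importance = as.numeric(ci$lead_node_importance),
                         temporal_importance =
                           as.numeric(ci$temporal_importance))
  utils::write.table(lead_tab, file.path(dir, "lead_importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ci$lead_pair_edge_importance,
                     file.path(dir, "lead_pair_importance.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  writeLines(c(paste0("class\t", ci$class),
               paste0("n_instances\t", ci$n_instances)),
             file.path(dir, "meta.tsv"))
  invisible(dir)
}

# stylized torso layout for the 12 leads (presentation only)
LEAD_LAYOUT <- data.frame(
  lead = c("I", "II", "III", "aVR", "aVL", "aVF",
           "V1", "V2", "V3", "V4", "V5", "V6"),
  x = c(0.15, 0.25, 0.40, 0.15, 0.30, 0.30, 0.55, 0.65, 0.75, 0.85, 0.92, 0.97),
  y = c(0.85, 0.35, 0.45, 0.60, 0.75, 0.55, 0.75, 0.62, 0.50, 0.42, 0.55, 0.70))

#' Render a cohort lead-importance map
#'
#' Draws the leads at fixed stylized torso positions; node color encodes the
#' lead node importance over a configurable range (default 0.2-0.5,
#' clipped), spatial lead-pair edges are annotated with their importance
#' rounded to two decimals and drawn with importance-scaled line width.
#' The output format follows the file extension: `.svg` (vector, default
#' device), `.pdf`, or `.ps`.
#'
#' @param ci a [aggregate_explanations()] result.
#' @param path output figure file.
#' @param node_range color-encoding range for node importance.
#' @return Invisibly, `path`.
#' @export
render_lead_map <- function(ci, path, node_range = c(0.2, 0.5)) {
  stopifnot(inherits(ci, "cohort_importance"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         svg = grDevices::svg(path, width = 7, height = 6),
         pdf = grDevices::pdf(path, width = 7, height = 6),
         ps = grDevices::postscript(path, width = 7, height = 6,
                                    paper = "special", horizontal = FALSE),
         stop("unsupported figure format: .", ext,
              " (use .svg, .pdf or .ps)"))
  on.exit(grDevices::dev.off())
  leads <- names(ci$lead_node_importance)
  lay <- LEAD_LAYOUT[match(leads, LEAD_LAYOUT$lead), ]
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot(NA, xlim = c(0, 1.05), ylim = c(0.2, 1), axes = FALSE,
                 xlab = "", ylab = "",
                 main = sprintf("%s (n = %d)", ci$class, ci$n_instances))
  pairm <- ci$lead_pair_edge_importance
  if (!is.null(pairm)) {
    for (i in seq_along(leads)) for (j in seq_along(leads)) {
      if (j <= i || is.na(pairm[i, j])) next
      w <- pairm[i, j]
      graphics::segments(lay$x[i], lay$y[i], lay$x[j], lay$y[j],
                         lwd = 0.5 + 4 * w,
                         col = grDevices::gray(max(0, 0.8 - 0.8 * w)))
      graphics::text((lay$x[i] + lay$x[j]) / 2, (lay$y[i] + lay$y[j]) / 2,
                     sprintf("%.2f", w), cex = 0.55, col = "gray25")
    }
  }
  ramp <- grDevices::colorRamp(c("#2166ac", "#f7f7f7", "#b2182b"))
  val <- pmin(pmax(ci$lead_node_importance, node_range[1]), node_range[2])
  frac <- (val - node_range[1]) / diff(node_range)
  cols <- grDevices::rgb(ramp(frac), maxColorValue = 255)
  graphics::points(lay$x, lay$y, pch = 21, bg = cols, cex = 4)
  graphics::text(lay$x, lay$y + 0.055, leads, font = 2, cex = 0.8)
  invisible(path)
}
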