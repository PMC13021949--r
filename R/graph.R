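#' Configuration of the spatial-temporal ECG graph
#'
#' Open parameters of the graph representation: the lead subset used as
#' spatial vertices, the spatial connectivity scheme, and the number of
#' uniform non-overlapping temporal patches. The default scheme connects all
#' six limb leads as one clique and all six chest leads as another, bridged
#' by the cross-system pairs between \{I, aVF\} and \{V4, V5\}.
#'
#' @param leads ordered subset of the canonical 12 leads (reordered to
#'   canonical order).
#' @param spatial_scheme `"limb_chest_bridged"` (default), `"fully_connected"`
#'   or `"custom"` (requires `custom_edges`).
#' @param num_patches number of temporal patches `p >= 1`; must divide the
#'   record's sample count when a graph is built.
#' @param bridge_leads the four bridging leads (two limb, two chest).
#' @param custom_edges for `"custom"`: data frame or 2-column matrix of lead
#'   pairs, all within `leads`.
#' @return object of class `"graph_config"`.
#' @examples
#' cfg <- graph_config(num_patches = 25)
#' nrow(build_spatial_edges(cfg))  # 34
#' @export
graph_config <- function(leads = CANONICAL_LEADS,
                         spatial_scheme = c("limb_chest_bridged",
                                            "fully_connected", "custom"),
                         num_patches = 25,
                         bridge_leads = c("I", "aVF", "V4", "V5"),
                         custom_edges = NULL) {
  spatial_scheme <- match.arg(spatial_scheme)
  leads <- normalize_lead_names(leads)
  if (length(leads) == 0) stop_field("leads", "must be non-empty")
  if (anyDuplicated(leads)) stop_field("leads", "must be unique")
  leads <- CANONICAL_LEADS[sort(match(leads, CANONICAL_LEADS))]
  if (!is.numeric(num_patches) || num_patches < 1 ||
      num_patches != round(num_patches))
    stop_field("num_patches", "must be a positive integer")
  bridge_leads <- normalize_lead_names(bridge_leads)
  if (spatial_scheme == "custom") {
    if (is.null(custom_edges))
      stop_field("custom_edges", "required for spatial_scheme = 'custom'")
    custom_edges <- as.data.frame(custom_edges, stringsAsFactors = FALSE)
    names(custom_edges)[1:2] <- c("lead_a", "lead_b")
    custom_edges$lead_a <- normalize_lead_names(custom_edges$lead_a)
    custom_edges$lead_b <- normalize_lead_names(custom_edges$lead_b)
    bad <- setdiff(unique(c(custom_edges$lead_a, custom_edges$lead_b)), leads)
    if (length(bad))
      stop_field("custom_edges",
                 paste("edge endpoint(s) outside the lead subset:",
                       paste(bad, collapse = ", ")))
  }
  structure(list(leads = leads, spatial_scheme = spatial_scheme,
                 num_patches = as.integer(num_patches),
                 bridge_leads = bridge_leads, custom_edges = custom_edges),
            class = "graph_config")
}

#' @export
print.graph_config <- function(x, ...) {
  cat(sprintf("<graph_config> %d lead(s), scheme %s, p = %d\n",
              length(x$leads), x$spatial_scheme, x$num_patches))
  invisible(x)
}

canonical_pair <- function(a, b) {
  ia <- match(a, CANONICAL_LEADS); ib <- match(b, CANONICAL_LEADS)
  swap <- ia > ib
  data.frame(lead_a = ifelse(swap, b, a), lead_b = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

clique_pairs <- function(leads) {
  if (length(leads) < 2)
    return(data.frame(lead_a = character(), lead_b = character()))
  cmb <- utils::combn(leads, 2)
  canonical_pair(cmb[1, ], cmb[2, ])
}

#' Build the within-patch spatial lead-pair edge set
#'
#' Under `"limb_chest_bridged"`: a complete graph on the limb leads present,
#' a complete graph on the chest leads present, plus the four cross-system
#' bridge pairs between the limb bridge leads (I, aVF) and the chest bridge
#' leads (V4, V5), restricted to leads present. Under `"fully_connected"`:
#' a clique on the whole subset. Edges are unordered pairs, no self-pairs.
#'
#' @param config a [graph_config].
#' @return data frame with columns `lead_a`, `lead_b`, each row one
#'   undirected lead pair (ordered canonically within row and across rows).
#' @export
build_spatial_edges <- function(config) {
  stopifnot(inherits(config, "graph_config"))
  S <- config$leads
  edges <- switch(config$spatial_scheme,
    fully_connected = clique_pairs(S),
    custom = canonical_pair(config$custom_edges$lead_a,
                            config$custom_edges$lead_b),
    limb_chest_bridged = {
      limb <- intersect(S, LIMB_LEADS)
      chest <- intersect(S, CHEST_LEADS)
      br_l <- intersect(config$bridge_leads, limb)
      br_c <- intersect(config$bridge_leads, chest)
      bridges <- if (length(br_l) && length(br_c)) {
        g <- expand.grid(a = br_l, b = br_c, stringsAsFactors = FALSE)
        canonical_pair(g$a, g$b)
      } else data.frame(lead_a = character(), lead_b = character())
      rbind(clique_pairs(limb), clique_pairs(chest), bridges)
    })
  edges <- unique(edges[edges$lead_a != edges$lead_b, , drop = FALSE])
  edges <- edges[order(match(edges$lead_a, CANONICAL_LEADS),
                       match(edges$lead_b, CANONICAL_LEADS)), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Segment a record into uniform non-overlapping temporal patches
#'
#' @param record an [ecg_record].
#' @param p number of patches; must divide the per-lead sample count exactly
#'   (no silent truncation).
#' @return named list (one element per lead) of lists of `p` numeric patch
#'   vectors, each of length `samples / p`; concatenating a lead's patches
#'   reproduces its signal exactly.
#' @export
segment_patches <- function(record, p) {
  stopifnot(inherits(record, "ecg_record"))
  nsamp <- ncol(record$signal)
  p <- as.integer(p)
  if (p < 1) stop("p must be >= 1")
  if (nsamp %% p != 0)
    stop("number of patches p = ", p, " does not divide the sample count ",
         nsamp)
  d <- nsamp %/% p
  out <- lapply(seq_len(nrow(record$signal)), function(i) {
    lapply(seq_len(p), function(t)
      record$signal[i, ((t - 1) * d + 1):(t * d)])
  })
  names(out) <- record$lead_names
  out
}

#' Build the spatial-temporal graph for one ECG record
#'
#' Vertices are (lead, patch) pairs `v[i, t]`, ordered lead-major in the
#' canonical lead order (all patches of lead 1, then lead 2, ...). The
#' binary adjacency contains every spatial lead-pair edge replicated within
#' each patch slice `t`, plus temporal edges linking `v[i, t]` to
#' `v[i, t+1]` for every lead. Node attributes are the raw patch samples in
#' mV. Self-loops are not stored; they enter only through `A + I` inside the
#' model.
#'
#' @param record an [ecg_record] containing at least the configured leads.
#' @param config a [graph_config].
#' @param label optional class label `Y` for the graph (e.g. from
#'   [assign_dominant_label()]).
#' @return object of class `"ecg_graph"`: list with `vertices` (data frame
#'   id/lead/patch), `A` (N x N binary symmetric, zero diagonal), `X`
#'   (N x d), `edges` (data frame from/to/class), `y`, `record_id`, `leads`,
#'   `p`, `d`, `fs`.
#' @examples
#' rec <- ecg_record(matrix(rnorm(12 * 2500), 12), 250, CANONICAL_LEADS)
#' g <- build_graph(rec, graph_config(num_patches = 25))
#' nrow(g$A)  # 300
#' @export
build_graph <- function(record, config, label = NA_character_) {
  stopifnot(inherits(record, "ecg_record"), inherits(config, "graph_config"))
  missing <- setdiff(config$leads, record$lead_names)
  if (length(missing))
    stop("record ", record$record_id, " is missing lead(s): ",
         paste(missing, collapse = ", "))
  S <- config$leads
  p <- config$num_patches
  nsamp <- ncol(record$signal)
  if (nsamp %% p != 0)
    stop("number of patches p = ", p, " does not divide the sample count ",
         nsamp)
  d <- nsamp %/% p
  N <- length(S) * p
  vertices <- data.frame(id = seq_len(N),
                         lead = rep(S, each = p),
                         patch = rep(seq_len(p), times = length(S)),
                         stringsAsFactors = FALSE)
  vid <- function(lead, t) (match(lead, S) - 1L) * p + t
  X <- matrix(0, N, d)
  for (i in seq_along(S)) {
    row <- record$signal[S[i], ]
    X[((i - 1) * p + 1):(i * p), ] <- matrix(row, nrow = p, byrow = TRUE)
  }
  sp <- build_spatial_edges(config)
  n_sp <- nrow(sp)
  from <- integer(0); to <- integer(0); cls <- character(0)
  if (n_sp > 0) {
    for (t in seq_len(p)) {
      from <- c(from, vid(sp$lead_a, t))
      to <- c(to, vid(sp$lead_b, t))
    }
    cls <- rep("spatial", n_sp * p)
  }
  if (p > 1) {
    for (i in seq_along(S)) {
      from <- c(from, vid(rep(S[i], p - 1), seq_len(p - 1)))
      to <- c(to, vid(rep(S[i], p - 1), seq_len(p - 1) + 1L))
    }
    cls <- c(cls, rep("temporal", length(S) * (p - 1)))
  }
  A <- matrix(0, N, N)
  A[cbind(from, to)] <- 1
  A[cbind(to, from)] <- 1
  structure(list(vertices = vertices, A = A, X = X,
                 edges = data.frame(from = from, to = to, class = cls,
                                    stringsAsFactors = FALSE),
                 y = label, record_id = record$record_id, leads = S,
                 p = p, d = d, fs = record$fs),
            class = "ecg_graph")
}

#' @export
print.ecg_graph <- function(x, ...) {
  cat(sprintf("<ecg_graph %s> N = %d (%d leads x %d patches), d = %d, %d undirected edges, y = %s\n",
              x$record_id, nrow(x$A), length(x$leads), x$p, x$d,
              nrow(x$edges), x$y))
  invisible(x)
}

#' Build graphs for a list of records
#'
#' @param records list of [ecg_record]s.
#' @param config a [graph_config].
#' @param scheme optional [label_scheme]; when given, each graph's label is
#'   the record's dominant label and records mapping to no class are dropped.
#' @return list of [build_graph()] results.
#' @export
build_graphs <- function(records, config, scheme = NULL) {
  out <- lapply(records, function(r) {
    lab <- if (is.null(scheme)) NA_character_ else
      assign_dominant_label(r, scheme)
    if (!is.null(scheme) && is.na(lab)) return(NULL)
    build_graph(r, config, label = lab)
  })
  out[!vapply(out, is.null, TRUE)]
}

#' Export an ECG graph as plain-text tables
#'
#' Writes `nodes.tsv` (id, lead, patch), `edges.tsv` (from, to, class),
#' `features.tsv` (dense N x d matrix, full precision) and `meta.tsv`
#' (key-value) into `dir`.
#'
#' @param graph an [build_graph()] result.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "ecg_graph"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(graph$vertices, file.path(dir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(graph$edges, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  xm <- apply(graph$X, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(xm, file.path(dir, "features.tsv"))
  meta <- c(record_id = graph$record_id, y = as.character(graph$y),
            leads = paste(graph$leads, collapse = "|"),
            p = graph$p, d = graph$d, fs = graph$fs)
  writeLines(paste(names(meta), meta, sep = "\t"),
             file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' Read an ECG graph written by [write_graph()]
#'
#' @param dir directory containing the graph tables.
#' @return an `"ecg_graph"` object; round-trips [write_graph()] exactly.
#' @export
read_graph <- function(dir) {
  vertices <- utils::read.table(file.path(dir, "nodes.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  edges <- utils::read.table(file.path(dir, "edges.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  xl <- strsplit(readLines(file.path(dir, "features.tsv")), "\t")
  X <- do.call(rbind, lapply(xl, as.numeric))
  meta_lines <- strsplit(readLines(file.path(dir, "meta.tsv")), "\t")
  meta <- stats::setNames(vapply(meta_lines, function(x)
    if (length(x) > 1) x[2] else "", ""),
    vapply(meta_lines, `[[`, "", 1))
  N <- nrow(vertices)
  A <- matrix(0, N, N)
  A[cbind(edges$from, edges$to)] <- 1
  A[cbind(edges$to, edges$from)] <- 1
  structure(list(vertices = vertices, A = A, X = X, edges = edges,
                 y = if (meta[["y"]] == "NA") NA_character_ else meta[["y"]],
                 record_id = meta[["record_id"]],
                 leads = strsplit(meta[["leads"]], "|", fixed = TRUE)[[1]],
                 p = as.integer(meta[["p"]]), d = as.integer(meta[["d"]]),
                 fs = as.numeric(meta[["fs"]])),
            class = "ecg_graph")
}
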