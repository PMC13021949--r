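# small synthetic explanation fixtures on a 3-lead, 3-patch graph
agg_fixture <- function(n = 1, value = NULL, seed = 1) {
  rec <- quantized_record(n_leads = 12, n_samp = 30, fs = 10)
  cfg <- graph_config(leads = c("I", "aVF", "V4"), num_patches = 3)
  g <- build_graph(rec, cfg, label = "demo")
  withr::with_seed(seed, {
    exs <- lapply(seq_len(n), function(i) {
      ME <- matrix(0, nrow(g$A), nrow(g$A))
      vals <- if (is.null(value)) stats::runif(sum(g$A == 1 & upper.tri(g$A)))
              else rep(value, sum(g$A == 1 & upper.tri(g$A)))
      ME[g$A == 1 & upper.tri(ME)] <- vals
      ME <- ME + t(ME)
      MX <- if (is.null(value))
        matrix(stats::runif(nrow(g$A) * g$d), nrow(g$A), g$d)
      else matrix(value, nrow(g$A), g$d)
      structure(list(M_E = ME, M_X = MX, mode = "feature",
                     target_class = "demo", trace = NULL,
                     record_id = paste0("r", i), iterations = 1,
                     n_edges = sum(g$A) / 2),
                class = "ecg_explanation")
    })
  })
  list(g = g, exs = exs)
}

test_that("true-positive selection matches hand enumeration", {
  labels <- c("A", "A", "B", "B", "A", "B", "A", "B", "A", "B")
  perfect <- labels
  expect_equal(select_true_positives(perfect, labels, "A"),
               which(labels == "A"))
  flipped <- ifelse(labels == "A", "B", "A")      # every prediction wrong
  expect_warning(got <- select_true_positives(flipped, labels, "A"),
                 "no true positives")
  expect_length(got, 0)
  # hand enumeration: true A at 1,2,5,7,9; predicted A at 1,5,6,7,8,10
  mixed <- c("A", "B", "B", "B", "A", "A", "A", "A", "B", "A")
  expect_equal(select_true_positives(mixed, labels, "A"), c(1, 5, 7))
  expect_equal(select_true_positives(mixed, labels, "B"), c(3, 4))
  expect_error(select_true_positives(mixed[1:3], labels, "A"), "aligned")
})

test_that("aggregation of constant masks returns those constants everywhere", {
  fx <- agg_fixture(n = 1, value = 1)
  ci <- aggregate_explanations(fx$exs, list(fx$g), "demo")
  expect_equal(unname(ci$lead_node_importance), rep(1, 3))
  expect_equal(unname(ci$temporal_importance), rep(1, 3))
  pairs <- ci$lead_pair_edge_importance
  expect_equal(unname(pairs[!is.na(pairs)]), rep(1, 6))  # 3 pairs, mirrored
  # two instances at 0.2 and 0.4 average to 0.3
  a <- agg_fixture(n = 1, value = 0.2)$exs
  b <- agg_fixture(n = 1, value = 0.4)$exs
  ci2 <- aggregate_explanations(c(a, b), list(fx$g, fx$g), "demo")
  expect_equal(unname(ci2$lead_node_importance), rep(0.3, 3))
  expect_equal(unname(ci2$temporal_importance), rep(0.3, 3))
})

test_that("aggregation equals an independent flat-loop average on random masks", {
  fx <- agg_fixture(n = 5)
  ci <- aggregate_explanations(fx$exs, rep(list(fx$g), 5), "demo")
  g <- fx$g
  leads <- g$leads
  # brute-force loops
  for (ld in leads) {
    vals <- c()
    for (e in fx$exs)
      for (v in which(g$vertices$lead == ld))
        vals <- c(vals, mean(e$M_X[v, ]))
    expect_equal(unname(ci$lead_node_importance[ld]), mean(vals))
  }
  sp <- g$edges[g$edges$class == "spatial", ]
  for (k in seq_len(nrow(sp))) {
    la <- g$vertices$lead[sp$from[k]]
    lb <- g$vertices$lead[sp$to[k]]
    rows <- which(g$vertices$lead[sp$from] == la &
                    g$vertices$lead[sp$to] == lb)
    vals <- c()
    for (e in fx$exs)
      vals <- c(vals, e$M_E[cbind(sp$from[rows], sp$to[rows])])
    expect_equal(ci$lead_pair_edge_importance[la, lb], mean(vals))
  }
  tp <- g$edges[g$edges$class == "temporal", ]
  for (ld in leads) {
    rows <- which(g$vertices$lead[tp$from] == ld)
    vals <- c()
    for (e in fx$exs) vals <- c(vals, e$M_E[cbind(tp$from[rows], tp$to[rows])])
    expect_equal(unname(ci$temporal_importance[ld]), mean(vals))
  }
})

test_that("aggregation is permutation-invariant over instances and stays in the convex hull", {
  fx <- agg_fixture(n = 4)
  gs <- rep(list(fx$g), 4)
  ci1 <- aggregate_explanations(fx$exs, gs, "demo")
  ci2 <- aggregate_explanations(rev(fx$exs), gs, "demo")
  expect_equal(ci1$lead_node_importance, ci2$lead_node_importance)
  expect_equal(ci1$lead_pair_edge_importance, ci2$lead_pair_edge_importance)
  per_instance <- vapply(fx$exs, function(e)
    tapply(rowMeans(e$M_X), fx$g$vertices$lead, mean), numeric(3))
  for (ld in rownames(per_instance)) {
    expect_gte(ci1$lead_node_importance[ld], min(per_instance[ld, ]))
    expect_lte(ci1$lead_node_importance[ld], max(per_instance[ld, ]))
  }
})

test_that("mismatched topologies across instances are rejected", {
  fx <- agg_fixture(n = 2)
  rec <- quantized_record(n_leads = 12, n_samp = 30, fs = 10)
  other <- build_graph(rec, graph_config(leads = c("I", "II", "V4"),
                                         num_patches = 3))
  expect_error(aggregate_explanations(fx$exs, list(fx$g, other), "demo"),
               "topolog")
  expect_error(aggregate_explanations(list(), list(), "demo"), "no explanations")
})

test_that("patient-level temporal importance equals the single-instance aggregate", {
  fx <- agg_fixture(n = 1)
  pt <- patient_temporal_importance(fx$exs[[1]], fx$g)
  ci <- aggregate_explanations(fx$exs, list(fx$g), "demo")
  expect_equal(pt, ci$temporal_importance)
})

test_that("cohort importance serializes to readable delimited text", {
  fx <- agg_fixture(n = 2)
  ci <- aggregate_explanations(fx$exs, rep(list(fx$g), 2), "demo")
  dir <- withr::local_tempdir()
  write_cohort_importance(ci, dir)
  lead_tab <- utils::read.table(file.path(dir, "lead_importance.tsv"),
                                header = TRUE, sep = "\t")
  expect_equal(lead_tab$lead, names(ci$lead_node_importance))
  expect_equal(lead_tab$node_importance,
               unname(ci$lead_node_importance), tolerance = 1e-12)
})

test_that("the lead map renders with edge labels equal to the rounded importances", {
  fx <- agg_fixture(n = 1)
  ci <- aggregate_explanations(fx$exs, list(fx$g), "demo")
  # svg output exists and is non-empty
  path_svg <- withr::local_tempfile(fileext = ".svg")
  render_lead_map(ci, path_svg)
  expect_true(file.exists(path_svg))
  expect_gt(file.info(path_svg)$size, 0)
  # parse-back on postscript, where strings stay literal: every edge label
  # equals the pair importance rounded to 2 decimals
  path_ps <- withr::local_tempfile(fileext = ".ps")
  render_lead_map(ci, path_ps)
  ps <- paste(readLines(path_ps, warn = FALSE), collapse = "\n")
  pairs <- ci$lead_pair_edge_importance
  labels <- sprintf("(%.2f)",
                    pairs[upper.tri(pairs)][!is.na(pairs[upper.tri(pairs)])])
  for (lb in labels) expect_match(ps, lb, fixed = TRUE)
  # uniform importance renders identical labels
  fx1 <- agg_fixture(n = 1, value = 0.37)
  ci1 <- aggregate_explanations(fx1$exs, list(fx1$g), "demo")
  path1 <- withr::local_tempfile(fileext = ".ps")
  render_lead_map(ci1, path1)
  ps1 <- paste(readLines(path1, warn = FALSE), collapse = "\n")
  expect_match(ps1, "(0.37)", fixed = TRUE)
  expect_error(render_lead_map(ci, "x.bmp"), "format")
})
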