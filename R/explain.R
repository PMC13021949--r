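# Perturbation-based instance explainer: learns soft masks over the edges of
# the adjacency and over the node features that retain the model's
# prediction, by maximizing the mutual information between the original
# prediction and the masked-input prediction. Since the entropy of the
# original prediction is constant in the masks, the objective reduces to
# minimizing the cross-entropy of the masked-input prediction against the
# model's own predicted class, plus sparsity and element-entropy
# regularization on both masks.

sigmoid <- function(z) 1 / (1 + exp(-z))

# Gradient of the loss w.r.t. the entries of At = A' + I, given G = dL/dS
# where S = Dt^{-1/2} At Dt^{-1/2}. Every At entry also moves its row degree,
# so the chain rule has a direct term and a degree term:
#   dL/dAt_kl = G_kl r_k r_l + u_k,  u_i = -(1/2) d_i^{-3/2} sum_j (G_ij +
#   G_ji) At_ij r_j,  r_i = d_i^{-1/2}.
# Verified against finite differences in the test suite.
normadj_backward <- function(G, At) {
  dvec <- rowSums(At)
  r <- 1 / sqrt(dvec)
  Gs <- G + t(G)
  u <- -0.5 * dvec^(-1.5) * as.vector((Gs * At) %*% r)
  direct <- G * outer(r, r)
  list(direct = direct, u = u)
}

#' Explain one prediction with learned edge and feature masks
#'
#' Learns a soft mask `M_E` over the existing edges of the graph's adjacency
#' and a soft mask `M_X` over the node features, so that the masked input
#' `A' = A * M_E`, `X' = X * M_X` preserves the model's prediction while the
#' masks stay sparse. The masks parameterize a Bernoulli keep-probability per
#' element (squashed into \[0, 1\] through a sigmoid, so `A'` can never gain
#' edges absent from `A`); each gradient step evaluates the objective at a
#' binary-concrete sample from that distribution (temperature `tau`), which
#' makes masking genuinely destructive — sampled near-zero entries delete
#' information rather than merely rescaling it — and keeps the data-fit term
#' informative even for confidently classified instances. Logits are
#' initialized from `seed` and updated by Adam for a fixed number of
#' iterations; the masked adjacency is renormalized inside the propagation
#' rule at every step, so a fully zeroed edge mask isolates all nodes. The
#' model is frozen: inference mode, no dropout, no parameter gradients. The
#' whole procedure is deterministic given `(model, graph, seed)`.
#'
#' @param model an [ecg_gcn()] model.
#' @param graph the graph instance to explain (shapes must match the model).
#' @param iterations gradient steps (default 200, no convergence test).
#' @param lr Adam learning rate for the mask logits.
#' @param tau binary-concrete temperature (> 0); smaller is closer to hard
#'   Bernoulli samples.
#' @param reg regularization coefficients: `edge_size` and `feat_size`
#'   (mean-mask sparsity), `ent` (element-wise Bernoulli entropy, applied to
#'   both masks).
#' @param feature_mask `"feature"` learns an N x d mask; `"node"` learns one
#'   value per node, broadcast across features.
#' @param seed integer seed for mask initialization and sampling.
#' @param target_class class to explain; defaults to the model's prediction
#'   on the unmasked graph.
#' @return object of class `"ecg_explanation"`: `M_E` (symmetric N x N mask
#'   of keep-probabilities, nonzero only on edges of `A`), `M_X` (N x d, or
#'   N x 1 in node mode), `mode`, `target_class`, `trace` (per-iteration
#'   total loss and data-fit term at the sampled masks), `record_id`,
#'   `iterations`.
#' @export
explain_instance <- function(model, graph, iterations = 200, lr = 0.1,
                             tau = 1,
                             reg = list(edge_size = 0.005, feat_size = 0.1,
                                        ent = 0.1),
                             feature_mask = c("feature", "node"),
                             seed = 1L, target_class = NULL) {
  stopifnot(inherits(model, "ecg_gcn"))
  feature_mask <- match.arg(feature_mask)
  if (iterations < 1) stop("iterations must be >= 1")
  A <- graph$A; X <- graph$X
  if (nrow(A) != model$N || ncol(X) != model$d)
    stop(sprintf("graph shape mismatch: model expects N = %d, d = %d",
                 model$N, model$d))
  N <- nrow(A); d <- ncol(X)
  cfg <- model$config
  infer_cfg <- cfg; infer_cfg$dropout <- 0
  if (is.null(target_class)) {
    target_class <- predict(model, graph, type = "class")
  }
  ti <- match(target_class, model$class_order)
  if (is.na(ti)) stop("unknown target class: ", target_class)
  eidx <- which(upper.tri(A) & A == 1)      # one logit per undirected edge
  n_edges <- length(eidx)
  nX <- if (feature_mask == "feature") N * d else N
  if (tau <= 0) stop("tau must be > 0")
  clamp01 <- function(m) pmin(pmax(m, 1e-7), 1 - 1e-7)
  ent_grad <- function(m) log((1 - clamp01(m)) / clamp01(m))
  masks <- withr::with_seed(as.integer(seed), {
    pars <- list(ze = stats::rnorm(n_edges, 0, 0.1),
                 zx = stats::rnorm(nX, 0, 0.1))
    opt <- adam_init(pars)
    trace <- data.frame(iteration = seq_len(iterations), loss = NA_real_,
                        data_fit = NA_real_)
    for (it in seq_len(iterations)) {
      # binary-concrete sample of each mask element
      ue <- stats::runif(n_edges)
      ux <- stats::runif(nX)
      be <- sigmoid((pars$ze + log(ue / (1 - ue))) / tau)
      bx <- sigmoid((pars$zx + log(ux / (1 - ux))) / tau)
      ME <- matrix(0, N, N)
      ME[eidx] <- be
      ME <- ME + t(ME)
      BX <- if (feature_mask == "feature") matrix(bx, N, d) else
        matrix(bx, N, d)                    # node mode: recycled by row
      At <- A * ME + diag(N)
      S <- {
        r <- 1 / sqrt(rowSums(At))
        At * outer(r, r)
      }
      fw <- gcn_forward(model$params, model$rstats, S, list(X * BX),
                        infer_cfg, training = FALSE)
      p_t <- fw$probs[1, ti]
      data_fit <- -log(max(p_t, 1e-12))
      me <- sigmoid(pars$ze)                # keep-probabilities (means)
      mx <- sigmoid(pars$zx)
      ent_term <- function(m) {
        mc <- clamp01(m)
        mean(-mc * log(mc) - (1 - mc) * log(1 - mc))
      }
      loss <- data_fit + reg$edge_size * mean(me) + reg$feat_size * mean(mx) +
        reg$ent * (ent_term(me) + ent_term(mx))
      if (!is.finite(loss))
        stop("non-finite explainer loss at iteration ", it)
      trace$loss[it] <- loss
      trace$data_fit[it] <- data_fit
      dlogits <- fw$probs
      dlogits[1, ti] <- dlogits[1, ti] - 1
      bw <- gcn_backward(model$params, fw$cache, infer_cfg, dlogits,
                         want_input_grads = TRUE)
      nb <- normadj_backward(bw$dS, At)
      # per undirected edge (i < j): both orientations' direct terms plus
      # both endpoints' degree terms, times A (=1 on edges)
      dAt_edge <- (nb$direct + t(nb$direct))[eidx] +
        nb$u[row(A)[eidx]] + nb$u[col(A)[eidx]]
      dMX <- bw$dX[[1]] * X
      g_bx <- if (feature_mask == "feature") as.vector(dMX) else rowSums(dMX)
      # chain: data fit through the concrete sample, regularizers through
      # the mean mask; d/dm of the Bernoulli entropy is log((1-m)/m)
      g_ze <- dAt_edge * be * (1 - be) / tau +
        (reg$edge_size / n_edges + reg$ent / n_edges * ent_grad(me)) *
          me * (1 - me)
      g_zx <- g_bx * bx * (1 - bx) / tau +
        (reg$feat_size / nX + reg$ent / nX * ent_grad(mx)) * mx * (1 - mx)
      st <- adam_step(pars, list(ze = g_ze, zx = g_zx), opt, lr)
      pars <- st$params; opt <- st$state
    }
    list(me = sigmoid(pars$ze), mx = sigmoid(pars$zx), trace = trace)
  })
  ME <- matrix(0, N, N)
  ME[eidx] <- masks$me
  ME <- ME + t(ME)
  MX <- if (feature_mask == "feature") matrix(masks$mx, N, d) else
    matrix(masks$mx, N, 1)
  structure(list(M_E = ME, M_X = MX, mode = feature_mask,
                 target_class = target_class, trace = masks$trace,
                 record_id = graph$record_id, iterations = iterations,
                 n_edges = n_edges),
            class = "ecg_explanation")
}

#' @export
print.ecg_explanation <- function(x, ...) {
  cat(sprintf("<ecg_explanation %s> class %s, %d edges, %s feature mask, %d iterations\n",
              x$record_id, x$target_class, x$n_edges, x$mode, x$iterations))
  tr <- x$trace
  cat(sprintf("  final loss %.4f (data fit %.4f)\n",
              tr$loss[nrow(tr)], tr$data_fit[nrow(tr)]))
  invisible(x)
}

#' Predict from a masked input
#'
#' Applies `A' = A * M_E`, `X' = X * M_X`, renormalizes the masked adjacency
#' inside the propagation rule, and runs the frozen model in inference mode.
#' With all-ones masks this reproduces the unmasked prediction exactly; with
#' an all-zero edge mask every spatial and temporal message is suppressed and
#' the model sees isolated nodes.
#'
#' @param model an [ecg_gcn()] model.
#' @param graph the graph to predict on.
#' @param M_E symmetric N x N edge mask in \[0, 1\] (entries off the edges of
#'   `A` are ignored).
#' @param M_X feature mask: N x d matrix, N x 1 matrix or length-N vector
#'   (broadcast across features).
#' @return named probability vector of length C.
#' @export
masked_predict <- function(model, graph, M_E, M_X) {
  stopifnot(inherits(model, "ecg_gcn"))
  A <- graph$A
  N <- nrow(A); d <- ncol(graph$X)
  if (is.vector(M_X)) M_X <- matrix(M_X, N, 1)
  MX <- if (ncol(M_X) == 1) matrix(M_X[, 1], N, d) else M_X
  if (any(M_E < 0 | M_E > 1) || any(MX < 0 | MX > 1))
    stop("mask entries must lie in [0, 1]")
  At <- A * M_E + diag(N)
  r <- 1 / sqrt(rowSums(At))
  S <- At * outer(r, r)
  cfg <- model$config
  cfg$dropout <- 0
  fw <- gcn_forward(model$params, model$rstats, S, list(graph$X * MX), cfg,
                    training = FALSE)
  stats::setNames(fw$probs[1, ], model$class_order)
}

#' Per-vertex node importance from a feature mask
#'
#' Reduces the feature mask to one scalar per vertex by the row mean (in
#' node-broadcast mode the single mask value per node).
#'
#' @param masks an [explain_instance()] result.
#' @return numeric vector of length N, values in \[0, 1\].
#' @export
node_importance <- function(masks) {
  stopifnot(inherits(masks, "ecg_explanation"))
  rowMeans(masks$M_X)
}

#' Per-edge importance from an edge mask
#'
#' One scalar per undirected edge; if the internal representation were
#' asymmetric the two orientations are merged by averaging.
#'
#' @param masks an [explain_instance()] result.
#' @param graph optionally, the explained graph — its edge table order is
#'   used for the output rows.
#' @return data frame with columns `from`, `to`, `importance`.
#' @export
edge_importance <- function(masks, graph = NULL) {
  stopifnot(inherits(masks, "ecg_explanation"))
  M <- (masks$M_E + t(masks$M_E)) / 2
  if (!is.null(graph)) {
    data.frame(from = graph$edges$from, to = graph$edges$to,
               importance = M[cbind(graph$edges$from, graph$edges$to)])
  } else {
    idx <- which(upper.tri(M) & M > 0, arr.ind = TRUE)
    data.frame(from = idx[, 1], to = idx[, 2],
               importance = M[idx])
  }
}

#' Write explanations to a delimited text container
#'
#' One directory per instance: node importances, the edge list with
#' importances, and the objective trace, as TSV files.
#'
#' @param expl an [explain_instance()] result.
#' @param graph the explained graph.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_explanation <- function(expl, graph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ni <- data.frame(id = graph$vertices$id, lead = graph$vertices$lead,
                   patch = graph$vertices$patch,
                   importance = node_importance(expl))
  utils::write.table(ni, file.path(dir, "node_importance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ei <- edge_importance(expl, graph)
  ei$class <- graph$edges$class
  utils::write.table(ei, file.path(dir, "edge_importance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expl$trace, file.path(dir, "trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("record_id\t", expl$record_id),
               paste0("target_class\t", expl$target_class),
               paste0("mode\t", expl$mode),
               paste0("iterations\t", expl$iterations)),
             file.path(dir, "meta.tsv"))
  invisible(dir)
}
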