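#' Symmetrically normalized adjacency with self-loops
#'
#' Computes the graph-convolution propagation matrix
#' `D^{-1/2} (A + I) D^{-1/2}` where `D` is the degree matrix of `A + I`.
#' Adding the identity guarantees strictly positive degrees, so the result
#' is always defined; it is symmetric with entries in \[0, 1\].
#'
#' @param A binary symmetric adjacency matrix with zero diagonal (weighted
#'   symmetric matrices with non-negative entries are also accepted, as used
#'   by the explainer's masked adjacency).
#' @return dense N x N propagation matrix.
#' @examples
#' normalize_adjacency(matrix(c(0, 1, 1, 0), 2))  # all entries 0.5
#' @export
normalize_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square matrix")
  if (max(abs(A - t(A))) > 1e-12)
    stop("A must be symmetric")
  At <- A + diag(nrow(A))
  r <- 1 / sqrt(rowSums(At))
  pmin(At * outer(r, r), 1)   # guard against 1 + ulp round-off
}

#' Model and training configuration
#'
#' Architecture: a feed-forward network (linear, batch norm, ReLU, dropout
#' per layer) transforming raw patch samples into node embeddings, five
#' graph-convolution layers with normalized-adjacency propagation (ReLU +
#' dropout each), a flatten readout in fixed vertex order, and a linear
#' classifier with softmax. Training: Adam on the categorical cross-entropy,
#' mini-batches, fixed epoch count, one global seed for initialization,
#' shuffling and dropout.
#'
#' @param ffn_widths integer vector of FFN hidden widths.
#' @param gcn_widths integer vector of graph-convolution layer widths
#'   (default five layers of 64).
#' @param dropout dropout rate in \[0, 1).
#' @param lr learning rate (>= 0; 0 freezes the parameters).
#' @param batch_size mini-batch size.
#' @param epochs number of training epochs (no early stopping).
#' @param weight_decay decoupled weight-decay coefficient: after each
#'   optimizer step every weight matrix (not biases or batch-norm parameters)
#'   is shrunk by the factor `1 - lr * weight_decay`. Keeps logit margins
#'   moderate, which both regularizes the fit and keeps the classifier
#'   amenable to perturbation-based explanation.
#' @param seed integer seed making training fully reproducible.
#' @return object of class `"gcn_config"`.
#' @export
model_config <- function(ffn_widths = c(64, 64), gcn_widths = rep(64, 5),
                         dropout = 0.2, lr = 0.001, batch_size = 32,
                         epochs = 150, weight_decay = 10, seed = 1L) {
  if (any(ffn_widths < 1) || any(gcn_widths < 1))
    stop_field("widths", "all layer widths must be >= 1")
  if (dropout < 0 || dropout >= 1)
    stop_field("dropout", "must be in [0, 1)")
  if (lr < 0) stop_field("lr", "must be >= 0")
  if (batch_size < 1) stop_field("batch_size", "must be >= 1")
  if (epochs < 1) stop_field("epochs", "must be >= 1")
  if (weight_decay < 0 || lr * weight_decay >= 1)
    stop_field("weight_decay", "must satisfy 0 <= lr * weight_decay < 1")
  structure(list(ffn_widths = as.integer(ffn_widths),
                 gcn_widths = as.integer(gcn_widths),
                 dropout = dropout, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "gcn_config")
}

init_gcn_params <- function(d, N, C, config) {
  params <- list()
  rstats <- list()
  nin <- d
  for (k in seq_along(config$ffn_widths)) {
    nout <- config$ffn_widths[k]
    params[[paste0("ffn", k, "_W")]] <- glorot_init(nin, nout)
    params[[paste0("ffn", k, "_b")]] <- numeric(nout)
    params[[paste0("ffn", k, "_gamma")]] <- rep(1, nout)
    params[[paste0("ffn", k, "_beta")]] <- numeric(nout)
    rstats[[paste0("ffn", k, "_mean")]] <- numeric(nout)
    rstats[[paste0("ffn", k, "_var")]] <- rep(1, nout)
    nin <- nout
  }
  for (l in seq_along(config$gcn_widths)) {
    nout <- config$gcn_widths[l]
    params[[paste0("gcn", l, "_W")]] <- glorot_init(nin, nout)
    params[[paste0("gcn", l, "_b")]] <- numeric(nout)
    nin <- nout
  }
  params$cls_W <- glorot_init(N * nin, C)
  params$cls_b <- numeric(C)
  list(params = params, rstats = rstats)
}

# Forward pass over a batch of graphs sharing one propagation matrix S.
# Xlist: list of N x d node-attribute matrices. Returns class probabilities,
# a cache for backprop and (in training mode) updated running statistics.
gcn_forward <- function(params, rstats, S, Xlist, config, training = FALSE) {
  B <- length(Xlist)
  N <- nrow(Xlist[[1]])
  H <- do.call(rbind, Xlist)              # (B*N) x d, graph-major blocks
  ffn_cache <- list()
  for (k in seq_along(config$ffn_widths)) {
    W <- params[[paste0("ffn", k, "_W")]]
    Z <- H %*% W
    Z <- sweep(Z, 2, params[[paste0("ffn", k, "_b")]], `+`)
    bn <- bn_forward(Z, params[[paste0("ffn", k, "_gamma")]],
                     params[[paste0("ffn", k, "_beta")]],
                     rstats[[paste0("ffn", k, "_mean")]],
                     rstats[[paste0("ffn", k, "_var")]], training)
    if (training) {
      rstats[[paste0("ffn", k, "_mean")]] <- bn$rstat$mean
      rstats[[paste0("ffn", k, "_var")]] <- bn$rstat$var
    }
    R <- relu(bn$out)
    dp <- dropout_forward(R, config$dropout, training)
    ffn_cache[[k]] <- list(inp = H, bn = bn$cache, pre_relu = bn$out,
                           mask = dp$mask)
    H <- dp$out
  }
  Hg <- lapply(seq_len(B), function(g)
    H[((g - 1) * N + 1):(g * N), , drop = FALSE])
  gcn_cache <- list()
  for (l in seq_along(config$gcn_widths)) {
    W <- params[[paste0("gcn", l, "_W")]]
    b <- params[[paste0("gcn", l, "_b")]]
    layer <- list(Hin = Hg, Z = vector("list", B), mask = vector("list", B))
    for (g in seq_len(B)) {
      Z <- S %*% (Hg[[g]] %*% W)
      Z <- sweep(Z, 2, b, `+`)
      layer$Z[[g]] <- Z
      R <- relu(Z)
      dp <- dropout_forward(R, config$dropout, training)
      layer$mask[g] <- list(dp$mask)   # keep NULL slots (no dropout)
      Hg[[g]] <- dp$out
    }
    gcn_cache[[l]] <- layer
  }
  V <- t(vapply(Hg, function(h) as.vector(t(h)),
                numeric(N * ncol(Hg[[1]]))))
  logits <- sweep(V %*% params$cls_W, 2, params$cls_b, `+`)
  probs <- softmax_rows(logits)
  list(probs = probs, rstats = rstats,
       cache = list(ffn = ffn_cache, gcn = gcn_cache, V = V, S = S,
                    B = B, N = N, w_last = ncol(Hg[[1]])))
}

# Backward pass. dlogits: B x C gradient of the loss w.r.t. logits.
# want_input_grads additionally returns dX (per graph) and dS (summed over
# the batch), needed by the explainer.
gcn_backward <- function(params, cache, config, dlogits,
                         want_input_grads = FALSE) {
  B <- cache$B; N <- cache$N; w <- cache$w_last
  grads <- list()
  grads$cls_W <- t(cache$V) %*% dlogits
  grads$cls_b <- colSums(dlogits)
  dV <- dlogits %*% t(params$cls_W)
  dHg <- lapply(seq_len(B), function(g) t(matrix(dV[g, ], nrow = w)))
  dS <- if (want_input_grads) matrix(0, N, N) else NULL
  for (l in rev(seq_along(config$gcn_widths))) {
    layer <- cache$gcn[[l]]
    W <- params[[paste0("gcn", l, "_W")]]
    dW <- W * 0; db <- numeric(ncol(W))
    for (g in seq_len(B)) {
      dH <- dHg[[g]]
      if (!is.null(layer$mask[[g]])) dH <- dH * layer$mask[[g]]
      dZ <- dH * (layer$Z[[g]] > 0)
      HW <- layer$Hin[[g]] %*% W
      dW <- dW + t(cache$S %*% layer$Hin[[g]]) %*% dZ
      db <- db + colSums(dZ)
      if (want_input_grads) dS <- dS + dZ %*% t(HW)
      dHg[[g]] <- cache$S %*% (dZ %*% t(W))
    }
    grads[[paste0("gcn", l, "_W")]] <- dW
    grads[[paste0("gcn", l, "_b")]] <- db
  }
  dH <- do.call(rbind, dHg)
  for (k in rev(seq_along(config$ffn_widths))) {
    fc <- cache$ffn[[k]]
    if (!is.null(fc$mask)) dH <- dH * fc$mask
    dR <- dH * (fc$pre_relu > 0)
    bb <- bn_backward(dR, fc$bn)
    if (!is.null(bb$dgamma)) {
      grads[[paste0("ffn", k, "_gamma")]] <- bb$dgamma
      grads[[paste0("ffn", k, "_beta")]] <- bb$dbeta
    } else {
      grads[[paste0("ffn", k, "_gamma")]] <-
        params[[paste0("ffn", k, "_gamma")]] * 0
      grads[[paste0("ffn", k, "_beta")]] <-
        params[[paste0("ffn", k, "_beta")]] * 0
    }
    dZ <- bb$dx
    grads[[paste0("ffn", k, "_W")]] <- t(fc$inp) %*% dZ
    grads[[paste0("ffn", k, "_b")]] <- colSums(dZ)
    dH <- dZ %*% t(params[[paste0("ffn", k, "_W")]])
  }
  dXlist <- if (want_input_grads)
    lapply(seq_len(B), function(g) dH[((g - 1) * N + 1):(g * N), ,
                                      drop = FALSE]) else NULL
  list(grads = grads, dX = dXlist, dS = dS)
}

check_graph_batch <- function(graphs) {
  if (length(graphs) == 0) stop("no graphs given")
  N <- nrow(graphs[[1]]$A); d <- ncol(graphs[[1]]$X)
  A <- graphs[[1]]$A
  for (g in graphs) {
    if (nrow(g$A) != N || ncol(g$X) != d)
      stop(sprintf("graph shape mismatch: expected N = %d, d = %d but got N = %d, d = %d (record %s)",
                   N, d, nrow(g$A), ncol(g$X), g$record_id))
    if (!identical(dim(g$A), dim(A)) || max(abs(g$A - A)) != 0)
      stop("all graphs must share the same adjacency (record ",
           g$record_id, " differs)")
  }
  list(N = N, d = d, A = A)
}

#' Fit the spatial-temporal graph convolutional classifier
#'
#' Trains the classifier `f_theta` by mini-batch Adam on the categorical
#' cross-entropy `sum_i l(f_theta(G_i), Y_i)`, for a fixed number of epochs
#' with dropout and batch normalization active. All graphs must share one
#' topology (identical adjacency) and feature dimension. Fully reproducible
#' given `config$seed`.
#'
#' @param graphs list of [build_graph()] results with labels `y` set; at
#'   least two classes must be present.
#' @param config a [model_config()].
#' @param class_order optional fixed class order; defaults to the sorted
#'   unique labels.
#' @param verbose print per-epoch loss.
#' @return object of class `"ecg_gcn"`: parameters, batch-norm running
#'   statistics, the adjacency and its normalized propagation matrix, the
#'   class order and the per-epoch loss/accuracy trace.
#' @seealso [predict.ecg_gcn()], [explain_instance()]
#' @export
ecg_gcn <- function(graphs, config = model_config(), class_order = NULL,
                    verbose = FALSE) {
  stopifnot(inherits(config, "gcn_config"))
  shp <- check_graph_batch(graphs)
  labels <- vapply(graphs, function(g) as.character(g$y), "")
  if (anyNA(labels) || any(labels == "NA"))
    stop("all training graphs must carry a class label y")
  if (is.null(class_order)) class_order <- sort(unique(labels))
  if (length(unique(labels)) < 2)
    stop("training requires at least two classes; got only '",
         unique(labels), "'")
  if (!all(labels %in% class_order))
    stop("labels outside class_order: ",
         paste(setdiff(labels, class_order), collapse = ", "))
  C <- length(class_order)
  y <- match(labels, class_order)
  S <- normalize_adjacency(shp$A)
  Xlist <- lapply(graphs, `[[`, "X")
  n <- length(graphs)
  trace <- data.frame(epoch = integer(), loss = numeric(),
                      accuracy = numeric())
  withr::with_seed(config$seed, {
    ini <- init_gcn_params(shp$d, shp$N, C, config)
    params <- ini$params; rstats <- ini$rstats
    wnames <- grep("_W$", names(params), value = TRUE)
    opt <- adam_init(params)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        fw <- gcn_forward(params, rstats, S, Xlist[idx], config,
                          training = TRUE)
        rstats <- fw$rstats
        pb <- fw$probs
        yb <- y[idx]
        pick <- pb[cbind(seq_along(idx), yb)]
        ep_loss <- ep_loss + sum(-log(pmax(pick, 1e-12)))
        ep_correct <- ep_correct + sum(max.col(pb, "first") == yb)
        dlogits <- pb
        dlogits[cbind(seq_along(idx), yb)] <-
          dlogits[cbind(seq_along(idx), yb)] - 1
        dlogits <- dlogits / length(idx)
        bw <- gcn_backward(params, fw$cache, config, dlogits)
        st <- adam_step(params, bw$grads, opt, config$lr)
        params <- st$params; opt <- st$state
        if (config$weight_decay > 0 && config$lr > 0) {
          shrink <- 1 - config$lr * config$weight_decay
          for (nm in wnames) params[[nm]] <- params[[nm]] * shrink
        }
      }
      trace <- rbind(trace, data.frame(epoch = epoch, loss = ep_loss / n,
                                       accuracy = ep_correct / n))
      if (!is.finite(ep_loss))
        stop("non-finite training loss at epoch ", epoch)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", epoch,
                        ep_loss / n, ep_correct / n))
    }
  })
  structure(list(params = params, rstats = rstats, config = config,
                 class_order = class_order, N = shp$N, d = shp$d,
                 A = shp$A, S = S, loss_trace = trace,
                 n_train = n, call = match.call()),
            class = "ecg_gcn")
}

#' Predict classes or probabilities for ECG graphs
#'
#' Inference mode: dropout disabled, batch normalization using running
#' statistics — deterministic. The predicted label is the argmax
#' probability, ties resolved to the lower class index.
#'
#' @param object an [ecg_gcn()] model.
#' @param graphs list of graphs (or one graph) matching the model's shapes.
#' @param type `"class"` for labels, `"prob"` for the probability matrix,
#'   `"both"` for a list of the two.
#' @param ... unused.
#' @return character vector, probability matrix (rows sum to 1), or list.
#' @export
predict.ecg_gcn <- function(object, graphs, type = c("class", "prob", "both"),
                            ...) {
  type <- match.arg(type)
  if (inherits(graphs, "ecg_graph")) graphs <- list(graphs)
  for (g in graphs)
    if (nrow(g$A) != object$N || ncol(g$X) != object$d)
      stop(sprintf("graph shape mismatch: model expects N = %d, d = %d but got N = %d, d = %d",
                   object$N, object$d, nrow(g$A), ncol(g$X)))
  n <- length(graphs)
  probs <- matrix(0, n, length(object$class_order),
                  dimnames = list(NULL, object$class_order))
  bs <- max(1L, object$config$batch_size)
  for (start in seq(1, n, by = bs)) {
    idx <- start:min(start + bs - 1, n)
    fw <- gcn_forward(object$params, object$rstats, object$S,
                      lapply(graphs[idx], `[[`, "X"), object$config,
                      training = FALSE)
    probs[idx, ] <- fw$probs
  }
  labels <- object$class_order[max.col(probs, "first")]
  switch(type, class = labels, prob = probs,
         both = list(class = labels, prob = probs))
}

#' @export
print.ecg_gcn <- function(x, ...) {
  cat(sprintf("<ecg_gcn> %d-class GCN classifier on N = %d vertices (d = %d)\n",
              length(x$class_order), x$N, x$d))
  cat("  classes:", paste(x$class_order, collapse = ", "), "\n")
  cat(sprintf("  FFN widths: %s | GCN widths: %s | dropout %.2f\n",
              paste(x$config$ffn_widths, collapse = ","),
              paste(x$config$gcn_widths, collapse = ","),
              x$config$dropout))
  tl <- x$loss_trace
  cat(sprintf("  trained %d epochs on %d graphs; final loss %.4f, accuracy %.3f\n",
              nrow(tl), x$n_train, tl$loss[nrow(tl)],
              tl$accuracy[nrow(tl)]))
  invisible(x)
}

#' @export
summary.ecg_gcn <- function(object, ...) {
  np <- sum(vapply(object$params, length, 0L))
  cat(sprintf("Graph convolutional ECG classifier: %d parameters\n", np))
  print(object)
  invisible(object)
}

#' @export
coef.ecg_gcn <- function(object, ...) object$params

#' Plot the training loss trace
#'
#' @param x an [ecg_gcn()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ecg_gcn <- function(x, ...) {
  tl <- x$loss_trace
  graphics::plot(tl$epoch, tl$loss, type = "l", xlab = "epoch",
                 ylab = "mean cross-entropy", ...)
  invisible(x)
}

#' Grid search over training configurations
#'
#' Trains each candidate configuration on the training graphs, scores
#' accuracy on the validation graphs, and returns the best configuration
#' (ties broken by grid order, the first maximum).
#'
#' @param grid list of [model_config()] objects.
#' @param train_graphs,val_graphs labelled graph lists.
#' @param class_order optional fixed class order.
#' @param verbose print progress.
#' @return list with `best_config`, `best_index`, and `scores` (data frame
#'   with one row per candidate).
#' @export
tune_ecg_gcn <- function(grid, train_graphs, val_graphs, class_order = NULL,
                         verbose = FALSE) {
  if (length(grid) == 0) stop("empty hyperparameter grid")
  val_y <- vapply(val_graphs, function(g) as.character(g$y), "")
  scores <- data.frame(candidate = seq_along(grid), accuracy = NA_real_)
  for (i in seq_along(grid)) {
    fit <- ecg_gcn(train_graphs, grid[[i]], class_order = class_order)
    pred <- predict(fit, val_graphs, type = "class")
    scores$accuracy[i] <- mean(pred == val_y)
    if (verbose)
      message(sprintf("candidate %d: val accuracy %.3f", i,
                      scores$accuracy[i]))
  }
  best <- which.max(scores$accuracy)
  list(best_config = grid[[best]], best_index = best, scores = scores)
}

#' Save a trained model as a JSON checkpoint
#'
#' Text container: configuration, class order, adjacency, named parameter
#' arrays and batch-norm running statistics, at full precision.
#'
#' @param model an [ecg_gcn()] model.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
save_ecg_gcn <- function(model, path) {
  ser <- function(x) list(dim = dim(x) %||% length(x), data = as.vector(x))
  obj <- list(config = unclass(model$config),
              class_order = model$class_order,
              N = model$N, d = model$d,
              A = ser(model$A),
              params = lapply(model$params, ser),
              rstats = lapply(model$rstats, ser),
              loss_trace = model$loss_trace,
              n_train = model$n_train)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint written by [save_ecg_gcn()]
#'
#' @param path checkpoint file.
#' @return an `"ecg_gcn"` model.
#' @export
load_ecg_gcn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de <- function(s) {
    if (length(s$dim) == 2) matrix(s$data, s$dim[1], s$dim[2])
    else as.numeric(s$data)
  }
  cfg <- do.call(model_config, obj$config[c("ffn_widths", "gcn_widths",
                                            "dropout", "lr", "batch_size",
                                            "epochs", "weight_decay",
                                            "seed")])
  A <- de(obj$A)
  params <- lapply(obj$params, de)
  rstats <- lapply(obj$rstats, de)
  structure(list(params = params, rstats = rstats, config = cfg,
                 class_order = obj$class_order, N = obj$N, d = obj$d,
                 A = A, S = normalize_adjacency(A),
                 loss_trace = as.data.frame(obj$loss_trace),
                 n_train = obj$n_train, call = NULL),
            class = "ecg_gcn")
}
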