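# Independent brute-force oracles, kept deliberately naive.

# element-wise evaluation of D^{-1/2} (A+I) D^{-1/2}
oracle_norm_adjacency <- function(A) {
  N <- nrow(A)
  At <- A + diag(N)
  deg <- rowSums(At)
  out <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    out[i, j] <- At[i, j] / (sqrt(deg[i]) * sqrt(deg[j]))
  out
}

# pairwise O(n^2) ranking AUC with 0.5 for ties
oracle_auc <- function(scores, positive) {
  pos <- which(positive); neg <- which(!positive)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

oracle_macro_auc <- function(labels, probs, class_order) {
  mean(vapply(seq_along(class_order), function(k)
    oracle_auc(probs[, k], labels == class_order[k]), 0))
}

# multiclass MCC via the covariance (correlation of one-hot encodings) form
oracle_mcc <- function(labels, predictions, class_order) {
  n <- length(labels)
  Y <- t(vapply(labels, function(l) as.numeric(class_order == l),
                numeric(length(class_order))))
  P <- t(vapply(predictions, function(l) as.numeric(class_order == l),
                numeric(length(class_order))))
  cov2 <- function(a, b) {
    s <- 0
    for (k in seq_len(ncol(a)))
      s <- s + sum((a[, k] - mean(a[, k])) * (b[, k] - mean(b[, k])))
    s / n
  }
  cov2(Y, P) / sqrt(cov2(Y, Y) * cov2(P, P))
}

# weighted F1 by explicit per-class enumeration from raw labels
oracle_weighted_f1 <- function(labels, predictions, class_order) {
  out <- 0
  for (cls in class_order) {
    tp <- sum(labels == cls & predictions == cls)
    fp <- sum(labels != cls & predictions == cls)
    fn <- sum(labels == cls & predictions != cls)
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    re <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (pre + re > 0) 2 * pre * re / (pre + re) else 0
    out <- out + f1 * sum(labels == cls) / length(labels)
  }
  out
}

# brute-force confusion by pair counting
oracle_confusion <- function(labels, predictions, class_order) {
  C <- length(class_order)
  m <- matrix(0L, C, C, dimnames = list(true = class_order,
                                        predicted = class_order))
  for (i in seq_along(labels))
    m[labels[i], predictions[i]] <- m[labels[i], predictions[i]] + 1L
  m
}

random_label_fixture <- function(n = 50, C = 3, seed = 99) {
  classes <- LETTERS[seq_len(C)]
  withr::with_seed(seed, {
    labels <- sample(classes, n, replace = TRUE)
    predictions <- sample(classes, n, replace = TRUE)
    probs <- matrix(stats::rexp(n * C), n, C)
    probs <- probs / rowSums(probs)
    colnames(probs) <- classes
    list(labels = labels, predictions = predictions, probs = probs,
         classes = classes)
  })
}
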