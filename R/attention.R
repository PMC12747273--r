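#' Initialize gated-attention parameters
#'
#' The gated attention map scores each patch vector `h_n` (a row of the
#' N x d bag matrix `H`) with three fully connected layers: weight matrices
#' `W_a` (1 x d), `V_a` (d x d) and `U_a` (d x d), combined as
#' `a_n = W_a (tanh(V_a h_n) * sigmoid(U_a h_n))` (elementwise product),
#' followed by a softmax over the bag. Bias terms are included; with zero
#' biases the layer reproduces the weight-only algebra exactly.
#'
#' @param d embedding dimension.
#' @param seed seed for the Gaussian initialization.
#' @param sd initialization scale.
#' @return a list of class `gated_attention_params` with `W_a` (length-d
#'   vector), `b_a` (scalar), `V_a`, `b_v`, `U_a`, `b_u`.
#' @export
init_attention_params <- function(d, seed = 1L, sd = 1 / sqrt(d)) {
  with_seed(substream_seed(seed, "attn_init"), {
    structure(list(
      W_a = stats::rnorm(d, sd = sd), b_a = 0,
      V_a = matrix(stats::rnorm(d * d, sd = sd), d), b_v = numeric(d),
      U_a = matrix(stats::rnorm(d * d, sd = sd), d), b_u = numeric(d)
    ), class = "gated_attention_params")
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass of the gate; returns intermediates needed by backprop.
attention_forward <- function(H, params) {
  Tm <- tanh(sweep(H %*% t(params$V_a), 2, params$b_v, "+"))
  G <- sigmoid(sweep(H %*% t(params$U_a), 2, params$b_u, "+"))
  Z <- Tm * G
  a <- as.vector(Z %*% params$W_a) + params$b_a
  a_shift <- a - max(a)  # max-subtraction stabilization
  e <- exp(a_shift)
  s <- e / sum(e)
  list(Tm = Tm, G = G, Z = Z, a = a, s = s)
}

#' Gated-attention scores for a bag of patches
#'
#' @param H numeric N x d matrix of patch embeddings for one slide.
#' @param params a [init_attention_params()] list (or any list with the same
#'   fields).
#' @return length-N vector of positive weights summing to 1.
#' @export
attention_scores <- function(H, params) {
  if (!is.matrix(H) || nrow(H) == 0L) stop("bag must contain at least one patch")
  if (ncol(H) != length(params$W_a)) {
    stop("bag dimension ", ncol(H), " does not match attention parameters (",
         length(params$W_a), ")")
  }
  attention_forward(H, params)$s
}

#' Attention-weighted bag aggregation
#'
#' Collapses a bag into one slide-level vector as the convex combination
#' `h = sum_n s_n h_n` of its rows under the attention weights.
#'
#' @param H numeric N x d bag matrix.
#' @param s length-N weights summing to 1.
#' @return length-d numeric vector.
#' @export
aggregate_bag <- function(H, s) {
  if (length(s) != nrow(H)) stop("weight/row count mismatch")
  if (abs(sum(s) - 1) > 1e-6) stop("weights must sum to 1")
  as.vector(crossprod(H, s))
}

#' Mean pooling of a bag
#'
#' The attention-free ablation: plain column means, equal to
#' `aggregate_bag(H, rep(1/N, N))`.
#'
#' @param H numeric N x d bag matrix with N >= 1.
#' @return length-d numeric vector.
#' @export
mean_pool <- function(H) {
  if (!is.matrix(H) || nrow(H) == 0L) stop("bag must contain at least one patch")
  colMeans(H)
}

#' Inverse-frequency class weights
#'
#' For imbalanced classification tasks the cross-entropy is weighted by
#' `w_c = 1 / p_c`, where `p_c` is the fraction of training instances in
#' class `c`, so rarer classes exert proportionally more influence.
#'
#' @param labels integer class ids in `0:(n_classes - 1)`.
#' @param n_classes number of classes (default 3).
#' @return numeric vector of length `n_classes`.
#' @export
class_weights <- function(labels, n_classes = 3L) {
  labels <- labels[!is.na(labels)]
  p <- tabulate(labels + 1L, nbins = n_classes) / length(labels)
  if (any(p == 0)) {
    stop("class(es) ", paste(which(p == 0) - 1L, collapse = ", "),
         " absent from training labels; re-split the cohort")
  }
  1 / p
}

weighted_ce <- function(logits, y, w) {
  z <- logits - max(logits)
  logp <- z - log(sum(exp(z)))
  -w[y + 1L] * logp[y + 1L]
}

#' Multi-task training loss
#'
#' Sum over classification tasks of the class-weighted cross-entropy plus sum
#' over regression tasks of the squared error, for one slide. Tasks with a
#' missing label (`NA`) contribute zero; a non-finite target not marked
#' missing is an error.
#'
#' @param predictions list with `logits` (list of length-3 numeric vectors,
#'   one per classification task) and `yhat` (numeric vector, one per
#'   regression task).
#' @param labels list with `classes` (integer vector, `NA` = missing) and
#'   `targets` (numeric vector, `NA` = missing).
#' @param weights list of per-task class-weight vectors.
#' @return scalar loss.
#' @export
total_loss <- function(predictions, labels, weights) {
  n_cls <- length(labels$classes)
  if (length(predictions$logits) != n_cls ||
      length(predictions$yhat) != length(labels$targets)) {
    stop("task counts disagree between predictions and labels")
  }
  bad <- !is.na(labels$targets) & !is.finite(labels$targets)
  if (any(bad)) stop("non-finite regression target(s) not marked missing")
  loss <- 0
  for (t in seq_len(n_cls)) {
    y <- labels$classes[t]
    if (is.na(y)) next
    loss <- loss + weighted_ce(predictions$logits[[t]], y, weights[[t]])
  }
  for (j in seq_along(labels$targets)) {
    y <- labels$targets[j]
    if (is.na(y)) next
    loss <- loss + (predictions$yhat[j] - y)^2
  }
  loss
}

#' Patient-level train / validation / test split
#'
#' Partitions patients (not slides) into train/validation/test with the given
#' fractions (sizes by largest remainder, so 10 patients at (0.8, 0.1, 0.1)
#' give 8/1/1), and resamples until every partition contains at least one
#' positive label (class 1) for every classification task, and the training
#' partition contains every class of every task (so class weights are
#' defined). All slides of a patient land in one partition.
#'
#' @param cohort a `mil_cohort` (or any list with a `labels` tibble holding
#'   `patient_id` and `mut_*` columns).
#' @param fractions length-3 positive fractions summing to 1.
#' @param seed integer seed.
#' @param max_attempts resampling bound before giving up.
#' @return a list with `train`, `val`, `test`: integer row indices into
#'   `cohort$labels`.
#' @export
split_cohort <- function(cohort, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                         max_attempts = 200L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions > 0))
  labels <- cohort$labels
  patients <- unique(labels$patient_id)
  np <- length(patients)
  sizes <- floor(fractions * np)
  rem <- np - sum(sizes)
  if (rem > 0) {
    order_rem <- order(fractions * np - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(rem)]] <- sizes[order_rem[seq_len(rem)]] + 1L
  }
  mut_cols <- grep("^mut_", names(labels), value = TRUE)
  ok <- function(parts) {
    for (col in mut_cols) {
      for (p in parts) {
        v <- labels[[col]][labels$patient_id %in% p]
        if (!any(v == 1L, na.rm = TRUE)) return(FALSE)
      }
      v <- labels[[col]][labels$patient_id %in% parts[[1]]]
      if (length(setdiff(0:2, unique(v[!is.na(v)]))) > 0) return(FALSE)
    }
    TRUE
  }
  for (attempt in seq_len(max_attempts)) {
    perm <- with_seed(substream_seed(seed, paste0("split_", attempt)),
                      sample(patients))
    parts <- list(train = perm[seq_len(sizes[1])],
                  val = perm[sizes[1] + seq_len(sizes[2])],
                  test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
    if (ok(parts)) {
      return(lapply(parts, function(p) which(labels$patient_id %in% p)))
    }
  }
  stop("could not satisfy the positive-label split constraint in ",
       max_attempts, " attempts")
}
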