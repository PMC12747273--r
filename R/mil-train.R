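#' Training configuration for the attention-MIL model
#'
#' Defaults follow the reference optimizer contract: Adam with learning rate
#' 1e-4, beta1 0.9, beta2 0.999, L2 weight decay 1e-5; gradients are averaged
#' across `grad_accum_subbatches` sub-batches of `batch_slides` slides before
#' each update, imitating large-batch training when bags have very different
#' sizes.
#'
#' @param lr,beta1,beta2,weight_decay Adam scalars.
#' @param epochs training epochs.
#' @param batch_slides slides per sub-batch.
#' @param grad_accum_subbatches sub-batches accumulated per update.
#' @param d_model shared embedding dimension of projection / attention /
#'   heads (256 in the reference configuration; smaller for desk-scale runs).
#' @param aggregation `"attention"` or `"mean"` (the ablation).
#' @param seed seed for initialization and epoch shuffling.
#' @return a list of class `mil_train_config`.
#' @export
mil_train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                             weight_decay = 1e-5, epochs = 100L,
                             batch_slides = 2L, grad_accum_subbatches = 8L,
                             d_model = 256L,
                             aggregation = c("attention", "mean"),
                             seed = 1L) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_slides = as.integer(batch_slides),
                 grad_accum_subbatches = as.integer(grad_accum_subbatches),
                 d_model = as.integer(d_model),
                 aggregation = match.arg(aggregation),
                 seed = as.integer(seed)),
            class = "mil_train_config")
}

init_mil_model <- function(d_raw, d_model, n_cls, n_reg, seed,
                           aggregation = "attention") {
  sd0 <- 1 / sqrt(d_model)
  with_seed(substream_seed(seed, "mil_init"), {
    model <- list(
      W_p = matrix(stats::rnorm(d_raw * d_model, sd = 1 / sqrt(d_raw)), d_raw),
      b_p = numeric(d_model),
      attn = init_attention_params(d_model, seed = seed),
      cls = lapply(seq_len(n_cls), function(t)
        list(W = matrix(stats::rnorm(d_model * 3, sd = sd0), d_model),
             b = numeric(3))),
      reg = lapply(seq_len(n_reg), function(j)
        list(w = stats::rnorm(d_model, sd = sd0), b = 0)),
      d_raw = d_raw, d_model = d_model, aggregation = aggregation
    )
    class(model) <- "mil_model"
    model
  })
}

# Forward pass for one bag; returns predictions and intermediates.
mil_forward <- function(model, X) {
  H <- sweep(X %*% model$W_p, 2, model$b_p, "+")
  if (model$aggregation == "attention") {
    att <- attention_forward(H, model$attn)
    s <- att$s
  } else {
    att <- NULL
    s <- rep(1 / nrow(H), nrow(H))
  }
  hbar <- as.vector(crossprod(H, s))
  logits <- lapply(model$cls, function(hd) as.vector(hbar %*% hd$W + hd$b))
  yhat <- vapply(model$reg, function(hd) sum(hbar * hd$w) + hd$b, 0)
  list(H = H, att = att, s = s, hbar = hbar, logits = logits, yhat = yhat)
}

# Backward pass for one bag: returns gradient list mirroring the model
# structure. Loss = sum over tasks (weighted CE + squared error).
mil_backward <- function(model, X, fwd, classes, targets, cls_weights) {
  d <- model$d_model
  u <- numeric(d)  # dL/d hbar
  g_cls <- vector("list", length(model$cls))
  for (t in seq_along(model$cls)) {
    y <- classes[t]
    if (is.na(y)) {
      g_cls[[t]] <- list(W = matrix(0, d, 3), b = numeric(3))
      next
    }
    z <- fwd$logits[[t]] - max(fwd$logits[[t]])
    p <- exp(z) / sum(exp(z))
    dlog <- cls_weights[[t]][y + 1L] * (p - (seq_len(3) == y + 1L))
    g_cls[[t]] <- list(W = outer(fwd$hbar, dlog), b = dlog)
    u <- u + as.vector(model$cls[[t]]$W %*% dlog)
  }
  g_reg <- vector("list", length(model$reg))
  for (j in seq_along(model$reg)) {
    y <- targets[j]
    if (is.na(y)) {
      g_reg[[j]] <- list(w = numeric(d), b = 0)
      next
    }
    dyhat <- 2 * (fwd$yhat[j] - y)
    g_reg[[j]] <- list(w = dyhat * fwd$hbar, b = dyhat)
    u <- u + dyhat * model$reg[[j]]$w
  }
  H <- fwd$H
  s <- fwd$s
  if (model$aggregation == "attention") {
    att <- fwd$att
    q <- as.vector(H %*% u)
    da <- s * (q - sum(s * q))
    dZ <- outer(da, model$attn$W_a)
    dT <- dZ * att$G
    dG <- dZ * att$Tm
    dPreV <- dT * (1 - att$Tm^2)
    dPreU <- dG * att$G * (1 - att$G)
    g_attn <- list(
      W_a = as.vector(crossprod(att$Z, da)), b_a = sum(da),
      V_a = crossprod(dPreV, H), b_v = colSums(dPreV),
      U_a = crossprod(dPreU, H), b_u = colSums(dPreU)
    )
    dH <- outer(s, u) + dPreV %*% model$attn$V_a + dPreU %*% model$attn$U_a
  } else {
    g_attn <- NULL
    dH <- outer(s, u)
  }
  list(W_p = crossprod(X, dH), b_p = colSums(dH), attn = g_attn,
       cls = g_cls, reg = g_reg)
}

# Flatten model parameters to a named list of numeric arrays for Adam.
mil_params_flat <- function(model) {
  out <- list(W_p = model$W_p, b_p = model$b_p)
  if (model$aggregation == "attention") {
    out <- c(out, stats::setNames(model$attn[c("W_a", "b_a", "V_a", "b_v",
                                               "U_a", "b_u")],
                                  paste0("attn.", c("W_a", "b_a", "V_a", "b_v",
                                                    "U_a", "b_u"))))
  }
  for (t in seq_along(model$cls)) {
    out[[paste0("cls", t, ".W")]] <- model$cls[[t]]$W
    out[[paste0("cls", t, ".b")]] <- model$cls[[t]]$b
  }
  for (j in seq_along(model$reg)) {
    out[[paste0("reg", j, ".w")]] <- model$reg[[j]]$w
    out[[paste0("reg", j, ".b")]] <- model$reg[[j]]$b
  }
  out
}

mil_set_params <- function(model, flat) {
  model$W_p <- flat$W_p; model$b_p <- flat$b_p
  if (model$aggregation == "attention") {
    for (nm in c("W_a", "b_a", "V_a", "b_v", "U_a", "b_u")) {
      model$attn[[nm]] <- flat[[paste0("attn.", nm)]]
    }
  }
  for (t in seq_along(model$cls)) {
    model$cls[[t]]$W <- flat[[paste0("cls", t, ".W")]]
    model$cls[[t]]$b <- flat[[paste0("cls", t, ".b")]]
  }
  for (j in seq_along(model$reg)) {
    model$reg[[j]]$w <- flat[[paste0("reg", j, ".w")]]
    model$reg[[j]]$b <- flat[[paste0("reg", j, ".b")]]
  }
  model
}

grads_flat <- function(g, model) {
  out <- list(W_p = g$W_p, b_p = g$b_p)
  if (model$aggregation == "attention") {
    for (nm in c("W_a", "b_a", "V_a", "b_v", "U_a", "b_u")) {
      out[[paste0("attn.", nm)]] <- g$attn[[nm]]
    }
  }
  for (t in seq_along(g$cls)) {
    out[[paste0("cls", t, ".W")]] <- g$cls[[t]]$W
    out[[paste0("cls", t, ".b")]] <- g$cls[[t]]$b
  }
  for (j in seq_along(g$reg)) {
    out[[paste0("reg", j, ".w")]] <- g$reg[[j]]$w
    out[[paste0("reg", j, ".b")]] <- g$reg[[j]]$b
  }
  out
}

#' Train the attention-MIL multi-task model
#'
#' First-order training with Adam (classical L2 weight decay added to the
#' gradients), gradient accumulation across sub-batches,
#' and best-epoch selection: the returned model carries the parameters of the
#' epoch with the highest overall score (sum of classification AUCs and
#' regression Spearman correlations) on the monitoring split; ties go to the
#' earliest epoch.
#'
#' @param cohort a `mil_cohort`.
#' @param config a [mil_train_config()].
#' @param split a [split_cohort()] result; computed with `config$seed` when
#'   `NULL`.
#' @param monitor which split to select the best epoch on (`"val"` default).
#' @return an object of class `mil_fit`: list with `model` (best-epoch
#'   parameters), `history` (tibble: epoch, train_loss, monitor_score),
#'   `best_epoch`, `split`, `config`, `class_weights`.
#' @export
mil_train <- function(cohort, config = mil_train_config(), split = NULL,
                      monitor = "val") {
  stopifnot(inherits(cohort, "mil_cohort"))
  if (is.null(split)) split <- split_cohort(cohort, seed = config$seed)
  labels <- cohort$labels
  mut_cols <- grep("^mut_", names(labels), value = TRUE)
  reg_cols <- grep("^expr_", names(labels), value = TRUE)
  cls_w <- lapply(mut_cols, function(col)
    class_weights(labels[[col]][split$train]))
  model <- init_mil_model(cohort$spec$d_raw, config$d_model,
                          length(mut_cols), length(reg_cols), config$seed,
                          config$aggregation)
  classes_m <- unname(as.matrix(labels[mut_cols]))
  targets_m <- unname(as.matrix(labels[reg_cols]))
  adam_m <- NULL; adam_v <- NULL; adam_t <- 0
  best <- list(score = -Inf, epoch = 0L, flat = mil_params_flat(model))
  history <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                            monitor_score = numeric())
  if (config$epochs == 0L) {
    return(structure(list(model = model, history = history, best_epoch = 0L,
                          split = split, config = config,
                          class_weights = cls_w),
                     class = "mil_fit"))
  }
  chunk_size <- config$batch_slides * config$grad_accum_subbatches
  for (epoch in seq_len(config$epochs)) {
    order_idx <- with_seed(substream_seed(config$seed, paste0("epoch_", epoch)),
                           sample(split$train))
    epoch_loss <- 0
    chunks <- split(order_idx, ceiling(seq_along(order_idx) / chunk_size))
    for (chunk in chunks) {
      acc <- NULL
      for (i in chunk) {
        fwd <- mil_forward(model, cohort$bags[[i]])
        loss_i <- total_loss(
          list(logits = fwd$logits, yhat = fwd$yhat),
          list(classes = classes_m[i, ], targets = targets_m[i, ]),
          cls_w)
        if (!is.finite(loss_i)) {
          stop("training diverged (non-finite loss) at epoch ", epoch)
        }
        epoch_loss <- epoch_loss + loss_i
        g <- grads_flat(
          mil_backward(model, cohort$bags[[i]], fwd,
                       classes_m[i, ], targets_m[i, ], cls_w),
          model)
        acc <- if (is.null(acc)) g else
          Map(function(a, b) a + b, acc, g)
      }
      acc <- lapply(acc, function(x) x / length(chunk))  # averaged gradients
      flat <- mil_params_flat(model)
      acc <- Map(function(g, p) g + config$weight_decay * p, acc, flat)
      if (is.null(adam_m)) {
        adam_m <- lapply(acc, function(x) x * 0)
        adam_v <- adam_m
      }
      adam_t <- adam_t + 1
      adam_m <- Map(function(m, g) config$beta1 * m + (1 - config$beta1) * g,
                    adam_m, acc)
      adam_v <- Map(function(v, g) config$beta2 * v + (1 - config$beta2) * g^2,
                    adam_v, acc)
      mh <- lapply(adam_m, function(m) m / (1 - config$beta1^adam_t))
      vh <- lapply(adam_v, function(v) v / (1 - config$beta2^adam_t))
      flat <- Map(function(p, m, v) p - config$lr * m / (sqrt(v) + 1e-8),
                  flat, mh, vh)
      model <- mil_set_params(model, flat)
    }
    ev <- mil_evaluate(model, cohort, split[[monitor]], quiet = TRUE)
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = epoch, train_loss = epoch_loss / length(order_idx),
      monitor_score = ev$overall_score))
    if (ev$overall_score > best$score) {  # strict: ties keep earliest epoch
      best <- list(score = ev$overall_score, epoch = epoch,
                   flat = mil_params_flat(model))
    }
  }
  model <- mil_set_params(model, best$flat)
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 split = split, config = config, class_weights = cls_w),
            class = "mil_fit")
}

#' Predict slide-level outputs
#'
#' @param object a `mil_fit` or bare `mil_model`.
#' @param cohort a `mil_cohort`.
#' @param idx slide indices (default all).
#' @param ... unused.
#' @return a tibble with one row per slide: `slide_id`, class-1 probability
#'   `prob1_t` and predicted class `pred_t` per classification task, and
#'   `pred_expr_j` per regression task.
#' @export
predict.mil_fit <- function(object, cohort, idx = NULL, ...) {
  mil_predict(object$model, cohort, idx)
}

#' @rdname predict.mil_fit
#' @export
mil_predict <- function(object, cohort, idx = NULL) {
  model <- if (inherits(object, "mil_fit")) object$model else object
  if (is.null(idx)) idx <- seq_along(cohort$bags)
  rows <- lapply(idx, function(i) {
    fwd <- mil_forward(model, cohort$bags[[i]])
    row <- list(slide_id = cohort$labels$slide_id[i])
    for (t in seq_along(fwd$logits)) {
      z <- fwd$logits[[t]] - max(fwd$logits[[t]])
      p <- exp(z) / sum(exp(z))
      row[[paste0("prob1_", t)]] <- p[2]
      row[[paste0("pred_", t)]] <- which.max(p) - 1L
    }
    for (j in seq_along(fwd$yhat)) row[[paste0("pred_expr_", j)]] <- fwd$yhat[j]
    tibble::as_tibble(row)
  })
  dplyr::bind_rows(rows)
}

#' Evaluate a model on a slide subset
#'
#' Classification tasks are scored by one-vs-rest AUC on the class-1
#' (functional mutation) probability; regression tasks by the Spearman
#' correlation of predictions with targets. The overall score is the sum of
#' all task AUCs and correlations. A task whose evaluation labels take a
#' single value is skipped with a warning and excluded from the sum.
#'
#' @param model a `mil_model` or `mil_fit`.
#' @param cohort a `mil_cohort`.
#' @param idx slide indices to evaluate on.
#' @param quiet suppress skip warnings.
#' @return a list with `classification` (tibble: task, auc), `regression`
#'   (tibble: task, spearman) and `overall_score`.
#' @export
mil_evaluate <- function(model, cohort, idx, quiet = FALSE) {
  if (inherits(model, "mil_fit")) model <- model$model
  preds <- mil_predict(model, cohort, idx)
  labels <- cohort$labels[idx, ]
  mut_cols <- grep("^mut_", names(labels), value = TRUE)
  reg_cols <- grep("^expr_", names(labels), value = TRUE)
  cls_rows <- list(); reg_rows <- list()
  for (t in seq_along(mut_cols)) {
    y <- as.integer(labels[[mut_cols[t]]] == 1L)
    p <- preds[[paste0("prob1_", t)]]
    keep <- !is.na(y)
    if (length(unique(y[keep])) < 2) {
      if (!quiet) warning("classification task ", t,
                          " has one label value in the evaluation set; skipped")
      next
    }
    auc <- as.numeric(pROC::auc(y[keep], p[keep], quiet = TRUE,
                                direction = "<", levels = c(0, 1)))
    cls_rows[[t]] <- tibble::tibble(task = t, auc = auc)
  }
  for (j in seq_along(reg_cols)) {
    y <- labels[[reg_cols[j]]]
    p <- preds[[paste0("pred_expr_", j)]]
    keep <- !is.na(y)
    if (sum(keep) < 3 || stats::sd(y[keep]) == 0) {
      if (!quiet) warning("regression task ", j,
                          " is degenerate in the evaluation set; skipped")
      next
    }
    rho <- suppressWarnings(stats::cor(y[keep], p[keep], method = "spearman"))
    if (is.na(rho)) rho <- 0
    reg_rows[[j]] <- tibble::tibble(task = j, spearman = rho)
  }
  classification <- dplyr::bind_rows(cls_rows)
  regression <- dplyr::bind_rows(reg_rows)
  overall <- (if (nrow(classification)) sum(classification$auc) else 0) +
    (if (nrow(regression)) sum(regression$spearman) else 0)
  list(classification = classification, regression = regression,
       overall_score = overall)
}

#' @export
tidy.mil_fit <- function(x, ...) {
  ev <- mil_evaluate(x$model, ...)
  dplyr::bind_rows(
    dplyr::mutate(ev$classification, metric = "auc",
                  value = .data$auc, .keep = "unused"),
    dplyr::mutate(ev$regression, metric = "spearman",
                  value = .data$spearman, .keep = "unused")
  )
}

#' @export
glance.mil_fit <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch,
                 epochs_run = nrow(x$history),
                 final_train_loss = if (nrow(x$history))
                   x$history$train_loss[nrow(x$history)] else NA_real_,
                 best_monitor_score = if (nrow(x$history))
                   max(x$history$monitor_score) else NA_real_)
}

#' Save / load a model checkpoint
#'
#' Single-file container: JSON header (dimensions, task counts, aggregation)
#' followed by the named parameter arrays as little-endian doubles in header
#' order.
#'
#' @param fit a `mil_fit` or `mil_model`.
#' @param path file path.
#' @return `save_mil_model` returns `path` invisibly; `load_mil_model`
#'   returns a `mil_model`.
#' @export
save_mil_model <- function(fit, path) {
  model <- if (inherits(fit, "mil_fit")) fit$model else fit
  flat <- mil_params_flat(model)
  header <- list(container = "patchseek-mil", version = 1L,
                 d_raw = model$d_raw, d_model = model$d_model,
                 n_cls = length(model$cls), n_reg = length(model$reg),
                 aggregation = model$aggregation,
                 params = lapply(flat, function(p)
                   if (is.matrix(p)) dim(p) else length(p)))
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("PSEEKMIL"), con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  for (p in flat) writeBin(as.numeric(p), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_mil_model
#' @export
load_mil_model <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, "PSEEKMIL")) stop("not a patchseek model checkpoint")
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  model <- init_mil_model(header$d_raw, header$d_model, header$n_cls,
                          header$n_reg, seed = 0L, header$aggregation)
  flat <- mil_params_flat(model)
  for (nm in names(header$params)) {
    shape <- header$params[[nm]]
    n <- prod(shape)
    vals <- readBin(con, "numeric", n, size = 8L, endian = "little")
    if (length(vals) != n) stop("truncated checkpoint")
    flat[[nm]] <- if (length(shape) == 2) matrix(vals, shape[1]) else
      if (n == 1) vals else vals
  }
  mil_set_params(model, flat)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
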