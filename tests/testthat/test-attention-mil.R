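test_that("gated attention weights are a stabilized softmax", {
  d <- 8
  params <- init_attention_params(d, seed = 3)
  # identical rows: uniform weights
  H <- matrix(rep(rnorm(d), 5), 5, d, byrow = TRUE)
  expect_equal(attention_scores(H, params), rep(1 / 5, 5))
  # W_a = 0: uniform weights regardless of H
  params0 <- params
  params0$W_a <- numeric(d); params0$b_a <- 0
  H2 <- matrix(rnorm(6 * d), 6)
  expect_equal(attention_scores(H2, params0), rep(1 / 6, 6))
  # empty bag is an error
  expect_error(attention_scores(matrix(numeric(0), 0, d), params), "at least")
  # softmax normalization over many random bags
  sums <- vapply(1:200, function(i) {
    set.seed(i)
    sum(attention_scores(matrix(rnorm(4 * d), 4), params))
  }, 0)
  expect_lt(max(abs(sums - 1)), 1e-9)
})

test_that("a 2-patch bag matches a direct transcription of the gate formula", {
  d <- 3
  params <- list(W_a = c(0.2, -0.5, 0.1), b_a = 0,
                 V_a = matrix(c(0.1, 0, -0.2, 0.3, 0.05, 0,
                                0, -0.1, 0.2), 3, byrow = TRUE),
                 b_v = numeric(3),
                 U_a = matrix(c(-0.1, 0.2, 0, 0, 0.1, 0.3,
                                0.2, 0, -0.1), 3, byrow = TRUE),
                 b_u = numeric(3))
  H <- matrix(c(1, 0.5, -1, -0.2, 0.8, 0.3), 2, 3, byrow = TRUE)
  # independent evaluation of the tanh/sigmoid/softmax chain, per patch
  logit_of <- function(h) {
    t_n <- tanh(params$V_a %*% h)
    g_n <- 1 / (1 + exp(-params$U_a %*% h))
    sum(params$W_a * (t_n * g_n))
  }
  a <- c(logit_of(H[1, ]), logit_of(H[2, ]))
  expected <- exp(a - max(a)) / sum(exp(a - max(a)))
  expect_equal(attention_scores(H, params), expected, tolerance = 1e-12)
})

test_that("bag aggregation is a convex combination of rows", {
  H <- matrix(rnorm(12), 4, 3)
  # single row: returned as is
  expect_equal(aggregate_bag(H[1, , drop = FALSE], 1), H[1, ])
  # uniform weights: arithmetic mean, equal to mean_pool
  expect_equal(aggregate_bag(H, rep(0.25, 4)), colMeans(H))
  expect_equal(mean_pool(H), colMeans(H))
  # convex hull: every coordinate between column min and max
  s <- runif(4); s <- s / sum(s)
  agg <- aggregate_bag(H, s)
  expect_true(all(agg >= apply(H, 2, min) - 1e-12))
  expect_true(all(agg <= apply(H, 2, max) + 1e-12))
  expect_error(aggregate_bag(H, c(0.5, 0.5)), "mismatch")
  # 2x2 hand-computed means
  expect_equal(mean_pool(matrix(c(1, 3, 2, 8), 2)), c(2, 5))
})

test_that("class weights are inverse frequencies and fail on absent classes", {
  expect_equal(class_weights(c(0, 0, 1, 1, 2, 2)), c(3, 3, 3))
  expect_equal(class_weights(rep(c(0L, 0L, 1L, 2L), 25)), c(2, 4, 4))
  expect_error(class_weights(c(0, 0, 1)), "absent")
})

test_that("total loss sums weighted CE and MSE with missing-label masking", {
  w <- list(c(1, 1, 1))
  # perfect prediction: loss 0 (CE of a near-one-hot prediction tends to 0)
  perfect <- list(logits = list(c(-1e3, 1e3, -1e3)), yhat = 2)
  lab <- list(classes = 1L, targets = 2)
  expect_equal(total_loss(perfect, lab, w), 0)
  # one regression task, yhat 2 vs y 0: contribution 4
  pr <- list(logits = list(), yhat = 2)
  expect_equal(total_loss(pr, list(classes = integer(0), targets = 0), list()), 4)
  # two-task case equals the independent per-term computation
  logits <- c(0.3, -0.2, 0.1)
  wts <- list(c(2, 4, 4))
  p <- exp(logits) / sum(exp(logits))
  expected <- -4 * log(p[2]) + (1.5 - 0.5)^2
  got <- total_loss(list(logits = list(logits), yhat = 1.5),
                    list(classes = 1L, targets = 0.5), wts)
  expect_equal(got, expected, tolerance = 1e-12)
  # masked labels contribute zero
  got_masked <- total_loss(list(logits = list(logits), yhat = 1.5),
                           list(classes = NA_integer_, targets = NA_real_), wts)
  expect_equal(got_masked, 0)
  # non-finite target not marked missing is an error
  expect_error(total_loss(list(logits = list(), yhat = 1),
                          list(classes = integer(0), targets = Inf), list()),
               "non-finite")
})

test_that("patient-level splits respect sizes, grouping and label constraints", {
  co <- gen_mil_cohort(mil_cohort_spec(n_patients = 10, patches_per_slide = 4,
                                       d_raw = 4, seed = 31))
  sp <- split_cohort(co, seed = 2)
  expect_equal(lengths(sp)[["train"]], 8L)
  expect_equal(lengths(sp)[["val"]], 1L)
  expect_equal(lengths(sp)[["test"]], 1L)
  expect_equal(sort(unname(unlist(sp))), 1:10)
  # every partition has a positive (class 1) label
  for (part in sp) expect_true(any(co$labels$mut_1[part] == 1L))
  # fixed seed: identical partition across runs
  expect_identical(split_cohort(co, seed = 2), sp)
  # multi-slide patients stay together
  co2 <- co
  co2$labels$patient_id <- rep(sprintf("P%02d", 1:5), each = 2)
  sp2 <- split_cohort(co2, fractions = c(0.6, 0.2, 0.2), seed = 3)
  for (part in sp2) {
    pats <- co2$labels$patient_id[part]
    expect_true(all(table(co2$labels$patient_id)[unique(pats)] ==
                    table(pats)[unique(pats)]))
  }
})

test_that("model outputs are invariant to bag permutation", {
  co <- gen_mil_cohort(mil_cohort_spec(n_patients = 12, patches_per_slide = 8,
                                       d_raw = 6, effect_size = 2, seed = 41))
  model <- patchseek:::init_mil_model(6, 8, 1, 1, seed = 1)
  X <- co$bags[[1]]
  fwd <- patchseek:::mil_forward(model, X)
  set.seed(5)
  perm <- sample(nrow(X))
  fwd_p <- patchseek:::mil_forward(model, X[perm, ])
  expect_equal(fwd_p$hbar, fwd$hbar, tolerance = 1e-12)
  expect_equal(fwd_p$logits, fwd$logits, tolerance = 1e-12)
  expect_equal(fwd_p$yhat, fwd$yhat, tolerance = 1e-12)
  expect_equal(fwd_p$s, fwd$s[perm], tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on a tiny model", {
  set.seed(7)
  d_raw <- 4; d_model <- 3
  model <- patchseek:::init_mil_model(d_raw, d_model, 1, 1, seed = 2)
  X <- matrix(rnorm(5 * d_raw), 5)
  classes <- 1L; targets <- 0.7
  w <- list(c(1.5, 2, 3))
  loss_of <- function(m) {
    fwd <- patchseek:::mil_forward(m, X)
    total_loss(list(logits = fwd$logits, yhat = fwd$yhat),
               list(classes = classes, targets = targets), w)
  }
  fwd <- patchseek:::mil_forward(model, X)
  g <- patchseek:::grads_flat(
    patchseek:::mil_backward(model, X, fwd, classes, targets, w), model)
  flat <- patchseek:::mil_params_flat(model)
  eps <- 1e-6
  for (nm in c("W_p", "attn.W_a", "attn.V_a", "attn.U_a", "cls1.W", "reg1.w",
               "attn.b_a", "b_p")) {
    p <- flat[[nm]]
    idx <- if (length(p) > 3) c(1, length(p)) else seq_along(p)
    for (i in idx) {
      fp <- flat; fp[[nm]][i] <- fp[[nm]][i] + eps
      fm <- flat; fm[[nm]][i] <- fm[[nm]][i] - eps
      num <- (loss_of(patchseek:::mil_set_params(model, fp)) -
              loss_of(patchseek:::mil_set_params(model, fm))) / (2 * eps)
      expect_equal(as.vector(g[[nm]])[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training loss decreases over the first epochs on planted data", {
  co <- gen_mil_cohort(mil_cohort_spec(n_patients = 40, patches_per_slide = 8,
                                       d_raw = 8, effect_size = 3,
                                       signal_fraction = 0.5, seed = 51))
  fit <- mil_train(co, mil_train_config(lr = 1e-3, epochs = 5, d_model = 8,
                                        seed = 1))
  expect_lt(fit$history$train_loss[5], fit$history$train_loss[1])
  # zero epochs returns the initialized model unchanged
  fit0 <- mil_train(co, mil_train_config(epochs = 0, d_model = 8, seed = 9))
  ref <- patchseek:::init_mil_model(8, 8, 1, 1, seed = 9)
  expect_equal(patchseek:::mil_params_flat(fit0$model),
               patchseek:::mil_params_flat(ref))
})

test_that("evaluation scores perfect predictions at their ceilings", {
  co <- gen_mil_cohort(mil_cohort_spec(n_patients = 30, patches_per_slide = 6,
                                       d_raw = 6, effect_size = 5,
                                       signal_fraction = 1, seed = 61))
  # degenerate eval subset (one label value) is skipped with a warning
  idx_single <- which(co$labels$mut_1 == 0L)[1:3]
  model <- patchseek:::init_mil_model(6, 8, 1, 1, seed = 1)
  expect_warning(mil_evaluate(model, co, idx_single), "skipped")
  # predictions equal to targets give Spearman 1 per regression task
  expect_equal(suppressWarnings(cor(1:10, 1:10, method = "spearman")), 1)
})

test_that("model checkpoints round-trip through the container format", {
  co <- gen_mil_cohort(mil_cohort_spec(n_patients = 12, patches_per_slide = 4,
                                       d_raw = 4, seed = 71))
  fit <- mil_train(co, mil_train_config(lr = 1e-3, epochs = 2, d_model = 6,
                                        seed = 1))
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_mil_model(fit, path)
  back <- load_mil_model(path)
  expect_equal(patchseek:::mil_params_flat(back),
               patchseek:::mil_params_flat(fit$model))
  p1 <- mil_predict(fit, co)
  p2 <- mil_predict(back, co)
  expect_equal(p2, p1)
})
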