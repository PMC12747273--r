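test_that("gen_slide rasterizes regions against a pixel-counting oracle", {
  # zero regions: no tissue at all
  empty <- gen_slide(slide_spec(64, 64, list(), noise_sd = 0, seed = 1))
  expect_equal(sum(empty$mask), 0)
  expect_true(all(empty$label_map == 0L))

  # one disc, no noise: mask area equals the count of pixels satisfying the
  # disc inequality, computed independently here
  spec <- slide_spec(300, 300,
                     list(list(shape = "disc", center = c(150, 150),
                               radius_px = 100, class_label = 2L)),
                     noise_sd = 0, seed = 1)
  sl <- gen_slide(spec)
  oracle_area <- sum(outer(seq_len(300), seq_len(300), function(y, x)
    (x - 150)^2 + (y - 150)^2 <= 100^2))
  expect_identical(sum(sl$mask), oracle_area)
  expect_true(all(sl$label_map[sl$mask] == 2L))

  # determinism: same spec, same seed, bit-identical output
  spec2 <- slide_spec(100, 100,
                      list(list(shape = "disc", center = c(50, 50),
                                radius_px = 20, class_label = 1L)),
                      noise_sd = 0.05, seed = 42)
  expect_identical(gen_slide(spec2), gen_slide(spec2))

  # conflicting overlapping labels are an error
  bad <- slide_spec(200, 200,
                    list(list(shape = "disc", center = c(90, 100),
                              radius_px = 40, class_label = 1L),
                         list(shape = "disc", center = c(110, 100),
                              radius_px = 40, class_label = 2L)),
                    seed = 1)
  expect_error(gen_slide(bad), "conflicting")
})

test_that("MIL cohort generator plants recoverable signal and honest nulls", {
  # large effect, half the patches shifted: closed-form linear probe on the
  # mean-pooled bags separates class 1 from the rest perfectly
  spec <- mil_cohort_spec(n_patients = 200, patches_per_slide = 16,
                          d_raw = 16, signal_fraction = 0.5, effect_size = 5,
                          seed = 7)
  co <- gen_mil_cohort(spec)
  pooled <- t(vapply(co$bags, colMeans, numeric(16)))
  y <- co$labels$mut_1 == 1L
  lda <- MASS::lda(pooled, grouping = y)
  pred <- predict(lda, pooled)$class
  expect_equal(mean(pred == y), 1.0)

  # zero effect: a fixed linear probe scores at chance over seeds
  aucs <- vapply(1:20, function(s) {
    co0 <- gen_mil_cohort(mil_cohort_spec(
      n_patients = 60, patches_per_slide = 8, d_raw = 8,
      signal_fraction = 0.5, effect_size = 0, seed = 1000 + s))
    pooled0 <- t(vapply(co0$bags, colMeans, numeric(8)))
    score <- pooled0 %*% rep(1, 8)  # fixed probe
    y0 <- as.integer(co0$labels$mut_1 == 1L)
    as.numeric(pROC::auc(y0, as.vector(score), quiet = TRUE,
                         direction = "<", levels = c(0, 1)))
  }, 0)
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)

  # unsatisfiable signal fraction is an error
  expect_error(mil_cohort_spec(n_patients = 10, patches_per_slide = 4,
                               d_raw = 8, signal_fraction = 0.1),
               "signal_fraction")
})

test_that("ST profile generator hits planted Cohen's d and calibrates nulls", {
  # planted d = 2 recovered within a Monte-Carlo band
  d_hat <- vapply(1:20, function(s) {
    pr <- gen_st_profile(st_profile_spec(
      n_spots = 400, n_genes = 5, n_clusters = 4,
      de_genes = list(list(gene_idx = 1, cluster_idx = 3,
                           cohens_d_target = 2.0)),
      seed = 2000 + s))
    expr <- log1p(as.matrix(pr$counts))[1, ]
    inside <- pr$true_clusters == 3
    sp <- sqrt(((sum(inside) - 1) * var(expr[inside]) +
                (sum(!inside) - 1) * var(expr[!inside])) /
               (length(expr) - 2))
    (mean(expr[inside]) - mean(expr[!inside])) / sp
  }, 0)
  expect_true(all(d_hat > 1.5 & d_hat < 2.5))

  # no planted effects: raw p < 0.05 at about the nominal rate
  rates <- vapply(1:10, function(s) {
    pr <- gen_st_profile(st_profile_spec(n_spots = 120, n_genes = 40,
                                         n_clusters = 4, seed = 3000 + s))
    st <- gene_cluster_stats(pr$counts, pr$true_clusters)
    mean(st$p_value < 0.05)
  }, 0)
  expect_lt(abs(mean(rates) - 0.05), 0.03)

  # degenerate spec: d target with zero baseline SD is undefined
  expect_error(st_profile_spec(n_spots = 50, n_genes = 2, baseline_sd = 0,
                               de_genes = list(list(gene_idx = 1,
                                                    cluster_idx = 1,
                                                    cohens_d_target = 1))),
               "undefined")
})

test_that("expression label construction follows the log2/center/median rules", {
  genes <- c("CD8A", "CD8B", "GZMA", "GZMB", "PRF1", "g6", "g7", "g8")
  # FPKM = 0 everywhere: all values and set means are 0
  zero <- matrix(0, 8, 4, dimnames = list(genes, paste0("s", 1:4)))
  lbl0 <- build_expression_labels(zero, list(setA = c("g6", "g7")),
                                  ctl_genes = genes[1:5])
  expect_true(all(lbl0$setA == 0))
  expect_true(all(lbl0$CTL == 0))

  # FPKM = 1 gives log2(2) = 1 before centering; centering by all samples
  # removes it again
  one <- matrix(1, 8, 4, dimnames = list(genes, paste0("s", 1:4)))
  expect_true(all(log2(one + 1) == 1))
  lbl1 <- build_expression_labels(one, list(setA = c("g6", "g7")), genes[1:5])
  expect_true(all(lbl1$setA == 0))

  # direct arithmetic: centered values {1,2,3} -> set mean 2;
  # ctl {0,0,1,2,5} -> median 1. Construct via normal samples at zero.
  m <- matrix(0, 8, 2, dimnames = list(genes, c("tumor", "normal")))
  m[, "tumor"] <- 2^c(0, 0, 1, 2, 5, 1, 2, 3) - 1  # log2(x+1) gives these
  lbl <- build_expression_labels(m, list(setA = c("g6", "g7", "g8")),
                                 ctl_genes = genes[1:5],
                                 normal_samples = "normal")
  expect_equal(lbl$setA[1], 2)
  expect_equal(lbl$CTL[1], 1)

  expect_error(build_expression_labels(m, list(setA = character(0)),
                                       genes[1:5]), "empty gene set")
})

test_that("majority-area patch labels follow the smallest-id tie rule", {
  mask <- matrix(0L, 40, 40)
  mask[1:40, 1:40] <- 3L
  expect_identical(label_patch_by_majority_area(mask, c(0, 0, 20)), 3L)

  # 60/40 split inside the box
  mask2 <- matrix(0L, 20, 20)
  mask2[, 1:12] <- 5L
  mask2[, 13:20] <- 2L
  expect_identical(label_patch_by_majority_area(mask2, c(0, 0, 20)), 5L)

  # exact 50/50 tie: smallest label id wins
  mask3 <- matrix(0L, 20, 20)
  mask3[, 1:10] <- 7L
  mask3[, 11:20] <- 4L
  expect_identical(label_patch_by_majority_area(mask3, c(0, 0, 20)), 4L)

  # fully unlabeled box
  expect_identical(label_patch_by_majority_area(matrix(0L, 10, 10),
                                                c(0, 0, 10)), "unlabeled")
})

test_that("generators are bit-reproducible and substreams are independent", {
  s1 <- mil_cohort_spec(n_patients = 10, patches_per_slide = 4, d_raw = 4,
                        seed = 5)
  expect_identical(gen_mil_cohort(s1), gen_mil_cohort(s1))
  p1 <- st_profile_spec(n_spots = 30, n_genes = 5, n_clusters = 3, seed = 5)
  expect_identical(gen_st_profile(p1), gen_st_profile(p1))
  # ST MTX/TSV round trip preserves counts and spot table
  pr <- gen_st_profile(p1)
  dir <- withr::local_tempdir()
  write_st_profile(pr, dir)
  back <- read_st_profile(dir)
  expect_equal(as.matrix(back$counts), as.matrix(pr$counts))
  expect_equal(back$spots$x_px, pr$spots$x_px)
  expect_equal(back$mpp, pr$mpp)
})
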