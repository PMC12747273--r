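test_that("BH q-values match an independent step-up implementation", {
  # worked example: {0.01, 0.02, 0.03, 0.04} -> all 0.04
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # single p: q = p; all ones stay 1
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # NaN propagates as NA without affecting the rest
  q <- bh_fdr(c(0.01, NaN, 0.5))
  expect_true(is.na(q[2]))
  expect_false(anyNA(q[c(1, 3)]))
  # 1000 random vectors against the cummin-from-the-right oracle
  set.seed(2)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 2)), "0, 1")
})

test_that("Cohen's d uses the pooled SD and matches hand arithmetic", {
  # in {0,0,1,1} vs out {1,1,2,2}: pooled SD sqrt(1/3), d = -1.732
  counts <- matrix(expm1(c(0, 0, 1, 1, 1, 1, 2, 2)), 1)
  rownames(counts) <- "g1"
  labels <- rep(c(1L, 2L), each = 4)
  st <- gene_cluster_stats(counts, labels, min_group = 2)
  d_in1 <- st$cohens_d[st$cluster_id == 1]
  expect_equal(d_in1, -1 / sqrt(1 / 3), tolerance = 1e-6)
  expect_equal(d_in1, -1.732, tolerance = 1e-3)
  # invariance: adding a constant to all of a gene's expression leaves d and
  # the rank-sum p unchanged (shift on the log1p scale)
  base <- matrix(expm1(abs(rnorm(40)) + 1), 2, 20)
  rownames(base) <- c("gA", "gB")
  cl <- rep(1:2, 10)
  s1 <- gene_cluster_stats(base, cl)
  shifted <- expm1(log1p(base) + 3)
  s2 <- gene_cluster_stats(shifted, cl)
  expect_equal(s2$cohens_d, s1$cohens_d, tolerance = 1e-9)
  expect_equal(s2$p_value, s1$p_value, tolerance = 1e-9)
  # spot-order invariance
  perm <- sample(20)
  s3 <- gene_cluster_stats(base[, perm], cl[perm])
  expect_equal(dplyr::arrange(s3, cluster_id, gene),
               dplyr::arrange(s1, cluster_id, gene), tolerance = 1e-9)
})

test_that("zero pooled SD yields NaN d excluded from gene queries", {
  counts <- matrix(c(rep(expm1(1), 10), 0:9), 2, 10, byrow = TRUE)
  rownames(counts) <- c("flat", "ok")
  st <- gene_cluster_stats(counts, rep(1:2, 5))
  expect_true(all(is.nan(st$cohens_d[st$gene == "flat"])))
  hits <- suppressMessages(query_gene("flat", st, d_min = -Inf, q_max = 1.1))
  expect_equal(nrow(hits), 0)
})

test_that("spot clustering recovers well-separated planted clusters", {
  pr <- gen_st_profile(st_profile_spec(n_spots = 160, n_genes = 3,
                                       n_clusters = 4, cluster_sep = 20,
                                       seed = 81))
  got <- cluster_spots(pr$spot_embeddings, k = 4, seed = 1)
  expect_equal(mclust::adjustedRandIndex(got, pr$true_clusters), 1.0)
  # same seed: identical labels
  expect_identical(cluster_spots(pr$spot_embeddings, k = 4, seed = 1), got)
  # degenerate identical embeddings: single occupied cluster with a warning
  flat <- matrix(rep(c(1, 0, 0, 0), 20), 20, 4, byrow = TRUE)
  expect_warning(cl <- cluster_spots(flat, k = 3, seed = 1), "empty")
  expect_equal(length(unique(cl)), 1)
  expect_error(cluster_spots(flat[1:2, ], k = 3), "at least")
})

test_that("planted (gene, cluster, d) triples survive the full pipeline", {
  hits <- vapply(1:20, function(s) {
    pr <- gen_st_profile(st_profile_spec(
      n_spots = 400, n_genes = 30, n_clusters = 8, cluster_sep = 20,
      de_genes = list(list(gene_idx = 5, cluster_idx = 3,
                           cohens_d_target = 2.0)),
      seed = 9000 + s))
    cl <- cluster_spots(pr$spot_embeddings, k = 8, seed = 1)
    st <- gene_cluster_stats(pr$counts, cl, profile_id = pr$profile_id)
    res <- query_gene("gene_0005", st)
    nrow(res) >= 1
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("fully null profiles control the false discovery rate", {
  fracs <- vapply(1:15, function(s) {
    pr <- gen_st_profile(st_profile_spec(n_spots = 160, n_genes = 30,
                                         n_clusters = 4, seed = 9500 + s))
    st <- gene_cluster_stats(pr$counts, pr$true_clusters)
    mean(st$q_value < 0.05, na.rm = TRUE)
  }, 0)
  expect_lte(mean(fracs), 0.05)
  # under the null, query_gene at default thresholds is almost always empty
  empty <- vapply(1:10, function(s) {
    pr <- gen_st_profile(st_profile_spec(n_spots = 160, n_genes = 30,
                                         n_clusters = 4, seed = 9700 + s))
    st <- gene_cluster_stats(pr$counts, pr$true_clusters)
    all(vapply(paste0("gene_", sprintf("%04d", 1:30)), function(g)
      nrow(suppressMessages(query_gene(g, st))) == 0, NA))
  }, NA)
  expect_gte(mean(empty), 0.9)
  # d_min = Inf: always empty
  pr <- gen_st_profile(st_profile_spec(n_spots = 80, n_genes = 5,
                                       n_clusters = 4, seed = 1))
  st <- gene_cluster_stats(pr$counts, pr$true_clusters)
  expect_equal(nrow(query_gene("gene_0001", st, d_min = Inf)), 0)
})

test_that("matched-spot expression applies the detection filter and ranking", {
  pr <- gen_st_profile(st_profile_spec(n_spots = 40, n_genes = 10,
                                       n_clusters = 2, seed = 91))
  spot_ids <- pr$spots$spot_id[1:10]
  # plant a gene detected in exactly 70% of the matched spots
  counts <- as.matrix(pr$counts)
  counts["gene_0001", ] <- 0
  counts["gene_0001", pr$spots$spot_id[1:7]] <- 5
  tab <- matched_spot_expression(spot_ids, modifyList(pr, list(
    counts = Matrix::Matrix(counts, sparse = TRUE,
                            dimnames = dimnames(counts)))),
    detect_frac = 0.75)
  expect_false("gene_0001" %in% tab$gene)
  # all genes detected everywhere: ranking equals ordering by mean log1p
  dense <- matrix(rpois(5 * 10, 20) + 1, 5, 10,
                  dimnames = list(paste0("g", 1:5), pr$spots$spot_id[1:10]))
  pr2 <- modifyList(pr, list(counts = Matrix::Matrix(dense, sparse = TRUE)))
  tab2 <- matched_spot_expression(spot_ids, pr2, detect_frac = 0.75)
  expect_equal(tab2$gene, names(sort(rowMeans(log1p(dense)),
                                     decreasing = TRUE)))
  # single spot: detection is 0/1 per gene
  tab3 <- matched_spot_expression(pr$spots$spot_id[1], pr2, detect_frac = 0.75)
  expect_true(all(tab3$detect_frac %in% c(0, 1)))
  expect_error(matched_spot_expression("nope", pr2), "no hits")
})

test_that("GSEA running sum behaves at its analytic anchors", {
  scores <- setNames(seq(10, 1), paste0("g", 1:10))
  # set = the top |set| genes: ES = 1 and p at the permutation floor
  res <- gsea(scores, paste0("g", 1:3), n_perm = 200, seed = 1)
  expect_equal(res$es, 1)
  expect_lte(res$p_value, 0.05)
  # hand-computed small case: set {g1, g4} in a 5-gene ranking
  s5 <- setNames(5:1, paste0("g", 1:5))
  r5 <- gsea(s5, c("g1", "g4"), n_perm = 10, seed = 1)
  # running sum: +1/2, -1/3, -1/3, +1/2, -1/3 -> cumulative max at 1/2
  expect_equal(r5$es, 0.5)
  # degenerate set covering all genes is an error
  expect_error(gsea(s5, paste0("g", 1:5)), "degenerate")
  expect_error(gsea(s5, c("zz")), "intersect")
})

test_that("GSEA p-values are near-uniform for random gene sets", {
  set.seed(3)
  scores <- setNames(rnorm(100), paste0("g", 1:100))
  ps <- vapply(1:300, function(i) {
    set.seed(i)
    gs <- sample(names(scores), 10)
    gsea(scores, gs, n_perm = 99, seed = 5000 + i)$p_value
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})
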