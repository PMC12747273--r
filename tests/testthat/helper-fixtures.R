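# Shared fixtures, built in code at test time.

# Random unit vectors, reproducible.
rand_unit <- function(n, d, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(n * d), n)
  m / sqrt(rowSums(m^2))
}

# A one-disc synthetic slide spec used across patching tests.
disc_slide <- function(seed = 3L, radius = 150, size = 512) {
  slide_spec(size, size,
             list(list(shape = "disc", center = c(size / 2, size / 2),
                       radius_px = radius, class_label = 1L)),
             seed = seed)
}

# Brute-force recall@K of an approximate search against the exact oracle.
recall_at_k <- function(exact_handle, approx_handle, emb, query_ids, K = 10L,
                        ...) {
  mean(vapply(query_ids, function(i) {
    truth <- index_search(exact_handle, emb[i, ], K = K)$item_id
    got <- index_search(approx_handle, emb[i, ], K = K, ...)$item_id
    length(intersect(truth, got)) / K
  }, 0))
}

# Independent step-up BH transcription (sort, p*(m/i), cummin from the right)
# used as the oracle for bh_fdr.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}
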