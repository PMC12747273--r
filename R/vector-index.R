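#' Build an exact brute-force index
#'
#' Stores the raw unit-norm vectors; search computes every Euclidean distance
#' and sorts. This backend is the oracle against which the approximate
#' backends (IVF-PQ, ITQ-LSH) are measured.
#'
#' @param embeddings numeric N x D matrix with unit-norm rows (tolerance
#'   1e-6).
#' @param meta optional tibble of per-item patch references.
#' @return an `patchseek_index` handle with `backend = "exact"`.
#' @export
build_exact <- function(embeddings, meta = NULL) {
  emb <- as.matrix(embeddings)
  if (is.null(meta)) meta <- attr(embeddings, "meta")
  norms <- sqrt(rowSums(emb^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("exact index requires unit-norm rows; call unit_normalize() first")
  }
  structure(list(backend = "exact", D = ncol(emb), n_items = nrow(emb),
                 params = list(), vectors = emb, item_meta = meta),
            class = "patchseek_index")
}

#' Train product-quantization codebooks
#'
#' Splits the D-dimensional space into `m` contiguous sub-spaces of equal
#' size and learns `ksub` k-means centroids per sub-space. A vector is coded
#' as the `m` nearest-centroid ids; with `ksub <= 256` each id fits one byte,
#' so an 8-sub-quantizer code occupies 8 bytes. When `ksub` reaches the
#' number of distinct training rows the codebook becomes lossless.
#'
#' @param embeddings numeric N x D matrix; D must be divisible by `m`.
#' @param m number of sub-quantizers.
#' @param ksub centroids per sub-space; must not exceed N.
#' @param seed k-means seed.
#' @return a `pq_codebooks` list: `m`, `dsub`, `ksub`, `centroids` (list of
#'   ksub x dsub matrices).
#' @export
train_pq <- function(embeddings, m, ksub, seed = 1L) {
  x <- as.matrix(embeddings)
  D <- ncol(x)
  if (D %% m != 0) stop("D (", D, ") must be divisible by m (", m, ")")
  if (ksub > nrow(x)) stop("ksub (", ksub, ") exceeds the number of items")
  dsub <- D %/% m
  centroids <- lapply(seq_len(m), function(b) {
    sub <- x[, ((b - 1) * dsub + 1):(b * dsub), drop = FALSE]
    uniq <- unique(sub)
    if (ksub >= nrow(uniq)) {
      uniq  # lossless: every distinct sub-vector is its own centroid
    } else {
      kmeans_pp(sub, ksub, seed = substream_seed(seed, paste0("pq_", b)))$centers
    }
  })
  structure(list(m = m, dsub = dsub, ksub = ksub, centroids = centroids),
            class = "pq_codebooks")
}

#' Encode vectors with trained PQ codebooks
#'
#' @param embeddings numeric N x D matrix.
#' @param codebooks a [train_pq()] result.
#' @return integer N x m matrix of 1-based centroid ids.
#' @export
encode_pq <- function(embeddings, codebooks) {
  x <- as.matrix(embeddings)
  dsub <- codebooks$dsub
  codes <- matrix(0L, nrow(x), codebooks$m)
  for (b in seq_len(codebooks$m)) {
    sub <- x[, ((b - 1) * dsub + 1):(b * dsub), drop = FALSE]
    d2 <- cross_sqdist(sub, codebooks$centroids[[b]])
    codes[, b] <- max.col(-d2, ties.method = "first")
  }
  codes
}

# Asymmetric-distance lookup tables for one query: list of m vectors of
# squared distances from the query sub-vector to every centroid.
adc_tables <- function(query, codebooks) {
  dsub <- codebooks$dsub
  lapply(seq_len(codebooks$m), function(b) {
    q <- query[((b - 1) * dsub + 1):(b * dsub)]
    as.vector(cross_sqdist(matrix(q, 1), codebooks$centroids[[b]]))
  })
}

#' Asymmetric (ADC) distance between a query and PQ codes
#'
#' Sums, over sub-spaces, the squared distance from the query sub-vector to
#' the coded centroid, then takes the square root: the standard
#' asymmetric-distance computation of product quantization.
#'
#' @param query numeric length-D vector.
#' @param codes integer N x m code matrix (or length-m vector for one item).
#' @param codebooks a [train_pq()] result.
#' @return numeric vector of approximate Euclidean distances.
#' @export
adc_distance <- function(query, codes, codebooks) {
  if (is.vector(codes)) codes <- matrix(codes, 1)
  tabs <- adc_tables(query, codebooks)
  d2 <- numeric(nrow(codes))
  for (b in seq_len(codebooks$m)) {
    d2 <- d2 + tabs[[b]][codes[, b]]
  }
  sqrt(pmax(d2, 0))
}

#' Build an inverted-file product-quantization (IVF-PQ) index
#'
#' Coarse k-means partitions the items into `nlist` Voronoi cells, each with
#' an inverted list of its member ids. Residuals (item minus its coarse
#' centroid, the default) or raw vectors are PQ-encoded. At query time the
#' `nprobe` nearest coarse centroids are located by an exact centroid scan
#' (adequate at desk scale, where a navigable-graph accelerator over a few
#' hundred centroids buys nothing) and ADC distances are computed within
#' their lists only.
#'
#' @param embeddings unit-norm N x D matrix.
#' @param nlist number of inverted lists (coarse centroids); at most N.
#' @param m,ksub PQ parameters (see [train_pq()]).
#' @param seed k-means seed.
#' @param encode `"residual"` (default) or `"direct"`.
#' @param meta optional tibble of per-item patch references.
#' @return a `patchseek_index` handle with `backend = "ivfpq"`.
#' @export
build_ivfpq <- function(embeddings, nlist, m, ksub, seed = 1L,
                        encode = c("residual", "direct"), meta = NULL) {
  encode <- match.arg(encode)
  x <- as.matrix(embeddings)
  if (is.null(meta)) meta <- attr(embeddings, "meta")
  if (nlist > nrow(x)) stop("nlist exceeds the number of items")
  coarse <- kmeans_pp(x, nlist, seed = substream_seed(seed, "ivf_coarse"))
  assign <- coarse$cluster
  train_x <- if (encode == "residual") x - coarse$centers[assign, , drop = FALSE] else x
  codebooks <- train_pq(train_x, m, ksub, seed = substream_seed(seed, "ivf_pq"))
  codes <- encode_pq(train_x, codebooks)
  lists <- split(seq_len(nrow(x)), factor(assign, levels = seq_len(nlist)))
  structure(list(backend = "ivfpq", D = ncol(x), n_items = nrow(x),
                 params = list(nlist = nlist, m = m, ksub = ksub,
                               encode = encode, seed = seed),
                 centroids = coarse$centers, lists = lists,
                 codes = codes, codebooks = codebooks, item_meta = meta),
            class = "patchseek_index")
}

#' Train an ITQ binary-hashing model
#'
#' PCA reduces (or zero-pads) the centred data to `n_bits` dimensions, then
#' iterative quantization alternates between assigning binary codes
#' `B = sign(V R)` and solving the orthogonal-Procrustes rotation `R`
#' minimizing the quantization error `|B - V R|_F`; the error is
#' non-increasing across iterations by construction.
#'
#' @param embeddings numeric N x D matrix.
#' @param n_bits code length (32 or 64 in the reference setting).
#' @param n_iter alternations; must be >= 1.
#' @param seed rotation-initialization seed.
#' @return an `itq_model` list: `mean`, `pca` (D x n_bits), `rotation`
#'   (n_bits x n_bits), `n_bits`, `quant_errors` (per iteration).
#' @export
train_itq <- function(embeddings, n_bits = 64L, n_iter = 50L, seed = 1L) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  x <- as.matrix(embeddings)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  pc <- stats::prcomp(xc, center = FALSE)
  W <- pc$rotation
  if (ncol(W) < n_bits) {  # PCA padding with zero directions
    W <- cbind(W, matrix(0, nrow(W), n_bits - ncol(W)))
  }
  W <- W[, seq_len(n_bits), drop = FALSE]
  V <- xc %*% W
  R <- with_seed(substream_seed(seed, "itq_rot"),
                 qr.Q(qr(matrix(stats::rnorm(n_bits^2), n_bits))))
  errors <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    VR <- V %*% R
    B <- ifelse(VR >= 0, 1, -1)
    errors[it] <- sum((B - VR)^2)
    sv <- svd(crossprod(V, B))
    R <- sv$u %*% t(sv$v)
  }
  structure(list(mean = mu, pca = W, rotation = R, n_bits = as.integer(n_bits),
                 quant_errors = errors),
            class = "itq_model")
}

#' Encode vectors into ITQ binary codes
#'
#' @param embeddings numeric N x D matrix.
#' @param model a [train_itq()] result.
#' @return logical N x n_bits matrix (`TRUE` = bit set).
#' @export
encode_itq <- function(embeddings, model) {
  xc <- sweep(as.matrix(embeddings), 2, model$mean, "-")
  (xc %*% model$pca %*% model$rotation) >= 0
}

#' Hamming-distance search over binary codes
#'
#' @param query_code logical length-n_bits vector.
#' @param codes logical N x n_bits matrix.
#' @param K number of neighbours.
#' @return a tibble: `item_id`, `distance` (Hamming, ascending; ties by
#'   item id).
#' @export
search_hamming <- function(query_code, codes, K) {
  dist <- rowSums(codes != matrix(query_code, nrow(codes), length(query_code),
                                  byrow = TRUE))
  ord <- order(dist, seq_along(dist))[seq_len(min(K, length(dist)))]
  tibble::tibble(item_id = ord, distance = as.numeric(dist[ord]))
}

#' Build an ITQ-LSH binary index
#'
#' @param embeddings unit-norm N x D matrix.
#' @param n_bits code length.
#' @param n_iter ITQ iterations.
#' @param seed seed.
#' @param meta optional tibble of per-item patch references.
#' @return a `patchseek_index` handle with `backend = "itq_lsh"`.
#' @export
build_itq_lsh <- function(embeddings, n_bits = 64L, n_iter = 50L, seed = 1L,
                          meta = NULL) {
  x <- as.matrix(embeddings)
  if (is.null(meta)) meta <- attr(embeddings, "meta")
  model <- train_itq(x, n_bits = n_bits, n_iter = n_iter, seed = seed)
  codes <- encode_itq(x, model)
  structure(list(backend = "itq_lsh", D = ncol(x), n_items = nrow(x),
                 params = list(n_bits = n_bits, n_iter = n_iter, seed = seed),
                 model = model, codes = codes, item_meta = meta),
            class = "patchseek_index")
}

#' Search a vector index
#'
#' Dispatches on the index backend; all backends return distances in
#' ascending order with 1-based item ids into the indexed set.
#'
#' @param handle a `patchseek_index`.
#' @param query numeric length-D vector (unit-norm for meaningful results).
#' @param K neighbours to return.
#' @param nprobe (ivfpq only) number of coarse cells to probe; values above
#'   `nlist` are clamped with a warning.
#' @return a tibble: `item_id`, `distance`. Fewer than `K` rows are returned
#'   (with attribute `underfilled = TRUE`) when the probed lists hold fewer
#'   items.
#' @export
index_search <- function(handle, query, K = 5L, nprobe = 8L) {
  stopifnot(inherits(handle, "patchseek_index"))
  if (length(query) != handle$D) {
    stop("query dimension ", length(query), " does not match index (",
         handle$D, ")")
  }
  switch(handle$backend,
    exact = {
      d2 <- as.vector(cross_sqdist(matrix(query, 1), handle$vectors))
      ord <- order(d2, seq_along(d2))[seq_len(min(K, length(d2)))]
      tibble::tibble(item_id = ord, distance = sqrt(pmax(d2[ord], 0)))
    },
    ivfpq = {
      nlist <- handle$params$nlist
      if (nprobe > nlist) {
        warning("nprobe (", nprobe, ") clamped to nlist (", nlist, ")")
        nprobe <- nlist
      }
      cd2 <- as.vector(cross_sqdist(matrix(query, 1), handle$centroids))
      probes <- order(cd2, seq_along(cd2))[seq_len(nprobe)]
      ids <- integer(0); dists <- numeric(0)
      for (cell in probes) {
        members <- handle$lists[[cell]]
        if (length(members) == 0L) next
        q_eff <- if (handle$params$encode == "residual")
          query - handle$centroids[cell, ] else query
        d <- adc_distance(q_eff, handle$codes[members, , drop = FALSE],
                          handle$codebooks)
        ids <- c(ids, members); dists <- c(dists, d)
      }
      ord <- order(dists, ids)[seq_len(min(K, length(ids)))]
      out <- tibble::tibble(item_id = ids[ord], distance = dists[ord])
      if (nrow(out) < K) attr(out, "underfilled") <- TRUE
      out
    },
    itq_lsh = {
      qc <- encode_itq(matrix(query, 1), handle$model)[1, ]
      search_hamming(qc, handle$codes, K)
    },
    stop("unknown backend: ", handle$backend)
  )
}

#' Mosaic subsampling of an indexed patch set
#'
#' Selects the most representative patches of a slide before indexing:
#' k-means over the concatenation of z-scored features and z-scored spatial
#' coordinates; within each cluster, patches are ranked by ascending distance
#' to their cluster centroid and the top `fraction` kept (rounded up, at
#' least one per non-empty cluster). `fraction = 0.05` and `0.2` reproduce
#' the 5% and 20% mosaic regimes.
#'
#' @param embeddings numeric N x D feature matrix.
#' @param coords numeric N x 2 patch-centre coordinates.
#' @param fraction fraction kept per cluster, in (0, 1\].
#' @param n_clusters number of mosaic clusters.
#' @param seed k-means seed.
#' @return sorted integer vector of selected item ids.
#' @export
mosaic_select <- function(embeddings, coords, fraction = 0.2, n_clusters = 9L,
                          seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  x <- as.matrix(embeddings)
  n <- nrow(x)
  if (n_clusters > n) stop("n_clusters exceeds the number of items")
  zs <- function(m) {
    s <- apply(m, 2, stats::sd)
    s[s == 0] <- 1
    sweep(sweep(m, 2, colMeans(m), "-"), 2, s, "/")
  }
  feat <- cbind(zs(x), zs(as.matrix(coords)))
  km <- kmeans_pp(feat, n_clusters, seed = substream_seed(seed, "mosaic"))
  selected <- integer(0)
  for (cl in seq_len(n_clusters)) {
    members <- which(km$cluster == cl)
    if (length(members) == 0L) next
    d2 <- rowSums(sweep(feat[members, , drop = FALSE], 2,
                        km$centers[cl, ], "-")^2)
    keep <- max(1L, ceiling(fraction * length(members)))
    selected <- c(selected, members[order(d2, members)][seq_len(keep)])
  }
  sort(selected)
}

# Single most representative patch of a slide under the mosaic ranking:
# the patch nearest its own cluster centroid, globally.
mosaic_representative <- function(embeddings, coords, n_clusters = 9L,
                                  seed = 1L) {
  x <- as.matrix(embeddings)
  n_clusters <- min(n_clusters, nrow(x))
  zs <- function(m) {
    s <- apply(m, 2, stats::sd)
    s[s == 0] <- 1
    sweep(sweep(m, 2, colMeans(m), "-"), 2, s, "/")
  }
  feat <- cbind(zs(x), zs(as.matrix(coords)))
  km <- kmeans_pp(feat, n_clusters, seed = substream_seed(seed, "mosaic"))
  d2 <- rowSums((feat - km$centers[km$cluster, , drop = FALSE])^2)
  which.min(d2)
}
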