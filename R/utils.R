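#' @keywords internal
"_PACKAGE"

#' @importFrom stats kmeans median prcomp quantile rnorm runif sd setNames
#'   wilcox.test cor p.adjust ks.test
#' @importFrom utils head
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Counter-based seed substreams: one user-facing seed expands into independent
# per-component seeds, so adding a generator never perturbs the draws of
# another.  Seeds are kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- as.integer(charToRaw(as.character(component)))
  h <- as.numeric(seed) %% 2147483647
  for (c in codes) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Seeded k-means with k-means++ initialization
#'
#' All clustering inside the package goes through this helper: k-means++
#' seeding (deterministic under `seed`) followed by Lloyd iterations via
#' [stats::kmeans()], capped at 25 iterations. Assignment ties go to the
#' lowest centroid index (the behaviour of `max.col(..., "first")`).
#'
#' @param x numeric matrix, rows are observations.
#' @param k number of centers.
#' @param seed integer seed for the initialization.
#' @param iter_max maximum Lloyd iterations.
#' @param nstart number of independent seeded restarts; the solution with the
#'   lowest total within-cluster sum of squares is kept.
#' @return a list with `centers` (k x d matrix) and `cluster`
#'   (integer vector of 1-based assignments).
#' @export
kmeans_pp <- function(x, k, seed = 1L, iter_max = 25L, nstart = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds the number of rows (", n, ")")
  if (k == n) {
    return(list(centers = x, cluster = seq_len(n)))
  }
  if (nstart > 1L) {
    runs <- lapply(seq_len(nstart), function(r)
      kmeans_pp(x, k, seed = seed + (r - 1L) * 7919L, iter_max = iter_max))
    wss <- vapply(runs, function(rn)
      sum((x - rn$centers[rn$cluster, , drop = FALSE])^2), 0)
    return(runs[[which.min(wss)]])
  }
  centers_idx <- with_seed(seed, {
    idx <- integer(k)
    idx[1] <- sample.int(n, 1L)
    d2 <- rowSums(sweep(x, 2, x[idx[1], ], "-")^2)
    if (k > 1) {
      for (j in 2:k) {
        prob <- d2 / sum(d2)
        if (all(d2 == 0)) prob <- rep(1 / n, n)
        idx[j] <- sample.int(n, 1L, prob = prob)
        d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ], "-")^2))
      }
    }
    idx
  })
  init <- x[centers_idx, , drop = FALSE]
  # duplicate initial centers break stats::kmeans; jitter deterministically
  if (anyDuplicated(round(init, 12))) {
    init <- init + matrix(
      with_seed(seed + 1L, stats::rnorm(length(init), sd = 1e-6)),
      nrow(init)
    )
  }
  km <- suppressWarnings(
    stats::kmeans(x, centers = init, iter.max = iter_max, algorithm = "Lloyd")
  )
  list(centers = unname(km$centers), cluster = unname(km$cluster))
}

assert_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("expected an RGB raster: numeric array of dimension h x w x 3")
  }
  invisible(image)
}

# Pairwise squared Euclidean distances between rows of a and rows of b.
cross_sqdist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Block-mean downsample of a 2-D matrix by integer factor f (area averaging).
block_mean <- function(mat, f) {
  h <- nrow(mat) %/% f * f
  w <- ncol(mat) %/% f * f
  m <- mat[seq_len(h), seq_len(w), drop = FALSE]
  # average over f x f blocks
  m <- matrix(colMeans(matrix(m, nrow = f)), nrow = h %/% f)
  t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = w %/% f))
}

block_mean_rgb <- function(image, f) {
  assert_rgb(image)
  out <- vapply(
    seq_len(dim(image)[3]),
    function(ch) block_mean(image[, , ch], f),
    matrix(0, nrow(image) %/% f, ncol(image) %/% f)
  )
  out
}
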