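#' Encoder specification
#'
#' The engine is encoder-agnostic: any function mapping a list of equally
#' sized RGB patches to an N x d_raw matrix can serve as the backbone. A
#' deterministic toy histogram encoder ships with the package so every
#' downstream component runs without pretrained weights.
#'
#' @param kind `"toy_histogram"` or `"external"`.
#' @param d_raw output dimension of the backbone.
#' @param d_proj projected dimension used downstream (default 256).
#' @param seed seed of the toy encoder's fixed random projection.
#' @param fn for `kind = "external"`, the encoding function.
#' @return an object of class `encoder_spec`.
#' @export
encoder_spec <- function(kind = c("toy_histogram", "external"), d_raw = 32L,
                         d_proj = 256L, seed = 1L, fn = NULL) {
  kind <- match.arg(kind)
  stopifnot(d_proj >= 1, d_raw >= 1)
  if (kind == "external" && !is.function(fn)) {
    stop("external encoders require `fn`")
  }
  structure(list(kind = kind, d_raw = as.integer(d_raw),
                 d_proj = as.integer(d_proj), seed = as.integer(seed),
                 fn = fn),
            class = "encoder_spec")
}

# Per-patch raw descriptor of the toy encoder: per-channel 8-bin colour
# histograms (24 values) plus 4 texture summaries (mean and sd of the
# gradient magnitude along each axis).
toy_descriptor <- function(patch) {
  hist3 <- unlist(lapply(1:3, function(ch) {
    v <- as.vector(patch[, , ch])
    tabulate(pmin(8L, floor(v * 8) + 1L), nbins = 8L) / length(v)
  }))
  gray <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  gx <- abs(gray[, -1, drop = FALSE] - gray[, -ncol(gray), drop = FALSE])
  gy <- abs(gray[-1, , drop = FALSE] - gray[-nrow(gray), , drop = FALSE])
  sdx <- if (length(gx) > 1) stats::sd(gx) else 0
  sdy <- if (length(gy) > 1) stats::sd(gy) else 0
  c(hist3, mean(gx), sdx, mean(gy), sdy)
}

#' Encode patches into raw feature vectors
#'
#' Applies the backbone named by `spec` to every patch, producing an
#' N x d_raw matrix. The toy histogram encoder computes a 28-value colour /
#' texture descriptor per patch and passes it through a fixed, seeded random
#' projection to `d_raw`; it is fully deterministic under a fixed spec.
#'
#' @param patches list of equally sized h x w x 3 arrays.
#' @param spec an [encoder_spec()].
#' @return numeric N x d_raw matrix.
#' @export
encode_patches <- function(patches, spec = encoder_spec()) {
  stopifnot(inherits(spec, "encoder_spec"), length(patches) >= 1)
  dims <- vapply(patches, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("patches must share one size")
  }
  if (spec$kind == "external") {
    out <- spec$fn(patches)
    stopifnot(is.matrix(out), nrow(out) == length(patches))
    return(out)
  }
  desc <- t(vapply(patches, toy_descriptor, numeric(28)))
  proj <- with_seed(substream_seed(spec$seed, "toy_proj"),
                    matrix(stats::rnorm(28 * spec$d_raw, sd = 1 / sqrt(28)),
                           28, spec$d_raw))
  desc %*% proj
}

#' Affine projection of raw features
#'
#' Maps each row of the raw N x d_raw matrix through a single fully connected
#' layer, `x W + b`, producing the shared d_proj-dimensional space used by the
#' attention module and the index. With `weights = NULL` an identity(-padded
#' or -truncated) map is used, so the index can be exercised on raw features
#' when no trained model is supplied.
#'
#' @param raw numeric N x d_raw matrix.
#' @param weights d_raw x d_proj matrix, or `NULL` for identity padding.
#' @param bias length-d_proj vector (default zeros).
#' @param d_proj target dimension when `weights` is `NULL`.
#' @return numeric N x d_proj matrix.
#' @export
project <- function(raw, weights = NULL, bias = NULL, d_proj = ncol(raw)) {
  stopifnot(is.matrix(raw))
  if (is.null(weights)) {
    weights <- diag(1, nrow = ncol(raw), ncol = d_proj)
  }
  if (ncol(raw) != nrow(weights)) {
    stop("shape mismatch: raw has ", ncol(raw), " columns but weights expect ",
         nrow(weights))
  }
  if (is.null(bias)) bias <- numeric(ncol(weights))
  if (length(bias) != ncol(weights)) stop("bias length must equal d_proj")
  sweep(raw %*% weights, 2, bias, "+")
}

#' Scale feature vectors to unit length
#'
#' Divides every row by its Euclidean norm, preserving direction. On
#' unit-norm vectors the squared Euclidean distance and the cosine similarity
#' are linked by the identity `|u - v|^2 = 2 - 2 u.v`, so Euclidean and
#' cosine top-K neighbour lists coincide; all indexes in the package assume
#' this normalization.
#'
#' @param matrix numeric N x D matrix without all-zero rows.
#' @param meta optional tibble of patch references (one row per vector),
#'   attached as the `"meta"` attribute.
#' @return the row-normalized matrix, of class `embedding_matrix`.
#' @export
unit_normalize <- function(matrix, meta = NULL) {
  m <- as.matrix(matrix)
  norms <- sqrt(rowSums(m^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    stop("cannot normalize all-zero row(s): ", paste(zero, collapse = ", "))
  }
  if (any(!is.finite(m))) stop("non-finite entries in embedding matrix")
  out <- m / norms
  if (!is.null(meta)) {
    stopifnot(nrow(meta) == nrow(out))
    attr(out, "meta") <- meta
  }
  class(out) <- c("embedding_matrix", class(out))
  out
}

#' Persist / restore an embedding matrix
#'
#' Single-file binary container: a JSON header (dimensions, encoder kind,
#' patch-reference table) followed by the matrix as little-endian doubles,
#' row-major. The layout is documented in the header itself
#' (`layout = "json_header + float64 row-major"`).
#'
#' @param emb matrix (ideally an `embedding_matrix` carrying `meta`).
#' @param path file path.
#' @return `write_embeddings` returns `path` invisibly; `read_embeddings`
#'   returns the matrix with its `meta` attribute restored.
#' @export
write_embeddings <- function(emb, path) {
  meta <- attr(emb, "meta")
  header <- list(
    container = "patchseek-embeddings", version = 1L,
    layout = "json_header + float64 row-major",
    n = nrow(emb), d = ncol(emb),
    meta = if (is.null(meta)) NULL else as.data.frame(meta)
  )
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("PSEEKEMB"), con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  writeBin(as.numeric(t(emb)), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, "PSEEKEMB")) stop("not a patchseek embedding file")
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  vals <- readBin(con, "numeric", header$n * header$d, size = 8L,
                  endian = "little")
  if (length(vals) != header$n * header$d) stop("truncated embedding file")
  m <- matrix(vals, nrow = header$n, byrow = TRUE)
  if (!is.null(header$meta)) attr(m, "meta") <- tibble::as_tibble(header$meta)
  class(m) <- c("embedding_matrix", class(m))
  m
}
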