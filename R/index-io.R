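# Index persistence: one binary file per index, with a JSON header declaring
# the backend, parameters, item metadata and an ordered array directory
# (name, dims, storage type), followed by the raw arrays in directory order.
# Doubles are little-endian float64; integer/logical arrays are little-endian
# int32. The layout is self-describing for cross-language readers.

INDEX_MAGIC <- "PSEEKIDX"
INDEX_VERSION <- 1L

index_arrays <- function(handle) {
  switch(handle$backend,
    exact = list(vectors = handle$vectors),
    ivfpq = c(
      list(centroids = handle$centroids,
           codes = handle$codes,
           list_assign = {
             a <- integer(handle$n_items)
             for (cell in seq_along(handle$lists)) a[handle$lists[[cell]]] <- cell
             a
           }),
      stats::setNames(handle$codebooks$centroids,
                      paste0("codebook_", seq_along(handle$codebooks$centroids)))
    ),
    itq_lsh = list(mean = handle$model$mean, pca = handle$model$pca,
                   rotation = handle$model$rotation,
                   codes = handle$codes * 1L,
                   quant_errors = handle$model$quant_errors)
  )
}

#' Save / load a vector index
#'
#' Round trips restore search behaviour bit-identically: `load_index()`
#' rebuilds the handle from the on-disk arrays, and searching the restored
#' handle returns exactly the results of the original. A version mismatch or
#' a truncated file is an error, not a crash.
#'
#' @param handle a `patchseek_index`.
#' @param path file path.
#' @return `save_index` returns `path` invisibly; `load_index` returns the
#'   restored `patchseek_index`.
#' @export
save_index <- function(handle, path) {
  stopifnot(inherits(handle, "patchseek_index"))
  arrays <- index_arrays(handle)
  atype <- vapply(arrays, function(a)
    if (is.double(a)) "float64" else "int32", "")
  header <- list(
    container = "patchseek-index", version = INDEX_VERSION,
    backend = handle$backend, D = handle$D, n_items = handle$n_items,
    params = handle$params,
    item_meta = if (is.null(handle$item_meta)) NULL else
      as.data.frame(handle$item_meta),
    arrays = lapply(names(arrays), function(nm) list(
      name = nm,
      dims = if (is.matrix(arrays[[nm]])) dim(arrays[[nm]]) else
        length(arrays[[nm]]),
      type = atype[[nm]]))
  )
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(INDEX_MAGIC), con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  for (a in arrays) {
    if (is.double(a)) {
      writeBin(as.numeric(a), con, size = 8L, endian = "little")
    } else {
      writeBin(as.integer(a), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, INDEX_MAGIC)) stop("not a patchseek index file")
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hraw <- readBin(con, "raw", hlen)
  if (length(hraw) < hlen) stop("truncated index file (header)")
  header <- jsonlite::fromJSON(rawToChar(hraw), simplifyDataFrame = FALSE)
  if (!identical(as.integer(header$version), INDEX_VERSION)) {
    stop("index version mismatch: file has ", header$version,
         ", reader supports ", INDEX_VERSION)
  }
  arrays <- list()
  for (ad in header$arrays) {
    n <- prod(unlist(ad$dims))
    vals <- if (identical(ad$type, "float64")) {
      readBin(con, "numeric", n, size = 8L, endian = "little")
    } else {
      readBin(con, "integer", n, size = 4L, endian = "little")
    }
    if (length(vals) != n) stop("truncated index file (array ", ad$name, ")")
    dims <- unlist(ad$dims)
    arrays[[ad$name]] <- if (length(dims) == 2) matrix(vals, dims[1]) else vals
  }
  meta <- if (is.null(header$item_meta)) NULL else
    tibble::as_tibble(do.call(rbind, lapply(header$item_meta, as.data.frame)))
  params <- header$params
  handle <- switch(header$backend,
    exact = structure(list(backend = "exact", D = header$D,
                           n_items = header$n_items, params = list(),
                           vectors = arrays$vectors, item_meta = meta),
                      class = "patchseek_index"),
    ivfpq = {
      nlist <- params$nlist
      lists <- split(seq_len(header$n_items),
                     factor(arrays$list_assign, levels = seq_len(nlist)))
      cb_names <- grep("^codebook_", names(arrays), value = TRUE)
      centroids_list <- arrays[cb_names[order(as.integer(
        sub("codebook_", "", cb_names)))]]
      codebooks <- structure(
        list(m = params$m, dsub = ncol(centroids_list[[1]]),
             ksub = params$ksub, centroids = unname(centroids_list)),
        class = "pq_codebooks")
      structure(list(backend = "ivfpq", D = header$D,
                     n_items = header$n_items, params = params,
                     centroids = arrays$centroids, lists = lists,
                     codes = arrays$codes, codebooks = codebooks,
                     item_meta = meta),
                class = "patchseek_index")
    },
    itq_lsh = {
      model <- structure(list(mean = arrays$mean, pca = arrays$pca,
                              rotation = arrays$rotation,
                              n_bits = params$n_bits,
                              quant_errors = arrays$quant_errors),
                         class = "itq_model")
      structure(list(backend = "itq_lsh", D = header$D,
                     n_items = header$n_items, params = params,
                     model = model, codes = arrays$codes == 1L,
                     item_meta = meta),
                class = "patchseek_index")
    },
    stop("unknown backend in index file: ", header$backend)
  )
  handle
}

#' @export
print.patchseek_index <- function(x, ...) {
  cat("<patchseek_index> backend:", x$backend,
      " items:", x$n_items, " dim:", x$D, "\n")
  if (length(x$params)) {
    cat("  params:", paste(names(x$params),
                           vapply(x$params, function(p) paste(p, collapse = ","), ""),
                           sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
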