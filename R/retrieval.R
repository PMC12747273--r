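#' Encode a query image region into one unit vector
#'
#' The region is tiled into non-overlapping patches (regions smaller than one
#' patch are centre-padded with the region's mean colour), each patch is
#' encoded and projected, and the patch vectors are merged into a single
#' vector: with a trained attention model via [attention_scores()] +
#' [aggregate_bag()], otherwise with uniform weights (flagged by message the
#' first time). The result is unit-normalized.
#'
#' @param image RGB raster of the query region.
#' @param encoder an [encoder_spec()].
#' @param model optional `mil_fit` / `mil_model` supplying projection and
#'   attention.
#' @param patch_size tiling size in pixels.
#' @param quiet suppress the uniform-attention message.
#' @return a unit-norm numeric vector.
#' @export
encode_query <- function(image, encoder = encoder_spec(), model = NULL,
                         patch_size = 256L, quiet = FALSE) {
  assert_rgb(image)
  if (nrow(image) < patch_size || ncol(image) < patch_size) {
    image <- pad_center(image, patch_size)
  }
  full <- matrix(TRUE, nrow(image), ncol(image))
  tiles <- extract_patches(image, full, size_px = patch_size,
                           min_tissue_frac = 0)
  if (length(tiles$pixels) == 0L) stop("query region is empty after tiling")
  raw <- encode_patches(tiles$pixels, encoder)
  if (!is.null(model)) {
    m <- if (inherits(model, "mil_fit")) model$model else model
    H <- sweep(raw %*% m$W_p, 2, m$b_p, "+")
    s <- attention_scores(H, m$attn)
  } else {
    H <- project(raw)
    if (!quiet && nrow(H) > 1) {
      message("no trained attention model supplied; using uniform weights")
    }
    s <- rep(1 / nrow(H), nrow(H))
  }
  v <- aggregate_bag(H, s)
  as.vector(unit_normalize(matrix(v, 1)))
}

pad_center <- function(image, size) {
  h <- nrow(image); w <- ncol(image)
  fill <- apply(image, 3, mean)
  out <- array(rep(fill, each = max(size, h) * max(size, w)),
               c(max(size, h), max(size, w), 3))
  y0 <- (nrow(out) - h) %/% 2
  x0 <- (ncol(out) - w) %/% 2
  out[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), ] <- image
  out
}

#' Sample a background patch set for significance scoring
#'
#' Drawn once per cohort (without replacement; the whole cohort when it holds
#' fewer items than `size`) and stored with its seed, so z-scores and
#' p-values are reproducible across queries.
#'
#' @param n_items number of items in the cohort.
#' @param size background size (reference default 10,000).
#' @param seed integer seed.
#' @return an object of class `background_sample` with `item_ids` and `seed`.
#' @export
sample_background <- function(n_items, size = 10000L, seed = 1L) {
  ids <- if (n_items <= size) seq_len(n_items) else
    with_seed(substream_seed(seed, "background"),
              sort(sample.int(n_items, size)))
  structure(list(item_ids = ids, seed = as.integer(seed)), class = "background_sample")
}

#' Empirical significance of a retrieval hit
#'
#' Against the background distances `d_bg` between the query vector and the
#' background patches: `z = (d_hit - mean(d_bg)) / sd(d_bg)` and
#' `p = #\{d_bg <= d_hit\} / |bg|`. A more negative z means a stronger match
#' than random; p = 0 is attainable by construction (no add-one smoothing —
#' the empirical fraction is used exactly).
#'
#' @param hit_distance Euclidean distance of the hit.
#' @param bg_distances numeric vector of background distances (non-empty,
#'   non-constant).
#' @return a list with `z` and `p`.
#' @export
significance <- function(hit_distance, bg_distances) {
  if (length(bg_distances) == 0L) stop("background is empty")
  s <- stats::sd(bg_distances)
  if (is.na(s) || s == 0) stop("background distances have zero variance")
  list(z = (hit_distance - mean(bg_distances)) / s,
       p = mean(bg_distances <= hit_distance))
}

#' Rank slides from a set of top-K patch hits
#'
#' Each hit contributes a rank score of `K + 1 - rank` to its slide; slides
#' are ordered by descending total score, ties broken toward the smaller
#' best-hit distance. A single slide holding all K hits scores
#' `K(K+1)/2`.
#'
#' @param hits tibble with columns `slide_id`, `rank`, `distance`.
#' @param K the K of the retrieval (default: max rank present).
#' @return a tibble: `slide_id`, `score`, `n_hits`, `best_distance`,
#'   ordered by descending score.
#' @export
rank_slides <- function(hits, K = max(hits$rank)) {
  stopifnot(K >= 1)
  out <- hits |>
    dplyr::mutate(rank_score = K + 1 - .data$rank) |>
    dplyr::group_by(.data$slide_id) |>
    dplyr::summarise(score = sum(.data$rank_score),
                     n_hits = dplyr::n(),
                     best_distance = min(.data$distance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$best_distance,
                   .data$slide_id)
  out
}

#' End-to-end retrieval query
#'
#' Encodes the query (or accepts a precomputed vector), searches the index,
#' scores each hit's empirical significance against the cohort background,
#' and ranks the contributing slides. In `unified` mode only the best
#' (smallest-distance) patch per slide is kept in the hit list, mirroring the
#' one-patch-per-slide presentation used for blinded method comparisons.
#'
#' @param query either an RGB raster or a precomputed unit-norm vector.
#' @param index a `patchseek_index` whose `item_meta` carries `slide_id`,
#'   `x`, `y`, `size_px`.
#' @param embeddings the indexed N x D matrix (needed for background
#'   distances).
#' @param background a [sample_background()] result (defaults to all items).
#' @param K hits to return (reference default 50).
#' @param unified keep only the best patch per slide.
#' @param ... passed to [index_search()] (e.g. `nprobe`).
#' @param encoder,model,patch_size passed to [encode_query()] for image
#'   queries.
#' @return a list with `hits` (tibble: rank, item_id, slide_id, x, y,
#'   size_px, distance, z, p) and `slides` (a [rank_slides()] tibble).
#' @export
query_index <- function(query, index, embeddings, background = NULL,
                        K = 50L, unified = FALSE, encoder = encoder_spec(),
                        model = NULL, patch_size = 256L, ...) {
  qvec <- if (is.array(query) && length(dim(query)) == 3) {
    encode_query(query, encoder = encoder, model = model,
                 patch_size = patch_size, quiet = TRUE)
  } else {
    as.numeric(query)
  }
  if (length(qvec) != index$D) {
    stop("query dimension ", length(qvec), " does not match index (", index$D, ")")
  }
  res <- index_search(index, qvec, K = K, ...)
  meta <- index$item_meta
  hits <- tibble::tibble(
    rank = seq_len(nrow(res)),
    item_id = res$item_id,
    slide_id = if (!is.null(meta)) meta$slide_id[res$item_id] else
      as.character(res$item_id),
    x = if (!is.null(meta)) meta$x[res$item_id] else NA_integer_,
    y = if (!is.null(meta)) meta$y[res$item_id] else NA_integer_,
    size_px = if (!is.null(meta)) meta$size_px[res$item_id] else NA_integer_,
    distance = res$distance
  )
  if (is.null(background)) background <- sample_background(nrow(embeddings))
  bg_d <- sqrt(pmax(0, as.vector(cross_sqdist(
    matrix(qvec, 1), embeddings[background$item_ids, , drop = FALSE]))))
  sig <- lapply(hits$distance, significance, bg_distances = bg_d)
  hits$z <- vapply(sig, `[[`, 0, "z")
  hits$p <- vapply(sig, `[[`, 0, "p")
  slides <- rank_slides(hits, K = K)
  if (unified) {
    hits <- hits |>
      dplyr::group_by(.data$slide_id) |>
      dplyr::slice_min(.data$distance, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$rank)
  }
  list(hits = hits, slides = slides)
}
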