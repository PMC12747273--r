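#' Average precision at 5 for one labelled retrieval
#'
#' With `Rel_i = 1` when the i-th retrieved label equals the query label and
#' `Precision_i` the fraction of correct matches among the top i,
#' `AP@5 = sum_i Precision_i * Rel_i / 5`. All five correct gives 1; only
#' rank 1 correct gives 0.2; the smallest nonzero value (single correct at
#' rank 5) is 0.04.
#'
#' @param query_label the query's class label.
#' @param retrieved_labels exactly five labels in rank order.
#' @return AP@5 in \[0, 1\].
#' @export
ap_at_5 <- function(query_label, retrieved_labels) {
  if (length(retrieved_labels) != 5L) {
    stop("AP@5 requires exactly 5 retrieved labels, got ",
         length(retrieved_labels))
  }
  rel <- as.numeric(retrieved_labels == query_label)
  precision <- cumsum(rel) / seq_len(5)
  sum(precision * rel) / 5
}

#' Mean average precision at 5, per class, with a median summary
#'
#' @param retrievals tibble with columns `query_label`, `ap` (per-query
#'   AP@5), and optionally `dataset`.
#' @return a list of class `map5_table`: `per_class` (tibble: dataset,
#'   class, n, map5) and `summary_median` (median of per-class mAP@5 across
#'   classes and datasets).
#' @export
map_at_5 <- function(retrievals) {
  stopifnot(all(c("query_label", "ap") %in% names(retrievals)))
  if (!"dataset" %in% names(retrievals)) retrievals$dataset <- "default"
  empty <- retrievals |>
    dplyr::count(.data$dataset, .data$query_label) |>
    dplyr::filter(.data$n == 0)
  if (nrow(empty)) warning("classes without queries excluded")
  per_class <- retrievals |>
    dplyr::group_by(.data$dataset, class = .data$query_label) |>
    dplyr::summarise(n = dplyr::n(), map5 = mean(.data$ap), .groups = "drop")
  structure(list(per_class = per_class,
                 summary_median = stats::median(per_class$map5)),
            class = "map5_table")
}

#' Leave-one-out patch retrieval evaluation
#'
#' Every item queries an index built over all items; the self-match is
#' removed before the top-5 truncation (otherwise AP inflates), and the top-5
#' labels are scored by [ap_at_5()] against the query's label.
#'
#' @param embeddings unit-norm N x D matrix.
#' @param labels length-N class labels.
#' @param backend `"exact"`, `"ivfpq"` or `"itq_lsh"`, or a prebuilt
#'   `patchseek_index` over `embeddings`.
#' @param dataset dataset name recorded in the table.
#' @param ... backend-build and search parameters (`nlist`, `m`, `ksub`,
#'   `nprobe`, `n_bits`, `seed`).
#' @return a `map5_table` (see [map_at_5()]).
#' @export
leave_one_out_patch_eval <- function(embeddings, labels, backend = "exact",
                                     dataset = "default", ...) {
  emb <- as.matrix(embeddings)
  n <- nrow(emb)
  if (n < 6) stop("leave-one-out AP@5 needs at least 6 items")
  dots <- list(...)
  handle <- if (inherits(backend, "patchseek_index")) backend else {
    switch(backend,
      exact = build_exact(emb),
      ivfpq = build_ivfpq(emb, nlist = dots$nlist %||% 32L,
                          m = dots$m %||% 8L, ksub = dots$ksub %||% 16L,
                          seed = dots$seed %||% 1L),
      itq_lsh = build_itq_lsh(emb, n_bits = dots$n_bits %||% 64L,
                              seed = dots$seed %||% 1L),
      stop("unknown backend: ", backend))
  }
  nprobe <- dots$nprobe %||% (if (handle$backend == "ivfpq")
    handle$params$nlist else 8L)
  ap <- vapply(seq_len(n), function(i) {
    res <- index_search(handle, emb[i, ], K = 6L, nprobe = nprobe)
    ids <- res$item_id[res$item_id != i]  # self-match removed first
    ids <- ids[seq_len(min(5L, length(ids)))]
    if (length(ids) < 5L) {  # refill from a wider search if PQ ties starved us
      res2 <- index_search(handle, emb[i, ], K = min(n, 20L), nprobe = nprobe)
      ids <- res2$item_id[res2$item_id != i][1:5]
    }
    ap_at_5(labels[i], labels[ids])
  }, 0)
  map_at_5(tibble::tibble(dataset = dataset, query_label = labels, ap = ap))
}

#' Leave-one-slide-out slide matching evaluation
#'
#' For each slide, one representative query patch is chosen by the mosaic
#' ranking (the patch nearest its mosaic-cluster centroid); the top-5
#' distinct other slides are retrieved by best-patch distance from the index
#' of the remaining cohort (optionally mosaic-subsampled at
#' `mosaic_fraction`), and AP@5 is computed against the slide's label
#' (cancer type, or binary mutation status of a queried gene). Labels with a
#' single slide are excluded with a warning.
#'
#' @param slide_bags list of per-slide embedding matrices (unit-norm rows).
#' @param slide_coords list of per-slide N x 2 patch-centre coordinates.
#' @param slide_labels per-slide labels.
#' @param mosaic_fraction fraction of each slide's patches indexed (1 = all).
#' @param n_clusters mosaic clusters per slide.
#' @param seed seed.
#' @return a `map5_table` over slide labels.
#' @export
leave_one_slide_out_eval <- function(slide_bags, slide_coords, slide_labels,
                                     mosaic_fraction = 1.0, n_clusters = 9L,
                                     seed = 1L) {
  ns <- length(slide_bags)
  stopifnot(ns == length(slide_labels), ns == length(slide_coords))
  singles <- names(which(table(slide_labels) < 2))
  if (length(singles)) {
    warning("label(s) with a single slide excluded: ",
            paste(singles, collapse = ", "))
  }
  keep_slides <- which(!slide_labels %in% singles)
  # per-slide indexed subset and representative query patch
  indexed <- lapply(seq_len(ns), function(i) {
    k <- min(n_clusters, nrow(slide_bags[[i]]))
    if (mosaic_fraction >= 1) seq_len(nrow(slide_bags[[i]])) else
      mosaic_select(slide_bags[[i]], slide_coords[[i]],
                    fraction = mosaic_fraction, n_clusters = k, seed = seed)
  })
  reps <- vapply(seq_len(ns), function(i)
    mosaic_representative(slide_bags[[i]], slide_coords[[i]],
                          n_clusters = n_clusters, seed = seed), 0L)
  all_emb <- do.call(rbind, lapply(seq_len(ns), function(i)
    slide_bags[[i]][indexed[[i]], , drop = FALSE]))
  all_slide <- rep(seq_len(ns), vapply(indexed, length, 0L))
  rows <- lapply(keep_slides, function(i) {
    q <- slide_bags[[i]][reps[i], ]
    other <- all_slide != i
    d2 <- as.vector(cross_sqdist(matrix(q, 1),
                                 all_emb[other, , drop = FALSE]))
    os <- all_slide[other]
    best <- tapply(d2, os, min)
    top5 <- as.integer(names(sort(best))[1:5])
    tibble::tibble(dataset = "cohort", query_label = slide_labels[i],
                   ap = ap_at_5(slide_labels[i], slide_labels[top5]))
  })
  map_at_5(dplyr::bind_rows(rows))
}
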