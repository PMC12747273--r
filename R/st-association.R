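#' Cluster spot patches by morphology
#'
#' K-means (seeded k-means++, 25 Lloyd iterations) over the unit-norm spot
#' patch embeddings of one profile; on unit vectors Euclidean distance is a
#' monotone function of cosine similarity, so this is cosine clustering.
#' Clustering is strictly per profile, never pooled across profiles, because
#' pooled embeddings cluster by sample (batch effects) rather than by
#' morphology.
#'
#' @param spot_embeddings unit-norm n_spots x D matrix.
#' @param k number of clusters (reference default 8).
#' @param seed integer seed; labels are deterministic under it.
#' @param nstart seeded k-means restarts; the lowest within-SS solution is
#'   kept, which protects against local optima that merge distinct
#'   morphology clusters.
#' @return integer vector of 1-based cluster labels. Empty clusters (possible
#'   on degenerate input) trigger a warning.
#' @export
cluster_spots <- function(spot_embeddings, k = 8L, seed = 1L, nstart = 5L) {
  emb <- as.matrix(spot_embeddings)
  if (nrow(emb) < k) stop("need at least k = ", k, " spots, got ", nrow(emb))
  km <- kmeans_pp(emb, k, seed = substream_seed(seed, "spot_clusters"),
                  nstart = nstart)
  occupied <- length(unique(km$cluster))
  if (occupied < k) {
    warning(k - occupied, " cluster(s) empty (degenerate embeddings)")
  }
  km$cluster
}

#' Per-gene, per-cluster association statistics
#'
#' For every (gene, cluster) pair, compares expression over spots inside the
#' cluster against spots outside it (within the same profile): a two-sided
#' Wilcoxon rank-sum p-value and Cohen's d with the pooled SD,
#' `d = (mean_in - mean_out) / s_p`,
#' `s_p^2 = ((n_in - 1) s_in^2 + (n_out - 1) s_out^2) / (n_in + n_out - 2)`.
#' Expression is `log1p` of the raw counts. Benjamini-Hochberg correction is
#' applied per profile across all gene-by-cluster tests. Pairs with zero
#' pooled SD get `d = NaN` and are excluded from gene queries.
#'
#' @param counts genes x spots count matrix (sparse or dense) with rownames.
#' @param cluster_labels per-spot integer labels.
#' @param profile_id recorded on every row.
#' @param min_group smallest in/out group size tested (default 2).
#' @return a tibble: `profile_id`, `cluster_id`, `gene`, `cohens_d`,
#'   `p_value`, `q_value`.
#' @export
gene_cluster_stats <- function(counts, cluster_labels, profile_id = "STP1",
                               min_group = 2L) {
  expr <- log1p(as.matrix(counts))
  genes <- rownames(expr) %||% sprintf("gene_%04d", seq_len(nrow(expr)))
  rows <- list()
  for (cl in sort(unique(cluster_labels))) {
    inside <- cluster_labels == cl
    if (sum(inside) < min_group || sum(!inside) < min_group) next
    ein <- expr[, inside, drop = FALSE]
    eout <- expr[, !inside, drop = FALSE]
    n_in <- ncol(ein); n_out <- ncol(eout)
    m_in <- rowMeans(ein); m_out <- rowMeans(eout)
    v_in <- apply(ein, 1, stats::var); v_out <- apply(eout, 1, stats::var)
    sp <- sqrt(((n_in - 1) * v_in + (n_out - 1) * v_out) / (n_in + n_out - 2))
    d <- ifelse(sp == 0, NaN, (m_in - m_out) / sp)
    p <- vapply(seq_len(nrow(expr)), function(g) {
      if (sp[g] == 0 && m_in[g] == m_out[g]) return(1)
      suppressWarnings(
        stats::wilcox.test(ein[g, ], eout[g, ], alternative = "two.sided")$p.value)
    }, 0)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      profile_id = profile_id, cluster_id = cl, gene = genes,
      cohens_d = unname(d), p_value = unname(p))
  }
  out <- dplyr::bind_rows(rows)
  out$q_value <- bh_fdr(out$p_value)
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity, capped
#' at 1; `NaN`/`NA` p-values propagate as `NA` and do not count toward the
#' number of tests.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  finite <- is.finite(p_values)
  if (any(p_values[finite] < 0 | p_values[finite] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p_values))
  q[finite] <- stats::p.adjust(p_values[finite], method = "BH")
  q
}

#' Query a gene against association tables
#'
#' Scans the association records of all profiles and returns the image
#' clusters where the gene's expression is significantly high: Cohen's d
#' above `d_min` and q-value below `q_max`, sorted by descending d.
#'
#' @param gene gene name.
#' @param assoc association tibble(s) from [gene_cluster_stats()] (a single
#'   tibble or a list of them).
#' @param d_min,q_max thresholds (reference defaults d > 1, FDR < 0.05).
#' @return tibble of matching records (possibly empty; an unknown gene gives
#'   an empty result with a message).
#' @export
query_gene <- function(gene, assoc, d_min = 1, q_max = 0.05) {
  if (is.list(assoc) && !is.data.frame(assoc)) assoc <- dplyr::bind_rows(assoc)
  if (!gene %in% assoc$gene) {
    message("gene ", gene, " not present in any profile")
    return(assoc[0, ])
  }
  assoc |>
    dplyr::filter(.data$gene == !!gene, is.finite(.data$cohens_d),
                  .data$cohens_d > d_min, !is.na(.data$q_value),
                  .data$q_value < q_max) |>
    dplyr::arrange(dplyr::desc(.data$cohens_d))
}

#' Expression over the spots matched by a retrieval
#'
#' Maps retrieval hits over ST-paired patches back to their spots, keeps
#' genes detected (count > 0) in at least `detect_frac` of those spots, and
#' ranks genes by mean `log1p` expression across the matched spots.
#'
#' @param hit_spot_ids character vector of spot ids matched by the hits.
#' @param profile an `st_profile`.
#' @param detect_frac detection threshold (reference default 0.75).
#' @return a tibble: `gene`, `detect_frac`, `mean_expr`, sorted by
#'   descending mean expression.
#' @export
matched_spot_expression <- function(hit_spot_ids, profile, detect_frac = 0.75) {
  spot_ids <- intersect(hit_spot_ids, colnames(profile$counts))
  if (length(spot_ids) == 0L) stop("no hits map to ST spots")
  sub <- as.matrix(profile$counts[, spot_ids, drop = FALSE])
  det <- rowMeans(sub > 0)
  keep <- det >= detect_frac
  tibble::tibble(gene = rownames(sub)[keep],
                 detect_frac = det[keep],
                 mean_expr = rowMeans(log1p(sub))[keep]) |>
    dplyr::arrange(dplyr::desc(.data$mean_expr))
}

# Classic (unweighted) running-sum enrichment score of a membership vector
# ordered by descending score: +1/|set| at members, -1/(N - |set|) otherwise;
# ES is the maximum of the running sum.
running_es <- function(member_ordered) {
  nh <- sum(member_ordered)
  n <- length(member_ordered)
  inc <- ifelse(member_ordered, 1 / nh, -1 / (n - nh))
  max(cumsum(inc))
}

#' Gene-set enrichment on a score profile
#'
#' Genes are ranked from high to low by their score (mean expression or
#' Cohen's d); the classic unweighted running sum increments by `1/|set|` at
#' set members and decrements by `1/(N - |set|)` elsewhere, and the
#' enrichment score is the maximum of the running sum. The one-sided p-value
#' is the fraction of `n_perm` random same-size gene sets whose ES reaches
#' the observed one.
#'
#' @param scores named numeric vector of per-gene ranking values.
#' @param gene_set character vector of member gene names; must intersect the
#'   ranked genes, and must not cover all of them (the running sum would be
#'   degenerate).
#' @param n_perm permutations (reference default 1000).
#' @param seed integer seed.
#' @return a list with `es`, `p_value`, `n_set` (members used), `n_perm`.
#' @export
gsea <- function(scores, gene_set, n_perm = 1000L, seed = 1L) {
  stopifnot(!is.null(names(scores)))
  member <- names(scores) %in% gene_set
  nh <- sum(member)
  if (nh == 0L) stop("gene set does not intersect the ranked genes")
  if (nh == length(scores)) {
    stop("gene set covers every ranked gene; enrichment is degenerate")
  }
  ord <- order(scores, decreasing = TRUE)
  obs <- running_es(member[ord])
  n <- length(scores)
  perm_es <- with_seed(substream_seed(seed, "gsea_perm"), {
    vapply(seq_len(n_perm), function(i) {
      m <- logical(n)
      m[sample.int(n, nh)] <- TRUE
      running_es(m)
    }, 0)
  })
  list(es = obs, p_value = mean(perm_es >= obs), n_set = nh,
       n_perm = as.integer(n_perm))
}
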