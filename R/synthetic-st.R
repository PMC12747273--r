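#' Specify a synthetic spatial-transcriptomics profile
#'
#' Describes a profile of expression spots on a regular grid over a tissue
#' image: per-spot patch embeddings forming separable morphology clusters,
#' and a sparse gene-by-spot count matrix with planted cluster-specific
#' differential expression at stated Cohen's d effect sizes.
#'
#' Counts are generated as rounded log-normal intensities: a continuous value
#' is drawn per (gene, spot) as Normal(`baseline_mean`, `baseline_sd`) on the
#' `log1p` scale — shifted by `d * baseline_sd` for planted (gene, cluster)
#' pairs — and converted to a count via `round(expm1(.))`. Cohen's d targets
#' are therefore met in expectation on the `log1p(count)` scale the
#' association statistics operate on, up to rounding.
#'
#' @param n_spots,n_genes,n_clusters counts; `n_clusters >= 2`.
#' @param spot_spacing_px grid spacing between spot centres, pixels.
#' @param mpp microns per pixel of the paired image.
#' @param de_genes list of planted effects, each a list with `gene_idx`,
#'   `cluster_idx` (1-based) and `cohens_d_target`.
#' @param baseline_mean,baseline_sd expression baseline on the log1p scale.
#' @param embedding_dim dimension of the per-spot patch embeddings.
#' @param cluster_sep separation of morphology cluster centres in embedding
#'   space, in units of the within-cluster SD.
#' @param seed integer seed.
#' @return an object of class `st_profile_spec`.
#' @export
st_profile_spec <- function(n_spots, n_genes, n_clusters = 8L,
                            spot_spacing_px = 100L, mpp = 0.5,
                            de_genes = list(),
                            baseline_mean = 2, baseline_sd = 0.5,
                            embedding_dim = 16L, cluster_sep = 10,
                            seed = 1L) {
  stopifnot(n_clusters >= 2, n_spots >= n_clusters, n_genes >= 1, mpp > 0)
  for (de in de_genes) {
    stopifnot(de$gene_idx >= 1, de$gene_idx <= n_genes,
              de$cluster_idx >= 1, de$cluster_idx <= n_clusters)
    if (baseline_sd == 0 && de$cohens_d_target != 0) {
      stop("cohens_d_target is undefined when baseline_sd = 0")
    }
  }
  structure(
    list(n_spots = as.integer(n_spots), n_genes = as.integer(n_genes),
         n_clusters = as.integer(n_clusters),
         spot_spacing_px = as.integer(spot_spacing_px), mpp = mpp,
         de_genes = de_genes, baseline_mean = baseline_mean,
         baseline_sd = baseline_sd, embedding_dim = as.integer(embedding_dim),
         cluster_sep = cluster_sep, seed = as.integer(seed)),
    class = "st_profile_spec"
  )
}

#' Generate a synthetic spatial-transcriptomics profile
#'
#' @param spec an [st_profile_spec()].
#' @param profile_id identifier stored on the result.
#' @return an object of class `st_profile`: a list with `profile_id`, `spots`
#'   (tibble: spot_id, x_px, y_px), `mpp`, `counts` (sparse dgCMatrix, genes x
#'   spots), `gene_names`, `spot_embeddings` (unit-norm matrix, spots x d),
#'   `true_clusters` (planted 1-based labels) and `spec`.
#' @export
gen_st_profile <- function(spec, profile_id = "STP1") {
  stopifnot(inherits(spec, "st_profile_spec"))
  n <- spec$n_spots; g <- spec$n_genes; k <- spec$n_clusters
  side <- ceiling(sqrt(n))
  spots <- tibble::tibble(
    spot_id = sprintf("spot_%04d", seq_len(n)),
    x_px = ((seq_len(n) - 1L) %% side) * spec$spot_spacing_px +
      spec$spot_spacing_px,
    y_px = ((seq_len(n) - 1L) %/% side) * spec$spot_spacing_px +
      spec$spot_spacing_px
  )
  clusters <- with_seed(substream_seed(spec$seed, "st_clusters"),
                        sample(rep_len(seq_len(k), n)))
  centers <- with_seed(substream_seed(spec$seed, "st_centers"), {
    m <- matrix(stats::rnorm(k * spec$embedding_dim), k)
    sweep(m, 1, sqrt(rowSums(m^2)), "/") * spec$cluster_sep
  })
  emb <- with_seed(substream_seed(spec$seed, "st_emb"),
                   centers[clusters, , drop = FALSE] +
                     matrix(stats::rnorm(n * spec$embedding_dim), n))
  emb <- unit_normalize(emb)
  mu <- matrix(spec$baseline_mean, g, n)
  for (de in spec$de_genes) {
    sel <- clusters == de$cluster_idx
    mu[de$gene_idx, sel] <- mu[de$gene_idx, sel] +
      de$cohens_d_target * spec$baseline_sd
  }
  y <- mu + with_seed(substream_seed(spec$seed, "st_counts"),
                      matrix(stats::rnorm(g * n, sd = spec$baseline_sd), g))
  counts <- round(expm1(pmax(y, 0)))
  gene_names <- sprintf("gene_%04d", seq_len(g))
  counts <- Matrix::Matrix(counts, sparse = TRUE,
                           dimnames = list(gene_names, spots$spot_id))
  structure(
    list(profile_id = profile_id, spots = spots, mpp = spec$mpp,
         counts = counts, gene_names = gene_names,
         spot_embeddings = emb, true_clusters = clusters, spec = spec),
    class = "st_profile"
  )
}

#' Write / read an ST profile as MTX + TSV
#'
#' Persists the sparse counts as Matrix Market (`counts.mtx`), the gene table
#' (`genes.tsv`: gene) and the spot table
#' (`spots.tsv`: spot_id, x_px, y_px, mpp).
#'
#' @param profile an `st_profile`.
#' @param dir output directory (created if absent).
#' @return `write_st_profile` returns `dir` invisibly; `read_st_profile`
#'   returns an `st_profile` (without embeddings or planted truth, which are
#'   not part of the on-disk exchange format).
#' @export
write_st_profile <- function(profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(profile$counts, file.path(dir, "counts.mtx"))
  utils::write.table(data.frame(gene = profile$gene_names),
                     file.path(dir, "genes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  spots <- profile$spots
  spots$mpp <- profile$mpp
  utils::write.table(spots, file.path(dir, "spots.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_st_profile
#' @export
read_st_profile <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")), "CsparseMatrix")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"))
  spots <- tibble::as_tibble(utils::read.delim(file.path(dir, "spots.tsv")))
  dimnames(counts) <- list(genes$gene, spots$spot_id)
  structure(
    list(profile_id = basename(dir),
         spots = spots[, c("spot_id", "x_px", "y_px")],
         mpp = spots$mpp[1], counts = counts, gene_names = genes$gene,
         spot_embeddings = NULL, true_clusters = NULL, spec = NULL),
    class = "st_profile"
  )
}
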