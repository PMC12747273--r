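#' Specify a synthetic stained-tissue slide
#'
#' Builds the specification consumed by [gen_slide()]: an image of given pixel
#' size holding saturated tissue regions (discs or axis-aligned squares) on a
#' near-white background, mimicking the appearance that HSV-saturation tissue
#' segmentation relies on in stained sections.
#'
#' @param width_px,height_px image size in pixels.
#' @param tissue_regions a list of regions; each region is a list with fields
#'   `shape` ("disc" or "rect"), `center` (c(x, y), 1-based pixel coordinates),
#'   `radius_px` (disc radius or rect half-width), and `class_label`
#'   (positive integer tissue class).
#' @param background_color RGB triple in \[0, 1\]; default near-white.
#' @param noise_sd Gaussian pixel noise, RGB units in \[0, 1\].
#' @param seed integer; fully determines the output.
#' @return an object of class `slide_spec`.
#' @seealso [gen_slide()]
#' @export
slide_spec <- function(width_px, height_px, tissue_regions = list(),
                       background_color = c(0.96, 0.96, 0.96),
                       noise_sd = 0.01, seed = 1L) {
  stopifnot(width_px >= 1, height_px >= 1, noise_sd >= 0,
            length(background_color) == 3)
  for (r in tissue_regions) {
    stopifnot(!is.null(r$center), !is.null(r$radius_px), !is.null(r$class_label))
    if (r$center[1] - r$radius_px < 1 || r$center[1] + r$radius_px > width_px ||
        r$center[2] - r$radius_px < 1 || r$center[2] + r$radius_px > height_px) {
      stop("tissue region exceeds image bounds")
    }
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         tissue_regions = tissue_regions,
         background_color = background_color,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "slide_spec"
  )
}

# Saturated colours per class: hues spread around the wheel at full saturation
# so the HSV saturation channel separates tissue from the near-white background.
class_color <- function(class_label) {
  hue <- ((as.integer(class_label) - 1L) * 0.23) %% 1
  grDevices::col2rgb(grDevices::hsv(hue, s = 0.85, v = 0.75))[, 1] / 255
}

#' Generate a synthetic slide image with ground truth
#'
#' Rasterizes the regions of a [slide_spec()] onto the background, adds
#' Gaussian pixel noise, and returns the image together with the ground-truth
#' tissue mask and per-pixel class label map, so segmentation and patch
#' labelling can be scored against known truth.
#'
#' Overlapping regions carrying different class labels are an error;
#' overlapping same-label regions merge.
#'
#' @param spec a [slide_spec()].
#' @return a list with `image` (h x w x 3 array in \[0, 1\]), `mask`
#'   (logical h x w, TRUE on tissue) and `label_map` (integer h x w,
#'   0 on background).
#' @export
gen_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  h <- spec$height_px; w <- spec$width_px
  label_map <- matrix(0L, h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  for (r in spec$tissue_regions) {
    inside <- if (identical(r$shape, "rect")) {
      abs(xs - r$center[1]) <= r$radius_px & abs(ys - r$center[2]) <= r$radius_px
    } else {
      (xs - r$center[1])^2 + (ys - r$center[2])^2 <= r$radius_px^2
    }
    clash <- inside & label_map != 0L & label_map != as.integer(r$class_label)
    if (any(clash)) stop("overlapping regions with conflicting labels")
    label_map[inside] <- as.integer(r$class_label)
  }
  image <- array(rep(spec$background_color, each = h * w), c(h, w, 3))
  for (cl in setdiff(sort(unique(as.vector(label_map))), 0L)) {
    col <- class_color(cl)
    sel <- label_map == cl
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[sel] <- col[ch]
      image[, , ch] <- plane
    }
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(substream_seed(spec$seed, "slide_noise"),
                       stats::rnorm(length(image), sd = spec$noise_sd))
    image <- image + array(noise, dim(image))
  }
  image[image < 0] <- 0
  image[image > 1] <- 1
  list(image = image, mask = label_map != 0L, label_map = label_map)
}

#' Majority-area patch label from an annotation mask
#'
#' Assigns a patch the class covering the largest pixel area inside its box,
#' the standard rule for deriving patch-level labels from region or nucleus
#' annotations. Exact ties are broken toward the smallest label identifier,
#' which is deterministic and independent of pixel order. A box containing no
#' labelled pixel returns the sentinel `"unlabeled"`.
#'
#' @param annotation_mask integer matrix; 0 means unlabeled.
#' @param patch_box c(x, y, size): 0-based top-left offsets and box size, the
#'   half-open box \[x, x+size) x \[y, y+size) in pixel coordinates.
#' @return the majority integer label, or the character sentinel
#'   `"unlabeled"`.
#' @export
label_patch_by_majority_area <- function(annotation_mask, patch_box) {
  x <- patch_box[1]; y <- patch_box[2]; size <- patch_box[3]
  if (x < 0 || y < 0 ||
      x + size > ncol(annotation_mask) || y + size > nrow(annotation_mask)) {
    stop("patch box exceeds mask bounds")
  }
  sub <- annotation_mask[(y + 1):(y + size), (x + 1):(x + size)]
  counts <- table(sub[sub != 0L])
  if (length(counts) == 0L) return("unlabeled")
  labs <- as.integer(names(counts))
  best <- labs[counts == max(counts)]
  min(best)  # tie rule: smallest label id
}

#' Build molecular expression labels from an FPKM matrix
#'
#' Transforms an FPKM gene-by-sample matrix to `log2(FPKM + 1)`, centres tumor
#' samples by subtracting the per-gene mean of designated normal samples (or
#' of all samples when no normals are given), and summarises: the mean centred
#' expression of each named gene set, and a cytotoxic-T-lymphocyte (CTL) score
#' as the per-sample median of five designated genes.
#'
#' @param expression_matrix numeric genes x samples FPKM matrix with rownames.
#' @param gene_sets named list of character vectors of gene names.
#' @param ctl_genes character vector of the five CTL marker genes.
#' @param normal_samples optional character/integer vector of columns treated
#'   as normal controls for centering.
#' @return a tibble with one row per sample: `sample`, one column per gene set
#'   (mean centred expression), and `CTL` (median of the centred CTL genes).
#' @export
build_expression_labels <- function(expression_matrix, gene_sets, ctl_genes,
                                    normal_samples = NULL) {
  stopifnot(is.matrix(expression_matrix), !is.null(rownames(expression_matrix)))
  missing_ctl <- setdiff(ctl_genes, rownames(expression_matrix))
  if (length(missing_ctl)) {
    stop("CTL genes absent from matrix: ", paste(missing_ctl, collapse = ", "))
  }
  if (any(lengths(gene_sets) == 0L)) stop("empty gene set")
  lg <- log2(expression_matrix + 1)
  ref <- if (is.null(normal_samples) || length(normal_samples) == 0L) {
    rowMeans(lg)
  } else {
    rowMeans(lg[, normal_samples, drop = FALSE])
  }
  centered <- lg - ref
  set_means <- vapply(gene_sets, function(genes) {
    genes <- intersect(genes, rownames(centered))
    if (length(genes) == 0L) stop("gene set has no gene present in the matrix")
    colMeans(centered[genes, , drop = FALSE])
  }, numeric(ncol(centered)))
  if (ncol(centered) == 1L) set_means <- matrix(set_means, nrow = 1,
                                                dimnames = list(NULL, names(gene_sets)))
  ctl <- apply(centered[ctl_genes, , drop = FALSE], 2, stats::median)
  out <- tibble::as_tibble(as.data.frame(set_means))
  out <- dplyr::bind_cols(
    tibble::tibble(sample = colnames(expression_matrix) %||% as.character(seq_len(ncol(expression_matrix)))),
    out
  )
  out$CTL <- unname(ctl)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
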