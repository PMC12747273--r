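#' Specify a synthetic multiple-instance-learning cohort
#'
#' Describes a cohort of patients, each contributing one slide represented as
#' a bag of raw patch embeddings, with planted molecular ground truth:
#' three-class mutation labels per classification task and continuous
#' expression targets per regression task.
#'
#' For each classification task, patients are assigned classes 0 (wild-type /
#' unknown), 1 (functional mutation, the "positive" class) or 2 (other). In a
#' class-1 slide a fraction `signal_fraction` of patches is shifted by
#' `effect_size` (in units of the unit patch-noise SD) along a task-specific
#' direction; class-2 slides are shifted along an orthogonal direction, so the
#' three classes are geometrically distinct. Regression targets are linear in
#' the slide's mean embedding plus observation noise.
#'
#' @param n_patients number of patients (one slide each).
#' @param patches_per_slide patches per bag.
#' @param d_raw raw embedding dimension.
#' @param signal_fraction fraction of patches per positive slide carrying the
#'   class signal; in (0, 1\].
#' @param effect_size mean shift of signal patches, in noise-SD units.
#' @param n_mutation_tasks,n_regression_tasks task counts.
#' @param class_probs probabilities of classes 0/1/2 per patient.
#' @param regression_noise_sd SD of the additive noise on regression targets.
#' @param seed integer seed; labels and embeddings are reproducible from it.
#' @return an object of class `mil_cohort_spec`.
#' @export
mil_cohort_spec <- function(n_patients, patches_per_slide = 32L, d_raw = 32L,
                            signal_fraction = 0.5, effect_size = 1,
                            n_mutation_tasks = 1L, n_regression_tasks = 1L,
                            class_probs = c(0.5, 0.3, 0.2),
                            regression_noise_sd = 0.1, seed = 1L) {
  stopifnot(signal_fraction > 0, signal_fraction <= 1,
            n_patients >= 3, patches_per_slide >= 1, d_raw >= 2)
  if (signal_fraction * patches_per_slide < 1) {
    stop("signal_fraction * patches_per_slide < 1: no patch can carry signal")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         patches_per_slide = as.integer(patches_per_slide),
         d_raw = as.integer(d_raw),
         signal_fraction = signal_fraction, effect_size = effect_size,
         n_mutation_tasks = as.integer(n_mutation_tasks),
         n_regression_tasks = as.integer(n_regression_tasks),
         class_probs = class_probs / sum(class_probs),
         regression_noise_sd = regression_noise_sd,
         seed = as.integer(seed)),
    class = "mil_cohort_spec"
  )
}

#' Generate a synthetic MIL cohort with planted signal
#'
#' @param spec a [mil_cohort_spec()].
#' @return a list of class `mil_cohort` with elements:
#'   * `bags`: list of raw patches_per_slide x d_raw embedding matrices, one
#'     per slide;
#'   * `labels`: tibble with `patient_id`, `slide_id`, mutation classes
#'     `mut_1..` (integers 0/1/2) and regression targets `expr_1..`;
#'   * `spec`: the input spec.
#' @export
gen_mil_cohort <- function(spec) {
  stopifnot(inherits(spec, "mil_cohort_spec"))
  n <- spec$n_patients; p <- spec$patches_per_slide; d <- spec$d_raw
  # task-specific unit directions: orthonormal pairs per task from a fixed draw
  dirs <- with_seed(substream_seed(spec$seed, "directions"), {
    m <- matrix(stats::rnorm(d * 2L * spec$n_mutation_tasks), d)
    qr.Q(qr(m))[, seq_len(min(ncol(m), d)), drop = FALSE]
  })
  classes <- with_seed(substream_seed(spec$seed, "classes"), {
    matrix(sample(0:2, n * spec$n_mutation_tasks, replace = TRUE,
                  prob = spec$class_probs),
           n, spec$n_mutation_tasks)
  })
  # ensure every class occurs at least once per task (keeps weights definable)
  for (t in seq_len(spec$n_mutation_tasks)) {
    for (cl in 0:2) {
      if (!any(classes[, t] == cl)) {
        classes[((t - 1L) * 3L + cl) %% n + 1L, t] <- cl
      }
    }
  }
  n_signal <- ceiling(spec$signal_fraction * p)
  bags <- vector("list", n)
  for (i in seq_len(n)) {
    x <- with_seed(substream_seed(spec$seed, paste0("bag_", i)),
                   matrix(stats::rnorm(p * d), p, d))
    for (t in seq_len(spec$n_mutation_tasks)) {
      cl <- classes[i, t]
      if (cl == 0L || spec$effect_size == 0) next
      dir_idx <- (t - 1L) * 2L + cl  # column 1 for class 1, column 2 for class 2
      if (dir_idx > ncol(dirs)) dir_idx <- ((dir_idx - 1L) %% ncol(dirs)) + 1L
      sel <- with_seed(substream_seed(spec$seed, paste0("sig_", i, "_", t)),
                       sample.int(p, n_signal))
      x[sel, ] <- x[sel, ] +
        matrix(spec$effect_size * dirs[, dir_idx], n_signal, d, byrow = TRUE)
    }
    bags[[i]] <- x
  }
  reg_dirs <- with_seed(substream_seed(spec$seed, "reg_dirs"), {
    m <- matrix(stats::rnorm(d * spec$n_regression_tasks), d)
    sweep(m, 2, sqrt(colSums(m^2)), "/")
  })
  means <- t(vapply(bags, colMeans, numeric(d)))
  reg_noise <- with_seed(substream_seed(spec$seed, "reg_noise"),
                         matrix(stats::rnorm(n * spec$n_regression_tasks,
                                             sd = spec$regression_noise_sd),
                                n))
  regression <- means %*% reg_dirs + reg_noise
  labels <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    slide_id = sprintf("S%04d", seq_len(n))
  )
  for (t in seq_len(spec$n_mutation_tasks)) {
    labels[[paste0("mut_", t)]] <- as.integer(classes[, t])
  }
  for (j in seq_len(spec$n_regression_tasks)) {
    labels[[paste0("expr_", j)]] <- as.numeric(regression[, j])
  }
  structure(list(bags = bags, labels = labels, spec = spec),
            class = "mil_cohort")
}

#' Generate clustered unit vectors
#'
#' Synthetic embedding sets with planted cluster structure, used to exercise
#' and score the approximate index backends: cluster centres are drawn
#' uniformly on the unit sphere, points get isotropic Gaussian noise around
#' their centre and are then unit-normalized.
#'
#' @param n number of vectors.
#' @param d dimension.
#' @param n_clusters number of planted clusters.
#' @param noise_sd per-coordinate Gaussian noise SD around the centre.
#' @param seed integer seed.
#' @return a list with `vectors` (unit-norm n x d matrix) and `cluster`
#'   (planted 1-based labels).
#' @export
gen_clustered_vectors <- function(n, d, n_clusters = 20L, noise_sd = 0.04,
                                  seed = 1L) {
  centers <- with_seed(substream_seed(seed, "cv_centers"), {
    m <- matrix(stats::rnorm(n_clusters * d), n_clusters)
    m / sqrt(rowSums(m^2))
  })
  cl <- with_seed(substream_seed(seed, "cv_assign"),
                  sample(rep_len(seq_len(n_clusters), n)))
  x <- with_seed(substream_seed(seed, "cv_noise"),
                 centers[cl, , drop = FALSE] +
                   matrix(stats::rnorm(n * d, sd = noise_sd), n))
  list(vectors = unit_normalize(x), cluster = cl)
}
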