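#' Specification of a class-structured synthetic feature set
#'
#' The generator emulates the structure that HOG encoding imposes on
#' handwritten digits: instances of one class share most of their low-level
#' features (high within-class overlap) while different classes share fewer
#' (lower cross-class overlap).  Overlap is measured as the fraction of the
#' 81 one-hot blocks on which two vectors agree; two independent uniform
#' blocks agree with probability 1/4, so 0.25 is chance level.
#'
#' @param n_classes number of classes.
#' @param n_instances instances per class.
#' @param within within-class block-agreement target in `[0, 1]`.
#' @param cross cross-class block-agreement target in `[0, 1]`;
#'   must be strictly below `within`.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_classes = 3, n_instances = 3,
                       within = 0.75, cross = 0.35) {
  stopifnot(n_classes >= 1, n_instances >= 1)
  if (!(cross >= 0 && cross <= within && within <= 1))
    stop("overlap targets must satisfy 0 <= cross <= within <= 1")
  if (cross < 0.25 && n_classes > 4)
    stop("cross-class agreement below chance (0.25) is infeasible for more ",
         "than 4 classes with 4-level blocks")
  structure(list(n_classes = n_classes, n_instances = n_instances,
                 within = within, cross = cross),
            class = "synth_spec")
}

#' Class prototype feature vectors
#'
#' Draws one 324-length one-hot-blocked vector per class whose expected
#' pairwise block agreement equals the `cross` target of the spec.  For
#' targets at or above chance each block is either shared by all classes
#' (probability `(cross - 1/4)/(3/4)`) or drawn independently per class;
#' for below-chance targets (possible only for up to 4 classes) blocks are
#' either assigned pairwise-distinct levels or drawn independently.
#'
#' @param spec a [synth_spec()].
#' @return List of `n_classes` feature vectors.
#' @export
make_prototypes <- function(spec) {
  K <- spec$n_classes
  n_blocks <- 81L
  levels_k <- matrix(0L, n_blocks, K)
  if (spec$cross >= 0.25) {
    p_share <- (spec$cross - 0.25) / 0.75
    shared <- runif(n_blocks) < p_share
    for (bl in seq_len(n_blocks)) {
      if (shared[bl]) {
        levels_k[bl, ] <- sample.int(4L, 1L)
      } else {
        levels_k[bl, ] <- sample.int(4L, K, replace = TRUE)
      }
    }
  } else {
    p_distinct <- 1 - spec$cross / 0.25
    distinct <- runif(n_blocks) < p_distinct
    for (bl in seq_len(n_blocks)) {
      if (distinct[bl]) {
        levels_k[bl, ] <- sample.int(4L, K, replace = FALSE)
      } else {
        levels_k[bl, ] <- sample.int(4L, K, replace = TRUE)
      }
    }
  }
  lapply(seq_len(K), function(k) levels_to_feature(levels_k[, k]))
}

#' Sample an instance around a class prototype
#'
#' Each of the 81 blocks is kept with probability `within` and otherwise
#' resampled to a uniformly random level (which may coincide with the
#' original), so the expected block agreement between instance and prototype
#' is `within + (1 - within)/4`.
#'
#' @param prototype a 324-length one-hot-blocked vector.
#' @param within keep probability per block, in `[0, 1]`.
#' @return A feature vector with the same block structure.
#' @export
sample_instance <- function(prototype, within) {
  validate_feature_vector(prototype)
  stopifnot(within >= 0, within <= 1)
  lev <- feature_to_levels(prototype)
  resample <- runif(81) >= within
  lev[resample] <- sample.int(4L, sum(resample), replace = TRUE)
  levels_to_feature(lev)
}

#' Generate a full synthetic training/test set
#'
#' @param spec a [synth_spec()].
#' @param n_holdout held-out instances per class (for classification tests).
#' @param holdout_within prototype fidelity of the held-out instances;
#'   defaults to the training `within`.  A lower value makes the test items
#'   harder (unseen-variant difficulty), which keeps classification accuracy
#'   below ceiling so that changes in it are measurable.
#' @return A list with `features` (list of training vectors, instance-major
#'   within class), `labels` (integer class of each training vector),
#'   `holdout` and `holdout_labels` (test vectors), and `prototypes`.
#' @export
make_synth_set <- function(spec = synth_spec(), n_holdout = 0,
                           holdout_within = NULL) {
  if (is.null(holdout_within)) holdout_within <- spec$within
  protos <- make_prototypes(spec)
  feats <- list(); labels <- integer(0)
  for (k in seq_len(spec$n_classes)) {
    for (i in seq_len(spec$n_instances)) {
      feats[[length(feats) + 1]] <- sample_instance(protos[[k]], spec$within)
      labels <- c(labels, k)
    }
  }
  hold <- list(); hlab <- integer(0)
  if (n_holdout > 0) {
    for (k in seq_len(spec$n_classes)) {
      for (i in seq_len(n_holdout)) {
        hold[[length(hold) + 1]] <- sample_instance(protos[[k]],
                                                    holdout_within)
        hlab <- c(hlab, k)
      }
    }
  }
  list(features = feats, labels = labels,
       holdout = hold, holdout_labels = hlab, prototypes = protos)
}

#' Block agreement between two feature vectors
#'
#' @param a,b 324-length one-hot-blocked vectors.
#' @return Fraction of the 81 blocks on which the active levels coincide.
#' @export
block_agreement <- function(a, b) {
  mean(feature_to_levels(a) == feature_to_levels(b))
}

feature_to_levels <- function(v) {
  apply(matrix(v, nrow = 4), 2, which.max)
}

levels_to_feature <- function(lev) {
  stopifnot(length(lev) == 81, all(lev %in% 1:4))
  out <- integer(324)
  out[(seq_along(lev) - 1L) * 4L + lev] <- 1L
  out
}

#' Toy stroke images for end-to-end feature tests
#'
#' Draws simple parameterised 28x28 grayscale strokes -- a bar, a ring, or a
#' corner -- with per-instance jitter in position and thickness, giving
#' distinguishable image families that exercise the HOG pipeline without any
#' external dataset.
#'
#' @param n_classes number of stroke families (up to 3).
#' @param n_instances images per family.
#' @param jitter_px positional jitter amplitude, pixels.
#' @return `list(images = <list of 28x28 matrices>, labels = <integer>)`.
#' @export
make_toy_images <- function(n_classes = 3, n_instances = 3, jitter_px = 2) {
  stopifnot(n_classes >= 1, n_classes <= 3)
  xs <- matrix(rep(1:28, each = 28), 28, 28)   # column index
  ys <- matrix(rep(1:28, times = 28), 28, 28)  # row index
  images <- list(); labels <- integer(0)
  for (k in seq_len(n_classes)) {
    for (i in seq_len(n_instances)) {
      dx <- runif(1, -jitter_px, jitter_px)
      dy <- runif(1, -jitter_px, jitter_px)
      th <- runif(1, 1.5, 2.5)
      img <- switch(k,
        {  # vertical bar
          d <- abs(xs - (14.5 + dx))
          exp(-(d / th)^2)
        },
        {  # ring
          r <- sqrt((xs - (14.5 + dx))^2 + (ys - (14.5 + dy))^2)
          exp(-((r - 8) / th)^2)
        },
        {  # corner: horizontal + vertical half-strokes
          d1 <- ifelse(xs <= 14.5 + dx, abs(ys - (8.5 + dy)), Inf)
          d2 <- ifelse(ys <= 14.5 + dy, abs(xs - (8.5 + dx)), Inf)
          pmax(exp(-(d1 / th)^2), exp(-(d2 / th)^2))
        })
      images[[length(images) + 1]] <- img
      labels <- c(labels, k)
    }
  }
  list(images = images, labels = labels)
}
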