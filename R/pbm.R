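# Prediction balance module (PBM).
#
# Long-tailed bird data concentrate annotated pixels in a few head species.
# PBM measures the total annotated box area p_k of every category, forms the
# inverse-frequency vector
#     Pix_k = log(sum_i p_i / p_k),
# and during training adds zero-mean Gaussian noise to the per-category
# classification logits, scaled per category by Pix_k / max_i Pix_i. Tail
# categories (small p_k, large Pix_k) are perturbed at full noise scale
# sigma; the head category is barely touched. At inference the perturbation
# is dropped entirely, so PBM adds no parameters, FLOPs, or inference cost.

#' Per-category pixel statistics and inverse class frequency
#'
#' @param annotations data.frame with columns `category` (0-based ids in
#'   `[0, n_categories)`), `w`, `h` (box sizes in pixels at original image
#'   resolution).
#' @param n_categories number of categories C.
#' @return an object of class `class_pixel_stats`: list with `pixel_sum`
#'   (p_k, clamped to >= 1) and `frequency` (Pix_k).
#' @examples
#' s <- compute_class_pixel_stats(
#'   data.frame(category = c(0, 1, 2), w = c(10, 5, 1), h = c(10, 2, 1)), 3)
#' s$frequency  # log(111/100), log(111/10), log(111/1)
#' @export
compute_class_pixel_stats <- function(annotations, n_categories) {
  if (n_categories < 1L) stop("n_categories must be >= 1")
  if (nrow(annotations) > 0) {
    if (any(annotations$category < 0 | annotations$category >= n_categories))
      stop("category id outside [0, ", n_categories, ")")
    if (any(annotations$w <= 0 | annotations$h <= 0))
      stop("box dimensions must be positive")
  }
  p <- rep(0, n_categories)
  if (nrow(annotations) > 0) {
    agg <- tapply(annotations$w * annotations$h, annotations$category, sum)
    p[as.integer(names(agg)) + 1L] <- agg
  }
  if (any(p < 1)) {
    empty <- sum(p == 0)
    if (empty > 0)
      warning(empty, " categor", if (empty == 1) "y" else "ies",
              " without annotated pixels; clamping p_k to 1")
    p <- pmax(p, 1)
  }
  structure(list(pixel_sum = p, frequency = log(sum(p) / p)),
            class = "class_pixel_stats")
}

#' Sample a per-category variation vector
#'
#' Draws one fresh Gaussian per category, `delta_k ~ N(0, sigma^2)`, and
#' scales it by the normalized inverse class frequency:
#' `Variation_k = Pix_k / max_i Pix_i * delta_k`. The most frequent category
#' has the smallest scale; with a single category (or all categories equal to
#' the total) the scale is zero by convention. `sigma` is the standard
#' deviation of the base noise; the reference configuration is `sigma = 4`.
#'
#' @param stats a [compute_class_pixel_stats()] result.
#' @param sigma noise scale, >= 0.
#' @param rng_seed optional integer seed for a reproducible draw; by default
#'   the current RNG stream is used.
#' @return numeric vector of length C (class `variation_vector`).
#' @export
sample_variation <- function(stats, sigma = 4, rng_seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  C <- length(stats$frequency)
  mx <- max(stats$frequency)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (mx <= 0 || sigma == 0) return(rep(0, C))
  delta <- stats::rnorm(C, mean = 0, sd = sigma)
  structure(stats$frequency / mx * delta, class = "variation_vector")
}

#' Apply the variation to prediction scores
#'
#' In training mode adds the variation vector elementwise to the
#' per-category scores (broadcast across prediction locations when `scores`
#' is a matrix with C columns). Out of training the scores are returned
#' unchanged, bitwise identical: the perturbation exists only in the
#' training loss path.
#'
#' @param scores numeric vector of length C, or a matrix with C columns
#'   (rows = prediction locations).
#' @param variation numeric vector of length C.
#' @param training logical flag.
#' @export
apply_variation <- function(scores, variation, training = TRUE) {
  if (!training) return(scores)
  if (is.matrix(scores)) {
    if (ncol(scores) != length(variation))
      stop("scores have ", ncol(scores), " categories, variation ",
           length(variation))
    return(sweep(scores, 2L, as.numeric(variation), "+"))
  }
  if (length(scores) != length(variation))
    stop("scores length ", length(scores), " != variation length ",
         length(variation))
  scores + as.numeric(variation)
}
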