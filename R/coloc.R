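# FISH / streptavidin colocalization quantification.
#
# Per channel: Gaussian blur + power-law contrast transform (parameters
# chosen by grid search), Otsu binarization, and a mask score defined as the
# percentage of foreground pixels whose *raw* intensity exceeds the raw
# image's 90th percentile. The optimized masks are then compared with
# labeling efficiency, specificity, and the Jaccard index, with the FISH
# mask as the ground-truth reference.

#' Blur and power-law transform an image channel
#'
#' Applies a Gaussian blur of standard deviation `sigma` (skipped when
#' `sigma = 0`), rescales the result to `[0, 1]` by min-max, and raises it
#' elementwise to the power `gamma`. Since `gamma > 0` the power step is
#' monotone: it reshapes contrast without reordering pixel intensities.
#'
#' @param image An [image_channel()] or numeric matrix.
#' @param sigma Gaussian blur standard deviation in pixels, `>= 0`.
#' @param gamma Power-law exponent, `> 0`. `gamma < 1` expands dim pixels,
#'   `gamma > 1` suppresses them.
#' @return Float matrix in `[0, 1]`. A constant input (no dynamic range after
#'   blurring) yields an all-zeros matrix flagged degenerate — see
#'   [is_degenerate()].
#' @export
preprocess <- function(image, sigma, gamma) {
  x <- as_pixels(image)
  if (!is_number(sigma) || sigma < 0) stop2("sigma must be >= 0")
  if (!is_number(gamma) || gamma <= 0) stop2("gamma must be > 0")
  if (sigma > 0) {
    # cap the kernel so it never exceeds the image (large sigma on a small
    # field); EBImage's default radius is 2 * ceiling(3 * sigma) + 1
    radius <- min(2 * ceiling(3 * sigma) + 1, min(dim(x)))
    if (radius %% 2 == 0) radius <- radius - 1
    x <- EBImage::imageData(EBImage::gblur(x, sigma = sigma,
                                           radius = radius))
  }
  rng <- range(x)
  if (rng[2] <= rng[1]) {
    return(set_degenerate(matrix(0, nrow(x), ncol(x))))
  }
  ((x - rng[1]) / (rng[2] - rng[1]))^gamma
}

#' Otsu threshold of a grayscale image
#'
#' Min-max scales the image, quantizes it to 256 gray levels, and picks the
#' level that maximizes the between-class variance of the two-class split —
#' the classic Otsu criterion. Foreground is every pixel whose level is
#' strictly greater than the threshold. Min-max scaling makes the mask
#' invariant to positive affine rescaling of the intensities, and quantizing
#' to 256 levels reproduces classic 8-bit behavior for float images.
#'
#' @param image An [image_channel()] or numeric matrix with at least two
#'   distinct values.
#' @return List with `threshold` (on the `[0, 1]` min-max scale;
#'   `level / 255`), `level` (integer gray level in `0..254`), and `mask`
#'   (logical foreground matrix). Ties in the criterion are broken toward
#'   the smallest level.
#' @export
otsu_threshold <- function(image) {
  x <- as_pixels(image)
  rng <- range(x)
  if (rng[2] <= rng[1]) stop2("cannot threshold a constant image")
  v <- pmin(as.integer(floor((x - rng[1]) / (rng[2] - rng[1]) * 256)), 255L)
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                      # class-0 mass for t = 0..255
  mu <- cumsum(p * (0:255))               # class-0 first moment
  mu_t <- mu[256]
  # between-class variance for thresholds t = 0..254
  w0 <- omega[1:255]
  m0 <- mu[1:255]
  bcv <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf            # empty class: invalid split
  level <- which.max(bcv) - 1L            # ties -> smallest level
  list(threshold = level / 255,
       level = level,
       mask = matrix(v > level, nrow(x), ncol(x)))
}

#' Score a binary mask against the raw image's 90th percentile
#'
#' The score of a candidate mask is the percentage of its foreground pixels
#' whose intensity in the raw, unpreprocessed channel strictly exceeds the
#' 90th percentile of all raw pixel intensities (linear interpolation,
#' `stats::quantile` type 7). Scoring against the raw data keeps the grid
#' search from rewarding transforms that merely inflate their own output.
#'
#' @param mask Logical foreground matrix.
#' @param raw_image The raw channel ([image_channel()] or matrix), same
#'   shape as `mask`.
#' @return Percentage in `[0, 100]`. An empty mask returns 0 flagged
#'   degenerate.
#' @export
score_mask <- function(mask, raw_image) {
  raw <- as_pixels(raw_image)
  if (!is.logical(mask)) stop2("mask must be logical")
  if (!identical(dim(mask), dim(raw))) {
    stop2("mask and raw image shapes differ")
  }
  n_fg <- sum(mask)
  if (n_fg == 0) return(set_degenerate(0))
  p90 <- stats::quantile(raw, 0.9, names = FALSE, type = 7)
  100 * sum(raw[mask] > p90) / n_fg
}

#' Grid-search preprocessing parameters for one channel
#'
#' For every `(sigma, gamma)` pair the channel is preprocessed
#' ([preprocess()]), binarized ([otsu_threshold()]), and the resulting mask
#' scored against the raw channel ([score_mask()]); the highest-scoring mask
#' wins. Parameters are meant to be optimized per image and per channel
#' independently. Ties are broken toward the smallest `sigma`, then the
#' smallest `gamma` (least-processed preference); parameter pairs whose
#' preprocessed image is constant are skipped.
#'
#' @param raw_image The raw channel.
#' @param sigma_grid,gamma_grid Numeric candidate vectors; defaults
#'   `c(0.5, 1, 2, 4, 8)` and `c(0.5, 1, 2, 3, 4)` span sub-spot to
#'   multi-spot smoothing and both contrast directions.
#' @return A `binary_mask` object: list with `foreground` (logical matrix),
#'   `sigma`, `gamma`, `otsu_threshold`, and `score` (percent).
#' @export
optimize_mask <- function(raw_image,
                          sigma_grid = c(0.5, 1, 2, 4, 8),
                          gamma_grid = c(0.5, 1, 2, 3, 4)) {
  raw <- as_pixels(raw_image)
  if (length(sigma_grid) == 0 || length(gamma_grid) == 0) {
    stop2("parameter grids must be nonempty")
  }
  best <- NULL
  for (sigma in sort(sigma_grid)) {
    for (gamma in sort(gamma_grid)) {
      pre <- preprocess(raw, sigma, gamma)
      if (is_degenerate(pre)) next
      ot <- otsu_threshold(pre)
      sc <- score_mask(ot$mask, raw)
      if (is.null(best) || sc > best$score) {
        best <- structure(
          list(foreground = ot$mask, sigma = sigma, gamma = gamma,
               otsu_threshold = ot$threshold, score = sc),
          class = "binary_mask")
      }
    }
  }
  if (is.null(best)) {
    stop2("all parameter sets degenerate (constant preprocessed image)")
  }
  best
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %d x %d px, sigma = %g, gamma = %g, score = %.2f%%, %d fg px\n",
    nrow(x$foreground), ncol(x$foreground), x$sigma, x$gamma, x$score,
    sum(x$foreground)))
  invisible(x)
}

#' Colocalization metrics for a FISH / streptavidin mask pair
#'
#' With `F` the FISH foreground and `S` the streptavidin foreground:
#' labeling efficiency is `100 * |F n S| / |F|` (how much of the FISH signal
#' was biotinylated), specificity is `100 * |F n S| / |S|` (how much of the
#' biotinylation landed on the FISH signal), and the Jaccard index is
#' `|F n S| / |F u S|`.
#'
#' @param fish_mask,strep_mask Logical matrices of identical shape, or
#'   `binary_mask` objects from [optimize_mask()].
#' @return List with `labeling_efficiency`, `specificity` (percent),
#'   `jaccard`, and the pixel counts `n_fish_fg`, `n_strep_fg`,
#'   `n_intersection`, `n_union`. Empty-denominator metrics are 0 and the
#'   result is flagged degenerate.
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' coloc_metrics(a, a)$jaccard
#' @export
coloc_metrics <- function(fish_mask, strep_mask) {
  f <- mask_matrix(fish_mask)
  s <- mask_matrix(strep_mask)
  if (!identical(dim(f), dim(s))) stop2("mask shapes differ")
  n_f <- sum(f)
  n_s <- sum(s)
  n_int <- sum(f & s)
  n_uni <- n_f + n_s - n_int
  out <- list(
    labeling_efficiency = if (n_f > 0) 100 * n_int / n_f else 0,
    specificity = if (n_s > 0) 100 * n_int / n_s else 0,
    jaccard = if (n_uni > 0) n_int / n_uni else 0,
    n_fish_fg = n_f, n_strep_fg = n_s,
    n_intersection = n_int, n_union = n_uni)
  if (n_f == 0 || n_s == 0) out <- set_degenerate(out)
  out
}

mask_matrix <- function(m) {
  if (inherits(m, "binary_mask")) m <- m$foreground
  if (!is.logical(m) || !is.matrix(m)) {
    stop2("expected a logical matrix or binary_mask")
  }
  m
}

#' Quantify colocalization for one image pair
#'
#' Optimizes the preprocessing of each channel independently
#' ([optimize_mask()]) and computes the overlap metrics with FISH as the
#' ground-truth reference ([coloc_metrics()]).
#'
#' @inheritParams optimize_mask
#' @param fish,strep Raw channels of identical shape.
#' @return List with `fish_mask`, `strep_mask` (`binary_mask` objects) and
#'   `metrics`.
#' @export
quantify_pair <- function(fish, strep,
                          sigma_grid = c(0.5, 1, 2, 4, 8),
                          gamma_grid = c(0.5, 1, 2, 3, 4)) {
  f <- as_pixels(fish)
  s <- as_pixels(strep)
  if (!identical(dim(f), dim(s))) stop2("channel shapes differ")
  fish_mask <- optimize_mask(f, sigma_grid, gamma_grid)
  strep_mask <- optimize_mask(s, sigma_grid, gamma_grid)
  list(fish_mask = fish_mask, strep_mask = strep_mask,
       metrics = coloc_metrics(fish_mask$foreground, strep_mask$foreground))
}

#' Batch colocalization over a manifest of image pairs
#'
#' @param manifest Data frame (or path to a TSV) with columns `pair_id`,
#'   `fish_path`, `strep_path`.
#' @inheritParams optimize_mask
#' @param save_masks_dir Optional directory; when given, each optimized mask
#'   is written as an 8-bit PNG named `<pair_id>_<channel>_mask.png`.
#' @return Data frame with one row per pair: chosen parameters and score per
#'   channel, the three metrics, and the pixel counts.
#' @export
quantify_manifest <- function(manifest,
                              sigma_grid = c(0.5, 1, 2, 4, 8),
                              gamma_grid = c(0.5, 1, 2, 3, 4),
                              save_masks_dir = NULL) {
  if (is.character(manifest)) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  need <- c("pair_id", "fish_path", "strep_path")
  if (!all(need %in% names(manifest))) {
    stop2("manifest needs columns: ", paste(need, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    fish <- read_channel(manifest$fish_path[i], "fish")
    strep <- read_channel(manifest$strep_path[i], "streptavidin")
    q <- quantify_pair(fish, strep, sigma_grid, gamma_grid)
    if (!is.null(save_masks_dir)) {
      write_channel(q$fish_mask$foreground, file.path(
        save_masks_dir, paste0(manifest$pair_id[i], "_fish_mask.png")))
      write_channel(q$strep_mask$foreground, file.path(
        save_masks_dir, paste0(manifest$pair_id[i], "_strep_mask.png")))
    }
    m <- q$metrics
    data.frame(
      pair_id = manifest$pair_id[i],
      sigma_fish = q$fish_mask$sigma, gamma_fish = q$fish_mask$gamma,
      score_fish = q$fish_mask$score,
      sigma_strep = q$strep_mask$sigma, gamma_strep = q$strep_mask$gamma,
      score_strep = q$strep_mask$score,
      efficiency_pct = m$labeling_efficiency,
      specificity_pct = m$specificity,
      jaccard = m$jaccard,
      n_fish_fg = m$n_fish_fg, n_strep_fg = m$n_strep_fg,
      n_intersection = m$n_intersection, n_union = m$n_union,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
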