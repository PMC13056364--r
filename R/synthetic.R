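# Seeded generators with known ground truth. Every downstream stage of the
# package is exercised on these fixtures, so all of them are deterministic
# given a seed and all of them return the truth alongside the data.

#' Simulate a two-channel puncta image pair with known colocalization
#'
#' Generates a FISH channel and a streptavidin channel of punctate spots on a
#' constant background with additive Gaussian noise. A fraction
#' `overlap_fraction` of the streptavidin spots share centers with FISH
#' spots; the remainder are placed at independent positions kept at least
#' `min_separation_px` away from every other spot, so the planted
#' colocalization level is unambiguous.
#'
#' Spots have an isotropic 2-D Gaussian intensity profile of standard
#' deviation `spot_sigma_px`; the ground-truth mask for a channel is the
#' union of discs of radius `2 * spot_sigma_px` around its spot centers.
#'
#' @param height,width Image dimensions in pixels (at least 8 each).
#' @param n_spots Number of spots per channel (at least 1).
#' @param overlap_fraction Fraction of streptavidin spots sharing a FISH
#'   center, in `[0, 1]`. The shared count is `round(overlap_fraction *
#'   n_spots)`.
#' @param spot_sigma_px Spot Gaussian sigma in pixels.
#' @param spot_amplitude Peak intensity added by one spot.
#' @param background_level Constant background intensity.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (negative pixels are clipped to zero).
#' @param min_separation_px Minimum center-to-center distance between any two
#'   placed spots; defaults to `5 * spot_sigma_px` so truth discs never
#'   touch.
#' @param noise_model `"gaussian"` (default) or `"poisson"`; the Poisson mode
#'   draws each pixel from `Poisson(lambda = clean * poisson_scale) /
#'   poisson_scale`.
#' @param poisson_scale Photon-count scale for the Poisson mode.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#' @return A list with `fish` and `strep` ([image_channel()] objects) and
#'   `truth`, a list holding `spot_centers_fish`, `spot_centers_strep`
#'   (two-column matrices of row/col pixel coordinates), `n_shared`,
#'   `overlap_fraction`, `spot_sigma_px`, and logical `truth_mask_fish` /
#'   `truth_mask_strep`.
#' @examples
#' pair <- simulate_puncta_pair(64, 64, n_spots = 6, overlap_fraction = 0.5,
#'                              seed = 1)
#' pair$truth$n_shared
#' @export
simulate_puncta_pair <- function(height, width, n_spots,
                                 overlap_fraction = 1,
                                 spot_sigma_px = 1.5,
                                 spot_amplitude = 1,
                                 background_level = 0.1,
                                 noise_sd = 0.05,
                                 min_separation_px = 5 * spot_sigma_px,
                                 noise_model = c("gaussian", "poisson"),
                                 poisson_scale = 1000,
                                 seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (height < 8 || width < 8) stop2("image dimensions must be at least 8x8")
  if (n_spots < 1) stop2("n_spots must be at least 1")
  if (!is_number(overlap_fraction) || overlap_fraction < 0 ||
      overlap_fraction > 1) {
    stop2("overlap_fraction must lie in [0, 1]")
  }
  if (spot_sigma_px <= 0 || spot_amplitude <= 0 || noise_sd < 0 ||
      background_level < 0) {
    stop2("spot_sigma_px and spot_amplitude must be positive; ",
          "background_level and noise_sd must be nonnegative")
  }

  n_shared <- round(overlap_fraction * n_spots)
  n_indep <- n_spots - n_shared

  with_seed_if(seed, {
    fish_centers <- place_spots(height, width, n_spots, spot_sigma_px,
                                min_separation_px)
    shared_idx <- if (n_shared > 0) sample(n_spots, n_shared) else integer()
    indep_centers <- place_spots(height, width, n_indep, spot_sigma_px,
                                 min_separation_px,
                                 avoid = fish_centers)
    strep_centers <- rbind(fish_centers[shared_idx, , drop = FALSE],
                           indep_centers)

    fish_clean <- render_spots(height, width, fish_centers, spot_sigma_px,
                               spot_amplitude, background_level)
    strep_clean <- render_spots(height, width, strep_centers, spot_sigma_px,
                                spot_amplitude, background_level)
    fish_px <- add_noise(fish_clean, noise_sd, noise_model, poisson_scale)
    strep_px <- add_noise(strep_clean, noise_sd, noise_model, poisson_scale)

    truth <- list(
      spot_centers_fish = fish_centers,
      spot_centers_strep = strep_centers,
      n_shared = n_shared,
      overlap_fraction = overlap_fraction,
      spot_sigma_px = spot_sigma_px,
      truth_mask_fish = disc_mask(height, width, fish_centers,
                                  2 * spot_sigma_px),
      truth_mask_strep = disc_mask(height, width, strep_centers,
                                   2 * spot_sigma_px)
    )
    list(fish = image_channel(fish_px, "float", "fish"),
         strep = image_channel(strep_px, "float", "streptavidin"),
         truth = truth)
  })
}

# Rejection-sample `n` spot centers at least `min_sep` apart from each other
# and from the `avoid` set, inside a margin that keeps the truth disc on the
# image. Errors when the requested count cannot be placed.
place_spots <- function(height, width, n, sigma, min_sep, avoid = NULL) {
  centers <- matrix(numeric(0), 0, 2,
                    dimnames = list(NULL, c("row", "col")))
  if (n == 0) return(centers)
  margin <- ceiling(2 * sigma) + 1
  if (height - 2 * margin < 1 || width - 2 * margin < 1) {
    stop2("image too small for the requested spot size")
  }
  taken <- rbind(avoid, centers)
  tries <- 0L
  max_tries <- 200L * n
  while (nrow(centers) < n) {
    if (tries >= max_tries) {
      stop2("could not place ", n, " spots with minimum separation ",
            min_sep, " px; spot count exceeds placeable area")
    }
    tries <- tries + 1L
    cand <- c(stats::runif(1, margin, height - margin + 1),
              stats::runif(1, margin, width - margin + 1))
    if (nrow(taken) == 0 ||
        min(sqrt((taken[, 1] - cand[1])^2 + (taken[, 2] - cand[2])^2)) >=
          min_sep) {
      centers <- rbind(centers, cand)
      taken <- rbind(taken, cand)
    }
  }
  dimnames(centers) <- list(NULL, c("row", "col"))
  centers
}

render_spots <- function(height, width, centers, sigma, amplitude,
                         background) {
  img <- matrix(background, height, width)
  if (nrow(centers) == 0) return(img)
  half <- ceiling(4 * sigma)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    rows <- max(1, floor(r0) - half):min(height, ceiling(r0) + half)
    cols <- max(1, floor(c0) - half):min(width, ceiling(c0) + half)
    g <- amplitude *
      exp(-outer((rows - r0)^2, (cols - c0)^2, "+") / (2 * sigma^2))
    img[rows, cols] <- img[rows, cols] + g
  }
  img
}

add_noise <- function(clean, noise_sd, noise_model, poisson_scale) {
  if (noise_model == "poisson") {
    noisy <- stats::rpois(length(clean), clean * poisson_scale) /
      poisson_scale
  } else if (noise_sd > 0) {
    noisy <- clean + stats::rnorm(length(clean), 0, noise_sd)
  } else {
    noisy <- clean
  }
  matrix(pmax(noisy, 0), nrow(clean), ncol(clean))
}

disc_mask <- function(height, width, centers, radius) {
  mask <- matrix(FALSE, height, width)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    rows <- max(1, floor(r0 - radius)):min(height, ceiling(r0 + radius))
    cols <- max(1, floor(c0 - radius)):min(width, ceiling(c0 + radius))
    d2 <- outer((rows - r0)^2, (cols - c0)^2, "+")
    mask[rows, cols] <- mask[rows, cols] | (d2 <= radius^2)
  }
  mask
}

#' Simulate matched input and pull-down read libraries
#'
#' Input counts are drawn multinomially with a uniform per-bin probability
#' over the genome binning. Pull-down probabilities are the uniform
#' background multiplied by `fold_enrichment` at `target_bins` and, around
#' `partner_bins`, by
#' `1 + partner_peak_fraction * (fold_enrichment - 1) * exp(-d / decay_length_bp)`
#' where `d` is the base-pair distance from a bin's midpoint to the nearest
#' partner-bin midpoint on the same chromosome. This emulates a pull-down
#' that recovers both the targeted locus and contacting partner loci (for
#' example the two anchors of a chromatin loop) with distance-decaying
#' signal; the partner peak is a fraction of the direct-target excess
#' because partner material is recovered indirectly, through the contact.
#'
#' @param chrom_sizes Two-column data frame (`chrom`, `size_bp`) or named
#'   numeric vector of chromosome lengths.
#' @param bin_size_bp Genomic window size in bp (default 100000).
#' @param target_bins Integer indices (1-based, into the genome binning) of
#'   directly targeted bins.
#' @param partner_bins Integer indices of contacting partner bins; may be
#'   empty.
#' @param fold_enrichment Pull-down enrichment multiple at target bins
#'   (> 0; 1 plants no signal).
#' @param decay_length_bp Exponential decay length of partner enrichment in
#'   bp.
#' @param partner_peak_fraction Peak partner enrichment as a fraction of the
#'   direct-target excess enrichment, in `(0, 1]` (default 0.75).
#' @param depth_input,depth_pulldown Total read counts per library.
#' @param seed Integer seed.
#' @return List with `input` and `pulldown` ([binned_counts()] objects over
#'   the same binning), `binning`, and `truth` (the per-bin pull-down
#'   probability weights plus the planted indices).
#' @examples
#' sim <- simulate_libraries(c(chrA = 3e6), target_bins = 5,
#'                           fold_enrichment = 10, depth_input = 1e4,
#'                           depth_pulldown = 1e4, seed = 1)
#' which.max(sim$pulldown$counts)
#' @export
simulate_libraries <- function(chrom_sizes, bin_size_bp = 100000,
                               target_bins = integer(),
                               partner_bins = integer(),
                               fold_enrichment = 10,
                               decay_length_bp = 2 * bin_size_bp,
                               partner_peak_fraction = 0.75,
                               depth_input = 1e5, depth_pulldown = 1e5,
                               seed = NULL) {
  binning <- bin_genome(chrom_sizes, bin_size_bp)
  n_bins <- length(binning$bins)
  if (n_bins == 0) stop2("empty genome")
  if (depth_input <= 0 || depth_pulldown <= 0) {
    stop2("library depths must be positive")
  }
  if (fold_enrichment <= 0) stop2("fold_enrichment must be positive")
  target_bins <- as.integer(target_bins)
  partner_bins <- as.integer(partner_bins)
  if (length(target_bins) && (min(target_bins) < 1 ||
                              max(target_bins) > n_bins)) {
    stop2("target_bins out of range for this binning")
  }
  if (length(partner_bins) && (min(partner_bins) < 1 ||
                               max(partner_bins) > n_bins)) {
    stop2("partner_bins out of range for this binning")
  }

  w <- rep(1, n_bins)
  if (length(partner_bins)) {
    mids <- bin_midpoints(binning)
    chrom <- as.character(GenomeInfoDb::seqnames(binning$bins))
    for (chr in unique(chrom[partner_bins])) {
      on_chr <- which(chrom == chr)
      pmids <- mids[partner_bins[chrom[partner_bins] == chr]]
      d <- vapply(mids[on_chr], function(m) min(abs(m - pmids)), numeric(1))
      mult <- 1 + partner_peak_fraction * (fold_enrichment - 1) *
        exp(-d / decay_length_bp)
      w[on_chr] <- pmax(w[on_chr], mult)
    }
  }
  w[target_bins] <- fold_enrichment

  with_seed_if(seed, {
    input_counts <- as.vector(
      stats::rmultinom(1, depth_input, rep(1, n_bins)))
    pd_counts <- as.vector(stats::rmultinom(1, depth_pulldown, w))
    list(
      input = binned_counts(binning, input_counts, "input"),
      pulldown = binned_counts(binning, pd_counts, "pulldown"),
      binning = binning,
      truth = list(weights = w, target_bins = target_bins,
                   partner_bins = partner_bins,
                   fold_enrichment = fold_enrichment)
    )
  })
}

#' Expand binned counts into per-read BED-style intervals
#'
#' Inverse of [count_reads()] for simulated libraries: emits one interval per
#' counted read, placed uniformly at random inside its bin so that the
#' midpoint rule re-assigns it to the same bin.
#'
#' @param counts A [binned_counts()] object.
#' @param read_length_bp Read length in bp (clamped to the bin width for
#'   short terminal bins).
#' @param seed Integer seed for the within-bin placement.
#' @return A `GRanges` with one range per read.
#' @export
reads_from_counts <- function(counts, read_length_bp = 100, seed = NULL) {
  bins <- counts$binning$bins
  n <- counts$counts
  with_seed_if(seed, {
    idx <- rep(seq_along(bins), n)
    bstart <- GenomicRanges::start(bins)[idx] - 1L  # 0-based
    bend <- GenomicRanges::end(bins)[idx]           # exclusive
    len <- pmin(read_length_bp, bend - bstart)
    start0 <- bstart + floor(stats::runif(length(idx)) *
                               (bend - bstart - len + 1))
    GenomicRanges::GRanges(
      seqnames = GenomeInfoDb::seqnames(bins)[idx],
      ranges = IRanges::IRanges(start = start0 + 1, width = len))
  })
}

#' Simulate a replicate protein-intensity matrix with planted effects
#'
#' Log2 intensities are `base + effect + Normal(0, noise_sd)` where `effect`
#' equals the protein's planted log2 fold change in condition
#' `condition_a` and 0 in `condition_b`; reported intensities are
#' `2^log2-intensity`. The returned truth table enumerates exactly the
#' planted effects, so downstream sensitivity and false-discovery proportion
#' can be measured.
#'
#' @param n_proteins Number of proteins.
#' @param n_affected Number of proteins with a nonzero planted effect.
#' @param effect_lfc Absolute planted log2 fold change; signs alternate so
#'   both enrichment directions are represented.
#' @param noise_sd Replicate noise standard deviation on the log2 scale.
#' @param n_rep_a,n_rep_b Replicates per condition (at least 2 each).
#' @param condition_a,condition_b Condition labels.
#' @param base_log2_range Range of per-protein baseline log2 intensities.
#' @param seed Integer seed.
#' @return List with `intensities` (proteins x samples numeric matrix),
#'   `design` (data frame: `sample`, `condition`, `replicate`), and `truth`
#'   (data frame: `protein`, `planted_lfc`).
#' @examples
#' sim <- simulate_proteome(100, n_affected = 10, seed = 1)
#' sum(sim$truth$planted_lfc != 0)
#' @export
simulate_proteome <- function(n_proteins, n_affected = 0, effect_lfc = 2,
                              noise_sd = 0.25, n_rep_a = 4, n_rep_b = 4,
                              condition_a = "pulldown",
                              condition_b = "control",
                              base_log2_range = c(6, 14), seed = NULL) {
  if (n_rep_a < 2 || n_rep_b < 2) {
    stop2("at least 2 replicates per condition are required")
  }
  if (n_affected > n_proteins) stop2("n_affected exceeds n_proteins")
  ids <- sprintf("P%04d", seq_len(n_proteins))
  samples <- c(paste0(condition_a, "_", seq_len(n_rep_a)),
               paste0(condition_b, "_", seq_len(n_rep_b)))
  design <- data.frame(
    sample = samples,
    condition = rep(c(condition_a, condition_b), c(n_rep_a, n_rep_b)),
    replicate = c(seq_len(n_rep_a), seq_len(n_rep_b)),
    stringsAsFactors = FALSE)

  with_seed_if(seed, {
    planted <- numeric(n_proteins)
    if (n_affected > 0) {
      hit <- sample(n_proteins, n_affected)
      planted[hit] <- effect_lfc * rep_len(c(1, -1), n_affected)
    }
    base <- stats::runif(n_proteins, base_log2_range[1], base_log2_range[2])
    eff <- outer(planted, as.numeric(design$condition == condition_a))
    log2i <- base + eff
    if (noise_sd > 0) {
      log2i <- log2i + matrix(stats::rnorm(length(log2i), 0, noise_sd),
                              n_proteins)
    }
    intensities <- 2^log2i
    dimnames(intensities) <- list(ids, samples)
    list(intensities = intensities, design = design,
         truth = data.frame(protein = ids, planted_lfc = planted,
                            stringsAsFactors = FALSE))
  })
}
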