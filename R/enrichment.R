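# Bin-based genomic enrichment scoring of pull-down versus input libraries,
# adapted from TSA-seq-style window statistics: the genome is tiled into
# fixed windows (100 kb by default), each library's per-bin read fraction is
# stabilized with a pseudocount equal to a fraction of that library's total
# reads added to every bin, and the per-bin score is the ratio of the two
# fractions. Coordinates are 0-based half-open (BED convention) at the file
# boundary and 1-based closed inside GRanges.

#' Tile a genome into fixed-size windows
#'
#' @param chrom_sizes Two-column data frame (`chrom`, `size_bp`), a named
#'   numeric vector, or a path to a two-column chrom.sizes text file.
#' @param bin_size_bp Window size in bp; the last bin of each chromosome may
#'   be short.
#' @return A `genome_binning` object: list with `bins` (a `GRanges` ordered
#'   by input chromosome order then position), `bin_size_bp`, and
#'   `chrom_sizes` (named vector).
#' @examples
#' b <- bin_genome(c(chr1 = 250000), 100000)
#' length(b$bins)  # 3 bins, the last one short
#' @export
bin_genome <- function(chrom_sizes, bin_size_bp = 100000) {
  sizes <- as_chrom_sizes(chrom_sizes)
  if (!is_number(bin_size_bp) || bin_size_bp <= 0) {
    stop2("bin_size_bp must be positive")
  }
  if (anyDuplicated(names(sizes))) stop2("duplicate chromosome names")
  if (any(sizes <= 0)) stop2("chromosome lengths must be positive")
  # manual tiling (rather than tileGenome) so chromosomes shorter than one
  # bin are allowed: they get a single short bin
  starts0 <- lapply(sizes, function(len) seq(0, len - 1, by = bin_size_bp))
  chrom <- rep(names(sizes), lengths(starts0))
  starts0 <- unlist(starts0, use.names = FALSE)
  ends <- pmin(starts0 + bin_size_bp, sizes[chrom])
  bins <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = names(sizes)),
    ranges = IRanges::IRanges(start = starts0 + 1, end = ends),
    seqlengths = sizes)
  structure(list(bins = bins, bin_size_bp = bin_size_bp,
                 chrom_sizes = sizes),
            class = "genome_binning")
}

as_chrom_sizes <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    tab <- utils::read.table(x, header = FALSE, sep = "",
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "size_bp"))
    x <- tab
  }
  if (is.numeric(x) && length(x) == 0) {
    stop2("empty genome")
  }
  if (is.data.frame(x)) {
    sizes <- as.numeric(x[[2]])
    names(sizes) <- as.character(x[[1]])
  } else if (is.numeric(x) && !is.null(names(x))) {
    sizes <- x
  } else {
    stop2("chrom_sizes must be a named vector, two-column data frame, ",
          "or chrom.sizes file path")
  }
  if (length(sizes) == 0) stop2("empty genome")
  sizes
}

# 0-based midpoint coordinate of every bin: floor((start0 + end0) / 2)
bin_midpoints <- function(binning) {
  s0 <- GenomicRanges::start(binning$bins) - 1L
  e0 <- GenomicRanges::end(binning$bins)
  floor((s0 + e0) / 2)
}

#' Per-bin read counts for one library
#'
#' @param binning A [bin_genome()] result.
#' @param counts Nonnegative integer vector, one entry per bin.
#' @param library_label `"input"` or `"pulldown"`.
#' @return A `binned_counts` object with `binning`, `counts`, `total_reads`,
#'   and `library_label`.
#' @export
binned_counts <- function(binning, counts,
                          library_label = c("input", "pulldown")) {
  library_label <- match.arg(library_label)
  stopifnot(inherits(binning, "genome_binning"))
  counts <- as.numeric(counts)
  if (length(counts) != length(binning$bins)) {
    stop2("counts length must equal the number of bins")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop2("counts must be nonnegative integers")
  }
  structure(list(binning = binning, counts = counts,
                 total_reads = sum(counts), library_label = library_label),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts %s> %d bins, %d reads\n", x$library_label,
              length(x$counts), as.integer(x$total_reads)))
  invisible(x)
}

#' Read a BED interval file
#'
#' Thin wrapper over `rtracklayer::import` returning a `GRanges`; BED3 or
#' richer is accepted.
#'
#' @param path BED file path.
#' @return `GRanges` of the intervals.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write intervals as BED3
#'
#' @param gr A `GRanges`.
#' @param path Output path (0-based half-open coordinates on disk).
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Assign reads to genome bins by interval midpoint
#'
#' Each read interval is assigned to exactly one bin: the bin containing its
#' 0-based midpoint `floor((start0 + end0) / 2)`. This counts every read
#' once even when it straddles a bin edge. Reads on chromosomes absent from
#' the binning are skipped; their number is recorded in the
#' `n_skipped` attribute and reported via `message()`.
#'
#' @param reads A `GRanges` of read intervals, or a BED file path.
#' @param binning A [bin_genome()] result.
#' @param library_label `"input"` or `"pulldown"`.
#' @return A [binned_counts()] whose counts sum to the number of assigned
#'   reads.
#' @export
count_reads <- function(reads, binning,
                        library_label = c("input", "pulldown")) {
  library_label <- match.arg(library_label)
  if (is.character(reads)) reads <- read_bed(reads)
  stopifnot(inherits(binning, "genome_binning"))
  if (any(GenomicRanges::width(reads) < 1)) {
    stop2("read intervals must have end > start")
  }
  chrom <- as.character(GenomeInfoDb::seqnames(reads))
  known <- chrom %in% names(binning$chrom_sizes)
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    message(n_skipped, " read(s) on chromosomes absent from the binning ",
            "were skipped")
  }
  reads <- reads[known]
  chrom <- chrom[known]

  s0 <- GenomicRanges::start(reads) - 1L
  e0 <- GenomicRanges::end(reads)
  mid0 <- floor((s0 + e0) / 2)
  # clamp midpoints beyond the chromosome end into the terminal bin
  mid0 <- pmin(mid0, binning$chrom_sizes[chrom] - 1)

  bins <- binning$bins
  bin_chrom <- as.character(GenomeInfoDb::seqnames(bins))
  first_bin <- match(names(binning$chrom_sizes), bin_chrom)
  idx <- first_bin[match(chrom, names(binning$chrom_sizes))] +
    mid0 %/% binning$bin_size_bp
  counts <- tabulate(idx, nbins = length(bins))
  out <- binned_counts(binning, counts, library_label)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Pseudocounted per-bin enrichment scores
#'
#' For each library a pseudocount equal to `pseudocount_fraction` times that
#' library's total read count is added to every bin, per-bin read fractions
#' are recomputed over the pseudocounted sums, and the score of a bin is the
#' ratio of the two fractions:
#' `score(b) = frac_input(b) / frac_pulldown(b)` in the `as_printed`
#' orientation. With this orientation an enriched (pulled-down) locus has a
#' score below 1; the `inverted` orientation returns the per-bin reciprocal
#' `frac_pulldown / frac_input`, under which enriched loci score high. The
#' orientation is stamped into the result so downstream ranking can adapt.
#' The pseudocount guarantees every score is finite and positive, and makes
#' all scores shrink toward 1 as `pseudocount_fraction` grows.
#'
#' @param input,pulldown [binned_counts()] over the same binning, each with
#'   a positive total.
#' @param pseudocount_fraction Fraction of a library's total reads added to
#'   every bin of that library (default 0.10). Set `pseudocount_mode =
#'   "per_bin_mean"` to instead add that fraction of the library's *mean
#'   per-bin count* — a gentler stabilization some window-based protocols
#'   use.
#' @param orientation `"as_printed"` (input over pull-down) or `"inverted"`.
#' @param pseudocount_mode `"total"` (default) or `"per_bin_mean"`.
#' @return An `enrichment_profile` object: list with `binning`, `score`
#'   (per bin), `frac_input`, `frac_pulldown`, `counts_input`,
#'   `counts_pulldown`, `pseudocount_input`, `pseudocount_pulldown`,
#'   `pseudocount_fraction`, `pseudocount_mode`, and `orientation`.
#' @examples
#' b <- bin_genome(c(chrA = 200000), 100000)
#' p <- enrichment_scores(binned_counts(b, c(90, 10), "input"),
#'                        binned_counts(b, c(10, 90), "pulldown"))
#' p$score  # 5.0, 0.2
#' @export
enrichment_scores <- function(input, pulldown, pseudocount_fraction = 0.10,
                              orientation = c("as_printed", "inverted"),
                              pseudocount_mode = c("total", "per_bin_mean")) {
  orientation <- match.arg(orientation)
  pseudocount_mode <- match.arg(pseudocount_mode)
  stopifnot(inherits(input, "binned_counts"),
            inherits(pulldown, "binned_counts"))
  if (!identical(GenomicRanges::granges(input$binning$bins),
                 GenomicRanges::granges(pulldown$binning$bins))) {
    stop2("input and pulldown binnings differ")
  }
  if (input$total_reads <= 0 || pulldown$total_reads <= 0) {
    stop2("both libraries must have positive totals")
  }
  if (pseudocount_fraction < 0) stop2("pseudocount_fraction must be >= 0")
  n_bins <- length(input$counts)
  pc_of <- function(total) {
    if (pseudocount_mode == "total") pseudocount_fraction * total
    else pseudocount_fraction * total / n_bins
  }
  pc_in <- pc_of(input$total_reads)
  pc_pd <- pc_of(pulldown$total_reads)
  if (pseudocount_fraction == 0 &&
      (any(input$counts == 0) || any(pulldown$counts == 0))) {
    stop2("zero-count bins require a positive pseudocount_fraction")
  }
  aug_in <- input$counts + pc_in
  aug_pd <- pulldown$counts + pc_pd
  frac_in <- aug_in / sum(aug_in)
  frac_pd <- aug_pd / sum(aug_pd)
  score <- frac_in / frac_pd
  if (orientation == "inverted") score <- 1 / score
  structure(list(binning = input$binning, score = score,
                 frac_input = frac_in, frac_pulldown = frac_pd,
                 counts_input = input$counts,
                 counts_pulldown = pulldown$counts,
                 pseudocount_input = pc_in, pseudocount_pulldown = pc_pd,
                 pseudocount_fraction = pseudocount_fraction,
                 pseudocount_mode = pseudocount_mode,
                 orientation = orientation),
            class = "enrichment_profile")
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat(sprintf(
    "<enrichment_profile> %d bins, orientation %s, pseudocount %g x %s\n",
    length(x$score), x$orientation, x$pseudocount_fraction,
    x$pseudocount_mode))
  cat(sprintf("  score range [%.4g, %.4g], median %.4g\n", min(x$score),
              max(x$score), stats::median(x$score)))
  invisible(x)
}

# score oriented so that pulled-down loci are LARGE, whatever the stored
# orientation
pulldown_oriented_score <- function(profile) {
  if (profile$orientation == "inverted") profile$score else 1 / profile$score
}

#' Enrichment as a function of distance from target regions
#'
#' Annotates every bin with the base-pair distance from its midpoint to the
#' nearest point of the nearest same-chromosome target region. Bins that
#' overlap a target are the on-target stratum and carry distance 0; bins on
#' chromosomes without any target have no defined distance and are excluded.
#' The log10 distance is reported only for the strictly positive distances
#' of off-target bins, so the log axis stays well defined.
#'
#' @param profile An [enrichment_scores()] result.
#' @param targets Target regions: a `GRanges` or BED file path.
#' @return Data frame with `bin_index`, `chrom`, `start`, `end` (0-based
#'   half-open), `distance_bp`, `log10_distance` (`NA` for on-target bins),
#'   `on_target`, and `score`.
#' @export
distance_profile <- function(profile, targets) {
  stopifnot(inherits(profile, "enrichment_profile"))
  if (is.character(targets)) targets <- read_bed(targets)
  if (length(targets) == 0) stop2("no target regions given")
  bins <- profile$binning$bins
  mids0 <- bin_midpoints(profile$binning)
  midpoints <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(bins),
    ranges = IRanges::IRanges(start = mids0 + 1, width = 1))
  GenomeInfoDb::seqlevels(targets) <- union(
    GenomeInfoDb::seqlevels(targets), GenomeInfoDb::seqlevels(midpoints))
  hits <- GenomicRanges::distanceToNearest(midpoints, targets,
                                           ignore.strand = TRUE)
  idx <- S4Vectors::queryHits(hits)
  d <- S4Vectors::mcols(hits)$distance
  on_target <- idx %in% unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(bins, targets, ignore.strand = TRUE)))
  d[on_target] <- 0
  data.frame(
    bin_index = idx,
    chrom = as.character(GenomeInfoDb::seqnames(bins))[idx],
    start = GenomicRanges::start(bins)[idx] - 1L,
    end = GenomicRanges::end(bins)[idx],
    distance_bp = d,
    log10_distance = ifelse(d > 0, log10(d), NA_real_),
    on_target = on_target,
    score = profile$score[idx],
    stringsAsFactors = FALSE)
}

#' Rank-based recovery summary for targets and partner loci
#'
#' Ranks all bins by pull-down-oriented enrichment (rank 1 = most enriched,
#' regardless of the profile's stored orientation) and summarizes where the
#' target bins and the contacting partner bins fall relative to background.
#' Used to ask whether a targeted locus tops the genome-wide ranking and
#' whether its interaction partners (for example, the opposite anchor of a
#' chromatin loop) outrank background.
#'
#' @param profile An [enrichment_scores()] result.
#' @param targets Target regions (`GRanges`, BED path) or integer bin
#'   indices.
#' @param partners Optional partner regions in the same forms; may be empty.
#' @return A list with `target_ranks`, `best_target_rank`, `partner_ranks`,
#'   `median_partner_rank`, `median_background_rank`,
#'   `median_background_score` (pull-down oriented), and `n_bins`.
#' @export
summarize_recovery <- function(profile, targets, partners = integer()) {
  stopifnot(inherits(profile, "enrichment_profile"))
  t_idx <- region_bin_indices(profile$binning, targets)
  p_idx <- setdiff(region_bin_indices(profile$binning, partners), t_idx)
  if (length(t_idx) == 0) stop2("no target bins identified")
  e <- pulldown_oriented_score(profile)
  # rank 1 = highest pull-down enrichment; ties averaged
  rk <- rank(-e, ties.method = "average")
  bg <- setdiff(seq_along(e), c(t_idx, p_idx))
  list(target_ranks = sort(rk[t_idx]),
       best_target_rank = min(rk[t_idx]),
       partner_ranks = sort(rk[p_idx]),
       median_partner_rank = if (length(p_idx)) stats::median(rk[p_idx])
                             else NA_real_,
       median_background_rank = stats::median(rk[bg]),
       median_background_score = stats::median(e[bg]),
       n_bins = length(e))
}

region_bin_indices <- function(binning, regions) {
  if (is.numeric(regions)) {
    idx <- as.integer(regions)
    if (length(idx) && (min(idx) < 1 || max(idx) > length(binning$bins))) {
      stop2("bin indices out of range")
    }
    return(idx)
  }
  if (is.character(regions)) regions <- read_bed(regions)
  if (length(regions) == 0) return(integer())
  GenomeInfoDb::seqlevels(regions) <- union(
    GenomeInfoDb::seqlevels(regions), GenomeInfoDb::seqlevels(binning$bins))
  unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
    binning$bins, regions, ignore.strand = TRUE)))
}

#' Write an enrichment profile as bedGraph and TSV
#'
#' @param profile An [enrichment_scores()] result.
#' @param bedgraph_path Optional bedGraph output (chrom, start, end, score).
#' @param tsv_path Optional TSV with counts, pseudocounted fractions and
#'   scores per bin.
#' @return Invisibly, the per-bin data frame that was (or would be) written.
#' @export
write_profile <- function(profile, bedgraph_path = NULL, tsv_path = NULL) {
  bins <- profile$binning$bins
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(bins)),
    start = GenomicRanges::start(bins) - 1L,
    end = GenomicRanges::end(bins),
    counts_input = profile$counts_input,
    counts_pulldown = profile$counts_pulldown,
    frac_input = profile$frac_input,
    frac_pulldown = profile$frac_pulldown,
    score = profile$score,
    stringsAsFactors = FALSE)
  if (!is.null(bedgraph_path)) {
    utils::write.table(df[c("chrom", "start", "end", "score")],
                       bedgraph_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(df)
}
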