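# Differential proximity-proteomics statistics: column normalization of the
# protein-by-sample intensity matrix, per-protein two-sided t-tests (Welch
# by default) on log2 intensities, Benjamini-Hochberg adjustment, and a
# fold-change + q-value significance gate.

#' Column-normalize an intensity matrix for total protein amount
#'
#' Each sample column is scaled so its sum equals the mean of the original
#' column sums; within-column ratios are unchanged. This removes per-sample
#' loading differences ahead of the per-protein tests, and is idempotent.
#'
#' @param intensities Proteins x samples numeric matrix with nonnegative
#'   values (`NA` marks a protein not quantified in a sample) and every
#'   column sum positive.
#' @return The normalized matrix; column scale factors are attached as the
#'   `scale_factors` attribute.
#' @examples
#' m <- cbind(a = c(60, 40), b = c(180, 120))
#' colSums(column_normalize(m))
#' @export
column_normalize <- function(intensities) {
  intensities <- as.matrix(intensities)
  vals <- intensities[!is.na(intensities)]
  if (any(is.nan(vals)) || any(is.infinite(vals)) || any(vals < 0)) {
    stop2("intensities must be nonnegative and finite (or NA)")
  }
  sums <- colSums(intensities, na.rm = TRUE)
  if (any(sums <= 0)) stop2("every column sum must be positive")
  f <- mean(sums) / sums
  out <- sweep(intensities, 2, f, "*")
  attr(out, "scale_factors") <- f
  out
}

#' Per-protein two-sided t-tests between two conditions
#'
#' Tests every protein for differential abundance between `contrast[1]`
#' (condition A) and `contrast[2]` (condition B) on log2-transformed
#' normalized intensities. `log2fc = mean_log2_a - mean_log2_b`, so positive
#' values mean higher abundance in condition A. The Welch variant uses
#' Welch-Satterthwaite degrees of freedom (unequal variances); the Student
#' variant pools variances. Proteins with zero variance in both groups get
#' `p = 1` when the means are equal and `p = 0` (infinite `t`) otherwise.
#' Zero intensities are floored at the smallest nonzero value of the matrix
#' before taking log2; proteins with fewer than 2 finite values in either
#' condition are excluded and listed in the `skipped` attribute.
#'
#' @param intensities Proteins x samples matrix (raw or already
#'   column-normalized; set `normalize = FALSE` to skip the internal
#'   [column_normalize()]).
#' @param design Data frame with columns `sample` and `condition`; `sample`
#'   must match the matrix column names.
#' @param contrast Length-2 character vector `c(condition_a, condition_b)`.
#' @param variant `"welch"` (default) or `"student"`.
#' @param normalize Column-normalize before testing (default `TRUE`).
#' @return A `differential_table`: data frame with `protein`, `mean_log2_a`,
#'   `mean_log2_b`, `log2fc`, `t_stat`, `df`, `p_value`, `q_value`
#'   (Benjamini-Hochberg), ordered as the input matrix minus skipped
#'   proteins. Attributes: `contrast`, `variant`, `skipped`.
#' @export
protein_tests <- function(intensities, design,
                          contrast,
                          variant = c("welch", "student"),
                          normalize = TRUE) {
  variant <- match.arg(variant)
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities))) {
    rownames(intensities) <- sprintf("protein_%d", seq_len(nrow(intensities)))
  }
  if (!all(c("sample", "condition") %in% names(design))) {
    stop2("design needs columns `sample` and `condition`")
  }
  if (length(contrast) != 2) stop2("contrast must name two conditions")
  cond <- design$condition[match(colnames(intensities), design$sample)]
  if (anyNA(cond)) stop2("matrix columns missing from the design")
  if (!all(contrast %in% cond)) {
    stop2("unknown condition label(s): ",
          paste(setdiff(contrast, cond), collapse = ", "))
  }
  a_cols <- which(cond == contrast[1])
  b_cols <- which(cond == contrast[2])
  if (length(a_cols) < 2 || length(b_cols) < 2) {
    stop2("each condition needs at least 2 replicates")
  }
  if (normalize) intensities <- column_normalize(intensities)

  floor_val <- suppressWarnings(min(intensities[intensities > 0], na.rm = TRUE))
  if (!is.finite(floor_val)) stop2("matrix has no positive intensities")
  n_floored <- sum(intensities <= 0, na.rm = TRUE)
  lg <- log2(pmax(intensities, floor_val))

  a <- lg[, a_cols, drop = FALSE]
  b <- lg[, b_cols, drop = FALSE]
  n_a <- rowSums(!is.na(a))
  n_b <- rowSums(!is.na(b))
  testable <- n_a >= 2 & n_b >= 2
  skipped <- rownames(intensities)[!testable]

  a <- a[testable, , drop = FALSE]
  b <- b[testable, , drop = FALSE]
  na <- n_a[testable]
  nb <- n_b[testable]
  m_a <- rowMeans(a, na.rm = TRUE)
  m_b <- rowMeans(b, na.rm = TRUE)
  v_a <- apply(a, 1, stats::var, na.rm = TRUE)
  v_b <- apply(b, 1, stats::var, na.rm = TRUE)

  if (variant == "welch") {
    se2 <- v_a / na + v_b / nb
    df <- se2^2 / ((v_a / na)^2 / (na - 1) + (v_b / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * v_a + (nb - 1) * v_b) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  delta <- m_a - m_b
  t_stat <- delta / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  # degenerate variance: both groups constant
  zero_var <- se2 == 0
  t_stat[zero_var & delta == 0] <- 0
  p[zero_var & delta == 0] <- 1
  t_stat[zero_var & delta != 0] <- sign(delta[zero_var & delta != 0]) * Inf
  p[zero_var & delta != 0] <- 0
  df[zero_var] <- NA_real_

  out <- data.frame(
    protein = rownames(intensities)[testable],
    mean_log2_a = m_a, mean_log2_b = m_b,
    log2fc = delta, t_stat = t_stat, df = df,
    p_value = p, q_value = bh_adjust(p),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, contrast = contrast, variant = variant,
            skipped = skipped, n_floored = n_floored,
            class = c("differential_table", "data.frame"))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values (BH-adjusted p-values), same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop2("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Apply fold-change and q-value significance gates
#'
#' A protein is called significant when `|log2fc| > lfc_min` AND
#' `q_value < q_max`, both strict. The defaults (`lfc_min = 1`, i.e. a
#' twofold change, and `q_max = 0.05`) are the conventional volcano-plot
#' gates; relaxed screens often use `q_max = 0.1` with the same fold gate.
#'
#' @param table A [protein_tests()] result (any data frame with `log2fc`
#'   and `q_value` columns).
#' @param lfc_min Minimum absolute log2 fold change (exclusive).
#' @param q_max Maximum q-value (exclusive).
#' @return The table with a logical `significant` column added; the gates
#'   are recorded in the `gates` attribute.
#' @export
call_significant <- function(table, lfc_min = 1, q_max = 0.05) {
  if (!all(c("log2fc", "q_value") %in% names(table))) {
    stop2("table needs `log2fc` and `q_value` columns")
  }
  table$significant <- abs(table$log2fc) > lfc_min & table$q_value < q_max
  attr(table, "gates") <- c(lfc_min = lfc_min, q_max = q_max)
  table
}

#' Run the full differential-proteomics stage
#'
#' Convenience wrapper: [column_normalize()] -> [protein_tests()] ->
#' [call_significant()], optionally writing the per-contrast TSV.
#'
#' @inheritParams protein_tests
#' @inheritParams call_significant
#' @param tsv_path Optional output TSV path.
#' @return The gated [protein_tests()] table.
#' @export
run_diffprot <- function(intensities, design, contrast,
                         variant = c("welch", "student"),
                         lfc_min = 1, q_max = 0.05, tsv_path = NULL) {
  tab <- protein_tests(intensities, design, contrast, variant)
  tab <- call_significant(tab, lfc_min = lfc_min, q_max = q_max)
  if (!is.null(tsv_path)) {
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tab
}

#' Read an intensity matrix TSV (first column protein IDs)
#' @param path TSV path.
#' @return Numeric matrix with protein row names.
#' @export
read_intensities <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write an intensity matrix TSV (first column protein IDs)
#' @param intensities Matrix with protein row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensities <- function(intensities, path) {
  df <- data.frame(protein = rownames(intensities), intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
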