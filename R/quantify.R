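# Unique-peptide label-free quantification: group intensities,
# enrichment ratios, volcano statistics, molecular weights.

#' Aggregate unique-peptide intensities per protein group
#'
#' Per-sample group intensity is the sum of the intensities of peptides
#' unique to the group; razor peptides (spanning groups) are excluded.
#' Groups with no unique peptide are flagged unquantifiable rather than
#' raising an error. Missing observations contribute 0.
#'
#' @param groups Tibble from [group_proteins()].
#' @param matches Tibble from [peptide_matches()] with per-sample
#'   intensity columns.
#' @return Tibble: `group_id`, `quantifiable`, one column per sample.
#' @export
aggregate_group_intensity <- function(groups, matches) {
  sample_cols <- setdiff(names(matches), c("peptide", "proteins"))
  member_group <- group_lookup(groups)
  pep_groups <- lapply(matches$proteins, function(p) unique(member_group[p]))
  unique_to <- ifelse(lengths(pep_groups) == 1,
    vapply(pep_groups, `[`, character(1), 1), NA_character_
  )
  out <- tibble::tibble(group_id = groups$group_id)
  for (s in sample_cols) {
    v <- tapply(matches[[s]], factor(unique_to, levels = groups$group_id), sum)
    v[is.na(v)] <- 0
    out[[s]] <- as.numeric(v)
  }
  out$quantifiable <- groups$group_id %in% unique_to[!is.na(unique_to)]
  out[, c("group_id", "quantifiable", sample_cols)]
}

#' Enrichment ratios and confidence bins
#'
#' Computes mitochondria/chloroplast and mitochondria/whole-cell ratios
#' from replicate means of the per-sample intensities. A zero denominator
#' with a positive numerator gives an infinite ratio (its own confidence
#' category, not a sentinel number); both zero gives an undefined ratio.
#' A group is enriched when both ratios exceed 1 (infinite counts as
#' greater than 1). The log10 Mt/Cp confidence bin is `infinite`,
#' `>1.0` for log10 > 1 (more than 10x), `0.0-1.0` for log10 in (0, 1]
#' (1-10x, interval closed on the right), else `not_enriched`.
#'
#' @param intensities Tibble from [aggregate_group_intensity()] with
#'   sample columns named `<fraction>_<replicate>` over fractions `mt`,
#'   `cp`, `wc`.
#' @return Tibble: `group_id`, `quantifiable`, `mean_mt`, `mean_cp`,
#'   `mean_wc`, `ratio_mt_cp`, `ratio_mt_wc`, `log10_mt_cp`, `enriched`,
#'   `confidence_bin`.
#' @export
enrichment_ratios <- function(intensities) {
  sample_cols <- setdiff(names(intensities), c("group_id", "quantifiable"))
  empty <- tibble::tibble(
    group_id = character(), quantifiable = logical(),
    mean_mt = numeric(), mean_cp = numeric(), mean_wc = numeric(),
    ratio_mt_cp = numeric(), ratio_mt_wc = numeric(),
    log10_mt_cp = numeric(), enriched = logical(),
    confidence_bin = character()
  )
  if (nrow(intensities) == 0) {
    return(empty)
  }
  fr <- sub("_[0-9]+$", "", sample_cols)
  if (!all(c("mt") %in% fr)) {
    stop("at least one mitochondrial-fraction sample (mt_*) is required",
      call. = FALSE
    )
  }
  mat <- as.matrix(intensities[, sample_cols, drop = FALSE])
  if (any(mat < 0)) stop("intensities must be nonnegative", call. = FALSE)
  frac_mean <- function(f) {
    cols <- sample_cols[fr == f]
    if (length(cols) == 0) {
      return(rep(NA_real_, nrow(mat)))
    }
    rowMeans(mat[, cols, drop = FALSE])
  }
  m_mt <- frac_mean("mt")
  m_cp <- frac_mean("cp")
  m_wc <- frac_mean("wc")
  ratio <- function(num, den) {
    ifelse(den > 0, num / den, ifelse(num > 0, Inf, NaN))
  }
  r_cp <- ratio(m_mt, m_cp)
  r_wc <- ratio(m_mt, m_wc)
  lg <- log10(r_cp)
  gt1 <- function(r) !is.nan(r) & r > 1 # Inf counts as > 1
  enriched <- gt1(r_cp) & gt1(r_wc)
  bin <- ifelse(is.nan(r_cp), "not_enriched",
    ifelse(is.infinite(r_cp), "infinite",
      ifelse(lg > 1, ">1.0",
        ifelse(lg > 0, "0.0-1.0", "not_enriched")
      )
    )
  )
  tibble::tibble(
    group_id = intensities$group_id,
    quantifiable = intensities$quantifiable %||% TRUE,
    mean_mt = m_mt, mean_cp = m_cp, mean_wc = m_wc,
    ratio_mt_cp = r_cp, ratio_mt_wc = r_wc,
    log10_mt_cp = lg,
    enriched = enriched,
    confidence_bin = bin
  )
}

#' Welch two-sample statistics for volcano plots
#'
#' Difference of means and two-sided Welch (unequal-variance) t-test
#' p-value on log10 intensities. With fewer than two replicates on
#' either side the p-value is undefined (`NA`). Degenerate zero-variance
#' cases: equal means give p = 1; unequal means give the smallest
#' representable positive double.
#'
#' @param x,y Numeric vectors of log10 intensities (e.g. mitochondrial
#'   vs chloroplast replicates).
#' @return List: `lfc` (mean(x) - mean(y)), `p_value`.
#' @export
volcano_stats <- function(x, y) {
  lfc <- mean(x) - mean(y)
  if (length(x) < 2 || length(y) < 2) {
    return(list(lfc = lfc, p_value = NA_real_))
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    p <- if (lfc == 0) 1 else .Machine$double.xmin
    return(list(lfc = lfc, p_value = p))
  }
  se2 <- vx / length(x) + vy / length(y)
  t_stat <- lfc / sqrt(se2)
  df <- se2^2 / (
    (vx / length(x))^2 / (length(x) - 1) +
      (vy / length(y))^2 / (length(y) - 1)
  )
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(lfc = lfc, p_value = max(p, .Machine$double.xmin))
}

# Average (not monoisotopic) residue masses in Da.
AA_AVERAGE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

#' Molecular weight of a protein sequence
#'
#' Average (not monoisotopic) residue masses plus one water, in kDa at
#' full precision; summary tables round to two decimals when written.
#'
#' @param sequence Amino-acid string (vectorised).
#' @return Numeric kDa.
#' @examples
#' molecular_weight("G")  # 0.0751 kDa
#' @export
molecular_weight <- function(sequence) {
  assert_aa(sequence)
  vapply(sequence, function(s) {
    if (nchar(s) == 0) {
      return(0)
    }
    residues <- strsplit(s, "")[[1]]
    (sum(AA_AVERAGE_MASS[residues]) + WATER_MASS) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}
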