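# Prophage activity: phage-to-host ratio, plasmid copy-number correction,
# activity classification and group comparison.

#' Phage-to-host ratio of a prophage region
#'
#' Mean depth over the prophage region divided by the median depth of its
#' genomic neighbourhood (the background segment containing the region); a
#' proxy for phage genome copies per host chromosome.
#'
#' @param region `c(start, end)` 0-based half-open interval on the contig.
#' @param depths Per-base depths of the contig.
#' @param stats [background_stats()] of the enclosing segment.
#' @return PtoH ratio (numeric); `NA` with a warning if the neighbourhood
#'   median is zero.
#' @export
compute_ptoh <- function(region, depths, stats) {
  stopifnot(region[1] >= 0, region[2] <= length(depths),
            region[2] > region[1])
  if (stats$median <= 0) {
    warning("neighbourhood median is zero; PtoH undefined")
    return(NA_real_)
  }
  mean(depths[(region[1] + 1):region[2]]) / stats$median
}

#' Plasmid copy-number corrected phage-to-host ratio
#'
#' For prophages residing on plasmid contigs the raw ratio compares the
#' region mean against the whole-genome median; it is then divided by the
#' plasmid copy number estimated from non-induced sequencing, but only when
#' the plasmid is multi-copy — the correction can only decrease PtoH.
#'
#' @param region_mean Mean depth over the prophage region.
#' @param genome_median Whole-genome median depth.
#' @param copy_number Plasmid copy number (>= 1) from non-induced data.
#' @return List with `raw` and `corrected` PtoH.
#' @export
correct_plasmid_ptoh <- function(region_mean, genome_median, copy_number) {
  stopifnot(genome_median > 0)
  if (copy_number < 1) {
    warning("copy number ", copy_number, " < 1; clamping to 1")
    copy_number <- 1
  }
  raw <- region_mean / genome_median
  list(raw = raw,
       corrected = if (copy_number > 1) raw / copy_number else raw)
}

#' Classify prophage activity from its coverage excess
#'
#' A prophage is highly active when its mean coverage exceeds the
#' neighbourhood median by at least three corrected standard deviations,
#' (low) active at one to three, and inactive below one (boundaries
#' inclusive).
#'
#' @param mean_coverage Mean depth over the prophage region.
#' @param stats [background_stats()] of the enclosing segment.
#' @return One of `"high_active"`, `"low_active"`, `"inactive"`.
#' @export
classify_activity <- function(mean_coverage, stats) {
  if (stats$corrected_std == 0 && mean_coverage > stats$median) {
    message("corrected SD is zero; any excess over the median is high_active")
    return("high_active")
  }
  if (mean_coverage >= stats$median + 3 * stats$corrected_std) "high_active"
  else if (mean_coverage >= stats$median + 1 * stats$corrected_std) "low_active"
  else "inactive"
}

#' Compare phage-to-host ratios between two groups
#'
#' Shapiro-Wilk normality per group, then a two-sided Wilcoxon rank-sum
#' test: exact when both groups have at most 25 observations and there are
#' no ties, otherwise the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param a,b Numeric vectors (each of length >= 3).
#' @return List with `shapiro_p` (length-2 vector), `normal` (logical
#'   length-2 at alpha = 0.05), `statistic` (rank-sum W), `p_value`,
#'   `exact` (logical).
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 observations")
  sw <- c(a = stats::shapiro.test(a)$p.value,
          b = stats::shapiro.test(b)$p.value)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- length(a) <= 25 && length(b) <= 25 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(shapiro_p = sw, normal = sw > 0.05,
       statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = use_exact)
}
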