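#' Detection parameters for induction-based prophage calling
#'
#' Container for every constant used by the coverage-based detection stage.
#' Defaults are the values used throughout the package; all are overridable.
#'
#' @param window_bp Sliding-window width in bp for coverage smoothing.
#' @param step_bp Step size between window starts in bp.
#' @param min_contig_stats_bp Minimum contig length for per-contig background
#'   statistics; shorter contigs fall under the plasmid rule or are ignored.
#' @param slice_threshold_bp Contigs longer than this are sliced into equal
#'   pieces for background estimation.
#' @param slice_max_bp Maximum slice length after slicing.
#' @param extreme_factor Depth values above `extreme_factor * median` are
#'   excluded from the corrected standard deviation.
#' @param plasmid_min_bp,plasmid_max_bp Contig size range (bp, half-open
#'   `[min, max)`) treated as potential multi-copy plasmids.
#' @param short_elem_min_bp,short_elem_max_bp Span range for short elements
#'   called at the stringent threshold.
#' @param short_factor Threshold multiplier (in corrected SDs above the
#'   median) for short elements.
#' @param long_factor Threshold multiplier for elements longer than
#'   `short_elem_max_bp`.
#' @param merge_gap_bp Elements closer than this (strictly) are merged.
#' @param min_reads Samples with at most this many reads are excluded.
#' @param min_identity,min_aln_len,min_read_fraction Alignment filters:
#'   minimum identity fraction, minimum alignment length (bp) and minimum
#'   fraction of the read aligned.
#' @param clip_min_reads Minimum clipped reads agreeing on a position for
#'   clip-based border refinement.
#' @param clip_agree_bp Clip positions within this many bp are counted as
#'   agreeing.
#' @param clip_search_bp Search radius around a candidate border for clip
#'   evidence and coverage-step refinement.
#'
#' @return A named list of class `detection_params`.
#' @export
detection_params <- function(window_bp = 250L, step_bp = 50L,
                             min_contig_stats_bp = 80000L,
                             slice_threshold_bp = 350000L,
                             slice_max_bp = 300000L,
                             extreme_factor = 3,
                             plasmid_min_bp = 5000L, plasmid_max_bp = 80000L,
                             short_elem_min_bp = 500L, short_elem_max_bp = 1500L,
                             short_factor = 3, long_factor = 1,
                             merge_gap_bp = 1000L,
                             min_reads = 250000L,
                             min_identity = 0.99, min_aln_len = 50L,
                             min_read_fraction = 0.80,
                             clip_min_reads = 3L, clip_agree_bp = 5L,
                             clip_search_bp = 500L) {
  p <- list(window_bp = as.integer(window_bp), step_bp = as.integer(step_bp),
            min_contig_stats_bp = as.integer(min_contig_stats_bp),
            slice_threshold_bp = as.integer(slice_threshold_bp),
            slice_max_bp = as.integer(slice_max_bp),
            extreme_factor = extreme_factor,
            plasmid_min_bp = as.integer(plasmid_min_bp),
            plasmid_max_bp = as.integer(plasmid_max_bp),
            short_elem_min_bp = as.integer(short_elem_min_bp),
            short_elem_max_bp = as.integer(short_elem_max_bp),
            short_factor = short_factor, long_factor = long_factor,
            merge_gap_bp = as.integer(merge_gap_bp),
            min_reads = as.integer(min_reads),
            min_identity = min_identity, min_aln_len = as.integer(min_aln_len),
            min_read_fraction = min_read_fraction,
            clip_min_reads = as.integer(clip_min_reads),
            clip_agree_bp = as.integer(clip_agree_bp),
            clip_search_bp = as.integer(clip_search_bp))
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x > 0, logical(1))),
            p$short_elem_min_bp < p$short_elem_max_bp)
  structure(p, class = "detection_params")
}

#' Curation rules for gene-content based prophage classification
#'
#' Marker labels, viral-origin keywords and realm-specific size thresholds
#' used to decide whether a candidate element is a prophage and which viral
#' realm it belongs to. Realms follow the three-realm vocabulary used for
#' temperate phages: `tailed` (Duplodnaviria; terminase / major capsid),
#' `filamentous` (Monodnaviria; pI-like ATPase, "gene 1" / zonular occludens
#' toxin homologs) and `tailless` (Varidnaviria; double jelly-roll capsid).
#'
#' @param min_genes Minimum gene count for a candidate.
#' @param min_keyword_genes Minimum number of distinct genes with a viral
#'   keyword for acceptance without a marker gene.
#' @param markers Named list mapping realm to character vector of marker label
#'   substrings (matched case-insensitively).
#' @param keywords Character vector of viral-origin keywords (case-insensitive
#'   substring match).
#' @param size_min_bp Named numeric vector of minimum element lengths per
#'   realm class (inclusive).
#'
#' @return A named list of class `curation_rules`.
#' @export
curation_rules <- function(min_genes = 5L, min_keyword_genes = 2L,
                           markers = list(
                             tailless    = c("double jelly-roll capsid",
                                             "double jelly roll capsid"),
                             filamentous = c("pI-like ATPase", "gene 1",
                                             "zonular occludens toxin"),
                             tailed      = c("terminase large subunit",
                                             "terminase endonuclease subunit",
                                             "major capsid protein")),
                           keywords = c("coat", "capsid", "head", "tail",
                                        "virion", "phage", "holin",
                                        "terminase", "replication",
                                        "packaging", "Vpf81",
                                        "BPPHL_Gene_1_protein",
                                        "BPFD_Gene_1_protein"),
                           size_min_bp = c(filamentous = 4000, other = 4000,
                                           tailless = 10000, tailed = 25000)) {
  stopifnot(min_genes >= 1, min_keyword_genes >= 1,
            all(c("tailless", "filamentous", "tailed") %in% names(markers)),
            all(c("filamentous", "other", "tailless", "tailed") %in%
                  names(size_min_bp)))
  structure(list(min_genes = as.integer(min_genes),
                 min_keyword_genes = as.integer(min_keyword_genes),
                 markers = markers, keywords = keywords,
                 size_min_bp = size_min_bp),
            class = "curation_rules")
}

#' Parameters for fragment-based ANI estimation and dereplication
#'
#' @param ani_threshold Minimum ANI (percent) for a pair to count as highly
#'   similar (recent common descent).
#' @param coverage_threshold Minimum fraction of the shorter sequence covered
#'   by mapped fragments for pair retention; 1.0 means complete coverage.
#' @param fragment_bp Fragment length the shorter sequence is cut into.
#' @param min_last_fragment_bp Trailing fragment kept only if at least this
#'   long.
#' @param kmer_seed Exact seed length used to anchor fragment mapping.
#' @param min_fragment_identity Minimum identity (fraction) for a fragment to
#'   count as mapped; below this a seeded hit is treated as spurious.
#' @param derep_identity ANI threshold (percent) for dereplication.
#' @param derep_coverage Coverage-of-shorter threshold (fraction) for
#'   dereplication.
#' @param band Half-width of the extension window (bp) added around a seeded
#'   candidate location before gapped alignment.
#'
#' @return A named list of class `similarity_params`.
#' @export
similarity_params <- function(ani_threshold = 99.9, coverage_threshold = 1.0,
                              fragment_bp = 1000L, min_last_fragment_bp = 500L,
                              kmer_seed = 15L, min_fragment_identity = 0.7,
                              derep_identity = 99.9, derep_coverage = 0.8,
                              band = 32L) {
  stopifnot(ani_threshold > 0, ani_threshold <= 100,
            coverage_threshold > 0, coverage_threshold <= 1,
            fragment_bp >= 100, kmer_seed >= 8)
  structure(list(ani_threshold = ani_threshold,
                 coverage_threshold = coverage_threshold,
                 fragment_bp = as.integer(fragment_bp),
                 min_last_fragment_bp = as.integer(min_last_fragment_bp),
                 kmer_seed = as.integer(kmer_seed),
                 min_fragment_identity = min_fragment_identity,
                 derep_identity = derep_identity,
                 derep_coverage = derep_coverage,
                 band = as.integer(band)),
            class = "similarity_params")
}

#' Parameters for Markov Clustering of protein similarity graphs
#'
#' @param inflation Inflation exponent applied elementwise each iteration.
#' @param prune Entries below this value are zeroed (then columns
#'   renormalised) to keep the matrix sparse and iterations stable.
#' @param max_iter Maximum number of expansion/inflation iterations.
#' @param tol Convergence: maximum absolute change of any matrix entry.
#' @param weight_cap Edge weights are `min(ceiling(-log10(evalue)), weight_cap)`.
#'
#' @return A named list of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 3, prune = 1e-6, max_iter = 200L,
                       tol = 1e-8, weight_cap = 200) {
  stopifnot(inflation > 1, prune >= 0, max_iter >= 1, tol > 0, weight_cap > 0)
  structure(list(inflation = inflation, prune = prune,
                 max_iter = as.integer(max_iter), tol = tol,
                 weight_cap = weight_cap),
            class = "mcl_params")
}
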