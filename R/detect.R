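# Coverage-based detection of actively induced genomic elements.
#
# The detector compares per-base read depth against a robust per-segment
# background (median and a corrected standard deviation that excludes
# depths above 3x the median, so that excising elements do not inflate the
# background spread), then calls elevated regions with a 250-bp / 50-bp
# sliding window at two stringencies: long elements (> 1500 bp) above
# median + 1 SD, short elements (500-1500 bp) above median + 3 SD.

#' Filter alignment records by identity, length, read fraction and primacy
#'
#' Keeps records that are primary alignments with identity >= 99%, aligned
#' length >= 50 bp and at least 80% of the read aligned (defaults from
#' `detection_params()`). Malformed records (NA in any required field) are
#' skipped and counted.
#'
#' @param records `data.frame` with columns `read_id`, `contig`, `start`,
#'   `end`, `identity`, `read_fraction`, `is_primary` (0-based half-open
#'   coordinates).
#' @param params A [detection_params()].
#' @return Filtered `data.frame`; attribute `n_malformed` counts skipped
#'   records.
#' @export
filter_alignments <- function(records, params = detection_params()) {
  req <- c("read_id", "contig", "start", "end", "identity",
           "read_fraction", "is_primary")
  stopifnot(all(req %in% names(records)))
  bad <- !stats::complete.cases(records[, c("start", "end", "identity",
                                            "read_fraction", "is_primary")])
  if (any(bad))
    warning(sum(bad), " malformed alignment record(s) skipped")
  rec <- records[!bad, , drop = FALSE]
  keep <- rec$is_primary &
    rec$identity >= params$min_identity &
    (rec$end - rec$start) >= params$min_aln_len &
    rec$read_fraction >= params$min_read_fraction
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Sample-level quality control on read count
#'
#' A sample is analysed only if it has strictly more than `min_reads`
#' (default 250,000) reads.
#'
#' @param total_reads Total read count of the sample.
#' @param params A [detection_params()].
#' @return Logical: keep the sample.
#' @export
sample_qc <- function(total_reads, params = detection_params()) {
  total_reads > params$min_reads
}

#' Partition contigs into background segments, plasmid candidates and short contigs
#'
#' Contigs longer than 350 kb are sliced into `ceiling(L / 300000)` pieces of
#' equal length (the last piece absorbs the integer-division remainder) so
#' that background statistics are not skewed by long-range coverage trends.
#' Contigs of 80-350 kb form one background segment; 5-80 kb contigs are
#' plasmid candidates; shorter contigs are ignored for calling.
#'
#' @param contig_lengths Named integer vector of contig lengths (bp).
#' @param params A [detection_params()].
#' @return `data.frame` with columns `contig`, `start`, `end` (0-based
#'   half-open) and `role` (`background_eligible`, `plasmid_candidate`,
#'   `too_short`).
#' @export
segment_contigs <- function(contig_lengths, params = detection_params()) {
  stopifnot(all(contig_lengths > 0))
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- paste0("contig_", seq_along(contig_lengths))
  rows <- list()
  for (nm in names(contig_lengths)) {
    L <- as.integer(contig_lengths[[nm]])
    if (L > params$slice_threshold_bp) {
      k <- ceiling(L / params$slice_max_bp)
      piece <- L %/% k
      starts <- (seq_len(k) - 1L) * piece
      ends <- c(starts[-1L], L)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = nm, start = starts, end = ends, role = "background_eligible")
    } else if (L >= params$min_contig_stats_bp) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = nm, start = 0L, end = L, role = "background_eligible")
    } else if (L >= params$plasmid_min_bp) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = nm, start = 0L, end = L, role = "plasmid_candidate")
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = nm, start = 0L, end = L, role = "too_short")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Background coverage statistics for a segment
#'
#' Median depth over all bases of the segment, plus a corrected standard
#' deviation: the population SD over bases whose depth does not exceed
#' `extreme_factor` (default 3) times the median. The correction keeps
#' actively replicating elements from inflating the background spread.
#'
#' @param depths Integer vector of per-base depths for the segment.
#' @param params A [detection_params()].
#' @return List with `median`, `corrected_std`, `n_bases_used`.
#' @export
background_stats <- function(depths, params = detection_params()) {
  if (length(depths) == 0) stop("empty segment")
  med <- stats::median(depths)
  keep <- depths <= params$extreme_factor * med
  x <- depths[keep]
  # population SD (divisor n): segments are large and the estimator choice
  # is immaterial, but it must match the documented definition exactly
  cstd <- sqrt(mean((x - mean(x))^2))
  list(median = med, corrected_std = cstd, n_bases_used = length(x))
}

#' Plasmid-contig coverage rule
#'
#' A 5-80 kb contig is recorded whole as a high-coverage (prophage-plasmid)
#' candidate when its median depth exceeds the genome median by more than
#' one corrected standard deviation of the contig itself.
#'
#' @param depths Per-base depths of the contig.
#' @param genome_median Median depth over the whole genome.
#' @param params A [detection_params()].
#' @return Logical flag.
#' @export
call_plasmid_contig <- function(depths, genome_median,
                                params = detection_params()) {
  L <- length(depths)
  if (L < params$plasmid_min_bp || L >= params$plasmid_max_bp)
    stop("contig length ", L, " outside the plasmid size range")
  st <- background_stats(depths, params)
  st$median > genome_median + 1 * st$corrected_std
}

#' Sliding-window mean coverage
#'
#' Means over 250-bp windows at 50-bp steps (defaults); the trailing partial
#' window is dropped.
#'
#' @param depths Per-base depth vector for one contig.
#' @param params A [detection_params()].
#' @return `data.frame` with columns `start` (0-based window start) and
#'   `mean`; zero rows when the contig is shorter than one window.
#' @export
sliding_window_means <- function(depths, params = detection_params()) {
  L <- length(depths)
  w <- params$window_bp
  s <- params$step_bp
  if (L < w) return(data.frame(start = integer(), mean = numeric()))
  starts <- seq.int(0L, L - w, by = s)
  cs <- c(0, cumsum(as.numeric(depths)))
  data.frame(start = starts, mean = (cs[starts + w + 1L] - cs[starts + 1L]) / w)
}

# Turn maximal runs of above-threshold windows into candidate intervals.
# `above` is a logical per window; span = first window start to last window
# end. Returns data.frame(start, end).
.runs_to_spans <- function(starts, above, window_bp) {
  if (!length(starts) || !any(above))
    return(data.frame(start = integer(), end = integer()))
  r <- rle(above)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  ok <- r$values
  data.frame(start = starts[idx_start[ok]],
             end = starts[idx_end[ok]] + window_bp)
}

#' Call high-coverage regions from window means
#'
#' Two-pass calling against the segment background: maximal runs of windows
#' with mean above `median + 1 * SD` are kept when their base span exceeds
#' 1500 bp; runs above `median + 3 * SD` are kept when their span is
#' 500-1500 bp. The union of both passes is returned (overlaps collapsed).
#' A zero corrected SD leaves the thresholds well defined (any excess above
#' the median qualifies).
#'
#' @param windows `data.frame` from [sliding_window_means()].
#' @param stats Background statistics ([background_stats()]) of the
#'   enclosing segment, or a list of two numeric vectors `t_long`/`t_short`
#'   giving per-window thresholds.
#' @param params A [detection_params()].
#' @return `data.frame` with columns `start`, `end`, `mean_coverage`
#'   (0-based half-open spans).
#' @export
call_high_coverage_regions <- function(windows, stats,
                                       params = detection_params()) {
  if (!nrow(windows))
    return(data.frame(start = integer(), end = integer(),
                      mean_coverage = numeric()))
  if (!is.null(stats$t_long)) {
    t_long <- stats$t_long
    t_short <- stats$t_short
  } else {
    if (stats$corrected_std == 0)
      message("corrected SD is zero; any excess over the median qualifies")
    t_long <- rep(stats$median + params$long_factor * stats$corrected_std,
                  nrow(windows))
    t_short <- rep(stats$median + params$short_factor * stats$corrected_std,
                   nrow(windows))
  }
  w <- params$window_bp
  long_runs <- .runs_to_spans(windows$start, windows$mean > t_long, w)
  long_runs <- long_runs[long_runs$end - long_runs$start >
                           params$short_elem_max_bp, , drop = FALSE]
  short_runs <- .runs_to_spans(windows$start, windows$mean > t_short, w)
  sp <- short_runs$end - short_runs$start
  short_runs <- short_runs[sp >= params$short_elem_min_bp &
                             sp <= params$short_elem_max_bp, , drop = FALSE]
  both <- rbind(long_runs, short_runs)
  if (!nrow(both))
    return(data.frame(start = integer(), end = integer(),
                      mean_coverage = numeric()))
  red <- IRanges::reduce(IRanges::IRanges(start = both$start + 1L,
                                          end = both$end))
  out <- data.frame(start = IRanges::start(red) - 1L, end = IRanges::end(red))
  out$mean_coverage <- vapply(seq_len(nrow(out)), function(i) {
    inw <- windows$start >= out$start[i] & windows$start + w <= out$end[i]
    mean(windows$mean[inw])
  }, numeric(1))
  out
}

#' Merge nearby candidate elements and link elements across contig junctions
#'
#' Same-contig elements overlapping or separated by strictly less than
#' 1000 bp are combined. An element ending within 1000 bp of its contig's
#' end and an element starting within 1000 bp of the next contig's start
#' (in assembly order) receive reciprocal `cross_contig_link` annotations;
#' coordinates are never concatenated across contigs, since draft contig
#' order is arbitrary. Idempotent.
#'
#' @param elements `data.frame` with columns `contig`, `start`, `end`,
#'   `source`, `mean_coverage`.
#' @param contig_lengths Named integer vector (assembly order).
#' @param params A [detection_params()].
#' @return Merged `data.frame` with added `element_id` and
#'   `cross_contig_link` columns.
#' @export
merge_elements <- function(elements, contig_lengths,
                           params = detection_params()) {
  cols <- c("contig", "start", "end", "source", "mean_coverage")
  stopifnot(all(cols %in% names(elements)))
  if (!nrow(elements)) {
    out <- elements[, cols, drop = FALSE]
    out$element_id <- character(0)
    out$cross_contig_link <- character(0)
    return(out)
  }
  merged <- list()
  for (ct in intersect(names(contig_lengths), unique(elements$contig))) {
    e <- elements[elements$contig == ct, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    cur <- e[1, cols, drop = FALSE]
    for (i in seq_len(nrow(e))[-1]) {
      if (e$start[i] - cur$end < params$merge_gap_bp) {
        len_a <- cur$end - cur$start
        len_b <- e$end[i] - e$start[i]
        cur$mean_coverage <- (cur$mean_coverage * len_a +
                                e$mean_coverage[i] * len_b) / (len_a + len_b)
        cur$end <- max(cur$end, e$end[i])
        if (cur$source != e$source[i]) cur$source <- "both"
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- e[i, cols, drop = FALSE]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out$element_id <- sprintf("%s:%d-%d", out$contig, out$start, out$end)
  out$cross_contig_link <- NA_character_
  ctg_order <- names(contig_lengths)
  for (i in seq_len(nrow(out))) {
    ct <- out$contig[i]
    pos <- match(ct, ctg_order)
    if (is.na(pos) || pos >= length(ctg_order)) next
    if (contig_lengths[[ct]] - out$end[i] < params$merge_gap_bp) {
      nxt <- ctg_order[pos + 1L]
      j <- which(out$contig == nxt & out$start < params$merge_gap_bp)
      if (length(j)) {
        j <- j[1]
        out$cross_contig_link[i] <- out$element_id[j]
        out$cross_contig_link[j] <- out$element_id[i]
      }
    }
  }
  out
}

#' Hierarchical border refinement for a candidate element
#'
#' Evidence tiers, best first: (1) clipped reads — if at least
#' `clip_min_reads` clip positions agree within `clip_agree_bp` on a
#' location within `clip_search_bp` of each candidate border, the modal clip
#' position is the border (clips mark the exact host/phage junction);
#' (2) for induction-derived elements, the position of maximal absolute
#' change of the 250-bp-smoothed depth within `clip_search_bp` of each
#' border; (3) the span from the first to the last gene of the overlapping
#' genomic island (discarding non-coding ends). If no tier applies the
#' original borders are kept with method `"raw"`.
#'
#' @param element One-row `data.frame` (or list) with `start`, `end`,
#'   `source`.
#' @param clips Alignment records with a `clip_pos` column (may be empty or
#'   NULL).
#' @param depths Per-base depth vector of the element's contig (may be NULL
#'   when no coverage evidence exists).
#' @param island Optional `c(start, end)` island interval.
#' @param genes Optional `data.frame` with `start`, `end` columns of gene
#'   calls within the island.
#' @param params A [detection_params()].
#' @return List with `start`, `end`, `border_method`.
#' @export
refine_borders <- function(element, clips = NULL, depths = NULL,
                           island = NULL, genes = NULL,
                           params = detection_params()) {
  s0 <- element$start
  e0 <- element$end
  clip_border <- function(target) {
    if (is.null(clips) || !nrow(clips)) return(NA_integer_)
    pos <- clips$clip_pos[!is.na(clips$clip_pos)]
    pos <- pos[abs(pos - target) <= params$clip_search_bp]
    if (!length(pos)) return(NA_integer_)
    support <- vapply(pos, function(p)
      sum(abs(pos - p) <= params$clip_agree_bp), integer(1))
    if (max(support) < params$clip_min_reads) return(NA_integer_)
    best <- pos[support == max(support)]
    # modal position: the most frequent exact value among the best cluster
    as.integer(names(sort(table(best), decreasing = TRUE))[1])
  }
  cs <- clip_border(s0)
  ce <- clip_border(e0)
  if (!is.na(cs) && !is.na(ce))
    return(list(start = cs, end = ce, border_method = "clip"))
  if (!is.null(depths) && isTRUE(element$source %in% c("induction", "both"))) {
    w <- params$window_bp
    csum <- c(0, cumsum(as.numeric(depths)))
    step_score <- function(p) {
      # difference of flanking w-bp means: matched filter for a step at p
      if (p - w < 0 || p + w > length(depths)) return(NA_real_)
      abs((csum[p + w + 1L] - csum[p + 1L]) / w -
            (csum[p + 1L] - csum[p - w + 1L]) / w)
    }
    cov_border <- function(target) {
      cand <- seq.int(max(w, target - params$clip_search_bp),
                      min(length(depths) - w, target + params$clip_search_bp))
      if (!length(cand)) return(NA_integer_)
      sc <- vapply(cand, step_score, numeric(1))
      if (all(is.na(sc))) return(NA_integer_)
      cand[which.max(sc)]
    }
    bs <- cov_border(s0)
    be <- cov_border(e0)
    if (!is.na(bs) && !is.na(be) && bs < be)
      return(list(start = bs, end = be, border_method = "coverage"))
  }
  if (!is.null(island) && !is.null(genes) && nrow(genes)) {
    g <- genes[genes$start >= island[1] & genes$end <= island[2], ,
               drop = FALSE]
    if (nrow(g))
      return(list(start = min(g$start), end = max(g$end),
                  border_method = "gene_span"))
  }
  warning("no border evidence available; keeping raw borders")
  list(start = s0, end = e0, border_method = "raw")
}

#' Detect induced elements in a depth profile
#'
#' End-to-end detection for one genome: segments contigs, computes per-
#' segment background statistics, calls high-coverage regions with the
#' sliding window (per-window thresholds come from the segment containing
#' the window midpoint, so calls may extend across slice boundaries),
#' applies the plasmid rule to 5-80 kb contigs, and merges nearby calls.
#'
#' @param depth Named list of per-base depth vectors (one per contig).
#' @param params A [detection_params()].
#' @return List with `elements` (merged candidate table), `segments`,
#'   `stats` (per background segment), `genome_median` and `report`
#'   (counts).
#' @export
detect_induced_elements <- function(depth, params = detection_params()) {
  lens <- vapply(depth, length, integer(1))
  segs <- segment_contigs(lens, params)
  genome_median <- stats::median(unlist(depth, use.names = FALSE))
  seg_stats <- list()
  calls <- list()
  for (ct in names(depth)) {
    s <- segs[segs$contig == ct, , drop = FALSE]
    role <- s$role[1]
    if (role == "too_short") next
    if (role == "plasmid_candidate") {
      if (call_plasmid_contig(depth[[ct]], genome_median, params))
        calls[[length(calls) + 1L]] <- data.frame(
          contig = ct, start = 0L, end = lens[[ct]], source = "induction",
          mean_coverage = mean(depth[[ct]]),
          border_method = "contig_whole")
      next
    }
    wins <- sliding_window_means(depth[[ct]], params)
    if (!nrow(wins)) next
    t_long <- t_short <- numeric(nrow(wins))
    for (r in seq_len(nrow(s))) {
      st <- background_stats(depth[[ct]][(s$start[r] + 1):s$end[r]], params)
      seg_stats[[paste0(ct, ":", s$start[r], "-", s$end[r])]] <- st
      mid <- wins$start + params$window_bp / 2
      inseg <- mid >= s$start[r] & mid < s$end[r]
      t_long[inseg] <- st$median + params$long_factor * st$corrected_std
      t_short[inseg] <- st$median + params$short_factor * st$corrected_std
    }
    hits <- call_high_coverage_regions(
      wins, list(t_long = t_long, t_short = t_short), params)
    if (nrow(hits)) {
      hits$contig <- ct
      hits$source <- "induction"
      hits$border_method <- "window"
      calls[[length(calls) + 1L]] <-
        hits[, c("contig", "start", "end", "source", "mean_coverage",
                 "border_method")]
    }
  }
  raw <- if (length(calls)) do.call(rbind, calls) else
    data.frame(contig = character(), start = integer(), end = integer(),
               source = character(), mean_coverage = numeric(),
               border_method = character())
  bm <- raw$border_method
  merged <- merge_elements(raw[, c("contig", "start", "end", "source",
                                   "mean_coverage")], lens, params)
  merged$border_method <- rep("window", nrow(merged))
  if (nrow(merged)) {
    whole <- raw$contig[bm == "contig_whole"]
    merged$border_method[merged$contig %in% whole &
                           merged$start == 0L] <- "contig_whole"
  }
  list(elements = merged, segments = segs, stats = seg_stats,
       genome_median = genome_median,
       report = list(n_contigs = length(depth),
                     n_too_short = sum(segs$role == "too_short"),
                     n_raw_calls = nrow(raw),
                     n_elements = nrow(merged)))
}
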