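# Independent oracles used to cross-check package implementations.
# Each oracle is deliberately naive/direct and shares no code with the
# implementation path it checks.

# filter-then-SD background statistics, written as the plainest possible
# translation of the definition
oracle_background_stats <- function(depths, extreme_factor = 3) {
  med <- median(depths)
  kept <- c()
  for (d in depths) if (d <= extreme_factor * med) kept <- c(kept, d)
  m <- sum(kept) / length(kept)
  list(median = med,
       corrected_std = sqrt(sum((kept - m)^2) / length(kept)),
       n_bases_used = length(kept))
}

# all-position Hamming scan via Biostrings (library route, independent of
# the package's byte-shift scan); returns 0-based plus-strand positions
oracle_hamming_hits <- function(genome, query, max_mismatches = 4) {
  g <- Biostrings::DNAString(genome)
  hit_one <- function(q) {
    n <- length(g) - nchar(q) + 1L
    ok <- Biostrings::isMatchingStartingAt(
      Biostrings::DNAString(q), g, starting.at = seq_len(n),
      max.mismatch = max_mismatches)
    which(ok) - 1L
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
  list(plus = hit_one(query), minus = hit_one(rc))
}

# exact global-alignment identity (percent) between two sequences
oracle_global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 5, gapExtension = 2)
  Biostrings::pid(aln, type = "PID1")
}

# greedy dereplication trace written independently: explicit sort, explicit
# first-matching-representative loop, using a caller-supplied pair oracle
oracle_greedy_derep <- function(ids, lengths, matches) {
  ord <- ids[order(-lengths, ids)]
  reps <- character(0)
  member <- setNames(character(length(ids)), ids)
  for (id in ord) {
    hit <- NA
    for (r in reps) {
      if (isTRUE(matches[[paste(sort(c(id, r)), collapse = "|")]])) {
        hit <- r
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, id)
      hit <- id
    }
    member[id] <- hit
  }
  list(representatives = reps, membership = member)
}

# reference MCL run: plain dense iteration with no pruning, independent of
# the package implementation; clusters read from attractor rows
oracle_mcl <- function(adj, inflation = 3, iters = 100) {
  n <- nrow(adj)
  diag(adj) <- apply(adj, 1, max)
  M <- sweep(adj, 2, colSums(adj), "/")
  for (i in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
  }
  attract <- which(diag(M) > 1e-6)
  clusters <- lapply(attract, function(a) sort(which(M[a, ] > 1e-6)))
  unique(clusters)
}

# per-base truth mask for planted elements of one simulated genome
truth_mask <- function(truth, contig, len) {
  mask <- logical(len)
  el <- truth$elements[truth$elements$contig_name == contig, , drop = FALSE]
  if (nrow(el)) for (i in seq_len(nrow(el)))
    mask[(el$start[i] + 1):el$end[i]] <- TRUE
  mask
}

# non-overlapping random element layout on [0, len)
random_layout <- function(n, len, min_len = 2000, max_len = 40000,
                          gap = 5000) {
  repeat {
    starts <- sort(sample.int(len - max_len, n))
    lens <- sample(seq(min_len, max_len, by = 500), n, replace = TRUE)
    ends <- starts + lens
    if (n == 1 || all(starts[-1] > ends[-n] + gap))
      return(data.frame(start = starts, end = ends))
  }
}
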