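# Fragment-based average nucleotide identity between prophage genomes,
# retained-pair search (recent transfer/inheritance), greedy dereplication
# and host-metadata summaries.

# Map consecutive fragments of `x` onto `y`: exact k-mer seeding, then
# gapped extension of the fragment inside a banded window around the seeded
# location. Returns per-fragment identity (NA = unmapped) and lengths.
.map_fragments <- function(x, y, params) {
  xd <- Biostrings::DNAString(x)
  yd <- Biostrings::DNAString(y)
  yrc <- Biostrings::reverseComplement(yd)
  Lx <- length(xd)
  Ly <- length(yd)
  starts <- seq.int(1L, Lx, by = params$fragment_bp)
  lens <- pmin(params$fragment_bp, Lx - starts + 1L)
  keep <- lens >= params$min_last_fragment_bp | starts == 1L
  starts <- starts[keep]
  lens <- lens[keep]
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  ident <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    frag <- Biostrings::subseq(xd, starts[i], width = lens[i])
    k <- params$kmer_seed
    if (lens[i] < k) next
    offs <- unique(pmax(1L, pmin(lens[i] - k + 1L,
                                 as.integer(seq(1L, lens[i] - k + 1L,
                                                length.out = 5L)))))
    best <- -Inf
    best_id <- NA_real_
    for (subject in list(yd, yrc)) {
      hit_off <- integer(0)
      for (o in offs) {
        seed <- Biostrings::subseq(frag, o, width = k)
        m <- Biostrings::matchPattern(seed, subject)
        if (length(m)) {
          hit_off <- c(hit_off, Biostrings::start(m) - (o - 1L))
          break
        }
      }
      for (ws in unique(hit_off)[seq_len(min(3L, length(unique(hit_off))))]) {
        a <- max(1L, ws - params$band)
        b <- min(Ly, ws + lens[i] - 1L + params$band)
        if (b - a + 1L < lens[i] %/% 2L) next
        aln <- Biostrings::pairwiseAlignment(
          frag, Biostrings::subseq(subject, a, b), type = "global-local",
          substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
        if (Biostrings::score(aln) > best) {
          best <- Biostrings::score(aln)
          best_id <- Biostrings::pid(aln, type = "PID1") / 100
        }
      }
    }
    if (!is.na(best_id) && best_id >= params$min_fragment_identity)
      ident[i] <- best_id
  }
  list(identity = ident, lengths = lens)
}

.direction_ani <- function(x, y, params) {
  mp <- .map_fragments(x, y, params)
  mapped <- !is.na(mp$identity)
  if (!any(mapped)) return(list(ani = NA_real_, coverage = 0))
  w <- mp$lengths[mapped]
  list(ani = 100 * sum(mp$identity[mapped] * w) / sum(w),
       coverage = sum(w) / sum(mp$lengths))
}

#' Estimate average nucleotide identity and alignment coverage of two sequences
#'
#' The shorter sequence is cut into consecutive 1000-bp fragments (trailing
#' fragment kept if >= 500 bp); each fragment is anchored in the other
#' sequence by an exact 15-mer seed (either strand) and aligned by gapped
#' extension in a banded window. ANI is the length-weighted mean identity of
#' mapped fragments; coverage is the mapped fraction of the shorter
#' sequence. Both directions are evaluated and the ANI averaged, making the
#' estimate symmetric.
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param params A [similarity_params()].
#' @return List with `ani` (percent; 0 when nothing maps) and `coverage`
#'   (fraction of the shorter sequence).
#' @export
estimate_ani <- function(seq_a, seq_b, params = similarity_params()) {
  if (!nchar(seq_a) || !nchar(seq_b)) stop("empty sequence")
  if (nchar(seq_a) <= nchar(seq_b)) {
    shorter <- seq_a; longer <- seq_b
  } else {
    shorter <- seq_b; longer <- seq_a
  }
  fwd <- .direction_ani(shorter, longer, params)
  rev <- .direction_ani(longer, shorter, params)
  anis <- c(fwd$ani, rev$ani)
  list(ani = if (all(is.na(anis))) 0 else mean(anis, na.rm = TRUE),
       coverage = fwd$coverage)
}

#' Find highly similar prophage pairs
#'
#' Evaluates all unordered pairs and keeps those with ANI at or above the
#' threshold (default 99.9%) and complete coverage of the shorter sequence
#' (threshold 1.0) — the signature of recent common descent that still
#' allows single nucleotide substitutions.
#'
#' @param prophages Named character vector of prophage sequences.
#' @param params A [similarity_params()].
#' @param keep_all Return all evaluated pairs with a `retained` column
#'   instead of only the retained ones.
#' @return `data.frame` with columns `id_a`, `id_b` (`id_a < id_b`), `ani`,
#'   `coverage` (and `retained` if `keep_all`).
#' @export
find_similar_pairs <- function(prophages, params = similarity_params(),
                               keep_all = FALSE) {
  ids <- names(prophages)
  stopifnot(!is.null(ids), !anyDuplicated(ids), length(ids) >= 2)
  rows <- list()
  for (i in seq_along(ids)[-length(ids)]) for (j in seq.int(i + 1L,
                                                            length(ids))) {
    a <- sort(c(ids[i], ids[j]))
    est <- estimate_ani(prophages[[ids[i]]], prophages[[ids[j]]], params)
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = a[1], id_b = a[2], ani = est$ani, coverage = est$coverage,
      retained = est$ani >= params$ani_threshold &
        est$coverage >= params$coverage_threshold)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_all) out else {
    res <- out[out$retained, setdiff(names(out), "retained"), drop = FALSE]
    rownames(res) <- NULL
    res
  }
}

#' Greedy dereplication of prophage sequences
#'
#' Longest-first greedy clustering: sequences are visited by decreasing
#' length (ties broken by id, ascending); each sequence joins the first
#' existing representative it matches at >= 99.9% ANI and >= 80% coverage of
#' the shorter sequence, otherwise it founds a new representative.
#' Deterministic.
#'
#' @param prophages Named character vector of sequences.
#' @param params A [similarity_params()].
#' @return List with `representatives` (ids) and `membership` (named map
#'   id -> representative id).
#' @export
dereplicate <- function(prophages, params = similarity_params()) {
  ids <- names(prophages)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  ord <- ids[order(-nchar(prophages), ids)]
  reps <- character(0)
  membership <- stats::setNames(character(length(ids)), ids)
  for (id in ord) {
    assigned <- NA_character_
    for (r in reps) {
      est <- estimate_ani(prophages[[id]], prophages[[r]], params)
      if (est$ani >= params$derep_identity &&
          est$coverage >= params$derep_coverage) {
        assigned <- r
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, id)
      assigned <- id
    }
    membership[[id]] <- assigned
  }
  list(representatives = reps, membership = membership)
}

#' Summarise retained pairs against host metadata
#'
#' Counts retained pairs by host relationship (same strain, same species
#' but different strain, different species) and flags prophages that appear
#' in no retained pair as unique.
#'
#' @param pairs `data.frame` from [find_similar_pairs()].
#' @param hosts `data.frame` with columns `prophage_id`, `strain`,
#'   `species` covering every prophage.
#' @param prophage_ids Optional character vector of all prophage ids (so
#'   prophages without any pair are counted); defaults to the ids in
#'   `hosts`.
#' @return List with `counts` (named: `same_strain`, `same_species`,
#'   `different_species`), `unique_ids`, `n_unique`, `n_prophages`.
#' @export
summarize_pairs <- function(pairs, hosts, prophage_ids = hosts$prophage_id) {
  stopifnot(all(c("prophage_id", "strain", "species") %in% names(hosts)))
  need <- unique(c(pairs$id_a, pairs$id_b, prophage_ids))
  missing <- setdiff(need, hosts$prophage_id)
  if (length(missing))
    stop("missing host metadata for: ", paste(missing, collapse = ", "))
  h <- hosts[match(c(pairs$id_a), hosts$prophage_id), ]
  g <- hosts[match(c(pairs$id_b), hosts$prophage_id), ]
  same_strain <- sum(h$strain == g$strain)
  same_species <- sum(h$strain != g$strain & h$species == g$species)
  diff_species <- sum(h$species != g$species)
  paired <- unique(c(pairs$id_a, pairs$id_b))
  uniq <- setdiff(prophage_ids, paired)
  list(counts = c(same_strain = same_strain, same_species = same_species,
                  different_species = diff_species),
       unique_ids = uniq, n_unique = length(uniq),
       n_prophages = length(unique(prophage_ids)))
}
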