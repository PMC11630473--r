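# Gene-content curation of candidate elements: marker/keyword rules,
# viral-realm assignment, realm-specific size filtering, and short-motif
# integration-site (dif) search.

#' Match a gene label against the viral keyword list
#'
#' Case-insensitive substring matching; returns the first matching keyword
#' in rule order, or `NA` if none matches.
#'
#' @param label Annotation label text.
#' @param rules A [curation_rules()].
#' @return Matching keyword or `NA_character_`.
#' @export
match_keywords <- function(label, rules = curation_rules()) {
  lo <- tolower(label)
  for (kw in rules$keywords)
    if (grepl(tolower(kw), lo, fixed = TRUE)) return(kw)
  NA_character_
}

# which realms have a marker label among these gene labels (ordered by
# precedence tailless > filamentous > tailed)
.marker_realms <- function(labels, rules) {
  lo <- tolower(labels)
  found <- character(0)
  for (realm in c("tailless", "filamentous", "tailed")) {
    pats <- tolower(rules$markers[[realm]])
    if (any(vapply(pats, function(p) any(grepl(p, lo, fixed = TRUE)),
                   logical(1))))
      found <- c(found, realm)
  }
  found
}

#' Classify a candidate element as prophage or not from its gene content
#'
#' A candidate is accepted as a putative prophage if it has at least five
#' genes and either (a) carries a clear realm marker gene (terminase or
#' major capsid for tailed, pI-like ATPase for filamentous, double
#' jelly-roll capsid for tailless), or (b) at least two distinct genes match
#' viral-origin keywords.
#'
#' @param genes `data.frame` with columns `gene_id` and `label` (one row per
#'   annotation label; genes may repeat with multiple labels).
#' @param rules A [curation_rules()].
#' @return List with `accepted`, `rule_path` (one of `marker`, `keyword`,
#'   `rejected_genes`, `rejected_content`), `realm`, `evidence` (gene ids).
#' @export
classify_candidate <- function(genes, rules = curation_rules()) {
  stopifnot(all(c("gene_id", "label") %in% names(genes)))
  n_genes <- length(unique(genes$gene_id))
  if (n_genes < rules$min_genes)
    return(list(accepted = FALSE, rule_path = "rejected_genes",
                realm = NA_character_, evidence = character(0)))
  realms <- .marker_realms(genes$label, rules)
  if (length(realms)) {
    marker_pats <- tolower(unlist(rules$markers))
    hit <- vapply(tolower(genes$label), function(l)
      any(vapply(marker_pats, grepl, logical(1), x = l, fixed = TRUE)),
      logical(1))
    return(list(accepted = TRUE, rule_path = "marker",
                realm = assign_realm(genes, rules),
                evidence = unique(genes$gene_id[hit])))
  }
  kw_gene <- vapply(split(genes$label, genes$gene_id), function(ls)
    any(!is.na(vapply(ls, match_keywords, character(1), rules = rules))),
    logical(1))
  if (sum(kw_gene) >= rules$min_keyword_genes)
    return(list(accepted = TRUE, rule_path = "keyword", realm = "other",
                evidence = names(kw_gene)[kw_gene]))
  list(accepted = FALSE, rule_path = "rejected_content",
       realm = NA_character_, evidence = character(0))
}

#' Assign the viral realm of an accepted prophage from its marker genes
#'
#' Double jelly-roll capsid proteins place a prophage in the tailless realm
#' (Varidnaviria); pI-like ATPase / "gene 1" / zonular occludens toxin
#' labels in the filamentous realm (Monodnaviria); capsid or terminase
#' (large/endonuclease subunit) labels in the tailed realm (Duplodnaviria).
#' When markers of several realms co-occur (e.g. a mis-merged tandem of two
#' prophages) precedence is tailless > filamentous > tailed and the conflict
#' is reported via a warning.
#'
#' @param genes `data.frame` with `gene_id`, `label`.
#' @param rules A [curation_rules()].
#' @return Realm string (`tailless`, `filamentous`, `tailed` or `other`).
#' @export
assign_realm <- function(genes, rules = curation_rules()) {
  realms <- .marker_realms(genes$label, rules)
  if (!length(realms)) return("other")
  if (length(realms) > 1)
    warning("conflicting realm markers (", paste(realms, collapse = ", "),
            "); keeping ", realms[1])
  realms[1]
}

#' Realm-specific minimum-size filter
#'
#' Minimum element lengths (inclusive): 4 kb for filamentous and unassigned
#' ("other") prophages, 10 kb for tailless, 25 kb for tailed.
#'
#' @param length_bp Element length in bp.
#' @param realm Realm string.
#' @param rules A [curation_rules()].
#' @return Logical: keep the element.
#' @export
size_filter <- function(length_bp, realm, rules = curation_rules()) {
  stopifnot(realm %in% names(rules$size_min_bp))
  length_bp >= rules$size_min_bp[[realm]]
}

# integer-coded sequence (A=1,C=2,G=3,T=4; other=0)
.dna_int <- function(s) {
  v <- as.integer(charToRaw(toupper(s)))
  out <- integer(length(v))
  out[v == 65L] <- 1L; out[v == 67L] <- 2L
  out[v == 71L] <- 3L; out[v == 84L] <- 4L
  out
}

.revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Find short integration-site motifs (dif sites) in a genome sequence
#'
#' Reports every position, on either strand, where a 20-40 bp query aligns
#' ungapped with at most `max_mismatches` mismatches. The scan evaluates the
#' Hamming distance at every position by vectorised shifted comparison, so
#' no hit within the mismatch budget can be missed (dif sites are short,
#' conserved motifs; indels are not modelled).
#'
#' @param genome Nucleotide string (one contig/replicon).
#' @param queries Named character vector of query motifs (20-40 bp typical).
#' @param max_mismatches Maximum Hamming distance (default 4).
#' @param min_query_len Queries shorter than this are rejected (default 12).
#' @return `data.frame` with columns `query`, `position` (0-based start on
#'   the plus strand), `strand` (`+`/`-`), `mismatches`, sorted by position.
#' @export
find_dif_sites <- function(genome, queries, max_mismatches = 4L,
                           min_query_len = 12L) {
  if (is.null(names(queries)))
    names(queries) <- paste0("query_", seq_along(queries))
  g <- .dna_int(genome)
  L <- length(g)
  scan_one <- function(q) {
    w <- nchar(q)
    if (w < min_query_len)
      stop("query shorter than ", min_query_len, " bp")
    if (w > L) return(integer(0))
    qi <- .dna_int(q)
    n <- L - w + 1L
    mm <- integer(n)
    for (j in seq_len(w))
      mm <- mm + (g[j:(j + n - 1L)] != qi[j])
    which(mm <= max_mismatches) - 1L  # 0-based
  }
  rows <- list()
  for (nm in names(queries)) {
    q <- queries[[nm]]
    for (strand in c("+", "-")) {
      qq <- if (strand == "+") q else .revcomp(q)
      hits <- scan_one(qq)
      if (length(hits)) {
        qi <- .dna_int(qq)
        mms <- vapply(hits, function(p)
          sum(g[(p + 1):(p + nchar(q))] != qi), integer(1))
        rows[[length(rows) + 1L]] <- data.frame(
          query = nm, position = hits, strand = strand, mismatches = mms)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(), position = integer(),
               strand = character(), mismatches = integer())
  out <- out[order(out$position, out$query, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integration-hotspot occupancy and composition
#'
#' For a strain-by-site occupancy table, computes per site the fill
#' percentage (strains with any occupant / total strains) and the occupant
#' class composition.
#'
#' @param site_table `data.frame` with columns `strain`, `site`, `occupant`
#'   (`NA` or empty string = unoccupied); every strain must be scored for
#'   every site.
#' @return `data.frame` with columns `site`, `n_strains`, `n_occupied`,
#'   `fill_percent`, `composition` (named counts collapsed to
#'   `class:count` strings separated by `,`).
#' @export
hotspot_occupancy <- function(site_table) {
  stopifnot(all(c("strain", "site", "occupant") %in% names(site_table)))
  tab <- table(site_table$site, site_table$strain)
  if (any(tab != 1))
    stop("every strain must be scored exactly once for every site")
  rows <- lapply(split(site_table, site_table$site), function(d) {
    occ <- d$occupant
    filled <- !is.na(occ) & occ != ""
    comp <- sort(table(occ[filled]), decreasing = TRUE)
    data.frame(site = d$site[1], n_strains = nrow(d),
               n_occupied = sum(filled),
               fill_percent = 100 * sum(filled) / nrow(d),
               composition = paste(sprintf("%s:%d", names(comp),
                                           as.integer(comp)),
                                   collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
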