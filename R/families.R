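# Protein gene families by Markov Clustering of a similarity graph, marker
# collections per viral realm, core/variable family classification within
# prophage clusters, variable-locus extraction and defense-content flags.

#' Build a weighted protein similarity graph from pairwise hits
#'
#' Edge weight is `min(ceiling(-log10(evalue)), 200)`; hits with
#' `evalue > 1e-5` are dropped, non-positive e-values get the cap, and
#' reciprocal hits collapse to the maximum weight. Self-hits are discarded.
#'
#' @param hits `data.frame` with columns `a`, `b`, `evalue`.
#' @param nodes Optional character vector of all protein ids (isolated
#'   proteins included); defaults to ids present in `hits`.
#' @param params A [mcl_params()] (supplies `weight_cap`).
#' @param max_evalue Hits above this e-value are ignored.
#' @return List of class `similarity_graph` with `nodes` and `edges`
#'   (`data.frame`: `a`, `b`, `weight`, with `a < b`).
#' @export
build_similarity_graph <- function(hits, nodes = NULL,
                                   params = mcl_params(),
                                   max_evalue = 1e-5) {
  stopifnot(all(c("a", "b", "evalue") %in% names(hits)))
  hits$a <- as.character(hits$a)
  hits$b <- as.character(hits$b)
  h <- hits[hits$evalue <= max_evalue & hits$a != hits$b, , drop = FALSE]
  w <- ifelse(h$evalue <= 0, params$weight_cap,
              pmin(ceiling(-log10(h$evalue)), params$weight_cap))
  lo <- pmin(h$a, h$b)
  hi <- pmax(h$a, h$b)
  key <- paste(lo, hi, sep = "\r")
  wmax <- tapply(w, key, max)
  ab <- do.call(rbind, strsplit(names(wmax), "\r", fixed = TRUE))
  edges <- if (length(wmax))
    data.frame(a = ab[, 1], b = ab[, 2], weight = as.numeric(wmax)) else
      data.frame(a = character(), b = character(), weight = numeric())
  rownames(edges) <- NULL
  all_nodes <- sort(unique(c(nodes, hits$a, hits$b)))
  structure(list(nodes = all_nodes, edges = edges),
            class = "similarity_graph")
}

#' Markov Clustering of a protein similarity graph
#'
#' Canonical MCL: self-loops are added with the node's maximum incident
#' edge weight (1 for isolated nodes), columns are normalised to stochastic,
#' then expansion (matrix squaring) and inflation (elementwise power,
#' default 3, then renormalisation) alternate, with entries below the prune
#' threshold zeroed, until the matrix changes by less than `tol`. Clusters
#' are read as connected components of the converged matrix's non-zero
#' structure. Node order is fixed (graph order), so results are
#' deterministic; disconnected graph components are never merged.
#'
#' @param graph A [build_similarity_graph()] result.
#' @param params A [mcl_params()].
#' @return List with `membership` (named integer vector: node -> family id)
#'   and `families` (list of character vectors, ordered by first member).
#' @export
mcl_cluster <- function(graph, params = mcl_params()) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0) return(list(membership = integer(0), families = list()))
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e)) {
    ia <- match(e$a, nodes)
    ib <- match(e$b, nodes)
    A[cbind(ia, ib)] <- e$weight
    A[cbind(ib, ia)] <- e$weight
  }
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  normalise <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalise(A)
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    M_prev <- M
    M <- M %*% M
    M <- M^params$inflation
    M[M < params$prune] <- 0
    M <- normalise(M)
    if (max(abs(M - M_prev)) < params$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("MCL did not converge in ", params$max_iter,
            " iterations; interpreting current matrix")
  # connected components of the non-zero structure
  adj <- (M > 0) | (t(M) > 0)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- which(adj[v, ] & comp == 0L)
      stack <- c(stack, nb)
    }
  }
  membership <- stats::setNames(comp, nodes)
  families <- split(nodes, comp)
  names(families) <- NULL
  list(membership = membership, families = families)
}

#' Collect marker gene families per viral realm
#'
#' Every member of a family containing at least one seed marker protein of
#' realm R joins R's marker collection; families containing seeds of more
#' than one realm are reported as conflicts and excluded.
#'
#' @param families List of character vectors (from [mcl_cluster()]).
#' @param seeds `data.frame` with columns `protein_id`, `realm`.
#' @return List with `collections` (named list realm -> protein ids) and
#'   `conflicts` (list of offending families).
#' @export
collect_marker_families <- function(families, seeds) {
  stopifnot(all(c("protein_id", "realm") %in% names(seeds)))
  collections <- list()
  conflicts <- list()
  for (fam in families) {
    r <- unique(seeds$realm[seeds$protein_id %in% fam])
    if (length(r) == 0) next
    if (length(r) > 1) {
      conflicts[[length(conflicts) + 1L]] <- fam
      next
    }
    collections[[r]] <- c(collections[[r]], fam)
  }
  list(collections = collections, conflicts = conflicts)
}

#' Gene-family frequencies and core/variable classes within a phage cluster
#'
#' A family's frequency is the fraction of cluster members carrying at
#' least one gene of the family. Families present in more than 80% of
#' members are core, in at most 30% variable, otherwise intermediate.
#'
#' @param cluster_members Character vector of prophage ids in the cluster.
#' @param gene_table `data.frame` with columns `genome`, `family` (one row
#'   per gene).
#' @return `data.frame` with columns `family`, `n_carrying`, `frequency`,
#'   `class`.
#' @export
family_frequencies <- function(cluster_members, gene_table) {
  stopifnot(length(cluster_members) >= 1,
            all(c("genome", "family") %in% names(gene_table)))
  g <- gene_table[gene_table$genome %in% cluster_members, , drop = FALSE]
  n <- length(unique(cluster_members))
  carry <- tapply(g$genome, g$family, function(x) length(unique(x)))
  freq <- as.numeric(carry) / n
  out <- data.frame(family = names(carry), n_carrying = as.integer(carry),
                    frequency = freq,
                    class = ifelse(freq > 0.8, "core",
                                   ifelse(freq <= 0.3, "variable",
                                          "intermediate")))
  rownames(out) <- NULL
  out
}

#' Extract variable loci from a prophage cluster
#'
#' Clusters with fewer than 5 members yield no loci. Within each genome,
#' maximal runs of non-core genes that contain at least one variable gene
#' and are bounded on both sides by core-family genes produce one locus
#' each, spanning from the first to the last variable gene of the run.
#'
#' @param cluster_members Character vector of prophage ids.
#' @param gene_table `data.frame` with columns `genome`, `gene_id`,
#'   `family`, `position` (1-based gene order within the genome).
#' @param freqs Optional precomputed [family_frequencies()] table.
#' @return `data.frame` with columns `genome`, `first_var_position`,
#'   `last_var_position`, `left_flank`, `right_flank`, `gene_ids`
#'   (comma-separated genes in the locus span).
#' @export
extract_variable_loci <- function(cluster_members, gene_table,
                                  freqs = NULL) {
  empty <- data.frame(genome = character(), first_var_position = integer(),
                      last_var_position = integer(), left_flank = character(),
                      right_flank = character(), gene_ids = character())
  if (length(unique(cluster_members)) < 5) return(empty)
  stopifnot(all(c("genome", "gene_id", "family", "position") %in%
                  names(gene_table)))
  if (is.null(freqs)) freqs <- family_frequencies(cluster_members, gene_table)
  cls <- stats::setNames(freqs$class, freqs$family)
  rows <- list()
  for (gm in intersect(unique(cluster_members), unique(gene_table$genome))) {
    g <- gene_table[gene_table$genome == gm, , drop = FALSE]
    g <- g[order(g$position), , drop = FALSE]
    k <- cls[g$family]
    is_core <- k == "core"
    i <- 1L
    while (i <= nrow(g)) {
      if (is_core[i]) { i <- i + 1L; next }
      j <- i
      while (j < nrow(g) && !is_core[j + 1L]) j <- j + 1L
      # run g[i..j] of non-core genes; needs core flanks on both sides
      if (i > 1L && j < nrow(g)) {
        vr <- which(k[i:j] == "variable")
        if (length(vr)) {
          a <- i + vr[1] - 1L
          b <- i + vr[length(vr)] - 1L
          rows[[length(rows) + 1L]] <- data.frame(
            genome = gm,
            first_var_position = g$position[a],
            last_var_position = g$position[b],
            left_flank = g$family[i - 1L],
            right_flank = g$family[j + 1L],
            gene_ids = paste(g$gene_id[a:b], collapse = ","))
        }
      }
      i <- j + 1L
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag defense content of a variable locus from annotation labels
#'
#' A locus is a complete system when an external defense tool reported a
#' complete system for it, or when neighbouring genes carry toxin and
#' antitoxin labels; it is an incomplete system when any defense-related
#' label (abortive infection, toxin/antitoxin, restriction, retron) occurs
#' without completeness; otherwise it is classified as other.
#'
#' @param genes `data.frame` with columns `gene_id`, `label`, ordered by
#'   genomic position.
#' @param external_complete Logical: an external defense tool reported a
#'   complete system among these genes.
#' @return List with `class` (one of `complete_system`,
#'   `incomplete_system`, `other`) and `systems` (character vector of
#'   evidence labels).
#' @export
flag_defense <- function(genes, external_complete = FALSE) {
  stopifnot(all(c("gene_id", "label") %in% names(genes)))
  lo <- tolower(genes$label)
  is_antitoxin <- grepl("antitoxin", lo, fixed = TRUE)
  is_toxin <- grepl("toxin", lo, fixed = TRUE) & !is_antitoxin
  defense_kw <- c("abortive infection", "toxin", "antitoxin", "restriction",
                  "retron")
  is_defense <- Reduce(`|`, lapply(defense_kw, grepl, x = lo, fixed = TRUE))
  systems <- unique(genes$label[is_defense])
  ta_adjacent <- FALSE
  if (nrow(genes) >= 2) {
    adj <- seq_len(nrow(genes) - 1L)
    ta_adjacent <- any((is_toxin[adj] & is_antitoxin[adj + 1L]) |
                         (is_antitoxin[adj] & is_toxin[adj + 1L]))
  }
  cls <- if (isTRUE(external_complete) || ta_adjacent) "complete_system"
  else if (any(is_defense)) "incomplete_system"
  else "other"
  list(class = cls, systems = systems)
}
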