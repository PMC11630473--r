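# Synthetic induction-sequencing data with known ground truth.
# Depth is generated directly (per-base counts), not via read simulation:
# downstream detection only consumes depth profiles and parsed alignment
# summaries, and direct generation keeps fixtures fast and exactly seeded.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators never perturb the
#' caller's random state.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Random DNA sequence
#' @param n Length in bp.
#' @param seed Optional integer seed.
#' @return A single character string over ACGT.
#' @export
random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Configuration for a synthetic induction-sequencing simulation
#'
#' Describes one simulated genome: contigs with negative-binomial (or
#' Poisson) background depth, planted elevated-coverage elements with a known
#' fold (the true phage-to-host ratio), and optional multi-copy plasmid
#' contigs.
#'
#' @param seed Integer seed; identical configs give byte-identical output.
#' @param contig_lengths Integer vector of chromosome-contig lengths (bp).
#' @param background_mean Mean background depth (reads per base).
#' @param dispersion Negative-binomial size parameter; larger is closer to
#'   Poisson. Default 20 reflects moderate depth overdispersion typical of
#'   short-read sequencing.
#' @param noise `"nb"` (negative binomial) or `"poisson"`.
#' @param planted_elements `data.frame` with columns `contig` (index into
#'   `contig_lengths`), `start`, `end` (0-based half-open bp), `fold`
#'   (coverage multiplier > 1) and `realm` (one of `tailless`, `filamentous`,
#'   `tailed`, `none`). May have zero rows.
#' @param plasmids `data.frame` with columns `length` (bp) and `copy_number`
#'   (>= 1); each row becomes an extra contig at
#'   `background_mean * copy_number`.
#' @param clip_reads_per_border Clipped reads planted at each element border
#'   by [simulate_clipped_alignments()].
#'
#' @return A named list of class `simulation_config`.
#' @export
simulation_config <- function(seed, contig_lengths,
                              background_mean = 50, dispersion = 20,
                              noise = c("nb", "poisson"),
                              planted_elements = NULL, plasmids = NULL,
                              clip_reads_per_border = 3L) {
  noise <- match.arg(noise)
  if (is.null(planted_elements))
    planted_elements <- data.frame(contig = integer(), start = integer(),
                                   end = integer(), fold = numeric(),
                                   realm = character())
  if (is.null(plasmids))
    plasmids <- data.frame(length = integer(), copy_number = numeric())
  stopifnot(length(seed) == 1, all(contig_lengths > 0),
            background_mean > 0, dispersion > 0,
            all(c("contig", "start", "end", "fold", "realm") %in%
                  names(planted_elements)),
            all(c("length", "copy_number") %in% names(plasmids)),
            all(plasmids$length > 0), all(plasmids$copy_number >= 1))
  pe <- planted_elements
  if (nrow(pe)) {
    stopifnot(all(pe$contig >= 1), all(pe$contig <= length(contig_lengths)),
              all(pe$start >= 0), all(pe$fold > 1),
              all(pe$end <= contig_lengths[pe$contig]),
              all(pe$realm %in% c("tailless", "filamentous", "tailed", "none")))
    if (any(pe$end - pe$start < 500))
      stop("planted elements must be at least 500 bp long")
    for (ct in unique(pe$contig)) {
      e <- pe[pe$contig == ct, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
        stop("planted elements overlap on contig ", ct)
    }
  }
  structure(list(seed = as.integer(seed),
                 contig_lengths = as.integer(contig_lengths),
                 background_mean = background_mean, dispersion = dispersion,
                 noise = noise, planted_elements = pe, plasmids = plasmids,
                 clip_reads_per_border = as.integer(clip_reads_per_border)),
            class = "simulation_config")
}

#' Simulate a per-base read-depth profile with planted induced elements
#'
#' Background depth per base is drawn from a negative binomial (mean
#' `background_mean`, size `dispersion`) or Poisson. Within each planted
#' element the mean is multiplied by the element's `fold`; plasmid contigs
#' use `background_mean * copy_number` throughout. Fully deterministic under
#' the config seed.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `depth` (named list of integer vectors, one
#'   per contig; chromosome contigs are `contig_<i>`, plasmids
#'   `plasmid_<j>`) and `truth` (list with `elements` — the planted-element
#'   table with a `contig_name` column — `plasmids`, `seed`).
#' @export
simulate_depth_profile <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    draw <- function(mu) {
      as.integer(
        if (config$noise == "poisson") stats::rpois(length(mu), lambda = mu)
        else stats::rnbinom(length(mu), mu = mu, size = config$dispersion))
    }
    depth <- vector("list", length(config$contig_lengths) +
                      nrow(config$plasmids))
    nms <- character(length(depth))
    for (i in seq_along(config$contig_lengths)) {
      L <- config$contig_lengths[i]
      mu <- rep(config$background_mean, L)
      pe <- config$planted_elements
      pe <- pe[pe$contig == i, , drop = FALSE]
      if (nrow(pe)) for (r in seq_len(nrow(pe)))
        mu[(pe$start[r] + 1):pe$end[r]] <- config$background_mean * pe$fold[r]
      depth[[i]] <- draw(mu)
      nms[i] <- paste0("contig_", i)
    }
    if (nrow(config$plasmids)) for (j in seq_len(nrow(config$plasmids))) {
      k <- length(config$contig_lengths) + j
      mu <- rep(config$background_mean * config$plasmids$copy_number[j],
                config$plasmids$length[j])
      depth[[k]] <- draw(mu)
      nms[k] <- paste0("plasmid_", j)
    }
    names(depth) <- nms
    truth_elements <- config$planted_elements
    truth_elements$contig_name <- if (nrow(truth_elements))
      paste0("contig_", truth_elements$contig) else character()
    list(depth = depth,
         truth = list(elements = truth_elements,
                      plasmids = config$plasmids, seed = config$seed))
  })
}

#' Simulate alignment records with clipped reads at planted borders
#'
#' Emits, for every border of every planted element, exactly
#' `reads_per_border` primary alignment records whose clip position equals
#' the true border, plus unclipped background records spread over the
#' contigs. Records carry the fields the alignment-filtering contract needs
#' (identity, aligned read fraction, primary flag).
#'
#' @param truth Truth list from [simulate_depth_profile()] (or any list with
#'   an `elements` data.frame carrying `contig_name`, `start`, `end`).
#' @param reads_per_border Clipped records per border.
#' @param read_len Read length in bp; must be >= 50 (shorter reads would not
#'   survive the alignment-length filter).
#' @param seed Integer seed.
#' @param n_background Unclipped background records to add.
#' @return `data.frame` with columns `read_id`, `contig`, `start`, `end`,
#'   `identity`, `read_fraction`, `is_primary`, `clip_pos` (NA when
#'   unclipped). Coordinates 0-based half-open.
#' @export
simulate_clipped_alignments <- function(truth, reads_per_border, read_len,
                                        seed, n_background = 100L) {
  stopifnot(reads_per_border >= 0, n_background >= 0)
  if (read_len < 50)
    stop("read_len must be >= 50 bp to pass the alignment-length filter")
  el <- truth$elements
  with_seed(seed, {
    recs <- list()
    if (!is.null(el) && nrow(el)) {
      borders <- data.frame(
        contig = rep(el$contig_name, 2L),
        pos = c(el$start, el$end),
        side = rep(c("start", "end"), each = nrow(el)))
      for (b in seq_len(nrow(borders))) {
        if (reads_per_border == 0) break
        pos <- borders$pos[b]
        # read straddles the border; the clip marks the exact junction
        st <- if (borders$side[b] == "start") pos - read_len %/% 2 else pos - read_len %/% 2
        recs[[length(recs) + 1L]] <- data.frame(
          read_id = paste0("clip_", borders$contig[b], "_", pos, "_",
                           seq_len(reads_per_border)),
          contig = borders$contig[b],
          start = pmax(0L, as.integer(st)),
          end = pmax(0L, as.integer(st)) + as.integer(read_len),
          identity = 1.0, read_fraction = 1.0, is_primary = TRUE,
          clip_pos = as.integer(pos))
      }
    }
    if (n_background > 0) {
      ctgs <- if (!is.null(el) && nrow(el)) unique(el$contig_name) else "contig_1"
      recs[[length(recs) + 1L]] <- data.frame(
        read_id = paste0("bg_", seq_len(n_background)),
        contig = sample(ctgs, n_background, replace = TRUE),
        start = as.integer(sample.int(100000L, n_background, replace = TRUE)),
        end = NA_integer_, identity = 1.0, read_fraction = 1.0,
        is_primary = TRUE, clip_pos = NA_integer_)
      n <- nrow(recs[[length(recs)]])
      recs[[length(recs)]]$end <- recs[[length(recs)]]$start +
        as.integer(read_len)
    }
    out <- if (length(recs)) do.call(rbind, recs) else
      data.frame(read_id = character(), contig = character(),
                 start = integer(), end = integer(), identity = numeric(),
                 read_fraction = numeric(), is_primary = logical(),
                 clip_pos = integer())
    rownames(out) <- NULL
    out
  })
}

#' Plant an exact number of substitutions into a nucleotide sequence
#'
#' Used to build sequence pairs of known identity: the output differs from
#' the input at exactly `n_subs` positions (Hamming distance `n_subs`),
#' length unchanged.
#'
#' @param seq Nucleotide string (ACGT).
#' @param n_subs Number of substitutions, `0 <= n_subs <= nchar(seq)`.
#' @param seed Integer seed.
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(seq, n_subs, seed) {
  if (n_subs < 0) stop("n_subs must be non-negative")
  L <- nchar(seq)
  if (n_subs > L) stop("n_subs exceeds sequence length")
  if (n_subs == 0) return(seq)
  with_seed(seed, {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    pos <- sample.int(L, n_subs)
    bases <- c("A", "C", "G", "T")
    for (p in pos) {
      alt <- setdiff(bases, chars[p])
      chars[p] <- alt[sample.int(3L, 1L)]
    }
    paste(chars, collapse = "")
  })
}

#' Generate a synthetic prophage cluster with core synteny and a variable locus
#'
#' Every genome carries the same `n_core_families` core gene families in
#' identical order; at `locus_slot` (between core gene `locus_slot` and
#' `locus_slot + 1`) each genome carries `variable_genes_per_genome` genes
#' drawn from a shared accessory pool such that no accessory family occurs in
#' more than 30% of genomes.
#'
#' @param n_genomes Number of genomes in the cluster (>= 2).
#' @param n_core_families Number of core families (>= 2).
#' @param variable_pool_size Size of the shared accessory-family pool.
#' @param locus_slot Index in `1:(n_core_families - 1)`: the variable locus
#'   sits between core families `locus_slot` and `locus_slot + 1`.
#' @param variable_genes_per_genome Accessory genes planted per genome.
#' @param seed Integer seed.
#' @return List with `genes` (`data.frame`: `genome`, `gene_id`, `family`,
#'   `position` — 1-based gene order index) and `truth` (list with
#'   `core_families`, `variable_families`, and `loci`, a `data.frame` of
#'   `genome`, `first_var_position`, `last_var_position`, `left_flank`,
#'   `right_flank`).
#' @export
generate_phage_cluster <- function(n_genomes, n_core_families,
                                   variable_pool_size, locus_slot,
                                   variable_genes_per_genome, seed) {
  if (n_genomes < 2) stop("n_genomes must be >= 2")
  stopifnot(n_core_families >= 2, locus_slot >= 1,
            locus_slot < n_core_families, variable_genes_per_genome >= 0)
  max_per_family <- floor(0.3 * n_genomes)
  if (variable_genes_per_genome > 0) {
    if (max_per_family < 1)
      stop("cluster too small: no accessory family can stay at <= 30%")
    need <- n_genomes * variable_genes_per_genome
    if (variable_pool_size * max_per_family < need ||
        variable_pool_size < variable_genes_per_genome)
      stop("variable pool too small to keep every accessory family at <= 30%")
  }
  core_fams <- paste0("core_", seq_len(n_core_families))
  var_fams <- paste0("var_", seq_len(variable_pool_size))
  with_seed(seed, {
    remaining <- stats::setNames(rep(max_per_family, variable_pool_size),
                                 var_fams)
    rows <- list()
    loci <- list()
    for (g in seq_len(n_genomes)) {
      genome <- sprintf("phage_%02d", g)
      picked <- character(0)
      if (variable_genes_per_genome > 0) {
        # most-available-first keeps the fill feasible whenever total
        # capacity suffices; random tie-break keeps draws varied
        avail <- names(remaining)[remaining > 0]
        ord <- avail[order(-remaining[avail], stats::runif(length(avail)))]
        picked <- ord[seq_len(variable_genes_per_genome)]
        remaining[picked] <- remaining[picked] - 1L
      }
      fams <- c(core_fams[seq_len(locus_slot)], picked,
                core_fams[(locus_slot + 1):n_core_families])
      rows[[g]] <- data.frame(
        genome = genome,
        gene_id = sprintf("%s_g%02d", genome, seq_along(fams)),
        family = fams, position = seq_along(fams))
      if (length(picked))
        loci[[length(loci) + 1L]] <- data.frame(
          genome = genome,
          first_var_position = locus_slot + 1L,
          last_var_position = locus_slot + length(picked),
          left_flank = core_fams[locus_slot],
          right_flank = core_fams[locus_slot + 1L])
    }
    list(genes = do.call(rbind, rows),
         truth = list(core_families = core_fams,
                      variable_families = var_fams[remaining < max_per_family],
                      loci = if (length(loci)) do.call(rbind, loci) else
                        data.frame(genome = character(),
                                   first_var_position = integer(),
                                   last_var_position = integer(),
                                   left_flank = character(),
                                   right_flank = character())))
  })
}

#' Generate annotated gene tables for curation testing
#'
#' Builds, per planned element, a gene table with planted marker and/or
#' keyword labels and records the expected curation outcome (known by
#' construction from the plan, not by running the classifier).
#'
#' @param plans List of plans; each a list with `n_genes` (integer),
#'   `marker_realm` (`NA` or one of `tailless`, `filamentous`, `tailed`) and
#'   `n_keyword_genes` (integer).
#' @param seed Integer seed (used to shuffle which genes carry labels).
#' @param rules A [curation_rules()] object supplying label vocabulary.
#' @return List with `genes` (`data.frame`: `element_id`, `gene_id`, `label`)
#'   and `truth` (`data.frame`: `element_id`, `accept`, `rule_path`,
#'   `realm`).
#' @export
generate_annotation_fixture <- function(plans, seed,
                                        rules = curation_rules()) {
  marker_label <- c(tailless = "double jelly-roll capsid protein",
                    filamentous = "pI-like ATPase",
                    tailed = "terminase large subunit")
  keyword_labels <- c("phage holin", "tail fiber protein",
                      "head-tail connector", "major coat protein",
                      "virion export protein", "DNA packaging protein")
  with_seed(seed, {
    genes <- list()
    truth <- list()
    for (i in seq_along(plans)) {
      p <- plans[[i]]
      eid <- sprintf("element_%02d", i)
      n <- as.integer(p$n_genes)
      nk <- as.integer(p$n_keyword_genes %||% 0L)
      realm <- p$marker_realm %||% NA_character_
      labels <- rep("hypothetical protein", n)
      slots <- sample.int(n, min(n, nk + !is.na(realm)))
      j <- 1L
      if (!is.na(realm)) { labels[slots[j]] <- marker_label[[realm]]; j <- j + 1L }
      if (nk > 0) labels[slots[seq.int(j, length.out = min(nk, n - j + 1L))]] <-
        keyword_labels[seq_len(min(nk, n - j + 1L))]
      genes[[i]] <- data.frame(element_id = eid,
                               gene_id = sprintf("%s_g%02d", eid, seq_len(n)),
                               label = labels)
      accept <- n >= rules$min_genes &&
        (!is.na(realm) || nk >= rules$min_keyword_genes)
      truth[[i]] <- data.frame(
        element_id = eid, accept = accept,
        rule_path = if (!accept) {
          if (n < rules$min_genes) "rejected_genes" else "rejected_content"
        } else if (!is.na(realm)) "marker" else "keyword",
        realm = if (accept && !is.na(realm)) realm else "other")
    }
    list(genes = do.call(rbind, genes), truth = do.call(rbind, truth))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
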