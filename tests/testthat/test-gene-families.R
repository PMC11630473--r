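# Similarity graph construction, Markov Clustering, marker collections,
# core/variable classification, locus extraction and defense flags.

clique_hits <- function(ids, evalue = 1e-20) {
  g <- expand.grid(a = ids, b = ids, stringsAsFactors = FALSE)
  g <- g[g$a != g$b, ]
  g$evalue <- evalue
  g
}

test_that("edge weights are capped ceil(-log10 e) with reciprocal collapse", {
  hits <- data.frame(a = c("p1", "p2", "p1", "p3"),
                     b = c("p2", "p1", "p3", "p1"),
                     evalue = c(1e-250, 1e-5, 3e-8, 1e-9))
  g <- build_similarity_graph(hits)
  w <- setNames(g$edges$weight, paste(g$edges$a, g$edges$b))
  expect_equal(unname(w["p1 p2"]), 200)   # capped
  expect_equal(unname(w["p1 p3"]), 9)     # max(ceil(7.52), ceil(9)) = 9
  g2 <- build_similarity_graph(data.frame(a = "x", b = "y", evalue = 1e-5))
  expect_equal(g2$edges$weight, 5)
  # e-value 0 treated as the cap; hits above the cutoff are dropped
  g3 <- build_similarity_graph(data.frame(a = c("x", "x"), b = c("y", "z"),
                                          evalue = c(0, 1e-3)))
  expect_equal(g3$edges$weight, 200)
  expect_false("z" %in% c(g3$edges$a, g3$edges$b))
})

test_that("MCL returns connected components on disconnected graphs", {
  hits <- rbind(clique_hits(paste0("a", 1:3)), clique_hits(paste0("b", 1:3)))
  g <- build_similarity_graph(hits)
  fam <- mcl_cluster(g)
  expect_equal(length(fam$families), 2L)
  expect_setequal(fam$families[[fam$membership[["a1"]]]],
                  paste0("a", 1:3))
  # isolated node is its own family
  g_iso <- build_similarity_graph(clique_hits(paste0("a", 1:3)),
                                  nodes = "lonely")
  fam_iso <- mcl_cluster(g_iso)
  expect_true(any(vapply(fam_iso$families, identical, logical(1), "lonely")))
  # partition: every node in exactly one family
  expect_setequal(unlist(fam_iso$families), g_iso$nodes)
  expect_equal(length(unlist(fam_iso$families)), length(g_iso$nodes))
})

test_that("MCL splits the two-clique barbell at the bridge", {
  hits <- rbind(clique_hits(paste0("p", 1:4)), clique_hits(paste0("q", 1:4)),
                data.frame(a = "p1", b = "q1", evalue = 1e-20))
  g <- build_similarity_graph(hits)
  fam <- mcl_cluster(g)
  expect_equal(length(fam$families), 2L)
  got <- lapply(fam$families, sort)
  expect_true(any(vapply(got, identical, logical(1), paste0("p", 1:4))))
  expect_true(any(vapply(got, identical, logical(1), paste0("q", 1:4))))
  # agrees with an independent reference run on the unit-weight barbell
  nodes <- c(paste0("p", 1:4), paste0("q", 1:4))
  adj <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
  for (i in 1:4) for (j in 1:4) if (i != j) {
    adj[i, j] <- 1
    adj[i + 4, j + 4] <- 1
  }
  adj["p1", "q1"] <- adj["q1", "p1"] <- 1
  ref <- oracle_mcl(adj, inflation = 3)
  ref_fams <- lapply(ref, function(ix) sort(nodes[ix]))
  expect_setequal(lapply(got, unname), ref_fams)
})

test_that("MCL is deterministic", {
  set.seed(91)
  ids <- paste0("n", 1:15)
  hits <- data.frame(a = sample(ids, 60, replace = TRUE),
                     b = sample(ids, 60, replace = TRUE),
                     evalue = 10^-runif(60, 6, 60))
  hits <- hits[hits$a != hits$b, ]
  g <- build_similarity_graph(hits)
  expect_identical(mcl_cluster(g), mcl_cluster(g))
})

test_that("marker families merge into per-realm collections with conflicts", {
  fams <- list(c("p1", "p2", "p3"), c("p4", "p5"), c("p6", "p7"))
  seeds <- data.frame(protein_id = c("p1", "p6", "p7"),
                      realm = c("tailed", "tailed", "tailless"))
  mc <- collect_marker_families(fams, seeds)
  expect_setequal(mc$collections$tailed, c("p1", "p2", "p3"))
  expect_null(mc$collections$tailless)
  expect_equal(length(mc$conflicts), 1L)
  expect_setequal(mc$conflicts[[1]], c("p6", "p7"))
})

test_that("family frequencies classify core, variable and intermediate", {
  members <- sprintf("g%02d", 1:10)
  tab <- rbind(
    data.frame(genome = members[1:9], family = "famA"),
    data.frame(genome = members[1:3], family = "famB"),
    data.frame(genome = members[1:5], family = "famC"))
  fr <- family_frequencies(members, tab)
  cls <- setNames(fr$class, fr$family)
  expect_equal(unname(cls["famA"]), "core")         # 0.9 > 0.8
  expect_equal(unname(cls["famB"]), "variable")     # 0.3 <= 0.3
  expect_equal(unname(cls["famC"]), "intermediate") # 0.5
})

test_that("variable loci require core flanks and >= 5 cluster members", {
  mk_genome <- function(gm, fams) data.frame(
    genome = gm, gene_id = paste0(gm, "_", seq_along(fams)),
    family = fams, position = seq_along(fams))
  freqs <- data.frame(
    family = c("C1", "C2", "C3", "v1", "v2", "i1"),
    n_carrying = 0, frequency = 0,
    class = c("core", "core", "core", "variable", "variable",
              "intermediate"))
  members <- sprintf("g%d", 1:5)
  # [C1 C2 v1 v2 C3] -> locus v1..v2 flanked by C2, C3
  tab <- mk_genome("g1", c("C1", "C2", "v1", "v2", "C3"))
  loci <- extract_variable_loci(members, tab, freqs)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$first_var_position, 3L)
  expect_equal(loci$last_var_position, 4L)
  expect_equal(loci$left_flank, "C2")
  expect_equal(loci$right_flank, "C3")

  # unflanked variable gene at the element edge yields nothing
  edge <- mk_genome("g1", c("v1", "C1", "C2", "C3"))
  expect_equal(nrow(extract_variable_loci(members, edge, freqs)), 0L)

  # run with only intermediate genes yields nothing
  mid_tab <- mk_genome("g1", c("C1", "i1", "C2"))
  expect_equal(nrow(extract_variable_loci(members, mid_tab, freqs)), 0L)

  # intermediate genes inside a variable run extend context but the span
  # is first-to-last *variable* gene
  mixed <- mk_genome("g1", c("C1", "i1", "v1", "i1", "C2"))
  lm <- extract_variable_loci(members, mixed, freqs)
  expect_equal(c(lm$first_var_position, lm$last_var_position), c(3L, 3L))

  # fewer than 5 members: no loci
  expect_equal(nrow(extract_variable_loci(sprintf("g%d", 1:4), tab, freqs)),
               0L)
})

test_that("planted loci are recovered exactly from generated clusters", {
  pc <- generate_phage_cluster(10, 6, 40, locus_slot = 2,
                               variable_genes_per_genome = 3, seed = 92)
  members <- unique(pc$genes$genome)
  fr <- family_frequencies(members, pc$genes)
  expect_setequal(fr$family[fr$class == "core"], pc$truth$core_families)
  loci <- extract_variable_loci(members, pc$genes, fr)
  key <- function(d) d[order(d$genome),
                       c("genome", "first_var_position",
                         "last_var_position", "left_flank", "right_flank")]
  expect_equal(key(loci), key(pc$truth$loci), ignore_attr = TRUE)
})

test_that("defense flags follow the completeness rules", {
  mk <- function(labels) data.frame(gene_id = paste0("g", seq_along(labels)),
                                    label = labels)
  ta <- flag_defense(mk(c("toxin HigB", "antitoxin HigA")))
  expect_equal(ta$class, "complete_system")
  abi <- flag_defense(mk(c("abortive infection protein",
                           "hypothetical protein")))
  expect_equal(abi$class, "incomplete_system")
  expect_equal(flag_defense(mk(c("hypothetical protein",
                                 "hypothetical protein")))$class, "other")
  # toxin and antitoxin not adjacent: incomplete
  apart <- flag_defense(mk(c("toxin HigB", "hypothetical protein",
                             "antitoxin HigA")))
  expect_equal(apart$class, "incomplete_system")
  # external tool reporting completeness wins
  ext <- flag_defense(mk("retron system protein"), external_complete = TRUE)
  expect_equal(ext$class, "complete_system")
})
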