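# Ortholog clustering: pairwise similarity, filtered similarity graph,
# MCL families, pan-genome partition and Venn counts.

test_that("pairwise similarity handles identity, length ratios and errors", {
  s <- pairwise_similarity("MKTAYIAK", "MKTAYIAK")
  expect_equal(s$identity, 100)
  expect_equal(s$coverage, 100)

  s2 <- pairwise_similarity("MKTAYIAK", "MKTA")
  expect_lte(s2$coverage, 50)

  expect_error(pairwise_similarity("", "MKTA"), "empty")
  expect_error(pairwise_similarity("MKTA", "MKB*"), "illegal character")
  expect_error(pairwise_similarity("MKTA", "MKBZ"), "'B'")
})

test_that("pairwise similarity score matches an independent Gotoh oracle", {
  B <- panselect:::blosum62_matrix()
  for (seed in 1:5) {
    a <- random_protein(60, seed)
    b <- random_protein(60, seed + 100)
    s <- pairwise_similarity(a, b)
    expect_equal(s$score, gotoh_score(a, b, B), tolerance = 1e-9)
  }
  # near-identical pair: identity/coverage forced by construction
  a <- random_protein(60, 7)
  b <- paste0(substr(a, 1, 59), "W")
  s <- pairwise_similarity(a, b)
  expect_equal(s$identity, 100 * 59 / 60, tolerance = 1e-9)
  expect_equal(s$coverage, 100, tolerance = 1e-9)
})

test_that("similarity graph filters short proteins and finds planted edges", {
  long_a <- random_protein(100, 1)
  long_b <- random_protein(100, 2)
  p1 <- proteome("g1", c(geneA = long_a, short = random_protein(40, 3)))
  p2 <- proteome("g2", c(geneA = long_a, geneB = long_b))
  g <- build_similarity_graph(list(p1, p2))
  expect_false("g1|short" %in% igraph::V(g)$name)   # 40 aa < 50 threshold
  expect_setequal(igraph::V(g)$name, c("g1|geneA", "g2|geneA", "g2|geneB"))
  ends <- igraph::as_edgelist(g)
  expect_equal(nrow(ends), 1L)
  expect_setequal(as.vector(ends), c("g1|geneA", "g2|geneA"))

  short_only <- proteome("g3", c(s1 = random_protein(30, 4)))
  expect_error(build_similarity_graph(list(short_only, short_only),
                                      clustering_config()),
               "empty graph")
})

test_that("raising min_identity never increases the edge count", {
  cfg <- mini_study_config(seed = 11L)
  cfg$n_core_families <- 6L
  cfg$n_accessory_families <- 6L
  sim <- simulate_proteomes(cfg)
  counts <- vapply(c(50, 70, 90, 99), function(thr) {
    g <- build_similarity_graph(sim$proteomes,
                                clustering_config(min_identity = thr))
    igraph::ecount(g)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("MCL clusters cliques, singletons and modular graphs", {
  # two disconnected 3-cliques
  g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
  g <- igraph::set_vertex_attr(g, "name",
                               value = paste0("g", 1:6, "|x"))
  igraph::E(g)$weight <- 1
  fams <- mcl_cluster(g)
  expect_length(fams, 2L)
  expect_setequal(vapply(fams, function(f) length(f$members), integer(1)),
                  c(3L, 3L))

  # single node
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  g1 <- igraph::set_vertex_attr(g1, "name", value = "g1|solo")
  fams1 <- mcl_cluster(g1)
  expect_length(fams1, 1L)
  expect_equal(fams1[[1L]]$members, "g1|solo")
})

test_that("MCL matches an independent reference implementation", {
  for (seed in c(3, 17, 29)) {
    g <- random_modular_graph(seed)
    fams <- mcl_cluster(g$graph)
    mine <- family_membership(fams)[g$names]
    ref <- mcl_reference(g$adj)
    expect_equal(ari(mine, ref), 1)
  }
})

test_that("MCL recovers planted families exactly on separated fixtures", {
  cfg <- mini_study_config(seed = 5L)
  cfg$n_core_families <- 10L
  cfg$n_accessory_families <- 10L
  sim <- simulate_proteomes(cfg)
  g <- build_similarity_graph(sim$proteomes)
  fams <- mcl_cluster(g)
  truth_membership <- stats::setNames(
    rep(seq_along(sim$truth$memberships),
        lengths(sim$truth$memberships)),
    unlist(sim$truth$memberships))
  mine <- family_membership(fams)
  common <- intersect(names(mine), names(truth_membership))
  expect_equal(length(common), length(truth_membership))
  expect_equal(ari(mine[common], truth_membership[common]), 1)
})

test_that("pan-genome partition follows the core/distributed/unique rule", {
  fam <- function(id, genomes) {
    list(family_id = id, members = paste0(genomes, "|g"),
         genomes_present = genomes)
  }
  G <- paste0("g", 1:4)
  fams <- list(fam("f1", G), fam("f2", G), fam("f3", G[1:3]),
               fam("f4", G[2]))
  part <- classify_pangenome(fams, 4L)
  expect_equal(unname(part$counts), c(2L, 1L, 1L))
  expect_setequal(part$core, c("f1", "f2"))
  expect_equal(part$distributed, "f3")
  expect_equal(part$unique, "f4")

  all_core <- classify_pangenome(list(fam("f1", G), fam("f2", G)), 4L)
  expect_length(all_core$distributed, 0L)
  expect_length(all_core$unique, 0L)

  expect_error(classify_pangenome(list(fam("f1", character(0))), 4L),
               "empty genomes_present")
})

test_that("partition sizes match a brute-force recount on random fixtures", {
  set.seed(99)
  G <- paste0("g", 1:6)
  fams <- lapply(1:50, function(i) {
    gs <- sample(G, sample.int(6, 1))
    list(family_id = paste0("f", i), members = paste0(gs, "|x"),
         genomes_present = gs)
  })
  part <- classify_pangenome(fams, 6L)
  np <- vapply(fams, function(f) length(f$genomes_present), integer(1))
  expect_equal(unname(part$counts),
               c(sum(np == 6L), sum(np > 1L & np < 6L), sum(np == 1L)))
  expect_equal(sum(part$counts), 50L)
})

test_that("Venn pattern counts match brute-force enumeration", {
  set.seed(7)
  G <- paste0("g", 1:5)
  fams <- lapply(1:40, function(i) {
    gs <- sample(G, sample.int(5, 1))
    list(family_id = paste0("f", i), members = paste0(gs, "|x"),
         genomes_present = gs)
  })
  sub <- c("g1", "g2", "g3")
  counts <- subset_venn_counts(fams, sub)
  # brute force
  pats <- vapply(fams, function(f) {
    paste(sort(intersect(f$genomes_present, sub)), collapse = "+")
  }, character(1))
  brute <- table(pats[pats != ""])
  expect_equal(counts[sort(names(brute))],
               stats::setNames(as.integer(brute[sort(names(brute))]),
                               sort(names(brute))))

  one <- subset_venn_counts(fams, "g1")
  expect_equal(sum(one),
               sum(vapply(fams, function(f) "g1" %in% f$genomes_present,
                          logical(1))))
  expect_error(subset_venn_counts(fams, c("g1", "nope")), "unknown genome")
})

test_that("families partition the filtered gene set", {
  cfg <- mini_study_config(seed = 23L)
  cfg$n_core_families <- 8L
  cfg$n_accessory_families <- 12L
  sim <- simulate_proteomes(cfg)
  g <- build_similarity_graph(sim$proteomes)
  fams <- mcl_cluster(g)
  members <- unlist(lapply(fams, `[[`, "members"))
  expect_false(anyDuplicated(members) > 0)
  expect_setequal(members, igraph::V(g)$name)
})
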