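# Alignment chain (progressive alignment, back-translation, concatenate
# and filter), NJ topology, and the GTR+Gamma likelihood machinery.

test_that("progressive alignment handles identity, single indels, scoring", {
  same <- progressive_align(c(a = "MKTAYIAK", b = "MKTAYIAK"))
  expect_equal(unname(nchar(same)), c(8L, 8L))
  expect_false(any(grepl("-", same)))

  gap <- progressive_align(c(a = "MKTA", b = "MKA"))
  expect_equal(unname(nchar(gap)), c(4L, 4L))
  expect_equal(sum(strsplit(gap[["b"]], "")[[1L]] == "-"), 1L)

  expect_warning(progressive_align(c(a = "MKTA")), "single sequence")
})

test_that("progressive alignment beats the padded baseline on sum-of-pairs", {
  B <- panselect:::blosum62_matrix()
  sp_score <- function(aln, gap = 8) {
    m <- do.call(rbind, strsplit(aln, ""))
    tot <- 0
    for (i in seq_len(nrow(m) - 1L)) {
      for (j in seq.int(i + 1L, nrow(m))) {
        for (k in seq_len(ncol(m))) {
          x <- m[i, k]; y <- m[j, k]
          tot <- tot + if (x == "-" && y == "-") 0
          else if (x == "-" || y == "-") -gap
          else B[x, y]
        }
      }
    }
    tot
  }
  set.seed(21)
  for (rep in 1:20) {
    base <- random_protein(40, 300 + rep)
    seqs <- vapply(1:4, function(i) {
      s <- strsplit(base, "")[[1L]]
      nmut <- sample.int(6, 1)
      pos <- sample(seq_along(s), nmut)
      s[pos] <- sample(c("A", "G", "L", "S", "V"), nmut, replace = TRUE)
      if (runif(1) < 0.5) s <- s[-sample(seq_along(s), 1)]
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0("s", 1:4)
    aln <- progressive_align(seqs)
    L <- max(nchar(seqs))
    padded <- vapply(seqs, function(s) {
      paste0(s, strrep("-", L - nchar(s)))
    }, character(1))
    expect_gte(sp_score(aln), sp_score(padded))
  }
})

test_that("back-translation maps residues to codons and strips stops", {
  out <- backtranslate(c(x = "M-A"), c(x = "ATGGCT"))
  expect_equal(unname(out), "ATG---GCT")

  out2 <- backtranslate(c(x = "MA"), c(x = "ATGGCTTAA"))
  expect_equal(unname(out2), "ATGGCT")

  expect_error(backtranslate(c(x = "MK"), c(x = "ATGGCT")),
               "does not translate")
  expect_error(backtranslate(c(x = "MA"), c(y = "ATGGCT")), "no CDS")
})

test_that("align + backtranslate round-trips simulated families", {
  tree <- rtree_scaled(5, 0.3, seed = 3)
  sim <- simulate_codon_alignment(tree, "M1a",
                                  list(kappa = 2, p0 = 0.8, omega0 = 0.2),
                                  n_codons = 40, seed = 13)
  cds <- sim$alignment
  prots <- vapply(names(cds), function(n) translate_cds(cds[[n]], n),
                  character(1))
  aln <- progressive_align(prots)
  codon_aln <- backtranslate(aln, cds)
  for (n in names(cds)) {
    expect_equal(gsub("-", "", codon_aln[[n]]), cds[[n]])
  }
})

test_that("concatenation filters gap and hyperdivergent columns", {
  a1 <- c(s1 = "AC-GT", s2 = "ACTGT", s3 = "ACTGT")
  res <- concatenate_and_filter(list(a1))
  expect_equal(unname(nchar(res$alignment)), rep(4L, 3))
  expect_false(3L %in% res$report$original_column)

  ident <- c(s1 = "AAAA", s2 = "AAAA", s3 = "AAAA")
  res2 <- concatenate_and_filter(list(ident))
  expect_equal(unname(nchar(res2$alignment)), rep(4L, 3))

  # 3 x 10 toy: columns 2 and 5 gapped, column 8 all-distinct
  r1 <- "AA CA TTGA AT"; r2 <- "AA-CATTCAAT"; r3 <- "AA-CA TTTA AT"
  a3 <- c(s1 = "AATCATTGAT", s2 = "AA-CATTCAT", s3 = "AACCA-TTAT")
  # gap columns: 3 and 6; divergent column: 8 (G/C/T); 7 survive
  res3 <- concatenate_and_filter(list(a3), filter_policy(divergence_rule = 0.5))
  expect_equal(unname(nchar(res3$alignment)), rep(7L, 3))
  expect_setequal(res3$report$original_column, c(1, 2, 4, 5, 7, 9, 10))

  expect_error(concatenate_and_filter(list(c(s1 = "AA", s2 = "AA"),
                                           c(s1 = "AA", s3 = "AA"))),
               "missing")
})

test_that("filtering is idempotent", {
  set.seed(8)
  a <- c(s1 = "ATGCATGCAGT", s2 = "ATGCATGCAGT", s3 = "ATG-ATGCCGT",
         s4 = "TTGCATGAAGT")
  res <- concatenate_and_filter(list(a))
  res2 <- concatenate_and_filter(list(res$alignment))
  expect_equal(res2$alignment, res$alignment)
})

test_that("NJ recovers additive four-taxon distances", {
  # additive tree: ((A:1,B:2):1,(C:3,D:1):1) as unrooted distances
  tr <- read_newick(text = "((A:1,B:2):1,(C:3,D:1):1);")
  d <- ape::cophenetic.phylo(tr)
  nj <- nj_topology(d)
  expect_equal(compare_trees(nj, tr)$rf, 0)
  expect_equal(sort(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)]),
               sort(d), tolerance = 1e-9)

  expect_error(nj_topology(d[1:2, 1:2]), "at least 3")

  # star distances: total length matches the forced resolution
  ds <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(ds) <- 0
  njs <- nj_topology(ds)
  expect_equal(sum(njs$edge.length), 4, tolerance = 1e-9)
})

test_that("NJ on ultrametric input matches the UPGMA topology", {
  src <- rtree_scaled(6, 1, seed = 14)
  d <- ape::cophenetic.phylo(src)
  expect_equal(compare_trees(nj_topology(d), upgma(d))$rf, 0)
})

test_that("GTR+Gamma likelihood matches brute-force enumeration", {
  tree <- read_newick(text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.07);")
  aln <- c(A = "ACGTA", B = "ACGTT", C = "ATGTA", D = "ACGCA")
  params <- list(rates = c(1.2, 2.5, 0.8, 1.1, 3.0, 1),
                 freqs = c(0.3, 0.2, 0.25, 0.25), alpha = 0.7)
  ll <- gtr_gamma_loglik(aln, tree, params)

  Q <- gtr_rate_matrix(params$rates, params$freqs)
  rates <- discrete_gamma_rates(params$alpha, 4)
  states <- sapply(strsplit(aln, ""), match, c("A", "C", "G", "T"))
  llb <- 0
  for (site in seq_len(nrow(states))) {
    tot <- 0
    for (r in rates) {
      P_A <- expm_oracle(Q * 0.1 * r); P_B <- expm_oracle(Q * 0.2 * r)
      P_C <- expm_oracle(Q * 0.15 * r); P_D <- expm_oracle(Q * 0.1 * r)
      P_6 <- expm_oracle(Q * 0.05 * r); P_7 <- expm_oracle(Q * 0.07 * r)
      s <- states[site, ]
      for (x6 in 1:4) for (x7 in 1:4) for (xr in 1:4) {
        tot <- tot + 0.25 * params$freqs[xr] * P_6[xr, x6] * P_7[xr, x7] *
          P_A[x6, s["A"]] * P_B[x6, s["B"]] *
          P_C[x7, s["C"]] * P_D[x7, s["D"]]
      }
    }
    llb <- llb + log(tot)
  }
  expect_equal(ll, unname(llb), tolerance = 1e-8)
})

test_that("GTR+Gamma likelihood agrees with phangorn", {
  skip_if_not_installed("phangorn")
  tree <- rtree_scaled(5, 0.5, seed = 6)
  set.seed(10)
  aln <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  }, character(1))
  names(aln) <- tree$tip.label
  params <- list(rates = c(1.5, 3, 0.7, 0.9, 2.5, 1),
                 freqs = c(0.28, 0.22, 0.26, 0.24), alpha = 0.9)
  ll <- gtr_gamma_loglik(aln, tree, params)

  dat <- phangorn::phyDat(t(sapply(strsplit(tolower(aln), ""), identity)))
  fit <- phangorn::pml(tree, dat, bf = params$freqs,
                       Q = params$rates, k = 4, shape = params$alpha)
  expect_equal(ll, as.numeric(stats::logLik(fit)), tolerance = 1e-6)
})

test_that("single-column GTR pattern probabilities sum to one", {
  tree <- read_newick(text = "(A:0.1,B:0.2,C:0.3);")
  params <- list(rates = c(1.2, 2.5, 0.8, 1.1, 3.0, 1),
                 freqs = c(0.3, 0.2, 0.25, 0.25), alpha = 0.6)
  nts <- c("A", "C", "G", "T")
  tot <- 0
  for (a in nts) for (b in nts) for (c in nts) {
    tot <- tot + exp(gtr_gamma_loglik(c(A = a, B = b, C = c), tree, params))
  }
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("GTR likelihood is invariant to re-rooting", {
  tree <- rtree_scaled(6, 0.5, seed = 19)
  sim_p <- list(rates = c(1, 2, 1, 1, 2, 1), freqs = rep(0.25, 4),
                alpha = 1)
  set.seed(20)
  aln <- vapply(1:6, function(i) {
    paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  }, character(1))
  names(aln) <- tree$tip.label
  ll1 <- gtr_gamma_loglik(aln, tree, sim_p)
  rerooted <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[3],
                        resolve.root = TRUE)
  ll2 <- gtr_gamma_loglik(aln, rerooted, sim_p)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("gaps are treated as missing data", {
  tree <- read_newick(text = "(A:0.1,B:0.2);")
  params <- list(rates = rep(1, 6), freqs = rep(0.25, 4), alpha = 1)
  ll_missing <- gtr_gamma_loglik(c(A = "A-", B = "AC"), tree, params)
  ll_one <- gtr_gamma_loglik(c(A = "A", B = "A"), tree, params)
  # second column marginalizes over A's state: contributes log pi(C...)=
  # log sum_x pi_x P(x->C) = log pi_C by reversibility/stationarity
  expect_equal(ll_missing, ll_one + log(0.25), tolerance = 1e-9)
})

test_that("branch-length/parameter optimization improves the likelihood", {
  tree <- rtree_scaled(5, 0.4, seed = 33)
  sim_p <- list(rates = c(1, 3, 1, 1, 3, 1), freqs = rep(0.25, 4),
                alpha = 5)
  sim <- simulate_nucleotide_alignment(tree, sim_p, n_sites = 10000,
                                       seed = 55)
  init_tree <- tree
  init_tree$edge.length <- rep(0.05, nrow(tree$edge))
  fit <- optimize_branch_lengths_and_params(sim, init_tree)
  ll_init <- gtr_gamma_loglik(sim, init_tree,
                              list(rates = rep(1, 6),
                                   freqs = panselect:::empirical_base_frequencies(sim),
                                   alpha = 1))
  expect_gte(fit$loglik, ll_init)
  expect_equal(fit$convergence, 0)
  # median relative branch-length error within 15 percent
  m1 <- ape::reorder.phylo(tree, "postorder")
  m2 <- ape::reorder.phylo(fit$tree, "postorder")
  rel <- abs(m2$edge.length - m1$edge.length) / pmax(m1$edge.length, 1e-6)
  expect_lt(stats::median(rel), 0.15)
  # starting from the truth cannot lose likelihood
  fit2 <- optimize_branch_lengths_and_params(
    sim, tree, init = list(rates = sim_p$rates, alpha = sim_p$alpha))
  expect_gte(fit2$loglik,
             gtr_gamma_loglik(sim, tree, list(
               rates = sim_p$rates,
               freqs = panselect:::empirical_base_frequencies(sim),
               alpha = sim_p$alpha)) - 1e-6)
})

test_that("fitted gamma shape preserves the true ordering", {
  tree <- rtree_scaled(5, 0.4, seed = 44)
  alphas <- c(0.5, 5)
  fitted <- vapply(alphas, function(a) {
    sim <- simulate_nucleotide_alignment(
      tree, list(rates = rep(1, 6), freqs = rep(0.25, 4), alpha = a),
      n_sites = 3000, seed = 60 + round(a * 10))
    optimize_branch_lengths_and_params(sim, tree)$params$alpha
  }, numeric(1))
  expect_lt(fitted[1L], fitted[2L])
})

test_that("bootstrap support is deterministic and finds true splits", {
  # balanced tree with long internal branches: strong structure
  tree <- read_newick(text = paste0("((A:0.3,B:0.3):0.2,(C:0.3,D:0.3):0.2,",
                                    "(E:0.3,F:0.3):0.2);"))
  sim <- simulate_nucleotide_alignment(
    tree, list(rates = rep(1, 6), freqs = rep(0.25, 4), alpha = 10),
    n_sites = 2000, seed = 71)
  bs1 <- bootstrap_support(sim, n_replicates = 50, seed = 5)
  bs2 <- bootstrap_support(sim, n_replicates = 50, seed = 5)
  expect_equal(write_newick(bs1), write_newick(bs2))
  sup <- suppressWarnings(as.numeric(bs1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 90))
  expect_equal(compare_trees(bs1, tree)$rf, 0)
})
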