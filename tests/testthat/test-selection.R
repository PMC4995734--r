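# Codon models: rate matrix structure, mixture likelihoods against
# enumeration oracles, LRTs, model fits and the core-gene scan.

test_that("codon rate matrix has generator structure and reversibility", {
  set.seed(2)
  for (rep in 1:3) {
    kappa <- runif(1, 0.5, 5)
    omega <- runif(1, 0.05, 3)
    pi <- as.vector(stats::rgamma(61, 1)) + 0.05
    pi <- pi / sum(pi)
    Q <- codon_rate_matrix(kappa, omega, pi)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    # detailed balance pi_i q_ij = pi_j q_ji
    expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-12)
    # scaling: expected rate 1
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  }
  # neutrality: omega = 1 makes single-step rates proportional to pi_j
  pi <- rep(1 / 61, 61)
  Q1 <- codon_rate_matrix(2, 1, pi, scale = FALSE)
  off <- Q1[upper.tri(Q1)]
  vals <- sort(unique(round(off[off > 0], 12)))
  expect_length(vals, 2L)  # pi_j and kappa * pi_j only
  expect_error(codon_rate_matrix(-1, 1, pi), "kappa")
  expect_error(codon_rate_matrix(1, -1, pi), "omega")
})

test_that("codon likelihood collapses to root frequencies at zero length", {
  tree <- read_newick(text = "((A:0,B:0):0,(C:0,D:0):0);")
  aln <- stats::setNames(rep("ATGAAA", 4), c("A", "B", "C", "D"))
  pi <- rep(1 / 61, 61)
  ll <- codon_site_loglik(aln, tree,
                          list(kappa = 2, pi = pi,
                               classes = data.frame(prop = 1, omega = 0.5)))
  expect_equal(ll, 2 * log(1 / 61), tolerance = 1e-9)
})

test_that("codon mixture likelihood matches ancestral enumeration", {
  tree <- read_newick(text = "((A:0.2,B:0.15):0.1,(C:0.3,D:0.05):0.08);")
  aln <- c(A = "ATGAAA", B = "ATGAAG", C = "ATGCAA", D = "CTGAAA")
  set.seed(77)
  pi <- as.vector(stats::rgamma(61, 2)) + 0.1
  pi <- pi / sum(pi)
  params <- list(kappa = 2.5, pi = pi,
                 classes = data.frame(prop = c(0.6, 0.4),
                                      omega = c(0.2, 1)))
  ll <- codon_site_loglik(aln, tree, params)

  # oracle: per site and class, sum over all 61^3 internal assignments
  mats <- panselect:::codon_class_matrices(params$kappa, pi,
    data.frame(prop = params$classes$prop,
               omega_bg = params$classes$omega,
               omega_fg = params$classes$omega))
  cods <- sense_codons()
  states <- t(vapply(aln, function(s) {
    match(substring(s, c(1, 4), c(3, 6)), cods)
  }, integer(2)))
  llb <- 0
  for (site in 1:2) {
    tot <- 0
    for (k in 1:2) {
      Q <- mats$bg[[k]]
      P_A <- expm_oracle(Q * 0.2); P_B <- expm_oracle(Q * 0.15)
      P_C <- expm_oracle(Q * 0.3); P_D <- expm_oracle(Q * 0.05)
      P_u <- expm_oracle(Q * 0.1); P_v <- expm_oracle(Q * 0.08)
      s <- states[, site]
      # enumerate the two internal ancestral codons; the root state is
      # summed out analytically per (u, v) pair
      acc <- 0
      for (xu in 1:61) {
        pa <- P_A[xu, s[1]] * P_B[xu, s[2]]
        if (pa == 0) next
        for (xv in 1:61) {
          pr_uv <- sum(pi * P_u[, xu] * P_v[, xv])
          acc <- acc + pr_uv * pa * P_C[xv, s[3]] * P_D[xv, s[4]]
        }
      }
      tot <- tot + params$classes$prop[k] * acc
    }
    llb <- llb + log(tot)
  }
  expect_equal(ll, unname(llb), tolerance = 1e-6)
})

test_that("two-taxon codon pattern probabilities sum to one", {
  tree <- read_newick(text = "(A:0.2,B:0.3);")
  pi <- rep(1 / 61, 61)
  params <- list(kappa = 2, pi = pi,
                 classes = data.frame(prop = c(0.7, 0.3),
                                      omega = c(0.1, 1)))
  cods <- sense_codons()
  prep <- panselect:::tree_prep(tree)
  # all 61^2 patterns in one compressed call
  grid <- expand.grid(a = 1:61, b = 1:61)
  states <- rbind(A = grid$a, B = grid$b)
  comp <- list(states = matrix(as.integer(states), nrow = 2,
                               dimnames = list(c("A", "B"), NULL)),
               weights = rep(1, nrow(grid)))
  lik <- exp(vapply(seq_len(nrow(grid)), function(i) {
    panselect:::codon_loglik_compressed(
      list(states = comp$states[, i, drop = FALSE], weights = 1),
      prep, params)
  }, numeric(1)))
  expect_equal(sum(lik), 1, tolerance = 1e-8)
})

test_that("codon likelihood is invariant to re-rooting", {
  tree <- rtree_scaled(5, 0.3, seed = 91)
  sim <- simulate_codon_alignment(tree, "M2a",
    list(kappa = 2, p0 = 0.5, p1 = 0.3, omega0 = 0.2, omega2 = 3),
    n_codons = 30, seed = 92)
  params <- list(kappa = 2, pi = rep(1 / 61, 61),
                 classes = data.frame(prop = c(0.5, 0.3, 0.2),
                                      omega = c(0.2, 1, 3)))
  ll1 <- codon_site_loglik(sim$alignment, tree, params)
  rr <- ape::root(ape::unroot(tree), outgroup = tree$tip.label[2],
                  resolve.root = TRUE)
  ll2 <- codon_site_loglik(sim$alignment, rr, params)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("internal stop codons are rejected with position", {
  tree <- read_newick(text = "(A:0.1,B:0.1);")
  aln <- c(A = "ATGTAAAAA", B = "ATGAAAAAA")
  expect_error(codon_site_loglik(aln, tree,
                                 list(kappa = 2, pi = rep(1 / 61, 61),
                                      classes = data.frame(prop = 1,
                                                           omega = 1))),
               "stop codon in sequence 'A' at codon 2")
})

test_that("LRT results follow the chi-square reference", {
  r0 <- panselect:::lrt_result(-100, -100, df = 2L)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  r <- panselect:::lrt_result(-100, -100 + 5.991465 / 2, df = 2L)
  expect_equal(r$p_value, 0.05, tolerance = 1e-4)

  r1 <- panselect:::lrt_result(-50, -50 + 3.841459 / 2, df = 1L)
  expect_equal(r1$p_value, 0.05, tolerance = 1e-4)
})

test_that("site models recover simulated parameters and nest properly", {
  tree <- rtree_scaled(8, 0.4, seed = 101)
  simA <- simulate_codon_alignment(
    tree, "M1a", list(kappa = 2, p0 = 0.8, omega0 = 0.2),
    n_codons = 300, seed = 102)
  sf <- fit_site_models(simA$alignment, tree, branch_lengths = "scale",
                        n_starts = 2)
  expect_gte(sf$m2a$loglik, sf$m1a$loglik - 1e-6)
  w0 <- sf$m1a$params$classes$omega[1L]
  expect_lt(abs(w0 - 0.2), 0.1)

  simB <- simulate_codon_alignment(
    tree, "M2a", list(kappa = 2, p0 = 0.6, p1 = 0.2, omega0 = 0.15,
                      omega2 = 4), n_codons = 300, seed = 103)
  sfB <- fit_site_models(simB$alignment, tree, branch_lengths = "scale",
                         n_starts = 2)
  expect_gte(sfB$m2a$loglik, sfB$m1a$loglik - 1e-6)
  expect_gt(sfB$m2a$params$classes$omega[3L], 1)
  expect_lt(site_lrt(sfB)$p_value, 0.05)
})

test_that("branch-site fits detect foreground selection and order lls", {
  tree <- rtree_scaled(6, 0.35, seed = 111)
  fg <- pick_clade(tree, 3L)
  simS <- simulate_codon_alignment(
    tree, "branch_site",
    list(kappa = 2, p0 = 0.7, p1 = 0.15, omega0 = 0.1, omega2 = 5,
         foreground = fg), n_codons = 300, seed = 112)
  bf <- fit_branch_site(simS$alignment, tree, fg,
                        branch_lengths = "scale", n_starts = 2)
  expect_gte(bf$alt$loglik, bf$null$loglik - 1e-6)
  expect_gt(bf$alt$params$classes$omega_fg[3L], 1)
  expect_gt(branch_site_lrt(bf)$statistic, 0)

  # foreground identical to background in truth
  simN <- simulate_codon_alignment(
    tree, "M1a", list(kappa = 2, p0 = 0.8, omega0 = 0.2),
    n_codons = 300, seed = 113)
  bfN <- fit_branch_site(simN$alignment, tree, fg,
                         branch_lengths = "scale", n_starts = 2)
  expect_gte(bfN$alt$loglik, bfN$null$loglik - 1e-6)
  expect_lt(branch_site_lrt(bfN)$statistic, 6)

  expect_error(fit_branch_site(simN$alignment, tree, character(0)),
               "foreground")
})

test_that("the core-gene scan ranks planted genes and counts correctly", {
  tree <- rtree_scaled(5, 0.35, seed = 121)
  fg <- pick_clade(tree, 2L)
  alns <- list()
  for (i in 1:8) {
    regime <- if (i <= 2) "branch_site" else "M1a"
    pars <- if (i <= 2) {
      list(kappa = 2, p0 = 0.6, p1 = 0.15, omega0 = 0.1, omega2 = 8,
           foreground = fg)
    } else {
      list(kappa = 2, p0 = 0.8, omega0 = 0.1)
    }
    alns[[sprintf("fam%02d", i)]] <-
      simulate_codon_alignment(tree, regime, pars, n_codons = 150,
                               seed = 130 + i)$alignment
  }
  scan <- scan_core_genes(alns, tree, fg, alpha = 0.05, n_starts = 1,
                          seed = 1)
  expect_equal(nrow(scan$table), 8L)
  expect_true(all(scan$table$status == "ok"))
  top2 <- scan$table$family_id[order(-scan$table$lrt_branch)][1:2]
  expect_setequal(top2, c("fam01", "fam02"))
  # percentages recount
  expect_equal(scan$summary$pct_site_selected,
               100 * sum(scan$table$site_selected) / 8)
  expect_equal(scan$summary$n_branch_only + scan$summary$n_shared,
               scan$summary$n_branch_selected)

  # alpha = 0 selects nothing
  scan0 <- scan_core_genes(alns[1:2], tree, fg, alpha = 0, n_starts = 1)
  expect_equal(scan0$summary$n_site_selected, 0L)
  expect_equal(scan0$summary$n_branch_selected, 0L)

  # non single-copy family is skipped with a reason
  bad <- alns[[1L]]
  names(bad)[2L] <- names(bad)[1L]
  scanB <- scan_core_genes(list(dup = bad), tree, fg, n_starts = 1)
  expect_match(scanB$table$status, "skipped")
})
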