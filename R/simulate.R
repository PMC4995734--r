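# Synthetic-data generators with known ground truth: gene-content
# histories on a tree, codon alignments under neutral/purifying/selected
# regimes, whole proteome fixtures, and serial-transfer competition series.
# Every generator is a pure function of its config and seed; independent
# substreams keep regimes decoupled.

#' Simulation configuration
#'
#' Bundles the study conditions for the synthetic fixtures. The default
#' `mini_study_config()` is a desk-scale analogue of a 16-genome bacterial
#' pan-genome study: 6 genomes, 200 core and 300 accessory families, and 3
#' core genes planted under branch-site positive selection on a 3-leaf
#' foreground clade.
#'
#' @param seed Integer seed (mandatory; all outputs reproducible).
#' @param n_genomes Number of genomes.
#' @param tree `phylo` tree (with branch lengths) or `NULL` for a seeded
#'   random Yule tree over `n_genomes` tips.
#' @param gain_rate,loss_rate Gene gain/loss events per unit branch length.
#' @param n_core_families,n_accessory_families Family counts.
#' @param n_codons Codon length of simulated genes.
#' @param kappa Transition/transversion ratio for sequence simulation.
#' @param core_regime `"M1a"`, `"M2a"` or `"branch_site"`; parameters in
#'   `regime_params`.
#' @param regime_params List of true site-class parameters (see
#'   [simulate_codon_alignment()]).
#' @param n_selected Number of core genes planted under the selected
#'   regime (others evolve under the purifying M1a regime).
#' @param foreground Tip labels of the planted foreground clade.
#' @param competition List: `w_true`, `cycles`, `n_replicates`,
#'   `inoculum_fraction`, `growth_factor`, `noise_sd`, `detection_limit`,
#'   `x0`, `y0`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genomes = 6L,
                       tree = NULL,
                       gain_rate = 0.5,
                       loss_rate = 0.5,
                       n_core_families = 200L,
                       n_accessory_families = 300L,
                       n_codons = 120L,
                       kappa = 2,
                       core_regime = "branch_site",
                       regime_params = list(p0 = 0.75, p1 = 0.2,
                                            omega0 = 0.1, omega2 = 5),
                       n_selected = 3L,
                       foreground = NULL,
                       competition = list(w_true = 1.4, cycles = 10L,
                                          n_replicates = 2L,
                                          inoculum_fraction = 0.05,
                                          growth_factor = 100,
                                          noise_sd = 0.05,
                                          detection_limit = 1e2,
                                          x0 = 1e7, y0 = 1e7)) {
  if (missing(seed)) stop("seed is mandatory")
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @export
mini_study_config <- function(seed = 20151L) {
  # fixed 6-genome tree with a defined 3-tip foreground clade (G4, G5,
  # G6) whose subtree carries enough length for branch-site signal to be
  # identifiable; depths are within-species scale (expected substitutions
  # per codon)
  tree <- ape::read.tree(text = paste0(
    "((G1:0.05,G2:0.05):0.03,(G3:0.06,((G4:0.05,G5:0.05):0.03,",
    "G6:0.07):0.03):0.02);"))
  sim_config(seed = seed, tree = tree, n_codons = 150L,
             gain_rate = 2, loss_rate = 2,
             regime_params = list(p0 = 0.65, p1 = 0.2,
                                  omega0 = 0.1, omega2 = 10),
             foreground = c("G4", "G5", "G6"))
}

#' Tips of a clade of a given size
#'
#' Deterministically picks the first internal node (in postorder) with
#' exactly `size` descendant tips; used to plant a monophyletic
#' foreground. Errors if the tree has no clade of that size.
#'
#' @param tree `phylo` tree.
#' @param size Number of tips in the clade.
#' @return Character vector of tip labels.
#' @export
pick_clade <- function(tree, size = 3L) {
  prep <- tree_prep(tree)
  ntips_below <- integer(prep$n_nodes)
  ntips_below[seq_len(prep$ntip)] <- 1L
  for (e in seq_len(nrow(prep$edges))) {
    p <- prep$edges[e, 1L]; ch <- prep$edges[e, 2L]
    ntips_below[p] <- ntips_below[p] + ntips_below[ch]
  }
  cand <- which(ntips_below == size)
  if (size > 1L) cand <- cand[cand > prep$ntip]
  if (!length(cand)) stop("tree has no clade with ", size, " tips")
  node <- cand[1L]
  in_clade <- rep(FALSE, prep$n_nodes)
  in_clade[node] <- TRUE
  for (e in rev(seq_len(nrow(prep$edges)))) {
    if (in_clade[prep$edges[e, 1L]]) in_clade[prep$edges[e, 2L]] <- TRUE
  }
  prep$labels[which(in_clade[seq_len(prep$ntip)])]
}

# seeded Yule-like random tree scaled to a given total depth
sim_tree <- function(n_genomes, seed, depth = 0.08) {
  set.seed(seed)
  tr <- ape::rcoal(n_genomes, tip.label = paste0("G", seq_len(n_genomes)))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) *
    depth
  tr
}

resolve_tree <- function(config) {
  if (!is.null(config$tree)) return(config$tree)
  sim_tree(config$n_genomes, config$seed * 13L + 1L)
}

#' Simulate gene content by gain/loss along a tree
#'
#' Each accessory family evolves as a two-state (present/absent)
#' continuous-time process with the given gain and loss rates, simulated
#' event-by-event (Gillespie) along every branch from a stationary root
#' draw; core families are present everywhere.
#'
#' @param config A [sim_config()].
#' @return List: `matrix` (presence/absence, genomes x families), `truth`
#'   (tree, per-family root states and total event counts).
#' @export
simulate_gene_content <- function(config) {
  tree <- resolve_tree(config)
  prep <- tree_prep(tree)
  set.seed(config$seed * 13L + 2L)
  g <- config$gain_rate; l <- config$loss_rate
  p_stat <- if (g + l > 0) g / (g + l) else 0.5
  nfam <- config$n_accessory_families
  n_core <- config$n_core_families

  states <- matrix(1L, prep$n_nodes, nfam + n_core)
  events <- numeric(nfam + n_core)
  if (nfam > 0) {
    acc_cols <- n_core + seq_len(nfam)
    root_state <- stats::rbinom(nfam, 1L, p_stat)
    states[prep$root, acc_cols] <- root_state
    # preorder = reversed postorder edges
    for (e in rev(seq_len(nrow(prep$edges)))) {
      parent <- prep$edges[e, 1L]; child <- prep$edges[e, 2L]
      t_len <- prep$blens[e]
      for (fi in seq_len(nfam)) {
        s <- states[parent, acc_cols[fi]]
        t_now <- 0
        repeat {
          rate <- if (s == 1L) l else g
          if (rate <= 0) break
          t_now <- t_now + stats::rexp(1L, rate)
          if (t_now > t_len) break
          s <- 1L - s
          events[acc_cols[fi]] <- events[acc_cols[fi]] + 1
        }
        states[child, acc_cols[fi]] <- s
      }
    }
  }
  fam_ids <- c(if (n_core) sprintf("CORE%04d", seq_len(n_core)),
               if (nfam) sprintf("ACC%04d", seq_len(nfam)))
  m <- states[seq_len(prep$ntip), , drop = FALSE]
  dimnames(m) <- list(prep$labels, fam_ids)
  # a family absent everywhere carries no gene; keep it in the truth table
  list(matrix = m,
       truth = list(tree = tree, family_ids = fam_ids,
                    event_counts = events,
                    total_tree_length = sum(prep$blens)))
}

#' Simulate a codon alignment under a site-class regime
#'
#' Draws a site class per column from the class proportions, a root codon
#' from the equilibrium frequencies, and evolves each column along the
#' tree under the class's Goldman-Yang generator (foreground branches use
#' the foreground omega in the branch-site regime). Stop codons never
#' arise because the state space is the 61 sense codons.
#'
#' @param tree `phylo` tree with branch lengths in expected substitutions
#'   per codon.
#' @param regime `"M1a"`, `"M2a"` or `"branch_site"`.
#' @param params List of true parameters: `kappa`, optional `pi` (61
#'   frequencies, uniform if absent), and per regime: M1a `p0`, `omega0`;
#'   M2a adds `p1`, `omega2`; branch_site `p0`, `p1`, `omega0`, `omega2`
#'   plus `foreground` tips (and optional `scope`).
#' @param n_codons Number of codon sites.
#' @param seed Integer seed.
#' @return List: `alignment` (named character vector of codon sequences),
#'   `truth` (per-site class, class table, params).
#' @export
simulate_codon_alignment <- function(tree, regime, params, n_codons, seed) {
  set.seed(seed)
  pi <- if (!is.null(params$pi)) params$pi else uniform_codon_frequencies()
  classes <- switch(regime,
    M1a = data.frame(prop = c(params$p0, 1 - params$p0),
                     omega_bg = c(params$omega0, 1),
                     omega_fg = c(params$omega0, 1)),
    M2a = data.frame(prop = c(params$p0, params$p1,
                              1 - params$p0 - params$p1),
                     omega_bg = c(params$omega0, 1, params$omega2),
                     omega_fg = c(params$omega0, 1, params$omega2)),
    branch_site = {
      pt <- params$p0 + params$p1
      f0 <- params$p0 / pt
      data.frame(prop = c(params$p0, params$p1,
                          f0 * (1 - pt), (1 - f0) * (1 - pt)),
                 omega_bg = c(params$omega0, 1, params$omega0, 1),
                 omega_fg = c(params$omega0, 1, params$omega2,
                              params$omega2))
    },
    stop("invalid regime '", regime, "'"))
  if (any(classes$prop < 0) || abs(sum(classes$prop) - 1) > 1e-8) {
    stop("regime proportions invalid")
  }
  prep <- tree_prep(tree)
  fg_mask <- if (regime == "branch_site") {
    if (is.null(params$foreground)) {
      stop("branch_site regime requires foreground tips")
    }
    foreground_edge_mask(NULL, prep, params$foreground,
                         scope = if (is.null(params$scope)) "clade"
                         else params$scope)
  } else rep(FALSE, nrow(prep$edges))

  mats <- codon_class_matrices(params$kappa, pi, classes)
  eig_bg <- lapply(mats$bg, rev_eigen, pi = pi)
  eig_fg <- lapply(mats$fg, rev_eigen, pi = pi)
  site_class <- sample.int(nrow(classes), n_codons, replace = TRUE,
                           prob = classes$prop)
  states <- matrix(0L, prep$n_nodes, n_codons)
  states[prep$root, ] <- sample.int(61L, n_codons, replace = TRUE,
                                    prob = pi)
  # per-edge transition matrices per class, then evolve column-wise
  for (e in rev(seq_len(nrow(prep$edges)))) {
    parent <- prep$edges[e, 1L]; child <- prep$edges[e, 2L]
    t_len <- prep$blens[e]
    for (k in sort(unique(site_class))) {
      eig <- if (fg_mask[e]) eig_fg[[k]] else eig_bg[[k]]
      P <- eig$A %*% (exp(eig$lambda * t_len) * eig$Ainv)
      P[P < 0] <- 0
      P <- P / rowSums(P)
      idx <- which(site_class == k)
      par_states <- states[parent, idx]
      for (s in unique(par_states)) {
        sel <- idx[par_states == s]
        states[child, sel] <- sample.int(61L, length(sel), replace = TRUE,
                                         prob = P[s, ])
      }
    }
  }
  cods <- codon_info()$codons
  aln <- stats::setNames(
    vapply(seq_len(prep$ntip), function(i) {
      paste(cods[states[i, ]], collapse = "")
    }, character(1)), prep$labels)
  list(alignment = aln,
       truth = list(site_class = site_class, classes = classes,
                    kappa = params$kappa, pi = pi, tree = tree))
}

#' Simulate a nucleotide alignment under GTR+Gamma
#'
#' Root states drawn from the equilibrium frequencies evolve along the
#' tree under the GTR generator, with per-site rates drawn from the
#' discrete-gamma categories when `params$alpha` is given.
#'
#' @param tree `phylo` tree, branch lengths in expected substitutions per
#'   site.
#' @param params List: `rates` (GTR exchangeabilities), `freqs`, optional
#'   `alpha` and `ncat`.
#' @param n_sites Number of sites.
#' @param seed Integer seed.
#' @return Named character vector of aligned sequences.
#' @export
simulate_nucleotide_alignment <- function(tree, params, n_sites, seed) {
  set.seed(seed)
  Q <- gtr_rate_matrix(params$rates, params$freqs)
  eig <- rev_eigen(Q, params$freqs)
  rates <- if (!is.null(params$alpha)) {
    discrete_gamma_rates(params$alpha,
                         if (is.null(params$ncat)) 4L else params$ncat)
  } else 1
  prep <- tree_prep(tree)
  site_rate <- rates[sample.int(length(rates), n_sites, replace = TRUE)]
  states <- matrix(0L, prep$n_nodes, n_sites)
  states[prep$root, ] <- sample.int(4L, n_sites, replace = TRUE,
                                    prob = params$freqs)
  for (e in rev(seq_len(nrow(prep$edges)))) {
    parent <- prep$edges[e, 1L]; child <- prep$edges[e, 2L]
    for (r in unique(site_rate)) {
      P <- eig$A %*% (exp(eig$lambda * prep$blens[e] * r) * eig$Ainv)
      P[P < 0] <- 0
      P <- P / rowSums(P)
      idx <- which(site_rate == r)
      par_states <- states[parent, idx]
      for (s in unique(par_states)) {
        sel <- idx[par_states == s]
        states[child, sel] <- sample.int(4L, length(sel), replace = TRUE,
                                         prob = P[s, ])
      }
    }
  }
  stats::setNames(vapply(seq_len(prep$ntip), function(i) {
    paste(NUC_STATES[states[i, ]], collapse = "")
  }, character(1)), prep$labels)
}

#' Simulate whole proteomes with planted families
#'
#' Core families receive a codon alignment simulated on the genome tree
#' (the planted selected genes under the configured selected regime, the
#' rest under purifying M1a); accessory families follow the simulated
#' presence/absence history and get their own family-specific sequences.
#' Proteins are the standard-code translations of the CDS.
#'
#' @param config A [sim_config()].
#' @return List: `proteomes` (list of [proteome()]), `truth` (tree, family
#'   memberships, presence matrix, selected gene ids, per-gene alignment
#'   truths).
#' @export
simulate_proteomes <- function(config) {
  tree <- resolve_tree(config)
  gc_sim <- simulate_gene_content(config)
  pres <- gc_sim$matrix
  n_core <- config$n_core_families
  fam_ids <- colnames(pres)
  set.seed(config$seed * 13L + 3L)
  fam_seeds <- sample.int(.Machine$integer.max %/% 2L,
                          length(fam_ids))
  selected <- if (config$n_selected > 0 && n_core > 0) {
    sprintf("CORE%04d", seq_len(min(config$n_selected, n_core)))
  } else character(0)
  rp <- config$regime_params
  fg <- config$foreground
  if (is.null(fg)) {
    for (sz in unique(pmin(c(3L, 2L, 1L), length(tree$tip.label) - 1L))) {
      fg <- tryCatch(pick_clade(tree, sz), error = function(e) NULL)
      if (!is.null(fg)) break
    }
  }

  alignments <- list()
  truth_regime <- stats::setNames(rep("M1a", length(fam_ids)), fam_ids)
  for (fi in seq_along(fam_ids)) {
    fam <- fam_ids[fi]
    present <- rownames(pres)[pres[, fam] == 1L]
    if (!length(present)) next
    if (fam %in% selected) {
      sim <- simulate_codon_alignment(
        tree, config$core_regime,
        list(kappa = config$kappa, p0 = rp$p0, p1 = rp$p1,
             omega0 = rp$omega0, omega2 = rp$omega2, foreground = fg),
        config$n_codons, fam_seeds[fi])
      truth_regime[fam] <- config$core_regime
    } else {
      sim <- simulate_codon_alignment(
        tree, "M1a",
        list(kappa = config$kappa, p0 = 0.8, omega0 = 0.1),
        config$n_codons, fam_seeds[fi])
    }
    alignments[[fam]] <- sim$alignment[present]
  }
  genome_ids <- tree$tip.label
  proteomes <- lapply(genome_ids, function(g) {
    fams <- names(alignments)[vapply(alignments, function(a) {
      g %in% names(a)
    }, logical(1))]
    cds <- stats::setNames(vapply(fams, function(f) {
      alignments[[f]][[g]]
    }, character(1)), paste0(f_gene_id(fams), "_", g))
    prots <- vapply(seq_along(cds), function(i) {
      translate_cds(cds[[i]], id = names(cds)[i])
    }, character(1))
    names(prots) <- names(cds)
    proteome(g, prots, cds)
  })
  names(proteomes) <- genome_ids
  memberships <- lapply(stats::setNames(names(alignments),
                                        names(alignments)), function(f) {
    paste0(names(alignments[[f]]), "|", f_gene_id(f), "_",
           names(alignments[[f]]))
  })
  list(proteomes = proteomes,
       truth = list(tree = tree, presence = pres,
                    memberships = memberships,
                    selected_families = selected,
                    regime = truth_regime,
                    foreground = fg,
                    alignments = alignments))
}

f_gene_id <- function(fam) tolower(fam)

#' Simulate a serial-transfer competition series
#'
#' Per cycle both strains grow from their start abundances; the reference
#' strain y realizes a fixed multiplicative growth (`growth_factor`) and
#' strain x realizes `growth_factor^w_true`, so the ratio of realized
#' Malthusian growth equals the planted fitness. Between cycles both are
#' diluted by `inoculum_fraction`. Multiplicative lognormal measurement
#' noise (sd `noise_sd` on the log scale) is applied independently to
#' every start/end read; measurements below `detection_limit` are
#' censored (coded `NA` with a flag, never zero).
#'
#' @param config A [sim_config()] (its `competition` element) or the
#'   competition list itself.
#' @return List: `series` (data.frame: replicate, cycle, strain, stage,
#'   true_abundance, measured, censored), `truth` (w_true and the
#'   noise-free per-cycle values).
#' @export
simulate_competition <- function(config) {
  cc <- if (inherits(config, "sim_config")) config$competition else config
  seed <- if (inherits(config, "sim_config")) config$seed * 13L + 4L
  else cc$seed
  if (is.null(seed)) stop("competition config needs a seed")
  if (cc$w_true <= 0) stop("w_true must be > 0")
  if (cc$cycles < 1L) stop("cycles must be >= 1")
  set.seed(seed)
  rows <- list()
  for (rep_i in seq_len(cc$n_replicates)) {
    x <- cc$x0; y <- cc$y0
    for (cyc in seq_len(cc$cycles)) {
      xF <- x * cc$growth_factor^cc$w_true
      yF <- y * cc$growth_factor
      for (strain in c("x", "y")) {
        for (stage in c("start", "end")) {
          tv <- switch(paste(strain, stage),
                       "x start" = x, "x end" = xF,
                       "y start" = y, "y end" = yF)
          meas <- tv * exp(stats::rnorm(1L, 0, cc$noise_sd))
          cens <- meas < cc$detection_limit
          rows[[length(rows) + 1L]] <- data.frame(
            replicate = rep_i, cycle = cyc, strain = strain,
            stage = stage, true_abundance = tv,
            measured = if (cens) NA_real_ else meas,
            censored = cens)
        }
      }
      x <- xF * cc$inoculum_fraction
      y <- yF * cc$inoculum_fraction
      if (x < 1 || y < 1) break  # extinction: truncate series
    }
  }
  series <- do.call(rbind, rows)
  list(series = series,
       truth = list(w_true = cc$w_true,
                    growth_factor = cc$growth_factor,
                    config = cc))
}
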