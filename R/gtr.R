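# GTR+Gamma nucleotide likelihood and ML fitting of branch lengths and
# model parameters on a fixed topology.

NUC_STATES <- c("A", "C", "G", "T")

# integer state matrix (taxa x sites) from a nucleotide alignment;
# anything outside ACGT (gaps, ambiguity codes) becomes NA = missing
nuc_state_matrix <- function(aln) {
  m <- aln_matrix(aln)
  s <- matrix(match(m, NUC_STATES), nrow = nrow(m),
              dimnames = dimnames(m))
  storage.mode(s) <- "integer"
  s
}

#' GTR rate matrix
#'
#' General time-reversible nucleotide generator, scaled to one expected
#' substitution per unit branch length at equilibrium.
#'
#' @param rates Exchangeabilities `c(AC, AG, AT, CG, CT, GT)`; `GT` is the
#'   reference and conventionally 1. A length-5 vector is taken as the first
#'   five with `GT = 1`.
#' @param freqs Base frequencies (A, C, G, T), summing to 1.
#' @return 4x4 generator with zero row sums.
#' @export
gtr_rate_matrix <- function(rates, freqs) {
  if (length(rates) == 5L) rates <- c(rates, 1)
  if (length(rates) != 6L) stop("rates must have length 5 or 6")
  if (any(rates <= 0)) stop("exchangeabilities must be positive")
  if (length(freqs) != 4L || any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8) {
    stop("freqs must be 4 non-negative values summing to 1")
  }
  R <- matrix(0, 4L, 4L, dimnames = list(NUC_STATES, NUC_STATES))
  R[1, 2] <- rates[1]; R[1, 3] <- rates[2]; R[1, 4] <- rates[3]
  R[2, 3] <- rates[4]; R[2, 4] <- rates[5]; R[3, 4] <- rates[6]
  R <- R + t(R)
  Q <- R * rep(freqs, each = 4L)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

#' Log-likelihood under GTR+Gamma
#'
#' Felsenstein pruning over all columns with discrete-gamma rate
#' heterogeneity (equal-probability categories, category-mean rates).
#' Gaps and ambiguity codes are treated as missing data.
#'
#' @param aln Named character vector: aligned nucleotide sequences.
#' @param tree `phylo` tree whose tip labels match `names(aln)`; branch
#'   lengths in expected substitutions per site.
#' @param params List with `rates` (length 5 or 6 exchangeabilities),
#'   `freqs` (A,C,G,T), `alpha` (gamma shape) and optional `ncat`
#'   (default 4).
#' @return Log-likelihood (single number).
#' @export
gtr_gamma_loglik <- function(aln, tree, params) {
  if (!length(aln) || unique(nchar(aln))[1L] == 0L) {
    stop("zero-length alignment")
  }
  if (!setequal(names(aln), tree$tip.label)) {
    stop("alignment labels do not match tree tips")
  }
  prep <- tree_prep(tree)
  s <- nuc_state_matrix(aln)[prep$labels, , drop = FALSE]
  comp <- compress_patterns(s)
  gtr_gamma_loglik_compressed(comp, prep, params)
}

# internal: likelihood on a precompressed pattern set
gtr_gamma_loglik_compressed <- function(comp, prep, params) {
  ncat <- if (is.null(params$ncat)) 4L else params$ncat
  Q <- gtr_rate_matrix(params$rates, params$freqs)
  eig <- rev_eigen(Q, params$freqs)
  eig$id <- "gtr"
  rates <- if (ncat > 1L) discrete_gamma_rates(params$alpha, ncat) else 1
  classes <- lapply(rates, function(r) {
    list(eigs = list(eig), edge_eig = rep(1L, nrow(prep$edges)),
         prob = 1 / length(rates), root_freq = params$freqs, rate = r)
  })
  mixture_loglik(comp, prep, classes)
}

empirical_base_frequencies <- function(aln) {
  s <- nuc_state_matrix(aln)
  f <- tabulate(s[!is.na(s)], nbins = 4L) + 0.5
  f / sum(f)
}

#' Fit branch lengths and GTR+Gamma parameters on a fixed topology
#'
#' Box-constrained quasi-Newton (L-BFGS-B on log/softmax transforms)
#' maximization of [gtr_gamma_loglik()] over branch lengths,
#' exchangeabilities, the gamma shape and (optionally) base frequencies.
#'
#' @param aln Nucleotide alignment (named character vector).
#' @param topology `phylo` topology; existing branch lengths are used as
#'   starting values (missing lengths start at 0.1).
#' @param init Optional list of starting `rates`, `freqs`, `alpha`.
#' @param optimize_freqs If `FALSE` (default) base frequencies are fixed at
#'   their empirical values, the common practice.
#' @param control Passed to [stats::optim()].
#' @return List: `tree` (fitted branch lengths), `params`, `loglik`,
#'   `convergence` (0 = converged).
#' @export
optimize_branch_lengths_and_params <- function(aln, topology, init = NULL,
                                               optimize_freqs = FALSE,
                                               control = list()) {
  tree <- ape::reorder.phylo(topology, "postorder")
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  tree$edge.length <- pmax(tree$edge.length, 1e-6)
  prep <- tree_prep(tree)
  s <- nuc_state_matrix(aln)[prep$labels, , drop = FALSE]
  comp <- compress_patterns(s)

  emp_freqs <- empirical_base_frequencies(aln)
  init_rates <- if (!is.null(init$rates)) init$rates[1:5] else rep(1, 5)
  init_freqs <- if (!is.null(init$freqs)) init$freqs else emp_freqs
  init_alpha <- if (!is.null(init$alpha)) init$alpha else 1

  nb <- length(prep$blens)
  par0 <- c(log(prep$blens), log(init_rates), log(init_alpha))
  if (optimize_freqs) par0 <- c(par0, log(init_freqs[1:3] / init_freqs[4]))

  unpack <- function(par) {
    bl <- exp(par[seq_len(nb)])
    rates <- c(exp(par[nb + 1:5]), 1)
    alpha <- exp(par[nb + 6L])
    freqs <- if (optimize_freqs) {
      z <- c(exp(par[nb + 7:9]), 1)
      z / sum(z)
    } else emp_freqs
    list(blens = bl, rates = rates, freqs = freqs, alpha = alpha)
  }
  negll <- function(par) {
    p <- unpack(par)
    pr <- prep
    pr$blens <- p$blens
    ll <- gtr_gamma_loglik_compressed(
      comp, pr, list(rates = p$rates, freqs = p$freqs, alpha = p$alpha))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  lower <- c(rep(log(1e-8), nb), rep(log(1e-4), 5), log(0.02),
             if (optimize_freqs) rep(-12, 3))
  upper <- c(rep(log(10), nb), rep(log(1e4), 5), log(50),
             if (optimize_freqs) rep(12, 3))
  ctl <- utils::modifyList(list(maxit = 500L), control)
  fit <- stats::optim(par0, negll, method = "L-BFGS-B",
                      lower = lower, upper = upper, control = ctl)
  p <- unpack(fit$par)
  out_tree <- tree
  out_tree$edge.length <- p$blens
  if (-fit$value < gtr_gamma_loglik_compressed(
        comp, prep,
        list(rates = c(init_rates, 1), freqs = init_freqs,
             alpha = init_alpha)) - 1e-6) {
    warning("optimizer ended below the starting log-likelihood")
  }
  list(tree = out_tree,
       params = list(rates = p$rates, freqs = p$freqs, alpha = p$alpha,
                     ncat = 4L),
       loglik = -fit$value,
       convergence = fit$convergence)
}

#' Bootstrap support by column resampling
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate by neighbor joining on model-based (TN93) distances, and
#' annotates the reference tree with the percentage of replicates
#' containing each internal bipartition.
#'
#' @param aln Nucleotide alignment (named character vector).
#' @param tree Reference `phylo` tree to annotate; if `NULL`, built from
#'   the full alignment by the same distance + NJ route.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the column resampling.
#' @return `tree` with `node.label` set to support percentages (root label
#'   empty).
#' @export
bootstrap_support <- function(aln, tree = NULL, n_replicates = 1000L,
                              seed = 1L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  m <- aln_matrix(aln)
  build <- function(mat) {
    seqs <- apply(mat, 1L, paste, collapse = "")
    d <- tn93_distances(seqs)
    nj_topology(d)
  }
  if (is.null(tree)) tree <- build(m)
  set.seed(seed)
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    # replicate trees routinely clamp tiny negative NJ branches; the
    # per-replicate warning carries no information
    reps[[b]] <- suppressWarnings(build(m[, cols, drop = FALSE]))
  }
  cnt <- ape::prop.clades(tree, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  support <- round(100 * cnt / n_replicates, 1)
  tree$node.label <- as.character(support)
  tree$node.label[1L] <- ""
  tree
}

# TN93 pairwise distances (ape), with a small floor for saturated pairs
tn93_distances <- function(seqs) {
  bin <- ape::as.DNAbin(t(vapply(seqs, function(s) {
    strsplit(tolower(s), "")[[1L]]
  }, character(unique(nchar(seqs))[1L]))))
  d <- ape::dist.dna(bin, model = "TN93", pairwise.deletion = TRUE)
  d[!is.finite(d)] <- max(d[is.finite(d)], 1) * 2
  as.matrix(d)
}
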