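# Shared phylogenetic-likelihood machinery: reversible-generator
# eigendecomposition, site-pattern compression, discrete-gamma rates and
# the R-side wrapper over the C++ pruning kernel.

# postorder edge bookkeeping for an ape tree
tree_prep <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  tree <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  list(edges = tree$edge,
       blens = tree$edge.length,
       ntip = length(tree$tip.label),
       n_nodes = max(tree$edge),
       root = length(tree$tip.label) + 1L,
       labels = tree$tip.label)
}

# Eigendecomposition of a reversible generator via pi^{1/2} symmetrization:
# P(t) = A exp(diag(lambda) t) Ainv with all-real factors.
rev_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  S <- Q * (sp %o% (1 / sp))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(A = e$vectors / sp, Ainv = t(e$vectors * sp), lambda = e$values)
}

# Collapse identical alignment columns; states NA -> 0 (missing).
compress_patterns <- function(state_mat) {
  key <- apply(state_mat, 2L, paste, collapse = ",")
  ux <- which(!duplicated(key))
  states <- state_mat[, ux, drop = FALSE]
  states[is.na(states)] <- 0L
  w <- as.numeric(table(factor(key, levels = key[ux])))
  storage.mode(states) <- "integer"
  list(states = states, weights = w)
}

#' Discrete-gamma rate categories
#'
#' Mean rates of `ncat` equal-probability bins of a Gamma(shape = alpha,
#' rate = alpha) distribution (mean 1), the standard discretization used
#' for among-site rate heterogeneity.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param ncat Number of categories (default 4).
#' @return Numeric vector of `ncat` relative rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4L) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  q <- stats::qgamma(seq(0, 1, length.out = ncat + 1L), shape = alpha,
                     rate = alpha)
  # E[X | bin] = ncat * (F_{alpha+1}(upper) - F_{alpha+1}(lower)), mean-1 gamma
  up <- stats::pgamma(q[-1L], shape = alpha + 1, rate = alpha)
  lo <- stats::pgamma(q[-(ncat + 1L)], shape = alpha + 1, rate = alpha)
  r <- ncat * (up - lo)
  r / mean(r)
}

# Mixture site likelihoods through the C++ kernel, one call for all
# classes. classes: list of list(eigs = list of rev_eigen results,
# edge_eig = integer per-edge eig index (into that class's eigs),
# prob, root_freq, rate = branch-length multiplier).
mixture_loglik <- function(comp, prep, classes) {
  nstate <- nrow(classes[[1L]]$eigs[[1L]]$A)
  nclass <- length(classes)
  nedge <- nrow(prep$edges)
  # pool distinct eigensystems across classes (identity-based)
  pool <- list()
  pool_ids <- character(0)
  edge_eig <- matrix(0L, nedge, nclass)
  for (c in seq_len(nclass)) {
    local_idx <- integer(length(classes[[c]]$eigs))
    for (i in seq_along(classes[[c]]$eigs)) {
      e <- classes[[c]]$eigs[[i]]
      id <- if (!is.null(e$id)) e$id
      else paste0(c, "_", i, "_", format(e$lambda[1L], digits = 15))
      hit <- match(id, pool_ids)
      if (is.na(hit)) {
        pool[[length(pool) + 1L]] <- e
        pool_ids <- c(pool_ids, id)
        hit <- length(pool)
      }
      local_idx[i] <- hit
    }
    edge_eig[, c] <- local_idx[classes[[c]]$edge_eig]
  }
  A <- array(0, c(nstate, nstate, length(pool)))
  Ai <- array(0, c(nstate, nstate, length(pool)))
  lam <- matrix(0, nstate, length(pool))
  for (i in seq_along(pool)) {
    A[, , i] <- pool[[i]]$A
    Ai[, , i] <- pool[[i]]$Ainv
    lam[, i] <- pool[[i]]$lambda
  }
  rates <- vapply(classes, function(cl) {
    if (is.null(cl$rate)) 1 else cl$rate
  }, numeric(1))
  probs <- vapply(classes, `[[`, numeric(1), "prob")
  rootf <- vapply(classes, `[[`, numeric(nstate), "root_freq")
  lik <- mixture_site_liks_cpp(comp$states, prep$edges, prep$blens,
                               A, Ai, lam, edge_eig, rates, probs,
                               matrix(rootf, nstate, nclass),
                               prep$n_nodes, prep$root)
  if (any(lik <= 0)) return(-Inf)
  sum(comp$weights * log(lik))
}
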