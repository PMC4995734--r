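# Independent oracles and small fixtures shared across test files. These
# deliberately avoid the package's internal code paths: matrix exponentials
# use scaling-and-squaring, alignment scoring uses a hand-rolled Gotoh DP,
# UPGMA uses stats::hclust.

# matrix exponential by scaling and squaring (Taylor), independent of the
# package's eigendecomposition route
expm_oracle <- function(M, k = 20L, terms = 24L) {
  Ms <- M / 2^k
  S <- diag(nrow(M))
  P <- diag(nrow(M))
  for (i in seq_len(terms)) {
    P <- P %*% Ms / i
    S <- S + P
  }
  for (i in seq_len(k)) S <- S %*% S
  S
}

# random n-tip coalescent tree rescaled to a given height
rtree_scaled <- function(n, depth, seed, prefix = "t") {
  set.seed(seed)
  tr <- ape::rcoal(n, tip.label = paste0(prefix, seq_len(n)))
  tr$edge.length <- tr$edge.length /
    max(ape::node.depth.edgelength(tr)) * depth
  tr
}

# global affine-gap alignment score (Gotoh), positive penalties
gotoh_score <- function(a, b, sub, gap_open = 10, gap_ext = 0.5) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)   # match/mismatch state
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (consume a)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a (consume b)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) {
    X[i + 1L, 1L] <- -(gap_open + gap_ext * i)
  }
  for (j in seq_len(m)) {
    Y[1L, j + 1L] <- -(gap_open + gap_ext * j)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- sub[A[i], B[j]]
      M[i + 1L, j + 1L] <- sc + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_ext,
                               X[i, j + 1L] - gap_ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_ext,
                               Y[i + 1L, j] - gap_ext)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

random_protein <- function(n, seed) {
  set.seed(seed)
  aas <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

# UPGMA oracle through stats::hclust (average linkage, heights halved)
upgma_hclust_oracle <- function(d) {
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tr <- ape::as.phylo(hc)
  tr
}

# adjusted Rand index between two partitions given as membership vectors
ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- ai * bj / n2
  (nij - exp_idx) / ((ai + bj) / 2 - exp_idx)
}

# membership vector (gene -> family index) from mcl_cluster output
family_membership <- function(families) {
  members <- unlist(lapply(families, `[[`, "members"))
  fam <- rep(seq_along(families),
             vapply(families, function(f) length(f$members), integer(1)))
  stats::setNames(fam, members)
}

# independent dense MCL with attractor-based cluster readout, used as the
# reference implementation for the package's mcl_cluster
mcl_reference <- function(adj, inflation = 2, max_iter = 200, tol = 1e-6) {
  diag(adj) <- apply(adj, 2, max)
  M <- sweep(adj, 2, colSums(adj), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < 1e-12] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      break
    }
    M <- M2
  }
  attract <- which(diag(M) > 1e-8)
  memb <- rep(NA_integer_, nrow(M))
  cl <- 0L
  for (a in attract) {
    if (!is.na(memb[a])) next
    cl <- cl + 1L
    covered <- which(M[a, ] > 1e-8 | M[, a] > 1e-8)
    group <- unique(c(a, covered))
    ex <- stats::na.omit(unique(memb[group]))
    if (length(ex)) {
      memb[group] <- ex[1L]
      memb[memb %in% ex] <- ex[1L]
    } else {
      memb[group] <- cl
    }
  }
  memb[is.na(memb)] <- seq.int(cl + 1L, length.out = sum(is.na(memb)))
  memb
}

# two planted blocks of 10 nodes: within-block edge probability 0.9,
# between 0.05
random_modular_graph <- function(seed, n = 20L) {
  set.seed(seed)
  block <- rep(1:2, each = n %/% 2L)
  adj <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (block[i] == block[j]) 0.9 else 0.05
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1
    }
  }
  nm <- paste0("g", seq_len(n), "|v")
  gi <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            weighted = TRUE)
  gi <- igraph::set_vertex_attr(gi, "name", value = nm)
  list(graph = gi, adj = adj, names = nm, block = block)
}
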