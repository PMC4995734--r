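# Genetic-code bookkeeping shared by the codon models and the sequence
# simulator. Everything is computed once and cached.

.ps_cache <- new.env(parent = emptyenv())

#' Sense codons of the universal genetic code
#'
#' The 61 sense codons (universal code; stops TAA, TAG, TGA excluded), in
#' the fixed order used throughout the package for codon state indices.
#'
#' @return Character vector of 61 codons.
#' @export
sense_codons <- function() {
  codon_info()$codons
}

# Precompute codon list, encoded amino acids, and for every ordered pair of
# codons differing at exactly one position whether the change is a
# transition and whether it is synonymous.
codon_info <- function() {
  if (!is.null(.ps_cache$codon_info)) return(.ps_cache$codon_info)
  nts <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(nts, nts, paste0), nts,
                           function(ab, c) paste0(ab, c)))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[all64])
  keep <- aa != "*"
  codons <- all64[keep]
  aa <- aa[keep]
  n <- length(codons)
  stopifnot(n == 61L)

  cmat <- do.call(rbind, strsplit(codons, ""))
  is_transition_nt <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  ii <- integer(0); jj <- integer(0)
  ti <- logical(0); syn <- logical(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      diffs <- which(cmat[i, ] != cmat[j, ])
      if (length(diffs) != 1L) next
      ii <- c(ii, i); jj <- c(jj, j)
      ti <- c(ti, is_transition_nt(cmat[i, diffs], cmat[j, diffs]))
      syn <- c(syn, aa[i] == aa[j])
    }
  }
  info <- list(codons = codons, aa = aa, codon_chars = cmat,
               pair_i = ii, pair_j = jj,
               pair_transition = ti, pair_synonymous = syn)
  .ps_cache$codon_info <- info
  info
}

#' Goldman-Yang codon rate matrix
#'
#' Builds the 61x61 generator of a codon substitution process in which only
#' single-nucleotide changes have nonzero rate. The rate from codon i to
#' codon j is \eqn{\pi_j} multiplied by \eqn{\kappa} for transitions and by
#' \eqn{\omega} for nonsynonymous changes. The generator is scaled so the
#' expected substitution rate at equilibrium is 1, i.e. branch lengths are
#' expected substitutions per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param pi Equilibrium frequencies of the 61 sense codons (simplex),
#'   in `sense_codons()` order.
#' @param scale If `TRUE` (default) normalize to one expected substitution
#'   per unit branch length; set `FALSE` to share a scale across site
#'   classes (see [codon_site_loglik()]).
#' @return 61x61 generator matrix with rows summing to zero.
#' @export
codon_rate_matrix <- function(kappa, omega, pi, scale = TRUE) {
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.numeric(omega) || omega < 0) stop("omega must be >= 0")
  ci <- codon_info()
  if (length(pi) != 61L) stop("pi must have 61 entries")
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  Q <- matrix(0, 61L, 61L, dimnames = list(ci$codons, ci$codons))
  rate <- ifelse(ci$pair_transition, kappa, 1) *
    ifelse(ci$pair_synonymous, 1, omega)
  idx_ij <- cbind(ci$pair_i, ci$pair_j)
  idx_ji <- cbind(ci$pair_j, ci$pair_i)
  Q[idx_ij] <- rate * pi[ci$pair_j]
  Q[idx_ji] <- rate * pi[ci$pair_i]
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

# F3x4-style codon frequencies: product of position-specific nucleotide
# frequencies, renormalized over the 61 sense codons.
f3x4_frequencies <- function(codon_aln) {
  ci <- codon_info()
  m <- codon_matrix(codon_aln)
  cods <- m[m != "---" & !is.na(m)]
  cods <- cods[grepl("^[ACGT]{3}$", cods)]
  if (!length(cods)) return(uniform_codon_frequencies())
  chars <- do.call(rbind, strsplit(cods, ""))
  nts <- c("T", "C", "A", "G")
  pos_freq <- lapply(1:3, function(p) {
    f <- table(factor(chars[, p], levels = nts))
    f <- as.numeric(f) + 0.5  # light regularization against zero counts
    f / sum(f)
  })
  pf <- vapply(seq_len(61L), function(k) {
    prod(vapply(1:3, function(p) {
      pos_freq[[p]][match(ci$codon_chars[k, p], nts)]
    }, numeric(1)))
  }, numeric(1))
  pf / sum(pf)
}

uniform_codon_frequencies <- function() {
  rep(1 / 61, 61L)
}

# Observed codon frequencies, regularized.
empirical_codon_frequencies <- function(codon_aln) {
  ci <- codon_info()
  m <- codon_matrix(codon_aln)
  f <- table(factor(m[m != "---" & !is.na(m)], levels = ci$codons))
  f <- as.numeric(f) + 0.5
  f / sum(f)
}

codon_frequencies <- function(codon_aln,
                              freq_model = c("F3x4", "uniform", "empirical")) {
  switch(match.arg(freq_model),
         F3x4 = f3x4_frequencies(codon_aln),
         uniform = uniform_codon_frequencies(),
         empirical = empirical_codon_frequencies(codon_aln))
}
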