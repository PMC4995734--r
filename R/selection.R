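# Codon-model positive-selection machinery: site-class mixture likelihoods
# (M1a, M2a), the branch-site model A and its null, likelihood-ratio tests,
# and the per-gene scan over single-copy core families.

# integer codon states (taxa x codon sites); whole-codon gaps and
# ambiguous codons -> NA (missing); internal stop codons are an error
codon_state_matrix <- function(aln) {
  ci <- codon_info()
  m <- codon_matrix(aln)
  s <- matrix(match(m, ci$codons), nrow = nrow(m),
              dimnames = list(rownames(m), NULL))
  stops <- c("TAA", "TAG", "TGA")
  bad <- which(matrix(m %in% stops, nrow = nrow(m)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("stop codon in sequence '%s' at codon %d",
                 rownames(m)[bad[1L, 1L]], bad[1L, 2L]))
  }
  storage.mode(s) <- "integer"
  s
}

# Re-root `tree` so the foreground tips can form a proper clade: on an
# unrooted tree (or one rooted inside the foreground) the MRCA of the
# foreground tips can span every edge, which would make the "foreground"
# the whole tree. Likelihoods are rooting-invariant under reversible
# models, so re-rooting at a background tip is safe.
ensure_foreground_clade <- function(tree, foreground) {
  prep <- tree_prep(tree)
  bg <- setdiff(prep$labels, foreground)
  if (!length(bg)) stop("foreground cannot be the whole tree")
  mask <- tryCatch(suppressWarnings(
    foreground_edge_mask(NULL, prep, foreground, "clade")),
    error = function(e) NULL)
  if (!is.null(mask) && !all(mask)) return(tree)
  tr <- ape::root(ape::unroot(tree), outgroup = bg[1L],
                  resolve.root = TRUE)
  if (is.null(tr$edge.length)) tr$edge.length <- tree$edge.length
  tr$edge.length[is.na(tr$edge.length)] <- 0
  tr
}

# tips of the MRCA clade spanned by `foreground` on `tree`, warning once
# when the given tips are not themselves monophyletic
effective_foreground <- function(tree, foreground, scope = "clade") {
  prep <- tree_prep(tree)
  mask <- foreground_edge_mask(NULL, prep, foreground, scope = "clade")
  in_clade <- rep(FALSE, prep$n_nodes)
  in_clade[prep$edges[mask, 2L]] <- TRUE
  tips <- prep$labels[which(in_clade[seq_len(prep$ntip)])]
  if (!length(tips)) foreground else tips
}

# edge rows of the postorder edge matrix belonging to the foreground
foreground_edge_mask <- function(tree, prep, foreground,
                                 scope = c("clade", "stem")) {
  scope <- match.arg(scope)
  if (is.null(foreground) || !length(foreground)) {
    stop("a foreground branch (tip set) is required")
  }
  if (!all(foreground %in% prep$labels)) {
    stop("foreground tips not in tree: ",
         paste(setdiff(foreground, prep$labels), collapse = ", "))
  }
  tips <- match(foreground, prep$labels)
  if (length(tips) == length(prep$labels)) {
    stop("foreground cannot be the whole tree")
  }
  if (length(tips) == 1L) {
    node <- tips
  } else {
    node <- ape::getMRCA(structure(list(edge = prep$edges,
                                        tip.label = prep$labels,
                                        Nnode = prep$n_nodes - prep$ntip),
                                   class = "phylo"), tips)
  }
  # descendants of `node` (post-order edges: child precedes parent row)
  in_clade <- rep(FALSE, prep$n_nodes)
  in_clade[node] <- TRUE
  for (e in rev(seq_len(nrow(prep$edges)))) {
    if (in_clade[prep$edges[e, 1L]]) in_clade[prep$edges[e, 2L]] <- TRUE
  }
  clade_tips <- which(in_clade[seq_len(prep$ntip)])
  if (!setequal(clade_tips, tips)) {
    warning("foreground tips are not monophyletic; using their MRCA clade")
  }
  if (scope == "stem") {
    prep$edges[, 2L] == node
  } else {
    in_clade[prep$edges[, 2L]]
  }
}

# Build per-class generators under a common scale. classes is a data.frame
# with prop, omega_bg, omega_fg; the common scale is the background-mixture
# expected rate, so branch lengths are expected substitutions per codon on
# background branches.
codon_class_matrices <- function(kappa, pi, classes) {
  Qb <- lapply(classes$omega_bg,
               function(w) codon_rate_matrix(kappa, w, pi, scale = FALSE))
  mu <- sum(vapply(seq_along(classes$prop), function(k) {
    -classes$prop[k] * sum(pi * diag(Qb[[k]]))
  }, numeric(1)))
  Qf <- lapply(classes$omega_fg,
               function(w) codon_rate_matrix(kappa, w, pi, scale = FALSE))
  list(bg = lapply(Qb, function(Q) Q / mu),
       fg = lapply(Qf, function(Q) Q / mu))
}

# Memoized eigensystem of the UNSCALED generator: eigenvectors do not
# change under the mixture rescaling, only lambda does, so one (kappa,
# omega) pair is decomposed once per fit however the class proportions
# move during optimization.
codon_eig_unscaled <- function(kappa, omega, pi, cache = NULL) {
  key <- sprintf("%.15g_%.15g", kappa, omega)
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  Q <- codon_rate_matrix(kappa, omega, pi, scale = FALSE)
  e <- rev_eigen(Q, pi)
  e$rate <- -sum(pi * diag(Q))
  e$id <- key
  if (!is.null(cache)) cache[[key]] <- e
  e
}

#' Codon site-class mixture log-likelihood
#'
#' Likelihood of a codon alignment under a mixture of dN/dS site classes
#' (Felsenstein pruning per class, mixed by class proportions). For the
#' branch-site model, classes carry separate background and foreground
#' omegas and `foreground` marks the foreground branches.
#'
#' @param aln Codon alignment (named character vector, whole-codon gaps).
#' @param tree `phylo` tree with branch lengths in expected substitutions
#'   per codon.
#' @param params List: `kappa`, `pi` (61 codon frequencies), `classes`
#'   (data.frame with `prop` and either `omega` or `omega_bg`/`omega_fg`).
#' @param foreground Character vector of tip labels defining the foreground
#'   clade (branch-site models only).
#' @param scope `"clade"` (stem plus all internal branches; default) or
#'   `"stem"`.
#' @return Log-likelihood.
#' @export
codon_site_loglik <- function(aln, tree, params, foreground = NULL,
                              scope = "clade") {
  prep <- tree_prep(tree)
  if (!setequal(names(aln), prep$labels)) {
    stop("alignment labels do not match tree tips")
  }
  s <- codon_state_matrix(aln)[prep$labels, , drop = FALSE]
  comp <- compress_patterns(s)
  codon_loglik_compressed(comp, prep, params, foreground, scope)
}

codon_loglik_compressed <- function(comp, prep, params, foreground = NULL,
                                    scope = "clade", fg_mask = NULL,
                                    eig_cache = NULL) {
  classes <- params$classes
  if (is.null(classes$omega_bg)) {
    classes$omega_bg <- classes$omega
    classes$omega_fg <- classes$omega
  }
  has_fg <- any(classes$omega_fg != classes$omega_bg)
  if (is.null(fg_mask)) {
    fg_mask <- if (!is.null(foreground)) {
      foreground_edge_mask(prep = prep, tree = NULL,
                           foreground = foreground, scope = scope)
    } else if (has_fg) {
      stop("branch-site classes given but no foreground branch marked")
    } else rep(FALSE, nrow(prep$edges))
  }
  eb <- lapply(classes$omega_bg, function(w) {
    codon_eig_unscaled(params$kappa, w, params$pi, eig_cache)
  })
  mu <- sum(classes$prop * vapply(eb, `[[`, numeric(1), "rate"))
  scale_eig <- function(e) list(A = e$A, Ainv = e$Ainv,
                                lambda = e$lambda / mu, id = e$id)
  cls <- lapply(seq_along(classes$prop), function(k) {
    if (any(fg_mask) && classes$omega_fg[k] != classes$omega_bg[k]) {
      ef <- codon_eig_unscaled(params$kappa, classes$omega_fg[k],
                               params$pi, eig_cache)
      list(eigs = list(scale_eig(eb[[k]]), scale_eig(ef)),
           edge_eig = ifelse(fg_mask, 2L, 1L),
           prob = classes$prop[k], root_freq = params$pi)
    } else {
      list(eigs = list(scale_eig(eb[[k]])),
           edge_eig = rep(1L, length(fg_mask)),
           prob = classes$prop[k], root_freq = params$pi)
    }
  })
  mixture_loglik(comp, prep, cls)
}

# ---- model fitting ---------------------------------------------------------

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# generic multi-start L-BFGS-B wrapper on a negative log-likelihood
ml_fit <- function(negll, starts, lower, upper, control = list()) {
  ctl <- utils::modifyList(list(maxit = 300L, factr = 1e9), control)
  best <- NULL
  for (par0 in starts) {
    fit <- tryCatch(
      stats::optim(par0, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = ctl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(list(par = starts[[1L]], value = negll(starts[[1L]]),
                convergence = 99L))
  }
  best
}

random_starts <- function(base, n_extra, lower, upper, seed) {
  set.seed(seed)
  out <- list(base)
  for (i in seq_len(n_extra)) {
    out[[i + 1L]] <- pmin(pmax(base + stats::rnorm(length(base), 0, 0.75),
                               lower + 1e-3), upper - 1e-3)
  }
  out
}

#' Fit the one-ratio (M0) codon model
#'
#' Single dN/dS ratio shared by all sites and branches; used to estimate
#' branch lengths once, which are then held fixed across the site-model and
#' branch-site fits.
#'
#' @inheritParams codon_site_loglik
#' @param pi Codon frequencies; computed from the alignment if `NULL`.
#' @param optimize_blens `"all"` (every branch length), `"scale"` (one
#'   multiplier of the input lengths) or `"none"`.
#' @return List: `kappa`, `omega`, `tree` (fitted lengths), `loglik`.
#' @export
fit_m0 <- function(aln, tree, pi = NULL,
                   optimize_blens = c("all", "scale", "none")) {
  optimize_blens <- match.arg(optimize_blens)
  prep <- tree_prep(tree)
  s <- codon_state_matrix(aln)[prep$labels, , drop = FALSE]
  comp <- compress_patterns(s)
  if (is.null(pi)) pi <- f3x4_frequencies(aln)

  cache <- new.env(parent = emptyenv())
  nb <- if (optimize_blens == "all") length(prep$blens)
  else if (optimize_blens == "scale") 1L else 0L
  base_bl <- pmax(prep$blens, 1e-6)
  par0 <- c(log(2), log(0.5),
            if (optimize_blens == "all") log(base_bl)
            else if (optimize_blens == "scale") 0)
  lower <- c(log(0.05), log(1e-4), rep(log(1e-8), nb))
  upper <- c(log(50), log(20), rep(log(20), nb))
  negll <- function(par) {
    pr <- prep
    if (optimize_blens == "all") pr$blens <- exp(par[2L + seq_len(nb)])
    if (optimize_blens == "scale") pr$blens <- base_bl * exp(par[3L])
    ll <- codon_loglik_compressed(
      comp, pr, list(kappa = exp(par[1L]), pi = pi,
                     classes = list(prop = 1, omega = exp(par[2L]))),
      eig_cache = cache)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  fit <- ml_fit(negll, list(par0), lower, upper)
  out_tree <- tree_from_prep(prep, switch(optimize_blens,
    all = exp(fit$par[2L + seq_len(nb)]),
    scale = base_bl * exp(fit$par[3L]),
    none = prep$blens))
  list(kappa = exp(fit$par[1L]), omega = exp(fit$par[2L]),
       tree = out_tree, loglik = -fit$value, pi = pi,
       convergence = fit$convergence)
}

tree_from_prep <- function(prep, blens) {
  structure(list(edge = prep$edges, edge.length = blens,
                 tip.label = prep$labels,
                 Nnode = prep$n_nodes - prep$ntip),
            class = "phylo")
}

#' Fit the site models M1a and M2a
#'
#' M1a ("nearly neutral") has two site classes with omega_0 in (0,1) and
#' omega_1 = 1; M2a ("positive selection") adds a third class with
#' omega_2 >= 1. Proportions are fitted on a softmax transform, omega_0 on
#' a logit transform and omega_2 as 1 + exp(u), so all constraints hold by
#' construction. Multi-start optimization guards against local optima.
#'
#' @inheritParams codon_site_loglik
#' @param freq_model Codon frequency model: `"F3x4"` (default),
#'   `"uniform"` or `"empirical"`.
#' @param branch_lengths `"m0"` (estimate once under M0, then fix;
#'   default), `"scale"` (M0 rescaling of the input lengths) or `"fixed"`.
#' @param n_starts Number of optimizer starts per model (default 3).
#' @param seed Seed for the randomized extra starts.
#' @param fix_kappa If `TRUE`, the transition/transversion ratio is held
#'   at its M0 estimate instead of being re-estimated per model; a common
#'   large-scan shortcut (kappa estimates barely differ between the
#'   nested models) that substantially reduces runtime.
#' @param control Optimizer control passed to [stats::optim()].
#' @param m0_fit Optional precomputed [fit_m0()] result to reuse; its
#'   fitted tree is used as-is and `branch_lengths` is ignored.
#' @return List with elements `m1a`, `m2a` (each: `params`, `loglik`,
#'   `convergence`), plus `tree`, `pi`, `m0`.
#' @export
fit_site_models <- function(aln, tree, freq_model = "F3x4",
                            branch_lengths = c("m0", "scale", "fixed"),
                            n_starts = 3L, seed = 1L, fix_kappa = FALSE,
                            control = list(), m0_fit = NULL) {
  branch_lengths <- match.arg(branch_lengths)
  pi <- codon_frequencies(aln, freq_model)
  m0 <- if (!is.null(m0_fit)) m0_fit else switch(branch_lengths,
    m0 = fit_m0(aln, tree, pi, optimize_blens = "all"),
    scale = fit_m0(aln, tree, pi, optimize_blens = "scale"),
    fixed = fit_m0(aln, tree, pi, optimize_blens = "none"))
  wtree <- m0$tree
  prep <- tree_prep(wtree)
  s <- codon_state_matrix(aln)[prep$labels, , drop = FALSE]
  comp <- compress_patterns(s)
  cache <- new.env(parent = emptyenv())
  lk0 <- log(max(m0$kappa, 0.1))
  kfun <- function(par, nk) if (fix_kappa) m0$kappa else exp(par[nk])

  # M1a: par = (logit p0, logit omega0[, log kappa])
  m1a_negll <- function(par) {
    p0 <- stats::plogis(par[1L])
    w0 <- stats::plogis(par[2L])
    ll <- codon_loglik_compressed(
      comp, prep, list(kappa = kfun(par, 3L), pi = pi,
                       classes = list(prop = c(p0, 1 - p0),
                                      omega = c(w0, 1))),
      eig_cache = cache)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  base1 <- c(stats::qlogis(0.7),
             stats::qlogis(min(max(m0$omega, 0.01), 0.9)),
             if (!fix_kappa) lk0)
  lo1 <- c(-12, -12, if (!fix_kappa) log(0.05))
  up1 <- c(12, 8, if (!fix_kappa) log(50))
  f1 <- ml_fit(m1a_negll, random_starts(base1, n_starts - 1L, lo1, up1,
                                        seed), lo1, up1, control)
  p0 <- stats::plogis(f1$par[1L]); w0 <- stats::plogis(f1$par[2L])
  kap1 <- kfun(f1$par, 3L)
  m1a <- list(params = list(kappa = kap1, pi = pi,
                            classes = data.frame(prop = c(p0, 1 - p0),
                                                 omega = c(w0, 1)),
                            model_tag = "M1a"),
              loglik = -f1$value, convergence = f1$convergence)

  # M2a: par = (a0, a2, logit omega0, log(omega2 - 1)[, log kappa])
  m2a_negll <- function(par) {
    p <- softmax(c(par[1L], 0, par[2L]))
    w0 <- stats::plogis(par[3L])
    w2 <- 1 + exp(par[4L])
    ll <- codon_loglik_compressed(
      comp, prep, list(kappa = kfun(par, 5L), pi = pi,
                       classes = list(prop = p,
                                      omega = c(w0, 1, w2))),
      eig_cache = cache)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  pr1 <- m1a$params$classes$prop
  base2 <- c(log(max(pr1[1L], 0.02) / max(pr1[2L], 0.02)),
             log(0.08 / max(pr1[2L], 0.02)),
             f1$par[2L], log(2 - 1),
             if (!fix_kappa) log(kap1))
  lo2 <- c(-12, -12, -12, -12, if (!fix_kappa) log(0.05))
  up2 <- c(12, 12, 8, 6, if (!fix_kappa) log(50))
  f2 <- ml_fit(m2a_negll, random_starts(base2, n_starts - 1L, lo2, up2,
                                        seed + 1L), lo2, up2, control)
  pack_m2a <- function(f) {
    p2 <- softmax(c(f$par[1L], 0, f$par[2L]))
    list(params = list(kappa = kfun(f$par, 5L), pi = pi,
                       classes = data.frame(
                         prop = p2,
                         omega = c(stats::plogis(f$par[3L]), 1,
                                   1 + exp(f$par[4L]))),
                       model_tag = "M2a"),
         loglik = -f$value, convergence = f$convergence)
  }
  m2a <- pack_m2a(f2)
  # nesting guard: M2a contains M1a (omega2 -> 1 or p2 -> 0)
  if (m2a$loglik < m1a$loglik - 1e-6) {
    refit <- ml_fit(m2a_negll,
                    list(c(f1$par[1L], -11.5, f1$par[2L], -11.5,
                           if (!fix_kappa) log(kap1))),
                    lo2, up2, control)
    if (-refit$value > m2a$loglik) m2a <- pack_m2a(refit)
    if (m2a$loglik < m1a$loglik) {
      # M2a contains M1a, so its optimum cannot lie below: report the
      # boundary point (p2 -> 0, omega2 -> 1) reached in the limit
      bd <- list(par = c(f1$par[1L], -12, f1$par[2L], -12,
                         if (!fix_kappa) log(kap1)),
                 value = f1$value, convergence = 0L)
      m2a <- pack_m2a(bd)
    }
  }
  list(m1a = m1a, m2a = m2a, tree = wtree, pi = pi, m0 = m0)
}

#' Likelihood-ratio test between nested codon models
#'
#' Statistic is twice the log-likelihood difference, compared with the
#' chi-square upper tail; tiny negative statistics (optimizer noise at the
#' boundary) are clamped to zero.
#'
#' @param fit Output of [fit_site_models()] (df = 2) or
#'   [fit_branch_site()] (df = 1).
#' @return List: `ll_null`, `ll_alt`, `statistic`, `df`, `p_value`.
#' @export
site_lrt <- function(fit) {
  lrt_result(fit$m1a$loglik, fit$m2a$loglik, df = 2L)
}

#' @rdname site_lrt
#' @export
branch_site_lrt <- function(fit) {
  lrt_result(fit$null$loglik, fit$alt$loglik, df = 1L)
}

lrt_result <- function(ll_null, ll_alt, df) {
  stat <- 2 * (ll_alt - ll_null)
  if (stat < -1e-4) {
    warning(sprintf("LRT statistic %.4g < 0: optimizer failure, refit advised",
                    stat))
  }
  stat <- max(stat, 0)
  list(ll_null = ll_null, ll_alt = ll_alt, statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Fit the branch-site model A and its null
#'
#' Model A has four site classes: 0 (omega_0 everywhere), 1 (neutral
#' everywhere), 2a (omega_0 on background, omega_2 on the foreground) and
#' 2b (neutral on background, omega_2 on the foreground), with
#' proportions (p0, p1, p2a, p2b) = (f0*pt, (1-f0)*pt, f0*(1-pt),
#' (1-f0)*(1-pt)) reparameterized for the optimizer. The null model fixes
#' omega_2 = 1.
#'
#' @inheritParams fit_site_models
#' @param foreground Tip labels defining the foreground branch/clade.
#' @param scope `"clade"` (default) or `"stem"`.
#' @return List with `null` and `alt` fits (each: `params`, `loglik`,
#'   `convergence`), plus `tree`, `pi`, `foreground`, `scope`.
#' @export
fit_branch_site <- function(aln, tree, foreground, scope = "clade",
                            freq_model = "F3x4",
                            branch_lengths = c("m0", "scale", "fixed"),
                            n_starts = 3L, seed = 1L, fix_kappa = FALSE,
                            control = list(), m0_fit = NULL) {
  branch_lengths <- match.arg(branch_lengths)
  if (is.null(foreground) || !length(foreground)) {
    stop("fit_branch_site requires a foreground branch (tip set)")
  }
  tree <- ensure_foreground_clade(tree, foreground)
  pi <- codon_frequencies(aln, freq_model)
  m0 <- if (!is.null(m0_fit)) m0_fit else switch(branch_lengths,
    m0 = fit_m0(aln, tree, pi, optimize_blens = "all"),
    scale = fit_m0(aln, tree, pi, optimize_blens = "scale"),
    fixed = fit_m0(aln, tree, pi, optimize_blens = "none"))
  wtree <- m0$tree
  prep <- tree_prep(wtree)
  s <- codon_state_matrix(aln)[prep$labels, , drop = FALSE]
  comp <- compress_patterns(s)
  cache <- new.env(parent = emptyenv())
  fg_mask <- foreground_edge_mask(NULL, prep, foreground, scope = scope)

  bs_classes <- function(pt, f0, w0, w2) {
    list(prop = c(f0 * pt, (1 - f0) * pt,
                  f0 * (1 - pt), (1 - f0) * (1 - pt)),
         omega_bg = c(w0, 1, w0, 1),
         omega_fg = c(w0, 1, w2, w2))
  }
  lk0 <- log(max(m0$kappa, 0.1))
  # par layout: (logit pt, logit f0, logit w0[, log(w2 - 1)][, log kappa])
  make_negll <- function(alt) {
    nk <- if (alt) 5L else 4L
    function(par) {
      pt <- stats::plogis(par[1L]); f0 <- stats::plogis(par[2L])
      w0 <- stats::plogis(par[3L])
      w2 <- if (alt) 1 + exp(par[4L]) else 1
      kap <- if (fix_kappa) m0$kappa else exp(par[nk])
      ll <- codon_loglik_compressed(
        comp, prep,
        list(kappa = kap, pi = pi,
             classes = bs_classes(pt, f0, w0, w2)),
        fg_mask = fg_mask, eig_cache = cache)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  }
  base_n <- c(stats::qlogis(0.85), stats::qlogis(0.7),
              stats::qlogis(min(max(m0$omega, 0.01), 0.9)),
              if (!fix_kappa) lk0)
  lo_n <- c(-12, -12, -12, if (!fix_kappa) log(0.05))
  up_n <- c(12, 12, 8, if (!fix_kappa) log(50))
  fn <- ml_fit(make_negll(FALSE), random_starts(base_n, n_starts - 1L,
                                                lo_n, up_n, seed),
               lo_n, up_n, control)
  base_a <- c(fn$par[1:3], log(2 - 1), if (!fix_kappa) fn$par[4L])
  lo_a <- c(-12, -12, -12, -12, if (!fix_kappa) log(0.05))
  up_a <- c(12, 12, 8, 6, if (!fix_kappa) log(50))
  fa <- ml_fit(make_negll(TRUE), random_starts(base_a, n_starts - 1L, lo_a,
                                               up_a, seed + 1L),
               lo_a, up_a, control)
  if (-fa$value < -fn$value - 1e-6) {
    # alt contains null at omega2 = 1: restart from the null optimum
    refit <- ml_fit(make_negll(TRUE),
                    list(c(fn$par[1:3], -11.5, if (!fix_kappa) fn$par[4L])),
                    lo_a, up_a, control)
    if (refit$value < fa$value) fa <- refit
    if (-fa$value < -fn$value) {
      # the alternative contains the null (omega2 = 1): report the
      # boundary point instead of an optimizer undershoot
      fa <- list(par = c(fn$par[1:3], -12, if (!fix_kappa) fn$par[4L]),
                 value = fn$value, convergence = 0L)
    }
  }
  pack <- function(f, alt, tag) {
    pt <- stats::plogis(f$par[1L]); f0 <- stats::plogis(f$par[2L])
    w2 <- if (alt) 1 + exp(f$par[4L]) else 1
    nk <- if (alt) 5L else 4L
    kap <- if (fix_kappa) m0$kappa else exp(f$par[nk])
    cl <- bs_classes(pt, f0, stats::plogis(f$par[3L]), w2)
    list(params = list(kappa = kap, pi = pi,
                       classes = as.data.frame(cl),
                       model_tag = tag),
         loglik = -f$value, convergence = f$convergence)
  }
  list(null = pack(fn, FALSE, "branch_site_null"),
       alt = pack(fa, TRUE, "branch_site_alt"),
       tree = wtree, pi = pi, foreground = foreground, scope = scope,
       m0 = m0)
}

#' Scan single-copy core genes for positive selection
#'
#' Runs the M2a-vs-M1a site test and the branch-site test on every
#' single-copy core family and summarizes counts: genes under selection in
#' the whole species, on the foreground branch, and the branch-only /
#' shared split.
#'
#' @param alignments Named list of codon alignments, one per family, with
#'   sequence names equal to genome ids (tree tip labels).
#' @param tree Species tree (`phylo`) used for all genes.
#' @param foreground Tip labels of the foreground clade.
#' @param alpha Significance level for the selected flags (default 0.05).
#' @param p_adjust `"none"` (default; raw LRT p-values) or `"BH"`.
#' @param branch_lengths Passed to the fitters; `"scale"` (default here)
#'   rescales the shared species-tree lengths per gene under M0.
#' @param n_starts,seed,freq_model,scope Passed to the fitters.
#' @param fix_kappa Hold kappa at each gene's M0 estimate across the four
#'   model fits (default `TRUE` for the scan; see [fit_site_models()]).
#' @param control Optimizer control for the per-gene fits.
#' @return List: `table` (one row per family) and `summary` (counts,
#'   percentages, branch-only/shared split).
#' @export
scan_core_genes <- function(alignments, tree, foreground, alpha = 0.05,
                            p_adjust = c("none", "BH"),
                            freq_model = "F3x4", branch_lengths = "scale",
                            scope = "clade", n_starts = 3L, seed = 1L,
                            fix_kappa = TRUE,
                            control = list(factr = 1e10)) {
  p_adjust <- match.arg(p_adjust)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0,1]")
  # resolve the foreground to a monophyletic clade once, so per-gene fits
  # do not each re-warn when the tips are not monophyletic on this tree
  tree <- ensure_foreground_clade(tree, foreground)
  foreground <- effective_foreground(tree, foreground, scope)
  rows <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    fam <- names(alignments)[i]
    aln <- alignments[[i]]
    if (anyDuplicated(names(aln)) || !setequal(names(aln), tree$tip.label)) {
      rows[[i]] <- data.frame(family_id = fam, n_codons = NA_integer_,
                              ll_m1a = NA_real_, ll_m2a = NA_real_,
                              lrt_site = NA_real_, p_site = NA_real_,
                              ll_bs_null = NA_real_, ll_bs_alt = NA_real_,
                              lrt_branch = NA_real_, p_branch = NA_real_,
                              status = "skipped: not single-copy core")
      next
    }
    res <- tryCatch({
      sf <- fit_site_models(aln, tree, freq_model = freq_model,
                            branch_lengths = branch_lengths,
                            n_starts = n_starts, seed = seed + i,
                            fix_kappa = fix_kappa, control = control)
      bf <- fit_branch_site(aln, sf$m0$tree, foreground, scope = scope,
                            freq_model = freq_model,
                            branch_lengths = "fixed",
                            n_starts = n_starts, seed = seed + i,
                            fix_kappa = fix_kappa, control = control,
                            m0_fit = sf$m0)
      sl <- site_lrt(sf)
      bl <- branch_site_lrt(bf)
      conv_ok <- sf$m1a$convergence == 0L && sf$m2a$convergence == 0L &&
        bf$null$convergence == 0L && bf$alt$convergence == 0L
      data.frame(family_id = fam, n_codons = nchar(aln[[1L]]) %/% 3L,
                 ll_m1a = sf$m1a$loglik, ll_m2a = sf$m2a$loglik,
                 lrt_site = sl$statistic, p_site = sl$p_value,
                 ll_bs_null = bf$null$loglik, ll_bs_alt = bf$alt$loglik,
                 lrt_branch = bl$statistic, p_branch = bl$p_value,
                 status = if (conv_ok) "ok" else "non-converged")
    }, error = function(e) {
      data.frame(family_id = fam, n_codons = NA_integer_,
                 ll_m1a = NA_real_, ll_m2a = NA_real_,
                 lrt_site = NA_real_, p_site = NA_real_,
                 ll_bs_null = NA_real_, ll_bs_alt = NA_real_,
                 lrt_branch = NA_real_, p_branch = NA_real_,
                 status = paste0("failed: ", conditionMessage(e)))
    })
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    tab$p_site_adj <- stats::p.adjust(tab$p_site, method = "BH")
    tab$p_branch_adj <- stats::p.adjust(tab$p_branch, method = "BH")
    ps <- tab$p_site_adj; pb <- tab$p_branch_adj
  } else {
    ps <- tab$p_site; pb <- tab$p_branch
  }
  tab$site_selected <- !is.na(ps) & ps < alpha
  tab$branch_selected <- !is.na(pb) & pb < alpha
  n_tested <- sum(!is.na(tab$p_site))
  n_site <- sum(tab$site_selected)
  n_branch <- sum(tab$branch_selected)
  shared <- sum(tab$site_selected & tab$branch_selected)
  summary <- list(
    n_tested = n_tested,
    n_site_selected = n_site,
    pct_site_selected = if (n_tested) 100 * n_site / n_tested else NA_real_,
    n_branch_selected = n_branch,
    pct_branch_selected = if (n_tested) 100 * n_branch / n_tested
    else NA_real_,
    n_branch_only = n_branch - shared,
    n_shared = shared)
  list(table = tab, summary = summary)
}
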