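# Pan-genome construction: filtered all-against-all protein similarity,
# Markov clustering (MCL) into ortholog families, and partition of the
# families into core / distributed / unique genes.

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Clustering configuration
#'
#' Thresholds for the similarity graph and MCL parameters. Defaults follow
#' common orthoMCL-style practice: proteins longer than 50 residues,
#' identity and coverage at least 70 percent, inflation 2.
#'
#' @param min_protein_len Minimum length in residues, exclusive (default
#'   50: proteins must be longer than this).
#' @param min_identity,min_coverage Percent thresholds in [0, 100].
#' @param inflation MCL inflation (> 1, default 2).
#' @param mcl_max_iter,mcl_convergence_tol MCL stopping rule.
#' @return A list of class `clustering_config`.
#' @export
clustering_config <- function(min_protein_len = 50L, min_identity = 70,
                              min_coverage = 70, inflation = 2,
                              mcl_max_iter = 200L,
                              mcl_convergence_tol = 1e-6) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (min_identity < 0 || min_identity > 100 ||
      min_coverage < 0 || min_coverage > 100) {
    stop("identity/coverage thresholds must be within [0, 100]")
  }
  structure(list(min_protein_len = min_protein_len,
                 min_identity = min_identity, min_coverage = min_coverage,
                 inflation = inflation, mcl_max_iter = mcl_max_iter,
                 mcl_convergence_tol = mcl_convergence_tol),
            class = "clustering_config")
}

#' Proteome container
#'
#' Per-genome protein and CDS sequences with matching gene ids.
#'
#' @param genome_id Genome label.
#' @param proteins Named character vector of amino-acid sequences.
#' @param cds Optional named character vector of nucleotide sequences with
#'   the same names; each CDS must translate to its protein.
#' @return A list of class `proteome`.
#' @export
proteome <- function(genome_id, proteins, cds = NULL) {
  if (anyDuplicated(names(proteins))) {
    stop("duplicate gene ids in genome ", genome_id)
  }
  if (!is.null(cds)) {
    if (!setequal(names(cds), names(proteins))) {
      stop("cds and protein gene ids differ in genome ", genome_id)
    }
    for (g in names(cds)) {
      tr <- translate_cds(cds[[g]], id = g)
      if (tr != toupper(proteins[[g]])) {
        stop(sprintf("CDS of gene '%s' does not translate to its protein",
                     g))
      }
    }
  }
  structure(list(genome_id = genome_id, proteins = proteins, cds = cds),
            class = "proteome")
}

check_protein_sequence <- function(x, who = "sequence") {
  if (!nchar(x)) stop(who, " is empty")
  chars <- unique(strsplit(toupper(x), "")[[1L]])
  bad <- setdiff(chars, c(AA_ALPHABET20, "X"))
  if (length(bad)) {
    stop(sprintf("illegal character '%s' in %s", bad[1L], who))
  }
  invisible(TRUE)
}

#' Pairwise protein similarity
#'
#' Global (Needleman-Wunsch) alignment with affine gaps and BLOSUM62
#' scores. Identity is the percentage of identical aligned residue pairs
#' over aligned columns excluding dual gaps; coverage is the smaller of the
#' two per-sequence aligned fractions (columns where both rows hold a
#' residue, divided by each sequence length).
#'
#' @param a,b Amino-acid sequences (20-letter alphabet plus X).
#' @param gap_opening,gap_extension Affine gap penalties (positive).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @return List: `identity`, `coverage` (percent), `score`.
#' @export
pairwise_similarity <- function(a, b, gap_opening = 10, gap_extension = 0.5,
                                matrix = "BLOSUM62") {
  check_protein_sequence(a, "sequence a")
  check_protein_sequence(b, "sequence b")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  cols <- !(pa == "-" & sa == "-")
  aligned_both <- sum(pa != "-" & sa != "-")
  ident <- 100 * sum(pa == sa & pa != "-") / sum(cols)
  cov <- 100 * min(aligned_both / nchar(a), aligned_both / nchar(b))
  list(identity = ident, coverage = cov, score = Biostrings::score(al))
}

# 5-mer prescreen: candidate pairs must share at least one 5-mer, a
# conservative filter at the 70 percent identity/coverage thresholds
kmer_candidate_pairs <- function(seqs, k = 5L) {
  n <- length(seqs)
  kms <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, seq_len(nchar(s) - k + 1L),
                     seq_len(nchar(s) - k + 1L) + k - 1L))
  })
  idx <- rep(seq_along(seqs), lengths(kms))
  km <- unlist(kms, use.names = FALSE)
  sp <- split(idx, km)
  sp <- sp[lengths(sp) > 1L]
  codes <- unique(unlist(lapply(sp, function(v) {
    v <- sort(unique(v))
    if (length(v) < 2L) return(numeric(0))
    cb <- utils::combn(v, 2L)
    (cb[1L, ] - 1) * n + cb[2L, ]
  }), use.names = FALSE))
  if (!length(codes)) return(matrix(integer(0), 0L, 2L))
  cbind((codes - 1) %/% n + 1, (codes - 1) %% n + 1)
}

#' Build the filtered similarity graph
#'
#' All-against-all pairwise similarity over proteins longer than the length
#' threshold (including within-genome pairs, so paralogs cluster too); an
#' edge is kept iff identity and coverage both reach their thresholds.
#' A shared-5-mer prescreen skips pairs that cannot reach 70 percent
#' identity; pass `similarity` to ingest a precomputed table instead.
#'
#' @param proteomes List of [proteome()] objects (>= 2).
#' @param config A [clustering_config()].
#' @param similarity Optional precomputed data.frame with columns
#'   `gene_a`, `gene_b`, `identity`, `coverage`, `score` (qualified
#'   `genome|gene` ids), e.g. from [read_similarity_tsv()].
#' @return An igraph weighted undirected graph over qualified gene ids.
#' @export
build_similarity_graph <- function(proteomes, config = clustering_config(),
                                   similarity = NULL) {
  if (length(proteomes) < 2L) stop("need at least 2 proteomes")
  seqs <- unlist(unname(lapply(proteomes, function(p) {
    s <- toupper(p$proteins)
    names(s) <- paste0(p$genome_id, "|", names(p$proteins))
    s
  })))
  keep <- nchar(seqs) > config$min_protein_len
  seqs <- seqs[keep]
  if (!length(seqs)) {
    stop("empty graph: all proteins filtered out by the length threshold")
  }
  g <- igraph::make_empty_graph(n = length(seqs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = names(seqs))
  if (is.null(similarity)) {
    pairs <- kmer_candidate_pairs(seqs)
    if (nrow(pairs)) {
      # batch the global alignments: one call per distinct first member
      keep_i <- integer(0); keep_j <- integer(0); keep_w <- numeric(0)
      for (i in unique(pairs[, 1L])) {
        js <- pairs[pairs[, 1L] == i, 2L]
        al <- Biostrings::pairwiseAlignment(
          Biostrings::AAStringSet(seqs[js]),
          Biostrings::AAString(seqs[[i]]),
          type = "global", substitutionMatrix = "BLOSUM62",
          gapOpening = 10, gapExtension = 0.5)
        nmat <- Biostrings::nmatch(al)
        both <- nmat + Biostrings::nmismatch(al)
        ident <- 100 * nmat / Biostrings::nchar(al)
        cov <- 100 * pmin(both / nchar(seqs[js]), both / nchar(seqs[[i]]))
        ok <- ident >= config$min_identity & cov >= config$min_coverage
        keep_i <- c(keep_i, rep(i, sum(ok)))
        keep_j <- c(keep_j, js[ok])
        keep_w <- c(keep_w, pmax(Biostrings::score(al)[ok], 1))
      }
      if (length(keep_i)) {
        g <- igraph::add_edges(g, rbind(names(seqs)[keep_i],
                                        names(seqs)[keep_j]),
                               weight = keep_w)
      }
    }
  } else {
    ok <- similarity$identity >= config$min_identity &
      similarity$coverage >= config$min_coverage &
      similarity$gene_a %in% names(seqs) &
      similarity$gene_b %in% names(seqs) &
      similarity$gene_a != similarity$gene_b
    sim <- similarity[ok, , drop = FALSE]
    if (nrow(sim)) {
      g <- igraph::add_edges(g, rbind(sim$gene_a, sim$gene_b),
                             weight = pmax(sim$score, 1))
      g <- igraph::simplify(g, edge.attr.comb = list(weight = "max"))
    }
  }
  g
}

#' Read/write a precomputed similarity table
#'
#' TSV with columns gene_a, gene_b, identity, coverage, score.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_similarity_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Markov clustering of the similarity graph
#'
#' MCL on the column-normalized weighted adjacency with self-loops (weight
#' of each self-loop = maximum incident edge weight): alternate expansion
#' (matrix squaring) and inflation (entry-wise power, column
#' renormalization) to convergence, then read clusters as connected
#' components of the limit matrix. Disconnected components are clustered
#' independently, which is exact and fast. Isolated nodes become singleton
#' families.
#'
#' @param graph igraph weighted graph from [build_similarity_graph()].
#' @param config A [clustering_config()].
#' @return List of gene families: each a list with `family_id`, `members`
#'   (qualified gene ids) and `genomes_present`.
#' @export
mcl_cluster <- function(graph, config = clustering_config()) {
  if (igraph::vcount(graph) < 1L) stop("graph has no nodes")
  comps <- igraph::components(graph)
  clusters <- list()
  non_converged <- FALSE
  for (ci in seq_len(comps$no)) {
    nodes <- which(comps$membership == ci)
    sub <- igraph::induced_subgraph(graph, nodes)
    nm <- igraph::V(sub)$name
    if (length(nm) == 1L) {
      clusters[[length(clusters) + 1L]] <- nm
      next
    }
    M <- as.matrix(igraph::as_adjacency_matrix(sub, attr = "weight",
                                               sparse = TRUE))
    diag(M) <- apply(M, 2L, max)
    res <- mcl_iterate(M, config$inflation, config$mcl_max_iter,
                       config$mcl_convergence_tol)
    if (!res$converged) non_converged <- TRUE
    for (cl in res$clusters) {
      clusters[[length(clusters) + 1L]] <- nm[cl]
    }
  }
  if (non_converged) {
    warning("MCL did not converge within mcl_max_iter on some components; ",
            "best-effort clusters returned")
  }
  # deterministic family order: by smallest member id
  ord <- order(vapply(clusters, function(x) sort(x)[1L], character(1)))
  clusters <- clusters[ord]
  lapply(seq_along(clusters), function(i) {
    members <- sort(clusters[[i]])
    list(family_id = sprintf("FAM%05d", i),
         members = members,
         genomes_present = sort(unique(sub("\\|.*$", "", members))))
  })
}

# dense MCL on one connected component
mcl_iterate <- function(M, inflation, max_iter, tol) {
  norm_cols <- function(X) sweep(X, 2L, pmax(colSums(X), 1e-300), "/")
  M <- norm_cols(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                    # expansion
    M2 <- norm_cols(M2^inflation)    # inflation
    M2[M2 < 1e-12] <- 0
    M2 <- norm_cols(M2)
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      converged <- TRUE
      break
    }
    M <- M2
  }
  adj <- (M + t(M)) > 1e-8
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  mem <- igraph::components(g)$membership
  list(clusters = split(seq_along(mem), mem), converged = converged)
}

#' Partition the pan-genome
#'
#' Core families are present in all `n_genomes` genomes, unique families in
#' exactly one, distributed families in between.
#'
#' @param families List of gene families from [mcl_cluster()].
#' @param n_genomes Total number of genomes (>= 2).
#' @return List: `core`, `distributed`, `unique` (family id vectors) and
#'   `counts`.
#' @export
classify_pangenome <- function(families, n_genomes) {
  if (n_genomes < 2L) stop("n_genomes must be >= 2")
  np <- vapply(families, function(f) {
    if (!length(f$genomes_present)) {
      stop("family ", f$family_id, " has empty genomes_present")
    }
    length(f$genomes_present)
  }, integer(1))
  if (any(np > n_genomes)) stop("family present in more than n_genomes")
  ids <- vapply(families, `[[`, character(1), "family_id")
  out <- list(core = ids[np == n_genomes],
              distributed = ids[np > 1L & np < n_genomes],
              unique = ids[np == 1L],
              n_genomes = n_genomes)
  out$counts <- c(core = length(out$core),
                  distributed = length(out$distributed),
                  unique = length(out$unique))
  out
}

#' Family counts by presence pattern within a genome subset
#'
#' Restricts each family's presence set to `genome_subset` and counts
#' families per exact presence pattern (Venn-diagram cells). Families
#' absent from every subset member are dropped.
#'
#' @param families List of gene families.
#' @param genome_subset Non-empty character vector of genome ids.
#' @return Named integer vector; names are `+`-joined genome subsets.
#' @export
subset_venn_counts <- function(families, genome_subset) {
  if (!length(genome_subset)) stop("genome_subset is empty")
  known <- sort(unique(unlist(lapply(families, `[[`, "genomes_present"))))
  bad <- setdiff(genome_subset, known)
  if (length(bad)) {
    stop("unknown genome id(s): ", paste(bad, collapse = ", "))
  }
  pats <- vapply(families, function(f) {
    present <- sort(intersect(f$genomes_present, genome_subset))
    paste(present, collapse = "+")
  }, character(1))
  pats <- pats[pats != ""]
  out <- table(pats)
  stats::setNames(as.integer(out), names(out))
}

#' Write family membership and partition summary tables
#'
#' @param families List of gene families.
#' @param path Output TSV path.
#' @return Path, invisibly.
#' @export
write_families_tsv <- function(families, path) {
  rows <- do.call(rbind, lapply(families, function(f) {
    data.frame(family_id = f$family_id,
               genome_id = sub("\\|.*$", "", f$members),
               gene_id = sub("^[^|]*\\|", "", f$members))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
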