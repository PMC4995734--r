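# Core-genome alignment chain: progressive protein alignment,
# back-translation to codon alignments, concatenation with Gblocks-style
# column filtering, and the NJ topology used as the ML starting tree.

# BLOSUM62 lookup with X scored 0 against everything
blosum62_matrix <- function() {
  if (!is.null(.ps_cache$blosum62)) return(.ps_cache$blosum62)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  keep <- c(AA_ALPHABET20, "X")
  B <- B[keep, keep]
  B["X", ] <- 0; B[, "X"] <- 0
  .ps_cache$blosum62 <- B
  B
}

#' Progressive multiple alignment of a protein family
#'
#' Deterministic progressive alignment: guide tree by UPGMA on pairwise
#' k-mer distances, then profile-profile Needleman-Wunsch merges with
#' BLOSUM62 column scores and a linear gap penalty.
#'
#' @param sequences Named character vector of unaligned amino-acid
#'   sequences.
#' @param gap_penalty Linear gap penalty per column (positive; default 8).
#' @param k k-mer size for the guide-tree distances (default 3).
#' @return Named character vector: aligned rows of equal length.
#' @export
progressive_align <- function(sequences, gap_penalty = 8, k = 3L) {
  if (length(sequences) < 2L) {
    warning("single sequence: returned unchanged")
    return(sequences)
  }
  seqs <- toupper(sequences)
  n <- length(seqs)
  # k-mer distance guide matrix
  kms <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    substring(s, seq_len(nchar(s) - k + 1L),
              seq_len(nchar(s) - k + 1L) + k - 1L)
  })
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared <- length(intersect(kms[[i]], kms[[j]]))
      denom <- max(min(length(unique(kms[[i]])),
                       length(unique(kms[[j]]))), 1L)
      d[i, j] <- d[j, i] <- 1 - shared / denom
    }
  }
  guide <- upgma(d)
  merge_order <- profile_merge_order(guide)
  profiles <- lapply(names(seqs), function(nm) {
    stats::setNames(seqs[nm], nm)
  })
  names(profiles) <- names(seqs)
  # walk merges from the guide tree
  for (m in merge_order) {
    p1 <- profiles[[m[1L]]]; p2 <- profiles[[m[2L]]]
    merged <- align_profiles(p1, p2, gap_penalty)
    profiles[[m[1L]]] <- merged
    profiles[[m[2L]]] <- NULL
  }
  out <- profiles[[1L]]
  out[names(seqs)]
}

# sequence of (cluster_rep_a, cluster_rep_b) merges implied by a rooted
# guide tree, children first
profile_merge_order <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  rep_of <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  merges <- list()
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  for (node in as.integer(names(kids))[order(match(as.integer(names(kids)),
                                                   tree$edge[, 1L]))]) {
    ch <- kids[[as.character(node)]]
    reps <- rep_of[ch]
    acc <- reps[1L]
    for (i in seq_along(reps)[-1L]) {
      merges[[length(merges) + 1L]] <- c(acc, reps[i])
    }
    rep_of[node] <- acc
  }
  merges
}

# profile-profile global alignment; profiles are named character vectors
# of already-aligned rows
align_profiles <- function(p1, p2, gap_penalty) {
  B <- blosum62_matrix()
  m1 <- aln_matrix(p1); m2 <- aln_matrix(p2)
  L1 <- ncol(m1); L2 <- ncol(m2)
  # column score: mean BLOSUM62 over residue pairs, gaps scored 0 vs
  # residues (the gap cost is carried by the DP penalty)
  col_codes <- function(m) {
    apply(m, 2L, function(col) match(col, rownames(B)), simplify = FALSE)
  }
  c1 <- col_codes(m1); c2 <- col_codes(m2)
  S <- matrix(0, L1, L2)
  for (i in seq_len(L1)) {
    a <- c1[[i]]
    for (j in seq_len(L2)) {
      b <- c2[[j]]
      pairs <- outer(a, b, function(x, y) {
        v <- B[cbind(x, y)]
        v[is.na(v)] <- 0
        v
      })
      S[i, j] <- mean(pairs)
    }
  }
  F <- matrix(0, L1 + 1L, L2 + 1L)
  F[, 1L] <- -gap_penalty * (0:L1)
  F[1L, ] <- -gap_penalty * (0:L2)
  ptr <- matrix(0L, L1 + 1L, L2 + 1L)
  ptr[, 1L] <- 1L; ptr[1L, ] <- 2L
  for (i in seq_len(L1)) {
    for (j in seq_len(L2)) {
      diag <- F[i, j] + S[i, j]
      up <- F[i, j + 1L] - gap_penalty
      left <- F[i + 1L, j] - gap_penalty
      best <- max(diag, up, left)
      F[i + 1L, j + 1L] <- best
      ptr[i + 1L, j + 1L] <- if (best == diag) 0L else if (best == up) 1L
      else 2L
    }
  }
  # traceback
  i <- L1; j <- L2
  cols1 <- integer(0); cols2 <- integer(0)  # 0 = gap column
  while (i > 0L || j > 0L) {
    p <- ptr[i + 1L, j + 1L]
    if (p == 0L) {
      cols1 <- c(i, cols1); cols2 <- c(j, cols2); i <- i - 1L; j <- j - 1L
    } else if (p == 1L) {
      cols1 <- c(i, cols1); cols2 <- c(0L, cols2); i <- i - 1L
    } else {
      cols1 <- c(0L, cols1); cols2 <- c(j, cols2); j <- j - 1L
    }
  }
  expand <- function(m, cols) {
    out <- matrix("-", nrow(m), length(cols), dimnames = list(rownames(m)))
    out[, cols != 0L] <- m[, cols[cols != 0L], drop = FALSE]
    out
  }
  o1 <- expand(m1, cols1); o2 <- expand(m2, cols2)
  res <- rbind(o1, o2)
  stats::setNames(apply(res, 1L, paste, collapse = ""), rownames(res))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino acid is replaced by its source codon and each protein gap by
#' `---`; a terminal stop codon on the CDS is stripped. The CDS must
#' translate exactly to the ungapped protein row.
#'
#' @param protein_msa Aligned protein sequences (named character vector).
#' @param cds_map Named character vector mapping each row name to its CDS.
#' @return Codon alignment (named character vector), 3x the protein
#'   alignment length.
#' @export
backtranslate <- function(protein_msa, cds_map) {
  out <- character(length(protein_msa))
  names(out) <- names(protein_msa)
  for (nm in names(protein_msa)) {
    if (is.na(match(nm, names(cds_map)))) {
      stop("no CDS for sequence '", nm, "'")
    }
    cds <- toupper(cds_map[[nm]])
    prot <- strsplit(toupper(protein_msa[[nm]]), "")[[1L]]
    tr <- translate_cds(cds, id = nm)
    ungapped <- paste(prot[prot != "-"], collapse = "")
    if (tr != ungapped) {
      mism <- which(strsplit(tr, "")[[1L]] != strsplit(ungapped, "")[[1L]])
      stop(sprintf(
        "CDS of '%s' does not translate to its alignment row (position %s)",
        nm, if (length(mism)) mism[1L] else "length"))
    }
    starts <- seq(1L, by = 3L, length.out = nchar(tr))
    cods <- substring(cds, starts, starts + 2L)
    res <- character(length(prot))
    res[prot == "-"] <- "---"
    res[prot != "-"] <- cods
    out[[nm]] <- paste(res, collapse = "")
  }
  out
}

#' Filter policy for concatenated alignments
#'
#' @param drop_gap_columns Drop every column containing at least one gap
#'   (default `TRUE`).
#' @param divergence_rule Minimum fraction of rows sharing the majority
#'   residue for a column to be kept (default 0.5; in (0, 1]).
#' @return List of class `filter_policy`.
#' @export
filter_policy <- function(drop_gap_columns = TRUE, divergence_rule = 0.5) {
  if (divergence_rule <= 0 || divergence_rule > 1) {
    stop("divergence_rule must be in (0, 1]")
  }
  structure(list(drop_gap_columns = drop_gap_columns,
                 divergence_rule = divergence_rule),
            class = "filter_policy")
}

#' Concatenate alignments and filter disordered columns
#'
#' Horizontally concatenates alignments sharing one label set, then drops
#' columns that contain any gap or whose majority-residue fraction falls
#' below the divergence rule (the Gblocks-style cleanup of a concatenated
#' core genome).
#'
#' @param alignments List of alignments (named character vectors) over the
#'   same labels.
#' @param policy A [filter_policy()].
#' @return List: `alignment` (filtered supermatrix), `report` (data.frame
#'   mapping kept columns to source alignment and 1-based original
#'   column).
#' @export
concatenate_and_filter <- function(alignments, policy = filter_policy()) {
  if (!length(alignments)) stop("no alignments given")
  labels <- sort(names(alignments[[1L]]))
  for (i in seq_along(alignments)) {
    if (!setequal(names(alignments[[i]]), labels)) {
      miss <- setdiff(labels, names(alignments[[i]]))
      stop("alignment ", i, " label mismatch; missing: ",
           paste(miss, collapse = ", "))
    }
  }
  mats <- lapply(alignments, function(a) aln_matrix(a[labels]))
  src <- rep(seq_along(mats), vapply(mats, ncol, integer(1)))
  origin <- unlist(lapply(mats, function(m) seq_len(ncol(m))))
  big <- do.call(cbind, mats)
  keep <- rep(TRUE, ncol(big))
  if (policy$drop_gap_columns) {
    keep <- keep & colSums(big == "-") == 0L
  }
  maj <- apply(big, 2L, function(col) {
    res <- col[col != "-"]
    if (!length(res)) return(0)
    max(table(res)) / length(col)
  })
  keep <- keep & maj >= policy$divergence_rule
  filtered <- big[, keep, drop = FALSE]
  aln <- stats::setNames(apply(filtered, 1L, paste, collapse = ""), labels)
  srcnames <- if (is.null(names(alignments))) as.character(src)
  else names(alignments)[src]
  list(alignment = aln,
       report = data.frame(source = srcnames[keep],
                           original_column = origin[keep]))
}

#' Neighbor-joining topology
#'
#' Standard NJ (Q-matrix criterion) via ape; negative branch lengths are
#' clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix with >= 3 labels.
#' @return Unrooted `phylo` tree.
#' @export
nj_topology <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 labels")
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length <- pmax(tr$edge.length, 0)
  }
  tr
}

#' Write an alignment in relaxed PHYLIP format
#'
#' @param aln Named character vector alignment.
#' @param path Output path.
#' @export
write_phylip <- function(aln, path) {
  lines <- c(sprintf("%d %d", length(aln), nchar(aln[[1L]])),
             sprintf("%s  %s", names(aln), unname(aln)))
  writeLines(lines, path)
  invisible(path)
}
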