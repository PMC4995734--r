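# Gene-content analysis: binary presence/absence matrix, Jaccard
# distances between genomes, and the UPGMA gene-content tree.

#' Gene presence/absence matrix
#'
#' Binary genomes x families matrix: entry (g, f) is 1 iff genome g carries
#' at least one member of family f (presence is binary regardless of copy
#' number).
#'
#' @param families List of gene families (see [mcl_cluster()]).
#' @param genome_ids Ordered genome ids covering all `genomes_present`.
#' @return 0/1 integer matrix with genome rows and family columns.
#' @export
presence_matrix <- function(families, genome_ids) {
  ids <- vapply(families, `[[`, character(1), "family_id")
  if (anyDuplicated(ids)) stop("duplicate family_ids")
  all_g <- unique(unlist(lapply(families, `[[`, "genomes_present")))
  if (!all(all_g %in% genome_ids)) {
    stop("genome_ids does not cover: ",
         paste(setdiff(all_g, genome_ids), collapse = ", "))
  }
  m <- matrix(0L, nrow = length(genome_ids), ncol = length(families),
              dimnames = list(genome_ids, ids))
  for (f in families) m[f$genomes_present, f$family_id] <- 1L
  m
}

#' Jaccard distances between genomes
#'
#' One minus the Jaccard coefficient on the gene-content sets:
#' d(g, h) = 1 - |F_g intersect F_h| / |F_g union F_h|.
#' Two genomes with an empty union get distance 0 with a warning.
#'
#' @param matrix Presence/absence matrix from [presence_matrix()].
#' @return Symmetric distance matrix with zero diagonal, entries in [0, 1].
#' @export
jaccard_distance <- function(matrix) {
  if (nrow(matrix) < 2L) stop("need at least 2 genomes")
  if (!all(matrix %in% c(0L, 1L))) stop("matrix must be binary")
  inter <- tcrossprod(matrix)
  sizes <- rowSums(matrix)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  if (any(uni == 0)) {
    warning("genome pair(s) with empty family union: distance set to 0")
    d[uni == 0] <- 0
  }
  diag(d) <- 0
  d
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering: repeatedly merge the pair of
#' clusters at minimal average distance; the merged node sits at half the
#' merge distance, so the output is ultrametric. Ties are broken by the
#' lexicographically smallest pair of cluster representatives (smallest
#' member label), making the output deterministic.
#'
#' @param d Symmetric non-negative distance matrix with labelled rows.
#' @return Rooted ultrametric `phylo` tree.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must have row labels")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 labels")
  if (any(is.na(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")

  newick <- labels                  # subtree strings
  height <- rep(0, n)               # current node heights
  size <- rep(1L, n)
  rep_label <- labels               # smallest member label, for tie-breaks
  active <- rep(TRUE, n)
  D <- d
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL
    for (ai in seq_along(idx)) {
      for (bi in seq_along(idx)) {
        if (bi <= ai) next
        i <- idx[ai]; j <- idx[bi]
        dij <- D[i, j]
        pair <- sort(c(rep_label[i], rep_label[j]))
        cand <- list(d = dij, i = i, j = j, key = pair)
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 &&
             (pair[1L] < best$key[1L] ||
              (pair[1L] == best$key[1L] && pair[2L] < best$key[2L])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    bi <- max(h - height[i], 0); bj <- max(h - height[j], 0)
    # child order by representative label, deterministic output
    if (rep_label[i] <= rep_label[j]) {
      newick[i] <- sprintf("(%s:%.10g,%s:%.10g)", newick[i], bi,
                           newick[j], bj)
    } else {
      newick[i] <- sprintf("(%s:%.10g,%s:%.10g)", newick[j], bj,
                           newick[i], bi)
    }
    height[i] <- h
    rep_label[i] <- min(rep_label[i], rep_label[j])
    # average-linkage update, weighted by cluster sizes
    for (k in which(active)) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
  }
  root <- which(active)
  ape::read.tree(text = paste0(newick[root], ";"))
}

#' Newick serialization
#'
#' Round-trip safe Newick writer/reader (branch lengths kept to 10
#' significant digits; node labels carry support values).
#'
#' @param tree `phylo` tree.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return `write_newick()`: the Newick string (invisibly if written to a
#'   file); `read_newick()`: a `phylo` tree.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @param text Newick string (used when `path` is `NULL`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    suppressWarnings(if (!is.null(path)) ape::read.tree(path)
                     else ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo") ||
      anyNA(tr$edge) || is.null(tr$tip.label)) {
    stop("malformed Newick input")
  }
  tr
}

#' Write a presence/absence matrix as TSV
#'
#' @param matrix Presence/absence matrix.
#' @param path Output path.
#' @export
write_presence_tsv <- function(matrix, path) {
  utils::write.table(matrix, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
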