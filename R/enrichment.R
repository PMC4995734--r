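# COG-category enrichment of positively selected genes against the
# core-genome background, one-sided (upper-tail) exact binomial tests.

COG_CATEGORIES <- strsplit("JAKLBDYVTMNZWUOCGEFHIPQRS", "")[[1L]]

#' Load a gene-to-COG-category map
#'
#' Two-column TSV (gene id, category letters). Multi-letter assignments
#' contribute the gene to every listed category; letters outside the
#' standard COG alphabet raise a warning and are bucketed as
#' uncategorized.
#'
#' @param path TSV path (header optional: detected on the first line).
#' @return Named character vector of category strings, one per gene
#'   (class `cog_map`).
#' @export
load_cog_map <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("gene", "category"))
  if (identical(tolower(raw$gene[1L]), "gene")) raw <- raw[-1L, ]
  cats <- toupper(trimws(raw$category))
  letters_used <- unique(unlist(strsplit(cats[cats != ""], "")))
  bad <- setdiff(letters_used, COG_CATEGORIES)
  if (length(bad)) {
    warning("unknown COG category letter(s) ",
            paste(bad, collapse = ", "), ": bucketed as uncategorized")
    for (b in bad) cats <- gsub(b, "", cats, fixed = TRUE)
  }
  structure(stats::setNames(cats, raw$gene), class = "cog_map")
}

#' @rdname load_cog_map
#' @param cogmap Named character vector of category strings.
#' @export
save_cog_map <- function(cogmap, path) {
  utils::write.table(data.frame(gene = names(cogmap),
                                category = unname(unclass(cogmap))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' One-sided binomial enrichment p-value
#'
#' Exact upper-tail probability P(X >= k) for X ~ Binomial(n, p0),
#' accumulated by direct summation of the exact point masses; the
#' enrichment direction only, no normal approximation.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Background proportion in [0, 1].
#' @return p-value.
#' @export
binomial_enrichment <- function(k, n, p0) {
  if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  if (k == 0) return(1)
  min(sum(stats::dbinom(k:n, n, p0)), 1)
}

# per-gene category letters (multi-category genes count once per
# category; unmapped genes are "uncategorized")
gene_categories <- function(genes, cogmap) {
  cats <- unclass(cogmap)[genes]
  cats[is.na(cats) | cats == ""] <- "-"
  stats::setNames(strsplit(cats, ""), genes)
}

#' COG enrichment table
#'
#' Per category: selected-set counts against the background proportion,
#' one-sided binomial p-values, and the paired proportions for plotting.
#'
#' @param selected Gene ids under selection (must be a subset of
#'   `background`).
#' @param background Background gene ids (e.g. all tested core genes).
#' @param cogmap A [load_cog_map()] result (or named character vector).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame sorted by p-value with columns category,
#'   k_selected, n_selected, k_core, n_core, proportion_selected,
#'   proportion_core, p_value (and p_adjusted when requested).
#' @export
enrichment_table <- function(selected, background, cogmap,
                             p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!length(background)) stop("empty background")
  if (!all(selected %in% background)) {
    stop("selected genes must be a subset of the background")
  }
  sel_cats <- gene_categories(selected, cogmap)
  bg_cats <- gene_categories(background, cogmap)
  cats <- sort(unique(unlist(bg_cats)))
  n_sel <- length(selected)
  n_bg <- length(background)
  rows <- lapply(cats, function(cl) {
    k_sel <- sum(vapply(sel_cats, function(x) cl %in% x, logical(1)))
    k_bg <- sum(vapply(bg_cats, function(x) cl %in% x, logical(1)))
    p0 <- k_bg / n_bg
    data.frame(category = if (cl == "-") "uncategorized" else cl,
               k_selected = k_sel, n_selected = n_sel,
               k_core = k_bg, n_core = n_bg,
               proportion_selected = if (n_sel) k_sel / n_sel else 0,
               proportion_core = p0,
               p_value = if (n_sel) binomial_enrichment(k_sel, n_sel, p0)
               else 1)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  out[order(out$p_value, out$category), , drop = FALSE]
}
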