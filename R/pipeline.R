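# End-to-end orchestration: simulate (or ingest) proteomes, cluster the
# pan-genome, build the gene-content and core-genome trees, scan for
# positive selection, test COG enrichment, and estimate competition
# fitness. All outputs are plain text (TSV + Newick), so stages are
# diffable and the pipeline is resumable.

#' Run the full comparative-genomics pipeline
#'
#' Executes the stages in order, writing one output file per stage into
#' `out_dir`; a stage whose output file already exists is skipped, so an
#' interrupted run can be resumed with the same config. A per-gene fit
#' failure in the selection scan is recorded in its row, never fatal.
#'
#' @param config List: `sim` (a [sim_config()]; used when no input data
#'   are given), `out_dir`, `alpha` (default 0.05), `foreground` (tip
#'   labels; defaults to the simulation's planted clade),
#'   `bootstrap_replicates` (default 100), `scan_n_starts` (default 1),
#'   `cog_map` (optional named category vector for the enrichment stage).
#' @return List of output paths plus the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  if (is.null(config$sim)) stop("config$sim (a sim_config) is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  nboot <- if (is.null(config$bootstrap_replicates)) 100L
  else config$bootstrap_replicates
  n_starts <- if (is.null(config$scan_n_starts)) 1L
  else config$scan_n_starts
  log_path <- file.path(out_dir, "pipeline.log")
  logln <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                paste0(...)), file = log_path, append = TRUE)
  }
  paths <- list(
    families = file.path(out_dir, "families.tsv"),
    partition = file.path(out_dir, "partition_summary.tsv"),
    presence = file.path(out_dir, "presence_matrix.tsv"),
    gene_content_tree = file.path(out_dir, "gene_content_tree.nwk"),
    core_tree = file.path(out_dir, "core_genome_tree.nwk"),
    selection = file.path(out_dir, "selection_scan.tsv"),
    selection_summary = file.path(out_dir, "selection_summary.tsv"),
    enrichment = file.path(out_dir, "enrichment.tsv"),
    fitness = file.path(out_dir, "fitness.tsv"),
    config_echo = file.path(out_dir, "config_echo.txt"))

  logln("pipeline start, seed ", config$sim$seed)
  writeLines(utils::capture.output(utils::str(config$sim)),
             paths$config_echo)

  # stage 1: synthetic inputs with ground truth
  sim <- simulate_proteomes(config$sim)
  foreground <- if (!is.null(config$foreground)) config$foreground
  else sim$truth$foreground

  # stage 2: pan-genome clustering
  if (!file.exists(paths$families)) {
    graph <- build_similarity_graph(sim$proteomes)
    families <- mcl_cluster(graph)
    write_families_tsv(families, paths$families)
    logln("pangenome: ", length(families), " families")
  } else {
    families <- read_families_tsv(paths$families)
    logln("pangenome: resumed from ", paths$families)
  }
  genome_ids <- names(sim$proteomes)
  part <- classify_pangenome(families, length(genome_ids))
  if (!file.exists(paths$partition)) {
    utils::write.table(
      data.frame(class = names(part$counts), n_families = part$counts),
      paths$partition, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # stage 3: gene-content tree
  pm <- presence_matrix(families, genome_ids)
  if (!file.exists(paths$presence)) write_presence_tsv(pm, paths$presence)
  if (!file.exists(paths$gene_content_tree)) {
    gtree <- upgma(jaccard_distance(pm))
    write_newick(gtree, paths$gene_content_tree)
  }
  gtree <- read_newick(paths$gene_content_tree)

  # stage 4: core-genome tree from concatenated single-copy core genes
  core_alns <- single_copy_core_alignments(families, sim$proteomes,
                                           genome_ids)
  if (!file.exists(paths$core_tree)) {
    cat_res <- concatenate_and_filter(core_alns)
    ml <- optimize_branch_lengths_and_params(
      cat_res$alignment, nj_topology(tn93_distances(cat_res$alignment)))
    ctree <- bootstrap_support(cat_res$alignment, ml$tree,
                               n_replicates = nboot,
                               seed = config$sim$seed + 1L)
    write_newick(ctree, paths$core_tree)
    logln("core tree: ", nchar(cat_res$alignment[[1L]]), " columns, ",
          "logLik ", round(ml$loglik, 2))
  }
  ctree <- read_newick(paths$core_tree)

  # stage 5: positive-selection scan
  if (!file.exists(paths$selection)) {
    scan_tree <- ctree
    scan_tree$node.label <- NULL
    scan <- scan_core_genes(core_alns, scan_tree, foreground,
                            alpha = alpha, branch_lengths = "scale",
                            n_starts = n_starts,
                            control = list(factr = 1e10, maxit = 100L),
                            seed = config$sim$seed + 2L)
    utils::write.table(scan$table, paths$selection, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(metric = names(unlist(scan$summary)),
                 value = unlist(scan$summary)),
      paths$selection_summary, sep = "\t", quote = FALSE,
      row.names = FALSE)
    logln("selection scan: ", scan$summary$n_tested, " genes tested")
  }
  scan_tab <- utils::read.delim(paths$selection,
                                stringsAsFactors = FALSE)

  # stage 6: COG enrichment of branch-selected genes
  if (!file.exists(paths$enrichment)) {
    cogmap <- if (!is.null(config$cog_map)) config$cog_map
    else synthetic_cog_map(scan_tab$family_id, config$sim$seed + 3L)
    sel <- scan_tab$family_id[scan_tab$branch_selected %in% TRUE]
    bg <- scan_tab$family_id[!is.na(scan_tab$p_branch)]
    enr <- if (length(sel)) enrichment_table(sel, bg, cogmap)
    else data.frame()
    utils::write.table(enr, paths$enrichment, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  # stage 7: competition fitness
  if (!file.exists(paths$fitness)) {
    comp <- simulate_competition(config$sim)
    est <- aggregate_fitness(comp$series)
    utils::write.table(
      rbind(data.frame(metric = "mean_w", value = est$mean),
            data.frame(metric = "sd_w", value = est$sd),
            data.frame(metric = "n_cycles", value = est$n_replicates),
            data.frame(metric = "w_true", value = comp$truth$w_true)),
      paths$fitness, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  logln("pipeline done")
  list(paths = paths, partition = part, gene_content_tree = gtree,
       core_tree = ctree, selection = scan_tab, truth = sim$truth)
}

# rebuild family objects from a families.tsv written by an earlier run
read_families_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$family_id), function(g) {
    list(family_id = g$family_id[1L],
         members = sort(paste0(g$genome_id, "|", g$gene_id)),
         genomes_present = sort(unique(g$genome_id)))
  })
}

# codon alignments of single-copy core families, keyed by family id with
# genome ids as sequence names (the planted simulator emits aligned CDS,
# so the per-family alignment is the CDS set itself)
single_copy_core_alignments <- function(families, proteomes, genome_ids) {
  out <- list()
  for (f in families) {
    g_of <- sub("\\|.*$", "", f$members)
    if (length(f$members) != length(genome_ids)) next
    if (!setequal(g_of, genome_ids) || anyDuplicated(g_of)) next
    aln <- vapply(f$members, function(m) {
      g <- sub("\\|.*$", "", m)
      gene <- sub("^[^|]*\\|", "", m)
      proteomes[[g]]$cds[[gene]]
    }, character(1))
    names(aln) <- g_of
    if (length(unique(nchar(aln))) != 1L) next
    out[[f$family_id]] <- aln
  }
  out
}

# deterministic synthetic COG assignment used when no real mapping is
# supplied (labelled synthetic: categories are drawn at random and carry
# no biological meaning)
synthetic_cog_map <- function(gene_ids, seed) {
  set.seed(seed)
  cats <- sample(COG_CATEGORIES, length(gene_ids), replace = TRUE)
  stats::setNames(cats, gene_ids)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions; 0 iff the
#' unrooted topologies agree. Also returns the shared bipartitions.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return List: `rf` (integer distance), `shared` (list of shared
#'   bipartitions as tip-label sets).
#' @export
compare_trees <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("leaf sets differ: ",
         paste(c(setdiff(t1$tip.label, t2$tip.label),
                 setdiff(t2$tip.label, t1$tip.label)), collapse = ", "))
  }
  b1 <- nontrivial_bipartitions(t1)
  b2 <- nontrivial_bipartitions(t2)
  shared <- intersect(b1, b2)
  list(rf = length(setdiff(b1, b2)) + length(setdiff(b2, b1)),
       shared = lapply(shared, function(s) strsplit(s, "\\|")[[1L]]))
}

# canonical strings for non-trivial bipartitions of an unrooted tree
nontrivial_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- sort(labs[p])
    other <- setdiff(tips, side)
    if (length(side) < 2L || length(other) < 2L) next
    canon <- if (side[1L] == tips[1L]) side else other
    out <- c(out, paste(sort(canon), collapse = "|"))
  }
  unique(out)
}
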