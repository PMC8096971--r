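#' Construct a cells-by-genes expression set
#'
#' @param values numeric matrix, cells x genes, nonnegative normalized
#'   expression; rownames are cell_ids, colnames gene_ids.
#' @param cells data frame with columns cell_id, pseudotime, branch,
#'   sample; cell_ids must match `rownames(values)` in order.
#' @return object of class `expression_set`.
#' @export
expression_set <- function(values, cells) {
  assert_that(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  assert_that(all(values >= 0), "expression values must be nonnegative")
  assert_that(!anyDuplicated(rownames(values)), "duplicate cell ids")
  assert_that(!anyDuplicated(colnames(values)), "duplicate gene ids")
  assert_that(identical(rownames(values), cells$cell_id),
              "rownames(values) must equal cells$cell_id in order")
  structure(list(values = values, cells = cells), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d cells x %d genes, branches: %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$cells$branch), collapse = ", ")))
  invisible(x)
}

#' Nearest-gene set for a collection of sites
#'
#' Maps sites to their nearest gene via a [nearest_tss()] annotation and
#' returns the deduplicated gene set. Unannotated sites are dropped with a
#' message.
#'
#' @param site_ids sites to map.
#' @param annotation [nearest_tss()] output covering the sites.
#' @return character vector of unique gene_ids.
#' @export
sites_to_gene_set <- function(site_ids, annotation) {
  idx <- match(site_ids, annotation$site_id)
  assert_that(!anyNA(idx), "annotation does not cover all sites")
  genes <- annotation$gene_id[idx]
  dropped <- sum(is.na(genes))
  if (dropped) message(sprintf("sites_to_gene_set: %d unannotated site(s) dropped", dropped))
  out <- unique(genes[!is.na(genes)])
  assert_that(length(out) > 0, "no annotated genes for the given sites")
  out
}

#' Control-matched module score per cell
#'
#' Re-implements the standard expression-bin-matched module score: genes
#' are binned by average expression across cells into `n_bins`
#' equal-frequency bins; for each gene in the set, `n_ctrl` control genes
#' are drawn (with replacement, seeded) from its bin; the per-cell score is
#' the mean expression over the set minus the mean over the pooled control
#' draws. Deterministic given `seed`.
#'
#' @param expr an [expression_set()].
#' @param gene_set character vector of gene_ids (duplicates are removed;
#'   genes absent from `expr` raise an error naming them).
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes drawn per set gene (default 100).
#' @param seed integer seed for the control draws.
#' @param gene_set_id label stored with the track.
#' @return object of class `module_score_track`: list with `score` (named
#'   per-cell numeric), `cells`, `gene_set_id`, `genes_used`.
#' @export
compute_module_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100,
                                 seed = 1, gene_set_id = "gene_set") {
  # canonical order: the score is invariant to gene order and duplication
  gene_set <- sort(unique(gene_set))
  all_genes <- colnames(expr$values)
  assert_that(length(all_genes) >= max(2, n_bins),
              "too few genes in the expression set for %d bins", n_bins)
  missing <- setdiff(gene_set, all_genes)
  if (length(missing) == length(gene_set)) {
    stopf("gene set disjoint from expression set; missing: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  gene_set <- intersect(gene_set, all_genes)
  avg <- colMeans(expr$values)
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / length(avg))
  by_bin <- split(all_genes, bin)
  ctrl <- with_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      pool <- by_bin[[as.character(bin[[g]])]]
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }), use.names = FALSE)
  })
  score <- rowMeans(expr$values[, gene_set, drop = FALSE]) -
    rowMeans(expr$values[, ctrl, drop = FALSE])
  structure(list(score = score, cells = expr$cells,
                 gene_set_id = gene_set_id, genes_used = gene_set),
            class = "module_score_track")
}

#' @export
print.module_score_track <- function(x, ...) {
  cat(sprintf("module_score_track '%s': %d cells, %d genes, mean score %.3f\n",
              x$gene_set_id, length(x$score), length(x$genes_used),
              mean(x$score)))
  invisible(x)
}

#' Rescale one branch's pseudotime to another's endpoint
#'
#' Multiplies `pt_b` by `max(pt_a) / max(pt_b)` so both branches share an
#' endpoint, as expected for two fates differentiating from the same
#' tissue. Positive scaling preserves cell order.
#'
#' @param pt_a,pt_b numeric pseudotime vectors sharing origin 0;
#'   `max(pt_b)` must be > 0.
#' @return rescaled `pt_b`.
#' @export
align_branch_endpoints <- function(pt_a, pt_b) {
  assert_that(max(pt_b) > 0, "max(pt_b) must be > 0")
  pt_b * max(pt_a) / max(pt_b)
}

#' Module-score trend along pseudotime
#'
#' Bins cells into `n_ptbins` equal-width pseudotime bins, reports per-bin
#' mean, SD and count of the score, and the Spearman correlation of score
#' with pseudotime.
#'
#' @param track a `module_score_track` from [compute_module_score()].
#' @param n_ptbins number of equal-width bins (default 20).
#' @param branch optional branch label to restrict to.
#' @return list with `bins` (data frame bin, pt_mid, mean, sd, n) and
#'   `rho` (Spearman correlation).
#' @export
trend_along_pseudotime <- function(track, n_ptbins = 20, branch = NULL) {
  cells <- track$cells
  score <- track$score
  if (!is.null(branch)) {
    keep <- cells$branch %in% branch
    cells <- cells[keep, , drop = FALSE]
    score <- score[keep]
  }
  pt <- cells$pseudotime
  assert_that(!anyNA(pt), "pseudotime missing for some cells")
  assert_that(diff(range(pt)) > 0, "all cells share one pseudotime; trend undefined")
  breaks <- seq(min(pt), max(pt), length.out = n_ptbins + 1)
  bin <- cut(pt, breaks, include.lowest = TRUE, labels = FALSE)
  bins <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    s <- score[bin == b]
    data.frame(bin = b, pt_mid = (breaks[b] + breaks[b + 1]) / 2,
               mean = mean(s), sd = stats::sd(s), n = length(s))
  }))
  assert_that(nrow(bins) >= 2, "need >= 2 nonempty pseudotime bins")
  list(bins = bins, rho = stats::cor(score, pt, method = "spearman"))
}

#' Read / write expression sets
#'
#' Expression values as a tab-delimited cells x genes table with a
#' `cell_id` first column; cell metadata as a tab-delimited sheet with
#' columns cell_id, pseudotime, branch, sample.
#'
#' @param values_path,cells_path file paths.
#' @return an [expression_set()].
#' @export
read_expression_set <- function(values_path, cells_path) {
  df <- utils::read.table(values_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  cells <- utils::read.table(cells_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  expression_set(vals[cells$cell_id, , drop = FALSE], cells)
}

#' @rdname read_expression_set
#' @param expr an [expression_set()] to write.
#' @export
write_expression_set <- function(expr, values_path, cells_path) {
  df <- data.frame(cell_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$cells, cells_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(values_path)
}
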