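#' Four-way passage-combination comparison grid
#'
#' Contrasts a metastatic cell line against its parental line in every
#' combination of passage classes — metastatic early vs parental early
#' (ME_PE), metastatic late vs parental early (ML_PE), metastatic early
#' vs parental late (ME_PL), metastatic late vs parental late (ML_PL) —
#' plus a pooled contrast of all metastatic vs all parental replicates.
#' The parental line is always the reference (denominator) group.
#'
#' @param expr an [expression_matrix()] holding both lines at both
#'   passage classes.
#' @param parental,metastatic cell line names.
#' @return A `comparison_grid`: list with `tables` (named list of
#'   `contrast_table`s keyed `ME_PE`, `ML_PE`, `ME_PL`, `ML_PL`),
#'   `pooled` (one `contrast_table`), and the line names.
#' @export
build_grid <- function(expr, parental, metastatic) {
  stopifnot(inherits(expr, "expression_matrix"))
  grp <- list(PE = samples_for(expr, parental, "early"),
              PL = samples_for(expr, parental, "late"),
              ME = samples_for(expr, metastatic, "early"),
              ML = samples_for(expr, metastatic, "late"))
  empty <- names(grp)[vapply(grp, length, 1L) == 0L]
  if (length(empty)) {
    stop_invalid("no samples for condition(s): %s",
                 paste(empty, collapse = ", "))
  }
  keys <- c("ME_PE", "ML_PE", "ME_PL", "ML_PL")
  tables <- stats::setNames(lapply(keys, function(k) {
    parts <- strsplit(k, "_")[[1]]
    contrast(expr, group_a = grp[[parts[2]]], group_b = grp[[parts[1]]])
  }), keys)
  pooled <- contrast(expr, group_a = c(grp$PE, grp$PL),
                     group_b = c(grp$ME, grp$ML))
  structure(list(tables = tables, pooled = pooled,
                 parental = parental, metastatic = metastatic),
            class = "comparison_grid")
}

#' @export
print.comparison_grid <- function(x, ...) {
  cat(sprintf("comparison_grid: %s vs %s, 4 passage-combination contrasts + pooled (%d genes)\n",
              x$metastatic, x$parental, nrow(x$pooled)))
  invisible(x)
}

# Signed linear fold change: 2^lfc for up, -2^(-lfc) for down.
signed_fold <- function(lfc) ifelse(lfc >= 0, 2^lfc, -(2^(-lfc)))

#' Genes consistently regulated across passage combinations
#'
#' Reports genes that pass the regulation criterion (fold change above
#' `fold_threshold`, p below `alpha`, strict inequalities) in the same
#' direction in at least `min_pass` of the four passage-combination
#' contrasts.  A gene regulated up in some combinations and down in
#' others is never reported, whatever the counts.  Passage-confounded
#' effects flip sign between the mixed combinations (ML_PE vs ME_PL) and
#' are thereby excluded; this is the procedure's purpose.
#'
#' The reported mean fold is the arithmetic mean of the four signed
#' linear fold changes (negative values denote down-regulation); set
#' `fold_scale = "log2"` for the mean of the log2 fold changes instead.
#'
#' @param grid a [build_grid()] result.
#' @param min_pass 3 or 4: minimum number of passing combinations.
#' @param fold_threshold linear fold threshold (default 2).
#' @param alpha significance level on the raw p value (default 0.05).
#' @param fold_scale `"linear"` (default) or `"log2"` for the mean fold.
#' @return data.frame with columns `gene_id`, `direction`, one signed
#'   linear fold column per combination (`fc_ME_PE`, ...), `n_pass` and
#'   `mean_fold`, sorted by direction and descending |mean_fold|.
#' @export
consistent_genes <- function(grid, min_pass = 4, fold_threshold = 2,
                             alpha = 0.05, fold_scale = c("linear", "log2")) {
  stopifnot(inherits(grid, "comparison_grid"))
  fold_scale <- match.arg(fold_scale)
  if (!min_pass %in% c(3, 4)) stop_invalid("`min_pass` must be 3 or 4")
  cut <- log2(fold_threshold)
  keys <- names(grid$tables)
  lfc <- vapply(grid$tables, function(tt) tt$log2fc, numeric(nrow(grid$pooled)))
  p <- vapply(grid$tables, function(tt) tt$p, numeric(nrow(grid$pooled)))
  up_pass <- lfc > cut & p < alpha
  down_pass <- lfc < -cut & p < alpha
  n_up <- rowSums(up_pass)
  n_down <- rowSums(down_pass)
  keep_up <- n_up >= min_pass & n_down == 0L
  keep_down <- n_down >= min_pass & n_up == 0L

  build <- function(keep, dir, n_pass) {
    if (!any(keep)) return(NULL)
    fc <- signed_fold(lfc[keep, , drop = FALSE])
    colnames(fc) <- paste0("fc_", keys)
    mean_fold <- if (fold_scale == "linear") rowMeans(fc)
                 else rowMeans(lfc[keep, , drop = FALSE])
    data.frame(gene_id = grid$pooled$gene_id[keep], direction = dir,
               fc, n_pass = n_pass[keep], mean_fold = mean_fold,
               row.names = NULL)
  }
  out <- rbind(build(keep_up, "up", n_up), build(keep_down, "down", n_down))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), direction = character(),
                      fc_ME_PE = numeric(), fc_ML_PE = numeric(),
                      fc_ME_PL = numeric(), fc_ML_PL = numeric(),
                      n_pass = integer(), mean_fold = numeric())
  }
  out <- out[order(out$direction, -abs(out$mean_fold)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent of a pooled gene list retained by the consistency filter
#'
#' @param n_consistent genes surviving the four-way consistency filter.
#' @param n_pooled genes regulated in the pooled contrast (> 0).
#' @return Percent retained (numeric; 14 of 56 gives 25).
#' @export
retention_pct <- function(n_consistent, n_pooled) {
  if (n_pooled <= 0) stop_invalid("`n_pooled` must be > 0")
  100 * n_consistent / n_pooled
}

#' Evaluate consistent genes against pathway gene sets
#'
#' Intersects a consistent-gene table with named gene sets (e.g. KEGG
#' pathways read from GMT) and computes, per set, the member lists split
#' by direction and the EASE-score enrichment p of set membership among
#' the consistent genes, against a universe of `universe_n` genes.
#'
#' @param genes a [consistent_genes()] data.frame.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param universe_n universe size.
#' @return data.frame with columns `set`, `n_set`, `n_members`, `n_up`,
#'   `n_down`, `ease_p`, `fisher_p`; the per-set member ids are attached
#'   as the `members` attribute (named list).
#' @export
pathway_filter <- function(genes, gene_sets, universe_n) {
  if (length(gene_sets) == 0L) stop_invalid("`gene_sets` must be non-empty")
  if (is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
    stop_invalid("gene sets must be named")
  }
  members <- lapply(gene_sets, function(set) {
    genes[genes$gene_id %in% set, c("gene_id", "direction"), drop = FALSE]
  })
  rows <- lapply(names(gene_sets), function(nm) {
    m <- members[[nm]]
    K <- min(length(gene_sets[[nm]]), universe_n)
    pp <- ease_p(nrow(m), min(nrow(genes), universe_n), K, universe_n)
    data.frame(set = nm, n_set = length(gene_sets[[nm]]),
               n_members = nrow(m),
               n_up = sum(m$direction == "up"),
               n_down = sum(m$direction == "down"),
               ease_p = pp$ease_p, fisher_p = pp$fisher_p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "members") <- lapply(members, function(m) m$gene_id)
  out
}

#' Genes shared between the consistent lists of several systems
#'
#' @param lists named list (>= 2) of character vectors of gene ids, one
#'   per cell-line system, with identifiers already harmonised.
#' @return List with `all` (genes in every list) and `pairwise` (named
#'   list of pairwise intersections, names like `"A&B"`).
#' @export
cross_system_intersection <- function(lists) {
  if (length(lists) < 2L) stop_invalid("need at least two gene lists")
  if (is.null(names(lists))) names(lists) <- paste0("system", seq_along(lists))
  pairs <- utils::combn(names(lists), 2, simplify = FALSE)
  pairwise <- stats::setNames(
    lapply(pairs, function(pr) intersect(lists[[pr[1]]], lists[[pr[2]]])),
    vapply(pairs, paste, "", collapse = "&"))
  list(all = Reduce(intersect, lists), pairwise = pairwise)
}
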