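#' EASE-score p value (modified one-sided Fisher exact test)
#'
#' The EASE score is the conservative enrichment statistic popularised by
#' DAVID: the one-sided Fisher exact test (upper hypergeometric tail) on
#' the 2x2 membership table, computed after removing one gene from the
#' in-list, on-unit cell.  Subtracting one hit penalises categories
#' supported by very few genes; for k = 0 the score is 1.  The standard
#' (unmodified) Fisher p is returned alongside.
#'
#' @param k_on_unit regulated genes on the unit (list hits).
#' @param n_list total regulated genes.
#' @param K_unit universe genes on the unit.
#' @param N_universe universe size.
#' @return List with `ease_p` and `fisher_p`.
#' @examples
#' ease_p(5, 10, 10, 100)
#' @export
ease_p <- function(k_on_unit, n_list, K_unit, N_universe) {
  if (k_on_unit > min(n_list, K_unit) || n_list > N_universe ||
      K_unit > N_universe || min(k_on_unit, n_list, K_unit) < 0) {
    stop_invalid("inconsistent 2x2 counts (k=%d, n=%d, K=%d, N=%d)",
                 k_on_unit, n_list, K_unit, N_universe)
  }
  fisher <- hyper_upper_tail(k_on_unit, n_list, K_unit, N_universe)
  ease <- hyper_upper_tail(max(k_on_unit - 1L, 0L), n_list, K_unit, N_universe)
  list(ease_p = ease, fisher_p = fisher)
}

# P(X >= k) for X ~ Hypergeometric(N, K, n); k = 0 gives 1.
hyper_upper_tail <- function(k, n_list, K_unit, N_universe) {
  if (k <= 0) return(1)
  stats::phyper(k - 1, K_unit, N_universe - K_unit, n_list,
                lower.tail = FALSE)
}

#' Scan chromosomes or cytobands for clustering of regulated genes
#'
#' Tests every chromosome (or cytoband) for over-representation of up-
#' and of down-regulated genes with the EASE score, against the supplied
#' genome map as background.  Units with EASE p below `alpha` are
#' returned, sorted by p.  At chromosome level, a reporting filter
#' suppresses chromosomes unless their combined up + down regulated count
#' exceeds `min_total` (default 20), mirroring how such imbalance tables
#' are usually restricted to substantially affected chromosomes.
#'
#' @param regulated a [regulated_set()]; all member genes must exist in
#'   the map.
#' @param map a [genome_map()] defining units and the background.
#' @param unit `"chromosome"` or `"cytoband"`.
#' @param alpha EASE-p cutoff for reporting (default 0.01).
#' @param min_total chromosome-level reporting threshold on up + down
#'   counts (default 20; not applied at cytoband level).
#' @return data.frame with columns `unit`, `unit_name`, `direction`,
#'   `k_on_unit`, `n_list`, `K_unit`, `N_universe`, `ease_p`, `fisher_p`,
#'   sorted by `ease_p`.
#' @export
cluster_scan <- function(regulated, map, unit = c("cytoband", "chromosome"),
                         alpha = 0.01, min_total = 20) {
  unit <- match.arg(unit)
  stopifnot(inherits(regulated, "regulated_set"), inherits(map, "genome_map"))
  genes <- map$genes
  missing <- setdiff(c(regulated$up, regulated$down), genes$gene_id)
  if (length(missing)) {
    stop_invalid("regulated gene(s) absent from map: %s",
                 paste(utils::head(missing, 5), collapse = ", "))
  }
  key <- if (unit == "chromosome") genes$chrom else genes$band
  units <- unique(key)
  N <- nrow(genes)
  K <- table(factor(key, levels = units))

  rows <- list()
  for (dir in c("up", "down")) {
    ids <- regulated[[dir]]
    n_list <- length(ids)
    if (n_list == 0L) next
    k <- table(factor(key[genes$gene_id %in% ids], levels = units))
    for (u in units) {
      if (k[[u]] == 0L) next
      pp <- ease_p(k[[u]], n_list, K[[u]], N)
      rows[[length(rows) + 1L]] <- data.frame(
        unit = unit, unit_name = u, direction = dir,
        k_on_unit = k[[u]], n_list = n_list, K_unit = K[[u]],
        N_universe = N, ease_p = pp$ease_p, fisher_p = pp$fisher_p)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit = character(), unit_name = character(),
               direction = character(), k_on_unit = integer(),
               n_list = integer(), K_unit = integer(), N_universe = integer(),
               ease_p = numeric(), fisher_p = numeric())
  out <- out[out$ease_p < alpha, , drop = FALSE]
  if (unit == "chromosome" && nrow(out) > 0L) {
    up_ids <- regulated$up
    down_ids <- regulated$down
    tot <- vapply(out$unit_name, function(u) {
      sum(genes$gene_id[key == u] %in% c(up_ids, down_ids))
    }, 0L)
    out <- out[tot > min_total, , drop = FALSE]
  }
  out <- out[order(out$ease_p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
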