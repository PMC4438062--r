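#' Coincidence of expression changes with same-direction CN changes
#'
#' Counts regulated genes lying in regions whose copy number changed in
#' the same direction (up-regulated genes in gain-change regions, or
#' down-regulated genes in loss-change regions) and compares the count
#' with the expectation under a random genomic distribution of the
#' regulated genes: `expected = n_regulated * K / N`, where K genes of
#' the N-gene universe sit in the matching CN-change class.  The
#' observed/expected ratio measures how much of the expression change is
#' explained by copy number.  With no CN changes of the matching class
#' (expected and observed both 0) the ratio is reported as 1 by
#' convention.
#'
#' A per-cytoband breakdown flags hotspot bands, defined as bands with at
#' least 2 coincident genes and a band-level ratio of at least 2.
#'
#' @param regulated a [regulated_set()] over the map's gene universe.
#' @param delta a [cn_delta()] over the same universe.
#' @param map the [genome_map()] defining the universe and bands.
#' @param direction `"up"` (matched with gain-change) or `"down"`
#'   (matched with loss-change).
#' @return A `coincidence_result`: list with `direction`, `cn_class`,
#'   `observed`, `expected`, `ratio`, `n_regulated`, `n_class`,
#'   `universe_n` and `bands` (data.frame `band`, `observed`, `expected`,
#'   `ratio`, `hotspot`).
#' @export
coincidence <- function(regulated, delta, map,
                        direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(regulated, "regulated_set"), inherits(delta, "cn_delta"),
            inherits(map, "genome_map"))
  genes <- map$genes
  N <- nrow(genes)
  if (regulated$universe_n != N || nrow(delta$per_gene) != N ||
      !identical(delta$per_gene$gene_id, genes$gene_id)) {
    stop_invalid("regulated set, CN delta and map must share the universe")
  }
  cn_class <- if (direction == "up") "gain-change" else "loss-change"
  in_class <- delta$per_gene$delta == cn_class
  reg_ids <- regulated[[direction]]
  is_reg <- genes$gene_id %in% reg_ids
  observed <- sum(is_reg & in_class)
  K <- sum(in_class)
  expected <- length(reg_ids) * K / N
  ratio <- if (expected == 0) {
    if (observed > 0) Inf else 1
  } else {
    observed / expected
  }

  band_obs <- tapply(is_reg & in_class, genes$band, sum)
  band_K <- tapply(in_class, genes$band, sum)
  bands <- data.frame(band = names(band_obs),
                      observed = as.integer(band_obs),
                      expected = length(reg_ids) * as.numeric(band_K) / N)
  bands <- bands[bands$observed > 0, , drop = FALSE]
  bands$ratio <- ifelse(bands$expected == 0, Inf,
                        bands$observed / bands$expected)
  bands$hotspot <- bands$observed >= 2 & bands$ratio >= 2
  bands <- bands[order(-bands$observed), , drop = FALSE]
  rownames(bands) <- NULL

  structure(list(direction = direction, cn_class = cn_class,
                 observed = observed, expected = expected, ratio = ratio,
                 n_regulated = length(reg_ids), n_class = K,
                 universe_n = N, bands = bands),
            class = "coincidence_result")
}

#' @export
print.coincidence_result <- function(x, ...) {
  cat(sprintf(
    "coincidence (%s vs %s): observed %d, expected %.2f, ratio %.2f (%d hotspot band(s))\n",
    x$direction, x$cn_class, x$observed, x$expected, x$ratio,
    sum(x$bands$hotspot)))
  invisible(x)
}

#' Permutation significance for a coincidence ratio
#'
#' Resamples the regulated gene labels uniformly from the universe
#' `n_perm` times and reports the one-sided empirical p value
#' `(1 + #(permuted observed >= real observed)) / (n_perm + 1)` for the
#' observed coincidence count.
#'
#' @inheritParams coincidence
#' @param n_perm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @return List with `observed`, `expected`, `ratio`, `p` and
#'   `perm_mean` (mean permuted observed count).
#' @export
coincidence_permutation_p <- function(regulated, delta, map,
                                      direction = c("up", "down"),
                                      n_perm = 1000, seed = 1) {
  direction <- match.arg(direction)
  if (n_perm < 100) stop_invalid("`n_perm` must be >= 100")
  real <- coincidence(regulated, delta, map, direction)
  n_reg <- real$n_regulated
  cn_class <- real$cn_class
  in_class <- delta$per_gene$delta == cn_class
  N <- real$universe_n
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sum(in_class[sample.int(N, n_reg)])
    }, 0L)
  })
  p <- (1 + sum(perm >= real$observed)) / (n_perm + 1)
  list(observed = real$observed, expected = real$expected,
       ratio = real$ratio, p = p, perm_mean = mean(perm))
}
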