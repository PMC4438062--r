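#' Log2 expression matrix with sample metadata
#'
#' Container for a gene-level log2 intensity matrix together with its
#' sample sheet.  Values must be finite; gene and sample ids unique;
#' every sample must carry cell line, passage class and replicate.
#'
#' @param values numeric matrix, genes x samples, with dimnames.
#' @param samples data.frame with columns `sample`, `cell_line`,
#'   `passage`, `replicate`; rows match the matrix columns.
#' @return An object of class `expression_matrix` (list with `values`,
#'   `samples`).
#' @export
expression_matrix <- function(values, samples) {
  values <- as.matrix(values)
  samples <- as.data.frame(samples)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_invalid("expression values need gene and sample dimnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop_invalid("duplicated gene id(s): %s",
                 paste(unique(rownames(values)[duplicated(rownames(values))]),
                       collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) stop_invalid("duplicated sample id(s)")
  if (!all(is.finite(values))) stop_invalid("expression values must be finite")
  need <- c("sample", "cell_line", "passage", "replicate")
  if (!all(need %in% names(samples))) {
    stop_invalid("sample sheet must have columns: %s", paste(need, collapse = ", "))
  }
  if (!setequal(samples$sample, colnames(values)) ||
      nrow(samples) != ncol(values)) {
    stop_invalid("sample sheet does not match matrix columns")
  }
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  if (anyNA(samples[need])) stop_invalid("incomplete sample metadata")
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d cell line(s))\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$cell_line))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Select sample ids by cell line and passage class
#'
#' @param expr an [expression_matrix()].
#' @param cell_line,passage selectors; `"*"` matches anything.
#' @return Character vector of matching sample ids.
#' @export
samples_for <- function(expr, cell_line = "*", passage = "*") {
  s <- expr$samples
  s$sample[match_field(s$cell_line, cell_line) & match_field(s$passage, passage)]
}

#' Two-group differential expression by pooled-variance t test
#'
#' For each gene computes the log2 fold change (mean of group B minus
#' mean of group A) and the two-sided p value of the ordinary
#' pooled-variance two-sample Student t test, then Benjamini-Hochberg q
#' values across genes.  Genes with zero variance in both groups and
#' equal means get p = 1 and fold 0; zero-variance genes with unequal
#' means get p = 0 (the limit of the statistic).
#'
#' @param expr an [expression_matrix()].
#' @param group_a,group_b character vectors of sample ids; disjoint, each
#'   of size >= 2.  Group A is the reference (denominator) group, so a
#'   "late versus early" contrast takes `group_a` = early samples.
#' @return A `contrast_table`: data.frame with columns `gene_id`,
#'   `log2fc`, `t`, `p`, `q` and attributes `n_a`, `n_b`.
#' @examples
#' # for one gene with A = (1,2,3), B = (4,5,6): log2fc 3, t 3.674, p 0.021
#' @export
contrast <- function(expr, group_a, group_b) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (length(intersect(group_a, group_b)) > 0L) {
    stop_invalid("groups must be disjoint")
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_invalid("each group needs >= 2 samples")
  }
  missing <- setdiff(c(group_a, group_b), colnames(expr$values))
  if (length(missing)) {
    stop_invalid("unknown sample(s): %s", paste(missing, collapse = ", "))
  }
  A <- expr$values[, group_a, drop = FALSE]
  B <- expr$values[, group_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, stats::var); vb <- apply(B, 1, stats::var)
  df <- na + nb - 2L
  sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  lfc <- mb - ma
  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df)
  flat <- se == 0 & lfc == 0        # no variance, no difference
  degen <- se == 0 & lfc != 0       # no variance, real difference
  lfc[flat] <- 0
  p[flat] <- 1
  p[degen] <- 0
  tstat[flat] <- 0
  out <- data.frame(gene_id = rownames(expr$values), log2fc = lfc,
                    t = tstat, p = p, q = bh_fdr(p),
                    row.names = NULL)
  structure(out, class = c("contrast_table", "data.frame"),
            n_a = na, n_b = nb)
}

#' Benjamini-Hochberg step-up q values
#'
#' Standard BH step-up adjustment: in sorted order,
#' `q(i) = min over j >= i of p(j) * m / j`, capped at 1, with the
#' original order restored.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return Numeric vector of q values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_invalid("p values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Regulated gene sets at fold and significance thresholds
#'
#' Splits a contrast into up- and down-regulated gene sets using strict
#' inequalities: up means `log2fc > log2(fold_threshold)` and the chosen
#' statistic (raw p or BH q) `< alpha`; down is symmetric.  Genes at
#' exactly the fold threshold are excluded (the criterion is ">2-fold",
#' not ">=").
#'
#' @param table a `contrast_table` from [contrast()].
#' @param fold_threshold linear fold-change threshold (>= 1; default 2).
#' @param alpha significance level (default 0.05).
#' @param criterion `"p"` for raw p values or `"fdr"` for BH q values.
#' @param universe_n universe size; defaults to the number of genes in
#'   the table.
#' @return A `regulated_set`: list with `up`, `down` (character vectors),
#'   `universe_n` and the thresholds used.
#' @export
regulated_set <- function(table, fold_threshold = 2, alpha = 0.05,
                          criterion = c("p", "fdr"), universe_n = NULL) {
  criterion <- match.arg(criterion)
  if (fold_threshold < 1) stop_invalid("`fold_threshold` must be >= 1")
  stat <- if (criterion == "p") table$p else table$q
  cut <- log2(fold_threshold)
  sig <- stat < alpha
  up <- table$gene_id[table$log2fc > cut & sig]
  down <- table$gene_id[table$log2fc < -cut & sig]
  structure(list(up = up, down = down,
                 universe_n = universe_n %||% nrow(table),
                 fold_threshold = fold_threshold, alpha = alpha,
                 criterion = criterion),
            class = "regulated_set")
}

#' @export
print.regulated_set <- function(x, ...) {
  cat(sprintf("regulated_set: %d up, %d down of %d genes (>%g-fold, %s < %g)\n",
              length(x$up), length(x$down), x$universe_n, x$fold_threshold,
              x$criterion, x$alpha))
  invisible(x)
}

#' Population doublings implied by a passage interval
#'
#' A culture split 1:k and regrown to confluence undergoes about log2(k)
#' population doublings, so `delta_passages` splits at ratio 1:k give
#' `delta_passages * log2(k)` doublings (log2(20) = 4.32, log2(200) =
#' 7.64 doublings per passage).
#'
#' @param delta_passages number of passages between the compared samples
#'   (>= 0).
#' @param split_ratio the k of a 1:k split (integer > 1).
#' @return Doublings (numeric).
#' @examples
#' doublings_from_passages(1, 20)   # 4.32
#' doublings_from_passages(1, 200)  # 7.64
#' @export
doublings_from_passages <- function(delta_passages, split_ratio) {
  if (any(delta_passages < 0)) stop_invalid("`delta_passages` must be >= 0")
  if (any(split_ratio < 2)) stop_invalid("`split_ratio` must be >= 2")
  delta_passages * log2(split_ratio)
}

#' Regulated genes per population doubling
#'
#' Normalises a regulated-gene count to the number of population
#' doublings separating the compared passages, making instability
#' comparable across cell lines cultured under different split ratios.
#'
#' @param n_regulated regulated-gene count (>= 0).
#' @param doublings population doublings (> 0).
#' @return Genes per doubling (numeric).
#' @export
genes_per_doubling <- function(n_regulated, doublings) {
  if (any(doublings <= 0)) stop_invalid("`doublings` must be > 0")
  n_regulated / doublings
}
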