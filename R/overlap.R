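#' Overlap enrichment of common regulated genes
#'
#' Compares the number of genes regulated in the same direction in two
#' cell lines with the expectation under independent random selection
#' from a shared universe: if the two lines regulate fractions a and b
#' of the universe independently, the expected common fraction is a*b.
#' Fold enrichment is observed over expected.
#'
#' Two conventions are reported.  The raw fold uses unrounded counts
#' (`n_common * N / (n_a * n_b)`).  The printed-style fold mimics how
#' such results are usually typeset: marginal percents are rounded to 2
#' decimals, their product (the expected percent) to 2 significant
#' digits, the observed percent to 2 decimals, and the fold is the
#' ratio of the rounded values, to 1 decimal (0.94/0.18 = 5.2, not
#' 5.12).
#'
#' @param n_common genes regulated (same direction) in both lines.
#' @param n_a,n_b genes regulated in each line.
#' @param universe_n shared universe size.
#' @param direction `"up"` or `"down"` (annotation only).
#' @return An `overlap_result`: list with `n_common`, `observed_pct`,
#'   `expected_pct`, `fold` (raw), and `observed_pct_printed`,
#'   `expected_pct_printed`, `fold_printed` (printed-style), plus the
#'   inputs.  An expected of 0 with observed > 0 yields `fold = Inf`.
#' @examples
#' overlap_from_counts(201, 810, 1035, 21339)$fold_printed  # 5.2
#' @export
overlap_from_counts <- function(n_common, n_a, n_b, universe_n,
                                direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (universe_n < 1) stop_invalid("`universe_n` must be >= 1")
  if (n_common > min(n_a, n_b)) {
    stop_invalid("overlap (%d) exceeds a marginal set size", n_common)
  }
  obs <- 100 * n_common / universe_n
  exp_pct <- (100 * n_a / universe_n) * (100 * n_b / universe_n) / 100
  fold <- if (exp_pct == 0) {
    if (obs > 0) Inf else 1
  } else {
    obs / exp_pct
  }
  obs_p <- round(obs, 2)
  exp_p <- signif2(round(100 * n_a / universe_n, 2) *
                     round(100 * n_b / universe_n, 2) / 100, 2)
  fold_p <- if (exp_p == 0) {
    if (obs_p > 0) Inf else 1
  } else {
    round(obs_p / exp_p, 1)
  }
  structure(list(direction = direction, n_common = n_common,
                 n_a = n_a, n_b = n_b, universe_n = universe_n,
                 observed_pct = obs, expected_pct = exp_pct, fold = fold,
                 observed_pct_printed = obs_p, expected_pct_printed = exp_p,
                 fold_printed = fold_p),
            class = "overlap_result")
}

#' Common regulated genes between two cell lines
#'
#' Intersects the up (or down) gene lists of two [regulated_set()]s over
#' a shared universe and quantifies the enrichment of the overlap against
#' independent selection; see [overlap_from_counts()] for the statistics.
#'
#' @param set_a,set_b [regulated_set()]s over the same universe.
#' @param universe_n shared universe size; must equal both sets' recorded
#'   universe sizes.
#' @param direction `"up"` or `"down"`.
#' @return An `overlap_result` with an extra `genes` element (the common
#'   gene ids).
#' @export
common_regulated <- function(set_a, set_b, universe_n,
                             direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(set_a, "regulated_set"), inherits(set_b, "regulated_set"))
  if (set_a$universe_n != universe_n || set_b$universe_n != universe_n) {
    stop_invalid("universe size mismatch: sets record %d and %d, got %d",
                 set_a$universe_n, set_b$universe_n, universe_n)
  }
  a <- set_a[[direction]]
  b <- set_b[[direction]]
  common <- intersect(a, b)
  out <- overlap_from_counts(length(common), length(a), length(b),
                             universe_n, direction)
  out$genes <- common
  out
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap_result (%s): %d common of %d/%d in N=%d\n  observed %.3f%%, expected %.4f%%, fold %.2f (printed-style %.2f/%.3g -> %.1f)\n",
    x$direction, x$n_common, x$n_a, x$n_b, x$universe_n,
    x$observed_pct, x$expected_pct, x$fold,
    x$observed_pct_printed, x$expected_pct_printed, x$fold_printed))
  invisible(x)
}
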