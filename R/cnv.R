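#' Copy-number profile for one condition
#'
#' Holds the gain/loss/LOH segments called for one condition (cell line
#' at one passage class) against a reference [genome_map()].  Segments
#' use 0-based half-open coordinates.  Within a condition, segments of
#' the same state must not overlap, and gain and loss segments must not
#' overlap each other (conflicting calls); LOH is copy-neutral
#' information and may overlap either.
#'
#' @param condition condition label, e.g. `"SAOS_early"`.
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `state` (`"gain"`, `"loss"`, `"LOH"`), `n_probes`, and optional
#'   logical `recurrent` (known recurrent aberration; default FALSE).
#' @param map a [genome_map()].
#' @return An object of class `cn_profile`.
#' @export
cn_profile <- function(condition, segments, map) {
  stopifnot(inherits(map, "genome_map"))
  segments <- as.data.frame(segments)
  if (is.null(segments$recurrent)) segments$recurrent <- FALSE
  if (nrow(segments) > 0L) {
    if (!all(segments$state %in% c("gain", "loss", "LOH"))) {
      stop_invalid("segment state must be gain, loss or LOH")
    }
    if (any(segments$end <= segments$start)) stop_invalid("segment end must exceed start")
    if (any(segments$n_probes < 1)) stop_invalid("segments need >= 1 probe")
    len <- stats::setNames(map$chromosomes$length, map$chromosomes$chrom)
    bad <- !(segments$chrom %in% names(len)) |
      segments$start < 0 | segments$end > len[segments$chrom]
    if (any(bad)) stop_invalid("segment(s) outside chromosome bounds")
    for (cc in unique(segments$chrom)) {
      s <- segments[segments$chrom == cc, , drop = FALSE]
      for (st in c("gain", "loss", "LOH")) {
        ss <- s[s$state == st, , drop = FALSE]
        if (nrow(ss) > 1L && has_overlap(ss)) {
          stop_invalid("overlapping %s segments on %s", st, cc)
        }
      }
      g <- s[s$state == "gain", , drop = FALSE]
      l <- s[s$state == "loss", , drop = FALSE]
      if (nrow(g) > 0L && nrow(l) > 0L &&
          any(IRanges::countOverlaps(seg_ranges(g), seg_ranges(l)) > 0L)) {
        stop_invalid("conflicting gain/loss overlap on %s", cc)
      }
    }
  }
  rownames(segments) <- NULL
  structure(list(condition = condition, segments = segments, map = map),
            class = "cn_profile")
}

#' An empty (all-neutral) copy-number profile
#'
#' Convenience constructor for a condition with no called segments.
#'
#' @param condition condition label.
#' @param map a [genome_map()].
#' @return A [cn_profile()] with zero segments.
#' @export
empty_cn_profile <- function(condition, map) {
  cn_profile(condition, data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    state = character(), n_probes = numeric(), recurrent = logical()), map)
}

seg_ranges <- function(seg) {
  # 0-based half-open [start, end) -> IRanges closed [start+1, end]
  IRanges::IRanges(start = seg$start + 1L, end = seg$end)
}

has_overlap <- function(seg) {
  r <- seg_ranges(seg)
  any(IRanges::countOverlaps(r, r) > 1L)
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("cn_profile '%s': %d segment(s) (%d gain, %d loss, %d LOH)\n",
              x$condition, nrow(x$segments),
              sum(x$segments$state == "gain"), sum(x$segments$state == "loss"),
              sum(x$segments$state == "LOH")))
  invisible(x)
}

#' Filter copy-number segments by size, probe support and CNV overlap
#'
#' Applies the usual aCGH reporting filters: gain/loss segments are
#' dropped when shorter than `min_size_bp` or supported by fewer than
#' `min_probes` probes; LOH segments are dropped when shorter than
#' `min_loh_bp`; segments overlapping any interval of `cnv_exclusion`
#' (e.g. known germline copy-number variants) are dropped.  Segments
#' flagged as known recurrent aberrations are always retained regardless
#' of the other rules.  The operation is idempotent.
#'
#' @param profile a [cn_profile()].
#' @param min_size_bp minimum gain/loss segment length (default 100 kb).
#' @param min_probes minimum probe support for gain/loss (default 50).
#' @param min_loh_bp minimum LOH length (default 3 Mb).
#' @param cnv_exclusion NULL or data.frame with `chrom`, `start`, `end`
#'   (0-based half-open) of intervals to exclude.
#' @return The filtered [cn_profile()].
#' @export
filter_segments <- function(profile, min_size_bp = 1e5, min_probes = 50,
                            min_loh_bp = 3e6, cnv_exclusion = NULL) {
  stopifnot(inherits(profile, "cn_profile"))
  if (min_size_bp <= 0 || min_probes <= 0 || min_loh_bp <= 0) {
    stop_invalid("filter thresholds must be positive")
  }
  seg <- profile$segments
  if (nrow(seg) == 0L) return(profile)
  len <- seg$end - seg$start
  drop <- ifelse(seg$state == "LOH",
                 len < min_loh_bp,
                 len < min_size_bp | seg$n_probes < min_probes)
  if (!is.null(cnv_exclusion) && nrow(cnv_exclusion) > 0L) {
    for (cc in unique(seg$chrom)) {
      ex <- cnv_exclusion[cnv_exclusion$chrom == cc, , drop = FALSE]
      if (nrow(ex) == 0L) next
      i <- which(seg$chrom == cc)
      hits <- IRanges::countOverlaps(seg_ranges(seg[i, , drop = FALSE]),
                                     seg_ranges(ex)) > 0L
      drop[i] <- drop[i] | hits
    }
  }
  drop <- drop & !seg$recurrent
  cn_profile(profile$condition, seg[!drop, , drop = FALSE], profile$map)
}

#' Call macro-aberrations (whole-cytoband gains and losses)
#'
#' A macro-aberration is the gain or loss of at least one entire
#' cytoband.  A (band, state) pair is emitted iff the union of that
#' state's segments covers the band's full interval; adjacent segments
#' jointly covering a band count, a segment covering 99% of it does not.
#'
#' @param profile a (filtered) [cn_profile()].
#' @return data.frame with columns `chrom`, `band`, `state`.
#' @export
macro_aberrations <- function(profile) {
  stopifnot(inherits(profile, "cn_profile"))
  bands <- profile$map$cytobands
  out <- list()
  for (st in c("gain", "loss")) {
    seg <- profile$segments[profile$segments$state == st, , drop = FALSE]
    if (nrow(seg) == 0L) next
    for (cc in unique(seg$chrom)) {
      covered <- IRanges::reduce(seg_ranges(seg[seg$chrom == cc, , drop = FALSE]))
      b <- bands[bands$chrom == cc, , drop = FALSE]
      if (nrow(b) == 0L) next
      br <- seg_ranges(b)
      cov_w <- sum_overlap_width(br, covered)
      full <- cov_w == IRanges::width(br)
      if (any(full)) {
        out[[length(out) + 1L]] <-
          data.frame(chrom = cc, band = b$band[full], state = st)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), band = character(),
                      state = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, profile$map$chromosomes$chrom),
                   match(res$band, bands$band)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# For each query range, total width of its intersection with `subject`.
sum_overlap_width <- function(query, subject) {
  hits <- IRanges::findOverlaps(query, subject)
  w <- IRanges::width(IRanges::pintersect(
    query[S4Vectors::queryHits(hits)], subject[S4Vectors::subjectHits(hits)]))
  out <- numeric(length(query))
  if (length(w)) {
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}

# Majority-overlap gain/loss state per gene for a segment table.
majority_state <- function(genes, seg) {
  state <- rep("neutral", nrow(genes))
  glen <- genes$end - genes$start
  for (st in c("gain", "loss")) {
    ss <- seg[seg$state == st, , drop = FALSE]
    if (nrow(ss) == 0L) next
    ov <- numeric(nrow(genes))
    for (cc in unique(ss$chrom)) {
      i <- which(genes$chrom == cc)
      if (length(i) == 0L) next
      gr <- IRanges::IRanges(genes$start[i] + 1L, genes$end[i])
      ov[i] <- sum_overlap_width(gr, IRanges::reduce(
        seg_ranges(ss[ss$chrom == cc, , drop = FALSE])))
    }
    state[ov > glen / 2] <- st   # gain/loss never overlap, at most one wins
  }
  state
}

#' Per-gene copy-number status
#'
#' Assigns each gene of the universe the state of the segment class
#' (gain or loss) covering the majority (> 50%) of its span, `neutral`
#' otherwise.  LOH is tracked in a separate logical column with the same
#' majority rule and never overrides a gain/loss call.
#'
#' @param profile a (filtered) [cn_profile()].
#' @param map a [genome_map()]; defaults to the profile's map.
#' @return A `gene_cn_status`: data.frame with columns `gene_id`, `state`
#'   (`gain`/`loss`/`neutral`) and `loh` (logical), one row per universe
#'   gene, with the condition label as attribute.
#' @export
gene_cn_status <- function(profile, map = profile$map) {
  stopifnot(inherits(profile, "cn_profile"), inherits(map, "genome_map"))
  genes <- map$genes
  seg <- profile$segments
  state <- majority_state(genes, seg)
  loh_seg <- seg[seg$state == "LOH", , drop = FALSE]
  if (nrow(loh_seg) > 0L) loh_seg$state <- "gain"  # reuse the majority machinery
  loh <- majority_state(genes, loh_seg) == "gain"
  structure(data.frame(gene_id = genes$gene_id, state = state, loh = loh),
            class = c("gene_cn_status", "data.frame"),
            condition = profile$condition)
}

#' Fraction of the gene universe with aberrant copy number
#'
#' @param status a [gene_cn_status()].
#' @return Named numeric: `gain_pct`, `loss_pct`, `total_pct` (percent of
#'   universe genes; total = gain + loss).
#' @export
aberrant_fraction <- function(status) {
  stopifnot(inherits(status, "gene_cn_status"))
  n <- nrow(status)
  gain <- 100 * sum(status$state == "gain") / n
  loss <- 100 * sum(status$state == "loss") / n
  c(gain_pct = gain, loss_pct = loss, total_pct = gain + loss)
}

#' Per-gene copy-number change between two conditions
#'
#' Orders states as loss < neutral < gain and classifies each gene as a
#' `gain-change` (state increased from A to B), `loss-change` (state
#' decreased) or `none`.
#'
#' @param status_a,status_b [gene_cn_status()] objects over the same
#'   universe (e.g. early and late passage of one line).
#' @return A `cn_delta` object: list with `per_gene` (data.frame
#'   `gene_id`, `delta`) and `summary` (named numeric `gain_pct`,
#'   `loss_pct`, `total_pct`).
#' @export
cn_delta <- function(status_a, status_b) {
  stopifnot(inherits(status_a, "gene_cn_status"),
            inherits(status_b, "gene_cn_status"))
  if (!identical(status_a$gene_id, status_b$gene_id)) {
    stop_invalid("copy-number status universes differ")
  }
  ord <- c(loss = -1L, neutral = 0L, gain = 1L)
  d <- ord[status_b$state] - ord[status_a$state]
  delta <- ifelse(d > 0L, "gain-change", ifelse(d < 0L, "loss-change", "none"))
  n <- length(delta)
  gain <- 100 * sum(delta == "gain-change") / n
  loss <- 100 * sum(delta == "loss-change") / n
  structure(list(per_gene = data.frame(gene_id = status_a$gene_id,
                                       delta = unname(delta)),
                 summary = c(gain_pct = gain, loss_pct = loss,
                             total_pct = gain + loss)),
            class = "cn_delta")
}

#' @export
print.cn_delta <- function(x, ...) {
  cat(sprintf("cn_delta: %.1f%% gain-change, %.1f%% loss-change (%.1f%% total)\n",
              x$summary[["gain_pct"]], x$summary[["loss_pct"]],
              x$summary[["total_pct"]]))
  invisible(x)
}
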