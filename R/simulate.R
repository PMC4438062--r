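#' Study design for a passage experiment
#'
#' Describes the cell-line systems (parental/metastatic pairs), the two
#' passage classes (early/late) and the number of replicate cultures per
#' condition, mirroring a triplicate early/late microarray design.
#'
#' @param systems a data.frame with columns `parental`, `metastatic`, or a
#'   list of named character vectors `c(parental = ..., metastatic = ...)`.
#' @param replicates replicate samples per condition (>= 2; default 3).
#' @return An object of class `design_spec` with elements `systems`
#'   (data.frame), `passages` (`c("early", "late")`), `replicates`, and
#'   `samples`: the full sample sheet (sample, cell_line, passage,
#'   replicate).
#' @examples
#' design_spec(data.frame(parental = "SAOS", metastatic = "LM5"))
#' @export
design_spec <- function(systems, replicates = 3L) {
  if (is.list(systems) && !is.data.frame(systems)) {
    systems <- do.call(rbind, lapply(systems, function(s) {
      data.frame(parental = s[["parental"]], metastatic = s[["metastatic"]])
    }))
  }
  systems <- as.data.frame(systems)
  stopifnot(all(c("parental", "metastatic") %in% names(systems)))
  if (replicates < 2L) stop_invalid("`replicates` must be >= 2")
  lines <- unique(c(rbind(systems$parental, systems$metastatic)))
  if (any(grepl("_", lines))) {
    stop_invalid("cell line names must not contain '_' (used as a label separator)")
  }
  passages <- c("early", "late")
  samples <- expand.grid(replicate = seq_len(replicates), passage = passages,
                         cell_line = lines, stringsAsFactors = FALSE)
  samples <- samples[, c("cell_line", "passage", "replicate")]
  samples$sample <- paste(samples$cell_line, samples$passage,
                          samples$replicate, sep = "_")
  samples <- samples[, c("sample", "cell_line", "passage", "replicate")]
  structure(list(systems = systems, passages = passages,
                 replicates = as.integer(replicates), samples = samples),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("design_spec: %d system(s), %d replicates/condition, %d samples\n",
              nrow(x$systems), x$replicates, nrow(x$samples)))
  invisible(x)
}

condition_label <- function(line, passage) paste(line, passage, sep = "_")

split_condition <- function(cond) {
  parts <- strsplit(cond, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop_invalid("malformed condition label: %s", cond[bad][1])
  list(line = vapply(parts, `[[`, "", 1L),
       passage = vapply(parts, `[[`, "", 2L))
}

empty_de_truth <- function() {
  data.frame(gene_id = character(), cell_line = character(),
             passage = character(), log2fc = numeric(), source = character(),
             stringsAsFactors = FALSE)
}

#' Simulate a log2 expression experiment with known ground truth
#'
#' Draws a baseline log2 intensity per gene (normal, mean 8, sd 2), adds
#' i.i.d. normal replicate noise, and injects the requested additive log2
#' effects into the samples of the conditions they target.  Effects are
#' specified per gene with cell-line and passage selectors; `"*"` matches
#' every line or passage, so a "passage effect" targets
#' `(cell_line = "*", passage = "late")` and a "metastatic effect" targets
#' `(cell_line = <metastatic line>, passage = "*")`.
#'
#' @param map a [genome_map()].
#' @param design a [design_spec()].
#' @param de_spec NULL or data.frame with columns `gene_id`, `cell_line`,
#'   `passage`, `log2fc` (selectors may be `"*"`).
#' @param cluster_spec NULL or data.frame with columns `band`, `n`,
#'   `direction` (`"up"`/`"down"`) and optionally `cell_line`, `passage`
#'   (default `"*"`/`"late"`) and `log2fc` magnitude (default 2): injects
#'   `n` same-direction effects on genes of one cytoband, to plant
#'   positional clusters.
#' @param noise_sd replicate noise standard deviation in log2 units (> 0).
#' @param seed integer RNG seed.
#' @return A list with `expr` (an [expression_matrix()]) and `truth`: a
#'   `truth_record` whose `de` data.frame lists every injected effect
#'   (gene, selectors, log2fc, source `"de"` or `"cluster"`).
#' @export
generate_expression <- function(map, design, de_spec = NULL,
                                cluster_spec = NULL, noise_sd = 0.25,
                                seed = 1) {
  stopifnot(inherits(map, "genome_map"), inherits(design, "design_spec"))
  if (noise_sd <= 0) stop_invalid("`noise_sd` must be > 0")
  genes <- map$genes
  samples <- design$samples

  de <- empty_de_truth()
  if (!is.null(de_spec) && nrow(de_spec) > 0L) {
    de_spec <- as.data.frame(de_spec)
    unknown <- setdiff(de_spec$gene_id, genes$gene_id)
    if (length(unknown)) {
      stop_invalid("de_spec names unknown gene(s): %s",
                   paste(utils::head(unknown, 5), collapse = ", "))
    }
    de <- rbind(de, data.frame(gene_id = de_spec$gene_id,
                               cell_line = de_spec$cell_line,
                               passage = de_spec$passage,
                               log2fc = de_spec$log2fc, source = "de"))
  }
  if (!is.null(cluster_spec) && nrow(cluster_spec) > 0L) {
    cluster_spec <- as.data.frame(cluster_spec)
    for (i in seq_len(nrow(cluster_spec))) {
      cs <- cluster_spec[i, ]
      on_band <- genes$gene_id[genes$band == cs$band]
      if (length(on_band) == 0L) stop_invalid("unknown cytoband: %s", cs$band)
      avail <- setdiff(on_band, de$gene_id)
      if (length(avail) < cs$n) {
        stop_invalid("cytoband %s holds only %d unused genes, %d requested",
                     cs$band, length(avail), cs$n)
      }
      eff <- if (is.null(cluster_spec$log2fc)) 2 else cs$log2fc
      sgn <- if (identical(cs$direction, "down")) -1 else 1
      de <- rbind(de, data.frame(
        gene_id = avail[seq_len(cs$n)],
        cell_line = if (is.null(cluster_spec$cell_line)) "*" else cs$cell_line,
        passage = if (is.null(cluster_spec$passage)) "late" else cs$passage,
        log2fc = sgn * abs(eff), source = "cluster"))
    }
  }

  expr <- with_seed(seed, {
    G <- nrow(genes); S <- nrow(samples)
    base <- stats::rnorm(G, mean = 8, sd = 2)
    vals <- matrix(base, G, S) + matrix(stats::rnorm(G * S, 0, noise_sd), G, S)
    dimnames(vals) <- list(genes$gene_id, samples$sample)
    vals
  })
  expr <- apply_effects(expr, samples, de)
  em <- expression_matrix(expr, samples)
  truth <- structure(list(de = de,
                          coupling = empty_coupling_truth()),
                     class = "truth_record")
  list(expr = em, truth = truth)
}

empty_coupling_truth <- function() {
  data.frame(gene_id = character(), condition = character(),
             state = character(), log2fc = numeric(), stringsAsFactors = FALSE)
}

# Add each truth row's log2 effect to the samples its selectors match.
apply_effects <- function(vals, samples, de) {
  if (nrow(de) == 0L) return(vals)
  for (i in seq_len(nrow(de))) {
    cols <- match_field(samples$cell_line, de$cell_line[i]) &
      match_field(samples$passage, de$passage[i])
    vals[de$gene_id[i], cols] <- vals[de$gene_id[i], cols] + de$log2fc[i]
  }
  vals
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("truth_record: %d injected expression effect(s), %d CN-coupled effect(s)\n",
              nrow(x$de), nrow(x$coupling)))
  invisible(x)
}

#' Simulate copy-number profiles coupled to expression
#'
#' Builds one filtered-input CN profile per condition from an event table
#' and, for genes lying (by majority of their span) inside a gain or loss
#' event, flips a coin with probability `couple_prob` to add a
#' same-direction expression shift of `couple_effect` log2 units
#' (positive in gains, negative in losses) to the samples of that
#' condition.  LOH events never couple to expression.  Sub-threshold
#' events (below the size/probe filters) may be injected deliberately to
#' exercise [filter_segments()].
#'
#' @param map a [genome_map()].
#' @param design a [design_spec()].
#' @param event_spec data.frame with columns `condition`
#'   (`"<line>_<passage>"`), `state` (`"gain"`, `"loss"`, `"LOH"`),
#'   `n_probes`, and either `band` (a cytoband name) or `chrom`, `start`,
#'   `end` (0-based half-open); optional `recurrent` flag.
#' @param couple_prob probability in `[0, 1]` that a gene in a gain/loss
#'   event receives the coupled expression shift.
#' @param couple_effect magnitude of the coupled shift in log2 units.
#' @param seed integer RNG seed (used for the coupling coin flips).
#' @param expr optionally, an [expression_matrix()] to which coupled
#'   shifts are applied.
#' @return A list with `profiles` (named list of [cn_profile()], one per
#'   design condition), `truth` (a `truth_record` whose `coupling`
#'   data.frame lists every coupled gene with its condition, state and
#'   shift), and `expr` (the shifted matrix, or NULL if none supplied).
#' @export
generate_cn_profiles <- function(map, design, event_spec,
                                 couple_prob = 0, couple_effect = 0,
                                 seed = 1, expr = NULL) {
  stopifnot(inherits(map, "genome_map"), inherits(design, "design_spec"))
  if (couple_prob < 0 || couple_prob > 1) stop_invalid("`couple_prob` must be in [0, 1]")
  event_spec <- as.data.frame(event_spec)
  if (nrow(event_spec) > 0 && !is.null(event_spec$band)) {
    need <- !is.na(event_spec$band)
    if (any(need)) {
      idx <- match(event_spec$band[need], map$cytobands$band)
      if (anyNA(idx)) {
        stop_invalid("unknown cytoband: %s",
                     event_spec$band[need][is.na(idx)][1])
      }
      event_spec$chrom[need] <- map$cytobands$chrom[idx]
      event_spec$start[need] <- map$cytobands$start[idx]
      event_spec$end[need] <- map$cytobands$end[idx]
    }
  }
  if (is.null(event_spec$recurrent)) event_spec$recurrent <- FALSE

  conds <- unique(condition_label(design$samples$cell_line,
                                  design$samples$passage))
  profiles <- stats::setNames(lapply(conds, function(cond) {
    ev <- event_spec[event_spec$condition == cond, , drop = FALSE]
    seg <- data.frame(chrom = as.character(ev$chrom), start = ev$start,
                      end = ev$end, state = ev$state,
                      n_probes = ev$n_probes, recurrent = ev$recurrent,
                      stringsAsFactors = FALSE)
    cn_profile(cond, seg, map)
  }), conds)
  orphan <- setdiff(event_spec$condition, conds)
  if (length(orphan)) {
    stop_invalid("event condition(s) not in design: %s",
                 paste(orphan, collapse = ", "))
  }

  coupling <- with_seed(seed, {
    out <- empty_coupling_truth()
    for (cond in conds) {
      seg <- profiles[[cond]]$segments
      seg <- seg[seg$state %in% c("gain", "loss"), , drop = FALSE]
      if (nrow(seg) == 0L) next
      st <- majority_state(map$genes, seg)
      hit <- which(st != "neutral")
      if (length(hit) == 0L) next
      flip <- stats::runif(length(hit)) < couple_prob
      hit <- hit[flip]
      if (length(hit) == 0L) next
      sgn <- ifelse(st[hit] == "gain", 1, -1)
      out <- rbind(out, data.frame(gene_id = map$genes$gene_id[hit],
                                   condition = cond, state = st[hit],
                                   log2fc = sgn * abs(couple_effect)))
    }
    out
  })

  if (!is.null(expr) && nrow(coupling) > 0L) {
    stopifnot(inherits(expr, "expression_matrix"))
    cond <- split_condition(coupling$condition)
    de_like <- data.frame(gene_id = coupling$gene_id, cell_line = cond$line,
                          passage = cond$passage, log2fc = coupling$log2fc)
    expr$values <- apply_effects(expr$values, expr$samples, de_like)
  }

  truth <- structure(list(de = empty_de_truth(), coupling = coupling),
                     class = "truth_record")
  list(profiles = profiles, truth = truth, expr = expr)
}
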