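#' Simulate a complete passage study
#'
#' Builds a genome map and a parental/metastatic early/late triplicate
#' experiment with a fixed ground-truth scenario: metastatic effects
#' present in both passage classes (the recoverable signal), passage
#' effects injected into late-passage samples of both lines (the
#' confounder the consistency filter must reject), a positional cluster
#' of passage-regulated genes on one cytoband, and whole-band
#' copy-number events in the late conditions with probabilistic coupling
#' to expression, plus one deliberately sub-threshold segment to
#' exercise the size/probe filters.  Scenario genes are chosen at
#' deterministic, evenly spaced universe indices so their identities do
#' not depend on the seed; the seed drives coordinates, noise and
#' coupling only.
#'
#' @param params list of scenario settings; any subset of:
#'   `n_chromosomes` (6), `genes_per_chromosome` (250),
#'   `bands_per_chromosome` (4), `chrom_length` (1e8), `parental`
#'   ("SAOS"), `metastatic` ("LM5"), `replicates` (3), `noise_sd`
#'   (0.25), `n_met` (30), `met_log2fc` (2), `n_passage` (40),
#'   `passage_log2fc` (2), `n_cluster` (12), `couple_prob` (0.8),
#'   `couple_effect` (1.5).
#' @param seed integer RNG seed.
#' @return List with `map`, `design`, `expr`, `profiles`, `truth`
#'   (merged `truth_record`) and `params` (the settings used).
#' @export
simulate_study <- function(params = list(), seed = 1) {
  p <- utils::modifyList(list(
    n_chromosomes = 6, genes_per_chromosome = 250,
    bands_per_chromosome = 4, chrom_length = 1e8,
    parental = "SAOS", metastatic = "LM5", replicates = 3,
    noise_sd = 0.25, n_met = 30, met_log2fc = 2,
    n_passage = 40, passage_log2fc = 2, n_cluster = 12,
    couple_prob = 0.8, couple_effect = 1.5), params)

  map <- generate_genome_map(p$n_chromosomes, p$genes_per_chromosome,
                             p$bands_per_chromosome, p$chrom_length,
                             seed = seed)
  design <- design_spec(data.frame(parental = p$parental,
                                   metastatic = p$metastatic),
                        replicates = p$replicates)
  G <- universe_size(map)
  ids <- map$genes$gene_id

  idx_met <- unique(round(seq(1, G, length.out = p$n_met)))
  idx_pass <- setdiff(unique(round(seq(2, G - 1,
                                       length.out = 2 * p$n_passage))),
                      idx_met)[seq_len(p$n_passage)]
  n_met_up <- ceiling(length(idx_met) * 2 / 3)
  n_pass_up <- ceiling(length(idx_pass) / 2)
  de_spec <- rbind(
    data.frame(gene_id = ids[idx_met], cell_line = p$metastatic,
               passage = "*",
               log2fc = rep(c(p$met_log2fc, -p$met_log2fc),
                            c(n_met_up, length(idx_met) - n_met_up))),
    data.frame(gene_id = ids[idx_pass], cell_line = "*", passage = "late",
               log2fc = rep(c(p$passage_log2fc, -p$passage_log2fc),
                            c(n_pass_up, length(idx_pass) - n_pass_up))))

  bands <- map$cytobands$band
  cluster_band <- bands[min(p$bands_per_chromosome + 1L, length(bands))]
  cluster_spec <- data.frame(band = cluster_band, n = p$n_cluster,
                             direction = "up", cell_line = "*",
                             passage = "late", log2fc = p$passage_log2fc)

  sim <- generate_expression(map, design, de_spec, cluster_spec,
                             noise_sd = p$noise_sd, seed = seed + 1)

  gain_band <- bands[min(2L * p$bands_per_chromosome + 1L, length(bands))]
  loss_band <- bands[min(2L * p$bands_per_chromosome + 2L, length(bands))]
  late_conds <- condition_label(c(p$parental, p$metastatic), "late")
  event_spec <- rbind(
    data.frame(condition = late_conds, band = gain_band, chrom = NA,
               start = NA, end = NA, state = "gain", n_probes = 500),
    data.frame(condition = late_conds, band = loss_band, chrom = NA,
               start = NA, end = NA, state = "loss", n_probes = 500),
    # sub-threshold noise segment: must be removed by filter_segments()
    data.frame(condition = late_conds[1], band = NA, chrom = "chr1",
               start = 0, end = 5e4, state = "gain", n_probes = 30))
  cn <- generate_cn_profiles(map, design, event_spec,
                             couple_prob = p$couple_prob,
                             couple_effect = p$couple_effect,
                             seed = seed + 2, expr = sim$expr)

  truth <- structure(list(de = sim$truth$de, coupling = cn$truth$coupling),
                     class = "truth_record")
  list(map = map, design = design, expr = cn$expr, profiles = cn$profiles,
       truth = truth, params = p)
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_invalid("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

#' Run the full passage-instability workflow
#'
#' Executes the analysis stages in study order — differential expression
#' per cell line (late vs early), common-gene overlap enrichment between
#' the two lines, positional clustering of regulated genes, copy-number
#' filtering, macro-aberration calling and early/late deltas,
#' copy-number/expression coincidence, and the four-way consistency
#' filter with optional pathway evaluation — writing one tab-separated
#' table per stage into the output directory, each with a `#` header
#' recording package version, seed and thresholds.  Progress is logged
#' to stderr with stage-tagged lines.  The run is deterministic for a
#' fixed config (the config seed drives simulation and permutations).
#'
#' @param config path to a YAML config file, or an equivalent list.
#'   Keys: `seed`, `outdir`, `thresholds` (`fold`, `alpha`, `criterion`),
#'   `cluster_alpha`, `min_pass`, `n_perm`, `gene_sets` (GMT path,
#'   optional), and either `simulate` (scenario settings for
#'   [simulate_study()], including `parental`/`metastatic`) or `inputs`
#'   (paths `matrix`, `samples`, `annotation`, `cytobands`, optional
#'   `segments`, plus `parental`/`metastatic` line names).
#' @return Invisibly, the report bundle: a list with every stage result
#'   (`map`, `expr`, `contrasts`, `regulated`, `overlap`, `clusters`,
#'   `profiles`, `macro`, `delta`, `coincidence`, `grid`, `consistent`,
#'   `pathways`, `summary`) and `files`, the paths written.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  seed <- cfg$seed %||% 1
  outdir <- cfg$outdir %||% stop_invalid("config needs an `outdir`")
  thr <- utils::modifyList(list(fold = 2, alpha = 0.05, criterion = "p"),
                           cfg$thresholds %||% list())
  if (thr$fold < 1 || thr$alpha <= 0 || thr$alpha > 1) {
    stop_invalid("invalid thresholds: fold %s, alpha %s", thr$fold, thr$alpha)
  }
  cluster_alpha <- cfg$cluster_alpha %||% 0.01
  min_pass <- cfg$min_pass %||% 4
  n_perm <- cfg$n_perm %||% 1000
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(paste0("metastab ", as.character(utils::packageVersion("metastab"))),
           paste0("seed: ", seed),
           sprintf("thresholds: fold %s, alpha %s, criterion %s",
                   thr$fold, thr$alpha, thr$criterion))
  files <- character(0)
  out_file <- function(name) {
    path <- file.path(outdir, name)
    files[[length(files) + 1L]] <<- path
    path
  }
  log_stage <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  fail_stage <- function(stage, e) {
    stop_invalid("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }

  # --- input stage -------------------------------------------------------
  profiles <- NULL
  tryCatch({
    if (!is.null(cfg$simulate)) {
      sim <- simulate_study(cfg$simulate, seed = seed)
      map <- sim$map; expr <- sim$expr; profiles <- sim$profiles
      parental <- sim$params$parental; metastatic <- sim$params$metastatic
      log_stage("input", "simulated %d genes x %d samples (%s/%s)",
                nrow(expr$values), ncol(expr$values), parental, metastatic)
    } else {
      inp <- cfg$inputs %||% stop_invalid("config needs `simulate` or `inputs`")
      map <- read_genome_map(inp$annotation, inp$cytobands)
      expr <- read_expression(inp$matrix, inp$samples)
      parental <- inp$parental; metastatic <- inp$metastatic
      if (!is.null(inp$segments)) profiles <- read_segments(inp$segments, map)
      log_stage("input", "read %d genes x %d samples", nrow(expr$values),
                ncol(expr$values))
    }
  }, error = function(e) fail_stage("input", e))

  N <- universe_size(map)
  lines <- c(parental, metastatic)
  summary_rows <- list()
  note <- function(stage, metric, value) {
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(stage = stage, metric = metric, value = value)
  }

  # --- differential expression: late vs early per line -------------------
  contrasts <- list(); regulated <- list()
  tryCatch({
    for (ln in lines) {
      tab <- contrast(expr, samples_for(expr, ln, "early"),
                      samples_for(expr, ln, "late"))
      rs <- regulated_set(tab, thr$fold, thr$alpha, thr$criterion,
                          universe_n = N)
      contrasts[[ln]] <- tab
      regulated[[ln]] <- rs
      write_tsv_commented(as.data.frame(tab),
                          out_file(sprintf("de_%s_late_vs_early.tsv", ln)), hdr)
      write_gene_list(rs$up, out_file(sprintf("regulated_%s_up.txt", ln)))
      write_gene_list(rs$down, out_file(sprintf("regulated_%s_down.txt", ln)))
      note("de", paste0(ln, "_up"), length(rs$up))
      note("de", paste0(ln, "_down"), length(rs$down))
      log_stage("de", "%s: %d up, %d down", ln, length(rs$up), length(rs$down))
    }
  }, error = function(e) fail_stage("de", e))

  # --- overlap enrichment between the two lines --------------------------
  tryCatch({
    overlap <- lapply(c(up = "up", down = "down"), function(d) {
      common_regulated(regulated[[parental]], regulated[[metastatic]], N, d)
    })
    ov_tab <- do.call(rbind, lapply(overlap, function(o) {
      data.frame(direction = o$direction, n_common = o$n_common,
                 n_a = o$n_a, n_b = o$n_b, universe_n = o$universe_n,
                 observed_pct = o$observed_pct, expected_pct = o$expected_pct,
                 fold = o$fold, fold_printed = o$fold_printed)
    }))
    write_tsv_commented(ov_tab, out_file("overlap.tsv"), hdr)
    for (d in names(overlap)) note("overlap", paste0("fold_", d), overlap[[d]]$fold)
    log_stage("overlap", "up fold %.2f, down fold %.2f",
              overlap$up$fold, overlap$down$fold)
  }, error = function(e) fail_stage("overlap", e))

  # --- positional clustering --------------------------------------------
  clusters <- list()
  tryCatch({
    for (ln in lines) {
      sc <- rbind(cluster_scan(regulated[[ln]], map, "cytoband", cluster_alpha),
                  cluster_scan(regulated[[ln]], map, "chromosome", cluster_alpha))
      clusters[[ln]] <- sc
      write_tsv_commented(sc, out_file(sprintf("clusters_%s.tsv", ln)), hdr)
      note("cluster", paste0(ln, "_units"), nrow(sc))
      log_stage("cluster", "%s: %d enriched unit(s) at alpha %g", ln,
                nrow(sc), cluster_alpha)
    }
  }, error = function(e) fail_stage("cluster", e))

  # --- copy number -------------------------------------------------------
  macro <- NULL; delta <- list(); coincidence_tab <- NULL
  if (is.null(profiles)) {
    log_stage("cnv", "skipped (no copy-number input)")
    log_stage("coincide", "skipped (no copy-number input)")
  } else {
    tryCatch({
      # a condition with no called segments is a neutral genome
      for (cond in condition_label(rep(lines, each = 2), c("early", "late"))) {
        if (is.null(profiles[[cond]])) {
          profiles[[cond]] <- empty_cn_profile(cond, map)
        }
      }
      profiles <- lapply(profiles, filter_segments)
      macro <- do.call(rbind, lapply(names(profiles), function(cond) {
        m <- macro_aberrations(profiles[[cond]])
        if (nrow(m)) cbind(condition = cond, m) else NULL
      }))
      if (is.null(macro)) {
        macro <- data.frame(condition = character(), chrom = character(),
                            band = character(), state = character())
      }
      write_tsv_commented(macro, out_file("macro_aberrations.tsv"), hdr)
      status <- lapply(profiles, gene_cn_status, map = map)
      frac <- do.call(rbind, lapply(names(status), function(cond) {
        f <- aberrant_fraction(status[[cond]])
        data.frame(condition = cond, gain_pct = f[["gain_pct"]],
                   loss_pct = f[["loss_pct"]], total_pct = f[["total_pct"]])
      }))
      write_tsv_commented(frac, out_file("aberrant_fraction.tsv"), hdr)
      delta_rows <- list()
      for (ln in lines) {
        ea <- condition_label(ln, "early"); la <- condition_label(ln, "late")
        if (!all(c(ea, la) %in% names(status))) next
        dl <- cn_delta(status[[ea]], status[[la]])
        delta[[ln]] <- dl
        delta_rows[[ln]] <- data.frame(
          cell_line = ln, gain_pct = dl$summary[["gain_pct"]],
          loss_pct = dl$summary[["loss_pct"]],
          total_pct = dl$summary[["total_pct"]])
      }
      write_tsv_commented(do.call(rbind, delta_rows),
                          out_file("cn_delta.tsv"), hdr)
      note("cnv", "macro_aberrations", nrow(macro))
      log_stage("cnv", "%d macro-aberration(s); deltas for %s",
                nrow(macro), paste(names(delta), collapse = ", "))
    }, error = function(e) fail_stage("cnv", e))

    # --- CN/expression coincidence --------------------------------------
    tryCatch({
      rows <- list()
      k <- 0L
      for (ln in names(delta)) {
        for (d in c("up", "down")) {
          k <- k + 1L
          cp <- coincidence_permutation_p(regulated[[ln]], delta[[ln]], map,
                                          d, n_perm = n_perm,
                                          seed = seed + 100 + k)
          rows[[k]] <- data.frame(cell_line = ln, direction = d,
                                  observed = cp$observed,
                                  expected = cp$expected, ratio = cp$ratio,
                                  perm_p = cp$p)
          note("coincide", paste(ln, d, "ratio", sep = "_"), cp$ratio)
        }
      }
      coincidence_tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(cell_line = character(), direction = character(),
                   observed = integer(), expected = numeric(),
                   ratio = numeric(), perm_p = numeric())
      write_tsv_commented(coincidence_tab, out_file("coincidence.tsv"), hdr)
      log_stage("coincide", "%d line/direction combination(s)", k)
    }, error = function(e) fail_stage("coincide", e))
  }

  # --- four-way consistency ---------------------------------------------
  grid <- NULL; consistent <- NULL; pathways <- NULL
  tryCatch({
    grid <- build_grid(expr, parental, metastatic)
    consistent <- consistent_genes(grid, min_pass = min_pass,
                                   fold_threshold = thr$fold,
                                   alpha = thr$alpha)
    write_tsv_commented(consistent, out_file("consistent_genes.tsv"), hdr)
    pooled_rs <- regulated_set(grid$pooled, thr$fold, thr$alpha,
                               thr$criterion, universe_n = N)
    n_pooled <- length(pooled_rs$up) + length(pooled_rs$down)
    note("consistent", "n_consistent", nrow(consistent))
    note("consistent", "n_pooled", n_pooled)
    if (n_pooled > 0) {
      note("consistent", "retention_pct",
           retention_pct(nrow(consistent), n_pooled))
    }
    log_stage("consistent", "%d gene(s) at min_pass %d (pooled: %d)",
              nrow(consistent), min_pass, n_pooled)
    if (!is.null(cfg$gene_sets)) {
      sets <- read_gmt(cfg$gene_sets)
      pathways <- pathway_filter(consistent, sets, N)
      write_tsv_commented(pathways, out_file("pathways.tsv"), hdr)
      log_stage("consistent", "pathway evaluation over %d set(s)", length(sets))
    }
  }, error = function(e) fail_stage("consistent", e))

  summary_tab <- do.call(rbind, summary_rows)
  write_tsv_commented(summary_tab, out_file("summary.tsv"), hdr)
  log_stage("done", "%d file(s) in %s", length(files), outdir)

  invisible(list(map = map, expr = expr, contrasts = contrasts,
                 regulated = regulated, clusters = clusters,
                 profiles = profiles, macro = macro, delta = delta,
                 coincidence = coincidence_tab, grid = grid,
                 consistent = consistent, pathways = pathways,
                 summary = summary_tab, files = files))
}
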