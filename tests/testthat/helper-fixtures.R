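# Small fixtures built in code.

tiny_map <- function(seed = 11) {
  generate_genome_map(n_chromosomes = 2, genes_per_chromosome = c(30, 20),
                      bands_per_chromosome = c(3, 2), chrom_length = 1e7,
                      seed = seed)
}

one_system_design <- function(replicates = 3) {
  design_spec(data.frame(parental = "SAOS", metastatic = "LM5"),
              replicates = replicates)
}

# Expression matrix from an explicit value matrix for a 2-condition,
# one-line layout (early/late, nrep each).
expr_from_matrix <- function(values, nrep = ncol(values) / 2,
                             line = "SAOS") {
  n <- ncol(values)
  samples <- data.frame(
    sample = paste0("s", seq_len(n)),
    cell_line = line,
    passage = rep(c("early", "late"), each = nrep),
    replicate = rep(seq_len(nrep), 2))
  colnames(values) <- samples$sample
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%05d", seq_len(nrow(values)))
  }
  expression_matrix(values, samples)
}

# A handmade four-band single-chromosome map with genes at known spots.
hand_map <- function() {
  chroms <- data.frame(chrom = "chr1", length = 4000L)
  bands <- data.frame(chrom = "chr1", start = c(0, 1000, 2000, 3000),
                      end = c(1000, 2000, 3000, 4000),
                      band = c("1p2", "1p1", "1q1", "1q2"))
  genes <- data.frame(gene_id = sprintf("g%05d", 1:8), chrom = "chr1",
                      start = c(100, 300, 1100, 1300, 2100, 2300, 3100, 3300),
                      end = c(200, 400, 1200, 1400, 2200, 2400, 3200, 3400))
  genome_map(chroms, bands, genes)
}

hand_profile <- function(segments, condition = "SAOS_late", map = hand_map()) {
  cn_profile(condition, segments, map)
}

seg_row <- function(chrom, start, end, state, n_probes = 100,
                    recurrent = FALSE) {
  data.frame(chrom = chrom, start = start, end = end, state = state,
             n_probes = n_probes, recurrent = recurrent)
}

# Regulated set from explicit id vectors.
make_regulated <- function(up, down, universe_n) {
  structure(list(up = up, down = down, universe_n = universe_n,
                 fold_threshold = 2, alpha = 0.05, criterion = "p"),
            class = "regulated_set")
}
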