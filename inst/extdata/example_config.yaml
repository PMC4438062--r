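# Annotated example configuration for metastab::run_pipeline() and
# `metastab run --config ...`.
#
# Every run needs `seed` (drives simulation and permutations), `outdir`
# (stage tables are written there) and either a `simulate:` block or an
# `inputs:` block.

seed: 1
outdir: metastab-run        # created if missing

# Regulation criterion used by the differential-expression, overlap and
# consistency stages ("p" = raw p value, "fdr" = BH q value).
thresholds:
  fold: 2                   # linear fold-change threshold (strict >)
  alpha: 0.05               # significance level (strict <)
  criterion: p

cluster_alpha: 0.01         # EASE-p cutoff for positional clustering
min_pass: 4                 # 3 or 4 passage combinations for consistency
n_perm: 1000                # permutations for the coincidence p value

# --- synthetic study ----------------------------------------------------
# Generates a parental/metastatic early/late triplicate experiment with
# known ground truth.  Replace this block with an `inputs:` block (paths
# matrix/samples/annotation/cytobands and optionally segments, plus
# parental/metastatic line names) to analyse real data.
simulate:
  n_chromosomes: 6
  genes_per_chromosome: 250
  bands_per_chromosome: 4
  parental: SAOS
  metastatic: LM5
  replicates: 3
  noise_sd: 0.25            # log2 replicate noise sd
  n_met: 30                 # metastatic-effect genes (present in both passages)
  met_log2fc: 2
  n_passage: 40             # passage-effect genes (late samples of both lines)
  passage_log2fc: 2
  n_cluster: 12             # extra passage-up genes planted on one cytoband
  couple_prob: 0.8          # P(gene in a CN event gets a coupled expression shift)
  couple_effect: 1.5        # magnitude of the coupled shift (log2)

# Optional GMT file for the pathway evaluation of consistent genes, e.g.
# the bundled synthetic_pathways.gmt whose sets match the scenario above:
# gene_sets: /path/to/synthetic_pathways.gmt
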