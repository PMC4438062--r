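#' Genome maps: chromosomes, cytobands and gene coordinates
#'
#' A `genome_map` is the positional universe used by every enrichment
#' statistic in the package.  It holds chromosome lengths, a cytoband
#' partition of each chromosome and gene coordinates, all in 0-based
#' half-open coordinates.
#'
#' @param chromosomes data.frame with columns `chrom`, `length`.
#' @param cytobands data.frame with columns `chrom`, `start`, `end`, `band`.
#'   Bands must partition each chromosome without gaps or overlaps.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#'   Every gene must lie fully within its chromosome; gene ids must be
#'   unique.  A `band` column is added (band containing the gene midpoint)
#'   if absent.
#'
#' @return An object of class `genome_map`: a list with elements
#'   `chromosomes`, `cytobands` and `genes` (each a data.frame).
#' @export
genome_map <- function(chromosomes, cytobands, genes) {
  chromosomes <- as.data.frame(chromosomes)
  cytobands <- as.data.frame(cytobands)
  genes <- as.data.frame(genes)
  if (nrow(chromosomes) == 0L) stop_invalid("a genome map needs at least one chromosome")
  if (nrow(genes) == 0L) stop_invalid("a genome map needs at least one gene")
  if (anyDuplicated(chromosomes$chrom)) stop_invalid("duplicated chromosome names")
  if (anyDuplicated(genes$gene_id)) {
    stop_invalid("duplicated gene id(s): %s",
                 paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  len <- stats::setNames(chromosomes$length, chromosomes$chrom)
  for (cc in chromosomes$chrom) {
    b <- cytobands[cytobands$chrom == cc, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) == 0L) stop_invalid("chromosome %s has no cytobands", cc)
    ok <- b$start[1] == 0 &&
      b$end[nrow(b)] == len[[cc]] &&
      all(b$end > b$start) &&
      (nrow(b) == 1L || all(b$start[-1] == b$end[-nrow(b)]))
    if (!ok) stop_invalid("cytobands do not partition chromosome %s", cc)
  }
  bad <- !(genes$chrom %in% chromosomes$chrom) |
    genes$start < 0 | genes$end > len[genes$chrom] | genes$end <= genes$start
  if (any(bad)) {
    stop_invalid("gene(s) outside chromosome bounds: %s",
                 paste(utils::head(genes$gene_id[bad], 5), collapse = ", "))
  }
  if (is.null(genes$band)) genes$band <- assign_bands(genes, cytobands)
  rownames(chromosomes) <- rownames(cytobands) <- rownames(genes) <- NULL
  structure(list(chromosomes = chromosomes, cytobands = cytobands, genes = genes),
            class = "genome_map")
}

# Band containing each gene's midpoint (bands partition, so this is unique).
assign_bands <- function(genes, cytobands) {
  band <- character(nrow(genes))
  mid <- (genes$start + genes$end) / 2
  for (cc in unique(genes$chrom)) {
    b <- cytobands[cytobands$chrom == cc, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    i <- genes$chrom == cc
    band[i] <- b$band[findInterval(mid[i], b$start)]
  }
  band
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %d chromosomes, %d cytobands, %d genes\n",
              nrow(x$chromosomes), nrow(x$cytobands), nrow(x$genes)))
  invisible(x)
}

#' Number of genes in the universe of a genome map
#'
#' @param map a [genome_map()].
#' @return Integer gene count.
#' @export
universe_size <- function(map) {
  stopifnot(inherits(map, "genome_map"))
  nrow(map$genes)
}

#' Simulate a genome map
#'
#' Draws chromosome band boundaries and gene coordinates at random to build
#' a [genome_map()] with the requested number of chromosomes, genes and
#' cytobands.  Gene ids are `g00001`, `g00002`, ... assigned sequentially
#' along chromosomes, so the identity of "the first k genes" is stable
#' across seeds; only coordinates move.  Deterministic for a fixed seed.
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param genes_per_chromosome gene count per chromosome; scalar or vector
#'   of length `n_chromosomes`.
#' @param bands_per_chromosome cytoband count per chromosome; scalar or
#'   vector.
#' @param chrom_length chromosome length in bp (scalar or vector).
#' @param seed integer RNG seed.
#' @return A [genome_map()].
#' @examples
#' m <- generate_genome_map(2, 50, 4, seed = 1)
#' universe_size(m)
#' @export
generate_genome_map <- function(n_chromosomes,
                                genes_per_chromosome,
                                bands_per_chromosome,
                                chrom_length = 1e8,
                                seed = 1) {
  if (n_chromosomes < 1L) stop_invalid("`n_chromosomes` must be >= 1")
  ng <- recycle_counts(genes_per_chromosome, n_chromosomes, "genes_per_chromosome")
  nb <- recycle_counts(bands_per_chromosome, n_chromosomes, "bands_per_chromosome")
  ln <- recycle_counts(chrom_length, n_chromosomes, "chrom_length")
  if (any(ng < 1L)) stop_invalid("each chromosome needs at least one gene")
  if (any(nb < 1L)) stop_invalid("each chromosome needs at least one cytoband")

  with_seed(seed, {
    chroms <- data.frame(chrom = paste0("chr", seq_len(n_chromosomes)),
                         length = ln)
    bands <- list()
    genes <- list()
    next_id <- 1L
    for (i in seq_len(n_chromosomes)) {
      cc <- chroms$chrom[i]
      L <- ln[i]
      # band boundaries: jittered even spacing so bands never degenerate
      if (nb[i] > 1L) {
        cuts <- seq(0, L, length.out = nb[i] + 1L)[-c(1L, nb[i] + 1L)]
        cuts <- round(cuts + stats::runif(nb[i] - 1L, -0.3, 0.3) * (L / nb[i]))
        cuts <- sort(cuts)
      } else {
        cuts <- numeric(0)
      }
      starts <- c(0, cuts)
      ends <- c(cuts, L)
      bands[[i]] <- data.frame(chrom = cc, start = starts, end = ends,
                               band = band_names(i, nb[i]))
      glen <- pmax(1000, round(stats::rlnorm(ng[i], log(3e4), 0.8)))
      gstart <- round(stats::runif(ng[i], 0, pmax(1, L - glen - 1)))
      ord <- order(gstart)
      gstart <- gstart[ord]
      glen <- glen[ord]
      genes[[i]] <- data.frame(
        gene_id = sprintf("g%05d", seq.int(next_id, length.out = ng[i])),
        chrom = cc, start = gstart, end = gstart + glen)
      next_id <- next_id + ng[i]
    }
    genome_map(chroms, do.call(rbind, bands), do.call(rbind, genes))
  })
}

# Cytogenetic-style band names: p-arm bands numbered outward from the
# centre, then q-arm bands, e.g. 1p2 1p1 1q1 1q2.
band_names <- function(chrom_index, n_bands) {
  np <- ceiling(n_bands / 2)
  nq <- n_bands - np
  c(sprintf("%dp%d", chrom_index, rev(seq_len(np))),
    if (nq > 0) sprintf("%dq%d", chrom_index, seq_len(nq)))
}
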