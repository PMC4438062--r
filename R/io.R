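# Readers and writers for the tab-separated interchange formats.
# All writers accept a `comments` character vector emitted as leading
# "# " lines (provenance: seed, thresholds); all readers skip them.

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) stop_invalid("%s file not found: %s", what, path)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv_commented <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix and its sample sheet
#'
#' The matrix file is tab-separated with a `gene_id` column followed by
#' one numeric column per sample; the sample sheet is tab-separated with
#' columns `sample`, `cell_line`, `passage`, `replicate`.  Lines
#' starting with `#` are ignored.  Duplicate gene ids, non-numeric cells
#' and missing metadata are rejected with the offending row or column
#' named.
#'
#' @param matrix_path path to the expression matrix file.
#' @param samples_path path to the sample sheet.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_path, samples_path) {
  tab <- read_tsv_checked(matrix_path, "expression matrix")
  if (names(tab)[1] != "gene_id") {
    stop_invalid("first column of %s must be 'gene_id'", matrix_path)
  }
  ids <- as.character(tab$gene_id)
  if (anyDuplicated(ids)) {
    stop_invalid("duplicated gene id in %s: %s", matrix_path,
                 ids[duplicated(ids)][1])
  }
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop_invalid("non-numeric value in %s, column '%s', data row %d",
                   matrix_path, names(vals)[j], bad)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  samples <- read_tsv_checked(samples_path, "sample sheet")
  expression_matrix(m, samples)
}

#' Write an expression matrix and its sample sheet
#'
#' @param expr an [expression_matrix()].
#' @param matrix_path,samples_path output paths.
#' @param comments optional character vector of `#` header lines.
#' @return The matrix path, invisibly.
#' @export
write_expression <- function(expr, matrix_path, samples_path,
                             comments = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, row.names = NULL)
  write_tsv_commented(df, matrix_path, comments)
  write_tsv_commented(expr$samples, samples_path, comments)
  invisible(matrix_path)
}

#' Read copy-number segments (SEG-style)
#'
#' Tab-separated with columns `sample`, `chrom`, `start`, `end`,
#' `n_probes`, `state` and optional `recurrent`; coordinates on disk are
#' 1-based inclusive (SEG convention) and are converted to the internal
#' 0-based half-open representation, so a row `start=1 end=100` becomes
#' the interval `[0, 100)`.
#'
#' @param path path to the segment file.
#' @param map a [genome_map()] for the resulting profiles.
#' @return Named list of [cn_profile()], one per distinct `sample`
#'   (condition) value in the file.
#' @export
read_segments <- function(path, map) {
  tab <- read_tsv_checked(path, "segment")
  need <- c("sample", "chrom", "start", "end", "n_probes", "state")
  if (!all(need %in% names(tab))) {
    stop_invalid("segment file needs columns: %s", paste(need, collapse = ", "))
  }
  start0 <- tab$start - 1L
  if (any(tab$end <= start0)) {
    stop_invalid("segment end <= start after coordinate conversion (row %d)",
                 which(tab$end <= start0)[1])
  }
  if (is.null(tab$recurrent)) tab$recurrent <- FALSE
  conds <- unique(tab$sample)
  stats::setNames(lapply(conds, function(cond) {
    s <- tab[tab$sample == cond, , drop = FALSE]
    cn_profile(cond, data.frame(chrom = s$chrom, start = s$start - 1L,
                                end = s$end, state = s$state,
                                n_probes = s$n_probes,
                                recurrent = as.logical(s$recurrent)), map)
  }), conds)
}

#' Write copy-number profiles as a SEG-style file
#'
#' Internal 0-based half-open coordinates are written 1-based inclusive;
#' [read_segments()] inverts the conversion bit-exactly.
#'
#' @param profiles a [cn_profile()] or list of them.
#' @param path output path.
#' @param comments optional `#` header lines.
#' @return The path, invisibly.
#' @export
write_segments <- function(profiles, path, comments = NULL) {
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (nrow(p$segments) == 0L) return(NULL)
    data.frame(sample = p$condition, chrom = p$segments$chrom,
               start = p$segments$start + 1L, end = p$segments$end,
               n_probes = p$segments$n_probes, state = p$segments$state,
               recurrent = p$segments$recurrent)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(sample = character(), chrom = character(),
                     start = integer(), end = integer(),
                     n_probes = integer(), state = character(),
                     recurrent = logical())
  }
  write_tsv_commented(df, path, comments)
}

#' Read a UCSC cytoBand file
#'
#' Five tab-separated columns without header: chrom, start, end, band
#' name, Giemsa stain.  UCSC coordinates are already 0-based half-open
#' and pass through unchanged.  Band names are stored with the
#' chromosome prefix (chrom "chr12", name "p13.33" becomes "12p13.33").
#'
#' @param path path to the cytoBand file.
#' @return data.frame with columns `chrom`, `start`, `end`, `band`.
#' @export
read_cytobands <- function(path) {
  if (!file.exists(path)) stop_invalid("cytoband file not found: %s", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop_invalid("cytoBand format needs >= 4 columns")
  if (any(tab[[3]] <= tab[[2]])) {
    stop_invalid("cytoband end <= start (row %d)", which(tab[[3]] <= tab[[2]])[1])
  }
  data.frame(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
             band = paste0(sub("^chr", "", tab[[1]]), tab[[4]]))
}

#' Write cytobands in UCSC cytoBand format
#'
#' @param cytobands data.frame with `chrom`, `start`, `end`, `band`
#'   (chromosome-prefixed band names are written without the prefix).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_cytobands <- function(cytobands, path) {
  name <- mapply(function(ch, bd) sub(paste0("^", sub("^chr", "", ch)), "", bd),
                 cytobands$chrom, cytobands$band)
  df <- data.frame(cytobands$chrom, cytobands$start, cytobands$end,
                   name, "gneg")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED-like gene annotation
#'
#' Tab-separated with header columns `chrom`, `start`, `end`, `gene_id`
#' and optional `band`; BED coordinates are 0-based half-open and pass
#' through unchanged.
#'
#' @param path path to the annotation file.
#' @return data.frame of genes (`gene_id`, `chrom`, `start`, `end`, and
#'   `band` if present), suitable for [genome_map()].
#' @export
read_annotation <- function(path) {
  tab <- read_tsv_checked(path, "annotation")
  need <- c("chrom", "start", "end", "gene_id")
  if (!all(need %in% names(tab))) {
    stop_invalid("annotation needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(tab$end <= tab$start)) {
    stop_invalid("annotation end <= start (row %d)", which(tab$end <= tab$start)[1])
  }
  cols <- c("gene_id", "chrom", "start", "end",
            if ("band" %in% names(tab)) "band")
  tab[, cols, drop = FALSE]
}

#' Write a gene annotation as BED-like TSV
#'
#' @param map a [genome_map()] (its `genes` table is written).
#' @param path output path.
#' @param comments optional `#` header lines.
#' @return The path, invisibly.
#' @export
write_annotation <- function(map, path, comments = NULL) {
  stopifnot(inherits(map, "genome_map"))
  g <- map$genes[, c("chrom", "start", "end", "gene_id", "band")]
  write_tsv_commented(g, path, comments)
}

#' Assemble a genome map from annotation and cytoband files
#'
#' Chromosome lengths are taken as the end of the last cytoband of each
#' chromosome.
#'
#' @param annotation_path BED-like gene annotation ([read_annotation()]).
#' @param cytoband_path UCSC cytoBand file ([read_cytobands()]).
#' @return A [genome_map()].
#' @export
read_genome_map <- function(annotation_path, cytoband_path) {
  genes <- read_annotation(annotation_path)
  bands <- read_cytobands(cytoband_path)
  lens <- tapply(bands$end, bands$chrom, max)
  chroms <- data.frame(chrom = names(lens), length = as.numeric(lens))
  genome_map(chroms, bands, genes)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields set name,
#' description, then member ids.  Lines with fewer than three fields are
#' rejected with their line number.
#'
#' @param path path to the GMT file.
#' @return Named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_invalid("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop_invalid("malformed GMT line %d: need name, description and >= 1 member", i)
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  sets
}

#' Write gene sets as a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write gene lists one id per line
#'
#' @param ids character vector of gene ids.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Read a gene list (one id per line, `#` comments ignored)
#'
#' @param path input path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_invalid("gene list not found: %s", path)
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
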