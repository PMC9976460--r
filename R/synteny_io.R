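# Plain-text interfaces for the synteny analytics: BED-like gene tables,
# 2-column orthology and ALG label TSVs, and block export.

#' Read a BED-like gene table
#'
#' Tab-separated (chrom, start, end, gene_id, score, strand), no header.
#'
#' @param path input file.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_bed <- function(path) {
  d <- data.table::fread(path, header = FALSE, sep = "\t",
                         colClasses = list(character = 1), data.table = FALSE)
  if (ncol(d) < 4L) stop_sc("gene BED needs at least 4 columns")
  data.frame(gene_id = as.character(d[[4]]), chrom = d[[1]],
             start = d[[2]], end = d[[3]],
             strand = if (ncol(d) >= 6L) d[[6]] else "+",
             stringsAsFactors = FALSE)
}

#' Attach orthogroup and ALG columns to a gene table
#'
#' @param genes data.frame from [read_gene_bed()].
#' @param orthology data.frame (`gene_id`, `orthogroup`) or TSV path.
#' @param alg data.frame (`gene_id`, `alg`) or TSV path; optional.
#' @return the gene table with `orthogroup` and `alg` columns (NA where
#'   unannotated).
#' @export
annotate_genes <- function(genes, orthology, alg = NULL) {
  read2 <- function(x, cols) {
    if (is.character(x) && length(x) == 1L)
      x <- data.table::fread(x, sep = "\t", data.table = FALSE)
    names(x)[1:2] <- cols
    x
  }
  o <- read2(orthology, c("gene_id", "orthogroup"))
  genes$orthogroup <- o$orthogroup[match(genes$gene_id, o$gene_id)]
  if (!is.null(alg)) {
    a <- read2(alg, c("gene_id", "alg"))
    genes$alg <- a$alg[match(genes$gene_id, a$gene_id)]
  } else genes$alg <- NA_character_
  genes
}

#' Write detected microsyntenic blocks as a TSV
#'
#' One row per block with per-species chromosome and bp span, member
#' count, and the semicolon-joined orthogroup list.
#'
#' @param blocks list of `microsynteny_block`s.
#' @param path output file.
#' @export
write_blocks_tsv <- function(blocks, path) {
  d <- do.call(rbind, lapply(seq_along(blocks), function(k) {
    b <- blocks[[k]]
    data.frame(block = k, n_orthogroups = length(b$orthogroups),
               chrom_a = b$chrom_a, start_a = b$span_a[1], end_a = b$span_a[2],
               chrom_b = b$chrom_b, start_b = b$span_b[1], end_b = b$span_b[2],
               orthogroups = paste(b$orthogroups, collapse = ";"))
  }))
  if (is.null(d))
    d <- data.frame(block = integer(), n_orthogroups = integer(),
                    chrom_a = character(), start_a = integer(),
                    end_a = integer(), chrom_b = character(),
                    start_b = integer(), end_b = integer(),
                    orthogroups = character())
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}
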