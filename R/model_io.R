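# Serialisation of chromosome models: a modified-PDB dialect (CA-trace
# pseudo-atoms, one residue per bead, CONECT records along the backbone,
# REMARK 250 metadata) and a plain xyz TSV.

#' Write a chromosome model as modified PDB
#'
#' One pseudo-atom per bead (record `ATOM`, atom name `CA`, residue `CHR`,
#' sequential residue numbers), CONECT records linking consecutive beads,
#' and `REMARK 250` lines carrying the chromosome id, bin size, and the
#' nm-per-unit coordinate divisor. Residue numbers beyond 9999 roll into
#' the next chain letter (PDB column limits); bead order is preserved.
#'
#' @param conf n x 3 coordinates, nm.
#' @param path output file.
#' @param chrom chromosome id recorded in the header.
#' @param bin_size bin size in bp recorded in the header.
#' @param scale nm per PDB coordinate unit (divisor); pick it large enough
#'   that scaled coordinates fit the fixed 8.3 columns.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(conf, path, chrom = "chr", bin_size = 150000L,
                      scale = 1) {
  stopifnot(is.matrix(conf), ncol(conf) == 3L, all(is.finite(conf)), scale > 0)
  xyz <- conf / scale
  # %8.3f needs < 10000 positive and > -1000 negative to stay in 8 columns
  if (any(xyz >= 10000 - 5e-4) || any(xyz <= -1000 + 5e-4))
    stop_sc("scaled coordinate overflows the 8.3 PDB columns; increase scale (currently %g nm/unit)",
            scale)
  n <- nrow(xyz)
  res <- (seq_len(n) - 1L) %% 9999L + 1L
  chain <- LETTERS[(seq_len(n) - 1L) %/% 9999L + 1L]
  lines <- c(
    sprintf("REMARK 250 CHROM %s", chrom),
    sprintf("REMARK 250 BINSIZE %d", as.integer(bin_size)),
    sprintf("REMARK 250 SCALE %.6g", scale),
    sprintf("ATOM  %5d  CA  CHR %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            seq_len(n), chain, res, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0))
  if (n >= 2L)
    lines <- c(lines, sprintf("CONECT%5d%5d", seq_len(n - 1L), seq_len(n)[-1L]))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a chromosome model written by [write_pdb()] (or any single-chain
#' CA-trace PDB)
#'
#' Bead order follows residue numbering; the nm-per-unit scale is recovered
#' from the `REMARK 250 SCALE` header when present, else taken as 1 with a
#' warning. Files with several chains are rejected unless they carry the
#' package's own chain-rollover header.
#'
#' @param path PDB file.
#' @return list with `conformation` (n x 3, nm), `chrom`, `bin_size`,
#'   `scale`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop_sc("empty PDB file: %s", path)
  atoms <- lines[startsWith(lines, "ATOM")]
  if (!length(atoms)) stop_sc("no ATOM records in %s", path)
  chains <- substr(atoms, 22, 22)
  remarks <- lines[startsWith(lines, "REMARK 250")]
  get_tag <- function(tag) {
    hit <- grep(paste0("^REMARK 250 ", tag, " "), remarks, value = TRUE)
    if (length(hit)) sub(paste0("^REMARK 250 ", tag, " "), "", hit[1]) else NULL
  }
  chrom <- get_tag("CHROM")
  if (length(unique(chains)) > 1L && is.null(chrom))
    stop_sc("multiple chains in %s: one chromosome per model", path)
  scale_txt <- get_tag("SCALE")
  if (is.null(scale_txt)) {
    warn_sc("no SCALE remark in %s; assuming 1 nm per unit", path)
    scale <- 1
  } else scale <- as.numeric(scale_txt)
  xyz <- cbind(as.numeric(substr(atoms, 31, 38)),
               as.numeric(substr(atoms, 39, 46)),
               as.numeric(substr(atoms, 47, 54)))
  if (any(!is.finite(xyz))) stop_sc("unparseable coordinates in %s", path)
  list(conformation = xyz * scale,
       chrom = chrom %||% NA_character_,
       bin_size = as.integer(get_tag("BINSIZE") %||% NA),
       scale = scale)
}

#' Write a model as an xyz TSV (bead_index, x_nm, y_nm, z_nm)
#' @param conf n x 3 coordinates, nm.
#' @param path output file.
#' @export
write_xyz <- function(conf, path) {
  d <- data.frame(bead_index = seq_len(nrow(conf)) - 1L,
                  x_nm = conf[, 1], y_nm = conf[, 2], z_nm = conf[, 3])
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' Read an xyz TSV written by [write_xyz()]
#' @param path input file.
#' @return n x 3 coordinate matrix ordered by bead index.
#' @export
read_xyz <- function(path) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  d <- d[order(d$bead_index), , drop = FALSE]
  as.matrix(d[, c("x_nm", "y_nm", "z_nm")])
}
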