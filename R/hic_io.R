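# Reading HiC-Pro style binned matrices, cis extraction, interaction
# frequency thresholds, constraint selection, and sequencing depth.

#' Build a genome bin table
#'
#' Tiles each chromosome with fixed-size bins (0-based, half-open; the last
#' bin of a chromosome may be shorter) and assigns the 1-based global bin
#' ids used by the HiC-Pro abs-BED dialect.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (default 150000, the working resolution
#'   of the modeling pipeline: one bead per 150 kb bin).
#' @return a `genome_bins` data.frame with columns `chrom`, `start`, `end`,
#'   `bin` (0-based index within chromosome) and `id` (global 1-based id).
#' @export
make_bins <- function(chrom_sizes, bin_size = 150000L) {
  stopifnot(length(chrom_sizes) >= 1L, !is.null(names(chrom_sizes)),
            all(chrom_sizes > 0), bin_size > 0)
  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len),
               bin = seq_along(starts) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$id <- seq_len(nrow(out))
  attr(out, "bin_size") <- as.integer(bin_size)
  class(out) <- c("genome_bins", "data.frame")
  out
}

validate_bins <- function(bins) {
  stopifnot(inherits(bins, "genome_bins"))
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (any(diff(b$start) != (b$end[-nrow(b)] - b$start[-nrow(b)])))
      stop_sc("bins on %s are not contiguous", ch)
  }
  invisible(bins)
}

#' Read a HiC-Pro abs-BED bin file and sparse matrix file
#'
#' The bins file is tab-separated (chrom, start, end, global id); the
#' matrix file is tab-separated (idA, idB, IF). Entries are canonicalised
#' to idA < idB; self interactions (idA == idB) are dropped — the model
#' never uses them.
#'
#' @param bins_path path to the abs-BED file.
#' @param matrix_path path to the 3-column sparse matrix file.
#' @return list with `bins` (a `genome_bins`) and `entries` (data.frame
#'   `id1`, `id2`, `IF` with `id1 < id2`).
#' @export
read_hicpro <- function(bins_path, matrix_path) {
  braw <- data.table::fread(bins_path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1),
                            data.table = FALSE)
  if (ncol(braw) < 4L) stop_sc("bins file needs 4 columns (chrom, start, end, id)")
  names(braw)[1:4] <- c("chrom", "start", "end", "id")
  braw <- braw[, 1:4]
  ord <- order(braw$id)
  braw <- braw[ord, , drop = FALSE]
  # per-chromosome 0-based bin index; chromosomes keep file order of first id
  braw$bin <- stats::ave(braw$start, braw$chrom,
                         FUN = function(x) seq_along(x) - 1)
  braw$bin <- as.integer(braw$bin)
  sizes <- braw$end - braw$start
  attr(braw, "bin_size") <- as.integer(max(sizes))
  class(braw) <- c("genome_bins", "data.frame")

  info <- file.info(matrix_path)
  if (is.na(info$size)) stop_sc("matrix file not found: %s", matrix_path)
  if (info$size == 0) {
    entries <- data.frame(id1 = integer(), id2 = integer(), IF = numeric())
    return(list(bins = braw, entries = entries))
  }
  m <- data.table::fread(matrix_path, header = FALSE, sep = "\t",
                         data.table = FALSE)
  if (ncol(m) < 3L) stop_sc("matrix file needs 3 columns (idA, idB, IF)")
  names(m)[1:3] <- c("id1", "id2", "IF")
  m <- m[, 1:3]
  if (!is.numeric(m$IF)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m$IF))))[1]
    stop_sc("non-numeric IF at matrix line %d", bad)
  }
  known <- braw$id
  miss <- !(m$id1 %in% known & m$id2 %in% known)
  if (any(miss))
    stop_sc("matrix line %d references unknown bin id %s", which(miss)[1],
            paste(setdiff(unique(c(m$id1[miss], m$id2[miss])), known)[1]))
  keep <- m$id1 != m$id2
  m <- m[keep, , drop = FALSE]
  swap <- m$id1 > m$id2
  if (any(swap)) {
    tmp <- m$id1[swap]; m$id1[swap] <- m$id2[swap]; m$id2[swap] <- tmp
  }
  rownames(m) <- NULL
  list(bins = braw, entries = m)
}

#' Extract one chromosome's cis contacts
#'
#' Keeps only entries with both ends on `chrom` and re-indexes them to
#' 0-based chromosome-local bin indices.
#'
#' @param bins a `genome_bins`.
#' @param entries entry data.frame from [read_hicpro()].
#' @param chrom chromosome id.
#' @return a `cis_matrix`: list with `chrom`, `n_bins`, and data.frame
#'   `entries` (`i`, `j`, `IF`; `i < j`, 0-based).
#' @export
extract_cis <- function(bins, entries, chrom) {
  if (!chrom %in% bins$chrom)
    stop_sc("unknown chromosome '%s' (available: %s)", chrom,
            paste(unique(bins$chrom), collapse = ", "))
  b <- bins[bins$chrom == chrom, ]
  id2bin <- stats::setNames(b$bin, b$id)
  on_ch <- entries$id1 %in% b$id & entries$id2 %in% b$id
  e <- entries[on_ch, , drop = FALSE]
  out <- data.frame(i = unname(id2bin[as.character(e$id1)]),
                    j = unname(id2bin[as.character(e$id2)]),
                    IF = e$IF)
  if (nrow(out)) {
    swap <- out$i > out$j
    tmp <- out$i[swap]; out$i[swap] <- out$j[swap]; out$j[swap] <- tmp
    out <- out[order(out$i, out$j), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(list(chrom = chrom, n_bins = nrow(b), entries = out,
                 bin_size = attr(bins, "bin_size") %||% 150000L),
            class = "cis_matrix")
}

#' Interaction-frequency threshold summary
#'
#' Mean, median, and percentile thresholds over the nonzero cis entries,
#' with the fraction of entries strictly above each — the table the
#' modeling cutoff choice is based on. Percentiles use linear interpolation
#' between order statistics (the inclusive convention, `quantile` type 7).
#'
#' @param cis a `cis_matrix`.
#' @param q percentile in (0, 100); default 35.
#' @return a `threshold_set`: list with `mean`, `median`, `percentile`,
#'   `q`, and `frac_above` (percent strictly above each threshold).
#' @export
if_thresholds <- function(cis, q = 35) {
  stopifnot(inherits(cis, "cis_matrix"), q > 0, q < 100)
  x <- cis$entries$IF
  if (length(x) == 0L) stop_sc("no cis contacts on %s", cis$chrom)
  thr <- c(mean = mean(x), median = stats::median(x),
           percentile = unname(stats::quantile(x, q / 100, type = 7)))
  frac <- vapply(thr, function(t) 100 * mean(x > t), numeric(1))
  structure(list(mean = thr[["mean"]], median = thr[["median"]],
                 percentile = thr[["percentile"]], q = q,
                 frac_above = frac, n = length(x)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("IF thresholds over %d cis contacts\n", x$n))
  cat(sprintf("  mean  %.4g  (%.2f%% above)\n", x$mean, x$frac_above[["mean"]]))
  cat(sprintf("  median %.4g (%.2f%% above)\n", x$median, x$frac_above[["median"]]))
  cat(sprintf("  p%g   %.4g  (%.2f%% above)\n", x$q, x$percentile,
              x$frac_above[["percentile"]]))
  invisible(x)
}

#' Select Hi-C modeling constraints by IF cutoff
#'
#' Constraints are the cis entries with IF strictly greater than the cutoff
#' (ties at the cutoff are excluded). In `explicit` mode a pre-filtered
#' pair list (e.g. significant FitHiC interactions) is used as-is.
#'
#' @param cis a `cis_matrix`.
#' @param mode one of `"mean"`, `"median"`, `"percentile"`, `"explicit"`.
#' @param q percentile used when `mode = "percentile"`.
#' @param explicit data.frame with columns `i`, `j` (0-based bin indices,
#'   optionally `IF`) for `mode = "explicit"`.
#' @return a `constraint_set`: list with `chrom`, `cutoff`, `provenance`,
#'   `constraints` (data.frame `i`, `j`, `IF`), `n_source`, `pct_retained`.
#' @export
select_constraints <- function(cis, mode = c("mean", "median", "percentile",
                                             "explicit"),
                               q = 35, explicit = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cis, "cis_matrix"))
  e <- cis$entries
  if (mode == "explicit") {
    if (is.null(explicit)) stop_sc("explicit mode requires a pair list")
    if (!all(c("i", "j") %in% names(explicit)))
      stop_sc("explicit list needs columns i, j")
    bad <- explicit$i < 0 | explicit$j < 0 |
      explicit$i >= cis$n_bins | explicit$j >= cis$n_bins
    if (any(bad)) stop_sc("explicit list references unknown bins (row %d)",
                          which(bad)[1])
    cons <- explicit
    if (!"IF" %in% names(cons)) {
      key <- paste(e$i, e$j)
      cons$IF <- e$IF[match(paste(cons$i, cons$j), key)]
    }
    cutoff <- NA_real_
    prov <- "explicit-list"
  } else {
    th <- if_thresholds(cis, q = q)
    cutoff <- switch(mode, mean = th$mean, median = th$median,
                     percentile = th$percentile)
    cons <- e[e$IF > cutoff, , drop = FALSE]
    prov <- if (mode == "percentile") sprintf("percentile(%g)", q) else mode
    if (nrow(cons) == 0L)
      warn_sc("cutoff %.4g is at or above the maximum IF: empty constraint set",
              cutoff)
  }
  rownames(cons) <- NULL
  structure(list(chrom = cis$chrom, cutoff = cutoff, provenance = prov,
                 constraints = cons, n_source = nrow(e),
                 pct_retained = if (nrow(e)) 100 * nrow(cons) / nrow(e)
                                else NA_real_),
            class = "constraint_set")
}

#' Read a FitHiC-style significant-interaction file as an explicit pair list
#'
#' Expects tab-separated columns (chr1, mid1, chr2, mid2, ...); only cis
#' rows on `chrom` are kept and fragment midpoints are mapped to bins.
#'
#' @param path FitHiC output path (plain text, optional header).
#' @param bins a `genome_bins`.
#' @param chrom chromosome to extract.
#' @return data.frame with columns `i`, `j` suitable for
#'   [select_constraints()] explicit mode.
#' @export
read_fithic <- function(path, bins, chrom) {
  d <- data.table::fread(path, header = "auto", sep = "\t", data.table = FALSE)
  if (ncol(d) < 4L) stop_sc("FitHiC file needs at least 4 columns")
  names(d)[1:4] <- c("chr1", "mid1", "chr2", "mid2")
  d <- d[d$chr1 == chrom & d$chr2 == chrom, , drop = FALSE]
  b <- bins[bins$chrom == chrom, ]
  bs <- attr(bins, "bin_size") %||% 150000L
  to_bin <- function(mid) {
    idx <- findInterval(mid, b$start)
    if (any(idx < 1L | mid >= max(b$end)))
      stop_sc("FitHiC midpoint outside binned chromosome %s", chrom)
    b$bin[idx]
  }
  i <- to_bin(d$mid1); j <- to_bin(d$mid2)
  sw <- i > j
  tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
  keep <- i != j
  unique(data.frame(i = i[keep], j = j[keep]))
}

#' Sequencing depth (fold coverage) of a paired-end library
#'
#' `depth = n_paired_reads * 2 * read_length / genome_size`, returned
#' unrounded.
#'
#' @param n_paired_reads number of read pairs.
#' @param read_length read length in bp.
#' @param genome_size assembly size in bp.
#' @return fold coverage as a plain number.
#' @examples
#' sequencing_depth(174148156, 150, 884566040) # 59.06 for a muscle Hi-C library
#' @export
sequencing_depth <- function(n_paired_reads, read_length, genome_size) {
  stopifnot(n_paired_reads > 0, read_length > 0)
  if (genome_size <= 0) stop_sc("genome size must be positive")
  n_paired_reads * 2 * read_length / genome_size
}
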