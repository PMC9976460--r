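# Gene-to-bead mapping, ALG/nonALG bin classification, microsynteny block
# detection and randomisation, and Fisher-exact chromosome homology.

#' Assign genes to genome bins by midpoint
#'
#' Each gene lands in the bin containing its midpoint — one gene, one bead,
#' so downstream density statistics never double count. Genes whose
#' midpoint falls beyond the last bin of their chromosome are assigned to
#' that last bin with a warning.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open bp) and optionally `strand`, `orthogroup`, `alg`.
#' @param bins a `genome_bins` from [make_bins()] or [read_hicpro()].
#' @return a `bin_annotation`: list with `genes` (the input plus a 0-based
#'   `bin` column), `bins`, and a per-bin `status` factor (filled by
#'   [classify_alg_bins()], initially all computed from `orthogroup`/`alg`
#'   columns when present).
#' @export
map_genes_to_bins <- function(genes, bins) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            all(genes$start < genes$end))
  if (anyDuplicated(genes$gene_id))
    stop_sc("duplicated gene ids in annotation")
  unknown <- setdiff(unique(genes$chrom), unique(bins$chrom))
  if (length(unknown))
    stop_sc("gene chromosome(s) not in bins: %s", paste(unknown, collapse = ", "))
  genes$bin <- NA_integer_
  n_clamped <- 0L
  for (ch in unique(genes$chrom)) {
    b <- bins[bins$chrom == ch, ]
    sel <- genes$chrom == ch
    mid <- floor((genes$start[sel] + genes$end[sel]) / 2)
    idx <- findInterval(mid, b$start)
    over <- mid >= max(b$end)
    n_clamped <- n_clamped + sum(over)
    idx[idx > nrow(b)] <- nrow(b)
    genes$bin[sel] <- b$bin[idx]
  }
  if (n_clamped > 0L)
    warn_sc("%d gene(s) beyond the binned chromosome end; assigned to the last bin",
            n_clamped)
  ann <- structure(list(genes = genes, bins = bins), class = "bin_annotation")
  if (all(c("orthogroup", "alg") %in% names(genes)))
    ann <- classify_alg_bins(ann, genes$gene_id[!is.na(genes$alg)])
  ann
}

#' Classify bins as ALG, nonALG, or unannotated
#'
#' A bin counts as ALG content if at least one of its genes carries an
#' ancestral-linkage-group label (low resolution mixes ALG and nonALG
#' genes inside one 150 kb bead; presence wins). Bins with orthologous but
#' no ALG genes are nonALG; bins without orthologous genes are
#' unannotated.
#'
#' @param ann a `bin_annotation`.
#' @param alg_genes character vector of ALG-labelled gene ids (must be a
#'   subset of the annotation's genes).
#' @return the annotation with a `status` data.frame (`chrom`, `bin`,
#'   `status`).
#' @export
classify_alg_bins <- function(ann, alg_genes) {
  g <- ann$genes
  bad <- setdiff(alg_genes, g$gene_id)
  if (length(bad)) stop_sc("unknown ALG gene id(s): %s", paste(head(bad, 3), collapse = ", "))
  g$is_alg <- g$gene_id %in% alg_genes
  g$is_orth <- if ("orthogroup" %in% names(g)) !is.na(g$orthogroup) else g$is_alg
  key <- paste(g$chrom, g$bin)
  has_alg <- tapply(g$is_alg, key, any)
  has_orth <- tapply(g$is_orth, key, any)
  st <- rep("unannotated", nrow(ann$bins))
  bkey <- paste(ann$bins$chrom, ann$bins$bin)
  m <- match(names(has_alg), bkey)
  st[m[has_alg]] <- "ALG"
  st[m[!has_alg & has_orth]] <- "nonALG"
  ann$status <- data.frame(chrom = ann$bins$chrom, bin = ann$bins$bin,
                           status = factor(st, levels = c("ALG", "nonALG",
                                                          "unannotated")))
  ann
}

# Split an orthogroup set S by the gap rule in one species: member genes
# (orthogroup in S) on one chromosome are chained while at most
# max_intervening non-member genes separate consecutive members.
split_by_gaps <- function(S, genes_ch, max_intervening) {
  idx <- which(genes_ch$orthogroup %in% S)
  if (!length(idx)) return(list())
  breaks <- which(diff(idx) - 1L > max_intervening)
  grp <- cumsum(c(1L, seq_along(idx)[-1] %in% (breaks + 1L)))
  lapply(split(idx, grp), function(ix) unique(genes_ch$orthogroup[ix]))
}

#' Detect microsyntenic blocks between two species
#'
#' A block is a maximal set of shared orthogroups such that, in BOTH
#' species, sorting the member genes by chromosomal position leaves at
#' most `max_intervening` non-member genes between consecutive members.
#' Gene order and strand within a block are not required to match
#' (order-free definition: deep conservation survives local scrambling).
#' Blocks with fewer than `min_genes` orthogroups are discarded.
#'
#' @param genes_a,genes_b gene tables (columns `gene_id`, `chrom`, `start`,
#'   `end`, `orthogroup`; `orthogroup` NA for non-orthologous genes).
#' @param min_genes minimum shared orthogroups per block (default 3).
#' @param max_intervening maximum non-member genes between consecutive
#'   members (default 5).
#' @return list of `microsynteny_block`s: each with `orthogroups`,
#'   `chrom_a`, `chrom_b`, per-species gene data.frames and bp spans.
#' @export
detect_microsynteny <- function(genes_a, genes_b, min_genes = 3L,
                                max_intervening = 5L) {
  for (g in list(genes_a, genes_b))
    if (anyDuplicated(g$gene_id)) stop_sc("duplicated gene ids")
  ga <- genes_a[order(genes_a$chrom, genes_a$start), ]
  gb <- genes_b[order(genes_b$chrom, genes_b$start), ]
  ga_by <- split(ga, ga$chrom)
  gb_by <- split(gb, gb$chrom)
  blocks <- list()
  for (ca in names(ga_by)) for (cb in names(gb_by)) {
    shared <- intersect(stats::na.omit(ga_by[[ca]]$orthogroup),
                        stats::na.omit(gb_by[[cb]]$orthogroup))
    if (length(shared) < min_genes) next
    queue <- list(shared)
    seen <- character()
    while (length(queue)) {
      S <- queue[[1]]; queue <- queue[-1]
      if (length(S) < min_genes) next
      key <- paste(sort(S), collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      stable <- TRUE
      for (gch in list(ga_by[[ca]], gb_by[[cb]])) {
        parts <- split_by_gaps(S, gch, max_intervening)
        whole <- vapply(parts, function(p) setequal(p, S), logical(1))
        if (!(length(parts) == 1L && whole[1])) {
          queue <- c(queue, parts[!whole])
          if (!any(whole)) { stable <- FALSE; break }
        }
      }
      if (!stable) next
      sa <- ga_by[[ca]][ga_by[[ca]]$orthogroup %in% S, ]
      sb <- gb_by[[cb]][gb_by[[cb]]$orthogroup %in% S, ]
      blocks[[length(blocks) + 1L]] <- structure(
        list(orthogroups = sort(S), chrom_a = ca, chrom_b = cb,
             genes_a = sa, genes_b = sb,
             span_a = c(min(sa$start), max(sa$end)),
             span_b = c(min(sb$start), max(sb$end))),
        class = "microsynteny_block")
    }
  }
  blocks
}

#' Sample random blocks matched to an observed microsyntenic block
#'
#' Draws `n` contiguous runs of orthologous genes with the same gene count
#' as the observed block, each starting at a uniformly sampled position in
#' the orthologous-gene order — genome-wide or restricted to the block's
#' own chromosome.
#'
#' @param block a `microsynteny_block` (its species-A gene count sets the
#'   run length) or an integer run length.
#' @param genes gene table of the species being sampled (needs
#'   `orthogroup`).
#' @param n number of random blocks (default 100).
#' @param mode `"genome"` or `"chromosome"`.
#' @param seed RNG seed.
#' @param chrom chromosome for `mode = "chromosome"`; defaults to the
#'   block's chromosome.
#' @return list of `n` data.frames of sampled genes.
#' @export
sample_random_blocks <- function(block, genes, n = 100L,
                                 mode = c("genome", "chromosome"),
                                 seed = 1L, chrom = NULL) {
  mode <- match.arg(mode)
  k <- if (inherits(block, "microsynteny_block")) nrow(block$genes_a)
       else as.integer(block)
  stopifnot(k >= 1L)
  orth <- genes[!is.na(genes$orthogroup), ]
  orth <- orth[order(orth$chrom, orth$start), ]
  if (mode == "chromosome") {
    chrom <- chrom %||% if (inherits(block, "microsynteny_block")) block$chrom_a
                        else stop_sc("chromosome mode needs `chrom`")
    orth <- orth[orth$chrom == chrom, ]
  }
  starts <- do.call(rbind, lapply(split(seq_len(nrow(orth)), orth$chrom),
                                  function(ix) {
    if (length(ix) < k) return(NULL)
    data.frame(first = ix[seq_len(length(ix) - k + 1L)])
  }))
  if (is.null(starts) || nrow(starts) == 0L)
    stop_sc("sampling universe too small for block size %d", k)
  with_seed(seed, {
    picks <- starts$first[sample.int(nrow(starts), n, replace = TRUE)]
    lapply(picks, function(s) orth[s:(s + k - 1L), ])
  })
}

#' Chromosome homology by Fisher exact test on shared one-to-one orthologs
#'
#' For every chromosome pair, the 2x2 table of orthologs on/off the pair
#' is tested one-sided for enrichment against the gene-permutation null
#' (hypergeometric), with Benjamini-Hochberg correction across all pairs;
#' pairs with `q < alpha` are called homologous.
#'
#' @param orthologs data.frame with columns `orthogroup`, `chrom_a`,
#'   `chrom_b` (one row per one-to-one ortholog).
#' @param alpha FDR threshold for homology calls (default 0.05).
#' @return a `homology_matrix` data.frame: `chrom_a`, `chrom_b`, `n_shared`,
#'   `p`, `q`, `homologous`.
#' @export
chromosome_homology <- function(orthologs, alpha = 0.05) {
  if (nrow(orthologs) == 0L) stop_sc("empty ortholog set")
  tab <- table(orthologs$chrom_a, orthologs$chrom_b)
  total <- sum(tab)
  rows <- expand.grid(chrom_a = rownames(tab), chrom_b = colnames(tab),
                      stringsAsFactors = FALSE)
  rows$n_shared <- mapply(function(a, b) tab[a, b], rows$chrom_a, rows$chrom_b)
  rows$p <- mapply(function(a, b) {
    x <- tab[a, b]
    m <- sum(tab[a, ])          # orthologs on chromosome a of species A
    nn <- sum(tab[, b])         # orthologs on chromosome b of species B
    stats::phyper(x - 1, m, total - m, nn, lower.tail = FALSE)
  }, rows$chrom_a, rows$chrom_b)
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows$homologous <- rows$q < alpha
  class(rows) <- c("homology_matrix", "data.frame")
  rows
}

#' Clade-presence filter for blocks
#'
#' Generic ancestral-presence predicate over a user-supplied species
#' grouping: a block passes if it is present in at least `min_per_ingroup`
#' species of every ingroup, or in at least `min_per_ingroup` species of
#' one ingroup plus at least one outgroup species.
#'
#' @param present character vector of species in which the block was
#'   detected.
#' @param ingroups list of character vectors (species per ingroup).
#' @param outgroup character vector of outgroup species.
#' @param min_per_ingroup minimum species per ingroup (default 2).
#' @return logical.
#' @export
clade_presence_filter <- function(present, ingroups, outgroup = character(),
                                  min_per_ingroup = 2L) {
  counts <- vapply(ingroups, function(g) sum(present %in% g), integer(1))
  all(counts >= min_per_ingroup) ||
    (any(counts >= min_per_ingroup) && any(present %in% outgroup))
}
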