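# Seeded synthetic-data generator: known 3D structures, distance-decay
# contact matrices in HiC-Pro format, and two pseudo-species gene /
# orthology / ALG / microsynteny annotations with a planted-truth manifest.

#' Generate a known 3D bead structure
#'
#' `sarw` draws a self-avoiding random walk; `helix` and `rosette` have
#' closed-form coordinates (constant consecutive spacing for the helix),
#' handy for analytic checks and for structures rich in long-range
#' contacts.
#'
#' @param n_beads number of beads (>= 2).
#' @param motif `"sarw"`, `"helix"`, or `"rosette"`.
#' @param seed RNG seed (only the walk consumes randomness).
#' @param step consecutive bead spacing, nm (helix/rosette approximate it).
#' @return n x 3 coordinate matrix.
#' @export
make_structure <- function(n_beads, motif = c("sarw", "helix", "rosette"),
                           seed = 1L, step = 50) {
  motif <- match.arg(motif)
  stopifnot(n_beads >= 2L)
  i <- seq_len(n_beads) - 1L
  switch(motif,
    sarw = init_sarw(n_beads, step_length = step, exclusion = 0.9 * step,
                     seed = seed),
    helix = {
      dtheta <- 0.6
      radius <- 2 * step
      dz <- sqrt(max(step^2 - (2 * radius * sin(dtheta / 2))^2, (0.1 * step)^2))
      cbind(radius * cos(i * dtheta), radius * sin(i * dtheta), i * dz)
    },
    rosette = {
      # petal-looped curve: revisits the core, creating long-range contacts
      theta <- i * (4 * pi / n_beads)
      radius <- step * n_beads / (2 * pi) * 0.25 * (1 + 0.6 * cos(3 * theta))
      cbind(radius * cos(theta), radius * sin(theta), i * (0.2 * step))
    })
}

#' Simulate a cis contact matrix from a known structure
#'
#' Interaction frequencies follow a power-law distance decay,
#' `IF_ij = scale * (d_ij / d_ref)^(-alpha)`, optionally Poisson-sampled;
#' zero draws are dropped (a sparse matrix never stores them).
#'
#' @param conf n x 3 coordinate matrix.
#' @param alpha decay exponent (>= 0; 1 = generic polymer-like decay).
#' @param scale expected IF at the reference distance.
#' @param d_ref reference distance, nm.
#' @param noise `"none"` or `"poisson"`.
#' @param seed RNG seed (used only for Poisson noise).
#' @param chrom chromosome id stored in the matrix.
#' @param bin_size bin size in bp.
#' @return a `cis_matrix` over all bead pairs (minus dropped zeros).
#' @export
contacts_from_structure <- function(conf, alpha = 1, scale = 10, d_ref = 50,
                                    noise = c("none", "poisson"), seed = 1L,
                                    chrom = "chrS", bin_size = 150000L) {
  noise <- match.arg(noise)
  n <- nrow(conf)
  d <- as.matrix(stats::dist(conf))
  up <- which(upper.tri(d), arr.ind = TRUE)
  dd <- d[up]
  if (any(dd <= 0)) stop_sc("structure has coincident beads")
  ifv <- scale * (dd / d_ref)^(-alpha)
  if (noise == "poisson")
    ifv <- with_seed(seed, stats::rpois(length(ifv), ifv))
  keep <- ifv > 0
  e <- data.frame(i = up[keep, 1] - 1L, j = up[keep, 2] - 1L, IF = ifv[keep])
  e <- e[order(e$i, e$j), ]
  rownames(e) <- NULL
  structure(list(chrom = chrom, n_bins = n, entries = e,
                 bin_size = as.integer(bin_size)),
            class = "cis_matrix")
}

# Lay one chromosome out as a unit sequence: ortholog units (planted
# blocks or single orthologs) separated by >= gap filler genes, padded
# with fillers to n_genes. Returns a character vector of unit tokens.
layout_units <- function(units, n_genes, gap) {
  used <- sum(lengths(units)) + gap * (length(units) + 1L)
  if (used > n_genes)
    stop_sc("infeasible packing: %d slots needed, %d genes per chromosome",
            used, n_genes)
  tokens <- character()
  for (u in units) tokens <- c(tokens, rep("", gap), u)
  c(tokens, rep("", n_genes - length(tokens)))
}

#' Generate two pseudo-species genomes with planted synteny
#'
#' Builds two species with a one-to-one homologous chromosome map.
#' Orthologous genes come in "units": planted microsyntenic blocks
#' (contiguous runs of `block_size` orthogroups kept contiguous in both
#' species, with scrambled internal order in species B) and single
#' orthologs. A fraction `alg_fraction` of the single orthologs keep their
#' ancestral chromosome in species B (ALG genes, as do all block genes);
#' the rest move to a different chromosome (nonALG). Ortholog units are
#' separated by more than `max_intervening` filler genes in both species,
#' so on noise-free output the planted blocks are exactly the detectable
#' microsyntenies.
#'
#' @param n_chrom chromosomes per species.
#' @param genes_per_chrom genes per chromosome.
#' @param alg_fraction fraction of single orthologs retaining their
#'   ancestral chromosome (default 0.4, the ALG/nonALG balance regime of
#'   chromosome-scale animal assemblies).
#' @param n_blocks planted microsyntenic blocks (spread round-robin over
#'   chromosome pairs).
#' @param block_size orthogroups per planted block (>= 3).
#' @param singles_per_chrom single-ortholog units per chromosome.
#' @param chrom_len chromosome length in bp (default 50 beads of 150 kb).
#' @param max_intervening gap rule the layout must defeat (default 5).
#' @param seed RNG seed; everything is deterministic given it.
#' @return list with `genes_a`, `genes_b` (gene tables), `orthology`
#'   (gene_id, orthogroup), `alg` (gene_id, alg), `orthologs` (one row per
#'   orthogroup with both chromosomes), and `truth` (planted blocks,
#'   homologous pairs, parameters).
#' @export
make_genomes <- function(n_chrom = 8L, genes_per_chrom = 100L,
                         alg_fraction = 0.4, n_blocks = 3L, block_size = 4L,
                         singles_per_chrom = 12L,
                         chrom_len = 50L * 150000L, max_intervening = 5L,
                         seed = 1L) {
  stopifnot(n_chrom >= 1L, block_size >= 3L, alg_fraction >= 0,
            alg_fraction <= 1, n_chrom >= 2L || alg_fraction == 1)
  gap <- max_intervening + 1L
  og_counter <- 0L
  new_og <- function(k) {
    ids <- sprintf("OG%05d", og_counter + seq_len(k))
    og_counter <<- og_counter + k
    ids
  }
  blocks_per_pair <- tabulate((seq_len(n_blocks) - 1L) %% n_chrom + 1L,
                              nbins = n_chrom)
  with_seed(seed, {
    units_a <- vector("list", n_chrom)   # per A chromosome: list of og vectors
    unit_alg <- vector("list", n_chrom)  # TRUE if unit keeps its chromosome
    unit_block <- vector("list", n_chrom)
    truth_blocks <- list()
    for (ch in seq_len(n_chrom)) {
      us <- list(); alg <- logical(); blk <- logical()
      for (b in seq_len(blocks_per_pair[ch])) {
        ogs <- new_og(block_size)
        us <- c(us, list(ogs)); alg <- c(alg, TRUE); blk <- c(blk, TRUE)
        truth_blocks[[length(truth_blocks) + 1L]] <-
          list(orthogroups = ogs, chrom_a = sprintf("chrA%d", ch),
               chrom_b = sprintf("chrB%d", ch))
      }
      n_alg_singles <- round(alg_fraction * singles_per_chrom)
      for (s in seq_len(singles_per_chrom)) {
        us <- c(us, list(new_og(1L)))
        alg <- c(alg, s <= n_alg_singles); blk <- c(blk, FALSE)
      }
      ord <- sample.int(length(us))
      units_a[[ch]] <- us[ord]
      unit_alg[[ch]] <- alg[ord]
      unit_block[[ch]] <- blk[ord]
    }
    # destination chromosome in species B per unit; nonALG units rotate
    # evenly over the other chromosomes so no B chromosome overflows
    units_b <- lapply(seq_len(n_chrom), function(i) list())
    for (ch in seq_len(n_chrom)) {
      moved <- which(!unit_alg[[ch]])
      others <- setdiff(seq_len(n_chrom), ch)
      dests <- rep_len(others[sample.int(length(others))], length(moved))
      for (k in seq_along(units_a[[ch]])) {
        u <- units_a[[ch]][[k]]
        dest <- if (unit_alg[[ch]][k]) ch else dests[match(k, moved)]
        if (length(u) > 1L) u <- sample(u)  # scramble order inside blocks
        units_b[[dest]] <- c(units_b[[dest]], list(u))
      }
    }
    units_b <- lapply(units_b, function(us) if (length(us)) us[sample.int(length(us))] else us)

    build_species <- function(units_by_chrom, prefix) {
      rows <- list()
      spacing <- chrom_len / genes_per_chrom
      glen <- min(2000, floor(spacing * 0.8))
      for (ch in seq_along(units_by_chrom)) {
        tokens <- layout_units(units_by_chrom[[ch]], genes_per_chrom, gap)
        starts <- round((seq_along(tokens) - 1L) * spacing) + 100
        rows[[ch]] <- data.frame(
          gene_id = sprintf("%s%d_g%03d", prefix, ch, seq_along(tokens)),
          chrom = sprintf("chr%s%d", prefix, ch),
          start = starts, end = starts + glen,
          strand = sample(c("+", "-"), length(tokens), replace = TRUE),
          orthogroup = ifelse(tokens == "", NA_character_, tokens),
          stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }
    genes_a <- build_species(units_a, "A")
    genes_b <- build_species(units_b, "B")
  })
  # ALG labels: orthologs that kept their ancestral chromosome in both species
  og_chrom_a <- stats::setNames(genes_a$chrom, genes_a$orthogroup)
  og_chrom_b <- stats::setNames(genes_b$chrom, genes_b$orthogroup)
  shared <- intersect(names(og_chrom_a), names(og_chrom_b))
  shared <- shared[!is.na(shared)]
  alg_og <- shared[sub("chrA", "", og_chrom_a[shared]) ==
                     sub("chrB", "", og_chrom_b[shared])]
  alg_label <- stats::setNames(paste0("ALG", sub("chrA", "", og_chrom_a[alg_og])),
                               alg_og)
  alg_tab <- rbind(
    data.frame(gene_id = genes_a$gene_id[genes_a$orthogroup %in% alg_og],
               alg = unname(alg_label[genes_a$orthogroup[genes_a$orthogroup %in% alg_og]])),
    data.frame(gene_id = genes_b$gene_id[genes_b$orthogroup %in% alg_og],
               alg = unname(alg_label[genes_b$orthogroup[genes_b$orthogroup %in% alg_og]])))
  genes_a$alg <- ifelse(genes_a$orthogroup %in% alg_og,
                        unname(alg_label[genes_a$orthogroup]), NA_character_)
  genes_b$alg <- ifelse(genes_b$orthogroup %in% alg_og,
                        unname(alg_label[genes_b$orthogroup]), NA_character_)
  orthology <- rbind(
    genes_a[!is.na(genes_a$orthogroup), c("gene_id", "orthogroup")],
    genes_b[!is.na(genes_b$orthogroup), c("gene_id", "orthogroup")])
  orthologs <- data.frame(orthogroup = shared,
                          chrom_a = unname(og_chrom_a[shared]),
                          chrom_b = unname(og_chrom_b[shared]))
  list(genes_a = genes_a, genes_b = genes_b, orthology = orthology,
       alg = alg_tab, orthologs = orthologs,
       truth = list(blocks = truth_blocks,
                    homologous_pairs = data.frame(
                      chrom_a = sprintf("chrA%d", seq_len(n_chrom)),
                      chrom_b = sprintf("chrB%d", seq_len(n_chrom))),
                    params = list(n_chrom = n_chrom,
                                  genes_per_chrom = genes_per_chrom,
                                  alg_fraction = alg_fraction,
                                  n_blocks = n_blocks,
                                  block_size = block_size,
                                  singles_per_chrom = singles_per_chrom,
                                  chrom_len = chrom_len,
                                  max_intervening = max_intervening,
                                  seed = seed)))
}

#' Write a complete synthetic input bundle
#'
#' Emits everything the pipeline consumes, all as plain text: a HiC-Pro
#' abs-BED bin table and sparse matrix built from known per-chromosome 3D
#' structures of species A (with distance-decay contacts), BED-like gene
#' tables for both pseudo-species, orthology and ALG TSVs, the true
#' structures as xyz TSVs, and a self-describing JSON manifest carrying
#' seeds, parameters and the planted truth.
#'
#' @param dir output directory (created if needed).
#' @param n_beads beads per chromosome (chromosome length follows).
#' @param n_chrom chromosomes per species.
#' @param alpha distance-decay exponent of the synthetic contacts.
#' @param noise `"none"` or `"poisson"`.
#' @param motif structure motif passed to [make_structure()].
#' @param seed master seed; all child seeds derive from it.
#' @param ... further arguments for [make_genomes()].
#' @return invisibly, a named list of written file paths plus the
#'   in-memory objects (`genomes`, `structures`, `cis`).
#' @export
write_fixture_bundle <- function(dir, n_beads = 50L, n_chrom = 8L, alpha = 1,
                                 noise = "none", motif = "sarw", seed = 1L,
                                 ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bin_size <- 150000L
  chrom_len <- n_beads * bin_size
  chroms <- sprintf("chrA%d", seq_len(n_chrom))
  bins <- make_bins(stats::setNames(rep(chrom_len, n_chrom), chroms), bin_size)
  sseeds <- derive_seeds(seed, 2L * n_chrom, stream = 3L)
  structures <- list()
  entries <- list()
  for (k in seq_len(n_chrom)) {
    conf <- make_structure(n_beads, motif = motif, seed = sseeds[k])
    cis <- contacts_from_structure(conf, alpha = alpha, noise = noise,
                                   seed = sseeds[n_chrom + k],
                                   chrom = chroms[k], bin_size = bin_size)
    b <- bins[bins$chrom == chroms[k], ]
    entries[[k]] <- data.frame(id1 = b$id[cis$entries$i + 1L],
                               id2 = b$id[cis$entries$j + 1L],
                               IF = cis$entries$IF)
    structures[[chroms[k]]] <- conf
  }
  genomes <- make_genomes(n_chrom = n_chrom, chrom_len = chrom_len,
                          seed = derive_seeds(seed, 1L, stream = 5L), ...)

  paths <- list(
    bins = file.path(dir, "fixture_abs.bed"),
    matrix = file.path(dir, "fixture.matrix"),
    genes_a = file.path(dir, "genes_speciesA.bed"),
    genes_b = file.path(dir, "genes_speciesB.bed"),
    orthology = file.path(dir, "orthology.tsv"),
    alg = file.path(dir, "alg_labels.tsv"),
    manifest = file.path(dir, "manifest.json"))
  data.table::fwrite(as.data.frame(bins)[, c("chrom", "start", "end", "id")],
                     paths$bins, sep = "\t", col.names = FALSE)
  data.table::fwrite(do.call(rbind, entries), paths$matrix, sep = "\t",
                     col.names = FALSE)
  write_gene_bed <- function(g, path) {
    data.table::fwrite(data.frame(g$chrom, g$start, g$end, g$gene_id, 0L,
                                  g$strand),
                       path, sep = "\t", col.names = FALSE)
  }
  write_gene_bed(genomes$genes_a, paths$genes_a)
  write_gene_bed(genomes$genes_b, paths$genes_b)
  data.table::fwrite(genomes$orthology, paths$orthology, sep = "\t")
  data.table::fwrite(genomes$alg, paths$alg, sep = "\t")
  for (ch in names(structures)) {
    p <- file.path(dir, sprintf("truth_%s.xyz.tsv", ch))
    write_xyz(structures[[ch]], p)
    paths[[paste0("truth_", ch)]] <- p
  }
  manifest <- list(seed = seed, n_beads = n_beads, n_chrom = n_chrom,
                   alpha = alpha, noise = noise, motif = motif,
                   bin_size = bin_size,
                   files = lapply(paths, basename),
                   truth = genomes$truth)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, list(genomes = genomes, structures = structures)))
}
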