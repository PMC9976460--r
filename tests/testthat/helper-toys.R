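# Shared small fixtures and independent oracles, built in code.

# Minimal cis_matrix over a bead chain: entry k joins bins (k-1, k) with
# the supplied IF value (plus optional extra pairs).
toy_cis <- function(ifs, n_bins = length(ifs) + 1L, chrom = "toy") {
  e <- data.frame(i = seq_along(ifs) - 1L, j = seq_along(ifs), IF = ifs)
  structure(list(chrom = chrom, n_bins = as.integer(n_bins), entries = e,
                 bin_size = 150000L),
            class = "cis_matrix")
}

random_conf <- function(n, seed, spread = 200) {
  set.seed(seed)
  matrix(stats::rnorm(n * 3, sd = spread), n, 3)
}

# O(n^2) double-loop neighbour recount: the brute-force oracle for
# contact_density (kept deliberately naive and loop-based).
brute_density <- function(conf, r) {
  n <- nrow(conf)
  out <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      if (sqrt(sum((conf[i, ] - conf[j, ])^2)) <= r) cnt <- cnt + 1L
    }
    out[i] <- cnt
  }
  out
}

# Independent gap-rule verifier for a detected block: in each species the
# member genes, sorted by position, must never be separated by more than
# max_intervening non-member genes.
verify_block_gaps <- function(block, genes_a, genes_b, max_intervening = 5L) {
  chk <- function(genes, chrom) {
    g <- genes[genes$chrom == chrom, ]
    g <- g[order(g$start), ]
    pos <- which(g$orthogroup %in% block$orthogroups)
    all(diff(pos) - 1L <= max_intervening)
  }
  chk(genes_a, block$chrom_a) && chk(genes_b, block$chrom_b)
}

# Exact two-sided rank-sum p by full enumeration of group assignments.
perm_rank_sum_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  rk <- rank(pooled)
  obs <- sum(rk[seq_len(m)])
  combs <- utils::combn(length(pooled), m)
  stat <- apply(combs, 2, function(ix) sum(rk[ix]))
  mu <- m * (length(pooled) + 1) / 2
  mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
}

mk_genes <- function(chrom, starts, ogs, prefix = "g", width = 1000) {
  data.frame(gene_id = paste0(prefix, seq_along(starts)), chrom = chrom,
             start = starts, end = starts + width, strand = "+",
             orthogroup = ogs, stringsAsFactors = FALSE)
}
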