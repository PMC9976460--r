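# Comparative spatiosynteny statistics: spatial ratios, randomized
# orthology nulls, the Fasano-Franceschini 2D two-sample test, ALG/nonALG
# contact-class counting, microsynteny contact-density tests, and
# conserved spatial-neighbour discovery.

#' Euclidean and genomic distances for bin pairs of one chromosome model
#'
#' Same-bin pairs carry no genomic distance and are dropped (the count is
#' attached as an attribute). Genomic distance is `|i - j| * bin_size`;
#' the spatial ratio is nm per Mb.
#'
#' @param conf n x 3 coordinate matrix, nm.
#' @param pairs data.frame with 0-based bin columns `i`, `j`.
#' @param bin_size bin size in bp (default 150000).
#' @return data.frame `i`, `j`, `euclid_nm`, `genomic_mb`, `ratio_nm_mb`,
#'   with attribute `n_same_bin_dropped`.
#' @export
pair_distances <- function(conf, pairs, bin_size = 150000) {
  n <- nrow(conf)
  if (any(pairs$i < 0 | pairs$j < 0 | pairs$i >= n | pairs$j >= n))
    stop_sc("bin index out of range for a %d-bead model", n)
  same <- pairs$i == pairs$j
  p <- pairs[!same, , drop = FALSE]
  d <- sqrt(rowSums((conf[p$j + 1L, , drop = FALSE] -
                       conf[p$i + 1L, , drop = FALSE])^2))
  mb <- abs(p$i - p$j) * bin_size / 1e6
  out <- data.frame(i = p$i, j = p$j, euclid_nm = d, genomic_mb = mb,
                    ratio_nm_mb = d / mb)
  attr(out, "n_same_bin_dropped") <- sum(same)
  out
}

#' Fasano-Franceschini two-dimensional two-sample test
#'
#' 2D generalisation of the Kolmogorov-Smirnov test: with each data point
#' of the pooled sample as origin, the plane is split into four quadrants
#' (closed on the lower-left, each point counting itself in its own
#' lower-left quadrant) and the discrepancy at that origin is the largest
#' absolute difference between the two samples' quadrant fractions. The
#' statistic D averages the maximal discrepancy over sample-A origins with
#' that over sample-B origins. The p-value comes from label permutations,
#' which is exact in distribution regardless of sample size.
#'
#' @param a,b two-column numeric matrices (2D samples, >= 5 points each).
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return an `ff_test` list: `statistic`, `p.value`, `n_perm`, `seed`,
#'   `n_a`, `n_b`.
#' @export
ff_test <- function(a, b, n_perm = 999L, seed = 1L) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 2L, ncol(b) == 2L)
  na <- nrow(a); nb <- nrow(b)
  if (na < 5L || nb < 5L) stop_sc("each sample needs at least 5 points")
  pool <- rbind(a, b)
  if (all(abs(sweep(pool, 2, pool[1, ])) < .Machine$double.eps))
    stop_sc("degenerate input: all points identical")
  n <- na + nb
  gx <- outer(pool[, 1], pool[, 1], function(xi, xj) xj > xi)
  gy <- outer(pool[, 2], pool[, 2], function(yi, yj) yj > yi)
  # rows = origins, cols = points; each point counts itself in (<=, <=)
  q <- list(gx & gy, gx & !gy, !gx & gy, !gx & !gy)
  qn <- lapply(q, function(m) matrix(as.numeric(m), n, n))
  tot <- lapply(qn, rowSums)

  perms <- matrix(0, n, n_perm + 1L)
  perms[seq_len(na), 1L] <- 1
  with_seed(seed, {
    for (p in seq_len(n_perm) + 1L)
      perms[sample.int(n, na), p] <- 1
  })
  maxq <- matrix(-Inf, n, n_perm + 1L)
  for (k in 1:4) {
    cntA <- qn[[k]] %*% perms
    diffk <- abs(cntA / na - (tot[[k]] - cntA) / nb)
    maxq <- pmax(maxq, diffk)
  }
  inA <- perms == 1
  mA <- maxq; mA[!inA] <- -Inf
  mB <- maxq; mB[inA] <- -Inf
  d_all <- (matrixStats::colMaxs(mA) + matrixStats::colMaxs(mB)) / 2
  d_obs <- d_all[1]
  p_val <- (1 + sum(d_all[-1] >= d_obs - 1e-12)) / (n_perm + 1)
  structure(list(statistic = d_obs, p.value = p_val, n_perm = n_perm,
                 seed = seed, n_a = na, n_b = nb),
            class = "ff_test")
}

#' @export
print.ff_test <- function(x, ...) {
  cat(sprintf("Fasano-Franceschini 2D test: D = %.4g, p = %.4g (%d permutations, n = %d/%d)\n",
              x$statistic, x$p.value, x$n_perm, x$n_a, x$n_b))
  invisible(x)
}

#' Randomized-orthology null for a pairwise statistic
#'
#' Re-draws the partner assignment of a pair table uniformly `n_runs`
#' times, evaluates `stat_fn` on each permuted table, and reports the
#' per-run values with their median — the background against which the
#' observed pairing is compared. Bonferroni correction over the number of
#' comparisons in a run is the caller's bookkeeping; the factor is echoed
#' in the result.
#'
#' @param pairs data.frame of observed pairings; `partner_cols` names the
#'   columns that constitute the second-species side.
#' @param stat_fn function(data.frame) -> numeric scalar.
#' @param n_runs number of randomized runs (default 10).
#' @param seed RNG seed.
#' @param partner_cols columns permuted together (default `"j"`).
#' @param bonferroni number of comparisons for downstream p adjustment.
#' @return list with `stats` (length `n_runs`), `median_stat`, `perms`,
#'   `observed` (stat on the unpermuted table), `bonferroni`, `seed`.
#' @export
randomized_orthology_null <- function(pairs, stat_fn, n_runs = 10L, seed = 1L,
                                      partner_cols = "j", bonferroni = 1L) {
  stopifnot(nrow(pairs) >= 2L, all(partner_cols %in% names(pairs)))
  seeds <- derive_seeds(seed, n_runs, stream = 17L)
  perms <- lapply(seeds, function(s)
    with_seed(s, sample.int(nrow(pairs))))
  stats <- vapply(perms, function(pm) {
    pp <- pairs
    pp[partner_cols] <- pairs[pm, partner_cols, drop = FALSE]
    stat_fn(pp)
  }, numeric(1))
  list(stats = stats, median_stat = stats::median(stats), perms = perms,
       observed = stat_fn(pairs), bonferroni = as.integer(bonferroni),
       seed = seed)
}

#' ALG/nonALG contact-class counts within interaction spheres
#'
#' Every unordered centre-member pair of the IntSph profile increments the
#' class given by its two bin statuses; pairs involving unannotated beads
#' are excluded. Each pair is counted once even though the centre-member
#' relation sees it twice.
#'
#' @param profile an `intsph_profile` computed with `members = TRUE`.
#' @param status character/factor vector of per-bead statuses
#'   (`"ALG"`, `"nonALG"`, `"unannotated"`), length = bead count.
#' @return a `contact_class_counts` named integer vector
#'   (`ALG-ALG`, `ALG-nonALG`, `nonALG-nonALG`) with attribute `total`.
#' @export
alg_contact_counts <- function(profile, status) {
  if (is.null(profile$members))
    stop_sc("profile must be computed with members = TRUE")
  n <- length(profile$density)
  status <- as.character(status)
  if (length(status) != n) stop_sc("status must cover all %d beads", n)
  ii <- rep.int(seq_len(n), lengths(profile$members))
  jj <- unlist(profile$members, use.names = FALSE)
  keep <- ii < jj                       # dedupe unordered pairs
  ii <- ii[keep]; jj <- jj[keep]
  si <- status[ii]; sj <- status[jj]
  ok <- si != "unannotated" & sj != "unannotated"
  cls <- ifelse(si[ok] == sj[ok],
                paste0(si[ok], "-", sj[ok]),
                "ALG-nonALG")
  out <- c(`ALG-ALG` = sum(cls == "ALG-ALG"),
           `ALG-nonALG` = sum(cls == "ALG-nonALG"),
           `nonALG-nonALG` = sum(cls == "nonALG-nonALG"))
  structure(out, total = sum(out), class = "contact_class_counts")
}

# Rank-sum (Mann-Whitney) two-sided test: exact enumeration for small
# tie-free samples, normal approximation with tie correction otherwise.
rank_sum_test <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) <= 12L && length(y) <= 12L
  if (stats::var(c(x, y)) == 0) return(list(statistic = NA_real_, p = 1))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Contact-density test for microsyntenic vs random IntSphs
#'
#' Compares the contact densities of interaction spheres centred on bins
#' holding at least one observed-block gene against spheres centred on
#' random-block bins, with a two-sided Wilcoxon rank-sum test.
#'
#' @param profile an `intsph_profile` for the chromosome model.
#' @param observed_bins 0-based centre bins of observed blocks.
#' @param random_bins 0-based centre bins of randomized blocks.
#' @return list with `observed_mean`, `observed_median`, `random_mean`,
#'   `random_median`, `statistic`, `p.value`, sample sizes.
#' @export
microsynteny_density_test <- function(profile, observed_bins, random_bins) {
  n <- length(profile$density)
  obs <- profile$density[unique(observed_bins) + 1L]
  ran <- profile$density[random_bins + 1L]
  if (!length(obs) || !length(ran)) stop_sc("empty density sample")
  if (any(c(observed_bins, random_bins) < 0 |
          c(observed_bins, random_bins) >= n))
    stop_sc("bin index out of range")
  ht <- rank_sum_test(obs, ran)
  list(observed_mean = mean(obs), observed_median = stats::median(obs),
       random_mean = mean(ran), random_median = stats::median(ran),
       statistic = ht$statistic, p.value = ht$p,
       n_observed = length(obs), n_random = length(ran))
}

#' Orthogroups in conserved spatial proximity of a query set in two species
#'
#' An orthogroup qualifies when, in BOTH species, at least one of its
#' genes' beads lies within `r` (closed ball) of at least one query-gene
#' bead. Query orthogroups themselves are excluded from the result. A
#' species in which the query is absent contributes no qualification.
#'
#' @param conf_a,conf_b chromosome models (n x 3, nm) of the two species.
#' @param ann_a,ann_b `bin_annotation`s whose genes carry `bin` and
#'   `orthogroup` columns (chromosomes matching the models).
#' @param query_orthogroups orthogroup ids defining the query neighbourhood.
#' @param r sphere radius in nm (default 50).
#' @return sorted character vector of qualifying orthogroup ids.
#' @export
shared_spatial_neighbors <- function(conf_a, conf_b, ann_a, ann_b,
                                     query_orthogroups, r = 50) {
  if (!length(query_orthogroups)) return(character())
  qualify <- function(conf, ann) {
    g <- ann$genes[!is.na(ann$genes$orthogroup), ]
    qbins <- unique(g$bin[g$orthogroup %in% query_orthogroups])
    if (!length(qbins)) {
      message("query orthogroups absent in one species: no qualification")
      return(character())
    }
    qc <- conf[qbins + 1L, , drop = FALSE]
    d2 <- outer(rowSums(conf^2), rowSums(qc^2), "+") - 2 * conf %*% t(qc)
    d2[d2 < 0] <- 0
    near <- sqrt(matrixStats::rowMins(d2)) <= r + 1e-9
    unique(g$orthogroup[near[g$bin + 1L]])
  }
  hits <- intersect(qualify(conf_a, ann_a), qualify(conf_b, ann_b))
  sort(setdiff(hits, query_orthogroups))
}
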