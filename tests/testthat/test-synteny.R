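test_that("map_genes_to_bins uses the midpoint rule", {
  bins <- make_bins(c(chr1 = 600000), 150000)
  genes <- data.frame(
    gene_id = c("inside3", "boundary", "offend"),
    chrom = "chr1",
    start = c(470000, 440000, 599000),
    end = c(480000, 470000, 620000))   # midpoints 475000, 455000, 609500
  expect_warning(ann <- map_genes_to_bins(genes, bins), "last bin")
  expect_equal(ann$genes$bin, c(3L, 3L, 3L))

  genes2 <- data.frame(gene_id = "spanner", chrom = "chr1",
                       start = 440000, end = 465000)  # midpoint 452500 in bin 3
  expect_equal(map_genes_to_bins(genes2, bins)$genes$bin, 3L)
  genes3 <- data.frame(gene_id = "b2", chrom = "chr1",
                       start = 310000, end = 440000)  # midpoint 375000 in bin 2
  expect_equal(map_genes_to_bins(genes3, bins)$genes$bin, 2L)

  # recount oracle on a 10-gene toy
  set.seed(5)
  st <- sort(sample(0:590000, 10))
  g10 <- data.frame(gene_id = paste0("g", 1:10), chrom = "chr1",
                    start = st, end = st + 5000)
  got <- map_genes_to_bins(g10, bins)$genes$bin
  expect_equal(got, as.integer(floor((st + st + 5000) / 2 / 150000)))
})

test_that("classify_alg_bins applies the presence-wins rule", {
  bins <- make_bins(c(chr1 = 600000), 150000)
  g <- data.frame(
    gene_id = paste0("g", 1:6), chrom = "chr1",
    start = c(10000, 20000, 30000, 160000, 170000, 310000),
    end = c(11000, 21000, 31000, 161000, 171000, 311000),
    orthogroup = c("o1", "o2", "o3", "o4", "o5", NA))
  ann <- map_genes_to_bins(g, bins)
  ann <- classify_alg_bins(ann, alg_genes = "g1")   # 1 ALG + 2 nonALG in bin 0
  st <- as.character(ann$status$status)
  expect_equal(st, c("ALG", "nonALG", "unannotated", "unannotated"))
  expect_error(classify_alg_bins(ann, "nope"), "unknown ALG gene")
})

test_that("detect_microsynteny follows the gap and size rules", {
  # identical chromosomes sharing orthogroups at adjacent positions 2,3,4
  a <- mk_genes("c1", (0:9) * 10000,
                c(NA, "s1", "s2", "s3", NA, NA, NA, NA, NA, NA), prefix = "a")
  b <- mk_genes("c1", (0:9) * 10000,
                c(NA, "s1", "s2", "s3", NA, NA, NA, NA, NA, NA), prefix = "b")
  blocks <- detect_microsynteny(a, b)
  expect_length(blocks, 1L)
  expect_setequal(blocks[[1]]$orthogroups, c("s1", "s2", "s3"))

  # a 6-gene gap splits; both 2-orthogroup fragments fall below min_genes
  a2 <- mk_genes("c1", (0:9) * 10000,
                 c("s1", "s2", NA, NA, NA, NA, NA, NA, "s3", "s4"), prefix = "a")
  b2 <- mk_genes("c1", (0:9) * 10000,
                 c("s1", "s2", NA, NA, NA, NA, NA, NA, "s3", "s4"), prefix = "b")
  expect_length(detect_microsynteny(a2, b2), 0L)
  # relaxing the gap rule to 6 intervening genes re-joins them
  expect_length(detect_microsynteny(a2, b2, max_intervening = 6L), 1L)
  # a surviving 3-orthogroup fragment is kept on its own
  a2b <- mk_genes("c1", (0:9) * 10000,
                  c("s1", NA, NA, NA, NA, NA, NA, "s2", "s3", "s4"), prefix = "a")
  b2b <- mk_genes("c1", (0:9) * 10000,
                  c("s1", NA, NA, NA, NA, NA, NA, "s2", "s3", "s4"), prefix = "b")
  frag <- detect_microsynteny(a2b, b2b)
  expect_length(frag, 1L)
  expect_setequal(frag[[1]]$orthogroups, c("s2", "s3", "s4"))

  # 2-gene clusters are rejected by min_genes
  a3 <- mk_genes("c1", (0:3) * 10000, c("s1", "s2", NA, NA), prefix = "a")
  b3 <- mk_genes("c1", (0:3) * 10000, c("s1", "s2", NA, NA), prefix = "b")
  expect_length(detect_microsynteny(a3, b3), 0L)

  # order-free: scrambled order in B still one block
  a4 <- mk_genes("c1", (0:4) * 10000, c("s1", "s2", "s3", "s4", NA), prefix = "a")
  b4 <- mk_genes("c1", (0:4) * 10000, c("s3", "s1", "s4", "s2", NA), prefix = "b")
  b4ok <- detect_microsynteny(a4, b4)
  expect_length(b4ok, 1L)
  expect_setequal(b4ok[[1]]$orthogroups, c("s1", "s2", "s3", "s4"))

  expect_error(detect_microsynteny(rbind(a4, a4), b4), "duplicated")
})

test_that("planted blocks are recovered exactly and verify independently", {
  for (s in c(2, 13, 27)) {
    g <- make_genomes(seed = s)
    blocks <- detect_microsynteny(g$genes_a, g$genes_b)
    truth_keys <- vapply(g$truth$blocks,
                         function(b) paste(sort(b$orthogroups), collapse = ","),
                         character(1))
    det_keys <- vapply(blocks,
                       function(b) paste(sort(b$orthogroups), collapse = ","),
                       character(1))
    expect_setequal(det_keys, truth_keys)
    for (b in blocks)
      expect_true(verify_block_gaps(b, g$genes_a, g$genes_b))
  }
})

test_that("sample_random_blocks draws size-matched uniform contiguous runs", {
  g <- make_genomes(seed = 4)
  blocks <- detect_microsynteny(g$genes_a, g$genes_b)
  rb <- sample_random_blocks(blocks[[1]], g$genes_a, n = 100, seed = 6)
  expect_length(rb, 100L)
  expect_true(all(vapply(rb, nrow, integer(1)) == nrow(blocks[[1]]$genes_a)))
  expect_true(all(vapply(rb, function(b) all(!is.na(b$orthogroup)), logical(1))))
  expect_true(all(vapply(rb, function(b) length(unique(b$chrom)) == 1L,
                         logical(1))))

  rbc <- sample_random_blocks(blocks[[1]], g$genes_a, n = 50,
                              mode = "chromosome", seed = 6)
  expect_true(all(vapply(rbc, function(b) unique(b$chrom), character(1)) ==
                    blocks[[1]]$chrom_a))

  expect_identical(sample_random_blocks(3L, g$genes_a, n = 5, seed = 9),
                   sample_random_blocks(3L, g$genes_a, n = 5, seed = 9))
  expect_error(sample_random_blocks(10000L, g$genes_a), "too small")

  # start positions uniform over the universe: chi-square over 10,000 draws
  toy <- mk_genes("c1", (0:29) * 1000, paste0("o", 1:30))
  draws <- sample_random_blocks(3L, toy, n = 10000, seed = 11)
  first <- vapply(draws, function(b) b$gene_id[1], character(1))
  tab <- table(factor(first, levels = paste0("g", 1:28)))
  chi <- sum((tab - 10000 / 28)^2 / (10000 / 28))
  expect_lt(chi, qchisq(0.999, df = 27))
})

test_that("chromosome_homology matches the hypergeometric closed form", {
  orth <- data.frame(orthogroup = paste0("o", 1:20),
                     chrom_a = rep(c("a1", "a2"), each = 10),
                     chrom_b = rep(c("b1", "b2"), each = 10))
  hm <- chromosome_homology(orth)
  diag_p <- hm$p[hm$chrom_a == "a1" & hm$chrom_b == "b1"]
  expect_equal(diag_p, 1 / choose(20, 10), tolerance = 1e-12)  # ~5.41e-6
  expect_true(all(hm$homologous[hm$chrom_a == sub("b", "a", hm$chrom_b)]))
  expect_false(any(hm$homologous[hm$chrom_a != sub("b", "a", hm$chrom_b)]))
  expect_true(all(hm$q >= hm$p))
  expect_true(all(diff(hm$q[order(hm$p)]) >= -1e-12))  # BH monotone in p
  expect_error(chromosome_homology(orth[0, ]), "empty")
})

test_that("permutation-null chromosome assignments rarely produce calls", {
  set.seed(123)
  n_sim <- 100
  false_call <- 0
  for (k in seq_len(n_sim)) {
    orth <- data.frame(orthogroup = paste0("o", 1:200),
                       chrom_a = sample(paste0("a", 1:5), 200, TRUE),
                       chrom_b = sample(paste0("b", 1:5), 200, TRUE))
    hm <- chromosome_homology(orth)
    if (any(hm$homologous)) false_call <- false_call + 1
  }
  expect_lte(false_call / n_sim, 0.05)
})

test_that("clade_presence_filter implements the ancestral-presence rule", {
  in1 <- c("sp1", "sp2", "sp3"); in2 <- c("sp4", "sp5"); out <- "sp6"
  grps <- list(in1, in2)
  expect_true(clade_presence_filter(c("sp1", "sp2", "sp4", "sp5"), grps, out))
  expect_true(clade_presence_filter(c("sp1", "sp2", "sp6"), grps, out))
  expect_false(clade_presence_filter(c("sp1", "sp4", "sp6"), grps, out))
  expect_false(clade_presence_filter(c("sp1", "sp2"), grps, out))
})
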