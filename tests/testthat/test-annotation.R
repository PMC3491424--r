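test_that("annotate_overlap flags and ratios match the per-bp oracle", {
  asm <- toy_assembly()
  peaks <- make_track(asm, c("chrA", "chrA"), c(1000, 5000), c(2000, 5100),
                      path = "histones:H3K4me1:H1hESC")
  set <- make_regions(asm, c("chrA", "chrA", "chrA"),
                      c(1200, 0, 40000), c(1300, 1000, 41000))
  ov <- annotate_overlap(set, peaks)
  expect_identical(ov$flag, c(TRUE, FALSE, FALSE))
  expect_equal(ov$ratio, c(1, 0, 0))

  quarter <- make_track(asm, "chrA", 0, 250)
  set2 <- make_regions(asm, "chrA", 0, 1000)
  expect_equal(annotate_overlap(set2, quarter)$ratio, 0.25)

  set.seed(13)
  iv <- data.frame(chrom = sample(c("chrA", "chrB"), 40, replace = TRUE),
                   start = sample(0:30000, 40))
  iv$end <- iv$start + sample(1:3000, 40)
  track <- make_track(asm, iv$chrom, iv$start, iv$end)
  start <- sample(0:30000, 80)
  set3 <- make_regions(asm, sample(c("chrA", "chrB"), 80, replace = TRUE),
                       start, start + sample(1:2000, 80))
  ov3 <- annotate_overlap(set3, track)
  for (i in seq_len(80)) {
    r <- as.list(set3$regions[i, ])
    cov <- bf_covered_bp(r, iv)
    expect_identical(ov3$flag[i], cov >= 1)
    expect_equal(ov3$ratio[i], cov / (r$end - r$start))
    expect_identical(ov3$ratio[i] > 0, ov3$flag[i])
  }
  expect_true(all(ov3$ratio >= 0 & ov3$ratio <= 1))
})

test_that("categorical tracks yield one flag per state label", {
  asm <- toy_assembly()
  states <- annotation_track(
    "chromstate", "categorical-interval",
    data.frame(chrom = "chrA", start = c(0, 1000, 2000),
               end = c(1000, 2000, 3000),
               category = c("Enhancer", "Promoter", "Enhancer")),
    asm)
  set <- make_regions(asm, c("chrA", "chrA", "chrA"),
                      c(500, 1500, 5000), c(600, 1600, 5100))
  ov <- annotate_overlap(set, states)
  expect_identical(ov$categories$Enhancer, c(TRUE, FALSE, FALSE))
  expect_identical(ov$categories$Promoter, c(FALSE, TRUE, FALSE))
  expect_identical(ov$flag, c(TRUE, TRUE, FALSE))
})

test_that("annotate_methylation counts positions and averages unweighted", {
  asm <- toy_assembly()
  meth <- annotation_track(
    "dnameth:ES", "position-numeric",
    data.frame(chrom = "chrA", pos = c(100, 150, 200, 250, 300, 9000),
               ratio = c(0.2, 0.3, 0.4, 0.3, 0.3, 0.9),
               coverage = c(10, 50, 5, 7, 30, 12)),
    asm)
  set <- make_regions(asm, c("chrA", "chrA"), c(50, 5000), c(350, 6000))
  me <- annotate_methylation(set, meth)
  expect_equal(me$count, c(5L, 0L))
  expect_equal(me$mean_ratio[1], 0.30)
  expect_true(is.na(me$mean_ratio[2]))
  # permutation invariance of the position order
  perm <- meth$data[sample(nrow(meth$data)), ]
  meth2 <- annotation_track("dnameth:ES", "position-numeric", perm, asm)
  me2 <- annotate_methylation(set, meth2)
  expect_equal(me2$mean_ratio, me$mean_ratio, tolerance = 1e-12)

  set.seed(19)
  pos <- sort(sample(0:20000, 300))
  rat <- runif(300)
  meth3 <- annotation_track("dnameth:ES", "position-numeric",
                            data.frame(chrom = "chrA", pos = pos,
                                       ratio = rat, coverage = 1), asm)
  start <- sample(0:18000, 40)
  set3 <- make_regions(asm, "chrA", start, start + sample(10:3000, 40))
  me3 <- annotate_methylation(set3, meth3)
  for (i in seq_len(40)) {
    inside <- pos >= set3$regions$start[i] & pos < set3$regions$end[i]
    expect_equal(me3$count[i], sum(inside))
    if (sum(inside) > 0) {
      expect_equal(me3$mean_ratio[i], mean(rat[inside]), tolerance = 1e-12)
    } else {
      expect_true(is.na(me3$mean_ratio[i]))
    }
  }
})

test_that("sequence composition counts CpG dinucleotides and G+C content", {
  asm <- genome_assembly("seq", c(s1 = 20, s2 = 10))
  seqs <- c(s1 = "CGCGCGAAAAAAAAAAAAAA", s2 = "NNNNNNNNNN")
  set <- region_set("s", asm, data.frame(chrom = c("s1", "s1", "s2"),
                                         start = c(0, 0, 0),
                                         end = c(6, 20, 10)))
  sc <- annotate_sequence_composition(set, seqs)
  expect_equal(sc$cpg_freq[1], 3 / 5)
  expect_equal(sc$gc_freq[1], 1)
  expect_equal(sc$cpg_freq[3], 0)
  expect_equal(sc$gc_freq[3], 0)
  # case-insensitive
  sc2 <- annotate_sequence_composition(set, c(s1 = "cgcgcgaaaaaaaaaaaaaa",
                                              s2 = "nnnnnnnnnn"))
  expect_equal(sc2$cpg_freq, sc$cpg_freq)
  # assembly/FASTA mismatch aborts
  expect_error(annotate_sequence_composition(set, c(s1 = "CG", s2 = "AA")),
               "extends beyond")
})

test_that("gene links respect the proximity threshold exactly and are monotone", {
  asm <- toy_assembly()
  genes <- gene_records(
    data.frame(gene_id = c("BRCA2", "FARGENE"), chrom = c("chrA", "chrA"),
               start = c(1000, 60000), end = c(5000, 65000)),
    data.frame(gene_id = "BRCA2", namespace = "go",
               term = "cell differentiation"),
    asm)
  set <- make_regions(asm, c("chrA", "chrA", "chrA"),
                      c(2000, 15000, 30000), c(2500, 15100, 30100))
  ga <- annotate_genes(set, genes, proximity_bp = 10000)
  expect_identical(ga$links[[1]], "BRCA2")
  expect_equal(ga$nearest[1], 0)
  expect_identical(ga$links[[2]], "BRCA2")   # gap 10000 exactly
  expect_equal(ga$nearest[2], 10000)
  expect_identical(ga$links[[3]], character(0))  # gap > 10 kb on both sides
  # boundary: 10,001 bp away with proximity 10,000 gives no link
  set_b <- make_regions(asm, "chrA", 15001, 15101)
  expect_identical(annotate_genes(set_b, genes, 10000)$links[[1]],
                   character(0))
  # monotone in proximity
  g1 <- annotate_genes(set, genes, 1000)
  g2 <- annotate_genes(set, genes, 20000)
  for (i in 1:3) expect_true(all(g1$links[[i]] %in% g2$links[[i]]))

  set.seed(23)
  gd <- data.frame(gene_id = paste0("G", 1:25),
                   chrom = sample(c("chrA", "chrB"), 25, replace = TRUE),
                   start = sample(0:40000, 25))
  gd$end <- gd$start + sample(500:5000, 25)
  genes_r <- gene_records(gd, data.frame(gene_id = character(0),
                                         namespace = character(0),
                                         term = character(0)), asm)
  start <- sample(0:40000, 50)
  set_r <- make_regions(asm, sample(c("chrA", "chrB"), 50, replace = TRUE),
                        start, start + sample(50:1000, 50))
  ga_r <- annotate_genes(set_r, genes_r, proximity_bp = 3000)
  for (i in seq_len(50)) {
    r <- as.list(set_r$regions[i, ])
    gaps <- vapply(seq_len(25), function(j) {
      if (gd$chrom[j] != r$chrom) return(Inf)
      max(0, max(gd$start[j] - r$end, r$start - gd$end[j]))
    }, numeric(1))
    expect_setequal(ga_r$links[[i]], gd$gene_id[gaps <= 3000])
    if (any(is.finite(gaps))) {
      expect_equal(ga_r$nearest[i], min(gaps))
    } else {
      expect_true(is.na(ga_r$nearest[i]))
    }
  }
})
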