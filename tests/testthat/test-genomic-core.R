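test_that("read_bed parses minimal and scored lines, skipping junk", {
  asm <- toy_assembly()
  f <- withr::local_tempfile()
  writeLines(c("track name=up", "# comment", "browser position chrA",
               "chrA\t100\t500",
               "chrA\t1000\t2000\thot1\t300\t+",
               "chrB\t5\t10\t.\tnotanumber"), f)
  set <- read_bed(f, asm)
  expect_equal(n_regions(set), 3)
  expect_equal(set$regions$region_id, c("R1", "hot1", "R3"))
  expect_equal(set$regions$end[1] - set$regions$start[1], 400)
  expect_equal(set$regions$score[2], 300)
  expect_equal(set$regions$strand, c(".", "+", "."))
  expect_true(is.na(set$regions$score[3]))
})

test_that("malformed BED lines are skipped with a warning, or abort in strict mode", {
  asm <- toy_assembly()
  f <- withr::local_tempfile()
  writeLines(c("chrA\t100\t50",          # start >= end
               "chrA\tx\t500",           # non-integer
               "chrZ\t10\t20",           # unknown chromosome
               "chrA\t10\t20"), f)
  expect_warning(expect_warning(expect_warning(set <- read_bed(f, asm))))
  expect_equal(n_regions(set), 1)
  expect_error(read_bed(f, asm, strict = TRUE), "skipping BED line 1")
})

test_that("read_bed then write_bed round-trips region tuples exactly", {
  asm <- toy_assembly(c(chr1 = 5e6, chr2 = 3e6))
  set.seed(41)
  n <- 1000
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- sample.int(2e6, n)
  df <- data.frame(chrom = chrom, start = start,
                   end = start + sample.int(5000, n),
                   region_id = paste0("reg", seq_len(n)),
                   score = sample.int(1000, n),
                   strand = sample(c("+", "-"), n, replace = TRUE))
  set <- region_set("rt", asm, df)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_bed(set, f1)
  back <- read_bed(f1, asm)
  write_bed(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  cols <- c("chrom", "start", "end", "region_id", "score", "strand")
  expect_equal(back$regions[, cols], set$regions[, cols])
})

test_that("write_bed handles empty sets and UCSC track lines", {
  asm <- toy_assembly()
  empty <- region_set("e", asm, data.frame(chrom = character(0),
                                           start = numeric(0),
                                           end = numeric(0)))
  f <- withr::local_tempfile()
  write_bed(empty, f, ucsc_track_line = "mySet")
  expect_identical(readLines(f), "track name=mySet")
})

test_that("overlap_bp matches the per-bp intersection oracle", {
  r1 <- list(chrom = "c", start = 100, end = 200)
  expect_equal(overlap_bp(r1, list(chrom = "c", start = 199, end = 300)), 1)
  expect_equal(overlap_bp(r1, list(chrom = "c", start = 200, end = 300)), 0)
  expect_equal(overlap_bp(r1, list(chrom = "d", start = 100, end = 200)), 0)
  set.seed(7)
  for (i in 1:500) {
    a <- list(chrom = sample(c("x", "y"), 1), start = sample(0:300, 1))
    a$end <- a$start + sample(1:100, 1)
    b <- list(chrom = sample(c("x", "y"), 1), start = sample(0:300, 1))
    b$end <- b$start + sample(1:100, 1)
    got <- overlap_bp(a, b)
    expect_identical(got, bf_overlap_bp(a, b))
    expect_identical(got, overlap_bp(b, a))      # symmetric
    expect_lte(got, min(a$end - a$start, b$end - b$start))
    expect_gte(got, 0L)
  }
})

test_that("nearest_distance matches the exhaustive all-pairs minimum", {
  asm <- toy_assembly()
  genes <- make_track(asm, c("chrA", "chrA", "chrB"),
                      c(1000, 50000, 100), c(2000, 60000, 500),
                      path = "genes", kind = "interval")
  expect_equal(nearest_distance(list(chrom = "chrA", start = 1200,
                                     end = 1400), genes), 0L)
  # region exactly 20 kb upstream of the nearest gene
  expect_equal(nearest_distance(list(chrom = "chrA", start = 29500,
                                     end = 30000), genes), 20000L)
  expect_true(is.na(nearest_distance(list(chrom = "chrB", start = 10000,
                                          end = 10100),
                                     make_track(asm, "chrA", 0, 10,
                                                path = "g2"))))
  set.seed(11)
  iv <- data.frame(chrom = sample(c("chrA", "chrB"), 30, replace = TRUE),
                   start = sample(0:50000, 30))
  iv$end <- iv$start + sample(1:2000, 30)
  track <- make_track(asm, iv$chrom, iv$start, iv$end, path = "rnd")
  for (i in 1:100) {
    r <- list(chrom = sample(c("chrA", "chrB"), 1),
              start = sample(0:50000, 1))
    r$end <- r$start + sample(1:500, 1)
    expect_identical(nearest_distance(r, track), bf_nearest(r, iv))
  }
})

test_that("genome_coverage uses union semantics and matches the bp mask", {
  asm <- toy_assembly(c(c1 = 1e6, c2 = 1e6))
  tiling <- make_track(asm, "c1", 0, 1e6)
  expect_equal(genome_coverage(tiling, asm), 0.5)
  dup <- make_track(asm, c("c1", "c1"), c(100, 100), c(200, 200))
  expect_equal(genome_coverage(dup, asm),
               genome_coverage(make_track(asm, "c1", 100, 200), asm))
  small <- toy_assembly(c(c1 = 3000, c2 = 2000))
  set.seed(5)
  iv <- data.frame(chrom = sample(c("c1", "c2"), 25, replace = TRUE),
                   start = sample(0:1500, 25))
  iv$end <- iv$start + sample(1:400, 25)
  tr <- make_track(small, iv$chrom, iv$start, iv$end)
  expect_equal(genome_coverage(tr, small), bf_coverage(iv, small))
  # invariant under permutation
  perm <- iv[sample(nrow(iv)), ]
  expect_equal(genome_coverage(make_track(small, perm$chrom, perm$start,
                                          perm$end), small),
               genome_coverage(tr, small))
})

test_that("shuffle_regions preserves count and length multiset, reproducibly", {
  asm <- toy_assembly(c(c1 = 50000))
  one <- make_regions(asm, "c1", 100, 500)
  sh <- shuffle_regions(one, seed = 3)
  expect_equal(n_regions(sh), 1)
  expect_equal(sh$regions$end - sh$regions$start, 400)
  expect_gte(sh$regions$start, 0)
  expect_lte(sh$regions$end, 50000)
  expect_equal(sh$regions$region_id, "shuffled:R1")

  big <- toy_assembly(c(c1 = 2e6, c2 = 1e6, c3 = 5e5))
  set.seed(21)
  start <- sample.int(4e5, 1000)
  set <- make_regions(big, sample(names(big$chromosomes), 1000,
                                  replace = TRUE),
                      start, start + sample.int(3000, 1000))
  s1 <- shuffle_regions(set, seed = 1)
  s2 <- shuffle_regions(set, seed = 2)
  s1b <- shuffle_regions(set, seed = 1)
  lens <- function(s) sort(s$regions$end - s$regions$start)
  expect_identical(lens(s1), lens(set))
  expect_identical(lens(s2), lens(set))
  expect_identical(s1$regions, s1b$regions)
  expect_false(identical(s1$regions$start, s2$regions$start))
  # every placement valid
  expect_true(all(s1$regions$end <=
                    big$chromosomes[s1$regions$chrom]))
})

test_that("shuffle_regions rejects regions longer than every chromosome", {
  asm <- toy_assembly(c(c1 = 1000))
  set <- make_regions(asm, "c1", 0, 1000)
  sh <- shuffle_regions(set, seed = 1)     # exactly fits: start must be 0
  expect_equal(sh$regions$start, 0)
  asm2 <- genome_assembly("t2", c(c1 = 1000, c2 = 2000))
  set2 <- region_set("s", asm2, data.frame(chrom = "c2", start = 0,
                                           end = 1800))
  expect_no_error(shuffle_regions(set2, seed = 1))
  # construct an impossible case by shrinking the assembly
  asm3 <- genome_assembly("t3", c(c1 = 100))
  expect_error(region_set("s", asm3, data.frame(chrom = "c1", start = 0,
                                                end = 500)),
               "invalid coordinates")
})

test_that("empirical shuffle overlap matches the analytic null", {
  asm <- genome_assembly("mc", c(c1 = 2e6, c2 = 2e6))
  track <- make_coverage_track(asm, "marks:null", coverage = 0.2,
                               interval_bp = 50000, seed = 9)
  set.seed(33)
  n <- 2000
  start <- sample.int(1e6, n)
  set <- make_regions(asm, sample(c("c1", "c2"), n, replace = TRUE),
                      start, start + sample(50:500, n, replace = TRUE))
  sh <- shuffle_regions(set, seed = 17)
  ann <- annotate_overlap(sh, track)
  emp <- mean(ann$flag)
  p <- expected_shuffle_overlap(set, track)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(emp - p), 3 * se)
})
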