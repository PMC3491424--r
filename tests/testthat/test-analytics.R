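# a small annotated collection with known overlap structure
analytics_fixture <- function() {
  docs <- lapply(1:10, function(i) {
    sort(c("region:chrom:c1", sprintf("region:length:%08d", 500),
           sprintf("attr:val:%02d", c(5, 5, 5, 12, 12, 30, 30, 55, 80, 97)[i]),
           if (i <= 8) "overlap:marks:A",
           if (i <= 2) "overlap:marks:B"), method = "radix")
  })
  names(docs) <- paste0("R", 1:10)
  build_search_index(structure(docs, class = "document_set"))
}

test_that("overlap_summary reports exact percentages and control bars", {
  idx <- analytics_fixture()
  os <- overlap_summary(idx, idx$region_ids, c("marks:A", "marks:B"))
  expect_equal(os$overlap_pct, c(80, 20))
  # identical base and control give identical bars
  os2 <- overlap_summary(idx, idx$region_ids, c("marks:A", "marks:B"),
                         control = idx$region_ids)
  expect_equal(os2$control_pct, os2$overlap_pct)
  expect_error(overlap_summary(idx, character(0), "marks:A"), "empty base")
})

test_that("area_histogram selection equals the range query at bin resolution", {
  idx <- analytics_fixture()
  cd <- numeric_codec("attr:val", 1, 2, 0, 99)
  ah <- area_histogram(idx, cd, value_range = c(12, 55))
  expect_identical(ah$query, "attr:val:12--attr:val:55")
  expect_identical(ah$selection,
                   evaluate(idx, "attr:val:12--attr:val:55"))
  expect_identical(ah$selection, sort(paste0("R", 4:8), method = "radix"))
  expect_equal(sum(ah$bins$count), 10)   # every region carries the attribute
  # single-bin data
  one <- build_search_index(structure(list(R1 = "attr:val:07",
                                           R2 = "attr:val:07"),
                                      class = "document_set"))
  h1 <- histogram_via_completion(one, cd)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$count, 2)
})

test_that("pie_partition counts sum to the histogram total and drill down", {
  idx <- analytics_fixture()
  cd <- numeric_codec("attr:val", 1, 2, 0, 99)
  pie <- pie_partition(idx, cd, edges = c(20, 60))
  expect_equal(nrow(pie), 3)
  expect_equal(pie$count, c(5, 3, 2))
  expect_equal(sum(pie$count), sum(histogram_via_completion(idx, cd)$count))
  # each segment's drill-down query reproduces its count
  for (i in 1:3) {
    expect_equal(length(evaluate(idx, pie$query[i])), pie$count[i])
  }
  expect_error(pie_partition(idx, cd, edges = c(20, 200)),
               "inside the codec clamp")
  expect_error(pie_partition(idx, cd, edges = c(60, 20)))
})

test_that("region-length partition at 1 kb separates short from long regions", {
  docs <- lapply(c(400, 900, 1000, 1500, 20000), function(L) {
    sprintf("region:length:%08d", L)
  })
  names(docs) <- paste0("R", 1:5)
  idx <- build_search_index(structure(docs, class = "document_set"))
  cd <- default_codec_registry()[["region:length"]]
  pie <- pie_partition(idx, cd, edges = 1000)
  expect_equal(pie$count, c(2, 3))
  expect_identical(evaluate(idx, pie$query[2]),
                   sort(paste0("R", 3:5), method = "radix"))
})

test_that("neighborhood profiles recover a planted offset window exactly", {
  asm <- toy_assembly(c(c1 = 1e6))
  # midpoints on a sparse grid so one region's window never reaches
  # another region's bins
  mid <- seq(20000, 960000, by = 15000)
  set <- make_regions(asm, "c1", mid - 100, mid + 100)
  # identical copies of every region put the center bin at exactly 1
  self <- make_track(asm, "c1", mid - 100, mid + 100, path = "self")
  prof0 <- neighborhood_profile(set, self, flank_bp = 2000,
                                bins_per_side = 2)
  expect_equal(prof0$value[prof0$offset_bp == 0], 1.0)
  # a track tiling [+1 kb, +2 kb) downstream of every midpoint
  win <- make_track(asm, "c1", mid + 1000, mid + 2000, path = "win")
  prof <- neighborhood_profile(set, win, flank_bp = 4000, bins_per_side = 4)
  # bins of width 1000 centered at offsets -4000..4000; the bins at +1000
  # and +2000 share bp with [+1000, +2000), all others do not
  expect_equal(prof$offset_bp, seq(-4000, 4000, by = 1000))
  expect_equal(prof$value, c(0, 0, 0, 0, 0, 1, 1, 0, 0))
  expect_true(all(prof$n == length(mid)))
  expect_true(all(prof$value >= 0 & prof$value <= 1))
  expect_error(neighborhood_profile(region_set("e", asm,
                                               data.frame(chrom = character(0),
                                                          start = numeric(0),
                                                          end = numeric(0))),
                                    win), "empty region set")
})

test_that("a genome-wide track saturates every neighborhood bin", {
  asm <- toy_assembly(c(c1 = 200000))
  set <- make_regions(asm, "c1", c(50000, 120000), c(50500, 120400))
  all_track <- make_track(asm, "c1", 0, 200000, path = "all")
  prof <- neighborhood_profile(set, all_track, flank_bp = 5000,
                               bins_per_side = 5)
  expect_true(all(prof$value == 1))
})

test_that("bubble data combines overlap, coverage and control", {
  asm <- toy_assembly(c(c1 = 1e6))
  half <- make_track(asm, "c1", 0, 5e5, path = "marks:half")
  set.seed(71)
  start <- sample(0:999000, 400)
  set <- make_regions(asm, "c1", start, start + 100)
  ann <- add_overlap_track(region_annotations(set), half)
  idx <- build_search_index(build_region_documents(ann))
  bd <- bubble_data(idx, idx$region_ids, list(half), asm)
  expect_equal(bd$coverage, 0.5)
  # uniform placement: observed ~ expected-by-chance (a diagonal bubble)
  expect_lt(abs(bd$overlap_pct / 100 -
                  expected_shuffle_overlap(set, half)), 3 * 0.025)
  os <- overlap_summary(idx, idx$region_ids, "marks:half",
                        control = idx$region_ids)
  bd2 <- bubble_data(idx, idx$region_ids, list(half), asm,
                     control = idx$region_ids)
  expect_equal(bd2$control_pct, os$control_pct)
})

test_that("term enrichment is exactly 1 when base equals control and recovers planted ratios", {
  # planted wiring: every base region links to a gene carrying term T;
  # 10% of control regions do
  n <- 1000
  reg_docs <- lapply(seq_len(n), function(i) c("gene:GA"))
  names(reg_docs) <- paste0("R", seq_len(n))
  ctl_docs <- lapply(seq_len(n), function(i) {
    if (i <= n / 10) "gene:GA" else "gene:GB"
  })
  names(ctl_docs) <- paste0("C", seq_len(n))
  gene_docs <- structure(list(`gene:GA` = "geneannot:go:special_term",
                              `gene:GB` = "geneannot:go:other_term"),
                         class = "document_set")
  idx <- build_search_index(
    structure(c(reg_docs, ctl_docs), class = "document_set"), gene_docs)
  base <- paste0("R", seq_len(n))
  ctrl <- paste0("C", seq_len(n))
  rows <- term_enrichment(idx, base, ctrl, min_universe = 1,
                          max_universe = 5000)
  sp <- rows[rows$term == "geneannot:go:special_term", ]
  expect_equal(sp$observed, n)
  expect_equal(sp$expected, n / 10)
  expect_equal(sp$ratio, (n + 1) / (n / 10 + 1))  # ~10, pseudocount-adjusted
  # base == control: every ratio exactly 1
  rows_id <- term_enrichment(idx, base, base, min_universe = 1)
  expect_true(all(rows_id$ratio == 1))
  # universe suppression drops both terms at the default thresholds
  expect_equal(nrow(term_enrichment(idx, base, ctrl)), 0)
})
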