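#' Synthetic fixture specification
#'
#' Describes a fully synthetic study: a toy assembly, a region set with
#' controlled length/score distributions, annotation tracks with genome
#' coverage targets and planted enrichment factors, genes with term
#' vocabularies (including a subset of terms containing "regulation"), and a
#' per-CpG methylation track with stratified region means.  Everything is
#' deterministic given `seed`, and [generate_fixture()] emits a bookkeeping
#' ledger of the planted truths (per-filter survivor counts, true overlap
#' counts, achieved coverages) computed by direct interval arithmetic on the
#' planted data, independently of the annotation/index pipeline.
#'
#' @param seed Integer seed.
#' @param n_chrom,chrom_length Assembly shape (equal-length chromosomes).
#' @param n_regions Number of regions.
#' @param region_length_range Log-uniform region length range in bp.
#' @param score_max Scores are integers drawn uniformly from `0:score_max`.
#' @param tracks List of track specs: `path`, `coverage` (genome fraction),
#'   `enrichment` (planted overlap fraction as a multiple of the analytic
#'   shuffle-null overlap probability of the final layout, so the measured
#'   enrichment over a shuffled control recovers this factor),
#'   `interval_bp` (typical filler interval length).
#' @param n_genes Number of genes (each placed on the interval of a distinct
#'   region).
#' @param regulation_gene_frac Fraction of genes carrying at least one term
#'   containing "regulation".
#' @param terms_per_gene Terms assigned per gene.
#' @param gene_proximity_bp Gap threshold used for the planted gene-link
#'   truth.
#' @param meth_fraction Fraction of regions with measured CpGs.
#' @param meth_cpg_range Measured CpGs per covered region (uniform integer).
#' @param meth_background_cpgs Measured CpGs placed outside all regions.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(
    seed = 1,
    n_chrom = 4,
    chrom_length = 2.5e6,
    n_regions = 2000,
    region_length_range = c(200, 3000),
    score_max = 1000,
    tracks = list(
      list(path = "histones:H3K4me1:H1hESC", coverage = 0.2,
           enrichment = 2, interval_bp = 100000),
      list(path = "hotspots:alt5hmC", coverage = 0.05,
           enrichment = 2, interval_bp = 50000)
    ),
    n_genes = 200,
    regulation_gene_frac = 0.5,
    terms_per_gene = 3,
    gene_proximity_bp = 10000,
    meth_fraction = 0.7,
    meth_cpg_range = c(1, 12),
    meth_background_cpgs = 2000) {
  spec <- list(seed = seed, n_chrom = n_chrom, chrom_length = chrom_length,
               n_regions = n_regions,
               region_length_range = region_length_range,
               score_max = score_max, tracks = tracks, n_genes = n_genes,
               regulation_gene_frac = regulation_gene_frac,
               terms_per_gene = terms_per_gene,
               gene_proximity_bp = gene_proximity_bp,
               meth_fraction = meth_fraction,
               meth_cpg_range = meth_cpg_range,
               meth_background_cpgs = meth_background_cpgs)
  total <- n_chrom * chrom_length
  for (tr in tracks) {
    if (tr$coverage <= 0 || tr$coverage >= 1) {
      stop("track coverage targets must lie in (0, 1): ", tr$path)
    }
    if (tr$enrichment * tr$coverage > 1) {
      stop("track '", tr$path, "': enrichment x coverage exceeds 1, the ",
           "planted hit probability is unsatisfiable")
    }
  }
  if (region_length_range[2] > chrom_length) {
    stop("regions longer than the chromosomes cannot be placed")
  }
  structure(spec, class = "fixture_spec")
}

# --- planted-truth helpers (plain arithmetic, no pipeline code) ------------

truth_overlap_flags <- function(reg, iv) {
  flag <- logical(nrow(reg))
  for (ch in unique(reg$chrom)) {
    ri <- which(reg$chrom == ch)
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    flag[ri] <- vapply(ri, function(i) {
      any(sub$start < reg$end[i] & reg$start[i] < sub$end)
    }, logical(1))
  }
  flag
}

# Union length of intervals given lo/hi vectors sorted by lo (plain sweep).
union_bp <- function(lo, hi, sorted = FALSE) {
  if (length(lo) == 0) return(0)
  if (!sorted) {
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
  }
  m <- length(lo)
  prev_hi <- c(-Inf, cummax(hi)[-m])
  sum(pmax(0, hi - pmax(lo, prev_hi)))
}

# Exact probability that a uniformly reshuffled region of each length in
# `lens` overlaps the interval layout `iv`; returns the mean over `lens`.
# Plain arithmetic, kept separate from the pipeline's interval code.
null_overlap_prob <- function(iv, lens, clen) {
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  by_chrom <- split(iv, iv$chrom)
  ulen <- sort(unique(lens))
  p <- vapply(ulen, function(L) {
    valid <- sum(pmax(0, clen - L + 1))
    hit <- 0
    for (ch in names(by_chrom)) {
      sub <- by_chrom[[ch]]
      # expansion by L-1 on the left preserves the sort order by start
      lo <- pmax(0, sub$start - L + 1)
      hi <- pmin(sub$end, clen[[ch]] - L + 1)
      keep <- hi > lo
      hit <- hit + union_bp(lo[keep], hi[keep], sorted = TRUE)
    }
    hit / valid
  }, numeric(1))
  names(p) <- ulen
  mean(p[as.character(lens)])
}

# Lay out one track: a short interval inside each hit region plus disjoint
# filler intervals in the region-free gaps, to an exact total of
# coverage * genome bp.
lay_track <- function(tr, reg, len, gaps_df, total, hit) {
  iv_len <- pmax(1, pmin(len, 50))
  iv <- data.frame(
    chrom = reg$chrom[hit],
    start = reg$start[hit] + floor((len[hit] - iv_len[hit]) / 2),
    end = reg$start[hit] + floor((len[hit] - iv_len[hit]) / 2) +
      iv_len[hit],
    stringsAsFactors = FALSE
  )
  remaining <- round(tr$coverage * total) - sum(iv$end - iv$start)
  if (remaining < 0) {
    stop("track '", tr$path, "': coverage target below the bp needed ",
         "to plant the region hits")
  }
  gidx <- sample.int(nrow(gaps_df))
  fillers <- list()
  for (g in gidx) {
    if (remaining <= 0) break
    glen <- gaps_df$end[g] - gaps_df$start[g]
    chunk <- min(glen, tr$interval_bp, remaining)
    if (chunk < 1) next
    off <- if (glen > chunk) sample.int(glen - chunk + 1, 1) - 1 else 0
    fillers[[length(fillers) + 1]] <-
      data.frame(chrom = gaps_df$chrom[g],
                 start = gaps_df$start[g] + off,
                 end = gaps_df$start[g] + off + chunk,
                 stringsAsFactors = FALSE)
    remaining <- remaining - chunk
  }
  if (remaining > 0) {
    stop("track '", tr$path, "': coverage target ", tr$coverage,
         " is unsatisfiable in the region-free space")
  }
  iv_all <- rbind(iv, do.call(rbind, fillers))
  iv_all[order(iv_all$chrom, iv_all$start), , drop = FALSE]
}

# Solve for the number of hit regions so that the planted overlap fraction is
# `enrichment` times the analytic shuffle-null probability of the resulting
# layout (the in-region hit intervals themselves contribute to the null, so
# the two are coupled; a short fixed-point iteration settles it).
plant_track <- function(tr, reg, len, gaps_df, total, clen) {
  n <- nrow(reg)
  n_hit <- round(n * min(0.95, tr$enrichment * tr$coverage))
  hit <- rep(FALSE, n)
  iv_all <- NULL
  p_null <- NA_real_
  for (it in seq_len(25)) {
    hit <- rep(FALSE, n)
    hit[sample.int(n, n_hit)] <- TRUE
    iv_all <- lay_track(tr, reg, len, gaps_df, total, hit)
    p_null <- null_overlap_prob(iv_all, len, clen)
    target <- tr$enrichment * p_null
    if (target > 0.98) {
      stop("track '", tr$path, "': enrichment ", tr$enrichment,
           " over a null overlap probability of ", round(p_null, 3),
           " is unsatisfiable")
    }
    n_hit_new <- round(n * target)
    if (abs(n_hit_new - n_hit) <= 1) break
    n_hit <- n_hit_new
  }
  list(intervals = iv_all, hit = hit, n_hit = sum(hit), p_null = p_null)
}

truth_gene_gap <- function(reg, genes) {
  # per region, the minimal gap in bp to each gene set (list of row indices)
  gap <- matrix(Inf, nrow(reg), nrow(genes))
  for (ch in unique(reg$chrom)) {
    ri <- which(reg$chrom == ch)
    gi <- which(genes$chrom == ch)
    for (i in ri) {
      gap[i, gi] <- pmax(0, pmax(genes$start[gi] - reg$end[i],
                                 reg$start[i] - genes$end[gi]))
    }
  }
  gap
}

# --- generator -------------------------------------------------------------

#' Generate a synthetic fixture with a planted-truth ledger
#'
#' Writes all input files (chrom sizes, regions BED, one BED per track, gene
#' sidecar, methylation track, the seven-step filter chain, a CLI config) to
#' `dir`, and returns the in-memory objects together with `truth`, the
#' bookkeeping ledger of planted quantities: per-step survivor counts of the
#' filter chain, per-track true overlap counts, achieved genome coverages and
#' planted hit fractions.  Re-running with the same spec reproduces the files
#' byte for byte.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return A list with `assembly`, `regions` (a [region_set()]), `tracks`
#'   (list of [annotation_track()]), `genes` ([gene_records()]), `meth`
#'   (position-numeric track), `chain` ([filter_chain()]), `truth`, `files`.
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, generate_fixture_impl(spec, dir))
}

generate_fixture_impl <- function(spec, dir) {
  chroms <- stats::setNames(rep(spec$chrom_length, spec$n_chrom),
                            paste0("chr", seq_len(spec$n_chrom)))
  assembly <- genome_assembly("synth1", chroms)
  total <- assembly$total_length
  n <- spec$n_regions

  ## regions: log-uniform lengths, integer scores, disjoint placement
  lr <- log(spec$region_length_range)
  len <- floor(exp(stats::runif(n, lr[1], lr[2])))
  score <- floor(stats::runif(n, 0, spec$score_max + 1))
  chrom_of <- rep(names(chroms), length.out = n)
  reg <- data.frame(region_id = paste0("R", seq_len(n)),
                    chrom = chrom_of, start = NA_real_, end = NA_real_,
                    score = score, strand = ".", stringsAsFactors = FALSE)
  for (ch in names(chroms)) {
    ri <- which(reg$chrom == ch)
    if (length(ri) == 0) next
    li <- len[ri]
    free <- chroms[[ch]] - sum(li)
    if (free < 0) stop("regions do not fit on ", ch)
    gaps <- diff(c(0, sort(stats::runif(length(ri))), 1)) * free
    pos <- floor(cumsum(gaps[-length(gaps)]) + cumsum(c(0, li[-length(li)])))
    reg$start[ri] <- pos
    reg$end[ri] <- pos + li
  }
  regions <- region_set("synth_regions", assembly, reg)

  ## complement gaps (region-free space), per chromosome, for fillers
  gaps_df <- do.call(rbind, lapply(names(chroms), function(ch) {
    ri <- which(reg$chrom == ch)
    s <- sort(reg$start[ri]); e <- sort(reg$end[ri])
    lo <- c(0, e); hi <- c(s, chroms[[ch]])
    keep <- hi > lo
    data.frame(chrom = ch, start = lo[keep], end = hi[keep],
               stringsAsFactors = FALSE)
  }))

  ## tracks: planted hits inside regions + disjoint fillers in the gaps;
  ## hit fraction = enrichment x analytic shuffle-null probability
  tracks <- list()
  truth_tracks <- list()
  for (tr in spec$tracks) {
    planted <- plant_track(tr, reg, len, gaps_df, total, chroms)
    iv_all <- planted$intervals
    tracks[[tr$path]] <- annotation_track(tr$path, "interval", iv_all,
                                          assembly)
    truth_tracks[[tr$path]] <- list(
      path = tr$path,
      planted_hit_fraction = planted$n_hit / n,
      null_overlap_prob = planted$p_null,
      expected_ratio = (planted$n_hit / n) / planted$p_null,
      n_overlapping = sum(truth_overlap_flags(reg, iv_all)),
      achieved_coverage = sum(iv_all$end - iv_all$start) / total,
      target_coverage = tr$coverage,
      enrichment = tr$enrichment
    )
  }

  ## genes: one per sampled region, transcribed interval = the region itself
  reg_vocab <- paste0("regulation of ",
                      c("signal transduction", "transcription",
                        "cell differentiation", "apoptotic process",
                        "cell migration", "dna repair", "gene expression",
                        "kinase activity"))
  other_vocab <- c("cell adhesion", "dna replication", "ion transport",
                   "protein folding", "lipid metabolic process",
                   "translation", "chromatin organization", "cell cycle",
                   "immune response", "axon guidance", "rna splicing",
                   "oxidation reduction process")
  ng <- min(spec$n_genes, n)
  host <- sample.int(n, ng)
  n_reg_genes <- round(ng * spec$regulation_gene_frac)
  is_reg_gene <- seq_len(ng) <= n_reg_genes
  genes_df <- data.frame(gene_id = paste0("G", seq_len(ng)),
                         chrom = reg$chrom[host], start = reg$start[host],
                         end = reg$end[host], strand = ifelse(
                           stats::runif(ng) < 0.5, "+", "-"),
                         stringsAsFactors = FALSE)
  term_rows <- list()
  for (i in seq_len(ng)) {
    k <- spec$terms_per_gene
    terms <- if (is_reg_gene[i]) {
      c(sample(reg_vocab, 1), sample(other_vocab, k - 1))
    } else {
      sample(other_vocab, k)
    }
    term_rows[[i]] <- data.frame(gene_id = genes_df$gene_id[i],
                                 namespace = "go", term = terms,
                                 stringsAsFactors = FALSE)
  }
  genes <- gene_records(genes_df, do.call(rbind, term_rows), assembly)

  ## methylation: stratified region means + background CpGs in the gaps
  has_meth <- stats::runif(n) < spec$meth_fraction
  meth_rows <- list()
  meth_count <- integer(n)
  meth_mean <- rep(NA_real_, n)
  for (i in which(has_meth)) {
    k <- sample(seq(spec$meth_cpg_range[1], spec$meth_cpg_range[2]), 1)
    k <- min(k, len[i])
    stratum <- sample(c("low", "mid", "high"), 1, prob = c(0.3, 0.4, 0.3))
    mu <- switch(stratum, low = stats::runif(1, 0.0, 0.15),
                 mid = stats::runif(1, 0.25, 0.45),
                 high = stats::runif(1, 0.70, 0.95))
    ratio <- round(pmin(1, pmax(0, stats::rnorm(k, mu, 0.03))), 3)
    pos <- reg$start[i] + sort(sample.int(len[i], k)) - 1
    meth_rows[[length(meth_rows) + 1]] <-
      data.frame(chrom = reg$chrom[i], pos = pos, ratio = ratio,
                 coverage = floor(stats::runif(k, 5, 60)),
                 stringsAsFactors = FALSE)
    meth_count[i] <- k
    meth_mean[i] <- mean(ratio)
  }
  gap_len <- gaps_df$end - gaps_df$start
  bg <- sample.int(nrow(gaps_df), spec$meth_background_cpgs, replace = TRUE,
                   prob = gap_len)
  off <- floor(stats::runif(spec$meth_background_cpgs) * gap_len[bg])
  meth_rows[[length(meth_rows) + 1]] <-
    data.frame(chrom = gaps_df$chrom[bg], pos = gaps_df$start[bg] + off,
               ratio = round(stats::runif(spec$meth_background_cpgs), 3),
               coverage = floor(stats::runif(spec$meth_background_cpgs,
                                             5, 60)),
               stringsAsFactors = FALSE)
  meth_df <- do.call(rbind, meth_rows)
  meth_df <- unique(meth_df[order(meth_df$chrom, meth_df$pos), ,
                            drop = FALSE])
  meth <- annotation_track("dnameth:ES", "position-numeric", meth_df,
                           assembly)

  ## gene-link and methylation truths by direct attribute logic
  has_reg_term <- vapply(split(
    grepl("regulation", tolower(genes$terms$term), fixed = TRUE),
    genes$terms$gene_id), any, logical(1))[genes$genes$gene_id]
  has_reg_term[is.na(has_reg_term)] <- FALSE
  reg_gene_rows <- which(has_reg_term)
  gap <- truth_gene_gap(reg, genes$genes)
  near_reg_gene <- if (length(reg_gene_rows) > 0) {
    apply(gap[, reg_gene_rows, drop = FALSE] <= spec$gene_proximity_bp, 1,
          any)
  } else rep(FALSE, n)
  meth_bin <- ifelse(is.na(meth_mean), NA_integer_,
                     pmin(99, floor(meth_mean * 100 + 1e-9)))

  ## seven-step filter chain + survivor truth (needs two planted tracks)
  track_paths <- names(tracks)
  chain <- NULL
  counts <- NULL
  alive <- rep(TRUE, n)
  if (length(track_paths) >= 2) {
    chain <- filter_chain(
      labels = c("length >= 1 kb", "score >= 300",
                 paste0("overlap ", track_paths[1]),
                 "near gene with 'regulation' term",
                 paste0("overlap ", track_paths[2]),
                 "CpG coverage >= 5", "methylation 20-50%"),
      queries = c(
        "region:length:00001000--region:length:99999999",
        "region:score:000300--region:score:999999",
        encode_binary(track_paths[1]),
        "@gene(~regulation)",
        encode_binary(track_paths[2]),
        "dnameth:ES:cov:0005--dnameth:ES:cov:9999",
        "dnameth:ES:ratio:20--dnameth:ES:ratio:50"
      )
    )
    surv <- list(
      len >= 1000,
      score >= 300,
      truth_overlap_flags(reg, tracks[[track_paths[1]]]$data),
      near_reg_gene,
      truth_overlap_flags(reg, tracks[[track_paths[2]]]$data),
      meth_count >= 5,
      !is.na(meth_bin) & meth_bin >= 20 & meth_bin <= 50
    )
    counts <- integer(8)
    counts[1] <- n
    for (s in seq_along(surv)) {
      alive <- alive & surv[[s]]
      counts[s + 1] <- sum(alive)
    }
  }

  truth <- list(
    seed = spec$seed,
    n_regions = n,
    total_genome_bp = total,
    chain_counts = counts,
    final_region_ids = if (is.null(chain)) NULL else reg$region_id[alive],
    tracks = truth_tracks,
    n_genes = ng,
    n_regulation_genes = length(reg_gene_rows),
    gene_proximity_bp = spec$gene_proximity_bp,
    n_regions_near_regulation_gene = sum(near_reg_gene),
    n_regions_with_meth = sum(meth_count > 0),
    n_meth_positions = nrow(meth_df)
  )

  ## files
  files <- list(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    regions = file.path(dir, "regions.bed"),
    genes = file.path(dir, "genes.tsv"),
    methylation = file.path(dir, "methylation_ES.tsv"),
    chain = file.path(dir, "chain.tsv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml")
  )
  write_chrom_sizes(assembly, files$chrom_sizes)
  write_bed(regions, files$regions)
  files$tracks <- character(0)
  for (p in track_paths) {
    f <- file.path(dir, paste0("track_", gsub(":", "_", p), ".bed"))
    files$tracks[p] <- f
    d <- tracks[[p]]$data
    writeLines(sprintf("%s\t%d\t%d", d$chrom, as.integer(d$start),
                       as.integer(d$end)), f)
  }
  write_gene_table(genes, files$genes)
  write_position_track(meth, files$methylation)
  if (!is.null(chain)) write_filter_chain(chain, files$chain) else {
    files$chain <- NULL
  }
  jsonlite::write_json(truth, files$truth, auto_unbox = TRUE, digits = NA)
  cfg <- list(
    assembly = "chrom.sizes",
    regions = "regions.bed",
    tracks = lapply(track_paths, function(p) {
      list(path = p, file = basename(files$tracks[[p]]), kind = "interval")
    }),
    genes = "genes.tsv",
    methylation = list(list(path = "dnameth:ES",
                            file = "methylation_ES.tsv")),
    gene_proximity_bp = spec$gene_proximity_bp,
    flank_bp = 10000, bins_per_side = 20,
    min_universe = 50, max_universe = 5000
  )
  yaml::write_yaml(cfg, files$config)

  list(assembly = assembly, regions = regions, tracks = tracks,
       genes = genes, meth = meth, chain = chain, truth = truth,
       files = files, dir = dir)
}

#' Generate a disjoint-interval track with an exact coverage fraction
#'
#' Places non-overlapping intervals of roughly `interval_bp` length uniformly
#' over the assembly until the target fraction of the genome is covered
#' (exact to the base pair).  Useful as a null track for shuffle calibration.
#'
#' @param assembly A [genome_assembly()].
#' @param path Attribute path for the track.
#' @param coverage Target genome fraction in (0, 1).
#' @param interval_bp Interval length.
#' @param seed Integer seed.
#' @return An interval [annotation_track()].
#' @export
make_coverage_track <- function(assembly, path, coverage, interval_bp,
                                seed) {
  stopifnot(coverage > 0, coverage < 1)
  with_seed(seed, {
    target <- round(coverage * assembly$total_length)
    n_iv <- ceiling(target / interval_bp)
    # lay intervals on a jittered grid so they never overlap
    clen <- assembly$chromosomes
    per_chrom <- ceiling(n_iv * clen / sum(clen))
    rows <- list()
    remaining <- target
    for (ch in names(clen)) {
      k <- per_chrom[[ch]]
      if (k == 0 || remaining <= 0) next
      cell <- floor(clen[[ch]] / k)
      if (cell <= interval_bp) stop("coverage target too dense for ",
                                    interval_bp, " bp intervals")
      for (j in seq_len(k)) {
        if (remaining <= 0) break
        size <- min(interval_bp, remaining)
        off <- sample.int(cell - size + 1, 1) - 1
        s <- (j - 1) * cell + off
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, start = s, end = s + size, stringsAsFactors = FALSE)
        remaining <- remaining - size
      }
    }
    if (remaining > 0) stop("coverage target unsatisfiable")
    annotation_track(path, "interval", do.call(rbind, rows), assembly)
  })
}

#' Analytic overlap probability under the shuffle null
#'
#' For each region length in the set, the exact probability that a region of
#' that length, placed uniformly over all valid (chromosome, start)
#' positions, shares at least one bp with the track; returns the mean over
#' regions — the expected overlap fraction of a shuffled control.
#'
#' @param set A [region_set()] (its length multiset defines the null).
#' @param track An interval [annotation_track()].
#' @return Expected overlap fraction in \[0, 1\].
#' @export
expected_shuffle_overlap <- function(set, track) {
  clen <- set$assembly$chromosomes
  iv <- track$data
  lens <- set$regions$end - set$regions$start
  p_of_len <- vapply(sort(unique(lens)), function(L) {
    valid <- sum(pmax(0, clen - L + 1))
    if (valid == 0) return(NA_real_)
    hitting <- 0
    for (ch in names(clen)) {
      sub <- iv[iv$chrom == ch, , drop = FALSE]
      if (nrow(sub) == 0) next
      lo <- pmax(0, sub$start - L + 1)
      hi <- pmin(sub$end, clen[[ch]] - L + 1)
      keep <- hi > lo
      if (!any(keep)) next
      r <- IRanges::reduce(IRanges::IRanges(start = lo[keep] + 1,
                                            end = hi[keep]))
      hitting <- hitting + sum(IRanges::width(r))
    }
    hitting / valid
  }, numeric(1))
  names(p_of_len) <- sort(unique(lens))
  mean(p_of_len[as.character(lens)])
}
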