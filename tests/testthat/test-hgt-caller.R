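test_that("identity filtering is inclusive at the threshold", {
  panel <- toy_panel()
  blocks <- rbind(block_row("non01", "chr1", 0, 100, 0.40),
                  block_row("non02", "chr1", 0, 100, 0.399),
                  block_row("mam01", "chr1", 0, 100, 0.80))
  q <- qualifying_blocks(blocks, panel, "non_mammal", 0.40)
  expect_identical(q$species, "non01")
  # brute-force equality on 10,000 random blocks
  set.seed(11)
  big <- random_block_config(10000, panel, list(chr1 = 50000))
  for (thr in c(0.4, 0.6)) for (cl in c("mammal", "non_mammal")) {
    want <- big[big$identity >= thr &
                  big$species %in% panel$species[panel$clade == cl], ]
    expect_identical(qualifying_blocks(big, panel, cl, thr), want)
  }
})

test_that("conserved-region length threshold is strict at 1000 bp", {
  panel <- toy_panel()
  p <- call_params()
  two_nons <- function(s, e)
    rbind(block_row("non01", "chr1", s, e, 0.5),
          block_row("non02", "chr1", s, e, 0.5))
  expect_equal(nonmammal_conserved_regions(two_nons(1000, 2200), panel, p),
               data.frame(chrom = "chr1", start = 1000L, end = 2200L))
  # length 900: below threshold
  expect_identical(nrow(nonmammal_conserved_regions(two_nons(1000, 1900),
                                                    panel, p)), 0L)
  # length exactly 1000 rejected, 1001 kept ("longer than 1000 bps")
  expect_identical(nrow(nonmammal_conserved_regions(two_nons(0, 1000),
                                                    panel, p)), 0L)
  expect_identical(nrow(nonmammal_conserved_regions(two_nons(0, 1001),
                                                    panel, p)), 1L)
  # a single species at depth 1 never makes a region
  one <- block_row("non01", "chr1", 0, 5000, 0.9)
  expect_identical(nrow(nonmammal_conserved_regions(one, panel, p)), 0L)
  # overlapping blocks of one species are unioned before depth counting
  dup <- rbind(block_row("non01", "chr1", 0, 3000, 0.5),
               block_row("non01", "chr1", 1000, 2500, 0.9))
  expect_identical(nrow(nonmammal_conserved_regions(dup, panel, p)), 0L)
})

test_that("merge_gap bridges nearby sub-intervals before the length filter", {
  panel <- toy_panel()
  blocks <- rbind(
    block_row(c("non01", "non02"), "chr1", 0, 700, 0.5),
    block_row(c("non01", "non02"), "chr1", 750, 1500, 0.5))
  p0 <- call_params(merge_gap = 0)
  expect_identical(nrow(nonmammal_conserved_regions(blocks, panel, p0)), 0L)
  p50 <- call_params(merge_gap = 50)
  r <- nonmammal_conserved_regions(blocks, panel, p50)
  expect_equal(r, data.frame(chrom = "chr1", start = 0L, end = 1500L))
  p49 <- call_params(merge_gap = 49)
  expect_identical(nrow(nonmammal_conserved_regions(blocks, panel, p49)), 0L)
})

test_that("mammal coverage support is strict at 40% of the region", {
  panel <- toy_panel()
  p <- call_params()
  region <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  # exactly 400 of 1000 bp: not a supporter
  ms <- mammal_support(region, block_row("mam01", "chr1", 0, 400, 0.5),
                       panel, p)
  expect_identical(ms$count, 0L)
  # 401 bp: supporter
  ms <- mammal_support(region, block_row("mam01", "chr1", 0, 401, 0.5),
                       panel, p)
  expect_identical(ms$supporters, "mam01")
  # coverage passes but identity 0.39 fails
  ms <- mammal_support(region, block_row("mam01", "chr1", 0, 401, 0.39),
                       panel, p)
  expect_identical(ms$count, 0L)
  # coverage is the union over blocks, intersected with the region
  ms <- mammal_support(region,
                       rbind(block_row("mam01", "chr1", 0, 250, 0.5),
                             block_row("mam01", "chr1", 200, 420, 0.5),
                             block_row("mam01", "chr1", 900, 5000, 0.5)),
                       panel, p)
  expect_identical(ms$supporters, "mam01")   # 420 + 100 bp > 400
})

test_that("eight mammal supporters pass, nine fail", {
  panel <- toy_panel(n_mam = 12, n_non = 4)
  mk <- function(n_mam_sup) {
    rbind(block_row(c("non01", "non02"), "chr1", 1000, 2600, 0.6),
          if (n_mam_sup > 0)
            block_row(sprintf("mam%02d", seq_len(n_mam_sup)),
                      "chr1", 1000, 1801, 0.5))
  }
  expect_identical(nrow(call_hgt(mk(8), panel)), 1L)
  expect_identical(nrow(call_hgt(mk(9), panel)), 0L)
})

test_that("interval-algebra caller equals the per-base oracle", {
  panel <- toy_panel(n_mam = 6, n_non = 4)
  lens <- list(chr1 = 30000L, chr2 = 20000L)
  set.seed(101)
  for (rep in 1:40) {
    blocks <- random_block_config(sample(20:80, 1), panel, lens)
    p <- call_params(min_length = sample(c(500L, 1000L), 1),
                     merge_gap = sample(c(0L, 40L), 1),
                     max_mammal_support = sample(0:3, 1))
    got <- call_hgt(blocks, panel, p)
    want <- oracle_caller(blocks, panel, p, lens)
    expect_identical(got$chrom, want$chrom)
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
    expect_identical(got$mammal_support, want$n_mammal)
  }
})

test_that("mammal support matches its per-base oracle on random configs", {
  panel <- toy_panel(n_mam = 8, n_non = 3)
  set.seed(77)
  for (rep in 1:100) {
    blocks <- random_block_config(40, panel, list(chr1 = 20000L))
    region <- data.frame(chrom = "chr1", start = 4000L, end = 9000L)
    p <- call_params()
    got <- mammal_support(region, blocks, panel, p)
    want <- oracle_mammal_support("chr1", 4000, 9000, blocks, panel, p)
    expect_identical(got$supporters, want)
  }
})

test_that("calls satisfy their invariants and are deterministic", {
  cfg <- sim_config(seed = 21, n_chroms = 3, n_planted_hgt = 5,
                    background_block_rate = 0.1)
  res <- simulate_and_run(cfg)
  expect_true(validate_hgt_calls(res$calls))
  res2 <- simulate_and_run(cfg)
  expect_identical(res$calls, res2$calls)
  expect_true(all(res$calls$n_nonmammal >= 2))
})

test_that("threshold grid is consistent with direct calls and monotone", {
  cfg <- sim_config(seed = 31, n_chroms = 2, n_planted_hgt = 4,
                    hgt_nonmammal_identity = 0.55,
                    background_block_rate = 0.1)
  sizes <- setNames(rep(100000L, 2), paste0("chr", 1:2))
  panel <- sim_panel(cfg)
  blocks <- plant_hgt_alignments(cfg, sizes, panel)$blocks
  # single-cell grid equals direct call_hgt
  g1 <- threshold_grid(blocks, panel, 0.4, 0.4)
  direct <- call_hgt(blocks, panel, call_params())
  expect_identical(g1$n_regions, nrow(direct))
  expect_identical(g1$total_bases, sum(direct$end - direct$start))
  # identity grid point above all block identities empties the call set
  g_hi <- threshold_grid(blocks, panel, 0.99, 0.4)
  expect_identical(g_hi$n_regions, 0L)
  expect_identical(g_hi$total_bases, 0L)
  # non-increasing in identity at fixed coverage
  g <- threshold_grid(blocks, panel, c(0.4, 0.5, 0.6), c(0.4, 0.2, 0))
  for (cov in unique(g$mammal_min_coverage)) {
    sub <- g[g$mammal_min_coverage == cov, ]
    sub <- sub[order(sub$min_identity), ]
    expect_true(all(diff(sub$n_regions) <= 0))
    expect_true(all(diff(sub$total_bases) <= 0))
  }
})

test_that("region support mode offers the laxer per-species reading", {
  panel <- toy_panel()
  # two species align to disjoint halves: no base reaches depth 2
  blocks <- rbind(block_row("non01", "chr1", 0, 1200, 0.5),
                  block_row("non02", "chr1", 1200, 2400, 0.5))
  expect_identical(nrow(call_hgt(blocks, panel, call_params())), 0L)
  lax <- call_params(support_mode = "region", region_support_fraction = 0.4)
  expect_identical(nrow(call_hgt(blocks, panel, lax)), 1L)
})
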