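test_that("end bias test matches the one-sample t computation", {
  sizes <- c(chr1 = 100000L, chr2 = 100000L, chr3 = 100000L,
             chr4 = 100000L, chr5 = 100000L)
  set.seed(5)
  regions <- do.call(rbind, lapply(names(sizes), function(ch) {
    mid <- sample.int(100000, 30)
    data.frame(chrom = ch, start = pmax(0L, mid - 50L), end = mid + 50L)
  }))
  r <- end_bias_test(regions, sizes, end_fraction = 0.1)
  # cross-check against stats::t.test on the per-chromosome differences
  tt <- t.test(r$per_chrom$diff, alternative = "greater")
  expect_equal(r$t, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)
  expect_identical(r$df, 4L)
  # counts add up
  expect_equal(sum(r$per_chrom$n_end + r$per_chrom$n_mid), nrow(regions))
})

test_that("all regions at chromosome ends give a significant bias", {
  sizes <- setNames(rep(100000L, 6), paste0("chr", 1:6))
  set.seed(6)
  n_per <- c(3, 5, 8, 4, 6, 7)   # unequal counts keep the variance positive
  regions <- do.call(rbind, lapply(seq_along(n_per), function(i) {
    k <- n_per[i]
    mid <- c(sample.int(8000, ceiling(k / 2)),
             100000 - sample.int(8000, floor(k / 2)))
    data.frame(chrom = names(sizes)[i], start = mid - 50L, end = mid + 50L)
  }))
  r <- end_bias_test(regions, sizes, end_fraction = 0.1)
  expect_true(all(r$per_chrom$diff > 0))
  expect_lt(r$p, 0.05)
})

test_that("degenerate zero-variance differences warn instead of crashing", {
  sizes <- c(chr1 = 10000L, chr2 = 10000L)
  regions <- data.frame(chrom = c("chr1", "chr2"),
                        start = c(100L, 100L), end = c(200L, 200L))
  expect_warning(r <- end_bias_test(regions, sizes), "degenerate")
  expect_true(is.na(r$p))
  expect_error(end_bias_test(regions, c(chr1 = 10000L)), "at least 2")
})

test_that("composition handles overlap priority and the default label", {
  sizes <- c(chr1 = 10000L)
  track <- annotation_track("chr1", c(1000, 1500), c(2000, 2500),
                            c("protein_coding", "lincRNA"), track = "gene")
  # region fully inside a protein_coding gene
  r1 <- genome_regions("chr1", 1200, 1400)
  comp <- composition(r1, track, sizes, gene_biotype_priority())
  expect_equal(comp$foreground_fraction[comp$label == "protein_coding"], 1.0)
  # half inside the gene, half unannotated: 0.5 / 0.5 with default label
  r2 <- genome_regions("chr1", 1800, 3000)
  comp2 <- composition(r2, track, sizes, gene_biotype_priority())
  pc <- comp2$foreground_fraction[comp2$label == "protein_coding"]
  li <- comp2$foreground_fraction[comp2$label == "lincRNA"]
  ng <- comp2$foreground_fraction[comp2$label == "non_gene"]
  # bases 1800-2000 are protein_coding (priority), 2000-2500 lincRNA,
  # 2500-3000 non_gene
  expect_equal(pc, 200 / 1200)
  expect_equal(li, 500 / 1200)
  expect_equal(ng, 500 / 1200)
  expect_equal(sum(comp2$foreground_fraction), 1)
  expect_equal(sum(comp2$background_fraction), 1)
  expect_error(composition(r1, track, sizes, c("lincRNA", "non_gene")),
               "protein_coding")
})

test_that("composition agrees with a per-base oracle on random tracks", {
  set.seed(9)
  sizes <- c(chr1 = 5000L, chr2 = 4000L)
  labs <- c("A", "B", "C", "rest")
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    ch <- sample(names(sizes), n, replace = TRUE)
    st <- vapply(ch, function(c_) sample.int(sizes[[c_]] - 300, 1), 1L)
    track <- annotation_track(ch, st, st + sample.int(300, n),
                              sample(labs[1:3], n, replace = TRUE),
                              track = "chromatin")
    m <- sample(1:4, 1)
    rch <- sample(names(sizes), m, replace = TRUE)
    rst <- vapply(rch, function(c_) sample.int(sizes[[c_]] - 500, 1), 1L)
    regions <- genome_regions(rch, rst, rst + sample.int(500, m))
    got <- composition(regions, track, sizes, labs)
    # oracle: explicit per-base label array, first-in-priority wins
    base_lab <- lapply(sizes, function(L) rep("rest", L))
    for (lab in rev(labs[1:3])) {   # apply lowest priority first, overwrite
      t2 <- track[track$label == lab, , drop = FALSE]
      for (i in seq_len(nrow(t2)))
        base_lab[[t2$chrom[i]]][(t2$start[i] + 1):t2$end[i]] <- lab
    }
    fg_mask <- lapply(sizes, function(L) logical(L))
    for (i in seq_len(nrow(regions)))
      fg_mask[[regions$chrom[i]]][(regions$start[i] + 1):regions$end[i]] <- TRUE
    fg_bases <- unlist(mapply(function(l, m_) l[m_], base_lab, fg_mask,
                              SIMPLIFY = FALSE))
    bg_bases <- unlist(base_lab)
    want_fg <- table(factor(fg_bases, levels = got$label)) / length(fg_bases)
    want_bg <- table(factor(bg_bases, levels = got$label)) / length(bg_bases)
    expect_equal(got$foreground_fraction, unname(as.numeric(want_fg)))
    expect_equal(got$background_fraction, unname(as.numeric(want_bg)))
  }
})

test_that("gene overlap uses any-overlap half-open semantics", {
  genes <- annotation_track("chr1", c(199, 200), c(300, 300),
                            c("protein_coding", "lincRNA"),
                            id = c("g1", "g2"), track = "gene")
  region <- genome_regions("chr1", 100, 200)
  ov <- gene_overlap(region, genes)
  expect_identical(ov$id, "g1")         # 1 bp overlap counts
  expect_identical(attr(ov, "n_genes"), 1L)  # adjacency does not
  # distinct-gene count equals a brute-force all-pairs scan, and is
  # invariant to input ordering
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(5:20, 1)
    gs <- sample.int(9000, n)
    genes <- annotation_track("chr1", gs, gs + sample.int(800, n),
                              sample(gene_biotype_priority()[1:4], n, TRUE),
                              id = sprintf("g%03d", seq_len(n)),
                              track = "gene")
    m <- sample(2:6, 1)
    rs <- sample.int(9000, m)
    regions <- genome_regions("chr1", rs, rs + sample.int(900, m))
    ov <- gene_overlap(regions, genes)
    brute <- sum(vapply(seq_len(n), function(g)
      any(regions$start < genes$end[g] & regions$end > genes$start[g]),
      logical(1)))
    expect_identical(attr(ov, "n_genes"), brute)
    perm <- sample(m)
    ov_p <- gene_overlap(regions[perm, ], genes)
    expect_identical(ov_p$id, ov$id)
  }
})
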