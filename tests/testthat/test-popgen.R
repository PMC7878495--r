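test_that("region extraction is strand-aware and clips at chromosome edges", {
  # + strand, start codon at 5000: the 5' flank is the 2 kb immediately
  # upstream
  g <- one_gene("+", 5000, 8000)
  r <- extract_regions(g, flank_bp = 2000)
  five <- r[r$region == "five_prime", ]
  expect_equal(c(five$begin, five$end), c(3000, 5000))
  expect_false(five$truncated)
  expect_equal(r$end[r$region == "three_prime"], 10000)

  # - strand: downstream of the stop codon is leftward, clipped at 0
  g <- one_gene("-", 1000, 4000)
  r <- extract_regions(g, flank_bp = 2000)
  three <- r[r$region == "three_prime", ]
  expect_equal(c(three$begin, three$end), c(0, 1000))
  expect_true(three$truncated)
  five <- r[r$region == "five_prime", ]
  expect_equal(c(five$begin, five$end), c(4000, 6000))

  # clipping against a known chromosome length flags the 5' flank too
  r <- extract_regions(g, flank_bp = 2000, chrom_lengths = c(chr1 = 5000))
  five <- r[r$region == "five_prime", ]
  expect_equal(five$end, 5000)
  expect_true(five$truncated)

  # flank of 1 bp is honoured exactly
  r <- extract_regions(one_gene("+", 5000, 8000), flank_bp = 1)
  five <- r[r$region == "five_prime", ]
  expect_equal(five$end - five$begin, 1)
})

test_that("pi matches hand-derived values on tiny configurations", {
  # 4 sequences, one 2/2 SNP, region of 10 bp: 4 differing pairs of 6
  vt <- make_vt(matrix(c(0L, 0L, 1L, 1L), nrow = 1), rep("wild", 4))
  res <- nucleotide_diversity(vt, "wild", "chr1", 0, 10)
  expect_equal(res$pi, (4 / 6) / 10)
  expect_equal(res$n_sites_used, 1L)

  # monomorphic region: records exist upstream but none in the region
  expect_equal(nucleotide_diversity(vt, "wild", "chr1", 5, 15)$pi, 0)

  # two sequences differing at 3 of 100 sites
  g <- matrix(0L, nrow = 3, ncol = 2)
  g[, 2] <- 1L
  vt <- make_vt(g, c("wild", "wild"), pos = c(10, 20, 30))
  expect_equal(nucleotide_diversity(vt, "wild", "chr1", 0, 100)$pi, 0.03)
})

test_that("pi signals undefined (not zero) when no site is callable", {
  g <- matrix(c(0L, NA, NA, 1L), nrow = 2)  # <2 calls at every site
  vt <- make_vt(g, c("wild", "wild"))
  res <- nucleotide_diversity(vt, "wild", "chr1", 0, 10)
  expect_true(is.na(res$pi))
  expect_equal(res$n_sites_used, 0L)
  # and an empty table errors rather than returning 0
  expect_error(
    nucleotide_diversity(
      make_vt(matrix(integer(0), ncol = 2), c("wild", "wild")),
      "wild", "chr1", 0, 10
    )
  )
})

test_that("dxy matches enumerated cross-pair values and is symmetric", {
  # fixed difference at one site, region of 10 bp
  vt <- make_vt(matrix(c(0L, 0L, 1L, 1L), nrow = 1),
                c("wild", "wild", "indica", "indica"))
  expect_equal(dxy(vt, "wild", "indica", "chr1", 0, 10)$dxy, 0.1)

  # popA {0,0,1}, popB {0,1}: 3 differing of 6 cross pairs, length 1
  vt <- make_vt(matrix(c(0L, 0L, 1L, 0L, 1L), nrow = 1),
                c(rep("wild", 3), rep("indica", 2)))
  expect_equal(dxy(vt, "wild", "indica", "chr1", 0, 1)$dxy, 3 / 6)
  expect_identical(
    dxy(vt, "wild", "indica", "chr1", 0, 1),
    dxy(vt, "indica", "wild", "chr1", 0, 1)
  )

  # identical monomorphic populations
  vt <- make_vt(matrix(0L, nrow = 2, ncol = 4),
                c("wild", "wild", "indica", "indica"))
  expect_equal(dxy(vt, "wild", "indica", "chr1", 0, 10)$dxy, 0)
})

test_that("streaming estimators equal the all-pairs oracle with missing data", {
  set.seed(42)
  for (i in 1:50) {
    vt <- random_small_vt()
    len <- 1000
    for (pop in c("wild", "japonica", "indica")) {
      got <- nucleotide_diversity(vt, pop, "chr1", 0, len)
      exp <- oracle_pi(vt$geno[, vt$seqs$population == pop, drop = FALSE], len)
      if (exp$n_usable == 0 && nrow(vt$sites) > 0) {
        expect_true(is.na(got$pi))
      } else {
        expect_equal(got$pi, exp$pi, tolerance = 1e-12)
      }
    }
    got <- dxy(vt, "wild", "indica", "chr1", 0, len)
    exp <- oracle_dxy(vt$geno[, vt$seqs$population == "wild", drop = FALSE],
                      vt$geno[, vt$seqs$population == "indica", drop = FALSE],
                      len)
    if (!(exp$n_usable == 0 && nrow(vt$sites) > 0)) {
      expect_equal(got$dxy, exp$dxy, tolerance = 1e-12)
    }
  }
})

test_that("pi is invariant under ref/alt relabelling and bounded", {
  set.seed(7)
  vt <- random_small_vt()
  flipped <- vt
  flipped$geno <- 1L - flipped$geno
  for (pop in c("wild", "japonica")) {
    a <- nucleotide_diversity(vt, pop, "chr1", 0, 100)$pi
    b <- nucleotide_diversity(flipped, pop, "chr1", 0, 100)$pi
    expect_equal(a, b)
    if (!is.na(a)) expect_true(a >= 0 && a <= 1)
  }
})

test_that("region_diversity agrees with the single-region estimators", {
  set.seed(11)
  cfg <- sim_config(n_genes = 12, seed = 5)
  hap <- simulate_haplotypes(cfg)
  regions <- extract_regions(hap$genes)
  rd <- region_diversity(hap$variants, regions)
  expect_equal(nrow(rd), nrow(regions))
  for (i in sample(nrow(rd), 6)) {
    row <- rd[i, ]
    expect_equal(
      row$pi_japonica,
      nucleotide_diversity(hap$variants, "japonica", row$chrom,
                           row$begin, row$end)$pi
    )
    expect_equal(
      row$dxy_indica,
      dxy(hap$variants, "wild", "indica", row$chrom, row$begin, row$end)$dxy
    )
  }
  # ratio is undefined exactly where dxy is zero or missing
  bad <- is.na(rd$dxy_japonica) | rd$dxy_japonica == 0
  expect_true(all(is.na(rd$ratio_japonica[bad])))
  expect_true(all(!is.na(rd$ratio_japonica[!bad & !is.na(rd$pi_japonica)])))
})

test_that("low-ratio flagging takes exactly the lowest quantile with stable ties", {
  base <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    region = "five_prime",
    ratio_japonica = sample(1:100) / 100
  )
  flagged <- flag_low_ratio(base, cultivars = "japonica", quantile = 0.05)
  expect_equal(sum(flagged$low_ratio_japonica), 5)
  expect_setequal(
    flagged$gene_id[flagged$low_ratio_japonica],
    base$gene_id[order(base$ratio_japonica)][1:5]
  )

  # n = 40 shuffled ranks, q = 0.05: ceiling(2) = 2 flagged, the two smallest
  shuf <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40), region = "coding",
    ratio_indica = sample(1:40)
  )
  f <- flag_low_ratio(shuf, cultivars = "indica", quantile = 0.05)
  expect_setequal(shuf$ratio_indica[f$low_ratio_indica], c(1, 2))

  # all-equal ratios: first genes in id order take the flags
  ties <- tibble::tibble(
    gene_id = sprintf("g%02d", 40:1), region = "coding",
    ratio_indica = 1
  )
  f <- flag_low_ratio(ties, cultivars = "indica", quantile = 0.05)
  expect_equal(sort(f$gene_id[f$low_ratio_indica]), c("g01", "g02"))

  # undefined ratios are never flagged, and tiny strata error
  base$ratio_japonica[1:30] <- NA
  f <- flag_low_ratio(base, cultivars = "japonica", quantile = 0.05)
  expect_true(all(!f$low_ratio_japonica[1:30]))
  expect_error(
    flag_low_ratio(base[1:25, ], cultivars = "japonica"),
    "defined ratios"
  )
})

test_that("sweeps lower the cultivar ratio in the targeted region only", {
  cfg <- sim_config(n_genes = 300, n_true_deg = 60, sweep_factor = 0.3,
                    sweep_region = "five_prime", seed = 21)
  hap <- simulate_haplotypes(cfg)
  rd <- region_diversity(hap$variants, extract_regions(hap$genes))
  swept <- rd$gene_id %in% hap$truth$swept_gene_ids
  five <- rd$region == "five_prime"
  expect_lt(
    median(rd$ratio_japonica[five & swept], na.rm = TRUE),
    median(rd$ratio_japonica[five & !swept], na.rm = TRUE)
  )
  # wild diversity untouched by the sweep
  tt <- welch_ttest(rd$pi_wild[five & swept], rd$pi_wild[five & !swept])
  expect_gt(tt$p_value, 0.01)
})
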