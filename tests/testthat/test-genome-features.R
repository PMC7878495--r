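toy_genes <- function() {
  # one gene [0, 1000) with exons [50, 300) + [600, 900), another on chr2
  gene_models(
    c("gA", "gB"), c("chr1", "chr2"), c("+", "-"),
    begin = c(0, 0), end = c(1000, 1000),
    exons = list(
      tibble::tibble(begin = c(50, 600), end = c(300, 900)),
      tibble::tibble(begin = c(100, 500), end = c(400, 800))
    )
  )
}

test_that("fragment classification follows the containment precedence", {
  frags <- tibble::tibble(
    fragment_id = sprintf("f%d", 1:5),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr9"),
    begin = c(100, 250, 350, 1500, 10),
    end = c(200, 400, 500, 1600, 20)
  )
  expect_warning(
    cls <- classify_fragments(frags, toy_genes()),
    "absent"
  )
  expect_equal(
    as.character(cls$class),
    c("annotated_exon",  # [100,200) inside exon [50,300)
      "exon_overlap",    # [250,400) crosses the exon end at 300
      "intron",          # [350,500) between the exons, inside the gene
      "intergenic",      # beyond the gene span
      "intergenic")      # unknown chromosome
  )
  expect_equal(cls$length, frags$end - frags$begin)
})

test_that("classification is a partition, order-invariant and split-stable", {
  cfg <- sim_config(n_genes = 60, seed = 41)
  sim <- simulate_annotation_fragments(cfg, n_fragments = 100)
  cls <- classify_fragments(sim$fragments, sim$genes)
  # planted labels recovered exactly
  expect_equal(as.character(cls$class), sim$truth$class)
  expect_equal(sum(table(cls$class)), 100)

  shuffled <- sim$fragments[sample(nrow(sim$fragments)), ]
  cls2 <- classify_fragments(shuffled, sim$genes)
  expect_equal(
    as.character(cls2$class[match(cls$fragment_id, cls2$fragment_id)]),
    as.character(cls$class)
  )

  # classifying chromosome by chromosome gives the same labels
  per_chrom <- dplyr::bind_rows(lapply(
    split(sim$fragments, sim$fragments$chrom),
    classify_fragments, genes = sim$genes
  ))
  expect_equal(
    as.character(per_chrom$class[match(cls$fragment_id,
                                       per_chrom$fragment_id)]),
    as.character(cls$class)
  )
})

test_that("planted class proportions are emitted exactly as requested", {
  cfg <- sim_config(n_genes = 60, seed = 43)
  sim <- simulate_annotation_fragments(
    cfg, n_fragments = 100,
    class_props = c(annotated_exon = 0.25, exon_overlap = 0.25,
                    intron = 0.25, intergenic = 0.25)
  )
  expect_equal(unname(table(sim$truth$class)[c(
    "annotated_exon", "exon_overlap", "intron", "intergenic"
  )]), rep(25L, 4), ignore_attr = TRUE)
})

test_that("nTAR evidence flags honour thresholds including the 90% boundary", {
  genes <- toy_genes()
  frags <- tibble::tibble(
    fragment_id = c("n1", "n2", "n3", "n4"),
    chrom = "chr1",
    begin = c(1200, 1400, 1600, 1000),
    end = c(1300, 1500, 1700, 1100),
    strand = c("+", "+", "+", "+"),
    n_exons = c(1L, 2L, 1L, 1L)
  )
  aln <- tibble::tibble(
    fragment_id = c("n1", "n2", "n3"),
    identity_pct = c(95, 90, 89.9),
    evalue = c(1e-8, 1e-6, 1e-7)
  )
  cls <- classify_fragments(frags, genes)
  nt <- identify_ntars(cls, genes, aln)
  expect_equal(nrow(nt), 4)
  n <- setNames(seq_len(4), nt$fragment_id)
  expect_true(nt$est_supported[n["n1"]])    # 95 >= 90
  expect_true(nt$est_supported[n["n2"]])    # boundary: exactly 90 qualifies
  expect_false(nt$est_supported[n["n3"]])   # 89.9 fails
  expect_true(nt$ncrna_like[n["n1"]])       # 1e-8 < 1e-6
  expect_false(nt$ncrna_like[n["n2"]])      # boundary: 1e-6 is not < 1e-6
  expect_equal(nt$single_exon, c(TRUE, FALSE, TRUE, TRUE)[n[nt$fragment_id]])
  # n4 abuts the gA span end at 1000 on the + strand
  expect_true(nt$utr_extension[n["n4"]])
  expect_false(nt$utr_extension[n["n1"]])
  # fragment without alignment rows is counted untested, flags FALSE
  expect_equal(attr(nt, "n_untested"), 1)
  expect_false(nt$est_supported[n["n4"]])
})

test_that("planted nTAR flag proportions are recovered exactly", {
  cfg <- sim_config(n_genes = 80, seed = 47)
  sim <- simulate_annotation_fragments(
    cfg, n_fragments = 200,
    ntar_props = c(est_supported = 0.4, ncrna_like = 0.2, single_exon = 0.6)
  )
  cls <- classify_fragments(sim$fragments, sim$genes)
  nt <- identify_ntars(cls, sim$genes, sim$alignments)
  n_int <- sum(sim$truth$class == "intergenic")
  expect_equal(sum(nt$est_supported), round(0.4 * n_int))
  expect_equal(sum(nt$ncrna_like), round(0.2 * n_int))
  expect_equal(sum(nt$single_exon), round(0.6 * n_int))
})

test_that("window scan matches the direct hypergeometric tail on a planted cluster", {
  # 1000 genes every 20 kb on one chromosome; the first 500-kb window holds
  # 25 genes; 20 of the 20 DEGs sit inside it
  genes <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:1000),
    chrom = "chr1",
    begin = (0:999) * 20000,
    end = (0:999) * 20000 + 1000
  )
  deg <- genes$gene_id[1:20]
  scan <- deg_cluster_scan(genes, deg, window_bp = 500000, step_bp = 10000)
  w1 <- scan[scan$begin == 0, ]
  expect_equal(w1$n_genes, 25)
  expect_equal(w1$n_deg, 20)
  expect_equal(w1$p_value, oracle_hyper_tail(20, 20, 1000, 25),
               tolerance = 1e-12)
  expect_equal(w1$p_value, choose(25, 20) / choose(1000, 20),
               tolerance = 1e-12)
  expect_true(w1$enriched)

  # no DEGs: every window at p = 1, nothing enriched
  scan0 <- deg_cluster_scan(genes, character(0))
  expect_true(all(scan0$p_value == 1))
  expect_false(any(scan0$enriched))
})

test_that("window scan p-values are preserved under a constant coordinate shift", {
  set.seed(3)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:200),
    chrom = "chr1",
    begin = sort(sample.int(2e6, 200)),
    end = 0
  )
  genes$end <- genes$begin + 500
  deg <- sample(genes$gene_id, 15)
  a <- deg_cluster_scan(genes, deg, window_bp = 200000, step_bp = 200000)
  shifted <- genes
  shifted$begin <- genes$begin + 400000  # two full window steps
  shifted$end <- genes$end + 400000
  b <- deg_cluster_scan(shifted, deg, window_bp = 200000, step_bp = 200000)
  matched <- match(a$begin + 400000, b$begin)
  expect_equal(b$p_value[matched], a$p_value)

  # hypergeometric p matches enumeration for small populations
  small <- genes[1:30, ]
  sdeg <- small$gene_id[c(1, 3, 5, 7)]
  sc <- deg_cluster_scan(small, sdeg, window_bp = 1e6, step_bp = 1e6)
  for (i in seq_len(nrow(sc))) {
    if (sc$n_genes[i] > 0) {
      expect_equal(
        sc$p_value[i],
        oracle_hyper_tail(sc$n_deg[i], 4, 30, sc$n_genes[i]),
        tolerance = 1e-12
      )
    }
  }
})
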