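test_that("transcript overlap is same-strand, 1-bp, span- or exon-level", {
  a <- tx_tbl("a", "1", 100, 200, "+")
  b <- tx_tbl("b", "1", 200, 300, "+")
  expect_true(transcripts_overlap(a, b, "span"))   # bookended: 1 shared bp
  expect_false(transcripts_overlap(a, tx_tbl("b", "1", 201, 300, "+")))
  expect_false(transcripts_overlap(a, tx_tbl("b", "1", 150, 250, "-")))
  expect_false(transcripts_overlap(a, tx_tbl("b", "2", 100, 200, "+")))
  # '.' strand never matches, even itself
  expect_false(transcripts_overlap(tx_tbl("a", "1", 100, 200, "."),
                                   tx_tbl("b", "1", 150, 250, ".")))

  # spans overlap but exons interleave: span-level TRUE, exon-level FALSE
  x <- tx_tbl("x", "1", c(100, 300), c(150, 350), "+")
  y <- tx_tbl("y", "1", c(160, 400), c(290, 450), "+")
  expect_true(transcripts_overlap(x, y, "span"))
  expect_false(transcripts_overlap(x, y, "exon"))
  # brute-force pairwise exon intersection agrees on random two-exon pairs
  set.seed(11)
  for (i in 1:50) {
    s1 <- sample.int(1000, 2); s2 <- sample.int(1000, 2)
    p <- tx_tbl("p", "1", sort(s1), sort(s1) + c(40, 40), "+")
    q <- tx_tbl("q", "1", sort(s2), sort(s2) + c(40, 40), "+")
    brute <- any(outer(p$start, q$end, `<=`) & outer(p$end, q$start, `>=`))
    expect_equal(transcripts_overlap(p, q, "exon"), brute)
  }
})

test_that("CAGE support windows are inclusive and strand-blind", {
  cat <- as_catalogue(tx_tbl("g1", "1", 1000, 2000, "+"))
  peak_near <- tibble::tibble(chrom = "1", start = 1020, end = 1025)
  expect_equal(cage_support(cat, peak_near, 30)$fraction, 1)
  # peak at 1031 extended by 30 reaches only down to 1001 > tss 1000
  peak_far <- tibble::tibble(chrom = "1", start = 1031, end = 1031)
  expect_equal(cage_support(cat, peak_far, 30)$fraction, 0)
  # exact boundary: 1030 - 30 = 1000 is covered
  peak_edge <- tibble::tibble(chrom = "1", start = 1030, end = 1030)
  expect_equal(cage_support(cat, peak_edge, 30)$fraction, 1)
  expect_error(
    cage_support(cat, peak_near, 30, biotype = "protein_coding"),
    "empty denominator"
  )
})

test_that("planted CAGE fractions are recovered exactly", {
  cfg <- sim_config(
    seed = 3,
    sources = tibble::tibble(
      source = c("s1", "s2"), n_genes = 100L,
      overlap_fraction = 0, cage_fraction = c(0.40, 0.10)
    )
  )
  cats <- simulate_catalogues(cfg)
  cage <- simulate_cage(cfg, cats$sources)
  s1 <- cage_support(cats$sources$s1, cage$peaks, 30)
  expect_equal(s1$fraction, 0.40)
  expect_equal(s1$n_supported, 40L)
  expect_equal(cage_support(cats$sources$s2, cage$peaks, 30)$fraction, 0.10)
})

test_that("sources are ordered by descending support with lexicographic ties", {
  peaks <- tibble::tibble(chrom = "1", start = 995, end = 1005)
  supported <- as_catalogue(tx_tbl("gs", "1", 1000, 2000, "+"))
  unsupported <- as_catalogue(tx_tbl("gu", "1", 5000, 6000, "+"))
  both <- as_catalogue(dplyr::bind_rows(
    tx_tbl("gb1", "1", 1000, 2000, "+"),
    tx_tbl("gb2", "1", 5000, 6000, "+")
  ))
  ord <- order_sources_by_cage(
    list(lo = both, hi = supported, zero = unsupported), peaks, 30
  )
  expect_equal(ord$source, c("hi", "lo", "zero"))
  expect_equal(ord$fraction, c(1, 0.5, 0))
  # equal fractions break lexicographically
  tie <- order_sources_by_cage(list(x = supported, w = supported), peaks, 30)
  expect_equal(tie$source, c("w", "x"))
  single <- order_sources_by_cage(list(only = supported), peaks, 30)
  expect_equal(single$source, "only")
})

test_that("merge rejects same-strand overlaps gene-atomically", {
  base <- as_catalogue(tx_tbl("G1", "1", 150, 250, "+", "lncRNA",
                              "ensembl"))
  hit <- as_catalogue(tx_tbl("c1", "1", 100, 200, "+", "lncRNA", "src"))
  miss_strand <- as_catalogue(tx_tbl("c2", "1", 100, 200, "-", "lncRNA",
                                     "src"))
  merged <- merge_catalogues(base, list(a = hit, b = miss_strand))
  rep <- merge_report(merged)
  expect_equal(rep$n_added, c(0L, 1L))
  expect_setequal(unique(merged$gene_id), c("G1", "c2"))

  # one overlapping transcript rejects the whole gene
  two_tx <- as_catalogue(dplyr::bind_rows(
    tx_tbl("c3", "1", 200, 260, "+", transcript_id = "c3.t1"),
    tx_tbl("c3", "1", 5000, 6000, "+", transcript_id = "c3.t2")
  ))
  m2 <- merge_catalogues(base, list(s = two_tx))
  expect_equal(merge_report(m2)$n_added, 0L)
})

test_that("gene-id collisions across sources are a hard error", {
  base <- as_catalogue(tx_tbl("G1", "1", 100, 200, "+"))
  dup <- as_catalogue(tx_tbl("G1", "2", 100, 200, "+"))
  expect_error(merge_catalogues(base, list(s = dup)), "duplicate gene_id")
})

test_that("planted overlap fractions give exact admission counts", {
  for (f in c(0, 0.4, 1)) {
    cfg <- sim_config(
      seed = 5,
      sources = tibble::tibble(source = "s1", n_genes = 100L,
                               overlap_fraction = f, cage_fraction = 0.1)
    )
    cats <- simulate_catalogues(cfg)
    merged <- merge_catalogues(cats$base, cats$sources)
    expect_equal(merge_report(merged)$n_added, round((1 - f) * 100))
  }
})

test_that("re-merging a constituent source adds nothing (idempotence)", {
  cfg <- sim_config(
    seed = 9,
    sources = tibble::tibble(source = c("s1", "s2"), n_genes = 50L,
                             overlap_fraction = c(0.3, 0.1),
                             cage_fraction = 0.1)
  )
  cats <- simulate_catalogues(cfg)
  merged <- merge_catalogues(cats$base, cats$sources)
  added_s1 <- merge_report(merged)$rejected_ids[[1]]
  s1_admitted <- cats$sources$s1[
    !cats$sources$s1$gene_id %in% added_s1, ]
  s1_renamed <- dplyr::mutate(
    s1_admitted,
    gene_id = paste0(.data$gene_id, ".bis"),
    transcript_id = paste0(.data$transcript_id, ".bis")
  )
  again <- merge_catalogues(merged, list(rep = as_catalogue(s1_renamed)))
  expect_equal(merge_report(again)$n_added, 0L)
})

test_that("merge agrees with the O(n^2) brute-force oracle", {
  set.seed(21)
  for (rep_i in 1:3) {
    base <- random_catalogue(60, "b", span_max = 40000)
    s1 <- random_catalogue(70, "x", span_max = 40000)
    s2 <- random_catalogue(70, "y", span_max = 40000)
    for (level in c("span", "exon")) {
      merged <- merge_catalogues(base, list(s1 = s1, s2 = s2),
                                 level = level)
      oracle <- brute_merge_added(base, list(s1 = s1, s2 = s2),
                                  level = level)
      rep <- merge_report(merged)
      expect_setequal(
        setdiff(unique(s1$gene_id), rep$rejected_ids[[1]]), oracle$s1
      )
      expect_setequal(
        setdiff(unique(s2$gene_id), rep$rejected_ids[[2]]), oracle$s2
      )
    }
  }
})

test_that("order matters only when sources overlap each other", {
  base <- as_catalogue(tx_tbl("B", "1", 10, 20, "+", source = "ensembl"))
  s1 <- as_catalogue(tx_tbl("S1", "1", 1000, 2000, "+", source = "s1"))
  s2 <- as_catalogue(tx_tbl("S2", "1", 1500, 2500, "+", source = "s2"))
  ab <- merge_catalogues(base, list(s1 = s1, s2 = s2))
  ba <- merge_catalogues(base, list(s2 = s2, s1 = s1))
  expect_setequal(unique(ab$gene_id), c("B", "S1"))
  expect_setequal(unique(ba$gene_id), c("B", "S2"))

  # overlap-free sources: admitted set is order-invariant
  s3 <- as_catalogue(tx_tbl("S3", "1", 5000, 6000, "+", source = "s3"))
  fwd <- merge_catalogues(base, list(s1 = s1, s3 = s3))
  rev <- merge_catalogues(base, list(s3 = s3, s1 = s1))
  expect_setequal(unique(fwd$gene_id), unique(rev$gene_id))
})

test_that("merge conserves admitted gene models bit-identically", {
  cfg <- sim_config(
    seed = 13,
    sources = tibble::tibble(source = "s1", n_genes = 40L,
                             overlap_fraction = 0.25, cage_fraction = 0.1)
  )
  cats <- simulate_catalogues(cfg)
  merged <- merge_catalogues(cats$base, cats$sources)
  admitted <- merged[merged$source == "s1", ]
  orig <- cats$sources$s1[
    cats$sources$s1$gene_id %in% admitted$gene_id, ]
  expect_equal(as.data.frame(dplyr::arrange(admitted, gene_id, start)),
               as.data.frame(dplyr::arrange(orig, gene_id, start)),
               ignore_attr = TRUE)
})

test_that("assembly update drops mapped genes with any reference overlap", {
  reference <- as_catalogue(tx_tbl("R1", "1", 1000, 2000, "+",
                                   "protein_coding", "ensembl_v100"))
  # one of two transcripts overlaps the reference: whole gene removed
  partial <- as_catalogue(dplyr::bind_rows(
    tx_tbl("M1", "1", 1900, 2500, "+", transcript_id = "M1.t1"),
    tx_tbl("M1", "1", 9000, 9500, "+", transcript_id = "M1.t2")
  ))
  clean <- as_catalogue(tx_tbl("M2", "1", 5000, 6000, "+"))
  upd <- update_to_new_assembly(
    dplyr::bind_rows(partial, clean), reference
  )
  expect_setequal(unique(upd$gene_id), c("R1", "M2"))
  # empty mapped set: output equals the reference
  empty <- clean[0, ]
  upd2 <- update_to_new_assembly(empty, reference)
  expect_equal(unique(upd2$gene_id), "R1")
})
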