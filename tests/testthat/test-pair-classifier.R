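test_that("pair distance counts bases strictly between spans", {
  expect_equal(
    pair_distance(list(chrom = "1", start = 5000, end = 8000),
                  list(chrom = "1", start = 10000, end = 12000)),
    1999L    # positions 8001..9999
  )
  expect_equal(
    pair_distance(list(chrom = "1", start = 100, end = 200),
                  list(chrom = "1", start = 201, end = 300)),
    0L       # bookended
  )
  expect_equal(
    pair_distance(list(chrom = "1", start = 100, end = 300),
                  list(chrom = "1", start = 200, end = 400)),
    0L       # overlapping
  )
  expect_error(
    pair_distance(list(chrom = "1", start = 1, end = 2),
                  list(chrom = "2", start = 1, end = 2)),
    "same chromosome"
  )
})

test_that("distance bins are inclusive on the small side", {
  expect_equal(distance_bin(c(0, 1000, 1001, 5000, 5001)),
               c("<=1kb", "<=1kb", "<=5kb", "<=5kb", ">5kb"))
})

test_that("intergenic orientation follows the head/tail truth table", {
  # worked cases
  div <- classify_transcript_pair(
    tx_tbl("L", "1", 5000, 8000, "-"),
    tx_tbl("P", "1", 10000, 12000, "+", "protein_coding")
  )
  expect_equal(div$ptype, "intergenic")
  expect_equal(div$direction, "divergent")
  expect_equal(div$location, "upstream")
  expect_equal(div$distance_bp, 1999L)

  conv <- classify_transcript_pair(
    tx_tbl("L", "1", 5000, 8000, "+"),
    tx_tbl("P", "1", 10000, 12000, "-", "protein_coding")
  )
  expect_equal(conv$direction, "convergent")
  expect_equal(conv$distance_bp, 1999L)

  # full enumeration: lnc side x lnc strand x pcg strand
  grid <- expand.grid(lnc_left = c(TRUE, FALSE), ls = c("+", "-"),
                      ps = c("+", "-"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    lnc <- if (g$lnc_left) {
      tx_tbl("L", "1", 1000, 2000, g$ls)
    } else {
      tx_tbl("L", "1", 9000, 10000, g$ls)
    }
    pcg <- tx_tbl("P", "1", 4000, 6000, g$ps, "protein_coding")
    got <- classify_transcript_pair(lnc, pcg)
    # independent expectation: divergent iff the TSS-bearing ends face
    # away across the gap (5'-5'), convergent iff 3'-3'
    expected <- if (g$ls == g$ps) {
      "same_strand"
    } else if ((g$lnc_left && g$ls == "-") || (!g$lnc_left && g$ls == "+")) {
      "divergent"
    } else {
      "convergent"
    }
    expect_equal(got$direction, expected)
    expected_loc <- if ((g$ps == "+") == g$lnc_left) "upstream" else
      "downstream"
    expect_equal(got$location, expected_loc)
  }
})

test_that("genic subtype and exonic/intronic location follow the geometry", {
  pcg <- tx_tbl("P", "1", c(10000, 11500), c(10200, 12000), "+",
                "protein_coding")
  nested <- classify_transcript_pair(
    tx_tbl("L", "1", 10500, 10800, "-"), pcg
  )
  expect_equal(nested$ptype, "genic")
  expect_equal(nested$direction, "antisense")
  expect_equal(nested$subtype, "nested")
  expect_equal(nested$location, "intronic")
  expect_equal(nested$distance_bp, 0L)

  containing <- classify_transcript_pair(
    tx_tbl("L", "1", 9000, 13000, "+"), pcg
  )
  expect_equal(containing$subtype, "containing")
  expect_equal(containing$location, "exonic")

  overlapping <- classify_transcript_pair(
    tx_tbl("L", "1", 9000, 10100, "+"), pcg
  )
  expect_equal(overlapping$subtype, "overlapping")
  expect_equal(overlapping$direction, "sense")

  expect_error(
    classify_transcript_pair(tx_tbl("L", "1", 100, 200, "."), pcg),
    "unstranded"
  )
})

test_that("closest PCG selection respects window, distance and tie rules", {
  lnc <- tx_tbl("L", "1", 50000, 51000, "+")
  pcgs <- as_catalogue(dplyr::bind_rows(
    tx_tbl("Pnear", "1", 51501, 52000, "+", "protein_coding"),  # gap 500
    tx_tbl("Pfar", "1", 53001, 54000, "+", "protein_coding")    # gap 2000
  ))
  got <- find_closest_pcg(lnc, pcgs)
  expect_equal(got$pcg_gene_id, "Pnear")
  expect_equal(got$distance_bp, 500L)

  # no PCG within the window: unclassified
  lonely <- find_closest_pcg(tx_tbl("L", "2", 1, 1000, "+"), pcgs)
  expect_equal(lonely$ptype, "unclassified")
  out_of_window <- find_closest_pcg(lnc, pcgs, window_bp = 400)
  expect_equal(out_of_window$ptype, "unclassified")

  # equal gaps on both sides: the candidate on the lncRNA's 5' side wins
  tied <- as_catalogue(dplyr::bind_rows(
    tx_tbl("Pleft", "1", 48500, 49499, "+", "protein_coding"),
    tx_tbl("Pright", "1", 51501, 52500, "+", "protein_coding")
  ))
  expect_equal(find_closest_pcg(lnc, tied)$pcg_gene_id, "Pleft")
  minus <- tx_tbl("L", "1", 50000, 51000, "-")
  expect_equal(find_closest_pcg(minus, tied)$pcg_gene_id, "Pright")
})

test_that("gene-level collapse keeps agreement and flags conflicts", {
  rec <- function(ptype, dir, pcg, d) {
    tibble::tibble(
      lnc_transcript_id = "t", lnc_gene_id = "L",
      pcg_transcript_id = paste0(pcg, ".t"), pcg_gene_id = pcg,
      ptype = ptype, direction = dir, subtype = NA_character_,
      location = "upstream", distance_bp = as.integer(d)
    )
  }
  same <- gene_level_classification(
    dplyr::bind_rows(rec("intergenic", "divergent", "P1", 500),
                     rec("intergenic", "divergent", "P1", 300))
  )
  expect_false(same$conflict)
  expect_equal(same$distance_bp, 300L)

  mixed <- gene_level_classification(
    dplyr::bind_rows(rec("genic", "sense", "P1", 0),
                     rec("intergenic", "divergent", "P2", 300))
  )
  expect_true(mixed$conflict)
  expect_equal(mixed$ptype, "genic")

  two_pcg <- gene_level_classification(
    dplyr::bind_rows(rec("intergenic", "divergent", "P1", 800),
                     rec("intergenic", "divergent", "P2", 200))
  )
  expect_true(two_pcg$conflict)
  expect_equal(two_pcg$pcg_gene_id, "P2")

  expect_error(gene_level_classification(same[0, ]), "no transcript-level")
})

test_that("planted configurations are recovered exactly, one record per gene", {
  cfg <- sim_config(seed = 17)
  pr <- simulate_pairs(cfg)
  cls <- classify_pairs(pr$catalogue, pr$catalogue)
  n_lnc <- sum(gene_table(pr$catalogue)$biotype == "lncRNA")
  expect_equal(nrow(cls), n_lnc)
  expect_equal(anyDuplicated(cls$lnc_gene_id), 0L)

  j <- dplyr::inner_join(pr$truth, cls, by = "lnc_gene_id",
                         suffix = c(".planted", ""))
  expect_equal(nrow(j), nrow(pr$truth))
  expect_equal(j$ptype, j$ptype.planted)
  expect_equal(j$direction, j$direction.planted)
  expect_equal(j$location, j$location.planted)
  expect_equal(j$distance_bp, j$distance_bp.planted)
  expect_equal(j$distance_class, j$distance_class.planted)
  genic <- !is.na(j$subtype.planted)
  expect_equal(j$subtype[genic], j$subtype.planted[genic])
  expect_false(any(j$conflict))
  # host lncRNAs sit in PCG-free blocks: unclassified
  host_rows <- cls[cls$lnc_gene_id %in% pr$host_truth$host_lnc_id, ]
  expect_true(all(host_rows$ptype == "unclassified"))
})

test_that("classification is invariant under genome reflection with strand flip", {
  cfg <- sim_config(seed = 23)
  pr <- simulate_pairs(cfg)
  L <- max(cfg$chrom_lengths)
  refl <- reflect_catalogue(pr$catalogue, L)
  cls <- classify_pairs(pr$catalogue, pr$catalogue)
  cls_r <- classify_pairs(refl, refl)
  j <- dplyr::inner_join(cls, cls_r, by = "lnc_gene_id",
                         suffix = c("", ".r"))
  expect_equal(j$ptype, j$ptype.r)
  expect_equal(j$direction, j$direction.r)
  expect_equal(j$subtype, j$subtype.r)
  expect_equal(j$location, j$location.r)
  expect_equal(j$distance_bp, j$distance_bp.r)
})

test_that("classifier agrees with brute-force candidate enumeration", {
  set.seed(31)
  for (rep_i in 1:3) {
    lncs <- random_catalogue(30, "L", chroms = "1", span_max = 3e5)
    pcgs <- random_catalogue(40, "P", chroms = "1", span_max = 3e5,
                             biotype = "protein_coding")
    cls <- classify_pairs(lncs, pcgs)
    pcg_tt <- transcript_table(pcgs)
    for (g in unique(lncs$gene_id)) {
      lt <- transcript_table(lncs[lncs$gene_id == g, ])
      # single-transcript genes: gene level == transcript level
      oracle <- brute_classify(as.list(lt[1, ]), pcg_tt)
      got <- cls[cls$lnc_gene_id == g, ]
      if (is.null(oracle)) {
        expect_equal(got$ptype, "unclassified")
      } else {
        expect_equal(got$pcg_gene_id, oracle$pcg)
        expect_equal(got$ptype, oracle$ptype)
        expect_equal(got$direction, oracle$direction)
        expect_equal(got$distance_bp, oracle$distance)
      }
    }
  }
})

test_that("host detection requires full containment and records geometry", {
  lnc <- tx_tbl("H1", "1", c(5000, 7500), c(5500, 8000), "+")
  mi_in <- tx_tbl("mi1", "1", 6000, 6080, "+", "miRNA")
  mi_anti <- tx_tbl("mi2", "1", 6000, 6080, "-", "miRNA")
  mi_straddle <- tx_tbl("mi3", "1", 4900, 5100, "+", "miRNA")
  mi_exonic <- tx_tbl("mi4", "1", 5100, 5200, "+", "miRNA")
  hosts <- find_hosts(
    as_catalogue(dplyr::bind_rows(mi_in, mi_anti, mi_straddle, mi_exonic)),
    as_catalogue(lnc)
  )
  expect_setequal(hosts$small_rna_id, c("mi1", "mi2", "mi4"))
  expect_equal(hosts$strand_relation[hosts$small_rna_id == "mi1"], "sense")
  expect_equal(hosts$location[hosts$small_rna_id == "mi1"], "intronic")
  expect_equal(hosts$strand_relation[hosts$small_rna_id == "mi2"],
               "antisense")
  expect_equal(hosts$location[hosts$small_rna_id == "mi4"], "exonic")

  # planted host relations from the generator are recovered exactly
  pr <- simulate_pairs(sim_config(seed = 41))
  got <- find_hosts(pr$catalogue, pr$catalogue)
  expect_equal(
    as.data.frame(dplyr::arrange(got, host_lnc_id)),
    as.data.frame(dplyr::arrange(pr$host_truth, host_lnc_id))
  )
})
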