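#' Gap between two genomic spans
#'
#' Number of bases strictly between two spans on the same chromosome;
#' overlapping or bookended spans have distance 0.
#'
#' @param a,b Each a list or one-row data frame with `chrom`, `start`, `end`.
#' @return Integer distance in bp.
#' @examples
#' pair_distance(list(chrom = "1", start = 5000, end = 8000),
#'               list(chrom = "1", start = 10000, end = 12000))  # 1999
#' @export
pair_distance <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) {
    stop("pair_distance requires intervals on the same chromosome",
         call. = FALSE)
  }
  as.integer(max(0, max(a$start[1], b$start[1]) - min(a$end[1], b$end[1]) - 1))
}

#' Bin an intergenic distance
#'
#' Distances are binned at 1 kb and 5 kb with boundaries inclusive on the
#' small side: `<=1kb`, `<=5kb` ("close"), `>5kb` ("distant").
#'
#' @param d Non-negative distance(s) in bp.
#' @param thresholds Two increasing cut points in bp.
#' @return Character vector of bins.
#' @export
distance_bin <- function(d, thresholds = c(1000, 5000)) {
  stopifnot(all(d >= 0), length(thresholds) == 2, diff(thresholds) > 0)
  dplyr::case_when(
    d <= thresholds[1] ~ "<=1kb",
    d <= thresholds[2] ~ "<=5kb",
    TRUE ~ ">5kb"
  )
}

# direction of a disjoint lnc/pcg span pair from side and strands
#' @keywords internal
intergenic_direction <- function(lnc_left, lnc_strand, pcg_strand) {
  if (lnc_strand == pcg_strand) return("same_strand")
  # opposite strands: head-to-head (5'-5') = divergent, tail-to-tail = convergent
  if (lnc_left) {
    if (lnc_strand == "-") "divergent" else "convergent"
  } else {
    if (lnc_strand == "+") "divergent" else "convergent"
  }
}

#' Classify one lncRNA transcript against one protein-coding transcript
#'
#' Overlapping spans give the genic type: direction `sense`/`antisense` by
#' strand, subtype `containing` (lncRNA span contains the PCG span), `nested`
#' (contained in it) or `overlapping`, and location `exonic` when any
#' lncRNA exon intersects any PCG exon, else `intronic`. Disjoint spans give
#' the intergenic type: `same_strand`, or for opposite strands `divergent`
#' (5'-to-5', head-to-head) / `convergent` (3'-to-3'); location is `upstream`
#' when the lncRNA lies 5' of the PCG TSS, else `downstream`.
#'
#' @param lnc_t,pcg_t Exon-level tibbles each restricted to one transcript,
#'   on the same chromosome, both stranded.
#' @return A one-row tibble: `lnc_transcript_id`, `lnc_gene_id`,
#'   `pcg_transcript_id`, `pcg_gene_id`, `ptype`, `direction`, `subtype`,
#'   `location`, `distance_bp`.
#' @export
classify_transcript_pair <- function(lnc_t, pcg_t) {
  stopifnot(dplyr::n_distinct(lnc_t$transcript_id) == 1,
            dplyr::n_distinct(pcg_t$transcript_id) == 1)
  if (lnc_t$chrom[1] != pcg_t$chrom[1]) {
    stop("transcripts on different chromosomes", call. = FALSE)
  }
  ls <- lnc_t$strand[1]; ps <- pcg_t$strand[1]
  if (ls == "." || ps == ".") {
    stop("unstranded transcript not classifiable", call. = FALSE)
  }
  l <- list(start = min(lnc_t$start), end = max(lnc_t$end))
  p <- list(start = min(pcg_t$start), end = max(pcg_t$end))
  overlapping <- l$start <= p$end && p$start <= l$end

  if (overlapping) {
    subtype <- if (l$start <= p$start && l$end >= p$end) {
      "containing"
    } else if (p$start <= l$start && p$end >= l$end) {
      "nested"
    } else {
      "overlapping"
    }
    exonic <- any(outer(lnc_t$start, pcg_t$end, `<=`) &
                    outer(lnc_t$end, pcg_t$start, `>=`))
    out <- tibble::tibble(
      ptype = "genic",
      direction = if (ls == ps) "sense" else "antisense",
      subtype = subtype,
      location = if (exonic) "exonic" else "intronic",
      distance_bp = 0L
    )
  } else {
    lnc_left <- l$end < p$start
    pcg_tss <- if (ps == "+") p$start else p$end
    upstream <- if (ps == "+") lnc_left else !lnc_left
    out <- tibble::tibble(
      ptype = "intergenic",
      direction = intergenic_direction(lnc_left, ls, ps),
      subtype = NA_character_,
      location = if (upstream) "upstream" else "downstream",
      distance_bp = as.integer(max(l$start, p$start) - min(l$end, p$end) - 1)
    )
  }
  dplyr::bind_cols(
    tibble::tibble(
      lnc_transcript_id = lnc_t$transcript_id[1],
      lnc_gene_id = lnc_t$gene_id[1],
      pcg_transcript_id = pcg_t$transcript_id[1],
      pcg_gene_id = pcg_t$gene_id[1]
    ),
    out
  )
}

#' Closest protein-coding transcript for each transcript of one lncRNA gene
#'
#' For each lncRNA transcript, the PCG transcript minimising the span gap is
#' selected among those within `window_bp` on the same chromosome
#' (overlapping candidates have distance 0 and take priority). Ties at equal
#' gap prefer the candidate upstream of the lncRNA (its 5' side), then the
#' lexicographically smaller PCG gene id. Transcripts with no candidate in
#' the window are unclassified.
#'
#' @param lnc Exon-level catalogue restricted to one lncRNA gene.
#' @param pcgs Catalogue of protein-coding genes.
#' @param window_bp Search window in bp measured from the span edge
#'   (default 100 kb).
#' @return Transcript-level classification tibble (one row per lncRNA
#'   transcript; unclassified rows have `ptype = "unclassified"` and `NA`
#'   partner fields).
#' @export
find_closest_pcg <- function(lnc, pcgs, window_bp = 1e5) {
  stopifnot(window_bp > 0, dplyr::n_distinct(lnc$gene_id) == 1)
  pcg_tt <- dplyr::filter(transcript_table(pcgs),
                          .data$biotype == "protein_coding")
  lnc_exons <- split(lnc, lnc$transcript_id)
  rows <- purrr::map(lnc_exons, function(lt) {
    lspan <- list(start = min(lt$start), end = max(lt$end))
    cand <- dplyr::filter(pcg_tt, .data$chrom == lt$chrom[1])
    if (nrow(cand) > 0) {
      cand$gap <- pmax(0L, pmax(lspan$start, cand$start) -
                         pmin(lspan$end, cand$end) - 1L)
      cand <- dplyr::filter(cand, .data$gap <= window_bp)
    }
    if (nrow(cand) == 0) {
      return(tibble::tibble(
        lnc_transcript_id = lt$transcript_id[1],
        lnc_gene_id = lt$gene_id[1],
        pcg_transcript_id = NA_character_, pcg_gene_id = NA_character_,
        ptype = "unclassified", direction = NA_character_,
        subtype = NA_character_, location = NA_character_,
        distance_bp = NA_integer_
      ))
    }
    # tie order: min gap, then candidate on the lncRNA's 5' side, then id
    side_upstream <- if (lt$strand[1] == "-") {
      cand$start > lspan$end        # 5' side of a '-' lncRNA is to its right
    } else {
      cand$end < lspan$start
    }
    ord <- order(cand$gap, !side_upstream, cand$gene_id, cand$transcript_id)
    best <- cand[ord[1], ]
    pcg_t <- pcgs[pcgs$transcript_id == best$transcript_id, ]
    classify_transcript_pair(lt, pcg_t)
  })
  dplyr::bind_rows(rows)
}

#' Collapse transcript-level pair classifications to one gene-level record
#'
#' When all transcript records agree on type, direction and partner gene the
#' gene inherits that call at the minimum distance with `conflict = FALSE`.
#' Otherwise the record of the transcript with minimal distance wins (genic,
#' at distance 0, beats intergenic) and `conflict = TRUE` marks the
#' disagreement.
#'
#' @param per_transcript Tibble of transcript-level records as produced by
#'   [find_closest_pcg()] (for one lncRNA gene).
#' @return One-row gene-level tibble with `lnc_gene_id`, `pcg_gene_id`,
#'   `ptype`, `direction`, `subtype`, `location`, `distance_bp`,
#'   `distance_class`, `conflict`.
#' @export
gene_level_classification <- function(per_transcript) {
  if (nrow(per_transcript) == 0) {
    stop("no transcript-level classifications supplied", call. = FALSE)
  }
  classified <- dplyr::filter(per_transcript, .data$ptype != "unclassified")
  if (nrow(classified) == 0) {
    best <- per_transcript[1, ]
    conflict <- FALSE
  } else {
    keys <- dplyr::distinct(classified, .data$ptype, .data$direction,
                            .data$pcg_gene_id)
    all_agree <- nrow(keys) == 1 && nrow(classified) == nrow(per_transcript)
    ord <- order(classified$ptype != "genic", classified$distance_bp,
                 classified$pcg_gene_id)
    best <- classified[ord[1], ]
    conflict <- !all_agree
  }
  tibble::tibble(
    lnc_gene_id = best$lnc_gene_id,
    pcg_gene_id = best$pcg_gene_id,
    ptype = best$ptype,
    direction = best$direction,
    subtype = best$subtype,
    location = best$location,
    distance_bp = best$distance_bp,
    distance_class = ifelse(is.na(best$distance_bp), NA_character_,
                            distance_bin(best$distance_bp)),
    conflict = conflict
  )
}

#' Classify every lncRNA gene against its closest protein-coding gene
#'
#' Runs [find_closest_pcg()] and [gene_level_classification()] over all
#' lncRNA genes of the catalogue, yielding exactly one record per lncRNA
#' gene (classified or unclassified).
#'
#' @param lncs Catalogue whose `lncRNA` genes are classified.
#' @param pcgs Catalogue providing the protein-coding genes (may be the same
#'   object).
#' @param window_bp Search window in bp (default 100 kb).
#' @return Gene-level classification tibble, one row per lncRNA gene.
#' @export
classify_pairs <- function(lncs, pcgs, window_bp = 1e5) {
  lnc_only <- dplyr::filter(lncs, .data$biotype == "lncRNA")
  if (nrow(lnc_only) == 0) {
    stop("no lncRNA genes in catalogue", call. = FALSE)
  }
  purrr::map(split(lnc_only, lnc_only$gene_id), function(g) {
    gene_level_classification(find_closest_pcg(g, pcgs, window_bp))
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$lnc_gene_id)
}

#' Detect lncRNA genes hosting small-RNA genes
#'
#' A lncRNA hosts a small RNA when the small-RNA gene span lies fully inside
#' the lncRNA gene span, regardless of strand. The strand relation
#' (`sense`/`antisense`) and the location (`exonic` when any small-RNA exon
#' intersects any lncRNA exon, else `intronic`) are recorded; a small RNA may
#' have several hosts and a host several small RNAs.
#'
#' @param small_rnas Catalogue of small-RNA genes (`miRNA`, `snoRNA`,
#'   `snRNA`).
#' @param lncs Catalogue whose `lncRNA` genes are candidate hosts.
#' @return A tibble `host_lnc_id`, `small_rna_id`, `small_rna_biotype`,
#'   `strand_relation`, `location`.
#' @export
find_hosts <- function(small_rnas, lncs) {
  sm <- dplyr::filter(gene_table(small_rnas),
                      .data$biotype %in% c("miRNA", "snoRNA", "snRNA"))
  ln <- dplyr::filter(gene_table(lncs), .data$biotype == "lncRNA")
  if (nrow(sm) == 0 || nrow(ln) == 0) {
    return(tibble::tibble(
      host_lnc_id = character(), small_rna_id = character(),
      small_rna_biotype = character(), strand_relation = character(),
      location = character()
    ))
  }
  sm_gr <- GenomicRanges::GRanges(sm$chrom, IRanges::IRanges(sm$start, sm$end))
  ln_gr <- GenomicRanges::GRanges(ln$chrom, IRanges::IRanges(ln$start, ln$end))
  hits <- GenomicRanges::findOverlaps(sm_gr, ln_gr, type = "within",
                                      ignore.strand = TRUE)
  purrr::map2(
    S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits),
    function(i, j) {
      sm_ex <- small_rnas[small_rnas$gene_id == sm$gene_id[i], ]
      ln_ex <- lncs[lncs$gene_id == ln$gene_id[j], ]
      exonic <- any(outer(sm_ex$start, ln_ex$end, `<=`) &
                      outer(sm_ex$end, ln_ex$start, `>=`))
      tibble::tibble(
        host_lnc_id = ln$gene_id[j],
        small_rna_id = sm$gene_id[i],
        small_rna_biotype = sm$biotype[i],
        strand_relation = ifelse(sm$strand[i] == ln$strand[j],
                                 "sense", "antisense"),
        location = ifelse(exonic, "exonic", "intronic")
      )
    }
  ) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$host_lnc_id, .data$small_rna_id)
}
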