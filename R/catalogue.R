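#' Build a validated exon-level gene catalogue
#'
#' A catalogue is an ordinary tibble with one row per exon and the columns
#' `gene_id`, `transcript_id`, `chrom`, `start`, `end`, `strand`, `biotype`
#' and `source`. Coordinates are 1-based inclusive (GTF convention); strand is
#' one of `"+"`, `"-"`, `"."`. Biotypes are mapped onto the six-value
#' vocabulary used throughout the package: `lncRNA`, `protein_coding`,
#' `miRNA`, `snoRNA`, `snRNA`, `other`.
#'
#' `as_catalogue()` checks the structural invariants and refuses inconsistent
#' input rather than repairing it:
#' * `start >= 1`, `end >= start`, non-empty `chrom`;
#' * all exons of a transcript share `chrom` and `strand` and do not overlap;
#' * all transcripts of a gene share `chrom`, `strand`, `biotype`, `source`;
#' * `gene_id`/`transcript_id` pairs are consistent (a transcript belongs to
#'   exactly one gene).
#'
#' @param x A data frame with the columns listed above. `biotype` and
#'   `source` may be omitted and default to `"other"` / `"unknown"`.
#' @return A tibble sorted by gene, transcript and exon start, with `biotype`
#'   normalised to the six-value vocabulary.
#' @examples
#' as_catalogue(tibble::tibble(
#'   gene_id = "G1", transcript_id = "T1", chrom = "1",
#'   start = c(100, 300), end = c(200, 400), strand = "+",
#'   biotype = "lncRNA", source = "ensembl"
#' ))
#' @export
as_catalogue <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"biotype" %in% names(x)) x$biotype <- "other"
  if (!"source" %in% names(x)) x$source <- "unknown"
  needed <- c("gene_id", "transcript_id", "chrom", "start", "end",
              "strand", "biotype", "source")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    stop("catalogue is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- dplyr::select(x, dplyr::all_of(needed))
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$biotype <- normalise_biotype(x$biotype)
  if (nrow(x) == 0) return(x)

  if (any(is.na(x$start) | is.na(x$end)) || any(x$start < 1)) {
    stop("exon coordinates must be >= 1 and non-missing", call. = FALSE)
  }
  bad <- which(x$end < x$start)
  if (length(bad) > 0) {
    stop("exon with end < start (first offending row ", bad[1], ")",
         call. = FALSE)
  }
  if (any(!nzchar(x$chrom) | is.na(x$chrom))) {
    stop("chrom must be non-empty", call. = FALSE)
  }
  if (!all(x$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }

  # one gene per transcript_id
  t2g <- dplyr::distinct(x, .data$transcript_id, .data$gene_id)
  dup_t <- t2g$transcript_id[duplicated(t2g$transcript_id)]
  if (length(dup_t) > 0) {
    stop("transcript assigned to multiple genes: ",
         paste(unique(dup_t), collapse = ", "), call. = FALSE)
  }

  # genes homogeneous in chrom/strand/biotype/source
  g <- dplyr::summarise(
    dplyr::group_by(x, .data$gene_id),
    n_chrom = dplyr::n_distinct(.data$chrom),
    n_strand = dplyr::n_distinct(.data$strand),
    n_bio = dplyr::n_distinct(.data$biotype),
    n_src = dplyr::n_distinct(.data$source),
    .groups = "drop"
  )
  bad_g <- g$gene_id[g$n_chrom > 1 | g$n_strand > 1]
  if (length(bad_g) > 0) {
    stop("gene(s) with transcripts on multiple chromosomes or strands: ",
         paste(utils::head(bad_g, 5), collapse = ", "), call. = FALSE)
  }
  if (any(g$n_bio > 1 | g$n_src > 1)) {
    stop("gene(s) with inconsistent biotype or source", call. = FALSE)
  }

  x <- dplyr::arrange(x, .data$gene_id, .data$transcript_id, .data$start)

  # non-overlapping exons within a transcript
  ov <- dplyr::summarise(
    dplyr::group_by(x, .data$transcript_id),
    overlap = dplyr::n() > 1 && any(.data$start[-1] <= .data$end[-dplyr::n()]),
    .groups = "drop"
  )
  if (any(ov$overlap)) {
    stop("transcript(s) with overlapping exons: ",
         paste(utils::head(ov$transcript_id[ov$overlap], 5), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @keywords internal
normalise_biotype <- function(b) {
  known <- c("lncRNA", "protein_coding", "miRNA", "snoRNA", "snRNA")
  alias <- c(lincRNA = "lncRNA", lnc_RNA = "lncRNA", lncrna = "lncRNA")
  b <- as.character(b)
  hit <- b %in% names(alias)
  b[hit] <- unname(alias[b[hit]])
  b[!b %in% known] <- "other"
  b
}

#' Per-transcript view of a catalogue
#'
#' Collapses the exon rows to one row per transcript with the transcript span,
#' exon count and transcription start site (span start on `+`, span end on
#' `-`; for unstranded transcripts the span start).
#'
#' @param catalogue An exon-level catalogue (see [as_catalogue()]).
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `biotype`, `source`, `n_exons`, `tss`.
#' @export
transcript_table <- function(catalogue) {
  dplyr::summarise(
    dplyr::group_by(catalogue, .data$transcript_id, .data$gene_id,
                    .data$chrom, .data$strand, .data$biotype, .data$source),
    start = min(.data$start),
    end = max(.data$end),
    n_exons = dplyr::n(),
    .groups = "drop"
  ) |>
    dplyr::mutate(tss = ifelse(.data$strand == "-", .data$end, .data$start)) |>
    dplyr::select("transcript_id", "gene_id", "chrom", "start", "end",
                  "strand", "biotype", "source", "n_exons", "tss") |>
    dplyr::arrange(.data$gene_id, .data$transcript_id)
}

#' Per-gene view of a catalogue
#'
#' One row per gene with the gene span (min start to max end over all
#' transcripts) and transcript count.
#'
#' @inheritParams transcript_table
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype`, `source`, `n_transcripts`.
#' @export
gene_table <- function(catalogue) {
  dplyr::summarise(
    dplyr::group_by(catalogue, .data$gene_id, .data$chrom, .data$strand,
                    .data$biotype, .data$source),
    start = min(.data$start),
    end = max(.data$end),
    n_transcripts = dplyr::n_distinct(.data$transcript_id),
    .groups = "drop"
  ) |>
    dplyr::select("gene_id", "chrom", "start", "end", "strand", "biotype",
                  "source", "n_transcripts") |>
    dplyr::arrange(.data$gene_id)
}

#' Chromosome length and size-class table
#'
#' Chicken chromosomes fall into three broad size classes with distinct gene
#' densities; the defaults follow that convention: macro-chromosomes are chr
#' 1-5, micro-chromosomes chr 11-33, and everything else named is "medium".
#'
#' @param chrom Character vector of chromosome names.
#' @param length Integer vector of chromosome lengths in bp (all > 0).
#' @param class Optional character vector of size classes (`macro`, `medium`,
#'   `micro`); derived from the chromosome number when `NULL`.
#' @return A tibble with columns `chrom`, `length`, `class`.
#' @export
chrom_table <- function(chrom, length, class = NULL) {
  if (any(length <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  if (is.null(class)) {
    num <- suppressWarnings(as.integer(sub("^chr", "", chrom)))
    class <- dplyr::case_when(
      !is.na(num) & num >= 1 & num <= 5 ~ "macro",
      !is.na(num) & num >= 11 & num <= 33 ~ "micro",
      TRUE ~ "medium"
    )
  }
  tibble::tibble(chrom = chrom, length = as.numeric(length), class = class)
}

#' @keywords internal
#' GRanges of transcript spans or exons, used by the overlap machinery.
catalogue_granges <- function(catalogue, level = c("span", "exon")) {
  level <- match.arg(level)
  if (level == "span") {
    tt <- transcript_table(catalogue)
    gr <- GenomicRanges::GRanges(
      seqnames = tt$chrom,
      ranges = IRanges::IRanges(start = tt$start, end = tt$end),
      strand = ifelse(tt$strand == ".", "*", tt$strand)
    )
    gr$transcript_id <- tt$transcript_id
    gr$gene_id <- tt$gene_id
    gr$raw_strand <- tt$strand
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = catalogue$chrom,
      ranges = IRanges::IRanges(start = catalogue$start, end = catalogue$end),
      strand = ifelse(catalogue$strand == ".", "*", catalogue$strand)
    )
    gr$transcript_id <- catalogue$transcript_id
    gr$gene_id <- catalogue$gene_id
    gr$raw_strand <- catalogue$strand
  }
  gr
}
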