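#' Same-strand transcript overlap test
#'
#' Two transcripts overlap when they are on the same chromosome, the same
#' strand (`.` never matches anything), and share at least one base — at the
#' level of transcript extents (`level = "span"`) or of any exon pair
#' (`level = "exon"`). This is the 1-bp same-strand rule that drives the
#' sequential catalogue aggregation.
#'
#' @param a,b Exon-level catalogue tibbles each restricted to a single
#'   transcript.
#' @param level `"span"` (transcript extents) or `"exon"` (exon blocks).
#' @return `TRUE` or `FALSE`.
#' @export
transcripts_overlap <- function(a, b, level = c("span", "exon")) {
  level <- match.arg(level)
  stopifnot(dplyr::n_distinct(a$transcript_id) == 1,
            dplyr::n_distinct(b$transcript_id) == 1)
  if (a$chrom[1] != b$chrom[1]) return(FALSE)
  sa <- a$strand[1]; sb <- b$strand[1]
  if (sa == "." || sb == "." || sa != sb) return(FALSE)
  if (level == "span") {
    min(a$start) <= max(b$end) && min(b$start) <= max(a$end)
  } else {
    any(outer(a$start, b$end, `<=`) & outer(a$end, b$start, `>=`))
  }
}

#' CAGE support of transcript 5' ends
#'
#' A transcript is CAGE-supported when some peak, extended by `window_bp` on
#' both sides, covers its transcription start site (both window endpoints
#' inclusive). Peak strand is ignored by default, since TSS-centred CAGE
#' evidence is scored purely positionally; set `match_strand = TRUE` to
#' require it.
#'
#' @param catalogue An exon-level catalogue.
#' @param peaks Tibble of peak intervals (`chrom`, `start`, `end`, optionally
#'   `strand`).
#' @param window_bp Half-width of the support window in bp (e.g. 30 or 100).
#' @param biotype Biotype whose transcripts are scored (default `"lncRNA"`).
#' @param match_strand Require peak strand to equal transcript strand.
#' @return A one-row tibble: `source`, `window_bp`, `n_transcripts`,
#'   `n_supported`, `fraction`.
#' @export
cage_support <- function(catalogue, peaks, window_bp = 30,
                         biotype = "lncRNA", match_strand = FALSE) {
  stopifnot(window_bp >= 0)
  tt <- dplyr::filter(transcript_table(catalogue), .data$biotype == !!biotype)
  if (nrow(tt) == 0) {
    stop("empty denominator: no transcripts of biotype '", biotype, "'",
         call. = FALSE)
  }
  tss_gr <- GenomicRanges::GRanges(
    tt$chrom, IRanges::IRanges(tt$tss, tt$tss), strand = "*"
  )
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(pmax(1L, peaks$start - as.integer(window_bp)),
                     peaks$end + as.integer(window_bp)),
    strand = "*"
  )
  hits <- GenomicRanges::findOverlaps(tss_gr, peak_gr, ignore.strand = TRUE)
  supported <- logical(nrow(tt))
  if (match_strand && "strand" %in% names(peaks)) {
    ok <- tt$strand[S4Vectors::queryHits(hits)] ==
      peaks$strand[S4Vectors::subjectHits(hits)]
    supported[unique(S4Vectors::queryHits(hits)[ok])] <- TRUE
  } else {
    supported[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  tibble::tibble(
    source = paste(unique(tt$source), collapse = "+"),
    window_bp = window_bp,
    n_transcripts = nrow(tt),
    n_supported = sum(supported),
    fraction = sum(supported) / nrow(tt)
  )
}

#' Order annotation sources by CAGE support of their lncRNA transcripts
#'
#' Sources are ranked by descending fraction of lncRNA transcripts whose TSS
#' falls within `window_bp` of a CAGE peak; ties break lexicographically by
#' source label so the order is deterministic.
#'
#' @param sources Named list of exon-level catalogues.
#' @param peaks CAGE peak tibble as in [cage_support()].
#' @param window_bp Support half-width in bp.
#' @param biotype Biotype scored (default `"lncRNA"`).
#' @return A tibble `source`, `fraction`, `n_transcripts`, `n_supported`,
#'   ordered by rank; the ordered labels are `$source`.
#' @export
order_sources_by_cage <- function(sources, peaks, window_bp = 30,
                                  biotype = "lncRNA") {
  stopifnot(length(sources) >= 1, !is.null(names(sources)))
  res <- purrr::imap(sources, function(cat, label) {
    s <- cage_support(cat, peaks, window_bp = window_bp, biotype = biotype)
    s$source <- label
    s
  })
  dplyr::bind_rows(res) |>
    dplyr::arrange(dplyr::desc(.data$fraction), .data$source) |>
    dplyr::select("source", "fraction", "n_transcripts", "n_supported")
}

# gene ids of candidate genes having >=1 transcript overlapping the growing
# catalogue, via strand-aware findOverlaps ('.' strands are kept out).
#' @keywords internal
overlapping_gene_ids <- function(candidate, growing, level) {
  if (nrow(growing) == 0 || nrow(candidate) == 0) return(character())
  a <- catalogue_granges(candidate, level)
  b <- catalogue_granges(growing, level)
  keep_a <- a$raw_strand != "."
  keep_b <- b$raw_strand != "."
  a <- a[keep_a]; b <- b[keep_b]
  hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = FALSE)
  unique(a$gene_id[S4Vectors::queryHits(hits)])
}

#' Sequentially aggregate annotation sources into a growing catalogue
#'
#' Starting from `base` (retained unconditionally, all biotypes), each source
#' is processed in the given order; a candidate gene is added only if none of
#' its transcripts has a same-strand 1-bp-or-more overlap with any transcript
#' already in the growing catalogue. Rejection is gene-atomic: one overlapping
#' transcript rejects the whole gene. Admitted gene models are passed through
#' unchanged (no merging or editing of models).
#'
#' @param base Exon-level catalogue retained unconditionally.
#' @param sources Named list of candidate catalogues, in order of addition
#'   (see [order_sources_by_cage()]).
#' @param level Overlap level, `"span"` or `"exon"` (see
#'   [transcripts_overlap()]).
#' @return The merged catalogue, with a per-source admission report attached
#'   as the `"merge_report"` attribute (retrieve with [merge_report()]).
#' @export
merge_catalogues <- function(base, sources, level = c("span", "exon")) {
  level <- match.arg(level)
  stopifnot(is.list(sources), !is.null(names(sources)))
  all_ids <- c(unique(base$gene_id),
               unlist(purrr::map(sources, ~ unique(.x$gene_id))))
  if (anyDuplicated(all_ids)) {
    stop("duplicate gene_id across base/sources: ",
         paste(utils::head(unique(all_ids[duplicated(all_ids)]), 5),
               collapse = ", "), call. = FALSE)
  }
  growing <- as_catalogue(base)
  rows <- list()
  for (label in names(sources)) {
    src <- as_catalogue(sources[[label]])
    rejected_ids <- overlapping_gene_ids(src, growing, level)
    admitted <- dplyr::filter(src, !.data$gene_id %in% rejected_ids)
    growing <- dplyr::bind_rows(growing, admitted)
    rows[[label]] <- tibble::tibble(
      source = label,
      n_candidates = dplyr::n_distinct(src$gene_id),
      n_added = dplyr::n_distinct(admitted$gene_id),
      n_rejected = length(rejected_ids),
      rejected_ids = list(sort(rejected_ids))
    )
  }
  attr(growing, "merge_report") <- dplyr::bind_rows(rows)
  growing
}

#' Per-source admission report of a merge
#'
#' @param catalogue A catalogue produced by [merge_catalogues()] or
#'   [update_to_new_assembly()].
#' @return A tibble with columns `source`, `n_candidates`, `n_added`,
#'   `n_rejected`, `rejected_ids` (list-column).
#' @export
merge_report <- function(catalogue) {
  rep <- attr(catalogue, "merge_report")
  if (is.null(rep)) stop("no merge report attached", call. = FALSE)
  rep
}

#' Carry a catalogue onto a new assembly annotation
#'
#' Given gene models mapped onto new-assembly coordinates and the reference
#' annotation of that assembly, keeps the reference plus every mapped gene
#' none of whose transcripts overlaps (same-strand, 1 bp or more) any
#' reference gene; a gene with even one overlapping transcript is removed
#' whole. Genes whose transcripts disagree on chromosome or strand must have
#' been removed upstream — [as_catalogue()] refuses them.
#'
#' @param mapped Catalogue in post-mapping coordinates.
#' @param reference Reference annotation catalogue of the new assembly.
#' @param level Overlap level as in [merge_catalogues()].
#' @return Combined catalogue with a `"merge_report"` attribute.
#' @export
update_to_new_assembly <- function(mapped, reference,
                                   level = c("span", "exon")) {
  level <- match.arg(level)
  merge_catalogues(reference, list(mapped = mapped), level = level)
}
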