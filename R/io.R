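#' Read an Ensembl-dialect GTF into an exon-level catalogue
#'
#' Only `exon` feature rows are used (transcript/gene rows, if present, are
#' ignored); each transcript's span is derived from its exons. The gene
#' biotype is taken from the `gene_biotype` attribute and mapped to the
#' package's six-value vocabulary (unknown biotypes become `other`); the
#' provenance label is taken from GTF column 2.
#'
#' @param path Path to a GTF file.
#' @param chrom_map Optional named character vector harmonising chromosome
#'   names at read time, e.g. `c(chr1 = "1")`; unmapped names pass through.
#' @return An exon-level catalogue tibble (see [as_catalogue()]).
#' @export
read_gtf <- function(path, chrom_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  n_rows <- check_gtf_structure(path)
  gr <- if (n_rows == 0) {
    GenomicRanges::GRanges()
  } else {
    rtracklayer::import(path, format = "gtf")
  }
  if (length(gr) > 0) gr <- gr[is.na(gr$type) | gr$type == "exon"]
  if (length(gr) == 0) {
    warning("no exon records in ", path, "; returning empty catalogue")
    return(as_catalogue(tibble::tibble(
      gene_id = character(), transcript_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      biotype = character(), source = character()
    )))
  }
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (!is.null(chrom_map)) {
    hit <- chrom %in% names(chrom_map)
    chrom[hit] <- unname(chrom_map[chrom[hit]])
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  biotype <- if ("gene_biotype" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$gene_biotype)
  } else {
    rep("other", length(gr))
  }
  biotype[is.na(biotype)] <- "other"
  as_catalogue(tibble::tibble(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = chrom,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    biotype = biotype,
    source = as.character(gr$source)
  ))
}

# Cheap structural pass so malformed rows are reported with a line number
# before the real parser runs; returns the number of body rows.
#' @keywords internal
check_gtf_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) return(0L)
  body <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(body)
  if (length(idx) == 0) return(0L)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    stop("malformed GTF row at line ", idx[which(nf < 9)[1]],
         ": expected 9 tab-separated fields", call. = FALSE)
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5)))
  bad <- which(is.na(starts) | is.na(ends) | ends < starts)
  if (length(bad) > 0) {
    stop("malformed GTF coordinates at line ", idx[bad[1]], call. = FALSE)
  }
  attrs <- vapply(fields, `[[`, "", 9)
  types <- vapply(fields, `[[`, "", 3)
  need <- which(types == "exon" &
                  (!grepl("gene_id", attrs) | !grepl("transcript_id", attrs)))
  if (length(need) > 0) {
    stop("GTF exon row missing gene_id/transcript_id attribute at line ",
         idx[need[1]], call. = FALSE)
  }
  length(idx)
}

#' Write a catalogue as an Ensembl-dialect GTF
#'
#' Emits one `exon` row per catalogue row, with `gene_id`, `transcript_id`
#' and `gene_biotype` attributes and the provenance label in column 2, so
#' that `read_gtf(write_gtf(x))` reproduces `x`.
#'
#' @param catalogue An exon-level catalogue.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_gtf <- function(catalogue, path) {
  catalogue <- as_catalogue(catalogue)
  gr <- GenomicRanges::GRanges(
    seqnames = catalogue$chrom,
    ranges = IRanges::IRanges(start = catalogue$start, end = catalogue$end),
    strand = ifelse(catalogue$strand == ".", "*", catalogue$strand)
  )
  gr$source <- catalogue$source
  gr$type <- "exon"
  gr$gene_id <- catalogue$gene_id
  gr$transcript_id <- catalogue$transcript_id
  gr$gene_biotype <- catalogue$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a BED file as intervals or as a single-source catalogue
#'
#' BED coordinates (0-based half-open) are converted to the package's 1-based
#' inclusive convention. With `mode = "transcripts"` each BED line becomes one
#' transcript (of a single-transcript gene): BED12 blocks become exons, BED6
#' lines become single-exon transcripts.
#'
#' @param path Path to a BED6 or BED12 file.
#' @param mode `"intervals"` for a plain interval tibble (e.g. CAGE peaks),
#'   `"transcripts"` for a catalogue.
#' @param source Provenance label for `mode = "transcripts"`.
#' @param biotype Biotype assigned in `mode = "transcripts"` (BED catalogues
#'   carry no biotype of their own).
#' @return A tibble of `chrom`, `start`, `end`, `strand`, `name` for
#'   `mode = "intervals"`; an exon-level catalogue otherwise.
#' @export
read_bed <- function(path, mode = c("intervals", "transcripts"),
                     source = "bed", biotype = "lncRNA") {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  name <- if ("name" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$name)
  } else {
    paste0("bed_", seq_along(gr))
  }
  name[is.na(name)] <- paste0("bed_", which(is.na(name)))
  if (mode == "intervals") {
    return(tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = strand,
      name = name
    ))
  }
  has_blocks <- "blocks" %in% names(S4Vectors::mcols(gr))
  rows <- purrr::map(seq_along(gr), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(gr))[i]
    if (has_blocks && length(gr$blocks[[i]]) > 0) {
      bl <- gr$blocks[[i]]   # block coords relative to feature start
      ex_start <- GenomicRanges::start(gr)[i] + IRanges::start(bl) - 1L
      ex_end <- GenomicRanges::start(gr)[i] + IRanges::end(bl) - 1L
      if (max(ex_end) > GenomicRanges::end(gr)[i]) {
        stop("BED12 block extends past feature end for '", name[i], "'",
             call. = FALSE)
      }
    } else {
      ex_start <- GenomicRanges::start(gr)[i]
      ex_end <- GenomicRanges::end(gr)[i]
    }
    tibble::tibble(
      gene_id = name[i], transcript_id = paste0(name[i], ".t1"),
      chrom = chrom, start = ex_start, end = ex_end, strand = strand[i]
    )
  })
  as_catalogue(dplyr::bind_rows(rows) |>
                 dplyr::mutate(biotype = biotype, source = source))
}

#' Write intervals as BED6
#'
#' Converts 1-based inclusive intervals back to BED's 0-based half-open
#' convention.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `strand`, `name`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
  name <- if ("name" %in% names(intervals)) {
    intervals$name
  } else {
    paste0("iv_", seq_len(nrow(intervals)))
  }
  readr::write_tsv(
    tibble::tibble(
      chrom = intervals$chrom,
      start = intervals$start - 1L,
      end = intervals$end,
      name = name,
      score = 0L,
      strand = strand
    ),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read a chromosome-length table
#'
#' TSV with columns `chrom`, `length` and optionally `class`; missing classes
#' are derived from the chromosome number as in [chrom_table()].
#'
#' @param path Path to the TSV file.
#' @return A tibble with `chrom`, `length`, `class`.
#' @export
read_chrom_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  chrom_table(tab$chrom, tab$length,
              class = if ("class" %in% names(tab)) tab$class else NULL)
}

#' Read a gene-by-sample expression table
#'
#' TSV with genes as rows (`gene_id` first column) and one column per sample.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `gene_id` and one numeric column per sample.
#' @export
read_expression_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  names(tab)[1] <- "gene_id"
  tab
}

#' Read a sample-to-tissue map
#'
#' TSV with columns `sample` and `tissue`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `sample`, `tissue`.
#' @export
read_sample_map <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  names(tab)[1:2] <- c("sample", "tissue")
  tab[, c("sample", "tissue")]
}
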