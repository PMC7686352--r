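#' Collapse a gene-by-sample TPM table to tissue means
#'
#' Replicates of a tissue are summarised by their arithmetic mean (the
#' conventional TPM tissue summary; `summary = "median"` is available).
#'
#' @param sample_tpm Tibble with `gene_id` and one numeric column per sample.
#' @param sample_map Tibble with columns `sample`, `tissue` covering every
#'   sample column.
#' @param summary `"mean"` or `"median"`.
#' @return A tibble with `gene_id` and one column per tissue, tissues in
#'   first-appearance order of `sample_map`.
#' @export
build_expression_matrix <- function(sample_tpm, sample_map,
                                    summary = c("mean", "median")) {
  summary <- match.arg(summary)
  samples <- setdiff(names(sample_tpm), "gene_id")
  unmapped <- setdiff(samples, sample_map$sample)
  if (length(unmapped) > 0) {
    stop("sample(s) not in sample map: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(sample_tpm[samples])) {
    stop("ragged input: missing TPM values (gene absent from some sample)",
         call. = FALSE)
  }
  fun <- if (summary == "mean") mean else stats::median
  long <- tidyr::pivot_longer(sample_tpm, -"gene_id",
                              names_to = "sample", values_to = "tpm") |>
    dplyr::inner_join(sample_map, by = "sample") |>
    dplyr::summarise(tpm = fun(.data$tpm),
                     .by = c("gene_id", "tissue"))
  tissue_order <- unique(sample_map$tissue[sample_map$sample %in% samples])
  tidyr::pivot_wider(long, names_from = "tissue", values_from = "tpm") |>
    dplyr::select("gene_id", dplyr::all_of(tissue_order)) |>
    dplyr::arrange(match(.data$gene_id, sample_tpm$gene_id))
}

#' Flag expressed genes and count expressing tissues
#'
#' A gene is expressed when its TPM reaches `threshold` in at least one
#' tissue (boundary inclusive).
#'
#' @param m Tissue-mean expression tibble from [build_expression_matrix()].
#' @param threshold TPM threshold (default 0.1).
#' @return A tibble `gene_id`, `max_tpm`, `n_tissues`, `expressed`.
#' @export
expressed_genes <- function(m, threshold = 0.1) {
  stopifnot(threshold >= 0)
  vals <- as.matrix(m[setdiff(names(m), "gene_id")])
  tibble::tibble(
    gene_id = m$gene_id,
    max_tpm = apply(vals, 1, max),
    n_tissues = rowSums(vals >= threshold),
    expressed = apply(vals, 1, max) >= threshold
  )
}

#' Retain gene models supported by expression and read counts
#'
#' A model is retained when (a) its TPM reaches `min_tpm` in at least one
#' tissue and (b) there is a tissue whose samples support it with at least
#' `min_reads` reads. Under the default `rule = "all"` every sample of that
#' tissue must reach `min_reads`, which discards models supported by one or
#' two reads regardless of replicate; `"any"` and `"sum"` relax this to any
#' single sample or to the tissue read sum.
#'
#' @param m Tissue-mean TPM tibble (see [build_expression_matrix()]).
#' @param counts Tibble with `gene_id` and one read-count column per sample.
#' @param sample_map Tibble `sample`, `tissue`.
#' @param min_tpm Expression threshold (default 0.1 TPM).
#' @param min_reads Read-support threshold (default 5).
#' @param rule How samples of a tissue must meet `min_reads`.
#' @return A tibble `gene_id`, `expressed_ok`, `reads_ok`, `retained`.
#' @export
retention_filter <- function(m, counts, sample_map, min_tpm = 0.1,
                             min_reads = 5, rule = c("all", "any", "sum")) {
  rule <- match.arg(rule)
  expr <- expressed_genes(m, threshold = min_tpm)
  agg <- tidyr::pivot_longer(counts, -"gene_id",
                             names_to = "sample", values_to = "reads") |>
    dplyr::inner_join(sample_map, by = "sample") |>
    dplyr::summarise(
      ok = switch(rule,
                  all = all(.data$reads >= min_reads),
                  any = any(.data$reads >= min_reads),
                  sum = sum(.data$reads) >= min_reads),
      .by = c("gene_id", "tissue")
    ) |>
    dplyr::summarise(reads_ok = any(.data$ok), .by = "gene_id")
  dplyr::left_join(expr[, c("gene_id", "expressed")], agg, by = "gene_id") |>
    dplyr::mutate(
      reads_ok = dplyr::coalesce(.data$reads_ok, FALSE),
      expressed_ok = .data$expressed,
      retained = .data$expressed_ok & .data$reads_ok
    ) |>
    dplyr::select("gene_id", "expressed_ok", "reads_ok", "retained")
}

#' Draw length-matched background-noise loci
#'
#' Places one artificial locus per requested length, uniformly over all
#' genomic start positions that keep the locus within its chromosome and at
#' least `min_gap` bp away from every transcribed region. The emitted length
#' multiset equals the input multiset, and the draw is reproducible for a
#' fixed seed. Loci are drawn independently (they may overlap each other).
#'
#' @param lnc_lengths Integer vector of locus lengths (typically the lncRNA
#'   gene-length distribution).
#' @param transcribed Tibble of transcribed intervals (`chrom`, `start`,
#'   `end`).
#' @param chroms Chromosome table ([chrom_table()]) restricted to the
#'   chromosomes to draw from (the atlas uses chr 1-33).
#' @param min_gap Minimum clearance from transcribed regions in bp
#'   (default 5000).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A tibble `chrom`, `start`, `end`, `length`, `name`.
#' @export
shuffle_noise_loci <- function(lnc_lengths, transcribed, chroms,
                               min_gap = 5000, seed) {
  stopifnot(all(lnc_lengths >= 1), min_gap >= 0)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  lnc_lengths <- as.integer(lnc_lengths)

  # allowed intervals per chromosome: complement of transcribed +- min_gap
  allowed <- purrr::pmap(chroms, function(chrom, length, class) {
    full <- IRanges::IRanges(1, length)
    tr <- transcribed[transcribed$chrom == chrom, , drop = FALSE]
    if (nrow(tr) == 0) return(list(chrom = chrom, gaps = full))
    excl <- IRanges::IRanges(pmax(1, tr$start - min_gap),
                             pmin(length, tr$end + min_gap))
    list(chrom = chrom,
         gaps = IRanges::gaps(IRanges::reduce(excl), start = 1, end = length))
  })

  rows <- purrr::map(seq_along(lnc_lengths), function(i) {
    len <- lnc_lengths[i]
    # count valid starts in every gap of every chromosome
    per_chrom <- purrr::map(allowed, function(a) {
      w <- IRanges::width(a$gaps)
      n <- pmax(0L, w - len + 1L)
      list(chrom = a$chrom, gaps = a$gaps, n = n)
    })
    total <- sum(purrr::map_dbl(per_chrom, ~ sum(.x$n)))
    if (total == 0) {
      stop("no feasible placement for locus length ", len, call. = FALSE)
    }
    pick <- sample.int(total, 1)
    for (a in per_chrom) {
      if (pick <= sum(a$n)) {
        cum <- cumsum(a$n)
        g <- which(pick <= cum)[1]
        offset <- pick - c(0, cum)[g] - 1
        start <- IRanges::start(a$gaps)[g] + offset
        return(tibble::tibble(chrom = a$chrom, start = start,
                              end = start + len - 1L, length = len,
                              name = sprintf("noise_%04d", i)))
      }
      pick <- pick - sum(a$n)
    }
  })
  dplyr::bind_rows(rows)
}

#' Hierarchically cluster tissues on expression profiles
#'
#' Pairwise tissue distance is 1 - Pearson correlation of per-gene
#' log10(TPM + 1) profiles; linkage is Ward (the squared-distance
#' Lance-Williams variant, `ward.D2`). Merge order for tied heights follows
#' `stats::hclust`'s deterministic lowest-index rule. A zero-variance tissue
#' profile has its correlations set to 0 with a warning.
#'
#' @param m Tissue-mean expression tibble.
#' @param genes Optional character vector restricting the genes used (e.g.
#'   expressed lncRNAs).
#' @param log_transform Apply log10(TPM + 1) before correlating
#'   (default `TRUE`).
#' @return An object of class `hclust`.
#' @export
cluster_tissues <- function(m, genes = NULL, log_transform = TRUE) {
  if (!is.null(genes)) m <- m[m$gene_id %in% genes, , drop = FALSE]
  tissues <- setdiff(names(m), "gene_id")
  if (length(tissues) < 2) stop("need at least 2 tissues", call. = FALSE)
  if (nrow(m) == 0) stop("empty gene subset", call. = FALSE)
  vals <- as.matrix(m[tissues])
  if (log_transform) vals <- log10(vals + 1)
  zerovar <- apply(vals, 2, stats::sd) == 0
  cors <- suppressWarnings(stats::cor(vals, method = "pearson"))
  if (any(zerovar)) {
    warning("zero-variance tissue profile(s): ",
            paste(tissues[zerovar], collapse = ", "),
            "; correlations set to 0")
    cors[zerovar, ] <- 0
    cors[, zerovar] <- 0
    diag(cors) <- 1
  }
  stats::hclust(stats::as.dist(1 - cors), method = "ward.D2")
}

#' Newick string for a tissue dendrogram
#'
#' @param hc An `hclust` object from [cluster_tissues()].
#' @return A single Newick string.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Gene density per chromosome and size class
#'
#' Computes lncRNA and protein-coding gene densities (genes per Mb) for each
#' chromosome, their Spearman correlation across chromosomes, and aggregate
#' densities per chromosome size class (macro/medium/micro).
#'
#' @param catalogue An exon-level catalogue.
#' @param chroms Chromosome table ([chrom_table()]) covering every chromosome
#'   present in the catalogue.
#' @return An object of class `chrom_density`: a list with `per_chrom` and
#'   `by_class` tibbles plus `rho`, `p`. Use [generics::tidy()] /
#'   [generics::glance()] or [autoplot.chrom_density()].
#' @export
density_by_chromosome <- function(catalogue, chroms) {
  genes <- gene_table(catalogue)
  unknown <- setdiff(unique(genes$chrom), chroms$chrom)
  if (length(unknown) > 0) {
    stop("gene(s) on chromosome(s) absent from the chromosome table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- dplyr::summarise(
    genes,
    n_lnc = sum(.data$biotype == "lncRNA"),
    n_pcg = sum(.data$biotype == "protein_coding"),
    .by = "chrom"
  )
  per_chrom <- dplyr::left_join(chroms, counts, by = "chrom") |>
    dplyr::mutate(
      n_lnc = dplyr::coalesce(.data$n_lnc, 0L),
      n_pcg = dplyr::coalesce(.data$n_pcg, 0L),
      lnc_per_mb = .data$n_lnc / (.data$length / 1e6),
      pcg_per_mb = .data$n_pcg / (.data$length / 1e6)
    )
  ct <- suppressWarnings(
    stats::cor.test(per_chrom$lnc_per_mb, per_chrom$pcg_per_mb,
                    method = "spearman")
  )
  by_class <- dplyr::summarise(
    per_chrom,
    total_mb = sum(.data$length) / 1e6,
    lnc_per_mb = sum(.data$n_lnc) / sum(.data$length) * 1e6,
    pcg_per_mb = sum(.data$n_pcg) / sum(.data$length) * 1e6,
    .by = "class"
  )
  structure(
    list(per_chrom = per_chrom, by_class = by_class,
         rho = unname(ct$estimate), p = ct$p.value),
    class = "chrom_density"
  )
}

#' @export
print.chrom_density <- function(x, ...) {
  cat("Gene density across", nrow(x$per_chrom), "chromosomes\n")
  cat(sprintf("Spearman rho = %.3f, p = %.3g\n", x$rho, x$p))
  print(x$by_class)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname density_by_chromosome
#' @param x A `chrom_density` object.
#' @param ... Unused.
#' @export
tidy.chrom_density <- function(x, ...) x$per_chrom

#' @rdname density_by_chromosome
#' @export
glance.chrom_density <- function(x, ...) {
  tibble::tibble(rho = x$rho, p = x$p, n_chroms = nrow(x$per_chrom))
}
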