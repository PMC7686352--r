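#' Default 21-tissue panel labels
#'
#' The four-letter abbreviations of the 21-tissue expression panel used as
#' the generator's default tissue set.
#' @return Character vector of 21 labels.
#' @export
default_tissues <- function() {
  c("burs", "cctl", "crbl", "duod", "fatG", "hard", "hert", "ileu", "kdny",
    "livr", "lung", "mscB", "optc", "ovry", "pcrs", "pvtc", "skin", "spln",
    "thym", "thyr", "trch")
}

#' Configuration of the synthetic-data generators
#'
#' Bundles every knob of the seeded generators. The defaults emulate the
#' study conditions: a base annotation plus four candidate lncRNA sources
#' with CAGE support fractions 0.073/0.055/0.053/0.042 (inra/aldb/ncbi/
#' noncode), planted lncRNA:PCG pairs in every configuration including the
#' 1 kb / 5 kb boundary distances, and a 21-tissue, 8-replicate expression
#' panel. Replicate noise is off by default so planted quantities are
#' recovered exactly; set `noise_sd` for robustness experiments.
#'
#' @param seed Integer seed driving every generator.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n_base_pcg,n_base_lnc,n_base_other Gene counts of the base
#'   (reference) annotation.
#' @param sources Tibble `source`, `n_genes`, `overlap_fraction`,
#'   `cage_fraction` describing the candidate sources.
#' @param pair_spec Tibble `ptype`, `direction`, `subtype`, `location`,
#'   `distance_bp`, `count` of planted pair configurations.
#' @param host_spec Tibble `small_biotype`, `strand_relation`, `location`,
#'   `count` of planted small-RNA/host-lncRNA relations.
#' @param tau_spec Tibble `tau`, `count`, `tier` of planted
#'   tissue-specificity profiles (`tier` is `"ge1"` or `"lt1"` by Top1 TPM).
#' @param cor_spec Tibble `rho`, `count` of planted Spearman-correlated
#'   pairs.
#' @param n_null_pairs Number of independent (null) pairs.
#' @param n_fail_retention Genes planted to fail the read-support filter.
#' @param tissues Tissue labels (length >= 2).
#' @param replicates Replicates per tissue.
#' @param noise_sd Log-normal replicate noise scale (0 = noise-free).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1,
    chrom_lengths = c("1" = 1e7, "2" = 1e7, "3" = 1e7),
    n_base_pcg = 500, n_base_lnc = 200, n_base_other = 50,
    sources = tibble::tibble(
      source = c("inra", "aldb", "ncbi", "noncode"),
      n_genes = 1000L,
      overlap_fraction = 0.2,
      cage_fraction = c(0.073, 0.055, 0.053, 0.042)
    ),
    pair_spec = default_pair_spec(),
    host_spec = tibble::tibble(
      small_biotype = c("miRNA", "miRNA", "miRNA", "snoRNA", "snRNA"),
      strand_relation = c("sense", "antisense", "sense", "antisense",
                          "sense"),
      location = c("intronic", "intronic", "exonic", "exonic", "intronic"),
      count = 1L
    ),
    tau_spec = tibble::tibble(
      tau = c(1, 0, 0.9875, 0.94, 0.97),
      count = c(8, 8, 6, 6, 6),
      tier = c("ge1", "ge1", "ge1", "lt1", "lt1")
    ),
    cor_spec = tibble::tibble(rho = c(1, 0.9, -1), count = c(6, 6, 3)),
    n_null_pairs = 50,
    n_fail_retention = 10,
    tissues = default_tissues(),
    replicates = 8,
    noise_sd = 0) {
  stopifnot(
    all(sources$overlap_fraction >= 0 & sources$overlap_fraction <= 1),
    all(sources$cage_fraction >= 0 & sources$cage_fraction <= 1),
    all(pair_spec$distance_bp >= 0 | pair_spec$ptype == "genic"),
    all(tau_spec$tau >= 0 & tau_spec$tau <= 1),
    all(cor_spec$rho >= -1 & cor_spec$rho <= 1),
    length(tissues) >= 2, replicates >= 1, noise_sd >= 0,
    all(chrom_lengths > 0)
  )
  structure(
    list(seed = seed, chrom_lengths = chrom_lengths,
         n_base_pcg = n_base_pcg, n_base_lnc = n_base_lnc,
         n_base_other = n_base_other, sources = sources,
         pair_spec = pair_spec, host_spec = host_spec, tau_spec = tau_spec,
         cor_spec = cor_spec, n_null_pairs = n_null_pairs,
         n_fail_retention = n_fail_retention, tissues = tissues,
         replicates = replicates, noise_sd = noise_sd),
    class = "sim_config"
  )
}

#' Default planted pair configurations
#'
#' Every intergenic direction at the boundary distances 1,000 / 5,000 /
#' 5,001 bp and at the atlas's reported median distances (3,957; 5,130;
#' 6,005 bp), plus genic cases covering each subtype x location x strand
#' combination.
#' @return A tibble `ptype`, `direction`, `subtype`, `location`,
#'   `distance_bp`, `count`.
#' @export
default_pair_spec <- function() {
  inter <- tidyr::expand_grid(
    direction = c("divergent", "convergent", "same_strand"),
    distance_bp = c(1000L, 3957L, 5000L, 5001L, 5130L, 6005L)
  ) |>
    dplyr::mutate(ptype = "intergenic", subtype = NA_character_,
                  location = NA_character_, count = 1L)
  genic <- tibble::tibble(
    ptype = "genic",
    direction = c("sense", "antisense", "sense", "antisense", "sense",
                  "antisense"),
    subtype = c("overlapping", "overlapping", "containing", "containing",
                "nested", "nested"),
    location = c("exonic", "intronic", "intronic", "exonic", "intronic",
                 "exonic"),
    distance_bp = 0L,
    count = 1L
  )
  dplyr::bind_rows(inter, genic)[, c("ptype", "direction", "subtype",
                                     "location", "distance_bp", "count")]
}

# vectorised two-exon gene bodies (width 1000) at given starts
#' @keywords internal
gene_exons <- function(gene_id, chrom, start, strand, biotype, source) {
  n <- length(gene_id)
  i2 <- rep(seq_len(n), each = 2)
  cols <- list(
    gene_id = gene_id[i2],
    transcript_id = paste0(gene_id, ".t1")[i2],
    chrom = rep(chrom, length.out = n)[i2],
    start = rep(as.integer(start), each = 2) + c(0L, 600L),
    strand = rep(strand, length.out = n)[i2],
    biotype = rep(biotype, length.out = n)[i2],
    source = rep(source, length.out = n)[i2]
  )
  cols$end <- cols$start + 399L
  tibble::as_tibble(cols)[, c("gene_id", "transcript_id", "chrom", "start",
                              "end", "strand", "biotype", "source")]
}

#' Generate a base annotation and overlapping candidate sources
#'
#' Lays out non-overlapping two-exon base genes on the configured
#' chromosomes, then builds one candidate catalogue per source in which
#' exactly `round(overlap_fraction * n_genes)` genes are planted to overlap
#' a distinct base gene on the same strand (by at least 1 bp) while all
#' remaining genes sit in private slots with clearance. Deterministic given
#' the seed.
#'
#' @param cfg A [sim_config()].
#' @return A list: `base` (catalogue), `sources` (named list of catalogues),
#'   `truth` (per-gene tibble: `gene_id`, `source`, `biotype`,
#'   `overlaps_base`, `partner_id`).
#' @export
simulate_catalogues <- function(cfg) {
  set.seed(cfg$seed)
  slot_w <- 5000
  slots_per_chrom <- floor(cfg$chrom_lengths / slot_w) - 1
  slot_chrom <- rep(names(cfg$chrom_lengths), slots_per_chrom)
  slot_start <- unlist(purrr::map(slots_per_chrom,
                                  ~ (seq_len(.x) - 1) * slot_w + 1))
  n_base <- cfg$n_base_pcg + cfg$n_base_lnc + cfg$n_base_other
  n_free <- sum(round((1 - cfg$sources$overlap_fraction) *
                        cfg$sources$n_genes))
  if (n_base + n_free > length(slot_chrom)) {
    stop("infeasible config: not enough chromosome space", call. = FALSE)
  }
  gene_pos <- slot_start + 1000L  # gene body offset inside its slot
  cursor <- 0L
  take_slots <- function(k) {
    idx <- cursor + seq_len(k)
    cursor <<- cursor + k
    idx
  }

  base_bio <- c(rep("protein_coding", cfg$n_base_pcg),
                rep("lncRNA", cfg$n_base_lnc),
                rep("other", cfg$n_base_other))
  idx <- take_slots(n_base)
  base_ids <- sprintf("base.g%04d", seq_len(n_base))
  base <- as_catalogue(gene_exons(
    base_ids, slot_chrom[idx], gene_pos[idx],
    sample(c("+", "-"), n_base, replace = TRUE), base_bio, "ensembl"
  ))
  base_genes <- gene_table(base)

  truth <- list(tibble::tibble(
    gene_id = base_genes$gene_id, source = "ensembl",
    biotype = base_genes$biotype, overlaps_base = FALSE,
    partner_id = NA_character_
  ))
  sources <- list()
  for (j in seq_len(nrow(cfg$sources))) {
    src <- cfg$sources$source[j]
    n <- cfg$sources$n_genes[j]
    k_ov <- round(cfg$sources$overlap_fraction[j] * n)
    if (k_ov > nrow(base_genes)) {
      stop("infeasible config: more planted overlaps than base genes",
           call. = FALSE)
    }
    ids <- sprintf("%s.g%04d", src, seq_len(n))
    partners <- base_genes[sample.int(nrow(base_genes), k_ov), ]
    # overlap the partner by 1 + 250*(j-1) bp on its strand; the per-source
    # offset keeps TSSs of co-planted candidates > 100 bp apart so CAGE
    # support stays source-exact
    ov <- if (k_ov > 0) {
      gene_exons(ids[seq_len(k_ov)], partners$chrom,
                 partners$end - 250L * (j - 1L), partners$strand,
                 "lncRNA", src)
    } else {
      NULL
    }
    free <- if (n > k_ov) {
      idx <- take_slots(n - k_ov)
      gene_exons(ids[(k_ov + 1):n], slot_chrom[idx], gene_pos[idx],
                 sample(c("+", "-"), n - k_ov, replace = TRUE),
                 "lncRNA", src)
    } else {
      NULL
    }
    sources[[src]] <- as_catalogue(dplyr::bind_rows(ov, free))
    truth[[src]] <- tibble::tibble(
      gene_id = ids, source = src, biotype = "lncRNA",
      overlaps_base = seq_len(n) <= k_ov,
      partner_id = c(partners$gene_id, rep(NA_character_, n - k_ov))
    )
  }
  list(base = base, sources = sources, truth = dplyr::bind_rows(truth))
}

#' Generate CAGE peaks supporting a planted fraction of transcripts
#'
#' For each source, exactly `round(cage_fraction * n)` lncRNA transcripts
#' receive a 10-bp peak centred on their TSS; decoy peaks are placed at
#' least 200 bp away from every TSS.
#'
#' @param cfg A [sim_config()].
#' @param sources Named list of catalogues from [simulate_catalogues()].
#' @return A list: `peaks` (tibble `chrom`, `start`, `end`, `strand`,
#'   `name`) and `truth` (tibble `transcript_id`, `source`,
#'   `cage_supported`).
#' @export
simulate_cage <- function(cfg, sources) {
  set.seed(cfg$seed + 1L)
  peak_rows <- list()
  truth <- list()
  for (src in names(sources)) {
    tt <- dplyr::filter(transcript_table(sources[[src]]),
                        .data$biotype == "lncRNA")
    frac <- cfg$sources$cage_fraction[cfg$sources$source == src]
    k <- round(frac * nrow(tt))
    supported <- rep(FALSE, nrow(tt))
    supported[sample.int(nrow(tt), k)] <- TRUE
    peak_rows[[src]] <- tibble::tibble(
      chrom = tt$chrom[supported],
      start = tt$tss[supported] - 5L,
      end = tt$tss[supported] + 4L,
      strand = ".",
      name = paste0("cage_", tt$transcript_id[supported])
    )
    truth[[src]] <- tibble::tibble(
      transcript_id = tt$transcript_id, source = src,
      cage_supported = supported
    )
  }
  # decoy peaks far from every TSS (slot interiors are gene-free)
  decoys <- tibble::tibble(
    chrom = names(cfg$chrom_lengths)[1],
    start = (seq_len(20) - 1) * 5000 + 3500,
    end = (seq_len(20) - 1) * 5000 + 3509,
    strand = ".",
    name = sprintf("cage_decoy_%02d", seq_len(20))
  )
  list(peaks = dplyr::bind_rows(c(peak_rows, list(decoys))),
       truth = dplyr::bind_rows(truth))
}

#' Generate planted lncRNA:PCG pair configurations
#'
#' Each planted pair occupies its own 250-kb block so the planted partner is
#' the only protein-coding transcript within the classifier's 100-kb window.
#' Intergenic pairs are built at the requested gap with strands derived from
#' the direction (the lncRNA is placed left or right of the PCG at random);
#' genic pairs use fixed exon templates realising each subtype x location.
#' Host relations from `cfg$host_spec` are planted as standalone lncRNAs
#' containing a small-RNA gene.
#'
#' @param cfg A [sim_config()].
#' @return A list: `catalogue` (lncRNAs + PCGs + small RNAs), `truth`
#'   (planted pair labels) and `host_truth` (planted host relations).
#' @export
simulate_pairs <- function(cfg) {
  set.seed(cfg$seed + 2L)
  block_w <- 250000L
  blocks_per_chrom <- floor(cfg$chrom_lengths / block_w)
  blk_chrom <- rep(names(cfg$chrom_lengths), blocks_per_chrom)
  blk_start <- unlist(purrr::map(blocks_per_chrom,
                                 ~ (seq_len(.x) - 1L) * block_w + 1L))
  spec <- tidyr::uncount(cfg$pair_spec, weights = .data$count)
  n_blocks_needed <- nrow(spec) + sum(cfg$host_spec$count)
  if (n_blocks_needed > length(blk_chrom)) {
    stop("infeasible config: not enough blocks for planted pairs",
         call. = FALSE)
  }
  used <- 0L
  next_block <- function() {
    used <<- used + 1L
    list(chrom = blk_chrom[used], c = blk_start[used] + 110000L)
  }

  cat_rows <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(spec))) {
    b <- next_block()
    c0 <- b$c
    lid <- sprintf("sim.lnc%03d", i)
    pid <- sprintf("sim.pcg%03d", i)
    pcg_strand <- sample(c("+", "-"), 1)
    pcg <- tibble::tibble(
      gene_id = pid, transcript_id = paste0(pid, ".t1"), chrom = b$chrom,
      start = c(c0, c0 + 1200L), end = c(c0 + 800L, c0 + 1999L),
      strand = pcg_strand, biotype = "protein_coding", source = "sim"
    )
    if (spec$ptype[i] == "intergenic") {
      d <- spec$distance_bp[i]
      lnc_left <- sample(c(TRUE, FALSE), 1)
      # divergent = 5'-to-5' facing across the gap, convergent = 3'-to-3'
      if (spec$direction[i] == "same_strand") {
        lnc_strand <- pcg_strand
      } else if (spec$direction[i] == "divergent") {
        lnc_strand <- if (lnc_left) "-" else "+"
        pcg_strand <- if (lnc_left) "+" else "-"
      } else {
        lnc_strand <- if (lnc_left) "+" else "-"
        pcg_strand <- if (lnc_left) "-" else "+"
      }
      pcg$strand <- pcg_strand
      if (lnc_left) {
        lend <- c0 - d - 1L
        lstart <- lend - 1499L
      } else {
        lstart <- c0 + 1999L + d + 1L
        lend <- lstart + 1499L
      }
      lnc <- tibble::tibble(
        gene_id = lid, transcript_id = paste0(lid, ".t1"), chrom = b$chrom,
        start = c(lstart, lstart + 900L), end = c(lstart + 600L, lend),
        strand = lnc_strand, biotype = "lncRNA", source = "sim"
      )
      upstream <- if (pcg_strand == "+") lnc_left else !lnc_left
      truth_rows[[i]] <- tibble::tibble(
        lnc_gene_id = lid, pcg_gene_id = pid, ptype = "intergenic",
        direction = spec$direction[i], subtype = NA_character_,
        location = if (upstream) "upstream" else "downstream",
        distance_bp = d, distance_class = distance_bin(d)
      )
    } else {
      lnc_strand <- if (spec$direction[i] == "sense") {
        pcg_strand
      } else {
        if (pcg_strand == "+") "-" else "+"
      }
      tpl <- paste(spec$subtype[i], spec$location[i], sep = ".")
      ex <- switch(
        tpl,
        overlapping.exonic = list(start = c0 - 500L, end = c0 + 500L),
        overlapping.intronic = list(start = c(c0 - 500L, c0 + 900L),
                                    end = c(c0 - 10L, c0 + 1100L)),
        containing.intronic = list(start = c(c0 - 500L, c0 + 2100L),
                                   end = c(c0 - 10L, c0 + 2500L)),
        containing.exonic = list(start = c0 - 500L, end = c0 + 2500L),
        nested.intronic = list(start = c0 + 850L, end = c0 + 1150L),
        nested.exonic = list(start = c0 + 700L, end = c0 + 900L),
        stop("no template for genic case ", tpl, call. = FALSE)
      )
      lnc <- tibble::tibble(
        gene_id = lid, transcript_id = paste0(lid, ".t1"), chrom = b$chrom,
        start = ex$start, end = ex$end, strand = lnc_strand,
        biotype = "lncRNA", source = "sim"
      )
      truth_rows[[i]] <- tibble::tibble(
        lnc_gene_id = lid, pcg_gene_id = pid, ptype = "genic",
        direction = spec$direction[i], subtype = spec$subtype[i],
        location = spec$location[i], distance_bp = 0L,
        distance_class = "<=1kb"
      )
    }
    cat_rows[[i]] <- dplyr::bind_rows(lnc, pcg)
  }

  host_spec <- tidyr::uncount(cfg$host_spec, weights = .data$count)
  host_rows <- list()
  host_truth <- list()
  for (i in seq_len(nrow(host_spec))) {
    b <- next_block()
    c0 <- b$c
    hid <- sprintf("sim.host%02d", i)
    sid <- sprintf("sim.small%02d", i)
    host_strand <- sample(c("+", "-"), 1)
    small_strand <- if (host_spec$strand_relation[i] == "sense") {
      host_strand
    } else {
      if (host_strand == "+") "-" else "+"
    }
    sm_pos <- if (host_spec$location[i] == "intronic") {
      c(c0 + 700L, c0 + 780L)     # inside the host intron [c0+501, c0+1499]
    } else {
      c(c0 + 100L, c0 + 180L)     # inside host exon 1
    }
    host_rows[[i]] <- dplyr::bind_rows(
      tibble::tibble(
        gene_id = hid, transcript_id = paste0(hid, ".t1"), chrom = b$chrom,
        start = c(c0, c0 + 1500L), end = c(c0 + 500L, c0 + 2000L),
        strand = host_strand, biotype = "lncRNA", source = "sim"
      ),
      tibble::tibble(
        gene_id = sid, transcript_id = paste0(sid, ".t1"), chrom = b$chrom,
        start = sm_pos[1], end = sm_pos[2], strand = small_strand,
        biotype = host_spec$small_biotype[i], source = "sim"
      )
    )
    host_truth[[i]] <- tibble::tibble(
      host_lnc_id = hid, small_rna_id = sid,
      small_rna_biotype = host_spec$small_biotype[i],
      strand_relation = host_spec$strand_relation[i],
      location = host_spec$location[i]
    )
  }

  list(
    catalogue = as_catalogue(dplyr::bind_rows(c(cat_rows, host_rows))),
    truth = dplyr::bind_rows(truth_rows),
    host_truth = dplyr::bind_rows(host_truth)
  )
}

#' Two-level expression profile with an exact tau value
#'
#' Inverts the tau formula: with `k` tissues at the top level, one tissue at
#' a fractional level and the rest at 0, any target in `[0, 1]` is
#' attainable exactly.
#'
#' @param tau_target Target tau in `[0, 1]`.
#' @param n_tissues Number of tissues (>= 2).
#' @param top Top expression level in TPM.
#' @return Numeric vector of length `n_tissues` whose [tau()] equals
#'   `tau_target` exactly.
#' @export
profile_from_tau <- function(tau_target, n_tissues, top = 50) {
  stopifnot(tau_target >= 0, tau_target <= 1, n_tissues >= 2, top > 0)
  s <- tau_target * (n_tissues - 1)
  k <- as.integer(ceiling(n_tissues - 1 - s))
  a <- n_tissues - k - s
  c(rep(top, k), top * a, rep(0, n_tissues - k - 1))
}

#' Generate expression tables with planted tau profiles and correlations
#'
#' Builds per-sample TPM and read-count tables over the configured tissue
#' panel. Tau-planted genes get tissue-mean profiles from
#' [profile_from_tau()] (Top1 tissue rotated across the panel; top level 50
#' TPM for tier `ge1`, 0.5 TPM for `lt1`). Correlation-planted pairs use a
#' Gaussian copula with the Pearson parameter `2 sin(pi rho / 6)` so the
#' rank correlation targets the requested Spearman rho (exact rank identity
#' at rho = +/-1); null pairs are independent. Replicates multiply the
#' tissue mean by mean-one log-normal noise (`noise_sd = 0` leaves them
#' identical). Read counts respect the planted retention outcomes: pass
#' genes are supported by >= 5 reads in every sample of their top tissue,
#' fail genes by <= 2 reads everywhere.
#'
#' @param cfg A [sim_config()].
#' @param pairs Optional tibble `lnc_gene_id`, `pcg_gene_id`: planted
#'   correlations are assigned to these ids (recycled over `cor_spec` rows
#'   in order) instead of generated ids.
#' @return A list: `sample_tpm`, `sample_counts`, `sample_map`,
#'   `truth_genes`, `truth_pairs`.
#' @export
simulate_expression <- function(cfg, pairs = NULL) {
  set.seed(cfg$seed + 3L)
  tn <- length(cfg$tissues)
  means <- list()
  truth_genes <- list()
  truth_pairs <- list()

  rot <- function(x, off) x[((seq_along(x) - 1 + off) %% length(x)) + 1]

  gi <- 0L
  for (r in seq_len(nrow(cfg$tau_spec))) {
    top <- if (cfg$tau_spec$tier[r] == "ge1") 50 else 0.5
    for (k in seq_len(cfg$tau_spec$count[r])) {
      gi <- gi + 1L
      gid <- sprintf("tau.g%03d", gi)
      prof <- rot(profile_from_tau(cfg$tau_spec$tau[r], tn, top), -(gi - 1L))
      means[[gid]] <- prof
      truth_genes[[gid]] <- tibble::tibble(
        gene_id = gid, kind = "tau", tau_target = cfg$tau_spec$tau[r],
        top1_tissue = cfg$tissues[((gi - 1L) %% tn) + 1L],
        tier = cfg$tau_spec$tier[r], fail_retention = FALSE
      )
    }
  }

  copula_profile <- function(z) stats::qlnorm(stats::pnorm(z),
                                              meanlog = 1, sdlog = 1)
  pair_i <- 0L
  cor_rows <- tidyr::uncount(cfg$cor_spec, weights = .data$count)
  for (r in seq_len(nrow(cor_rows))) {
    pair_i <- pair_i + 1L
    rho <- cor_rows$rho[r]
    ida <- sprintf("corA.g%03d", pair_i)
    idb <- sprintf("corB.g%03d", pair_i)
    if (!is.null(pairs) && pair_i <= nrow(pairs)) {
      ida <- pairs$lnc_gene_id[pair_i]
      idb <- pairs$pcg_gene_id[pair_i]
    }
    z1 <- stats::rnorm(tn)
    z2 <- if (abs(rho) == 1) {
      sign(rho) * z1
    } else {
      rp <- 2 * sin(pi * rho / 6)
      rp * z1 + sqrt(1 - rp^2) * stats::rnorm(tn)
    }
    means[[ida]] <- copula_profile(z1)
    means[[idb]] <- copula_profile(z2)
    truth_pairs[[pair_i]] <- tibble::tibble(
      id_a = ida, id_b = idb, rho_target = rho, null_pair = FALSE
    )
    truth_genes[[ida]] <- tibble::tibble(
      gene_id = ida, kind = "cor", tau_target = NA_real_,
      top1_tissue = NA_character_, tier = NA_character_,
      fail_retention = FALSE
    )
    truth_genes[[idb]] <- dplyr::mutate(truth_genes[[ida]], gene_id = idb)
  }
  for (r in seq_len(cfg$n_null_pairs)) {
    pair_i <- pair_i + 1L
    ida <- sprintf("nullA.g%03d", r)
    idb <- sprintf("nullB.g%03d", r)
    if (!is.null(pairs) && pair_i <= nrow(pairs)) {
      ida <- pairs$lnc_gene_id[pair_i]
      idb <- pairs$pcg_gene_id[pair_i]
    }
    means[[ida]] <- copula_profile(stats::rnorm(tn))
    means[[idb]] <- copula_profile(stats::rnorm(tn))
    truth_pairs[[pair_i]] <- tibble::tibble(
      id_a = ida, id_b = idb, rho_target = 0, null_pair = TRUE
    )
    truth_genes[[ida]] <- tibble::tibble(
      gene_id = ida, kind = "null", tau_target = NA_real_,
      top1_tissue = NA_character_, tier = NA_character_,
      fail_retention = FALSE
    )
    truth_genes[[idb]] <- dplyr::mutate(truth_genes[[ida]], gene_id = idb)
  }
  for (r in seq_len(cfg$n_fail_retention)) {
    gid <- sprintf("fail.g%03d", r)
    means[[gid]] <- rep(0.5, tn)
    truth_genes[[gid]] <- tibble::tibble(
      gene_id = gid, kind = "fail_retention", tau_target = NA_real_,
      top1_tissue = NA_character_, tier = NA_character_,
      fail_retention = TRUE
    )
  }

  sample_map <- tidyr::expand_grid(
    tissue = cfg$tissues, rep = seq_len(cfg$replicates)
  ) |>
    dplyr::mutate(sample = paste0(.data$tissue, "_r", .data$rep)) |>
    dplyr::select("sample", "tissue")

  mean_mat <- do.call(rbind, means)
  colnames(mean_mat) <- cfg$tissues
  noise <- if (cfg$noise_sd > 0) {
    matrix(exp(stats::rnorm(nrow(mean_mat) * nrow(sample_map), 0,
                            cfg$noise_sd) - cfg$noise_sd^2 / 2),
           nrow = nrow(mean_mat))
  } else {
    matrix(1, nrow(mean_mat), nrow(sample_map))
  }
  tpm_mat <- mean_mat[, match(sample_map$tissue, cfg$tissues),
                      drop = FALSE] * noise
  colnames(tpm_mat) <- sample_map$sample

  truth_genes <- dplyr::bind_rows(truth_genes)
  count_mat <- round(tpm_mat * 20)
  fail <- truth_genes$fail_retention[match(rownames(mean_mat),
                                           truth_genes$gene_id)]
  count_mat[fail, ] <- pmin(count_mat[fail, , drop = FALSE], 2)
  # guarantee >= 5 reads in every sample of each pass gene's top tissue
  top_tissue <- colnames(mean_mat)[max.col(mean_mat, ties.method = "first")]
  for (g in which(!fail)) {
    cols <- sample_map$tissue == top_tissue[g]
    count_mat[g, cols] <- pmax(count_mat[g, cols], 5)
  }

  list(
    sample_tpm = dplyr::bind_cols(
      tibble::tibble(gene_id = rownames(mean_mat)),
      tibble::as_tibble(tpm_mat)
    ),
    sample_counts = dplyr::bind_cols(
      tibble::tibble(gene_id = rownames(mean_mat)),
      tibble::as_tibble(count_mat)
    ),
    sample_map = sample_map,
    truth_genes = truth_genes,
    truth_pairs = dplyr::bind_rows(truth_pairs)
  )
}
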