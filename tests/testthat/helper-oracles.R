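# Fixture builders and brute-force oracles, kept independent of the package
# code paths they check.

# one-transcript exon tibble
tx_tbl <- function(gene_id, chrom, starts, ends, strand,
                   biotype = "lncRNA", source = "test",
                   transcript_id = paste0(gene_id, ".t1")) {
  tibble::tibble(
    gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
    start = as.integer(starts), end = as.integer(ends), strand = strand,
    biotype = biotype, source = source
  )
}

# random single/two-exon gene catalogue for oracle comparisons
random_catalogue <- function(n, prefix, chroms = c("1", "2"),
                             span_max = 50000, biotype = "lncRNA",
                             source = "test") {
  rows <- lapply(seq_len(n), function(i) {
    chrom <- sample(chroms, 1)
    start <- sample.int(span_max, 1)
    width <- sample(200:2000, 1)
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("%s%04d", prefix, i)
    if (stats::runif(1) < 0.5) {
      tx_tbl(gid, chrom, start, start + width, strand, biotype, source)
    } else {
      mid <- start + floor(width / 2)
      tx_tbl(gid, chrom, c(start, mid + 50), c(mid, start + width + 50),
             strand, biotype, source)
    }
  })
  as_catalogue(dplyr::bind_rows(rows))
}

# O(n^2) same-strand 1-bp overlap between all gene pairs of two catalogues
brute_gene_overlaps <- function(cat_a, cat_b, level = "span") {
  ta <- split(cat_a, cat_a$gene_id)
  tb <- split(cat_b, cat_b$gene_id)
  out <- character()
  for (ga in names(ta)) {
    for (gb in names(tb)) {
      ea <- ta[[ga]]; eb <- tb[[gb]]
      hit <- FALSE
      for (tia in unique(ea$transcript_id)) {
        for (tib in unique(eb$transcript_id)) {
          xa <- ea[ea$transcript_id == tia, ]
          xb <- eb[eb$transcript_id == tib, ]
          if (xa$chrom[1] != xb$chrom[1]) next
          if (xa$strand[1] == "." || xb$strand[1] == ".") next
          if (xa$strand[1] != xb$strand[1]) next
          if (level == "span") {
            if (min(xa$start) <= max(xb$end) &&
                min(xb$start) <= max(xa$end)) hit <- TRUE
          } else {
            for (i in seq_len(nrow(xa))) {
              for (j in seq_len(nrow(xb))) {
                if (xa$start[i] <= xb$end[j] &&
                    xb$start[j] <= xa$end[i]) hit <- TRUE
              }
            }
          }
        }
      }
      if (hit) out <- c(out, paste(ga, gb))
    }
  }
  out
}

# brute-force sequential merge: returns admitted gene ids per source
brute_merge_added <- function(base, sources, level = "span") {
  growing <- base
  added <- list()
  for (label in names(sources)) {
    src <- sources[[label]]
    hits <- brute_gene_overlaps(src, growing, level)
    rejected <- unique(vapply(strsplit(hits, " "), `[[`, "", 1))
    keep <- setdiff(unique(src$gene_id), rejected)
    added[[label]] <- keep
    growing <- dplyr::bind_rows(growing, src[src$gene_id %in% keep, ])
  }
  added
}

# element-by-element loop oracle for the tau index
tau_loop <- function(x) {
  if (max(x) == 0) return(NA_real_)
  m <- max(x)
  acc <- 0
  for (v in x) acc <- acc + (1 - v / m)
  acc / (length(x) - 1)
}

# independent full-permutation Spearman p (recursive enumeration distinct
# from the implementation's iterative-block generator)
perm_recurse <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perm_recurse(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

spearman_perm_oracle <- function(x, y) {
  rho_obs <- stats::cor(rank(x), rank(y))
  rhos <- vapply(perm_recurse(seq_along(y)),
                 function(idx) stats::cor(rank(x), rank(y)[idx]), 0)
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# one-sided (greater) Fisher p for [[a,b],[c,d]] by hypergeometric sum
fisher_greater_oracle <- function(a, b, c, d) {
  sum(stats::dhyper(a:min(a + b, a + c), a + b, c + d, a + c))
}

# build a correlation-results frame realising a given 2x2 configuration
# table against the convergent reference
enrichment_frame <- function(a, b, c, d, config = "divergent") {
  tibble::tibble(
    direction = c(rep(config, a + b), rep("convergent", c + d)),
    significant = c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
  )
}

# independent single-transcript classifier used for agreement tests:
# plain coordinate comparisons, no shared code with the package geometry
brute_classify <- function(lnc_tt, pcg_tt_all, window = 1e5) {
  cand <- pcg_tt_all[pcg_tt_all$chrom == lnc_tt$chrom, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  gaps <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$end[i] < lnc_tt$start) {
      gaps[i] <- lnc_tt$start - cand$end[i] - 1L
    } else if (cand$start[i] > lnc_tt$end) {
      gaps[i] <- cand$start[i] - lnc_tt$end - 1L
    } else {
      gaps[i] <- 0L
    }
  }
  cand <- cand[gaps <= window, , drop = FALSE]
  gaps <- gaps[gaps <= window]
  if (nrow(cand) == 0) return(NULL)
  upstream_side <- if (lnc_tt$strand == "+") {
    cand$end < lnc_tt$start
  } else {
    cand$start > lnc_tt$end
  }
  ord <- order(gaps, !upstream_side, cand$gene_id)
  best <- cand[ord[1], ]
  gap <- gaps[ord[1]]
  if (gap == 0) {
    list(pcg = best$gene_id, ptype = "genic",
         direction = if (best$strand == lnc_tt$strand) "sense"
         else "antisense",
         distance = 0L)
  } else {
    lnc_left <- lnc_tt$end < best$start
    dir <- if (lnc_tt$strand == best$strand) {
      "same_strand"
    } else if ((lnc_left && lnc_tt$strand == "-" && best$strand == "+") ||
               (!lnc_left && lnc_tt$strand == "+" && best$strand == "-")) {
      "divergent"
    } else {
      "convergent"
    }
    list(pcg = best$gene_id, ptype = "intergenic", direction = dir,
         distance = gap)
  }
}

# reflect a catalogue through position L+1-x and flip all strands
reflect_catalogue <- function(cat, L) {
  new_start <- L + 1L - cat$end
  new_end <- L + 1L - cat$start
  cat$start <- new_start
  cat$end <- new_end
  cat$strand <- ifelse(cat$strand == "+", "-",
                       ifelse(cat$strand == "-", "+", "."))
  as_catalogue(cat)
}
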