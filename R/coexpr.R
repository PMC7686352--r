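#' Spearman rank correlation with calibrated p-values
#'
#' Computes rho on average-ranked data. The two-sided p-value uses the full
#' permutation distribution of rho for n < 10 (every permutation of one
#' vector's ranks is enumerated); for n >= 10 it uses the exact null
#' distribution of the rank statistic (AS 89) when there are no ties, which
#' keeps the extreme tail honest for multiple-testing control, and the t
#' approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} when ties prevent
#' the exact computation. Constant vectors give an undefined rho and p = 1
#' with a warning.
#'
#' @param x,y Numeric vectors of equal length n >= 4; ties allowed.
#' @return One-row tibble: `rho`, `p`, `n`, `method`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  stopifnot(n >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman rho undefined")
    return(tibble::tibble(rho = NA_real_, p = 1, n = n,
                          method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (n < 10) {
    perms <- all_permutations(n)
    # rho is monotone in sum(rx * ry[perm]); enumerate it for all n! orders
    rho_perm <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else if (!ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    )
    method <- "exact_distribution"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t_approximation"
  }
  tibble::tibble(rho = rho, p = p, n = n, method = method)
}

# all n! permutations of 1..n as a matrix (rows); n <= 9
#' @keywords internal
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validating wrapper over the standard step-up procedure
#' (`p.adjust(method = "BH")`): adjusted values are monotone in the raw
#' ordering, capped at 1 and returned in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Significance stars
#' @keywords internal
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "n.s.",
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "n.s."
  )
}

#' Co-expression of classified gene pairs across tissues
#'
#' Tests every pair whose two members are present in the matrix and
#' expressed in at least one tissue, with one Spearman test per pair and
#' Benjamini-Hochberg control over that family. Constant-profile pairs are
#' kept as not-significant so denominators stay auditable; pairs with a
#' member absent from the matrix are skipped with a warning.
#'
#' @param pairs Tibble with columns `lnc_gene_id`, `pcg_gene_id` (e.g. from
#'   [classify_pairs()]); extra columns are carried through.
#' @param m Tissue-mean expression tibble.
#' @param fdr_level FDR threshold for the significance call (default 0.05).
#' @param expr_threshold Member expression requirement in TPM (default 0.1).
#' @param pair_kind Label recorded on every result row.
#' @return A tibble with the input columns plus `pair_kind`, `rho`, `p`,
#'   `p_fdr`, `significant`, `n_tissues_used`.
#' @export
pair_correlations <- function(pairs, m, fdr_level = 0.05,
                              expr_threshold = 0.1,
                              pair_kind = "LNC:PCG") {
  tissues <- setdiff(names(m), "gene_id")
  vals <- as.matrix(m[tissues])
  rownames(vals) <- m$gene_id
  present <- pairs$lnc_gene_id %in% m$gene_id &
    pairs$pcg_gene_id %in% m$gene_id
  if (any(!present)) {
    warning(sum(!present), " pair(s) skipped: member absent from matrix")
  }
  pairs <- pairs[present, , drop = FALSE]
  expressed_id <- m$gene_id[apply(vals, 1, max) >= expr_threshold]
  pairs <- pairs[pairs$lnc_gene_id %in% expressed_id &
                   pairs$pcg_gene_id %in% expressed_id, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(dplyr::mutate(pairs, pair_kind = character(), rho = numeric(),
                         p = numeric(), p_fdr = numeric(),
                         significant = logical(),
                         n_tissues_used = integer()))
  }
  tests <- purrr::map2(pairs$lnc_gene_id, pairs$pcg_gene_id, function(a, b) {
    suppressWarnings(spearman_test(vals[a, ], vals[b, ]))
  }) |>
    dplyr::bind_rows()
  dplyr::bind_cols(pairs, tests[, c("rho", "p")]) |>
    dplyr::mutate(
      pair_kind = pair_kind,
      p_fdr = bh_adjust(.data$p),
      significant = !is.na(.data$rho) & .data$p_fdr < fdr_level,
      n_tissues_used = length(tissues)
    )
}

#' Fisher enrichment of co-expression by genomic configuration
#'
#' For each configuration, tests whether it is enriched in significantly
#' correlated pairs relative to the reference configuration (one-sided
#' "greater" Fisher exact test on the 2x2 table configuration x
#' significance). Convergent pairs — the configuration with no shared
#' promoter and no overlap — are the conventional reference.
#'
#' @param results Correlation results joined to a `direction` (or
#'   configuration) column and carrying `significant`.
#' @param reference Reference configuration label (default `"convergent"`).
#' @param config_col Column holding the configuration label.
#' @param alternative Fisher alternative (default one-sided `"greater"`).
#' @return A tibble per non-reference configuration: the full 2x2 counts,
#'   `odds_ratio`, `p`, `stars`, `testable`.
#' @export
configuration_enrichment <- function(results, reference = "convergent",
                                     config_col = "direction",
                                     alternative = "greater") {
  cfgs <- results[[config_col]]
  ref <- results[cfgs == reference & !is.na(cfgs), , drop = FALSE]
  if (nrow(ref) == 0) stop("reference class is empty", call. = FALSE)
  others <- setdiff(unique(cfgs[!is.na(cfgs)]), reference)
  purrr::map(others, function(cf) {
    x <- results[cfgs == cf & !is.na(cfgs), , drop = FALSE]
    tab <- matrix(c(sum(x$significant), sum(!x$significant),
                    sum(ref$significant), sum(!ref$significant)),
                  nrow = 2, byrow = TRUE)
    testable <- nrow(x) > 0
    if (testable) {
      ft <- stats::fisher.test(tab, alternative = alternative)
      p <- ft$p.value; or <- unname(ft$estimate)
    } else {
      p <- NA_real_; or <- NA_real_
    }
    tibble::tibble(
      comparison = paste0(cf, " vs. ", reference),
      n_sig = tab[1, 1], n_not = tab[1, 2],
      n_sig_ref = tab[2, 1], n_not_ref = tab[2, 2],
      odds_ratio = or, p = p, stars = p_stars(p), testable = testable
    )
  }) |>
    dplyr::bind_rows()
}

#' Fisher enrichment of co-expression in close versus distant pairs
#'
#' Within each configuration, tests whether pairs separated by at most 5 kb
#' are enriched in significant correlations relative to pairs further apart
#' (one-sided "greater" Fisher exact test).
#'
#' @param results Correlation results with `significant`, `distance_bp` and
#'   a configuration column.
#' @param close_bp Closeness cut in bp, boundary inclusive (default 5000).
#' @inheritParams configuration_enrichment
#' @return A tibble per configuration with the 2x2 counts, `odds_ratio`,
#'   `p`, `stars`, `testable` (FALSE when either distance class is empty).
#' @export
distance_enrichment <- function(results, close_bp = 5000,
                                config_col = "direction",
                                alternative = "greater") {
  results <- results[!is.na(results[[config_col]]) &
                       !is.na(results$distance_bp), , drop = FALSE]
  purrr::map(unique(results[[config_col]]), function(cf) {
    x <- results[results[[config_col]] == cf, , drop = FALSE]
    close <- x$distance_bp <= close_bp
    tab <- matrix(c(sum(x$significant[close]), sum(!x$significant[close]),
                    sum(x$significant[!close]), sum(!x$significant[!close])),
                  nrow = 2, byrow = TRUE)
    testable <- any(close) && any(!close)
    if (testable) {
      ft <- stats::fisher.test(tab, alternative = alternative)
      p <- ft$p.value; or <- unname(ft$estimate)
    } else {
      p <- NA_real_; or <- NA_real_
    }
    tibble::tibble(
      configuration = cf,
      n_sig_close = tab[1, 1], n_not_close = tab[1, 2],
      n_sig_distant = tab[2, 1], n_not_distant = tab[2, 2],
      odds_ratio = or, p = p, stars = p_stars(p), testable = testable
    )
  }) |>
    dplyr::bind_rows()
}

#' Compare pair distances between two configurations
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test with the usual exact
#' small-sample / tie-corrected normal approximation behaviour, plus the two
#' medians.
#'
#' @param dist_a,dist_b Numeric distance samples (bp) of the two
#'   configurations.
#' @return One-row tibble: `median_a`, `median_b`, `n_a`, `n_b`, `p`.
#' @export
distance_comparison <- function(dist_a, dist_b) {
  stopifnot(length(dist_a) > 0, length(dist_b) > 0)
  wt <- suppressWarnings(stats::wilcox.test(dist_a, dist_b))
  tibble::tibble(
    median_a = stats::median(dist_a),
    median_b = stats::median(dist_b),
    n_a = length(dist_a),
    n_b = length(dist_b),
    p = wt$p.value
  )
}

#' Screen host lncRNAs for correlated protein-coding genes
#'
#' For each expressed small-RNA-hosting lncRNA, correlates its profile with
#' every expressed protein-coding gene (Spearman), adjusts within that
#' host's family (Benjamini-Hochberg) and keeps partners with
#' |rho| >= `rho_min` and adjusted p <= `fdr_level`, recording the sign.
#'
#' @param hosts Tibble from [find_hosts()] (column `host_lnc_id`), or a
#'   character vector of host lncRNA ids.
#' @param m Tissue-mean expression tibble containing hosts and PCGs.
#' @param pcg_ids Character vector of protein-coding gene ids to screen.
#' @param rho_min Correlation magnitude threshold (default 0.8).
#' @param fdr_level Adjusted-p threshold (default 0.01; 0.05 matches the
#'   laxer convention).
#' @param expr_threshold Expression requirement in TPM (default 0.1).
#' @return A tibble `host_lnc_id`, `pcg_gene_id`, `rho`, `p`, `p_fdr`,
#'   `sign` for retained partners (zero rows when none pass).
#' @export
host_lnc_screen <- function(hosts, m, pcg_ids, rho_min = 0.8,
                            fdr_level = 0.01, expr_threshold = 0.1) {
  host_ids <- if (is.data.frame(hosts)) unique(hosts$host_lnc_id) else
    unique(hosts)
  tissues <- setdiff(names(m), "gene_id")
  vals <- as.matrix(m[tissues])
  rownames(vals) <- m$gene_id
  expressed_id <- m$gene_id[apply(vals, 1, max) >= expr_threshold]
  host_ids <- intersect(host_ids, expressed_id)
  pcg_ids <- intersect(pcg_ids, expressed_id)
  purrr::map(host_ids, function(h) {
    tests <- purrr::map(pcg_ids, function(p) {
      suppressWarnings(spearman_test(vals[h, ], vals[p, ]))
    }) |>
      dplyr::bind_rows()
    res <- tibble::tibble(
      host_lnc_id = h, pcg_gene_id = pcg_ids,
      rho = tests$rho, p = tests$p,
      p_fdr = bh_adjust(tests$p)
    )
    dplyr::filter(res, !is.na(.data$rho), abs(.data$rho) >= rho_min,
                  .data$p_fdr <= fdr_level) |>
      dplyr::mutate(sign = ifelse(.data$rho >= 0, "positive", "negative"))
  }) |>
    dplyr::bind_rows()
}
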