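#' Tissue-specificity index tau
#'
#' For a gene with expression \eqn{x_{t}} across \eqn{T} tissues,
#' \deqn{\tau = \frac{\sum_{t=1}^{T} (1 - \hat{x}_{t})}{T - 1}, \qquad
#'       \hat{x}_{t} = \frac{x_{t}}{\max_t x_{t}},}
#' ranging from 0 (identical expression in every tissue) to 1 (expression in
#' exactly one tissue). Computed on raw tissue-mean TPM; an all-zero vector
#' has no defined maximum and yields `NA`. Optional flags accommodate the
#' variants found in the literature: `log_transform` applies log2(TPM + 1)
#' first, `zero_below` zeroes entries under a floor before scoring.
#'
#' @param x Numeric vector of per-tissue expression (length \eqn{T \ge 2}),
#'   or a matrix with genes as rows.
#' @param log_transform Score log2(TPM + 1) instead of raw TPM.
#' @param zero_below Optional floor; entries below it are set to 0 first.
#' @return A tau value in `[0, 1]` (or `NA` for all-zero input); a vector of
#'   them for matrix input.
#' @examples
#' tau(c(10, rep(0, 20)))       # 1: single-tissue expression
#' tau(rep(5, 21))              # 0: uniform expression
#' tau(c(8, 2, rep(0, 19)))     # 0.9875
#' @export
tau <- function(x, log_transform = FALSE, zero_below = NULL) {
  if (is.matrix(x)) {
    if (ncol(x) < 2) stop("tau requires at least 2 tissues", call. = FALSE)
    if (any(x < 0)) stop("negative expression values", call. = FALSE)
    if (!is.null(zero_below)) x[x < zero_below] <- 0
    if (log_transform) x <- log2(x + 1)
    mx <- apply(x, 1, max)
    res <- (ncol(x) - rowSums(x / mx)) / (ncol(x) - 1)
    res[mx == 0] <- NA_real_
    return(unname(res))
  }
  if (length(x) < 2) stop("tau requires at least 2 tissues", call. = FALSE)
  if (any(x < 0)) stop("negative expression values", call. = FALSE)
  if (!is.null(zero_below)) x[x < zero_below] <- 0
  if (log_transform) x <- log2(x + 1)
  if (max(x) == 0) return(NA_real_)
  sum(1 - x / max(x)) / (length(x) - 1)
}

#' Top-expressing tissues of one gene
#'
#' Identifies the tissue with the highest expression (Top1) and the second
#' highest (Top2); ties are broken by the order of the tissue labels and
#' flagged. The Top1/Top2 fold change is `NA` when Top2 is 0.
#'
#' @param x Numeric expression vector (length >= 2).
#' @param labels Tissue labels, same length as `x`.
#' @return One-row tibble: `top1_tissue`, `top1_tpm`, `top2_tissue`,
#'   `top2_tpm`, `fold_change`, `top1_tie`.
#' @export
top_tissues <- function(x, labels) {
  stopifnot(length(x) >= 2, length(x) == length(labels))
  x <- unname(x)
  ord <- order(-x)  # stable: label order breaks ties
  tibble::tibble(
    top1_tissue = labels[ord[1]],
    top1_tpm = x[ord[1]],
    top2_tissue = labels[ord[2]],
    top2_tpm = x[ord[2]],
    fold_change = ifelse(x[ord[2]] > 0, x[ord[1]] / x[ord[2]], NA_real_),
    top1_tie = sum(x == x[ord[1]]) > 1
  )
}

#' Tissue-specificity table for an expression matrix
#'
#' Scores every gene expressed in at least one tissue: tau, Top1/Top2
#' tissues and TPM, number of expressing tissues, the tissue-specific call
#' (tau >= `tau_threshold`) and the expression tier by Top1 TPM
#' (`lt1` / `ge1` at `tier_threshold`).
#'
#' @param m Tissue-mean expression tibble ([build_expression_matrix()]).
#' @param tau_threshold Tissue-specificity call threshold (default 0.95).
#' @param expr_threshold Expression threshold in TPM (default 0.1).
#' @param tier_threshold Tier split on Top1 TPM (default 1).
#' @inheritParams tau
#' @return A tibble with one row per expressed gene: `gene_id`, `tau`,
#'   `top1_tissue`, `top1_tpm`, `top2_tissue`, `top2_tpm`, `fold_change`,
#'   `top1_tie`, `n_tissues_expressed`, `tissue_specific`, `expression_tier`.
#' @export
specificity_table <- function(m, tau_threshold = 0.95, expr_threshold = 0.1,
                              tier_threshold = 1, log_transform = FALSE,
                              zero_below = NULL) {
  tissues <- setdiff(names(m), "gene_id")
  vals <- as.matrix(m[tissues])
  expressed <- apply(vals, 1, max) >= expr_threshold
  vals <- vals[expressed, , drop = FALSE]
  if (nrow(vals) == 0) {
    stop("no gene expressed at >= ", expr_threshold, " TPM", call. = FALSE)
  }
  tops <- purrr::map(seq_len(nrow(vals)),
                     ~ top_tissues(vals[.x, ], tissues)) |>
    dplyr::bind_rows()
  tibble::tibble(
    gene_id = m$gene_id[expressed],
    tau = tau(vals, log_transform = log_transform, zero_below = zero_below)
  ) |>
    dplyr::bind_cols(tops) |>
    dplyr::mutate(
      n_tissues_expressed = rowSums(vals >= expr_threshold),
      tissue_specific = !is.na(.data$tau) & .data$tau >= tau_threshold,
      expression_tier = ifelse(.data$top1_tpm >= tier_threshold, "ge1", "lt1")
    )
}

#' Count tissue-specific genes per tissue
#'
#' Assigns each tissue-specific gene to its Top1 tissue and counts per
#' tissue, optionally split by biotype.
#'
#' @param spec Tibble from [specificity_table()].
#' @param biotypes Optional tibble `gene_id`, `biotype` (e.g. from
#'   [gene_table()]).
#' @return A tibble of counts per `top1_tissue` (and `biotype` if supplied).
#' @export
specific_tissue_counts <- function(spec, biotypes = NULL) {
  ts <- dplyr::filter(spec, .data$tissue_specific)
  if (!is.null(biotypes)) {
    ts <- dplyr::inner_join(ts, biotypes[, c("gene_id", "biotype")],
                            by = "gene_id")
    return(dplyr::count(ts, .data$top1_tissue, .data$biotype, name = "n"))
  }
  dplyr::count(ts, .data$top1_tissue, name = "n")
}

#' Tissue-specific genes common to two datasets
#'
#' Intersects the tissue-specific gene sets of two specificity tables,
#' restricted to genes Top1-assigned to the given tissue in both.
#'
#' @param spec_a,spec_b Tibbles from [specificity_table()] computed with
#'   identical thresholds.
#' @param tissue Tissue label.
#' @return Character vector of common gene ids.
#' @export
intersect_specific <- function(spec_a, spec_b, tissue) {
  pick <- function(s) {
    s$gene_id[s$tissue_specific & s$top1_tissue == tissue]
  }
  intersect(pick(spec_a), pick(spec_b))
}
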