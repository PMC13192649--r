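#' Quantile-matched expression threshold for reconstructed data
#'
#' Reconstructed expression is dense, so "expressed" needs a cutoff. The
#' threshold mu is the empirical quantile of the reconstructed entries at
#' the zero fraction of the raw counts, picked so that the number of
#' reconstructed entries >= mu matches the number of nonzero raw entries as
#' closely as ties allow.
#'
#' @param x_hat Reconstructed (dense) expression matrix.
#' @param x Raw count matrix of the same shape.
#' @return A list of class `expression_threshold`: `mu`, `zero_fraction`,
#'   `n_expressed` (entries >= mu in `x_hat`), `n_nonzero` (in `x`).
#' @export
expression_threshold <- function(x_hat, x) {
  stopifnot(all(dim(x_hat) == dim(x)))
  v <- as.numeric(if (inherits(x_hat, "sparseMatrix")) as.matrix(x_hat) else x_hat)
  n_nonzero <- if (inherits(x, "sparseMatrix")) {
    Matrix::nnzero(x)
  } else {
    sum(x != 0)
  }
  total <- length(v)
  zero_fraction <- 1 - n_nonzero / total
  if (n_nonzero == 0) {
    warning("raw matrix is all-zero; threshold set to +Inf", call. = FALSE)
    mu <- Inf
  } else if (n_nonzero == total) {
    mu <- min(v)
  } else {
    vs <- sort(v, decreasing = TRUE)
    # candidate cuts around the target count; ties can make the exact count
    # unattainable, so take the cut minimizing the mismatch
    above <- vs[vs > vs[n_nonzero]]
    cand <- unique(c(vs[n_nonzero], if (length(above)) min(above)))
    counts <- vapply(cand, function(m) sum(v >= m), 0L)
    mu <- cand[which.min(abs(counts - n_nonzero))]
  }
  structure(list(mu = mu, zero_fraction = zero_fraction,
                 n_expressed = sum(v >= mu), n_nonzero = n_nonzero),
            class = "expression_threshold")
}

#' Binarize reconstructed expression at a threshold
#'
#' @param x_hat Reconstructed expression matrix.
#' @param threshold An [expression_threshold()] (or a bare numeric mu).
#' @return Logical matrix: entry is `TRUE` iff `x_hat >= mu`.
#' @export
binarize_expression <- function(x_hat, threshold) {
  mu <- if (inherits(threshold, "expression_threshold")) threshold$mu else threshold
  m <- as.matrix(x_hat) >= mu
  dimnames(m) <- dimnames(x_hat)
  m
}

#' Genes expressed in a cell group
#'
#' A gene counts as expressed in a group when it is expressed in strictly
#' more than `frac` of the group's cells (default: more than 25%).
#'
#' @param binary Logical cells x genes matrix.
#' @param group_cells Row indices (or logical mask / cell names) of the group.
#' @param frac Strict lower bound on the within-group expressing fraction.
#' @return Character vector of gene identifiers (or column indices when the
#'   matrix is unnamed).
#' @export
group_expressed_genes <- function(binary, group_cells, frac = 0.25) {
  sub <- binary[group_cells, , drop = FALSE]
  if (nrow(sub) == 0) stop("empty cell group", call. = FALSE)
  hit <- colMeans(sub) > frac
  if (!is.null(colnames(binary))) colnames(binary)[hit] else which(hit)
}

# assemble c(n11, n12, n21, n22) from a table-like input
as_table4 <- function(table) {
  t4 <- if (is.matrix(table)) as.numeric(t(table)) else as.numeric(table)
  if (length(t4) != 4 || any(t4 < 0)) {
    stop("contingency table must be 4 non-negative counts", call. = FALSE)
  }
  names(t4) <- c("n11", "n12", "n21", "n22")
  t4
}

#' Odds ratio of a 2x2 contingency table
#'
#' Computes n11*n22 / (n12*n21) for the table
#' (set genes expressed, set genes not expressed, non-set genes expressed,
#' non-set genes not expressed). When any cell is zero the Haldane-Anscombe
#' correction adds 0.5 to all four cells first (flagged via the
#' `"corrected"` attribute).
#'
#' @param table Length-4 numeric `c(n11, n12, n21, n22)` or a 2x2 matrix in
#'   row-major layout (rows: in set / not in set; columns: expressed / not).
#' @return Positive scalar with attribute `corrected`.
#' @export
odds_ratio <- function(table) {
  t4 <- as_table4(table)
  corrected <- any(t4 == 0)
  if (corrected) t4 <- t4 + 0.5
  structure(t4[["n11"]] * t4[["n22"]] / (t4[["n12"]] * t4[["n21"]]),
            corrected = corrected)
}

#' P-value for 2x2 enrichment
#'
#' `"fisher_exact"` gives the two-sided Fisher exact (hypergeometric)
#' p-value. `"normal_approx"` gives the Wald/Woolf normal approximation on
#' the log odds ratio, `p = 2 Phi(-|log OR| / sqrt(sum 1/n_ij))`, with the
#' Haldane-Anscombe correction when any cell is zero.
#'
#' @inheritParams odds_ratio
#' @param method `"fisher_exact"` (default) or `"normal_approx"`.
#' @return P-value in (0, 1].
#' @export
enrichment_pvalue <- function(table, method = c("fisher_exact", "normal_approx")) {
  method <- match.arg(method)
  t4 <- as_table4(table)
  if (method == "fisher_exact") {
    m <- matrix(round(t4), 2L, 2L, byrow = TRUE)
    stats::fisher.test(m)$p.value
  } else {
    if (any(t4 == 0)) t4 <- t4 + 0.5
    z <- abs(log(t4[["n11"]] * t4[["n22"]] / (t4[["n12"]] * t4[["n21"]]))) /
      sqrt(sum(1 / t4))
    2 * stats::pnorm(-z)
  }
}

# core: one enrichment row from expressed/not-expressed gene counts
enrich_row <- function(n11, n12, n21, n22, alpha, method) {
  or <- odds_ratio(c(n11, n12, n21, n22))
  p <- enrichment_pvalue(c(n11, n12, n21, n22), method)
  tibble::tibble(
    n11 = n11, n12 = n12, n21 = n21, n22 = n22,
    odds_ratio = as.numeric(or), corrected = attr(or, "corrected"),
    p_value = p, enriched = as.numeric(or) > 1 & p <= alpha
  )
}

#' Per-cell gene-set enrichment by odds ratio
#'
#' For every cell, builds the 2x2 table of gene-set membership against
#' expression status and tests for over-representation of expressed set
#' genes. On raw counts a gene is expressed in a cell when its count is
#' positive; pass a binarized matrix (see [binarize_expression()]) for
#' reconstructed data.
#'
#' @param x Cells x genes matrix: raw counts, or logical (already binarized).
#' @param gene_set A [gene_set()] (or character vector of members).
#' @param universe Gene identifiers to test within; defaults to all columns.
#'   The gene set is intersected with the universe (size reported via
#'   message).
#' @param alpha Significance level for the `enriched` flag.
#' @param method P-value method, see [enrichment_pvalue()].
#' @return A tibble of class `starmaps_enrichment` with one row per cell:
#'   `unit_id`, the four counts, `odds_ratio`, `p_value`, `enriched`.
#' @export
per_cell_enrichment <- function(x, gene_set, universe = NULL, alpha = 0.05,
                                method = c("fisher_exact", "normal_approx")) {
  method <- match.arg(method)
  members <- if (inherits(gene_set, "gene_set")) gene_set$members else gene_set
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("gene", seq_len(ncol(x)))
  universe <- universe %||% colnames(x)
  universe <- intersect(universe, colnames(x))
  set_in <- intersect(members, universe)
  if (length(set_in) == 0) {
    stop("gene set does not intersect the universe", call. = FALSE)
  }
  message("gene set intersects universe in ", length(set_in), " of ",
          length(members), " genes")
  bin <- if (is.logical(x)) x[, universe, drop = FALSE] else x[, universe, drop = FALSE] > 0
  is_set <- universe %in% set_in
  n_set <- sum(is_set)
  n_non <- length(universe) - n_set
  n11 <- as.integer(rowSums(bin[, is_set, drop = FALSE]))
  n21 <- as.integer(rowSums(bin[, !is_set, drop = FALSE]))
  out <- purrr::map_dfr(seq_len(nrow(bin)), function(i) {
    enrich_row(n11[i], n_set - n11[i], n21[i], n_non - n21[i], alpha, method)
  })
  out <- dplyr::bind_cols(tibble::tibble(unit_id = rownames(x) %||%
                                           as.character(seq_len(nrow(x)))), out)
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  class(out) <- c("starmaps_enrichment", class(out))
  out
}

#' Per-group gene-set enrichment with optional Bonferroni correction
#'
#' Each group's expressed-gene set is obtained with
#' [group_expressed_genes()] (strictly more than `frac` of the group's
#' cells), then tested as in [per_cell_enrichment()]. With
#' `correction = "bonferroni"` p-values are multiplied by the number of
#' groups (capped at 1) and the `enriched` flag uses the adjusted value.
#'
#' @param binary Logical cells x genes matrix (binarized expression).
#' @param groups Per-cell group labels.
#' @param frac Within-group expression fraction threshold (strict).
#' @param correction `"bonferroni"` or `"none"`.
#' @inheritParams per_cell_enrichment
#' @return A tibble of class `starmaps_enrichment`, one row per group, with
#'   `p_adjusted` when correction is applied.
#' @export
per_group_enrichment <- function(binary, groups, gene_set, universe = NULL,
                                 alpha = 0.05,
                                 method = c("fisher_exact", "normal_approx"),
                                 correction = c("bonferroni", "none"),
                                 frac = 0.25) {
  method <- match.arg(method)
  correction <- match.arg(correction)
  members <- if (inherits(gene_set, "gene_set")) gene_set$members else gene_set
  binary <- as.matrix(binary)
  if (is.null(colnames(binary))) colnames(binary) <- paste0("gene", seq_len(ncol(binary)))
  stopifnot(is.logical(binary), nrow(binary) == length(groups))
  universe <- universe %||% colnames(binary)
  universe <- intersect(universe, colnames(binary))
  set_in <- intersect(members, universe)
  if (length(set_in) == 0) {
    stop("gene set does not intersect the universe", call. = FALSE)
  }
  bin <- binary[, universe, drop = FALSE]
  is_set <- universe %in% set_in
  n_set <- sum(is_set)
  n_non <- length(universe) - n_set
  levs <- sort(unique(as.character(groups)))
  out <- purrr::map_dfr(levs, function(g) {
    expressed <- colMeans(bin[groups == g, , drop = FALSE]) > frac
    n11 <- sum(expressed & is_set)
    n21 <- sum(expressed & !is_set)
    enrich_row(n11, n_set - n11, n21, n_non - n21, alpha, method)
  })
  out <- dplyr::bind_cols(tibble::tibble(unit_id = levs), out)
  if (correction == "bonferroni") {
    out$p_adjusted <- pmin(out$p_value * length(levs), 1)
    out$enriched <- out$odds_ratio > 1 & out$p_adjusted <= alpha
  }
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  attr(out, "correction") <- correction
  class(out) <- c("starmaps_enrichment", class(out))
  out
}

#' Percentage of enriched cells per region
#'
#' Cell-level (rather than group-level) summaries are used because group
#' sizes are highly heterogeneous; the per-region percentage of cells that
#' belong to enriched units reflects the extent of enrichment more stably.
#'
#' @param cell_results A `starmaps_enrichment` tibble with one row per cell
#'   (an `enriched` logical column is required).
#' @param region_labels Per-cell region labels, aligned with `cell_results`.
#' @return A tibble (`region`, `pct_enriched`, `n_cells`) of class
#'   `starmaps_region_summary`.
#' @export
region_enrichment_summary <- function(cell_results, region_labels) {
  stopifnot(nrow(cell_results) == length(region_labels))
  out <- tibble::tibble(region = as.character(region_labels),
                        enriched = cell_results$enriched) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(pct_enriched = 100 * mean(.data$enriched),
                     n_cells = dplyr::n(), .groups = "drop")
  class(out) <- c("starmaps_region_summary", class(out))
  out
}

#' Fold enrichment of a composition fraction
#'
#' Ratio of a within-cluster composition fraction to the overall fraction,
#' rounded half-to-even (e.g. a region contributing 18.3% of the cells in
#' enriched clusters against 7.1% overall is 2.6-fold enriched).
#'
#' @param cluster_fraction Fraction within the cluster(s) of interest.
#' @param overall_fraction Fraction in the full population (must be > 0).
#' @param decimals Decimal places of the rounded result.
#' @return The rounded fold change.
#' @export
fold_enrichment <- function(cluster_fraction, overall_fraction, decimals = 1L) {
  stopifnot(all(cluster_fraction >= 0), all(cluster_fraction <= 1))
  if (any(overall_fraction <= 0)) {
    stop("overall_fraction must be positive", call. = FALSE)
  }
  round(cluster_fraction / overall_fraction, decimals)
}
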