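#' Construct a labelled expression dataset
#'
#' Bundles a non-negative cells x genes expression matrix with per-cell
#' metadata. Every cell must carry exactly one (batch, region) assignment;
#' together these define the tasks the factorization decomposes.
#'
#' @param matrix Non-negative numeric matrix (dense or `Matrix` sparse),
#'   cells in rows, genes in columns.
#' @param cells A data frame with one row per cell, containing at least
#'   `cell_id`, `batch` and `region` columns; `stage` and `cell_type` are
#'   carried along when present, as is any other column.
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   the matrix column names.
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix` (cells x genes), `cells` (tibble of metadata) and `genes`.
#' @export
expression_dataset <- function(matrix, cells, gene_ids = colnames(matrix)) {
  cells <- tibble::as_tibble(cells)
  required <- c("cell_id", "batch", "region")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    stop("cell metadata is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cells) != nrow(matrix)) {
    stop("metadata has ", nrow(cells), " rows but matrix has ",
         nrow(matrix), " cells", call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(matrix)))
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique", call. = FALSE)
  if (length(gene_ids) != ncol(matrix)) {
    stop("gene_ids length does not match number of matrix columns", call. = FALSE)
  }
  vals <- if (inherits(matrix, "sparseMatrix")) matrix@x else matrix
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("expression matrix contains NA or non-finite entries", call. = FALSE)
  }
  if (length(vals) && min(vals) < 0) {
    stop("expression matrix contains negative entries", call. = FALSE)
  }
  if (anyNA(cells$batch) || anyNA(cells$region)) {
    stop("every cell needs a batch and a region label", call. = FALSE)
  }
  rownames(matrix) <- cells$cell_id
  colnames(matrix) <- gene_ids
  structure(
    list(matrix = matrix, cells = cells, genes = gene_ids),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  tasks <- dplyr::distinct(x$cells, .data$batch, .data$region)
  cat("<expression_dataset> ", nrow(x$matrix), " cells x ", length(x$genes),
      " genes; ", dplyr::n_distinct(x$cells$batch), " batch(es), ",
      dplyr::n_distinct(x$cells$region), " region(s), ",
      nrow(tasks), " occupied task(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Read an expression dataset from Matrix Market + TSV files
#'
#' Expects the conventional sparse trio (matrix.mtx, genes/features file,
#' barcodes file) plus a metadata TSV with header
#' `cell_id  batch  region  [stage]  [cell_type]`.
#'
#' @param matrix_path Path to the Matrix Market file.
#' @param genes_path Path to the one-gene-per-line TSV (first column used).
#' @param cells_path Path to the one-barcode-per-line TSV (first column used).
#' @param metadata_path Path to the per-cell metadata TSV.
#' @param transpose Set `TRUE` when the matrix is stored genes x cells.
#' @param missing_metadata `"error"` rejects cells without metadata,
#'   `"drop"` removes them with a message.
#' @return An [expression_dataset()].
#' @export
read_expression_dataset <- function(matrix_path, genes_path, cells_path,
                                    metadata_path,
                                    transpose = FALSE,
                                    missing_metadata = c("error", "drop")) {
  missing_metadata <- match.arg(missing_metadata)
  m <- Matrix::readMM(matrix_path)
  if (transpose) m <- Matrix::t(m)
  genes <- readr::read_tsv(genes_path, col_names = FALSE,
                           show_col_types = FALSE)[[1]]
  barcodes <- readr::read_tsv(cells_path, col_names = FALSE,
                              show_col_types = FALSE)[[1]]
  if (nrow(m) != length(barcodes) || ncol(m) != length(genes)) {
    stop("matrix is ", nrow(m), " x ", ncol(m), " but ", length(barcodes),
         " barcodes and ", length(genes), " genes were supplied",
         call. = FALSE)
  }
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  required <- c("cell_id", "batch", "region")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  idx <- match(barcodes, meta$cell_id)
  if (anyNA(idx)) {
    n_missing <- sum(is.na(idx))
    if (missing_metadata == "error") {
      stop(n_missing, " cell(s) have no metadata row", call. = FALSE)
    }
    message("dropping ", n_missing, " cell(s) without metadata")
    keep <- !is.na(idx)
    m <- m[keep, , drop = FALSE]
    barcodes <- barcodes[keep]
    idx <- idx[keep]
  }
  meta <- meta[idx, , drop = FALSE]
  meta$cell_id <- barcodes
  expression_dataset(m, meta, gene_ids = genes)
}

#' Read a gene set from a plain-text list
#'
#' One gene identifier per line; blank lines and duplicates are dropped.
#'
#' @param path Path to the text file.
#' @param name Name for the set; defaults to the file name.
#' @return A `gene_set`: list with `name` and `members`.
#' @export
read_gene_set <- function(path, name = NULL) {
  members <- unique(trimws(readLines(path)))
  members <- members[nzchar(members)]
  gene_set(members, name = name %||% basename(path))
}

#' @rdname read_gene_set
#' @param members Character vector of gene identifiers.
#' @export
gene_set <- function(members, name = "gene_set") {
  members <- unique(as.character(members))
  if (length(members) == 0) stop("gene set is empty", call. = FALSE)
  structure(list(name = name, members = members), class = "gene_set")
}

#' Library-size normalize, log-transform and variance-scale counts
#'
#' Each cell is scaled to a common library size `target_sum`, log1p
#' transformed, and (optionally) each gene divided by its standard deviation.
#' No centering is performed, so the output stays non-negative as the
#' factorization requires. Cells with zero total count are dropped with a
#' warning. Zero-variance genes are left unscaled.
#'
#' @param dataset An [expression_dataset()] of raw counts.
#' @param target_sum Library size every cell is scaled to.
#' @param scale Divide each gene by its standard deviation?
#' @return A normalized [expression_dataset()] (dense matrix).
#' @export
normalize_counts <- function(dataset, target_sum = 1e4, scale = TRUE) {
  stopifnot(inherits(dataset, "expression_dataset"), target_sum > 0)
  m <- as.matrix(dataset$matrix)
  lib <- rowSums(m)
  if (any(lib == 0)) {
    n_zero <- sum(lib == 0)
    warning("dropping ", n_zero, " cell(s) with zero total count",
            call. = FALSE)
    keep <- lib > 0
    m <- m[keep, , drop = FALSE]
    dataset$cells <- dataset$cells[keep, , drop = FALSE]
    lib <- lib[keep]
  }
  m <- log1p(m * (target_sum / lib))
  if (scale) {
    sds <- apply(m, 2L, stats::sd)
    nonconst <- sds > 0
    m[, nonconst] <- sweep(m[, nonconst, drop = FALSE], 2L, sds[nonconst], "/")
  }
  expression_dataset(m, dataset$cells, gene_ids = dataset$genes)
}

#' Rank genes by dispersion and select shared anchors
#'
#' Computes a dispersion (variance / mean) ranking per dataset on the shared
#' gene universe and aggregates ranks across datasets; the top `n_genes` by
#' mean rank are returned. Ties break deterministically by gene identifier,
#' and the result is invariant to cell order.
#'
#' @param datasets An [expression_dataset()] or list of them.
#' @param n_genes Number of anchors to return; truncated with a warning when
#'   it exceeds the shared universe.
#' @return Character vector of gene identifiers, best-ranked first.
#' @export
select_anchor_genes <- function(datasets, n_genes) {
  if (inherits(datasets, "expression_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1, n_genes >= 1)
  shared <- Reduce(intersect, lapply(datasets, function(d) d$genes))
  if (length(shared) == 0) stop("datasets share no genes", call. = FALSE)
  if (n_genes > length(shared)) {
    warning("n_genes exceeds the shared universe (", length(shared),
            "); truncating", call. = FALSE)
    n_genes <- length(shared)
  }
  ranks <- vapply(datasets, function(d) {
    m <- d$matrix[, shared, drop = FALSE]
    mu <- Matrix::colMeans(m)
    v <- Matrix::colMeans(m^2) - mu^2
    disp <- ifelse(mu > 0, v / mu, 0)
    rank(-disp, ties.method = "average")
  }, numeric(length(shared)))
  # best rank across datasets first (a gene strongly dispersed anywhere is a
  # useful anchor), mean rank as tie-break, then gene identifier
  best <- apply(ranks, 1L, min)
  shared[order(best, rowMeans(ranks), shared)][seq_len(n_genes)]
}

#' Partition a dataset into per-task expression blocks
#'
#' Splits the matrix by the observed (batch, region) pairs. Blocks are
#' disjoint and exhaustive; unoccupied combinations are omitted.
#'
#' @param dataset An [expression_dataset()].
#' @return A named list of dense matrix blocks (names `batch:region`), with
#'   attributes `tasks` (tibble of `name`, `batch`, `region`, `n`) and
#'   `cell_index` (row indices of each block in the original matrix).
#' @export
split_by_task <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  key <- paste(dataset$cells$batch, dataset$cells$region, sep = ":")
  idx <- split(seq_len(nrow(dataset$matrix)), key)
  blocks <- lapply(idx, function(i) as.matrix(dataset$matrix[i, , drop = FALSE]))
  tasks <- tibble::tibble(
    name = names(idx),
    batch = dataset$cells$batch[vapply(idx, `[`, integer(1), 1L)],
    region = dataset$cells$region[vapply(idx, `[`, integer(1), 1L)],
    n = unname(lengths(idx))
  )
  attr(blocks, "tasks") <- tasks
  attr(blocks, "cell_index") <- idx
  blocks
}

#' Uniform random cell subsample
#'
#' @param dataset An [expression_dataset()].
#' @param n Number of cells to keep (without replacement).
#' @param seed Integer seed; the same seed reproduces the same subset.
#' @return An [expression_dataset()] of `n` cells.
#' @export
subsample_cells <- function(dataset, n, seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  n_cells <- nrow(dataset$matrix)
  if (n > n_cells) stop("requested ", n, " cells from ", n_cells, call. = FALSE)
  set.seed(seed)
  keep <- sort(sample.int(n_cells, n))
  expression_dataset(dataset$matrix[keep, , drop = FALSE],
                     dataset$cells[keep, , drop = FALSE],
                     gene_ids = dataset$genes)
}
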