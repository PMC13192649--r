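#' Write a fitted model to a plain-text container
#'
#' Serializes the model to a directory with the layout
#' `H.tsv`, `E/<batch>.tsv`, `F/<region>.tsv`, `W/<task>.tsv` and an
#' `attrs.json` holding k, the penalties, the seed, the convergence state
#' and the objective traces. Values are written with 17 significant digits
#' so the round trip is exact to double precision.
#'
#' @param fit A `starmaps_fit`.
#' @param path Directory to create (must not already contain a model).
#' @return `path`, invisibly.
#' @export
write_starmaps <- function(fit, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_mat <- function(m, f) {
    utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                       f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_mat(fit$H, file.path(path, "H.tsv"))
  for (sub in c("E", "F", "W")) dir.create(file.path(path, sub), showWarnings = FALSE)
  for (j in names(fit$E)) write_mat(fit$E[[j]], file.path(path, "E", paste0(j, ".tsv")))
  for (r in names(fit$F)) write_mat(fit$F[[r]], file.path(path, "F", paste0(r, ".tsv")))
  for (t in names(fit$W)) {
    write_mat(fit$W[[t]], file.path(path, "W", paste0(gsub(":", "__", t), ".tsv")))
  }
  attrs <- list(
    k = fit$k, lambda1 = fit$lambda1, lambda2 = fit$lambda2,
    seed = fit$seed, converged = isTRUE(fit$converged),
    n_iter = fit$n_iter %||% (length(fit$objective_trace) - 1L),
    objective_trace = fit$objective_trace,
    pass_trace = fit$pass_trace,
    tasks = fit$tasks,
    gene_ids = colnames(fit$H)
  )
  jsonlite::write_json(attrs, file.path(path, "attrs.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a model written by [write_starmaps()]
#'
#' @param path Model directory.
#' @return A `starmaps_fit`.
#' @export
read_starmaps <- function(path) {
  attrs <- jsonlite::read_json(file.path(path, "attrs.json"),
                               simplifyVector = TRUE)
  gene_ids <- attrs$gene_ids
  read_mat <- function(f, named = TRUE) {
    m <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
    if (named) colnames(m) <- gene_ids else dimnames(m) <- NULL
    m
  }
  tasks <- tibble::as_tibble(attrs$tasks)
  E <- stats::setNames(lapply(unique(tasks$batch), function(j) {
    read_mat(file.path(path, "E", paste0(j, ".tsv")))
  }), unique(tasks$batch))
  F_ <- stats::setNames(lapply(unique(tasks$region), function(r) {
    read_mat(file.path(path, "F", paste0(r, ".tsv")))
  }), unique(tasks$region))
  W <- stats::setNames(lapply(tasks$name, function(t) {
    read_mat(file.path(path, "W", paste0(gsub(":", "__", t), ".tsv")),
             named = FALSE)
  }), tasks$name)
  structure(list(
    H = read_mat(file.path(path, "H.tsv")),
    E = E, F = F_, W = W, tasks = tasks,
    k = attrs$k, lambda1 = attrs$lambda1, lambda2 = attrs$lambda2,
    objective_trace = attrs$objective_trace, pass_trace = attrs$pass_trace,
    converged = attrs$converged, n_iter = attrs$n_iter,
    seed = attrs$seed
  ), class = "starmaps_fit")
}

#' Write a dataset as Matrix Market + TSV files
#'
#' Emits `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `metadata.tsv` into
#' a directory, the same layout [read_expression_dataset()] consumes.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_expression_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(Matrix::Matrix(as.matrix(dataset$matrix),
                                              sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  Matrix::writeMM(m, file.path(path, "matrix.mtx"))
  writeLines(dataset$genes, file.path(path, "genes.tsv"))
  writeLines(dataset$cells$cell_id, file.path(path, "barcodes.tsv"))
  readr::write_tsv(dataset$cells, file.path(path, "metadata.tsv"))
  invisible(path)
}
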