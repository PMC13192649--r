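#' Validate and normalize a pipeline configuration
#'
#' A run configuration is one JSON document (or equivalent list). Unknown
#' keys are rejected. Defaults cover every stage; a minimal config can be
#' just `list(seed = 1)` plus either `simulate` or `input` paths.
#'
#' @param config A named list or path to a JSON file.
#' @return The completed configuration list (class `starmaps_config`).
#' @export
starmaps_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(
    seed = 1L,
    input = NULL,            # dir with matrix.mtx/genes.tsv/barcodes.tsv/metadata.tsv
    simulate = NULL,         # list(M, R, k, p, n_per_task, ...)
    normalize = list(target_sum = 1e4, scale = TRUE),
    fit = list(k = 4L, lambda = 1e-3, max_iter = 200L, tol = 1e-5),
    cluster = list(resolutions = c(0.2, 0.5, 1, 2), n_neighbors = 20L,
                   n_boot = 5L, stability_floor = 0.8),
    enrich = list(gene_set = NULL, alpha = 0.05, method = "fisher_exact",
                  correction = "bonferroni", frac = 0.25,
                  reconstruction = "full"),
    log_level = "info"
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, config)
  for (stage in c("normalize", "fit", "cluster", "enrich")) {
    bad <- setdiff(names(out[[stage]]), names(defaults[[stage]]))
    if (length(bad) > 0) {
      stop("unknown key(s) in '", stage, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  class(out) <- c("starmaps_config", "list")
  out
}

#' Run the full pipeline: load/simulate, normalize, fit, cluster, enrich
#'
#' Composes the package end to end and writes all artifacts under
#' `output_dir`: the serialized model, cluster labels TSV, enrichment TSVs,
#' a metrics JSON and a run manifest (configuration hash, package version,
#' seed). The run is deterministic given the seed; one master seed fans out
#' to per-stage seeds by fixed offsets so stages are individually
#' reproducible. On a stage error, artifacts already written are renamed
#' with a `.partial` suffix and the error is rethrown.
#'
#' @param config A [starmaps_config()], list, or JSON path.
#' @param output_dir Directory for artifacts.
#' @return Invisibly, a manifest list with artifact paths and stage
#'   summaries.
#' @export
run_starmaps_pipeline <- function(config, output_dir) {
  cfg <- starmaps_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    for (f in written) {
      if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
    }
    stop(e)
  }
  tryCatch({
    seed <- as.integer(cfg$seed)
    # --- input -----------------------------------------------------------
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      truth <- simulate_truth(
        M = sim$M %||% 2L, R = sim$R %||% 3L, k = sim$k %||% 4L,
        p = sim$p %||% 60L,
        perturb_sparsity = sim$perturb_sparsity %||% 0.05,
        perturb_scale = sim$perturb_scale %||% 1,
        seed = derive_seed(seed, 1L)
      )
      dataset <- sample_expression(
        truth, n_per_task = sim$n_per_task %||% 50L,
        noise_sd = sim$noise_sd %||% 0.05,
        dropout = sim$dropout %||% 0,
        counts = isTRUE(sim$counts),
        seed = derive_seed(seed, 2L)
      )
      raw <- dataset
    } else if (!is.null(cfg$input)) {
      dataset <- read_expression_dataset(
        file.path(cfg$input, "matrix.mtx"),
        file.path(cfg$input, "genes.tsv"),
        file.path(cfg$input, "barcodes.tsv"),
        file.path(cfg$input, "metadata.tsv")
      )
      raw <- dataset
      dataset <- normalize_counts(dataset,
                                  target_sum = cfg$normalize$target_sum,
                                  scale = isTRUE(cfg$normalize$scale))
    } else {
      stop("config needs either 'simulate' or 'input'", call. = FALSE)
    }
    # --- fit -------------------------------------------------------------
    blocks <- split_by_task(dataset)
    fit <- starmaps_fit(blocks, k = cfg$fit$k, lambda = cfg$fit$lambda,
                        max_iter = cfg$fit$max_iter, tol = cfg$fit$tol,
                        seed = derive_seed(seed, 3L))
    model_dir <- file.path(output_dir, "model")
    write_starmaps(fit, model_dir)
    written <- c(written, model_dir)
    # --- cluster ---------------------------------------------------------
    emb <- embed_cells(fit, attr(blocks, "cell_index"))
    clu <- select_resolution(emb, resolutions = cfg$cluster$resolutions,
                             n_boot = cfg$cluster$n_boot,
                             seed = derive_seed(seed, 4L),
                             n_neighbors = min(cfg$cluster$n_neighbors,
                                               nrow(emb) - 1L),
                             stability_floor = cfg$cluster$stability_floor)
    labels_path <- file.path(output_dir, "clusters.tsv")
    readr::write_tsv(tibble::tibble(cell_id = dataset$cells$cell_id,
                                    cluster = clu$cluster), labels_path)
    written <- c(written, labels_path)
    # --- metrics ---------------------------------------------------------
    mix <- mixing_score(clu$cluster, dataset$cells$region)
    pert <- perturbation_magnitudes(fit)
    metrics <- list(
      objective = utils::tail(fit$objective_trace, 1L),
      converged = isTRUE(fit$converged),
      n_clusters = attr(clu, "n_clusters"),
      resolution = attr(clu, "resolution"),
      mixing_score = stats::setNames(as.list(mix$score), mix$region),
      perturbation = stats::setNames(as.list(pert$distance),
                                     paste(pert$type, pert$label, sep = ":"))
    )
    metrics_path <- file.path(output_dir, "metrics.json")
    jsonlite::write_json(metrics, metrics_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, metrics_path)
    # --- enrichment (optional: needs a gene set) -------------------------
    enrich_summary <- NULL
    if (!is.null(cfg$enrich$gene_set)) {
      gs <- if (inherits(cfg$enrich$gene_set, "gene_set")) {
        cfg$enrich$gene_set
      } else if (is.character(cfg$enrich$gene_set) &&
                 length(cfg$enrich$gene_set) == 1 &&
                 file.exists(cfg$enrich$gene_set)) {
        read_gene_set(cfg$enrich$gene_set)
      } else {
        gene_set(cfg$enrich$gene_set)
      }
      recon <- reconstruct_expression(fit, mode = cfg$enrich$reconstruction)
      x_hat <- do.call(rbind, recon)
      ord <- order(unlist(attr(blocks, "cell_index"), use.names = FALSE))
      x_hat <- x_hat[ord, , drop = FALSE]
      colnames(x_hat) <- dataset$genes
      rownames(x_hat) <- dataset$cells$cell_id
      thr <- expression_threshold(x_hat, as.matrix(raw$matrix))
      bin <- binarize_expression(x_hat, thr)
      cell_res <- suppressMessages(per_cell_enrichment(
        bin, gs, alpha = cfg$enrich$alpha, method = cfg$enrich$method))
      cells_path <- file.path(output_dir, "enrichment_cells.tsv")
      readr::write_tsv(cell_res, cells_path)
      written <- c(written, cells_path)
      grp_res <- per_group_enrichment(
        bin, clu$cluster, gs, alpha = cfg$enrich$alpha,
        method = cfg$enrich$method, correction = cfg$enrich$correction,
        frac = cfg$enrich$frac)
      groups_path <- file.path(output_dir, "enrichment_groups.tsv")
      readr::write_tsv(grp_res, groups_path)
      written <- c(written, groups_path)
      enrich_summary <- region_enrichment_summary(cell_res,
                                                  dataset$cells$region)
      summary_path <- file.path(output_dir, "enrichment_regions.tsv")
      readr::write_tsv(enrich_summary, summary_path)
      written <- c(written, summary_path)
    }
    # --- manifest --------------------------------------------------------
    manifest <- list(
      package_version = as.character(utils::packageVersion("starmaps")),
      seed = seed,
      config_hash = rlang::hash(unclass(cfg)),
      artifacts = written,
      n_cells = nrow(dataset$matrix),
      n_genes = length(dataset$genes)
    )
    manifest_path <- file.path(output_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
    manifest$path <- manifest_path
    invisible(manifest)
  }, error = on_fail)
}
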