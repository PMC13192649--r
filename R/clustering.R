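#' Shared-nearest-neighbour graph of an embedding
#'
#' Builds the undirected k-nearest-neighbour graph (Euclidean) and weights
#' each edge by the Jaccard overlap of the two endpoints' neighbourhoods,
#' the usual construction for single-cell community detection. Deterministic
#' given the input. A degenerate embedding (all rows identical) yields a
#' complete unit-weight graph with a warning.
#'
#' @param embedding Cells x features numeric matrix.
#' @param n_neighbors Neighbourhood size (must be < number of cells).
#' @return An undirected weighted `igraph` graph with one vertex per cell.
#' @export
build_knn_graph <- function(embedding, n_neighbors = 20L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  stopifnot(n_neighbors >= 1, n_neighbors < n)
  d2 <- cross_dist2(embedding, embedding)
  if (all(d2 < 1e-24)) {
    warning("embedding is degenerate (all rows identical); returning complete graph",
            call. = FALSE)
    return(igraph::make_full_graph(n))
  }
  diag(d2) <- Inf
  nb <- t(apply(d2, 1L, function(d) order(d)[seq_len(n_neighbors)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = n_neighbors),
                            j = as.integer(t(nb)), x = 1, dims = c(n, n))
  shared <- A %*% Matrix::t(A)                       # common-neighbour counts
  mask <- (A + Matrix::t(A)) > 0                     # i-j kNN in either direction
  jac <- shared / (2 * n_neighbors - shared)
  Wadj <- jac * mask
  diag(Wadj) <- 0
  Wadj <- Matrix::drop0(Wadj)
  igraph::graph_from_adjacency_matrix(Wadj, mode = "max", weighted = TRUE)
}

#' Cluster cells by community detection
#'
#' Leiden modularity communities on a shared-nearest-neighbour graph at a
#' given resolution; seeded and reproducible.
#'
#' @param graph An `igraph` graph from [build_knn_graph()].
#' @param resolution Modularity resolution parameter.
#' @param seed Integer seed.
#' @return A tibble (`cell`, `cluster`) of class `cluster_assignment`, with
#'   attributes `resolution` and `n_clusters`.
#' @export
cluster_cells <- function(graph, resolution = 1, seed = 1L) {
  set.seed(seed)
  w <- igraph::E(graph)$weight
  comm <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution,
                                 weights = w, n_iterations = 5L)
  labels <- igraph::membership(comm)
  out <- tibble::tibble(cell = seq_along(labels),
                        cluster = as.integer(labels))
  attr(out, "resolution") <- resolution
  attr(out, "n_clusters") <- dplyr::n_distinct(out$cluster)
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Pick a clustering resolution by bootstrap stability
#'
#' A light-weight stand-in for tree-based multi-resolution reconciliation:
#' for every candidate resolution, cells are repeatedly subsampled and
#' reclustered, and stability is the mean pairwise adjusted Rand index of
#' the subsampled labelings (computed on the cells two draws share). The
#' assignment at the highest resolution whose stability exceeds
#' `stability_floor` is returned; if none qualifies, the most stable one is
#' returned with a warning.
#'
#' @param embedding Cells x features matrix (e.g. [embed_cells()] output).
#' @param resolutions Numeric vector (>= 2 values) of candidate resolutions.
#' @param n_boot Number of bootstrap reclusterings per resolution (>= 2).
#' @param seed Integer seed.
#' @param n_neighbors Neighbourhood size for the graph.
#' @param stability_floor Minimum acceptable stability.
#' @param subsample_frac Fraction of cells per bootstrap draw.
#' @return A `cluster_assignment` for the full data at the chosen
#'   resolution, with a `stability` attribute and a `stability_profile`
#'   tibble attribute (`resolution`, `stability`, `n_clusters`).
#' @export
select_resolution <- function(embedding, resolutions, n_boot = 10L, seed = 1L,
                              n_neighbors = 20L, stability_floor = 0.8,
                              subsample_frac = 0.8) {
  stopifnot(length(resolutions) >= 2)
  if (n_boot < 2) stop("n_boot must be at least 2 to measure stability",
                       call. = FALSE)
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  m <- max(2L, floor(subsample_frac * n))
  full_graph <- build_knn_graph(embedding, n_neighbors)
  profile <- purrr::map_dfr(seq_along(resolutions), function(ri) {
    res <- resolutions[ri]
    draws <- lapply(seq_len(n_boot), function(b) {
      set.seed(derive_seed(seed, 1000L * ri + b))
      idx <- sort(sample.int(n, m))
      g <- build_knn_graph(embedding[idx, , drop = FALSE],
                           min(n_neighbors, m - 1L))
      list(idx = idx,
           labels = cluster_cells(g, res, seed = derive_seed(seed, b))$cluster)
    })
    pairs <- utils::combn(n_boot, 2L)
    aris <- apply(pairs, 2L, function(pr) {
      a <- draws[[pr[1]]]; b <- draws[[pr[2]]]
      common <- intersect(a$idx, b$idx)
      adjusted_rand_index(a$labels[match(common, a$idx)],
                          b$labels[match(common, b$idx)])
    })
    full <- cluster_cells(full_graph, res, seed = derive_seed(seed, 99L + ri))
    tibble::tibble(resolution = res, stability = mean(aris),
                   n_clusters = attr(full, "n_clusters"))
  })
  ok <- profile$stability > stability_floor
  chosen <- if (any(ok)) {
    max(profile$resolution[ok])
  } else {
    warning("no resolution reached stability ", stability_floor,
            "; returning the most stable", call. = FALSE)
    profile$resolution[which.max(profile$stability)]
  }
  ri <- which(profile$resolution == chosen)[1]
  out <- cluster_cells(full_graph, chosen, seed = derive_seed(seed, 99L + ri))
  attr(out, "stability") <- profile$stability[ri]
  attr(out, "stability_profile") <- profile
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two partitions of the same cells.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar in (-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Rank marker genes by cluster mean difference
#'
#' A simple log-fold ranking utility (cluster mean vs rest mean on the
#' provided matrix) used for synthetic sanity checks.
#'
#' @param x Cells x genes matrix (normalized scale).
#' @param clusters Per-cell cluster labels.
#' @param n_top Markers per cluster.
#' @return A tibble (`cluster`, `gene`, `log_fold`).
#' @export
rank_markers <- function(x, clusters, n_top = 10L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("gene", seq_len(ncol(x)))
  purrr::map_dfr(sort(unique(as.character(clusters))), function(cl) {
    inside <- clusters == cl
    lf <- log1p(colMeans(x[inside, , drop = FALSE])) -
      log1p(colMeans(x[!inside, , drop = FALSE]))
    ord <- order(-lf)[seq_len(min(n_top, ncol(x)))]
    tibble::tibble(cluster = cl, gene = colnames(x)[ord], log_fold = lf[ord])
  })
}
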