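#' Region mixing score of a clustering
#'
#' Measures how unevenly each region distributes across clusters. With
#' q_{r,k} the fraction of cluster k's cells that come from region r and
#' qbar_r the overall region-r fraction, the default score is the
#' cluster-size-weighted total-variation-style deviation
#' \deqn{score(r) = \sum_k (n_k / n) | q_{r,k} - \bar q_r |.}
#' A score of 0 means region r has identical composition in every cluster
#' (perfect mixing); larger values mean clusters segregate by region.
#' `weights = "uniform"` replaces n_k/n by 1/K.
#'
#' @param cluster_labels Per-cell cluster labels.
#' @param region_labels Per-cell region labels (same length).
#' @param weights `"size"` (default) or `"uniform"` cluster weighting.
#' @return A tibble (`region`, `score`) of class `starmaps_mixing`, with the
#'   number of clusters in attribute `n_clusters`.
#' @export
mixing_score <- function(cluster_labels, region_labels,
                         weights = c("size", "uniform")) {
  weights <- match.arg(weights)
  stopifnot(length(cluster_labels) == length(region_labels),
            length(cluster_labels) > 0)
  tab <- table(region = region_labels, cluster = cluster_labels)
  n_k <- colSums(tab)
  n <- sum(n_k)
  q <- sweep(tab, 2L, n_k, "/")          # q_{r,k}
  qbar <- rowSums(tab) / n               # overall region fractions
  wt <- if (weights == "size") n_k / n else rep(1 / ncol(tab), ncol(tab))
  score <- as.numeric(abs(q - qbar) %*% wt)
  out <- tibble::tibble(region = rownames(tab), score = score)
  attr(out, "n_clusters") <- ncol(tab)
  attr(out, "weights") <- weights
  class(out) <- c("starmaps_mixing", class(out))
  out
}

#' Resampled k-nearest-neighbour label-transfer accuracy
#'
#' Checks that a representation preserves biological signal: repeatedly
#' draws disjoint query and reference cell sets, labels each query cell by a
#' shared-nearest-neighbour weighted majority vote among its `n_neighbors`
#' Euclidean neighbours in the reference, and scores agreement with the
#' held-out truth. Reports the mean accuracy and half the standard deviation
#' across repeats.
#'
#' @param x Numeric matrix (cells x features): an embedding or expression.
#' @param labels Per-cell class labels (the signal to preserve).
#' @param n_query,n_ref Sizes of the disjoint query / reference draws.
#' @param n_repeats Number of resampling repeats.
#' @param n_neighbors Neighbourhood size for the vote.
#' @param seed Integer seed.
#' @return A one-row tibble: `mean_accuracy`, `half_sd`, `n_repeats`,
#'   `n_query`, `n_ref`, `n_neighbors`.
#' @export
label_transfer_accuracy <- function(x, labels, n_query = 1000L, n_ref = 4000L,
                                    n_repeats = 10L, n_neighbors = 15L,
                                    seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels), n_repeats >= 1,
            n_query + n_ref <= nrow(x), n_neighbors >= 1)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("labels are degenerate (single class)", call. = FALSE)
  }
  accs <- vapply(seq_len(n_repeats), function(rep_i) {
    set.seed(derive_seed(seed, rep_i))
    pick <- sample.int(nrow(x), n_query + n_ref)
    q_idx <- pick[seq_len(n_query)]
    r_idx <- pick[n_query + seq_len(n_ref)]
    missing_classes <- setdiff(unique(labels[q_idx]), labels[r_idx])
    if (length(missing_classes) > 0) {
      message("repeat ", rep_i, ": class(es) absent from reference: ",
              paste(missing_classes, collapse = ", "))
    }
    pred <- snn_classify(x[q_idx, , drop = FALSE], x[r_idx, , drop = FALSE],
                         labels[r_idx], n_neighbors)
    mean(pred == labels[q_idx])
  }, 0)
  tibble::tibble(
    mean_accuracy = mean(accs),
    half_sd = if (n_repeats > 1) stats::sd(accs) / 2 else 0,
    n_repeats = n_repeats, n_query = n_query, n_ref = n_ref,
    n_neighbors = n_neighbors
  )
}

# shared-nearest-neighbour weighted kNN vote; ties and all-zero weights fall
# back to plain majority via a small constant added to every neighbour
snn_classify <- function(query, ref, ref_labels, n_neighbors) {
  n_neighbors <- min(n_neighbors, nrow(ref))
  dq <- cross_dist2(query, ref)
  dr <- cross_dist2(ref, ref)
  knn_q <- t(apply(dq, 1L, function(d) order(d)[seq_len(n_neighbors)]))
  knn_r <- t(apply(dr, 1L, function(d) order(d)[seq_len(n_neighbors)]))
  classes <- sort(unique(ref_labels))
  vapply(seq_len(nrow(query)), function(i) {
    nb <- knn_q[i, ]
    shared <- vapply(nb, function(j) {
      length(intersect(knn_q[i, ], knn_r[j, ]))
    }, 0L)
    w <- shared / n_neighbors + 1e-6
    votes <- tapply(w, factor(ref_labels[nb], levels = classes), sum,
                    default = 0)
    classes[which.max(votes)]
  }, character(1))
}

#' Normalized Gram-based distance between factor subspaces
#'
#' An approximate subspace distance for k x p factor matrices:
#' \deqn{d(A, B) = \|A A^T - B B^T\|_2 / \|B B^T\|_2} with the spectral norm
#' of the k x k Gram difference. Invariant to right-multiplication of both
#' arguments by an orthogonal matrix and to joint rescaling.
#'
#' @param A,B Numeric matrices of identical shape; `B` must be nonzero.
#' @return Non-negative scalar.
#' @export
subspace_distance <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  gB <- tcrossprod(B)
  nB <- norm(gB, type = "2")
  if (nB == 0) stop("B is all-zero; distance undefined", call. = FALSE)
  norm(tcrossprod(A) - gB, type = "2") / nB
}

#' Perturbation magnitude of each batch and region
#'
#' Summarizes how far each task-specific factor space sits from the shared
#' one: `subspace_distance(H + E_j, H)` per batch and
#' `subspace_distance(H + F_r, H)` per region.
#'
#' @param fit A fitted `starmaps_fit`.
#' @return A tibble (`type` in `"batch"`/`"region"`, `label`, `distance`)
#'   of class `starmaps_perturbation`.
#' @export
perturbation_magnitudes <- function(fit) {
  out <- dplyr::bind_rows(
    purrr::imap_dfr(fit$E, function(e, j) {
      tibble::tibble(type = "batch", label = j,
                     distance = subspace_distance(fit$H + e, fit$H))
    }),
    purrr::imap_dfr(fit$F, function(f, r) {
      tibble::tibble(type = "region", label = r,
                     distance = subspace_distance(fit$H + f, fit$H))
    })
  )
  class(out) <- c("starmaps_perturbation", class(out))
  out
}
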