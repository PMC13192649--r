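#' Draw ground-truth factors for the generative model
#'
#' Samples the exact structure the factorization assumes: a non-negative
#' shared factor matrix H (gamma entries), sparse batch and region
#' perturbations E_j / F_r with Bernoulli supports and signed gamma
#' magnitudes, clipped so every H + E_j + F_r stays non-negative, and
#' archetype-concentrated Dirichlet membership rows.
#'
#' @param M Number of batches.
#' @param R Number of regions.
#' @param k Number of latent factors (archetypes).
#' @param p Number of genes.
#' @param perturb_sparsity Probability an entry of E_j / F_r is nonzero.
#' @param perturb_scale Magnitude multiplier for the perturbation entries.
#' @param seed Integer seed.
#' @return A `starmaps_truth` object: `H_true`, `E_true`, `F_true` (named
#'   lists), `k`, `p`, `batches`, `regions`, `gene_ids`, `seed`.
#' @export
simulate_truth <- function(M = 2L, R = 3L, k = 4L, p = 60L,
                           perturb_sparsity = 0.05, perturb_scale = 1,
                           seed = 1L) {
  stopifnot(perturb_sparsity >= 0, perturb_sparsity < 1, perturb_scale > 0)
  set.seed(seed)
  gene_ids <- sprintf("gene%03d", seq_len(p))
  H <- matrix(stats::rgamma(k * p, shape = 2, rate = 2), k, p,
              dimnames = list(NULL, gene_ids))
  draw_perturb <- function() {
    support <- matrix(stats::rbinom(k * p, 1L, perturb_sparsity), k, p)
    mag <- matrix(stats::rgamma(k * p, shape = 2, rate = 2) * perturb_scale, k, p)
    sign <- matrix(sample(c(-1, 1), k * p, replace = TRUE), k, p)
    P <- support * sign * mag
    dimnames(P) <- list(NULL, gene_ids)
    P
  }
  E <- stats::setNames(lapply(seq_len(M), function(j) draw_perturb()),
                       paste0("batch", seq_len(M)))
  F_ <- stats::setNames(lapply(seq_len(R), function(r) draw_perturb()),
                        paste0("region", seq_len(R)))
  # rescale negative entries only at the (factor, gene) positions where the
  # tightest pairwise sum would go negative, leaving all other entries intact
  guard <- 0L
  repeat {
    deficit <- -(H + Reduce(pmin, E) + Reduce(pmin, F_))
    if (all(deficit <= 0) || guard >= 500L) break
    bad <- deficit > 0
    shrink <- function(P) {
      hit <- bad & P < 0
      P[hit] <- P[hit] * 0.8
      P
    }
    E <- lapply(E, shrink)
    F_ <- lapply(F_, shrink)
    guard <- guard + 1L
  }
  if (guard > 0L) {
    warning("negative perturbation entries rescaled to keep H + E_j + F_r >= 0",
            call. = FALSE)
  }
  structure(list(H_true = H, E_true = E, F_true = F_, k = k, p = p,
                 batches = names(E), regions = names(F_),
                 gene_ids = gene_ids, seed = as.integer(seed)),
            class = "starmaps_truth")
}

#' Sample expression data from a ground truth
#'
#' Generates one block per (batch, region) task: membership rows are drawn
#' from an archetype-concentrated Dirichlet (each cell is assigned an
#' archetype whose weight dominates), the mean surface is
#' W_jr (H + E_j + F_r), and either Gaussian noise clipped at zero
#' (normalized-scale view) or Poisson counts with Bernoulli dropout
#' (count view) are emitted.
#'
#' @param truth A [simulate_truth()] object.
#' @param n_per_task Cells per (batch, region) task.
#' @param noise_sd Gaussian noise standard deviation (ignored for counts).
#' @param dropout Probability a count entry is zeroed (counts mode only).
#' @param counts Emit Poisson counts with dropout instead of the
#'   Gaussian-noise surface.
#' @param concentration Dirichlet weight of each cell's own archetype
#'   (off-archetype weights are 1).
#' @param seed Integer seed.
#' @return An [expression_dataset()] whose metadata carries `batch`,
#'   `region` and the generating `archetype`; the per-task true memberships
#'   are stored in attribute `W_true` and the truth in `truth`.
#' @export
sample_expression <- function(truth, n_per_task = 50L, noise_sd = 0.05,
                              dropout = 0, counts = FALSE,
                              concentration = 10, seed = 1L) {
  stopifnot(inherits(truth, "starmaps_truth"))
  set.seed(seed)
  tasks <- expand.grid(batch = truth$batches, region = truth$regions,
                       stringsAsFactors = FALSE)
  W_true <- list()
  mats <- list()
  meta <- list()
  for (t in seq_len(nrow(tasks))) {
    j <- tasks$batch[t]; r <- tasks$region[t]
    arche <- sample(rep_len(seq_len(truth$k), n_per_task))
    alpha <- matrix(1, n_per_task, truth$k)
    alpha[cbind(seq_len(n_per_task), arche)] <- concentration
    g <- matrix(stats::rgamma(n_per_task * truth$k, shape = alpha, rate = 1),
                n_per_task, truth$k)
    W <- g / rowSums(g)
    A <- truth$H_true + truth$E_true[[j]] + truth$F_true[[r]]
    mu <- W %*% A
    X <- if (counts) {
      cnt <- matrix(stats::rpois(length(mu), lambda = pmax(mu, 0)),
                    nrow(mu), ncol(mu))
      if (dropout > 0) {
        keep <- matrix(stats::rbinom(length(cnt), 1L, 1 - dropout),
                       nrow(cnt), ncol(cnt))
        cnt <- cnt * keep
      }
      cnt
    } else {
      pmax(mu + matrix(stats::rnorm(length(mu), sd = noise_sd),
                       nrow(mu), ncol(mu)), 0)
    }
    key <- paste(j, r, sep = ":")
    W_true[[key]] <- W
    mats[[key]] <- X
    meta[[key]] <- tibble::tibble(
      cell_id = sprintf("%s_c%03d", key, seq_len(n_per_task)),
      batch = j, region = r, archetype = arche
    )
  }
  X_all <- do.call(rbind, mats)
  cells <- dplyr::bind_rows(meta)
  ds <- expression_dataset(X_all, cells, gene_ids = truth$gene_ids)
  attr(ds, "W_true") <- W_true
  attr(ds, "truth") <- truth
  ds
}

#' Plant gene-set over-expression in designated cell groups
#'
#' Multiplies the expression of the gene set's members by `effect` within
#' the target groups only; all other entries are untouched (bit-exactly).
#' Used to give enrichment tests a known positive control.
#'
#' @param dataset An [expression_dataset()].
#' @param gene_set A [gene_set()] (members must be present in the dataset).
#' @param groups Per-cell group labels (or name of a metadata column).
#' @param target_groups Values of `groups` to receive the effect.
#' @param effect Multiplicative effect (> 1).
#' @param seed Unused for the deterministic magnitude effect; kept for
#'   interface stability.
#' @return The modified dataset.
#' @export
plant_gene_set <- function(dataset, gene_set, groups, target_groups,
                           effect = 3, seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"), effect >= 1)
  members <- if (inherits(gene_set, "gene_set")) gene_set$members else gene_set
  if (is.character(groups) && length(groups) == 1 &&
      groups %in% names(dataset$cells)) {
    groups <- dataset$cells[[groups]]
  }
  stopifnot(length(groups) == nrow(dataset$matrix))
  hit_genes <- dataset$genes %in% members
  if (!any(hit_genes)) stop("gene set members absent from dataset", call. = FALSE)
  rows <- groups %in% target_groups
  m <- dataset$matrix
  m[rows, hit_genes] <- m[rows, hit_genes] * effect
  out <- expression_dataset(m, dataset$cells, gene_ids = dataset$genes)
  attr(out, "W_true") <- attr(dataset, "W_true")
  attr(out, "truth") <- attr(dataset, "truth")
  out
}

# best factor alignment: column permutation maximizing summed row
# correlations between fitted and true H (exhaustive for k <= 8, greedy
# otherwise); positive rescaling does not affect Pearson correlation
align_factors <- function(H_fit, H_true) {
  k <- nrow(H_true)
  cors <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    cors[a, b] <- suppressWarnings(stats::cor(H_fit[a, ], H_true[b, ]))
  }
  cors[!is.finite(cors)] <- 0
  if (k <= 8L) {
    perms <- gtools_permutations(k)
    scores <- apply(perms, 1L, function(pp) sum(cors[cbind(pp, seq_len(k))]))
    perm <- perms[which.max(scores), ]
  } else {
    perm <- integer(k)
    avail <- seq_len(k)
    for (b in seq_len(k)) {
      best <- avail[which.max(cors[avail, b])]
      perm[b] <- best
      avail <- setdiff(avail, best)
    }
  }
  perm  # perm[b] = fitted factor matching true factor b
}

# all permutations of 1..k as rows (small k only)
gtools_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- gtools_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Compare a fitted model with the generating truth
#'
#' Aligns fitted factors to the truth by the correlation-maximizing column
#' permutation (positive rescaling is implicit in the correlation), then
#' reports: mean per-factor Pearson correlation of H, precision and recall
#' of the region-perturbation supports (entries with magnitude above
#' `support_floor`), and the mean row-wise cosine similarity of the
#' membership blocks.
#'
#' @param fit A fitted `starmaps_fit`.
#' @param truth The generating `starmaps_truth`.
#' @param W_true Named list of true membership blocks (as stored on the
#'   dataset by [sample_expression()]), optional.
#' @param support_floor Magnitude above which a perturbation entry counts
#'   as support.
#' @return A named list: `h_correlation`, `f_support_precision`,
#'   `f_support_recall`, `w_cosine` (NA when `W_true` absent), `permutation`.
#' @export
recovery_report <- function(fit, truth, W_true = NULL, support_floor = 0.05) {
  stopifnot(inherits(truth, "starmaps_truth"))
  if (fit$k != truth$k) stop("factor count mismatch between fit and truth",
                             call. = FALSE)
  perm <- align_factors(fit$H, truth$H_true)
  H_al <- fit$H[perm, , drop = FALSE]
  h_cor <- mean(vapply(seq_len(truth$k), function(l) {
    ct <- suppressWarnings(stats::cor(H_al[l, ], truth$H_true[l, ]))
    if (is.finite(ct)) ct else 0
  }, 0))
  true_support <- unlist(lapply(truth$F_true, function(f) f != 0))
  fit_support <- unlist(lapply(names(truth$F_true), function(r) {
    abs(fit$F[[r]][perm, , drop = FALSE]) > support_floor
  }))
  tp <- sum(true_support & fit_support)
  precision <- if (sum(fit_support) > 0) tp / sum(fit_support) else NA_real_
  recall <- if (sum(true_support) > 0) tp / sum(true_support) else NA_real_
  w_cos <- NA_real_
  if (!is.null(W_true)) {
    keys <- intersect(names(fit$W), names(W_true))
    w_cos <- mean(unlist(lapply(keys, function(key) {
      Wf <- fit$W[[key]][, perm, drop = FALSE]
      Wt <- W_true[[key]]
      rowSums(Wf * Wt) /
        pmax(sqrt(rowSums(Wf^2)) * sqrt(rowSums(Wt^2)), .Machine$double.eps)
    })))
  }
  list(h_correlation = h_cor, f_support_precision = precision,
       f_support_recall = recall, w_cosine = w_cos, permutation = perm)
}
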