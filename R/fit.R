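#' Sparse task-perturbed non-negative factorization
#'
#' Fits the model X_jr ~ W_jr (H + E_j + F_r) over all observed
#' (batch j, region r) tasks, where H is a shared non-negative k x p factor
#' matrix, E_j and F_r are sparse batch- and region-specific additive
#' perturbations (L1-penalized with weights `lambda1`, `lambda2`), and each
#' row of the membership matrix W_jr lives on the probability simplex.
#' The objective is
#' \deqn{\sum_{j,r} \frac{1}{2 n_{jr}} \|X_{jr} - W_{jr}(H+E_j+F_r)\|_F^2
#'   + \lambda_1 \sum_j \|E_j\|_1 + \lambda_2 \sum_r \|F_r\|_1}
#' subject to H >= 0, H + E_j + F_r >= 0 and simplex rows of W. Optimization
#' alternates a simplex-constrained least-squares pass on the W blocks with
#' exact coordinate-descent passes on H (non-negative), E and F
#' (soft-thresholded), each clipped against the joint non-negativity
#' constraint, so the objective never increases.
#'
#' @param data An [expression_dataset()] (split into tasks internally) or a
#'   task-block list from [split_by_task()].
#' @param k Number of latent factors.
#' @param lambda Convenience single penalty setting both `lambda1` and
#'   `lambda2` (the usual operating mode).
#' @param lambda1,lambda2 L1 weights on the batch / region perturbations.
#'   `Inf` pins the corresponding perturbations at zero.
#' @param max_iter Maximum outer iterations.
#' @param tol Relative objective-change convergence threshold.
#' @param seed Integer seed (initialization tie-breaking and reproducibility).
#' @param inner_w_iter Maximum projected-gradient iterations per W pass.
#' @param init_iter Alternating passes used by the unperturbed initialization.
#' @return A `starmaps_fit` object: list with `H`, `E` (named by batch), `F`
#'   (named by region), `W` (named by task), `tasks`, `k`, `lambda1`,
#'   `lambda2`, `objective_trace` (one value per outer iteration, starting at
#'   initialization), `pass_trace` (objective after every update pass),
#'   `converged`, `n_iter` and `seed`.
#' @export
starmaps_fit <- function(data, k, lambda = 1e-3,
                         lambda1 = lambda, lambda2 = lambda,
                         max_iter = 200L, tol = 1e-5, seed = 1L,
                         inner_w_iter = 100L, init_iter = 30L) {
  blocks <- if (inherits(data, "expression_dataset")) split_by_task(data) else data
  tasks <- attr(blocks, "tasks")
  if (is.null(tasks)) stop("blocks must carry a 'tasks' attribute; use split_by_task()",
                           call. = FALSE)
  k <- as.integer(k)
  stopifnot(k >= 1, lambda1 >= 0, lambda2 >= 0, tol > 0, max_iter >= 1)
  p <- ncol(blocks[[1]])
  n_total <- sum(tasks$n)
  if (k > min(n_total, p)) stop("k exceeds min(cells, genes)", call. = FALSE)

  model <- starmaps_init(blocks, k, seed = seed, init_iter = init_iter)
  model$lambda1 <- lambda1
  model$lambda2 <- lambda2

  obj <- starmaps_objective(model, blocks)
  model$objective_trace <- obj
  model$pass_trace <- obj
  model$converged <- FALSE

  for (it in seq_len(max_iter)) {
    model <- update_memberships(model, blocks, max_iter = inner_w_iter)
    model$pass_trace <- c(model$pass_trace, starmaps_objective(model, blocks))
    model <- update_shared_factor(model, blocks)
    model$pass_trace <- c(model$pass_trace, starmaps_objective(model, blocks))
    model <- update_batch_perturbations(model, blocks)
    model$pass_trace <- c(model$pass_trace, starmaps_objective(model, blocks))
    model <- update_region_perturbations(model, blocks)
    new_obj <- starmaps_objective(model, blocks)
    model$pass_trace <- c(model$pass_trace, new_obj)
    model$objective_trace <- c(model$objective_trace, new_obj)
    rel <- abs(obj - new_obj) / max(obj, .Machine$double.eps)
    obj <- new_obj
    if (rel < tol) {
      model$converged <- TRUE
      break
    }
  }
  model$n_iter <- length(model$objective_trace) - 1L
  model
}

#' Evaluate the factorization objective
#'
#' @param model A `starmaps_fit` (fitted or in progress).
#' @param blocks Task-block list the model was built from.
#' @return The scalar objective value (non-negative).
#' @export
starmaps_objective <- function(model, blocks) {
  tasks <- attr(blocks, "tasks")
  recon <- 0
  for (t in seq_along(blocks)) {
    A <- model$H + model$E[[tasks$batch[t]]] + model$F[[tasks$region[t]]]
    if (!all(dim(blocks[[t]]) == c(nrow(model$W[[t]]), ncol(A)))) {
      stop("dimension mismatch between model and blocks", call. = FALSE)
    }
    R <- blocks[[t]] - model$W[[t]] %*% A
    recon <- recon + sum(R^2) / (2 * tasks$n[t])
  }
  pen1 <- if (is.finite(model$lambda1)) {
    model$lambda1 * sum(vapply(model$E, function(e) sum(abs(e)), 0))
  } else 0
  pen2 <- if (is.finite(model$lambda2)) {
    model$lambda2 * sum(vapply(model$F, function(f) sum(abs(f)), 0))
  } else 0
  unname(recon + pen1 + pen2)
}

#' Initialize the model with an unperturbed simplex NMF
#'
#' Runs a deterministic SVD-seeded (NNDSVD-type) non-negative factorization
#' of the stacked blocks with all perturbations held at zero: alternating
#' exact non-negative least-squares passes on H and simplex-projected
#' least-squares passes on W. The simplex projection's scale loss is
#' compensated by rescaling H with the mean pre-projection row sum.
#'
#' @inheritParams starmaps_objective
#' @param k Number of factors.
#' @param seed Integer seed.
#' @param init_iter Maximum alternating passes.
#' @return An unfitted `starmaps_fit` with `E = F = 0`.
#' @export
starmaps_init <- function(blocks, k, seed = 1L, init_iter = 30L) {
  tasks <- attr(blocks, "tasks")
  p <- ncol(blocks[[1]])
  X <- do.call(rbind, blocks)
  n <- nrow(X)
  if (k > min(n, p)) stop("k exceeds min(cells, genes)", call. = FALSE)
  set.seed(seed)

  # NNDSVD seeding: per singular triplet keep the dominant sign-consistent part
  sv <- svd(X, nu = k, nv = k)
  W0 <- matrix(0, n, k)
  H0 <- matrix(0, k, p)
  for (l in seq_len(k)) {
    u <- sv$u[, l]; v <- sv$v[, l]; s <- sv$d[l]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    if (sqrt(sum(up^2)) * sqrt(sum(vp^2)) >= sqrt(sum(un^2)) * sqrt(sum(vn^2))) {
      nu <- sqrt(sum(up^2)); nv <- sqrt(sum(vp^2))
      if (nu * nv > 0) {
        W0[, l] <- sqrt(s * nu * nv) * up / nu
        H0[l, ] <- sqrt(s * nu * nv) * vp / nv
      }
    } else {
      nu <- sqrt(sum(un^2)); nv <- sqrt(sum(vn^2))
      if (nu * nv > 0) {
        W0[, l] <- sqrt(s * nu * nv) * un / nu
        H0[l, ] <- sqrt(s * nu * nv) * vn / nv
      }
    }
    if (all(W0[, l] == 0)) W0[, l] <- stats::runif(n, 0, 1e-4)
    if (all(H0[l, ] == 0)) H0[l, ] <- stats::runif(p, 0, 1e-4)
  }
  rs <- rowSums(W0)
  rs[rs == 0] <- 1
  W0 <- W0 / rs
  H0 <- H0 * mean(rs)
  colnames(H0) <- colnames(blocks[[1]])

  batches <- unique(tasks$batch)
  regions <- unique(tasks$region)
  k <- as.integer(k)
  zero <- matrix(0, k, p, dimnames = list(NULL, colnames(blocks[[1]])))
  model <- structure(list(
    H = H0,
    E = stats::setNames(rep(list(zero), length(batches)), batches),
    F = stats::setNames(rep(list(zero), length(regions)), regions),
    W = NULL,
    tasks = tasks,
    k = k, lambda1 = 0, lambda2 = 0,
    seed = as.integer(seed)
  ), class = "starmaps_fit")
  ends <- cumsum(tasks$n)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  model$W <- stats::setNames(lapply(seq_along(blocks), function(t) {
    W0[starts[t]:ends[t], , drop = FALSE]
  }), tasks$name)

  # alternating minimization with perturbations pinned at zero
  prev <- Inf
  for (i in seq_len(init_iter)) {
    model <- update_memberships(model, blocks)
    model <- update_shared_factor(model, blocks)
    obj <- starmaps_objective(model, blocks)
    if (is.finite(prev) && abs(prev - obj) / max(prev, .Machine$double.eps) < 1e-8) break
    prev <- obj
  }
  model
}

#' One simplex-constrained least-squares pass over all membership blocks
#'
#' Each row of each W_jr is set to
#' argmin ||x_i - w (H+E_j+F_r)||^2 over the probability simplex. For
#' k <= 8 the quadratic program is solved exactly by enumerating active
#' sets (all rows of a task share the Gram matrix, so each support's
#' equality-constrained solution vectorizes across cells); for larger k a
#' monotone projected-gradient descent with step 1/L is used. Either way
#' the pass cannot increase the objective.
#'
#' @inheritParams starmaps_objective
#' @param max_iter Maximum projected-gradient iterations (large-k path).
#' @param tol Convergence tolerance for the projected-gradient path.
#' @return The model with updated `W`.
#' @export
update_memberships <- function(model, blocks, max_iter = 100L, tol = 1e-8) {
  tasks <- model$tasks
  for (t in seq_along(blocks)) {
    A <- model$H + model$E[[tasks$batch[t]]] + model$F[[tasks$region[t]]]
    G <- tcrossprod(A)                      # k x k Gram
    B <- tcrossprod(blocks[[t]], A)         # n x k
    W_new <- if (model$k <= 8L) {
      simplex_ls_exact(G, B)
    } else {
      simplex_ls_pgd(G, B, model$W[[t]], max_iter, tol)
    }
    if (!all(is.finite(W_new))) {
      stop("non-finite membership encountered in task ", tasks$name[t],
           call. = FALSE)
    }
    # guard: keep the old row wherever the solver failed to improve
    old_f <- 0.5 * rowSums((model$W[[t]] %*% G) * model$W[[t]]) -
      rowSums(model$W[[t]] * B)
    new_f <- 0.5 * rowSums((W_new %*% G) * W_new) - rowSums(W_new * B)
    keep_old <- new_f > old_f
    if (any(keep_old)) W_new[keep_old, ] <- model$W[[t]][keep_old, ]
    model$W[[t]] <- W_new
  }
  model
}

# exact simplex-constrained least squares for all rows sharing one Gram
# matrix: enumerate supports, solve the equality-constrained system per
# support, keep each row's feasible candidate with the lowest objective
simplex_ls_exact <- function(G, B) {
  k <- ncol(G)
  n <- nrow(B)
  best_f <- rep(Inf, n)
  best_W <- matrix(0, n, k)
  for (code in seq_len(2^k - 1L)) {
    S <- which(bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
    GS <- G[S, S, drop = FALSE]
    Gi <- tryCatch(solve(GS), error = function(e) NULL)
    if (is.null(Gi)) next
    u <- rowSums(Gi)                        # Gi %*% 1
    c1 <- sum(u)
    if (abs(c1) < .Machine$double.eps) next
    P <- B[, S, drop = FALSE] %*% Gi        # Gi symmetric: rows are Gi b_S
    mu <- (rowSums(P) - 1) / c1
    WS <- P - outer(mu, u)
    feas <- rowSums(WS < -1e-10) == 0
    if (!any(feas)) next
    f <- 0.5 * rowSums((WS %*% GS) * WS) - rowSums(WS * B[, S, drop = FALSE])
    take <- feas & f < best_f - 1e-15
    if (any(take)) {
      best_f[take] <- f[take]
      best_W[take, ] <- 0
      best_W[take, S] <- pmax(WS[take, , drop = FALSE], 0)
    }
  }
  # renormalize away the tiny negative clips
  best_W / rowSums(best_W)
}

# monotone projected-gradient fallback for large k
simplex_ls_pgd <- function(G, B, W, max_iter, tol) {
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 0)
  if (L <= 0) return(W)
  for (i in seq_len(max_iter)) {
    W_new <- project_rows_simplex(W - (W %*% G - B) / L)
    delta <- max(abs(W_new - W))
    W <- W_new
    if (delta < tol) break
  }
  W
}

# residual list X_jr - W_jr (H + E_j + F_r), recomputed fresh at pass entry
task_residuals <- function(model, blocks) {
  tasks <- model$tasks
  lapply(seq_along(blocks), function(t) {
    A <- model$H + model$E[[tasks$batch[t]]] + model$F[[tasks$region[t]]]
    blocks[[t]] - model$W[[t]] %*% A
  })
}

#' One exact coordinate-descent pass on the shared factor H
#'
#' Factor rows are updated jointly across genes (coordinates within a row do
#' not interact), each coordinate minimized exactly and clipped against both
#' H >= 0 and the joint H + E_j + F_r >= 0 constraints.
#'
#' @inheritParams starmaps_objective
#' @return The model with updated `H`.
#' @export
update_shared_factor <- function(model, blocks) {
  tasks <- model$tasks
  R <- task_residuals(model, blocks)
  wts <- 1 / tasks$n
  # lower bound: H[l,g] >= -min over (j,r) pairs of (E_j + F_r)[l,g], and >= 0
  lb <- matrix(0, model$k, ncol(model$H))
  for (j in names(model$E)) for (r in names(model$F)) {
    lb <- pmax(lb, -(model$E[[j]] + model$F[[r]]))
  }
  lb <- pmax(lb, 0)
  for (l in seq_len(model$k)) {
    c_l <- sum(vapply(seq_along(blocks),
                      function(t) wts[t] * sum(model$W[[t]][, l]^2), 0))
    if (c_l <= 0) next
    b <- Reduce(`+`, lapply(seq_along(blocks), function(t) {
      wts[t] * crossprod(model$W[[t]][, l, drop = FALSE], R[[t]])
    }))
    h_new <- pmax(model$H[l, ] + as.numeric(b) / c_l, lb[l, ])
    delta <- h_new - model$H[l, ]
    model$H[l, ] <- h_new
    for (t in seq_along(blocks)) {
      R[[t]] <- R[[t]] - tcrossprod(model$W[[t]][, l], delta)
    }
  }
  model
}

# shared machinery for the E / F passes: exact soft-thresholded coordinate
# minimization for the perturbation rows of one label (batch or region),
# clipped against the joint non-negativity lower bound
update_perturbation_set <- function(model, blocks, what = c("E", "F")) {
  what <- match.arg(what)
  tasks <- model$tasks
  lambda <- if (what == "E") model$lambda1 else model$lambda2
  own_col <- if (what == "E") tasks$batch else tasks$region
  other <- if (what == "E") model$F else model$E
  R <- task_residuals(model, blocks)
  wts <- 1 / tasks$n
  for (lab in names(model[[what]])) {
    t_idx <- which(own_col == lab)
    if (length(t_idx) == 0) next
    # feasibility: P[l,g] >= max over other-labels of -(H + other)[l,g]
    lb <- Reduce(pmax, lapply(other, function(o) -(model$H + o)))
    P <- model[[what]][[lab]]
    for (l in seq_len(model$k)) {
      c_l <- sum(vapply(t_idx, function(t) wts[t] * sum(model$W[[t]][, l]^2), 0))
      if (c_l <= 0) {
        p_new <- pmax(0, lb[l, ])        # drop penalty mass where unused
      } else {
        b <- Reduce(`+`, lapply(t_idx, function(t) {
          wts[t] * as.numeric(crossprod(model$W[[t]][, l, drop = FALSE], R[[t]]))
        }))
        b <- b + c_l * P[l, ]
        p_new <- pmax(soft_threshold(b, lambda) / c_l, lb[l, ])
      }
      delta <- p_new - P[l, ]
      P[l, ] <- p_new
      for (t in t_idx) {
        R[[t]] <- R[[t]] - tcrossprod(model$W[[t]][, l], delta)
      }
    }
    model[[what]][[lab]] <- P
  }
  model
}

#' @describeIn update_shared_factor One soft-thresholded coordinate pass on
#'   the batch perturbations E_j (threshold `lambda1`).
#' @export
update_batch_perturbations <- function(model, blocks) {
  update_perturbation_set(model, blocks, "E")
}

#' @describeIn update_shared_factor One soft-thresholded coordinate pass on
#'   the region perturbations F_r (threshold `lambda2`).
#' @export
update_region_perturbations <- function(model, blocks) {
  update_perturbation_set(model, blocks, "F")
}

#' Reconstruct expression from a fitted model
#'
#' @param fit A fitted `starmaps_fit`.
#' @param mode `"full"` gives W_jr(H+E_j+F_r) (the model's view of the data),
#'   `"region_corrected"` gives W_jr(H+E_j) (regional perturbation removed),
#'   `"fully_corrected"` gives W_jr H (batch and region removed).
#' @return Named list of reconstructed matrices, one per task.
#' @export
reconstruct_expression <- function(fit, mode = c("full", "region_corrected",
                                                 "fully_corrected")) {
  mode <- match.arg(mode)
  tasks <- fit$tasks
  out <- lapply(seq_len(nrow(tasks)), function(t) {
    A <- switch(mode,
      full = fit$H + fit$E[[tasks$batch[t]]] + fit$F[[tasks$region[t]]],
      region_corrected = fit$H + fit$E[[tasks$batch[t]]],
      fully_corrected = fit$H
    )
    fit$W[[t]] %*% A
  })
  stats::setNames(out, tasks$name)
}

#' Stack the per-task memberships into one embedding
#'
#' Rows follow the original cell order when the fit was built from an
#' [expression_dataset()] via [split_by_task()] (block index attribute);
#' otherwise blocks are stacked in task order.
#'
#' @param fit A fitted `starmaps_fit`.
#' @param cell_index Optional list of original row indices per task (as in
#'   the `cell_index` attribute of [split_by_task()]).
#' @return A cells x k matrix with rows on the probability simplex.
#' @export
embed_cells <- function(fit, cell_index = NULL) {
  W <- do.call(rbind, fit$W)
  if (!is.null(cell_index)) {
    ord <- order(unlist(cell_index, use.names = FALSE))
    W <- W[ord, , drop = FALSE]
  }
  W
}

#' @export
print.starmaps_fit <- function(x, ...) {
  cat("<starmaps_fit> k = ", x$k, ", ", length(x$E), " batch(es), ",
      length(x$F), " region(s), ", nrow(x$tasks), " task(s)\n",
      "lambda1 = ", x$lambda1, ", lambda2 = ", x$lambda2, "\n",
      "objective ", utils::tail(x$objective_trace, 1L), " after ",
      x$n_iter %||% (length(x$objective_trace) - 1L), " iteration(s); converged: ",
      isTRUE(x$converged), "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted factorization into a long tibble
#'
#' @param x A `starmaps_fit`.
#' @param ... Unused.
#' @return A tibble with columns `matrix` (`"H"`, `"E"` or `"F"`), `label`
#'   (batch/region, `NA` for H), `factor`, `gene` and `value`.
#' @export
tidy.starmaps_fit <- function(x, ...) {
  gene_ids <- colnames(x$H) %||% paste0("gene", seq_len(ncol(x$H)))
  one <- function(m, what, label) {
    tibble::tibble(
      matrix = what, label = label,
      factor = rep(seq_len(nrow(m)), times = ncol(m)),
      gene = rep(gene_ids, each = nrow(m)),
      value = as.numeric(m)
    )
  }
  dplyr::bind_rows(
    one(x$H, "H", NA_character_),
    purrr::imap_dfr(x$E, function(m, j) one(m, "E", j)),
    purrr::imap_dfr(x$F, function(m, r) one(m, "F", r))
  )
}

#' One-row model summary
#'
#' @param x A `starmaps_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `lambda1`, `lambda2`, `n_iter`,
#'   `objective`, `converged`, and the L1 mass of the perturbations.
#' @export
glance.starmaps_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, lambda1 = x$lambda1, lambda2 = x$lambda2,
    n_iter = x$n_iter %||% (length(x$objective_trace) - 1L),
    objective = utils::tail(x$objective_trace, 1L),
    converged = isTRUE(x$converged),
    batch_l1 = sum(vapply(x$E, function(e) sum(abs(e)), 0)),
    region_l1 = sum(vapply(x$F, function(f) sum(abs(f)), 0))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
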