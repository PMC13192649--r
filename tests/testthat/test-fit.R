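# helper: hand-assembled model object around given factors
manual_model <- function(H, E, F_, W, tasks, lambda1 = 0, lambda2 = 0) {
  structure(list(H = H, E = E, F = F_, W = W, tasks = tasks,
                 k = nrow(H), lambda1 = lambda1, lambda2 = lambda2,
                 seed = 1L),
            class = "starmaps_fit")
}

# helper: blocks list with tasks attribute from a list of matrices
as_blocks <- function(mats, batch, region) {
  tasks <- tibble::tibble(name = paste(batch, region, sep = ":"),
                          batch = batch, region = region,
                          n = vapply(mats, nrow, 0L))
  names(mats) <- tasks$name
  attr(mats, "tasks") <- tasks
  mats
}

test_that("objective matches an elementwise brute-force oracle", {
  set.seed(4)
  k <- 2; p <- 5
  H <- matrix(runif(k * p), k, p)
  E <- list(b1 = matrix(rnorm(k * p, sd = 0.1), k, p))
  F_ <- list(r1 = matrix(rnorm(k * p, sd = 0.1), k, p),
             r2 = matrix(rnorm(k * p, sd = 0.1), k, p))
  W <- list(`b1:r1` = matrix(c(.3, .7, .5, .5, 1, 0), 3, 2, byrow = TRUE),
            `b1:r2` = matrix(c(.2, .8, .6, .4, 0, 1), 3, 2, byrow = TRUE))
  X <- list(matrix(runif(15), 3, 5), matrix(runif(15), 3, 5))
  blocks <- as_blocks(X, batch = c("b1", "b1"), region = c("r1", "r2"))
  lam1 <- 0.013; lam2 <- 0.031
  model <- manual_model(H, E, F_, W, attr(blocks, "tasks"), lam1, lam2)
  # brute force: loop every entry of every block
  obj_oracle <- 0
  for (t in 1:2) {
    A <- H + E$b1 + F_[[t]]
    for (i in 1:3) for (g in 1:5) {
      pred <- sum(W[[t]][i, ] * A[, g])
      obj_oracle <- obj_oracle + (X[[t]][i, g] - pred)^2 / (2 * 3)
    }
  }
  obj_oracle <- obj_oracle + lam1 * sum(abs(E$b1)) +
    lam2 * (sum(abs(F_$r1)) + sum(abs(F_$r2)))
  expect_equal(starmaps_objective(model, blocks), obj_oracle, tolerance = 1e-12)
})

test_that("objective is zero at perfect reconstruction and penalty-free at lambda 0", {
  set.seed(8)
  H <- matrix(runif(12), 3, 4)
  W <- matrix(c(.2, .3, .5, .1, .8, .1), 2, 3, byrow = TRUE)
  X <- W %*% H
  blocks <- as_blocks(list(X), "b1", "r1")
  zero <- matrix(0, 3, 4)
  model <- manual_model(H, list(b1 = zero), list(r1 = zero),
                        list(`b1:r1` = W), attr(blocks, "tasks"), 0.5, 0.5)
  expect_equal(starmaps_objective(model, blocks), 0, tolerance = 1e-14)
  model$E$b1 <- matrix(0.2, 3, 4)
  model$lambda1 <- 0; model$lambda2 <- 0
  R <- X - W %*% (H + model$E$b1)
  expect_equal(starmaps_objective(model, blocks), sum(R^2) / (2 * 2))
})

test_that("initialization nails an exactly factorizable planted instance", {
  set.seed(12)
  k <- 3; p <- 30; n <- 40
  H_star <- matrix(rgamma(k * p, 2), k, p)
  W_star <- matrix(rgamma(n * k, 1), n, k)
  W_star <- W_star / rowSums(W_star)
  X <- W_star %*% H_star
  blocks <- as_blocks(list(X[1:20, ], X[21:40, ]), c("b1", "b1"), c("r1", "r2"))
  model <- starmaps_init(blocks, k, seed = 1, init_iter = 200)
  obj <- starmaps_objective(model, blocks)
  expect_lt(obj, 1e-6 * sum(X^2))
})

test_that("initialization is deterministic under a fixed seed", {
  inst <- model_instance(seed = 3, n_per_task = 15L)
  m1 <- starmaps_init(inst$blocks, 4, seed = 5, init_iter = 5)
  m2 <- starmaps_init(inst$blocks, 4, seed = 5, init_iter = 5)
  expect_identical(m1$H, m2$H)
  expect_identical(m1$W, m2$W)
})

test_that("rank-1 initialization degenerates to all-ones W and weighted mean H", {
  set.seed(6)
  X1 <- matrix(rgamma(5 * 6, 2), 5, 6)
  X2 <- matrix(rgamma(10 * 6, 2), 10, 6)
  blocks <- as_blocks(list(X1, X2), c("b1", "b2"), c("r1", "r1"))
  model <- starmaps_init(blocks, 1, init_iter = 50)
  expect_true(all(vapply(model$W, function(w) all(w == 1), TRUE)))
  # exact coordinate solution: mean over tasks of per-task gene means
  expected <- (colMeans(X1) + colMeans(X2)) / 2
  expect_equal(as.numeric(model$H), expected, tolerance = 1e-10)
})

test_that("membership solver finds vertex optima and the singleton simplex", {
  set.seed(14)
  A <- matrix(runif(3 * 10), 3, 10)
  blocks <- as_blocks(list(A[2, , drop = FALSE]), "b1", "r1")
  zero <- matrix(0, 3, 10)
  model <- manual_model(A, list(b1 = zero), list(r1 = zero),
                        list(`b1:r1` = matrix(1 / 3, 1, 3)),
                        attr(blocks, "tasks"))
  model <- update_memberships(model, blocks)
  expect_equal(as.numeric(model$W[[1]]), c(0, 1, 0), tolerance = 1e-8)
  # k = 1: the only simplex point is 1
  b1 <- as_blocks(list(matrix(runif(8), 2, 4)), "b1", "r1")
  m1 <- starmaps_init(b1, 1, init_iter = 3)
  m1 <- update_memberships(m1, b1)
  expect_equal(as.numeric(m1$W[[1]]), c(1, 1))
})

test_that("membership solver matches an exhaustive simplex grid search", {
  set.seed(15)
  k <- 3; p <- 12
  A <- matrix(runif(k * p), k, p)
  x <- runif(p)
  blocks <- as_blocks(list(matrix(x, 1, p)), "b1", "r1")
  zero <- matrix(0, k, p)
  model <- manual_model(A, list(b1 = zero), list(r1 = zero),
                        list(`b1:r1` = matrix(1 / 3, 1, 3)),
                        attr(blocks, "tasks"))
  model <- update_memberships(model, blocks)
  w_fit <- as.numeric(model$W[[1]])
  # oracle: grid over the simplex at step 0.01
  best <- Inf; w_best <- NULL
  for (w1 in seq(0, 1, by = 0.01)) {
    for (w2 in seq(0, 1 - w1, by = 0.01)) {
      w <- c(w1, w2, 1 - w1 - w2)
      val <- sum((x - drop(w %*% A))^2)
      if (val < best) { best <- val; w_best <- w }
    }
  }
  expect_lt(max(abs(w_fit - w_best)), 1e-2)
  expect_lte(sum((x - drop(w_fit %*% A))^2), best + 1e-10)
})

test_that("shared-factor coordinate step solves the scalar system in closed form", {
  x <- 3.7
  blocks <- as_blocks(list(matrix(x, 1, 1)), "b1", "r1")
  zero <- matrix(0, 1, 1)
  model <- manual_model(matrix(0.5, 1, 1), list(b1 = zero), list(r1 = zero),
                        list(`b1:r1` = matrix(1, 1, 1)),
                        attr(blocks, "tasks"))
  model <- update_shared_factor(model, blocks)
  expect_equal(model$H[1, 1], x)
  # negative target clips at zero
  blocks0 <- as_blocks(list(matrix(0, 1, 1)), "b1", "r1")
  model$H[1, 1] <- 2
  model <- update_shared_factor(model, blocks0)
  expect_equal(model$H[1, 1], 0)
})

test_that("infinite region penalty pins F at zero through a fit", {
  inst <- model_instance(seed = 20, n_per_task = 20L)
  fit <- starmaps_fit(inst$blocks, k = 4, lambda1 = 1e-3, lambda2 = Inf,
                      seed = 20, max_iter = 10, init_iter = 10)
  expect_true(all(vapply(fit$F, function(f) all(f == 0), TRUE)))
})

test_that("planted sparse region perturbations are recovered with their signs", {
  truth <- suppressWarnings(simulate_truth(perturb_scale = 1.5, seed = 11))
  ds <- sample_expression(truth, noise_sd = 0.01, seed = 111)
  fit <- starmaps_fit(split_by_task(ds), k = 4, lambda = 1e-3, seed = 11,
                      max_iter = 150)
  perm <- recovery_report(fit, truth)$permutation
  hits <- 0; total <- 0
  for (r in names(truth$F_true)) {
    Ft <- truth$F_true[[r]]
    Ff <- fit$F[[r]][perm, , drop = FALSE]
    s <- Ft != 0
    total <- total + sum(s)
    hits <- hits + sum(s & abs(Ff) > 0.05 & sign(Ff) == sign(Ft))
  }
  expect_gte(hits / total, 0.9)
})

test_that("fit descends and honors the stopping contract", {
  inst <- model_instance(seed = 30, n_per_task = 20L)
  fit <- starmaps_fit(inst$blocks, k = 4, lambda = 0, seed = 30,
                      max_iter = 15, init_iter = 10)
  expect_lte(utils::tail(fit$objective_trace, 1),
             fit$objective_trace[1] * (1 + 1e-9))
  # huge tolerance: stop after one iteration, trace length 2
  f1 <- starmaps_fit(inst$blocks, k = 4, lambda = 1e-3, seed = 30,
                     tol = 1e10, init_iter = 5)
  expect_length(f1$objective_trace, 2L)
  expect_true(f1$converged)
  expect_equal(f1$n_iter, 1L)
})

test_that("fit preserves constraints: simplex rows and joint non-negativity", {
  inst <- model_instance(seed = 31, n_per_task = 25L)
  fit <- starmaps_fit(inst$blocks, k = 4, lambda = 1e-3, seed = 31,
                      max_iter = 20, init_iter = 10)
  for (W in fit$W) {
    expect_true(all(W >= -1e-12))
    expect_lt(max(abs(rowSums(W) - 1)), 1e-8)
  }
  for (j in names(fit$E)) for (r in names(fit$F)) {
    expect_gte(min(fit$H + fit$E[[j]] + fit$F[[r]]), -1e-10)
  }
  expect_true(all(fit$H >= 0))
})

test_that("region perturbation mass shrinks as lambda2 grows", {
  inst <- model_instance(seed = 32)
  l1 <- vapply(c(0, 1e-3, 1e-2), function(lam) {
    fit <- starmaps_fit(inst$blocks, k = 4, lambda1 = 1e-3, lambda2 = lam,
                        seed = 32, max_iter = 40, init_iter = 15)
    sum(vapply(fit$F, function(f) sum(abs(f)), 0))
  }, 0)
  expect_true(all(diff(l1) <= 1e-8))
})

test_that("with one task and no penalty the fit matches a generic NMF solver", {
  truth <- suppressWarnings(simulate_truth(M = 1, R = 1, k = 3, p = 40,
                                           perturb_sparsity = 0, seed = 5))
  ds <- sample_expression(truth, n_per_task = 60, noise_sd = 0.05, seed = 55)
  blocks <- split_by_task(ds)
  fit <- starmaps_fit(blocks, k = 3, lambda = 0, seed = 5, max_iter = 300)
  X <- blocks[[1]]
  res_fit <- sqrt(sum((X - fit$W[[1]] %*% fit$H)^2))
  # oracle: plain multiplicative-update NMF, independent of the fit path
  set.seed(5)
  W <- matrix(runif(60 * 3) + 0.1, 60, 3)
  H <- matrix(runif(3 * 40) + 0.1, 3, 40)
  for (i in 1:2000) {
    H <- H * (t(W) %*% X) / pmax(t(W) %*% W %*% H, 1e-12)
    W <- W * (X %*% t(H)) / pmax(W %*% H %*% t(H), 1e-12)
  }
  res_nmf <- sqrt(sum((X - W %*% H)^2))
  expect_lt(res_fit, res_nmf * 1.05)
})

test_that("reconstruction modes collapse when perturbations vanish and are exact on noiseless data", {
  truth <- suppressWarnings(simulate_truth(M = 1, R = 2, k = 3, p = 20,
                                           perturb_sparsity = 0, seed = 40))
  ds <- sample_expression(truth, n_per_task = 15, noise_sd = 0, seed = 41)
  blocks <- split_by_task(ds)
  W_true <- attr(ds, "W_true")
  model <- manual_model(truth$H_true, truth$E_true, truth$F_true,
                        W_true[attr(blocks, "tasks")$name],
                        attr(blocks, "tasks"))
  full <- reconstruct_expression(model, "full")
  rc <- reconstruct_expression(model, "region_corrected")
  fc <- reconstruct_expression(model, "fully_corrected")
  expect_equal(full, rc)
  expect_equal(full, fc)
  for (key in names(full)) {
    expect_equal(full[[key]], blocks[[key]], ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  expect_error(reconstruct_expression(model, "bogus"))
})

test_that("full correction shrinks between-region mean differences", {
  truth <- suppressWarnings(simulate_truth(M = 1, R = 2, k = 3, p = 30,
                                           perturb_sparsity = 0.15,
                                           perturb_scale = 1.5, seed = 50))
  # batch perturbations off so all difference is regional
  truth$E_true <- lapply(truth$E_true, function(e) e * 0)
  ds <- sample_expression(truth, n_per_task = 40, noise_sd = 0.02, seed = 51)
  fit <- starmaps_fit(split_by_task(ds), k = 3, lambda = 1e-3, seed = 50,
                      max_iter = 100)
  full <- reconstruct_expression(fit, "full")
  fc <- reconstruct_expression(fit, "fully_corrected")
  gap <- function(l) sqrt(sum((colMeans(l[[1]]) - colMeans(l[[2]]))^2))
  expect_lt(gap(fc), gap(full))
})

test_that("cell embedding is simplex-valued, order-faithful and separates archetypes", {
  truth <- suppressWarnings(simulate_truth(M = 2, R = 2, k = 3, p = 40,
                                           perturb_sparsity = 0.02, seed = 60))
  ds <- sample_expression(truth, n_per_task = 25, noise_sd = 0.02,
                          concentration = 25, seed = 61)
  blocks <- split_by_task(ds)
  fit <- starmaps_fit(blocks, k = 3, lambda = 1e-3, seed = 60, max_iter = 60)
  emb <- embed_cells(fit, attr(blocks, "cell_index"))
  expect_equal(rowSums(emb), rep(1, nrow(emb)), tolerance = 1e-8)
  # order round trip: task rows land back at their original indices
  idx <- attr(blocks, "cell_index")
  expect_equal(emb[idx[[2]], ], fit$W[[2]], ignore_attr = TRUE)
  # archetype separation: positive mean silhouette on the truth labels
  arch <- ds$cells$archetype
  d <- as.matrix(dist(emb))
  sil <- vapply(seq_len(nrow(emb)), function(i) {
    a <- mean(d[i, arch == arch[i] & seq_len(nrow(emb)) != i])
    b <- min(vapply(setdiff(unique(arch), arch[i]),
                    function(g) mean(d[i, arch == g]), 0))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)
})

test_that("model serialization round-trips exactly", {
  inst <- model_instance(seed = 70, n_per_task = 10L)
  fit <- starmaps_fit(inst$blocks, k = 3, lambda = 1e-3, seed = 70,
                      max_iter = 5, init_iter = 5)
  dir <- withr::local_tempdir()
  write_starmaps(fit, file.path(dir, "model"))
  back <- read_starmaps(file.path(dir, "model"))
  expect_equal(back$H, fit$H, tolerance = 0)
  expect_equal(back$E, fit$E, tolerance = 0)
  expect_equal(back$F, fit$F, tolerance = 0)
  expect_equal(back$W, fit$W, tolerance = 0, ignore_attr = TRUE)
  expect_equal(back$objective_trace, fit$objective_trace, tolerance = 1e-12)
  expect_identical(back$k, fit$k)
})

test_that("tidy and glance summarize a fit", {
  inst <- model_instance(seed = 71, n_per_task = 8L)
  fit <- starmaps_fit(inst$blocks, k = 2, lambda = 1e-3, seed = 71,
                      max_iter = 3, init_iter = 3)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 60 * (1 + 2 + 3))  # H + 2 E + 3 F, k x p each
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_equal(gl$objective, utils::tail(fit$objective_trace, 1))
})
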