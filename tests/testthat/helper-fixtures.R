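# shared fixtures, built in code at test time

# tiny labelled dataset with a known task grid
tiny_dataset <- function(n_per_task = 5L, p = 8L, batches = c("b1", "b2"),
                         regions = c("rA", "rB"), seed = 42L) {
  set.seed(seed)
  grid <- expand.grid(batch = batches, region = regions,
                      stringsAsFactors = FALSE)
  n <- nrow(grid) * n_per_task
  m <- matrix(rpois(n * p, lambda = 3), n, p)
  cells <- tibble::tibble(
    cell_id = sprintf("cell%03d", seq_len(n)),
    batch = rep(grid$batch, each = n_per_task),
    region = rep(grid$region, each = n_per_task)
  )
  expression_dataset(m, cells, gene_ids = sprintf("g%02d", seq_len(p)))
}

# write an MTX + TSV trio to a temp dir, return the dir
write_mtx_fixture <- function(dataset, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_expression_dataset(dataset, dir)
  dir
}

# standard small model-generated instance used across fit tests
model_instance <- function(seed = 1L, n_per_task = 50L, noise_sd = 0.05, ...) {
  truth <- suppressWarnings(simulate_truth(seed = seed, ...))
  dataset <- sample_expression(truth, n_per_task = n_per_task,
                               noise_sd = noise_sd, seed = seed + 1000L)
  list(truth = truth, dataset = dataset, blocks = split_by_task(dataset))
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration
# (independent oracle; sums the probabilities of all tables with the same
# margins that are no more likely than the observed one)
fisher_enumeration_p <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12
  c1 <- n11 + n21
  n <- n11 + n12 + n21 + n22
  lo <- max(0L, c1 - (n - r1))
  hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- dhyper(n11, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# normal upper-tail probability by quadrature, independent of pnorm's
# algorithm (integrates the density formula directly)
normal_tail_oracle <- function(z) {
  stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi), z, Inf,
                   rel.tol = 1e-13, abs.tol = 1e-16)$value
}
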