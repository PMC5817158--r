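# Shared test helpers: random strictly-positive compositions and a tiny
# reference logistic-normal setup used across files.

random_comp_set <- function(n, parts = c("P", "C", "L"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rgamma(n * length(parts), shape = 2), n)
  m <- m / rowSums(m)
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- parts
  out
}

ref_mean <- function() tibble::tibble(P = 0.35, C = 0.33, L = 0.32)

ref_cov <- function(scale = 0.1) scale * diag(2)

expect_valid_composition <- function(data, parts = c("P", "C", "L"), tol = 1e-9) {
  m <- as.matrix(data[parts])
  expect_true(all(m > 0))
  expect_true(max(abs(rowSums(m) - 1)) < tol)
}
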