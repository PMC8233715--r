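# small grids and datasets used across test files

tiny_grid <- function(n = 21, start = 1000, step = 10)
  wl_grid(start, step, n)

# spectra matrix with known latent structure: y is linear in one spectral
# direction plus optional noise
latent_fixture <- function(n = 30, p = 15, rank = 2, noise = 0, seed = 42) {
  set.seed(seed)
  scores <- matrix(rnorm(n * rank), n, rank)
  load <- matrix(rnorm(rank * p), rank, p)
  X <- scores %*% load + noise * matrix(rnorm(n * p), n, p)
  y <- scores %*% seq_len(rank) + noise * rnorm(n)
  list(X = X, y = as.vector(y), scores = scores)
}

small_sim <- function(n = 40, seed = 7, ...)
  sim_config(n_samples = n, seed = seed, ...)
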