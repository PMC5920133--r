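# Shared fixture builders for the test suite.

# Variables-by-samples omics_matrix of i.i.d. standard normal values.
noise_layer <- function(n_vars, n_samples, layer = "metabolite", seed = NULL,
                        prefix = substr(layer, 1, 1)) {
  if (!is.null(seed)) set.seed(seed)
  omics_matrix(matrix(rnorm(n_vars * n_samples), n_vars, n_samples,
                      dimnames = list(sprintf("%s%03d", prefix,
                                              seq_len(n_vars)),
                                      sprintf("s%03d", seq_len(n_samples)))),
               layer = layer)
}

# n x k data matrix whose columns have EXACT sample correlation matrix S:
# orthonormal centered basis times the Cholesky factor of S.
exact_cor_data <- function(n, S, seed = 1) {
  set.seed(seed)
  k <- nrow(S)
  X <- scale(matrix(rnorm(n * (k + 1)), n, k + 1), scale = FALSE)
  Q <- qr.Q(qr(X))[, seq_len(k), drop = FALSE]
  Q %*% chol(S)
}

# Transcript layer with a planted low-rank latent structure; returns the
# factor matrix alongside so tests can control on the true factors.
latent_transcripts <- function(n_vars, n_samples, n_factors = 3,
                               loading_scale = 1, noise_sd = 0.4, seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(n_factors * n_samples), n_factors, n_samples)
  l <- matrix(rnorm(n_vars * n_factors, sd = loading_scale), n_vars, n_factors)
  vals <- l %*% f + matrix(rnorm(n_vars * n_samples, sd = noise_sd),
                           n_vars, n_samples)
  dimnames(vals) <- list(sprintf("t%04d", seq_len(n_vars)),
                         sprintf("s%03d", seq_len(n_samples)))
  list(layer = omics_matrix(vals, layer = "transcript"), factors = f)
}

# Small matched dataset of independent layers.
small_dataset <- function(n_metabolites = 8, n_transcripts = 40,
                          n_samples = 30, seed = 1) {
  set.seed(seed)
  align_samples(noise_layer(n_transcripts, n_samples, "transcript"),
                noise_layer(n_metabolites, n_samples, "metabolite"),
                min_samples = 3)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
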