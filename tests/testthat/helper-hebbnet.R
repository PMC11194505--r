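# shared helpers for the test suite

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# small linear single-neuron setup used in several dynamics tests
linear_act <- activation_params(a = 1, b = 0, n = 1)

# a tiny stable random weight set for steady-state tests (spectral radius
# of the signed recurrent matrix kept well below 1)
tiny_stable_weights <- function(seed = 42, NE = 3, NI = 2, NF = 4) {
  set.seed(seed)
  dims <- network_dims(NE, NI, NF)
  weight_set(dims,
             W_EE = matrix(runif(NE * NE, 0, 0.1), NE),
             W_EI = matrix(runif(NE * NI, 0, 0.1), NE),
             W_EF = matrix(runif(NE * NF, 0, 0.5), NE),
             W_IE = matrix(runif(NI * NE, 0, 0.1), NI),
             W_II = matrix(runif(NI * NI, 0, 0.1), NI),
             W_IF = matrix(runif(NI * NF, 0, 0.5), NI))
}

# ascending coefficients of det(lambda I - M) via the Faddeev-LeVerrier
# recursion: an eigenvalue oracle independent of eigen()
charpoly_coefs <- function(M) {
  n <- nrow(M)
  coefs <- numeric(n + 1)
  coefs[n + 1] <- 1
  N <- diag(n)
  for (k in seq_len(n)) {
    N <- M %*% N
    ck <- -sum(diag(N)) / k
    coefs[n + 1 - k] <- ck
    N <- N + ck * diag(n)
  }
  coefs
}

# environment for caching expensive trained fits across test files
.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(key, builder) {
  if (is.null(.fit_cache[[key]])) .fit_cache[[key]] <- builder()
  .fit_cache[[key]]
}
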