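## Shared fixtures and independent oracles, built in code at test time.

## Random gamete at linkage equilibrium (complex-normal, unit mode variances).
random_gamete <- function(K) {
  x <- stats::rnorm(K + 1, sd = sqrt(0.5)) + 1i * stats::rnorm(K + 1, sd = sqrt(0.5))
  x[1] <- stats::rnorm(1) + 0i
  x
}

## Grid-masking oracle for the recombination operator: sample both parents on
## an L-point angular grid, mask with the two half-circle indicator functions
## at a crossover angle on a grid point (trapezoid value 1/2 at the two jump
## samples, the quadrature convention for a discontinuous integrand), and
## transform back. Entirely independent of the odd-harmonic coefficient
## formula used by recombine().
grid_recombine_oracle <- function(X, Xp, shift_index, L = 65536L) {
  K <- length(X) - 1L
  sample_profile <- function(X) {
    S <- complex(L)
    S[1] <- X[1]
    S[2:(K + 1)] <- X[-1]
    S[L - (1:K) + 1] <- Conj(X[-1])
    Re(stats::fft(S, inverse = TRUE))
  }
  x <- sample_profile(X); xp <- sample_profile(Xp)
  frac <- ((seq_len(L) - 1L) - shift_index) %% L
  H <- ifelse(frac >= 1L & frac <= L / 2L - 1L, 1,
              ifelse(frac == 0L | frac == L / 2L, 0.5, 0))
  y <- x * H + xp * (1 - H)
  (stats::fft(y) / L)[1:(K + 1)]
}

## Deterministic recursion runs shared between acceptance tests (computed
## once per session).
.run_cache <- new.env(parent = emptyenv())
cached_recursion <- function(cutoff, generations) {
  key <- paste0("N", cutoff, "G", generations)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- suppressWarnings(
      iterate_recursion(model_params(cutoff = cutoff, generations = generations)))
  }
  .run_cache[[key]]
}

## Mode-truncated projection recursion: the deterministic counterpart of a
## simulator that stores modes 0..K only (absent modes carry no variance,
## i.e. deficit 1 beyond K). Kernel carried out to half-width J.
truncated_projection_sigma2 <- function(K, generations, J = 20001L) {
  kern <- build_kernel(J)
  ones <- rep(1, J)
  cdef <- numeric(K + 1L)
  out <- numeric(generations)
  for (g in seq_len(generations)) {
    cdef[1] <- 1
    cdef <- convolve_direct(cdef, kern, tail = ones)
    out[g] <- 1 - cdef[1]
  }
  out
}
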