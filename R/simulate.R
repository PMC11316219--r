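#' Configuration of the Monte-Carlo gamete simulator
#'
#' The forward simulator follows a finite population of P gametes, each
#' represented by its truncated Fourier coefficients X_0..X_K, through cycles
#' of exact-value selection and two-crossover recombination. It is a
#' validation instrument for the deterministic recursion: finite P and the
#' two truncations are explicit approximations, so replicate counts and
#' standard errors are first-class.
#'
#' @param population_size Number of gametes P (>= 2).
#' @param mode_cutoff Largest Fourier mode stored, K.
#' @param recomb_truncation Largest odd step-function harmonic retained in the
#'   recombination operator, J_r (odd). Recombination mixes mode k with modes
#'   k +/- j, so J_r >> K reduces truncation bias at small k.
#' @param beta Selection intensity.
#' @param selection_window Window half-width epsilon (in units of sigma) for
#'   the selection step; `0` (the default) applies hard conditioning, i.e.
#'   every gamete's X_0 is overwritten with mu + beta*sigma.
#' @param generations Number of selection-recombination cycles.
#' @param seed Base RNG seed.
#' @param replicates Number of independent replicate populations.
#' @return A `sim_config` list.
#' @export
sim_config <- function(population_size, mode_cutoff = 128L,
                       recomb_truncation = 1023L, beta = 1,
                       selection_window = 0, generations = 1L,
                       seed = 1L, replicates = 1L) {
  population_size <- as.integer(population_size)
  if (population_size < 2L) stop("population_size must be >= 2")
  recomb_truncation <- as.integer(recomb_truncation)
  if (recomb_truncation %% 2L != 1L) stop("recomb_truncation must be odd")
  if (selection_window < 0) stop("selection_window must be >= 0")
  if (as.integer(generations) < 1L) stop("generations must be >= 1")
  if (as.integer(replicates) < 1L) stop("replicates must be >= 1")
  structure(
    list(population_size = population_size,
         mode_cutoff = as.integer(mode_cutoff),
         recomb_truncation = recomb_truncation, beta = beta,
         selection_window = selection_window,
         generations = as.integer(generations),
         seed = as.integer(seed), replicates = as.integer(replicates)),
    class = "sim_config")
}

new_population <- function(coeffs, generation) {
  g <- Re(coeffs[1L, ])
  structure(
    list(coeffs = coeffs, generation = as.integer(generation),
         mean_G = mean(g), var_G = stats::var(g)),
    class = "gamete_population")
}

#' @export
print.gamete_population <- function(x, ...) {
  cat("Gamete population: P =", ncol(x$coeffs), " K =", nrow(x$coeffs) - 1L,
      " g =", x$generation,
      " mean G =", format(x$mean_G, digits = 6),
      " Var G =", format(x$var_G, digits = 6), "\n")
  invisible(x)
}

#' Draw an initial population at linkage equilibrium
#'
#' Each gamete is drawn independently from the rotation-invariant complex
#' normal of the equilibrium population: X_0 real Gaussian with mean 0 and
#' variance 1; for k >= 1 the real and imaginary parts are independent
#' Gaussians of variance 1/2 each, so the complex variance E|X_k|^2 is 1 and
#' the pseudo-variance E[X_k^2] vanishes.
#'
#' @param config A `sim_config`.
#' @param seed Seed applied before drawing (default `config$seed`); pass
#'   `NULL` to use the current RNG stream.
#' @return A `gamete_population`.
#' @export
init_population <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  P <- config$population_size; K <- config$mode_cutoff
  n <- (K + 1L) * P
  co <- matrix(stats::rnorm(n, sd = sqrt(0.5)) +
                 1i * stats::rnorm(n, sd = sqrt(0.5)),
               nrow = K + 1L, ncol = P)
  co[1L, ] <- stats::rnorm(P) + 0i
  new_population(co, 0L)
}

#' Genetic value of a gamete
#'
#' In the Fourier normalization the genetic value G (the integral of the
#' allelic profile) is the mode-0 coefficient, which is real.
#'
#' @param gamete A complex coefficient vector X_0..X_K, or a
#'   `gamete_population` (then a vector of values is returned).
#' @return G, i.e. Re(X_0).
#' @export
genetic_value <- function(gamete) {
  if (inherits(gamete, "gamete_population")) return(Re(gamete$coeffs[1L, ]))
  Re(gamete[1L])
}

#' Selection phase of the simulator
#'
#' Computes mu and sigma from the current population and selects at the
#' threshold mu + beta*sigma. With `epsilon = 0` (hard conditioning) every
#' gamete is kept and its X_0 overwritten with the threshold value — valid
#' under the complex-normal projection, where X_0 is independent of the other
#' modes — so the post-selection Var(G) is exactly 0. With `epsilon > 0`,
#' gametes with |G - (mu + beta*sigma)| <= epsilon*sigma are retained (an
#' error is signalled if fewer than 2 fall in the window); this mode probes
#' whether hard conditioning distorts the true mixture population.
#'
#' @param pop A `gamete_population` with positive Var(G).
#' @param beta Selection intensity (>= 0).
#' @param epsilon Window half-width in units of sigma (>= 0).
#' @return The selected `gamete_population` (same generation).
#' @export
select_gametes <- function(pop, beta, epsilon = 0) {
  if (!(pop$var_G > 0)) stop("population Var(G) must be positive for selection")
  mu <- pop$mean_G; sig <- sqrt(pop$var_G)
  threshold <- mu + beta * sig
  co <- pop$coeffs
  if (epsilon == 0) {
    co[1L, ] <- complex(real = threshold, imaginary = 0)
  } else {
    keep <- abs(Re(co[1L, ]) - threshold) <= epsilon * sig
    if (sum(keep) < 2L) stop("empty selection window: fewer than 2 gametes retained")
    co <- co[, keep, drop = FALSE]
  }
  p <- new_population(co, pop$generation)
  if (epsilon == 0) p$var_G <- 0
  p
}

## Odd-harmonic Fourier coefficients of the periodic step function:
## h_j = -i/(pi j) for odd j, h_0 = 1/2, h_j = 0 for even j != 0.
step_fourier_coef <- function(j) {
  out <- rep(0 + 0i, length(j))
  odd <- j %% 2 != 0
  out[odd] <- -1i / (pi * j[odd])
  out[j == 0] <- 0.5 + 0i
  out
}

#' Two-crossover recombination of a pair of gametes
#'
#' The child inherits x(theta) on the half-circle [psi, psi + pi) from the
#' first parent and x'(theta) on the complementary half from the second
#' (two diametrically opposed crossovers). In Fourier space,
#' Y_k = (X_k + X'_k)/2 + sum over odd j, |j| <= J_r, of
#' (-i/(pi j)) e^{-i j psi} (X_{k-j} - X'_{k-j}), with X_{-m} the conjugate
#' of X_m: the masking multiplies by the periodic step function, whose only
#' non-zero harmonics are h_0 = 1/2 and h_j = -i/(pi j) at odd j.
#'
#' @param parent1,parent2 Complex coefficient vectors X_0..X_K.
#' @param psi Crossover angle in [0, 2*pi).
#' @param recomb_truncation Largest odd harmonic retained, J_r (odd).
#' @return The child's coefficient vector Y_0..Y_K.
#' @export
recombine <- function(parent1, parent2, psi, recomb_truncation = 1023L) {
  J_r <- as.integer(recomb_truncation)
  if (J_r %% 2L != 1L) stop("recomb_truncation must be odd")
  K <- length(parent1) - 1L
  stopifnot(length(parent2) == length(parent1))
  dif <- parent1 - parent2
  D <- c(Conj(rev(dif[-1L])), dif)              # m = -K .. K
  jmat <- outer(0:K, (-K):K, "-")               # j = k - m
  sel <- (jmat %% 2 != 0) & (abs(jmat) <= J_r)
  W <- matrix(0 + 0i, K + 1L, 2L * K + 1L)
  W[sel] <- (-1i / (pi * jmat[sel])) * exp(-1i * jmat[sel] * psi)
  Y <- (parent1 + parent2) / 2 + drop(W %*% D)
  Y[1L] <- complex(real = Re(Y[1L]), imaginary = 0)
  Y
}

#' Advance the population by one generation
#'
#' Produces P children by panmictic mating of the (already selected)
#' population: each child's two parents are drawn uniformly with replacement
#' but forced distinct, and its crossover angle psi is drawn uniformly on
#' [0, 2*pi). The batched recombination operator runs in compiled code and
#' is exact (it applies the same odd-harmonic coefficient formula as
#' [recombine()]).
#'
#' @param pop The selected `gamete_population`.
#' @param config A `sim_config`.
#' @return The offspring `gamete_population` (generation incremented).
#' @export
advance_generation <- function(pop, config) {
  P <- config$population_size
  np <- ncol(pop$coeffs)
  if (np < 2L) stop("need at least 2 selected gametes to mate")
  p1 <- sample.int(np, P, replace = TRUE)
  p2 <- sample.int(np - 1L, P, replace = TRUE)
  p2 <- ifelse(p2 >= p1, p2 + 1L, p2)          # distinct from p1
  psi <- stats::runif(P, 0, 2 * pi)
  co <- cpp_next_generation(pop$coeffs, p1 - 1L, p2 - 1L, psi,
                            config$recomb_truncation)
  new_population(co, pop$generation + 1L)
}

#' Empirical variance spectrum of a population
#'
#' Per-mode empirical complex variance E|X_k|^2 - |E X_k|^2, with a
#' diagnostic of the diagonality claim: the magnitudes of empirical
#' covariances Cov(X_k, X_k') for a sample of mode pairs (under rotation
#' invariance the population covariance matrix is diagonal).
#'
#' @param pop A `gamete_population` with at least 100 gametes.
#' @param n_offdiag Number of random mode pairs in the diagnostic.
#' @return A list with `spectrum` (data.frame `k`, `emp_variance`) and
#'   `offdiag` (data.frame `k1`, `k2`, `cov_magnitude`).
#' @export
estimate_spectrum <- function(pop, n_offdiag = 50L) {
  co <- pop$coeffs
  if (ncol(co) < 100L) stop("need at least 100 gametes")
  K <- nrow(co) - 1L
  m <- rowMeans(co)
  v <- rowMeans(Mod(co)^2) - Mod(m)^2
  pairs <- cbind(sample.int(K + 1L, n_offdiag, replace = TRUE),
                 sample.int(K + 1L, n_offdiag, replace = TRUE))
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  cv <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    Mod(mean(co[a, ] * Conj(co[b, ])) - m[a] * Conj(m[b]))
  }, numeric(1))
  list(spectrum = data.frame(k = 0:K, emp_variance = v),
       offdiag = data.frame(k1 = pairs[, 1L] - 1L, k2 = pairs[, 2L] - 1L,
                            cov_magnitude = cv))
}

#' Run the forward simulation across replicates
#'
#' For each replicate, initializes a population from a replicate-specific
#' seed and iterates selection + recombination, recording the empirical
#' mean and variance of G and the per-mode empirical variances at every
#' generation. Replicates are aggregated into means and standard errors.
#'
#' @param config A `sim_config`.
#' @return An object of class `sim_result`: list with `trajectory` (columns
#'   `generation`, `sigma2_0`, `sigma_0`, `mu`, `total_deficit`,
#'   `injected_mass`, aggregated over replicates), `spectrum` (columns
#'   `generation`, `k`, `emp_variance`, `std_err`), `config`, and
#'   `replicate_sigma2_0` (replicate-by-generation matrix of mode-0
#'   variances).
#' @export
run_simulation <- function(config) {
  G <- config$generations; R <- config$replicates
  K <- config$mode_cutoff
  var0 <- matrix(NA_real_, R, G)
  meanG <- matrix(NA_real_, R, G)
  inj <- matrix(NA_real_, R, G)
  specs <- array(NA_real_, c(R, G, K + 1L))
  for (r in seq_len(R)) {
    set.seed((config$seed + 7919L * (r - 1L)) %% .Machine$integer.max)
    pop <- init_population(config, seed = NULL)
    for (g in seq_len(G)) {
      inj[r, g] <- pop$var_G
      selpop <- select_gametes(pop, config$beta, config$selection_window)
      pop <- advance_generation(selpop, config)
      var0[r, g] <- pop$var_G
      meanG[r, g] <- pop$mean_G
      m <- rowMeans(pop$coeffs)
      specs[r, g, ] <- rowMeans(Mod(pop$coeffs)^2) - Mod(m)^2
    }
  }
  emp <- apply(specs, c(2, 3), mean)
  se <- apply(specs, c(2, 3), stats::sd) / sqrt(R)
  if (R == 1L) se[] <- NA_real_
  spectrum <- data.frame(
    generation = rep(seq_len(G), each = K + 1L),
    k = rep(0:K, times = G),
    emp_variance = as.vector(t(emp)),
    std_err = as.vector(t(se)))
  total_deficit <- (1 - emp[, 1L]) + 2 * rowSums(1 - emp[, -1L, drop = FALSE])
  trajectory <- data.frame(
    generation = seq_len(G),
    sigma2_0 = colMeans(var0),
    sigma_0 = sqrt(pmax(colMeans(var0), 0)),
    mu = colMeans(meanG),
    total_deficit = total_deficit,
    injected_mass = colMeans(inj))
  structure(list(trajectory = trajectory, spectrum = spectrum,
                 config = config, replicate_sigma2_0 = var0),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  tr <- x$trajectory
  cat("Forward simulation: P =", x$config$population_size,
      " K =", x$config$mode_cutoff,
      " replicates =", x$config$replicates, "\n")
  cat("  mode-0 variance by generation:",
      paste(format(tr$sigma2_0, digits = 4), collapse = " "), "\n")
  invisible(x)
}
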