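#' Finite-M multi-Gaussian loci model (no linkage)
#'
#' The classical no-linkage infinitesimal model at finite M: the M allelic
#' effects are jointly Gaussian; initially i.i.d. with mean 0 and variance
#' 1/M, so the genetic value G = sum(x_m) has unit variance for every M.
#'
#' @param num_loci Number of loci M (>= 2).
#' @param mean Optional mean vector (default zeros).
#' @param covariance Optional covariance matrix (default identity/M).
#' @return An object of class `loci_model`.
#' @export
loci_model <- function(num_loci, mean = NULL, covariance = NULL) {
  M <- as.integer(num_loci)
  if (M < 2L) stop("num_loci must be >= 2")
  if (is.null(mean)) mean <- numeric(M)
  if (is.null(covariance)) covariance <- diag(1 / M, M)
  stopifnot(length(mean) == M, all(dim(covariance) == c(M, M)))
  structure(list(num_loci = M, locus_variance = 1 / M,
                 mean = mean, covariance = covariance),
            class = "loci_model")
}

#' Variance of the genetic value G = sum(x_m)
#' @param model A `loci_model`.
#' @return sum of the covariance matrix.
#' @export
genetic_variance <- function(model) sum(model$covariance)

#' Condition the loci model on its sum (exact-value selection)
#'
#' Exact linear-Gaussian conditioning of the M-variate normal on
#' sum(x_m) = target. Means shift by Cov(x_i, S)/Var(S) * (target - E[S]);
#' the covariance loses the rank-one term. For the initial model this yields
#' per-locus variance 1/M - 1/M^2 and off-diagonal covariance -1/M^2 exactly
#' (the Bulmer covariances; in units of the 1/M locus variance these read
#' 1 - 1/M and -1/M), and Var(G) = 0 after selection.
#'
#' Conditioning twice on the same sum is a no-op (idempotent); conditioning a
#' degenerate model on a different sum is an error.
#'
#' @param model A `loci_model`.
#' @param target The imposed value of the sum (e.g. mu + beta * sigma).
#' @return The conditioned `loci_model`.
#' @export
condition_on_sum <- function(model, target) {
  C <- model$covariance
  s <- sum(C)
  es <- sum(model$mean)
  if (s <= 1e-12) {
    if (abs(target - es) <= 1e-8) return(model)
    stop("degenerate Var(S): cannot condition on a different sum")
  }
  cvec <- rowSums(C)
  model$mean <- model$mean + cvec * (target - es) / s
  model$covariance <- C - tcrossprod(cvec) / s
  model
}

#' Variance of a transmitted half-sum
#'
#' Variance of the sum of the allelic effects over a subset of M/2 loci (the
#' alleles one gamete transmits). For the conditioned initial model this is
#' exactly 1/4 for every even M and every subset: the -1/(2M) diagonal and
#' +1/(2M) off-diagonal corrections cancel identically.
#'
#' @param model A `loci_model` with even M.
#' @param subset Indices of the transmitted loci (default the first M/2;
#'   for exchangeable models the value is subset-independent).
#' @return The half-sum variance.
#' @export
half_sum_variance <- function(model, subset = NULL) {
  M <- model$num_loci
  if (M %% 2L != 0L) stop("num_loci must be even")
  if (is.null(subset)) subset <- seq_len(M / 2L)
  if (length(subset) != M / 2L) stop("subset must contain M/2 loci")
  sum(model$covariance[subset, subset])
}

#' Released genetic variance after random assortment
#'
#' Variance of G in an offspring built from two independent selected gametes:
#' each parent contributes an independent half-sum, so the released variance
#' is the sum of the two half-sum variances — exactly 1/2 for the conditioned
#' initial model (to be compared with 0 right after selection).
#'
#' @param model A `loci_model` conditioned on its sum.
#' @return The offspring Var(G).
#' @export
released_variance <- function(model) {
  M <- model$num_loci
  if (M %% 2L != 0L) stop("num_loci must be even")
  h1 <- seq_len(M / 2L)
  half_sum_variance(model, h1) + half_sum_variance(model, setdiff(seq_len(M), h1))
}

#' Offspring loci model from two independent parents
#'
#' The recombined gamete takes the loci in `subset` from one conditioned
#' parent and the complementary loci from an independent second parent,
#' giving a block covariance (the two blocks are independent). Used to
#' iterate the no-linkage cycle at finite M.
#'
#' @param model1,model2 Conditioned `loci_model`s (independent parents).
#' @param subset Loci transmitted by the first parent (default the first
#'   M/2; pass a random subset to emulate random assortment).
#' @return A `loci_model` for the offspring gamete.
#' @export
offspring_model <- function(model1, model2 = model1, subset = NULL) {
  M <- model1$num_loci
  if (M %% 2L != 0L) stop("num_loci must be even")
  if (is.null(subset)) subset <- seq_len(M / 2L)
  if (length(subset) != M / 2L) stop("subset must contain M/2 loci")
  h2 <- setdiff(seq_len(M), subset)
  C <- matrix(0, M, M)
  C[subset, subset] <- model1$covariance[subset, subset]
  C[h2, h2] <- model2$covariance[h2, h2]
  mn <- numeric(M)
  mn[subset] <- model1$mean[subset]
  mn[h2] <- model2$mean[h2]
  loci_model(M, mean = mn, covariance = C)
}

#' No-linkage steady-state summary
#'
#' In the no-linkage model the cycle reaches its steady state in one
#' generation: selection sets Var(G) to 0 and random assortment restores a
#' variance of 1/2 at every subsequent generation. The per-generation gain is
#' beta * sqrt(1/2) under the literal `"std_dev"` mean recursion, or
#' beta * 1/2 under the `"variance"` reading; the cumulative gain is linear
#' in g either way. Both readings are reported because the printed
#' steady-state gain in the source material is ambiguous between them.
#'
#' @param beta Selection intensity (>= 0).
#' @param gain_rule `"std_dev"` or `"variance"`.
#' @return A list with `steady_state_variance`, `gain_per_generation` (under
#'   the chosen rule), `gain_rule`, and both candidate gains.
#' @export
steady_state_summary <- function(beta, gain_rule = c("std_dev", "variance")) {
  gain_rule <- match.arg(gain_rule)
  if (beta < 0) stop("beta must be >= 0")
  v <- 0.5
  gains <- c(std_dev = beta * sqrt(v), variance = beta * v)
  list(steady_state_variance = v,
       gain_per_generation = unname(gains[gain_rule]),
       gain_rule = gain_rule,
       gain_std_dev_rule = unname(gains["std_dev"]),
       gain_variance_rule = unname(gains["variance"]),
       cumulative_gain = function(g) unname(gains[gain_rule]) * g)
}

#' Monte-Carlo check of the released variance
#'
#' Samples gametes from the conditioned multi-Gaussian model, recombines them
#' in random pairs with a fresh random half-subset per offspring, and returns
#' the empirical Var(G) of the offspring (expected 1/2) with its standard
#' error.
#'
#' @param model A conditioned `loci_model` with even M.
#' @param n Number of offspring to generate.
#' @return A list with `var_g`, `std_err` and `n`.
#' @export
sample_released_variance <- function(model, n = 1e5) {
  M <- model$num_loci
  if (M %% 2L != 0L) stop("num_loci must be even")
  half <- M / 2L
  X1 <- MASS::mvrnorm(n, model$mean, model$covariance)
  X2 <- MASS::mvrnorm(n, model$mean, model$covariance)
  ## per offspring, a uniformly chosen subset of M/2 loci comes from parent 1
  S <- vapply(seq_len(n), function(i) sample.int(M, half), integer(half))
  D <- X1 - X2
  picked <- matrix(D[cbind(rep(seq_len(n), each = half), as.vector(S))],
                   nrow = half)
  G <- rowSums(X2) + colSums(picked)
  v <- stats::var(G)
  list(var_g = v, std_err = v * sqrt(2 / (n - 1)), n = n)
}
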