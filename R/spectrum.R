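#' Initial variance spectrum (linkage equilibrium)
#'
#' The state of the deterministic recursion is the per-mode complex variance
#' sigma^2_k at generation g, stored as the deficit c_k = 1 - sigma^2_k for
#' 0 <= k <= N. At linkage equilibrium (generation 0) all variances are 1, so
#' all deficits vanish. Negative modes are resolved by mirroring
#' (sigma^2_{-k} = sigma^2_k); the boundary condition is sigma^2_k -> 1
#' (c_k -> 0) as |k| -> infinity.
#'
#' @param cutoff Mode cutoff N (>= 8): deficits are stored for 0 <= k <= N.
#' @return An object of class `variance_spectrum` with fields `cutoff`,
#'   `deficit` (length N+1), `generation`, `tail_exponent`, `tail_amplitude`.
#' @export
initial_spectrum <- function(cutoff) {
  cutoff <- as.integer(cutoff)
  if (cutoff < 8L) stop("cutoff must be >= 8")
  structure(
    list(cutoff = cutoff, deficit = numeric(cutoff + 1L), generation = 0L,
         tail_exponent = 2, tail_amplitude = 0),
    class = "variance_spectrum")
}

#' Construct a variance spectrum from a deficit array
#'
#' @param deficit Numeric vector c_k for k = 0..N, values in [0, 1].
#' @param generation Generation label (non-negative integer).
#' @param tail_exponent,tail_amplitude Power-law tail model c_k ~ a k^-p used
#'   beyond the cutoff (recorded by [diffuse()]).
#' @return A `variance_spectrum`.
#' @export
variance_spectrum <- function(deficit, generation = 0L,
                              tail_exponent = 2, tail_amplitude = 0) {
  if (any(!is.finite(deficit)) || any(deficit < -1e-10) || any(deficit > 1 + 1e-10))
    stop("deficit values must be finite and within [0, 1]")
  if (length(deficit) < 9L) stop("cutoff must be >= 8")
  structure(
    list(cutoff = length(deficit) - 1L, deficit = as.numeric(deficit),
         generation = as.integer(generation),
         tail_exponent = tail_exponent, tail_amplitude = tail_amplitude),
    class = "variance_spectrum")
}

#' Per-mode variances of a spectrum
#' @param state A `variance_spectrum`.
#' @return Numeric vector sigma^2_k for k = 0..N.
#' @export
mode_variances <- function(state) 1 - state$deficit

#' @export
print.variance_spectrum <- function(x, ...) {
  cat("Variance spectrum: N =", x$cutoff, " g =", x$generation,
      " sigma2_0 =", format(1 - x$deficit[1], digits = 8),
      " total deficit =", format(x$deficit[1] + 2 * sum(x$deficit[-1]), digits = 8), "\n")
  invisible(x)
}

#' Selection phase: reset the genetic-value mode
#'
#' Selecting gametes at an exact genetic value collapses the distribution of
#' the k = 0 Fourier coefficient: sigma^2_0 is set to 0 (deficit c_0 = 1),
#' all other modes are untouched. The pre-reset sigma^2_0 is returned so the
#' caller can log the injected matter and update the mean via the gain rule.
#'
#' @param state A `variance_spectrum`.
#' @return A list with `state` (the reset spectrum) and `sigma2_0` (the
#'   pre-reset mode-0 variance, which equals the matter injected at k = 0).
#' @export
selection_reset <- function(state) {
  stopifnot(inherits(state, "variance_spectrum"))
  sigma2_0 <- 1 - state$deficit[1]
  state$deficit[1] <- 1
  list(state = state, sigma2_0 = sigma2_0)
}

#' Model parameters for the recursion
#'
#' @param beta Selection intensity: gametes are selected at genetic value
#'   mu + beta * sigma. Affects only the mean trajectory, not the variances.
#' @param cutoff Mode cutoff N (>= 8).
#' @param generations Number of cycles to iterate, G_max (>= 1).
#' @param gain_rule `"std_dev"` for the literal mean recursion
#'   mu' = mu + beta * sigma_0 (the default), or `"variance"` for
#'   mu' = mu + beta * sigma^2_0 (the alternative reading of the printed
#'   no-linkage steady-state gain).
#' @param conv_method `"fft"` (zero-padded linear convolution, default) or
#'   `"direct"` (literal O(N J) sum; reference oracle).
#' @param kernel_half_width Largest odd kernel offset J; default
#'   `cutoff + tail_extent`, so that every beyond-kernel source index for a
#'   retained mode lies in the analytic-tail region.
#' @param tail_extent Number of modes beyond the cutoff closed by the
#'   power-law tail model; default `cutoff`.
#' @param snapshots If `TRUE`, [iterate_recursion()] stores full deficit
#'   spectra at generations that are powers of 2.
#' @return A `model_params` list.
#' @export
model_params <- function(beta = 1, cutoff = 1024L, generations = 256L,
                         gain_rule = c("std_dev", "variance"),
                         conv_method = c("fft", "direct"),
                         kernel_half_width = NULL, tail_extent = NULL,
                         snapshots = FALSE) {
  gain_rule <- match.arg(gain_rule)
  conv_method <- match.arg(conv_method)
  cutoff <- as.integer(cutoff); generations <- as.integer(generations)
  if (is.na(beta) || beta < 0) stop("beta must be >= 0")
  if (cutoff < 8L) stop("cutoff must be >= 8")
  if (generations < 1L) stop("generations must be >= 1")
  if (is.null(tail_extent)) tail_extent <- cutoff
  tail_extent <- as.integer(tail_extent)
  if (tail_extent < 1L) stop("tail_extent must be >= 1")
  if (is.null(kernel_half_width)) kernel_half_width <- cutoff + tail_extent
  kernel_half_width <- as.integer(kernel_half_width)
  if (kernel_half_width < 1L) stop("kernel_half_width must be >= 1")
  structure(
    list(beta = beta, cutoff = cutoff, generations = generations,
         gain_rule = gain_rule, conv_method = conv_method,
         kernel_half_width = kernel_half_width, tail_extent = tail_extent,
         snapshots = snapshots),
    class = "model_params")
}

## Power-law fit of the deficit tail on the top 20% of retained modes.
## Returns list(a, p) or NULL when the window is numerically empty.
tail_fit <- function(state) {
  N <- state$cutoff
  if (N + 1L < 16L) stop("state must have at least 16 modes")
  kw <- seq.int(ceiling(0.8 * N), N)
  cw <- state$deficit[kw + 1L]
  ok <- cw > 1e-14
  if (sum(ok) < 8L) return(NULL)
  x <- log(kw[ok]); y <- log(cw[ok])
  mx <- mean(x)
  slope <- sum((x - mx) * y) / sum((x - mx)^2)
  p <- min(4, max(1, -slope))
  la <- mean(y + p * x)
  if (!is.finite(p) || !is.finite(la)) stop("non-finite tail fit")
  list(a = exp(la), p = p)
}

#' Analytic tail closure beyond the cutoff
#'
#' The recursion couples every mode to arbitrarily distant modes, so the
#' deficits beyond the cutoff N are replaced by a power law c_k = a k^-p
#' matched to the retained values: (a, p) are fit by log-log least squares on
#' the window k in [0.8 N, N], with p clamped to [1, 4]. If the window is
#' numerically empty (all values below 1e-14) the extension is zero.
#'
#' @param state A `variance_spectrum` with at least 16 modes.
#' @param extent Number of modes to extrapolate (>= 1).
#' @return Numeric vector of deficit estimates for k = N+1 .. N+extent.
#' @export
tail_closure <- function(state, extent) {
  extent <- as.integer(extent)
  if (extent < 1L) stop("extent must be >= 1")
  fit <- tail_fit(state)
  if (is.null(fit)) return(numeric(extent))
  k <- seq.int(state$cutoff + 1L, state$cutoff + extent)
  pmin(fit$a * k^(-fit$p), 1)
}

## Shared literal definition of one diffusion application on the deficits:
## out_k = retention * e(k) + sum_{odd j <= J} w_j (e(k+j) + e(k-j)) + residual_value,
## where e(m) = deficit[|m|] for |m| <= N and tail[|m| - N] beyond.
## `tail` must have length >= kernel$half_width.

#' Direct (reference) convolution of a deficit array with the kernel
#'
#' Literal O(N J) evaluation of the diffusion sum with mirroring and tail
#' closure; this is, term for term, the definition that the FFT path must
#' reproduce, and serves as its oracle in tests.
#'
#' @param deficit Deficit array c_k, k = 0..N (already selection-reset when
#'   used inside a cycle).
#' @param kernel A `kernel_spec`.
#' @param tail Deficit values for k = N+1 .. N+J (defaults to zeros).
#' @param residual_value Constant added to every output entry, accounting for
#'   matter arriving from beyond the kernel half-width (see [diffuse()]).
#' @return The diffused deficit array, k = 0..N.
#' @export
convolve_direct <- function(deficit, kernel, tail = NULL, residual_value = 0) {
  N <- length(deficit) - 1L
  J <- kernel$half_width
  if (is.null(tail)) tail <- numeric(J)
  if (length(tail) < J) tail <- c(tail, numeric(J - length(tail)))
  ext <- c(deficit, tail[seq_len(J)])     # e(m) for m = 0 .. N+J
  out <- kernel$retention * deficit
  k <- 0:N
  for (i in seq_along(kernel$offsets)) {
    j <- kernel$offsets[i]
    w <- kernel$transfer_weights[i]
    out <- out + w * (ext[k + j + 1L] + ext[abs(k - j) + 1L])
  }
  out + residual_value
}

#' FFT convolution of a deficit array with the kernel
#'
#' Same contract as [convolve_direct()], computed as a zero-padded linear
#' convolution: the mirrored, tail-closed spectrum (length 2(N+J)+1) is
#' convolved with the kernel (length 2J+1) in a buffer large enough that
#' circular wrap-around cannot reach any retained index.
#'
#' @inheritParams convolve_direct
#' @return The diffused deficit array, k = 0..N.
#' @export
convolve_fft <- function(deficit, kernel, tail = NULL, residual_value = 0) {
  conv <- make_convolver(length(deficit) - 1L, kernel)
  conv(deficit, tail, residual_value)
}

## Closure performing the FFT convolution with the kernel transform cached;
## used by iterate_recursion() so the kernel FFT is computed once per run.
make_convolver <- function(N, kernel) {
  J <- kernel$half_width
  kv <- numeric(2L * J + 1L)
  kv[J + 1L] <- kernel$retention
  kv[J + 1L + kernel$offsets] <- kernel$transfer_weights
  kv[J + 1L - kernel$offsets] <- kernel$transfer_weights
  ns <- 2L * (N + J) + 1L
  nf <- stats::nextn(ns + 2L * J, c(2, 3, 5))
  if (nf < ns + 2L * J)
    stop("insufficient FFT padding for the requested kernel half-width")
  fk <- stats::fft(c(kv, numeric(nf - length(kv))))
  function(deficit, tail = NULL, residual_value = 0) {
    if (length(deficit) != N + 1L) stop("deficit length does not match convolver")
    if (is.null(tail)) tail <- numeric(J)
    if (length(tail) < J) tail <- c(tail, numeric(J - length(tail)))
    ext <- c(deficit, tail[seq_len(J)])
    s <- c(rev(ext[-1L]), ext)            # m = -(N+J) .. (N+J)
    fs <- stats::fft(c(s, numeric(nf - ns)))
    r <- Re(stats::fft(fs * fk, inverse = TRUE)) / nf
    r[N + 2L * J + 1L + (0:N)] + residual_value
  }
}

#' Recombination phase: diffuse the deficit spectrum
#'
#' Applies one application of the diffusion kernel to a selection-reset
#' spectrum: c'_k = c_k/2 + sum over odd j of 2/(pi^2 j^2) c_{k+j}, with
#' negative indices mirrored and indices beyond the cutoff supplied by the
#' analytic tail closure. Matter arriving through kernel offsets beyond the
#' half-width J is approximated by residual_mass times the tail model at the
#' outermost extension point (with the default J = N + tail_extent every such
#' source lies in the tail region). The generation counter is incremented.
#'
#' @param state A selection-reset `variance_spectrum` (c_0 = 1).
#' @param kernel A `kernel_spec`.
#' @param method `"fft"` or `"direct"`.
#' @param convolver Optional cached closure from `make_convolver` (internal
#'   use by [iterate_recursion()]).
#' @return The diffused `variance_spectrum` at generation g+1.
#' @export
diffuse <- function(state, kernel, method = c("fft", "direct"), convolver = NULL) {
  method <- match.arg(method)
  if (abs(state$deficit[1] - 1) > 1e-12)
    stop("diffuse() expects a selection-reset state (c_0 = 1)")
  N <- state$cutoff
  J <- kernel$half_width
  fit <- tail_fit(state)
  if (is.null(fit)) {
    tail <- numeric(J); residual_value <- 0
    tp <- state$tail_exponent; ta <- 0
  } else {
    kt <- seq.int(N + 1L, N + J)
    tail <- pmin(fit$a * kt^(-fit$p), 1)
    residual_value <- kernel$residual_mass * min(fit$a * (N + J)^(-fit$p), 1)
    tp <- fit$p; ta <- fit$a
  }
  out <- if (method == "fft") {
    if (is.null(convolver)) convolver <- make_convolver(N, kernel)
    convolver(state$deficit, tail, residual_value)
  } else {
    convolve_direct(state$deficit, kernel, tail, residual_value)
  }
  if (any(out < -1e-10) || any(out > 1 + 1e-10))
    stop("diffusion produced deficits outside [0, 1]: numerical blow-up")
  structure(
    list(cutoff = N, deficit = out, generation = state$generation + 1L,
         tail_exponent = tp, tail_amplitude = ta),
    class = "variance_spectrum")
}

#' One full selection-recombination cycle
#'
#' Performs the selection reset followed by the diffusion, and advances the
#' population mean: mu' = mu + beta * sigma_{0,g} under the `"std_dev"` gain
#' rule (the literal mean recursion; sigma_{0,g} is the pre-reset standard
#' deviation of mode 0), or mu' = mu + beta * sigma^2_{0,g} under
#' `"variance"`.
#'
#' @param state A `variance_spectrum`.
#' @param params A `model_params` (supplies beta and the gain rule).
#' @param kernel A `kernel_spec`.
#' @param mu Current population mean of the genetic value.
#' @return A list with `state` (next generation), `mu` (updated mean) and
#'   `injected` (matter injected at k = 0, equal to the pre-reset
#'   sigma^2_0).
#' @export
recursion_step <- function(state, params, kernel, mu = 0) {
  sr <- selection_reset(state)
  gain <- if (params$gain_rule == "std_dev") sqrt(sr$sigma2_0) else sr$sigma2_0
  new_state <- diffuse(sr$state, kernel, params$conv_method)
  list(state = new_state, mu = mu + params$beta * gain, injected = sr$sigma2_0)
}

#' Iterate the selection-recombination recursion
#'
#' Runs `params$generations` cycles from the linkage-equilibrium state and
#' records, for each generation, the mode-0 variance, the mean, the total
#' deficit over |k| <= N, and the matter injected during the cycle. The run
#' is deterministic: identical parameters give identical output. A warning is
#' issued when the generation budget exceeds N/4, beyond which finite-cutoff
#' errors become visible.
#'
#' @param params A `model_params`.
#' @return An object of class `recursion_trajectory`: a list with
#'   `trajectory` (a data.frame with columns `generation`, `sigma2_0`,
#'   `sigma_0`, `mu`, `total_deficit`, `injected_mass`), `params`, `state`
#'   (the final spectrum) and, if requested, `spectra` (full deficit snapshots
#'   at power-of-2 generations).
#' @export
iterate_recursion <- function(params) {
  stopifnot(inherits(params, "model_params"))
  N <- params$cutoff; G <- params$generations
  if (G > N / 4)
    warning("generations exceed cutoff/4: finite-cutoff errors become visible when g is comparable to N")
  kernel <- build_kernel(params$kernel_half_width)
  convolver <- if (params$conv_method == "fft") make_convolver(N, kernel) else NULL
  state <- initial_spectrum(N)
  mu <- 0
  sigma2_0 <- sigma_0 <- muv <- total <- injected <- numeric(G)
  spectra <- if (isTRUE(params$snapshots)) list() else NULL
  for (g in seq_len(G)) {
    sr <- selection_reset(state)
    gain <- if (params$gain_rule == "std_dev") sqrt(sr$sigma2_0) else sr$sigma2_0
    state <- diffuse(sr$state, kernel, params$conv_method, convolver = convolver)
    mu <- mu + params$beta * gain
    sigma2_0[g] <- 1 - state$deficit[1]
    sigma_0[g] <- sqrt(max(sigma2_0[g], 0))
    muv[g] <- mu
    total[g] <- state$deficit[1] + 2 * sum(state$deficit[-1])
    injected[g] <- sr$sigma2_0
    if (!is.null(spectra) && bitwAnd(g, g - 1L) == 0L)
      spectra[[as.character(g)]] <- state$deficit
  }
  structure(
    list(trajectory = data.frame(
           generation = seq_len(G), sigma2_0 = sigma2_0, sigma_0 = sigma_0,
           mu = muv, total_deficit = total, injected_mass = injected),
         params = params, state = state, spectra = spectra),
    class = "recursion_trajectory")
}

#' @export
print.recursion_trajectory <- function(x, ...) {
  tr <- x$trajectory
  cat("Recursion trajectory: N =", x$params$cutoff, ", G =", nrow(tr),
      ", beta =", x$params$beta, "\n")
  cat("  final sigma2_0 =", format(tr$sigma2_0[nrow(tr)], digits = 8),
      " final mu =", format(tr$mu[nrow(tr)], digits = 8), "\n")
  invisible(x)
}
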