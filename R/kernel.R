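#' Build the recombination diffusion kernel on Fourier-mode space
#'
#' One cycle of selection and two-crossover recombination redistributes the
#' per-mode variance deficit as a lazy random walk on the mode lattice: a
#' fraction 1/2 of the matter at each site stays put, and the transferred half
#' is shared among sites at odd distances j with weight 4/(pi^2 j^2) per
#' distance, split equally over the two signs (so 2/(pi^2 j^2) per signed
#' offset). The weights sum to one: retention + transfer + residual = 1.
#'
#' @param half_width Largest odd offset retained, J (positive integer). Even
#'   values are accepted; the largest odd offset is then `half_width - 1`.
#' @return An object of class `kernel_spec` with fields `half_width`,
#'   `retention` (= 1/2 exactly), `offsets` (odd j from 1 to J),
#'   `transfer_weights` (per-sign weight 2/(pi^2 j^2) for each offset) and
#'   `residual_mass` (total weight on both signs beyond +/-J, in closed form
#'   via the trigamma function).
#' @examples
#' k <- build_kernel(9)
#' k$retention + 2 * sum(k$transfer_weights) + k$residual_mass # 1
#' @export
build_kernel <- function(half_width) {
  if (length(half_width) != 1L || !is.finite(half_width) || half_width < 1)
    stop("half_width must be a single integer >= 1")
  half_width <- floor(half_width)
  j <- seq(1, half_width, by = 2)
  w <- 2 / (pi^2 * j^2)
  ## smallest excluded odd offset j0 = 2*m0 + 1; sum_{odd n >= j0} 1/n^2
  ## equals trigamma(m0 + 1/2)/4 exactly.
  j0 <- if (half_width %% 2 == 1) half_width + 2 else half_width + 1
  m0 <- (j0 - 1) / 2
  residual <- (4 / pi^2) * trigamma(m0 + 0.5) / 4
  structure(
    list(half_width = half_width, retention = 0.5,
         offsets = j, transfer_weights = w, residual_mass = residual),
    class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("Mode-space diffusion kernel\n")
  cat("  half-width J      :", x$half_width, "\n")
  cat("  retention         :", x$retention, "\n")
  cat("  transfer (both signs):", format(2 * sum(x$transfer_weights), digits = 12), "\n")
  cat("  residual mass     :", format(x$residual_mass, digits = 12), "\n")
  invisible(x)
}

#' Total probability mass of a kernel
#'
#' Retention plus both-sign transfer weights plus the analytic residual; equal
#' to 1 up to floating-point summation error for every half-width.
#'
#' @param kernel A `kernel_spec`.
#' @return A number (should be 1).
#' @export
kernel_total_mass <- function(kernel) {
  kernel$retention + 2 * sum(kernel$transfer_weights) + kernel$residual_mass
}
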