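#' Estimate the Planck constant of an image
#'
#' In the quantum-inspired model the Planck constant is a free scale parameter
#' of the kinetic term rather than a physical constant. It is estimated a
#' priori as the ratio of the image "energy" to its maximum frequency:
#' the energy is the total squared intensity after normalizing by the peak
#' intensity, and the maximum frequency is half the number of pixels along one
#' side (`N / 2`, with `N = max(n_rows, n_cols)` for rectangular images).
#' The estimate is invariant under multiplying the image by a positive scalar.
#'
#' @param image Numeric intensity matrix (see [as_image()]).
#' @return An object of class `planck_estimate`: a list with `hbar`,
#'   `energy_numerator` (sum of squared max-normalized intensities) and
#'   `frequency_denominator` (`N / 2`).
#' @examples
#' estimate_planck(matrix(7, 4, 4))$hbar # == 8: all normalized terms are 1
#' @export
estimate_planck <- function(image) {
  image <- as_image(image)
  hi <- max(image)
  if (hi <= 0) stop("cannot normalize by zero maximum intensity", call. = FALSE)
  energy <- sum((image / hi)^2)
  freq <- max(dim(image)) / 2
  structure(
    list(hbar = energy / freq,
         energy_numerator = energy,
         frequency_denominator = freq),
    class = "planck_estimate"
  )
}

#' @export
print.planck_estimate <- function(x, ...) {
  cat("Planck estimate: hbar =", format(x$hbar),
      " (energy", format(x$energy_numerator),
      "/ max frequency", format(x$frequency_denominator), ")\n")
  invisible(x)
}

#' Kinetic-term parameters of the Hamiltonian
#'
#' Bundles the effective Planck constant `hbar_eff = alpha * hbar`, the
#' particle mass `m` (never observable separately from `hbar` in this model;
#' fixed to 1 by default) and the resulting off-diagonal coupling
#' `hbar_eff^2 / (2 m)` of the discrete operator.
#'
#' @param hbar Positive base Planck constant, typically from
#'   [estimate_planck()].
#' @param alpha Positive scale factor for the augmented constant
#'   `hbar' = alpha * hbar`. Default 1. Fractional values are allowed.
#' @param mass Positive particle mass. Default 1.
#' @return An object of class `hamiltonian_params` with fields `hbar_eff`,
#'   `alpha`, `mass`, `coupling`.
#' @export
hamiltonian_params <- function(hbar, alpha = 1, mass = 1) {
  stopifnot(is.numeric(hbar), length(hbar) == 1L, is.finite(hbar), hbar > 0,
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha > 0,
            is.numeric(mass), length(mass) == 1L, is.finite(mass), mass > 0)
  hbar_eff <- alpha * hbar
  structure(
    list(hbar_eff = hbar_eff, alpha = alpha, mass = mass,
         coupling = hbar_eff^2 / (2 * mass)),
    class = "hamiltonian_params"
  )
}

#' Build the discrete Hamiltonian of an image
#'
#' Discretizes the stationary Schroedinger operator whose potential is the
#' pixel intensity: for the vectorized image (row-major), the diagonal entry
#' of pixel i is `x(i) + 4 * coupling` and each in-grid 4-neighbour pair
#' (horizontal and vertical) carries an off-diagonal `-coupling`, where
#' `coupling = hbar_eff^2 / (2 m)`. Boundaries use zero padding (Dirichlet):
#' couplings that would wrap across a row boundary are omitted, and the
#' diagonal keeps the full `4 * coupling` at edge pixels, consistent with the
#' padding. The result is an exactly symmetric sparse matrix with at most 5
#' nonzeros per row.
#'
#' @param image Numeric intensity matrix.
#' @param params A [hamiltonian_params()] object.
#' @return A symmetric sparse `Matrix::dsCMatrix` of dimension
#'   `n_rows * n_cols`.
#' @examples
#' H <- build_hamiltonian(matrix(0, 2, 2), hamiltonian_params(hbar = 1))
#' @export
build_hamiltonian <- function(image, params) {
  image <- as_image(image)
  if (!inherits(params, "hamiltonian_params")) {
    stop("params must be a hamiltonian_params object", call. = FALSE)
  }
  nr <- nrow(image); nc <- ncol(image)
  n_tot <- nr * nc
  cpl <- params$coupling
  x <- vectorize(image)

  # 1-based row-major index of pixel (r, c) is (r-1)*nc + c
  idx <- matrix(seq_len(n_tot), nrow = nr, ncol = nc, byrow = TRUE)
  right_i <- as.vector(idx[, -nc, drop = FALSE])
  right_j <- as.vector(idx[, -1L, drop = FALSE])
  down_i <- as.vector(idx[-nr, , drop = FALSE])
  down_j <- as.vector(idx[-1L, , drop = FALSE])

  Matrix::sparseMatrix(
    i = c(seq_len(n_tot), right_i, down_i),
    j = c(seq_len(n_tot), right_j, down_j),
    x = c(x + 4 * cpl, rep(-cpl, length(right_i) + length(down_i))),
    dims = c(n_tot, n_tot),
    symmetric = TRUE
  )
}
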