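#' Eigendecompose an image Hamiltonian into its adaptive basis
#'
#' Computes the full spectrum of the symmetric operator. Eigenvalues are
#' returned ascending; eigenvectors are orthonormal columns, with a
#' deterministic sign convention (the largest-magnitude component of each
#' vector is positive, ties broken at the lowest index) and, within groups of
#' numerically equal eigenvalues, columns ordered lexicographically after
#' sign fixing so that repeated runs are reproducible.
#'
#' @param H Symmetric operator from [build_hamiltonian()] (any symmetric
#'   numeric matrix or `Matrix` is accepted).
#' @param shape Optional `c(n_rows, n_cols)` recorded for devectorizing modes.
#' @return An object of class `mode_spectrum`: list with
#'   `eigenvalues` (ascending), `eigenvectors` (orthonormal columns; column
#'   n is mode n), `participation` (raw participation numbers, see
#'   [participation_ratio()]), `normalized_participation`, `n_tot`, `shape`.
#' @export
decompose <- function(H, shape = NULL) {
  H <- as.matrix(H)
  if (nrow(H) == 0L) stop("operator has dimension 0", call. = FALSE)
  if (nrow(H) != ncol(H) || max(abs(H - t(H))) > 1e-10 * (1 + max(abs(H)))) {
    stop("operator must be symmetric", call. = FALSE)
  }
  es <- eigen(H, symmetric = TRUE)
  ord <- order(es$values)            # eigen() returns decreasing
  values <- es$values[ord]
  vectors <- es$vectors[, ord, drop = FALSE]
  vectors <- fix_signs(vectors)
  vectors <- order_degenerate(values, vectors)
  new_mode_spectrum(values, vectors, shape)
}

# sign convention: largest |component| positive, ties -> lowest index
fix_signs <- function(vectors) {
  for (n in seq_len(ncol(vectors))) {
    v <- vectors[, n]
    k <- which.max(abs(v))
    if (v[k] < 0) vectors[, n] <- -v
  }
  vectors
}

# reproducible column order inside numerically degenerate eigenvalue groups
order_degenerate <- function(values, vectors, tol = 1e-9) {
  if (length(values) < 2L) return(vectors)
  scale <- max(abs(values), 1)
  grp <- cumsum(c(TRUE, diff(values) > tol * scale))
  for (g in unique(grp[duplicated(grp)])) {
    cols <- which(grp == g)
    if (length(cols) > 1L) {
      o <- do.call(order, as.data.frame(t(round(vectors[, cols, drop = FALSE], 10))))
      vectors[, cols] <- vectors[, cols[o], drop = FALSE]
    }
  }
  vectors
}

new_mode_spectrum <- function(values, vectors, shape = NULL) {
  n_tot <- length(values)
  pr <- if (is.null(vectors)) NULL else participation_numbers(vectors)
  structure(
    list(eigenvalues = values,
         eigenvectors = vectors,
         participation = pr,
         normalized_participation = if (is.null(pr)) NULL else pr / n_tot,
         n_tot = n_tot,
         shape = shape),
    class = "mode_spectrum"
  )
}

#' Construct a mode spectrum from components
#'
#' Mainly useful for building synthetic spectra (e.g. to exercise mode
#' selection); [decompose()] is the standard route. Eigenvectors may be
#' omitted when only eigenvalues and participation values are needed.
#'
#' @param eigenvalues Numeric vector, ascending.
#' @param eigenvectors Optional orthonormal matrix, one column per mode.
#' @param normalized_participation Optional vector in `(0, 1]`; computed from
#'   the eigenvectors when they are given.
#' @return A `mode_spectrum` object.
#' @export
mode_spectrum <- function(eigenvalues, eigenvectors = NULL,
                          normalized_participation = NULL) {
  if (is.unsorted(eigenvalues)) stop("eigenvalues must be ascending", call. = FALSE)
  s <- new_mode_spectrum(eigenvalues, eigenvectors)
  if (is.null(s$participation)) {
    if (is.null(normalized_participation)) {
      stop("supply eigenvectors or normalized_participation", call. = FALSE)
    }
    if (length(normalized_participation) != s$n_tot) {
      stop("participation length must match eigenvalues", call. = FALSE)
    }
    s$normalized_participation <- normalized_participation
    s$participation <- normalized_participation * s$n_tot
  }
  s
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat("Mode spectrum:", x$n_tot, "modes",
      if (!is.null(x$shape)) paste0("(", x$shape[1], "x", x$shape[2], " image)"),
      "\n  eigenvalues in [", format(min(x$eigenvalues)), ",",
      format(max(x$eigenvalues)), "]\n",
      " normalized participation in [",
      format(min(x$normalized_participation)), ",",
      format(max(x$normalized_participation)), "]\n")
  invisible(x)
}

participation_numbers <- function(vectors) {
  s2 <- colSums(vectors^2)
  s4 <- colSums(vectors^4)
  if (any(s2 == 0)) stop("zero eigenvector", call. = FALSE)
  s2^2 / s4
}

#' Mode-resolved participation ratio
#'
#' The participation ratio of mode n with components `e_{i,n}` is
#' `P_n = (sum_i e_{i,n}^2)^2 / sum_i e_{i,n}^4`: the effective number of
#' pixels the mode occupies. It ranges from 1 (a single-pixel, maximally
#' localized mode) to `N_tot` (a uniform, maximally delocalized mode). The
#' normalized ratio `p_n = P_n / N_tot` lies in `(0, 1]`; low values flag
#' Anderson-localized modes, high values the extended, noise-carrying ones.
#'
#' @param spectrum A `mode_spectrum`, or a matrix of mode columns.
#' @return A list with `participation` (raw `P_n`) and
#'   `normalized_participation` (`p_n`).
#' @export
participation_ratio <- function(spectrum) {
  vectors <- if (inherits(spectrum, "mode_spectrum")) spectrum$eigenvectors
             else as.matrix(spectrum)
  if (is.null(vectors)) stop("spectrum carries no eigenvectors", call. = FALSE)
  p <- participation_numbers(vectors)
  list(participation = p, normalized_participation = p / nrow(vectors))
}

#' Project an image onto the adaptive basis
#'
#' Computes the expansion coefficients `a_n = <psi_n, x>` of the vectorized
#' image in the eigenbasis. Because the basis is orthonormal and complete,
#' the coefficients satisfy Parseval's identity
#' `sum a_n^2 = ||x||^2`.
#'
#' @param spectrum A `mode_spectrum` with eigenvectors.
#' @param image Numeric intensity matrix with `n_tot` pixels.
#' @return Numeric vector of coefficients, one per mode.
#' @export
project <- function(spectrum, image) {
  stopifnot(inherits(spectrum, "mode_spectrum"))
  if (is.null(spectrum$eigenvectors)) {
    stop("spectrum carries no eigenvectors", call. = FALSE)
  }
  v <- vectorize(as.matrix(image))
  if (length(v) != spectrum$n_tot) {
    stop("image has ", length(v), " pixels but spectrum has ",
         spectrum$n_tot, " modes", call. = FALSE)
  }
  as.vector(crossprod(spectrum$eigenvectors, v))
}

#' Tidy a mode spectrum into a tibble
#'
#' @param x A `mode_spectrum`.
#' @param ... Unused.
#' @return A tibble with columns `mode_index` (1-based, eigenvalue-ascending),
#'   `eigenvalue`, `participation`, `normalized_participation`.
#' @importFrom generics tidy
#' @export
tidy.mode_spectrum <- function(x, ...) {
  tibble::tibble(
    mode_index = seq_len(x$n_tot),
    eigenvalue = x$eigenvalues,
    participation = x$participation,
    normalized_participation = x$normalized_participation
  )
}

#' Export a spectrum to CSV
#'
#' Writes the [tidy.mode_spectrum()] table (header
#' `mode_index,eigenvalue,participation,normalized_participation`).
#'
#' @param spectrum A `mode_spectrum`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(tidy(spectrum)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
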