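#' Row-permutations of an unmixing matrix
#'
#' A row-permutation is a fixed-point-free bijection `phi` on a subset
#' `R` of row indices with `|R| >= 2`.  Applied to an unmixing matrix it
#' moves row `r` to row `phi(r)` for every `r` in `R` and leaves the
#' remaining rows unchanged.  Row-permutations generate the ICA
#' equivalence class of a directed graph: the class consists of all
#' graphs whose unmixing matrices are admissible row-permutations of each
#' other (up to row scaling).
#'
#' @param domain integer vector `R` of row indices, `|R| >= 2`.
#' @param image integer vector of the same length; `image[k] = phi(domain[k])`.
#' @return object of class `row_permutation` with elements `domain`, `image`.
#' @examples
#' phi <- row_permutation(1:3, c(3, 1, 2))
#' decompose_permutation(phi)
#' @export
row_permutation <- function(domain, image) {
  domain <- as.integer(domain); image <- as.integer(image)
  if (length(domain) < 2L) stop("|R| must be at least 2", call. = FALSE)
  if (length(domain) != length(image)) {
    stop("`domain` and `image` must have equal length", call. = FALSE)
  }
  if (anyDuplicated(domain)) stop("`domain` must be distinct", call. = FALSE)
  if (!setequal(domain, image)) {
    stop("`image` must be a bijection of `domain`", call. = FALSE)
  }
  if (any(domain == image)) {
    stop("row-permutations have no fixed points (phi(r) != r)", call. = FALSE)
  }
  structure(list(domain = domain, image = image), class = "row_permutation")
}

#' @export
print.row_permutation <- function(x, ...) {
  cat("<row_permutation> ",
      paste0(x$domain, "→", x$image, collapse = ", "), "\n", sep = "")
  invisible(x)
}

phi_of <- function(phi, r) phi$image[match(r, phi$domain)]

#' Build a row-permutation from a full permutation vector
#'
#' The non-fixed points of `perm` form the domain; returns `NULL` when
#' `perm` is the identity.
#'
#' @param perm integer vector with `perm[r] = phi(r)`.
#' @return a [row_permutation()] or `NULL`.
#' @export
row_permutation_from_perm <- function(perm) {
  moved <- which(perm != seq_along(perm))
  if (!length(moved)) return(NULL)
  row_permutation(moved, perm[moved])
}

#' Inverse of a row-permutation
#' @param phi a [row_permutation()].
#' @return the inverse [row_permutation()].
#' @export
invert_permutation <- function(phi) {
  row_permutation(phi$image, phi$domain)
}

#' Apply a row-permutation to an unmixing matrix
#'
#' Output row `phi(r)` equals input row `r` for every `r` in the domain;
#' rows outside the domain are unchanged.  No normalization is performed.
#'
#' @param W square numeric matrix.
#' @param phi a [row_permutation()].
#' @return the row-permuted matrix.
#' @export
apply_permutation <- function(W, phi) {
  W <- as.matrix(W)
  if (!inherits(phi, "row_permutation")) {
    stop("`phi` must be a row_permutation", call. = FALSE)
  }
  if (any(phi$domain < 1L | phi$domain > nrow(W))) {
    stop("permutation domain outside the row range of `W`", call. = FALSE)
  }
  W2 <- W
  W2[phi$image, ] <- W[phi$domain, ]
  W2
}

#' Admissibility of a row-permutation
#'
#' A row-permutation applied to an unmixing matrix is admissible when all
#' diagonal elements of the result are nonzero, so that the permuted
#' matrix still corresponds to a graph without self-loops.
#'
#' @param W square numeric matrix.
#' @param phi a [row_permutation()].
#' @param zero_tol magnitude below which a diagonal entry counts as zero.
#' @return `TRUE` or `FALSE`.
#' @export
is_admissible <- function(W, phi, zero_tol = 1e-8) {
  # diagonal of the permuted matrix at row phi(r) is W[r, phi(r)]
  if (any(phi$domain < 1L | phi$domain > nrow(W))) {
    stop("permutation domain outside the row range of `W`", call. = FALSE)
  }
  fixed <- setdiff(seq_len(nrow(W)), phi$image)
  all(abs(W[cbind(phi$domain, phi$image)]) > zero_tol) &&
    all(abs(diag(as.matrix(W))[fixed]) > zero_tol)
}

#' Decompose a row-permutation into irreducible components
#'
#' Every row-permutation splits uniquely into disjoint cyclic components;
#' each component is irreducible (it admits no sub-permutation on a
#' proper subset of its domain), the component domains partition `R`, and
#' applying the components sequentially reproduces the original
#' permutation.
#'
#' @param phi a [row_permutation()].
#' @return list of irreducible [row_permutation()] objects, ordered by
#'   smallest domain element.
#' @export
decompose_permutation <- function(phi) {
  remaining <- phi$domain
  comps <- list()
  while (length(remaining)) {
    start <- min(remaining)
    orbit <- start
    nxt <- phi_of(phi, start)
    while (nxt != start) {
      orbit <- c(orbit, nxt)
      nxt <- phi_of(phi, nxt)
    }
    comps[[length(comps) + 1L]] <-
      row_permutation(orbit, phi_of(phi, orbit))
    remaining <- setdiff(remaining, orbit)
  }
  comps
}

#' Is a row-permutation irreducible?
#'
#' @param phi a [row_permutation()].
#' @return `TRUE` iff `phi` consists of a single cyclic component.
#' @export
is_irreducible <- function(phi) {
  length(decompose_permutation(phi)) == 1L
}
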