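#' County adjacency graph
#'
#' Undirected neighbourhood structure over county identifiers; the spatial
#' random effect of the small-area model smooths over this graph.
#'
#' @param counties Character vector of county identifiers (the node set).
#' @param edges Two-column matrix or data.frame of county identifiers; each
#'   row one undirected edge. Self-loops are rejected, duplicate /
#'   mirrored edges collapsed.
#' @return An object of class `county_graph` with elements `counties` and
#'   `edges` (two-column character matrix, each edge stored once with
#'   endpoints in sorted order).
#' @export
county_graph <- function(counties, edges) {
  counties <- as.character(counties)
  if (anyDuplicated(counties)) stop("duplicated county identifiers")
  e <- as.matrix(edges)
  if (length(e) == 0L) {
    e <- matrix(character(), ncol = 2L)
  } else {
    if (ncol(e) != 2L) stop("edges must have two columns")
    e <- matrix(as.character(e), ncol = 2L)
    bad <- setdiff(c(e), counties)
    if (length(bad))
      stop("edge endpoint not in county set: ", paste(bad, collapse = ", "))
    if (any(e[, 1] == e[, 2])) stop("self-loops are not allowed")
    e <- t(apply(e, 1L, sort))
    e <- unique(e)
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  structure(list(counties = counties, edges = e), class = "county_graph")
}

#' @export
print.county_graph <- function(x, ...) {
  cat("county_graph:", length(x$counties), "counties,",
      nrow(x$edges), "edges,", n_components(x), "component(s)\n")
  invisible(x)
}

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$counties), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$counties)
  if (nrow(g$edges))
    ig <- igraph::add_edges(ig, t(matrix(match(g$edges, g$counties),
                                         ncol = 2L)))
  ig
}

# component membership (integer), named by county
graph_components <- function(g) {
  comp <- igraph::components(as_igraph(g))$membership
  setNames(as.integer(comp), g$counties)
}

n_components <- function(g) length(unique(graph_components(g)))

#' ICAR structure matrix of a county graph
#'
#' Returns the intrinsic conditional autoregressive precision structure
#' `Q = D - W` (degree matrix minus adjacency), a sparse symmetric
#' positive-semidefinite matrix whose null space is spanned by the
#' indicator of each connected component.
#'
#' @param g A [county_graph()].
#' @return A sparse `dsCMatrix` with dimnames equal to the county ids.
#' @export
icar_structure <- function(g) {
  n <- length(g$counties)
  if (nrow(g$edges)) {
    i <- match(g$edges[, 1], g$counties)
    j <- match(g$edges[, 2], g$counties)
    W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n, n))
  } else {
    W <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
  }
  Q <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  dimnames(Q) <- list(g$counties, g$counties)
  Matrix::forceSymmetric(Q)
}

#' First-order random-walk structure matrix
#'
#' Precision structure of an RW1 prior over an ordered index of length
#' `n`: the cross-product of the first-difference operator, a tridiagonal
#' matrix with pattern `(1, 2, ..., 2, 1)` on the diagonal and `-1` off
#' it. PSD with null space spanned by the constant vector.
#'
#' @param n Length of the ordered index (age groups or years).
#' @return A sparse symmetric matrix of dimension `n`.
#' @export
rw1_structure <- function(n) {
  if (n < 1L) stop("n must be >= 1")
  if (n == 1L) return(Matrix::Matrix(0, 1, 1, sparse = TRUE))
  D <- Matrix::bandSparse(n - 1L, n, k = 0:1,
                          diagonals = list(rep(-1, n - 1L), rep(1, n - 1L)))
  Matrix::forceSymmetric(Matrix::crossprod(D))
}

# orthonormal basis of the sum-to-zero subspace of R^n (n x (n-1)),
# columns orthogonal to the constant vector (normalised Helmert contrasts)
sum_to_zero_basis <- function(n) {
  if (n < 2L) return(matrix(numeric(), nrow = n, ncol = 0L))
  H <- stats::contr.helmert(n)
  sweep(H, 2L, sqrt(colSums(H^2)), "/")
}

# block basis over connected components: per-component sum-to-zero
component_basis <- function(membership) {
  n <- length(membership)
  comps <- sort(unique(membership))
  A <- matrix(0, n, n - length(comps))
  at <- 0L
  for (cm in comps) {
    rows <- which(membership == cm)
    B <- sum_to_zero_basis(length(rows))
    if (ncol(B)) {
      A[rows, at + seq_len(ncol(B))] <- B
      at <- at + ncol(B)
    }
  }
  A
}
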