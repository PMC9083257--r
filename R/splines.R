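# Penalized B-spline machinery: clamped bases, divided-difference penalties,
# tensor products, and constraint absorption. This is the engine behind the
# trajectory regression; it is a structural analog of a GAMM smoother, not a
# clone of any particular implementation.

#' Clamped B-spline basis with equally spaced knots
#'
#' Interior knots are equally spaced over \code{range}; boundary knots are
#' repeated (clamped), so with \code{n_basis = degree + 1} the basis reduces
#' to the Bernstein polynomials. Rows sum to 1 (partition of unity).
#'
#' @param x numeric vector (finite, non-constant unless \code{range} given).
#' @param n_basis number of basis functions (>= degree + 1).
#' @param degree spline degree (default 3, cubic).
#' @param range basis support; defaults to \code{range(x)}.
#' @return matrix with \code{n_basis} columns; attributes \code{knots},
#'   \code{range}, \code{degree} and \code{greville} (Greville abscissae,
#'   used by the difference penalties).
#' @export
bspline_basis <- function(x, n_basis, degree = 3, range = NULL) {
  if (any(!is.finite(x))) stopf("domain error: 'x' must be finite")
  if (n_basis < degree + 1)
    stopf("configuration error: n_basis must be >= degree + 1")
  if (is.null(range)) {
    range <- base::range(x)
    if (range[1] == range[2])
      stopf("domain error: constant 'x' spans no interval")
  }
  n_interior <- n_basis - degree - 1
  interior <- if (n_interior > 0)
    seq(range[1], range[2], length.out = n_interior + 2)[-c(1, n_interior + 2)]
  else numeric(0)
  knots <- c(rep(range[1], degree + 1), interior, rep(range[2], degree + 1))
  xc <- pmin(pmax(x, range[1]), range[2])
  # right-boundary limit handled like bs(): evaluate max(x) from the left
  eps <- (range[2] - range[1]) * 1e-10
  B <- splines::splineDesign(knots, pmin(xc, range[2] - eps),
                             ord = degree + 1)
  at_max <- xc >= range[2] - eps
  if (any(at_max)) {
    B[at_max, ] <- 0
    B[at_max, n_basis] <- 1
  }
  grev <- vapply(seq_len(n_basis), function(j)
    mean(knots[(j + 1):(j + degree)]), numeric(1))
  structure(B, knots = knots, range = range, degree = degree,
            greville = grev)
}

# Divided-difference penalty matrix of given order w.r.t. the Greville
# abscissae: null space is exactly {polynomials of degree < order in x},
# so an order-2 penalty shrinks toward the straight line a + b*x.
diff_penalty <- function(greville, order = 2) {
  K <- length(greville)
  if (K < order + 1)
    stopf("configuration error: basis too small for penalty order %d", order)
  D <- diag(K)
  xi <- greville
  for (o in seq_len(order)) {
    D <- diff(D) / diff(xi)
    xi <- (xi[-1] + xi[-length(xi)]) / 2
  }
  crossprod(D)
}

# Row-wise Kronecker (tensor) product of two marginal bases.
row_kronecker <- function(B1, B2) {
  K1 <- ncol(B1); K2 <- ncol(B2)
  if (nrow(B1) != nrow(B2)) stopf("dimension mismatch in tensor product")
  B1[, rep(seq_len(K1), each = K2), drop = FALSE] *
    B2[, rep(seq_len(K2), K1), drop = FALSE]
}

#' Tensor-product smooth block
#'
#' Builds the design block and penalty list for a full tensor-product smooth
#' of two covariates (row-wise Kronecker product of the marginal bases, with
#' each marginal difference penalty Kronecker-expanded). For a partial tensor
#' (interaction-only, the \code{ti()} analog) the subspace spanned by the
#' marginal main effects and the intercept is removed through exact
#' orthogonality constraints.
#'
#' @param B1,B2 marginal bases from \code{\link{bspline_basis}}.
#' @param partial if \code{TRUE}, remove the marginal main-effect subspace.
#' @param penalty_order difference-penalty order (default 2).
#' @return list with \code{X} (design block), \code{S} (list of two
#'   penalties) and, for partial tensors, the reparameterization matrix
#'   \code{Z}.
#' @export
tensor_term <- function(B1, B2, partial = FALSE, penalty_order = 2) {
  K1 <- ncol(B1); K2 <- ncol(B2)
  X <- row_kronecker(B1, B2)
  S1 <- diff_penalty(attr(B1, "greville"), penalty_order) %x% diag(K2)
  S2 <- diag(K1) %x% diff_penalty(attr(B2, "greville"), penalty_order)
  if (!partial) return(list(X = X, S = list(S1, S2), Z = NULL))
  M <- cbind(1, B1, B2)
  C <- crossprod(M, X)
  Z <- nullspace_of(C)
  list(X = X %*% Z, S = list(crossprod(Z, S1 %*% Z),
                             crossprod(Z, S2 %*% Z)), Z = Z)
}

# Orthonormal basis of the null space of a constraint matrix C (C beta = 0).
nullspace_of <- function(C) {
  qrC <- qr(t(C))
  r <- qrC$rank
  Q <- qr.Q(qrC, complete = TRUE)
  if (r >= ncol(Q))
    return(matrix(0, nrow(Q), 0))
  Q[, seq.int(r + 1, ncol(Q)), drop = FALSE]
}
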