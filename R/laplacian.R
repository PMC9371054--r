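#' Legendre-series spline kernel
#'
#' Evaluates the spherical-spline kernel
#' \deqn{p(c) = \frac{1}{4\pi}\sum_{n=1}^{o} \frac{(2n+1)\,P_n(c)}{(n(n+1))^{e}}}
#' where \eqn{P_n} is the Legendre polynomial of degree n, computed by the
#' stable three-term recurrence. With exponent \eqn{e = \rho} this is the
#' g-kernel of the surface Laplacian; with \eqn{e = \rho - 1} the h-kernel.
#'
#' @param cos_angle cosine of the inter-electrode angle, in `[-1, 1]`
#'   (vectorized).
#' @param order_o highest Legendre degree (>= 1).
#' @param exponent exponent applied to `n(n+1)` in the denominator.
#' @return kernel value(s), same length as `cos_angle`.
#' @export
legendre_kernel <- function(cos_angle, order_o = 10, exponent = 4) {
  if (order_o < 1) stop("order_o must be at least 1")
  if (any(abs(cos_angle) > 1 + 1e-12))
    stop("cos_angle must lie in [-1, 1]")
  x <- pmin(1, pmax(-1, cos_angle))
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  acc <- 3 * p_cur / 2^exponent
  if (order_o >= 2) {
    for (n in 2:order_o) {
      p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
      acc <- acc + (2 * n + 1) * p_next / (n * (n + 1))^exponent
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  acc / (4 * pi)
}

#' Build spherical-spline matrices for the surface Laplacian
#'
#' Computes the symmetric weighting matrices G (g-kernel, exponent `rho`) and H
#' (h-kernel, exponent `rho - 1`) over all electrode pairs, together with the
#' inverse of the regularized matrix `Gs = G + lambda * I`. The pairwise
#' argument is the cosine distance `1 - ||e_c - e_c'||^2 / 2`, which for
#' unit-norm positions equals the dot product.
#'
#' @param positions channels x 3 matrix of unit-norm electrode positions.
#' @param order_o highest Legendre degree (default 10).
#' @param rho smoothness constant (default 4).
#' @param lambda_reg regularization added to the diagonal of G (default 1e-5).
#' @return An object of class `spline_matrices` with elements `G`, `H`,
#'   `Gs_inverse`, `order_o`, `rho`, `lambda_reg`.
#' @export
build_spline_matrices <- function(positions, order_o = 10, rho = 4,
                                  lambda_reg = 1e-5) {
  positions <- as.matrix(positions)
  nrm <- sqrt(rowSums(positions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("positions must be unit-norm")
  if (lambda_reg < 0) stop("lambda_reg must be non-negative")
  C <- nrow(positions)
  cosang <- tcrossprod(positions)          # = 1 - ||e - e'||^2 / 2 on the sphere
  cosang[] <- pmin(1, pmax(-1, cosang))
  off <- cosang[upper.tri(cosang)]
  if (any(off > 1 - 1e-12))
    warning("duplicate electrode positions detected (cosine distance = 1)")
  G <- matrix(legendre_kernel(cosang, order_o, rho), C, C)
  H <- matrix(legendre_kernel(cosang, order_o, rho - 1), C, C)
  Gs <- G + lambda_reg * diag(C)
  Gs_inverse <- tryCatch(solve(Gs),
                         error = function(e) stop("G + lambda*I is singular: ",
                                                  conditionMessage(e)))
  structure(list(G = G, H = H, Gs_inverse = Gs_inverse, order_o = order_o,
                 rho = rho, lambda_reg = lambda_reg),
            class = "spline_matrices")
}

#' Surface Laplacian (spherical-spline current source density) filter
#'
#' Applies the spherical-spline surface Laplacian to every trial: the spline
#' coefficients are solved from the regularized system with the constant
#' (common-mode) term removed, then mapped through H. The output has the same
#' shape as the input; a spatially constant field maps to zero exactly, which
#' is what suppresses volume-conducted (spatially broad) activity.
#'
#' @param trials a [trialset()] whose channel count matches `sm`.
#' @param sm a `spline_matrices` object from [build_spline_matrices()], or
#'   `NULL` to build one from `trials$positions` with default parameters.
#' @return A `trialset` of Laplacian-filtered data (unnormalized CSD scale).
#' @export
surface_laplacian <- function(trials, sm = NULL) {
  stopifnot(inherits(trials, "trialset"))
  if (is.null(sm)) sm <- build_spline_matrices(trials$positions)
  C <- n_channels(trials)
  if (nrow(sm$G) != C) stop("channel count does not match spline matrices")
  Gi <- sm$Gs_inverse
  gi_rows <- rowSums(Gi)        # Gi %*% 1
  denom <- sum(gi_rows)         # 1' Gi 1
  out <- trials$data
  for (t in seq_len(n_trials(trials))) {
    X <- trials$data[t, , ]                       # C x T
    GiX <- Gi %*% X
    const <- colSums(GiX) / denom                 # fitted common-mode, 1 x T
    coef <- GiX - outer(gi_rows, const)
    out[t, , ] <- sm$H %*% coef
  }
  with_data(trials, out)
}
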