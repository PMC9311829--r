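#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: the square root of
#' the summed squared distances of all landmarks from their centroid.
#' Invariant to translation and rotation; scales linearly under isotropic
#' scaling. Used as the side size \eqn{R} and \eqn{L} in the FA2 index.
#'
#' @param config numeric k x 2 matrix of landmark coordinates, k >= 2.
#' @return a non-negative scalar; 0 only when all landmarks coincide
#'   (callers must treat a zero size as degenerate).
#' @examples
#' sq <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
#' centroid_size(sq)  # sqrt(8)
#' @export
centroid_size <- function(config) {
  config <- as_config(config)
  if (nrow(config) < 2L) stop("centroid size needs at least 2 landmarks")
  ctr <- colMeans(config)
  sqrt(sum(sweep(config, 2L, ctr)^2))
}

#' Reflect a configuration about a coordinate axis
#'
#' Reflection about the x-axis negates the y coordinate; reflection about
#' the y-axis negates x. An involution that preserves centroid size.
#'
#' @param config numeric k x 2 matrix.
#' @param axis `"x"` or `"y"`: the axis of reflection (kept fixed).
#' @return the reflected k x 2 matrix.
#' @export
reflect <- function(config, axis = c("x", "y")) {
  axis <- match.arg(axis)
  config <- as_config(config)
  if (axis == "x") config[, 2L] <- -config[, 2L] else config[, 1L] <- -config[, 1L]
  config
}

as_config <- function(config) {
  config <- as.matrix(config)
  if (ncol(config) != 2L) stop("a landmark configuration must be a k x 2 matrix")
  if (!all(is.finite(config))) stop("landmark coordinates must be finite")
  storage.mode(config) <- "double"
  config
}

#' Ordinary (pairwise) Procrustes alignment
#'
#' Finds the similarity transform (translation, rotation, optional
#' reflection, optional scaling) of `target` that minimizes the summed
#' squared distance to `reference`, in closed form via the singular value
#' decomposition of the cross-covariance of the centered configurations.
#'
#' @param target,reference k x 2 matrices with equal k, neither degenerate.
#' @param allow_reflection if `FALSE` (default) the returned transform has
#'   determinant +1 (a proper rotation).
#' @param scale if `TRUE` (default) the optimal scale factor is applied;
#'   otherwise only rotation and translation.
#' @return a list with `aligned` (transformed target), `rotation` (2 x 2),
#'   `scale`, `translation`, and `rss` (residual sum of squares, the
#'   squared partial Procrustes distance when `scale = FALSE` on
#'   unit-size inputs).
#' @export
opa_align <- function(target, reference, allow_reflection = FALSE, scale = TRUE) {
  X <- as_config(target)
  Y <- as_config(reference)
  if (nrow(X) != nrow(Y)) stop("configurations must have equal landmark counts")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  nx <- sqrt(sum(Xc^2)); ny <- sqrt(sum(Yc^2))
  if (nx == 0 || ny == 0) stop("degenerate (zero-size) configuration")
  M <- crossprod(Xc, Yc)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (allow_reflection) {
    R <- sv$u %*% t(sv$v)
    trace <- sum(sv$d)
  } else {
    S <- diag(c(1, d))
    R <- sv$u %*% S %*% t(sv$v)
    trace <- sum(sv$d * c(1, d))
  }
  s <- if (scale) trace / nx^2 else 1
  aligned <- s * (Xc %*% R)
  aligned <- sweep(aligned, 2L, cy, `+`)
  rss <- sum((aligned - Y)^2)
  list(aligned = aligned, rotation = R, scale = s,
       translation = cy - s * drop(cx %*% R), rss = rss)
}

## Rotation-only alignment of many unit-size centered configurations
## to a consensus, closed form: theta = atan2(m21 - m12, m11 + m22)
## where M = X^T C. Operates on k x 2 x n arrays, vectorized over n.
rotate_to_consensus <- function(A, C) {
  X1 <- A[, 1L, , drop = TRUE]
  X2 <- A[, 2L, , drop = TRUE]
  if (is.null(dim(X1))) { X1 <- matrix(X1, ncol = 1L); X2 <- matrix(X2, ncol = 1L) }
  a <- drop(crossprod(X1, C[, 1L])) + drop(crossprod(X2, C[, 2L]))  # m11 + m22
  b <- drop(crossprod(X2, C[, 1L])) - drop(crossprod(X1, C[, 2L]))  # m21 - m12
  th <- atan2(b, a)
  co <- rep(cos(th), each = nrow(X1))
  si <- rep(sin(th), each = nrow(X1))
  N1 <- X1 * co + X2 * si
  N2 <- X2 * co - X1 * si
  out <- A
  out[, 1L, ] <- N1
  out[, 2L, ] <- N2
  out
}

#' Generalized Procrustes analysis
#'
#' Iterative least-squares superimposition of a set of configurations:
#' all are centered and scaled to unit centroid size, rotated to a
#' provisional consensus, and the consensus re-estimated until its
#' root-mean-square change falls below `tol`. The fit is a full
#' Procrustes fit with fixed (unit) scale, so shape and size are cleanly
#' separable; original centroid sizes are returned alongside.
#'
#' The final orientation is canonicalized by rotating the whole aligned
#' set so that the consensus' first landmark lies on the positive x-axis,
#' making the output invariant to arbitrary similarity transforms of the
#' inputs (not merely invariant up to rotation).
#'
#' @param x a `landmark_dataset`, or a k x 2 x n array, or a list of
#'   k x 2 matrices (n >= 2, equal k, none degenerate).
#' @param tol convergence tolerance on the RMS change of the consensus.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @return an object of class `gpa_fit`: list with `consensus` (k x 2,
#'   centroid at origin, unit centroid size), `aligned` (k x 2 x n),
#'   `centroid_sizes` (length n, the pre-scaling sizes), `iterations`,
#'   and `converged`.
#' @export
gpa <- function(x, tol = 1e-10, max_iter = 200L) {
  A <- coords_array(x)
  n <- dim(A)[3L]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  k <- dim(A)[1L]
  cs <- numeric(n)
  for (i in seq_len(n)) {
    A[, , i] <- sweep(A[, , i], 2L, colMeans(A[, , i]))
    cs[i] <- sqrt(sum(A[, , i]^2))
    if (cs[i] == 0) stop("degenerate (zero-size) configuration at index ", i)
    A[, , i] <- A[, , i] / cs[i]
  }
  C <- A[, , 1L]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    A <- rotate_to_consensus(A, C)
    Cnew <- apply(A, c(1L, 2L), mean)
    Cnew <- sweep(Cnew, 2L, colMeans(Cnew))
    Cnew <- Cnew / sqrt(sum(Cnew^2))
    delta <- sqrt(mean((Cnew - C)^2))
    C <- Cnew
    if (delta < tol) { converged <- TRUE; break }
  }
  ## canonical orientation: consensus landmark 1 on the positive x-axis
  th <- atan2(C[1L, 2L], C[1L, 1L])
  if (abs(th) > 0) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    C <- C %*% R
    for (i in seq_len(n)) A[, , i] <- A[, , i] %*% R
    A <- rotate_to_consensus(A, C)
  }
  structure(list(consensus = C, aligned = A, centroid_sizes = cs,
                 iterations = iter, converged = converged),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes fit\n")
  cat(sprintf("  configurations: %d   landmarks: %d\n",
              dim(x$aligned)[3L], dim(x$aligned)[1L]))
  cat(sprintf("  iterations: %d   converged: %s\n", x$iterations, x$converged))
  cat(sprintf("  centroid size range: [%.4g, %.4g]\n",
              min(x$centroid_sizes), max(x$centroid_sizes)))
  invisible(x)
}

## Accepts landmark_dataset, array, or list of matrices -> k x 2 x n array
coords_array <- function(x) {
  if (inherits(x, "landmark_dataset")) return(x$coords)
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[2L] != 2L) stop("coordinate array must be k x 2 x n")
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.list(x)) {
    mats <- lapply(x, as_config)
    ks <- vapply(mats, nrow, 1L)
    if (length(unique(ks)) != 1L) stop("all configurations must share k")
    A <- array(unlist(mats), dim = c(ks[1L], 2L, length(mats)))
    return(A)
  }
  stop("cannot interpret input as landmark configurations")
}

## Full Procrustes distance between two already-aligned unit-size shapes
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))
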