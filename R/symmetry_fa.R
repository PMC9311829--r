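#' Matching-symmetry decomposition
#'
#' Prepares a paired bilateral structure (e.g. left and right wings) for
#' FA analysis: all left-side configurations are reflected about the
#' y-axis so both sides share an orientation, then a joint generalized
#' Procrustes fit is run over every configuration. Individuals missing
#' one side entirely are excluded with a warning. Classifiers are
#' carried through unchanged.
#'
#' @param dataset a `landmark_dataset` with `symmetry_mode = "matching"`.
#' @param tol,max_iter forwarded to [gpa()].
#' @return an object of class `fa_decomposition` with elements `mode`
#'   (`"matching"`), `gpa` (the joint fit), `info` (classifiers for the
#'   retained configurations), `k`, and `excluded` (ids of dropped
#'   individuals).
#' @export
matching_decomposition <- function(dataset, tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (dataset$symmetry_mode != "matching")
    stop("matching_decomposition needs a matching-symmetry dataset")
  info <- dataset$info
  sides_per_ind <- tapply(info$side, info$individual,
                          function(s) length(unique(s)))
  incomplete <- names(sides_per_ind)[sides_per_ind < 2L]
  keep <- !(info$individual %in% incomplete)
  if (length(incomplete))
    warning("excluding individual(s) missing a side: ",
            paste(incomplete, collapse = ", "))
  if (sum(keep) < 4L) stop("too few complete individuals for decomposition")
  A <- dataset$coords[, , keep, drop = FALSE]
  info <- info[keep, , drop = FALSE]
  rownames(info) <- NULL
  left <- info$side == "left"
  A[, 1L, left] <- -A[, 1L, left]
  fit <- gpa(A, tol = tol, max_iter = max_iter)
  structure(list(mode = "matching", gpa = fit, info = info, k = dataset$k,
                 excluded = incomplete),
            class = "fa_decomposition")
}

## reflect about the y-axis and swap paired landmark labels
reflect_relabel <- function(config, pairing) {
  out <- config
  out[, 1L] <- -out[, 1L]
  perm <- seq_len(nrow(config))
  perm[pairing$pairs[, 1L]] <- pairing$pairs[, 2L]
  perm[pairing$pairs[, 2L]] <- pairing$pairs[, 1L]
  out[perm, , drop = FALSE]
}

#' Object-symmetry decomposition
#'
#' For a structure with an internal midline (e.g. a head), each
#' configuration is duplicated as a reflected copy with paired landmark
#' labels swapped (midline labels unchanged), and a joint generalized
#' Procrustes fit is run over the doubled set. The symmetric component
#' of each specimen is the mean of its original and reflected aligned
#' copies; the asymmetric component is half their difference.
#'
#' @param dataset a `landmark_dataset` with `symmetry_mode = "object"`
#'   and a valid pairing.
#' @param tol,max_iter forwarded to [gpa()].
#' @return an `fa_decomposition` with `mode = "object"`, the joint `gpa`
#'   over 2n configurations (originals first), `info`, `pairing`, and
#'   per-original-configuration `symmetric` and `asymmetric` component
#'   arrays (k x 2 x n).
#' @export
object_decomposition <- function(dataset, tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (dataset$symmetry_mode != "object")
    stop("object_decomposition needs an object-symmetry dataset")
  pairing <- validate_pairing(dataset$pairing$pairs, dataset$pairing$midline,
                              dataset$k)
  A <- dataset$coords
  n <- dim(A)[3L]
  doubled <- array(0, dim = c(dataset$k, 2L, 2L * n))
  doubled[, , seq_len(n)] <- A
  for (i in seq_len(n))
    doubled[, , n + i] <- reflect_relabel(A[, , i], pairing)
  fit <- gpa(doubled, tol = tol, max_iter = max_iter)
  orig <- fit$aligned[, , seq_len(n), drop = FALSE]
  refl <- fit$aligned[, , n + seq_len(n), drop = FALSE]
  structure(list(mode = "object", gpa = fit, info = dataset$info,
                 k = dataset$k, pairing = pairing,
                 symmetric = (orig + refl) / 2,
                 asymmetric = (orig - refl) / 2,
                 excluded = character()),
            class = "fa_decomposition")
}

#' @export
print.fa_decomposition <- function(x, ...) {
  cat(sprintf("FA decomposition (%s symmetry): %d configurations, k = %d\n",
              x$mode, nrow(x$info), x$k))
  if (length(x$excluded))
    cat("  excluded individuals:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Shape-space dimensions of the symmetry components
#'
#' For matching symmetry the shape dimension is `2k - 4`. For object
#' symmetry with p landmark pairs and m midline landmarks (2p + m = k),
#' the symmetric and asymmetric components each span `2p + m - 2`
#' dimensions; the implementation asserts that the two add up to
#' `2k - 4`.
#'
#' @param decomp an `fa_decomposition`.
#' @return named list with `total` and, for object mode, `symmetric` and
#'   `asymmetric`.
#' @export
shape_dimensions <- function(decomp) {
  k <- decomp$k
  total <- 2L * k - 4L
  if (decomp$mode == "matching") return(list(total = total))
  p <- nrow(decomp$pairing$pairs)
  m <- length(decomp$pairing$midline)
  dsym <- 2L * p + m - 2L
  dasym <- 2L * p + m - 2L
  stopifnot(dsym + dasym == total)
  list(total = total, symmetric = dsym, asymmetric = dasym)
}
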