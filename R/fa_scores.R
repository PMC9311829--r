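#' FA2 size-asymmetry index
#'
#' The size-standardized signed side difference
#' \deqn{FA2 = (R - L) / ((R + L)/2)}
#' where R and L are the sizes (here: centroid sizes) of the right and
#' left side. Antisymmetric under swapping R and L, invariant to
#' rescaling both sides, zero exactly when R = L.
#'
#' @param R,L positive side sizes (vectorized).
#' @return signed numeric vector.
#' @examples
#' fa2(11, 9)  # 0.2
#' @export
fa2 <- function(R, L) {
  if (any(!is.finite(R)) || any(!is.finite(L)) || any(R <= 0) || any(L <= 0))
    stop("side sizes must be positive and finite")
  (R - L) / ((R + L) / 2)
}

#' Per-individual fluctuating-asymmetry scores
#'
#' Computes, for every individual in a decomposed dataset, the signed
#' size asymmetry `fa2_size` (FA2 on the side centroid sizes) and the
#' non-negative shape asymmetry `fa_shape` (the Procrustes distance
#' between the individual's two side configurations after subtracting
#' the sample-mean directional asymmetry). Replicate measurements are
#' averaged before scoring. The sign convention is right minus left.
#'
#' Under matching symmetry the side sizes are the centroid sizes of the
#' raw left/right configurations (replicate-averaged). Under object
#' symmetry "sides" are the pairing-defined left and right landmark
#' subsets of the whole structure, and the shape asymmetry is twice the
#' norm of the individual's mean asymmetric component after directional
#' correction (the Procrustes distance between the original and its
#' reflected relabeled copy, directionally corrected).
#'
#' @param decomp an `fa_decomposition`.
#' @return a data frame of class `fa_scores`: `individual`, `fa2_size`,
#'   `fa_shape`, `size_right`, `size_left`, `n_configs`, plus any
#'   `nest`/`location`/`species` classifiers (constant per individual).
#' @export
fa_scores <- function(decomp) {
  stopifnot(inherits(decomp, "fa_decomposition"))
  if (decomp$mode == "matching") fa_scores_matching(decomp)
  else fa_scores_object(decomp)
}

carry_classifiers <- function(info, individuals) {
  out <- data.frame(individual = individuals, stringsAsFactors = FALSE)
  for (col in intersect(c("nest", "location", "species", "pool_id"),
                        names(info))) {
    v <- tapply(as.character(info[[col]]), info$individual,
                function(x) x[1L])
    out[[col]] <- unname(v[individuals])
  }
  out
}

fa_scores_matching <- function(decomp) {
  info <- decomp$info
  A <- decomp$gpa$aligned
  cs <- decomp$gpa$centroid_sizes
  k2 <- decomp$k * 2L
  Y <- t(matrix(A, nrow = k2, ncol = dim(A)[3L]))
  inds <- unique(info$individual)
  key <- paste(info$individual, info$side, sep = "\r")
  Ym <- rowsum(Y, key, reorder = FALSE) /
    as.vector(table(factor(key, levels = unique(key))))
  csm <- tapply(cs, key, mean)
  rget <- function(ind, side) Ym[match(paste(ind, side, sep = "\r"),
                                       rownames(Ym)), ]
  diffs <- do.call(rbind, lapply(inds, function(i) rget(i, "right") - rget(i, "left")))
  da <- colMeans(diffs)
  fa_shape <- sqrt(rowSums(sweep(diffs, 2L, da)^2))
  size_r <- unname(csm[paste(inds, "right", sep = "\r")])
  size_l <- unname(csm[paste(inds, "left", sep = "\r")])
  out <- carry_classifiers(info, inds)
  out$fa2_size <- fa2(size_r, size_l)
  out$fa_shape <- fa_shape
  out$size_right <- size_r
  out$size_left <- size_l
  out$n_configs <- as.vector(table(factor(info$individual, levels = inds)))
  class(out) <- c("fa_scores", "data.frame")
  out
}

fa_scores_object <- function(decomp) {
  info <- decomp$info
  n <- dim(decomp$asymmetric)[3L]
  k2 <- decomp$k * 2L
  As <- t(matrix(decomp$asymmetric, nrow = k2, ncol = n))
  inds <- unique(info$individual)
  Am <- rowsum(As, info$individual, reorder = FALSE) /
    as.vector(table(factor(info$individual, levels = unique(info$individual))))
  Am <- Am[match(inds, rownames(Am)), , drop = FALSE]
  da <- colMeans(As)
  fa_shape <- 2 * sqrt(rowSums(sweep(Am, 2L, da)^2))
  ## side sizes from the pairing-defined subsets of the raw coordinates
  pr <- decomp$pairing
  left_idx <- pr$pairs[, 1L]
  right_idx <- pr$pairs[, 2L]
  raw <- decomp$gpa$aligned[, , seq_len(n), drop = FALSE]
  cs <- decomp$gpa$centroid_sizes[seq_len(n)]
  size_of_subset <- function(i, idx)
    centroid_size(raw[idx, , i, drop = FALSE][, , 1L] * cs[i])
  sl <- vapply(seq_len(n), size_of_subset, 0, idx = left_idx)
  sr <- vapply(seq_len(n), size_of_subset, 0, idx = right_idx)
  size_l <- unname(tapply(sl, info$individual, mean)[inds])
  size_r <- unname(tapply(sr, info$individual, mean)[inds])
  out <- carry_classifiers(info, inds)
  out$fa2_size <- fa2(size_r, size_l)
  out$fa_shape <- fa_shape
  out$size_right <- size_r
  out$size_left <- size_l
  out$n_configs <- as.vector(table(factor(info$individual, levels = inds)))
  class(out) <- c("fa_scores", "data.frame")
  out
}

#' @export
print.fa_scores <- function(x, ...) {
  cat(sprintf("FA scores for %d individuals\n", nrow(x)))
  cat(sprintf("  fa2_size: mean %.4g, sd %.4g;  fa_shape: mean %.4g\n",
              mean(x$fa2_size), sd(x$fa2_size), mean(x$fa_shape)))
  NextMethod()
}
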