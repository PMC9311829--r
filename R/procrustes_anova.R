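## Expand per-group means back to one row per observation.
## f: factor-like; Y: n x p matrix. Returns n x p matrix of group means.
expand_means <- function(Y, f) {
  f <- as.character(f)
  M <- rowsum(Y, f, reorder = FALSE)
  cnt <- as.vector(table(factor(f, levels = rownames(M))))
  (M / cnt)[match(f, rownames(M)), , drop = FALSE]
}

ssq <- function(x) sum(x^2)

harmonic_mean <- function(x) length(x) / sum(1 / x)

#' Procrustes analysis of variance
#'
#' Goodall-style variance partitioning of superimposed landmark
#' coordinates: sums of squares are accumulated over all landmarks and
#' both coordinates at each stratum of the nested design, and degrees of
#' freedom are the conventional univariate df multiplied by the shape
#' dimension (`2k - 4` under matching symmetry; the symmetric /
#' asymmetric subspace dimensions under object symmetry, see
#' [shape_dimensions()]).
#'
#' Under matching symmetry the strata are individual, directional
#' asymmetry (the side main effect), fluctuating asymmetry (the
#' individual-by-side interaction), then imaging and digitizing error
#' where replicate images/digitizations exist. Under object symmetry the
#' symmetric component carries location (when >1 present) and individual
#' effects, the asymmetric component the directional and fluctuating
#' asymmetry effects, and replicate strata are computed on both
#' components jointly. Each F ratio uses the mean square of the next
#' stratum down as its denominator (individual and directional
#' asymmetry are both tested over fluctuating asymmetry); the lowest
#' stratum has no F or p. Without replicate measurements the
#' object-symmetry FA row therefore carries no F or p.
#'
#' With a balanced replicate structure the effect sums of squares plus
#' the residual add up to the total exactly. Unbalanced crossed designs
#' (matching mode) are handled by computing the upper strata from
#' side-by-individual cell means with harmonic-mean replicate weighting;
#' the table is then flagged `balanced = FALSE` and additivity is
#' approximate. Purely nested strata are exact regardless of balance.
#'
#' @param decomp an `fa_decomposition` from [matching_decomposition()]
#'   or [object_decomposition()].
#' @param effects optional character vector naming the effects to keep
#'   (in table order); dropping effects breaks SS additivity and warns.
#' @return a data frame of class `procrustes_anova` with columns
#'   `effect`, `SS`, `MS`, `df`, `F`, `p`, and attributes `total_SS`,
#'   `balanced`, `dims`, `mode`.
#' @export
procrustes_anova <- function(decomp, effects = NULL) {
  stopifnot(inherits(decomp, "fa_decomposition"))
  tab <- if (decomp$mode == "matching") anova_matching(decomp)
         else anova_object(decomp)
  if (!is.null(effects)) {
    keep <- tab$effect %in% effects
    if (!all(keep))
      warning("dropping effect rows breaks SS additivity: ",
              paste(tab$effect[!keep], collapse = ", "))
    att <- attributes(tab)
    tab <- tab[keep, , drop = FALSE]
    rownames(tab) <- NULL
    for (a in c("total_SS", "balanced", "dims", "mode"))
      attr(tab, a) <- att[[a]]
    class(tab) <- c("procrustes_anova", "data.frame")
  }
  tab
}

finish_anova <- function(rows, denom_map, total_ss, balanced, dims, mode) {
  tab <- do.call(rbind, lapply(rows, as.data.frame))
  tab$MS <- tab$SS / tab$df
  tab$F <- NA_real_
  tab$p <- NA_real_
  for (i in seq_len(nrow(tab))) {
    den <- denom_map[[tab$effect[i]]]
    if (!is.null(den) && den %in% tab$effect) {
      j <- match(den, tab$effect)
      tab$F[i] <- tab$MS[i] / tab$MS[j]
      tab$p[i] <- pf(tab$F[i], tab$df[i], tab$df[j], lower.tail = FALSE)
    }
  }
  tab <- tab[, c("effect", "SS", "MS", "df", "F", "p")]
  rownames(tab) <- NULL
  structure(tab, total_SS = total_ss, balanced = balanced, dims = dims,
            mode = mode, class = c("procrustes_anova", "data.frame"))
}

anova_matching <- function(decomp) {
  dims <- shape_dimensions(decomp)$total
  A <- decomp$gpa$aligned
  n_obs <- dim(A)[3L]
  Y <- t(matrix(A, nrow = dim(A)[1L] * 2L, ncol = n_obs))
  info <- decomp$info
  ind <- as.character(info$individual)
  side <- as.character(info$side)
  cell <- paste(ind, side, sep = "\r")
  ism <- paste(cell, info$image_rep, sep = "\r")
  n_ind <- length(unique(ind))
  has_img <- length(unique(info$image_rep)) > 1L
  has_digit <- length(unique(info$digit_rep)) > 1L
  grand <- matrix(colMeans(Y), n_obs, ncol(Y), byrow = TRUE)
  cell_counts <- table(cell)
  balanced <- length(unique(cell_counts)) == 1L
  if (has_img) {
    img_counts <- table(ism)
    balanced <- balanced && length(unique(img_counts)) == 1L &&
      length(unique(table(sub("\r[^\r]*$", "", names(img_counts))))) == 1L
  }
  if (balanced) {
    E_ind <- expand_means(Y, ind)
    E_side <- expand_means(Y, side)
    E_cell <- expand_means(Y, cell)
    ss_ind <- ssq(E_ind - grand)
    ss_da <- ssq(E_side - grand)
    ss_fa <- ssq(E_cell - E_ind - E_side + grand)
  } else {
    ## harmonic-mean weighting on side-by-individual cell means
    Cm <- rowsum(Y, cell, reorder = FALSE) /
      as.vector(table(factor(cell, levels = unique(cell))))
    key <- do.call(rbind, strsplit(rownames(Cm), "\r", fixed = TRUE))
    w <- harmonic_mean(as.vector(cell_counts))
    g <- matrix(colMeans(Cm), nrow(Cm), ncol(Cm), byrow = TRUE)
    Ei <- expand_means(Cm, key[, 1L])
    Es <- expand_means(Cm, key[, 2L])
    ss_ind <- w * ssq(Ei - g)
    ss_da <- w * ssq(Es - g)
    ss_fa <- w * ssq(Cm - Ei - Es + g)
    E_cell <- expand_means(Y, cell)
  }
  rows <- list(
    list(effect = "individual", SS = ss_ind, df = (n_ind - 1L) * dims),
    list(effect = "directional_asymmetry", SS = ss_da, df = 1L * dims),
    list(effect = "fluctuating_asymmetry", SS = ss_fa, df = (n_ind - 1L) * dims)
  )
  n_cells <- length(unique(cell))
  if (has_img && has_digit) {
    E_ism <- expand_means(Y, ism)
    n_ism <- length(unique(ism))
    rows <- c(rows, list(
      list(effect = "imaging_error", SS = ssq(E_ism - E_cell),
           df = (n_ism - n_cells) * dims),
      list(effect = "digitizing_error", SS = ssq(Y - E_ism),
           df = (n_obs - n_ism) * dims)))
  } else if (has_img) {
    rows <- c(rows, list(
      list(effect = "imaging_error", SS = ssq(Y - E_cell),
           df = (n_obs - n_cells) * dims)))
  } else if (has_digit) {
    rows <- c(rows, list(
      list(effect = "digitizing_error", SS = ssq(Y - E_cell),
           df = (n_obs - n_cells) * dims)))
  }
  present <- vapply(rows, `[[`, "", "effect")
  err1 <- intersect(c("imaging_error", "digitizing_error"), present)
  denom <- list(individual = "fluctuating_asymmetry",
                directional_asymmetry = "fluctuating_asymmetry",
                fluctuating_asymmetry = if (length(err1)) err1[1L] else NULL,
                imaging_error = if ("digitizing_error" %in% present)
                  "digitizing_error" else NULL)
  finish_anova(rows, denom, total_ss = ssq(Y - grand), balanced = balanced,
               dims = list(total = dims), mode = "matching")
}

anova_object <- function(decomp) {
  dims <- shape_dimensions(decomp)
  n_obs <- dim(decomp$symmetric)[3L]
  k2 <- decomp$k * 2L
  S <- t(matrix(decomp$symmetric, nrow = k2, ncol = n_obs))
  As <- t(matrix(decomp$asymmetric, nrow = k2, ncol = n_obs))
  V <- cbind(S, As)
  info <- decomp$info
  ind <- as.character(info$individual)
  n_ind <- length(unique(ind))
  has_loc <- !is.null(info$location) && length(unique(info$location)) > 1L
  has_img <- length(unique(info$image_rep)) > 1L
  has_digit <- length(unique(info$digit_rep)) > 1L
  gS <- matrix(colMeans(S), n_obs, ncol(S), byrow = TRUE)
  gA <- matrix(colMeans(As), n_obs, ncol(As), byrow = TRUE)
  EiS <- expand_means(S, ind)
  EiA <- expand_means(As, ind)
  rows <- list()
  if (has_loc) {
    loc <- as.character(info$location)
    ElS <- expand_means(S, loc)
    n_loc <- length(unique(loc))
    rows <- c(rows, list(
      list(effect = "location", SS = ssq(ElS - gS),
           df = (n_loc - 1L) * dims$symmetric)))
    ss_ind <- ssq(EiS - ElS)
    df_ind <- (n_ind - n_loc) * dims$symmetric
  } else {
    ss_ind <- ssq(EiS - gS)
    df_ind <- (n_ind - 1L) * dims$symmetric
  }
  rows <- c(rows, list(
    list(effect = "individual", SS = ss_ind, df = df_ind),
    list(effect = "directional_asymmetry", SS = ssq(gA),
         df = 1L * dims$asymmetric),
    list(effect = "fluctuating_asymmetry", SS = ssq(EiA - gA),
         df = (n_ind - 1L) * dims$asymmetric)))
  EiV <- cbind(EiS, EiA)
  if (has_img || has_digit) {
    im <- paste(ind, info$image_rep, sep = "\r")
    n_im <- length(unique(im))
    if (has_img && has_digit && n_im > n_ind && n_obs > n_im) {
      EimV <- expand_means(V, im)
      rows <- c(rows, list(
        list(effect = "imaging_error", SS = ssq(EimV - EiV),
             df = (n_im - n_ind) * dims$total),
        list(effect = "digitizing_error", SS = ssq(V - EimV),
             df = (n_obs - n_im) * dims$total)))
    } else {
      nm <- if (has_img) "imaging_error" else "digitizing_error"
      rows <- c(rows, list(
        list(effect = nm, SS = ssq(V - EiV),
             df = (n_obs - n_ind) * dims$total)))
    }
  }
  present <- vapply(rows, `[[`, "", "effect")
  err1 <- intersect(c("imaging_error", "digitizing_error"), present)
  denom <- list(location = "individual",
                individual = "fluctuating_asymmetry",
                directional_asymmetry = "fluctuating_asymmetry",
                fluctuating_asymmetry = if (length(err1)) err1[1L] else NULL,
                imaging_error = if ("digitizing_error" %in% present)
                  "digitizing_error" else NULL)
  total <- ssq(S - gS) + ssq(As)
  finish_anova(rows, denom, total_ss = total, balanced = TRUE, dims = dims,
               mode = "object")
}

#' @export
print.procrustes_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Procrustes ANOVA (%s symmetry)%s\n", attr(x, "mode"),
              if (isTRUE(attr(x, "balanced"))) "" else "  [unbalanced design]"))
  df <- as.data.frame(x)
  df$SS <- signif(df$SS, digits)
  df$MS <- signif(df$MS, digits)
  df$F <- ifelse(is.na(df$F), "-", formatC(df$F, digits = 3, format = "fg"))
  df$p <- ifelse(is.na(df$p), "-",
                 ifelse(as.data.frame(x)$p < 1e-4, "<0.0001",
                        formatC(as.data.frame(x)$p, digits = 4, format = "f")))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Measurement-error study
#'
#' Runs the Procrustes ANOVA on a dataset with duplicated imaging and/or
#' digitizing measurements and tests, per error stratum, whether the
#' individual and fluctuating-asymmetry mean squares significantly
#' exceed the error mean square (F tests at `alpha`). The verdict
#' "errors nonsignificant" means biological variation dominates
#' measurement error at every tested stratum, the precondition for
#' interpreting FA downstream.
#'
#' @param decomp an `fa_decomposition` whose design includes at least
#'   one replicate stratum (refused otherwise).
#' @param alpha significance level for the stratum verdicts.
#' @return list with `anova` (the full table) and `verdicts` (one row
#'   per error stratum: F and p for FA over error and individual over
#'   error, and the verdict string).
#' @export
error_study <- function(decomp, alpha = 0.05) {
  stopifnot(inherits(decomp, "fa_decomposition"))
  info <- decomp$info
  if (length(unique(info$image_rep)) == 1L &&
      length(unique(info$digit_rep)) == 1L)
    stop("no replicate imaging or digitizing measurements: ",
         "an error study requires image_rep or digit_rep > 1 for a subset")
  tab <- procrustes_anova(decomp)
  strata <- intersect(c("imaging_error", "digitizing_error"), tab$effect)
  get <- function(e, col) tab[[col]][match(e, tab$effect)]
  verdicts <- do.call(rbind, lapply(strata, function(s) {
    fa_F <- get("fluctuating_asymmetry", "MS") / get(s, "MS")
    fa_p <- pf(fa_F, get("fluctuating_asymmetry", "df"), get(s, "df"),
               lower.tail = FALSE)
    ind_F <- get("individual", "MS") / get(s, "MS")
    ind_p <- pf(ind_F, get("individual", "df"), get(s, "df"),
                lower.tail = FALSE)
    data.frame(stratum = s, F_fa = fa_F, p_fa = fa_p, F_ind = ind_F,
               p_ind = ind_p,
               verdict = if (fa_p < alpha && ind_p < alpha)
                 "errors nonsignificant" else "error not negligible",
               stringsAsFactors = FALSE)
  }))
  rownames(verdicts) <- NULL
  list(anova = tab, verdicts = verdicts)
}
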