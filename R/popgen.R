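#' Construct a diploid genotype table
#'
#' Microsatellite genotypes for diploid individuals: two alleles per
#' locus per individual, expressed in repeat units (allele size in base
#' pairs divided by the repeat-motif length). Missing calls are `NA` in
#' both allele matrices.
#'
#' @param a1,a2 n x L numeric matrices of allele calls (repeat units,
#'   positive); `NA` = missing. The pair is unordered; callers need not
#'   sort.
#' @param ids individual identifiers (length n).
#' @param loci locus names (length L).
#' @param groups optional data frame (n rows) of group labels such as
#'   `species`, `location`, `nest`, `pool_id`.
#' @param motif optional named numeric vector of repeat-motif lengths
#'   per locus (informational once alleles are in repeat units).
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(a1, a2, ids = NULL, loci = NULL, groups = NULL,
                           motif = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!identical(dim(a1), dim(a2))) stop("a1 and a2 must have equal dimensions")
  n <- nrow(a1); L <- ncol(a1)
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(n))
  if (is.null(loci)) loci <- colnames(a1)
  if (is.null(loci)) loci <- sprintf("locus%02d", seq_len(L))
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing genotype calls (one allele NA) are not allowed")
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele calls must be positive (repeat units)")
  if (!is.null(groups)) {
    groups <- as.data.frame(groups, stringsAsFactors = FALSE)
    if (nrow(groups) != n) stop("groups must have one row per individual")
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2, groups = groups,
                 motif = motif),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  typed <- !is.na(x$a1)
  cat(sprintf("Genotype table: %d individuals x %d loci (%.1f%% typed)\n",
              length(x$ids), length(x$loci), 100 * mean(typed)))
  invisible(x)
}

#' Read genotypes from a CSV table
#'
#' Expects a header row with an `individual` column, optional group
#' columns (`species`, `location`, `nest`, `pool_id`), and one column
#' per locus containing `"a1/a2"` allele pairs; empty cells, `NA`, or
#' `0/0` denote missing calls.
#'
#' @param path CSV file path.
#' @param motifs optional named numeric vector of motif lengths; when
#'   supplied, allele calls are divided by the motif length on load
#'   (base pairs to repeat units).
#' @return a `genotype_table`.
#' @export
read_genotypes_csv <- function(path, motifs = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"individual" %in% names(df)) stop("genotype CSV needs an 'individual' column")
  group_cols <- intersect(c("species", "location", "nest", "pool_id"), names(df))
  locus_cols <- setdiff(names(df), c("individual", group_cols))
  if (!length(locus_cols)) stop("genotype CSV has no locus columns")
  parse_col <- function(v) {
    v[v %in% c("", "NA", "0/0")] <- NA
    parts <- strsplit(v, "/", fixed = TRUE)
    bad <- !is.na(v) & lengths(parts) != 2L
    if (any(bad)) stop("malformed genotype call(s): ",
                       paste(unique(v[bad]), collapse = ", "))
    a1 <- vapply(parts, function(p) if (length(p) == 2L)
      as.numeric(p[1L]) else NA_real_, 0)
    a2 <- vapply(parts, function(p) if (length(p) == 2L)
      as.numeric(p[2L]) else NA_real_, 0)
    cbind(a1, a2)
  }
  mats <- lapply(df[locus_cols], parse_col)
  a1 <- do.call(cbind, lapply(mats, `[`, , 1L))
  a2 <- do.call(cbind, lapply(mats, `[`, , 2L))
  colnames(a1) <- colnames(a2) <- locus_cols
  if (!is.null(motifs)) {
    mm <- motifs[locus_cols]
    if (anyNA(mm)) stop("motif length missing for locus/loci: ",
                        paste(locus_cols[is.na(mm)], collapse = ", "))
    a1 <- sweep(a1, 2L, mm, `/`)
    a2 <- sweep(a2, 2L, mm, `/`)
  }
  genotype_table(a1, a2, ids = df$individual, loci = locus_cols,
                 groups = if (length(group_cols)) df[group_cols] else NULL,
                 motif = motifs)
}

#' Write genotypes to a CSV table
#'
#' Inverse of [read_genotypes_csv()] (without motif conversion).
#'
#' @param table a `genotype_table`.
#' @param path output CSV path.
#' @return `invisible(path)`.
#' @export
write_genotypes_csv <- function(table, path) {
  df <- data.frame(individual = table$ids, stringsAsFactors = FALSE)
  if (!is.null(table$groups)) df <- cbind(df, table$groups)
  for (l in table$loci) {
    v <- ifelse(is.na(table$a1[, l]), NA,
                paste0(table$a1[, l], "/", table$a2[, l]))
    df[[l]] <- v
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read genotypes from a Genepop file
#'
#' Supports the de-facto Genepop dialect: a title line, locus names
#' (one per line or comma-separated), `Pop` section markers, and
#' individual lines `id , 0102 0304 ...` with 2- or 3-digit allele
#' encodings; `0000`/`000000` (or any all-zero allele) denotes missing.
#' `Pop` sections become a `location` group column.
#'
#' @param path Genepop file path.
#' @param motifs optional named numeric vector of motif lengths (base
#'   pairs per repeat); allele calls are divided by it on load.
#' @return a `genotype_table`.
#' @export
read_genepop <- function(path, motifs = NULL) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("Genepop file too short")
  body <- lines[-1L]
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("Genepop file has no 'Pop' marker")
  locus_lines <- body[seq_len(pop_idx[1L] - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(); pops <- integer(); calls <- list()
  pop <- 0L
  for (ln in body[pop_idx[1L]:length(body)]) {
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) { pop <- pop + 1L; next }
    parts <- strsplit(ln, ",")[[1L]]
    if (length(parts) < 2L) stop("malformed Genepop individual line: ", ln)
    id <- trimws(parts[1L])
    geno <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
    if (length(geno) != length(loci))
      stop("individual '", id, "' has ", length(geno), " genotype fields, ",
           "expected ", length(loci))
    w <- nchar(geno)
    if (!all(w %in% c(4L, 6L)))
      stop("allele encoding must be 2- or 3-digit: ",
           geno[which(!w %in% c(4L, 6L))[1L]])
    half <- w %/% 2L
    a1 <- as.numeric(substr(geno, 1L, half))
    a2 <- as.numeric(substr(geno, half + 1L, w))
    a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA; a2[miss] <- NA
    ids <- c(ids, id); pops <- c(pops, pop)
    calls[[length(calls) + 1L]] <- rbind(a1, a2)
  }
  a1 <- do.call(rbind, lapply(calls, `[`, 1L, ))
  a2 <- do.call(rbind, lapply(calls, `[`, 2L, ))
  colnames(a1) <- colnames(a2) <- loci
  if (!is.null(motifs)) {
    mm <- motifs[loci]
    if (anyNA(mm)) stop("motif length missing for locus/loci: ",
                        paste(loci[is.na(mm)], collapse = ", "))
    a1 <- sweep(a1, 2L, mm, `/`)
    a2 <- sweep(a2, 2L, mm, `/`)
  }
  genotype_table(a1, a2, ids = ids, loci = loci,
                 groups = data.frame(location = paste0("pop", pops),
                                     stringsAsFactors = FALSE),
                 motif = motifs)
}

#' Observed and expected heterozygosity at a locus
#'
#' `Ho` is the fraction of heterozygous individuals among those typed;
#' `He` is the unbiased expected heterozygosity
#' \eqn{\frac{2n}{2n-1}\,(1 - \sum_i \hat p_i^2)} from the sample allele
#' frequencies (small-sample correction appropriate for the small
#' per-nest samples typical of field collections).
#'
#' @param table a `genotype_table`.
#' @param locus locus name or index.
#' @return named numeric vector `c(Ho = , He = )`.
#' @export
het_stats <- function(table, locus) {
  g <- locus_calls(table, locus)
  n <- length(g$a1)
  if (n == 0L) stop("no typed individuals at locus ", locus)
  ho <- mean(g$a1 != g$a2)
  p <- table(c(g$a1, g$a2)) / (2 * n)
  he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  c(Ho = ho, He = he)
}

locus_calls <- function(table, locus) {
  a1 <- table$a1[, locus]; a2 <- table$a2[, locus]
  ok <- !is.na(a1)
  list(a1 = a1[ok], a2 = a2[ok], ids = table$ids[ok])
}

## log Levene probability of a genotype-count table conditional on
## allele counts: log[ n! prod(c_a!) 2^H / ((2n)! prod(d_ab!)) ]
log_levene <- function(d, allele_counts) {
  n <- sum(d)
  het <- sum(d) - sum(diag(as.matrix(d)))
  lgamma(n + 1) + sum(lgamma(allele_counts + 1)) + het * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(d + 1))
}

genotype_count_matrix <- function(a1, a2, alleles) {
  K <- length(alleles)
  i <- match(pmin(a1, a2), alleles)
  j <- match(pmax(a1, a2), alleles)
  matrix(tabulate(i + (j - 1L) * K, K * K), K, K,
         dimnames = list(alleles, alleles))
}

#' Exact Hardy-Weinberg test for one locus
#'
#' The exact conditional test: given the observed allele counts, the
#' p-value is the probability, under the multivariate-hypergeometric
#' (Levene) null, of genotype arrays at least as improbable as the one
#' observed. The full genotype-array space is enumerated when small
#' enough; otherwise a Monte-Carlo version shuffles the allele vector
#' into random pairs.
#'
#' @param table a `genotype_table` (missing calls ignored per locus).
#' @param locus locus name or index.
#' @param method `"auto"` (enumerate when the array space is below
#'   `enum_limit`, else Monte-Carlo), `"enumeration"`, or
#'   `"montecarlo"`.
#' @param B Monte-Carlo permutation count (>= 1e4 recommended).
#' @param seed optional integer seed for the Monte-Carlo draw.
#' @param enum_limit cap on enumerated genotype arrays for `"auto"`.
#' @return the p-value; 1 (with a message) for a monomorphic locus.
#' @export
hwe_exact <- function(table, locus, method = c("auto", "enumeration",
                                               "montecarlo"),
                      B = 10000L, seed = NULL, enum_limit = 1e6) {
  method <- match.arg(method)
  g <- locus_calls(table, locus)
  if (!length(g$a1)) stop("no typed individuals at locus ", locus)
  alleles <- sort(unique(c(g$a1, g$a2)))
  if (length(alleles) < 2L) {
    message("locus ", locus, " is monomorphic; HWE p = 1")
    return(1)
  }
  counts <- as.vector(table(factor(c(g$a1, g$a2), levels = alleles)))
  d_obs <- genotype_count_matrix(g$a1, g$a2, alleles)
  lp_obs <- log_levene(d_obs, counts)
  if (method == "auto") {
    n_arrays <- count_genotype_arrays(counts, cap = enum_limit)
    method <- if (!is.na(n_arrays)) "enumeration" else "montecarlo"
  }
  if (method == "enumeration") {
    hwe_enumerate(counts, lp_obs)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    pool <- rep(alleles, counts)
    hits <- 0L
    npair <- length(pool) / 2
    for (b in seq_len(B)) {
      v <- sample(pool)
      d <- genotype_count_matrix(v[seq_len(npair) * 2 - 1], v[seq_len(npair) * 2],
                                 alleles)
      if (log_levene(d, counts) <= lp_obs + 1e-9) hits <- hits + 1L
    }
    (hits + 1) / (B + 1)
  }
}

## cheap upper bound on the number of genotype-count arrays consistent
## with the allele counts (product of per-cell ranges for the free,
## off-diagonal-above-first-row cells); NA when it exceeds `cap`.
count_genotype_arrays <- function(counts, cap = 1e6) {
  K <- length(counts)
  lb <- 0
  for (i in seq_len(K)) for (j in i:K) {
    rng <- if (i == j) counts[i] %/% 2L else min(counts[i], counts[j])
    lb <- lb + log1p(rng)
    if (lb > log(cap)) return(NA)
  }
  exp(lb)
}

hwe_enumerate <- function(counts, lp_obs) {
  K <- length(counts)
  total <- 0
  d <- matrix(0L, K, K)
  recurse <- function(rem, i, j) {
    if (i > K) {
      lp <- log_levene(d, counts)
      if (lp <= lp_obs + 1e-9) total <<- total + exp(lp)
      return()
    }
    if (j > K) { if (rem[i] == 0L) recurse(rem, i + 1L, i + 1L); return() }
    if (i == j) {
      for (v in 0:(rem[i] %/% 2L)) {
        d[i, j] <<- v
        r <- rem; r[i] <- r[i] - 2L * v
        recurse(r, i, j + 1L)
      }
      d[i, j] <<- 0L
    } else {
      for (v in 0:min(rem[i], rem[j])) {
        d[i, j] <<- v
        r <- rem; r[i] <- r[i] - v; r[j] <- r[j] - v
        recurse(r, i, j + 1L)
      }
      d[i, j] <<- 0L
    }
  }
  recurse(as.integer(counts), 1L, 1L)
  min(total, 1)
}

#' Genotypic linkage-disequilibrium permutation test
#'
#' Log-likelihood-ratio (G) statistic on the two-locus genotypic
#' contingency table (no haplotype-phase estimation), with the p-value
#' obtained by permuting one locus's genotypes across the shared typed
#' individuals. The +1 permutation correction keeps p strictly positive,
#' so the minimum attainable p is `1/(n_perm + 1)`.
#'
#' @param table a `genotype_table`.
#' @param locusA,locusB locus names or indices.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return the permutation p-value.
#' @export
ld_test <- function(table, locusA, locusB, n_perm = 1000L, seed = NULL) {
  a <- paste(pmin(table$a1[, locusA], table$a2[, locusA]),
             pmax(table$a1[, locusA], table$a2[, locusA]))
  b <- paste(pmin(table$a1[, locusB], table$a2[, locusB]),
             pmax(table$a1[, locusB], table$a2[, locusB]))
  ok <- !is.na(table$a1[, locusA]) & !is.na(table$a1[, locusB])
  if (!any(ok)) stop("no individuals typed at both loci")
  a <- factor(a[ok]); b <- factor(b[ok])
  g_stat <- function(a, b) {
    o <- table(a, b)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    nz <- o > 0
    2 * sum(o[nz] * log(o[nz] / e[nz]))
  }
  g_obs <- g_stat(a, b)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  hits <- 0L
  for (i in seq_len(n_perm))
    if (g_stat(a, sample(b)) >= g_obs - 1e-9) hits <- hits + 1L
  (hits + 1) / (n_perm + 1)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Step-down Holm correction controlling the family-wise error rate:
#' with m p-values sorted ascending, the i-th adjusted value is
#' \eqn{\max_{j \le i} \min(1, (m - j + 1)\,p_{(j)})}, mapped back to
#' the input order. Never decreases a p-value and is monotone in the
#' sorted order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
holm_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(!is.finite(pvals)) ||
      any(pvals < 0) || any(pvals > 1))
    stop("p-values must be finite and lie in [0, 1]")
  p.adjust(pvals, method = "holm")
}

#' Per-individual inbreeding indices
#'
#' Multilocus heterozygosity (`mlh`: the fraction of typed loci at which
#' the individual is heterozygous) and mean squared allele distance
#' (`d2`: the mean over typed loci of the squared difference between the
#' two alleles, in repeat units). Individuals typed at zero loci are
#' omitted with a warning. `d2` depends only on allele differences, so
#' it is invariant to any additive relabeling of alleles.
#'
#' @param table a `genotype_table` with alleles in repeat units.
#' @return data frame of class `inbreeding_indices`: `individual`,
#'   `mlh`, `d2`, `n_typed`, plus any group columns.
#' @export
inbreeding_indices <- function(table) {
  typed <- !is.na(table$a1)
  n_typed <- rowSums(typed)
  keep <- n_typed > 0L
  if (any(!keep))
    warning("omitting individual(s) with no typed loci: ",
            paste(table$ids[!keep], collapse = ", "))
  het <- (table$a1 != table$a2) & typed
  sqd <- (table$a1 - table$a2)^2
  sqd[!typed] <- 0
  out <- data.frame(individual = table$ids[keep],
                    mlh = rowSums(het, na.rm = TRUE)[keep] / n_typed[keep],
                    d2 = rowSums(sqd)[keep] / n_typed[keep],
                    n_typed = n_typed[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(table$groups)) out <- cbind(out, table$groups[keep, , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("inbreeding_indices", "data.frame")
  out
}

#' Marker-quality screen for all loci
#'
#' Per-locus observed/expected heterozygosity and exact HWE p-values,
#' and per-locus-pair genotypic LD permutation p-values, each with
#' Holm-adjusted companions (adjusted within the HWE family and within
#' the LD family separately).
#'
#' @param table a `genotype_table`.
#' @param B Monte-Carlo permutations for [hwe_exact()].
#' @param n_perm permutations for [ld_test()].
#' @param seed integer seed used for both test families.
#' @return list with data frames `loci` (locus, Ho, He, hwe_p,
#'   hwe_p_holm) and `pairs` (locusA, locusB, ld_p, ld_p_holm).
#' @export
locus_stats <- function(table, B = 10000L, n_perm = 1000L, seed = NULL) {
  L <- table$loci
  het <- t(vapply(L, function(l) het_stats(table, l), c(Ho = 0, He = 0)))
  hwe <- vapply(seq_along(L), function(i)
    suppressMessages(hwe_exact(table, L[i], B = B,
                               seed = if (is.null(seed)) NULL else seed + i)),
    0)
  loci_df <- data.frame(locus = L, Ho = het[, "Ho"], He = het[, "He"],
                        hwe_p = hwe, hwe_p_holm = holm_adjust(hwe),
                        stringsAsFactors = FALSE)
  rownames(loci_df) <- NULL
  prs <- if (length(L) >= 2L) t(utils::combn(L, 2L)) else
    matrix(character(), 0L, 2L)
  ld <- vapply(seq_len(nrow(prs)), function(i)
    ld_test(table, prs[i, 1L], prs[i, 2L], n_perm = n_perm,
            seed = if (is.null(seed)) NULL else seed + 1000L + i), 0)
  pairs_df <- data.frame(locusA = prs[, 1L], locusB = prs[, 2L], ld_p = ld,
                         ld_p_holm = if (length(ld)) holm_adjust(ld) else numeric(),
                         stringsAsFactors = FALSE)
  list(loci = loci_df, pairs = pairs_df)
}

#' Two-group comparison with normality-dependent test choice
#'
#' Mirrors the common field practice: Shapiro-Wilk normality check on
#' each group at `alpha`; when both pass, a Welch two-sample t-test,
#' otherwise a Mann-Whitney U test. For a batch of comparisons supplied
#' together, Holm adjustment is applied across the batch.
#'
#' @param values_by_group either a named list of two numeric vectors
#'   (one comparison) or a list of such two-group lists (a batch).
#' @param alpha significance level for the normality screen.
#' @return data frame with one row per comparison: `comparison`, `test`
#'   (`"t"` or `"mann-whitney"`), `statistic`, `p`, `p_holm`.
#' @export
compare_groups <- function(values_by_group, alpha = 0.05) {
  is_batch <- !all(vapply(values_by_group, is.numeric, TRUE))
  batch <- if (is_batch) values_by_group else list(values_by_group)
  if (is.null(names(batch))) names(batch) <- paste0("comparison", seq_along(batch))
  one <- function(grps) {
    if (length(grps) != 2L) stop("each comparison needs exactly two groups")
    x <- grps[[1L]]; y <- grps[[2L]]
    if (length(x) < 3L || length(y) < 3L)
      stop("each group needs n >= 3")
    normal <- function(v) length(unique(v)) > 1L && shapiro.test(v)$p.value > alpha
    if (normal(x) && normal(y)) {
      tt <- t.test(x, y)
      data.frame(test = "t", statistic = unname(tt$statistic),
                 p = tt$p.value, stringsAsFactors = FALSE)
    } else {
      wt <- suppressWarnings(wilcox.test(x, y))
      data.frame(test = "mann-whitney", statistic = unname(wt$statistic),
                 p = wt$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, lapply(batch, one))
  out <- cbind(data.frame(comparison = names(batch),
                          stringsAsFactors = FALSE), out)
  out$p_holm <- holm_adjust(out$p)
  rownames(out) <- NULL
  out
}
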