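ANALYTES <- c("Hg", "PCB28", "PCB52", "PCB101", "PCB138", "PCB153", "PCB180")

#' Read a pooled body-burden table
#'
#' Long-format CSV with fixed column names `pool_id`, `location`,
#' `taxon`, `analyte`, `conc_ugkg_fw` (concentration in micrograms per
#' kilogram fresh weight, non-negative). Recognized analytes are Hg,
#' the six indicator PCB congeners (28, 52, 101, 138, 153, 180), and
#' `sumPCB`; when all six congeners and `sumPCB` are present for a
#' pool, their consistency is checked within rounding and a mismatch
#' warns.
#'
#' @param path CSV file path.
#' @return a validated data frame of class `pooled_burden`.
#' @export
read_burdens <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_burdens(df)
}

#' @rdname read_burdens
#' @param df a data frame already in the burden layout.
#' @export
validate_burdens <- function(df) {
  need <- c("pool_id", "location", "taxon", "analyte", "conc_ugkg_fw")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("burden table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$analyte), c(ANALYTES, "sumPCB"))
  if (length(bad)) stop("unknown analyte(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(df$conc_ugkg_fw)) || any(df$conc_ugkg_fw < 0))
    stop("concentrations must be finite and non-negative")
  congeners <- setdiff(ANALYTES, "Hg")
  for (p in unique(df$pool_id)) {
    sub <- df[df$pool_id == p, ]
    if ("sumPCB" %in% sub$analyte && all(congeners %in% sub$analyte)) {
      s <- sum(sub$conc_ugkg_fw[sub$analyte %in% congeners])
      r <- sub$conc_ugkg_fw[sub$analyte == "sumPCB"][1L]
      if (abs(s - r) > 0.005 + 0.02 * max(s, r))
        warning("pool ", p, ": sumPCB (", r,
                ") does not match the congener sum (", signif(s, 4), ")")
    }
  }
  class(df) <- c("pooled_burden", "data.frame")
  df
}

#' Expand pooled concentrations to individual covariates
#'
#' Chemical analyses are performed on pooled samples, so every member of
#' a pool shares its pool's concentration. This produces one row per
#' individual with one column per analyte, and warns that effective
#' replication for these covariates is at pool level (the number of
#' distinct covariate values equals the number of pools).
#'
#' @param burdens a `pooled_burden` table (or compatible data frame).
#' @param membership data frame with columns `individual` and `pool_id`
#'   mapping each modeled individual to exactly one pool.
#' @param analytes which analytes to expand (default the seven modeled
#'   ones, excluding `sumPCB`).
#' @return data frame `individual` + one numeric column per analyte,
#'   with attribute `n_pools`.
#' @export
expand_pools <- function(burdens, membership, analytes = ANALYTES) {
  burdens <- validate_burdens(as.data.frame(burdens))
  if (!all(c("individual", "pool_id") %in% names(membership)))
    stop("membership needs 'individual' and 'pool_id' columns")
  if (anyDuplicated(membership$individual))
    stop("individual(s) mapped to more than one pool: ",
         paste(unique(membership$individual[duplicated(membership$individual)]),
               collapse = ", "))
  unmapped <- setdiff(membership$pool_id, burdens$pool_id)
  if (length(unmapped))
    stop("membership references pool(s) absent from the burden table: ",
         paste(unmapped, collapse = ", "))
  out <- data.frame(individual = membership$individual,
                    pool_id = membership$pool_id,
                    stringsAsFactors = FALSE)
  for (an in analytes) {
    sub <- burdens[burdens$analyte == an, ]
    v <- sub$conc_ugkg_fw[match(membership$pool_id, sub$pool_id)]
    if (anyNA(v))
      stop("analyte ", an, " missing for pool(s): ",
           paste(unique(membership$pool_id[is.na(v)]), collapse = ", "))
    out[[an]] <- v
  }
  n_pools <- length(unique(membership$pool_id))
  if (n_pools < length(membership$individual))
    message("pool expansion: ", n_pools, " distinct covariate value(s) for ",
            nrow(out), " individuals; effective replication is at pool level")
  attr(out, "n_pools") <- n_pools
  out
}

#' Tukey ladder-of-powers transformation
#'
#' Selects, over a grid of exponents, the ladder transform that
#' maximizes the Shapiro-Wilk W statistic of the transformed values:
#' \eqn{x^\lambda} for \eqn{\lambda > 0}, \eqn{\log x} for
#' \eqn{\lambda = 0}, and \eqn{-x^\lambda} for \eqn{\lambda < 0} (the
#' sign flip keeps the transform order-preserving). Non-positive inputs
#' are shifted by `-min(x) + eps` first (reported in the result). The
#' default grid is -5 to 5 in steps of 0.025.
#'
#' @param x numeric vector, not constant.
#' @param lambda_grid candidate exponents.
#' @param eps shift margin for non-positive inputs.
#' @return list with `lambda` (the selected exponent), `transformed`,
#'   `shift` (0 when no shift was needed), and `W` (the attained
#'   Shapiro-Wilk statistic).
#' @export
tukey_transform <- function(x, lambda_grid = seq(-5, 5, by = 0.025),
                            eps = 1e-6) {
  if (!is.numeric(x) || length(x) < 3L) stop("need at least 3 numeric values")
  if (length(unique(x)) == 1L)
    stop("constant input: no normalizing transformation is defined")
  shift <- 0
  if (min(x) <= 0) {
    shift <- -min(x) + eps * diff(range(x))
    message("tukey_transform: shifting values by ", signif(shift, 4),
            " to make them positive")
    x <- x + shift
  }
  apply_lambda <- function(l) {
    if (l > 0) x^l else if (l == 0) log(x) else -(x^l)
  }
  xs <- if (length(x) > 5000L) sort(x)[round(seq(1, length(x), length.out = 5000L))] else x
  w_of <- function(l) {
    v <- if (l > 0) xs^l else if (l == 0) log(xs) else -(xs^l)
    if (any(!is.finite(v)) || length(unique(v)) == 1L) return(-Inf)
    tryCatch(shapiro.test(v)$statistic, error = function(e) -Inf)
  }
  ws <- vapply(lambda_grid, w_of, 0)
  best <- which.max(ws)
  list(lambda = lambda_grid[best], transformed = apply_lambda(lambda_grid[best]),
       shift = shift, W = unname(ws[best]))
}

#' Fit one burden-inbreeding-asymmetry linear model
#'
#' Ordinary least squares of a per-individual FA response on an
#' inbreeding index and an (expanded, pool-level) analyte covariate,
#' optionally with a location factor. Reports the coefficient t-values
#' in fixed order (t1 = inbreeding, t2 = analyte, t3 = location),
#' adjusted R-squared, and a Kolmogorov-Smirnov residual-normality
#' p-value. Standard errors are plain OLS; the result records the
#' number of distinct analyte values so the pool-level
#' pseudo-replication is visible. Rank deficiency (e.g. a constant
#' covariate from a single pool) yields a flagged result naming the
#' collinear columns, not an exception.
#'
#' @param fa numeric response vector.
#' @param inbreeding numeric covariate, same length.
#' @param analyte numeric covariate (typically from [expand_pools()]).
#' @param location optional factor; include for designs spanning
#'   multiple sampling locations.
#' @return an object of class `linkage_model`.
#' @export
fit_linkage_model <- function(fa, inbreeding, analyte, location = NULL) {
  n <- length(fa)
  if (length(inbreeding) != n || length(analyte) != n)
    stop("response and covariates must have equal length")
  dat <- data.frame(fa = fa, inbreeding = inbreeding, analyte = analyte)
  form <- fa ~ inbreeding + analyte
  if (!is.null(location)) {
    dat$location <- factor(location)
    form <- fa ~ inbreeding + analyte + location
  }
  p <- if (is.null(location)) 2L else 1L + nlevels(dat$location)
  if (n < p + 2L) stop("need at least p + 2 observations")
  const <- vapply(dat[-1L], function(v) length(unique(v)) == 1L, TRUE)
  fit <- lm(form, data = dat)
  aliased <- is.na(coef(fit))
  rank_deficient <- any(aliased) || any(const)
  dropped <- unique(c(names(const)[const], names(aliased)[aliased]))
  sm <- summary(fit)
  tv <- sm$coefficients[, "t value"]
  pv <- sm$coefficients[, "Pr(>|t|)"]
  get_t <- function(nm) {
    hit <- grep(paste0("^", nm), names(tv))
    if (length(hit)) unname(tv[hit[1L]]) else NA_real_
  }
  get_p <- function(nm) {
    hit <- grep(paste0("^", nm), names(pv))
    if (length(hit)) unname(pv[hit[1L]]) else NA_real_
  }
  diag <- residual_diagnostics(fit)
  structure(list(model = fit,
                 coefficients = coef(fit),
                 t_values = c(t1 = get_t("inbreeding"), t2 = get_t("analyte"),
                              t3 = get_t("location")),
                 p_values = c(p1 = get_p("inbreeding"), p2 = get_p("analyte"),
                              p3 = get_p("location")),
                 r2_adj = sm$adj.r.squared,
                 ks_p = diag$ks_p,
                 n = n,
                 n_distinct_analyte = length(unique(analyte)),
                 rank_deficient = rank_deficient,
                 dropped = dropped),
            class = "linkage_model")
}

#' @export
print.linkage_model <- function(x, ...) {
  cat("Linkage model: fa ~ inbreeding + analyte",
      if (!is.na(x$t_values["t3"])) "+ location", "\n")
  cat(sprintf("  n = %d (%d distinct analyte value(s))\n",
              x$n, x$n_distinct_analyte))
  cat(sprintf("  t1 = %.3f  t2 = %.3f  t3 = %s   R2_adj = %.3f   KS p = %s\n",
              x$t_values["t1"], x$t_values["t2"],
              ifelse(is.na(x$t_values["t3"]), "n.a.",
                     sprintf("%.3f", x$t_values["t3"])),
              x$r2_adj, ifelse(is.na(x$ks_p), "n.a.", signif(x$ks_p, 3))))
  if (x$rank_deficient)
    cat("  RANK DEFICIENT: ", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Residual normality diagnostics
#'
#' Kolmogorov-Smirnov test of the standardized residuals against the
#' standard normal, plus a residual-versus-fitted table for plotting.
#' Skipped (with a note) below 10 residuals or for degenerate
#' (zero-variance) residuals.
#'
#' @param model a fitted `lm` (or `linkage_model`).
#' @param alpha pass/fail level.
#' @return list with `ks_p` (`NA` when skipped), `pass`, `note`, and
#'   `table` (data frame `fitted`, `residual`, `standardized`).
#' @export
residual_diagnostics <- function(model, alpha = 0.05) {
  if (inherits(model, "linkage_model")) model <- model$model
  r <- resid(model)
  tab <- data.frame(fitted = fitted(model), residual = r)
  if (length(r) < 10L)
    return(list(ks_p = NA_real_, pass = NA, table = tab,
                note = "fewer than 10 residuals; diagnostic skipped"))
  s <- sd(r)
  if (s < 1e-10 * (mean(abs(fitted(model))) + 1))
    return(list(ks_p = NA_real_, pass = NA, table = tab,
                note = "degenerate (constant) residuals; diagnostic skipped"))
  z <- (r - mean(r)) / s
  tab$standardized <- z
  p <- suppressWarnings(ks.test(z, "pnorm")$p.value)
  list(ks_p = p, pass = p >= alpha, table = tab, note = NULL)
}

stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Run the full linkage-model battery
#'
#' The Cartesian battery of linear models over FA responses, the two
#' inbreeding indices (MLH and d-squared), and the seven analytes
#' (Hg and six PCB congeners): e.g. 2 responses x 2 indices x 7
#' analytes = 28 models for a paired-wing dataset, 1 x 2 x 7 = 14 for a
#' head dataset. For each response, the untransformed models are fit
#' first; when any of them fails the Kolmogorov-Smirnov residual check
#' at `alpha`, the response is transformed once with
#' [tukey_transform()] and all of its models refit (the selected lambda
#' is recorded on every row).
#'
#' @param responses named list of per-individual FA response vectors,
#'   each a named numeric vector keyed by individual id (or a data
#'   frame with `individual` plus one column per response).
#' @param indices an `inbreeding_indices` data frame (columns
#'   `individual`, `mlh`, `d2`).
#' @param analyte_covariates output of [expand_pools()].
#' @param location optional named vector of location labels keyed by
#'   individual; include for multi-location designs.
#' @param transform `"auto"` (ladder transform on diagnostic failure),
#'   `"never"`, or `"always"`.
#' @param alpha diagnostic level.
#' @return data frame of class `linkage_battery`: one row per model
#'   with `response`, `index`, `analyte`, `t1`, `t2`, `t3`, `sig1`,
#'   `sig2`, `sig3`, `r2_adj`, `ks_p`, `lambda`, `n`, `n_pools`.
#' @export
run_model_battery <- function(responses, indices, analyte_covariates,
                              location = NULL,
                              transform = c("auto", "never", "always"),
                              alpha = 0.05) {
  transform <- match.arg(transform)
  if (is.data.frame(responses)) {
    ids <- responses$individual
    responses <- lapply(responses[setdiff(names(responses), "individual")],
                        function(v) setNames(v, ids))
  }
  if (!length(responses)) stop("empty response set")
  if (is.null(names(responses)))
    names(responses) <- paste0("response", seq_along(responses))
  analytes <- intersect(ANALYTES, names(analyte_covariates))
  if (!length(analytes)) stop("no analyte columns found")
  index_names <- c("mlh", "d2")
  rows <- list()
  for (rn in names(responses)) {
    resp <- responses[[rn]]
    ids <- intersect(names(resp),
                     intersect(indices$individual,
                               analyte_covariates$individual))
    ids <- sort(ids)
    if (length(ids) < 6L) stop("too few individuals shared across inputs for ", rn)
    y0 <- unname(resp[ids])
    loc <- if (is.null(location)) NULL else unname(location[ids])
    im <- match(ids, indices$individual)
    am <- match(ids, analyte_covariates$individual)
    fit_set <- function(y, lambda) {
      out <- list()
      for (ix in index_names) for (an in analytes) {
        m <- fit_linkage_model(y, indices[[ix]][im],
                               analyte_covariates[[an]][am], location = loc)
        out[[paste(ix, an)]] <- data.frame(
          response = rn, index = ix, analyte = an,
          t1 = m$t_values["t1"], t2 = m$t_values["t2"], t3 = m$t_values["t3"],
          sig1 = stars(m$p_values["p1"]), sig2 = stars(m$p_values["p2"]),
          sig3 = stars(m$p_values["p3"]),
          r2_adj = m$r2_adj, ks_p = m$ks_p, lambda = lambda,
          n = m$n, n_pools = m$n_distinct_analyte,
          stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }
    tab <- fit_set(y0, NA_real_)
    needs <- switch(transform,
                    never = FALSE,
                    always = TRUE,
                    auto = any(tab$ks_p < alpha, na.rm = TRUE))
    if (needs) {
      tr <- suppressMessages(tukey_transform(y0))
      tab <- fit_set(tr$transformed, tr$lambda)
    }
    rows[[rn]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("linkage_battery", "data.frame")
  out
}
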