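make_burden_df <- function(pools = c("p1", "p2"),
                           hg = c(1.5, 0.39)) {
  do.call(rbind, lapply(seq_along(pools), function(i) {
    cong <- seq(0.05, 0.3, length.out = 6) * i
    data.frame(pool_id = pools[i], location = "site_a", taxon = "bumblebee",
               analyte = c("Hg", "PCB28", "PCB52", "PCB101", "PCB138",
                           "PCB153", "PCB180", "sumPCB"),
               conc_ugkg_fw = c(hg[i], cong, sum(cong)),
               stringsAsFactors = FALSE)
  }))
}

test_that("burden validation checks analytes, signs, and the congener sum", {
  df <- make_burden_df()
  expect_s3_class(validate_burdens(df), "pooled_burden")
  bad <- df; bad$analyte[1] <- "DDT"
  expect_error(validate_burdens(bad), "unknown analyte")
  neg <- df; neg$conc_ugkg_fw[2] <- -1
  expect_error(validate_burdens(neg), "non-negative")
  off <- df; off$conc_ugkg_fw[off$analyte == "sumPCB"][1] <- 99
  expect_warning(validate_burdens(off), "does not match")
})

test_that("pool expansion shares each pool's concentration across its members", {
  df <- make_burden_df()
  mem <- data.frame(individual = sprintf("i%02d", 1:68),
                    pool_id = rep(c("p1", "p2"), c(64, 4)))
  expect_message(cov <- expand_pools(df, mem), "pool level")
  expect_equal(nrow(cov), 68)
  expect_equal(sort(unique(cov$Hg)), c(0.39, 1.5))
  expect_equal(length(unique(cov$PCB52)), 2)
  expect_equal(attr(cov, "n_pools"), 2)
  # order invariance
  cov2 <- suppressMessages(expand_pools(df, mem[sample(68), ]))
  m <- match(cov$individual, cov2$individual)
  expect_equal(cov2$Hg[m], cov$Hg)
  # unmapped pool
  mem_bad <- rbind(mem, data.frame(individual = "x", pool_id = "p9"))
  expect_error(suppressMessages(expand_pools(df, mem_bad)), "p9")
  # duplicate mapping
  expect_error(suppressMessages(expand_pools(df, rbind(mem, mem[1, ]))),
               "more than one pool")
})

test_that("the Tukey ladder matches its branch definitions and preserves rank", {
  expect_equal(tukey_transform(c(exp(1), exp(2), exp(0.5), exp(1.5)),
                               lambda_grid = 0)$transformed,
               c(1, 2, 0.5, 1.5))
  set.seed(61)
  x <- rexp(50) + 0.1
  neg <- tukey_transform(x, lambda_grid = -1)
  expect_equal(order(neg$transformed), order(x))
  for (lg in list(seq(-3, 3, 0.5), c(-2, 0, 2))) {
    tr <- tukey_transform(x, lambda_grid = lg)
    expect_equal(rank(tr$transformed), rank(x))
  }
  expect_error(tukey_transform(rep(1, 10)), "constant")
  # non-positive values are shifted, order preserved
  y <- rnorm(40)
  expect_message(trs <- tukey_transform(y), "shifting")
  expect_equal(rank(trs$transformed), rank(y))
})

test_that("an exact linear response gives a perfect fit with ordered t-values", {
  set.seed(62)
  n <- 40
  inb <- runif(n); an <- rep(c(2, 5), each = n / 2)
  y <- 1 + 2 * inb - 0.5 * an
  m <- suppressWarnings(fit_linkage_model(y, inb, an))
  expect_equal(m$r2_adj, 1, tolerance = 1e-6)
  expect_lt(sum(resid(m$model)^2), 1e-16)
  expect_named(m$t_values, c("t1", "t2", "t3"))
  expect_true(is.na(m$t_values["t3"]))
  # with a location factor, t3 appears
  loc <- rep(c("a", "b"), n / 2)
  m2 <- fit_linkage_model(y + rnorm(n, sd = 0.1), inb, an, location = loc)
  expect_false(is.na(m2$t_values["t3"]))
})

test_that("a constant covariate yields a flagged rank-deficient result, not an error", {
  set.seed(63)
  n <- 30
  m <- fit_linkage_model(rnorm(n), runif(n), rep(1.5, n))
  expect_true(m$rank_deficient)
  expect_true("analyte" %in% m$dropped)
})

test_that("residual diagnostics calibrate against normal and heavy-tailed errors", {
  set.seed(64)
  n <- 200
  passes <- vapply(1:40, function(i) {
    fit <- lm(y ~ x, data.frame(x = runif(n), y = rnorm(n)))
    residual_diagnostics(fit)$pass
  }, TRUE)
  expect_gt(mean(passes), 0.8)
  fails <- vapply(1:40, function(i) {
    fit <- lm(y ~ x, data.frame(x = runif(n), y = rt(n, df = 2)))
    isFALSE(residual_diagnostics(fit)$pass)
  }, TRUE)
  expect_gt(mean(fails), 0.5)
  # degenerate inputs are skipped with a note
  few <- lm(y ~ x, data.frame(x = 1:5, y = rnorm(5)))
  expect_match(residual_diagnostics(few)$note, "fewer than 10")
  const <- lm(y ~ 1, data.frame(y = rep(2, 20)))
  expect_match(residual_diagnostics(const)$note, "degenerate")
})

test_that("the model battery has the study shape and constant |t2| across analytes", {
  set.seed(65)
  df <- make_burden_df()
  n <- 68
  ids <- sprintf("i%02d", 1:n)
  mem <- data.frame(individual = ids, pool_id = rep(c("p1", "p2"), c(64, 4)))
  cov <- suppressMessages(expand_pools(df, mem))
  idx <- data.frame(individual = ids, mlh = runif(n), d2 = rexp(n) * 10)
  responses <- list(fore = setNames(rnorm(n, 1, 0.2), ids),
                    hind = setNames(rnorm(n, 1, 0.2), ids))
  bat <- run_model_battery(responses, idx, cov)
  expect_equal(nrow(bat), 28)
  one <- run_model_battery(responses["fore"], idx, cov)
  expect_equal(nrow(one), 14)
  # two pools: all analyte covariates are affine images of each other
  for (rn in c("fore", "hind")) for (ix in c("mlh", "d2")) {
    t2 <- abs(bat$t2[bat$response == rn & bat$index == ix])
    expect_equal(max(t2) - min(t2), 0, tolerance = 1e-10)
  }
  expect_equal(unique(bat$n_pools), 2)
})

test_that("battery output is invariant to input row order and reproducible", {
  set.seed(66)
  df <- make_burden_df(pools = c("p1", "p2", "p3"), hg = c(1.2, 4.5, 7.8))
  n <- 45
  ids <- sprintf("i%02d", 1:n)
  mem <- data.frame(individual = ids, pool_id = rep(c("p1", "p2", "p3"), 15))
  cov <- suppressMessages(expand_pools(df, mem))
  idx <- data.frame(individual = ids, mlh = runif(n), d2 = rexp(n))
  resp <- list(head = setNames(rgamma(n, 4, 10), ids))
  b1 <- run_model_battery(resp, idx, cov)
  shuf <- sample(n)
  b2 <- run_model_battery(list(head = resp$head[shuf]), idx[sample(n), ], cov)
  expect_equal(b2, b1)
  b3 <- run_model_battery(resp, idx, cov)
  expect_identical(b3, b1)
})

test_that("the ladder transform is applied only when diagnostics fail", {
  set.seed(67)
  df <- make_burden_df()
  n <- 68
  ids <- sprintf("i%02d", 1:n)
  mem <- data.frame(individual = ids, pool_id = rep(c("p1", "p2"), c(64, 4)))
  cov <- suppressMessages(expand_pools(df, mem))
  idx <- data.frame(individual = ids, mlh = runif(n), d2 = rexp(n))
  normal_resp <- list(r = setNames(rnorm(n, 5, 0.5), ids))
  b_norm <- run_model_battery(normal_resp, idx, cov)
  expect_true(all(is.na(b_norm$lambda)))
  skewed_resp <- list(r = setNames(exp(rnorm(n, 0, 1.5)), ids))
  b_skew <- run_model_battery(skewed_resp, idx, cov)
  expect_true(all(!is.na(b_skew$lambda)))
  expect_equal(length(unique(b_skew$lambda)), 1)
})
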