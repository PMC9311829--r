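test_that("perfectly symmetric individuals have coinciding aligned sides", {
  d <- make_landmarks(8, k = 10, sd_individual = 0.05, sd_fa = 0,
                      sd_digit = 0, seed = 21)
  dec <- matching_decomposition(d)
  info <- dec$info
  for (ind in unique(info$individual)[1:4]) {
    r <- which(info$individual == ind & info$side == "right")[1]
    l <- which(info$individual == ind & info$side == "left")[1]
    expect_lt(sqrt(sum((dec$gpa$aligned[, , r] - dec$gpa$aligned[, , l])^2)),
              1e-9)
  }
})

test_that("FA-only data shows side differences but no individual differences", {
  d <- make_landmarks(30, k = 10, sd_individual = 0, sd_fa = 0.02,
                      sd_digit = 0, seed = 22)
  tab <- procrustes_anova(matching_decomposition(d))
  ms <- function(e) tab$MS[match(e, tab$effect)]
  expect_gt(ms("fluctuating_asymmetry") / ms("individual"), 1.5)
})

test_that("individuals missing a side are excluded with a warning", {
  d <- make_landmarks(8, k = 8, sd_individual = 0.03, sd_fa = 0.01,
                      sd_digit = 0.01, seed = 23)
  keep <- !(d$info$individual == "ind0001" & d$info$side == "left")
  d_cut <- landmark_dataset(d$coords[, , keep], d$info[keep, ],
                            symmetry_mode = "matching")
  expect_warning(dec <- matching_decomposition(d_cut), "ind0001")
  expect_false("ind0001" %in% dec$info$individual)
})

test_that("replicated designs produce imaging and digitizing strata", {
  d <- make_landmarks(10, k = 8, sd_individual = 0.03, sd_fa = 0.01,
                      sd_image = 0.005, sd_digit = 0.002,
                      n_image_rep = 2, n_digit_rep = 2, seed = 24)
  expect_equal(n_configs(d), 10 * 2 * 2 * 2)
  tab <- procrustes_anova(matching_decomposition(d))
  expect_setequal(tab$effect,
                  c("individual", "directional_asymmetry",
                    "fluctuating_asymmetry", "imaging_error",
                    "digitizing_error"))
  # nesting: FA tested over imaging, imaging over digitizing
  expect_false(is.na(tab$F[tab$effect == "imaging_error"]))
  expect_true(is.na(tab$F[tab$effect == "digitizing_error"]))
})

test_that("object symmetry: exactly symmetric configurations have zero asymmetric component", {
  d <- make_landmarks(6, k = 29, symmetry_mode = "object",
                      sd_individual = 0.02, sd_fa = 0, sd_digit = 0, seed = 25)
  dec <- object_decomposition(d)
  expect_lt(max(abs(dec$asymmetric)), 1e-9)
})

test_that("object symmetry: the doubled-set consensus is reflection-symmetric", {
  d <- make_landmarks(15, k = 29, symmetry_mode = "object",
                      sd_individual = 0.03, sd_fa = 0.01, sd_digit = 0.005,
                      seed = 26)
  dec <- object_decomposition(d)
  C <- dec$gpa$consensus
  Ct <- asymlink:::reflect_relabel(C, dec$pairing)
  expect_lt(opa_align(Ct, C, scale = FALSE)$rss, 1e-18)
})

test_that("object symmetry: reflecting a configuration negates its asymmetric component", {
  d <- make_landmarks(8, k = 13, symmetry_mode = "object",
                      pairing = default_pairing(13, 3),
                      sd_individual = 0.02, sd_fa = 0.02, seed = 27)
  n <- n_configs(d)
  both <- array(0, c(13, 2, 2 * n))
  both[, , 1:n] <- d$coords
  for (i in 1:n)
    both[, , n + i] <- asymlink:::reflect_relabel(d$coords[, , i], d$pairing)
  info <- rbind(d$info, transform(d$info, individual = paste0(individual, "_r"),
                                  specimen_id = paste0(specimen_id, "_r")))
  d2 <- landmark_dataset(both, info, symmetry_mode = "object",
                         pairing = d$pairing)
  dec <- object_decomposition(d2)
  expect_equal(dec$asymmetric[, , n + 1:n], -dec$asymmetric[, , 1:n],
               tolerance = 1e-8)
})

test_that("symmetric/asymmetric shape dimensions split 2k - 4 as 2p+m-2 each", {
  d <- make_landmarks(5, k = 29, symmetry_mode = "object",
                      sd_individual = 0.02, sd_fa = 0.01, seed = 28)
  dims <- shape_dimensions(object_decomposition(d))
  expect_equal(dims$symmetric, 2 * 13 + 3 - 2)
  expect_equal(dims$asymmetric, dims$symmetric)
  expect_equal(dims$symmetric + dims$asymmetric, 2 * 29 - 4)
})

test_that("ANOVA sums of squares are additive and df bookkeeping is Goodall-style", {
  for (s in 1:3) {
    d <- make_landmarks(12, k = 10, sd_individual = 0.04, sd_fa = 0.015,
                        sd_digit = 0.004, n_digit_rep = 2, seed = 40 + s)
    tab <- procrustes_anova(matching_decomposition(d))
    expect_equal(sum(tab$SS), attr(tab, "total_SS"), tolerance = 1e-8)
    dims <- 2 * 10 - 4
    expect_equal(tab$df[tab$effect == "individual"], 11 * dims)
    expect_equal(tab$df[tab$effect == "digitizing_error"], 12 * 2 * 1 * dims)
    expect_equal(tab$MS, tab$SS / tab$df)
  }
  # object mode is additive too (nested strata)
  d <- make_landmarks(10, k = 13, symmetry_mode = "object",
                      pairing = default_pairing(13, 3),
                      sd_individual = 0.03, sd_fa = 0.01, sd_digit = 0.003,
                      n_digit_rep = 2, seed = 44)
  tab <- procrustes_anova(object_decomposition(d))
  expect_equal(sum(tab$SS), attr(tab, "total_SS"), tolerance = 1e-8)
})

test_that("left = right with no error yields zero FA sum of squares", {
  d <- make_landmarks(10, k = 8, sd_individual = 0.05, sd_fa = 0,
                      sd_digit = 0, seed = 29)
  tab <- procrustes_anova(matching_decomposition(d))
  expect_lt(tab$SS[tab$effect == "fluctuating_asymmetry"], 1e-16)
})

test_that("object-mode FA carries F and p only with replicate measurements", {
  d1 <- make_landmarks(10, k = 13, symmetry_mode = "object",
                       pairing = default_pairing(13, 3),
                       sd_individual = 0.03, sd_fa = 0.01, sd_digit = 0.003,
                       n_digit_rep = 1, seed = 30)
  t1 <- procrustes_anova(object_decomposition(d1))
  expect_true(is.na(t1$F[t1$effect == "fluctuating_asymmetry"]))
  d2 <- make_landmarks(10, k = 13, symmetry_mode = "object",
                       pairing = default_pairing(13, 3),
                       sd_individual = 0.03, sd_fa = 0.01, sd_digit = 0.003,
                       n_digit_rep = 2, seed = 30)
  t2 <- procrustes_anova(object_decomposition(d2))
  expect_false(is.na(t2$F[t2$effect == "fluctuating_asymmetry"]))
})

test_that("location enters the object-mode table as a between-individual effect", {
  da <- make_landmarks(8, k = 13, symmetry_mode = "object",
                       pairing = default_pairing(13, 3), sd_individual = 0.03,
                       sd_fa = 0.01, sd_digit = 0.003, n_digit_rep = 2,
                       location = "site_a", id_prefix = "a", seed = 31)
  db <- make_landmarks(8, k = 13, symmetry_mode = "object",
                       pairing = default_pairing(13, 3), sd_individual = 0.03,
                       sd_fa = 0.01, sd_digit = 0.003, n_digit_rep = 2,
                       location = "site_b", id_prefix = "b", seed = 32)
  coords <- lapply(seq_len(n_configs(da)), function(i) da$coords[, , i])
  coords <- c(coords, lapply(seq_len(n_configs(db)), function(i) db$coords[, , i]))
  d <- landmark_dataset(coords, rbind(da$info, db$info),
                        symmetry_mode = "object", pairing = da$pairing)
  tab <- procrustes_anova(object_decomposition(d))
  expect_true("location" %in% tab$effect)
  expect_equal(tab$df[tab$effect == "location"], 1 * (2 * 5 + 3 - 2))
  expect_equal(sum(tab$SS), attr(tab, "total_SS"), tolerance = 1e-8)
})

test_that("error study verdicts track the injected error magnitude", {
  # error variance 100x smaller than FA variance: errors nonsignificant
  d_small <- make_landmarks(25, k = 10, sd_individual = 0.04, sd_fa = 0.02,
                            sd_digit = 0.002, n_digit_rep = 2, seed = 33)
  es <- error_study(matching_decomposition(d_small))
  expect_equal(es$verdicts$verdict, "errors nonsignificant")
  expect_gt(es$verdicts$F_ind, 1)
  # zero injected measurement error: error mean square ~ 0
  d_zero <- make_landmarks(10, k = 10, sd_individual = 0.04, sd_fa = 0.02,
                           sd_digit = 0, n_digit_rep = 2, seed = 34)
  tz <- procrustes_anova(matching_decomposition(d_zero))
  expect_lt(tz$MS[tz$effect == "digitizing_error"], 1e-16)
  # error variance equal to FA variance: F ~ 1, FA not significant
  set.seed(35)
  fs <- vapply(1:12, function(s) {
    d <- make_landmarks(20, k = 10, sd_individual = 0.03, sd_fa = 0,
                        sd_digit = 0.01, n_digit_rep = 2, seed = 350 + s)
    tab <- procrustes_anova(matching_decomposition(d))
    tab$F[tab$effect == "fluctuating_asymmetry"]
  }, 0)
  expect_equal(mean(fs), 1, tolerance = 0.15)
  expect_error(error_study(matching_decomposition(
    make_landmarks(8, k = 8, sd_individual = 0.02, sd_fa = 0.01, seed = 36))),
    "replicate")
})

test_that("FA2 follows its closed form, antisymmetry, and scale invariance", {
  expect_equal(fa2(10, 10), 0)
  expect_equal(fa2(11, 9), 0.2)
  set.seed(37)
  R <- runif(100, 0.1, 10); L <- runif(100, 0.1, 10)
  expect_equal(fa2(L, R), -fa2(R, L))
  expect_equal(fa2(3 * R, 3 * L), fa2(R, L))
  expect_error(fa2(-1, 2), "positive")
})

test_that("FA scores are zero for symmetric individuals and recover size asymmetry", {
  d0 <- make_landmarks(6, k = 10, sd_individual = 0.05, sd_fa = 0,
                       sd_digit = 0, seed = 38)
  sc0 <- fa_scores(matching_decomposition(d0))
  expect_lt(max(abs(sc0$fa2_size)), 1e-12)
  expect_lt(max(sc0$fa_shape), 1e-9)
  # deterministic R = L(1 + delta): fa2 = delta / (1 + delta/2) exactly
  delta <- 0.01
  dd <- make_landmarks(20, k = 10, sd_individual = 0.05, sd_fa = 0,
                       sd_digit = 0, size_delta = delta, seed = 39)
  scd <- fa_scores(matching_decomposition(dd))
  expect_equal(mean(scd$fa2_size), delta / (1 + delta / 2), tolerance = 1e-10)
})

test_that("FA scores are invariant to uniform rescaling of the whole dataset", {
  d <- make_landmarks(8, k = 10, sd_individual = 0.04, sd_fa = 0.01,
                      sd_digit = 0.003, seed = 41)
  sc1 <- fa_scores(matching_decomposition(d))
  d2 <- d
  d2$coords <- d$coords * 2
  sc2 <- fa_scores(matching_decomposition(d2))
  expect_equal(sc2$fa2_size, sc1$fa2_size, tolerance = 1e-9)
  expect_equal(sc2$fa_shape, sc1$fa_shape, tolerance = 1e-9)
  expect_equal(sc2$size_right, 2 * sc1$size_right, tolerance = 1e-9)
})

test_that("object-mode FA scores use pairing-subset sizes and directional correction", {
  d <- make_landmarks(10, k = 13, symmetry_mode = "object",
                      pairing = default_pairing(13, 3),
                      sd_individual = 0.02, sd_fa = 0.01, sd_digit = 0.002,
                      n_digit_rep = 2, seed = 42)
  sc <- fa_scores(object_decomposition(d))
  expect_equal(nrow(sc), 10)
  expect_true(all(sc$fa_shape >= 0))
  expect_true(all(is.finite(sc$fa2_size)))
  # symmetric heads score zero
  d0 <- make_landmarks(5, k = 13, symmetry_mode = "object",
                       pairing = default_pairing(13, 3),
                       sd_individual = 0.02, sd_fa = 0, sd_digit = 0, seed = 43)
  sc0 <- fa_scores(object_decomposition(d0))
  expect_lt(max(abs(sc0$fa2_size)), 1e-9)
  expect_lt(max(sc0$fa_shape), 1e-9)
})
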