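## Deterministic, slightly irregular template shapes (unit centroid size)

template_matching <- function(k) {
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  r <- 1 + 0.25 * sin(2 * th) + 0.15 * cos(3 * th + 0.7)
  X <- cbind(r * cos(th), r * sin(th))
  X <- sweep(X, 2L, colMeans(X))
  X / sqrt(sum(X^2))
}

## object-symmetric template about the y-axis: p pairs + m midline points
template_object <- function(pairing, k) {
  p <- nrow(pairing$pairs)
  m <- length(pairing$midline)
  stopifnot(2L * p + m == k)
  th <- seq(0.2, pi - 0.2, length.out = p)
  r <- 1 + 0.2 * sin(3 * th)
  left <- cbind(-abs(r * sin(th)) - 0.2, r * cos(th))
  X <- matrix(0, k, 2L)
  X[pairing$pairs[, 1L], ] <- left
  X[pairing$pairs[, 2L], ] <- cbind(-left[, 1L], left[, 2L])
  if (m > 0L)
    X[pairing$midline, ] <- cbind(rep(0, m), seq(-1.2, 1.2, length.out = m))
  X <- sweep(X, 2L, colMeans(X))
  X / sqrt(sum(X^2))
}

#' Default landmark pairing for a synthetic object-symmetric structure
#'
#' A consistent left/right pairing for a k-landmark structure with an
#' internal midline: `(k - m)/2` pairs followed by `m` midline points.
#' The 29-landmark default (13 pairs + 3 midline points) matches the
#' scheme used for synthetic heads throughout the package.
#'
#' @param k total landmark count.
#' @param m number of midline landmarks (same parity as k).
#' @return a validated pairing list (`pairs`, `midline`).
#' @export
default_pairing <- function(k = 29L, m = k %% 2L + 2L) {
  if ((k - m) %% 2L != 0L) stop("k - m must be even")
  p <- (k - m) / 2L
  validate_pairing(cbind(seq_len(p), p + seq_len(p)),
                   midline = 2L * p + seq_len(m), k = k)
}

rigid_jitter <- function(X) {
  th <- runif(1L, -pi, pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  sweep(X %*% R, 2L, runif(2L, -2, 2), `+`)
}

#' Generate a synthetic landmark dataset with known variance components
#'
#' Simulates the measurement design of a landmarking study: a fixed
#' template shape (unit centroid size) receives, per individual, an
#' independent Gaussian shape deviation (`sd_individual` per
#' coordinate); each side receives an antisymmetric fluctuating
#' deviation (`+G_i` on the right, `-G_i` on the left) scaled so that
#' `sd_fa^2` is exactly the FA variance component of the nested ANOVA:
#' the expected FA mean square is `sigma_err^2 + r * sd_fa^2` with `r`
#' replicate measurements per side, so `(MS_FA - MS_err) / r` recovers
#' `sd_fa^2`; an optional directional offset drawn once per dataset
#' with scale `sd_da` (half added to the right, half subtracted from
#' the left); then independent imaging noise per photograph (`sd_image`)
#' and digitizing noise per digitization (`sd_digit`). Left
#' configurations are stored reflected about the y-axis, as digitized.
#' Each stored configuration additionally receives a random rigid
#' rotation and translation (removed again by superimposition), and
#' sizes can vary between individuals (`sd_size_ind`, log scale) and
#' between sides (`sd_size_asym` on the signed relative side
#' difference, plus a deterministic offset `size_delta` with
#' R = L(1 + size_delta)).
#'
#' Everything is a pure function of the arguments and `seed`.
#'
#' @param n_individuals number of individuals.
#' @param k landmark count (>= 3).
#' @param symmetry_mode `"matching"` or `"object"`.
#' @param pairing object-mode pairing (default [default_pairing()]).
#' @param sd_individual,sd_fa,sd_da,sd_image,sd_digit per-coordinate
#'   Gaussian scales in units of the unit-size template.
#' @param n_image_rep,n_digit_rep replicate photographs per side and
#'   digitizations per photograph.
#' @param mean_size mean centroid size of generated configurations.
#' @param sd_size_ind log-normal sd of individual size.
#' @param sd_size_asym sd of the relative size difference between sides.
#' @param size_delta deterministic relative size asymmetry (R = L(1+d)).
#' @param location optional location label applied to all individuals.
#' @param id_prefix prefix for individual ids.
#' @param seed mandatory integer seed.
#' @return a `landmark_dataset`.
#' @export
make_landmarks <- function(n_individuals, k = 20L,
                           symmetry_mode = c("matching", "object"),
                           pairing = NULL,
                           sd_individual = 0.01, sd_fa = 0.005, sd_da = 0,
                           sd_image = 0, sd_digit = 0.002,
                           n_image_rep = 1L, n_digit_rep = 1L,
                           mean_size = 1, sd_size_ind = 0,
                           sd_size_asym = 0, size_delta = 0,
                           location = NULL, id_prefix = "ind", seed) {
  symmetry_mode <- match.arg(symmetry_mode)
  if (missing(seed)) stop("a seed is mandatory for synthetic data")
  if (k < 3L) stop("k must be >= 3")
  stopifnot(sd_individual >= 0, sd_fa >= 0, sd_da >= 0, sd_image >= 0,
            sd_digit >= 0, n_image_rep >= 1L, n_digit_rep >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (symmetry_mode == "object" && is.null(pairing))
    pairing <- default_pairing(k)
  tmpl <- if (symmetry_mode == "matching") template_matching(k)
          else template_object(pairing, k)
  da <- if (sd_da > 0) matrix(rnorm(2L * k, 0, sd_da), k, 2L) else
    matrix(0, k, 2L)
  ids <- sprintf("%s%04d", id_prefix, seq_len(n_individuals))
  coords <- list(); info <- list()
  noise <- function(s) if (s > 0) matrix(rnorm(2L * k, 0, s), k, 2L)
                       else matrix(0, k, 2L)
  for (i in seq_len(n_individuals)) {
    D <- noise(sd_individual)
    size_i <- mean_size * exp(if (sd_size_ind > 0) rnorm(1L, 0, sd_size_ind) else 0)
    delta <- size_delta + (if (sd_size_asym > 0) rnorm(1L, 0, sd_size_asym) else 0)
    if (symmetry_mode == "matching") {
      FF <- noise(sd_fa) / sqrt(2)
      sides <- list(right = tmpl + D + FF + da / 2,
                    left = tmpl + D - FF - da / 2)
      side_size <- c(right = size_i * (1 + delta), left = size_i)
      for (s in names(sides)) for (im in seq_len(n_image_rep)) {
        img <- noise(sd_image)
        for (dg in seq_len(n_digit_rep)) {
          X <- (sides[[s]] + img + noise(sd_digit)) * side_size[[s]]
          if (s == "left") X[, 1L] <- -X[, 1L]
          coords[[length(coords) + 1L]] <- rigid_jitter(X)
          info[[length(info) + 1L]] <- data.frame(
            specimen_id = sprintf("%s_%s_i%d_d%d", ids[i], s, im, dg),
            individual = ids[i], side = s, image_rep = im, digit_rep = dg,
            stringsAsFactors = FALSE)
        }
      }
    } else {
      Traw <- function(X) reflect_relabel(X, pairing)
      Ds <- (noise(sd_individual * sqrt(2)) +
               Traw(noise(sd_individual * sqrt(2)))) / 2
      Ds <- (Ds + Traw(Ds)) / 2
      E <- noise(sd_fa)
      FF <- (E - Traw(E)) / 2
      DAc <- (da - Traw(da)) / 2
      base <- tmpl + Ds + FF + DAc
      for (im in seq_len(n_image_rep)) {
        img <- noise(sd_image)
        for (dg in seq_len(n_digit_rep)) {
          X <- (base + img + noise(sd_digit)) * size_i
          coords[[length(coords) + 1L]] <- rigid_jitter(X)
          info[[length(info) + 1L]] <- data.frame(
            specimen_id = sprintf("%s_i%d_d%d", ids[i], im, dg),
            individual = ids[i], side = "none", image_rep = im, digit_rep = dg,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  info <- do.call(rbind, info)
  if (!is.null(location)) info$location <- location
  landmark_dataset(coords, info, symmetry_mode = symmetry_mode,
                   pairing = pairing)
}

#' Generate synthetic diploid microsatellite genotypes under inbreeding
#'
#' Per locus and individual, with probability `F` the two alleles are
#' identical by descent (a single draw from the allele-frequency
#' spectrum), otherwise two independent draws. Higher `F` therefore
#' lowers expected heterozygosity by the factor `(1 - F)`.
#'
#' @param n_individuals number of diploid individuals.
#' @param loci list of locus specifications, each a list with `name`,
#'   `alleles` (repeat counts), `freqs` (summing to 1 within 1e-9);
#'   default: 7 loci with 4-8 alleles in the 10-25 repeat range.
#' @param F inbreeding coefficient in \[0, 1\].
#' @param groups optional data frame of group labels (n rows).
#' @param id_prefix id prefix.
#' @param seed mandatory integer seed.
#' @return a `genotype_table`.
#' @export
make_genotypes <- function(n_individuals, loci = default_loci(), F = 0,
                           groups = NULL, id_prefix = "ind", seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic data")
  if (F < 0 || F > 1) stop("F must lie in [0, 1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (l in loci) {
    if (abs(sum(l$freqs) - 1) > 1e-9)
      stop("allele frequencies for locus ", l$name, " do not sum to 1")
    if (length(l$freqs) != length(l$alleles))
      stop("alleles/freqs length mismatch at locus ", l$name)
  }
  n <- n_individuals
  a1 <- matrix(NA_real_, n, length(loci))
  a2 <- matrix(NA_real_, n, length(loci))
  for (j in seq_along(loci)) {
    l <- loci[[j]]
    ibd <- runif(n) < F
    x <- sample(l$alleles, n, replace = TRUE, prob = l$freqs)
    y <- sample(l$alleles, n, replace = TRUE, prob = l$freqs)
    y[ibd] <- x[ibd]
    a1[, j] <- pmin(x, y); a2[, j] <- pmax(x, y)
  }
  colnames(a1) <- colnames(a2) <- vapply(loci, `[[`, "", "name")
  genotype_table(a1, a2, ids = sprintf("%s%04d", id_prefix, seq_len(n)),
                 groups = groups)
}

#' @rdname make_genotypes
#' @param n_loci number of loci in the default spec.
#' @export
default_loci <- function(n_loci = 7L) {
  lapply(seq_len(n_loci), function(j) {
    n_all <- 4L + (j %% 5L)
    alleles <- 10L + j + seq_len(n_all) * 2L
    w <- (seq_len(n_all))^-0.5
    list(name = sprintf("loc%02d", j), alleles = alleles, freqs = w / sum(w))
  })
}

#' Generate a complete synthetic study
#'
#' Builds a coherent study bundle mirroring a two-location field design:
#' a bumblebee-like taxon with paired forewings and hindwings (20 and 6
#' landmarks) pooled into one large and one small pool, and an ant-like
#' taxon with object-symmetric heads (29 landmarks) in four pools,
#' together with microsatellite genotypes, a pooled body-burden table
#' spanning field-realistic concentration ranges, and the
#' individual-to-pool membership map. Ids are shared across components
#' so the landmark, genotype, and burden stages join on individual.
#'
#' An optional positive-control dependence couples the pooled burden to
#' the FA *variance* (not its mean): each pool's size-asymmetry and
#' shape-FA scales are multiplied by `exp(burden_fa_coupling * z)` where
#' z is the pool's standardized Hg concentration. FA is a variance
#' phenomenon, so a mean shift would be the wrong test signal;
#' magnitude-type responses (`fa_shape`, `abs(fa2)`) pick the coupling
#' up as a mean effect.
#'
#' @param n_bumblebees per-pool bumblebee counts (two pools).
#' @param n_ants per-pool ant counts (four pools: two locations x two
#'   species).
#' @param inbreeding_F inbreeding coefficient for the genotypes.
#' @param burden_fa_coupling log-scale coupling of pool burden to FA
#'   variance (0 = none).
#' @param sd_fa,sd_digit,sd_size_asym base noise scales (see
#'   [make_landmarks()]).
#' @param n_digit_rep digitizations per photograph.
#' @param seed mandatory integer seed; stage seeds are derived from it
#'   by fixed offsets.
#' @param dir optional directory: when given, writes `*.tps`,
#'   `*_classifiers.csv`, `genotypes_*.csv`, `burdens.csv`, and
#'   `membership.csv` there.
#' @return a list bundle with elements `landmarks` (named
#'   `landmark_dataset`s: forewing, hindwing, head), `genotypes` (named
#'   `genotype_table`s: bumblebee, ant), `burdens`, `membership`,
#'   `params`, and (when written) `files`.
#' @export
make_study <- function(n_bumblebees = c(64L, 4L),
                       n_ants = c(67L, 49L, 48L, 40L),
                       inbreeding_F = 0.1,
                       burden_fa_coupling = 0,
                       sd_fa = 0.005, sd_digit = 0.001,
                       sd_size_asym = 0.01, n_digit_rep = 2L,
                       seed, dir = NULL) {
  if (missing(seed)) stop("a seed is mandatory for synthetic data")
  if (length(n_bumblebees) != 2L) stop("n_bumblebees must give two pools")
  if (length(n_ants) != 4L) stop("n_ants must give four pools")
  locs <- c("site_a", "site_b")
  pools <- data.frame(
    pool_id = paste0("pool", 1:6),
    location = c("site_a", "site_a", "site_a", "site_b", "site_b", "site_b"),
    taxon = c("bumblebee", "ant_sp1", "ant_sp2",
              "bumblebee", "ant_sp1", "ant_sp2"),
    n = c(n_bumblebees[1L], n_ants[1L], n_ants[2L],
          n_bumblebees[2L], n_ants[3L], n_ants[4L]),
    stringsAsFactors = FALSE)
  ## pooled concentrations spanning field-realistic ranges (ug/kg fw):
  ## Hg of order 1-11, individual PCB congeners of order 0.05-0.5
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 11L)
  burdens <- do.call(rbind, lapply(seq_len(nrow(pools)), function(i) {
    ## the per-pool offset keeps concentrations distinct across pools
    ## (tied pool values would make the analyte covariate degenerate)
    cong <- round(runif(6L, 0.05, 0.45), 3) + i / 1e4
    hg <- round(runif(1L, 1.2, 11), 2) + i / 1e4
    data.frame(pool_id = pools$pool_id[i], location = pools$location[i],
               taxon = pools$taxon[i],
               analyte = c("Hg", setdiff(ANALYTES, "Hg"), "sumPCB"),
               conc_ugkg_fw = c(hg, cong, sum(cong)),
               stringsAsFactors = FALSE)
  }))
  hg <- burdens$conc_ugkg_fw[burdens$analyte == "Hg"]
  z <- (hg - mean(hg)) / sd(hg)
  fa_factor <- exp(burden_fa_coupling * z)
  names(fa_factor) <- pools$pool_id
  membership <- list(); landmark_sets <- list()
  gen_pool <- function(i, k, mode, offs) {
    make_landmarks(pools$n[i], k = k, symmetry_mode = mode,
                   sd_individual = 0.01,
                   sd_fa = sd_fa * fa_factor[[i]],
                   sd_digit = sd_digit,
                   sd_size_asym = sd_size_asym * fa_factor[[i]],
                   n_digit_rep = n_digit_rep,
                   location = pools$location[i],
                   id_prefix = paste0(pools$pool_id[i], "_", substr(mode, 1, 1)),
                   seed = seed + offs + i)
  }
  bind_sets <- function(sets) {
    coords <- do.call(c, lapply(sets, function(d)
      lapply(seq_len(n_configs(d)), function(i) d$coords[, , i])))
    info <- do.call(rbind, lapply(sets, `[[`, "info"))
    landmark_dataset(coords, info, symmetry_mode = sets[[1L]]$symmetry_mode,
                     pairing = sets[[1L]]$pairing)
  }
  bb_pools <- which(pools$taxon == "bumblebee")
  ant_pools <- which(pools$taxon != "bumblebee")
  fore <- bind_sets(lapply(bb_pools, gen_pool, 20L, "matching", 100L))
  hind <- bind_sets(lapply(bb_pools, gen_pool, 6L, "matching", 200L))
  head_ <- bind_sets(lapply(ant_pools, gen_pool, 29L, "object", 300L))
  ind_pool <- function(ds) {
    u <- unique(ds$info$individual)
    data.frame(individual = u, pool_id = sub("_.*$", "", u),
               stringsAsFactors = FALSE)
  }
  ## forewing and hindwing share ids: the same bumblebee individuals
  mem_bb <- ind_pool(fore)
  mem_ant <- ind_pool(head_)
  membership <- rbind(mem_bb, mem_ant)
  loc_of <- setNames(pools$location, pools$pool_id)
  geno_groups <- function(mem) data.frame(
    pool_id = mem$pool_id, location = unname(loc_of[mem$pool_id]),
    stringsAsFactors = FALSE)
  gb <- make_genotypes(nrow(mem_bb), default_loci(7L), F = inbreeding_F,
                       groups = geno_groups(mem_bb), seed = seed + 401L)
  gb$ids <- mem_bb$individual
  rownames(gb$a1) <- rownames(gb$a2) <- gb$ids
  ga <- make_genotypes(nrow(mem_ant), default_loci(13L), F = inbreeding_F,
                       groups = geno_groups(mem_ant), seed = seed + 402L)
  ga$ids <- mem_ant$individual
  rownames(ga$a1) <- rownames(ga$a2) <- ga$ids
  bundle <- list(landmarks = list(forewing = fore, hindwing = hind,
                                  head = head_),
                 genotypes = list(bumblebee = gb, ant = ga),
                 burdens = validate_burdens(burdens),
                 membership = membership,
                 params = list(seed = seed, inbreeding_F = inbreeding_F,
                               burden_fa_coupling = burden_fa_coupling,
                               sd_fa = sd_fa, sd_digit = sd_digit,
                               sd_size_asym = sd_size_asym,
                               pools = pools))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c()
    for (nm in names(bundle$landmarks)) {
      tps <- file.path(dir, paste0(nm, ".tps"))
      cls <- file.path(dir, paste0(nm, "_classifiers.csv"))
      write_tps(bundle$landmarks[[nm]], tps, cls)
      files <- c(files, tps, cls)
    }
    for (nm in names(bundle$genotypes)) {
      f <- file.path(dir, paste0("genotypes_", nm, ".csv"))
      write_genotypes_csv(bundle$genotypes[[nm]], f)
      files <- c(files, f)
    }
    fb <- file.path(dir, "burdens.csv")
    write.csv(bundle$burdens, fb, row.names = FALSE, quote = FALSE)
    fm <- file.path(dir, "membership.csv")
    write.csv(bundle$membership, fm, row.names = FALSE, quote = FALSE)
    bundle$files <- c(files, fb, fm)
  }
  bundle
}
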