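# shared fixture builders and independent oracles

random_shape <- function(k, sd = 0.5) matrix(rnorm(2 * k, sd = sd), k, 2)

similarity_transform <- function(X) {
  th <- runif(1, -pi, pi)
  s <- exp(runif(1, -1, 1))
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(s * X %*% R, 2, runif(2, -5, 5), `+`)
}

# longhand step-down Holm, written independently of the implementation:
# walk the sorted p-values, tracking the running max of (m - j + 1) p_(j)
holm_longhand <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (j in seq_len(m)) {
    running <- max(running, min(1, (m - j + 1) * p[ord[j]]))
    adj[ord[j]] <- running
  }
  adj
}

# exact HWE p by direct summation over heterozygote counts for a
# biallelic locus: P(h hets | allele counts cA, cB) via the Levene
# formula, summing classes no more probable than the observed one
hwe_biallelic_oracle <- function(a1, a2) {
  all_alleles <- c(a1, a2)
  alleles <- sort(unique(all_alleles))
  stopifnot(length(alleles) == 2)
  cA <- sum(all_alleles == alleles[1])
  cB <- sum(all_alleles == alleles[2])
  n <- length(a1)
  h_obs <- sum(a1 != a2)
  hs <- seq(cA %% 2, min(cA, cB), by = 2)
  prob_of <- function(h) {
    nAA <- (cA - h) / 2
    nBB <- (cB - h) / 2
    exp(lfactorial(n) + lfactorial(cA) + lfactorial(cB) + h * log(2) -
          lfactorial(2 * n) - lfactorial(nAA) - lfactorial(h) - lfactorial(nBB))
  }
  probs <- vapply(hs, prob_of, 0)
  p_obs <- probs[hs == h_obs]
  sum(probs[probs <= p_obs + 1e-12])
}

# tiny genotype table from explicit allele vectors
gt_from <- function(a1, a2, loci = NULL) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  if (is.null(loci)) loci <- sprintf("L%d", seq_len(ncol(a1)))
  genotype_table(a1, a2, loci = loci)
}
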