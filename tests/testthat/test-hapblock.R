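test_that("a SNP paired with itself is in complete LD", {
  set.seed(3)
  g <- rbinom(400, 2, 0.4)
  ld <- pairwise_ld(g, g)
  expect_equal(ld$r2, 1, tolerance = 1e-9)
  expect_equal(ld$dprime, 1, tolerance = 1e-9)
})

test_that("independent markers show negligible LD at large n", {
  set.seed(5)
  ld <- pairwise_ld(rbinom(5000, 2, 0.4), rbinom(5000, 2, 0.3))
  expect_lt(ld$r2, 0.01)
})

test_that("monomorphic input is flagged, not computed", {
  ld <- pairwise_ld(rep(1, 50), rbinom(50, 2, 0.4))
  expect_equal(ld$flag, "monomorphic")
  expect_true(is.na(ld$r2))
})

test_that("two-locus EM recovers known founder haplotype frequencies", {
  pool <- list(list(haps = rbind(c(1L, 1L), c(0L, 0L), c(1L, 0L)),
                    freqs = c(0.45, 0.35, 0.20)))
  cfg <- sim_config(n_samples = 5000, n_blocks = 1, snps_per_block = 2,
                    founder_pool = pool, causal_spec = NULL,
                    missing_rate = 0, seed = 21L)
  g <- simulate_genotypes(cfg)
  ld <- pairwise_ld(g$G$dosage[, 1], g$G$dosage[, 2])
  # truth-table oracle: plug-in D and r2 from the founder frequencies
  h11 <- 0.45; pA <- 0.65; pB <- 0.45
  D <- h11 - pA * pB
  r2_true <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  expect_lt(abs(ld$d - D), 0.01)
  expect_lt(abs(ld$r2 - r2_true), 0.03)
})

test_that("a planted perfect-LD pair becomes exactly one 2-SNP block", {
  set.seed(4)
  n <- 400
  a <- rbinom(n, 2, 0.4)
  doz <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.5), a, a,
               rbinom(n, 2, 0.35), rbinom(n, 2, 0.45))
  G <- toy_genotypes(doz, pos = seq(1000, 6000, by = 1000))
  bl <- partition_blocks(G)
  expect_length(bl, 1)
  expect_identical(bl[[1]]$snp_ids, c("t03", "t04"))
  expect_equal(bl[[1]]$length, 1000)
})

test_that("perfect LD beyond the window cap is never merged", {
  set.seed(4)
  a <- rbinom(500, 2, 0.4)
  G <- toy_genotypes(cbind(a, a), pos = c(1, 150001))
  expect_length(partition_blocks(G, window_kb = 100), 0)
})

test_that("unsorted positions are rejected", {
  G <- toy_genotypes(matrix(rbinom(40, 2, 0.4), 10),
                     pos = c(3000, 1000, 2000, 4000))
  expect_error(partition_blocks(G), "sorted")
})

test_that("planted blocks are recovered on simulated data", {
  cfg <- sim_config(n_samples = 800, n_blocks = 8, snps_per_block = 5,
                    founder_haplotypes_per_block = 3,
                    causal_spec = NULL, missing_rate = 0, seed = 33L)
  d <- simulate_dataset(cfg)
  bl <- partition_blocks(d$G)
  expect_gte(block_boundary_recovery(bl, d$truth, d$G), 0.75)
})

test_that("all-homozygous samples phase in a single pass to allele frequencies", {
  doz <- rbind(c(0, 0, 0), c(2, 2, 2), c(2, 2, 2), c(0, 0, 0))
  ph <- em_phase(doz)
  expect_setequal(ph$haplotypes, c("000", "111"))
  expect_equal(sort(ph$freqs), c(0.5, 0.5))
  expect_true(all(ph$assign$posterior == 1))
})

test_that("a single-SNP block has haplotype frequencies equal to allele frequencies", {
  set.seed(12)
  g <- matrix(rbinom(200, 2, 0.3), ncol = 1)
  ph <- em_phase(g)
  p1 <- mean(g) / 2
  expect_equal(ph$freqs[ph$haplotypes == "1"], p1, tolerance = 1e-9)
  expect_equal(sum(ph$freqs), 1, tolerance = 1e-9)
})

test_that("EM phasing attains the grid-search likelihood optimum on a 2-SNP mixture", {
  pool <- list(list(haps = rbind(c(1L, 1L), c(0L, 0L), c(1L, 0L),
                                 c(0L, 1L)),
                    freqs = c(0.4, 0.3, 0.2, 0.1)))
  cfg <- sim_config(n_samples = 500, n_blocks = 1, snps_per_block = 2,
                    founder_pool = pool, causal_spec = NULL,
                    missing_rate = 0, seed = 9L)
  g <- simulate_genotypes(cfg)
  X <- g$G$dosage
  ph <- em_phase(X, debug = TRUE)
  # oracle: profile the observed-data likelihood over the coupling
  # fraction of the double heterozygotes on a fine grid
  pA <- mean(X[, 1]) / 2; pB <- mean(X[, 2]) / 2
  n3 <- table(factor(X[, 1], 0:2), factor(X[, 2], 0:2))
  grid_ll <- vapply(seq(0, 1, length.out = 101), function(cc) {
    Dmax <- min(pA * (1 - pB), (1 - pA) * pB)
    Dmin <- -min(pA * pB, (1 - pA) * (1 - pB))
    D <- Dmin + cc * (Dmax - Dmin)
    h <- pmax(c((1 - pA) * (1 - pB) + D, (1 - pA) * pB - D,
                pA * (1 - pB) - D, pA * pB + D), 1e-12)
    hx <- c(0, 0, 1, 1); hy <- c(0, 1, 0, 1)
    P <- matrix(0, 3, 3)
    for (i in 1:4) for (j in 1:4)
      P[hx[i] + hx[j] + 1, hy[i] + hy[j] + 1] <-
      P[hx[i] + hx[j] + 1, hy[i] + hy[j] + 1] + h[i] * h[j]
    sum(n3 * log(P))
  }, numeric(1))
  expect_gte(ph$loglik, max(grid_ll) - 0.02)
  # haplotype frequency of "11" close to the grid-optimal value
  cc_hat <- seq(0, 1, length.out = 101)[which.max(grid_ll)]
  Dmax <- min(pA * (1 - pB), (1 - pA) * pB)
  Dmin <- -min(pA * pB, (1 - pA) * (1 - pB))
  h11_grid <- pA * pB + Dmin + cc_hat * (Dmax - Dmin)
  expect_lt(abs(ph$freqs[ph$haplotypes == "11"] - h11_grid), 0.02)
})

test_that("haplotype frequencies sum to one after pruning", {
  for (seed in c(2L, 14L)) {
    cfg <- sim_config(n_samples = 150, n_blocks = 2, snps_per_block = 6,
                      founder_haplotypes_per_block = 6,
                      causal_spec = NULL, missing_rate = 0, seed = seed)
    d <- simulate_genotypes(cfg)
    ph <- em_phase(d$G$dosage[, 1:6], debug = TRUE)
    expect_equal(sum(ph$freqs), 1, tolerance = 1e-6)
  }
})

test_that("the enumeration bounds are enforced", {
  expect_error(em_phase(matrix(1, 2, 30)), "enumeration bound")
  expect_error(em_phase(matrix(1L, 1, 14), max_het = 12),
               "heterozygous sites")
  expect_error(em_phase(matrix(c(NA, 1), 1, 2)), "missing")
})

test_that("a monomorphic block is flagged with P = 1", {
  d <- med_dataset()
  fit <- med_mlm_fit()
  ph <- em_phase(matrix(0L, 400, 2))
  res <- block_assoc(fit$y, fit$W, ph, fit$K, fit$vc)
  expect_equal(res$p, 1)
  expect_equal(res$flag, "monomorphic")
})

test_that("a 2-SNP perfect-LD block test equals the single-marker test", {
  d <- med_dataset()
  fit <- med_mlm_fit()
  set.seed(77)
  x <- rbinom(400, 2, 0.35)
  X2 <- cbind(x, x)
  ph <- em_phase(X2)
  ba <- block_assoc(fit$y, fit$W, ph, fit$K, fit$vc)
  Gx <- toy_genotypes(matrix(x, ncol = 1))
  sc <- snp_scan(fit$y, fit$W, Gx, fit$K, fit$vc)
  expect_equal(ba$chi2, sc$chi2[1], tolerance = 1e-6)
})

test_that("block Wald P-values are calibrated under the null", {
  set.seed(55)
  n <- 300
  pool <- list(list(haps = rbind(c(1L, 1L, 0L), c(0L, 0L, 1L)),
                    freqs = c(0.6, 0.4)))
  cfg <- sim_config(n_samples = n, n_blocks = 1, snps_per_block = 3,
                    founder_pool = pool, causal_spec = NULL,
                    missing_rate = 0, seed = 3L)
  g <- simulate_genotypes(cfg)
  ph <- em_phase(g$G$dosage)
  W <- matrix(1, n, 1)
  vc0 <- structure(list(sigma_a2 = 0, sigma_e2 = 1, h2 = 0),
                   class = "variance_components")
  K <- diag(n)
  ps <- replicate(200, block_assoc(rnorm(n), W, ph, K, vc0)$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a strong low-frequency haplotype effect is detected", {
  cfg <- sim_config(
    n_samples = 1000, n_blocks = 40,
    founder_haplotypes_per_block = 4,
    causal_spec = list(list(type = "haplotype", block = 20L, hap = 1L,
                            beta = 0.45, freq = 0.06)),
    missing_rate = 0, seed = 501L)
  d <- suppressWarnings(simulate_dataset(cfg))
  K <- compute_kinship(d$G, seed = 1L)
  W <- build_design(d$pheno)
  vc <- suppressWarnings(reml_variance_components(d$pheno$adg, W, K))
  tb <- d$truth$blocks[20, ]
  ph <- em_phase(d$G$dosage[, tb$start_snp:tb$end_snp])
  ba <- block_assoc(d$pheno$adg, W, ph, K, vc)
  expect_lt(ba$p, 1e-5)
})

test_that("rank-deficient haplotype designs yield finite estimates", {
  d <- med_dataset()
  fit <- med_mlm_fit()
  set.seed(31)
  x <- rbinom(400, 2, 0.5)
  ph <- em_phase(cbind(x, x))
  # duplicate one design column to force collinearity
  ph$H <- cbind(ph$H, dup = ph$H[, 1])
  ph$haplotypes <- c(ph$haplotypes, "dup")
  ph$freqs <- c(ph$freqs * 0.9, 0.1)
  res <- block_assoc(fit$y, fit$W, ph, fit$K, fit$vc)
  expect_true(is.finite(res$chi2))
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("two equal-frequency haplotypes reduce block VE to the biallelic formula", {
  pool <- list(list(haps = rbind(c(1L, 0L), c(0L, 1L)),
                    freqs = c(0.5, 0.5)))
  cfg <- sim_config(n_samples = 600, n_blocks = 1, snps_per_block = 2,
                    founder_pool = pool, causal_spec = NULL,
                    missing_rate = 0, seed = 41L)
  g <- simulate_genotypes(cfg)
  ph <- em_phase(g$G$dosage)
  set.seed(9)
  counts <- rowSums(matrix(g$truth$hap_assign[[1]] == 2, ncol = 2))
  y <- 0.98 + 0.1 * counts + rnorm(600, 0, 0.1)
  sp2 <- var(y)
  ve <- block_variance_explained(y, ph, sp2)
  g2 <- attr(ve, "groups")
  p_mass <- sum(ph$freqs[g2 == 1]); q_mass <- sum(ph$freqs[g2 == 2])
  beta <- attr(ve, "beta")
  expect_equal(as.numeric(ve),
               snp_variance_explained(p_mass, q_mass, beta, sp2),
               tolerance = 1e-10)
  expect_lt(abs(as.numeric(ve) - 2 * 0.5 * 0.5 * 0.1^2 / sp2), 0.05)
})

test_that("zero haplotype effects give zero variance explained", {
  ph <- em_phase(rbind(c(0, 0), c(2, 2), c(0, 0), c(2, 2)))
  y <- rep(1, 4)
  ve <- block_variance_explained(y, ph, 1)
  expect_equal(as.numeric(ve), 0)
})

test_that("three-haplotype effects cluster and reproduce the two-step oracle", {
  # constructed block: 3 haplotypes with LS effects {0, 0.01, 0.40}
  set.seed(71)
  n <- 900
  hap_draw <- cbind(sample(1:3, n, TRUE, prob = c(0.6, 0.25, 0.15)),
                    sample(1:3, n, TRUE, prob = c(0.6, 0.25, 0.15)))
  haps01 <- rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L))
  X <- haps01[hap_draw[, 1], ] + haps01[hap_draw[, 2], ]
  ph <- em_phase(X)
  eff_true <- c(`00` = 0, `10` = 0.01, `11` = 0.40)
  y <- 1 + eff_true[hap_draw[, 1]] + eff_true[hap_draw[, 2]] +
    rnorm(n, 0, 0.05)
  sp2 <- var(y)
  ve <- block_variance_explained(y, ph, sp2)
  grp <- attr(ve, "groups")
  # the 0.40 haplotype must sit alone in the high group
  expect_equal(sum(grp == 2), 1)
  expect_equal(names(grp)[grp == 2], "11")
  # hand-run oracle for the full two-step statistic
  g2 <- grp == 2
  ind <- g2[ph$assign$hap1] + g2[ph$assign$hap2]
  beta_or <- unname(coef(lm(y ~ ind))[2])
  p_or <- sum(ph$freqs[!g2]); q_or <- sum(ph$freqs[g2])
  expect_equal(as.numeric(ve), 2 * p_or * q_or * beta_or^2 / sp2,
               tolerance = 1e-10)
})

test_that("block length is the end minus start coordinate", {
  # worked examples on genome-scale coordinate pairs
  expect_equal(block_length(38704872, 38707716), 2844)
  expect_equal(block_length(38711873, 38734752), 22879)
  expect_equal(block_length(38735901, 38736441), 540)
  expect_equal(block_length(38737206, 38837159), 99953)
  expect_equal(block_length(89890121, 89893239), 3118)
  expect_equal(block_length(5, 6), 1)
  expect_error(block_length(10, 10), "less than")
})
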