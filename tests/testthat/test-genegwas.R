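test_that("gene windows match a brute-force interval oracle", {
  set.seed(6)
  n_snps <- 20
  map_pos <- sort(sample(1e4:1e6, n_snps))
  G <- toy_genotypes(matrix(rbinom(10 * n_snps, 2, 0.4), nrow = 10),
                     pos = map_pos)
  ann <- data.frame(gene_id = paste0("g", 1:5), chrom = "1",
                    start = c(2e4, 1e5, 3e5, 5e5, 9e5),
                    end = c(5e4, 2e5, 4e5, 6e5, 9.5e5))
  flank <- 25000
  win <- build_gene_windows(ann, G, flank_bp = flank, min_snps = 0)
  for (w in win) {
    i <- match(w$gene_id, ann$gene_id)
    oracle <- G$map$snp_id[G$map$pos >= ann$start[i] - flank &
                             G$map$pos <= ann$end[i] + flank]
    expect_identical(w$snp_ids, oracle)
  }
})

test_that("genes with fewer than three SNPs are excluded", {
  G <- toy_genotypes(matrix(rbinom(30, 2, 0.4), nrow = 10),
                     pos = c(100, 200, 100000))
  ann <- data.frame(gene_id = c("sparse", "rich"), chrom = "1",
                    start = c(99000, 50), end = c(101000, 250))
  expect_message(win <- build_gene_windows(ann, G, flank_bp = 0),
                 "fewer than 3")
  expect_length(win, 0)  # "rich" covers only 2 SNPs too
  ann2 <- data.frame(gene_id = "ok", chrom = "1", start = 50,
                     end = 100001)
  win2 <- build_gene_windows(ann2, G, flank_bp = 0)
  expect_length(win2, 1)
  expect_equal(win2[[1]]$n_snps, 3)
})

test_that("a SNP exactly at the window edge is included (closed interval)", {
  G <- toy_genotypes(matrix(rbinom(40, 2, 0.4), nrow = 10),
                     pos = c(100, 150, 200, 300))
  ann <- data.frame(gene_id = "g", chrom = "1", start = 100, end = 200)
  win <- build_gene_windows(ann, G, flank_bp = 0)
  expect_identical(win[[1]]$snp_ids, c("t01", "t02", "t03"))
})

test_that("non-autosomal genes are dropped and heavy malformation is an error", {
  G <- toy_genotypes(matrix(rbinom(50, 2, 0.4), nrow = 10),
                     pos = (1:5) * 100)
  ann <- data.frame(gene_id = c("a", "x"), chrom = c("1", "X"),
                    start = c(100, 100), end = c(500, 500))
  expect_message(win <- build_gene_windows(ann, G, flank_bp = 0),
                 "non-autosomal")
  expect_length(win, 1)
  bad <- data.frame(gene_id = c("a", "b"), chrom = c("1", "1"),
                    start = c(100, 500), end = c(500, 100))
  expect_error(suppressWarnings(build_gene_windows(bad, G)), "malformed")
})

test_that("PC retention follows the strict cumulative-proportion rule", {
  # exact eigenvalue shares via orthogonal construction
  n <- 40
  set.seed(10)
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n)))
  Q <- scale(Q, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Q))[, 1:3]
  make_X <- function(shares)
    Q[, seq_along(shares), drop = FALSE] %*%
      diag(sqrt(shares), length(shares))
  # shares {0.5, 0.3, 0.2}: cumulative 0.5, 0.8, 1.0 -> 3 PCs
  pcs <- gene_pcs(make_X(c(0.5, 0.3, 0.2)))
  expect_equal(attr(pcs, "m"), 3)
  expect_equal(attr(pcs, "shares")[1:3], c(0.5, 0.3, 0.2),
               tolerance = 1e-8)
  # shares {0.9, 0.1}: immediate exceedance -> 1 PC
  pcs2 <- gene_pcs(cbind(make_X(c(0.9, 0.1)), 0))
  expect_equal(attr(pcs2, "m"), 1)
})

test_that("a rank-1 gene (perfect LD) yields exactly one PC", {
  set.seed(3)
  x <- rbinom(50, 2, 0.4)
  pcs <- gene_pcs(cbind(x, x, x))
  expect_equal(attr(pcs, "m"), 1)
  expect_error(gene_pcs(matrix(1, 20, 3)), "zero total variance")
})

test_that("PC signs are deterministic under loading-sign convention", {
  set.seed(8)
  X <- matrix(rbinom(200, 2, 0.4), 50)
  p1 <- gene_pcs(X)
  p2 <- gene_pcs(X)
  expect_identical(p1, p2)
})

test_that("EBVs vanish when additive variance is zero", {
  vc0 <- structure(list(sigma_a2 = 0, sigma_e2 = 1),
                   class = "variance_components")
  expect_equal(compute_ebv(rnorm(10), matrix(1, 10, 1), diag(10), vc0),
               rep(0, 10))
})

test_that("GBLUP solution matches a dense Henderson MME solve at n = 5", {
  set.seed(5)
  n <- 5
  L <- matrix(rnorm(25), n)
  K <- tcrossprod(L) / n + 0.1 * diag(n)   # invertible PSD
  W <- cbind(1, rnorm(n))
  y <- rnorm(n)
  vc <- structure(list(sigma_a2 = 0.6, sigma_e2 = 1.1),
                  class = "variance_components")
  u_pkg <- compute_ebv(y, W, K, vc)
  # oracle: Henderson mixed-model equations
  lam <- vc$sigma_e2 / vc$sigma_a2
  lhs <- rbind(cbind(crossprod(W), t(W)),
               cbind(W, diag(n) + lam * solve(K)))
  rhs <- c(crossprod(W, y), y)
  sol <- solve(lhs, rhs)
  expect_equal(u_pkg, sol[-(1:2)], tolerance = 1e-8)
})

test_that("EBVs track true polygenic values on simulated data", {
  d <- med_dataset()
  fit <- med_mlm_fit()
  ebv <- compute_ebv(fit$y, fit$W, fit$K, fit$vc)
  g_true <- d$truth$polygenic + d$truth$causal_values
  expect_gt(cor(ebv, g_true), 0.5)
})

test_that("per-PC regressions match hand-computed values and min-P rule", {
  set.seed(20)
  n <- 80
  pcs <- matrix(rnorm(3 * n), n)
  colnames(pcs) <- paste0("PC", 1:3)
  ebv <- 0.3 * pcs[, 2] + rnorm(n)
  gt <- gene_test(ebv, pcs, "g1")
  for (k in 1:3) {
    or <- summary(lm(ebv ~ pcs[, k]))$coefficients[2, ]
    expect_equal(gt$per_pc$b[k], unname(or[1]), tolerance = 1e-9)
    expect_equal(gt$per_pc$chi2[k], unname(or[3])^2, tolerance = 1e-9)
  }
  expect_equal(gt$p, min(gt$per_pc$p))
  expect_lte(gt$p, min(gt$per_pc$p))
})

test_that("gene P is invariant to PC sign flips", {
  set.seed(21)
  pcs <- matrix(rnorm(160), 80)
  ebv <- rnorm(80)
  g1 <- gene_test(ebv, pcs)
  g2 <- gene_test(ebv, pcs %*% diag(c(-1, 1)))
  expect_equal(g1$p, g2$p, tolerance = 1e-12)
})

test_that("an EBV equal to a PC is underflow-guarded, orthogonality gives nulls", {
  set.seed(22)
  p1 <- rnorm(60)
  gt <- gene_test(p1, cbind(p1))
  expect_equal(gt$p, .Machine$double.xmin)
  # constant PC: skipped; all constant: untestable
  gt2 <- gene_test(rnorm(60), cbind(rep(1, 60), p1))
  expect_true(gt2$per_pc$skipped[1])
  gt3 <- gene_test(rnorm(60), cbind(rep(1, 60)))
  expect_equal(gt3$flag, "untestable")
})

test_that("with one PC the gene test equals a plain Wald regression", {
  set.seed(23)
  x <- rnorm(100); ebv <- 0.2 * x + rnorm(100)
  gt <- gene_test(ebv, cbind(x))
  tval <- summary(lm(ebv ~ x))$coefficients[2, 3]
  expect_equal(gt$p, pchisq(tval^2, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("permutation pool bookkeeping is n_genes x n_perm", {
  expect_identical(perm_pool_size(23856, 1000), 23856000)
  set.seed(30)
  pcs_list <- replicate(7, cbind(rnorm(40)), simplify = FALSE)
  pt <- permutation_threshold(rnorm(40), pcs_list, n_perm = 50,
                              alpha = 0.1, seed = 2L)
  expect_equal(pt$n_pool, 7 * 50)
  expect_equal(pt$rank, ceiling(0.1 * 350))
  expect_error(permutation_threshold(rnorm(40), pcs_list, n_perm = 0),
               "at least 1")
})

test_that("the cutoff approximates alpha for uniform single-PC nulls", {
  set.seed(31)
  n <- 60
  pcs_list <- replicate(50, cbind(rnorm(n)), simplify = FALSE)
  pt <- permutation_threshold(rnorm(n), pcs_list, n_perm = 200,
                              alpha = 0.05, seed = 3L)
  # each pooled statistic is a uniform P under the null; the empirical
  # alpha-quantile of 10,000 uniforms has SE ~ sqrt(a(1-a)/N)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(pt$cutoff - 0.05), 3 * se + 1 / 10000)
})

test_that("alpha = 1 returns the maximum pooled statistic and seeds reproduce", {
  set.seed(32)
  pcs_list <- replicate(5, cbind(rnorm(30)), simplify = FALSE)
  e <- rnorm(30)
  pt1 <- permutation_threshold(e, pcs_list, n_perm = 20, alpha = 1,
                               seed = 7L)
  expect_equal(pt1$rank, pt1$n_pool)
  pt2 <- permutation_threshold(e, pcs_list, n_perm = 20, alpha = 1,
                               seed = 7L)
  expect_identical(pt1$cutoff, pt2$cutoff)
})

test_that("the phenotype-permutation scheme reproduces gene-test statistics exactly", {
  # operator consistency: A y must equal compute_ebv
  fit <- med_mlm_fit()
  A <- ebv_operator(fit$W, fit$K, fit$vc)
  ebv <- compute_ebv(fit$y, fit$W, fit$K, fit$vc)
  expect_equal(drop(A %*% fit$y), ebv, tolerance = 1e-8)
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
})
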