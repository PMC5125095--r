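# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# medium simulated dataset with default (study-condition) settings,
# cached across test files
med_dataset <- function() {
  if (is.null(.fixture_env$med)) {
    cfg <- sim_config(n_samples = 400, n_blocks = 12, missing_rate = 0,
                      seed = 101L)
    .fixture_env$med <- simulate_dataset(cfg)
  }
  .fixture_env$med
}

med_mlm_fit <- function() {
  if (is.null(.fixture_env$med_fit)) {
    d <- med_dataset()
    K <- compute_kinship(d$G, seed = 1L)
    W <- build_design(d$pheno)
    vc <- suppressWarnings(
      reml_variance_components(d$pheno$adg, W, K))
    .fixture_env$med_fit <- list(K = K, W = W, vc = vc,
                                 y = d$pheno$adg)
  }
  .fixture_env$med_fit
}

# tiny genotype matrix built by hand
toy_genotypes <- function(dosage, pos = NULL, chrom = "1") {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  genotype_matrix(dosage,
                  data.frame(snp_id = sprintf("t%02d", seq_len(m)),
                             chrom = chrom,
                             pos = pos,
                             a1 = "A", a2 = "G",
                             stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent HWE oracle: direct log-factorial enumeration of all
# heterozygote counts compatible with the allele counts
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# independent restricted log-likelihood via dense solves (grid oracle)
reml_ll_oracle <- function(y, W, K, lambda) {
  n <- length(y); c <- ncol(W)
  V0 <- K + lambda * diag(n)
  V0i <- solve(V0)
  P0 <- V0i - V0i %*% W %*% solve(t(W) %*% V0i %*% W, t(W) %*% V0i)
  quad <- drop(t(y) %*% P0 %*% y)
  sa2 <- quad / (n - c)
  as.numeric(
    -0.5 * ((n - c) * log(2 * pi) + (n - c) * log(sa2) + (n - c) +
              determinant(V0, logarithm = TRUE)$modulus +
              determinant(t(W) %*% V0i %*% W, logarithm = TRUE)$modulus -
              determinant(crossprod(W), logarithm = TRUE)$modulus))
}
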