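# Mixed-linear-model core: VanRaden kinship, EMMA-style REML variance
# components, EMMAX/P3D single-marker scan, per-marker variance explained.

# internal: VanRaden genomic relationship matrix from a complete dosage
# matrix; monomorphic columns are dropped by the caller's bookkeeping.
vanraden_kinship <- function(X) {
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2, 2 * p)
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("no polymorphic SNPs for kinship")
  tcrossprod(Z) / denom
}

#' Genomic relationship (kinship) matrix
#'
#' VanRaden form on a random draw of markers: dosages centered by twice
#' the allele frequency, cross-product scaled by `sum(2 p (1 - p))`. At
#' most `n_random` SNPs are sampled without replacement (the full panel
#' is used when it is smaller); monomorphic SNPs in the draw are excluded
#' with a message.
#'
#' @param G complete (imputed) [genotype_matrix()], autosomal SNPs.
#' @param n_random number of random SNPs to use (default 50,000).
#' @param seed integer seed for the marker draw.
#' @return object of class `kinship_matrix`: the n x n matrix with
#'   attributes `snp_ids` (markers used) and `n_excluded`.
#' @export
compute_kinship <- function(G, n_random = 50000, seed = 1L) {
  if (anyNA(G$dosage))
    stop("kinship requires a complete matrix; run impute_missing() first")
  m <- ncol(G$dosage)
  idx <- if (n_random >= m) seq_len(m) else
    sort(with_seed(seed, sample.int(m, n_random)))
  X <- G$dosage[, idx, drop = FALSE]
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  n_excl <- sum(!poly)
  if (n_excl > 0)
    message(n_excl, " monomorphic SNP(s) excluded from kinship")
  K <- vanraden_kinship(X)
  dimnames(K) <- list(G$sample_ids, G$sample_ids)
  structure(K, snp_ids = G$map$snp_id[idx][poly], n_excluded = n_excl,
            class = c("kinship_matrix", "matrix", "array"))
}

#' Fixed-effect design matrix
#'
#' Intercept plus treatment-coded categorical covariates from the
#' phenotype table, optionally augmented with population-stratification
#' principal components; reduced to full column rank.
#'
#' @param pheno phenotype/covariate data.frame.
#' @param covariates covariate column names (default: everything except
#'   `sample_id` and `adg`).
#' @param pcs optional matrix of stratification PCs
#'   ([stratification_pcs()]).
#' @return numeric design matrix with an intercept column.
#' @export
build_design <- function(pheno, covariates = setdiff(names(pheno),
                                                     c("sample_id", "adg")),
                         pcs = NULL) {
  if (length(covariates)) {
    fml <- stats::as.formula(paste("~", paste(covariates, collapse = "+")))
    W <- stats::model.matrix(fml, data = pheno)
  } else {
    W <- matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  }
  if (!is.null(pcs)) {
    colnames(pcs) <- paste0("stratPC", seq_len(ncol(pcs)))
    W <- cbind(W, pcs)
  }
  qrW <- qr(W)
  W[, qrW$pivot[seq_len(qrW$rank)], drop = FALSE]
}

#' Genotype principal components for stratification
#'
#' Top `k` principal components of the centered dosage matrix, used as
#' population-stratification covariates in the fixed-effect design.
#'
#' @param G complete [genotype_matrix()].
#' @param k number of components (default 3).
#' @return n x k matrix of scores.
#' @export
stratification_pcs <- function(G, k = 3) {
  Z <- scale(G$dosage, center = TRUE, scale = FALSE)
  sv <- La.svd(Z, nu = min(k, min(dim(Z))), nv = 0)
  sv$u %*% diag(sv$d[seq_len(ncol(sv$u))], ncol(sv$u))
}

# internal: direct restricted log-likelihood at (sigma_a2, sigma_e2),
# dense algebra; also the reporting convention for reml fits
reml_loglik_direct <- function(y, W, K, sigma_a2, sigma_e2) {
  n <- length(y); c <- ncol(W)
  V <- sigma_a2 * K + sigma_e2 * diag(n)
  cV <- chol(V)
  Vi <- chol2inv(cV)
  WtViW <- crossprod(W, Vi %*% W)
  P <- Vi - Vi %*% W %*% solve(WtViW, crossprod(W, Vi))
  as.numeric(
    -0.5 * ((n - c) * log(2 * pi) + 2 * sum(log(diag(cV))) +
              determinant(WtViW, logarithm = TRUE)$modulus -
              determinant(crossprod(W), logarithm = TRUE)$modulus +
              drop(crossprod(y, P %*% y))))
}

#' REML variance components via spectral decomposition
#'
#' Single-kinship EMMA-style restricted maximum likelihood: the model
#' `y = W v + u + e`, `u ~ N(0, sigma_a2 K)`, `e ~ N(0, sigma_e2 I)` is
#' rotated onto the eigenvectors of the projected kinship and the REML
#' criterion optimized in one dimension over `delta = sigma_e2 /
#' sigma_a2` on a log grid interval.
#'
#' @param y trait vector.
#' @param W fixed-effect design matrix (full column rank, including the
#'   intercept); see [build_design()].
#' @param K kinship matrix (symmetric PSD up to tolerance).
#' @param interval search interval for `log(delta)`.
#' @return list of class `variance_components`: `sigma_a2`, `sigma_e2`,
#'   `h2 = sigma_a2 / (sigma_a2 + sigma_e2)`, `loglik` (restricted
#'   log-likelihood at the optimum) and `boundary` flag.
#' @export
reml_variance_components <- function(y, W, K, interval = c(-12, 12)) {
  y <- as.numeric(y)
  n <- length(y)
  W <- as.matrix(W)
  stopifnot(nrow(W) == n, nrow(K) == n, ncol(K) == n)
  if (qr(W)$rank < ncol(W)) stop("W is not full column rank")
  c <- ncol(W)
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")

  eK <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(eK) < -1e-8 * max(abs(eK), 1))
    stop("K is not positive semi-definite within tolerance")
  if (stats::sd(eK) < 1e-8 * max(mean(abs(eK)), 1e-12))
    warning("kinship is numerically proportional to the identity; ",
            "variance components are unidentifiable")

  # rotate out the fixed effects: eigen of Q2' K Q2 with Q2 an
  # orthonormal basis of the complement of span(W) (valid for low-rank K)
  Q2 <- qr.Q(qr(W), complete = TRUE)[, -seq_len(c), drop = FALSE]
  M <- crossprod(Q2, K %*% Q2)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  xi <- pmax(eg$values, 0)
  eta <- drop(crossprod(eg$vectors, crossprod(Q2, y)))

  crit <- function(logdelta) {
    d <- exp(logdelta)
    0.5 * ((n - c) * (log((n - c) / (2 * pi)) - 1 -
                        log(sum(eta^2 / (xi + d)))) -
             sum(log(xi + d)))
  }
  # coarse grid first (the restricted likelihood can be multimodal in
  # delta), then a local refinement around the best grid cell
  grid <- seq(interval[1], interval[2], length.out = 121)
  gv <- vapply(grid, crit, numeric(1))
  i0 <- which.max(gv)
  lo <- grid[max(i0 - 1, 1)]; hi <- grid[min(i0 + 1, length(grid))]
  opt <- stats::optimize(crit, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-9)
  cand <- c(opt$maximum, interval, grid[i0])
  vals <- vapply(cand, crit, numeric(1))
  logdelta <- cand[which.max(vals)]
  boundary <- logdelta %in% interval ||
    min(abs(logdelta - interval)) < 1e-6
  if (boundary)
    warning("REML optimum at the search boundary; ",
            "a variance component is effectively zero")
  delta <- exp(logdelta)
  sigma_a2 <- sum(eta^2 / (xi + delta)) / (n - c)
  sigma_e2 <- delta * sigma_a2
  structure(list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
                 h2 = 1 / (1 + delta),
                 loglik = reml_loglik_direct(y, W, K, sigma_a2, sigma_e2),
                 delta = delta, boundary = boundary),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance components: sigma_a2 = %.5g, sigma_e2 = %.5g, h2 = %.3f\n",
    x$sigma_a2, x$sigma_e2, x$h2))
  invisible(x)
}

#' Whitening transform of the mixed model
#'
#' The matrix `T` with `T V T' = I` for `V = sigma_a2 K + sigma_e2 I`,
#' built from the eigendecomposition of the kinship. Rotating `y`, the
#' design and the markers by `T` turns every GLS fit under `V` into
#' ordinary least squares.
#'
#' @param K kinship matrix.
#' @param vc a [reml_variance_components()] fit.
#' @return n x n transform matrix.
#' @export
mlm_transform <- function(K, vc) {
  eg <- eigen(K, symmetric = TRUE)
  d <- vc$sigma_a2 * pmax(eg$values, 0) + vc$sigma_e2
  t(eg$vectors) / sqrt(d)   # rows scaled: diag(1/sqrt(d)) %*% t(U)
}

#' Single-marker mixed-model scan (EMMAX/P3D)
#'
#' Generalized-least-squares effect estimates for each SNP under
#' `V = sigma_a2 K + sigma_e2 I`, with the variance components fixed at
#' the global REML fit (the P3D/EMMAX approximation). Wald chi-square
#' P-values with one degree of freedom. Setting `per_snp_reml = TRUE`
#' re-estimates the variance components for every marker (exact, slow;
#' intended for small panels).
#'
#' @param y trait vector.
#' @param W fixed-effect design (intercept, covariates, stratification
#'   PCs).
#' @param G complete [genotype_matrix()].
#' @param K kinship matrix.
#' @param vc optional precomputed [reml_variance_components()] fit.
#' @param per_snp_reml refit variance components per marker.
#' @return data.frame (one row per SNP): `snp_id`, `chrom`, `pos`,
#'   `beta`, `se`, `chi2`, `p`, `var_explained`, `degenerate`.
#' @export
snp_scan <- function(y, W, G, K, vc = NULL, per_snp_reml = FALSE) {
  y <- as.numeric(y); W <- as.matrix(W)
  if (is.null(vc)) vc <- reml_variance_components(y, W, K)
  if (per_snp_reml) return(snp_scan_exact(y, W, G, K))
  Tm <- mlm_transform(K, vc)
  yt <- drop(Tm %*% y)
  Wt <- Tm %*% W
  Xt <- Tm %*% G$dosage
  qrW <- qr(Wt)
  yr <- stats::resid(stats::lm.fit(Wt, yt))
  Xr <- Xt - qr.fitted(qrW, Xt)
  cs <- colSums(Xr^2)
  degenerate <- cs < 1e-10 * nrow(Wt)
  beta <- ifelse(degenerate, NA_real_, colSums(Xr * yr) / cs)
  se <- ifelse(degenerate, NA_real_, 1 / sqrt(cs))
  chi2 <- ifelse(degenerate, 0, (beta / se)^2)
  p <- ifelse(degenerate, 1, stats::pchisq(chi2, 1, lower.tail = FALSE))
  p <- pmax(p, .Machine$double.xmin)
  pf <- allele_freq(G)
  sp2 <- stats::var(y)
  ve <- ifelse(degenerate, 0,
               vapply(seq_along(beta), function(j) {
                 if (is.na(beta[j])) 0 else
                   snp_variance_explained(pf[j], 1 - pf[j], beta[j], sp2)
               }, numeric(1)))
  data.frame(snp_id = G$map$snp_id, chrom = G$map$chrom, pos = G$map$pos,
             beta = beta, se = se, chi2 = chi2, p = p,
             var_explained = ve, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

# exact per-marker REML scan for small panels
snp_scan_exact <- function(y, W, G, K) {
  m <- ncol(G$dosage)
  sp2 <- stats::var(y)
  pf <- allele_freq(G)
  rows <- lapply(seq_len(m), function(j) {
    x <- G$dosage[, j]
    if (stats::var(x) < 1e-12)
      return(data.frame(beta = NA_real_, se = NA_real_, chi2 = 0, p = 1,
                        var_explained = 0, degenerate = TRUE))
    Wj <- cbind(W, snp = x)
    vc <- reml_variance_components(y, Wj, K)
    Tm <- mlm_transform(K, vc)
    fit <- stats::lm.fit(Tm %*% Wj, drop(Tm %*% y))
    XtX_inv <- chol2inv(chol(crossprod(Tm %*% Wj)))
    beta <- fit$coefficients["snp"]
    se <- sqrt(XtX_inv[ncol(Wj), ncol(Wj)])
    chi2 <- (beta / se)^2
    data.frame(beta = beta, se = se, chi2 = chi2,
               p = max(stats::pchisq(chi2, 1, lower.tail = FALSE),
                       .Machine$double.xmin),
               var_explained = snp_variance_explained(pf[j], 1 - pf[j],
                                                      beta, sp2),
               degenerate = FALSE)
  })
  cbind(data.frame(snp_id = G$map$snp_id, chrom = G$map$chrom,
                   pos = G$map$pos, stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

#' Phenotypic variance explained by a biallelic factor
#'
#' `2 p q beta^2 / sigma_p2`, clipped to `[0, 1]`.
#'
#' @param p,q allele frequencies (must sum to 1 within 1e-9).
#' @param beta additive effect (trait units per allele).
#' @param sigma_p2 phenotypic variance (> 0).
#' @return fraction of variance explained.
#' @export
snp_variance_explained <- function(p, q, beta, sigma_p2) {
  if (abs(p + q - 1) > 1e-9) stop("allele frequencies must sum to 1")
  if (sigma_p2 <= 0) stop("sigma_p2 must be positive")
  min(max(2 * p * q * beta^2 / sigma_p2, 0), 1)
}
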