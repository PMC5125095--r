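# Haplotype-based GWAS: pairwise LD with D' confidence intervals,
# Gabriel-style block partitioning, EM phasing over enumerated
# diplotypes, block-level mixed-model tests and the two-step
# variance-explained statistic.

#' Pairwise linkage disequilibrium from unphased genotypes
#'
#' Two-locus haplotype frequencies are estimated by EM (only the double
#' heterozygote is ambiguous); D, D' and r-squared follow from them. The
#' D' confidence interval is the likelihood-based interval used in block
#' partitioning: the likelihood of the 3x3 genotype table is profiled
#' over |D'| on a 101-point grid with allele frequencies held at their
#' estimates, and the central 90% support interval reported.
#'
#' @param gA,gB dosage vectors for two biallelic SNPs on the same
#'   samples (`NA` allowed; pairwise-complete used).
#' @param ci compute the D' confidence interval (skippable for speed).
#' @return list of class `ld_stats`: `r2`, `dprime`, `d`, `ci_low`,
#'   `ci_high`, `flag` (`NA` or `"monomorphic"`).
#' @export
pairwise_ld <- function(gA, gB, ci = TRUE) {
  ok <- !is.na(gA) & !is.na(gB)
  a <- gA[ok]; b <- gB[ok]
  out <- list(r2 = NA_real_, dprime = NA_real_, d = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_, flag = NA_character_)
  class(out) <- "ld_stats"
  if (length(a) == 0 || stats::var(a) == 0 || stats::var(b) == 0) {
    out$flag <- "monomorphic"
    return(out)
  }
  n <- table(factor(a, 0:2), factor(b, 0:2))
  h <- em_two_locus(n)
  pA <- h[3] + h[4]   # alt freq locus A  (h = c(h00, h01, h10, h11))
  pB <- h[2] + h[4]
  D <- h[4] - pA * pB
  out$d <- D
  out$r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  out$dprime <- if (dmax > 0) D / dmax else 0
  if (ci) {
    cis <- dprime_ci(n, pA, pB, sign(D + .Machine$double.eps))
    out$ci_low <- cis[1]; out$ci_high <- cis[2]
  }
  out
}

# internal: EM for two-locus haplotype frequencies from a 3x3 genotype
# count table (rows gA = 0:2, cols gB = 0:2)
em_two_locus <- function(n, tol = 1e-10, max_iter = 200) {
  N <- sum(n)
  # fixed (unambiguous) haplotype contributions
  base <- c(
    h00 = 2 * n[1, 1] + n[1, 2] + n[2, 1],
    h01 = 2 * n[1, 3] + n[1, 2] + n[2, 3],
    h10 = 2 * n[3, 1] + n[2, 1] + n[3, 2],
    h11 = 2 * n[3, 3] + n[3, 2] + n[2, 3])
  dh <- n[2, 2]                      # double heterozygotes
  h <- rep(0.25, 4)
  for (it in seq_len(max_iter)) {
    denom <- h[1] * h[4] + h[2] * h[3]
    pc <- if (denom > 0) h[1] * h[4] / denom else 0.5
    cnt <- base + dh * c(pc, 1 - pc, 1 - pc, pc)
    h_new <- cnt / (2 * N)
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  unname(h)
}

# internal: likelihood-based support interval for |D'|
dprime_ci <- function(n, pA, pB, s, grid = seq(0, 1, length.out = 101)) {
  dmax_pos <- min(pA * (1 - pB), (1 - pA) * pB)
  dmax_neg <- min(pA * pB, (1 - pA) * (1 - pB))
  dmax <- if (s >= 0) dmax_pos else dmax_neg
  # genotype-pair probabilities under random union of gametes
  hx <- c(0, 0, 1, 1); hy <- c(0, 1, 0, 1)
  ll <- vapply(grid, function(dp) {
    D <- s * dp * dmax
    h <- pmax(c((1 - pA) * (1 - pB) + D, (1 - pA) * pB - D,
                pA * (1 - pB) - D, pA * pB + D), 1e-12)
    P <- matrix(0, 3, 3)
    for (i in 1:4) for (j in 1:4)
      P[hx[i] + hx[j] + 1, hy[i] + hy[j] + 1] <-
      P[hx[i] + hx[j] + 1, hy[i] + hy[j] + 1] + h[i] * h[j]
    sum(n * log(P))
  }, numeric(1))
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  lo <- grid[which(cumsum(w) > 0.05)[1]]
  tail <- rev(cumsum(rev(w)))
  hi <- grid[max(which(tail > 0.05))]
  c(lo, hi)
}

#' Partition SNPs into haplotype blocks (Gabriel CI method)
#'
#' A SNP pair is in "strong LD" when its D' confidence interval has
#' lower bound >= `strong_low` and upper bound >= `strong_high`, and
#' shows "strong recombination" when the upper bound is below
#' `recomb_high`. A candidate span is a block when its outermost pair is
#' in strong LD and at least `inform_frac` of its informative pairs are
#' strong LD; spans never exceed `window_kb`. Candidates are ranked by
#' physical length and chosen greedily without overlap, so the result is
#' deterministic.
#'
#' @param G a [genotype_matrix()] with SNPs sorted by position within
#'   chromosome (unsorted input is an error).
#' @param window_kb maximum block span in kb (default 100).
#' @param strong_low,strong_high,recomb_high,inform_frac Gabriel CI
#'   thresholds (PLINK 1.7 defaults).
#' @return list of blocks; each is a list with `name`
#'   (`Hap-<chr>-N<index>`), `chrom`, `start`, `end`, `length`,
#'   `snp_ids`, `snp_idx` (column indices into `G`).
#' @export
partition_blocks <- function(G, window_kb = 100, strong_low = 0.70,
                             strong_high = 0.98, recomb_high = 0.90,
                             inform_frac = 0.95) {
  window_bp <- window_kb * 1000
  out <- list()
  for (chr in unique(G$map$chrom)) {
    idx <- which(G$map$chrom == chr)
    pos <- G$map$pos[idx]
    if (is.unsorted(pos))
      stop("SNPs must be sorted by position within chromosome ", chr)
    m <- length(idx)
    if (m < 2) next
    cls <- matrix(0L, m, m)   # 1 strong LD, -1 strong recomb, 0 uninform.
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (pos[j] - pos[i] > window_bp) break
        ld <- pairwise_ld(G$dosage[, idx[i]], G$dosage[, idx[j]])
        if (!is.na(ld$flag)) next
        if (ld$ci_low >= strong_low && ld$ci_high >= strong_high) {
          cls[i, j] <- 1L
        } else if (ld$ci_high < recomb_high) {
          cls[i, j] <- -1L
        }
      }
    }
    cand <- list()
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (pos[j] - pos[i] > window_bp) break
        if (cls[i, j] != 1L) next
        sub <- cls[i:j, i:j, drop = FALSE]
        vals <- sub[upper.tri(sub)]
        n_inf <- sum(vals != 0L)
        if (n_inf == 0) next
        if (sum(vals == 1L) / n_inf >= inform_frac)
          cand[[length(cand) + 1L]] <-
            c(i = i, j = j, span = pos[j] - pos[i], nsnp = j - i + 1L)
      }
    }
    if (!length(cand)) next
    cm <- do.call(rbind, cand)
    ord <- order(-cm[, "span"], -cm[, "nsnp"], cm[, "i"])
    cm <- cm[ord, , drop = FALSE]
    used <- rep(FALSE, m)
    sel <- list()
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, "i"]; j <- cm[r, "j"]
      if (any(used[i:j])) next
      used[i:j] <- TRUE
      sel[[length(sel) + 1L]] <- c(i, j)
    }
    sel <- sel[order(vapply(sel, `[`, numeric(1), 1))]
    for (k in seq_along(sel)) {
      i <- sel[[k]][1]; j <- sel[[k]][2]
      out[[length(out) + 1L]] <- list(
        name = sprintf("Hap-%s-N%d", chr, k),
        chrom = chr, start = pos[i], end = pos[j],
        length = block_length(pos[i], pos[j]),
        snp_ids = G$map$snp_id[idx[i:j]],
        snp_idx = idx[i:j])
    }
  }
  out
}

#' Physical length of a haplotype block
#'
#' The end coordinate minus the start coordinate in bp.
#'
#' @param start,end block boundary positions (bp), `start < end`.
#' @return length in bp.
#' @export
block_length <- function(start, end) {
  if (any(start >= end)) stop("start must be less than end")
  end - start
}

# internal: enumerate compatible haplotype pairs for one genotype vector
# (values 0/1/2). Haplotypes are encoded as strings over {0,1}.
compat_pairs <- function(g, max_het) {
  het <- which(g == 1L)
  k <- length(het)
  if (k > max_het)
    stop("sample with ", k, " heterozygous sites exceeds the ",
         "enumeration bound; split the block")
  base <- ifelse(g == 2L, 1L, 0L)
  if (k == 0) {
    h <- paste(base, collapse = "")
    return(list(h1 = h, h2 = h))
  }
  n_combo <- 2L^(k - 1L)
  h1 <- character(n_combo); h2 <- character(n_combo)
  for (c0 in seq_len(n_combo) - 1L) {
    bits <- as.integer(intToBits(c0))[seq_len(max(k - 1L, 1L))]
    al1 <- c(1L, if (k > 1) bits[seq_len(k - 1L)])
    a <- base; a[het] <- al1
    b <- base; b[het] <- 1L - al1
    h1[c0 + 1L] <- paste(a, collapse = "")
    h2[c0 + 1L] <- paste(b, collapse = "")
  }
  list(h1 = h1, h2 = h2)
}

#' EM haplotype phasing within a block
#'
#' Expectation-maximization over the haplotype pairs compatible with
#' each sample's unphased genotypes. Converged when the largest
#' frequency change drops below `tol` or after `max_iter` iterations;
#' haplotypes below frequency `prune` are then removed and frequencies
#' renormalized. Per-sample output is both the most probable diplotype
#' (with its posterior probability) and the expected haplotype dosage
#' matrix used as the association design.
#'
#' @param block_G dosage matrix (samples x block SNPs, no missing) or a
#'   [genotype_matrix()] subset.
#' @param max_snps enumeration bound on block width (error above).
#' @param max_het bound on per-sample heterozygous sites.
#' @param tol,max_iter,prune EM controls.
#' @param debug assert monotonicity of the observed-data log-likelihood
#'   at every iteration.
#' @param name,chrom optional block annotations.
#' @return list of class `haplotype_block`: `haplotypes` (0/1 strings),
#'   `freqs`, `assign` (data.frame `hap1`, `hap2`, `posterior`), `H`
#'   (expected dosage matrix), `loglik`, plus coordinates when the input
#'   was a `genotype_matrix`.
#' @export
em_phase <- function(block_G, max_snps = 25, max_het = 12, tol = 1e-6,
                     max_iter = 1000, prune = 1e-4, debug = FALSE,
                     name = NULL, chrom = NULL) {
  meta <- NULL
  if (inherits(block_G, "genotype_matrix")) {
    meta <- block_G
    block_G <- block_G$dosage
  }
  X <- as.matrix(block_G)
  if (anyNA(X)) stop("missing genotypes in block; impute first")
  s <- ncol(X); n <- nrow(X)
  if (s > max_snps)
    stop("block of ", s, " SNPs exceeds the enumeration bound (",
         max_snps, "); split the block")
  pairs <- lapply(seq_len(n), function(i)
    compat_pairs(as.integer(X[i, ]), max_het))
  pool <- sort(unique(unlist(lapply(pairs, function(p) c(p$h1, p$h2)))))
  t_all <- length(pool)
  f <- rep(1 / t_all, t_all)
  names(f) <- pool
  i1 <- lapply(pairs, function(p) match(p$h1, pool))
  i2 <- lapply(pairs, function(p) match(p$h2, pool))
  mult <- lapply(pairs, function(p) ifelse(p$h1 == p$h2, 1, 2))

  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    cnt <- numeric(t_all)
    ll <- 0
    W_list <- vector("list", n)
    for (i in seq_len(n)) {
      w <- mult[[i]] * f[i1[[i]]] * f[i2[[i]]]
      sw <- sum(w)
      if (sw <= 0) { w <- rep(1 / length(w), length(w)); sw <- 1 }
      ll <- ll + log(sw)
      w <- w / sw
      W_list[[i]] <- w
      for (k in seq_along(w)) {
        cnt[i1[[i]][k]] <- cnt[i1[[i]][k]] + w[k]
        cnt[i2[[i]][k]] <- cnt[i2[[i]][k]] + w[k]
      }
    }
    if (debug && ll < ll_prev - 1e-8)
      stop("EM log-likelihood decreased: ", ll_prev, " -> ", ll)
    ll_prev <- ll
    f_new <- cnt / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }

  keep <- f >= prune
  if (!any(keep)) keep <- f == max(f)
  f_kept <- f[keep] / sum(f[keep])
  pool_kept <- pool[keep]

  # final per-sample assignments and expected dosages under kept pool
  t_k <- length(pool_kept)
  H <- matrix(0, n, t_k, dimnames = list(rownames(X), pool_kept))
  hap1 <- integer(n); hap2 <- integer(n); post <- numeric(n)
  fk <- stats::setNames(numeric(t_all), pool)
  fk[pool_kept] <- f_kept
  for (i in seq_len(n)) {
    w <- mult[[i]] * fk[i1[[i]]] * fk[i2[[i]]]
    if (sum(w) <= 0) w <- W_list[[i]] else w <- w / sum(w)
    k1 <- match(pool[i1[[i]]], pool_kept)
    k2 <- match(pool[i2[[i]]], pool_kept)
    for (k in seq_along(w)) {
      if (!is.na(k1[k])) H[i, k1[k]] <- H[i, k1[k]] + w[k]
      if (!is.na(k2[k])) H[i, k2[k]] <- H[i, k2[k]] + w[k]
    }
    best <- which.max(w)
    hap1[i] <- if (is.na(k1[best])) NA_integer_ else k1[best]
    hap2[i] <- if (is.na(k2[best])) NA_integer_ else k2[best]
    post[i] <- w[best]
  }
  ord <- order(-f_kept)
  rank_map <- match(seq_len(t_k), ord)
  blk <- list(
    name = name %||% (if (!is.null(meta)) "block" else "block"),
    chrom = chrom %||% (if (!is.null(meta)) meta$map$chrom[1] else NA),
    start = if (!is.null(meta)) min(meta$map$pos) else NA,
    end = if (!is.null(meta)) max(meta$map$pos) else NA,
    snp_ids = if (!is.null(meta)) meta$map$snp_id else colnames(X),
    haplotypes = pool_kept[ord],
    freqs = unname(f_kept[ord]),
    assign = data.frame(hap1 = rank_map[hap1], hap2 = rank_map[hap2],
                        posterior = post),
    H = H[, ord, drop = FALSE],
    loglik = ll_prev,
    n_iter = it)
  class(blk) <- "haplotype_block"
  blk
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat(sprintf("haplotype_block %s: %d SNPs, %d haplotypes\n",
              x$name, length(x$snp_ids), length(x$haplotypes)))
  print(stats::setNames(round(x$freqs, 4), x$haplotypes))
  invisible(x)
}

#' Block-level mixed-model association test
#'
#' Haplotype effects are estimated jointly by generalized least squares
#' on the expected haplotype dosages under `V = sigma_a2 K + sigma_e2 I`
#' (variance components from the global REML fit), with the most
#' frequent haplotype dropped as the baseline. The block statistic is
#' the squared Wald ratio of the largest-magnitude haplotype effect,
#' referred to chi-square with one degree of freedom.
#'
#' @param y trait vector.
#' @param W fixed-effect design matrix.
#' @param block a phased [em_phase()] block.
#' @param K kinship matrix.
#' @param vc [reml_variance_components()] fit.
#' @param Tm optional precomputed whitening transform
#'   ([mlm_transform()]); avoids re-decomposing `K` when testing many
#'   blocks under the same fit.
#' @return one-row data.frame: `id`, `n_haps`, `effect` (beta of the
#'   maximum-effect haplotype), `se`, `chi2`, `p`, `flag`; per-haplotype
#'   effects in `attr(, "hap_effects")`.
#' @export
block_assoc <- function(y, W, block, K, vc, Tm = NULL) {
  t_h <- length(block$haplotypes)
  if (t_h < 2) {
    res <- data.frame(id = block$name, n_haps = t_h, effect = NA_real_,
                      se = NA_real_, chi2 = 0, p = 1,
                      flag = "monomorphic", stringsAsFactors = FALSE)
    return(res)
  }
  base <- which.max(block$freqs)
  X <- block$H[, -base, drop = FALSE]
  if (is.null(Tm)) Tm <- mlm_transform(K, vc)
  D <- cbind(Tm %*% as.matrix(W), Tm %*% X)
  yt <- drop(Tm %*% y)
  fit <- stats::lm.fit(D, yt)
  coefs <- fit$coefficients
  ok <- !is.na(coefs)
  R <- qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  covb <- chol2inv(R)
  pos <- fit$qr$pivot[seq_len(fit$rank)]
  se_all <- rep(NA_real_, length(coefs))
  se_all[pos] <- sqrt(diag(covb))
  hap_cols <- (ncol(W) + 1):ncol(D)
  b <- coefs[hap_cols]; se <- se_all[hap_cols]
  usable <- !is.na(b) & !is.na(se)
  hap_eff <- stats::setNames(rep(0, t_h), block$haplotypes)
  hap_eff[-base] <- ifelse(is.na(b), 0, b)
  if (!any(usable)) {
    res <- data.frame(id = block$name, n_haps = t_h, effect = NA_real_,
                      se = NA_real_, chi2 = 0, p = 1,
                      flag = "degenerate", stringsAsFactors = FALSE)
    attr(res, "hap_effects") <- hap_eff
    return(res)
  }
  z2 <- (b[usable] / se[usable])^2
  k <- which.max(z2)
  chi2 <- z2[k]
  res <- data.frame(
    id = block$name, n_haps = t_h,
    effect = b[usable][k], se = se[usable][k], chi2 = chi2,
    p = max(stats::pchisq(chi2, 1, lower.tail = FALSE),
            .Machine$double.xmin),
    flag = NA_character_, stringsAsFactors = FALSE)
  attr(res, "hap_effects") <- hap_eff
  res
}

#' Two-step block variance explained
#'
#' Step 1: per-haplotype effects by ordinary least squares (most
#' frequent haplotype as baseline), then one-dimensional two-means
#' clustering of the effects (centers initialized at the extremes) into
#' groups G1 (lower mean effect) and G2 (higher). Step 2: each sample is
#' coded 0/1/2 by its count of G2 haplotypes in the most probable
#' diplotype, the trait is regressed on that indicator, and the variance
#' explained is `2 p q beta^2 / sigma_p2` with `p`, `q` the G1/G2
#' haplotype-frequency masses.
#'
#' @param y trait vector.
#' @param block a phased [em_phase()] block with >= 2 haplotypes.
#' @param sigma_p2 phenotypic variance.
#' @return fraction in `[0, 1]`; attribute `groups` records the
#'   clustering; an all-equal-effects block returns 0 with attribute
#'   `flag = "no-contrast"`.
#' @export
block_variance_explained <- function(y, block, sigma_p2) {
  t_h <- length(block$haplotypes)
  if (t_h < 2) stop("block must have at least 2 haplotypes")
  base <- which.max(block$freqs)
  X <- block$H[, -base, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, X), y)
  eff <- stats::setNames(rep(0, t_h), block$haplotypes)
  cf <- fit$coefficients[-1]
  eff[-base] <- ifelse(is.na(cf), 0, cf)
  if (max(eff) - min(eff) < 1e-12) {
    out <- 0
    attr(out, "flag") <- "no-contrast"
    return(out)
  }
  grp <- two_means_1d(eff)
  g2 <- grp == 2L
  counts <- (g2[block$assign$hap1] + g2[block$assign$hap2])
  beta <- unname(stats::coef(stats::lm(y ~ counts))[2])
  if (is.na(beta)) beta <- 0
  p <- sum(block$freqs[!g2]); q <- sum(block$freqs[g2])
  out <- min(max(2 * p * q * beta^2 / sigma_p2, 0), 1)
  attr(out, "groups") <- grp
  attr(out, "beta") <- beta
  out
}

# internal: deterministic 1-D two-means, centers initialized at the
# extreme values; group 2 is the one with the larger mean
two_means_1d <- function(x, max_iter = 100) {
  centers <- range(x)
  assign_old <- rep(0L, length(x))
  for (it in seq_len(max_iter)) {
    asg <- ifelse(abs(x - centers[1]) <= abs(x - centers[2]), 1L, 2L)
    if (identical(asg, assign_old)) break
    assign_old <- asg
    if (any(asg == 1L)) centers[1] <- mean(x[asg == 1L])
    if (any(asg == 2L)) centers[2] <- mean(x[asg == 2L])
  }
  if (centers[1] > centers[2]) asg <- 3L - asg
  stats::setNames(asg, names(x))
}

#' Recovery of planted block boundaries
#'
#' Fraction of simulated blocks whose start and end SNPs are both
#' matched by some detected block within `tol_snps` SNP positions.
#'
#' @param blocks output of [partition_blocks()].
#' @param truth a `sim_truth`.
#' @param G the genotype matrix the blocks were detected on.
#' @param tol_snps boundary tolerance in SNP index units (default 1).
#' @return fraction in `[0, 1]`.
#' @export
block_boundary_recovery <- function(blocks, truth, G, tol_snps = 1) {
  det <- lapply(blocks, function(b)
    range(match(b$snp_ids, G$map$snp_id)))
  hit <- vapply(seq_len(nrow(truth$blocks)), function(i) {
    s <- truth$blocks$start_snp[i]; e <- truth$blocks$end_snp[i]
    any(vapply(det, function(d)
      abs(d[1] - s) <= tol_snps && abs(d[2] - e) <= tol_snps,
      logical(1)))
  }, logical(1))
  mean(hit)
}
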