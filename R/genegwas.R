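# Gene-based GWAS: windows around annotated genes, PCA of intragenic
# genotypes, GBLUP breeding values, per-PC regression tests with min-P
# aggregation, permutation significance thresholds and BH FDR.

#' Build gene testing windows
#'
#' A gene's window is its body extended by `flank_bp` both ways (clipped
#' at 1); SNPs are assigned by position within the closed interval.
#' Genes on non-autosomal sequences and genes covered by fewer than
#' `min_snps` SNPs are dropped, with counts reported via `message()`.
#'
#' @param annotation data.frame `gene_id`, `chrom`, `start`, `end`
#'   (1-based closed; use [read_annotation()] for BED/GFF3 input), or a
#'   file path to a BED/GFF3 file.
#' @param G a [genotype_matrix()].
#' @param flank_bp flank on each side in bp (default 50,000).
#' @param min_snps minimum SNPs per tested gene (default 3).
#' @param autosomes chromosome names considered autosomal; defaults to
#'   all-numeric names.
#' @return list of gene windows: `gene_id`, `chrom`, `start`, `end`
#'   (window bounds), `snp_ids`, `snp_idx`, `n_snps`.
#' @export
build_gene_windows <- function(annotation, G, flank_bp = 50000,
                               min_snps = 3, autosomes = NULL) {
  if (is.character(annotation) && length(annotation) == 1)
    annotation <- read_annotation(annotation)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in%
                  names(annotation)))
  n_in <- nrow(annotation)
  bad <- is.na(annotation$start) | is.na(annotation$end) |
    is.na(annotation$chrom) | annotation$start > annotation$end
  if (any(bad)) {
    if (mean(bad) > 0.10)
      stop(sum(bad), " of ", n_in, " annotation records malformed")
    warning(sum(bad), " malformed annotation record(s) skipped")
    annotation <- annotation[!bad, , drop = FALSE]
  }
  if (is.null(autosomes))
    autosomes <- unique(annotation$chrom[grepl("^[0-9]+$",
                                               annotation$chrom)])
  non_auto <- !(annotation$chrom %in% autosomes)
  if (any(non_auto))
    message(sum(non_auto), " non-autosomal gene(s) dropped")
  annotation <- annotation[!non_auto, , drop = FALSE]

  gene_gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(pmax(annotation$start - flank_bp, 1),
                     annotation$end + flank_bp))
  snp_gr <- GenomicRanges::GRanges(G$map$chrom,
                                   IRanges::IRanges(G$map$pos,
                                                    G$map$pos))
  ov <- GenomicRanges::findOverlaps(gene_gr, snp_gr)
  hits <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  windows <- lapply(seq_len(nrow(annotation)), function(i) {
    idx <- sort(hits[[as.character(i)]] %||% integer(0))
    list(gene_id = annotation$gene_id[i], chrom = annotation$chrom[i],
         start = max(annotation$start[i] - flank_bp, 1),
         end = annotation$end[i] + flank_bp,
         snp_ids = G$map$snp_id[idx], snp_idx = idx,
         n_snps = length(idx))
  })
  few <- vapply(windows, function(w) w$n_snps < min_snps, logical(1))
  if (any(few))
    message(sum(few), " gene(s) dropped with fewer than ", min_snps,
            " SNPs")
  windows[!few]
}

#' Principal components of intragenic genotypes
#'
#' PCA on the column-centered (unstandardized) dosage matrix of one
#' gene's SNPs. The smallest number of components whose cumulative
#' explained-variance proportion strictly exceeds `cum_threshold` is
#' retained. Signs are fixed by making the largest-magnitude element of
#' each loading vector positive, so results are deterministic.
#'
#' @param subG dosage matrix (samples x intragenic SNPs, >= `min_snps`
#'   columns, no missing) or a [genotype_matrix()] subset.
#' @param cum_threshold cumulative proportion bound (default 0.85).
#' @param standardize scale columns to unit variance before the PCA.
#' @return score matrix (samples x m) with attributes `shares`
#'   (explained-variance proportions of all components) and `m`.
#' @export
gene_pcs <- function(subG, cum_threshold = 0.85, standardize = FALSE) {
  if (inherits(subG, "genotype_matrix")) subG <- subG$dosage
  X <- as.matrix(subG)
  if (anyNA(X)) stop("missing genotypes; impute first")
  Z <- scale(X, center = TRUE, scale = standardize)
  Z[is.nan(Z)] <- 0
  sv <- svd(Z)
  ev <- sv$d^2
  if (sum(ev) <= 1e-12) stop("zero total variance in gene window")
  shares <- ev / sum(ev)
  m <- which(cumsum(shares) > cum_threshold)[1]
  if (is.na(m)) m <- length(shares)
  scores <- sv$u[, seq_len(m), drop = FALSE] %*%
    diag(sv$d[seq_len(m)], m)
  for (k in seq_len(m)) {
    v <- sv$v[, k]
    if (v[which.max(abs(v))] < 0) scores[, k] <- -scores[, k]
  }
  colnames(scores) <- paste0("PC", seq_len(m))
  attr(scores, "shares") <- shares
  attr(scores, "m") <- m
  scores
}

#' GBLUP estimated breeding values
#'
#' `u_hat = sigma_a2 K V^-1 (y - W v_hat)` with `v_hat` the GLS
#' fixed-effect solution under `V = sigma_a2 K + sigma_e2 I`; equivalent
#' to solving Henderson's mixed-model equations.
#'
#' @param y trait vector.
#' @param W fixed-effect design matrix.
#' @param K kinship matrix.
#' @param vc a [reml_variance_components()] fit.
#' @return numeric vector of EBVs, one per sample.
#' @export
compute_ebv <- function(y, W, K, vc) {
  n <- length(y)
  if (vc$sigma_a2 <= 0) return(numeric(n))
  V <- vc$sigma_a2 * K + vc$sigma_e2 * diag(n)
  cV <- tryCatch(chol(V), error = function(e) stop("V is singular"))
  Vi <- chol2inv(cV)
  W <- as.matrix(W)
  vhat <- solve(crossprod(W, Vi %*% W), crossprod(W, Vi %*% y))
  drop(vc$sigma_a2 * K %*% (Vi %*% (y - W %*% vhat)))
}

#' Gene-level association test
#'
#' Each retained PC is regressed against the breeding values (simple
#' regression with intercept); the per-PC statistic is the squared Wald
#' ratio on one degree of freedom and the gene P-value is the minimum
#' over PCs. Constant PCs are skipped; if every PC is constant the gene
#' is flagged untestable.
#'
#' @param ebv breeding-value vector (the "phenotype" of the gene model).
#' @param pcs PC score matrix from [gene_pcs()].
#' @param gene_id optional identifier carried into the result.
#' @return list of class `gene_test`: `gene_id`, `p` (min over PCs),
#'   `per_pc` data.frame (`b`, `se`, `chi2`, `p`, `skipped`), `n_pcs`,
#'   `flag`.
#' @export
gene_test <- function(ebv, pcs, gene_id = NA_character_) {
  pcs <- as.matrix(pcs)
  stopifnot(ncol(pcs) >= 1, nrow(pcs) == length(ebv))
  n <- length(ebv)
  per <- data.frame(b = rep(NA_real_, ncol(pcs)), se = NA_real_,
                    chi2 = NA_real_, p = NA_real_, skipped = FALSE)
  for (k in seq_len(ncol(pcs))) {
    x <- pcs[, k]
    if (stats::var(x) < 1e-14) { per$skipped[k] <- TRUE; next }
    xc <- x - mean(x); yc <- ebv - mean(ebv)
    b <- sum(xc * yc) / sum(xc^2)
    rss <- sum((yc - b * xc)^2)
    se <- sqrt(rss / (n - 2) / sum(xc^2))
    chi2 <- if (se > 0) (b / se)^2 else Inf
    p <- max(stats::pchisq(chi2, 1, lower.tail = FALSE),
             .Machine$double.xmin)
    per[k, c("b", "se", "chi2", "p")] <- c(b, se, chi2, p)
  }
  testable <- !per$skipped
  out <- list(gene_id = gene_id,
              p = if (any(testable)) min(per$p[testable]) else NA_real_,
              per_pc = per, n_pcs = ncol(pcs),
              flag = if (any(testable)) NA_character_ else "untestable")
  class(out) <- "gene_test"
  out
}

#' Scan all gene windows
#'
#' Convenience wrapper: PCs per window, [gene_test()] per gene, BH FDR
#' across genes.
#'
#' @param ebv breeding-value vector.
#' @param G complete [genotype_matrix()].
#' @param windows gene windows from [build_gene_windows()].
#' @param cum_threshold passed to [gene_pcs()].
#' @return `list(results = data.frame(gene_id, chrom, n_snps, n_pcs, p,
#'   fdr), pcs = list of score matrices)`.
#' @export
gene_scan <- function(ebv, G, windows, cum_threshold = 0.85) {
  pcs_list <- lapply(windows, function(w)
    gene_pcs(G$dosage[, w$snp_idx, drop = FALSE], cum_threshold))
  tests <- Map(function(w, pcs) gene_test(ebv, pcs, w$gene_id),
               windows, pcs_list)
  res <- data.frame(
    gene_id = vapply(windows, `[[`, character(1), "gene_id"),
    chrom = vapply(windows, `[[`, character(1), "chrom"),
    n_snps = vapply(windows, `[[`, numeric(1), "n_snps"),
    n_pcs = vapply(tests, function(t) t$n_pcs, numeric(1)),
    p = vapply(tests, function(t) t$p, numeric(1)),
    stringsAsFactors = FALSE)
  res$fdr <- bh_fdr(res$p)
  list(results = res, pcs = pcs_list)
}

#' Linear GBLUP operator
#'
#' The matrix `A` with `u_hat = A y` for fixed variance components:
#' `A = sigma_a2 K V^-1 (I - W (W' V^-1 W)^-1 W' V^-1)`. Used by the
#' phenotype-permutation scheme of [permutation_threshold()], where
#' breeding values are recomputed from each permuted trait vector
#' without refitting REML.
#'
#' @inheritParams compute_ebv
#' @return n x n matrix.
#' @export
ebv_operator <- function(W, K, vc) {
  n <- nrow(K)
  W <- as.matrix(W)
  V <- vc$sigma_a2 * K + vc$sigma_e2 * diag(n)
  Vi <- chol2inv(chol(V))
  P <- diag(n) - W %*% solve(crossprod(W, Vi %*% W), crossprod(W, Vi))
  vc$sigma_a2 * K %*% (Vi %*% P)
}

#' Permutation significance threshold for the gene scan
#'
#' Each cycle permutes the phenotype labels against the genotypes,
#' recomputes every gene's min-P, and pools all `n_perm * n_genes`
#' statistics. The cutoff is the `ceiling(alpha * N)`-th smallest pooled
#' P-value (the alpha-quantile of the permutation null). Two schemes:
#' \describe{
#'   \item{ebv}{(default) the breeding-value vector itself is permuted;
#'     cheap, preserves per-gene LD, but does not reproduce the
#'     mechanical correlation between the EBV and intragenic PCs that
#'     arises because the genes' SNPs also enter the kinship, so it is
#'     mildly anti-conservative when the tested genes make up a
#'     non-negligible share of the kinship panel.}
#'   \item{phenotype}{the raw trait is permuted and mapped through the
#'     fixed GBLUP operator ([ebv_operator()]) each cycle, reproducing
#'     that dependence in the null (variance components are not refit).}
#' }
#'
#' @param ebv breeding-value vector.
#' @param pcs_per_gene list of PC score matrices (one per gene), e.g.
#'   `gene_scan(...)$pcs`.
#' @param n_perm permutation cycles (default 1,000).
#' @param alpha significance level (default 0.01).
#' @param seed integer seed; a fixed seed reproduces the pool exactly.
#' @param scheme `"ebv"` or `"phenotype"`.
#' @param y,operator trait vector and [ebv_operator()] matrix, required
#'   for `scheme = "phenotype"`.
#' @return list of class `perm_threshold`: `cutoff`, `n_pool`, `rank`,
#'   `alpha`, `n_perm`, `n_genes`.
#' @export
permutation_threshold <- function(ebv, pcs_per_gene, n_perm = 1000,
                                  alpha = 0.01, seed = 1L,
                                  scheme = c("ebv", "phenotype"),
                                  y = NULL, operator = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  scheme <- match.arg(scheme)
  if (scheme == "phenotype" && (is.null(y) || is.null(operator)))
    stop("scheme = 'phenotype' needs y and operator")
  n <- length(ebv)
  n_genes <- length(pcs_per_gene)
  # stack standardized PC columns; per-gene grouping for the min
  cols <- lapply(pcs_per_gene, function(p) {
    p <- as.matrix(p)
    keep <- apply(p, 2, stats::var) > 1e-14
    scale(p[, keep, drop = FALSE])
  })
  gene_of <- rep(seq_len(n_genes),
                 vapply(cols, ncol, numeric(1)))
  P_all <- do.call(cbind, cols) / sqrt(n - 1)  # unit-norm columns
  pool <- with_seed(seed, {
    vapply(seq_len(n_perm), function(cycle) {
      ep <- if (scheme == "ebv") sample(ebv) else
        drop(operator %*% sample(y))
      ec <- ep - mean(ep)
      nrm <- sqrt(sum(ec^2))
      r <- drop(crossprod(P_all, ec)) / nrm
      chi2 <- (n - 2) * r^2 / pmax(1 - r^2, 1e-300)
      p <- pmax(stats::pchisq(chi2, 1, lower.tail = FALSE),
                .Machine$double.xmin)
      vapply(split(p, gene_of), min, numeric(1))
    }, numeric(n_genes))
  })
  pool <- as.numeric(pool)
  n_pool <- perm_pool_size(n_genes, n_perm)
  stopifnot(length(pool) == n_pool)
  rank <- ceiling(alpha * n_pool)
  cutoff <- sort(pool, partial = rank)[rank]
  structure(list(cutoff = cutoff, n_pool = n_pool, rank = rank,
                 alpha = alpha, n_perm = n_perm, n_genes = n_genes),
            class = "perm_threshold")
}

#' Size of the pooled permutation null
#'
#' The bookkeeping behind the permutation threshold: `n_genes` gene
#' statistics per cycle times `n_perm` cycles.
#'
#' @param n_genes number of tested genes.
#' @param n_perm number of permutation cycles.
#' @return integer-valued count `n_genes * n_perm`.
#' @export
perm_pool_size <- function(n_genes, n_perm) {
  as.numeric(n_genes) * as.numeric(n_perm)
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf(
    "permutation threshold: P <= %.3g (rank %s of %s pooled, alpha %.3g)\n",
    x$cutoff, format(x$rank, big.mark = ","),
    format(x$n_pool, big.mark = ","), x$alpha))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`).
#'
#' @param pvalues numeric vector of P-values in `(0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  stats::p.adjust(pvalues, method = "BH")
}
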