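#' Quality-control thresholds
#'
#' Marker and sample filters: minimum SNP call rate 0.95, minimum minor
#' allele frequency 0.05 (markers with MAF *less than* the bound are
#' removed), Hardy-Weinberg exact-test significance level 1e-5, and a
#' maximum per-sample missing fraction of 0.10 (samples with *more than*
#' the bound missing are removed).
#'
#' @param min_call_rate,min_maf,hwe_alpha,max_sample_missing fractions in
#'   `[0, 1]`.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.05,
                          hwe_alpha = 1e-5, max_sample_missing = 0.10) {
  t <- list(min_call_rate = min_call_rate, min_maf = min_maf,
            hwe_alpha = hwe_alpha, max_sample_missing = max_sample_missing)
  stopifnot(all(unlist(t) >= 0), all(unlist(t) <= 1))
  class(t) <- "qc_thresholds"
  t
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' P-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (Wigginton-style recurrence, as used by PLINK).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @return P-value in `(0, 1]`; a monomorphic locus returns 1.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes observed")
  rare <- 2L * min(n_AA, n_aa) + n_Aa   # copies of the rarer allele
  if (rare == 0L) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  # start from the modal heterozygote count and recur outwards
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  mid <- min(max(mid, hets[1]), hets[length(hets)])
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  if (i_mid > 1) {
    for (i in seq(i_mid, 2)) {
      het <- hets[i]
      hom_r <- (rare - het) / 2
      hom_c <- n - het - hom_r
      probs[i - 1] <- probs[i] * het * (het - 1) /
        (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  if (i_mid < length(hets)) {
    for (i in seq(i_mid, length(hets) - 1)) {
      het <- hets[i]
      hom_r <- (rare - het) / 2
      hom_c <- n - het - hom_r
      probs[i + 1] <- probs[i] * 4 * hom_r * hom_c /
        ((het + 2) * (het + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# internal: per-SNP QC statistics on called genotypes only
snp_qc_stats <- function(G) {
  d <- G$dosage
  cr <- colMeans(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  mafs <- pmin(p, 1 - p)
  hwe <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  data.frame(snp_id = G$map$snp_id, call_rate = cr, maf = mafs,
             hwe_p = hwe, stringsAsFactors = FALSE)
}

#' Marker quality control
#'
#' Removes SNPs with call rate below `min_call_rate`, minor allele
#' frequency below `min_maf`, or Hardy-Weinberg exact-test P below
#' `hwe_alpha`. All three statistics are computed once on the input
#' (called genotypes only) and the rules are applied in the order
#' call-rate, MAF, HWE, so each removed SNP is attributed to the first
#' rule it fails.
#'
#' @param G a [genotype_matrix()].
#' @param t a [qc_thresholds()].
#' @return `list(G = filtered genotype_matrix, report = qc_report)`; the
#'   report carries per-SNP statistics, the removal reason per dropped
#'   SNP and counts per rule.
#' @export
snp_qc_filter <- function(G, t = qc_thresholds()) {
  if (ncol(G$dosage) == 0) stop("empty genotype matrix")
  st <- snp_qc_stats(G)
  reason <- rep(NA_character_, nrow(st))
  reason[is.na(reason) & st$call_rate < t$min_call_rate] <- "call_rate"
  reason[is.na(reason) & st$maf < t$min_maf] <- "maf"
  reason[is.na(reason) & !is.na(st$hwe_p) &
           st$hwe_p < t$hwe_alpha] <- "hwe"
  keep <- is.na(reason)
  report <- list(
    scope = "snp",
    stats = cbind(st, removed = !keep, reason = reason,
                  stringsAsFactors = FALSE),
    n_input = nrow(st),
    n_removed = sum(!keep),
    n_kept = sum(keep),
    counts = c(call_rate = sum(reason == "call_rate", na.rm = TRUE),
               maf = sum(reason == "maf", na.rm = TRUE),
               hwe = sum(reason == "hwe", na.rm = TRUE)),
    kept_ids = st$snp_id[keep])
  class(report) <- "qc_report"
  list(G = G[, keep], report = report)
}

#' Sample quality control
#'
#' Removes samples whose missing-genotype fraction is strictly greater
#' than `max_sample_missing`; a sample missing exactly the bound is
#' retained.
#'
#' @inheritParams snp_qc_filter
#' @return `list(G, report)` as in [snp_qc_filter()].
#' @export
sample_qc_filter <- function(G, t = qc_thresholds()) {
  miss <- rowMeans(is.na(G$dosage))
  keep <- miss <= t$max_sample_missing
  if (!any(keep)) stop("all samples removed by missingness filter")
  report <- list(
    scope = "sample",
    stats = data.frame(sample_id = G$sample_ids, missing = miss,
                       removed = !keep, stringsAsFactors = FALSE),
    n_input = length(miss),
    n_removed = sum(!keep),
    n_kept = sum(keep),
    counts = c(sample_missing = sum(!keep)),
    kept_ids = G$sample_ids[keep])
  class(report) <- "qc_report"
  list(G = G[keep, ], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report (%s): %d in, %d removed, %d kept\n",
              x$scope, x$n_input, x$n_removed, x$n_kept))
  for (nm in names(x$counts))
    cat(sprintf("  %-14s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Frequency-based imputation of missing genotypes
#'
#' Replaces each missing dosage by a draw from Binomial(2, p-hat) with
#' p-hat the SNP's observed alternate-allele frequency. This is a
#' deliberately simple allele-frequency imputer: it preserves marginal
#' allele frequencies and Hardy-Weinberg proportions but ignores LD, so
#' it is suitable for completing a matrix ahead of kinship construction,
#' not for recovering individual genotypes.
#'
#' @param G a post-QC [genotype_matrix()].
#' @param seed integer seed; draws are reproducible.
#' @return a complete [genotype_matrix()].
#' @export
impute_missing <- function(G, seed = 1L) {
  d <- G$dosage
  nm <- colSums(!is.na(d))
  if (any(nm == 0))
    stop("SNP(s) with zero observed calls cannot be imputed: ",
         paste(G$map$snp_id[nm == 0], collapse = ", "))
  if (!anyNA(d)) return(G)
  p <- colMeans(d, na.rm = TRUE) / 2
  with_seed(seed, {
    for (j in which(colSums(is.na(d)) > 0)) {
      idx <- is.na(d[, j])
      d[idx, j] <- stats::rbinom(sum(idx), 2L, p[j])
    }
  })
  genotype_matrix(d, G$map, G$sample_ids)
}
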