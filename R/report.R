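# Cross-strategy integration: Venn sets over significant SNPs, regional
# LD classes, Manhattan export, and the expression-association follow-up.

#' Intersection of the three strategies' significant SNP sets
#'
#' Blocks and genes are expanded to their member SNP ids; the seven
#' Venn regions and the union are computed over the three resulting SNP
#' sets.
#'
#' @param snp_sig character vector of significant SNP ids from the
#'   single-marker scan.
#' @param block_sig significant blocks: list of blocks carrying
#'   `snp_ids`, or a character vector of SNP ids.
#' @param gene_sig significant genes: list of gene windows carrying
#'   `snp_ids`, or a character vector of SNP ids.
#' @param universe optional character vector of valid SNP ids; ids
#'   outside it raise an error (guards against mixed id namespaces).
#' @return list of class `significant_sets`: the three sets, the seven
#'   region counts (`only_snp`, `only_block`, `only_gene`, `snp_block`,
#'   `snp_gene`, `block_gene`, `all_three`), `union_size` and the
#'   per-strategy sizes.
#' @export
intersect_significant_sets <- function(snp_sig, block_sig, gene_sig,
                                       universe = NULL) {
  expand <- function(x) {
    if (is.character(x) || is.null(x)) return(unique(x %||% character(0)))
    unique(unlist(lapply(x, function(b) b$snp_ids)))
  }
  s1 <- expand(snp_sig); s2 <- expand(block_sig); s3 <- expand(gene_sig)
  if (!is.null(universe)) {
    stray <- setdiff(c(s1, s2, s3), universe)
    if (length(stray))
      stop("SNP id(s) outside the genotype universe: ",
           paste(utils::head(stray, 5), collapse = ", "))
  }
  in1 <- function(x) x %in% s1
  u <- sort(unique(c(s1, s2, s3)))
  m <- cbind(snp = u %in% s1, block = u %in% s2, gene = u %in% s3)
  regions <- c(
    only_snp   = sum(m[, 1] & !m[, 2] & !m[, 3]),
    only_block = sum(!m[, 1] & m[, 2] & !m[, 3]),
    only_gene  = sum(!m[, 1] & !m[, 2] & m[, 3]),
    snp_block  = sum(m[, 1] & m[, 2] & !m[, 3]),
    snp_gene   = sum(m[, 1] & !m[, 2] & m[, 3]),
    block_gene = sum(!m[, 1] & m[, 2] & m[, 3]),
    all_three  = sum(m[, 1] & m[, 2] & m[, 3]))
  structure(list(snp = s1, block = s2, gene = s3, regions = regions,
                 union_size = length(u),
                 sizes = c(snp = length(s1), block = length(s2),
                           gene = length(s3))),
            class = "significant_sets")
}

#' @export
print.significant_sets <- function(x, ...) {
  cat("significant SNP sets:",
      paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "),
      "| union", x$union_size, "\n")
  print(x$regions)
  invisible(x)
}

#' Regional LD classes against lead SNPs
#'
#' Each SNP in the region is assigned the maximum r-squared against the
#' lead set and binned into the five display classes (strict
#' inequalities, boundaries falling to the lower class): `>0.9`, `>0.7`,
#' `>0.5`, `>0.3` and the residual `<0.3` class.
#'
#' @param G a [genotype_matrix()].
#' @param lead_snp_ids ids of the lead SNP(s); must lie in the region.
#' @param region `list(chrom =, start =, end =)` or NULL for all SNPs.
#' @return data.frame `snp_id`, `pos`, `max_r2`, `class`.
#' @export
regional_ld_classes <- function(G, lead_snp_ids, region = NULL) {
  if (!is.null(region)) {
    sel <- G$map$chrom == region$chrom & G$map$pos >= region$start &
      G$map$pos <= region$end
    G <- G[, sel]
  }
  if (ncol(G$dosage) == 0)
    return(data.frame(snp_id = character(0), pos = integer(0),
                      max_r2 = numeric(0), class = character(0)))
  lead_idx <- match(lead_snp_ids, G$map$snp_id)
  if (anyNA(lead_idx)) stop("lead SNP(s) not in region")
  r2max <- vapply(seq_len(ncol(G$dosage)), function(j) {
    max(vapply(lead_idx, function(l)
      pairwise_ld(G$dosage[, j], G$dosage[, l], ci = FALSE)$r2,
      numeric(1)), na.rm = TRUE)
  }, numeric(1))
  cls <- ifelse(r2max > 0.9, ">0.9",
                ifelse(r2max > 0.7, ">0.7",
                       ifelse(r2max > 0.5, ">0.5",
                              ifelse(r2max > 0.3, ">0.3", "<0.3"))))
  data.frame(snp_id = G$map$snp_id, pos = G$map$pos, max_r2 = r2max,
             class = cls, stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = ct_target - ct_ref`; `ddCt = dCt - calibrator_dct`; fold
#' change `2^-ddCt`.
#'
#' @param ct_target,ct_ref cycle-threshold values of the target and the
#'   reference (housekeeping) gene.
#' @param calibrator_dct the calibrator sample's dCt.
#' @return fold change (dimensionless, > 0).
#' @export
fold_change_ddct <- function(ct_target, ct_ref, calibrator_dct) {
  stopifnot(is.finite(ct_target), is.finite(ct_ref),
            is.finite(calibrator_dct))
  2^-((ct_target - ct_ref) - calibrator_dct)
}

#' Association between transcript abundance and the trait
#'
#' Ordinary least squares of the trait on fold change plus covariates
#' (general linear model); reports the slope in trait units per unit
#' fold change with its standard error and P-value.
#'
#' @param adg trait vector (kg/day).
#' @param fold_change relative expression per sample.
#' @param covariates optional data.frame of fixed effects (e.g. calving
#'   season, stratification axes).
#' @return one-row data.frame: `effect`, `se`, `t`, `p`, `n`.
#' @export
expression_assoc <- function(adg, fold_change, covariates = NULL) {
  df <- data.frame(adg = adg, fold_change = fold_change)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  if (nrow(df) < ncol(df) + 1)
    stop("too few samples for the covariate-adjusted model")
  fit <- stats::lm(adg ~ ., data = df)
  al <- stats::alias(fit)$Complete
  if (!is.null(al))
    stop("collinear design; aliased column(s): ",
         paste(rownames(al), collapse = ", "))
  cf <- summary(fit)$coefficients
  data.frame(effect = cf["fold_change", 1], se = cf["fold_change", 2],
             t = cf["fold_change", 3],
             p = max(cf["fold_change", 4], .Machine$double.xmin),
             n = nrow(df))
}

#' Plot-ready Manhattan table
#'
#' Cumulative genome coordinates and -log10 P per marker, with a
#' significance flag, for any plotting front-end.
#'
#' @param results data.frame with `chrom`, `pos`, `p` (e.g. from
#'   [snp_scan()]).
#' @param threshold significance threshold on P (default 1e-6).
#' @return data.frame `chrom`, `pos`, `cum_pos`, `neglog10p`,
#'   `significant`, ordered by chromosome then position.
#' @export
manhattan_export <- function(results, threshold = 1e-6) {
  stopifnot(nrow(results) > 0,
            all(c("chrom", "pos", "p") %in% names(results)))
  chrn <- suppressWarnings(as.numeric(results$chrom))
  ordc <- if (anyNA(chrn)) order(results$chrom, results$pos) else
    order(chrn, results$pos)
  r <- results[ordc, , drop = FALSE]
  offs <- 0
  cum <- numeric(nrow(r))
  for (ch in unique(r$chrom)) {
    sel <- r$chrom == ch
    cum[sel] <- offs + r$pos[sel]
    offs <- max(cum[sel]) + 1
  }
  data.frame(chrom = r$chrom, pos = r$pos, cum_pos = cum,
             neglog10p = -log10(r$p), significant = r$p < threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
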