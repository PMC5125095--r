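#' Genotype matrix container
#'
#' Bundles an additive-dosage matrix (samples x SNPs, counting copies of
#' the alternate allele, `NA` = missing) with per-SNP metadata.
#'
#' @param dosage numeric/integer matrix, samples in rows, SNPs in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos`, `a1`
#'   (reference allele) and `a2` (alternate, counted allele).
#' @param sample_ids character vector of sample identifiers; defaults to
#'   `rownames(dosage)` or `S1..Sn`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `map` and `sample_ids`.
#' @export
genotype_matrix <- function(dosage, map, sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(map),
            all(c("snp_id", "chrom", "pos", "a1", "a2") %in% names(map)),
            ncol(dosage) == nrow(map))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0) || any(bad > 2)))
    stop("dosages must lie in [0, 2]")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosage)
    if (is.null(sample_ids))
      sample_ids <- paste0("S", seq_len(nrow(dosage)))
  }
  stopifnot(length(sample_ids) == nrow(dosage))
  rownames(dosage) <- sample_ids
  colnames(dosage) <- map$snp_id
  map$snp_id <- as.character(map$snp_id)
  map$chrom  <- as.character(map$chrom)
  rownames(map) <- NULL
  structure(list(dosage = dosage, map = map,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (logical, integer or sample id).
#' @param j SNP index (logical, integer or snp id).
#' @param ... ignored.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(j)) j <- match(j, x$map$snp_id)
  if (is.character(i)) i <- match(i, x$sample_ids)
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  x$map[j, , drop = FALSE],
                  x$sample_ids[i])
}

#' Per-SNP alternate-allele frequencies
#'
#' Computed on called genotypes only (missing entries excluded).
#'
#' @param G a `genotype_matrix`.
#' @return numeric vector of length `ncol(G)`.
#' @export
allele_freq <- function(G) {
  colMeans(G$dosage, na.rm = TRUE) / 2
}

#' Per-SNP minor-allele frequencies
#' @param G a `genotype_matrix`.
#' @export
maf <- function(G) {
  p <- allele_freq(G)
  pmin(p, 1 - p)
}

#' Per-SNP call rates
#' @param G a `genotype_matrix`.
#' @export
call_rate <- function(G) {
  colMeans(!is.na(G$dosage))
}

# internal: run expr with a local, restored RNG stream
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
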