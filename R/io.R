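#' Write genotypes to PLINK bed/bim/fam or VCF
#'
#' Both writers round-trip exactly through [read_plink()] /
#' [read_vcf()]: dosages, the missingness mask and SNP metadata are
#' preserved. The PLINK triple uses the SNP-major 1.x bit encoding with
#' the counted (alternate) allele written as A1.
#'
#' @param G a [genotype_matrix()].
#' @param path output prefix (PLINK) or file path (VCF).
#' @param format `"plink"` or `"vcf"`.
#' @return the paths written, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  if (format == "plink") write_plink(G, path) else write_vcf(G, path)
}

write_plink <- function(G, prefix) {
  n <- nrow(G$dosage); m <- ncol(G$dosage)
  bim <- data.frame(G$map$chrom, G$map$snp_id, rep(0, m), G$map$pos,
                    G$map$a2, G$map$a1)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(G$sample_ids, G$sample_ids, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # bed codes per 2-bit pair: 00 hom A1 (dosage 2), 10 het, 11 hom A2, 01 NA
  code <- matrix(3L, n, max(m, 1L))
  if (m > 0) {
    d <- G$dosage
    code[!is.na(d) & d == 2] <- 0L
    code[!is.na(d) & d == 1] <- 2L
    code[!is.na(d) & d == 0] <- 3L
    code[is.na(d)] <- 1L
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0) {
    npad <- ceiling(n / 4) * 4
    for (j in seq_len(m)) {
      cj <- c(code[, j], integer(npad - n))
      b <- matrix(cj, nrow = 4)
      bytes <- b[1, ] + 4L * b[2, ] + 16L * b[3, ] + 64L * b[4, ]
      writeBin(as.raw(bytes), con)
    }
  }
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read a PLINK bed/bim/fam triple
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` files.
#' @return a [genotype_matrix()] counting the A1 allele of the `.bim`.
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           colClasses = "character")
  bim_path <- paste0(prefix, ".bim")
  empty_bim <- file.size(bim_path) == 0
  bim <- if (empty_bim) {
    data.frame(V1 = character(), V2 = character(), V3 = integer(),
               V4 = integer(), V5 = character(), V6 = character())
  } else {
    utils::read.table(bim_path, colClasses = c("character", "character",
                                               "integer", "integer",
                                               "character", "character"))
  }
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + m * ceiling(n / 4))
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK 1.x bed file")
  dosage <- matrix(NA_integer_, n, m)
  if (m > 0) {
    body <- as.integer(raw[-(1:3)])
    per <- ceiling(n / 4)
    lut <- c(2L, NA_integer_, 1L, 0L)  # codes 0..3 -> dosage of A1
    for (j in seq_len(m)) {
      bytes <- body[((j - 1) * per + 1):(j * per)]
      codes <- c(rbind(bytes %% 4, (bytes %/% 4) %% 4,
                       (bytes %/% 16) %% 4, (bytes %/% 64) %% 4))
      dosage[, j] <- lut[codes[seq_len(n)] + 1L]
    }
  }
  map <- data.frame(snp_id = bim$V2, chrom = bim$V1, pos = bim$V4,
                    a1 = bim$V6, a2 = bim$V5, stringsAsFactors = FALSE)
  genotype_matrix(dosage, map, sample_ids = fam$V2)
}

write_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=multigwas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", G$sample_ids),
                     collapse = "\t")), con)
  m <- ncol(G$dosage)
  if (m > 0) {
    gt_lut <- c("0/0", "0/1", "1/1")
    for (j in seq_len(m)) {
      d <- G$dosage[, j]
      gt <- ifelse(is.na(d), "./.", gt_lut[d + 1L])
      writeLines(paste(c(G$map$chrom[j], G$map$pos[j], G$map$snp_id[j],
                         G$map$a1[j], G$map$a2[j], ".", "PASS", ".", "GT",
                         gt),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a VCF (v4.x, GT field) into a genotype matrix
#'
#' Minimal reader for biallelic-SNP VCFs as written by
#' [write_genotypes()]; dosages count the ALT allele.
#'
#' @param path VCF file path.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in ", path)
  fields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- fields[-(1:9)]
  body <- lines[-seq_len(hdr)]
  m <- length(body)
  n <- length(samples)
  dosage <- matrix(NA_integer_, n, m)
  map <- data.frame(snp_id = character(m), chrom = character(m),
                    pos = integer(m), a1 = character(m),
                    a2 = character(m), stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    f <- strsplit(body[j], "\t", fixed = TRUE)[[1]]
    map$chrom[j] <- f[1]; map$pos[j] <- as.integer(f[2])
    map$snp_id[j] <- f[3]; map$a1[j] <- f[4]; map$a2[j] <- f[5]
    gt <- sub(":.*", "", f[-(1:9)])
    alt <- vapply(strsplit(gt, "[/|]"), function(a) {
      if (any(a == ".")) NA_integer_ else sum(a == "1")
    }, integer(1))
    dosage[, j] <- alt
  }
  genotype_matrix(dosage, map, sample_ids = samples)
}

#' Write the phenotype/covariate table as TSV
#'
#' Header `sample_id  adg  sex  birth_year  calving_season` (plus any
#' further covariate columns).
#'
#' @param pheno data.frame as returned by [simulate_phenotype()].
#' @param path output path.
#' @export
write_phenotype <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate TSV
#' @param path file path.
#' @return data.frame with `sample_id` as character and covariates as
#'   factors.
#' @export
read_phenotype <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ph$sample_id <- as.character(ph$sample_id)
  for (nm in setdiff(names(ph), c("sample_id", "adg")))
    ph[[nm]] <- factor(ph[[nm]])
  ph
}

#' Read gene annotation from BED or GFF3
#'
#' BED input (0-based half-open) and GFF3 input (1-based closed) are both
#' normalized to 1-based closed coordinates. GFF3 records are restricted
#' to `type == "gene"` when a type column is present.
#'
#' @param path annotation file (`.bed`, `.gff`, `.gff3`).
#' @return data.frame `gene_id`, `chrom`, `start`, `end` (1-based closed).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE) &&
      "type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene")) {
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  }
  mc <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(mc) && !all(is.na(mc$ID))) {
    as.character(mc$ID)
  } else if ("name" %in% names(mc) && !all(is.na(mc$name))) {
    as.character(mc$name)
  } else if ("Name" %in% names(mc)) {
    as.character(mc$Name)
  } else {
    sprintf("gene%03d", seq_along(gr))
  }
  data.frame(gene_id = id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write gene annotation as BED
#'
#' Converts the package's 1-based closed intervals to BED's 0-based
#' half-open convention.
#'
#' @param annotation data.frame `gene_id`, `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_annotation_bed <- function(annotation, path) {
  utils::write.table(
    data.frame(annotation$chrom, annotation$start - 1L, annotation$end,
               annotation$gene_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(path)
}
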