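#' Simulation configuration
#'
#' Defines the conditions for the synthetic genotype/phenotype generator.
#' Defaults emulate the study population the package's analyses assume:
#' roughly one thousand fattening bulls genotyped on an LD-block-structured
#' SNP panel with MAF >= 0.05, an additive trait with mean 0.98 kg/day,
#' SD 0.16 kg/day and narrow-sense heritability 0.48, categorical fixed
#' effects (sex, birth year, calving season), and planted causal signals
#' at the SNP, haplotype and gene level.
#'
#' @param n_samples number of individuals.
#' @param n_blocks number of haplotype blocks in the panel.
#' @param snps_per_block SNPs per block (>= 2).
#' @param block_span_bp physical span of each block in bp.
#' @param founder_haplotypes_per_block size of the founder haplotype pool
#'   each block's chromosomes are drawn from (>= 2); a small pool creates
#'   strong within-block LD.
#' @param maf_min lower bound on the expected alternate-allele frequency
#'   (and on 1 minus it) at every simulated SNP.
#' @param heritability_target narrow-sense h2 of the trait, in (0, 1).
#' @param trait_mean,trait_sd trait mean and standard deviation (kg/day).
#' @param causal_spec list of planted effects; see Details. `NULL` plants
#'   nothing (pure polygenic trait).
#' @param fixed_effect_levels named list of per-level effect vectors for
#'   the categorical covariates; level labels are generated automatically.
#' @param missing_rate missing-completely-at-random genotype rate.
#' @param n_chromosomes chromosomes the blocks are spread over.
#' @param gap_bp gap between consecutive blocks on a chromosome; large
#'   gaps keep blocks in linkage equilibrium and far beyond any block
#'   window.
#' @param founder_pool optional list (one element per block) of
#'   `list(haps = <F x s 0/1 matrix>, freqs = <numeric F>)` overriding the
#'   random founder pools; MAF feasibility is not enforced for explicit
#'   pools.
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @details `causal_spec` entries are lists with a `type` field:
#' \describe{
#'   \item{snp}{`list(type = "snp", block, snp, beta)` — additive effect
#'     `beta` (kg/day per alternate allele) on the `snp`-th SNP of the
#'     given block.}
#'   \item{haplotype}{`list(type = "haplotype", block, hap, beta, freq)` —
#'     effect per copy of founder haplotype `hap`; `freq` (optional)
#'     pins that haplotype's founder frequency.}
#'   \item{gene}{`list(type = "gene", block, snps, betas)` — a multi-SNP
#'     effect spread over the SNPs of one block, standing in for a causal
#'     gene.}
#' }
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 1000,
                       n_blocks = 30,
                       snps_per_block = 5,
                       block_span_bp = 20000,
                       founder_haplotypes_per_block = 4,
                       maf_min = 0.05,
                       heritability_target = 0.48,
                       trait_mean = 0.98,
                       trait_sd = 0.16,
                       causal_spec = "default",
                       fixed_effect_levels = default_fixed_effects(),
                       missing_rate = 0.01,
                       n_chromosomes = 5,
                       gap_bp = 1e6,
                       founder_pool = NULL,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_blocks = as.integer(n_blocks),
              snps_per_block = as.integer(snps_per_block),
              block_span_bp = as.integer(block_span_bp),
              founder_haplotypes_per_block =
                as.integer(founder_haplotypes_per_block),
              maf_min = maf_min,
              heritability_target = heritability_target,
              trait_mean = trait_mean,
              trait_sd = trait_sd,
              causal_spec = causal_spec,
              fixed_effect_levels = fixed_effect_levels,
              missing_rate = missing_rate,
              n_chromosomes = as.integer(n_chromosomes),
              gap_bp = as.numeric(gap_bp),
              founder_pool = founder_pool,
              seed = as.integer(seed))
  stopifnot(cfg$n_samples >= 2, cfg$snps_per_block >= 2,
            cfg$n_blocks >= 1,
            cfg$maf_min >= 0, cfg$maf_min <= 0.5,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$trait_sd > 0)
  if (cfg$heritability_target <= 0 || cfg$heritability_target >= 1)
    stop("heritability_target must lie in (0, 1)")
  if (identical(cfg$causal_spec, "default"))
    cfg$causal_spec <- default_causal_spec(cfg$n_blocks,
                                           cfg$snps_per_block)
  for (cs in cfg$causal_spec %||% list()) {
    if (cs$block > cfg$n_blocks)
      stop("causal_spec refers to block ", cs$block, " but n_blocks is ",
           cfg$n_blocks)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted causal effects
#'
#' One causal SNP (0.05 kg/day per allele, about 4\% of a 0.16^2
#' phenotypic variance at intermediate frequency), one causal haplotype
#' (0.10 kg/day per copy at founder frequency 0.20) and one three-SNP
#' causal gene, spread over three different blocks of the panel.
#'
#' @param n_blocks,snps_per_block panel dimensions the planted effects
#'   must fit in.
#' @export
default_causal_spec <- function(n_blocks = 30, snps_per_block = 5) {
  b <- unique(pmax(1L, round(n_blocks * c(0.17, 0.33, 0.50))))
  spec <- list(
    list(type = "snp", block = b[1],
         snp = min(3L, snps_per_block), beta = 0.05),
    if (length(b) >= 2)
      list(type = "haplotype", block = b[2], hap = 1L, beta = 0.10,
           freq = 0.20),
    if (length(b) >= 3)
      list(type = "gene", block = b[3],
           snps = seq_len(min(3L, snps_per_block)),
           betas = rep(0.02, min(3L, snps_per_block))))
  Filter(Negate(is.null), spec)
}

#' Default categorical fixed effects
#'
#' Sex (2 levels), birth year (6 levels) and calving season (4 levels)
#' with small level effects in kg/day, mirroring herd-management
#' covariates of a fattening trial.
#' @export
default_fixed_effects <- function() {
  list(sex = c(0, 0.04),
       birth_year = seq(-0.025, 0.025, length.out = 6),
       calving_season = c(0, 0.01, -0.01, 0.02))
}

# internal: draw one block's founder pool subject to the expected-MAF bound
draw_founder_pool <- function(block, s, n_founders, maf_min,
                              forced_freq = NULL, forced_hap = NULL,
                              max_attempts = 200L) {
  if (n_founders < 2)
    stop("founder pool must contain at least 2 haplotypes")
  for (attempt in seq_len(max_attempts)) {
    haps <- matrix(stats::rbinom(n_founders * s, 1L, 0.5),
                   nrow = n_founders)
    if (nrow(unique(haps)) < 2) next
    w <- stats::rgamma(n_founders, shape = 1)
    freqs <- w / sum(w)
    if (!is.null(forced_freq)) {
      freqs[forced_hap] <- forced_freq
      rest <- setdiff(seq_len(n_founders), forced_hap)
      freqs[rest] <- (1 - forced_freq) * w[rest] / sum(w[rest])
    }
    p <- as.numeric(crossprod(freqs, haps))
    if (all(p >= maf_min & p <= 1 - maf_min))
      return(list(haps = haps, freqs = freqs))
  }
  stop(sprintf(
    "block %d: could not satisfy MAF >= %.3g after %d founder resamples",
    block, maf_min, max_attempts))
}

#' Simulate LD-block-structured genotypes
#'
#' Each individual's genotype within a block is the sum of two founder
#' haplotypes drawn independently from that block's pool, so within-block
#' LD is controlled by the pool while blocks are mutually in linkage
#' equilibrium. Entries are masked missing-completely-at-random at
#' `config$missing_rate`.
#'
#' @param config a [sim_config()].
#' @return `list(G = genotype_matrix, truth = sim_truth)` where `truth`
#'   records the phased haplotypes, founder pools, true block boundaries
#'   and the realized planted effects.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_genotypes_impl(config))
}

simulate_genotypes_impl <- function(cfg) {
  n <- cfg$n_samples; s <- cfg$snps_per_block; B <- cfg$n_blocks
  forced <- list()
  for (cs in cfg$causal_spec %||% list()) {
    if (identical(cs$type, "haplotype") && !is.null(cs$freq))
      forced[[as.character(cs$block)]] <- list(freq = cs$freq,
                                               hap = cs$hap)
  }
  pools <- vector("list", B)
  for (b in seq_len(B)) {
    if (!is.null(cfg$founder_pool)) {
      pool <- cfg$founder_pool[[b]]
      if (nrow(pool$haps) < 2)
        stop("founder pool must contain at least 2 haplotypes")
      pool$freqs <- pool$freqs / sum(pool$freqs)
      pools[[b]] <- pool
    } else {
      f <- forced[[as.character(b)]]
      pools[[b]] <- draw_founder_pool(b, s,
                                      cfg$founder_haplotypes_per_block,
                                      cfg$maf_min,
                                      forced_freq = f$freq,
                                      forced_hap = f$hap)
    }
  }

  # block coordinates: blocks dealt round-robin over chromosomes
  chrom <- ((seq_len(B) - 1L) %% cfg$n_chromosomes) + 1L
  idx_on_chrom <- stats::ave(seq_len(B), chrom, FUN = seq_along)
  block_start <- 1e6 + (idx_on_chrom - 1) * (cfg$block_span_bp + cfg$gap_bp)

  dosage <- matrix(0L, n, B * s)
  hap_assign <- vector("list", B)
  map_list <- vector("list", B)
  blocks <- data.frame(block = seq_len(B), chrom = as.character(chrom),
                       start_snp = (seq_len(B) - 1L) * s + 1L,
                       end_snp = seq_len(B) * s,
                       start_bp = NA_real_, end_bp = NA_real_,
                       stringsAsFactors = FALSE)
  for (b in seq_len(B)) {
    pool <- pools[[b]]
    f <- nrow(pool$haps)
    a1 <- sample.int(f, n, replace = TRUE, prob = pool$freqs)
    a2 <- sample.int(f, n, replace = TRUE, prob = pool$freqs)
    hap_assign[[b]] <- cbind(a1, a2)
    cols <- ((b - 1L) * s + 1L):(b * s)
    dosage[, cols] <- pool$haps[a1, , drop = FALSE] +
      pool$haps[a2, , drop = FALSE]
    offs <- sort(sample.int(cfg$block_span_bp, s))
    pos <- as.integer(block_start[b] + offs)
    blocks$start_bp[b] <- pos[1]; blocks$end_bp[b] <- pos[s]
    map_list[[b]] <- data.frame(
      snp_id = sprintf("snp%05d", cols),
      chrom = as.character(chrom[b]), pos = pos,
      a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, map_list)
  complete <- dosage
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(length(dosage)) < cfg$missing_rate
    dosage[miss] <- NA_integer_
  }
  G <- genotype_matrix(dosage, map)

  causal <- resolve_causal(cfg, map, pools)
  truth <- structure(list(hap_assign = hap_assign, pools = pools,
                          blocks = blocks, causal = causal,
                          complete_dosage = complete,
                          config = cfg),
                     class = "sim_truth")
  list(G = G, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: turn causal_spec into realized marker ids / column indices
resolve_causal <- function(cfg, map, pools) {
  out <- list()
  s <- cfg$snps_per_block
  for (cs in cfg$causal_spec %||% list()) {
    if (cs$type == "snp") {
      col <- (cs$block - 1L) * s + cs$snp
      out[[length(out) + 1L]] <- list(type = "snp", block = cs$block,
                                      col = col, snp_id = map$snp_id[col],
                                      beta = cs$beta)
    } else if (cs$type == "haplotype") {
      out[[length(out) + 1L]] <- list(
        type = "haplotype", block = cs$block, hap = cs$hap,
        beta = cs$beta,
        hap_allele = paste(pools[[cs$block]]$haps[cs$hap, ],
                           collapse = ""))
    } else if (cs$type == "gene") {
      cols <- (cs$block - 1L) * s + cs$snps
      out[[length(out) + 1L]] <- list(type = "gene", block = cs$block,
                                      cols = cols,
                                      snp_ids = map$snp_id[cols],
                                      betas = cs$betas)
    } else stop("unknown causal_spec type: ", cs$type)
  }
  out
}

#' Reconstruct the unphased genotype matrix from simulation truth
#'
#' Sums the two founder haplotypes assigned to every individual in every
#' block; equals the emitted dosage matrix at all non-missing entries.
#'
#' @param truth a `sim_truth`.
#' @return integer matrix, samples x SNPs.
#' @export
unphase_truth <- function(truth) {
  cfg <- truth$config
  s <- cfg$snps_per_block
  out <- matrix(0L, cfg$n_samples, cfg$n_blocks * s)
  for (b in seq_len(cfg$n_blocks)) {
    haps <- truth$pools[[b]]$haps
    asg <- truth$hap_assign[[b]]
    out[, ((b - 1L) * s + 1L):(b * s)] <-
      haps[asg[, 1], , drop = FALSE] + haps[asg[, 2], , drop = FALSE]
  }
  out
}

#' Simulate the quantitative trait
#'
#' Builds `y = mu + W v + sum_k x_k beta_k + u + e`: categorical fixed
#' effects, planted causal effects, a polygenic term `u` with covariance
#' `sigma_a^2 * K_true` (VanRaden relationships from all simulated SNPs)
#' and iid residuals. Variance components are scaled so the narrow-sense
#' heritability (genetic variance, planted plus polygenic, over genetic
#' plus residual) equals `heritability_target` and the total phenotypic
#' SD equals `trait_sd`.
#'
#' @param G genotype matrix from [simulate_genotypes()] (only dimensions
#'   and ids are used; genetic values come from `truth`).
#' @param truth matching `sim_truth`.
#' @param config the same [sim_config()].
#' @return `list(pheno = data.frame(sample_id, adg, sex, birth_year,
#'   calving_season), truth = truth)` with the truth augmented by the
#'   realized variance components, covariate design and polygenic values.
#' @export
simulate_phenotype <- function(G, truth, config) {
  stopifnot(inherits(config, "sim_config"),
            identical(G$sample_ids, paste0("S", seq_len(config$n_samples))) ||
              nrow(G$dosage) == config$n_samples)
  if (config$heritability_target <= 0 || config$heritability_target >= 1)
    stop("heritability_target must lie in (0, 1)")
  with_seed(config$seed + 1L, simulate_phenotype_impl(G, truth, config))
}

simulate_phenotype_impl <- function(G, truth, cfg) {
  n <- cfg$n_samples
  X <- truth$complete_dosage

  # categorical covariates with recorded level effects
  fe <- cfg$fixed_effect_levels
  covars <- data.frame(row.names = seq_len(n))
  wv <- numeric(n)
  for (nm in names(fe)) {
    lev <- sample.int(length(fe[[nm]]), n, replace = TRUE)
    covars[[nm]] <- factor(paste0(nm, lev),
                           levels = paste0(nm, seq_along(fe[[nm]])))
    wv <- wv + fe[[nm]][lev]
  }
  wv_c <- wv - mean(wv)

  # planted causal genetic values
  g <- numeric(n)
  for (cs in truth$causal) {
    if (cs$type == "snp") {
      g <- g + cs$beta * X[, cs$col]
    } else if (cs$type == "haplotype") {
      cnt <- rowSums(truth$hap_assign[[cs$block]] == cs$hap)
      g <- g + cs$beta * cnt
    } else if (cs$type == "gene") {
      g <- g + as.numeric(X[, cs$cols, drop = FALSE] %*% cs$betas)
    }
  }
  g_c <- g - mean(g)

  # variance budget: fixed effects come off the top, the remainder is
  # split h2 : (1 - h2) between genetic (planted + polygenic) and residual
  sp2 <- cfg$trait_sd^2
  var_fixed <- stats::var(wv_c) * (n - 1) / n
  avail <- sp2 - var_fixed
  if (avail <= 0)
    stop("fixed-effect variance exceeds the target phenotypic variance")
  sg2 <- cfg$heritability_target * avail
  se2 <- (1 - cfg$heritability_target) * avail
  var_causal <- stats::var(g_c) * (n - 1) / n
  sa2 <- sg2 - var_causal
  if (sa2 < 0) {
    warning("planted causal variance exceeds the genetic budget; ",
            "polygenic variance set to 0")
    sa2 <- 0
  }

  u <- numeric(n)
  if (sa2 > 0) {
    K <- vanraden_kinship(X)
    eg <- eigen(K, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    u <- as.numeric(eg$vectors %*% (sqrt(lam) * stats::rnorm(n))) *
      sqrt(sa2)
    u <- u - mean(u)
  }
  e <- stats::rnorm(n, sd = sqrt(se2))

  y <- cfg$trait_mean + wv_c + g_c + u + e
  pheno <- data.frame(sample_id = G$sample_ids, adg = y, covars,
                      stringsAsFactors = FALSE)
  truth$sigma_a2 <- sa2
  truth$sigma_e2 <- se2
  truth$sigma_g2 <- sg2
  truth$var_fixed <- var_fixed
  truth$polygenic <- u
  truth$causal_values <- g_c
  truth$fixed_values <- wv_c
  list(pheno = pheno, truth = truth)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_phenotype()] and [simulate_annotation()].
#'
#' @param config a [sim_config()].
#' @return list with `G`, `pheno`, `truth`, `annotation`.
#' @export
simulate_dataset <- function(config) {
  gt <- simulate_genotypes(config)
  ph <- simulate_phenotype(gt$G, gt$truth, config)
  ann <- simulate_annotation(ph$truth)
  list(G = gt$G, pheno = ph$pheno, truth = ph$truth, annotation = ann)
}

#' Gene annotation matching the simulated panel
#'
#' Emits one gene per simulated block whose body spans the block, so the
#' planted "gene" effect and block boundaries have a known annotation.
#'
#' @param truth a `sim_truth`.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end` (1-based,
#'   closed).
#' @export
simulate_annotation <- function(truth) {
  b <- truth$blocks
  data.frame(gene_id = sprintf("gene%03d", b$block),
             chrom = b$chrom,
             start = as.integer(b$start_bp),
             end = as.integer(b$end_bp),
             stringsAsFactors = FALSE)
}

#' Simulate repeated weight records
#'
#' Weights at a series of ages following `w = w0 + adg * age` plus
#' measurement noise, for exercising [adg_from_weights()].
#'
#' @param adg named numeric vector of per-sample daily gains (kg/day).
#' @param ages numeric vector of measurement ages (days).
#' @param w0 birth weight (kg).
#' @param noise_sd measurement noise SD (kg).
#' @param seed integer seed.
#' @return data.frame `sample_id`, `age`, `weight`.
#' @export
simulate_weights <- function(adg, ages = c(0, 210, 365, 545, 720),
                             w0 = 40, noise_sd = 5, seed = 1L) {
  stopifnot(length(ages) >= 2, !is.unsorted(ages, strictly = TRUE))
  ids <- names(adg) %||% paste0("S", seq_along(adg))
  with_seed(seed, {
    data.frame(
      sample_id = rep(ids, each = length(ages)),
      age = rep(ages, times = length(adg)),
      weight = w0 + as.numeric(outer(ages, adg)) +
        stats::rnorm(length(adg) * length(ages), sd = noise_sd))
  })
}

#' Average daily gain from longitudinal weights
#'
#' The OLS slope of body weight (kg) on age (days), per sample. An
#' optional age window restricts the regression to the fattening period.
#'
#' @param records data.frame with `sample_id`, `age` (days), `weight`
#'   (kg).
#' @param window optional `c(min_age, max_age)` (inclusive) selecting the
#'   records used for the slope.
#' @return named numeric vector of slopes (kg/day).
#' @export
adg_from_weights <- function(records, window = NULL) {
  stopifnot(all(c("sample_id", "age", "weight") %in% names(records)))
  if (!is.null(window)) {
    records <- records[records$age >= window[1] & records$age <= window[2], ,
                       drop = FALSE]
  }
  split_r <- split(records, records$sample_id)
  out <- vapply(split_r, function(r) {
    if (length(unique(r$age)) < 2)
      stop("need at least 2 distinct ages per sample to fit a slope")
    unname(stats::coef(stats::lm(weight ~ age, data = r))[2])
  }, numeric(1))
  out[unique(as.character(records$sample_id))]
}
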