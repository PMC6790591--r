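#' Simulation configuration
#'
#' Describes a synthetic landscape-genomics dataset: spatially clustered
#' demes on a rectangle, neutral SNPs with Balding-Nichols
#' population-structured allele frequencies, and optional "adaptive" SNPs
#' whose homozygous-alt genotype presence follows a logistic link to one
#' environmental gradient.
#'
#' Defaults emulate a modest field study: 300 samples, one panmictic deme
#' (no structure), 500 neutral SNPs, one adaptive SNP with a strong planted
#' effect (beta1 = 2 on the standardised gradient), 2% missing calls and a
#' moderate-noise longitudinal environmental gradient.
#'
#' @param n_samples number of sampled individuals.
#' @param n_neutral_snps neutral SNP count.
#' @param n_adaptive_snps adaptive SNP count.
#' @param demes number of demes K (1 = no structure).
#' @param fst Balding-Nichols divergence F in \[0, 1).
#' @param beta1 logistic effect of the standardised gradient on the adaptive
#'   genotype class.
#' @param beta0 logistic intercept (baseline prevalence of the adaptive
#'   class; default `qlogis(0.3)`).
#' @param env_noise_sd standard deviation of the non-spatial noise added to
#'   the gradient (gradient itself has unit range before noise).
#' @param missing_rate per-call dropout probability.
#' @param seed mandatory integer seed.
#' @return Object of class `SimConfig`.
#' @export
sim_config <- function(n_samples = 300L, n_neutral_snps = 500L,
                       n_adaptive_snps = 1L, demes = 1L, fst = 0,
                       beta1 = 2, beta0 = qlogis(0.3), env_noise_sd = 0.3,
                       missing_rate = 0.02, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_samples >= 2, n_neutral_snps + n_adaptive_snps >= 1,
            demes >= 1, fst >= 0, fst < 1,
            missing_rate >= 0, missing_rate <= 1, env_noise_sd >= 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_neutral_snps = as.integer(n_neutral_snps),
                 n_adaptive_snps = as.integer(n_adaptive_snps),
                 demes = as.integer(demes), fst = fst,
                 beta1 = beta1, beta0 = beta0,
                 env_noise_sd = env_noise_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Preset simulation configurations
#'
#' `"null"`: panmictic, no adaptive loci (type-I calibration). `"adaptive"`:
#' 500 samples, 500 neutral + 1 adaptive SNP with beta1 = 2 (power).
#' `"structured"`: two demes with F = 0.15 (population-structure tests).
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @return `SimConfig`.
#' @export
sim_preset <- function(preset = c("null", "adaptive", "structured"), seed) {
  preset <- match.arg(preset)
  switch(preset,
         null = sim_config(n_samples = 300L, n_neutral_snps = 500L,
                           n_adaptive_snps = 0L, demes = 1L, fst = 0,
                           beta1 = 0, seed = seed),
         adaptive = sim_config(n_samples = 500L, n_neutral_snps = 500L,
                               n_adaptive_snps = 1L, demes = 1L, fst = 0,
                               beta1 = 2, seed = seed),
         structured = sim_config(n_samples = 300L, n_neutral_snps = 500L,
                                 n_adaptive_snps = 0L, demes = 2L,
                                 fst = 0.15, beta1 = 0, seed = seed))
}

#' Simulate a landscape-genomics dataset with known truth
#'
#' Sample coordinates are uniform around `demes` cluster centres spread over
#' a 10 x 10 degree rectangle. The environmental gradient `env1` is a linear
#' function of longitude plus Gaussian noise; `env2` is pure noise. Neutral
#' SNP j draws an ancestral frequency `p_j ~ U(0.05, 0.95)` and per-deme
#' frequencies from the Balding-Nichols Beta distribution with variance
#' `F p_j (1 - p_j)`; genotypes are Binomial(2, p_deme). For each adaptive
#' SNP, presence of the homozygous-alt class is Bernoulli with probability
#' `plogis(beta0 + beta1 * scale(env1))`; absent samples fall back to 0/1
#' genotypes at Hardy-Weinberg proportions for a background frequency of
#' 0.3. Calls are then masked at `missing_rate`. All randomness flows from
#' `cfg$seed`; the same config gives byte-identical output.
#'
#' @param cfg a [sim_config()] or [sim_preset()].
#' @return List: `genotypes` (GenotypeMatrix), `env` (EnvTable with `env1`,
#'   `env2`), `truth` (data.frame: `snp`, `class`, `beta1`), `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  .with_seed(cfg$seed, {
    n <- cfg$n_samples
    K <- cfg$demes
    deme <- rep_len(seq_len(K), n)
    centers <- cbind(lon = runif(K, -5, 5), lat = runif(K, 40, 50))
    lon <- centers[deme, 1L] + runif(n, -1, 1)
    lat <- centers[deme, 2L] + runif(n, -1, 1)
    env1 <- (lon - min(lon)) / max(diff(range(lon)), 1e-9) +
      rnorm(n, sd = cfg$env_noise_sd)
    env2 <- rnorm(n)
    mn <- cfg$n_neutral_snps
    ma <- cfg$n_adaptive_snps
    m <- mn + ma
    calls <- matrix(NA_integer_, n, m)
    p_anc <- runif(mn, 0.05, 0.95)
    for (j in seq_len(mn)) {
      if (cfg$fst > 0 && K > 1L) {
        shape <- (1 - cfg$fst) / cfg$fst
        pd <- rbeta(K, shape * p_anc[j], shape * (1 - p_anc[j]))
      } else pd <- rep(p_anc[j], K)
      calls[, j] <- rbinom(n, 2L, pd[deme])
    }
    z <- as.numeric(scale(env1))
    for (a in seq_len(ma)) {
      j <- mn + a
      pr <- plogis(cfg$beta0 + cfg$beta1 * z)
      present <- rbinom(n, 1L, pr) == 1L
      g <- integer(n)
      g[present] <- 2L
      bg <- 0.3
      phet <- 2 * bg * (1 - bg) / ((1 - bg)^2 + 2 * bg * (1 - bg))
      g[!present] <- rbinom(sum(!present), 1L, phet)
      calls[, j] <- g
    }
    if (cfg$missing_rate > 0) {
      drop <- matrix(runif(n * m) < cfg$missing_rate, n, m)
      calls[drop] <- NA_integer_
    }
    ids <- sprintf("S%03d", seq_len(n))
    snp_names <- c(sprintf("neut%04d", seq_len(mn)),
                   if (ma) sprintf("adap%04d", seq_len(ma)))
    snps <- data.frame(name = snp_names,
                       chrom = as.character(((seq_len(m) - 1L) %% 5L) + 1L),
                       pos = 1000L * seq_len(m),
                       ref = "A", alt = "G", stringsAsFactors = FALSE)
    snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
    calls <- calls[, match(snps$name, snp_names), drop = FALSE]
    g <- genotype_matrix(calls, ids, snps)
    env <- env_table(ids, lon, lat,
                     data.frame(env1 = env1, env2 = env2))
    truth <- if (ma) data.frame(snp = sprintf("adap%04d", seq_len(ma)),
                                class = "homAlt", beta1 = cfg$beta1,
                                stringsAsFactors = FALSE)
    else data.frame(snp = character(), class = character(),
                    beta1 = numeric(), stringsAsFactors = FALSE)
    list(genotypes = g, env = env, truth = truth, config = cfg)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits `genotypes.vcf` (VCFv4.2), `samples.csv` (ID, lon, lat, EPSG),
#' `env.csv` and `truth.tsv` under `dir`.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  write.csv(data.frame(ID = sim$env$ID, lon = sim$env$lon,
                       lat = sim$env$lat, epsg = 4326L),
            file.path(dir, "samples.csv"), row.names = FALSE, quote = FALSE)
  write_env_csv(sim$env, file.path(dir, "env.csv"))
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}

#' Write a GenotypeMatrix as a minimal VCFv4.2 file
#'
#' GT-only, unphased; missing calls are `./.`.
#'
#' @param g GenotypeMatrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=geascan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", g$samples),
                     collapse = "\t")), con)
  gtmap <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$calls))) {
    d <- g$calls[, j]
    gt <- ifelse(is.na(d), "./.", gtmap[d + 1L])
    writeLines(paste(c(g$snps$chrom[j], g$snps$pos[j], g$snps$name[j],
                       g$snps$ref[j], g$snps$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
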