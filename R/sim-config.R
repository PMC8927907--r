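#' Simulation configuration
#'
#' Builds and validates the configuration object that drives all synthetic
#' generators. Defaults emulate the study design the pipeline targets:
#' 18 organ donors spanning HbA1c 4.6--7% in three glycemic strata
#' (NGT / IGT / T2D, roughly 7/6/5), 470 expressed miRNAs of which 9 are
#' planted as upregulated-and-positively-correlated with HbA1c (Up-Pos) and
#' 22 as downregulated-and-negatively-correlated (Down-Neg), plus a
#' co-expression panel with five planted gene modules coupled to a
#' phenotypic trait, and genotypes carrying planted cis-eQTLs.
#'
#' Planted effect magnitudes are chosen so that the effects sit at the
#' detectability edge of the 18-donor design: with `noise_sd = 0.25` log2
#' units, `hba1c_beta = 1` log2/% is four feature-SDs per percent HbA1c,
#' the magnitude an association must have to survive BH correction at
#' q < 0.1 over ~500 features when glycemic status -- itself a threshold
#' function of HbA1c -- is adjusted for. See the methods vignette.
#'
#' @param seed integer root seed; every generator derives its own stream
#'   from it (see [sim_seed()]).
#' @param n_donors number of donors (>= 6 so each glycemic stratum is
#'   populated).
#' @param n_mirnas number of profiled miRNAs.
#' @param n_genes number of genes in the mRNA panel.
#' @param n_up_pos,n_down_neg numbers of planted Up-Pos / Down-Neg miRNAs.
#' @param group_shift_sd case-vs-control mean shift, in units of the
#'   feature noise SD.
#' @param hba1c_beta planted slope on log2 expression per unit HbA1c (%).
#' @param module_sizes integer vector of planted co-expression module sizes
#'   (each >= 3; their sum <= `n_genes`; remaining genes are background).
#' @param module_trait_cor correlation (in \[-1, 1\]) of each module's latent
#'   factor with the designated phenotypic trait; recycled to the number of
#'   modules.
#' @param module_loading loading of member genes on their module factor,
#'   in \[0, 1\]; member gene = loading * factor + sqrt(1 - loading^2) *
#'   noise (0 makes member genes pure noise, a null check).
#' @param noise_sd residual SD of log2 expression (> 0).
#' @param n_snps total number of simulated SNPs.
#' @param n_eqtls number of planted cis-eQTL (SNP, miRNA) pairs.
#' @param maf_range length-2 numeric, minor-allele-frequency range in
#'   (0, 0.5].
#' @param eqtl_beta planted per-allele slope on log2 miRNA expression.
#' @param cis_span half-width (bp) of the cis window planted eQTL SNPs are
#'   placed in around the miRNA start.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_donors = 18L,
                       n_mirnas = 470L,
                       n_genes = 600L,
                       n_up_pos = 9L,
                       n_down_neg = 22L,
                       group_shift_sd = 1.5,
                       hba1c_beta = 1.0,
                       module_sizes = rep(100L, 5L),
                       module_trait_cor = 0.6,
                       module_loading = 0.8,
                       noise_sd = 0.25,
                       n_snps = 120L,
                       n_eqtls = 10L,
                       maf_range = c(0.05, 0.5),
                       eqtl_beta = 0.2,
                       cis_span = 1e6) {
  cfg <- list(
    seed = as.integer(seed), n_donors = as.integer(n_donors),
    n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
    n_up_pos = as.integer(n_up_pos), n_down_neg = as.integer(n_down_neg),
    group_shift_sd = group_shift_sd, hba1c_beta = hba1c_beta,
    module_sizes = as.integer(module_sizes),
    module_trait_cor = rep_len(module_trait_cor, length(module_sizes)),
    module_loading = module_loading, noise_sd = noise_sd,
    n_snps = as.integer(n_snps), n_eqtls = as.integer(n_eqtls),
    maf_range = as.numeric(maf_range), eqtl_beta = eqtl_beta,
    cis_span = as.numeric(cis_span)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_donors <= 0) stop("invalid config: n_donors must be positive")
  if (cfg$n_up_pos + cfg$n_down_neg > cfg$n_mirnas)
    stop("invalid config: n_up_pos + n_down_neg exceeds n_mirnas")
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("invalid config: sum(module_sizes) exceeds n_genes")
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("invalid config: maf_range must lie within (0, 0.5]")
  if (any(abs(cfg$module_trait_cor) > 1))
    stop("invalid config: module_trait_cor must lie in [-1, 1]")
  if (cfg$module_loading < 0 || cfg$module_loading > 1)
    stop("invalid config: module_loading must lie in [0, 1]")
  if (cfg$cis_span <= 0) stop("invalid config: cis_span must be positive")
  invisible(cfg)
}

#' Derive a deterministic sub-seed for a named random stream
#'
#' All generator randomness flows from the single root seed in
#' [sim_config()]: each generator sets its RNG state to
#' `sim_seed(cfg$seed, "<stream name>")`, so regenerating any one table is
#' reproducible without replaying the others.
#'
#' @param seed integer root seed.
#' @param stream character stream label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
sim_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 10007 + h * 31 + 17) %%
               2147483647)
}
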