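## Synthetic placental cohort generator.
##
## Emulates the study design the downstream stages expect: mother-fetus
## pairs from two populations sampled at one site, each placenta dissected
## into seven layers, RNA-seq counts per layer, allele-specific read counts
## at shared SNPs, and newborn traits driven by latent co-expression
## modules. Every generated quantity is recorded as ground truth so
## recovery can be measured.

#' Default module-to-trait loading matrix
#'
#' Rows are latent modules (`M1`, `M2`, ...), columns the 11 newborn traits.
#' A nonzero entry makes the trait a noisy linear readout of that module's
#' latent eigengene. Defaults load four modules on birth weight / placental
#' weight, placental volume, amniotic fluid measures, and fundal height /
#' fetal heart, mirroring the kinds of module-trait pairs seen in layered
#' placenta studies.
#'
#' @param n_modules Number of latent modules.
#' @return `n_modules` x 11 numeric matrix with dimnames.
#' @export
default_trait_loadings <- function(n_modules = 4) {
  L <- matrix(0, n_modules, length(NEWBORN_TRAITS),
              dimnames = list(paste0("M", seq_len(n_modules)), NEWBORN_TRAITS))
  if (n_modules >= 1) L["M1", c("BW", "PW")] <- c(0.6, 0.3)
  if (n_modules >= 2) L["M2", "PLV"] <- -0.5
  if (n_modules >= 3) L["M3", c("AFI", "AFMD")] <- c(0.5, 0.4)
  if (n_modules >= 4) L["M4", c("FUH", "FH")] <- c(0.4, 0.3)
  L
}

#' Configuration of the synthetic cohort
#'
#' Defaults reproduce the study design downstream stages assume: 35 + 34
#' mother-fetus pairs (male/female newborns 16/19 and 21/13), seven
#' placental layers, layer-specific fetal fractions (umbilical cord and
#' fetal villus fully fetal, chorion mostly maternal), a negative-binomial
#' expression model whose between-population effects are concentrated in
#' specific layers and strongly male-biased, and newborn traits correlated
#' with latent module eigengenes. The gene and SNP universes default to
#' 2000 each - large enough for calibrated differential-expression and
#' module statistics while keeping a full cohort cheap to simulate.
#'
#' @param n_pairs_pop1,n_pairs_pop2 Mother-fetus pairs per population.
#' @param sex_split Per-population named counts of male/female newborns.
#' @param layers Layer codes (default the seven standard layers).
#' @param n_snps,n_genes Sizes of the variant and gene universes.
#' @param layer_fetal_fraction Named map layer -> fetal RNA fraction in
#'   `[0, 1]`.
#' @param read_depth Mean reads per informative SNP (Poisson).
#' @param seq_error Per-read sequencing error rate in `[0, 1)`.
#' @param deg_architecture List with `male` (named per-layer counts of true
#'   male-stratum DEGs), and `lfc_mean`, `lfc_sd`, `lfc_min` describing the
#'   magnitude distribution of true log2 fold changes.
#' @param male_bias_factor Ratio of male-stratum to female-stratum true DEG
#'   counts; female counts are `round(male / male_bias_factor)`.
#' @param age_effect_frac Fraction of genes with a (small) maternal-age
#'   effect.
#' @param age_effect_size SD of maternal-age log2 coefficients (per SD of
#'   age).
#' @param dispersion_shape,dispersion_scale Gamma parameters of gene-wise
#'   NB dispersions.
#' @param libsize_sd Log-scale SD of sample library-size factors.
#' @param n_modules,module_sizes Latent co-expression modules and their
#'   gene counts (`sum(module_sizes) <= n_genes`).
#' @param module_effect Log2-scale strength of the latent module signal in
#'   member genes.
#' @param trait_loadings Module x trait loading matrix (see
#'   [default_trait_loadings()]).
#' @param trait_noise_sd SD of trait noise (traits are on standardized,
#'   unitless scales).
#' @param maternal_age_range Integer range maternal ages are drawn from.
#' @param seed Integer seed; with the config it fully determines the cohort.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs_pop1 = 35,
                       n_pairs_pop2 = 34,
                       sex_split = list(pop1 = c(male = 16, female = 19),
                                        pop2 = c(male = 21, female = 13)),
                       layers = PLACENTA_LAYERS,
                       n_snps = 2000,
                       n_genes = 2000,
                       layer_fetal_fraction = c(UC = 1, AN = 0.97, CN = 0.30,
                                                CP = 0.97, VF = 1, VI = 0.97,
                                                VM = 0.97),
                       read_depth = 100,
                       seq_error = 0.002,
                       deg_architecture = list(
                         male = c(UC = 40, AN = 18, CN = 2, CP = 2,
                                  VF = 19, VI = 3, VM = 2),
                         lfc_mean = 1.5, lfc_sd = 0.5, lfc_min = 0.5),
                       male_bias_factor = 10,
                       age_effect_frac = 0.05,
                       age_effect_size = 0.1,
                       dispersion_shape = 2,
                       dispersion_scale = 0.05,
                       libsize_sd = 0.2,
                       n_modules = 4,
                       module_sizes = c(100, 80, 60, 50),
                       module_effect = 0.8,
                       trait_loadings = NULL,
                       trait_noise_sd = 0.5,
                       maternal_age_range = c(20L, 40L),
                       seed = 1L) {
  if (is.null(trait_loadings)) trait_loadings <- default_trait_loadings(n_modules)
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

#' Validate a `sim_config`
#'
#' @param cfg A `sim_config` list.
#' @return The config, invisibly unchanged, or an error.
#' @export
validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_pairs_pop1 > 0, n_pairs_pop2 > 0,
              n_snps > 0, n_genes > 0, read_depth > 0,
              seq_error >= 0, seq_error < 1,
              libsize_sd >= 0, trait_noise_sd >= 0,
              dispersion_shape > 0, dispersion_scale > 0,
              male_bias_factor > 0)
    if (sum(sex_split$pop1) != n_pairs_pop1 ||
        sum(sex_split$pop2) != n_pairs_pop2)
      stop("sex_split totals must match pair counts")
    if (!all(layers %in% names(layer_fetal_fraction)))
      stop("layer_fetal_fraction must cover every layer")
    if (any(layer_fetal_fraction < 0 | layer_fetal_fraction > 1))
      stop("fetal fractions must be in [0, 1]")
    if (length(module_sizes) != n_modules)
      stop("module_sizes must have length n_modules")
    if (sum(module_sizes) > n_genes)
      stop("sum of module sizes exceeds n_genes")
    if (!all(names(deg_architecture$male) %in% layers))
      stop("deg_architecture layers unknown")
    if (!all(rownames(trait_loadings) == paste0("M", seq_len(n_modules))))
      stop("trait_loadings rows must be M1..Mk")
    if (!all(colnames(trait_loadings) %in% NEWBORN_TRAITS))
      stop("unknown trait name in loadings: ",
           paste(setdiff(colnames(trait_loadings), NEWBORN_TRAITS),
                 collapse = ", "))
  })
  invisible(cfg)
}

#' Simulate fetal genotypes from maternal genotypes
#'
#' Each fetal genotype is one maternal transmitted allele (random for
#' heterozygous mothers) plus one paternal allele drawn from the population
#' allele frequency, so every fetus is Mendelian-consistent with its mother.
#'
#' @param mother_gt Integer matrix (variants x individuals) of 0/1/2 ALT
#'   dosages; `NA` allowed.
#' @param allele_freqs ALT allele frequencies in (0, 1), one per variant.
#' @param seed Integer seed.
#' @return Integer matrix like `mother_gt`; `NA` where the mother is `NA`.
#' @export
simulate_fetus_genotypes <- function(mother_gt, allele_freqs, seed = 1L) {
  m <- as.matrix(mother_gt)
  if (length(allele_freqs) != nrow(m))
    stop("allele_freqs must have one entry per variant")
  if (any(allele_freqs <= 0 | allele_freqs >= 1))
    stop("allele_freqs must be in (0, 1)")
  if (any(!is.na(m) & !(m %in% 0:2))) stop("genotypes must be 0/1/2 or NA")
  set.seed(seed)
  transmitted <- matrix(NA_integer_, nrow(m), ncol(m))
  hom <- !is.na(m) & m != 1L
  transmitted[hom] <- as.integer(m[hom] / 2L)
  het <- !is.na(m) & m == 1L
  transmitted[het] <- stats::rbinom(sum(het), 1L, 0.5)
  paternal <- matrix(stats::rbinom(length(m), 1L, rep(allele_freqs, ncol(m))),
                     nrow(m), ncol(m))
  out <- transmitted + paternal
  out[is.na(m)] <- NA_integer_
  dimnames(out) <- dimnames(m)
  out
}

#' Simulate allele-specific read counts for one mother-fetus pair
#'
#' Reads per variant are Poisson around `depth`; each read originates from
#' the fetal haplotype pool with probability `fetal_fraction`, otherwise the
#' maternal pool, and carries the ALT allele according to the source
#' genotype, flipped by a per-read error `seq_error`. At a fetal-specific
#' SNP (mother 0, fetus 1) the ALT-read probability is
#' `f/2 * (1 - e) + (1 - f/2) * e`.
#'
#' @param mother_gt,fetus_gt Integer 0/1/2 vectors over the same variants
#'   (names taken as variant ids).
#' @param fetal_fraction Fetal RNA fraction `f` in `[0, 1]`.
#' @param depth Mean read depth per variant (> 0).
#' @param seq_error Per-read error rate `e` in `[0, 1)`.
#' @param seed Integer seed.
#' @return `data.frame(variant_id, a_count, b_count)` where `b_count` is
#'   ALT-allele reads and `a_count` REF-allele reads.
#' @export
simulate_allelic_counts <- function(mother_gt, fetus_gt, fetal_fraction,
                                    depth, seq_error = 0, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  if (fetal_fraction < 0 || fetal_fraction > 1)
    stop("fetal_fraction must be in [0, 1]")
  if (length(mother_gt) != length(fetus_gt))
    stop("genotype vectors must have equal length")
  set.seed(seed)
  n <- length(mother_gt)
  dosage <- fetal_fraction * fetus_gt / 2 + (1 - fetal_fraction) * mother_gt / 2
  p_alt <- dosage * (1 - seq_error) + (1 - dosage) * seq_error
  reads <- stats::rpois(n, depth)
  b <- ifelse(is.na(p_alt), NA_integer_, stats::rbinom(n, reads, ifelse(is.na(p_alt), 0, p_alt)))
  ids <- names(mother_gt)
  if (is.null(ids)) ids <- paste0("v", seq_len(n))
  data.frame(variant_id = ids, a_count = reads - b, b_count = b,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Draw the ground-truth parameters of a synthetic cohort
#'
#' Samples the latent module partition, the per-layer per-stratum true DEG
#' sets with signed log2 fold changes (female counts scaled down from male
#' counts by `male_bias_factor`), and the maternal-age-responsive gene set.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List of class `sim_truth` with elements `gene_ids`,
#'   `module_assignment` (0 = unassigned), `deg` (per layer: per stratum
#'   data frame of `gene_id`, `lfc`), `age_genes`, `trait_loadings`.
#' @export
sim_truth <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(stage_seed(seed, "truth"))
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  assignment <- integer(config$n_genes)
  names(assignment) <- genes
  pool <- sample(genes, sum(config$module_sizes))
  off <- 0L
  for (m in seq_len(config$n_modules)) {
    assignment[pool[off + seq_len(config$module_sizes[m])]] <- m
    off <- off + config$module_sizes[m]
  }
  arch <- config$deg_architecture
  n_male <- arch$male[config$layers]
  n_male[is.na(n_male)] <- 0L
  names(n_male) <- config$layers
  n_female <- round(n_male / config$male_bias_factor)
  draw_degs <- function(k) {
    if (k == 0)
      return(data.frame(gene_id = character(), lfc = numeric(),
                        stringsAsFactors = FALSE))
    ids <- sample(genes, k)
    mag <- pmax(stats::rnorm(k, arch$lfc_mean, arch$lfc_sd), arch$lfc_min)
    data.frame(gene_id = ids, lfc = mag * sample(c(-1, 1), k, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  deg <- lapply(config$layers, function(L) {
    list(male = draw_degs(n_male[[L]]), female = draw_degs(n_female[[L]]))
  })
  names(deg) <- config$layers
  n_age <- round(config$age_effect_frac * config$n_genes)
  age_genes <- data.frame(
    gene_id = sample(genes, n_age),
    beta = stats::rnorm(n_age, 0, config$age_effect_size),
    stringsAsFactors = FALSE)
  structure(list(gene_ids = genes, module_assignment = assignment,
                 deg = deg, age_genes = age_genes,
                 trait_loadings = config$trait_loadings),
            class = "sim_truth")
}

#' Simulate layered RNA-seq count matrices
#'
#' Counts are NB(mean = libsize x baseline x 2^(design effects), gene-wise
#' gamma dispersion). The population effect is nonzero exactly for the true
#' DEGs of the sample's layer and sex stratum; a small maternal-age effect
#' applies to `truth$age_genes`; module member genes share a latent
#' per-pair eigengene signal that also drives the newborn traits.
#'
#' @param config A [sim_config()].
#' @param metadata Sample metadata with columns `sample_id`, `pair_id`,
#'   `population`, `infant_sex`, `layer`, `maternal_age`.
#' @param truth A [sim_truth()].
#' @param latents Optional pairs x modules latent matrix (rownames pair
#'   ids); if `NULL`, module effects are omitted.
#' @param seed Integer seed.
#' @return Named list (one per layer) of gene x sample integer matrices.
#' @export
simulate_counts <- function(config, metadata, truth, latents = NULL,
                            seed = config$seed) {
  validate_sim_config(config)
  .need_cols(metadata, c("sample_id", "pair_id", "population", "infant_sex",
                         "layer", "maternal_age"), "metadata")
  set.seed(stage_seed(seed, "counts"))
  ng <- config$n_genes
  genes <- truth$gene_ids
  baseline <- stats::rlnorm(ng, meanlog = log(100), sdlog = 1.3)
  dispersion <- stats::rgamma(ng, shape = config$dispersion_shape,
                              scale = config$dispersion_scale)
  libsize <- stats::rlnorm(nrow(metadata), 0, config$libsize_sd)
  names(libsize) <- metadata$sample_id
  age_z <- as.numeric(scale(metadata$maternal_age))
  if (all(is.na(age_z))) age_z <- rep(0, nrow(metadata))
  names(age_z) <- metadata$sample_id
  age_beta <- numeric(ng)
  names(age_beta) <- genes
  age_beta[truth$age_genes$gene_id] <- truth$age_genes$beta
  mod_w <- stats::runif(ng, 0.5, 1)  # per-gene loading on its module latent
  is_pop1 <- metadata$population == sort(unique(metadata$population))[2]
  out <- vector("list", length(config$layers))
  names(out) <- config$layers
  for (L in config$layers) {
    rows <- which(metadata$layer == L)
    md <- metadata[rows, ]
    log2mu <- matrix(rep(log2(baseline), length(rows)), ng, length(rows))
    for (stratum in c("male", "female")) {
      dg <- truth$deg[[L]][[stratum]]
      if (nrow(dg)) {
        cols <- which(md$infant_sex == stratum & is_pop1[rows])
        idx <- match(dg$gene_id, genes)
        log2mu[idx, cols] <- log2mu[idx, cols] + dg$lfc
      }
    }
    log2mu <- log2mu + outer(age_beta, age_z[md$sample_id])
    if (!is.null(latents)) {
      lat <- latents[md$pair_id, , drop = FALSE]
      for (m in seq_len(config$n_modules)) {
        idx <- which(truth$module_assignment == m)
        log2mu[idx, ] <- log2mu[idx, ] +
          config$module_effect * outer(mod_w[idx], lat[, m])
      }
    }
    mu <- 2^log2mu * rep(libsize[md$sample_id], each = ng)
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = rep(1 / pmax(dispersion, 1e-8),
                                            length(rows))),
                  ng, length(rows),
                  dimnames = list(genes, md$sample_id))
    out[[L]] <- cnt
  }
  out
}

#' Simulate newborn traits from latent module eigengenes
#'
#' Each trait is a linear combination of the latent module values plus
#' Gaussian noise: `trait = latents %*% loadings + N(0, noise_sd)`. Traits
#' without loadings are pure noise. Traits are on standardized, unitless
#' scales.
#'
#' @param latents Pairs x modules numeric matrix.
#' @param loadings Modules x traits matrix; column names must be a subset
#'   of [NEWBORN_TRAITS] (error otherwise).
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @return Data frame with one column per trait in [NEWBORN_TRAITS].
#' @export
simulate_traits <- function(latents, loadings, noise_sd = 0.5, seed = 1L) {
  latents <- as.matrix(latents)
  loadings <- as.matrix(loadings)
  bad <- setdiff(colnames(loadings), NEWBORN_TRAITS)
  if (length(bad)) stop("unknown trait name in loadings: ",
                        paste(bad, collapse = ", "))
  if (nrow(loadings) != ncol(latents))
    stop("loadings must have one row per latent module")
  set.seed(seed)
  n <- nrow(latents)
  full <- matrix(0, nrow(loadings), length(NEWBORN_TRAITS),
                 dimnames = list(rownames(loadings), NEWBORN_TRAITS))
  full[, colnames(loadings)] <- loadings
  traits <- latents %*% full +
    matrix(stats::rnorm(n * length(NEWBORN_TRAITS), 0, noise_sd), n)
  as.data.frame(traits)
}

#' Generate a complete synthetic cohort with ground truth
#'
#' Runs every generator stage under named sub-seeds of `config$seed`:
#' maternal and fetal genotypes at shared SNPs, per-sample allele-specific
#' counts whose fetal fraction is the layer's true value, layered NB count
#' matrices with the configured DE architecture, and module-driven newborn
#' traits. Identical config and seed give bit-identical cohorts.
#'
#' @param config A [sim_config()].
#' @param components Character subset of `c("genotypes", "allelic",
#'   "counts")`; traits and metadata are always generated. Dropping
#'   `"allelic"` skips the (large) per-SNP count table.
#' @return List of class `sim_cohort` with `metadata` (per sample),
#'   `pair_metadata`, `mother_gt`, `fetus_gt`, `allele_freqs`,
#'   `allelic_counts`, `counts` (per layer), `traits`, `latents`, `truth`,
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            components = c("genotypes", "allelic", "counts")) {
  validate_sim_config(config)
  seed <- config$seed
  n_pairs <- config$n_pairs_pop1 + config$n_pairs_pop2
  pair_id <- sprintf("P%03d", seq_len(n_pairs))
  population <- rep(c("Tibetan", "Han"),
                    c(config$n_pairs_pop1, config$n_pairs_pop2))
  infant_sex <- c(rep(c("male", "female"), config$sex_split$pop1),
                  rep(c("male", "female"), config$sex_split$pop2))
  set.seed(stage_seed(seed, "metadata"))
  maternal_age <- sample(seq(config$maternal_age_range[1],
                             config$maternal_age_range[2]),
                         n_pairs, replace = TRUE)
  pair_md <- data.frame(pair_id, population, infant_sex, maternal_age,
                        stringsAsFactors = FALSE)

  set.seed(stage_seed(seed, "latents"))
  latents <- matrix(stats::rnorm(n_pairs * config$n_modules), n_pairs,
                    dimnames = list(pair_id, paste0("M", seq_len(config$n_modules))))
  traits <- simulate_traits(latents, config$trait_loadings,
                            config$trait_noise_sd,
                            seed = stage_seed(seed, "traits"))
  truth <- sim_truth(config, seed)

  md <- merge(expand.grid(pair_id = pair_id, layer = config$layers,
                          stringsAsFactors = FALSE),
              pair_md, by = "pair_id", sort = FALSE)
  md <- md[order(match(md$layer, config$layers), md$pair_id), ]
  md$sample_id <- paste(md$pair_id, md$layer, sep = "_")
  md <- cbind(md[, c("sample_id", "pair_id", "population", "infant_sex",
                     "layer", "maternal_age")],
              traits[match(md$pair_id, pair_id), ])
  rownames(md) <- NULL
  truth$fetal_fraction <- stats::setNames(
    unname(config$layer_fetal_fraction[md$layer]), md$sample_id)

  out <- list(metadata = md, pair_metadata = pair_md, traits = traits,
              latents = latents, truth = truth, config = config)

  if ("genotypes" %in% components || "allelic" %in% components) {
    set.seed(stage_seed(seed, "genotypes"))
    freqs <- stats::runif(config$n_snps, 0.1, 0.9)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, config$n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    vid <- sprintf("1:%d:%s:%s", seq_len(config$n_snps) * 1000L, ref, alt)
    mother <- matrix(stats::rbinom(config$n_snps * n_pairs, 2L,
                                   rep(freqs, n_pairs)),
                     config$n_snps, n_pairs, dimnames = list(vid, pair_id))
    fetus <- simulate_fetus_genotypes(mother, freqs,
                                      seed = stage_seed(seed, "fetus"))
    out$mother_gt <- mother
    out$fetus_gt <- fetus
    out$allele_freqs <- stats::setNames(freqs, vid)
  }
  if ("allelic" %in% components) {
    ac <- lapply(seq_len(nrow(md)), function(i) {
      s <- md$sample_id[i]
      f <- config$layer_fetal_fraction[[md$layer[i]]]
      cbind(sample_id = s,
            simulate_allelic_counts(out$mother_gt[, md$pair_id[i]],
                                    out$fetus_gt[, md$pair_id[i]],
                                    f, config$read_depth, config$seq_error,
                                    seed = stage_seed(seed, paste0("ac_", s))))
    })
    out$allelic_counts <- do.call(rbind, ac)
  }
  if ("counts" %in% components) {
    out$counts <- simulate_counts(config, md, truth, latents, seed)
  }
  structure(out, class = "sim_cohort")
}
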