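## End-to-end pipeline driver: simulate (or load) a cohort, deconvolve
## maternal/fetal origin, run per-layer DE (combined and sex-stratified),
## summarize DEG sharing and direction discordance, build co-expression
## modules with trait association, and test panel enrichment. One global
## seed flows through named per-stage substreams; reruns with the same
## config are byte-identical apart from the timestamp field.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] for the synthetic cohort (its `seed` is
#'   overridden by `seed`).
#' @param alpha DEG significance level (BH-adjusted p).
#' @param min_mean DE independent-filter threshold.
#' @param min_snps,min_depth Origin-deconvolution parameters.
#' @param module_layers,module_strata Layer/stratum combinations to build
#'   modules for (defaults `"UC"` x male/female; building all 14 networks
#'   is possible but rarely needed at once).
#' @param min_module_size,cut_height,soft_power Module detection
#'   parameters; `soft_power = NULL` picks the power per network.
#' @param trait_threshold `"meff"` or `"nominal"` SDM trait threshold.
#' @param panel Optional gene panel for the enrichment stage; if `NULL` a
#'   synthetic selection-nominated panel is drawn (see
#'   [make_synthetic_panel()]).
#' @param panel_size Panel size when drawing a synthetic panel.
#' @param n_perm Enrichment permutations.
#' @param stages Named logical toggles for `deconv`, `de`, `modules`,
#'   `enrichment`.
#' @param seed Global integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            alpha = 0.05, min_mean = 1,
                            min_snps = 5, min_depth = 10,
                            module_layers = "UC",
                            module_strata = c("male", "female"),
                            min_module_size = 30, cut_height = 0.98,
                            soft_power = NULL,
                            trait_threshold = "meff",
                            panel = NULL, panel_size = 192,
                            n_perm = 10000,
                            stages = c(deconv = TRUE, de = TRUE,
                                       modules = TRUE, enrichment = TRUE),
                            seed = 1L) {
  sim$seed <- seed
  structure(as.list(environment()), class = "pipeline_config")
}

#' Draw a synthetic selection-nominated gene panel
#'
#' Emulates a panel of positive-selection candidates that is enriched for
#' true male-stratum DEGs: a fixed fraction of the panel is drawn from the
#' generator's true male DEG union, the rest uniformly from the remaining
#' universe.
#'
#' @param truth A [sim_truth()].
#' @param universe Gene universe to draw from.
#' @param panel_size Panel size.
#' @param frac_true_deg Fraction of the panel taken from true male DEGs
#'   (default 0.25).
#' @param seed Integer seed.
#' @return Character vector of panel gene ids.
#' @export
make_synthetic_panel <- function(truth, universe, panel_size = 192,
                                 frac_true_deg = 0.25, seed = 1L) {
  set.seed(seed)
  male_true <- intersect(
    unique(unlist(lapply(truth$deg, function(l) l$male$gene_id))), universe)
  n_true <- min(length(male_true), round(frac_true_deg * panel_size))
  chosen <- sample(male_true, n_true)
  rest <- sample(setdiff(universe, chosen), panel_size - n_true)
  sort(c(chosen, rest))
}

#' Run the full synthetic-cohort pipeline
#'
#' @param config A [pipeline_config()].
#' @param out_json Optional path; when given, the report is written as
#'   JSON.
#' @return Nested report list (also written to `out_json` if requested).
#' @export
run_pipeline <- function(config = pipeline_config(), out_json = NULL) {
  seed <- config$seed
  report <- list(
    parameters = list(alpha = config$alpha, min_mean = config$min_mean,
                      min_snps = config$min_snps,
                      min_depth = config$min_depth,
                      n_perm = config$n_perm, panel_size = config$panel_size,
                      trait_threshold = config$trait_threshold,
                      seed = seed),
    versions = list(package = as.character(utils::packageVersion("placentex")),
                    r = R.version.string),
    stages = list())

  cohort <- simulate_cohort(config$sim)
  md <- cohort$metadata
  report$cohort <- list(n_pairs = nrow(cohort$pair_metadata),
                        n_samples = nrow(md),
                        n_layers = length(config$sim$layers),
                        n_genes = config$sim$n_genes,
                        n_snps = config$sim$n_snps)

  ## ---- origin deconvolution ------------------------------------------
  if (isTRUE(config$stages[["deconv"]])) {
    orig <- estimate_origin_cohort(cohort$allelic_counts, md,
                                   cohort$mother_gt, cohort$fetus_gt,
                                   seed = stage_seed(seed, "deconv"),
                                   min_snps = config$min_snps,
                                   min_depth = config$min_depth,
                                   seq_error = config$sim$seq_error)
    truth_f <- cohort$truth$fetal_fraction[orig$sample_id]
    est_ok <- !is.na(orig$fetal_fraction)
    by_layer <- tapply(orig$fetal_fraction[est_ok], orig$layer[est_ok], mean)
    report$stages$deconv <- list(
      n_estimated = sum(est_ok),
      n_skipped = sum(!est_ok),
      mean_fetal_fraction_by_layer = as.list(
        round(by_layer[config$sim$layers], 4)),
      mean_abs_error = round(mean(abs(orig$fetal_fraction[est_ok] -
                                        truth_f[est_ok])), 4))
    orig_tab <- orig
  } else {
    report$stages$deconv <- "skipped"
    orig_tab <- NULL
  }

  ## ---- differential expression ---------------------------------------
  de_results <- NULL
  if (isTRUE(config$stages[["de"]])) {
    strata <- c("combined", "male", "female")
    de_results <- lapply(stats::setNames(nm = config$sim$layers), function(L) {
      cnt <- cohort$counts[[L]]
      mdl <- md[match(colnames(cnt), md$sample_id), ]
      lapply(stats::setNames(nm = strata), function(s)
        run_de(cnt, mdl, stratum = s, alpha = config$alpha,
               min_mean = config$min_mean))
    })
    deg_ids <- function(stratum) lapply(de_results, function(l)
      deg_set(l[[stratum]])$gene_id)
    counts_tab <- lapply(stats::setNames(nm = strata), function(s)
      lapply(deg_ids(s), length))
    sharing <- lapply(stats::setNames(nm = strata), function(s) {
      sets <- deg_ids(s)
      if (!any(lengths(sets) > 0)) return(NULL)
      sh <- classify_layer_sharing(sets)
      list(total_degs = sh$total_degs, one_layer = sh$one_layer_count,
           one_layer_share_pct = sh$one_layer_share_pct,
           shared = sh$shared_count)
    })
    discord <- lapply(stats::setNames(nm = config$sim$layers), function(L) {
      d <- direction_discordance(de_results[[L]]$male,
                                 de_results[[L]]$female)
      list(n_male_deg = d$n_male_deg, n_opposite = d$n_opposite,
           percent = d$percent)
    })
    universe <- rownames(cohort$counts[[1]])
    tested <- unique(unlist(lapply(de_results, function(l)
      l$combined$gene_id[!is.na(l$combined$p)])))
    comb_union <- unique(unlist(deg_ids("combined")))
    report$stages$de <- list(
      universe_size = length(tested),
      deg_counts = counts_tab,
      sharing = sharing,
      direction_discordance = discord,
      combined_deg_union = length(comb_union),
      deg_universe_share_pct = if (length(tested))
        percent_share(length(comb_union), length(tested), 1) else NA)
  } else {
    report$stages$de <- "skipped"
  }

  ## ---- co-expression modules -----------------------------------------
  if (isTRUE(config$stages[["modules"]]) && !is.null(de_results)) {
    trait_cols <- intersect(NEWBORN_TRAITS, colnames(md))
    mods_out <- list()
    for (L in config$module_layers) {
      for (s in config$module_strata) {
        cnt <- cohort$counts[[L]]
        mdl <- md[match(colnames(cnt), md$sample_id), ]
        if (s != "combined") {
          keep <- mdl$infant_sex == s
          cnt <- cnt[, keep, drop = FALSE]
          mdl <- mdl[keep, , drop = FALSE]
        }
        expr <- t(vst_like_transform(cnt))
        # floor the picked power at the conventional unsigned default 6:
        # the static cut needs enough adjacency contrast to isolate modules
        pw <- if (is.null(config$soft_power))
          max(suppressWarnings(pick_soft_power(expr)$power), 6) else
            config$soft_power
        ms <- detect_modules(expr, pw, min_size = config$min_module_size,
                             cut_height = config$cut_height)
        key <- paste(L, s, sep = "_")
        if (is.null(ms$eigengenes)) {
          mods_out[[key]] <- list(soft_power = pw, n_modules = 0)
          next
        }
        traits <- mdl[, trait_cols, drop = FALSE]
        assoc <- module_trait_association(ms$eigengenes, traits,
                                          mdl$population)
        tc <- cbind(traits,
                    population = as.numeric(factor(mdl$population)) - 1)
        meff <- effective_trait_number(
          stats::cor(tc, use = "pairwise.complete.obs"))
        degs <- deg_set(de_results[[L]][[s]])$gene_id
        flagged <- flag_sdm_and_key(assoc, ms, degs,
                                    universe_size = config$sim$n_genes,
                                    meff = meff$meff,
                                    trait_threshold = config$trait_threshold)
        hubs <- hub_genes(ms, expr, traits)
        mods_out[[key]] <- list(
          soft_power = pw,
          n_modules = ncol(ms$eigengenes),
          n_unassigned = sum(ms$assignments == 0),
          meff = round(meff$meff, 3),
          trait_alpha = meff$trait_alpha,
          n_sdm_nominal = sum(flagged$is_sdm_05),
          n_sdm_meff = sum(flagged$is_sdm_meff),
          key_module = if (any(flagged$is_key))
            flagged$module[flagged$is_key] else NA,
          n_hub_genes = nrow(hubs))
      }
    }
    report$stages$modules <- mods_out
  } else {
    report$stages$modules <- "skipped"
  }

  ## ---- panel enrichment ----------------------------------------------
  if (isTRUE(config$stages[["enrichment"]]) && !is.null(de_results)) {
    universe <- rownames(cohort$counts[[1]])
    panel <- config$panel
    if (is.null(panel))
      panel <- make_synthetic_panel(cohort$truth, universe,
                                    panel_size = config$panel_size,
                                    seed = stage_seed(seed, "panel"))
    sets <- list(
      combined = unique(unlist(lapply(de_results, function(l)
        deg_set(l$combined)$gene_id))),
      male = unique(unlist(lapply(de_results, function(l)
        deg_set(l$male)$gene_id))),
      female = unique(unlist(lapply(de_results, function(l)
        deg_set(l$female)$gene_id))))
    report$stages$enrichment <- lapply(
      stats::setNames(nm = names(sets)), function(nm) {
        er <- permutation_enrichment(universe, sets[[nm]], panel = panel,
                                     n_perm = config$n_perm,
                                     seed = stage_seed(seed,
                                                       paste0("perm_", nm)))
        list(set_size = er$set_size, observed_overlap = er$observed_overlap,
             n_ge_observed = er$n_ge_observed,
             empirical_p = er$empirical_p,
             empirical_p_label = er$empirical_p_label,
             hypergeom_p = signif(er$hypergeom_p, 6))
      })
  } else {
    report$stages$enrichment <- "skipped"
  }

  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = 10,
                         na = "null", null = "null", pretty = TRUE)
  }
  invisible(report)
}
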