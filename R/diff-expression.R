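## Per-layer negative-binomial differential expression between populations.
##
## Counts are normalized with median-of-ratios size factors, a gene-wise NB
## dispersion is estimated by method of moments on Poisson-fit residuals,
## and a log-link NB GLM is fitted by IRLS with a Wald test on the
## population coefficient. This is deliberately a plain, shrinkage-free NB
## GLM whose behaviour is validated by simulation (type-I error, effect
## recovery) rather than by identity to any particular published estimator.

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median across genes of its count divided by
#' the gene's geometric mean, computed over genes expressed in every
#' sample. If no gene is positive in all samples, falls back to total-count
#' scaling (factors normalized to geometric mean 1) with a warning.
#'
#' @param counts Nonnegative integer gene x sample matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  log_geo <- rowMeans(log(counts))
  ok <- is.finite(log_geo)
  if (!any(ok)) {
    warning("no gene expressed in all samples; using total-count scaling")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  apply(counts[ok, , drop = FALSE], 2,
        function(cl) exp(stats::median(log(cl) - log_geo[ok])))
}

#' Benjamini-Hochberg adjustment with NA passthrough
#'
#' Step-up FDR adjustment; `NA` p-values are passed through unchanged and
#' do not count toward the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# internal: MoM NB dispersion from a Poisson working fit, then NB IRLS fit
# with a Wald test on the last design column. Returns NULL on failure.
.nb_wald_one <- function(y, X, off) {
  p <- ncol(X)
  n <- length(y)
  fit0 <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::poisson(),
                                    offset = off)),
    error = function(e) NULL)
  if (is.null(fit0) || !fit0$converged) return(NULL)
  mu0 <- pmax(fit0$fitted.values, 1e-8)
  alpha <- sum((y - mu0)^2 / mu0^2 - 1 / mu0) / (n - p)
  alpha <- min(max(alpha, 1e-8), 100)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      X, y, family = MASS::negative.binomial(theta = 1 / alpha, link = "log"),
      offset = off, start = fit0$coefficients)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  covb <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(covb) || any(!is.finite(diag(covb))) || any(diag(covb) <= 0))
    return(NULL)
  beta <- fit$coefficients[p]
  se <- sqrt(covb[p, p])
  z <- beta / se
  # t reference with n - p df: the plug-in dispersion makes the normal
  # reference anticonservative at cohort-scale n
  list(log2FC = beta / log(2), se = se / log(2), stat = z,
       p = 2 * stats::pt(-abs(z), n - p), dispersion = alpha)
}

#' Negative-binomial Wald test per gene
#'
#' Fits, for every gene passing the expression filter, a log-link NB GLM of
#' counts on the covariates plus the population term (an offset carries the
#' log size factors), and reports a Wald test of the population
#' coefficient. The log2 fold change is oriented second factor level over
#' first (for levels `Han`, `Tibetan` a positive value means higher in
#' Tibetans). Genes failing the filter, or whose fit does not converge, get
#' `NA` statistics and are excluded from the BH adjustment.
#'
#' @param counts Gene x sample integer matrix.
#' @param metadata Data frame with one row per sample (same order as
#'   columns of `counts`), containing `population` and any covariates.
#' @param covariates Character vector of covariate column names (default
#'   `c("infant_sex", "maternal_age")`; use `"maternal_age"` alone for
#'   sex-stratified runs). `maternal_age` is z-scored before fitting.
#' @param alpha DEG significance level on BH-adjusted p (default 0.05).
#' @param min_mean Independent filter: genes with mean normalized count
#'   below this are not tested (default 1).
#' @param sf Optional precomputed size factors.
#' @return Data frame of class `de_result`: `gene_id`, `base_mean`,
#'   `log2FC`, `se`, `stat`, `p`, `p_adj`, `is_deg`, `dispersion`,
#'   `status`; attribute `lfc_levels` records the fold-change orientation.
#' @export
nb_glm_wald <- function(counts, metadata, covariates = c("infant_sex",
                                                         "maternal_age"),
                        alpha = 0.05, min_mean = 1, sf = NULL) {
  counts <- as.matrix(counts)
  .need_cols(metadata, c("population", covariates), "metadata")
  if (nrow(metadata) != ncol(counts))
    stop("metadata rows must match count columns")
  pop <- factor(metadata$population)
  if (nlevels(pop) != 2) stop("population must have exactly two levels")
  if (min(table(pop)) < 2) stop("need >= 2 samples per population")
  if (anyNA(metadata[, covariates, drop = FALSE]))
    stop("covariates must be complete for used samples")
  md <- metadata
  if ("maternal_age" %in% covariates)
    md$maternal_age <- as.numeric(scale(md$maternal_age))
  md$population <- pop
  form <- stats::reformulate(c(covariates, "population"))
  X <- stats::model.matrix(form, data = md)
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  if (is.null(sf)) sf <- size_factors(counts)
  off <- log(sf)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)
  testable <- base_mean >= min_mean & rowSums(counts) > 0
  res <- data.frame(gene_id = rownames(counts), base_mean = base_mean,
                    log2FC = NA_real_, se = NA_real_, stat = NA_real_,
                    p = NA_real_, p_adj = NA_real_, is_deg = FALSE,
                    dispersion = NA_real_,
                    status = ifelse(testable, "ok", "low_count"),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (i in which(testable)) {
    fit <- .nb_wald_one(counts[i, ], X, off)
    if (is.null(fit)) {
      res$status[i] <- "fit_failed"
      next
    }
    res$log2FC[i] <- fit$log2FC
    res$se[i] <- fit$se
    res$stat[i] <- fit$stat
    res$p[i] <- fit$p
    res$dispersion[i] <- fit$dispersion
  }
  res$p_adj <- bh_adjust(res$p)
  res$is_deg <- !is.na(res$p_adj) & res$p_adj < alpha
  attr(res, "lfc_levels") <- paste(levels(pop)[2], "over", levels(pop)[1])
  class(res) <- c("de_result", class(res))
  res
}

#' Run differential expression for one layer and stratum
#'
#' Combined runs adjust for infant sex and maternal age; sex-stratified
#' runs subset to one sex and adjust for maternal age only.
#'
#' @param counts Gene x sample matrix for one layer.
#' @param metadata Matching sample metadata (`population`, `infant_sex`,
#'   `maternal_age`).
#' @param stratum `"combined"`, `"male"` or `"female"`.
#' @param ... Passed to [nb_glm_wald()].
#' @return A `de_result` data frame (see [nb_glm_wald()]).
#' @export
run_de <- function(counts, metadata, stratum = c("combined", "male",
                                                 "female"), ...) {
  stratum <- match.arg(stratum)
  if (stratum == "combined")
    return(nb_glm_wald(counts, metadata,
                       covariates = c("infant_sex", "maternal_age"), ...))
  keep <- metadata$infant_sex == stratum
  nb_glm_wald(counts[, keep, drop = FALSE], metadata[keep, , drop = FALSE],
              covariates = "maternal_age", ...)
}

#' Extract the DEG set (with direction) from a `de_result`
#'
#' @param res A [nb_glm_wald()] result.
#' @return Data frame `gene_id`, `direction` (`"up"`/`"down"`).
#' @export
deg_set <- function(res) {
  d <- res[res$is_deg, c("gene_id", "log2FC")]
  data.frame(gene_id = d$gene_id,
             direction = ifelse(d$log2FC > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Classify DEGs by the number of layers sharing them
#'
#' Labels each DEG with the set of layers in which it is called and
#' summarizes how many DEGs are layer-specific versus shared, with
#' percentages reported half-up to two decimals.
#'
#' @param deg_sets Named list (layer -> character vector of DEG ids, or
#'   data frame with a `gene_id` column).
#' @return List with `per_gene` (`gene_id`, `n_layers`, `layers`),
#'   `per_k` (`n_layers`, `count`), `total_degs`, `one_layer_count`,
#'   `one_layer_share_pct`, `shared_count`.
#' @export
classify_layer_sharing <- function(deg_sets) {
  sets <- lapply(deg_sets, function(s) {
    if (is.data.frame(s)) unique(s$gene_id) else unique(as.character(s))
  })
  if (!length(sets) || !any(lengths(sets) > 0))
    stop("need at least one layer with DEGs")
  long <- data.frame(
    gene_id = unlist(sets, use.names = FALSE),
    layer = rep(names(sets), lengths(sets)), stringsAsFactors = FALSE)
  layers_by_gene <- split(long$layer, long$gene_id)
  per_gene <- data.frame(
    gene_id = names(layers_by_gene),
    n_layers = lengths(layers_by_gene),
    layers = vapply(layers_by_gene, function(x) paste(sort(x), collapse = ","),
                    ""),
    row.names = NULL, stringsAsFactors = FALSE)
  tab <- table(per_gene$n_layers)
  per_k <- data.frame(n_layers = as.integer(names(tab)),
                      count = as.integer(tab))
  total <- nrow(per_gene)
  one <- sum(per_gene$n_layers == 1L)
  list(per_gene = per_gene, per_k = per_k, total_degs = total,
       one_layer_count = one,
       one_layer_share_pct = percent_share(one, total),
       shared_count = total - one)
}

#' Fraction of male DEGs with opposite-signed female fold change
#'
#' Among the male-stratum DEGs of a layer, the fraction whose female-stratum
#' log2 fold change has the opposite sign (a zero female effect counts as
#' non-opposite). Genes absent from the female results are excluded from
#' the denominator.
#'
#' @param male_res,female_res `de_result` data frames for the same layer.
#' @return List `n_male_deg`, `n_compared`, `n_opposite`, `fraction`,
#'   `percent` (half-up, two decimals), `n_missing`.
#' @export
direction_discordance <- function(male_res, female_res) {
  md <- male_res[male_res$is_deg, c("gene_id", "log2FC")]
  idx <- match(md$gene_id, female_res$gene_id)
  f_lfc <- female_res$log2FC[idx]
  usable <- !is.na(idx) & !is.na(f_lfc)
  opp <- sign(f_lfc[usable]) == -sign(md$log2FC[usable]) &
    sign(f_lfc[usable]) != 0
  n <- sum(usable)
  list(n_male_deg = nrow(md), n_compared = n, n_opposite = sum(opp),
       fraction = if (n) sum(opp) / n else NA_real_,
       percent = if (n) percent_share(sum(opp), n) else NA_real_,
       n_missing = nrow(md) - n)
}
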