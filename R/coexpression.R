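## Weighted co-expression modules and module-trait association.
##
## Unsigned weighted network: adjacency |cor|^beta with beta picked for
## approximate scale-free topology, topological overlap matrix (TOM),
## average-linkage clustering of 1 - TOM with a static height cut, module
## eigengenes as first principal components, Pearson module-trait
## correlation with an effective-number-of-traits Bonferroni threshold,
## and the significantly-differential-module / key-module / hub-gene rules.

#' Variance-stabilizing-style transform of counts
#'
#' `log2(count / size_factor + 1)`. A simple transform whose purpose here
#' is to put counts on a scale where the mean-variance relationship is
#' flat enough for correlation networks.
#'
#' @param counts Gene x sample nonnegative matrix.
#' @param sf Optional size factors (computed with [size_factors()] if
#'   omitted).
#' @return Transformed matrix, same shape.
#' @export
vst_like_transform <- function(counts, sf = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(sf)) sf <- size_factors(counts)
  log2(sweep(counts, 2, sf, "/") + 1)
}

# internal: scale-free topology fit index R^2 of a degree vector
.scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 10) return(0)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  km <- tapply(k, bin, mean)
  keep <- !is.na(pk) & pk > 0 & !is.na(km) & km > 0
  if (sum(keep) < 3) return(0)
  summary(stats::lm(log10(pk[keep]) ~ log10(km[keep])))$r.squared
}

#' Pick a soft-thresholding power for scale-free topology
#'
#' For each candidate power, the connectivity `k = colSums(|cor|^power)` is
#' binned and `log10 p(k)` regressed on `log10 k`; the smallest power whose
#' fit R-squared reaches `r2_target` is chosen. Powers that thin the
#' network below a mean connectivity of `min_mean_k` are not considered:
#' at very high powers the connectivity of even an uncorrelated matrix
#' spans orders of magnitude and the log-log fit becomes spuriously good.
#' If no admissible power reaches the target, the admissible power with
#' the largest R-squared is returned with a warning (typical of data
#' without scale-free structure, such as i.i.d. noise).
#'
#' @param expr Sample x gene expression matrix.
#' @param powers Candidate integer powers (default 1:20).
#' @param r2_target Scale-free fit target (default 0.8).
#' @param n_bins Degree histogram bins (default 10).
#' @param min_mean_k Minimum admissible mean connectivity (default 1).
#' @return List `power`, `r2` (per candidate; `NA` for inadmissible
#'   powers), `mean_k`, `reached_target`.
#' @export
pick_soft_power <- function(expr, powers = 1:20, r2_target = 0.8,
                            n_bins = 10, min_mean_k = 1) {
  expr <- as.matrix(expr)
  v <- apply(expr, 2, stats::var)
  expr <- expr[, !is.na(v) & v > 0, drop = FALSE]
  if (!ncol(expr)) stop("all genes are constant")
  if (nrow(expr) < 20)
    warning("fewer than 20 samples; soft-power selection is unstable")
  ac <- abs(stats::cor(expr))
  mean_k <- vapply(powers, function(b) mean(colSums(ac^b) - 1), 0)
  r2 <- vapply(powers, function(b) .scale_free_r2(colSums(ac^b) - 1, n_bins),
               0)
  names(r2) <- names(mean_k) <- powers
  admissible <- mean_k >= min_mean_k
  if (!any(admissible)) {
    warning("no candidate power keeps mean connectivity >= ", min_mean_k)
    admissible <- rep(TRUE, length(powers))
  }
  r2[!admissible] <- NA_real_
  hit <- which(admissible & r2 >= r2_target)
  if (length(hit)) {
    power <- powers[hit[1]]
    reached <- TRUE
  } else {
    power <- powers[which.max(replace(r2, !admissible, -Inf))]
    reached <- FALSE
    warning("no admissible power reached the scale-free fit target; ",
            "using max-R2 power ", power)
  }
  list(power = power, r2 = r2, mean_k = mean_k, reached_target = reached)
}

#' Topological overlap matrix of an adjacency matrix
#'
#' Standard unsigned TOM: with `a_ii = 0`,
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` and
#' unit diagonal. Values lie in `[0, 1]` for adjacencies in `[0, 1]`.
#'
#' @param adj Symmetric adjacency matrix with entries in `[0, 1]`.
#' @return TOM matrix, same shape.
#' @export
tom_similarity <- function(adj) {
  adj <- as.matrix(adj)
  if (any(adj < 0 | adj > 1)) stop("adjacency entries must be in [0, 1]")
  diag(adj) <- 0
  L <- adj %*% adj
  k <- colSums(adj)
  tom <- (L + adj) / (outer(k, k, pmin) + 1 - adj)
  diag(tom) <- 1
  tom
}

#' First-principal-component module eigengene
#'
#' First PC of the column-standardized member submatrix, scaled to unit
#' variance and sign-oriented so that its mean correlation with the member
#' genes is nonnegative.
#'
#' @param expr Sample x gene expression matrix.
#' @param members Character or integer index of at least 2 member genes.
#' @return Numeric per-sample vector (unit variance).
#' @export
module_eigengene <- function(expr, members) {
  x <- as.matrix(expr)[, members, drop = FALSE]
  if (ncol(x) < 2) stop("a module eigengene needs >= 2 member genes")
  xs <- scale(x)
  xs[, !is.finite(colSums(xs))] <- 0  # constant members carry no signal
  e <- svd(xs, nu = 1, nv = 0)$u[, 1]
  e <- e / stats::sd(e)
  cors <- suppressWarnings(stats::cor(e, xs))
  if (mean(cors, na.rm = TRUE) < 0) e <- -e
  e
}

#' Detect co-expression modules
#'
#' Builds the unsigned adjacency `|cor|^power`, its TOM, average-linkage
#' hierarchical clustering of `1 - TOM`, and cuts the tree at a static
#' height on the dissimilarity scale (default 0.98; `1 - TOM` is bounded
#' by 1, so genes join a module only through merges at TOM > 1 -
#' `cut_height`). Clusters smaller than `min_size` are left unassigned
#' (module 0); surviving modules are relabelled 1, 2, ... by decreasing
#' size and given eigengenes.
#'
#' @param expr Sample x gene expression matrix.
#' @param power Soft-thresholding power (>= 1).
#' @param min_size Minimum module size (default 30).
#' @param cut_height Static dissimilarity cut height (default 0.98).
#' @return List of class `module_set`: `assignments` (named integer, 0 =
#'   unassigned), `eigengenes` (sample x module matrix, columns `M1`...),
#'   `tom`, `power`, `min_size`, `cut_height`.
#' @export
detect_modules <- function(expr, power, min_size = 30, cut_height = 0.98) {
  if (power < 1) stop("power must be >= 1")
  expr <- as.matrix(expr)
  v <- apply(expr, 2, stats::var)
  if (all(is.na(v) | v == 0)) stop("all genes are constant")
  keep <- !is.na(v) & v > 0
  genes <- colnames(expr)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(expr)))
  assignments <- stats::setNames(integer(ncol(expr)), genes)
  if (sum(keep) < min_size) {
    warning("fewer informative genes than min_size; all genes unassigned")
    return(structure(list(assignments = assignments, eigengenes = NULL,
                          tom = NULL, power = power, min_size = min_size,
                          cut_height = NA_real_),
                     class = "module_set"))
  }
  ex <- expr[, keep, drop = FALSE]
  adj <- abs(stats::cor(ex))^power
  tom <- tom_similarity(adj)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = min(cut_height, max(hc$height)))
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_size]
  relabel <- stats::setNames(integer(length(sizes)), names(sizes))
  relabel[big[order(-sizes[big])]] <- seq_along(big)
  mods <- relabel[as.character(cl)]
  names(mods) <- names(cl)
  assignments[colnames(ex)] <- mods
  k <- max(mods)
  eig <- NULL
  if (k > 0) {
    eig <- sapply(seq_len(k), function(m)
      module_eigengene(ex, names(mods)[mods == m]))
    colnames(eig) <- paste0("M", seq_len(k))
    rownames(eig) <- rownames(expr)
  }
  structure(list(assignments = assignments, eigengenes = eig, tom = tom,
                 power = power, min_size = min_size,
                 cut_height = cut_height),
            class = "module_set")
}

# internal: pairwise-complete Pearson r and two-sided t-test p
.cor_test <- function(x, y, min_n = 4) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < min_n) return(c(r = NA_real_, p = NA_real_, n = n))
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x[ok], y[ok])
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  c(r = r, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' Correlate module eigengenes with population and newborn traits
#'
#' Pearson correlation with pairwise-complete samples; two-sided p from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` df. Population membership
#' is encoded 0/1 (point-biserial correlation). Zero-variance traits give
#' `NA` with a message.
#'
#' @param eigengenes Sample x module matrix (columns `M1`, ...).
#' @param traits Data frame of per-sample trait values (columns from
#'   [NEWBORN_TRAITS] or any numeric traits).
#' @param population Per-sample population labels (2 levels).
#' @return Data frame, one row per module: `module`, `r_pop`, `p_pop`,
#'   `r_<trait>`, `p_<trait>` per trait, `min_trait_p`, `best_trait`.
#' @export
module_trait_association <- function(eigengenes, traits, population) {
  eigengenes <- as.matrix(eigengenes)
  traits <- as.data.frame(traits)
  if (nrow(traits) != nrow(eigengenes))
    stop("traits and eigengenes must cover the same samples")
  pop <- as.numeric(factor(population)) - 1
  if (length(unique(pop[!is.na(pop)])) != 2)
    stop("population must have two levels")
  zero_var <- vapply(traits, function(tr)
    stats::sd(tr, na.rm = TRUE) == 0 || all(is.na(tr)), TRUE)
  if (any(zero_var))
    message("zero-variance trait(s) give NA: ",
            paste(names(traits)[zero_var], collapse = ", "))
  rows <- lapply(seq_len(ncol(eigengenes)), function(j) {
    e <- eigengenes[, j]
    pp <- .cor_test(e, pop)
    out <- data.frame(module = colnames(eigengenes)[j],
                      r_pop = pp[["r"]], p_pop = pp[["p"]],
                      stringsAsFactors = FALSE)
    ps <- rs <- stats::setNames(numeric(ncol(traits)), names(traits))
    for (tn in names(traits)) {
      ct <- .cor_test(e, traits[[tn]])
      rs[tn] <- ct[["r"]]
      ps[tn] <- ct[["p"]]
      out[[paste0("r_", tn)]] <- ct[["r"]]
      out[[paste0("p_", tn)]] <- ct[["p"]]
    }
    out$min_trait_p <- if (all(is.na(ps))) NA_real_ else min(ps, na.rm = TRUE)
    out$best_trait <- if (all(is.na(ps))) NA_character_ else
      names(ps)[which.min(ps)]
    out
  })
  do.call(rbind, rows)
}

#' Effective number of independent traits (eigenvalue estimator)
#'
#' Li-Ji-style estimator on the trait correlation matrix's eigenvalues:
#' `Meff = sum_i [ I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`.
#' The Bonferroni threshold divides 0.05 by `Meff` rounded to the nearest
#' integer (so `Meff = 4` gives 0.0125).
#'
#' @param trait_cor Square symmetric correlation matrix (unit diagonal).
#' @param tol Symmetry / PSD tolerance (default 1e-8).
#' @return List `meff`, `meff_int`, `trait_alpha`, `n_traits`, `lambda`.
#' @export
effective_trait_number <- function(trait_cor, tol = 1e-8) {
  C <- as.matrix(trait_cor)
  if (nrow(C) != ncol(C)) stop("correlation matrix must be square")
  if (max(abs(C - t(C))) > tol) stop("correlation matrix must be symmetric")
  if (max(abs(diag(C) - 1)) > tol) stop("diagonal must be 1")
  lambda <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) < -1e-6)
    stop("correlation matrix is not positive semidefinite")
  # snap eigenvalues to tolerance first: floor() is discontinuous and a
  # value like 3 - 1e-10 would otherwise contribute ~2 instead of 1
  lambda <- pmax(round(lambda, 8), 0)
  meff <- sum((lambda >= 1) + (lambda - floor(lambda)))
  meff_int <- max(1L, as.integer(round(meff)))
  list(meff = meff, meff_int = meff_int, trait_alpha = 0.05 / meff_int,
       n_traits = nrow(C), lambda = lambda)
}

#' Flag significantly differential modules (SDMs) and the key module
#'
#' A module is an SDM when its eigengene associates with population
#' membership (p < 0.05) and with at least one newborn trait below the
#' trait threshold; both the nominal (0.05) and the Meff-Bonferroni
#' (0.05/Meff) thresholds are computed and flagged. Overlap of each module
#' with the DEG set is scored by a hypergeometric upper tail, and the key
#' module is the SDM minimizing (best trait p, overlap p) lexicographically.
#'
#' @param stats A [module_trait_association()] result.
#' @param module_set A [detect_modules()] result (for module memberships).
#' @param deg_genes Character vector of DEG ids (empty set gives overlap
#'   p = 1 everywhere).
#' @param universe_size Number of genes in the tested universe.
#' @param meff Effective number of traits (e.g. from
#'   [effective_trait_number()]); rounded before dividing.
#' @param trait_threshold Which threshold drives `is_sdm` / `is_key`:
#'   `"meff"` (default) or `"nominal"`.
#' @return `stats` with added columns `module_size`, `deg_overlap`,
#'   `overlap_p`, `is_sdm_05`, `is_sdm_meff`, `is_sdm`, `is_key`, and
#'   attributes `meff`, `trait_alpha`.
#' @export
flag_sdm_and_key <- function(stats, module_set, deg_genes, universe_size,
                             meff, trait_threshold = c("meff", "nominal")) {
  trait_threshold <- match.arg(trait_threshold)
  alpha_meff <- 0.05 / max(1L, round(meff))
  asg <- module_set$assignments
  deg_genes <- unique(deg_genes)
  if (length(deg_genes) > universe_size)
    stop("more DEGs than universe genes")
  stats$module_size <- NA_integer_
  stats$deg_overlap <- NA_integer_
  stats$overlap_p <- NA_real_
  for (i in seq_len(nrow(stats))) {
    m <- as.integer(sub("^M", "", stats$module[i]))
    members <- names(asg)[asg == m]
    ov <- length(intersect(members, deg_genes))
    stats$module_size[i] <- length(members)
    stats$deg_overlap[i] <- ov
    stats$overlap_p[i] <- hypergeom_overlap_p(universe_size,
                                              length(deg_genes),
                                              length(members), ov)
  }
  sig_pop <- !is.na(stats$p_pop) & stats$p_pop < 0.05
  stats$is_sdm_05 <- sig_pop & !is.na(stats$min_trait_p) &
    stats$min_trait_p < 0.05
  stats$is_sdm_meff <- sig_pop & !is.na(stats$min_trait_p) &
    stats$min_trait_p < alpha_meff
  stats$is_sdm <- if (trait_threshold == "meff") stats$is_sdm_meff else
    stats$is_sdm_05
  stats$is_key <- FALSE
  cand <- which(stats$is_sdm)
  if (length(cand)) {
    ord <- cand[order(stats$min_trait_p[cand], stats$overlap_p[cand])]
    stats$is_key[ord[1]] <- TRUE
  }
  attr(stats, "meff") <- meff
  attr(stats, "trait_alpha") <- alpha_meff
  stats
}

#' Hub genes of each module
#'
#' A hub gene satisfies all three criteria: gene-module correlation (kME)
#' above `kme_min`, best absolute gene-trait correlation above
#' `trait_r_min`, and intra-module TOM connectivity ranked in the top
#' `top_degree` (ties at the boundary are all included and flagged).
#'
#' @param module_set A [detect_modules()] result.
#' @param expr Sample x gene expression matrix used for the modules.
#' @param traits Per-sample trait data frame.
#' @param kme_min Gene-module correlation threshold (default 0.2).
#' @param trait_r_min Gene-trait correlation threshold (default 0.8).
#' @param top_degree Degree-rank cutoff (default 3).
#' @return Data frame of hub genes: `module`, `gene_id`, `kme`,
#'   `best_trait`, `best_trait_r`, `degree`, `degree_rank`, `tied`.
#'   Zero rows when no gene qualifies.
#' @export
hub_genes <- function(module_set, expr, traits, kme_min = 0.2,
                      trait_r_min = 0.8, top_degree = 3) {
  asg <- module_set$assignments
  expr <- as.matrix(expr)
  traits <- as.data.frame(traits)
  out <- list()
  for (m in seq_len(max(0L, max(asg)))) {
    members <- names(asg)[asg == m]
    if (length(members) < 2) next
    e <- module_set$eigengenes[, paste0("M", m)]
    kme <- suppressWarnings(stats::cor(expr[, members, drop = FALSE], e))[, 1]
    tr_cor <- suppressWarnings(
      stats::cor(expr[, members, drop = FALSE], as.matrix(traits),
                 use = "pairwise.complete.obs"))
    best_idx <- apply(abs(tr_cor), 1, function(z)
      if (all(is.na(z))) NA_integer_ else which.max(z))
    best_r <- vapply(seq_along(members), function(i)
      if (is.na(best_idx[i])) NA_real_ else tr_cor[i, best_idx[i]], 0)
    tomm <- module_set$tom[members, members, drop = FALSE]
    degree <- rowSums(tomm) - 1
    rk <- rank(-degree, ties.method = "min")
    thr <- sort(degree, decreasing = TRUE)[min(top_degree, length(degree))]
    in_top <- degree >= thr
    tied <- in_top & sum(in_top) > top_degree & degree == thr
    hub <- !is.na(kme) & kme > kme_min & !is.na(best_r) &
      abs(best_r) > trait_r_min & in_top
    if (any(hub))
      out[[length(out) + 1L]] <- data.frame(
        module = paste0("M", m), gene_id = members[hub], kme = kme[hub],
        best_trait = colnames(tr_cor)[best_idx[hub]],
        best_trait_r = best_r[hub], degree = degree[hub],
        degree_rank = rk[hub], tied = tied[hub],
        row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(module = character(), gene_id = character(),
                      kme = numeric(), best_trait = character(),
                      best_trait_r = numeric(), degree = numeric(),
                      degree_rank = integer(), tied = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
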