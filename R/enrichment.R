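## Permutation enrichment of DEG sets for a selection-nominated gene panel.
##
## Each permutation draws a random panel of the same size from the
## expressed-gene universe and counts its overlap with the DEG set; the
## empirical p-value is the fraction of permutations with overlap at least
## the observed one. The closed-form hypergeometric upper tail is the
## exact oracle for this sampling scheme.

#' Hypergeometric upper-tail overlap probability
#'
#' Exact `P(X >= k)` for the overlap of a random size-`panel_size` draw
#' from a universe of `universe_size` genes with a fixed set of `set_size`
#' genes. Computed in log space via [stats::phyper()]. An `observed` beyond
#' the support returns 0.
#'
#' @param universe_size,panel_size,set_size,observed Integers with
#'   `panel_size <= universe_size`, `set_size <= universe_size`,
#'   `observed >= 0`.
#' @return Upper-tail probability.
#' @export
hypergeom_overlap_p <- function(universe_size, panel_size, set_size,
                                observed) {
  if (panel_size > universe_size || set_size > universe_size)
    stop("panel and set sizes cannot exceed the universe size")
  if (observed < 0) stop("observed overlap must be nonnegative")
  if (observed > min(panel_size, set_size)) return(0)
  stats::phyper(observed - 1, panel_size, universe_size - panel_size,
                set_size, lower.tail = FALSE)
}

#' Empirical p-value from permutation counts
#'
#' The convention is `count / n_perm`; a zero count is reported as the
#' upper bound `< 1/n_perm` (numeric value `1/n_perm`, flagged). The
#' `(count + 1) / (n_perm + 1)` convention is available via `plus_one`.
#'
#' @param n_ge_observed Permutations with statistic >= observed.
#' @param n_perm Total permutations.
#' @param plus_one Use the add-one convention (default `FALSE`).
#' @return List `p` (numeric), `label` (printable, e.g. `"0.0603"` or
#'   `"<1e-04"`), `is_upper_bound`.
#' @export
empirical_p_from_counts <- function(n_ge_observed, n_perm,
                                    plus_one = FALSE) {
  stopifnot(n_perm > 0, n_ge_observed >= 0, n_ge_observed <= n_perm)
  if (plus_one) {
    p <- (n_ge_observed + 1) / (n_perm + 1)
    return(list(p = p, label = format(p, digits = 4),
                is_upper_bound = FALSE))
  }
  if (n_ge_observed == 0)
    return(list(p = 1 / n_perm,
                label = paste0("<", format(1 / n_perm, scientific = TRUE)),
                is_upper_bound = TRUE))
  p <- n_ge_observed / n_perm
  list(p = p, label = format(p, digits = 4, scientific = FALSE),
       is_upper_bound = FALSE)
}

#' Permutation test of panel enrichment within a DEG set
#'
#' Draws `n_perm` random panels of `panel_size` genes without replacement
#' from the universe, counts each panel's overlap with `deg_genes`, and
#' compares with the observed overlap.
#'
#' @param universe Character vector, the expressed-gene universe.
#' @param deg_genes Character vector, the DEG set (must be a subset of the
#'   universe).
#' @param panel Character vector, the selection-nominated panel (subset of
#'   the universe); alternatively supply `panel_size` and `observed`.
#' @param panel_size,observed Used when `panel` is `NULL`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param plus_one Empirical p convention flag (see
#'   [empirical_p_from_counts()]).
#' @return List of class `enrichment_result`: `universe_size`,
#'   `panel_size`, `set_size`, `observed_overlap`, `n_perm`,
#'   `n_ge_observed`, `empirical_p`, `empirical_p_label`,
#'   `is_upper_bound`, `hypergeom_p`, `null_overlap_table`, `seed`.
#' @export
permutation_enrichment <- function(universe, deg_genes, panel = NULL,
                                   panel_size = NULL, observed = NULL,
                                   n_perm = 10000, seed = 1L,
                                   plus_one = FALSE) {
  universe <- unique(as.character(universe))
  deg_genes <- unique(as.character(deg_genes))
  if (length(setdiff(deg_genes, universe)))
    stop("deg_genes must be a subset of the universe")
  if (!is.null(panel)) {
    panel <- unique(as.character(panel))
    if (length(setdiff(panel, universe)))
      stop("panel genes outside the universe")
    panel_size <- length(panel)
    observed <- length(intersect(panel, deg_genes))
  }
  if (is.null(panel_size) || is.null(observed))
    stop("supply `panel` or both `panel_size` and `observed`")
  if (panel_size > length(universe))
    stop("panel_size exceeds the universe size")
  N <- length(universe)
  flag <- universe %in% deg_genes
  set.seed(seed)
  null_overlap <- vapply(seq_len(n_perm), function(i)
    sum(flag[sample.int(N, panel_size)]), 0L)
  n_ge <- sum(null_overlap >= observed)
  ep <- empirical_p_from_counts(n_ge, n_perm, plus_one = plus_one)
  structure(list(universe_size = N, panel_size = panel_size,
                 set_size = sum(flag), observed_overlap = observed,
                 n_perm = n_perm, n_ge_observed = n_ge,
                 empirical_p = ep$p, empirical_p_label = ep$label,
                 is_upper_bound = ep$is_upper_bound,
                 hypergeom_p = hypergeom_overlap_p(N, panel_size, sum(flag),
                                                   observed),
                 null_overlap_table = table(null_overlap), seed = seed),
            class = "enrichment_result")
}
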