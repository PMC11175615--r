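## Maternal/fetal origin deconvolution.
##
## A placental layer is a maternal-fetal mosaic. At a fetal-specific
## informative SNP (fetus heterozygous A/B, mother homozygous A/A) reads
## carrying the B allele can only come from the fetal genome; symmetrically
## for maternal-specific SNPs. The pooled allelic ratio R = B/(B+A) over a
## random tag-SNP subset, averaged over replicates, estimates each
## sample's fetal (R_f) and maternal (R_m) contribution, from which the
## fetal RNA fraction is derived.

#' Classify informative SNPs for a mother-fetus pair
#'
#' Fetal-specific: heterozygous in the fetus, homozygous in the mother.
#' Maternal-specific: the opposite. Variants heterozygous in both or
#' homozygous in both carry no origin information and are excluded. The
#' pair-specific allele B is whichever allele the heterozygous member
#' carries that the homozygous member lacks.
#'
#' @param mother_gt,fetus_gt Named 0/1/2 ALT-dosage vectors; names are
#'   variant ids and the shared ids define the variant universe.
#' @return List of class `informative_snps` with data frames
#'   `fetal_specific` and `maternal_specific`, each with `variant_id` and
#'   `specific_allele` (`"alt"` or `"ref"`).
#' @export
find_informative_snps <- function(mother_gt, fetus_gt) {
  if (is.null(names(mother_gt)) || is.null(names(fetus_gt)))
    stop("genotype vectors must be named by variant id")
  shared <- intersect(names(mother_gt), names(fetus_gt))
  if (!length(shared)) stop("no shared variants between mother and fetus")
  m <- mother_gt[shared]
  f <- fetus_gt[shared]
  ok <- !is.na(m) & !is.na(f)
  fetal <- ok & f == 1L & m != 1L
  maternal <- ok & m == 1L & f != 1L
  structure(list(
    fetal_specific = data.frame(
      variant_id = shared[fetal],
      specific_allele = ifelse(m[fetal] == 0L, "alt", "ref"),
      row.names = NULL, stringsAsFactors = FALSE),
    maternal_specific = data.frame(
      variant_id = shared[maternal],
      specific_allele = ifelse(f[maternal] == 0L, "alt", "ref"),
      row.names = NULL, stringsAsFactors = FALSE)),
    class = "informative_snps")
}

#' Pooled allelic ratio R = B / (B + A)
#'
#' Counts are pooled over the SNP subset before the ratio is taken, which
#' is robust to uneven per-SNP depth. With equal depth at every SNP the
#' pooled ratio equals the mean of per-SNP ratios.
#'
#' @param a_count,b_count Nonnegative read counts of the common (A) and
#'   specific (B) allele over a SNP subset.
#' @return The ratio in `[0, 1]`, or `NA_real_` when the subset has zero
#'   total reads (undefined, deliberately not 0).
#' @export
allelic_ratio <- function(a_count, b_count) {
  if (!length(a_count)) stop("empty SNP subset")
  if (length(a_count) != length(b_count)) stop("count vectors differ in length")
  if (any(a_count < 0 | b_count < 0, na.rm = TRUE)) stop("negative counts")
  tot <- sum(a_count, na.rm = TRUE) + sum(b_count, na.rm = TRUE)
  if (tot == 0) return(NA_real_)
  sum(b_count, na.rm = TRUE) / tot
}

# internal: per-class table of (A, B) counts keyed to the specific allele
.specific_counts <- function(allelic_counts, class_df) {
  idx <- match(class_df$variant_id, allelic_counts$variant_id)
  found <- !is.na(idx)
  ac <- allelic_counts[idx[found], ]
  alt_specific <- class_df$specific_allele[found] == "alt"
  data.frame(variant_id = class_df$variant_id[found],
             a = ifelse(alt_specific, ac$a_count, ac$b_count),
             b = ifelse(alt_specific, ac$b_count, ac$a_count),
             stringsAsFactors = FALSE)
}

#' Estimate the maternal/fetal origin of one sample
#'
#' Draws `n_reps` random tag-SNP subsets of size `subset_size` (without
#' replacement) from the covered fetal-specific and maternal-specific SNPs,
#' computes the pooled allelic ratio for each, and averages the replicate
#' values into `R_f` and `R_m`. The fetal fraction is derived from `R_f`:
#' a heterozygous fetus contributes the specific allele at rate 1/2, so by
#' default `f = clip((2 R_f - 2e) / (1 - 2e), 0, 1)` with `e` the assumed
#' sequencing error rate; the alternative normalization
#' `R_f / (R_f + R_m)` is available via `method = "ratio"`.
#'
#' @param allelic_counts Data frame with `variant_id`, `a_count` (REF
#'   reads), `b_count` (ALT reads) for one sample.
#' @param snps An [find_informative_snps()] result for the sample's pair.
#' @param n_reps Number of replicate subsets (default 5).
#' @param min_snps Tag-SNP subset size and the minimum number of covered
#'   informative SNPs required in each class (default 5).
#' @param min_depth Minimum reads at a SNP for it to count as covered
#'   (default 10).
#' @param seq_error Assumed sequencing error rate used in the fraction
#'   conversion (default 0).
#' @param method `"double"` (default) or `"ratio"` fraction conversion.
#' @param seed Integer seed for the subset draws.
#' @return List of class `origin_estimate`: `R_f`, `R_m` (replicate means),
#'   `replicate_R_f`, `replicate_R_m`, `fetal_fraction`, `n_snps_f`,
#'   `n_snps_m` (covered SNPs per class), `method`, `seed`.
#' @export
estimate_origin <- function(allelic_counts, snps, n_reps = 5, min_snps = 5,
                            min_depth = 10, seq_error = 0,
                            method = c("double", "ratio"), seed = 1L) {
  method <- match.arg(method)
  .need_cols(allelic_counts, c("variant_id", "a_count", "b_count"),
             "allelic_counts")
  fet <- .specific_counts(allelic_counts, snps$fetal_specific)
  mat <- .specific_counts(allelic_counts, snps$maternal_specific)
  fet <- fet[!is.na(fet$a + fet$b) & fet$a + fet$b >= min_depth, ]
  mat <- mat[!is.na(mat$a + mat$b) & mat$a + mat$b >= min_depth, ]
  if (nrow(fet) < min_snps || nrow(mat) < min_snps)
    stop(structure(class = c("placentex_insufficient_snps", "error",
                             "condition"),
                   list(message = sprintf(
                     paste0("insufficient covered informative SNPs ",
                            "(fetal %d, maternal %d, need %d)"),
                     nrow(fet), nrow(mat), min_snps),
                     call = sys.call(-1))))
  set.seed(seed)
  rf <- rm <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    i <- sample.int(nrow(fet), min_snps)
    j <- sample.int(nrow(mat), min_snps)
    rf[r] <- allelic_ratio(fet$a[i], fet$b[i])
    rm[r] <- allelic_ratio(mat$a[j], mat$b[j])
  }
  R_f <- mean(rf)
  R_m <- mean(rm)
  f <- switch(method,
    double = min(max((2 * R_f - 2 * seq_error) / (1 - 2 * seq_error), 0), 1),
    ratio = if (R_f + R_m == 0) NA_real_ else R_f / (R_f + R_m))
  structure(list(R_f = R_f, R_m = R_m, replicate_R_f = rf,
                 replicate_R_m = rm, fetal_fraction = f,
                 n_snps_f = nrow(fet), n_snps_m = nrow(mat),
                 method = method, seed = seed),
            class = "origin_estimate")
}

#' Estimate origin for every sample of a cohort
#'
#' Per-sample wrapper around [estimate_origin()]. Samples with too few
#' covered informative SNPs are skipped with the error recorded, and the
#' run continues.
#'
#' @param allelic_counts Long data frame `sample_id`, `variant_id`,
#'   `a_count`, `b_count`.
#' @param metadata Sample metadata (`sample_id`, `pair_id`, `layer`).
#' @param mother_gt,fetus_gt Variant x pair genotype matrices.
#' @param seed Global seed; each sample uses a named sub-seed.
#' @param ... Passed to [estimate_origin()].
#' @return Data frame, one row per sample: `sample_id`, `layer`, `R_f`,
#'   `R_m`, `fetal_fraction`, `n_snps_f`, `n_snps_m`, `error` (NA unless
#'   the sample was skipped).
#' @export
estimate_origin_cohort <- function(allelic_counts, metadata, mother_gt,
                                   fetus_gt, seed = 1L, ...) {
  .need_cols(metadata, c("sample_id", "pair_id", "layer"), "metadata")
  snp_sets <- lapply(stats::setNames(nm = unique(metadata$pair_id)),
                     function(p) find_informative_snps(mother_gt[, p],
                                                       fetus_gt[, p]))
  by_sample <- split(allelic_counts, allelic_counts$sample_id)
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    s <- metadata$sample_id[i]
    base <- data.frame(sample_id = s, layer = metadata$layer[i],
                       R_f = NA_real_, R_m = NA_real_,
                       fetal_fraction = NA_real_,
                       n_snps_f = NA_integer_, n_snps_m = NA_integer_,
                       error = NA_character_, stringsAsFactors = FALSE)
    ac <- by_sample[[s]]
    if (is.null(ac)) {
      base$error <- "no allelic counts"
      return(base)
    }
    est <- tryCatch(
      estimate_origin(ac, snp_sets[[metadata$pair_id[i]]],
                      seed = stage_seed(seed, paste0("origin_", s)), ...),
      error = function(e) e)
    if (inherits(est, "error")) {
      base$error <- conditionMessage(est)
      return(base)
    }
    base$R_f <- est$R_f
    base$R_m <- est$R_m
    base$fetal_fraction <- est$fetal_fraction
    base$n_snps_f <- est$n_snps_f
    base$n_snps_m <- est$n_snps_m
    base
  })
  do.call(rbind, rows)
}
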