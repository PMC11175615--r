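## File readers/writers. Variant ids are CHROM:POS:REF:ALT (1-based POS);
## tables are tab-separated with a header row and "." for missing.

#' Write a minimal GT-only VCF
#'
#' @param gt Variant x sample 0/1/2 dosage matrix; rownames must be
#'   `CHROM:POS:REF:ALT` ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gt, path) {
  gt <- as.matrix(gt)
  ids <- rownames(gt)
  if (is.null(ids)) stop("gt must have CHROM:POS:REF:ALT rownames")
  parts <- strsplit(ids, ":", fixed = TRUE)
  if (any(lengths(parts) != 4)) stop("malformed variant ids")
  chrom <- vapply(parts, `[`, "", 1)
  pos <- vapply(parts, `[`, "", 2)
  ref <- vapply(parts, `[`, "", 3)
  alt <- vapply(parts, `[`, "", 4)
  code <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt))
  code[is.na(gt)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(gt)), collapse = "\t")),
             con)
  body <- cbind(chrom, pos, ids, ref, alt, ".", ".", ".", "GT", code)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotypes from a VCF with GT
#'
#' Biallelic sites only; multi-allelic records are skipped with a warning.
#' Missing genotypes (`./.`) become `NA`.
#'
#' @param path VCF path.
#' @return Variant x sample integer 0/1/2 matrix keyed `CHROM:POS:REF:ALT`.
#' @export
read_vcf_genotypes <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fx <- vcfR::getFIX(v)
  fx <- matrix(fx, ncol = ncol(fx), dimnames = dimnames(fx))  # keep matrix for 1-row files
  multi <- grepl(",", fx[, "ALT"], fixed = TRUE)
  if (any(multi))
    warning(sum(multi), " multi-allelic site(s) skipped")
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt_raw <- gt_raw[!multi, , drop = FALSE]
  fx <- fx[!multi, , drop = FALSE]
  dose <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw))
  norm <- gsub("|", "/", gt_raw, fixed = TRUE)
  dose[norm == "0/0"] <- 0L
  dose[norm %in% c("0/1", "1/0")] <- 1L
  dose[norm == "1/1"] <- 2L
  dimnames(dose) <- list(paste(fx[, "CHROM"], fx[, "POS"], fx[, "REF"],
                               fx[, "ALT"], sep = ":"),
                         colnames(gt_raw))
  dose
}

#' Read a gene x sample count matrix from TSV
#'
#' First column is the gene id; all counts must be nonnegative integers.
#'
#' @param path TSV path.
#' @return Integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("counts must be numeric")
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count(s) at gene(s): ",
         paste(unique(genes[bad[, 1]]), collapse = ", "))
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a count matrix as TSV
#'
#' @param counts Gene x sample matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate sample metadata from TSV
#'
#' Requires `sample_id`, `pair_id`, `population`, `infant_sex`, `layer`,
#' `maternal_age`; layer values must be among the seven standard codes,
#' sample ids unique, and population and infant sex binary.
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_metadata_tsv <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  .need_cols(md, c("sample_id", "pair_id", "population", "infant_sex",
                   "layer", "maternal_age"), "metadata")
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup))
    stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(md$layer), PLACENTA_LAYERS)
  if (length(bad))
    stop("unknown layer label(s): ", paste(bad, collapse = ", "))
  if (length(unique(md$population)) > 2)
    stop("population must be binary")
  if (!all(md$infant_sex %in% c("male", "female")))
    stop("infant_sex must be 'male' or 'female'")
  md
}

#' Read a plain-text gene list (one id per line)
#'
#' @param path File path.
#' @return Character vector; duplicates dropped with a warning.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x)]
  if (anyDuplicated(x)) {
    warning("duplicate gene id(s) dropped")
    x <- unique(x)
  }
  x
}
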