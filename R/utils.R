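#' @keywords internal
"_PACKAGE"

## Canonical layer and trait vocabularies used throughout the package.

#' Placental layer codes, fetal to maternal side
#'
#' Umbilical cord (UC), amnion (AN), chorion (CN), chorionic plate (CP),
#' villus of fetal (VF), villus of intermediate (VI), villus of maternal (VM).
#'
#' @format Character vector of length 7.
#' @export
PLACENTA_LAYERS <- c("UC", "AN", "CN", "CP", "VF", "VI", "VM")

#' Newborn trait codes
#'
#' Birth weight (BW), biparietal diameter (BPD), femur length (FL),
#' gestation time (GT), placental weight (PW), placental volume (PLV),
#' abdominal girth (AG), amniotic fluid maximum depth (AFMD), amniotic
#' fluid index (AFI), fetal heart (FH), fundal height (FUH).
#'
#' @format Character vector of length 11.
#' @export
NEWBORN_TRAITS <- c("BW", "BPD", "FL", "GT", "PW", "PLV",
                    "AG", "AFMD", "AFI", "FH", "FUH")

#' Round half away from zero
#'
#' Base [round()] rounds half to even; printed cohort summaries use
#' conventional half-up rounding (82.555... -> 82.56), so that convention is
#' applied to every reported percentage.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share, half-up rounded
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param digits Decimal digits of the reported percentage (default 2).
#' @return `100 * numerator / denominator`, rounded half-up.
#' @examples
#' percent_share(399, 579) # 68.91
#' @export
percent_share <- function(numerator, denominator, digits = 2) {
  if (length(denominator) != 1L || is.na(denominator) || denominator <= 0)
    stop("`denominator` must be a single positive number")
  round_half_up(100 * numerator / denominator, digits)
}

#' Derive a per-stage seed from the global seed
#'
#' All randomness in the pipeline flows from one global seed through named
#' substreams so stages can be rerun independently yet reproducibly.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  ch <- utf8ToInt(stage)
  h <- sum(ch * seq_along(ch))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# internal: stop unless all names are present in a data frame
.need_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")))
  invisible(TRUE)
}
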