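#' Neutral-lipid concentration by difference
#'
#' Total lipid is the sum of the neutral and phospholipid fractions, so the
#' neutral-fraction concentration of an analyte is `total - phospholipid`.
#' Small negative differences can arise from measurement noise when the two
#' fractions are assayed independently; they are clipped to 0 with a warning.
#'
#' @param total,phospholipid concentrations in mg/100 g (vectors recycle).
#' @return Neutral-fraction concentration(s), mg/100 g.
#' @export
neutral_from_total <- function(total, phospholipid) {
  stopifnot(all(is.finite(total)), all(is.finite(phospholipid)))
  d <- total - phospholipid
  if (any(d < 0)) {
    warning(sprintf("%d negative neutral value(s) clipped to 0", sum(d < 0)))
    d[d < 0] <- 0
  }
  d
}

#' Phospholipid share of the total fraction (percent)
#'
#' `phospholipid / total * 100`. Undefined (NA) where `total` is zero.
#'
#' @param phospholipid,total concentrations in mg/100 g.
#' @return Share in percent.
#' @export
fraction_share <- function(phospholipid, total) {
  stopifnot(all(phospholipid >= 0), all(total >= 0))
  out <- ifelse(total > 0, phospholipid / total * 100, NA_real_)
  if (anyNA(out)) warning("share undefined where total = 0; reported as NA")
  out
}
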