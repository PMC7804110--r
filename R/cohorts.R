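# Age-interval cohort definitions (5- or 10-year bins, open-ended top bin).

#' Define age-interval cohorts
#'
#' Partitions the cohort age range into 5- or 10-year bins starting at age
#' 20, with an open-ended top bin from age 70. The representative age of a
#' bounded bin is its midpoint; the open top bin uses the observed mean age
#' of its members, so representative ages track the actual sampling of old
#' ages.
#'
#' @param ages Numeric vector of ages (years) of the cohort's eyes.
#' @param width Bin width in years: 5 or 10.
#' @return A `cohort_spec` tibble with columns `cohort` (label), `lower`,
#'   `upper`, `rep_age` and `n`. Bins with no members are kept (with `n = 0`
#'   and midpoint representative age) so the partition is data-independent;
#'   downstream summaries error on empty cohorts.
#' @export
#' @examples
#' cohort_spec(c(25, 34, 47, 52, 66, 78), width = 10)
cohort_spec <- function(ages, width = c(10, 5)) {
  width <- match.arg(as.character(width[1]), c("10", "5"))
  width <- as.numeric(width)
  stopifnot(is.numeric(ages), length(ages) > 0, !anyNA(ages))
  if (any(ages < 18 | ages > 100)) {
    stop("ages outside [18, 100] are not supported", call. = FALSE)
  }
  lo <- c(seq(20, 70 - width, by = width), 70)
  hi <- c(seq(20 + width, 70, by = width), Inf)
  bins <- tibble::tibble(lower = lo, upper = hi)
  top <- !is.finite(bins$upper)
  bins$cohort <- "70+"
  bins$cohort[!top] <- sprintf("%d-%d", as.integer(bins$lower[!top]),
                               as.integer(bins$upper[!top]) - 1L)
  idx <- findInterval(pmax(ages, 20), bins$lower)
  bins$n <- tabulate(idx, nbins = nrow(bins))
  top <- !is.finite(bins$upper)
  bins$rep_age <- (bins$lower + bins$upper) / 2
  bins$rep_age[top] <- if (bins$n[top] > 0) mean(ages[idx == which(top)]) else 77.5
  if (any(diff(bins$rep_age) <= 0)) {
    stop("representative ages are not strictly increasing", call. = FALSE)
  }
  out <- bins[, c("cohort", "lower", "upper", "rep_age", "n")]
  class(out) <- c("cohort_spec", class(out))
  attr(out, "width") <- width
  out
}

#' Assign ages to cohorts
#'
#' @param ages Numeric vector of ages.
#' @param spec A [cohort_spec()].
#' @return A factor of cohort labels in the cohort definition's order.
#' @export
assign_cohort <- function(ages, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  idx <- findInterval(pmax(ages, 20), spec$lower)
  factor(spec$cohort[idx], levels = spec$cohort)
}
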