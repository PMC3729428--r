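#' Convert month indices to decimal calendar years
#'
#' Dates are carried as integer month indices in the century-month-code
#' (CMC) style used by DHS: months elapsed since January 1900, so CMC 1 is
#' January 1900. A month is placed at its midpoint, giving
#' `year = 1900 + (cmc - 0.5) / 12`.
#'
#' @param cmc Integer vector of month indices.
#' @return Numeric vector of decimal years.
#' @examples
#' cmc_to_year(1)     # mid-January 1900
#' cmc_to_year(1201)  # mid-January 2000
#' @export
cmc_to_year <- function(cmc) {
  1900 + (cmc - 0.5) / 12
}

#' Convert decimal calendar years to month indices
#'
#' Inverse of [cmc_to_year()] up to month resolution: returns the month
#' index whose span contains the given decimal year.
#'
#' @param year Numeric vector of decimal years.
#' @return Integer vector of month indices.
#' @export
year_to_cmc <- function(year) {
  as.integer(floor((year - 1900) * 12) + 1L)
}
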