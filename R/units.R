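#' Convert between picograms of DNA and megabases
#'
#' Uses the standard genome-size conversion 1 pg = 978 Mb. Values are kept
#' unrounded; rounding happens only when tables are reported.
#'
#' @param x numeric vector of DNA amounts (pg for `pg_to_mb`, Mb for
#'   `mb_to_pg`). All values must be non-negative.
#' @return numeric vector of the same length in the other unit.
#' @examples
#' pg_to_mb(1)      # 978
#' mb_to_pg(10083)  # ~10.31
#' @export
pg_to_mb <- function(x) {
  .assert(is.numeric(x) && all(is.finite(x)), "'x' must be finite numeric",
          "cytokmer_domain_error")
  .assert(all(x >= 0), "DNA amounts must be non-negative",
          "cytokmer_domain_error")
  x * 978
}

#' @rdname pg_to_mb
#' @export
mb_to_pg <- function(x) {
  .assert(is.numeric(x) && all(is.finite(x)), "'x' must be finite numeric",
          "cytokmer_domain_error")
  .assert(all(x >= 0), "DNA amounts must be non-negative",
          "cytokmer_domain_error")
  x / 978
}
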