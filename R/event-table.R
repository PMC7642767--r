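#' Flow-cytometry event tables
#'
#' An `event_table` holds the per-replicate raw output of an ungated
#' flow-cytometry acquisition: one relative fluorescence intensity per
#' particle, plus the metadata needed downstream (species, sex, which
#' internal standard was co-prepared and its known 1C value in pg).
#'
#' @param fluorescence numeric vector of per-event fluorescence intensities
#'   (arbitrary units); must be finite and non-negative, length >= 1.
#' @param replicate_id character scalar identifying the biological replicate.
#' @param species,sex sample metadata; `sex` is `"F"` or `"M"` (or `NA`).
#' @param standard_name name of the co-prepared internal standard.
#' @param standard_1c known haploid DNA content of the standard, pg (> 0).
#' @param population_truth optional factor/character of the same length as
#'   `fluorescence` with levels among `sample`, `standard`, `debris` —
#'   ground-truth labels emitted by the simulator for test assertions only;
#'   estimators never read it.
#' @param truth optional list of simulator ground-truth parameters.
#' @return an object of class `event_table`.
#' @export
event_table <- function(fluorescence, replicate_id = "r1", species = NA_character_,
                        sex = NA_character_, standard_name = NA_character_,
                        standard_1c = NA_real_, population_truth = NULL,
                        truth = NULL) {
  .assert(is.numeric(fluorescence) && length(fluorescence) >= 1,
          "event table needs at least one fluorescence value",
          "cytokmer_empty_input_error")
  .assert(all(is.finite(fluorescence)) && all(fluorescence >= 0),
          "fluorescence values must be finite and >= 0",
          "cytokmer_validation_error")
  if (!is.null(population_truth)) {
    .assert(length(population_truth) == length(fluorescence),
            "population_truth must match fluorescence in length",
            "cytokmer_validation_error")
    population_truth <- as.character(population_truth)
  }
  if (!is.na(standard_1c)) {
    .assert(is.numeric(standard_1c) && standard_1c > 0,
            "standard_1c must be > 0 pg", "cytokmer_validation_error")
  }
  structure(
    list(replicate_id = as.character(replicate_id),
         species = as.character(species), sex = as.character(sex),
         standard_name = as.character(standard_name),
         standard_1c = as.numeric(standard_1c),
         fluorescence = as.numeric(fluorescence),
         population_truth = population_truth, truth = truth),
    class = "event_table"
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> replicate", x$replicate_id,
      sprintf("(%s %s)", x$species, x$sex), "\n")
  cat("  events:", length(x$fluorescence),
      " standard:", x$standard_name,
      sprintf("(1C = %.3f pg)", x$standard_1c), "\n")
  invisible(x)
}

#' @export
length.event_table <- function(x) length(x$fluorescence)

#' Read and write event tables as CSV
#'
#' The on-disk format has columns `replicate_id`, `population_truth`,
#' `fluorescence`; `population_truth` is blank for real instrument exports
#' and carries simulator ground truth otherwise.
#'
#' @param x an [event_table()].
#' @param path file path.
#' @param ... metadata fields (`species`, `sex`, `standard_name`,
#'   `standard_1c`) passed to [event_table()] when reading.
#' @return `write_event_csv` returns `path` invisibly; `read_event_csv`
#'   returns an `event_table`.
#' @export
write_event_csv <- function(x, path) {
  stopifnot(inherits(x, "event_table"))
  df <- data.frame(replicate_id = x$replicate_id,
                   population_truth = x$population_truth %||%
                     rep("", length(x$fluorescence)),
                   fluorescence = x$fluorescence)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_csv
#' @export
read_event_csv <- function(path, ...) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("replicate_id", "fluorescence") %in% names(df)),
          "event CSV needs columns replicate_id, fluorescence",
          "cytokmer_validation_error")
  truth <- NULL
  if ("population_truth" %in% names(df) &&
      any(nzchar(df$population_truth))) {
    truth <- df$population_truth
  }
  event_table(df$fluorescence,
              replicate_id = df$replicate_id[1],
              population_truth = truth, ...)
}
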