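#' Internal-standard specification and registry
#'
#' `standard_spec()` describes one calibration organism with a known haploid
#' DNA content. `standard_registry()` loads the packaged registry of the
#' four standards commonly co-prepared with large insect genomes: chicken
#' (*Gallus domesticus*, 1C = 1.165 pg), house mouse (*Mus musculus*,
#' 3.30 pg), American cockroach (*Periplaneta americana*, 3.41 pg) and
#' migratory locust (*Locusta migratoria*, male 6.20 pg). Users can extend
#' the registry with their own CSV (columns `name`, `sex`, `one_c_pg`).
#'
#' @param name organism name.
#' @param sex `"F"` or `"M"`.
#' @param one_c haploid DNA content, pg (> 0).
#' @param path optional CSV path replacing the packaged registry.
#' @return `standard_spec()`: a `standard_spec` object; `standard_registry()`:
#'   a `data.frame` with columns `name`, `sex`, `one_c_pg`.
#' @export
standard_spec <- function(name, sex = "M", one_c) {
  .assert(is.numeric(one_c) && length(one_c) == 1 && one_c > 0,
          "'one_c' must be a single value > 0 pg", "cytokmer_validation_error")
  .assert(sex %in% c("F", "M"), "'sex' must be 'F' or 'M'",
          "cytokmer_validation_error")
  structure(list(name = as.character(name), sex = sex, one_c = one_c),
            class = "standard_spec")
}

#' @rdname standard_spec
#' @export
standard_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "standards_registry.csv",
                        package = "cytokmer", mustWork = TRUE)
  }
  reg <- read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("name", "sex", "one_c_pg") %in% names(reg)),
          "registry CSV needs columns name, sex, one_c_pg",
          "cytokmer_validation_error")
  .assert(all(reg$one_c_pg > 0), "registry 1C values must be > 0",
          "cytokmer_validation_error")
  reg
}

#' Suitability rule for internal standards
#'
#' A standard is considered reliable for samples whose genome lies within a
#' fixed ratio band of the standard's own DNA content; far outside it,
#' nonlinearity and offset error degrade the calibration. The default band
#' (0.33, 3.30) is a calibration chosen so the migratory locust male
#' standard (6.20 pg) covers genomes of roughly 2-20 Gb, the working range
#' reported for that standard; it is a convention, not a measurement.
#'
#' @param ratio_lo,ratio_hi sample/standard 1C ratio bounds,
#'   `0 < ratio_lo < 1 < ratio_hi`.
#' @param min_separation minimum distance between sample and standard 2C
#'   peaks, in multiples of their combined standard deviation (default 3).
#' @param nominal_cv CV (percent) assumed for the separation check.
#' @return an object of class `suitability_rule`.
#' @export
suitability_rule <- function(ratio_lo = 0.33, ratio_hi = 3.30,
                             min_separation = 3, nominal_cv = 3) {
  .assert(is.numeric(ratio_lo) && is.numeric(ratio_hi) &&
            0 < ratio_lo && ratio_lo < 1 && 1 < ratio_hi,
          "need 0 < ratio_lo < 1 < ratio_hi", "cytokmer_validation_error")
  .assert(min_separation > 0 && nominal_cv >= 0,
          "'min_separation' must be > 0 and 'nominal_cv' >= 0",
          "cytokmer_validation_error")
  structure(list(ratio_lo = ratio_lo, ratio_hi = ratio_hi,
                 min_separation = min_separation, nominal_cv = nominal_cv),
            class = "suitability_rule")
}

#' Optimal measurable range of an internal standard
#'
#' @param std a [standard_spec()] (or a one-row registry slice with
#'   `one_c_pg`).
#' @param rule a [suitability_rule()].
#' @return named numeric `c(lo, hi)` in Mb:
#'   `ratio * one_c * 978` at each bound.
#' @examples
#' suitability_range(standard_spec("Locusta migratoria", "M", 6.20))
#' @export
suitability_range <- function(std, rule = suitability_rule()) {
  one_c <- if (inherits(std, "standard_spec")) std$one_c else std$one_c_pg[1]
  .assert(is.numeric(one_c) && one_c > 0, "standard 1C must be > 0",
          "cytokmer_validation_error")
  stopifnot(inherits(rule, "suitability_rule"))
  c(lo = rule$ratio_lo * pg_to_mb(one_c),
    hi = rule$ratio_hi * pg_to_mb(one_c))
}

#' Rank internal standards for a target genome
#'
#' Keeps the standards whose suitability range covers the target genome,
#' ranked by how close (on a log scale) the standard's 1C is to the target.
#' A covering standard whose 2C peak would sit within `min_separation`
#' combined standard deviations of the sample's (peak positions proportional
#' to 1C, spread from `nominal_cv`) is flagged `overlap`: its estimate would
#' be ambiguous and an alternative standard should be used.
#'
#' @param target expected sample 1C, pg.
#' @param registry data.frame as returned by [standard_registry()].
#' @param rule a [suitability_rule()].
#' @return data.frame with columns `name`, `sex`, `one_c_pg`, `lo_mb`,
#'   `hi_mb`, `log_distance`, `overlap` (logical), sorted by `log_distance`.
#'   Zero rows (with a `diagnostic` attribute `"no suitable standard"`) when
#'   nothing covers the target.
#' @export
select_standards <- function(target, registry = standard_registry(),
                             rule = suitability_rule()) {
  .assert(is.numeric(target) && length(target) == 1 && target > 0,
          "'target' must be a single 1C value > 0 pg",
          "cytokmer_validation_error")
  .assert(nrow(registry) >= 1, "registry is empty",
          "cytokmer_validation_error")
  target_mb <- pg_to_mb(target)
  ranges <- t(vapply(registry$one_c_pg, function(p) {
    suitability_range(standard_spec("x", "M", p), rule)
  }, numeric(2)))
  out <- data.frame(name = registry$name, sex = registry$sex,
                    one_c_pg = registry$one_c_pg,
                    lo_mb = ranges[, 1], hi_mb = ranges[, 2])
  out$log_distance <- abs(log(target / out$one_c_pg))
  # 2C positions proportional to 1C; overlap when peaks are closer than
  # min_separation combined sds under the nominal CV
  pos_sample <- 2 * target
  pos_std <- 2 * out$one_c_pg
  sd_sample <- rule$nominal_cv / 100 * pos_sample
  sd_std <- rule$nominal_cv / 100 * pos_std
  out$overlap <- abs(pos_sample - pos_std) <
    rule$min_separation * sqrt(sd_sample^2 + sd_std^2)
  out <- out[out$lo_mb <= target_mb & target_mb <= out$hi_mb, , drop = FALSE]
  out <- out[order(out$log_distance), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    attr(out, "diagnostic") <-
      sprintf("no suitable standard: no registry range covers %.0f Mb",
              target_mb)
  }
  out
}

#' Labelled replicate groups for variance-based tests
#'
#' @param label group label.
#' @param values numeric replicate values (pg).
#' @return a `group_data` object.
#' @export
group_data <- function(label, values) {
  .assert(is.numeric(values) && length(values) >= 1 && all(is.finite(values)),
          "group values must be finite numeric", "cytokmer_validation_error")
  structure(list(label = as.character(label), values = as.numeric(values)),
            class = "group_data")
}

.stack_groups <- function(groups) {
  .assert(is.list(groups) && length(groups) >= 2,
          "need at least two groups", "cytokmer_validation_error")
  groups <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (inherits(g, "group_data")) g else group_data(paste0("g", i), g)
  })
  data.frame(
    value = unlist(lapply(groups, `[[`, "values")),
    label = factor(rep(vapply(groups, `[[`, character(1), "label"),
                       vapply(groups, function(g) length(g$values),
                              integer(1))))
  )
}

#' One-way ANOVA across replicate groups
#'
#' Classical fixed-effects decomposition (via `stats::lm`/`anova`):
#' `F = MS_between / MS_within` on (k - 1, N - k) degrees of freedom.
#'
#' @param groups list of [group_data()] objects (or bare numeric vectors),
#'   each with >= 2 values.
#' @param alpha significance level passed to the attached Tukey table.
#' @param tukey attach a [tukey_hsd()] table (default TRUE).
#' @return list of class `anova_result`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `ms_within`, `tukey_table`.
#' @export
one_way_anova <- function(groups, alpha = 0.05, tukey = TRUE) {
  df <- .stack_groups(groups)
  sizes <- table(df$label)
  .assert(all(sizes >= 2), "every group needs >= 2 values",
          "cytokmer_validation_error")
  fit <- lm(value ~ label, data = df)
  av <- anova(fit)
  ms_within <- av$`Mean Sq`[2]
  .assert(ms_within > 0, "zero within-group variance",
          "cytokmer_degenerate_variance_error")
  res <- list(f_stat = av$`F value`[1],
              df_between = av$Df[1], df_within = av$Df[2],
              p_value = av$`Pr(>F)`[1], ms_within = ms_within,
              tukey_table = NULL)
  if (tukey) res$tukey_table <- tukey_hsd(groups, alpha = alpha)
  structure(res, class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  if (!is.null(x$tukey_table)) print(x$tukey_table)
  invisible(x)
}

#' Tukey honestly-significant-difference comparisons
#'
#' For each pair of groups computes the studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(MS_within/2 * (1/n_i + 1/n_j))`
#' (the Tukey-Kramer form for unequal n) and its family-wise p-value from
#' the studentized range distribution on `(k, df_within)`.
#'
#' @inheritParams one_way_anova
#' @param alpha family-wise significance level.
#' @return data.frame with one row per pair: `group_i`, `group_j`,
#'   `mean_diff`, `q`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  df <- .stack_groups(groups)
  sizes <- table(df$label)
  .assert(all(sizes >= 2), "every group needs >= 2 values",
          "cytokmer_validation_error")
  k <- nlevels(df$label)
  means <- tapply(df$value, df$label, mean)
  ns <- as.numeric(sizes)
  df_within <- nrow(df) - k
  ss_within <- sum(tapply(df$value, df$label,
                          function(v) sum((v - mean(v))^2)))
  ms_within <- ss_within / df_within
  .assert(ms_within > 0, "zero within-group variance",
          "cytokmer_degenerate_variance_error")
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    group_i = levels(df$label)[pairs[1, ]],
    group_j = levels(df$label)[pairs[2, ]],
    mean_diff = means[pairs[1, ]] - means[pairs[2, ]]
  )
  out$q <- abs(out$mean_diff) /
    sqrt(ms_within / 2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  out$p_adj <- ptukey(out$q, nmeans = k, df = df_within, lower.tail = FALSE)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Two-sample Student's t-test on replicate groups
#'
#' Pooled-variance two-sample t by default (`df = n_a + n_b - 2`), matching
#' the usual reporting convention for C-value comparisons; Welch's unequal-
#' variance form is available via `var_equal = FALSE`. A group with a single
#' replicate is allowed when its companion has >= 2: the pooled variance
#' then comes entirely from the larger group and the result is flagged
#' low-confidence.
#'
#' @param a,b [group_data()] objects or numeric vectors.
#' @param var_equal pooled (TRUE, default) vs Welch (FALSE).
#' @return list of class `t_result`: `t`, `df`, `p_value`, `mean_diff`
#'   (mean(a) - mean(b)), `low_confidence`.
#' @export
students_t <- function(a, b, var_equal = TRUE) {
  av <- if (inherits(a, "group_data")) a$values else as.numeric(a)
  bv <- if (inherits(b, "group_data")) b$values else as.numeric(b)
  .assert(length(av) >= 1 && length(bv) >= 1 && length(av) + length(bv) >= 3,
          "need at least three observations overall",
          "cytokmer_validation_error")
  low_conf <- min(length(av), length(bv)) < 2
  .assert(!(low_conf && !var_equal),
          "Welch's test needs >= 2 values per group",
          "cytokmer_validation_error")
  pooled_ss <- sum((av - mean(av))^2) + sum((bv - mean(bv))^2)
  .assert(pooled_ss > 0 || !var_equal, "zero pooled variance",
          "cytokmer_degenerate_variance_error")
  tt <- t.test(av, bv, var.equal = var_equal)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_diff = mean(av) - mean(bv),
                 low_confidence = low_conf),
            class = "t_result")
}

#' @export
print.t_result <- function(x, ...) {
  cat(sprintf("<t_result> t = %.4f, df = %.4g, p = %.4g, diff = %.4f%s\n",
              x$t, x$df, x$p_value, x$mean_diff,
              if (x$low_confidence) " [low confidence: n = 1 group]" else ""))
  invisible(x)
}
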