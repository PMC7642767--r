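#' Bundled C-value survey tables
#'
#' Loads the packaged example dataset: flow-cytometric genome-size
#' summaries for both sexes of 17 Caelifera (grasshopper) species, the
#' per-species sex-difference tests, and a two-species comparison between
#' flow-cytometric and k-mer C-value estimates. These tables drive the
#' study-level statistics in [study_stats()] and serve as a worked example
#' throughout the documentation.
#'
#' @return list with data.frames `flow` (species, sex, mean_1c, genome_mb,
#'   se_mb, n, standard), `sex` (species, female_pg, n_female, male_pg,
#'   n_male, p_value) and `methods` (species, n_fcm, sd_fcm, fcm_pg,
#'   kmer_pg, p_value).
#' @export
load_study_tables <- function() {
  get1 <- function(f) read.csv(system.file("extdata", f, package = "cytokmer",
                                           mustWork = TRUE),
                               stringsAsFactors = FALSE)
  list(flow = get1("caelifera_flow_cytometry_summaries.csv"),
       sex = get1("caelifera_sex_differences.csv"),
       methods = get1("caelifera_method_comparison.csv"))
}

#' Study-level summary statistics over a C-value table
#'
#' Computes the headline numbers of a multi-species C-value survey from a
#' table of per-species, per-sex summaries: the overall mean 1C across all
#' sex-specific values, the extremes with their species, the fold range
#' (max/min), the per-species female minus male differences with their
#' minimum, maximum and unweighted mean, and — when a method table is
#' supplied — the per-species flow-cytometry minus k-mer differences.
#' pg statistics are rounded to 2 decimals for reporting; internal
#' arithmetic is unrounded.
#'
#' @param flow data.frame with at least `species`, `sex` (`F`/`M`) and
#'   `mean_1c` (pg) — the shape of [load_study_tables()]`$flow`.
#' @param methods optional data.frame with `species`, `fcm_pg`, `kmer_pg`.
#' @return list of class `study_stats`: `overall_mean_1c`, `min_1c`,
#'   `min_species`, `max_1c`, `max_species`, `fold_range`,
#'   `sex_differences` (data.frame), `min_sex_difference`,
#'   `max_sex_difference`, `mean_sex_difference`, `method_differences`,
#'   `footnote`.
#' @export
study_stats <- function(flow, methods = NULL) {
  .assert(is.data.frame(flow) && nrow(flow) > 0, "empty study table",
          "cytokmer_validation_error")
  .assert(all(c("species", "sex", "mean_1c") %in% names(flow)),
          "study table needs columns species, sex, mean_1c",
          "cytokmer_validation_error")
  .assert(all(flow$mean_1c > 0), "1C values must be positive",
          "cytokmer_validation_error")
  i_min <- which.min(flow$mean_1c)
  i_max <- which.max(flow$mean_1c)

  fem <- flow[flow$sex == "F", ]
  mal <- flow[flow$sex == "M", ]
  both <- intersect(fem$species, mal$species)
  lonely <- setdiff(unique(flow$species), both)
  if (length(lonely)) {
    warning("species without both sexes skipped from sex differences: ",
            paste(lonely, collapse = ", "), call. = FALSE)
  }
  sexdiff <- data.frame(
    species = both,
    female_pg = fem$mean_1c[match(both, fem$species)],
    male_pg = mal$mean_1c[match(both, mal$species)]
  )
  sexdiff$difference_pg <- round(sexdiff$female_pg - sexdiff$male_pg, 2)

  methdiff <- NULL
  if (!is.null(methods) && nrow(methods) > 0) {
    .assert(all(c("species", "fcm_pg", "kmer_pg") %in% names(methods)),
            "method table needs columns species, fcm_pg, kmer_pg",
            "cytokmer_validation_error")
    methdiff <- data.frame(species = methods$species,
                           fcm_pg = methods$fcm_pg,
                           kmer_pg = methods$kmer_pg,
                           difference_pg = round(
                             methods$fcm_pg - methods$kmer_pg, 2))
  }

  structure(
    list(overall_mean_1c = round(mean(flow$mean_1c), 2),
         min_1c = flow$mean_1c[i_min], min_species = flow$species[i_min],
         max_1c = flow$mean_1c[i_max], max_species = flow$species[i_max],
         fold_range = round(flow$mean_1c[i_max] / flow$mean_1c[i_min], 2),
         sex_differences = sexdiff,
         min_sex_difference = if (nrow(sexdiff)) min(sexdiff$difference_pg)
           else NA_real_,
         max_sex_difference = if (nrow(sexdiff)) max(sexdiff$difference_pg)
           else NA_real_,
         mean_sex_difference = if (nrow(sexdiff))
           round(mean(sexdiff$difference_pg), 2) else NA_real_,
         method_differences = methdiff,
         footnote = paste(
           "mean_sex_difference is the unweighted mean of per-species",
           "(female - male) differences computed from rounded summary",
           "values; surveys sometimes report a smaller average computed",
           "from unrounded or replicate-weighted data")),
    class = "study_stats"
  )
}

#' @export
print.study_stats <- function(x, ...) {
  cat(sprintf("<study_stats> mean 1C = %.2f pg | range %.2f (%s) - %.2f (%s), %.2f-fold\n",
              x$overall_mean_1c, x$min_1c, x$min_species, x$max_1c,
              x$max_species, x$fold_range))
  if (nrow(x$sex_differences)) {
    cat(sprintf("  sex difference (F - M): min %.2f, max %.2f, mean %.2f pg\n",
                x$min_sex_difference, x$max_sex_difference,
                x$mean_sex_difference))
  }
  if (!is.null(x$method_differences)) {
    cat("  method difference (FCM - kmer):",
        paste(sprintf("%s %.2f pg", x$method_differences$species,
                      x$method_differences$difference_pg), collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' Per-species sex-difference t-tests on replicate estimates
#'
#' Groups replicate 1C estimates by species and sex and runs the pooled
#' two-sample t-test of [students_t()] for every species with both sexes
#' present (species with one sex are skipped with a warning). The n = 1
#' case is handled by pooled variance from the larger group and flagged
#' low-confidence.
#'
#' @param estimates data.frame with columns `species`, `sex` (`F`/`M`) and
#'   `one_c_pg` — one row per replicate.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame: `species`, `female_pg`, `male_pg`, `difference_pg`
#'   (mean F - mean M), `t`, `df`, `p_value`, `significant`,
#'   `low_confidence`.
#' @export
sex_difference_tests <- function(estimates, alpha = 0.05) {
  .assert(is.data.frame(estimates) &&
            all(c("species", "sex", "one_c_pg") %in% names(estimates)),
          "need columns species, sex, one_c_pg",
          "cytokmer_validation_error")
  out <- list()
  for (sp in unique(estimates$species)) {
    f <- estimates$one_c_pg[estimates$species == sp & estimates$sex == "F"]
    m <- estimates$one_c_pg[estimates$species == sp & estimates$sex == "M"]
    if (!length(f) || !length(m)) {
      warning("species with one sex missing skipped: ", sp, call. = FALSE)
      next
    }
    tt <- students_t(f, m)
    out[[sp]] <- data.frame(
      species = sp, female_pg = mean(f), male_pg = mean(m),
      difference_pg = tt$mean_diff, t = tt$t, df = tt$df,
      p_value = tt$p_value, significant = tt$p_value < alpha,
      low_confidence = tt$low_confidence)
  }
  .assert(length(out) > 0, "no species with both sexes",
          "cytokmer_validation_error")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates whichever stages the configuration names and writes their
#' tables plus a JSON summary and a run log to `out_dir`. Recognized
#' stages:
#' \describe{
#'   \item{`fcm`}{`event_csvs` (character vector), `species`, `sex` and
#'     `standard_1c` (vectors parallel to `event_csvs`),
#'     `expected_sample_range` (pg pair); optional `n_channels`,
#'     `smooth_window`, `cv_max`. Produces `estimates.csv` and
#'     `summary.csv`.}
#'   \item{`kmer`}{`histograms` (paths to two-column depth/count files) and
#'     `k`. Produces `kmer_report.csv`.}
#'   \item{`phylo`}{`tree` (Newick path), `traits` (species,value CSV),
#'     optional `n_perm`, `seed`. Produces `phylo_signal.json`.}
#'   \item{`tables`}{`use_packaged = TRUE` or paths `flow`/`methods`.
#'     Produces `study_stats.json`.}
#' }
#'
#' @param config list, or path to a YAML file with the structure above.
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a list with each stage's in-memory results and the
#'   paths written.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1) {
    .assert(file.exists(config), paste("config file not found:", config),
            "cytokmer_usage_error")
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    config <- rapply(config, function(p) {
      if (is.character(p) && !grepl("^(/|[A-Za-z]:)", p)) file.path(base, p)
      else p
    }, classes = "character", how = "replace")
  }
  .assert(is.list(config) && length(config) > 0 &&
            any(c("fcm", "kmer", "phylo", "tables") %in% names(config)),
          "usage: config must name at least one stage (fcm/kmer/phylo/tables)",
          "cytokmer_usage_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("cytokmer %s",
                         as.character(utils::packageVersion("cytokmer"))),
                 sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("config hash %s",
                         substr(digest_config(config), 1, 12)))
  results <- list()
  paths <- character()

  if (!is.null(config$fcm)) {
    fc <- config$fcm
    .assert(!is.null(fc$event_csvs) && !is.null(fc$expected_sample_range),
            "fcm stage needs 'event_csvs' and 'expected_sample_range'",
            "cytokmer_usage_error")
    nfile <- length(fc$event_csvs)
    rows <- vector("list", nfile)
    for (i in seq_len(nfile)) {
      et <- read_event_csv(fc$event_csvs[i],
                           species = (fc$species %||% rep(NA, nfile))[i],
                           sex = (fc$sex %||% rep(NA, nfile))[i],
                           standard_1c = fc$standard_1c[i])
      h <- build_histogram(et, n_channels = fc$n_channels %||% 1024)
      pk <- detect_and_fit_peaks(h, smooth_window = fc$smooth_window %||% 5,
                                 events = et)
      cl <- classify_peaks(pk, et$standard_1c,
                           unlist(fc$expected_sample_range))
      est <- estimate_gs(cl[cl$source == "sample" & cl$ploidy_label == "2C", ],
                         cl[cl$source == "standard" & cl$ploidy_label == "2C", ],
                         et$standard_1c, cv_max = fc$cv_max %||% 5,
                         replicate_id = et$replicate_id)
      rows[[i]] <- data.frame(
        replicate_id = et$replicate_id, species = et$species, sex = et$sex,
        standard_1c = et$standard_1c, one_c_pg = est$one_c,
        genome_mb = est$genome_mb,
        cv_sample = est$sample_peak$cv, cv_standard = est$standard_peak$cv,
        qc_pass = est$qc_pass)
    }
    est_df <- do.call(rbind, rows)
    grp <- split(est_df, paste(est_df$species, est_df$sex))
    summ <- do.call(rbind, lapply(grp, function(g) {
      ok <- g[g$qc_pass, ]
      n <- nrow(ok)
      data.frame(species = g$species[1], sex = g$sex[1],
                 mean_1c = round(mean(ok$one_c_pg), 2),
                 genome_mb = round(pg_to_mb(mean(ok$one_c_pg))),
                 se_mb = if (n >= 2)
                   round(pg_to_mb(sd(ok$one_c_pg) / sqrt(n))) else NA_real_,
                 n = n)
    }))
    rownames(summ) <- NULL
    write.csv(est_df, file.path(out_dir, "estimates.csv"), row.names = FALSE)
    write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
    paths <- c(paths, file.path(out_dir, c("estimates.csv", "summary.csv")))
    results$fcm <- list(estimates = est_df, summary = summ)
    log_lines <- c(log_lines, sprintf("fcm: %d replicates -> %d summary rows",
                                      nrow(est_df), nrow(summ)))
  }

  if (!is.null(config$kmer)) {
    km <- config$kmer
    .assert(!is.null(km$histograms), "kmer stage needs 'histograms'",
            "cytokmer_usage_error")
    k <- km$k %||% 21
    rep_rows <- lapply(km$histograms, function(p) {
      r <- kmer_report(read_spectrum(p, k = k))
      data.frame(histogram = p, k = r$k, error_cutoff = r$error_cutoff,
                 d_hom = r$d_hom, genome_bp = r$genome_size_bp,
                 genome_pg = r$genome_size_pg,
                 repeat_fraction = r$repeat_fraction,
                 heterozygosity = r$heterozygosity)
    })
    kdf <- do.call(rbind, rep_rows)
    write.csv(kdf, file.path(out_dir, "kmer_report.csv"), row.names = FALSE)
    paths <- c(paths, file.path(out_dir, "kmer_report.csv"))
    results$kmer <- kdf
    log_lines <- c(log_lines, sprintf("kmer: %d spectra (k = %d)",
                                      nrow(kdf), k))
  }

  if (!is.null(config$phylo)) {
    ph <- config$phylo
    .assert(!is.null(ph$tree) && !is.null(ph$traits),
            "phylo stage needs 'tree' and 'traits'", "cytokmer_usage_error")
    tree <- ape::read.tree(ph$tree)
    x <- read_trait_csv(ph$traits)
    lf <- fit_lambda(tree, x)
    kp <- k_permutation_p(tree, x, n_perm = ph$n_perm %||% 999,
                          seed = ph$seed %||% 1)
    sig <- list(lambda_hat = lf$lambda_hat, logL_max = lf$logL_max,
                logL_lambda0 = lf$logL_lambda0,
                logL_lambda1 = lf$logL_lambda1,
                p_vs_0 = lf$p_vs_0, p_vs_1 = lf$p_vs_1,
                K = kp$K, p_perm = kp$p_perm, n_perm = kp$n_perm,
                seed = kp$seed)
    jsonlite::write_json(sig, file.path(out_dir, "phylo_signal.json"),
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, file.path(out_dir, "phylo_signal.json"))
    results$phylo <- sig
    log_lines <- c(log_lines,
                   sprintf("phylo: lambda = %.3f, K = %.3f (seed %d)",
                           lf$lambda_hat, kp$K, kp$seed))
  }

  if (!is.null(config$tables)) {
    tb <- config$tables
    if (isTRUE(tb$use_packaged)) {
      tabs <- load_study_tables()
      flow <- tabs$flow
      methods <- tabs$methods
    } else {
      flow <- read.csv(tb$flow, stringsAsFactors = FALSE)
      methods <- if (!is.null(tb$methods))
        read.csv(tb$methods, stringsAsFactors = FALSE) else NULL
    }
    st <- study_stats(flow, methods)
    jsonlite::write_json(
      list(overall_mean_1c = st$overall_mean_1c, fold_range = st$fold_range,
           min_1c = st$min_1c, min_species = st$min_species,
           max_1c = st$max_1c, max_species = st$max_species,
           min_sex_difference = st$min_sex_difference,
           max_sex_difference = st$max_sex_difference,
           mean_sex_difference = st$mean_sex_difference,
           method_differences = st$method_differences,
           footnote = st$footnote),
      file.path(out_dir, "study_stats.json"), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, file.path(out_dir, "study_stats.json"))
    results$tables <- st
    log_lines <- c(log_lines, "tables: study statistics written")
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(c(results, list(paths = paths)))
}

# stable hash of a config list for the run log
digest_config <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(config, file = tf)
  unname(tools::md5sum(tf))
}
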