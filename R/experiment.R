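# Study orchestration: grouping plots into the canonical model families
# (treatment-level 32, development-stage 4, all-data 1), running the PLSR
# ensemble and the NDSI screen per group, cross-condition validation for the
# stages measured under opposite skies in the two replicates, and a
# residual-vs-condition check.

#' Canonical grouping factor sets
#'
#' `"treatment"` = stage x row spacing x tillage x replicate (cultivars
#' pooled; 4 x 2 x 2 x 2 = 32 groups on the canonical design),
#' `"stage"` = development stage (4 groups), `"pooled"` = everything together
#' (1 group). The treatment-level factorisation is switchable: any factor
#' subset can be passed to [build_groups()] directly.
#'
#' @param level one of `"treatment"`, `"stage"`, `"pooled"`.
#' @return Character vector of grouping factors (empty for pooled).
#' @export
grouping_factors <- function(level = c("treatment", "stage", "pooled")) {
  switch(match.arg(level),
         treatment = c("stage", "row_spacing", "tillage", "replicate"),
         stage = "stage",
         pooled = character())
}

#' Partition plots into model groups
#'
#' @param plots plot-record table.
#' @param factors character vector of grouping columns (empty = one pooled
#'   group named `"all"`).
#' @return Named list of integer row-index vectors into `plots`.
#' @export
build_groups <- function(plots, factors) {
  missing_f <- setdiff(factors, names(plots))
  if (length(missing_f) > 0L)
    stop("unknown grouping factor(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  if (length(factors) == 0L)
    return(list(all = seq_len(nrow(plots))))
  key <- do.call(paste, c(lapply(factors, function(f) plots[[f]]), sep = "|"))
  groups <- split(seq_len(nrow(plots)), key)
  if (any(lengths(groups) == 0L))
    stop("empty group in partition", call. = FALSE)
  groups[order(names(groups))]
}

#' Residual-vs-sky-condition check
#'
#' Compares ensemble residuals (predicted - measured) between cloudy and
#' sunny plots: difference in means with a two-sided permutation p-value.
#' Report-only; no pass/fail gate.
#'
#' @param result an `ensemble_result` (or any list with a `per_sample`
#'   data.frame containing `plot_id`, `measured`, `mean_predicted`).
#' @param plots plot table with `plot_id` and `condition`.
#' @param n_perm number of permutations (>= 999 recommended).
#' @param seed permutation seed.
#' @return List with `mean_residual_diff` (cloudy minus sunny), `p_value`,
#'   `n_sunny`, `n_cloudy`; or a `skipped` note for single-condition groups.
#' @export
residual_condition_check <- function(result, plots, n_perm = 999L, seed = 1L) {
  ps <- result$per_sample
  cond <- plots$condition[match(ps$plot_id, plots$plot_id)]
  ok <- !is.na(ps$mean_predicted) & !is.na(cond)
  resid <- (ps$mean_predicted - ps$measured)[ok]
  cond <- cond[ok]
  if (length(unique(cond)) < 2L)
    return(list(skipped = "single-condition group",
                mean_residual_diff = NA_real_, p_value = NA_real_))
  is_cloudy <- cond == "cloudy"
  obs <- mean(resid[is_cloudy]) - mean(resid[!is_cloudy])
  perm <- local_seed(seed, vapply(seq_len(n_perm), function(i) {
    g <- sample(is_cloudy)
    mean(resid[g]) - mean(resid[!g])
  }, numeric(1)))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(mean_residual_diff = obs, p_value = p,
       n_sunny = sum(!is_cloudy), n_cloudy = sum(is_cloudy))
}

#' Default study configuration
#'
#' All knobs of [run_study()] in one list: master seed, ensemble iterations
#' and topology, grouping levels, NDSI settings, and the simulator design
#' (used when no input CSVs are given). Override any entry via `...` or load
#' from YAML/JSON with [read_study_config()].
#'
#' @param ... named overrides of the defaults.
#' @return A config list.
#' @export
study_config <- function(...) {
  cfg <- list(
    seed = 1L,
    iterations = 100L,
    groupings = c("treatment", "stage", "pooled"),
    topology = "per-iteration",
    refit = "pool",
    max_components = 15L,
    holdout_fraction = 0.25,
    cal_fraction = 0.75,
    ndsi_pair = c(565, 710),
    ndsi_top_k = 10L,
    K = 1,
    min_irradiance = 1,
    n_perm = 999L,
    sequences_csv = NULL,
    plots_csv = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

#' Read a study configuration from YAML or JSON
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A config list merged over [study_config()] defaults.
#' @export
read_study_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(study_config, vals)
}

run_group_models <- function(X, y, ids, cfg, group_seed) {
  ens <- run_ensemble(X, y, iterations = cfg$iterations,
                      holdout_fraction = cfg$holdout_fraction,
                      cal_fraction = cfg$cal_fraction,
                      seed = group_seed, ids = ids,
                      topology = cfg$topology, refit = cfg$refit,
                      max_components = cfg$max_components)
  scan <- scan_ndsi(X, y)
  ndsi_x <- matrix(ndsi_value(X, as.numeric(colnames(X)),
                              cfg$ndsi_pair[1], cfg$ndsi_pair[2]),
                   ncol = 1L, dimnames = list(ids, "ndsi"))
  ndsi_ens <- run_ensemble(ndsi_x, y, iterations = cfg$iterations,
                           holdout_fraction = cfg$holdout_fraction,
                           cal_fraction = cfg$cal_fraction,
                           seed = derive_seed(group_seed, 7L), ids = ids,
                           topology = cfg$topology, refit = cfg$refit,
                           max_components = 1L)
  list(n_plots = length(y),
       plsr = ens,
       ndsi_top10 = head(scan, 10L),
       ndsi_pair_rank = pair_rank(scan, cfg$ndsi_pair),
       ndsi_model = ndsi_ens)
}

#' Run the full study
#'
#' Simulates (or loads) the trial, processes it to plot-mean analysis
#' spectra, then for every group of every requested grouping level fits the
#' resampled PLSR ensemble, runs the exhaustive NDSI screen, and fits the
#' configured single-pair NDSI model through the same resampling ensemble.
#' Stages whose two replicates were measured under opposite sky conditions
#' are cross-validated in both directions (sunny to cloudy and cloudy to
#' sunny), and stage-level ensembles get a residual-vs-condition check.
#' Deterministic from `config$seed`; the report carries no timestamps.
#'
#' @param config a [study_config()] list.
#' @param trial optional pre-generated `sim_trial` (else simulated from
#'   `config$seed`, or read from the configured CSVs).
#' @return An object of class `study_report`.
#' @export
run_study <- function(config = study_config(), trial = NULL) {
  cfg <- config
  if (is.null(trial)) {
    if (!is.null(cfg$sequences_csv)) {
      sequences <- read_sequences_csv(cfg$sequences_csv)
      plots <- read_plots_csv(cfg$plots_csv)
      trial <- list(plots = plots, sequences = sequences,
                    sensor = sensor_model())
    } else {
      trial <- generate_trial(trial_design(seed = cfg$seed))
    }
  }
  proc <- process_trial(trial, tm = throughput_model(K = cfg$K),
                        min_irradiance = cfg$min_irradiance)
  X <- proc$spectra
  plots <- proc$plots
  y <- plots$measured_population

  report_groups <- list()
  scans_by_level <- list()
  for (li in seq_along(cfg$groupings)) {
    level <- cfg$groupings[[li]]
    groups <- build_groups(plots, grouping_factors(level))
    level_out <- list()
    for (gi in seq_along(groups)) {
      idx <- groups[[gi]]
      gname <- names(groups)[gi]
      res <- run_group_models(X[idx, , drop = FALSE], y[idx],
                              plots$plot_id[idx], cfg,
                              derive_seed(cfg$seed, li * 1000L + gi))
      if (level == "stage")
        res$residual_condition <- residual_condition_check(
          res$plsr, plots, n_perm = cfg$n_perm,
          seed = derive_seed(cfg$seed, 500L + gi))
      level_out[[gname]] <- res
    }
    report_groups[[level]] <- level_out
    scans_by_level[[level]] <- lapply(level_out, `[[`, "ndsi_top10")
  }

  # cross-condition stages: replicates measured under opposite skies
  cross <- list()
  for (st in unique(plots$stage)) {
    sub <- plots[plots$stage == st, , drop = FALSE]
    conds <- tapply(sub$condition, sub$replicate, function(z) unique(z)[1])
    if (length(unique(conds)) < 2L) next
    reps <- names(conds)
    dir_res <- list()
    for (d in 1:2) {
      tr <- reps[d]; te <- reps[3 - d]
      tr_idx <- which(plots$stage == st & plots$replicate == as.integer(tr))
      te_idx <- which(plots$stage == st & plots$replicate == as.integer(te))
      cv <- cross_condition_validate(
        X[tr_idx, , drop = FALSE], y[tr_idx],
        X[te_idx, , drop = FALSE], y[te_idx],
        train_ids = plots$plot_id[tr_idx], test_ids = plots$plot_id[te_idx],
        iterations = cfg$iterations,
        seed = derive_seed(cfg$seed, 9000L + match(st, unique(plots$stage)) * 10L + d),
        cal_fraction = cfg$cal_fraction,
        max_components = cfg$max_components)
      dir_res[[paste0(conds[[tr]], "_to_", conds[[te]])]] <-
        list(train_replicate = as.integer(tr), metrics = cv$metrics)
    }
    cross[[st]] <- dir_res
  }

  # top-pair membership across the treatment-level datasets
  pair_freq <- if ("treatment" %in% names(report_groups)) {
    ranks <- vapply(report_groups$treatment,
                    function(g) as.numeric(g$ndsi_pair_rank), numeric(1))
    list(pair = cfg$ndsi_pair, k = cfg$ndsi_top_k,
         count = sum(!is.na(ranks) & ranks <= cfg$ndsi_top_k),
         n_datasets = length(ranks))
  } else NULL

  structure(list(
    config = cfg[setdiff(names(cfg), c("sequences_csv", "plots_csv"))],
    n_plots = nrow(plots),
    groups = report_groups,
    cross_condition = cross,
    ndsi_pair_frequency = pair_freq
  ), class = "study_report")
}

#' Write a study report to JSON
#'
#' Deterministic serialisation (full precision, no timestamps): rerunning
#' [run_study()] with the same config yields a byte-identical file.
#'
#' @param report a `study_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
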