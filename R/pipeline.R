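#' Configuration of a full analysis run
#'
#' Bundles every choice the pipeline needs: where the tables come from (the
#' synthetic generator, or CSV paths), the indicator direction map, the
#' component retention rule, the SYI standard-deviation convention, the
#' pairwise-comparison family, and the forest settings. A master `seed`
#' drives every stochastic stage through a fixed splitting rule: the yield
#' generator uses `seed`, the soil generator `seed + 1`, and the two forest
#' fits `seed + 2000` and `seed + 3000`.
#'
#' @param generator A [trial_config()] (used when `input` is `NULL`).
#' @param input Optional list with CSV paths `yields` and `soil`; exactly
#'   one of generator/input feeds each run.
#' @param direction_overrides Passed to [soil_indicators()].
#' @param retention,pca_on Passed to [soil_quality()].
#' @param sd_mode Passed to [yield_sustainability()].
#' @param method,alpha Passed to [pairwise_letters()].
#' @param n_trees,n_permutations Forest settings (see [importance_config()]).
#' @param seed Master seed; overrides the generator's own seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(generator = trial_config(), input = NULL,
                       direction_overrides = NULL, retention = "kaiser",
                       pca_on = "raw", sd_mode = "sample",
                       method = "tukey", alpha = 0.05,
                       n_trees = 1000L, n_permutations = 99L, seed = 1L) {
  seed <- as.integer(seed)
  if (is.na(seed)) sq_config_error("seed must be an integer")
  if (!is.null(input)) {
    if (!all(c("yields", "soil") %in% names(input))) {
      sq_config_error("input must name 'yields' and 'soil' CSV paths")
    }
    for (p in unlist(input)) {
      if (!file.exists(p)) sq_config_error(sprintf("input file not found: %s", p))
    }
    generator <- NULL
  } else {
    stopifnot(inherits(generator, "trial_config"))
    generator$seed <- seed
  }
  structure(list(generator = generator, input = input,
                 direction_overrides = direction_overrides,
                 retention = retention, pca_on = pca_on, sd_mode = sd_mode,
                 method = method, alpha = alpha,
                 n_trees = as.integer(n_trees),
                 n_permutations = as.integer(n_permutations),
                 seed = seed),
            class = "run_config")
}

#' @keywords internal
#' Full-precision CSV writer for pipeline intermediates, so downstream
#' stages re-reading them lose nothing.
write_table_full <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- sprintf("%.17g", out[[nm]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @keywords internal
pipeline_stages <- function() c("simulate", "score", "indices", "stats",
                                "importance", "report")

#' @keywords internal
#' Which files each stage produces (used for dependency checks and the
#' manifest).
stage_outputs <- function() {
  list(
    simulate   = c("yields.csv", "soil.csv", "resolved_config.yaml"),
    score      = c("scores.csv", "weights.csv"),
    indices    = c("sqi_plots.csv", "sqi_treatments.csv", "syi_plots.csv",
                   "syi_treatments.csv", "mean_yield_treatments.csv",
                   "mean_yield_plots.csv"),
    stats      = c("anova_summary.csv", "letters.csv", "assumptions.csv",
                   "correlation_r.csv", "correlation_p.csv",
                   "correlation_stars.csv", "regression.csv"),
    importance = c("importance_mean_yield.csv", "importance_syi.csv",
                   "importance_models.csv"),
    report     = "report.md"
  )
}

#' @keywords internal
require_upstream <- function(out_dir, files, producer) {
  missing <- files[!file.exists(file.path(out_dir, files))]
  if (length(missing) > 0) {
    sq_stage_error(sprintf(
      "missing upstream output(s) %s; run the '%s' stage first",
      paste(missing, collapse = ", "), producer
    ), stage = producer)
  }
}

#' Run the end-to-end trial analysis
#'
#' Executes the stages in order — simulate (or load), score, indices, stats,
#' importance, report — writing every intermediate as plain CSV under
#' `out_dir`, followed by a deterministic `manifest.json` (resolved
#' configuration, package version, per-file MD5 checksums, collected
#' warnings) and a `run.log` with stage wall times (the log is the one
#' non-deterministic file and is excluded from the manifest). With the same
#' configuration and master seed, two runs produce byte-identical artifact
#' files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param stage `"all"` (default) or a single stage name for a partial,
#'   resumable run; each stage checks that its upstream files exist and
#'   names the producing stage if not.
#' @param quiet Suppress progress messages.
#' @return `out_dir`, invisibly.
#' @export
#' @examples
#' \donttest{
#' dir <- file.path(tempdir(), "trial-run")
#' run_pipeline(run_config(seed = 1, n_trees = 100), dir)
#' list.files(dir)
#' }
run_pipeline <- function(config = run_config(), out_dir,
                         stage = c("all", pipeline_stages()), quiet = FALSE) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") pipeline_stages() else stage
  warnings_seen <- character(0)
  timings <- numeric(0)
  say <- function(...) if (!quiet) message(sprintf(...))

  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    say("stage: %s", st)
    withCallingHandlers(
      tryCatch(
        do.call(paste0("stage_", st), list(config = config, out_dir = out_dir)),
        soilqi_error = function(e) stop(e),
        error = function(e) {
          sq_stage_error(sprintf("stage '%s' failed: %s", st, conditionMessage(e)),
                         stage = st)
        }
      ),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, sprintf("[%s] %s", st, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    timings[st] <- proc.time()[["elapsed"]] - t0
  }

  # manifest: deterministic (no wall times); timings go to run.log
  produced <- unlist(stage_outputs(), use.names = FALSE)
  present <- produced[file.exists(file.path(out_dir, produced))]
  checksums <- as.list(tools::md5sum(file.path(out_dir, present)))
  names(checksums) <- present
  manifest <- list(
    package = "soilqi",
    version = as.character(utils::packageVersion("soilqi")),
    seed = config$seed,
    config = config_to_list(config),
    stages_run = stages,
    files = checksums,
    warnings = warnings_seen
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  cat(sprintf("%s: %.2fs\n", names(timings), timings), sep = "",
      file = file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @keywords internal
config_to_list <- function(config) {
  g <- config$generator
  list(
    source = if (is.null(config$input)) "generator" else "files",
    input = config$input,
    generator = if (is.null(g)) NULL else list(
      seed = g$seed, n_blocks = g$n_blocks, years = g$years,
      yield_model = g$yield_model, block_sd = g$block_sd,
      indicator_means = as.data.frame(g$indicator_means),
      indicator_cv = as.list(g$indicator_cv), rho = g$rho, shock = g$shock
    ),
    direction_overrides = config$direction_overrides,
    retention = config$retention, pca_on = config$pca_on,
    sd_mode = config$sd_mode, method = config$method, alpha = config$alpha,
    n_trees = config$n_trees, n_permutations = config$n_permutations,
    seed = config$seed
  )
}

#' @keywords internal
stage_simulate <- function(config, out_dir) {
  if (is.null(config$input)) {
    yields <- simulate_yields(config$generator)
    soil <- simulate_soil(config$generator)
    yaml::write_yaml(config_to_list(config)$generator,
                     file.path(out_dir, "resolved_config.yaml"))
  } else {
    yields <- read_yield_table(config$input$yields)
    soil <- read_soil_table(config$input$soil)
    yaml::write_yaml(config_to_list(config)["input"],
                     file.path(out_dir, "resolved_config.yaml"))
  }
  rep <- validate_design(yields, soil)
  if (nrow(rep) > 0) {
    warning(sprintf("design check found %d issue(s); first: %s",
                    nrow(rep), rep$detail[1]), call. = FALSE)
  }
  write_yield_table(yields, file.path(out_dir, "yields.csv"))
  write_soil_table(soil, file.path(out_dir, "soil.csv"))
}

#' @keywords internal
stage_score <- function(config, out_dir) {
  require_upstream(out_dir, "soil.csv", "simulate")
  soil <- read_soil_table(file.path(out_dir, "soil.csv"))
  meta <- soil_indicators(config$direction_overrides)
  fit <- soil_quality(soil, meta = meta, retention = config$retention,
                      pca_on = config$pca_on)
  sc <- as.data.frame(fit$scores$scores)
  sc <- cbind(data.frame(plot_id = fit$scores$plot_id,
                         treatment = as.character(fit$scores$treatment),
                         stringsAsFactors = FALSE), sc)
  write_table_full(sc, file.path(out_dir, "scores.csv"))
  w <- summary(fit)$weights
  w$eigenvalue <- fit$communality$eigenvalues[seq_len(nrow(w))]
  w$retained_component <- seq_len(nrow(w)) %in% fit$communality$retained
  write_table_full(w, file.path(out_dir, "weights.csv"))
}

#' @keywords internal
stage_indices <- function(config, out_dir) {
  require_upstream(out_dir, c("scores.csv", "weights.csv"), "score")
  require_upstream(out_dir, "yields.csv", "simulate")
  sc_df <- utils::read.csv(file.path(out_dir, "scores.csv"))
  w_df <- utils::read.csv(file.path(out_dir, "weights.csv"))
  inds <- intersect(indicator_names(), names(sc_df))
  scores <- structure(list(
    scores = as.matrix(sc_df[, inds, drop = FALSE]),
    plot_id = sc_df$plot_id, treatment = as_treatment(sc_df$treatment)
  ), class = "score_matrix")
  res <- compute_sqi(scores, stats::setNames(w_df$weight, w_df$indicator))
  write_table_full(res$plot, file.path(out_dir, "sqi_plots.csv"))
  write_table_full(res$treatment, file.path(out_dir, "sqi_treatments.csv"))

  yields <- read_yield_table(file.path(out_dir, "yields.csv"))
  ys <- yield_sustainability(yields, sd_mode = config$sd_mode)
  write_table_full(ys$plot[, c("plot_id", "treatment", "syi")],
                   file.path(out_dir, "syi_plots.csv"))
  write_table_full(group_mean_se(ys$plot$syi, ys$plot$treatment, "syi"),
                   file.path(out_dir, "syi_treatments.csv"))
  write_table_full(group_mean_se(ys$plot$mean_yield, ys$plot$treatment, "yield"),
                   file.path(out_dir, "mean_yield_treatments.csv"))
  write_table_full(ys$plot[, c("plot_id", "treatment", "mean_yield")],
                   file.path(out_dir, "mean_yield_plots.csv"))
}

#' @keywords internal
#' Per-plot response table joining soil indicators, mean yield, SQI, SYI.
load_responses <- function(out_dir) {
  soil <- read_soil_table(file.path(out_dir, "soil.csv"))
  sqi <- utils::read.csv(file.path(out_dir, "sqi_plots.csv"))
  syi <- utils::read.csv(file.path(out_dir, "syi_plots.csv"))
  my <- utils::read.csv(file.path(out_dir, "mean_yield_plots.csv"))
  d <- merge(merge(merge(soil, sqi[, c("plot_id", "sqi")], by = "plot_id"),
                   syi[, c("plot_id", "syi")], by = "plot_id"),
             my[, c("plot_id", "mean_yield")], by = "plot_id")
  d[order(match(d$plot_id, soil$plot_id)), ]
}

#' @keywords internal
stage_stats <- function(config, out_dir) {
  require_upstream(out_dir, c("sqi_plots.csv", "syi_plots.csv",
                              "mean_yield_plots.csv"), "indices")
  require_upstream(out_dir, "soil.csv", "simulate")
  d <- load_responses(out_dir)
  responses <- c(indicator_names(), "mean_yield", "sqi", "syi")

  an <- lapply(responses, function(r) {
    a <- one_way_anova(d[[r]], d$treatment, response = r)
    data.frame(index = r, df = a$df_between, F_value = a$F, P_value = a$p,
               stringsAsFactors = FALSE)
  })
  write_table_full(do.call(rbind, an), file.path(out_dir, "anova_summary.csv"))

  lt <- lapply(responses, function(r) {
    l <- pairwise_letters(d[[r]], d$treatment, method = config$method,
                          alpha = config$alpha)
    data.frame(index = r, treatment = names(l$letters),
               mean = unname(l$means[names(l$letters)]),
               letters = unname(l$letters), stringsAsFactors = FALSE)
  })
  write_table_full(do.call(rbind, lt), file.path(out_dir, "letters.csv"))

  as_rows <- lapply(responses, function(r) {
    rep <- check_assumptions(d[[r]], d$treatment, alpha = config$alpha)
    data.frame(index = r,
               shapiro_all_pass = all(rep$shapiro$pass[rep$shapiro$assessable]),
               shapiro_assessable = all(rep$shapiro$assessable),
               levene_F = rep$levene$statistic, levene_p = rep$levene$p,
               levene_pass = rep$levene$pass, stringsAsFactors = FALSE)
  })
  write_table_full(do.call(rbind, as_rows), file.path(out_dir, "assumptions.csv"))

  vars <- c(indicator_names(), "mean_yield", "sqi", "syi")
  pm <- pearson_matrix(d, vars)
  write_table_full(cbind(variable = rownames(pm$r), as.data.frame(pm$r)),
                   file.path(out_dir, "correlation_r.csv"))
  write_table_full(cbind(variable = rownames(pm$p), as.data.frame(pm$p)),
                   file.path(out_dir, "correlation_p.csv"))
  utils::write.csv(cbind(variable = rownames(pm$stars), as.data.frame(pm$stars)),
                   file.path(out_dir, "correlation_stars.csv"), row.names = FALSE)

  reg <- fit_linear(d$sqi, d$syi)
  write_table_full(data.frame(response = "syi", predictor = "sqi",
                              slope = reg$slope, intercept = reg$intercept,
                              r_squared = reg$r_squared, p = reg$p, n = reg$n),
                   file.path(out_dir, "regression.csv"))
}

#' @keywords internal
stage_importance <- function(config, out_dir) {
  require_upstream(out_dir, c("sqi_plots.csv", "syi_plots.csv",
                              "mean_yield_plots.csv"), "indices")
  require_upstream(out_dir, "soil.csv", "simulate")
  d <- load_responses(out_dir)
  X <- d[, indicator_names()]
  cfg_y <- importance_config(config$n_trees, config$n_permutations,
                             seed = config$seed + 2000L)
  cfg_s <- importance_config(config$n_trees, config$n_permutations,
                             seed = config$seed + 3000L)
  imp_y <- forest_importance(X, d$mean_yield, cfg_y, response_name = "mean_yield")
  imp_s <- forest_importance(X, d$syi, cfg_s, response_name = "syi")
  write_table_full(imp_y$table, file.path(out_dir, "importance_mean_yield.csv"))
  write_table_full(imp_s$table, file.path(out_dir, "importance_syi.csv"))
  write_table_full(data.frame(response = c("mean_yield", "syi"),
                              var_explained = c(imp_y$var_explained,
                                                imp_s$var_explained),
                              n_trees = config$n_trees,
                              n_permutations = config$n_permutations),
                   file.path(out_dir, "importance_models.csv"))
}

#' @keywords internal
stage_report <- function(config, out_dir) {
  require_upstream(out_dir, c("anova_summary.csv", "letters.csv", "regression.csv"),
                   "stats")
  require_upstream(out_dir, "importance_models.csv", "importance")
  an <- utils::read.csv(file.path(out_dir, "anova_summary.csv"))
  lt <- utils::read.csv(file.path(out_dir, "letters.csv"))
  reg <- utils::read.csv(file.path(out_dir, "regression.csv"))
  mods <- utils::read.csv(file.path(out_dir, "importance_models.csv"))
  md <- function(df) {
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(hdr, sep, rows)
  }
  head_lt <- lt[lt$index %in% c("mean_yield", "sqi", "syi"), ]
  head_lt$mean <- signif(head_lt$mean, 5)
  an$F_value <- signif(an$F_value, 6)
  an$P_value <- signif(an$P_value, 3)
  lines <- c(
    "# Trial analysis report", "",
    "## Treatment comparison (mean yield, SQI, SYI)", "",
    md(head_lt), "",
    "## One-way ANOVA summary", "",
    md(an), "",
    "## SQI-SYI regression", "",
    sprintf("y = %.5gx + %.5g, R^2 = %.5g, p = %.3g (n = %d)",
            reg$slope, reg$intercept, reg$r_squared, reg$p, reg$n), "",
    "## Random-forest models", "",
    md(transform(mods, var_explained = signif(var_explained, 4))), ""
  )
  writeLines(lines, file.path(out_dir, "report.md"))
}
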