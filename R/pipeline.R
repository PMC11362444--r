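#' Pipeline configuration
#'
#' Assembles (and validates) the settings of an end-to-end run: which
#' stages to execute, where to read/write, and every stage's tuning
#' parameters. Settings may also be given as a YAML/JSON file via
#' [read_pipeline_config()]; explicit arguments override file values.
#'
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "fit_irt", "score_errors", "code_complexity", "wpr",
#'   "tch", "report")` in dependency order.
#' @param input_dir directory holding `responses.csv`, `items.csv`,
#'   `cognition.csv` when `simulate` is disabled.
#' @param sim a [sim_config()] for the simulate stage.
#' @param seed integer seed for the whole run (overrides `sim$rng_seed`).
#' @param transform `"cube_root"` or `"none"` for the WPR/TCH stages.
#' @param min_items WPR minimum scored items per person.
#' @param cov_method WPR correlation-covariance estimator.
#' @param bootstrap_n resamples when `cov_method = "bootstrap"`.
#' @param n_quad GRM quadrature nodes.
#' @param grm_se,grm_fit_stats standard errors / SRMR-style summary per GRM.
#' @param latent_method `"joint"`, `"two_step"`, or `"auto"` (joint when
#'   enough persons have complete data, else the labeled two-step fallback).
#' @param wave which wave the WPR/TCH stages analyze (default 1).
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(stages = c("simulate", "fit_irt", "score_errors",
                                       "code_complexity", "wpr", "tch",
                                       "report"),
                            input_dir = NULL,
                            sim = sim_config(),
                            seed = 1L,
                            transform = "cube_root",
                            min_items = 10L,
                            cov_method = "influence",
                            bootstrap_n = 2000L,
                            n_quad = 61L,
                            grm_se = "none",
                            grm_fit_stats = FALSE,
                            latent_method = "auto",
                            wave = 1L) {
  all_stages <- c("simulate", "fit_irt", "score_errors", "code_complexity",
                  "wpr", "tch", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!"simulate" %in% stages && is.null(input_dir))
    stop("input_dir required when the simulate stage is disabled")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  seed <- as.integer(seed)
  sim$rng_seed <- seed
  out <- list(stages = stages, input_dir = input_dir, sim = sim, seed = seed,
              transform = transform, min_items = as.integer(min_items),
              cov_method = cov_method, bootstrap_n = as.integer(bootstrap_n),
              n_quad = as.integer(n_quad), grm_se = grm_se,
              grm_fit_stats = isTRUE(grm_fit_stats),
              latent_method = latent_method, wave = as.integer(wave))
  class(out) <- "pipeline_config"
  out
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file path; `.json` is parsed as JSON, anything else as YAML.
#' @param ... overrides passed to [pipeline_config()].
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  raw$sim <- do.call(sim_config, sim_args)
  over <- list(...)
  args <- modifyList(raw, over)
  do.call(pipeline_config, args)
}

stage_deps <- list(simulate = character(0),
                   fit_irt = character(0),
                   score_errors = "fit_irt",
                   code_complexity = character(0),
                   wpr = "score_errors",
                   tch = c("score_errors", "code_complexity"),
                   report = character(0))

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate (or load
#' input files), fit per-scale GRMs, score response errors, code item
#' complexity, run the worst-performance-rule analysis, fit the
#' task-complexity models, and write a report — and writes every stage's
#' artifacts plus a manifest (settings, seed, software version, per-stage
#' row counts, collected warnings) to `out_dir`. Reruns with an identical
#' config and inputs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(package = "resperr",
                   version = as.character(packageVersion("resperr")),
                   seed = config$seed,
                   stages = list(), warnings = list())
  # serialize settings (drop classes for clean JSON)
  manifest$settings <- lapply(unclass(config), function(x)
    if (inherits(x, "sim_config")) unclass(x) else x)
  grab <- function(stage, expr) {
    wl <- character(0)
    res <- withCallingHandlers(expr, warning = function(w) {
      wl <<- c(wl, conditionMessage(w)); invokeRestart("muffleWarning")
    })
    if (length(wl)) manifest$warnings[[stage]] <<- wl
    res
  }
  enabled <- function(s) s %in% config$stages
  require_dep <- function(stage) {
    for (dep in stage_deps[[stage]]) {
      if (!enabled(dep) && !stage_outputs_exist(dep, out_dir, config))
        stop("stage '", stage, "' requires outputs of disabled stage '",
             dep, "'")
    }
  }
  src <- out_dir

  if (enabled("simulate")) {
    sim <- grab("simulate", simulate_study(config$sim))
    write_sim(sim, out_dir)
    manifest$stages$simulate <- list(
      status = "completed", n_rows = nrow(sim$responses),
      n_items = nrow(sim$items), n_persons = config$sim$n_persons)
  } else {
    src <- config$input_dir
    for (f in c("responses.csv", "items.csv", "cognition.csv"))
      if (!file.exists(file.path(src, f))) stop("missing input file: ", f)
  }
  responses <- read.csv(file.path(src, "responses.csv"))
  items <- read.csv(file.path(src, "items.csv"))
  cognition <- read.csv(file.path(src, "cognition.csv"))

  scored <- NULL
  if (enabled("fit_irt") || enabled("score_errors")) {
    require_dep("score_errors")
    scored <- grab("fit_irt", score_scales(
      responses, se = config$grm_se, fit_stats = config$grm_fit_stats,
      n_quad = config$n_quad))
    params <- lapply(scored$fits, function(f)
      list(a = as.list(f$a), b = f$b, m = as.list(f$m),
           logLik = f$logLik, converged = f$converged,
           srmr = f$srmr %||% NA, reversed = as.list(f$reversed)))
    jsonlite::write_json(params, file.path(out_dir, "grm_params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(scored$thetas, file.path(out_dir, "thetas.csv"), row.names = FALSE)
    manifest$stages$fit_irt <- list(status = "completed",
                                    n_models = length(scored$fits))
    if (enabled("score_errors")) {
      write.csv(scored$error_scores, file.path(out_dir, "error_scores.csv"),
                row.names = FALSE)
      manifest$stages$score_errors <- list(
        status = "completed", n_rows = nrow(scored$error_scores),
        n_persons_scored = length(unique(scored$error_scores$person_id)))
    }
  }

  profile <- NULL
  if (enabled("code_complexity")) {
    profile <- grab("code_complexity", code_complexity(items))
    write.csv(as.data.frame(profile), file.path(out_dir, "complexity.csv"),
              row.names = FALSE)
    manifest$stages$code_complexity <- list(status = "completed",
                                            n_items = nrow(profile))
  }

  err <- if (!is.null(scored)) scored$error_scores
         else if (file.exists(file.path(out_dir, "error_scores.csv")))
           read.csv(file.path(out_dir, "error_scores.csv")) else NULL
  cogn_w <- cognition[cognition$wave == config$wave, , drop = FALSE]
  if (!nrow(cogn_w)) cogn_w <- cognition
  ability <- data.frame(person_id = cogn_w$person_id,
                        ability = cogn_w$composite)

  if (enabled("wpr")) {
    require_dep("wpr")
    ew <- err[err$wave == config$wave, ]
    wfit <- grab("wpr", wpr_analysis(
      ew[c("person_id", "error")], ability, transform = config$transform,
      min_items = config$min_items, cov_method = config$cov_method,
      bootstrap_n = config$bootstrap_n))
    write.csv(wfit$deciles, file.path(out_dir, "wpr_deciles.csv"),
              row.names = FALSE)
    write.csv(data.frame(decile = 1:10, r = wfit$r,
                         se = sqrt(diag(wfit$cov_r))),
              file.path(out_dir, "wpr_correlations.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(wald = wfit$wald, pairwise = wfit$pairwise,
           settings = wfit$settings),
      file.path(out_dir, "wpr_tests.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    manifest$stages$wpr <- list(status = "completed", n_persons = wfit$n,
                                wald_p = wfit$wald$p)
    if (length(unique(err$wave)) > 1L) {
      rt <- retest_correlations(err, transform = config$transform,
                                min_items = config$min_items)
      write.csv(rt, file.path(out_dir, "wpr_retest.csv"), row.names = FALSE)
      manifest$stages$wpr$n_wave_pairs <- nrow(rt)
    }
  }

  if (enabled("tch")) {
    require_dep("tch")
    if (is.null(profile))
      profile <- read.csv(file.path(out_dir, "complexity.csv"))
    ew <- err[err$wave == config$wave, ]
    ew$terr <- if (config$transform == "cube_root")
      cube_root_transform(ew$error) else ew$error
    long <- merge(
      data.frame(person_id = ew$person_id, item_id = ew$item_id,
                 scale_id = ew$scale_id, error = ew$terr),
      profile[c("item_id", "composite")], by = "item_id")
    names(long)[names(long) == "composite"] <- "complexity"
    long <- merge(long, ability, by = "person_id")
    tch <- grab("tch", fit_tch_stage(long, cogn_w, config))
    jsonlite::write_json(tch$json, file.path(out_dir, "tch_fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    pred <- predict(tch$mod)
    write.csv(pred, file.path(out_dir, "tch_predictions.csv"),
              row.names = FALSE)
    write.csv(tch$scale_level$table, file.path(out_dir, "scale_level.csv"),
              row.names = FALSE)
    manifest$stages$tch <- list(status = "completed",
                                n_obs = tch$mod$n_obs,
                                latent_method = tch$latent_method)
  }

  if (enabled("report")) {
    manifest$stages$report <- list(status = "completed")
    # manifest must exist before the report renders it, so write first
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (enabled("report")) {
    rep <- generate_report(out_dir)
    writeLines(rep, file.path(out_dir, "report.txt"))
  }
  invisible(manifest)
}

stage_outputs_exist <- function(stage, out_dir, config) {
  files <- switch(stage,
                  fit_irt = "grm_params.json",
                  score_errors = "error_scores.csv",
                  code_complexity = "complexity.csv",
                  simulate = c("responses.csv", "items.csv", "cognition.csv"),
                  character(0))
  all(file.exists(file.path(out_dir, files)))
}

fit_tch_stage <- function(long, cognition, config) {
  mod <- fit_moderated_mlm(long)
  binned <- fit_binned_mlm(long)
  basis <- fit_basis_mlm(long)
  sub_cols <- intersect(c("imm_recall", "del_recall", "serial7", "backward"),
                        names(cognition))
  latent <- NULL; latent_method <- "none"
  if (length(sub_cols) == 4L) {
    complete_n <- sum(table(long$person_id) == max(table(long$person_id)))
    latent_method <- config$latent_method
    if (latent_method == "auto")
      latent_method <- if (complete_n >= 200) "joint" else "two_step"
    latent <- fit_latent_mlm(long, cognition[c("person_id", sub_cols)],
                             method = latent_method)
  }
  sl <- scale_level_correlation(
    long[c("person_id", "scale_id", "item_id", "error")],
    data.frame(item_id = long$item_id, composite = long$complexity),
    unique(long[c("person_id", "ability")]), transform = "none")
  json <- list(
    moderated = list(gamma = as.list(mod$gamma), robust_se = as.list(mod$se),
                     tau = mod$T, sigma2 = mod$sigma2, logLik = mod$logLik,
                     converged = mod$converged),
    binned = list(gamma = as.list(binned$gamma),
                  percent_change = as.list(binned$percent_change)),
    basis = list(gamma = as.list(basis$gamma), Psi = basis$Psi,
                 cor_ability = as.list(basis$cor_ability),
                 logLik = basis$logLik,
                 logLik_conditional = basis$logLik_conditional),
    latent = if (!is.null(latent))
      list(method = latent$method, cor_ability = as.list(latent$cor_ability),
           loadings = as.list(latent$loadings)),
    scale_level = list(meta_r = sl$meta_r, ci = sl$ci))
  list(mod = mod, binned = binned, basis = basis, latent = latent,
       scale_level = sl, json = json, latent_method = latent_method)
}

#' Generate a plain-text report from a pipeline artifact directory
#'
#' Summarizes whatever stage outputs are present: the decile-correlation
#' table with the omnibus test, complexity-indicator frequencies and
#' composite summary, mixed-model coefficient tables, and a pointer to the
#' prediction grid for plotting. Missing stages are flagged as gaps rather
#' than errors.
#'
#' @param dir a directory written by [run_pipeline()].
#' @return character vector of report lines (also suitable for
#'   `writeLines`).
#' @export
generate_report <- function(dir) {
  out <- c("resperr pipeline report", strrep("=", 40))
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    m <- jsonlite::read_json(mf)
    out <- c(out, paste0("seed: ", m$seed, "   version: ", m$version),
             paste0("stages completed: ",
                    paste(names(m$stages), collapse = ", ")))
  }
  cf <- file.path(dir, "wpr_correlations.csv")
  if (file.exists(cf)) {
    wc <- read.csv(cf)
    out <- c(out, "", "Decile-ability correlations:",
             paste0("  decile ", wc$decile, ": r = ", sprintf("%+.3f", wc$r),
                    " (SE ", sprintf("%.3f", wc$se), ")"))
    tj <- jsonlite::read_json(file.path(dir, "wpr_tests.json"))
    p <- tj$wald$p
    out <- c(out, sprintf("  omnibus Wald chi2(%d) = %.2f, p = %.3g%s",
                          tj$wald$df, tj$wald$statistic, p,
                          if (p >= 0.05) "  [not significant at alpha = .05]"
                          else ""))
  } else out <- c(out, "", "[WPR stage outputs missing]")
  xf <- file.path(dir, "complexity.csv")
  if (file.exists(xf)) {
    cx <- read.csv(xf)
    ind <- c("WC", "DC", "UTT", "VRT", "VNP", "CON", "NEG", "DIS", "TEN", "EXC")
    out <- c(out, "", "Complexity indicators (% of items):",
             paste0("  ", ind, ": ",
                    sprintf("%.1f", 100 * colMeans(cx[ind]))),
             sprintf("  composite: mean %.2f, SD %.2f, range %d-%d",
                     mean(cx$composite), sd(cx$composite),
                     min(cx$composite), max(cx$composite)))
  } else out <- c(out, "", "[complexity stage outputs missing]")
  tf <- file.path(dir, "tch_fit.json")
  if (file.exists(tf)) {
    tj <- jsonlite::read_json(tf)
    g <- unlist(tj$moderated$gamma); s <- unlist(tj$moderated$robust_se)
    out <- c(out, "", "Moderated mixed model fixed effects (robust SE):",
             paste0("  ", names(g), " = ", sprintf("%.4f", g),
                    " (", sprintf("%.4f", s), ")"))
    if (!is.null(tj$latent))
      out <- c(out, sprintf("  latent corr(g, u_high) = %.3f [%s]",
                            tj$latent$cor_ability$high, tj$latent$method))
    out <- c(out, "  prediction grid: tch_predictions.csv")
  } else out <- c(out, "", "[TCH stage outputs missing]")
  out
}
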