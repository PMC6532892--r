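#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles the generator, simulation, fitting, and mixture settings with an
#' output directory and a global seed. Defaults encode the reference
#' analysis: fitting grid \eqn{-5..10} step 0.1, 10 replicate ensembles of
#' 2500 runs per grid point, noise sd 1.
#'
#' @param generator a [generator_spec()].
#' @param grid_low,grid_high,grid_step fitting grid for the tilt.
#' @param replicates,nsim simulation effort per grid point.
#' @param sigma noise standard deviation.
#' @param dt,n_steps,init simulation window.
#' @param fit_method `"simulation"` or `"quadrature"`.
#' @param weights fitting weights, see [onglide_distance()].
#' @param by_group also fit per speaker group.
#' @param mixture_n_boot bootstrap replicates for the condition contrasts
#'   (0 disables contrasts).
#' @param out_dir output directory.
#' @param seed global seed; stage seeds are derived from it.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(generator = generator_spec(),
                            grid_low = -5, grid_high = 10, grid_step = 0.1,
                            replicates = 10, nsim = 2500, sigma = 1,
                            dt = 0.005, n_steps = 2000, init = c(-1, 1),
                            fit_method = "simulation", weights = c(1, 1),
                            by_group = TRUE, mixture_n_boot = 500,
                            out_dir = tempfile("onglide_run_"), seed = 1) {
  stopifnot(grid_step > 0, grid_low < grid_high, replicates >= 1, nsim >= 1)
  structure(list(generator = generator, grid_low = grid_low,
                 grid_high = grid_high, grid_step = grid_step,
                 replicates = replicates, nsim = nsim, sigma = sigma,
                 dt = dt, n_steps = n_steps, init = init,
                 fit_method = fit_method, weights = weights,
                 by_group = by_group, mixture_n_boot = mixture_n_boot,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a nested
#' `generator:` block mirrors [generator_spec()] (its `fall_probability` as
#' a list of two numeric vectors, group 1 first).
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator
  if (!is.null(gen_args$fall_probability))
    gen_args$fall_probability <- rbind(group1 = gen_args$fall_probability[[1]],
                                       group2 = gen_args$fall_probability[[2]])
  gen <- do.call(generator_spec, gen_args %||% list())
  y$generator <- NULL
  do.call(pipeline_config, c(list(generator = gen), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Chains generation, normalisation, summarisation, speaker grouping,
#' tilt fitting (per condition and optionally per condition and group),
#' and the mixture analysis with condition contrasts; writes every result
#' as delimited text plus a run log with the seed and a configuration
#' hash. No record is dropped silently: exclusion counts per stage are
#' logged.
#'
#' @param config a [pipeline_config()].
#' @param data optional data frame of onglide records to analyse instead of
#'   generating one (columns as in [read_onglides()]).
#' @return Invisibly, a list of class `"pipeline_result"`: `files` (named
#'   paths), `fit_condition`, `fit_group` (or `NULL`), `summaries`,
#'   `groups`, `mixtures`, `contrasts`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  logline <- character(0)
  say <- function(...) logline <<- c(logline, sprintf(...))
  stage <- "setup"
  tryCatch({
    cfg_hash <- sum(utf8ToInt(paste(deparse(unclass(config)), collapse = "")))
    say("seed: %d", config$seed)
    say("config hash: %d", cfg_hash)

    stage <- "generate"
    if (is.null(data)) {
      gen <- config$generator
      gen$seed <- config$seed
      data <- generate_onglides(gen)
      say("generate: %d records", nrow(data))
    } else {
      say("input data: %d records", nrow(data))
    }

    stage <- "normalize"
    n0 <- nrow(data)
    acc <- drop_background(data)
    say("background/unaccented records excluded: %d (kept %d)",
        n0 - nrow(acc), nrow(acc))
    acc$onglide_norm <- signed_log(acc$onglide_st)
    write_onglides(acc, out("dataset.csv"))

    stage <- "summarize"
    sum_cond <- summarize_onglides(acc, by = "condition")
    utils::write.csv(sum_cond, out("summary_condition.csv"), row.names = FALSE)
    groups <- assign_groups(acc)
    acc$group <- groups$group[match(acc$speaker, groups$speaker)]
    utils::write.csv(groups, out("groups.csv"), row.names = FALSE)
    sum_cg <- summarize_onglides(acc, by = c("condition", "group"))
    utils::write.csv(sum_cg, out("summary_condition_group.csv"),
                     row.names = FALSE)
    say("groups: %d in group1, %d in group2",
        sum(groups$group == "group1"), sum(groups$group == "group2"))

    stage <- "fit"
    grid <- seq(config$grid_low, config$grid_high, by = config$grid_step)
    fit_cond <- landscape_fit(onglide_norm ~ condition, acc, grid = grid,
                              replicates = config$replicates,
                              nsim = config$nsim, sigma = config$sigma,
                              weights = config$weights,
                              method = config$fit_method, dt = config$dt,
                              n_steps = config$n_steps, init = config$init,
                              seed = config$seed + 1)
    utils::write.csv(summary(fit_cond), out("fit_condition.csv"),
                     row.names = FALSE)
    write_distance_curves(fit_cond, out("distance_curves_condition.csv"))
    say("fit per condition: %s",
        paste(names(coef(fit_cond)), signif(coef(fit_cond), 3),
              sep = "=", collapse = ", "))
    fit_group <- NULL
    if (config$by_group) {
      fit_group <- landscape_fit(onglide_norm ~ condition + group, acc,
                                 grid = grid,
                                 replicates = config$replicates,
                                 nsim = config$nsim, sigma = config$sigma,
                                 weights = config$weights,
                                 method = config$fit_method, dt = config$dt,
                                 n_steps = config$n_steps, init = config$init,
                                 seed = config$seed + 2)
      utils::write.csv(summary(fit_group), out("fit_condition_group.csv"),
                       row.names = FALSE)
      write_distance_curves(fit_group, out("distance_curves_group.csv"))
      say("fit per condition x group: %s",
          paste(names(coef(fit_group)), signif(coef(fit_group), 3),
                sep = "=", collapse = ", "))
    }

    stage <- "mixture"
    conds <- unique(acc$condition)
    mixtures <- lapply(conds, function(cc)
      suppressWarnings(mixture_fit(acc$onglide_norm[acc$condition == cc])))
    names(mixtures) <- conds
    mix_tab <- do.call(rbind, lapply(conds, function(cc) {
      m <- mixtures[[cc]]
      data.frame(condition = cc, theta = m$theta, mu_fall = m$mu_fall,
                 mu_rise = m$mu_rise, sd_fall = m$sd_fall,
                 sd_rise = m$sd_rise, converged = m$converged)
    }))
    utils::write.csv(mix_tab, out("mixture.csv"), row.names = FALSE)
    contrasts <- NULL
    if (config$mixture_n_boot > 0 && length(conds) > 1) {
      pairs <- utils::combn(conds, 2, simplify = FALSE)
      contrasts <- do.call(rbind, lapply(seq_along(pairs), function(i) {
        p <- pairs[[i]]
        ct <- bootstrap_contrast(acc$onglide_norm[acc$condition == p[1]],
                                 acc$onglide_norm[acc$condition == p[2]],
                                 statistic = "theta",
                                 n_boot = config$mixture_n_boot,
                                 seed = config$seed + 10 + i)
        data.frame(contrast = paste(p[2], "-", p[1]),
                   estimate = ct$estimate, ci_low = ct$ci[1],
                   ci_high = ct$ci[2], p_greater_0 = ct$p_greater_0)
      }))
      utils::write.csv(contrasts, out("mixture_contrasts.csv"),
                       row.names = FALSE)
    }

    stage <- "report"
    writeLines(logline, out("run_log.txt"))
  }, error = function(e) {
    writeLines(c(logline, paste("FAILED at stage:", stage),
                 conditionMessage(e)),
               out("run_log.txt"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  files <- list.files(config$out_dir, full.names = TRUE)
  invisible(structure(list(
    files = setNames(files, basename(files)),
    fit_condition = fit_cond, fit_group = fit_group,
    summaries = list(condition = sum_cond, condition_group = sum_cg),
    groups = groups, mixtures = mixtures, contrasts = contrasts,
    log = logline
  ), class = "pipeline_result"))
}

write_distance_curves <- function(fit, path) {
  tab <- do.call(rbind, lapply(names(fit$fits), function(nm)
    cbind(stratum = nm, fit$fits[[nm]]$distance)))
  utils::write.csv(tab, path, row.names = FALSE)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", length(x$files), "output files\n")
  cat("Fitted tilts per condition:\n")
  print(coef(x$fit_condition))
  if (!is.null(x$fit_group)) {
    cat("Per condition x group:\n")
    print(coef(x$fit_group))
  }
  invisible(x)
}
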