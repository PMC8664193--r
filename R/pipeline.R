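# End-to-end pipeline: region (generated or read) -> routing -> RT/TT/TPT ->
# golden hour / quintiles -> correlation, ANOVA, disparity models -> report.

#' Pipeline run configuration
#'
#' Either a [region_config()] (synthetic run) or an `input_dir` holding a
#' region file set (see [read_region()]) must be supplied.
#'
#' @param region A [region_config()], or `NULL`.
#' @param input_dir Directory with region files, or `NULL`.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param constants A [time_constants()] object.
#' @param model_specs list of lists with `measure`, `with_interaction`,
#'   `subset` entries; `NULL` uses the standard nine models (three measures,
#'   each without and with interaction on all areas, plus the quintile-5
#'   subset without interaction).
#' @param income_scale Income rescaling for the models (default 1 = raw
#'   currency units).
#' @param seed Seed for any run-level randomness; a synthetic region uses
#'   its own config seed.
#' @return A `run_config` list.
#' @export
run_config <- function(region = NULL, input_dir = NULL, out_dir = NULL,
                       constants = time_constants(), model_specs = NULL,
                       income_scale = 1, seed = 1L) {
  if (is.null(region) && is.null(input_dir)) {
    stop("either a region config or an input_dir is required")
  }
  if (is.null(model_specs)) {
    model_specs <- list()
    for (m in c("rt", "tt", "tpt")) {
      model_specs <- c(model_specs,
                       list(list(measure = m, with_interaction = FALSE, subset = "all"),
                            list(measure = m, with_interaction = TRUE, subset = "all"),
                            list(measure = m, with_interaction = FALSE, subset = "quintile5")))
    }
  }
  structure(list(region = region, input_dir = input_dir, out_dir = out_dir,
                 constants = constants, model_specs = model_specs,
                 income_scale = income_scale, seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Descriptive statistics by area type
#'
#' Mean, median, min and max for each measure, overall and per area type,
#' plus golden-hour shares.
#'
#' @param records Access records (see [compute_access()]).
#' @param areas Area table with `area_id`, `area_type`.
#' @return list with `measures` (data.frame) and `golden_hour` (data.frame
#'   of counts and shares within/outside by area type).
#' @export
summarize_by_area_type <- function(records, areas) {
  if (nrow(records) == 0) stop("no records to summarize")
  d <- merge(records, areas[, c("area_id", "area_type")], by = "area_id")
  groups <- c("all", sort(unique(d$area_type)))
  rows <- list()
  for (g in groups) {
    sub <- if (g == "all") d else d[d$area_type == g, ]
    for (ms in c("rt", "tt", "tpt")) {
      v <- sub[[paste0(ms, "_min")]]
      rows[[length(rows) + 1]] <- data.frame(
        area_type = g, measure = ms, n = length(v),
        mean = mean(v), median = stats::median(v), min = min(v), max = max(v))
    }
  }
  gh <- do.call(rbind, lapply(groups, function(g) {
    sub <- if (g == "all") d else d[d$area_type == g, ]
    w <- sum(sub$within_golden_hour)
    data.frame(area_type = g, n = nrow(sub), within = w,
               outside = nrow(sub) - w,
               share_within = w / nrow(sub),
               share_outside = 1 - w / nrow(sub))
  }))
  list(measures = do.call(rbind, rows), golden_hour = gh)
}

#' Run the full accessibility pipeline
#'
#' Generates (or reads) the region, routes closest facilities, composes
#' RT/TT/TPT, classifies areas, and runs the correlation, ANOVA/Tukey and
#' negative binomial disparity stages. Deterministic for a fixed config.
#'
#' @param config A [run_config()].
#' @return A `run_report` list: `summary` (see [summarize_by_area_type()]),
#'   `correlation`, `anova` (per measure), `models` (list of `nb_model`),
#'   `records`, `areas`, `provenance`. Files are written to
#'   `config$out_dir` when set: `access.csv`, `models.csv`, `model_fit.csv`,
#'   `anova.json`, `correlations.json`, `report.json`, `report.txt`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  region <- .stage("region", {
    if (!is.null(config$region)) generate_region(config$region)
    else read_region(config$input_dir)
  })
  records <- .stage("accessibility", {
    compute_access(region$network, region$stations, region$hospitals,
                   region$areas, config$constants)
  })
  summary <- .stage("summary", summarize_by_area_type(records, region$areas))
  correlation <- .stage("correlation", correlation_rt_tt(records))
  anova <- .stage("anova", {
    d <- merge(records, region$areas[, c("area_id", "area_type")], by = "area_id")
    if (length(unique(d$area_type)) >= 2) {
      list(rt = anova_by_area_type(d$rt_min, d$area_type),
           tt = anova_by_area_type(d$tt_min, d$area_type))
    } else NULL
  })
  models <- .stage("models", {
    out <- list()
    for (sp in config$model_specs) {
      id <- sprintf("%s_%s%s", sp$measure, sp$subset,
                    if (isTRUE(sp$with_interaction)) "_interaction" else "")
      out[[id]] <- fit_disparity_models(region$areas, records,
                                        measure = sp$measure,
                                        with_interaction = isTRUE(sp$with_interaction),
                                        subset = sp$subset,
                                        income_scale = config$income_scale)
    }
    out
  })

  provenance <- list(
    seed = if (!is.null(config$region)) config$region$seed else config$seed,
    config_hash = .config_hash(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ehcaccess")),
    timestamp_utc = format(Sys.time(), tz = "UTC")
  )
  report <- structure(list(summary = summary, correlation = correlation,
                           anova = anova, models = models, records = records,
                           areas = region$areas, provenance = provenance),
                      class = "run_report")
  if (!is.null(config$out_dir)) .stage("write", write_report(report, config$out_dir))
  report
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- rapply(unclass(config), unclass, how = "replace")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write pipeline outputs to a directory
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$records, file.path(dir, "access.csv"),
                   row.names = FALSE)
  mrows <- list()
  frows <- list()
  for (id in names(report$models)) {
    m <- report$models[[id]]
    cf <- m$coefficients
    cf$model <- id
    mrows[[id]] <- cf[, c("model", "term", "estimate", "se", "p")]
    frows[[id]] <- data.frame(model = id, n = m$n, alpha = m$alpha,
                              loglik = m$log_likelihood, aic = m$aic,
                              bic = m$bic)
  }
  if (length(mrows) > 0) {
    utils::write.csv(do.call(rbind, mrows), file.path(dir, "models.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, frows), file.path(dir, "model_fit.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    if (is.null(report$anova)) stats::setNames(list(), character()) else
      lapply(report$anova, unclass),
    file.path(dir, "anova.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", force = TRUE)
  jsonlite::write_json(report$correlation, file.path(dir, "correlations.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(summary = report$summary, provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", force = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  gh <- x$summary$golden_hour
  all_row <- gh[gh$area_type == "all", ]
  cat(sprintf("EHC accessibility report — %d areas, %.1f%% within the golden hour\n",
              all_row$n, 100 * all_row$share_within))
  cat("\nGolden hour by area type:\n")
  print(gh, row.names = FALSE, digits = 3)
  cat("\nMeasures (minutes):\n")
  print(x$summary$measures, row.names = FALSE, digits = 3)
  cat(sprintf("\nPearson r(RT, TT) = %.3f (p = %.3g, n = %d)\n",
              x$correlation$r, x$correlation$p, x$correlation$n))
  if (!is.null(x$anova)) {
    for (ms in names(x$anova)) {
      a <- x$anova[[ms]]
      cat(sprintf("ANOVA %s: F(%d, %d) = %.1f, p = %.3g\n",
                  toupper(ms), a$df_between, a$df_within, a$F, a$p))
    }
  }
  if (length(x$models) > 0) {
    cat("\nDisparity models (NB2):\n")
    for (id in names(x$models)) {
      m <- x$models[[id]]
      cat(sprintf("  %-24s n = %4d  logLik = %9.1f  AIC = %9.1f  BIC = %9.1f\n",
                  id, m$n, m$log_likelihood, m$aic, m$bic))
    }
  }
  invisible(x)
}
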