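# Statistical stages: correlation screen, ANOVA with Tukey post-hoc by area
# type, and negative binomial disparity regressions.

#' Pearson collinearity screen
#'
#' Flags every covariate pair with `|r| >= threshold` and drops, from each
#' flagged pair, the member that appears later in the priority order.
#' Constant columns (undefined r) are flagged and reported separately.
#'
#' @param covariates data.frame of numeric candidate covariates (>= 2
#'   columns, >= 3 rows).
#' @param threshold Absolute correlation at or above which a pair is flagged
#'   (default 0.6).
#' @param priority Character vector of column names, highest priority first;
#'   defaults to the column order of `covariates`.
#' @return list with `retained` (column names), `dropped`, `flagged_pairs`
#'   (data.frame var1, var2, r) and `constant` (columns with zero variance).
#' @export
pearson_screen <- function(covariates, threshold = 0.6,
                           priority = names(covariates)) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2) stop("need at least 2 covariates")
  if (nrow(covariates) < 3) stop("need at least 3 observations")
  if (!setequal(priority, names(covariates))) {
    stop("priority must be a permutation of the covariate names")
  }
  sds <- vapply(covariates, stats::sd, 0)
  constant <- names(covariates)[sds == 0 | is.na(sds)]
  vars <- setdiff(priority, constant)

  flagged <- data.frame(var1 = character(), var2 = character(), r = numeric())
  dropped <- character()
  if (length(vars) >= 2) {
    r <- stats::cor(covariates[vars])
    for (i in seq_along(vars)[-length(vars)]) {
      for (j in seq.int(i + 1, length(vars))) {
        if (abs(r[i, j]) >= threshold) {
          flagged <- rbind(flagged, data.frame(
            var1 = vars[i], var2 = vars[j], r = r[i, j]))
          dropped <- union(dropped, vars[j]) # later in priority order
        }
      }
    }
  }
  list(retained = setdiff(vars, dropped),
       dropped = dropped,
       flagged_pairs = flagged,
       constant = constant)
}

#' Pearson correlation between RT and TT
#'
#' @param records Access records with `rt_min` and `tt_min` columns.
#' @return list with `r`, `p` (two-sided), `n`.
#' @export
correlation_rt_tt <- function(records) {
  if (nrow(records) < 3) stop("need at least 3 records")
  if (stats::sd(records$rt_min) == 0 || stats::sd(records$tt_min) == 0) {
    stop("correlation undefined: a measure has zero variance")
  }
  ct <- stats::cor.test(records$rt_min, records$tt_min, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(records))
}

#' One-way ANOVA with Tukey HSD by area type
#'
#' Separates the variance of an accessibility measure by area type and runs
#' all pairwise Tukey comparisons on the studentized range distribution.
#'
#' @param values Numeric measure (minutes) per area.
#' @param types Group labels (e.g. urban / densely_populated / rural).
#' @return An `anova_result` list: `F`, `df_between`, `df_within`, `p`,
#'   `groups` (data.frame group, n, mean, sd), `tukey` (data.frame pair,
#'   diff, lwr, upr, p_adj).
#' @export
anova_by_area_type <- function(values, types) {
  types <- factor(types)
  if (nlevels(types) < 2) stop("need at least 2 groups")
  sizes <- table(types)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  fit <- stats::aov(values ~ types)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$types
  groups <- data.frame(
    group = levels(types),
    n = as.integer(sizes),
    mean = as.numeric(tapply(values, types, mean)),
    sd = as.numeric(tapply(values, types, stats::sd))
  )
  structure(list(
    F = tab[1, "F value"],
    df_between = tab[1, "Df"],
    df_within = tab[2, "Df"],
    p = tab[1, "Pr(>F)"],
    groups = groups,
    tukey = data.frame(pair = rownames(tk),
                       diff = tk[, "diff"], lwr = tk[, "lwr"],
                       upr = tk[, "upr"], p_adj = tk[, "p adj"],
                       row.names = NULL)
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.1f, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Negative binomial (NB2) regression
#'
#' Log-link NB2 fit with dispersion `alpha` (variance mu + alpha mu^2)
#' estimated by maximum likelihood jointly with the coefficients. Response
#' minutes are rounded to the nearest integer so the count likelihood is
#' well defined. With `alpha` supplied, dispersion is held fixed (a tiny
#' alpha recovers the Poisson fit).
#'
#' @param formula Model formula.
#' @param data data.frame with response and covariates.
#' @param alpha Optional fixed dispersion; `NULL` (default) estimates it.
#' @return An `nb_model` list: `coefficients` (data.frame term, estimate,
#'   se, p), `alpha`, `log_likelihood`, `aic`, `bic`, `n`, `k`, `converged`,
#'   and the underlying `fit`.
#' @export
fit_nb <- function(formula, data, alpha = NULL) {
  data <- as.data.frame(data)
  resp_name <- all.vars(formula[[2]])
  y <- data[[resp_name]]
  if (any(y < 0)) stop("response must be nonnegative")
  data[[resp_name]] <- round(y)

  mm <- stats::model.matrix(formula, data)
  if (qr(mm)$rank < ncol(mm)) {
    stop("rank-deficient design; collinear terms among: ",
         paste(colnames(mm), collapse = ", "))
  }

  if (is.null(alpha)) {
    fit <- tryCatch(
      withCallingHandlers(
        MASS::glm.nb(formula, data = data,
                     control = stats::glm.control(maxit = 100)),
        warning = function(w) {
          # theta drifting to +Inf on equi/under-dispersed data is the
          # alpha -> 0 boundary, not a failed fit
          if (grepl("iteration limit reached|alternation limit|NaNs produced",
                    conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit) || fit$theta > 1e7) {
      # dispersion at the Poisson boundary: theta ML diverges when the data
      # show no overdispersion; pin theta large and keep k counting alpha
      fit <- stats::glm(formula, data = data,
                        family = MASS::negative.binomial(theta = 1e8))
      fit$theta <- 1e8
    }
    theta <- fit$theta
    k <- length(stats::coef(fit)) + 1 # + dispersion
    mu_hat <- stats::fitted(fit)
    ll <- sum(stats::dnbinom(data[[resp_name]], size = theta, mu = mu_hat,
                             log = TRUE))
  } else {
    if (alpha <= 0) stop("alpha must be positive")
    theta <- 1 / alpha
    fit <- stats::glm(formula, data = data,
                      family = MASS::negative.binomial(theta = theta))
    k <- length(stats::coef(fit))
    mu <- stats::fitted(fit)
    yy <- data[[resp_name]]
    ll <- sum(stats::dnbinom(yy, size = theta, mu = mu, log = TRUE))
  }
  if (!fit$converged) stop("negative binomial fit did not converge after ",
                           fit$iter, " IWLS iterations")
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm),
                      estimate = sm[, 1], se = sm[, 2],
                      p = sm[, 4], row.names = NULL)
  n <- stats::nobs(fit)
  structure(list(coefficients = coefs,
                 alpha = 1 / theta,
                 log_likelihood = ll,
                 aic = 2 * k - 2 * ll,
                 bic = k * log(n) - 2 * ll,
                 n = n, k = k,
                 converged = fit$converged,
                 fit = fit),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("NB2 regression: n = %d, alpha = %.4g, logLik = %.1f, AIC = %.1f, BIC = %.1f\n",
              x$n, x$alpha, x$log_likelihood, x$aic, x$bic))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Build the disparity-model design table
#'
#' Joins access records to area covariates and sets factor reference levels:
#' urban for area type and the alphabetically first region.
#'
#' @param areas data.frame with `area_id`, `older_share`, `high_edu_share`,
#'   `median_income`, `has_station`, `area_type`, `region`.
#' @param records Access records from [compute_access()].
#' @param income_scale Multiplier applied to `median_income` before fitting
#'   (default 1 = raw currency units per year).
#' @return data.frame ready for [fit_nb()], with `rural` and `dense` dummies.
#' @export
disparity_design <- function(areas, records, income_scale = 1) {
  d <- merge(records, areas, by = "area_id", sort = TRUE)
  d$median_income <- d$median_income * income_scale
  d$area_type <- stats::relevel(factor(
    d$area_type, levels = c("urban", "densely_populated", "rural")), "urban")
  regs <- sort(unique(as.character(d$region)))
  d$region <- factor(d$region, levels = regs) # first region = reference
  d$rural <- as.integer(d$area_type == "rural")
  d$dense <- as.integer(d$area_type == "densely_populated")
  d$has_station <- as.integer(d$has_station)
  d
}

#' Fit a disparity regression for one accessibility measure
#'
#' Negative binomial model of an accessibility measure on area covariates:
#' older-adult share, highly-educated share, median income, ambulance-station
#' dummy, area-type dummies (urban reference) and region dummies (first
#' region alphabetically as reference); optionally a rural-by-older-adults
#' interaction. `subset = "quintile5"` restricts to the measure's 5th
#' quintile (the most underserviced areas).
#'
#' @param areas,records As in [disparity_design()].
#' @param measure `"rt"`, `"tt"` or `"tpt"`.
#' @param with_interaction Include `rural x older_share`?
#' @param subset `"all"` or `"quintile5"`.
#' @param income_scale Passed to [disparity_design()].
#' @return An `nb_model` (see [fit_nb()]) with attributes `measure`,
#'   `with_interaction`, `subset`.
#' @export
fit_disparity_models <- function(areas, records,
                                 measure = c("rt", "tt", "tpt"),
                                 with_interaction = FALSE,
                                 subset = c("all", "quintile5"),
                                 income_scale = 1) {
  measure <- match.arg(measure)
  subset <- match.arg(subset)
  d <- disparity_design(areas, records, income_scale)
  if (subset == "quintile5") {
    d <- d[d[[paste0("quintile_", measure)]] == 5L, , drop = FALSE]
    if (nrow(d) == 0) stop("quintile-5 subset is empty")
  }
  # degenerate (constant) terms carry no information in a subset and would
  # make the design rank-deficient; drop them
  base_terms <- c("older_share", "high_edu_share", "median_income",
                  "has_station", "dense", "rural")
  keep <- base_terms[vapply(base_terms,
                            function(v) length(unique(d[[v]])) > 1, TRUE)]
  # with no urban (reference) areas present, dense + rural == 1 is collinear
  # with the intercept; make densely populated the reference instead
  if (all(d$dense + d$rural == 1) && all(c("dense", "rural") %in% keep)) {
    keep <- setdiff(keep, "dense")
  }
  if (length(unique(d$region)) > 1) {
    d$region <- droplevels(d$region)
    keep <- c(keep, "region")
  }
  if (with_interaction && "rural" %in% keep) {
    keep <- c(keep, "rural:older_share")
  }
  # drop any remaining aliased terms (e.g. area type fully determined by
  # region in a small subset), preferring to keep the substantive covariates
  f <- stats::as.formula(paste(paste0(measure, "_min"), "~",
                               paste(keep, collapse = " + ")))
  repeat {
    mm <- stats::model.matrix(f, d)
    q <- qr(mm)
    if (q$rank == ncol(mm) || length(keep) == 1) break
    aliased_col <- q$pivot[ncol(mm)]
    term_idx <- attr(mm, "assign")[aliased_col]
    drop_term <- attr(stats::terms(f), "term.labels")[term_idx]
    keep <- setdiff(keep, drop_term)
    f <- stats::as.formula(paste(paste0(measure, "_min"), "~",
                                 paste(keep, collapse = " + ")))
  }
  m <- fit_nb(f, d)
  attr(m, "measure") <- measure
  attr(m, "with_interaction") <- with_interaction
  attr(m, "subset") <- subset
  m
}
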