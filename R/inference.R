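#' Fit a negative binomial (NB2) count regression
#'
#' Maximum-likelihood NB2 fit with log link: mean model
#' \eqn{\mu_i = \exp(x_i^T \beta)}, variance \eqn{\mu + \mu^2/\theta},
#' dispersion \eqn{\theta} estimated by ML (initialised from a Poisson
#' fit, as `MASS::glm.nb` does). Wald 95% confidence intervals are
#' `estimate +/- 1.96 * SE` on the log scale.
#'
#' @param formula Model formula, e.g. `n_dnm ~ father_age`.
#' @param data Data frame with a non-negative integer response.
#' @param min_n Minimum number of observations (default 10).
#' @param level Confidence level for Wald intervals.
#' @return An object of class `cdnm_fit`: list with `coefficients` (data
#'   frame: `term`, `estimate`, `se`, `ci_lo`, `ci_hi`, `p_value`),
#'   `theta`, `theta_se`, `loglik`, `converged`, `n`, `family`, `formula`
#'   and the underlying `model`.
#' @export
fit_nb_glm <- function(formula, data, min_n = 10L, level = 0.95) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (nrow(mf) < min_n) {
    stop("too few observations for a count model fit (", nrow(mf), " < ", min_n, ")")
  }
  if (any(y < 0) || any(y != round(y))) {
    stop("response must be non-negative integer counts")
  }
  if (all(y == 0)) stop("all-zero response; the count model is degenerate")
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient; drop collinear or constant covariates")
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    MASS::glm.nb(formula, data = data, control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("alternation limit|algorithm did not converge", conditionMessage(w))) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    }
  )
  .wrap_glm_fit(fit, family = "negbin", level = level,
                converged = converged && isTRUE(fit$converged))
}

.wrap_glm_fit <- function(fit, family, level = 0.95, converged = TRUE) {
  sm <- summary(fit)
  ct <- stats::coef(sm)
  z <- stats::qnorm(1 - (1 - level) / 2)
  coefs <- data.frame(
    term = rownames(ct),
    estimate = ct[, 1L],
    se = ct[, 2L],
    ci_lo = ct[, 1L] - z * ct[, 2L],
    ci_hi = ct[, 1L] + z * ct[, 2L],
    p_value = ct[, 4L],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    coefficients = coefs,
    theta = if (family == "negbin") fit$theta else NA_real_,
    theta_se = if (family == "negbin") fit$SE.theta else NA_real_,
    loglik = as.numeric(stats::logLik(fit)),
    converged = converged,
    n = stats::nobs(fit),
    family = family,
    formula = stats::formula(fit),
    level = level,
    model = fit
  ), class = "cdnm_fit")
}

#' @export
print.cdnm_fit <- function(x, ...) {
  cat("Count model (", x$family, ", log link): ",
      deparse(x$formula), "\n", sep = "")
  cat("n = ", x$n, if (x$family == "negbin") paste0(", theta = ", signif(x$theta, 4)),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  df <- x$coefficients
  df[-1L] <- lapply(df[-1L], signif, digits = 4)
  print.data.frame(df, ...)
  invisible(x)
}

#' @export
summary.cdnm_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.cdnm_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.cdnm_fit <- function(object, parm, ...) {
  ci <- as.matrix(object$coefficients[, c("ci_lo", "ci_hi")])
  rownames(ci) <- object$coefficients$term
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.cdnm_fit <- function(object, newdata = NULL, type = "response", ...) {
  stats::predict(object$model, newdata = newdata, type = type, ...)
}

#' Paternal-age effect on the outcome scale
#'
#' Converts the log-scale age coefficient of a count model into the
#' percent increase in expected mutations per year,
#' `100 * (exp(beta) - 1)`, and into absolute additional mutations per
#' year at a reference expected count.
#'
#' @param fit A `cdnm_fit` containing a paternal-age term.
#' @param term Name of the age coefficient (default `"father_age"`).
#' @param ref_count Reference expected count per generation used for the
#'   absolute scale (default 70, a typical per-generation DNM load).
#' @return List with `percent_per_year`, its Wald CI
#'   (`percent_ci_lo`/`percent_ci_hi`), and `dnms_per_year` at
#'   `ref_count`.
#' @export
paternal_age_effect <- function(fit, term = "father_age", ref_count = 70) {
  stopifnot(inherits(fit, "cdnm_fit"))
  row <- fit$coefficients[fit$coefficients$term == term, ]
  if (nrow(row) != 1L) stop("no coefficient named '", term, "' in the fit")
  list(percent_per_year = 100 * (exp(row$estimate) - 1),
       percent_ci_lo = 100 * (exp(row$ci_lo) - 1),
       percent_ci_hi = 100 * (exp(row$ci_hi) - 1),
       dnms_per_year = ref_count * (exp(row$estimate) - 1))
}

#' Bonferroni adjustment
#'
#' @param p_nom Nominal p-value(s).
#' @param m Number of tests (default 9).
#' @return `pmin(1, m * p_nom)`.
#' @export
bonferroni_adjust <- function(p_nom, m = 9) {
  stopifnot(m >= 1, all(p_nom >= 0 & p_nom <= 1))
  pmin(1, m * p_nom)
}

#' Cohort (or subgroup) contrast model for count outcomes
#'
#' Fits an NB2 model of the response on a group factor, optionally
#' adjusted for paternal age, and reports each non-reference group
#' coefficient with nominal and Bonferroni-adjusted p-values.
#'
#' @param data Per-offspring count table.
#' @param response Response column name (e.g. `"n_cdnm"`).
#' @param group Grouping column name (cohort or exposure subgroup).
#' @param ref_level Reference level of the group factor (e.g. the control
#'   cohort).
#' @param adjust_age Include `father_age` as covariate.
#' @param m_tests Bonferroni multiplier (default 9).
#' @return List of class `cohort_contrast`: `fit` (`cdnm_fit`),
#'   `contrasts` (data frame with `group`, `estimate`, `rate_ratio`,
#'   `ci_lo`, `ci_hi`, `p_nom`, `p_adj`), `alpha_adjusted` = 0.05 /
#'   `m_tests`.
#' @export
cohort_contrast_model <- function(data, response = "n_cdnm", group = "cohort",
                                  ref_level = NULL, adjust_age = TRUE,
                                  m_tests = 9) {
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) stop("grouping factor needs at least two levels")
  if (!is.null(ref_level)) g <- stats::relevel(g, ref = ref_level)
  d <- data
  d$.group <- g
  fml <- stats::as.formula(paste(response, "~ .group",
                                 if (adjust_age) "+ father_age" else ""))
  fit <- fit_nb_glm(fml, d)
  rows <- grepl("^\\.group", fit$coefficients$term)
  co <- fit$coefficients[rows, , drop = FALSE]
  contrasts <- data.frame(
    group = sub("^\\.group", "", co$term),
    estimate = co$estimate,
    rate_ratio = exp(co$estimate),
    ci_lo = exp(co$ci_lo),
    ci_hi = exp(co$ci_hi),
    p_nom = co$p_value,
    p_adj = bonferroni_adjust(co$p_value, m_tests),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(fit = fit, contrasts = contrasts, reference = levels(g)[1L],
                 alpha_adjusted = 0.05 / m_tests, m_tests = m_tests),
            class = "cohort_contrast")
}

#' @export
print.cohort_contrast <- function(x, ...) {
  cat("Cohort contrasts vs '", x$reference, "' (Bonferroni m = ", x$m_tests,
      ", adjusted alpha = ", signif(x$alpha_adjusted, 3), ")\n", sep = "")
  df <- x$contrasts
  df[-1L] <- lapply(df[-1L], signif, digits = 4)
  print.data.frame(df, ...)
  invisible(x)
}

#' Dose-response model for clustered mutation counts
#'
#' NB2 regression of the cluster count on paternal dose (mGy), reporting
#' the curve \eqn{f(n) = \exp(\beta_0) e^{\beta n}}: the dose coefficient
#' `beta` (per mGy, log scale) and the baseline `exp(beta_0)` (expected
#' clusters at dose 0), both with Wald CIs.
#'
#' @param data Per-offspring count table with `dose` in mGy.
#' @param response Response column (default `"n_cdnm"`).
#' @param restrict_exposed Keep only offspring with known dose > 0 (the
#'   exposed subgroup), dropping dose-0 and dose-missing rows.
#' @param min_n Minimum retained observations.
#' @return List of class `dose_response`: `fit`, `beta` (estimate, CI, p),
#'   `baseline` (exp-intercept with transformed CI), `n`.
#' @export
dose_response_model <- function(data, response = "n_cdnm",
                                restrict_exposed = TRUE, min_n = 10L) {
  d <- data
  if (restrict_exposed) {
    d <- d[!is.na(d$dose) & d$dose > 0, , drop = FALSE]
  } else {
    d <- d[!is.na(d$dose), , drop = FALSE]
  }
  if (nrow(d) < min_n) {
    stop("only ", nrow(d), " offspring retained after dose restriction (need >= ",
         min_n, ")")
  }
  if (stats::var(d$dose) == 0) {
    stop("dose has no variation in the retained subgroup; slope is not identifiable")
  }
  fml <- stats::as.formula(paste(response, "~ dose"))
  fit <- fit_nb_glm(fml, d)
  co <- fit$coefficients
  b <- co[co$term == "dose", ]
  b0 <- co[co$term == "(Intercept)", ]
  structure(list(
    fit = fit,
    beta = list(estimate = b$estimate, ci_lo = b$ci_lo, ci_hi = b$ci_hi,
                p_value = b$p_value),
    baseline = list(estimate = exp(b0$estimate), ci_lo = exp(b0$ci_lo),
                    ci_hi = exp(b0$ci_hi)),
    n = fit$n
  ), class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat("Dose response f(n) = ", signif(x$baseline$estimate, 4), " * exp(",
      signif(x$beta$estimate, 4), " * n mGy)  [n = ", x$n, "]\n", sep = "")
  cat("  beta 95% CI (", signif(x$beta$ci_lo, 4), ", ", signif(x$beta$ci_hi, 4),
      "), p = ", signif(x$beta$p_value, 3), "\n", sep = "")
  cat("  baseline 95% CI (", signif(x$baseline$ci_lo, 4), ", ",
      signif(x$baseline$ci_hi, 4), ")\n", sep = "")
  invisible(x)
}

#' Inverse model: infer paternal dose from the offspring cluster count
#'
#' Gamma GLM with log link of the (positive) dose on the cluster count.
#'
#' @param data Per-offspring table with positive `dose` rows to use.
#' @param response Count column used as predictor (default `"n_cdnm"`).
#' @return A `cdnm_fit` (family `"gamma"`).
#' @export
inverse_dose_model <- function(data, response = "n_cdnm") {
  d <- data[!is.na(data$dose) & data$dose > 0, , drop = FALSE]
  if (nrow(d) < 10L) stop("too few dose-positive offspring (", nrow(d), ")")
  if (stats::var(d[[response]]) == 0) {
    stop("count predictor is constant; inverse model is not identifiable")
  }
  fml <- stats::as.formula(paste("dose ~", response))
  fit <- stats::glm(fml, data = d, family = stats::Gamma(link = "log"))
  .wrap_glm_fit(fit, family = "gamma", converged = fit$converged)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Computed through the Beta quantile identity: lower =
#' `qbeta(a/2, k, n-k+1)` (0 when k = 0), upper =
#' `qbeta(1-a/2, k+1, n-k)` (1 when k = n).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return List with `estimate` (k/n), `lower`, `upper`, `level`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n, level > 0, level < 1)
  a <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  list(estimate = k / n, lower = lower, upper = upper, level = level)
}

#' Descriptive count statistics with PPV adjustment
#'
#' Per-group mean, sample standard deviation, median, and the
#' PPV-adjusted mean (mean times the positive predictive value of the
#' calls, i.e. the expected number of true clusters).
#'
#' @param counts Numeric count vector.
#' @param group Grouping vector (same length), or `NULL` for one group.
#' @param ppv Positive predictive value in (0, 1].
#' @return Data frame with `group`, `n`, `mean`, `sd`, `median`,
#'   `ppv_adjusted_mean`. Values are unrounded.
#' @export
descriptive_stats <- function(counts, group = NULL, ppv = 1) {
  stopifnot(ppv > 0, ppv <= 1)
  if (is.null(group)) group <- rep("all", length(counts))
  if (length(counts) == 0L) stop("empty count vector")
  sp <- split(counts, group)
  if (any(lengths(sp) == 0L)) stop("empty group")
  out <- do.call(rbind, lapply(names(sp), function(g) {
    x <- sp[[g]]
    data.frame(group = g, n = length(x), mean = mean(x), sd = stats::sd(x),
               median = stats::median(x), ppv_adjusted_mean = mean(x) * ppv,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' PPV robustness simulation by binomial thinning
#'
#' Models an imperfect positive predictive value by replacing each
#' offspring's cluster count c with a Binomial(c, ppv) draw and refitting
#' the contrast model, `reps` times. Reports the distribution of refit
#' p-values and effect estimates and the fraction of replicates
#' significant at `alpha`.
#'
#' @param data Per-offspring count table.
#' @param response Count column to thin.
#' @param group,ref_level,adjust_age,m_tests Passed to
#'   [cohort_contrast_model()].
#' @param contrast Which group level's contrast to track (default: first
#'   non-reference level).
#' @param ppv Positive predictive value in (0, 1].
#' @param reps Number of replicates.
#' @param alpha Significance level applied to the adjusted p-value.
#' @param seed Random seed.
#' @return List of class `ppv_simulation`: `p_values`, `estimates`
#'   (log rate ratios), `significant_fraction`, `n_failed`, `ppv`,
#'   `reps`, and the `unthinned` contrast table.
#' @export
ppv_thinning_simulation <- function(data, response = "n_cdnm", group = "cohort",
                                    ref_level = NULL, adjust_age = TRUE,
                                    contrast = NULL, ppv, reps = 200L,
                                    alpha = 0.05, m_tests = 9, seed = 1L) {
  stopifnot(ppv >= 0, ppv <= 1, reps >= 1)  # ppv = 0 allowed as a degenerate case
  base_model <- cohort_contrast_model(data, response = response, group = group,
                                      ref_level = ref_level,
                                      adjust_age = adjust_age, m_tests = m_tests)
  if (is.null(contrast)) contrast <- base_model$contrasts$group[1L]
  set.seed(seed)
  p_values <- numeric(0)
  estimates <- numeric(0)
  n_failed <- 0L
  for (r in seq_len(reps)) {
    d <- data
    d[[response]] <- stats::rbinom(nrow(d), size = d[[response]], prob = ppv)
    res <- tryCatch({
      m <- cohort_contrast_model(d, response = response, group = group,
                                 ref_level = ref_level, adjust_age = adjust_age,
                                 m_tests = m_tests)
      m$contrasts[m$contrasts$group == contrast, ]
    }, error = function(e) NULL)
    if (is.null(res) || nrow(res) != 1L) {
      n_failed <- n_failed + 1L
    } else {
      p_values <- c(p_values, res$p_adj)
      estimates <- c(estimates, res$estimate)
    }
  }
  structure(list(
    p_values = p_values, estimates = estimates,
    significant_fraction = if (length(p_values) > 0L) mean(p_values < alpha) else 0,
    n_failed = n_failed, ppv = ppv, reps = reps, alpha = alpha,
    contrast = contrast,
    unthinned = base_model$contrasts
  ), class = "ppv_simulation")
}

#' @export
print.ppv_simulation <- function(x, ...) {
  cat("PPV thinning simulation: ppv = ", x$ppv, ", ", x$reps, " reps (",
      x$n_failed, " failed refits)\n", sep = "")
  cat("  contrast '", x$contrast, "': significant fraction at alpha = ",
      x$alpha, ": ", signif(x$significant_fraction, 3), "\n", sep = "")
  if (length(x$estimates) > 0L) {
    cat("  median refit estimate (log RR): ", signif(stats::median(x$estimates), 4),
        "; median adjusted p: ", signif(stats::median(x$p_values), 3), "\n", sep = "")
  }
  invisible(x)
}
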