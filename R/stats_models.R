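#' Kendall rank correlation
#'
#' Tau-b with tie correction, normal-approximation z statistic and two-sided
#' p value.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return List with `tau`, `z`, `p`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("all-tied input: tau undefined")
    return(list(tau = NA_real_, z = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE, continuity = FALSE))
  list(tau = unname(ct$estimate), z = unname(ct$statistic), p = ct$p.value)
}

#' Welch's unequal-variance t-test
#'
#' @param x,y numeric samples (each >= 2 values).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    return(list(t = Inf * sign(mean(x) - mean(y)),
                df = length(x) + length(y) - 2, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Model ARS occurrence over trip sections
#'
#' Binomial (logit link) regression of ARS presence/absence per trip section
#' on the logit-transformed proportion of time sitting on the water surface,
#' the number of dives, their interaction, and trip duration.  With
#' `random_group` set, a per-group random intercept is fitted by Laplace
#' approximation (via \pkg{lme4}); when its variance estimate collapses to
#' zero the model reduces to a plain logistic regression, which is refitted
#' and reported.  Sitting proportions are clamped to `[0.5%, 99.5%]` before
#' the logit, since sections with 0% or 100% sitting occur.
#'
#' @param sections data frame with columns `ars_present` (logical or 0/1),
#'   `pct_sitting`, `n_dives`, `duration_h` (or `trip_duration_h`), and the
#'   grouping column when `random_group` is used.
#' @param random_group name of the random-intercept grouping column (default
#'   `"trip_id"`); `NULL` for a fixed-effects-only fit.
#' @param formula model formula on the derived columns; the default mirrors
#'   the sitting-by-dives interaction structure.
#' @param clamp clamping fraction for the logit transform (default 0.005).
#' @return An `ars_glmm`: list with `coefficients`, `se`, `vcov`, `z`, `p`,
#'   `re_var` (`NA` for plain logistic fits), `converged`, `model` and the
#'   underlying `fit`.
#' @export
fit_ars_glmm <- function(sections, random_group = "trip_id",
                         formula = NULL, clamp = 0.005) {
  d <- as.data.frame(sections)
  stopifnot(nrow(d) >= 20)
  if (!"trip_duration_h" %in% names(d) && "duration_h" %in% names(d))
    d$trip_duration_h <- d$duration_h
  d$ars_present <- as.integer(d$ars_present)
  if (length(unique(d$ars_present)) < 2)
    stop("both response classes must be present")
  if ("pct_sitting" %in% names(d))
    d$logit_sitting <- stats::qlogis(pmin(pmax(d$pct_sitting / 100, clamp),
                                          1 - clamp))
  if (is.null(formula))
    formula <- ars_present ~ logit_sitting * n_dives + trip_duration_h
  re_var <- NA_real_
  model <- "glm"
  if (!is.null(random_group) && random_group %in% names(d) &&
      length(unique(d[[random_group]])) > 1) {
    f2 <- stats::update(formula,
                        paste(". ~ . + (1 |", random_group, ")"))
    gf <- tryCatch(
      lme4::glmer(f2, data = d, family = stats::binomial()),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(gf)) {
      re_var <- unname(lme4::VarCorr(gf)[[random_group]][1, 1])
      if (re_var > 1e-8) {
        vc <- as.matrix(stats::vcov(gf))
        co <- lme4::fixef(gf)
        fit <- list(coefficients = co,
                    se = sqrt(diag(vc)), vcov = vc,
                    re_var = re_var, converged = TRUE, model = "glmer",
                    fit = gf, terms = stats::terms(formula))
        return(finish_glmm(fit))
      }
      # variance hit zero: reduce to plain logistic regression
    }
  }
  gl <- withCallingHandlers(
    stats::glm(formula, data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  converged <- gl$converged && all(abs(stats::coef(gl)) < 20)
  if (!converged)
    warning("possible complete separation: fit flagged non-converged")
  fit <- list(coefficients = stats::coef(gl),
              se = sqrt(diag(as.matrix(stats::vcov(gl)))),
              vcov = as.matrix(stats::vcov(gl)),
              re_var = re_var, converged = converged, model = model,
              fit = gl, terms = stats::terms(formula))
  finish_glmm(fit)
}

finish_glmm <- function(fit) {
  fit$z <- fit$coefficients / fit$se
  fit$p <- 2 * stats::pnorm(-abs(fit$z))
  structure(fit, class = "ars_glmm")
}

#' @export
print.ars_glmm <- function(x, ...) {
  cat(sprintf("<ars_glmm (%s)%s>\n", x$model,
              if (!x$converged) " NOT CONVERGED" else ""))
  print(round(data.frame(b = x$coefficients, se = x$se, z = x$z, p = x$p), 4))
  if (!is.na(x$re_var))
    cat(sprintf("random-intercept variance: %.4f\n", x$re_var))
  invisible(x)
}

#' Posterior-simulation predictions from a fitted ARS model
#'
#' Draws `n_draws` coefficient vectors from the multivariate-normal
#' approximation to the joint posterior (mean = estimates, covariance =
#' estimated covariance), applies the inverse logit per draw, and reports
#' the point prediction with a 95% credible interval from the 2.5 and 97.5
#' percentiles.
#'
#' @param fit a converged `ars_glmm`.
#' @param newdata data frame with the model covariates (`logit_sitting`,
#'   `n_dives`, `trip_duration_h` for the default formula).
#' @param n_draws number of posterior draws (default 1000).
#' @param seed optional RNG seed.
#' @return Data frame with `prob`, `lo`, `hi`, one row per `newdata` row.
#' @export
predict_probability <- function(fit, newdata, n_draws = 1000, seed = NULL) {
  stopifnot(inherits(fit, "ars_glmm"))
  if (!fit$converged) stop("cannot simulate from a non-converged fit")
  if (!is.null(seed)) set.seed(seed)
  tm <- stats::delete.response(fit$terms)
  X <- stats::model.matrix(tm, data = newdata)
  X <- X[, names(fit$coefficients), drop = FALSE]
  draws <- MASS::mvrnorm(n_draws, mu = fit$coefficients, Sigma = fit$vcov)
  eta <- X %*% t(draws)                       # rows x draws
  pr <- stats::plogis(eta)
  qs <- t(apply(pr, 1, stats::quantile, probs = c(0.025, 0.975)))
  data.frame(prob = as.vector(stats::plogis(X %*% fit$coefficients)),
             lo = qs[, 1], hi = qs[, 2])
}

#' Export a model report as JSON
#'
#' @param fit an `ars_glmm`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
export_glmm_json <- function(fit, file) {
  jsonlite::write_json(
    list(model = fit$model, converged = fit$converged,
         re_var = if (is.na(fit$re_var)) NULL else fit$re_var,
         coefficients = as.list(fit$coefficients),
         se = as.list(fit$se), z = as.list(fit$z), p = as.list(fit$p)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
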