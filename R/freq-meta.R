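#' Assemble meta-analysis input
#'
#' Collects per-study effect estimates (log odds ratios with known standard
#' errors) into the common input object of all pooling functions.
#'
#' @param x a list of [two_arm_trial()] or [effect_estimate()] objects, or a
#'   data frame with columns `label`, `estimate`, `se`.
#' @param ... passed to [log_odds_ratio()] when `x` contains trials.
#' @return An object of class `meta_input`: a data frame with columns
#'   `label`, `estimate`, `se`.
#' @export
meta_input <- function(x, ...) {
  if (is.data.frame(x)) {
    stopifnot(all(c("label", "estimate", "se") %in% names(x)))
    df <- x[, c("label", "estimate", "se")]
  } else {
    if (inherits(x, c("two_arm_trial", "effect_estimate"))) x <- list(x)
    ests <- lapply(x, function(e) {
      if (inherits(e, "two_arm_trial")) e <- log_odds_ratio(e, ...)
      stopifnot(inherits(e, "effect_estimate"))
      e
    })
    df <- data.frame(label = vapply(ests, `[[`, "", "label"),
                     estimate = vapply(ests, `[[`, 0, "log_or"),
                     se = vapply(ests, `[[`, 0, "se"),
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) < 1L) stop("meta_input needs at least one estimate", call. = FALSE)
  if (any(!is.finite(df$se)) || any(df$se <= 0)) {
    stop("all standard errors must be positive and finite", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("meta_input", "data.frame")
  df
}

meta_result <- function(estimate, se, level, weights, model, tau2,
                        q_stat = NA_real_, q_df = NA_integer_, q_p = NA_real_) {
  z <- stats::qnorm((1 + level) / 2)
  structure(list(estimate = estimate, se = se,
                 ci_low = estimate - z * se, ci_high = estimate + z * se,
                 level = level,
                 p_value = 2 * stats::pnorm(-abs(estimate / se)),
                 weights = weights, model = model, tau2 = tau2,
                 q_stat = q_stat, q_df = q_df, q_p = q_p),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %s-effect%s pooled log OR %.4f (SE %.4f), %d%% CI (%.4f, %.4f), p = %.3g\n",
              if (x$model == "fixed") "fixed" else "random",
              if (x$model == "random") sprintf(" (tau2 = %.4f)", x$tau2) else "",
              x$estimate, x$se, round(100 * x$level), x$ci_low, x$ci_high,
              x$p_value))
  if (!is.na(x$q_stat)) {
    cat(sprintf("  heterogeneity: Q = %.4f, df = %d, p = %.4f\n",
                x$q_stat, x$q_df, x$q_p))
  }
  invisible(x)
}

#' Frequentist fixed-effect meta-analysis
#'
#' Inverse-variance pooling under the common-effect assumption: weights
#' `w_i = 1/se_i^2`, pooled estimate `sum(w * d) / sum(w)` with variance
#' `1/sum(w)`. Cochran's Q is attached when two or more studies are present.
#'
#' @param input a [meta_input()].
#' @param level confidence level of the Wald interval.
#' @return A `meta_result`.
#' @export
fixed_effect_meta <- function(input, level = 0.95) {
  input <- meta_input(input)
  w <- 1 / input$se^2
  est <- sum(w * input$estimate) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- if (nrow(input) >= 2L) cochran_q(input) else
    list(q = NA_real_, df = NA_integer_, p = NA_real_)
  meta_result(est, se, level, weights = stats::setNames(w, input$label),
              model = "fixed", tau2 = 0,
              q_stat = q$q, q_df = q$df, q_p = q$p)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_i * (d_i - d_FE)^2)` with fixed-effect weights; under
#' homogeneity Q is approximately chi-square with `n - 1` degrees of freedom
#' (upper-tail p-value).
#'
#' @inheritParams fixed_effect_meta
#' @return A list with elements `q`, `df`, `p`.
#' @export
cochran_q <- function(input) {
  input <- meta_input(input)
  if (nrow(input) < 2L) stop("Cochran's Q needs at least 2 studies", call. = FALSE)
  w <- 1 / input$se^2
  est <- sum(w * input$estimate) / sum(w)
  q <- sum(w * (input$estimate - est)^2)
  df <- nrow(input) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Between-study variance estimators
#'
#' `dersimonian_laird_tau2()` is the moment estimator
#' `max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` built on fixed-effect
#' weights; `reml_tau2()` maximizes the restricted normal likelihood by
#' one-dimensional search (available behind the `method` flag of
#' [random_effects_meta()] but not the default).
#'
#' @inheritParams fixed_effect_meta
#' @return Non-negative scalar estimate of tau^2.
#' @export
dersimonian_laird_tau2 <- function(input) {
  input <- meta_input(input)
  if (nrow(input) < 2L) {
    stop("tau^2 estimation needs at least 2 studies", call. = FALSE)
  }
  w <- 1 / input$se^2
  q <- cochran_q(input)
  max(0, (q$q - q$df) / (sum(w) - sum(w^2) / sum(w)))
}

#' @rdname dersimonian_laird_tau2
#' @export
reml_tau2 <- function(input) {
  input <- meta_input(input)
  if (nrow(input) < 2L) {
    stop("tau^2 estimation needs at least 2 studies", call. = FALSE)
  }
  d <- input$estimate; v <- input$se^2
  nll <- function(t2) {
    wi <- 1 / (v + t2)
    mu <- sum(wi * d) / sum(wi)
    0.5 * (sum(log(v + t2)) + log(sum(wi)) + sum(wi * (d - mu)^2))
  }
  upper <- max(1e-4, 10 * stats::var(d))
  stats::optimize(nll, c(0, upper))$minimum
}

#' Frequentist random-effects meta-analysis
#'
#' Inverse-variance pooling with heterogeneity-adjusted weights
#' `w_i* = 1/(se_i^2 + tau2)`. With `tau2 = 0` this reduces exactly to
#' [fixed_effect_meta()].
#'
#' @inheritParams fixed_effect_meta
#' @param tau2 non-negative between-study variance, or `"estimate"` to use
#'   the estimator selected by `method`.
#' @param method `"DL"` (DerSimonian-Laird, default) or `"REML"`.
#' @return A `meta_result` with the `tau2` used.
#' @export
random_effects_meta <- function(input, tau2 = "estimate", level = 0.95,
                                method = c("DL", "REML")) {
  input <- meta_input(input)
  method <- match.arg(method)
  if (identical(tau2, "estimate")) {
    tau2 <- if (nrow(input) < 2L) 0 else
      switch(method, DL = dersimonian_laird_tau2(input),
             REML = reml_tau2(input))
  }
  stopifnot_scalar(tau2, "tau2", lower = 0)
  w <- 1 / (input$se^2 + tau2)
  est <- sum(w * input$estimate) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- if (nrow(input) >= 2L) cochran_q(input) else
    list(q = NA_real_, df = NA_integer_, p = NA_real_)
  meta_result(est, se, level, weights = stats::setNames(w, input$label),
              model = "random", tau2 = tau2,
              q_stat = q$q, q_df = q$df, q_p = q$p)
}
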