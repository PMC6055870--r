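#' Two-arm binary-outcome trial
#'
#' Container for the 2x2 event table of one randomized trial comparing a
#' treatment arm against a control arm. Event counts are binomial:
#' `treatment_events ~ Bin(treatment_total, p_T)` and likewise for control,
#' with the treatment effect defined on the logit scale,
#' `logit(p_T) = logit(p_C) + delta` (delta the log odds ratio).
#'
#' @param label non-empty study identifier.
#' @param treatment_events,treatment_total event count and arm size of the
#'   treatment arm; `0 <= events <= total`, `total >= 1`.
#' @param control_events,control_total same for the control arm.
#' @param role `"historical"` or `"new"`: whether the trial contributes prior
#'   (source-population) or prospective (target-population) evidence.
#' @return An object of class `two_arm_trial`.
#' @examples
#' two_arm_trial("Bond", 93, 219, 57, 219)
#' @export
two_arm_trial <- function(label, treatment_events, treatment_total,
                          control_events, control_total,
                          role = c("historical", "new")) {
  role <- match.arg(role)
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("`label` must be a non-empty string", call. = FALSE)
  }
  arms <- list(treatment = c(treatment_events, treatment_total),
               control = c(control_events, control_total))
  for (a in names(arms)) {
    ev <- arms[[a]][1]; tot <- arms[[a]][2]
    if (tot < 1) stop("invalid input: ", a, " arm has total 0", call. = FALSE)
    if (ev < 0 || ev > tot || ev != round(ev) || tot != round(tot)) {
      stop("invalid input: ", a, " arm counts must satisfy 0 <= events <= total",
           call. = FALSE)
    }
  }
  structure(list(label = label,
                 treatment = list(events = as.integer(treatment_events),
                                  total = as.integer(treatment_total)),
                 control = list(events = as.integer(control_events),
                                total = as.integer(control_total)),
                 role = role),
            class = "two_arm_trial")
}

#' @export
print.two_arm_trial <- function(x, ...) {
  cat(sprintf("<two_arm_trial> %s [%s]: treatment %d/%d (%.1f%%) vs control %d/%d (%.1f%%)\n",
              x$label, x$role,
              x$treatment$events, x$treatment$total,
              100 * x$treatment$events / x$treatment$total,
              x$control$events, x$control$total,
              100 * x$control$events / x$control$total))
  invisible(x)
}

#' @export
as.data.frame.two_arm_trial <- function(x, ...) {
  data.frame(label = x$label,
             treatment_events = x$treatment$events,
             treatment_total = x$treatment$total,
             control_events = x$control$events,
             control_total = x$control$total,
             role = x$role,
             stringsAsFactors = FALSE)
}

trials_to_df <- function(trials) {
  do.call(rbind, lapply(trials, as.data.frame))
}

df_to_trials <- function(df) {
  needed <- c("label", "treatment_events", "treatment_total",
              "control_events", "control_total", "role")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("trial table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials <- lapply(seq_len(nrow(df)), function(i) {
    two_arm_trial(df$label[i], df$treatment_events[i], df$treatment_total[i],
                  df$control_events[i], df$control_total[i],
                  role = df$role[i])
  })
  names(trials) <- df$label
  trials
}

#' Read / write two-arm trials as CSV or JSON
#'
#' The CSV schema is
#' `label,treatment_events,treatment_total,control_events,control_total,role`
#' with `role` one of `historical`/`new`; the JSON form is a list of objects
#' with the same six keys.
#'
#' @param path file path.
#' @param trials named list of [two_arm_trial()] objects.
#' @return Readers return a named list of `two_arm_trial`; writers return
#'   `path` invisibly.
#' @export
read_trials_csv <- function(path) {
  df_to_trials(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_trials_csv
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials_to_df(trials), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_trials_csv
#' @export
read_trials_json <- function(path) {
  df_to_trials(jsonlite::fromJSON(path, simplifyDataFrame = TRUE))
}

#' @rdname read_trials_csv
#' @export
write_trials_json <- function(trials, path) {
  jsonlite::write_json(trials_to_df(trials), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Effect estimate on the log odds ratio scale
#'
#' @param log_or point estimate (log odds ratio).
#' @param se positive standard error, treated as known in all meta-analytic
#'   models.
#' @param level confidence level of the attached Wald interval.
#' @param p_sided `"two_sided"` (default) or `"one_sided"` normal test of
#'   `log_or = 0`.
#' @param label study identifier.
#' @return An object of class `effect_estimate` with fields `log_or`, `se`,
#'   `ci_low`, `ci_high`, `level`, `p_value`, `p_sided`, `label`.
#' @export
effect_estimate <- function(log_or, se, level = 0.95,
                            p_sided = c("two_sided", "one_sided"),
                            label = "") {
  p_sided <- match.arg(p_sided)
  stopifnot_scalar(log_or, "log_or")
  stopifnot_scalar(se, "se", lower = .Machine$double.xmin)
  stopifnot_scalar(level, "level", lower = 1e-12, upper = 1 - 1e-12)
  ci <- log_or + c(-1, 1) * stats::qnorm((1 + level) / 2) * se
  z <- log_or / se
  p <- if (p_sided == "two_sided") 2 * stats::pnorm(-abs(z)) else
    stats::pnorm(z, lower.tail = FALSE)
  structure(list(log_or = log_or, se = se, ci_low = ci[1], ci_high = ci[2],
                 level = level, p_value = p, p_sided = p_sided, label = label),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s log OR %.3f (SE %.3f), %d%% CI (%.3f, %.3f), p[%s] = %.3g\n",
              x$label, x$log_or, x$se, round(100 * x$level), x$ci_low,
              x$ci_high, x$p_sided, x$p_value))
  invisible(x)
}

#' Log odds ratio of a two-arm trial
#'
#' Computes the observed log odds ratio `ln[(a/(n_T - a)) / (c/(n_C - c))]`
#' with the Woolf standard error `sqrt(1/a + 1/(n_T-a) + 1/c + 1/(n_C-c))`,
#' plus a Wald confidence interval and a normal test of no effect.
#'
#' @param trial a [two_arm_trial()].
#' @param correction if `TRUE` and any of the four table cells is zero, 0.5 is
#'   added to all four cells (continuity correction). With `FALSE` (default) a
#'   zero cell is an error: the log OR is undefined for a degenerate table.
#' @inheritParams effect_estimate
#' @return An [effect_estimate()].
#' @examples
#' log_odds_ratio(two_arm_trial("Bond", 93, 219, 57, 219))
#' @export
log_odds_ratio <- function(trial, correction = FALSE, level = 0.95,
                           p_sided = c("two_sided", "one_sided")) {
  stopifnot(inherits(trial, "two_arm_trial"))
  p_sided <- match.arg(p_sided)
  cells <- c(a = trial$treatment$events,
             b = trial$treatment$total - trial$treatment$events,
             c = trial$control$events,
             d = trial$control$total - trial$control$events)
  if (any(cells == 0)) {
    if (!correction) {
      bad <- names(cells)[cells == 0][1]
      what <- switch(bad,
                     a = "treatment events", b = "treatment non-events",
                     c = "control events", d = "control non-events")
      stop("degenerate table in study '", trial$label, "': zero ", what,
           " cell; enable `correction` to add 0.5 to each cell",
           call. = FALSE)
    }
    cells <- cells + 0.5
  }
  est <- log(cells["a"] / cells["b"]) - log(cells["c"] / cells["d"])
  se <- sqrt(sum(1 / cells))
  effect_estimate(unname(est), unname(se), level = level, p_sided = p_sided,
                  label = trial$label)
}

#' Wald interval for an effect estimate
#'
#' Symmetric normal-theory interval `log_or +/- z * se` with `z` the standard
#' normal `(1 + level)/2` quantile.
#'
#' @param est an [effect_estimate()].
#' @param level confidence level in (0, 1).
#' @return Numeric vector `c(low, high)`.
#' @export
wald_interval <- function(est, level = 0.95) {
  stopifnot(inherits(est, "effect_estimate"))
  stopifnot_scalar(level, "level", lower = 1e-12, upper = 1 - 1e-12)
  z <- stats::qnorm((1 + level) / 2)
  c(low = est$log_or - z * est$se, high = est$log_or + z * est$se)
}

#' Translate a risk-scale noninferiority margin to the log OR scale
#'
#' A margin of `rate_margin` (absolute excess event probability over the
#' control rate) corresponds on the log odds ratio scale to
#' `ln[odds(control_rate + rate_margin) / odds(control_rate)]`. A 10
#' percentage-point margin at a control rate near 31% gives roughly 0.43.
#'
#' @param control_rate control-arm event probability in (0, 1).
#' @param rate_margin non-negative risk-scale margin; `control_rate +
#'   rate_margin` must stay below 1.
#' @return The margin on the log odds ratio scale.
#' @examples
#' margin_to_log_or(0.311, 0.10)
#' @export
margin_to_log_or <- function(control_rate, rate_margin) {
  stopifnot_scalar(control_rate, "control_rate",
                   lower = 1e-12, upper = 1 - 1e-12)
  shifted <- control_rate + rate_margin
  if (rate_margin < 0 || shifted >= 1) {
    stop("`control_rate + rate_margin` must lie in [control_rate, 1)",
         call. = FALSE)
  }
  logit(shifted) - logit(control_rate)
}
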