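#' Decision configuration
#'
#' @param log_or_margin noninferiority margin on the log odds ratio scale;
#'   default 0.43 (a 10 percentage-point risk margin at a control rate near
#'   31%, see [margin_to_log_or()]).
#' @param level interval level used for the decisions.
#' @param direction `"events_are_harm"` (treatment failures; noninferiority
#'   applies) or `"events_are_benefit"` (e.g. symptom relief; noninferiority
#'   against an upper harm margin is not applicable).
#' @return A list of class `decision_config`.
#' @export
decision_config <- function(log_or_margin = 0.43, level = 0.95,
                            direction = c("events_are_harm",
                                          "events_are_benefit")) {
  stopifnot_scalar(log_or_margin, "log_or_margin")
  stopifnot_scalar(level, "level", lower = 1e-12, upper = 1 - 1e-12)
  structure(list(log_or_margin = log_or_margin, level = level,
                 direction = match.arg(direction)),
            class = "decision_config")
}

#' Apply significance and noninferiority rules to a result row
#'
#' Significance means the two-sided interval excludes 0. Noninferiority is
#' assessed only for harm-oriented outcomes and requires the upper interval
#' bound to fall strictly below the margin (equivalent to a one-sided test
#' at half the complement of the level); equality at the margin fails.
#'
#' @param row a list or one-row data frame with `method_label`, `estimate`,
#'   `ci_low`, `ci_high` and optionally `tau2_info`.
#' @param config a [decision_config()].
#' @return A one-row data frame of class `analysis_row` with columns
#'   `method_label`, `estimate`, `ci_low`, `ci_high`, `tau2_info`,
#'   `significant`, `noninferior` (`NA` when not applicable).
#' @export
assess <- function(row, config = decision_config()) {
  stopifnot(inherits(config, "decision_config"))
  row <- as.list(row)
  for (f in c("method_label", "estimate", "ci_low", "ci_high")) {
    if (is.null(row[[f]]) || is.na(row[[f]])) {
      stop("missing field `", f, "` in result row", call. = FALSE)
    }
  }
  if (!(row$ci_low <= row$estimate && row$estimate <= row$ci_high)) {
    stop("inconsistent row: estimate outside its interval", call. = FALSE)
  }
  out <- data.frame(method_label = row$method_label,
                    estimate = row$estimate,
                    ci_low = row$ci_low, ci_high = row$ci_high,
                    tau2_info = if (is.null(row$tau2_info)) "" else
                      as.character(row$tau2_info),
                    significant = row$ci_low > 0 || row$ci_high < 0,
                    noninferior = if (config$direction == "events_are_harm")
                      row$ci_high < config$log_or_margin else NA,
                    stringsAsFactors = FALSE)
  class(out) <- c("analysis_row", "data.frame")
  out
}

bayes_row <- function(label, fit, config, tau2_info = "") {
  assess(list(method_label = label,
              estimate = fit$summary$median,
              ci_low = fit$summary$cred_low,
              ci_high = fit$summary$cred_high,
              tau2_info = tau2_info), config)
}

freq_row <- function(label, fit, config, tau2_info = "") {
  assess(list(method_label = label, estimate = fit$estimate,
              ci_low = fit$ci_low, ci_high = fit$ci_high,
              tau2_info = tau2_info), config)
}

#' Run the full comparison battery
#'
#' Reproduces the forest-table layout of the worked examples, top to
#' bottom: one row per individual study, frequentist fixed-effect and
#' random-effects meta-analyses of all studies, Bayesian fixed-effect
#' meta-analysis, Bayesian random-effects meta-analyses across the
#' heterogeneity-prior battery, then (when a new study is present) the
#' fixed-effect MAP analysis and random-effects MAP analyses across the MAP
#' prior battery. Bayesian point estimates are posterior medians. All
#' Bayesian rows use the deterministic quadrature engine, so the battery is
#' fully reproducible.
#'
#' @param history list of historical [two_arm_trial()] objects.
#' @param new the new (target-population) [two_arm_trial()], or `NULL` for a
#'   meta-analysis-only battery.
#' @param decision a [decision_config()].
#' @param bayes a [bayes_config()] for the Bayesian meta-analysis rows.
#' @param re_priors named list of heterogeneity priors for the Bayesian
#'   random-effects rows (default: the five-prior grid).
#' @param map_priors named list for the random-effects MAP rows (default:
#'   the grid without IG(1/1000,1), whose near-zero heterogeneity
#'   duplicates the fixed-effect MAP row).
#' @return A data frame of `analysis_row` records in display order.
#' @export
run_comparison <- function(history, new = NULL,
                           decision = decision_config(),
                           bayes = bayes_config(),
                           re_priors = default_het_priors(),
                           map_priors = default_het_priors()[
                             setdiff(names(default_het_priors()),
                                     "IG(1/1000,1)")]) {
  if (inherits(history, "two_arm_trial")) history <- list(history)
  trials <- c(history, if (!is.null(new)) list(new))
  all_input <- meta_input(trials)
  rows <- list()
  add <- function(r, stage) {
    tryCatch(rows[[length(rows) + 1L]] <<- r,
             error = function(e) stop("stage '", stage, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  for (tr in trials) {
    est <- log_odds_ratio(tr, level = decision$level)
    add(assess(list(method_label = tr$label, estimate = est$log_or,
                    ci_low = est$ci_low, ci_high = est$ci_high), decision),
        tr$label)
  }

  fe <- fixed_effect_meta(all_input, level = decision$level)
  add(freq_row("F MA FE", fe, decision,
               sprintf("Q=%.2f, p=%.3f", fe$q_stat, fe$q_p)), "F MA FE")
  re <- random_effects_meta(all_input, level = decision$level)
  add(freq_row("F MA RE", re, decision,
               sprintf("tau2=%.4f", re$tau2)), "F MA RE")

  bfe <- bayes_fixed_effect(all_input, bayes)
  add(bayes_row("B MA FE", bfe, decision), "B MA FE")
  for (nm in names(re_priors)) {
    cfg <- bayes
    cfg$het_prior <- re_priors[[nm]]
    add(bayes_row(paste("B MA RE", nm),
                  bayes_random_effects(all_input, cfg), decision,
                  tau2_info = nm), paste("B MA RE", nm))
  }

  if (!is.null(new)) {
    hist_input <- meta_input(history)
    new_est <- log_odds_ratio(new, level = decision$level)
    add(bayes_row("B MAP FE",
                  map_update(map_prior_fixed(hist_input), new_est,
                             level = decision$level), decision), "B MAP FE")
    for (nm in names(map_priors)) {
      pr <- map_prior_random(hist_input, map_priors[[nm]])
      add(bayes_row(paste("B MAP RE", nm),
                    map_update(pr, new_est, level = decision$level),
                    decision, tau2_info = nm), paste("B MAP RE", nm))
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("analysis_row", "data.frame")
  out
}

#' Write / read analysis rows as CSV
#'
#' Header (bit-exact):
#' `method_label,estimate,ci_low,ci_high,tau2_info,significant,noninferior`.
#'
#' @param rows an `analysis_row` data frame ([run_comparison()] output).
#' @param path file path.
#' @return `path` (writer, invisibly) or the data frame (reader), with
#'   decision flags re-derivable from the numeric columns.
#' @export
write_analysis_rows <- function(rows, path) {
  df <- as.data.frame(rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("method_label,estimate,ci_low,ci_high,tau2_info",
                   "significant,noninferior", sep = ","), con)
  # method_label and tau2_info are quoted: prior labels contain commas
  writeLines(sprintf("\"%s\",%.6f,%.6f,%.6f,\"%s\",%s,%s",
                     df$method_label, df$estimate, df$ci_low, df$ci_high,
                     df$tau2_info, df$significant, df$noninferior), con)
  invisible(path)
}

#' @rdname write_analysis_rows
#' @export
read_analysis_rows <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(method_label = "character",
                                       estimate = "numeric",
                                       ci_low = "numeric",
                                       ci_high = "numeric",
                                       tau2_info = "character",
                                       significant = "logical",
                                       noninferior = "logical"))
  class(df) <- c("analysis_row", "data.frame")
  df
}
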