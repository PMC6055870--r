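#' Worked-example trial tables
#'
#' The seven printed two-arm trials used throughout: the Bond and Opera
#' omeprazole trials in functional dyspepsia (events are symptom relief, a
#' benefit), the three adult immunosuppression trials after kidney
#' transplantation (events are treatment failure, a harm), and the two
#' hypothetical paediatric scenarios for the same programme (Scenario 1
#' homogeneous with the adult effect, Scenario 2 with a true log OR just
#' above the 0.43 noninferiority margin).
#'
#' @return Named list of [two_arm_trial()] objects: `bond`, `opera`,
#'   `vitko`, `lorber`, `tedesco`, `scenario1`, `scenario2`.
#' @examples
#' trial_fixtures()$bond
#' @export
trial_fixtures <- function() {
  list(
    bond = two_arm_trial("Bond", 93, 219, 57, 219, role = "historical"),
    opera = two_arm_trial("Opera", 68, 202, 62, 203, role = "new"),
    vitko = two_arm_trial("Vitko", 58, 194, 61, 196, role = "historical"),
    lorber = two_arm_trial("Lorber", 48, 193, 54, 196, role = "historical"),
    tedesco = two_arm_trial("Tedesco Silva", 70, 277, 67, 277,
                            role = "historical"),
    scenario1 = two_arm_trial("Scenario 1", 16, 53, 16, 53, role = "new"),
    scenario2 = two_arm_trial("Scenario 2", 22, 53, 16, 53, role = "new")
  )
}

#' Simulate one two-arm binomial trial
#'
#' Control events are `Bin(n_c, control_rate)`; treatment events are
#' `Bin(n_t, inv_logit(logit(control_rate) + true_log_or))` — the effect
#' acts on the logit scale, matching the binomial-logit data model.
#'
#' @param control_rate control-arm event probability in (0, 1).
#' @param true_log_or true treatment effect (log odds ratio).
#' @param n_t,n_c arm sizes (>= 1).
#' @param seed integer seed; identical seeds give identical counts.
#' @param label,role passed to [two_arm_trial()].
#' @return A [two_arm_trial()].
#' @export
simulate_trial <- function(control_rate, true_log_or, n_t, n_c, seed,
                           label = "sim", role = "new") {
  stopifnot_scalar(control_rate, "control_rate",
                   lower = 1e-12, upper = 1 - 1e-12)
  stopifnot(n_t >= 1, n_c >= 1)
  set.seed(seed)
  p_t <- inv_logit(logit(control_rate) + true_log_or)
  two_arm_trial(label,
                treatment_events = stats::rbinom(1, n_t, p_t),
                treatment_total = n_t,
                control_events = stats::rbinom(1, n_c, control_rate),
                control_total = n_c,
                role = role)
}

#' Specification of a simulated adult + paediatric programme
#'
#' Defaults emulate the immunosuppression extrapolation setting: three
#' adult trials of about 195, 195 and 277 patients per arm, one paediatric
#' trial of 53 per arm, a control failure rate of 0.28 and a true log OR of
#' 0 (the adult evidence is consistent with no effect), with optional
#' between-study heterogeneity `tau` on the log OR scale.
#'
#' @param control_rate shared control-arm event probability.
#' @param true_log_or overall true treatment effect.
#' @param tau between-study SD of true study effects (`delta_i ~
#'   N(true_log_or, tau^2)`); 0 gives a fully homogeneous programme.
#' @param adult_n per-arm sizes of the adult trials (one entry per trial).
#' @param paediatric_n per-arm size of the paediatric trial.
#' @param seed integer seed.
#' @return A list of class `programme_spec`.
#' @export
programme_spec <- function(control_rate = 0.28, true_log_or = 0, tau = 0,
                           adult_n = c(195L, 195L, 277L),
                           paediatric_n = 53L, seed = 1L) {
  stopifnot_scalar(tau, "tau", lower = 0)
  stopifnot(length(adult_n) >= 1, all(adult_n >= 1), paediatric_n >= 1)
  structure(list(control_rate = control_rate, true_log_or = true_log_or,
                 tau = tau, adult_n = as.integer(adult_n),
                 paediatric_n = as.integer(paediatric_n),
                 seed = as.integer(seed)),
            class = "programme_spec")
}

#' Simulate an adult + paediatric development programme
#'
#' Study-specific true effects are drawn `delta_i ~ N(true_log_or, tau^2)`
#' (adult studies first, the paediatric study last), then each trial is
#' simulated with [simulate_trial()]. Per-study random streams are split
#' deterministically from `spec$seed`, so adding studies leaves earlier
#' ones unchanged.
#'
#' @param spec a [programme_spec()].
#' @return A list with `adult` (list of trials), `paediatric` (one trial),
#'   and `true_effects` (named vector of realized true study log ORs, the
#'   paediatric entry last).
#' @export
simulate_programme <- function(spec) {
  stopifnot(inherits(spec, "programme_spec"))
  k <- length(spec$adult_n)
  set.seed(derive_seed(spec$seed, 0L))
  true_effects <- stats::rnorm(k + 1L, spec$true_log_or, spec$tau)
  names(true_effects) <- c(paste0("Adult ", seq_len(k)), "Paediatric")
  adult <- lapply(seq_len(k), function(i) {
    simulate_trial(spec$control_rate, true_effects[i],
                   n_t = spec$adult_n[i], n_c = spec$adult_n[i],
                   seed = derive_seed(spec$seed, i),
                   label = paste0("Adult ", i), role = "historical")
  })
  paediatric <- simulate_trial(spec$control_rate, true_effects[k + 1L],
                               n_t = spec$paediatric_n,
                               n_c = spec$paediatric_n,
                               seed = derive_seed(spec$seed, k + 1L),
                               label = "Paediatric", role = "new")
  list(adult = adult, paediatric = paediatric, true_effects = true_effects)
}
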