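# Synthetic transient-editing experiments: cut/repair kinetics of the
# target-DNA population and a noisy qPCR readout.
#
# The DNA population at a target site is split into three states:
# intact wild type (cuttable), intact mutant (repaired with a mutation,
# never re-cut because the protospacer no longer matches), and broken
# (unamplifiable by PCR). Cutting converts wild type to broken at rate k;
# repair resolves broken DNA at rate rho, a fraction mu of repairs
# introducing a mutation and the rest restoring the cuttable wild type.

#' Kinetic parameters of the cut-and-repair model
#'
#' @param k_cut Cutting rate of intact wild-type DNA (per hour),
#'   proportional to the per-cell Cas9/gRNA activity.
#' @param rho_repair Resolution rate of broken DNA (per hour).
#' @param mu_mut Fraction of repair events that mutate the site, in `[0, 1]`.
#' @param t_end Simulated time span (hours). The default 48 matches the
#'   post-transformation window at which transient Cas9 expression peaks
#'   and samples are harvested.
#' @param cas9_level Relative Cas9 transcript abundance (drives `k_cut`
#'   and is what the cDNA assay observes).
#' @param delivery_scale Transformation-efficiency multiplier (models a
#'   delivery-boosting treatment such as sonication). It scales how much
#'   of the tissue carries the editing machinery, so in the qPCR readout
#'   it multiplies both the observed broken-DNA abundance and the observed
#'   Cas9 transcript abundance; within-cell kinetics are unaffected.
#' @return A validated list of class `"cut_repair_params"`.
#' @export
cut_repair_params <- function(k_cut = 0.1, rho_repair = 0.2, mu_mut = 0.3,
                              t_end = 48, cas9_level = 1, delivery_scale = 1) {
  stopifnot(k_cut >= 0, rho_repair >= 0, mu_mut >= 0, mu_mut <= 1,
            t_end > 0, cas9_level > 0, delivery_scale > 0)
  structure(list(k_cut = k_cut, rho_repair = rho_repair, mu_mut = mu_mut,
                 t_end = t_end, cas9_level = cas9_level,
                 delivery_scale = delivery_scale),
            class = "cut_repair_params")
}

#' qPCR readout parameters
#'
#' @param ct_baseline Ct of every assay in an untreated control sample
#'   (cycles). Its absolute value is immaterial to all estimators, which
#'   only use Ct differences.
#' @param amp_efficiency Per-cycle amplification efficiency E in `(0, 1]`;
#'   the per-cycle gain is `1 + E`. The estimators assume E = 1; lowering E
#'   here lets parameter-recovery studies probe that assumption.
#' @param ct_noise_sd Gaussian well-to-well noise on Ct (cycles).
#' @param seed Integer seed, or `NULL` to leave the RNG state alone.
#' @return A validated list of class `"readout_params"`.
#' @export
readout_params <- function(ct_baseline = 20, amp_efficiency = 1,
                           ct_noise_sd = 0.2, seed = NULL) {
  stopifnot(ct_baseline > 0, amp_efficiency > 0, amp_efficiency <= 1,
            ct_noise_sd >= 0)
  structure(list(ct_baseline = ct_baseline, amp_efficiency = amp_efficiency,
                 ct_noise_sd = ct_noise_sd, seed = seed),
            class = "readout_params")
}

#' Simulate cut-and-repair kinetics of the target-DNA population
#'
#' Integrates the three-state system from the all-wild-type initial state
#' `(1, 0, 0)`:
#' \deqn{df_{wt}/dt = -k f_{wt} + \rho (1-\mu) f_{broken}}
#' \deqn{df_{mut}/dt = \rho \mu f_{broken}}
#' \deqn{df_{broken}/dt = k f_{wt} - \rho f_{broken}}
#' with `k = k_cut`, `rho = rho_repair`, `mu = mu_mut`. Mutant DNA is an
#' absorbing state: its protospacer no longer matches the guide, so it is
#' never re-cut. The fractions are conserved (sum to 1) to within 1e-8,
#' enforced after integration.
#'
#' Integration uses `deSolve` on a fixed output grid; as a guard against a
#' meaninglessly coarse grid, `step` must not exceed the fastest system
#' timescale `1 / (k + rho)`.
#'
#' @param params A [cut_repair_params()].
#' @param step Output grid step (hours).
#' @return Data frame of class `"cut_repair_sim"` with columns `t`,
#'   `f_intact_wt`, `f_mutant`, `f_broken`.
#' @examples
#' sim <- simulate_cut_repair(cut_repair_params(k_cut = 0.1, rho_repair = 0.2))
#' final_state(sim)
#' @export
simulate_cut_repair <- function(params, step = 0.1) {
  stopifnot(inherits(params, "cut_repair_params"), step > 0)
  k <- params$k_cut
  rho <- params$rho_repair
  mu <- params$mu_mut
  rate_sum <- k + rho
  if (rate_sum > 0 && step > 1 / rate_sum) {
    stop(sprintf("step = %g exceeds the fastest kinetic timescale 1/(k + rho) = %g; use a smaller step",
                 step, 1 / rate_sum), call. = FALSE)
  }
  times <- seq(0, params$t_end, by = step)
  if (times[length(times)] < params$t_end) times <- c(times, params$t_end)
  deriv <- function(t, y, p) {
    list(c(-k * y[1] + rho * (1 - mu) * y[3],
           rho * mu * y[3],
           k * y[1] - rho * y[3]))
  }
  sol <- deSolve::ode(y = c(f_intact_wt = 1, f_mutant = 0, f_broken = 0),
                      times = times, func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  out <- as.data.frame(sol)
  names(out)[1] <- "t"
  drift <- abs(out$f_intact_wt + out$f_mutant + out$f_broken - 1)
  if (any(drift > 1e-8)) {
    stop("integration lost conservation of DNA fractions beyond 1e-8", call. = FALSE)
  }
  attr(out, "params") <- params
  class(out) <- c("cut_repair_sim", "data.frame")
  out
}

#' Final population state of a kinetics simulation
#'
#' @param sim A `"cut_repair_sim"`.
#' @param target_id Label attached to the returned row.
#' @return One-row data frame `target_id, f_intact_wt, f_mutant, f_broken`.
#' @export
final_state <- function(sim, target_id = "target") {
  stopifnot(inherits(sim, "cut_repair_sim"))
  last <- sim[nrow(sim), c("f_intact_wt", "f_mutant", "f_broken")]
  cbind(data.frame(target_id = target_id, stringsAsFactors = FALSE), last,
        row.names = NULL)
}

#' @export
plot.cut_repair_sim <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$f_intact_wt, x$f_mutant, x$f_broken),
                    type = "l", lty = 1, col = c("forestgreen", "orange", "red"),
                    xlab = "time (h)", ylab = "fraction of target DNA", ...)
  graphics::legend("right", legend = c("intact wild type", "intact mutant", "broken"),
                   col = c("forestgreen", "orange", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Write a kinetics time series as tidy CSV
#'
#' @param sim A `"cut_repair_sim"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinetics_csv <- function(sim, path) {
  utils::write.csv(as.data.frame(sim)[, c("t", "f_intact_wt", "f_mutant", "f_broken")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate the qPCR readout of a population state
#'
#' Turns per-target DNA population states into the long-format Ct table
#' that [tcep_quantify()] consumes. Broken DNA cannot be amplified, so the
#' amplifiable template at the cut-site amplicon is
#' `q = 1 - delivery_scale * f_broken` (intact wild type plus intact
#' mutant: a point mutation does not abolish primer binding), and the
#' test-sample Ct is delayed by `-log(q) / log(1 + E)` cycles relative to
#' `ct_baseline`. Reference assays and untreated controls sit at
#' `ct_baseline`. The Cas9 cDNA assay reads
#' `ct_baseline - log2(cas9_level * delivery_scale)`. Independent Gaussian
#' noise of sd `ct_noise_sd` is added to every well.
#'
#' `delivery_scale` enters as a population multiplier: a delivery-boosting
#' treatment puts the editing machinery into proportionally more cells, so
#' the tissue-level broken-DNA abundance and the Cas9 transcript abundance
#' rise together, and their ratio — the cutting efficiency — is unchanged
#' in expectation.
#'
#' @param states Data frame with one row per target: `target_id`,
#'   `f_intact_wt`, `f_mutant`, `f_broken` (see [final_state()]).
#' @param readout A [readout_params()].
#' @param cas9_level Relative Cas9 transcript abundance.
#' @param delivery_scale Transformation-efficiency multiplier.
#' @param n_replicates Biological replicates per group (default 3).
#' @param condition Condition label stamped on every record.
#' @return A validated Ct record data frame.
#' @export
simulate_ct_table <- function(states, readout = readout_params(),
                              cas9_level = 1, delivery_scale = 1,
                              n_replicates = 3, condition = "control") {
  stopifnot(inherits(readout, "readout_params"),
            is.data.frame(states), n_replicates >= 1,
            cas9_level > 0, delivery_scale > 0)
  need <- c("target_id", "f_intact_wt", "f_mutant", "f_broken")
  if (!all(need %in% names(states))) {
    stop("states must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(states$target_id)) stop("duplicate target_id", call. = FALSE)
  if (!is.null(readout$seed)) set.seed(readout$seed)
  base <- readout$ct_baseline
  gain <- log(1 + readout$amp_efficiency)
  rows <- list()
  add <- function(sample, target, assay, role, template, group, cond, rep, ct) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample, target_id = target, assay_id = assay, role = role,
      template = template, group = group, condition = cond,
      replicate = rep, ct = ct, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(states))) {
    tid <- states$target_id[i]
    b_obs <- delivery_scale * states$f_broken[i]
    q <- 1 - b_obs
    if (q <= 0) {
      stop(sprintf("target %s: observed broken abundance >= 1 (degenerate state)", tid),
           call. = FALSE)
    }
    ct_target_test <- base - log(q) / gain
    ct_cas <- base - log2(cas9_level * delivery_scale)
    for (r in seq_len(n_replicates)) {
      sm <- sprintf("%s_test_rep%d", condition, r)
      add(sm, tid, paste0(tid, "_amp"), "target_region", "genomic_dna",
          "test", condition, r, ct_target_test)
      add(sm, tid, "genomic_ref", "genomic_reference", "genomic_dna",
          "test", condition, r, base)
      add(sm, tid, "cas9", "cas9_transcript", "cdna", "test", condition, r, ct_cas)
      add(sm, tid, "transcript_ref", "transcript_reference", "cdna",
          "test", condition, r, base)
      sm <- sprintf("%s_control_rep%d", condition, r)
      add(sm, tid, paste0(tid, "_amp"), "target_region", "genomic_dna",
          "control", condition, r, base)
      add(sm, tid, "genomic_ref", "genomic_reference", "genomic_dna",
          "control", condition, r, base)
    }
  }
  out <- do.call(rbind, rows)
  if (readout$ct_noise_sd > 0) {
    out$ct <- out$ct + stats::rnorm(nrow(out), sd = readout$ct_noise_sd)
  }
  validate_ct_records(out)
  out
}

#' Simulate a multi-target experiment from prescribed broken fractions
#'
#' Direct shortcut past the kinetics: specify the true broken-DNA fraction
#' per target and get the full test-plus-control Ct table. With zero
#' readout noise, canonical quantification by [tcep_quantify()] returns
#' exactly the supplied fractions — the workhorse for estimator validation
#' and parameter-recovery studies.
#'
#' @param fractions Named numeric vector of true broken fractions in
#'   `[0, 1)`, one per target; names are the target ids.
#' @param cas9_level Relative Cas9 transcript abundance.
#' @param readout A [readout_params()].
#' @param n_replicates Biological replicates per group.
#' @param condition Condition label.
#' @param delivery_scale Transformation-efficiency multiplier (see
#'   [simulate_ct_table()]).
#' @return A validated Ct record data frame.
#' @examples
#' rec <- simulate_tcep_experiment(c(a = 0.08, b = 0.52),
#'                                 readout = readout_params(ct_noise_sd = 0))
#' coef(tcep_quantify(rec)) # folds 1 and 6.5
#' @export
simulate_tcep_experiment <- function(fractions, cas9_level = 1,
                                     readout = readout_params(),
                                     n_replicates = 3, condition = "control",
                                     delivery_scale = 1) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("fractions must be a named vector (names are target ids)", call. = FALSE)
  }
  if (anyDuplicated(names(fractions))) stop("duplicate target_id", call. = FALSE)
  if (any(fractions < 0 | fractions >= 1)) {
    stop("broken fractions must lie in [0, 1)", call. = FALSE)
  }
  states <- data.frame(target_id = names(fractions),
                       f_intact_wt = 1 - fractions, f_mutant = 0,
                       f_broken = as.numeric(fractions),
                       stringsAsFactors = FALSE)
  simulate_ct_table(states, readout = readout, cas9_level = cas9_level,
                    delivery_scale = delivery_scale,
                    n_replicates = n_replicates, condition = condition)
}
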