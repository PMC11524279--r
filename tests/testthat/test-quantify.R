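test_that("noiseless two-target quantification reproduces hand arithmetic", {
  # ddct 1 and 2 with equal Cas9: broken 0.5 and 0.75, folds 1 and 1.5
  rec <- rbind(manual_records("t1", ct_t = 21),
               manual_records("t2", ct_t = 22))
  fit <- tcep_quantify(rec)
  expect_s3_class(fit, "tcep_quant")
  expect_equal(fit$results$ddct, c(1, 2))
  expect_equal(fit$results$broken_fraction, c(0.5, 0.75))
  expect_equal(fit$results$intact_fraction, 2^(-fit$results$ddct))
  expect_equal(fit$results$broken_fraction + fit$results$intact_fraction,
               c(1, 1))
  expect_equal(unname(coef(fit)), c(1, 1.5))
  expect_equal(fit$reference, "t1")
})

test_that("quantification inverts the simulator exactly when noise is zero", {
  truth <- c(ts1 = 0.08, ts2 = 0.15, ts3 = 0.25, ts4 = 0.40, ts5 = 0.52)
  rec <- simulate_tcep_experiment(truth, readout = noiseless())
  fit <- tcep_quantify(rec)
  expect_equal(fit$results$broken_fraction, unname(truth), tolerance = 1e-12)
  expect_equal(fit$results$relative_efficiency, unname(truth), tolerance = 1e-12)
  expect_equal(unname(coef(fit)), unname(truth / min(truth)), tolerance = 1e-12)
  expect_equal(fit$results$sd, rep(0, 5))
  expect_equal(fit$results$n, rep(3L, 5))
})

test_that("literal mode reports the printed-formula abundance", {
  rec <- rbind(manual_records("t1", ct_t = 21), manual_records("t2", ct_t = 22))
  fit <- tcep_quantify(rec, mode = "literal")
  # abundance 2^-ddct: 0.5 and 0.25 -> weaker target is t2 in literal mode
  expect_equal(fit$results$relative_efficiency, c(0.5, 0.25))
  expect_equal(unname(coef(fit)), c(2, 1))
  expect_equal(fit$reference, "t2")
})

test_that("a null experiment is flagged instead of fold-normalised", {
  rec <- rbind(manual_records("t1", ct_t = 20), manual_records("t2", ct_t = 20))
  expect_warning(fit <- tcep_quantify(rec), "not meaningful")
  expect_equal(fit$results$broken_fraction, c(0, 0))
  expect_true(all(is.na(fit$results$normalized_efficiency)))
})

test_that("identical condition groups give t = 0 and no significance", {
  rec <- do.call(rbind, lapply(1:3, function(r) rbind(
    manual_records("t1", ct_t = 22, replicate = r, condition = "control"),
    manual_records("t1", ct_t = 22, replicate = r, condition = "heat"))))
  fit <- tcep_quantify(rec)
  expect_equal(unique(fit$results$t_statistic), 0)
  expect_equal(unique(fit$results$p_value), 1)
})

test_that("pairing choices agree when controls are replicate-identical", {
  rec <- do.call(rbind, lapply(1:3, function(r)
    manual_records("t1", ct_t = 22.5, replicate = r)))
  f1 <- tcep_quantify(rec, pairing = "mean_control")
  f2 <- tcep_quantify(rec, pairing = "per_replicate")
  expect_equal(f1$results$relative_efficiency, f2$results$relative_efficiency)
  # and diverge when control replicates differ
  rec2 <- rbind(manual_records("t1", ct_t = 22.5, ct_c = 20, replicate = 1),
                manual_records("t1", ct_t = 22.5, ct_c = 21, replicate = 2))
  f3 <- tcep_quantify(rec2, pairing = "per_replicate")
  expect_equal(f3$replicates$ddct, c(2.5, 1.5))
  f4 <- tcep_quantify(rec2, pairing = "mean_control")
  expect_equal(f4$replicates$ddct, c(2, 2))
})

test_that("incomplete replicates are dropped with a warning naming the role", {
  rec <- rbind(manual_records("t1", ct_t = 22, replicate = 1),
               manual_records("t1", ct_t = 22, replicate = 2))
  rec <- rec[!(rec$role == "cas9_transcript" & rec$replicate == 2), ]
  expect_warning(fit <- tcep_quantify(rec), "cas9_transcript")
  expect_equal(fit$results$n, 1L)
  # an undetermined well in a required role drops the replicate too
  rec2 <- rbind(manual_records("t1", ct_t = 22, replicate = 1),
                manual_records("t1", ct_t = 22, replicate = 2))
  rec2$ct[rec2$role == "target_region" & rec2$group == "test" &
            rec2$replicate == 2] <- NA
  expect_warning(fit2 <- tcep_quantify(rec2), "undetermined.*target_region")
  expect_equal(fit2$results$n, 1L)
  # and when nothing is usable the fit errors rather than inventing zeros
  rec3 <- manual_records("t1", ct_t = 22)
  rec3 <- rec3[rec3$role != "cas9_transcript", ]
  expect_error(suppressWarnings(tcep_quantify(rec3)), "no usable replicates")
})

test_that("quantification is invariant to per-sample Ct shifts end to end", {
  truth <- c(a = 0.2, b = 0.6)
  rec <- simulate_tcep_experiment(truth, readout = noiseless())
  fit0 <- tcep_quantify(rec)
  shifted <- rec
  for (sm in unique(shifted$sample_id)) {
    d <- stats::runif(1, -2, 2)
    shifted$ct[shifted$sample_id == sm] <- shifted$ct[shifted$sample_id == sm] + d
  }
  fit1 <- tcep_quantify(shifted)
  expect_equal(fit1$results$ddct, fit0$results$ddct, tolerance = 1e-10)
  expect_equal(fit1$results$relative_efficiency, fit0$results$relative_efficiency,
               tolerance = 1e-10)
})

test_that("summary-statistic t-test agrees with t.test on the raw replicates", {
  set.seed(42)
  for (i in 1:10) {
    x <- stats::rnorm(4, mean = 1, sd = 0.3)
    y <- stats::rnorm(5, mean = 1.4, sd = 0.3)
    mk <- function(v) data.frame(target_id = "t1",
                                 relative_efficiency = mean(v),
                                 sd = stats::sd(v), n = length(v),
                                 broken_fraction = NA_real_,
                                 cas9_abundance = NA_real_,
                                 stringsAsFactors = FALSE)
    cmp <- tcep_compare(mk(x), mk(y))
    ref <- stats::t.test(y, x, var.equal = TRUE)
    expect_equal(cmp$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("comparing an experiment with itself gives unit ratios and no stars", {
  rec <- do.call(rbind, lapply(1:3, function(r)
    manual_records("t1", ct_t = 21.5 + 0.1 * r, replicate = r)))
  fit <- tcep_quantify(rec)
  cmp <- tcep_compare(fit, fit)
  expect_equal(cmp$efficiency_ratio, 1)
  expect_equal(cmp$broken_ratio, 1)
  expect_equal(cmp$cas9_ratio, 1)
  expect_false(any(cmp$significant))
})

test_that("in vitro quantification aggregates replicates and normalises folds", {
  rec <- rbind(invitro_records("t1", ct_a = 21, replicate = 1),
               invitro_records("t1", ct_a = 21, replicate = 2),
               invitro_records("t2", ct_a = 22, replicate = 1),
               invitro_records("t2", ct_a = 22, replicate = 2))
  fit <- tcep_invitro(rec)
  expect_equal(fit$results$efficiency, c(0.5, 0.75))
  expect_equal(fit$results$normalized_efficiency, c(1, 1.5))
  expect_equal(fit$results$n, c(2L, 2L))
  # undetermined reference is fatal; undetermined target = complete digestion
  bad <- invitro_records("t1", ct_a = 21, ct_inter = NA)
  expect_error(tcep_invitro(bad), "undetermined reference")
  full <- rbind(invitro_records("t1", ct_a = NA), invitro_records("t2", ct_a = 21))
  expect_warning(fit2 <- tcep_invitro(full), "complete digestion")
  expect_equal(fit2$results$efficiency[fit2$results$target_id == "t1"], 1)
})
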