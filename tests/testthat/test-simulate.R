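test_that("without nuclease activity the population stays intact", {
  sim <- simulate_cut_repair(cut_repair_params(k_cut = 0, t_end = 24), step = 0.5)
  expect_true(all(sim$f_broken == 0))
  expect_true(all(sim$f_intact_wt == 1))
})

test_that("with no mutagenic repair the broken fraction reaches k/(k+rho)", {
  # closed-form steady state of the two-state cut/repair cycle
  for (pars in list(c(k = 0.1, rho = 0.2), c(k = 0.3, rho = 0.1))) {
    p <- cut_repair_params(k_cut = pars["k"], rho_repair = pars["rho"],
                           mu_mut = 0, t_end = 400)
    sim <- simulate_cut_repair(p, step = 0.5)
    expect_equal(sim$f_broken[nrow(sim)],
                 unname(pars["k"] / (pars["k"] + pars["rho"])), tolerance = 1e-6)
    expect_equal(sim$f_mutant[nrow(sim)], 0)
  }
})

test_that("fully mutagenic repair absorbs the whole population", {
  p <- cut_repair_params(k_cut = 0.5, rho_repair = 5, mu_mut = 1, t_end = 10 / 0.5)
  sim <- simulate_cut_repair(p, step = 0.1)
  expect_gt(sim$f_mutant[nrow(sim)], 0.999)
  expect_true(all(diff(sim$f_mutant) >= 0))   # absorbing state never drains
})

test_that("DNA fractions are conserved to 1e-8 across parameter space", {
  set.seed(5)
  for (i in 1:10) {
    p <- cut_repair_params(k_cut = stats::runif(1, 0, 0.5),
                           rho_repair = stats::runif(1, 0, 0.5),
                           mu_mut = stats::runif(1), t_end = 48)
    sim <- simulate_cut_repair(p, step = 0.5)
    expect_true(all(abs(sim$f_intact_wt + sim$f_mutant + sim$f_broken - 1) <= 1e-8))
    expect_true(all(sim$f_intact_wt >= 0 & sim$f_mutant >= 0 & sim$f_broken >= 0))
  }
})

test_that("a step coarser than the fastest timescale is refused", {
  p <- cut_repair_params(k_cut = 1, rho_repair = 4)
  expect_error(simulate_cut_repair(p, step = 0.5), "smaller step")
  expect_s3_class(simulate_cut_repair(p, step = 0.1), "cut_repair_sim")
})

test_that("faster cutting increases the broken fraction while cuttable DNA lasts", {
  # with non-mutagenic repair the cuttable pool is never exhausted and the
  # two-state monotone coupling makes the increase strict at every t > 0
  base <- simulate_cut_repair(cut_repair_params(k_cut = 0.1, mu_mut = 0), step = 0.5)
  hot <- simulate_cut_repair(cut_repair_params(k_cut = 0.3, mu_mut = 0), step = 0.5)
  expect_true(all(hot$f_broken[-1] > base$f_broken[-1]))
  # with mutagenic repair the same holds over the early transient, but the
  # faster cutter exhausts its cuttable pool sooner, so the curves cross
  # at late times
  base <- simulate_cut_repair(cut_repair_params(k_cut = 0.1, t_end = 24), step = 0.5)
  hot <- simulate_cut_repair(cut_repair_params(k_cut = 0.3, t_end = 24), step = 0.5)
  expect_true(all(hot$f_broken[-1] > base$f_broken[-1]))
})

test_that("the noiseless readout encodes template loss as a Ct delay", {
  st <- data.frame(target_id = "t", f_intact_wt = 0.5, f_mutant = 0, f_broken = 0.5)
  rec <- simulate_ct_table(st, readout = noiseless(), n_replicates = 1)
  ct_test <- rec$ct[rec$role == "target_region" & rec$group == "test"]
  ct_ctrl <- rec$ct[rec$role == "target_region" & rec$group == "control"]
  expect_equal(ct_test - ct_ctrl, 1)  # half the template, one doubling later
  # mutant DNA still amplifies: only the broken fraction delays Ct
  st2 <- data.frame(target_id = "t", f_intact_wt = 0.3, f_mutant = 0.2, f_broken = 0.5)
  rec2 <- simulate_ct_table(st2, readout = noiseless(), n_replicates = 1)
  expect_equal(rec2$ct[rec2$role == "target_region" & rec2$group == "test"],
               ct_test)
  # 75% broken corresponds to a delta-delta-Ct of 2
  rec3 <- simulate_tcep_experiment(c(t = 0.75), readout = noiseless())
  expect_equal(tcep_quantify(rec3)$results$ddct, 2, tolerance = 1e-12)
})

test_that("delivery scaling moves Cas9 Ct and broken abundance together", {
  st <- data.frame(target_id = "t", f_intact_wt = 0.8, f_mutant = 0, f_broken = 0.2)
  r1 <- simulate_ct_table(st, readout = noiseless(), delivery_scale = 1,
                          n_replicates = 1)
  r2 <- simulate_ct_table(st, readout = noiseless(), delivery_scale = 2,
                          n_replicates = 1)
  cas <- function(r) r$ct[r$role == "cas9_transcript"]
  expect_equal(cas(r1) - cas(r2), 1)  # doubled transcript: one cycle earlier
  f1 <- tcep_quantify(r1)
  f2 <- tcep_quantify(r2)
  expect_equal(f2$results$broken_fraction, 2 * f1$results$broken_fraction,
               tolerance = 1e-12)
  expect_equal(f2$results$cas9_abundance, 2 * f1$results$cas9_abundance,
               tolerance = 1e-12)
  # ... leaving the cutting efficiency invariant
  expect_equal(f2$results$relative_efficiency, f1$results$relative_efficiency,
               tolerance = 1e-12)
})

test_that("degenerate readouts are refused", {
  st <- data.frame(target_id = "t", f_intact_wt = 0, f_mutant = 0, f_broken = 1)
  expect_error(simulate_ct_table(st, readout = noiseless()), "degenerate")
  st2 <- data.frame(target_id = "t", f_intact_wt = 0.4, f_mutant = 0, f_broken = 0.6)
  expect_error(simulate_ct_table(st2, readout = noiseless(), delivery_scale = 2),
               "degenerate")
  expect_error(simulate_tcep_experiment(c(a = 0.2, a = 0.3)), "duplicate")
  expect_error(simulate_tcep_experiment(c(a = 1)), "\\[0, 1\\)")
})

test_that("a fixed seed makes the noisy readout reproducible", {
  ro <- readout_params(ct_noise_sd = 0.3, seed = 99)
  r1 <- simulate_tcep_experiment(c(a = 0.2, b = 0.5), readout = ro)
  r2 <- simulate_tcep_experiment(c(a = 0.2, b = 0.5), readout = ro)
  expect_identical(r1, r2)
  r3 <- simulate_tcep_experiment(c(a = 0.2, b = 0.5),
                                 readout = readout_params(ct_noise_sd = 0.3, seed = 100))
  expect_false(identical(r1$ct, r3$ct))
})

test_that("noisy triplicate experiments recover the true broken fraction", {
  set.seed(1)
  truth <- 0.5
  est <- replicate(100, {
    rec <- simulate_tcep_experiment(c(t = truth),
                                    readout = readout_params(ct_noise_sd = 0.2))
    suppressWarnings(tcep_quantify(rec)$results$broken_fraction)
  })
  expect_lt(abs(mean(est) - truth), 0.02)
})
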