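# Conformational space annealing machinery.

sys6 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- scaffold6()
      mod <- planted_energy_model(sc)
      fw <- delete_loop(sc$structure, sc$loop)
      cache <<- list(sc = sc, mod = mod, fw = fw,
                     sys = loopcsa:::csa_system(fw, sc$loop, mod))
    }
    cache
  }
})

test_that("the bank update rule follows the D_cut criterion", {
  fake <- function(e, bb) list(etotal = e, bb = bb, used = FALSE, age = 0L)
  b0 <- matrix(0, 4, 3)
  bank <- list(fake(5, b0), fake(2, b0 + 3), fake(8, b0 + 6))
  ## candidate worse than everyone and distant: unchanged
  up <- update_bank(bank, fake(9, b0 + 20), d_cut = 1)
  expect_false(up$replaced)
  ## candidate close to member 1 with lower energy: replaces member 1
  up <- update_bank(bank, fake(4, b0 + 0.1), d_cut = 1)
  expect_true(up$replaced); expect_equal(up$index, 1)
  ## candidate close to member 1 but higher energy: rejected even though
  ## it beats the global worst
  up <- update_bank(bank, fake(6, b0 + 0.1), d_cut = 1)
  expect_false(up$replaced)
  ## novel candidate better than the worst: replaces the worst
  up <- update_bank(bank, fake(6, b0 + 20), d_cut = 1)
  expect_true(up$replaced); expect_equal(up$index, 3)
  ## bank minimum is non-increasing over any update sequence
  set.seed(61)
  emin <- min(vapply(bank, function(m) m$etotal, numeric(1)))
  for (k in 1:50) {
    cand <- fake(runif(1, 0, 10), b0 + runif(1, 0, 10))
    bank <- update_bank(bank, cand, d_cut = 2)$bank
    newmin <- min(vapply(bank, function(m) m$etotal, numeric(1)))
    expect_lte(newmin, emin + 1e-12)
    emin <- newmin
    expect_length(bank, 3)
  }
})

test_that("crossover trials are closed; identical parents reproduce the seed", {
  s6 <- sys6()
  set.seed(62)
  states <- falc_sample(s6$fw, s6$sc$loop, s6$sys$library, 4, rng_seed = 8)
  m1 <- loopcsa:::member_from_state(s6$sys, states[[1]])
  m2 <- loopcsa:::member_from_state(s6$sys, states[[2]])
  cfg <- csa_config(6)
  ## identical seed and partner: closure preserves the seed
  tr <- generate_trial(m1, m1, s6$sys, cfg)
  expect_lt(max(abs(loopcsa:::wrap_angle(tr$phi - m1$state$phi))), 1e-6)
  expect_lt(max(abs(loopcsa:::wrap_angle(tr$psi - m1$state$psi))), 1e-6)
  ## mixed trials satisfy anchor closure
  for (k in 1:5) {
    tr <- generate_trial(m1, m2, s6$sys, cfg)
    built <- coords_from_torsions(s6$fw, s6$sc$loop, tr)
    tgt <- loopcsa:::c_anchor_targets(s6$fw, s6$sc$loop, tr, s6$sc$loop$end)
    expect_lt(loopcsa:::vnorm(
      loopcsa:::atom_xyz(built, "A", s6$sc$loop$end, "CA") - tgt$CA3), 1e-4)
  }
})

test_that("side-chain exchange is greedy and bounded", {
  s6 <- sys6()
  set.seed(63)
  states <- falc_sample(s6$fw, s6$sc$loop, s6$sys$library, 5, rng_seed = 9)
  bank <- lapply(states, function(st)
    loopcsa:::member_from_state(s6$sys, st))
  st <- states[[1]]
  e0 <- loopcsa:::member_from_state(s6$sys, st)$etotal
  ## max_trials = 0 leaves the state untouched
  expect_identical(sidechain_exchange(st, bank, s6$sys, max_trials = 0), st)
  ## energy never increases under exchange
  st2 <- sidechain_exchange(st, bank, s6$sys, max_trials = 3)
  e2 <- loopcsa:::member_from_state(s6$sys, st2)$etotal
  expect_lte(e2, e0 + 1e-9)
  ## with the native chi set planted in the bank, exchange recovers it
  ## when it lowers the energy (the planted chi tables make it favorable)
  nat_ts <- s6$sc$native_torsions
  bank2 <- c(bank, list(loopcsa:::member_from_state(s6$sys, nat_ts)))
  worst <- st
  worst$chi <- lapply(worst$chi, function(ch)
    if (length(ch)) loopcsa:::wrap_angle(ch + 120) else ch)
  e_w <- loopcsa:::member_from_state(s6$sys, worst)$etotal
  set.seed(64)
  got <- sidechain_exchange(worst, bank2[6], s6$sys, max_trials = 1)
  e_g <- loopcsa:::member_from_state(s6$sys, got)$etotal
  expect_lt(e_g, e_w)
  expect_equal(got$chi, nat_ts$chi, tolerance = 1e-9)
})

test_that("refinement never raises the energy and fixes closure", {
  s6 <- sys6()
  set.seed(65)
  states <- falc_sample(s6$fw, s6$sc$loop, s6$sys$library, 3, rng_seed = 10)
  cfg <- csa_config(6)
  for (st in states) {
    e0 <- loopcsa:::member_from_state(s6$sys, st)$etotal
    m <- refine_trial(st, s6$sys, cfg)
    expect_lte(m$etotal, e0 + 1e-9)
    built <- coords_from_torsions(s6$fw, s6$sc$loop, m$state)
    tgt <- loopcsa:::c_anchor_targets(s6$fw, s6$sc$loop, m$state,
                                      s6$sc$loop$end)
    expect_lt(loopcsa:::vnorm(
      loopcsa:::atom_xyz(built, "A", s6$sc$loop$end, "CA") - tgt$CA3), 1e-4)
  }
  ## refining from the planted native stays within its basin
  deep <- csa_config(6, shake_steps = 0, min_steps = 40)
  nat <- loopcsa:::member_from_state(s6$sys, s6$sc$native_torsions)
  m2 <- refine_trial(s6$sc$native_torsions, s6$sys, deep)
  expect_lte(m2$etotal, nat$etotal)
  bb <- loopcsa:::loop_backbone_rows(s6$fw, s6$sc$loop)
  expect_lt(loopcsa:::rmsd_direct(m2$xyz[bb, ], nat$xyz[bb, ]), 0.6)
})

test_that("torsion-space minimization solves a quadratic landscape", {
  sc <- scaffold6()
  mod <- toy_quadratic_model(sc)
  fw <- delete_loop(sc$structure, sc$loop)
  sys <- loopcsa:::csa_system(fw, sc$loop, mod)
  ## start from a mild closed perturbation of the optimum
  set.seed(67)
  st <- random_closed_state(sc, sd = 10)
  skip_if(is.null(st))
  cfg <- csa_config(6, shake_steps = 0, min_steps = 150, reclose_every = 3)
  m <- refine_trial(st, sys, cfg)
  ## analytic minimum is 0 at the native torsions (on the manifold)
  expect_lt(m$etotal, 1e-4 * max(1, loopcsa:::member_from_state(sys, st)$etotal))
  ## minimizer fixed point: a second minimization changes almost nothing
  m2 <- refine_trial(m$state, sys, csa_config(6, shake_steps = 0,
                                              min_steps = 30))
  expect_lt(m$etotal - m2$etotal, 1e-3)
})

test_that("run_csa is deterministic and its bank minimum is monotone", {
  s6 <- sys6()
  cfg <- csa_config(6, bank_size = 8, n_seeds = 3, n_iterations = 3,
                    trials_per_seed = 1, rng_seed = 68)
  r1 <- run_csa(s6$fw, s6$sc$loop, s6$mod, cfg)
  r2 <- run_csa(s6$fw, s6$sc$loop, s6$mod, cfg)
  expect_identical(loopcsa:::get_xyz(r1$final_model),
                   loopcsa:::get_xyz(r2$final_model))
  emin <- vapply(r1$trace, function(t) t$e_min, numeric(1))
  expect_true(all(diff(emin) <= 1e-9))
  dcut <- vapply(r1$trace, function(t) t$d_cut, numeric(1))
  expect_true(all(diff(dcut) < 0))
  expect_length(r1$bank, 8)
  ## all bank members closed
  for (m in r1$bank) {
    built <- coords_from_torsions(s6$fw, s6$sc$loop, m$state)
    tgt <- loopcsa:::c_anchor_targets(s6$fw, s6$sc$loop, m$state,
                                      s6$sc$loop$end)
    expect_lt(loopcsa:::vnorm(
      loopcsa:::atom_xyz(built, "A", s6$sc$loop$end, "CA") - tgt$CA3), 1e-4)
  }
})

test_that("the loop_model front end returns a usable fitted object", {
  s6 <- sys6()
  fit <- loop_model(s6$fw, s6$sc$loop, model = s6$mod,
                    config = csa_config(6, bank_size = 6, n_seeds = 2,
                                        n_iterations = 2,
                                        trials_per_seed = 1, rng_seed = 69),
                    reference = s6$sc$structure)
  expect_s3_class(fit, "loop_model")
  expect_output(print(fit), "Loop model")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.loop_model")
  expect_equal(nrow(sm$energy_terms), 10)
  expect_true(is.finite(fit$rmsd$loop_mainchain_rmsd))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
  ## loop spec string interface
  expect_error(loop_model(s6$fw, "A:banana"), "CHAIN:START-END")
})
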