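# Analytic tri-axial loop closure and FALC sampling.

# Independent oracle: enumerate closure solutions by brute numerical root
# finding on the cone-intersection residuals themselves (no resultants).
# For a dense grid of tau3, solve F_A(tau3, tau1) = 0 for tau1 by sign
# changes, then F_B(tau1, tau2) = 0 for tau2, and keep triples where
# F_C(tau2, tau3) changes sign along tau3.
closure_oracle <- function(problem, n_grid = 720) {
  s <- loopcsa:::tlc_setup(problem)
  if (!s$feasible) return(list())
  cs <- s$cones
  FA <- function(t3, t1) sum(loopcsa:::cone_eval(cs$vN1, t3) *
                               loopcsa:::cone_eval(cs$vC1, t1)) - cos(s$th[1])
  FB <- function(t1, t2) sum(loopcsa:::cone_eval(cs$wN2, t1) *
                               loopcsa:::cone_eval(cs$vC2, t2)) - cos(s$th[2])
  FC <- function(t2, t3) sum(loopcsa:::cone_eval(cs$wN3, t2) *
                               loopcsa:::cone_eval(cs$vC3, t3)) - cos(s$th[3])
  roots1d <- function(f, n = 360) {
    xs <- seq(-pi, pi, length.out = n + 1)
    ys <- vapply(xs, f, numeric(1))
    out <- c()
    for (k in seq_len(n)) {
      if (is.na(ys[k]) || is.na(ys[k + 1])) next
      if (ys[k] == 0) out <- c(out, xs[k])
      else if (ys[k] * ys[k + 1] < 0)
        out <- c(out, uniroot(f, c(xs[k], xs[k + 1]), tol = 1e-12)$root)
    }
    out
  }
  ## residual of the full system along tau3 branches
  g <- function(t3) {
    vals <- c()
    for (t1 in roots1d(function(x) FA(t3, x)))
      for (t2 in roots1d(function(x) FB(t1, x)))
        vals <- c(vals, FC(t2, t3))
    vals
  }
  xs <- seq(-pi, pi, length.out = n_grid + 1)
  sols <- list()
  prev <- NULL
  for (t3 in xs) {
    cur <- g(t3)
    if (!is.null(prev) && length(cur) == length(prev) && length(cur) > 0) {
      sw <- which(prev * cur < 0)
      for (b in sw) {
        r <- tryCatch(uniroot(function(x) {
          v <- g(x); if (length(v) >= b) v[b] else NA
        }, c(t3 - (xs[2] - xs[1]), t3), tol = 1e-10)$root,
        error = function(e) NULL)
        if (is.null(r)) next
        for (t1 in roots1d(function(x) FA(r, x)))
          for (t2 in roots1d(function(x) FB(t1, x)))
            if (abs(FC(t2, r)) < 1e-6)
              sols[[length(sols) + 1]] <- c(t1, t2, r)
      }
    }
    prev <- cur
  }
  ## deduplicate
  uniq <- list()
  for (tau in sols) {
    dup <- FALSE
    for (u in uniq) if (max(abs(loopcsa:::wrap_angle((tau - u) / pi * 180)))
                        < 0.01) dup <- TRUE
    if (!dup) uniq[[length(uniq) + 1]] <- tau
  }
  uniq
}

test_that("self-closure recovers the original pivot torsions", {
  for (seedk in 1:3) {
    sc <- make_scaffold(scaffold_spec(rng_seed = seedk))
    ts <- sc$native_torsions
    rs <- loop_resnos(sc$loop)
    for (piv in list(rs[c(1, 4, 8)], rs[c(2, 5, 7)], rs[c(1, 5, 8)])) {
      prb <- closure_problem(sc$structure, sc$loop, ts, piv)
      sols <- tlc_solve(prb)
      expect_gt(length(sols), 0)
      kp <- match(piv, ts$resnos)
      ref <- c(ts$phi[kp], ts$psi[kp])
      dev <- vapply(sols, function(s)
        max(abs(loopcsa:::wrap_angle(c(s$phi, s$psi) - ref))), numeric(1))
      expect_lt(min(dev), 1e-3)
      ## every returned solution satisfies the anchor postcondition
      for (sol in sols) {
        ts2 <- tlc_apply(ts, sol)
        built <- coords_from_torsions(sc$structure, sc$loop, ts2)
        tgt <- prb$targets
        expect_lt(loopcsa:::vnorm(
          loopcsa:::atom_xyz(built, "A", piv[3], "CA") - tgt$CA3), 1e-4)
        expect_lt(loopcsa:::vnorm(
          loopcsa:::atom_xyz(built, "A", piv[3], "C") - tgt$C3), 1e-4)
      }
    }
  }
})

test_that("an unreachable gap yields an empty solution list", {
  sc <- scaffold8()
  prot <- sc$structure
  ## displace the C-side anchor, including the framework-owned carbonyl
  rows <- which(prot$atoms$resno > sc$loop$end |
                  (prot$atoms$resno == sc$loop$end &
                     prot$atoms$name %in% c("C", "O")))
  xyz <- loopcsa:::get_xyz(prot)
  xyz[rows, 1] <- xyz[rows, 1] + 50
  prot2 <- loopcsa:::set_xyz(prot, xyz)
  prot2$breaks <- prot2$breaks[0, ]    # keep the loop formally valid
  prb <- closure_problem(prot2, sc$loop, sc$native_torsions,
                         loop_resnos(sc$loop)[c(1, 4, 8)])
  expect_length(tlc_solve(prb), 0)
})

test_that("the solution set matches a brute-force root-scan oracle", {
  sc <- scaffold8()
  ts <- sc$native_torsions
  rs <- loop_resnos(sc$loop)
  set.seed(31)
  for (rep in 1:3) {
    ts2 <- ts
    ts2$phi <- loopcsa:::wrap_angle(ts$phi + rnorm(8, 0, 25))
    ts2$psi <- loopcsa:::wrap_angle(ts$psi + rnorm(8, 0, 25))
    prb <- closure_problem(sc$structure, sc$loop, ts2, rs[c(1, 4, 8)])
    sols <- tlc_solve(prb)
    oracle <- closure_oracle(prb)
    expect_equal(length(sols), length(oracle))
    ## every oracle root appears among the returned solutions
    got <- lapply(sols, function(s) s$tau)
    for (tau in oracle) {
      dev <- vapply(got, function(g)
        max(abs(loopcsa:::wrap_angle((g - tau) * 180 / pi))), numeric(1))
      expect_lt(min(dev), 1e-3)
    }
  }
})

test_that("FALC generates closed, reproducible, diverse conformations", {
  sc <- scaffold8()
  sys <- loopcsa:::csa_system(sc$structure, sc$loop, energy_model())
  s1 <- falc_sample(sc$structure, sc$loop, sys$library, 12, rng_seed = 77)
  s2 <- falc_sample(sc$structure, sc$loop, sys$library, 12, rng_seed = 77)
  expect_length(s1, 12)
  ## bitwise reproducibility under the seed
  for (k in seq_along(s1)) {
    expect_identical(s1[[k]]$phi, s2[[k]]$phi)
    expect_identical(s1[[k]]$psi, s2[[k]]$psi)
  }
  ## closure exactness for every sample
  for (st in s1) {
    built <- coords_from_torsions(sc$structure, sc$loop, st)
    tgt <- loopcsa:::c_anchor_targets(sc$structure, sc$loop, st, sc$loop$end)
    expect_lt(loopcsa:::vnorm(
      loopcsa:::atom_xyz(built, "A", sc$loop$end, "CA") - tgt$CA3), 1e-4)
  }
  ## diversity: positive variance of pairwise main-chain RMSD
  bb <- loopcsa:::loop_backbone_rows(sc$structure, sc$loop)
  coords <- lapply(s1, function(st)
    loopcsa:::get_xyz(coords_from_torsions(sc$structure, sc$loop, st))[bb, ])
  d <- c()
  for (i in 1:11) for (j in (i + 1):12)
    d <- c(d, loopcsa:::rmsd_direct(coords[[i]], coords[[j]]))
  expect_gt(var(d), 0)
  expect_gt(mean(d), 0.5)
})

test_that("a library concentrated at the native basin samples near-native", {
  sc <- scaffold8()
  lib <- native_fragment_library(sc, spread = 8)
  states <- falc_sample(delete_loop(sc$structure, sc$loop), sc$loop, lib,
                        20, rng_seed = 5)
  rms <- vapply(states, function(st) {
    b <- coords_from_torsions(sc$structure, sc$loop, st)
    loop_mainchain_rmsd(b, sc$structure, sc$loop, "none")
  }, numeric(1))
  expect_lt(min(rms), 1.0)
})
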