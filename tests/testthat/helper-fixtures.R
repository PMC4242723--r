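# Shared fixtures, built once per test run and memoized.

.fix <- new.env(parent = emptyenv())

scaffold8 <- function() {
  if (is.null(.fix$sc8)) .fix$sc8 <- make_scaffold(scaffold_spec(rng_seed = 2))
  .fix$sc8
}

scaffold8b <- function() {
  if (is.null(.fix$sc8b))
    .fix$sc8b <- make_scaffold(scaffold_spec(rng_seed = 5))
  .fix$sc8b
}

scaffold6 <- function() {
  if (is.null(.fix$sc6))
    .fix$sc6 <- make_scaffold(scaffold_spec(rng_seed = 3, loop_length = 6))
  .fix$sc6
}

default_model_ctx <- function() {
  if (is.null(.fix$ctx8)) {
    sc <- scaffold8()
    .fix$mod8 <- energy_model()
    .fix$ctx8 <- energy_context(sc$structure, sc$loop, .fix$mod8)
  }
  list(model = .fix$mod8, ctx = .fix$ctx8)
}

# a random closed perturbation of the native loop (jitter + re-closure)
random_closed_state <- function(sc, sd = 25) {
  ts <- sc$native_torsions
  n <- length(ts$resnos)
  ts$phi <- loopcsa:::wrap_angle(ts$phi + rnorm(n, 0, sd))
  ts$psi <- loopcsa:::wrap_angle(ts$psi + rnorm(n, 0, sd))
  piv <- ts$resnos[c(1, ceiling(n / 2), n)]
  prb <- closure_problem(sc$structure, sc$loop, ts, piv)
  sols <- tlc_solve(prb)
  if (!length(sols)) return(NULL)
  tlc_apply(ts, sols[[1]])
}

# brute-force flip-minimized RMSD by exhaustive enumeration over all 2^k
# per-residue flip assignments (independent oracle)
brute_force_flip_rmsd <- function(model, reference, residues) {
  xm <- loopcsa:::get_xyz(model); xr <- loopcsa:::get_xyz(reference)
  per_res <- list()
  for (k in seq_len(nrow(residues))) {
    ch <- residues$chain[k]; i <- residues$resno[k]
    rows <- loopcsa:::residue_rows(reference, ch, i)
    rn <- reference$atoms$resname[rows[1]]
    nm <- reference$atoms$name[rows]
    nm <- nm[reference$atoms$element[rows] != "H"]
    ir <- loopcsa:::atom_indices(reference, ch, i, nm)
    im_id <- loopcsa:::atom_indices(model, ch, i, nm)
    pairs <- loopcsa:::FLIP_PAIRS[[rn]]
    nm_fl <- nm
    for (pr in pairs %||% list()) {
      nm_fl[nm == pr[1]] <- pr[2]; nm_fl[nm == pr[2]] <- pr[1]
    }
    im_fl <- loopcsa:::atom_indices(model, ch, i, nm_fl)
    per_res[[k]] <- list(ir = ir, options = if (is.null(pairs))
      list(im_id) else list(im_id, im_fl))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  nres <- length(per_res)
  combos <- expand.grid(rep(list(1:2), nres))
  best <- Inf; nat <- sum(vapply(per_res, function(p) length(p$ir), 0L))
  for (r in seq_len(nrow(combos))) {
    ssd <- 0
    okrow <- TRUE
    for (k in seq_len(nres)) {
      opt <- per_res[[k]]$options
      ci <- min(combos[r, k], length(opt))
      im <- opt[[ci]]
      ssd <- ssd + sum((xm[im, , drop = FALSE] -
                          xr[per_res[[k]]$ir, , drop = FALSE])^2)
    }
    best <- min(best, ssd)
  }
  sqrt(best / nat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a planted quadratic torsion landscape on a scaffold (global minimum at the
# native loop torsions, which lie on the closure manifold)
toy_quadratic_model <- function(sc, scale = 0.01) {
  nat <- sc$native_torsions
  cust <- function(tor, xyz, ctx)
    scale * sum(loopcsa:::wrap_angle(tor$phi - nat$phi)^2 +
                  loopcsa:::wrap_angle(tor$psi - nat$psi)^2)
  cgrad <- function(state, tmap) vapply(tmap, function(t) {
    if (t$kind == "phi")
      2 * scale * loopcsa:::wrap_angle(state$phi[t$k] - nat$phi[t$k])
    else if (t$kind == "psi")
      2 * scale * loopcsa:::wrap_angle(state$psi[t$k] - nat$psi[t$k])
    else 0
  }, numeric(1))
  energy_model(custom = cust, custom_grad = cgrad)
}

# Uniform "gas" of atoms of one class in a sphere of radius R, as an atom
# table for derive_pair_potential (sequence separations made large).
make_uniform_gas <- function(n = 3000, R = 100, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- R * runif(n)^(1 / 3)
  data.frame(class = "CH2", resno = 10 * seq_len(n),
             x = r * u[, 1], y = r * u[, 2], z = r * u[, 3])
}

# Pairs drawn from a planted Boltzmann distribution: p(r) proportional to
# (r / r_cut)^alpha exp(-u_true(r) / RT), placed as isolated two-atom units
# on a sparse grid so only intra-unit pairs fall inside r_cut.
make_boltzmann_pairs <- function(n_pairs = 1e5, depth = -1.0, r0 = 5,
                                 width = 0.6, alpha = 1.61, seed = 1) {
  set.seed(seed)
  rt <- loopcsa:::RT_KCAL
  centers <- seq(0.25, 14.75, by = 0.5)
  u_true <- depth * exp(-0.5 * ((centers - r0) / width)^2)
  w <- (centers / 14.75)^alpha * exp(-u_true / rt)
  bins <- sample(seq_along(centers), n_pairs, replace = TRUE, prob = w)
  r <- centers[bins] + runif(n_pairs, -0.25, 0.25)
  u <- matrix(rnorm(3 * n_pairs), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  ## batches of units strung along a line 40 A apart: cross-unit pairs all
  ## exceed r_cut, so the counted pairs are exactly the planted distances
  per <- 500
  lapply(split(seq_len(n_pairs), (seq_len(n_pairs) - 1) %/% per),
         function(ks) {
           gx <- 40 * (seq_along(ks) - 1)
           data.frame(class = "CH2",
                      resno = rep(10 * seq_along(ks), each = 2) +
                        rep(c(0, 5), length(ks)),
                      x = c(rbind(gx, gx + r[ks] * u[ks, 1])),
                      y = c(rbind(rep(0, length(ks)), r[ks] * u[ks, 2])),
                      z = c(rbind(rep(0, length(ks)), r[ks] * u[ks, 3])))
         })
}

# Minimal synthetic two-atom evaluation context for closed-form checks.
two_atom_ctx <- function(r1 = 1.7, r2 = 1.7, e1 = 0.1, e2 = 0.1,
                         q1 = 0, q2 = 0, r_on = 90, r_off = 100) {
  model <- energy_model(options = list(r_on = r_on, r_off = r_off))
  list(model = model, n = 2, loop_rows = 1L,
       scale = matrix(c(0, 1), 1, 2), ap_ok = matrix(FALSE, 1, 2),
       cls_idx = c(1L, 1L), heavy = c(TRUE, TRUE),
       q = c(q1, q2), radius = c(r1, r2), epsilon = c(e1, e2),
       gamma = c(0.015, 0.015), hct = c(0.72, 0.72),
       hb_pairs = NULL, bonds = matrix(integer(0), 0, 2), b0 = numeric(0),
       angles = matrix(integer(0), 0, 3), a0 = numeric(0),
       tors = matrix(integer(0), 0, 4),
       ppidx = list(), chi_idx = list(), resnames = character(0),
       frame_atoms = matrix(c(2L, 1L, 2L, 1L), 2, 2),
       sphere = loopcsa:::fibonacci_sphere(192))
}

xyz_pair <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))

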