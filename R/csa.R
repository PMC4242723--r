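## Conformational space annealing (CSA) of loop conformations.
##
## A fixed-size bank of closed conformations is evolved by genetic-style
## mixing: seed members are combined with partners by torsion-segment
## crossover, re-closed analytically, subjected to side-chain exchange with
## bank members, refined (noisy descent followed by deterministic
## minimization in torsion space with closure re-projection), and fed back
## into the bank under a shrinking diversity radius D_cut: a trial close to
## an existing member may only replace that member, a novel trial competes
## with the current worst.  The energy minimum of the final bank is the
## model.

#' CSA configuration
#'
#' Bank size defaults follow loop length: (M, N) = (10, 30) for loops
#' shorter than 12 residues and (20, 50) for 12 residues or longer.
#'
#' @param loop_length number of loop residues (sets the defaults).
#' @param bank_size N, number of bank members.
#' @param n_seeds M, seed members per iteration.
#' @param n_iterations annealing iterations.
#' @param trials_per_seed trial conformations per seed.
#' @param d_cut_init,d_cut_final annealing radius (Angstrom); by default
#'   half resp. one fifth of the initial average pairwise bank distance.
#' @param sidechain_exchange_max side-chain exchange attempts per trial.
#' @param patience stop after this many iterations without a replacement.
#' @param shake_steps,min_steps refinement schedule (noisy + deterministic).
#' @param init_min_steps minimization steps for initial bank members.
#' @param closure_retries retries for trial-generation closure.
#' @param final_min_steps deterministic minimization steps applied to every
#'   bank member before the final energy-minimum selection.
#' @param rng_seed integer seed.
#' @return object of class "csa_config".
#' @export
csa_config <- function(loop_length = 8, bank_size = NULL, n_seeds = NULL,
                       n_iterations = 50, trials_per_seed = 10,
                       d_cut_init = NULL, d_cut_final = NULL,
                       sidechain_exchange_max = 3, patience = 5,
                       shake_steps = 3, min_steps = 12, init_min_steps = 10,
                       reclose_every = 5, closure_retries = 10,
                       final_min_steps = 25, rng_seed = 1) {
  if (is.null(bank_size)) bank_size <- if (loop_length < 12) 30 else 50
  if (is.null(n_seeds)) n_seeds <- if (loop_length < 12) 10 else 20
  structure(list(bank_size = bank_size, n_seeds = n_seeds,
                 n_iterations = n_iterations,
                 trials_per_seed = trials_per_seed,
                 d_cut_init = d_cut_init, d_cut_final = d_cut_final,
                 sidechain_exchange_max = sidechain_exchange_max,
                 patience = patience, shake_steps = shake_steps,
                 min_steps = min_steps, init_min_steps = init_min_steps,
                 reclose_every = reclose_every,
                 closure_retries = closure_retries,
                 final_min_steps = final_min_steps, rng_seed = rng_seed),
            class = "csa_config")
}

## Bundle of everything the optimizer needs for one (structure, loop).
csa_system <- function(structure, loop, model = energy_model(),
                       library = NULL) {
  ctx <- energy_context(structure, loop, model)
  if (is.null(library))
    library <- fragment_library(model$phipsi, ctx$resnames)
  rs <- loop_resnos(loop)
  pivots <- rs[unique(round(c(1, (length(rs) + 1) / 2, length(rs))))]
  list(structure = structure, loop = loop, model = model, ctx = ctx,
       library = library, tmap = torsion_map(structure, loop),
       refine_pivots = pivots,
       bb_rows = loop_backbone_rows(structure, loop))
}

loop_backbone_rows <- function(prot, loop) {
  rs <- loop_resnos(loop)
  idx <- integer(0)
  for (i in rs)
    idx <- c(idx, atom_indices(prot, loop$chain, i, MAINCHAIN_ATOMS))
  idx
}

## --- torsion map for chain-rule gradients -----------------------------------

torsion_map <- function(prot, loop) {
  ch <- loop$chain
  rs <- loop_resnos(loop)
  rows_of <- lapply(rs, function(i) residue_rows(prot, ch, i))
  entries <- list()
  for (k in seq_along(rs)) {
    i <- rs[k]
    nm <- prot$atoms$name[rows_of[[k]]]
    resrows <- rows_of[[k]]
    after <- if (k < length(rs)) unlist(rows_of[(k + 1):length(rs)]) else
      integer(0)
    ax_phi <- atom_indices(prot, ch, i, c("N", "CA"))
    moved_phi <- c(resrows[!(nm %in% c("N", "H", "CA"))], after)
    entries[[length(entries) + 1]] <-
      list(kind = "phi", k = k, axis = ax_phi, moved = moved_phi)
    ax_psi <- atom_indices(prot, ch, i, c("CA", "C"))
    moved_psi <- c(resrows[nm == "O"], after)
    entries[[length(entries) + 1]] <-
      list(kind = "psi", k = k, axis = ax_psi, moved = moved_psi)
    rn <- prot$atoms$resname[resrows[1]]
    defs <- CHI_ATOMS[[rn]]
    if (!is.null(defs)) {
      zm <- SIDECHAIN_ZMAT[[rn]]
      for (c_k in seq_along(defs)) {
        ax <- atom_indices(prot, ch, i, defs[[c_k]][c(2, 3)])
        first <- which(!is.na(zm$chi) & zm$chi == c_k)[1]
        if (is.na(first)) next
        movnames <- zm$name[first:nrow(zm)]
        mov <- atom_indices(prot, ch, i, movnames)
        entries[[length(entries) + 1]] <-
          list(kind = "chi", k = k, chi = c_k, axis = ax,
               moved = mov[!is.na(mov)])
      }
    }
  }
  entries
}

## project a Cartesian gradient onto the mapped torsions (kcal/mol/degree)
torsion_gradient <- function(tmap, xyz, gcart) {
  vapply(tmap, function(t) {
    p <- xyz[t$axis[1], ]
    u <- unitv(xyz[t$axis[2], ] - p)
    m <- xyz[t$moved, , drop = FALSE]
    d <- sweep(m, 2, p)
    ## velocity of moved atoms under +1 rad rotation about the axis
    vel <- cbind(u[2] * d[, 3] - u[3] * d[, 2],
                 u[3] * d[, 1] - u[1] * d[, 3],
                 u[1] * d[, 2] - u[2] * d[, 1])
    ## increasing the dihedral rotates the downstream atoms by -1 about u
    -sum(vel * gcart[t$moved, , drop = FALSE]) * DEG
  }, numeric(1))
}

## knowledge-term gradient contributions on the same torsion entries
knowledge_torsion_gradient <- function(sys, state) {
  mod <- sys$model
  w <- mod$weights
  vapply(sys$tmap, function(t) {
    if (t$kind == "chi") {
      if (w$w_chi == 0) return(0)
      prof <- mod$chi$profiles[[sys$ctx$resnames[t$k]]]
      if (is.null(prof) || t$chi > length(prof)) return(0)
      w$w_chi * RT_KCAL *
        interp1_periodic_deriv(prof[[t$chi]], mod$chi$centers,
                               state$chi[[t$k]][t$chi])
    } else {
      if (w$w_phipsi == 0) return(0)
      g <- mod$phipsi$grid[[phipsi_class_for(mod$phipsi,
                                             sys$ctx$resnames[t$k])]]
      h <- 1
      if (t$kind == "phi") {
        d <- (interp2_periodic(g, mod$phipsi$centers, state$phi[t$k] + h,
                               state$psi[t$k]) -
                interp2_periodic(g, mod$phipsi$centers, state$phi[t$k] - h,
                                 state$psi[t$k])) / (2 * h)
      } else {
        d <- (interp2_periodic(g, mod$phipsi$centers, state$phi[t$k],
                               state$psi[t$k] + h) -
                interp2_periodic(g, mod$phipsi$centers, state$phi[t$k],
                                 state$psi[t$k] - h)) / (2 * h)
      }
      w$w_phipsi * RT_KCAL * d
    }
  }, numeric(1))
}

## Jacobian of the C-anchor atoms (CA, C, O of the last loop residue) wrt
## the mapped torsions; its null space is the tangent of the closure
## manifold.
closure_jacobian <- function(sys, xyz) {
  endrows <- atom_indices(sys$structure, sys$loop$chain, sys$loop$end,
                          c("CA", "C", "O"))
  J <- matrix(0, 9, length(sys$tmap))
  for (q in seq_along(sys$tmap)) {
    t <- sys$tmap[[q]]
    hit <- match(endrows, t$moved)
    if (all(is.na(hit))) next
    p <- xyz[t$axis[1], ]
    u <- unitv(xyz[t$axis[2], ] - p)
    for (w in which(!is.na(hit))) {
      d <- xyz[endrows[w], ] - p
      vel <- -DEG * c(u[2] * d[3] - u[3] * d[2],
                      u[3] * d[1] - u[1] * d[3],
                      u[1] * d[2] - u[2] * d[1])
      J[(3 * w - 2):(3 * w), q] <- vel
    }
  }
  J
}

## remove the gradient component that violates closure
project_gradient <- function(sys, xyz, gt) {
  J <- closure_jacobian(sys, xyz)
  JJ <- J %*% t(J)
  lam <- 1e-8 * max(diag(JJ), 1e-12)
  corr <- tryCatch(
    t(J) %*% solve(JJ + lam * diag(9), J %*% gt),
    error = function(e) NULL)
  if (is.null(corr)) return(gt)
  as.numeric(gt - corr)
}

## apply torsion increments (degrees) to a state
apply_torsion_step <- function(state, tmap, delta, free) {
  for (q in seq_along(tmap)) {
    if (!free[q] || delta[q] == 0) next
    t <- tmap[[q]]
    if (t$kind == "phi") state$phi[t$k] <- wrap_angle(state$phi[t$k] + delta[q])
    else if (t$kind == "psi")
      state$psi[t$k] <- wrap_angle(state$psi[t$k] + delta[q])
    else state$chi[[t$k]][t$chi] <- wrap_angle(state$chi[[t$k]][t$chi] +
                                                 delta[q])
  }
  state
}

## re-close a state on the system's refinement pivots; least-change root
reclose <- function(sys, state) {
  prb <- closure_problem(sys$structure, sys$loop, state, sys$refine_pivots)
  sols <- tlc_solve(prb)
  if (!length(sols)) return(NULL)
  tlc_apply(state, sols[[1]])
}

member_from_state <- function(sys, state) {
  built <- coords_from_torsions(sys$structure, sys$loop, state)
  xyz <- get_xyz(built)
  br <- total_energy(NULL, sys$loop, ctx = sys$ctx, xyz = xyz)
  list(state = state, xyz = xyz, energy = br, etotal = br$e_total,
       bb = xyz[sys$bb_rows, , drop = FALSE], used = FALSE, age = 0L)
}

## --- refinement -------------------------------------------------------------

#' Refine a trial conformation
#'
#' A short noisy-descent phase (thermal shaking) followed by deterministic
#' torsion-space minimization with analytic closure re-projection after
#' every step.  The returned member never has higher total energy than the
#' input state.
#'
#' @param state a closed "torsion_state".
#' @param sys a csa system (internal bundle from \code{\link{run_csa}}).
#' @param config a \code{\link{csa_config}}.
#' @param n_steps optional override of the minimization step count.
#' @return a bank member (list with state, coordinates, energy breakdown).
#' @export
refine_trial <- function(state, sys, config = csa_config(), n_steps = NULL) {
  mem <- member_from_state(sys, state)
  best <- mem
  free <- rep(TRUE, length(sys$tmap))
  shake <- config$shake_steps
  nmin <- if (is.null(n_steps)) config$min_steps else n_steps
  total <- shake + nmin
  every <- config$reclose_every %||% 5
  cur_state <- state
  cur_xyz <- mem$xyz
  cur_e <- mem$etotal
  eta <- 0.05
  consider_closed <- function(st) {
    cl <- reclose(sys, st)
    if (is.null(cl)) return(NULL)
    cm <- member_from_state(sys, cl)
    if (cm$etotal < best$etotal) best <<- cm
    cm
  }
  custom <- !is.null(sys$model$custom)
  for (it in seq_len(total)) {
    gt <- if (custom) {
      if (is.null(sys$model$custom_grad)) numeric(length(sys$tmap))
      else sys$model$custom_grad(cur_state, sys$tmap)
    } else {
      gc <- smooth_gradient(sys$ctx, cur_xyz)
      torsion_gradient(sys$tmap, cur_xyz, gc) +
        knowledge_torsion_gradient(sys, cur_state)
    }
    gt <- project_gradient(sys, cur_xyz, gt)
    delta <- -eta * gt
    mx <- max(abs(delta))
    if (mx > 10) delta <- delta * 10 / mx
    if (it <= shake) {
      noise <- rnorm(length(delta), 0, 1.5)
      delta <- delta + project_gradient(sys, cur_xyz, noise)
    }
    cand <- apply_torsion_step(cur_state, sys$tmap, delta, free)
    built <- coords_from_torsions(sys$structure, sys$loop, cand)
    bxyz <- get_xyz(built)
    be <- total_energy(NULL, sys$loop, ctx = sys$ctx, xyz = bxyz)$e_total
    if (it <= shake || be < cur_e) {
      cur_state <- cand; cur_xyz <- bxyz; cur_e <- be
      eta <- min(eta * 1.6, 4)
    } else {
      eta <- eta / 2
      if (eta < 1e-4) break
    }
    ## closure re-projection: the junction bond/angle terms restrain drift
    ## between re-closures; only closed states are candidates for the result
    if (it %% every == 0 || it == total) {
      cm <- consider_closed(cur_state)
      if (!is.null(cm)) {
        cur_state <- cm$state; cur_xyz <- cm$xyz; cur_e <- cm$etotal
      }
    }
  }
  if (best$etotal == mem$etotal) best <- mem
  best
}

## --- trial generation -------------------------------------------------------

#' Generate a trial conformation by bank crossover
#'
#' A contiguous torsion segment of the partner replaces the corresponding
#' segment of the seed; the spliced chain is re-closed analytically.  If
#' closure fails repeatedly, falls back to a single-torsion perturbation.
#'
#' @param seed_member,partner_member bank members.
#' @param sys csa system bundle.
#' @param config a \code{\link{csa_config}}.
#' @return a closed "torsion_state".
#' @export
generate_trial <- function(seed_member, partner_member, sys,
                           config = csa_config()) {
  n <- length(seed_member$state$resnos)
  for (try in seq_len(config$closure_retries)) {
    len <- sample(2:max(2, floor(n / 2)), 1)
    a <- sample.int(n - len + 1, 1)
    seg <- a:(a + len - 1)
    st <- seed_member$state
    st$phi[seg] <- partner_member$state$phi[seg]
    st$psi[seg] <- partner_member$state$psi[seg]
    st$omega[seg] <- partner_member$state$omega[seg]
    st$chi[seg] <- partner_member$state$chi[seg]
    st2 <- reclose_near(sys, st, seg)
    if (!is.null(st2)) return(st2)
  }
  ## fallback: pure single-torsion perturbation
  for (try in seq_len(config$closure_retries)) {
    st <- seed_member$state
    k <- sample.int(n, 1)
    if (runif(1) < 0.5) st$phi[k] <- wrap_angle(st$phi[k] + rnorm(1, 0, 30))
    else st$psi[k] <- wrap_angle(st$psi[k] + rnorm(1, 0, 30))
    st2 <- reclose(sys, st)
    if (!is.null(st2)) return(st2)
  }
  seed_member$state
}

## re-close with pivots flanking a spliced segment where possible
reclose_near <- function(sys, state, seg) {
  rs <- state$resnos
  n <- length(rs)
  p1 <- max(1, min(seg) - 1)
  p3 <- min(n, max(seg) + 1)
  p2 <- round((p1 + p3) / 2)
  piv <- unique(c(p1, p2, p3))
  if (length(piv) < 3 || min(diff(piv)) < 1) return(reclose(sys, state))
  prb <- closure_problem(sys$structure, sys$loop, state, rs[piv])
  sols <- tlc_solve(prb)
  if (!length(sols)) return(reclose(sys, state))
  tlc_apply(state, sols[[1]])
}

## --- side-chain exchange ----------------------------------------------------

#' Side-chain conformation exchange with bank members
#'
#' Up to \code{max_trials} times, the full side-chain chi set of a random
#' bank member is copied onto the trial; each exchange is kept only if the
#' total energy decreases.
#'
#' @param state a closed "torsion_state".
#' @param bank list of bank members.
#' @param sys csa system bundle.
#' @param max_trials maximum exchange attempts (default 3).
#' @return the (possibly improved) "torsion_state".
#' @export
sidechain_exchange <- function(state, bank, sys, max_trials = 3) {
  if (max_trials < 1) return(state)
  cur <- member_from_state(sys, state)
  for (t in seq_len(max_trials)) {
    donor <- bank[[sample.int(length(bank), 1)]]
    cand <- cur$state
    cand$chi <- donor$state$chi
    cm <- member_from_state(sys, cand)
    if (cm$etotal < cur$etotal) cur <- cm
  }
  cur$state
}

## --- bank update ------------------------------------------------------------

bank_distance <- function(m1, m2) rmsd_direct(m1$bb, m2$bb)

#' CSA bank update rule
#'
#' The bank member nearest to the candidate (unsuperposed loop main-chain
#' RMSD) is found; within D_cut the candidate may only replace that nearest
#' member, otherwise it competes with the current highest-energy member.
#' Either replacement happens only if the candidate's energy is lower.
#'
#' @param bank list of bank members.
#' @param candidate a bank member.
#' @param d_cut distance criterion in Angstrom.
#' @return list(bank, replaced, index).
#' @export
update_bank <- function(bank, candidate, d_cut) {
  d <- vapply(bank, bank_distance, numeric(1), m2 = candidate)
  nearest <- which.min(d)
  if (d[nearest] < d_cut) {
    if (candidate$etotal < bank[[nearest]]$etotal) {
      candidate$used <- bank[[nearest]]$used
      bank[[nearest]] <- candidate
      return(list(bank = bank, replaced = TRUE, index = nearest))
    }
    return(list(bank = bank, replaced = FALSE, index = NA_integer_))
  }
  worst <- which.max(vapply(bank, function(m) m$etotal, numeric(1)))
  if (candidate$etotal < bank[[worst]]$etotal) {
    candidate$used <- bank[[worst]]$used
    bank[[worst]] <- candidate
    return(list(bank = bank, replaced = TRUE, index = worst))
  }
  list(bank = bank, replaced = FALSE, index = NA_integer_)
}

## --- bank initialization ----------------------------------------------------

#' Initialize the CSA bank by FALC sampling
#'
#' @param sys csa system bundle.
#' @param config a \code{\link{csa_config}}.
#' @return list of locally minimized bank members of length
#'   \code{config$bank_size}.
#' @export
initialize_bank <- function(sys, config = csa_config()) {
  need <- config$bank_size
  states <- list()
  seed <- config$rng_seed
  while (length(states) < need) {
    got <- falc_sample(sys$structure, sys$loop, sys$library,
                       n_samples = need - length(states), rng_seed = seed)
    states <- c(states, got)
    seed <- seed + 10007
  }
  lapply(states[seq_len(need)], function(st)
    refine_trial(st, sys, config, n_steps = config$init_min_steps))
}

## --- the annealing loop -----------------------------------------------------

#' Run conformational space annealing for a loop
#'
#' @param structure "protein" with topology built (framework; the loop's
#'   input coordinates are not used beyond anchor geometry).
#' @param loop a \code{\link{loop_definition}}.
#' @param model an \code{\link{energy_model}}.
#' @param config a \code{\link{csa_config}}.
#' @return list with \code{final_model} (a "protein"), \code{bank},
#'   \code{trace} (per-iteration log) and \code{config}.
#' @export
run_csa <- function(structure, loop, model = energy_model(),
                    config = csa_config(loop$n_residues), library = NULL) {
  sys <- csa_system(structure, loop, model, library)
  set.seed(config$rng_seed)
  bank <- initialize_bank(sys, config)
  nd <- length(bank)
  dists <- c()
  for (i in seq_len(nd - 1)) for (j in (i + 1):nd)
    dists <- c(dists, bank_distance(bank[[i]], bank[[j]]))
  d_init <- config$d_cut_init %||% max(mean(dists) / 2, 0.5)
  d_final <- config$d_cut_final %||% max(mean(dists) / 5, 0.2)
  decay <- if (config$n_iterations > 1)
    (d_final / d_init)^(1 / (config$n_iterations - 1)) else 1
  trace <- list()
  no_repl <- 0
  d_cut <- d_init
  for (iter in seq_len(config$n_iterations)) {
    unused <- which(!vapply(bank, function(m) m$used, logical(1)))
    if (length(unused) < config$n_seeds)
      for (i in seq_along(bank)) bank[[i]]$used <- FALSE
    unused <- which(!vapply(bank, function(m) m$used, logical(1)))
    seeds <- sample(unused, min(config$n_seeds, length(unused)))
    nrep <- 0
    for (s in seeds) {
      bank[[s]]$used <- TRUE
      for (t in seq_len(config$trials_per_seed)) {
        partner <- sample(setdiff(seq_along(bank), s), 1)
        tst <- generate_trial(bank[[s]], bank[[partner]], sys, config)
        tst <- sidechain_exchange(tst, bank, sys,
                                  config$sidechain_exchange_max)
        cand <- refine_trial(tst, sys, config)
        up <- update_bank(bank, cand, d_cut)
        bank <- up$bank
        if (up$replaced) nrep <- nrep + 1
      }
    }
    es <- vapply(bank, function(m) m$etotal, numeric(1))
    trace[[iter]] <- list(iteration = iter, d_cut = d_cut,
                          e_min = min(es), e_mean = mean(es),
                          replacements = nrep)
    no_repl <- if (nrep == 0) no_repl + 1 else 0
    if (no_repl >= config$patience) break
    d_cut <- d_cut * decay
  }
  ## final local minimization of every bank member before selecting the
  ## energy minimum, so selection compares converged energies
  fin <- config$final_min_steps %||% 25
  if (fin > 0) {
    polish <- csa_config(loop$n_residues, shake_steps = 0, min_steps = fin)
    polish$reclose_every <- config$reclose_every
    bank <- lapply(bank, function(m) {
      p <- refine_trial(m$state, sys, polish)
      p$used <- m$used
      p
    })
  }
  es <- vapply(bank, function(m) m$etotal, numeric(1))
  bestm <- bank[[which.min(es)]]
  final <- set_xyz(structure, bestm$xyz)
  list(final_model = final, bank = bank, trace = trace, config = config,
       sys = sys)
}
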