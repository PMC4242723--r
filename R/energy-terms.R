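## Evaluation of the individual energy terms over a precomputed context.
## Internal workhorses take (ctx, xyz); exported wrappers take
## (structure, loop_region, model).

## --- bonded -----------------------------------------------------------------

eval_bonded <- function(ctx, xyz, grad = FALSE) {
  e <- 0
  g <- if (grad) matrix(0, ctx$n, 3) else NULL
  b <- ctx$bonds
  if (nrow(b)) {
    dv <- xyz[b[, 1], , drop = FALSE] - xyz[b[, 2], , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    dr <- r - ctx$b0
    e <- e + KBOND * sum(dr^2)
    if (grad) {
      f <- 2 * KBOND * dr / r
      gv <- dv * f
      g <- accum_rows(g, c(b[, 1], b[, 2]), rbind(gv, -gv))
    }
  }
  a <- ctx$angles
  if (nrow(a)) {
    u <- xyz[a[, 1], , drop = FALSE] - xyz[a[, 2], , drop = FALSE]
    v <- xyz[a[, 3], , drop = FALSE] - xyz[a[, 2], , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    ct <- pmax(-1, pmin(1, rowSums(u * v) / (nu * nv)))
    th <- acos(ct)
    dth <- th - ctx$a0 * DEG
    e <- e + KANGLE * sum(dth^2)
    if (grad) {
      st <- sqrt(pmax(1 - ct^2, 1e-10))
      uh <- u / nu; vh <- v / nv
      dci <- (vh - ct * uh) / nu
      dcl <- (uh - ct * vh) / nv
      pref <- -2 * KANGLE * dth / st
      gi <- pref * dci; gl <- pref * dcl
      g <- accum_rows(g, c(a[, 1], a[, 3], a[, 2]),
                      rbind(gi, gl, -gi - gl))
    }
  }
  tm <- ctx$tors
  if (nrow(tm)) {
    phi <- dihedral_angle_m(xyz[tm[, 1], , drop = FALSE],
                            xyz[tm[, 2], , drop = FALSE],
                            xyz[tm[, 3], , drop = FALSE],
                            xyz[tm[, 4], , drop = FALSE]) * DEG
    e <- e + sum(V3_CHI / 2 * (1 + cos(3 * phi)))
    if (grad) {
      for (k in seq_len(nrow(tm))) {
        dEdphi <- -1.5 * V3_CHI * sin(3 * phi[k])
        dg <- dihedral_grad(xyz[tm[k, 1], ], xyz[tm[k, 2], ],
                            xyz[tm[k, 3], ], xyz[tm[k, 4], ])
        g[tm[k, 1], ] <- g[tm[k, 1], ] + dEdphi * dg$da
        g[tm[k, 2], ] <- g[tm[k, 2], ] + dEdphi * dg$db
        g[tm[k, 3], ] <- g[tm[k, 3], ] + dEdphi * dg$dc
        g[tm[k, 4], ] <- g[tm[k, 4], ] + dEdphi * dg$dd
      }
    }
  }
  list(e = e, g = g)
}

## gradient of a dihedral angle (radians) wrt its four points, for the
## sign convention of dihedral_angle (verified against central differences)
dihedral_grad <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  nb2 <- vnorm(b2)
  da <- nb2 / sum(n1^2) * n1
  dd <- -nb2 / sum(n2^2) * n2
  s1 <- sum(b1 * b2) / nb2^2
  s2 <- sum(b3 * b2) / nb2^2
  db <- -(1 + s1) * da + s2 * dd
  dc <- s1 * da - (1 + s2) * dd
  list(da = da, db = db, dc = dc, dd = dd)
}

## --- Lennard-Jones ----------------------------------------------------------

eval_vdw <- function(ctx, xyz, grad = FALSE) {
  opt <- ctx$model$options
  D <- loop_dist(ctx, xyz)
  lr <- ctx$loop_rows
  Rm <- outer(ctx$radius[lr], ctx$radius, "+")
  Ep <- sqrt(outer(ctx$epsilon[lr], ctx$epsilon))
  W <- ctx$scale
  act <- which(W > 0 & D < opt$r_off, arr.ind = TRUE)
  if (!nrow(act)) return(list(e = 0, g = if (grad) matrix(0, ctx$n, 3)))
  r <- D[act]; rm <- Rm[act]; ep <- Ep[act]; w <- W[act]
  rc <- opt$cap_frac * rm
  lj <- function(r, rm, ep) {
    x6 <- (rm / r)^6
    ep * (x6^2 - 2 * x6)
  }
  ljd <- function(r, rm, ep) {
    x6 <- (rm / r)^6
    -12 * ep / r * (x6^2 - x6)
  }
  capped <- r < rc
  e0 <- ifelse(capped, lj(rc, rm, ep) + ljd(rc, rm, ep) * (r - rc),
               lj(r, rm, ep))
  d0 <- ifelse(capped, ljd(rc, rm, ep), ljd(r, rm, ep))
  sw <- switch_fn(r, opt$r_on, opt$r_off)
  e <- opt$vdw_scale * sum(w * e0 * sw$s)
  g <- NULL
  if (grad) {
    dEdr <- opt$vdw_scale * w * (d0 * sw$s + e0 * sw$ds)
    g <- pair_grad(ctx, xyz, act, dEdr / r)
  }
  list(e = e, g = g)
}

## accumulate pair gradients: factor = (dE/dr)/r per active pair
pair_grad <- function(ctx, xyz, act, factor) {
  g <- matrix(0, ctx$n, 3)
  gi <- ctx$loop_rows[act[, 1]]
  gj <- act[, 2]
  dv <- xyz[gi, , drop = FALSE] - xyz[gj, , drop = FALSE]
  gv <- dv * factor
  accum_rows(g, c(gi, gj), rbind(gv, -gv))
}

## add row-indexed contributions (with repeats) into a gradient matrix
accum_rows <- function(g, idx, contrib) {
  agg <- rowsum(contrib, idx)
  rows <- as.integer(rownames(agg))
  g[rows, ] <- g[rows, ] + agg
  g
}

## --- Coulomb + generalized Born --------------------------------------------

eval_coulomb <- function(ctx, xyz, grad = FALSE) {
  opt <- ctx$model$options
  D <- loop_dist(ctx, xyz)
  W <- ctx$scale
  lr <- ctx$loop_rows
  Q <- outer(ctx$q[lr], ctx$q)
  act <- which(W > 0 & D < opt$r_off & abs(Q) > 1e-12, arr.ind = TRUE)
  if (!nrow(act)) return(list(e = 0, g = if (grad) matrix(0, ctx$n, 3)))
  r <- D[act]; qq <- Q[act]; w <- W[act]
  e0 <- COULOMB_KCAL * qq / (opt$eps_in * r)
  d0 <- -e0 / r
  sw <- switch_fn(r, opt$r_on, opt$r_off)
  e <- sum(w * e0 * sw$s)
  g <- NULL
  if (grad) {
    dEdr <- w * (d0 * sw$s + e0 * sw$ds)
    g <- pair_grad(ctx, xyz, act, dEdr / r)
  }
  list(e = e, g = g)
}

## HCT pairwise-descreening Born radii for all atoms
born_radii <- function(ctx, xyz) {
  rho <- pmax(ctx$radius - BORN_OFFSET, 0.4)
  sk <- ctx$hct * rho
  n <- ctx$n
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  r <- sqrt(pmax(d2, 1e-12))
  diag(r) <- Inf
  A <- matrix(sk, n, n, byrow = TRUE)      # scaled radius of descreener j
  Rho <- matrix(rho, n, n)                 # rho_i by row
  U <- r + A
  L <- pmax(Rho, abs(r - A))
  valid <- Rho < U & is.finite(r)
  H <- matrix(0, n, n)
  idx <- which(valid)
  rl <- r[idx]; al <- A[idx]; Ll <- L[idx]; Ul <- U[idx]
  H[idx] <- 0.5 * (1 / Ll - 1 / Ul) +
    (al^2 - rl^2) / (8 * rl) * (1 / Ll^2 - 1 / Ul^2) -
    log(Ul / Ll) / (4 * rl)
  ## full-shell correction when atom i sits inside the descreening sphere
  deep <- which(valid & (A - r) > Rho)
  if (length(deep))
    H[deep] <- H[deep] + (1 / Rho[deep] - 1 / (A[deep] - r[deep]))
  invR <- 1 / rho - rowSums(H)
  R <- 1 / pmax(invR, 1e-3)
  pmax(R, rho)
}

eval_gb <- function(ctx, xyz) {
  tau <- 1 / ctx$model$options$eps_in - 1 / EPS_SOLVENT
  R <- born_radii(ctx, xyz)
  lr <- ctx$loop_rows
  q <- ctx$q
  ## self terms of loop atoms
  e <- sum(q[lr]^2 / R[lr])
  ## cross terms loop x all (loop-loop pairs once, doubled)
  D <- loop_dist(ctx, xyz)
  QQ <- outer(q[lr], q)
  RR <- outer(R[lr], R)
  x <- D^2 / (4 * RR)
  fgb <- sqrt(D^2 + RR * exp(-x))
  cross <- QQ / fgb
  self_cols <- cbind(seq_along(lr), lr)
  cross[self_cols] <- 0
  ## loop-loop pairs appear once in the matrix (scale matrix excluded them
  ## for bonded exclusions, but GB includes all pairs) -> build mask
  inloop <- seq_len(ctx$n) %in% lr
  M <- matrix(1, length(lr), ctx$n)
  M[, inloop] <- 2            # loop-loop unordered pairs counted once below
  dup <- outer(lr, seq_len(ctx$n), function(i, j) j %in% lr & j < i)
  M[matrix(as.logical(dup), length(lr), ctx$n)] <- 0
  M[self_cols] <- 0
  e <- e + sum(M * cross)
  -COULOMB_KCAL / 2 * tau * e
}

## --- surface area -----------------------------------------------------------

## Shrake-Rupley SASA of the loop atoms (probe-augmented spheres).  The
## sphere-point orientation is anchored to a local frame built from two
## bonded neighbors, so the result is exactly invariant under rigid
## transforms of the whole structure.
eval_sasa <- function(ctx, xyz, rows = ctx$loop_rows) {
  probe <- ctx$model$options$probe
  sp <- ctx$sphere
  rad <- ctx$radius + probe
  out <- numeric(length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    ri <- rad[i]
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ri + rad)^2 & seq_len(ctx$n) != i)
    fr <- ctx$frame_atoms[i, ]
    v1 <- xyz[fr[1], ] - xyz[i, ]
    e1 <- if (vnorm(v1) > 1e-6) unitv(v1) else c(1, 0, 0)
    w2 <- xyz[fr[2], ] - xyz[i, ]
    w2 <- w2 - sum(w2 * e1) * e1
    e2 <- if (vnorm(w2) > 1e-6) unitv(w2) else {
      tmp <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      unitv(tmp - sum(tmp * e1) * e1)
    }
    R <- cbind(e1, e2, vcross(e1, e2))
    pts <- sweep((sp %*% t(R)) * ri, 2, xyz[i, ], "+")
    if (length(nb)) {
      nxyz <- xyz[nb, , drop = FALSE]
      d2p <- outer(rowSums(pts^2), rowSums(nxyz^2), "+") -
        2 * pts %*% t(nxyz)
      occluded <- d2p <= matrix(rad[nb]^2, nrow(pts), length(nb),
                                byrow = TRUE)
      frac <- mean(rowSums(occluded) == 0)
    } else frac <- 1
    out[k] <- 4 * pi * ri^2 * frac
  }
  out
}

eval_sa_energy <- function(ctx, xyz) {
  s <- eval_sasa(ctx, xyz)
  sum(ctx$gamma[ctx$loop_rows] * s)
}

## --- hydrogen bonds ---------------------------------------------------------

hb_bump <- function(x) ifelse(abs(x) < 1, (1 - x^2)^2, 0)

eval_hbond <- function(ctx, xyz) {
  hp <- ctx$hb_pairs
  if (is.null(hp) || nrow(hp) == 0) return(0)
  hb <- ctx$model$options$hb
  H <- xyz[hp[, "H"], , drop = FALSE]; Dn <- xyz[hp[, "D"], , drop = FALSE]
  A <- xyz[hp[, "A"], , drop = FALSE]; B <- xyz[hp[, "B"], , drop = FALSE]
  dv <- A - H
  d <- sqrt(rowSums(dv^2))
  sel <- which(d < hb$d0 + hb$dw)
  if (!length(sel)) return(0)
  e <- 0
  for (k in sel) {
    th <- bond_angle(Dn[k, ], H[k, ], A[k, ])
    ps <- bond_angle(H[k, ], A[k, ], B[k, ])
    s <- hb_bump((d[k] - hb$d0) / hb$dw)
    e <- e - hb$e_d * s -
      s * (hb$e_th * hb_bump((th - hb$th0) / hb$thw) +
             hb$e_ps * hb_bump((ps - hb$ps0) / hb$psw))
  }
  unname(e)
}

## --- atom-pair potential ----------------------------------------------------

eval_atompair <- function(ctx, xyz) {
  tab <- ctx$model$pair
  D <- loop_dist(ctx, xyz)
  act <- which(ctx$ap_ok & D < tab$r_cut, arr.ind = TRUE)
  if (!nrow(act)) return(0)
  bi <- pmin(length(tab$centers), 1 + floor(D[act] / tab$bin_width))
  ci <- ctx$cls_idx[ctx$loop_rows[act[, 1]]]
  cj <- ctx$cls_idx[act[, 2]]
  sum(tab$values[cbind(ci, cj, bi)])
}

## --- torsion-statistics terms from coordinates ------------------------------

measure_loop_torsions <- function(ctx, xyz) {
  nr <- length(ctx$ppidx)
  pp <- do.call(rbind, ctx$ppidx)
  phi <- dihedral_angle_m(xyz[pp[, 1], , drop = FALSE],
                          xyz[pp[, 2], , drop = FALSE],
                          xyz[pp[, 3], , drop = FALSE],
                          xyz[pp[, 4], , drop = FALSE])
  psi <- dihedral_angle_m(xyz[pp[, 2], , drop = FALSE],
                          xyz[pp[, 3], , drop = FALSE],
                          xyz[pp[, 4], , drop = FALSE],
                          xyz[pp[, 5], , drop = FALSE])
  chi <- lapply(seq_len(nr), function(k) {
    cm <- ctx$chi_idx[[k]]
    if (!nrow(cm)) return(numeric(0))
    dihedral_angle_m(xyz[cm[, 1], , drop = FALSE], xyz[cm[, 2], , drop = FALSE],
                     xyz[cm[, 3], , drop = FALSE], xyz[cm[, 4], , drop = FALSE])
  })
  list(phi = phi, psi = psi, chi = chi)
}

## ---------------------------------------------------------------------------
## Total energy

#' Evaluate the hybrid energy of a loop region
#'
#' @param structure "protein" with topology built.
#' @param loop a \code{\link{loop_definition}}.
#' @param model an \code{\link{energy_model}} (weights + tables + options).
#' @param ctx optional precomputed \code{\link{energy_context}} (for
#'   repeated evaluation).
#' @param xyz optional coordinate matrix overriding the structure's.
#' @return object of class "energy_breakdown" with per-term energies
#'   (kcal/mol) and the weighted total.  Terms whose weight is zero are
#'   skipped and reported as 0.
#' @export
total_energy <- function(structure, loop, model = energy_model(),
                         ctx = NULL, xyz = NULL) {
  if (is.null(ctx)) ctx <- energy_context(structure, loop, model)
  if (is.null(xyz)) xyz <- get_xyz(if (is.null(structure)) ctx$prot else structure)
  w <- ctx$model$weights
  if (!is.null(ctx$model$custom)) {
    tor <- measure_loop_torsions(ctx, xyz)
    et <- ctx$model$custom(tor, xyz, ctx)
    br <- list(e_bonded = 0, e_vdw = 0, e_coulomb = 0, e_gb = 0, e_sa = 0,
               e_phipsi = 0, e_chi = 0, e_hbond = 0, e_atompair = 0,
               e_total = et, weights = w)
    return(structure(br, class = "energy_breakdown"))
  }
  eb <- eval_bonded(ctx, xyz)$e
  ev <- eval_vdw(ctx, xyz)$e
  ec <- eg <- es <- ep <- ech <- eh <- ea <- 0
  if (w$w_electrostatics > 0) {
    ec <- eval_coulomb(ctx, xyz)$e
    eg <- eval_gb(ctx, xyz)
  }
  if (w$w_sa > 0) es <- eval_sa_energy(ctx, xyz)
  if (w$w_phipsi > 0 || w$w_chi > 0) {
    tor <- measure_loop_torsions(ctx, xyz)
    ts <- list(resnos = loop_resnos(ctx$loop), phi = tor$phi, psi = tor$psi,
               chi = tor$chi)
    if (w$w_phipsi > 0)
      ep <- e_phipsi(ts, ctx$model$phipsi, ctx$resnames)
    if (w$w_chi > 0)
      ech <- e_chi(ts, ctx$model$chi, ctx$resnames)
  }
  if (w$w_hbond > 0) eh <- eval_hbond(ctx, xyz)
  if (w$w_atompair > 0) ea <- eval_atompair(ctx, xyz)
  et <- eb + ev + w$w_electrostatics * (ec + eg) + w$w_sa * es +
    w$w_phipsi * ep + w$w_chi * ech + w$w_hbond * eh + w$w_atompair * ea
  structure(list(e_bonded = eb, e_vdw = ev, e_coulomb = ec, e_gb = eg,
                 e_sa = es, e_phipsi = ep, e_chi = ech, e_hbond = eh,
                 e_atompair = ea, e_total = et, weights = w),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("bonded %10.3f  vdw %10.3f  coulomb %10.3f\n",
                     "gb     %10.3f  sa  %10.3f  phipsi  %10.3f\n",
                     "chi    %10.3f  hbond %8.3f  atompair %9.3f\n",
                     "total  %10.3f kcal/mol\n"),
              x$e_bonded, x$e_vdw, x$e_coulomb, x$e_gb, x$e_sa, x$e_phipsi,
              x$e_chi, x$e_hbond, x$e_atompair, x$e_total))
  invisible(x)
}

## Cartesian gradient of the smooth physics terms (bonded + LJ + Coulomb).
## Knowledge terms are handled in torsion space; GB/SA derivatives are
## neglected (fixed-solvation approximation during minimization).
smooth_gradient <- function(ctx, xyz) {
  g <- eval_bonded(ctx, xyz, grad = TRUE)$g
  g <- g + eval_vdw(ctx, xyz, grad = TRUE)$g
  if (ctx$model$weights$w_electrostatics > 0)
    g <- g + ctx$model$weights$w_electrostatics *
      eval_coulomb(ctx, xyz, grad = TRUE)$g
  g
}

## Exported per-term wrappers matching the module surface -------------------

#' Individual energy terms
#'
#' Convenience wrappers evaluating one term of the hybrid energy over the
#' loop region (loop-loop plus loop-environment interactions).
#'
#' @param structure "protein" with topology built.
#' @param loop a \code{\link{loop_definition}}.
#' @param model an \code{\link{energy_model}}.
#' @return energy in kcal/mol (\code{e_coulomb_gb} returns both parts).
#' @name energy_terms
NULL

#' @rdname energy_terms
#' @export
e_bonded <- function(structure, loop, model = energy_model()) {
  ctx <- energy_context(structure, loop, model)
  eval_bonded(ctx, get_xyz(structure))$e
}

#' @rdname energy_terms
#' @export
e_vdw <- function(structure, loop, model = energy_model()) {
  ctx <- energy_context(structure, loop, model)
  eval_vdw(ctx, get_xyz(structure))$e
}

#' @rdname energy_terms
#' @export
e_coulomb_gb <- function(structure, loop, model = energy_model()) {
  ctx <- energy_context(structure, loop, model)
  xyz <- get_xyz(structure)
  c(e_coulomb = eval_coulomb(ctx, xyz)$e, e_gb = eval_gb(ctx, xyz))
}

#' @rdname energy_terms
#' @export
e_sa <- function(structure, loop, model = energy_model()) {
  ctx <- energy_context(structure, loop, model)
  eval_sa_energy(ctx, get_xyz(structure))
}

#' @rdname energy_terms
#' @export
e_hbond <- function(structure, loop, model = energy_model()) {
  ctx <- energy_context(structure, loop, model)
  eval_hbond(ctx, get_xyz(structure))
}

#' @rdname energy_terms
#' @export
e_atompair <- function(structure, loop, model = energy_model()) {
  ctx <- energy_context(structure, loop, model)
  eval_atompair(ctx, get_xyz(structure))
}
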