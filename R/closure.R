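## Analytic tri-axial loop closure (TLC).
##
## Closing a backbone gap with three pivot residues reduces to three coupled
## cone-intersection equations in the rotation angles about the three
## virtual axes joining the pivot C-alpha atoms.  In tangent half-angle
## variables each equation is biquadratic; eliminating two variables by
## resultants yields a degree-16 polynomial whose real roots (found as
## companion-matrix eigenvalues) enumerate all closed conformations.  Each
## root is polished by Newton iteration on the exact trigonometric system
## and converted back to the six pivot (phi, psi) torsions.

## --- small polynomial helpers (coefficient vectors, lowest degree first) ---

polyval_c <- function(coef, x) {
  n <- length(coef)
  out <- 0 * x + coef[n]
  k <- n - 1L
  while (k >= 1L) {
    out <- out * x + coef[k]
    k <- k - 1L
  }
  out
}

polymul <- function(a, b) {
  out <- rep(0 + 0i, length(a) + length(b) - 1)
  for (i in seq_along(a)) out[i:(i + length(b) - 1)] <-
      out[i:(i + length(b) - 1)] + a[i] * b
  out
}

## Determinant of a small complex matrix by LU with partial pivoting.
cdet <- function(M) {
  n <- nrow(M)
  d <- 1 + 0i
  for (k in seq_len(n - 1)) {
    p <- which.max(Mod(M[k:n, k])) + k - 1
    if (Mod(M[p, k]) < 1e-300) return(0 + 0i)
    if (p != k) { M[c(k, p), ] <- M[c(p, k), ]; d <- -d }
    d <- d * M[k, k]
    rows <- (k + 1):n
    M[rows, ] <- M[rows, ] - outer(M[rows, k] / M[k, k], M[k, ])
  }
  d * M[n, n]
}

## Real roots of a real-coefficient polynomial via companion-matrix
## eigenvalues; coefficients lowest-first.
poly_real_roots <- function(coef, tol = 1e-7) {
  ## trim negligible leading coefficients
  scale <- max(abs(coef))
  if (scale == 0) return(numeric(0))
  coef <- coef / scale
  while (length(coef) > 1 && abs(coef[length(coef)]) < 1e-11)
    coef <- coef[-length(coef)]
  n <- length(coef) - 1
  if (n < 1) return(numeric(0))
  cp <- coef / coef[n + 1]
  C <- matrix(0, n, n)
  if (n > 1) C[cbind(2:n, 1:(n - 1))] <- 1
  C[, n] <- -cp[1:n]
  ev <- eigen(C, only.values = TRUE)$values
  re <- Re(ev)[abs(Im(ev)) < tol * (1 + abs(Re(ev)))]
  sort(re)
}

## --- cone algebra -----------------------------------------------------------

## Orthonormal frame (e1, e2) perpendicular to axis u, e1 derived from ref.
axis_frame <- function(u, ref = c(0, 1, 0)) {
  e1 <- ref - sum(ref * u) * u
  if (vnorm(e1) < 1e-8) stop("axis frame reference parallel to axis")
  e1 <- unitv(e1)
  list(e1 = e1, e2 = vcross(u, e1))
}

azimuth_about <- function(v, u, fr) atan2(sum(v * fr$e2), sum(v * fr$e1))

## A cone-constrained unit vector: v(tau) = cos(alpha) u +
## sin(alpha) (cos(tau) e1s + sin(tau) e2s), with azimuth offset delta
## folded into the shifted basis (e1s, e2s).
cone_spec <- function(u, alpha, delta, fr) {
  e1s <- cos(delta) * fr$e1 + sin(delta) * fr$e2
  e2s <- -sin(delta) * fr$e1 + cos(delta) * fr$e2
  list(u = u, alpha = alpha,
       c1 = cos(alpha) * u, c2 = sin(alpha) * e1s, c3 = sin(alpha) * e2s)
}

cone_eval <- function(cs, tau) cs$c1 + cos(tau) * cs$c2 + sin(tau) * cs$c3

cone_deriv <- function(cs, tau) -sin(tau) * cs$c2 + cos(tau) * cs$c3

## 3x3 coefficient matrix M of f(ta, tb) = g(ta)' M g(tb) with
## g = (1, cos, sin), for the constraint dot(va(ta), vb(tb)) = cos(theta).
cone_pair_matrix <- function(ca, cb, costheta) {
  A <- rbind(ca$c1, ca$c2, ca$c3)
  B <- rbind(cb$c1, cb$c2, cb$c3)
  M <- A %*% t(B)
  M[1, 1] <- M[1, 1] - costheta
  M
}

## Map trig coefficient matrix to biquadratic coefficients in tangent
## half-angle variables: rows/cols ordered (1, t, t^2).
TRIG2POLY <- rbind(c(1, 0, 1), c(1, 0, -1), c(0, 2, 0))

biquad_matrix <- function(M) t(TRIG2POLY) %*% M %*% TRIG2POLY

## --- the closure problem ----------------------------------------------------

#' Construct a tri-axial closure problem
#'
#' @param structure "protein" with topology built.
#' @param loop a \code{\link{loop_definition}}.
#' @param torsions a "torsion_state" supplying all non-pivot torsions.
#' @param pivots strictly increasing residue numbers of the three pivots,
#'   all inside the loop.
#' @param geometry geometry source, as in \code{\link{coords_from_torsions}}.
#' @return an object of class "closure_problem".
#' @export
closure_problem <- function(structure, loop, torsions, pivots,
                            geometry = c("ideal", "structure")) {
  geometry <- match.arg(geometry)
  stopifnot(length(pivots) == 3, all(diff(pivots) > 0))
  if (!all(pivots %in% loop_resnos(loop)))
    stop("pivots must lie inside the loop")
  ## forward build with current torsions gives the rigid legs
  built <- coords_from_torsions(structure, loop, torsions, geometry = geometry,
                                sidechains = FALSE)
  tgt <- c_anchor_targets(structure, loop, torsions, pivots[3],
                          geometry = geometry)
  structure(list(structure = structure, built = built, loop = loop,
                 torsions = torsions, pivots = pivots, geometry = geometry,
                 targets = tgt),
            class = "closure_problem")
}

## Gather the geometric scalars defining the closure equations.
tlc_setup <- function(problem) {
  loop <- problem$loop; ch <- loop$chain
  p1 <- problem$pivots[1]; p2 <- problem$pivots[2]; p3 <- problem$pivots[3]
  built <- problem$built
  xyz <- get_xyz(built)
  at <- function(resno, nm) xyz[atom_index(built, ch, resno, nm), ]
  tgt <- problem$targets

  A <- at(p1, "CA")
  C_lab <- tgt$CA3
  N1 <- at(p1, "N")
  Cprev <- at(p1 - 1, "C")

  ## leg marker atoms from the forward build
  leg1 <- list(CA1 = at(p1, "CA"), C1 = at(p1, "C"),
               Nn = at(p1 + 1, "N"),
               N2 = at(p2, "N"), CA2 = at(p2, "CA"),
               Cm = at(p2 - 1, "C"))
  leg2 <- list(CA2 = at(p2, "CA"), C2 = at(p2, "C"),
               Nn = at(p2 + 1, "N"),
               N3 = at(p3, "N"), CA3 = at(p3, "CA"),
               Cm = at(p3 - 1, "C"))

  d1 <- vnorm(leg1$CA2 - leg1$CA1)
  d2 <- vnorm(leg2$CA3 - leg2$CA2)
  d3 <- vnorm(C_lab - A)
  feasible <- (d3 <= d1 + d2 - 1e-9) && (d3 >= abs(d1 - d2) + 1e-9) &&
    d3 > 1e-6
  ## bond angles at the pivots (as the forward rebuild will produce them)
  g <- loop_geometry(problem$structure, loop,
                     ideal = problem$geometry == "ideal")
  thA <- g("a_NCAC", p1) * DEG
  thB <- g("a_NCAC", p2) * DEG
  thC <- g("a_NCAC", p3) * DEG

  ## lab-frame environment body (R3) data
  u3lab <- unitv(C_lab - A)
  vN1 <- unitv(N1 - A)
  vC3 <- unitv(tgt$C3 - tgt$CA3)
  ref <- if (abs(u3lab[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  fr3lab <- axis_frame(u3lab, ref)
  aN1 <- acos(max(-1, min(1, sum(vN1 * u3lab))))
  aC3 <- acos(max(-1, min(1, sum(vC3 * u3lab))))
  D3 <- azimuth_about(vC3, u3lab, fr3lab) - azimuth_about(vN1, u3lab, fr3lab)

  ## leg cone data measured in the build frame
  leg_cones <- function(leg, from, to, vout, vin) {
    u <- unitv(leg[[to]] - leg[[from]])
    refl <- if (abs(u[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
    fr <- axis_frame(u, refl)
    a_out <- acos(max(-1, min(1, sum(vout * u))))
    a_in <- acos(max(-1, min(1, sum(vin * u))))
    D <- azimuth_about(vin, u, fr) - azimuth_about(vout, u, fr)
    list(a_out = a_out, a_in = a_in, D = D)
  }
  l1 <- leg_cones(leg1, "CA1", "CA2",
                  unitv(leg1$C1 - leg1$CA1), unitv(leg1$N2 - leg1$CA2))
  l2 <- leg_cones(leg2, "CA2", "CA3",
                  unitv(leg2$C2 - leg2$CA2), unitv(leg2$N3 - leg2$CA3))

  ## triangle frame
  At <- c(0, 0, 0)
  Ct <- c(0, 0, d3)
  u3t <- c(0, 0, 1)
  cosb <- (d1^2 + d3^2 - d2^2) / (2 * d1 * d3)
  cosb <- max(-1, min(1, cosb))
  Bt <- c(d1 * sqrt(1 - cosb^2), 0, d1 * cosb)
  u1t <- unitv(Bt - At)
  u2t <- unitv(Ct - Bt)
  yref <- c(0, 1, 0)
  fr1 <- axis_frame(u1t, yref); fr2 <- axis_frame(u2t, yref)
  fr3 <- axis_frame(u3t, yref)

  ## cones (fixed azimuth offsets avoid exact tangent-half-angle poles)
  off <- c(0.31, 0.87, 1.63)
  cs <- list(
    vN1 = cone_spec(u3t, aN1, off[3], fr3),
    vC3 = cone_spec(u3t, aC3, off[3] + D3, fr3),
    vC1 = cone_spec(u1t, l1$a_out, off[1], fr1),
    wN2 = cone_spec(u1t, l1$a_in, off[1] + l1$D, fr1),
    vC2 = cone_spec(u2t, l2$a_out, off[2], fr2),
    wN3 = cone_spec(u2t, l2$a_in, off[2] + l2$D, fr2))

  list(A = A, C_lab = C_lab, N1 = N1, Cprev = Cprev, tgt = tgt,
       leg1 = leg1, leg2 = leg2, d = c(d1, d2, d3), feasible = feasible,
       th = c(thA, thB, thC), At = At, Bt = Bt, Ct = Ct,
       vN1lab = vN1, cones = cs)
}

#' Solve a tri-axial loop closure problem
#'
#' Returns every real closure solution as an assignment of the three pivot
#' residues' (phi, psi) torsions, sorted by total absolute torsion change
#' from the input state.  An infeasible gap yields an empty list.
#'
#' @param problem a \code{\link{closure_problem}}.
#' @return list of solutions; each has elements \code{pivots}, \code{phi},
#'   \code{psi} (length-3 vectors, degrees) and \code{tau} (internal).
#' @export
tlc_solve <- function(problem) {
  s <- tlc_setup(problem)
  if (!s$feasible) return(list())
  cs <- s$cones
  MA <- cone_pair_matrix(cs$vN1, cs$vC1, cos(s$th[1]))  # f(tau3, tau1)
  MB <- cone_pair_matrix(cs$wN2, cs$vC2, cos(s$th[2]))  # f(tau1, tau2)
  MC <- cone_pair_matrix(cs$wN3, cs$vC3, cos(s$th[3]))  # f(tau2, tau3)
  PA <- biquad_matrix(MA)  # rows t3 powers, cols t1 powers
  PB <- biquad_matrix(MB)  # rows t1, cols t2
  PC <- biquad_matrix(MC)  # rows t2, cols t3

  ## quadratic-in-t2 coefficients: PB columns (in t1), PC rows (in t3)
  A2 <- PB[, 3]; B2 <- PB[, 2]; C2 <- PB[, 1]      # each: coeffs in t1
  A3 <- PC[3, ]; B3 <- PC[2, ]; C3 <- PC[1, ]      # each: coeffs in t3

  ## P(t3) = Res_t1( Res_t2(PB, PC), PA ): the inner resultant is quartic in
  ## t1 with coefficients quartic in t3; the outer resultant is evaluated by
  ## the root-product formula over PA's two t1-roots (Sylvester determinant
  ## as fallback when PA degenerates).
  eval_P <- function(t3) {
    a3 <- polyval_c(A3, t3); b3 <- polyval_c(B3, t3); c3 <- polyval_c(C3, t3)
    q1 <- a3 * C2 - c3 * A2          # A3 C2 - C3 A2, quadratic in t1
    q2 <- a3 * B2 - b3 * A2
    q3 <- b3 * C2 - c3 * B2
    r <- polymul(q1, q1) - polymul(q2, q3)   # deg 4 in t1
    a1 <- polyval_c(PA[, 3], t3); b1 <- polyval_c(PA[, 2], t3)
    c1 <- polyval_c(PA[, 1], t3)
    if (Mod(a1) > 1e-8 * (Mod(b1) + Mod(c1) + 1e-30)) {
      sq <- sqrt(b1^2 - 4 * a1 * c1 + 0i)
      x1 <- (-b1 + sq) / (2 * a1); x2 <- (-b1 - sq) / (2 * a1)
      return(a1^4 * polyval_c(r, x1) * polyval_c(r, x2))
    }
    NA_complex_
  }
  eval_P_det <- function(t3) {
    a3 <- polyval_c(A3, t3); b3 <- polyval_c(B3, t3); c3 <- polyval_c(C3, t3)
    q1 <- a3 * C2 - c3 * A2
    q2 <- a3 * B2 - b3 * A2
    q3 <- b3 * C2 - c3 * B2
    r <- polymul(q1, q1) - polymul(q2, q3)
    a1 <- polyval_c(PA[, 3], t3); b1 <- polyval_c(PA[, 2], t3)
    c1 <- polyval_c(PA[, 1], t3)
    S <- matrix(0 + 0i, 6, 6)
    S[1, 1:5] <- rev(r)
    S[2, 2:6] <- rev(r)
    q <- c(a1, b1, c1)
    for (k in 0:3) S[3 + k, (1 + k):(3 + k)] <- q
    cdet(S)
  }
  ## coefficients of P by evaluation on a complex circle + inverse DFT
  npts <- 24
  rad <- 1.0
  zs <- rad * exp(2i * pi * (0:(npts - 1)) / npts)
  vals <- vapply(zs, eval_P, complex(1))
  if (anyNA(vals)) vals <- vapply(zs, eval_P_det, complex(1))
  if (all(Mod(vals) < 1e-280)) return(list())
  coef <- stats::fft(vals) / npts
  coef <- coef / rad^(0:(npts - 1))
  coef <- Re(coef[1:17])
  roots3 <- poly_real_roots(coef, tol = 1e-6)
  if (!length(roots3)) return(list())

  resid <- function(tau) {
    c(sum(cone_eval(cs$vN1, tau[3]) * cone_eval(cs$vC1, tau[1])) - cos(s$th[1]),
      sum(cone_eval(cs$wN2, tau[1]) * cone_eval(cs$vC2, tau[2])) - cos(s$th[2]),
      sum(cone_eval(cs$wN3, tau[2]) * cone_eval(cs$vC3, tau[3])) - cos(s$th[3]))
  }
  jac <- function(tau) {
    matrix(c(
      sum(cone_eval(cs$vN1, tau[3]) * cone_deriv(cs$vC1, tau[1])), 0,
      sum(cone_deriv(cs$vN1, tau[3]) * cone_eval(cs$vC1, tau[1])),
      sum(cone_deriv(cs$wN2, tau[1]) * cone_eval(cs$vC2, tau[2])),
      sum(cone_eval(cs$wN2, tau[1]) * cone_deriv(cs$vC2, tau[2])), 0,
      0, sum(cone_deriv(cs$wN3, tau[2]) * cone_eval(cs$vC3, tau[3])),
      sum(cone_eval(cs$wN3, tau[2]) * cone_deriv(cs$vC3, tau[3]))),
      3, 3, byrow = TRUE)
  }

  sols <- list()
  for (t3 in roots3) {
    tau3 <- 2 * atan(t3)
    a1 <- polyval_c(PA[, 3], t3); b1 <- polyval_c(PA[, 2], t3)
    c1 <- polyval_c(PA[, 1], t3)
    disc <- Re(b1)^2 - 4 * Re(a1) * Re(c1)
    if (abs(Re(a1)) < 1e-12) {
      t1s <- if (abs(Re(b1)) > 1e-12) -Re(c1) / Re(b1) else numeric(0)
    } else if (disc < -1e-8 * (Re(b1)^2 + 1e-12)) {
      next
    } else {
      sq <- sqrt(max(0, disc))
      t1s <- c((-Re(b1) + sq), (-Re(b1) - sq)) / (2 * Re(a1))
    }
    a3 <- Re(polyval_c(A3, t3)); b3 <- Re(polyval_c(B3, t3))
    c3 <- Re(polyval_c(C3, t3))
    for (t1 in t1s) {
      a2 <- Re(polyval_c(A2, t1)); b2 <- Re(polyval_c(B2, t1))
      c2 <- Re(polyval_c(C2, t1))
      den <- a3 * b2 - a2 * b3
      t2s <- if (abs(den) > 1e-10) {
        (a2 * c3 - a3 * c2) / den
      } else {
        d2q <- b2^2 - 4 * a2 * c2
        if (d2q < 0 || abs(a2) < 1e-12) numeric(0) else
          c(-b2 + sqrt(d2q), -b2 - sqrt(d2q)) / (2 * a2)
      }
      for (t2 in t2s) {
        tau <- c(2 * atan(t1), 2 * atan(t2), tau3)
        if (max(abs(resid(tau))) > 0.05) next   # spurious combination
        ## Newton polish on the exact system
        ok <- TRUE
        for (it in 1:12) {
          r <- resid(tau)
          if (max(abs(r)) < 1e-12) break
          J <- jac(tau)
          step <- tryCatch(solve(J, r), error = function(e) NULL)
          if (is.null(step)) { ok <- FALSE; break }
          if (max(abs(step)) > 0.5) step <- step * 0.5 / max(abs(step))
          tau <- tau - step
        }
        if (!ok || max(abs(resid(tau))) > 1e-8) next
        sols[[length(sols) + 1]] <- tau
      }
    }
  }
  if (!length(sols)) return(list())
  ## deduplicate in tau space
  uniq <- list()
  for (tau in sols) {
    dup <- FALSE
    for (u in uniq) {
      d <- abs(wrap_angle((tau - u) / DEG))
      if (max(d) < 0.005) { dup <- TRUE; break }
    }
    if (!dup) uniq[[length(uniq) + 1]] <- tau
  }
  out <- lapply(uniq, function(tau) tlc_reconstruct(problem, s, tau))
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(list())
  ## sort by total torsion change from the input pivot torsions
  tin <- problem$torsions
  kp <- match(problem$pivots, tin$resnos)
  ref <- c(tin$phi[kp], tin$psi[kp])
  chg <- vapply(out, function(sol)
    sum(abs(wrap_angle(c(sol$phi, sol$psi) - ref))), numeric(1))
  out[order(chg)]
}

## Turn a polished (tau1, tau2, tau3) into pivot (phi, psi) torsions by
## placing the legs in the lab frame and measuring dihedrals.
tlc_reconstruct <- function(problem, s, tau) {
  cs <- s$cones
  vN1t <- cone_eval(cs$vN1, tau[3])
  vC3t <- cone_eval(cs$vC3, tau[3])
  vC1t <- cone_eval(cs$vC1, tau[1])
  vC2t <- cone_eval(cs$vC2, tau[2])
  ## triangle frame -> lab: match A, C and the fixed N1 direction
  src <- rbind(s$At, s$Ct, s$At + vN1t)
  dst <- rbind(s$A, s$C_lab, s$A + s$vN1lab)
  M <- tryCatch(rigid_from_three_points(src, dst), error = function(e) NULL)
  if (is.null(M)) return(NULL)
  Bl <- as.numeric(M(matrix(s$Bt, 1)))
  vC1l <- as.numeric(M(matrix(s$At + vC1t, 1))) - s$A
  vC2l <- as.numeric(M(matrix(s$Bt + vC2t, 1))) - Bl

  l1 <- s$leg1; l2 <- s$leg2
  L1 <- vnorm(l1$C1 - l1$CA1)
  L2 <- vnorm(l2$C2 - l2$CA2)
  T1 <- tryCatch(rigid_from_three_points(
    rbind(l1$CA1, l1$CA2, l1$C1),
    rbind(s$A, Bl, s$A + L1 * vC1l)), error = function(e) NULL)
  T2 <- tryCatch(rigid_from_three_points(
    rbind(l2$CA2, l2$CA3, l2$C2),
    rbind(Bl, s$C_lab, Bl + L2 * vC2l)), error = function(e) NULL)
  if (is.null(T1) || is.null(T2)) return(NULL)

  m1 <- T1(rbind(l1$C1, l1$Nn, l1$N2, l1$CA2, l1$Cm))
  m2 <- T2(rbind(l2$C2, l2$Nn, l2$N3, l2$CA3, l2$Cm))
  C1 <- m1[1, ]; Nn1 <- m1[2, ]; N2 <- m1[3, ]; CA2 <- m1[4, ]; Cm1 <- m1[5, ]
  C2 <- m2[1, ]; Nn2 <- m2[2, ]; N3 <- m2[3, ]; CA3 <- m2[4, ]; Cm2 <- m2[5, ]

  phi <- c(dihedral_angle(s$Cprev, s$N1, s$A, C1),
           dihedral_angle(Cm1, N2, CA2, C2),
           dihedral_angle(Cm2, N3, s$C_lab - (s$C_lab - CA3), s$tgt$C3))
  ## pivot 3 CA should coincide with the target; use targets directly
  phi[3] <- dihedral_angle(Cm2, N3, s$tgt$CA3, s$tgt$C3)
  psi <- c(dihedral_angle(s$N1, s$A, C1, Nn1),
           dihedral_angle(N2, CA2, C2, Nn2),
           dihedral_angle(N3, s$tgt$CA3, s$tgt$C3, s$tgt$Npost))
  list(pivots = problem$pivots, phi = phi, psi = psi, tau = tau)
}

#' Apply a closure solution to a torsion state
#'
#' @param torsions a "torsion_state".
#' @param solution one element of the list returned by \code{\link{tlc_solve}}.
#' @return the torsion state with the three pivot (phi, psi) pairs replaced.
#' @export
tlc_apply <- function(torsions, solution) {
  kp <- match(solution$pivots, torsions$resnos)
  torsions$phi[kp] <- solution$phi
  torsions$psi[kp] <- solution$psi
  torsions
}
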