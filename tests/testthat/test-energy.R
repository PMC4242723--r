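# Hybrid energy terms: closed forms, oracles, gradients, invariances.

test_that("Lennard-Jones recovers -epsilon at the minimum and 0 past cutoff", {
  ctx <- two_atom_ctx(r1 = 1.55, r2 = 1.55, e1 = 0.21, e2 = 0.21)
  rmin <- 3.1                       # r1 + r2 = sigma 2^(1/6)
  e <- loopcsa:::eval_vdw(ctx, xyz_pair(rmin))$e
  expect_equal(e, -0.21, tolerance = 1e-12)
  ## beyond the switching window the term vanishes
  ctx2 <- two_atom_ctx(r_on = 8, r_off = 10)
  expect_identical(loopcsa:::eval_vdw(ctx2, xyz_pair(10.5))$e, 0)
  ## capped repulsion is linear below cap_frac * Rmin
  ctx3 <- two_atom_ctx()
  rc <- 0.6 * 3.4
  e_a <- loopcsa:::eval_vdw(ctx3, xyz_pair(rc - 0.2))$e
  e_b <- loopcsa:::eval_vdw(ctx3, xyz_pair(rc - 0.4))$e
  e_c <- loopcsa:::eval_vdw(ctx3, xyz_pair(rc - 0.6))$e
  expect_equal(e_b - e_a, e_c - e_b, tolerance = 1e-9)
})

test_that("Coulomb matches the 332.06 prefactor convention", {
  ctx <- two_atom_ctx(q1 = 1, q2 = 1)
  e <- loopcsa:::eval_coulomb(ctx, xyz_pair(10))$e
  expect_equal(e, 332.06 / 10, tolerance = 1e-12)
})

test_that("harmonic bond energy scales as k dr^2", {
  ctx <- two_atom_ctx()
  ctx$bonds <- matrix(c(1L, 2L), 1, 2)
  ctx$b0 <- 1.5
  es <- vapply(c(0.01, 0.02, 0.04), function(d)
    loopcsa:::eval_bonded(ctx, xyz_pair(1.5 + d))$e, numeric(1))
  expect_equal(es / es[1], c(1, 4, 16), tolerance = 1e-9)
})

test_that("bonded contribution of an ideal-geometry loop is tiny", {
  sc <- scaffold8()
  expect_lt(e_bonded(sc$structure, sc$loop), 2)
})

test_that("analytic gradients match central differences", {
  sc <- scaffold8()
  mc <- default_model_ctx()
  ctx <- mc$ctx
  f0 <- function(x) loopcsa:::eval_bonded(ctx, x)$e +
    loopcsa:::eval_vdw(ctx, x)$e + loopcsa:::eval_coulomb(ctx, x)$e
  set.seed(41)
  for (rep in 1:4) {
    st <- random_closed_state(sc)
    skip_if(is.null(st))
    xyz <- loopcsa:::get_xyz(coords_from_torsions(sc$structure, sc$loop, st))
    g <- loopcsa:::eval_bonded(ctx, xyz, grad = TRUE)$g +
      loopcsa:::eval_vdw(ctx, xyz, grad = TRUE)$g +
      loopcsa:::eval_coulomb(ctx, xyz, grad = TRUE)$g
    sel <- cbind(sample(nrow(xyz), 12), sample(3, 12, replace = TRUE))
    h <- 1e-5
    for (k in seq_len(nrow(sel))) {
      xp <- xyz; xp[sel[k, 1], sel[k, 2]] <- xp[sel[k, 1], sel[k, 2]] + h
      xm <- xyz; xm[sel[k, 1], sel[k, 2]] <- xm[sel[k, 1], sel[k, 2]] - h
      num <- (f0(xp) - f0(xm)) / (2 * h)
      expect_equal(g[sel[k, 1], sel[k, 2]], num,
                   tolerance = 1e-5 * max(1, abs(num)))
    }
  }
})

test_that("every term is invariant under rigid transforms", {
  sc <- scaffold8()
  mc <- default_model_ctx()
  xyz <- loopcsa:::get_xyz(sc$structure)
  br <- total_energy(NULL, sc$loop, ctx = mc$ctx, xyz = xyz)
  set.seed(42)
  terms <- c("e_bonded", "e_vdw", "e_coulomb", "e_gb", "e_sa", "e_phipsi",
             "e_chi", "e_hbond", "e_atompair", "e_total")
  for (rep in 1:3) {
    R <- loopcsa:::rotation_about_axis(rnorm(3), runif(1, 5, 355))
    x2 <- t(R %*% t(xyz)) + matrix(rnorm(3, 0, 8), nrow(xyz), 3, byrow = TRUE)
    br2 <- total_energy(NULL, sc$loop, ctx = mc$ctx, xyz = x2)
    for (t in terms)
      expect_lt(abs(br2[[t]] - br[[t]]), 1e-8)
  }
})

test_that("weights act linearly and the breakdown sums exactly", {
  sc <- scaffold8()
  mc <- default_model_ctx()
  br <- total_energy(NULL, sc$loop, ctx = mc$ctx,
                     xyz = loopcsa:::get_xyz(sc$structure))
  w <- br$weights
  ## bookkeeping identity
  s <- br$e_bonded + br$e_vdw + w$w_electrostatics * (br$e_coulomb + br$e_gb) +
    w$w_sa * br$e_sa + w$w_phipsi * br$e_phipsi + w$w_chi * br$e_chi +
    w$w_hbond * br$e_hbond + w$w_atompair * br$e_atompair
  expect_lt(abs(s - br$e_total), 1e-10)
  ## doubling one weight changes the total by exactly that term
  m2 <- energy_model(weights = energy_weights(w_hbond = 8))
  ctx2 <- energy_context(sc$structure, sc$loop, m2)
  br2 <- total_energy(NULL, sc$loop, ctx = ctx2,
                      xyz = loopcsa:::get_xyz(sc$structure))
  expect_equal(as.numeric(br2$e_total - br$e_total), 4 * br$e_hbond,
               tolerance = 1e-8)
  ## zeroed knowledge/solvation weights leave bonded + vdw + watompair * ap
  m0 <- energy_model(weights = energy_weights(0, 0, 0, 0, 0, 12))
  ctx0 <- energy_context(sc$structure, sc$loop, m0)
  br0 <- total_energy(NULL, sc$loop, ctx = ctx0,
                      xyz = loopcsa:::get_xyz(sc$structure))
  expect_equal(br0$e_total,
               br0$e_bonded + br0$e_vdw + 12 * br0$e_atompair,
               tolerance = 1e-10)
})

test_that("Born radii grow with burial and match a numeric descreening oracle", {
  sc <- scaffold8()
  mc <- default_model_ctx()
  ctx <- mc$ctx
  xyz <- loopcsa:::get_xyz(sc$structure)
  R <- loopcsa:::born_radii(ctx, xyz)
  ## most buried CA (most neighbors within 8 A) vs most exposed CA
  ca <- which(ctx$prot$atoms$name == "CA")
  nn <- vapply(ca, function(i)
    sum(sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2)) < 8) - 1, numeric(1))
  expect_gt(R[ca[which.max(nn)]], R[ca[which.min(nn)]])
  ## two-sphere oracle: HCT pair integral vs numeric quadrature
  rho_i <- 1.5; a_j <- 1.2
  for (r in c(2.8, 3.5, 5)) {
    got <- {
      L <- max(rho_i, abs(r - a_j)); U <- r + a_j
      0.5 * (1 / L - 1 / U) +
        (a_j^2 - r^2) / (8 * r) * (1 / L^2 - 1 / U^2) -
        log(U / L) / (4 * r)
    }
    ## numeric: (1/4pi) int over sphere j (outside rho_i) of s^-4
    num <- integrate(function(s) {
      mu <- (r^2 + s^2 - a_j^2) / (2 * r * s)
      0.5 * (1 - mu) / s^2
    }, lower = max(rho_i, r - a_j), upper = r + a_j,
    rel.tol = 1e-10)$value
    expect_equal(got, num, tolerance = 1e-8)
  }
})

test_that("a buried salt bridge is electrostatically stronger than an exposed one", {
  ## two opposite unit charges at fixed separation, with and without a
  ## shell of neutral descreening atoms around them
  mkctx <- function(n_extra) {
    n <- 2 + n_extra
    ctx <- two_atom_ctx(q1 = 1, q2 = -1)
    ctx$n <- n
    ctx$q <- c(1, -1, rep(0, n_extra))
    ctx$radius <- rep(1.7, n); ctx$epsilon <- rep(0.1, n)
    ctx$hct <- rep(0.72, n)
    ctx$scale <- cbind(matrix(c(0, 1), 1, 2), matrix(0, 1, n_extra))
    ctx$frame_atoms <- matrix(rep(c(2L, 1L), each = n), n, 2)
    ctx
  }
  d <- 3.5
  tau <- 1 - 1 / loopcsa:::EPS_SOLVENT
  interaction <- function(n_extra, xyz) {
    ctx <- mkctx(n_extra)
    R <- loopcsa:::born_radii(ctx, xyz)
    fgb <- sqrt(d^2 + R[1] * R[2] * exp(-d^2 / (4 * R[1] * R[2])))
    gb_cross <- -332.06 * tau * (1 * -1) / fgb
    -332.06 / d + gb_cross    # screened pair interaction
  }
  exposed <- interaction(0, xyz_pair(d))
  set.seed(43)
  shell <- matrix(rnorm(3 * 60), ncol = 3)
  shell <- 4.5 * shell / sqrt(rowSums(shell^2)) +
    matrix(c(d / 2, 0, 0), 60, 3, byrow = TRUE)
  buried <- interaction(60, rbind(xyz_pair(d), shell))
  ## solvent screening cancels most of the exposed attraction; burial
  ## (larger Born radii) recovers it
  expect_lt(buried, exposed)
  expect_gt(exposed, 0.4 * (-332.06 / d))
})

test_that("SASA matches closed forms and refinement", {
  ## single effectively isolated atom: 4 pi (r + probe)^2
  ctx <- two_atom_ctx()
  s1 <- loopcsa:::eval_sasa(ctx, xyz_pair(50), rows = 1L)
  expect_equal(s1, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-6)
  ## two overlapping atoms lose area
  s2 <- sum(loopcsa:::eval_sasa(ctx, xyz_pair(2.0), rows = 1:2))
  expect_lt(s2, 2 * 4 * pi * (1.7 + 1.4)^2)
  ## 192-point result within 2% of a 10000-point run on a real loop
  sc <- scaffold8()
  mc <- default_model_ctx()
  xyz <- loopcsa:::get_xyz(sc$structure)
  rows <- mc$ctx$loop_rows
  lo <- loopcsa:::eval_sasa(mc$ctx, xyz, rows = rows)
  hictx <- mc$ctx
  hictx$sphere <- loopcsa:::fibonacci_sphere(10000)
  hi <- loopcsa:::eval_sasa(hictx, xyz, rows = rows)
  expect_lt(abs(sum(lo) - sum(hi)) / max(sum(hi), 1), 0.02)
})

test_that("hydrogen bonds have a negative well, a hard cutoff and C1 smoothness", {
  sc <- scaffold8()
  mc <- default_model_ctx()
  ctx <- mc$ctx
  e0 <- loopcsa:::eval_hbond(ctx, loopcsa:::get_xyz(sc$structure))
  expect_lt(e0, 0)    # helix flanks donate backbone hydrogen bonds
  ## construct a single ideal-geometry pair and scan the distance
  hp <- ctx$hb_pairs[1, , drop = FALSE]
  ctx1 <- ctx
  ctx1$hb_pairs <- hp
  xyz <- loopcsa:::get_xyz(sc$structure)
  D <- xyz[hp[1, "D"], ]
  dir <- loopcsa:::unitv(xyz[hp[1, "H"], ] - D)
  scan <- function(d) {
    x2 <- xyz
    x2[hp[1, "A"], ] <- xyz[hp[1, "H"], ] + d * dir    # linear D-H...A
    x2[hp[1, "B"], ] <- x2[hp[1, "A"], ] +
      loopcsa:::rotation_about_axis(c(0, 0, 1), 60) %*% (1.23 * dir)
    loopcsa:::eval_hbond(ctx1, x2)
  }
  expect_lt(scan(1.95), -1.2)          # full well at ideal geometry
  expect_identical(scan(3.0), 0)       # zero outside the distance cutoff
  ## C1 continuity: numeric derivative along the scan has no jumps
  ds <- seq(1.2, 3.2, by = 0.005)
  es <- vapply(ds, scan, numeric(1))
  d1 <- diff(es) / diff(ds)[1]
  ## a C0 kink would give an O(1) derivative jump; smooth curvature gives
  ## jumps of order |E''| h
  expect_lt(max(abs(diff(d1))), 0.3)
})

test_that("torsion-statistics terms interpolate the tables correctly", {
  sc <- scaffold8()
  ts <- sc$native_torsions
  resnames <- vapply(ts$resnos, function(i)
    sc$structure$residues$resname[sc$structure$residues$resno == i],
    character(1))
  ## uniform table -> zero energy at any angles
  tab <- default_phipsi_table()
  for (cl in names(tab$grid)) tab$grid[[cl]][] <- 0
  expect_equal(e_phipsi(ts, tab, resnames), 0)
  ## exact at bin centers
  tab2 <- default_phipsi_table()
  ts2 <- ts
  ts2$phi[] <- tab2$centers[7]; ts2$psi[] <- tab2$centers[20]
  got <- e_phipsi(ts2, tab2, resnames)
  want <- loopcsa:::RT_KCAL *
    sum(vapply(resnames, function(rn)
      tab2$grid[[loopcsa:::phipsi_class(rn)]][7, 20], numeric(1)))
  expect_equal(got, want, tolerance = 1e-10)
  ## bilinear interpolation stays inside the 4 surrounding bin values
  g <- tab2$grid$GEN
  set.seed(44)
  for (rep in 1:50) {
    phi <- runif(1, -180, 180); psi <- runif(1, -180, 180)
    v <- loopcsa:::interp2_periodic(g, tab2$centers, phi, psi)
    i0 <- floor((phi - tab2$centers[1]) / 10); j0 <- floor((psi - tab2$centers[1]) / 10)
    w <- function(i) (i %% 36) + 1
    corners <- c(g[w(i0), w(j0)], g[w(i0 + 1), w(j0)],
                 g[w(i0), w(j0 + 1)], g[w(i0 + 1), w(j0 + 1)])
    expect_gte(v, min(corners) - 1e-12)
    expect_lte(v, max(corners) + 1e-12)
  }
})

test_that("the atom-pair term is linear in the table and matches a naive sum", {
  sc <- scaffold8()
  mc <- default_model_ctx()
  ctx <- mc$ctx
  xyz <- loopcsa:::get_xyz(sc$structure)
  e1 <- loopcsa:::eval_atompair(ctx, xyz)
  ## doubling the table doubles the term
  ctx2 <- ctx
  ctx2$model$pair$values <- 2 * ctx$model$pair$values
  expect_equal(loopcsa:::eval_atompair(ctx2, xyz), 2 * e1, tolerance = 1e-9)
  ## naive per-pair oracle
  tab <- ctx$model$pair
  at <- sc$structure$atoms
  rs <- loop_resnos(sc$loop)
  naive <- 0
  lrows <- which(at$resno %in% rs & at$element != "H")
  for (i in lrows) for (j in seq_len(nrow(at))) {
    if (j == i || at$element[j] == "H") next
    if (j %in% lrows && j < i) next
    if (abs(at$resno[i] - at$resno[j]) < 2) next
    d <- loopcsa:::vnorm(xyz[i, ] - xyz[j, ])
    if (d >= tab$r_cut) next
    bi <- min(length(tab$centers), 1 + floor(d / tab$bin_width))
    ci <- match(at$class[i], tab$classes); cj <- match(at$class[j], tab$classes)
    naive <- naive + tab$values[ci, cj, bi]
  }
  expect_equal(e1, naive, tolerance = 1e-9)
  ## pairs in the reference bin contribute zero
  ctx3 <- two_atom_ctx()
  ctx3$ap_ok <- matrix(c(FALSE, TRUE), 1, 2)
  ctx3$model$pair <- default_pair_potential()
  ctx3$cls_idx <- c(1L, 1L)
  expect_identical(loopcsa:::eval_atompair(ctx3, xyz_pair(14.8)), 0)
})
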