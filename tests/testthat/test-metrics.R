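# Superposition and RMSD metrics.

test_that("Kabsch superposition recovers exact transforms and is optimal", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  fit <- kabsch_superpose(x, x)
  expect_lt(fit$rms, 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  ## applied rotation + translation is inverted exactly
  R <- loopcsa:::rotation_about_axis(c(0, 0, 1), 90)
  y <- t(R %*% t(x)) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  fit2 <- kabsch_superpose(x, y)
  expect_lt(fit2$rms, 1e-10)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-9)
  expect_equal(fit2$transform(x), y, tolerance = 1e-9)
  ## optimality against 1000 random rotations
  set.seed(2)
  z <- matrix(rnorm(30), 10, 3)
  best <- kabsch_superpose(x, z)$rms
  cz <- sweep(z, 2, colMeans(z)); cx <- sweep(x, 2, colMeans(x))
  for (k in 1:1000) {
    R <- loopcsa:::rotation_about_axis(rnorm(3), runif(1, 0, 360))
    expect_gte(sqrt(mean(rowSums((t(R %*% t(cx)) - cz)^2))) + 1e-12, best)
  }
  expect_error(kabsch_superpose(x[1:2, ], z[1:2, ]), "3")
})

test_that("Kabsch agrees with the bio3d reference implementation", {
  set.seed(3)
  a <- matrix(rnorm(36), 12, 3)
  b <- a + matrix(rnorm(36, 0, 0.3), 12, 3)
  ours <- kabsch_superpose(a, b)
  ref <- bio3d::fit.xyz(fixed = as.numeric(t(b)), mobile = as.numeric(t(a)))
  ref_rms <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - b)^2)))
  expect_equal(ours$rms, ref_rms, tolerance = 1e-8)
})

test_that("loop main-chain RMSD matches a direct-sum oracle", {
  sc <- scaffold8()
  prot <- sc$structure; loop <- sc$loop
  expect_equal(loop_mainchain_rmsd(prot, prot, loop, "none"), 0)
  ## rigid 1 A translation of the loop only
  moved <- prot
  rows <- loopcsa:::residue_rows(prot, "A", loop_resnos(loop))
  xyz <- loopcsa:::get_xyz(moved)
  xyz[rows, 1] <- xyz[rows, 1] + 1
  moved <- loopcsa:::set_xyz(moved, xyz)
  expect_equal(loop_mainchain_rmsd(moved, prot, loop, "none"), 1,
               tolerance = 1e-12)
  ## arbitrary pair vs naive oracle
  set.seed(4)
  st <- random_closed_state(sc)
  model <- coords_from_torsions(prot, loop, st)
  got <- loop_mainchain_rmsd(model, prot, loop, "none")
  bb <- loopcsa:::loop_backbone_rows(prot, loop)
  naive <- sqrt(mean(rowSums((loopcsa:::get_xyz(model)[bb, ] -
                                loopcsa:::get_xyz(prot)[bb, ])^2)))
  expect_equal(got, naive, tolerance = 1e-9)
  ## sequence mismatch errors
  other <- prot
  other$residues$resname[other$residues$resno == loop$start] <- "GLY"
  expect_error(loop_mainchain_rmsd(other, prot, loop, "none"), "mismatch")
})

test_that("symmetric flips zero out pure relabelings and ring rotations", {
  sc <- scaffold8()
  prot <- sc$structure
  ## swap OD1/OD2 labels of an aspartate
  asp <- prot$residues$resno[prot$residues$resname == "ASP"][1]
  swapped <- prot
  i1 <- loopcsa:::atom_index(prot, "A", asp, "OD1")
  i2 <- loopcsa:::atom_index(prot, "A", asp, "OD2")
  swapped$atoms$name[c(i1, i2)] <- c("OD2", "OD1")
  swapped$atoms$key[c(i1, i2)] <- swapped$atoms$key[c(i2, i1)]
  sel <- data.frame(chain = "A", resno = asp)
  expect_equal(symmetric_flip_rmsd(swapped, prot, sel), 0, tolerance = 1e-9)
  ## PHE ring rotated by exactly 180 about CB-CG (chi2 + 180)
  phe <- prot$residues$resno[prot$residues$resname == "PHE"][1]
  chis <- loopcsa:::measure_chis(prot, "A", phe, "PHE")
  rot <- loopcsa:::set_sidechain_chis(prot, "A", phe,
                                      c(chis[1], chis[2] + 180))
  sel <- data.frame(chain = "A", resno = phe)
  ## exact up to the small idealized-ring closure asymmetry
  expect_lt(symmetric_flip_rmsd(rot, prot, sel), 0.01)
})

test_that("flip-minimized RMSD equals exhaustive enumeration", {
  sc <- scaffold8()
  prot <- sc$structure
  flippable <- prot$residues$resno[prot$residues$resname %in%
                                     names(loopcsa:::FLIP_PAIRS)]
  set.seed(5)
  for (rep in 1:12) {
    resnos <- sort(sample(prot$residues$resno, sample(4:9, 1)))
    sel <- data.frame(chain = "A", resno = resnos)
    noisy <- prot
    xyz <- loopcsa:::get_xyz(noisy) + matrix(rnorm(nrow(prot$atoms) * 3,
                                                   0, 0.3),
                                             ncol = 3)
    noisy <- loopcsa:::set_xyz(noisy, xyz)
    got <- symmetric_flip_rmsd(noisy, prot, sel)
    expect_equal(got, brute_force_flip_rmsd(noisy, prot, sel),
                 tolerance = 1e-9)
    expect_lte(got,
               symmetric_flip_rmsd(noisy, prot, sel) + 1e-12)
  }
})

test_that("environment selection honors the closed cutoff and matches a scan", {
  sc <- scaffold8()
  prot <- sc$structure; loop <- sc$loop
  env <- environment_residues(prot, loop, 10)
  expect_gt(nrow(env), 0)
  ## brute-force all-pairs oracle
  xyz <- loopcsa:::get_xyz(prot)
  cb <- vapply(loop_resnos(loop), function(i) {
    j <- loopcsa:::atom_index(prot, "A", i, "CB")
    if (is.na(j)) j <- loopcsa:::atom_index(prot, "A", i, "CA")
    j
  }, integer(1))
  oracle <- c()
  for (k in seq_len(nrow(prot$residues))) {
    i <- prot$residues$resno[k]
    if (i %in% loop_resnos(loop)) next
    rows <- loopcsa:::residue_rows(prot, "A", i)
    dmin <- min(sqrt(outer(rowSums(xyz[rows, , drop = FALSE]^2),
                           rowSums(xyz[cb, , drop = FALSE]^2), "+") -
                       2 * xyz[rows, , drop = FALSE] %*%
                       t(xyz[cb, , drop = FALSE])))
    if (dmin <= 10) oracle <- c(oracle, i)
  }
  expect_equal(env$resno, oracle)
  ## monotone in the cutoff
  for (cut in c(4, 6, 8, 12)) {
    e1 <- environment_residues(prot, loop, cut)
    e2 <- environment_residues(prot, loop, cut + 2)
    expect_true(all(e1$resno %in% e2$resno))
  }
  expect_error(environment_residues(prot, loop, 0), "positive")
})

test_that("boundary inclusion at exactly the cutoff is closed", {
  sc <- scaffold8()
  prot <- sc$structure; loop <- sc$loop
  ## place a single far-away residue at a controlled minimum distance from
  ## the loop CB set
  cbs <- t(vapply(loop_resnos(loop), function(i) {
    j <- loopcsa:::atom_index(prot, "A", i, "CB")
    if (is.na(j)) j <- loopcsa:::atom_index(prot, "A", i, "CA")
    loopcsa:::get_xyz(prot)[j, ]
  }, numeric(3)))
  ctr <- colMeans(cbs)
  far <- which.max(rowSums(sweep(cbs, 2, ctr)^2))
  u <- loopcsa:::unitv(cbs[far, ] - ctr)
  probe <- prot
  rows <- loopcsa:::residue_rows(probe, "A", 1)
  xyz <- loopcsa:::get_xyz(probe)
  xyz[rows, ] <- xyz[rows, ] + 500
  nidx <- loopcsa:::atom_index(probe, "A", 1, "N")
  for (d in c(9.99, 10.01)) {
    xyz[nidx, ] <- cbs[far, ] + d * u
    dmin <- min(sqrt(rowSums(sweep(cbs, 2, xyz[nidx, ])^2)))
    expect_equal(dmin, d, tolerance = 1e-9)   # geometry as constructed
    p2 <- loopcsa:::set_xyz(probe, xyz)
    env <- environment_residues(p2, loop, 10)
    expect_equal(1 %in% env$resno, d < 10)
  }
})

test_that("E-RMSD is zero on self and invariant under rigid transforms", {
  sc <- scaffold8()
  prot <- sc$structure; loop <- sc$loop
  expect_lt(e_rmsd(prot, prot, loop), 1e-10)
  p1 <- perturb_environment(prot, loop,
                            perturbation_spec("sidechain", 0.9,
                                              rng_seed = 21))
  e0 <- e_rmsd(p1, prot, loop)
  R <- loopcsa:::rotation_about_axis(c(1, 1, 0), 123)
  moved <- loopcsa:::set_xyz(p1, t(R %*% t(loopcsa:::get_xyz(p1))) +
                               matrix(c(3, -7, 11), nrow(p1$atoms), 3,
                                      byrow = TRUE))
  expect_lt(abs(e_rmsd(moved, prot, loop) - e0), 1e-8)
  ## also rotate the reference
  movedr <- loopcsa:::set_xyz(prot, t(R %*% t(loopcsa:::get_xyz(prot))))
  expect_lt(abs(e_rmsd(p1, movedr, loop) - e0), 1e-8)
})

test_that("rmsd_report is consistent and flip-minimization never hurts", {
  sc <- scaffold8()
  prot <- sc$structure; loop <- sc$loop
  set.seed(6)
  st <- random_closed_state(sc)
  model <- coords_from_torsions(prot, loop, st)
  rep <- rmsd_report(model, prot, loop)
  expect_gte(rep$loop_mainchain_rmsd, 0)
  expect_gte(rep$e_rmsd, 0)
  expect_equal(rep$n_env_residues, nrow(environment_residues(prot, loop, 10)))
  ## flip-minimized all-atom rmsd <= identity-assignment rmsd
  loopsel <- data.frame(chain = "A", resno = loop_resnos(loop))
  id_rmsd <- {
    ma <- loopcsa:::matched_atoms(model, prot, loopsel)
    sqrt(mean(rowSums((loopcsa:::get_xyz(model)[ma$model, ] -
                         loopcsa:::get_xyz(prot)[ma$reference, ])^2)))
  }
  expect_lte(symmetric_flip_rmsd(model, prot, loopsel), id_rmsd + 1e-12)
})
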