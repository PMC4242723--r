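# Structure model: PDB I/O, polar-hydrogen topology, validity checks.

test_that("polar-hydrogen topology has the expected atoms and is idempotent", {
  sc <- scaffold8()
  prot <- sc$structure
  for (k in seq_len(nrow(prot$residues))) {
    rn <- prot$residues$resname[k]
    n_at <- sum(prot$atoms$resno == prot$residues$resno[k])
    expect_equal(n_at, loopcsa:::residue_atom_count(rn), label = rn)
  }
  ## no aliphatic hydrogens, amide H present except proline
  expect_false(any(grepl("^HB|^HA", prot$atoms$name)))
  pro <- prot$residues$resno[prot$residues$resname == "PRO"]
  for (i in pro)
    expect_true(is.na(loopcsa:::atom_index(prot, "A", i, "H")))
  ## idempotence
  p2 <- build_polar_hydrogen_topology(prot)
  expect_lt(max(abs(loopcsa:::get_xyz(p2) - loopcsa:::get_xyz(prot))), 1e-9)
  expect_identical(p2$atoms$name, prot$atoms$name)
})

test_that("serine hydroxyl hydrogen is placed at ideal geometry", {
  sc <- scaffold8()
  prot <- sc$structure
  ser <- prot$residues$resno[prot$residues$resname == "SER"][1]
  skip_if(is.na(ser), "no serine in scaffold")
  og <- loopcsa:::atom_xyz(prot, "A", ser, "OG")
  hg <- loopcsa:::atom_xyz(prot, "A", ser, "HG")
  cb <- loopcsa:::atom_xyz(prot, "A", ser, "CB")
  expect_equal(loopcsa:::vnorm(hg - og), 0.96, tolerance = 1e-6)
  expect_equal(loopcsa:::bond_angle(hg, og, cb), 109.5, tolerance = 1e-4)
})

test_that("unknown residue names are rejected", {
  sc <- scaffold8()
  prot <- sc$structure
  prot$atoms$resname[prot$atoms$resno == 5] <- "XYZ"
  prot$residues$resname[prot$residues$resno == 5] <- "XYZ"
  expect_error(build_polar_hydrogen_topology(prot), "unknown residue")
})

test_that("PDB write/read round-trips coordinates to field precision", {
  sc <- scaffold8()
  f <- tempfile(fileext = ".pdb")
  write_pdb(sc$structure, f)
  back <- read_pdb(f)
  ma <- loopcsa:::matched_atoms(back, sc$structure,
                               sc$structure$residues[, c("chain", "resno")],
                               include_hydrogens = TRUE)
  dev <- abs(loopcsa:::get_xyz(back)[ma$model, ] -
               loopcsa:::get_xyz(sc$structure)[ma$reference, ])
  expect_lte(max(dev), 0.0011)
  expect_equal(nrow(back$atoms), nrow(sc$structure$atoms))
})

test_that("multi-chain structures get TER records and empty writes fail", {
  sc <- scaffold8()
  two <- sc$structure
  two$atoms$chain[two$atoms$resno > 14] <- "B"
  two$atoms$resno[two$atoms$chain == "B"] <-
    two$atoms$resno[two$atoms$chain == "B"] - 14
  two <- loopcsa:::new_protein(two$atoms)
  f <- tempfile(fileext = ".pdb")
  write_pdb(two, f)
  lines <- readLines(f)
  expect_gte(sum(grepl("^TER", lines)), 2)
  empty <- sc$structure
  empty$atoms <- empty$atoms[0, ]
  expect_error(write_pdb(empty, tempfile()), "empty")
})

test_that("alternate locations resolve to the highest occupancy", {
  sc <- scaffold8()
  f <- tempfile(fileext = ".pdb")
  write_pdb(sc$structure, f)
  lines <- readLines(f)
  ## duplicate one CB line as altLocs A (occ 0.6) and B (occ 0.4)
  i <- grep(" CB ", lines)[1]
  la <- lines[i]; lb <- lines[i]
  substr(la, 17, 17) <- "A"; substr(la, 57, 60) <- "0.60"
  substr(lb, 17, 17) <- "B"; substr(lb, 57, 60) <- "0.40"
  ## displace the B copy in x by +5
  xb <- as.numeric(substr(lb, 31, 38)) + 5
  substr(lb, 31, 38) <- sprintf("%8.3f", xb)
  lines <- c(lines[seq_len(i - 1)], la, lb, lines[-seq_len(i)])
  f2 <- tempfile(fileext = ".pdb")
  writeLines(lines, f2)
  back <- read_pdb(f2)
  xa <- as.numeric(substr(la, 31, 38))
  resno <- as.integer(substr(la, 23, 26))
  got <- loopcsa:::atom_xyz(back, "A", resno, "CB")
  expect_equal(got[1], xa, tolerance = 1e-3)
})

test_that("a missing backbone atom is reported with the residue", {
  sc <- scaffold8()
  f <- tempfile(fileext = ".pdb")
  broken <- sc$structure
  drop <- loopcsa:::atom_index(broken, "A", 7, "CA")
  broken$atoms <- broken$atoms[-drop, ]
  broken <- loopcsa:::new_protein(broken$atoms)
  write_pdb(broken, f)
  expect_error(read_pdb(f), "residue A 7")
})

test_that("chain breaks are detected and loops may not span them", {
  sc <- scaffold8()
  prot <- sc$structure
  rows <- which(prot$atoms$resno >= 20)
  xyz <- loopcsa:::get_xyz(prot)
  xyz[rows, 1] <- xyz[rows, 1] + 30
  prot <- loopcsa:::new_protein(loopcsa:::set_xyz(prot, xyz)$atoms)
  expect_true(any(prot$breaks$resno == 19))
  expect_error(loopcsa:::validate_loop(prot, loop_definition("A", 15, 22)),
               "chain break")
})

test_that("cis-proline is flagged from the omega torsion", {
  ## build a tiny chain with a cis peptide bond before a proline
  sc <- make_scaffold(scaffold_spec(
    rng_seed = 9, sequence = c(rep("ALA", 12), "PRO", rep("ALA", 15)),
    n_residues_total = 28))
  prot <- sc$structure
  ts <- torsions_from_coords(prot, loop_definition("A", 11, 16))
  ts$omega[match(13, ts$resnos)] <- 0
  prot2 <- coords_from_torsions(prot, loop_definition("A", 11, 16), ts)
  prot2 <- loopcsa:::detect_cispro(prot2)
  expect_true(prot2$residues$cispro[prot2$residues$resno == 13])
  expect_false(any(sc$structure$residues$cispro))
})

test_that("loop definitions are validated", {
  expect_error(loop_definition("A", 5, 6), "length")
  expect_error(loop_definition("A", 5, 40), "length")
  sc <- scaffold8()
  expect_error(loopcsa:::validate_loop(sc$structure,
                                       loop_definition("A", 26, 30)),
               "anchor")
})
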