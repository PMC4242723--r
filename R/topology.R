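## Polar-hydrogen topology builder: completes missing side-chain heavy atoms
## from ideal geometry at the most common rotamer, attaches hydrogens bound
## to N/O/S by ideal geometry, assigns partial charges and atom classes from
## the packaged parameter set, and records the bonded topology.

.loopcsa_env <- new.env(parent = emptyenv())

atom_class_table <- function() {
  if (is.null(.loopcsa_env$classes)) .loopcsa_env$classes <- load_atom_classes()
  .loopcsa_env$classes
}

#' Build the polar-hydrogen topology of a structure
#'
#' Missing side-chain heavy atoms are rebuilt from ideal internal coordinates
#' at the most common rotamer; hydrogens on N, O and S are placed by ideal
#' geometry (aliphatic/aromatic C-H hydrogens are absent: united-atom carbons
#' carry enlarged radii).  Partial charges, atom classes, Lennard-Jones
#' parameters and surface tensions are assigned from the packaged set.
#' Idempotent: applying it to an already-built structure reproduces it.
#'
#' @param structure a "protein" object with complete backbone heavy atoms.
#' @return a "protein" object with canonical atom ordering, parameters and a
#'   bond table.
#' @export
build_polar_hydrogen_topology <- function(structure) {
  prot <- structure
  res <- prot$residues
  unknown <- setdiff(unique(res$resname), AA3)
  if (length(unknown))
    stop("unknown residue name(s): ", paste(unknown, collapse = ", "))
  check_backbone(prot)
  cls <- atom_class_table()

  out <- vector("list", nrow(res))
  for (k in seq_len(nrow(res))) {
    ch <- res$chain[k]; i <- res$resno[k]; rn <- res$resname[k]
    bb <- backbone_atoms(rn)
    sc <- SIDECHAIN_ZMAT[[rn]]
    spec <- rbind(bb[, c("name", "element", "class", "charge")],
                  sc[, c("name", "element", "class", "charge")])
    pos <- matrix(NA_real_, nrow(spec), 3)
    rownames(pos) <- spec$name
    ## copy atoms already present
    for (nm in spec$name) {
      j <- atom_index(prot, ch, i, nm)
      if (!is.na(j))
        pos[nm, ] <- c(prot$atoms$x[j], prot$atoms$y[j], prot$atoms$z[j])
    }
    ## backbone amide H
    if ("H" %in% spec$name && anyNA(pos["H", ])) {
      cprev <- atom_index(prot, ch, i - 1, "C")
      caprev <- atom_index(prot, ch, i - 1, "CA")
      if (!is.na(cprev) && !is.na(caprev) && !is_break_after(prot, ch, i - 1)) {
        xyz <- get_xyz(prot)
        pos["H", ] <- place_atom(xyz[caprev, ], xyz[cprev, ], pos["N", ],
                                 BB$b_NH, BB$a_HNC, 0)
      } else {
        pos["H", ] <- place_atom(pos["C", ], pos["CA", ], pos["N", ],
                                 BB$b_NH, 118, 180)
      }
    }
    ## side-chain chi values: measured where possible, common rotamer else
    nchi <- N_CHI[[rn]]
    chiv <- if (nchi > 0 && !is.null(COMMON_ROTAMER[[rn]]))
      COMMON_ROTAMER[[rn]] else rep(180, max(nchi, 1))
    if (nchi > 0) {
      defs <- CHI_ATOMS[[rn]]
      for (c_k in seq_len(nchi)) {
        p4 <- pos[defs[[c_k]], , drop = FALSE]
        if (!anyNA(p4))
          chiv[c_k] <- dihedral_angle(p4[1, ], p4[2, ], p4[3, ], p4[4, ])
      }
    }
    ## place missing side-chain atoms in z-matrix order
    if (nrow(sc) > 0) for (j in seq_len(nrow(sc))) {
      nm <- sc$name[j]
      if (!anyNA(pos[nm, ])) next
      tors <- sc$tors[j]
      if (!is.na(sc$chi[j])) tors <- wrap_angle(chiv[sc$chi[j]] + tors)
      pos[nm, ] <- place_atom(pos[sc$a[j], ], pos[sc$b[j], ], pos[sc$c[j], ],
                              sc$bond[j], sc$angle[j], tors)
    }
    df <- data.frame(chain = ch, resno = i, resname = rn, name = spec$name,
                     element = spec$element, class = spec$class,
                     charge = spec$charge,
                     occ = 1, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                     stringsAsFactors = FALSE)
    out[[k]] <- df
  }
  atoms <- do.call(rbind, out)
  m <- match(atoms$class, cls$class)
  atoms$radius <- cls$radius[m]
  atoms$epsilon <- cls$epsilon[m]
  atoms$gamma <- cls$gamma[m]
  atoms$hct_scale <- cls$hct_scale[m]
  rownames(atoms) <- NULL
  newp <- new_protein(atoms, source = prot$source, topology = TRUE)
  newp$residues$cispro <- prot$residues$cispro
  newp$bonds <- build_bonds(newp)
  newp
}

## Extra intra-residue bonds closing rings (beyond z-matrix parent links).
RING_CLOSURE_BONDS <- list(
  PHE = list(c("CZ", "CE2")),
  TYR = list(c("CZ", "CE2")),
  HIS = list(c("CE1", "NE2")),
  TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")),
  PRO = list(c("CD", "N"))
)

build_bonds <- function(prot) {
  res <- prot$residues
  bonds <- list()
  add <- function(i, j) {
    if (!is.na(i) && !is.na(j)) bonds[[length(bonds) + 1]] <<- c(i, j)
  }
  for (k in seq_len(nrow(res))) {
    ch <- res$chain[k]; i <- res$resno[k]; rn <- res$resname[k]
    ai <- function(nm) atom_index(prot, ch, i, nm)
    add(ai("N"), ai("CA")); add(ai("CA"), ai("C")); add(ai("C"), ai("O"))
    add(ai("N"), ai("H"))
    sc <- SIDECHAIN_ZMAT[[rn]]
    if (nrow(sc) > 0) {
      add(ai("CA"), ai("CB"))
      for (j in seq_len(nrow(sc)))
        if (sc$name[j] != "CB") add(ai(sc$name[j]), ai(sc$c[j]))
    }
    for (pr in RING_CLOSURE_BONDS[[rn]] %||% list())
      add(ai(pr[1]), ai(pr[2]))
    if (!is_break_after(prot, ch, i))
      add(ai("C"), atom_index(prot, ch, i + 1, "N"))
  }
  mat <- do.call(rbind, bonds)
  mat[mat[, 1] > mat[, 2], ] <- mat[mat[, 1] > mat[, 2], c(2, 1)]
  unique(mat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Bonded-neighbor classification for nonbonded exclusions: returns a list
## with matrices `excl12_13` and `pairs14` of atom index pairs.
bond_separation <- function(prot) {
  n <- nrow(prot$atoms)
  adj <- vector("list", n)
  for (r in seq_len(nrow(prot$bonds))) {
    i <- prot$bonds[r, 1]; j <- prot$bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  p12 <- prot$bonds
  p13 <- list(); p14 <- list()
  for (i in seq_len(n)) {
    for (j in adj[[i]]) for (k in adj[[j]]) if (k > i)
      p13[[length(p13) + 1]] <- c(i, k)
    for (j in adj[[i]]) for (k in adj[[j]]) for (l in adj[[k]]) if (l > i)
      p14[[length(p14) + 1]] <- c(i, l)
  }
  p13 <- if (length(p13)) unique(do.call(rbind, p13)) else matrix(integer(0), 0, 2)
  p14 <- if (length(p14)) unique(do.call(rbind, p14)) else matrix(integer(0), 0, 2)
  ## 1-4 pairs that are also 1-2 or 1-3 (rings) are excluded, not scaled
  key <- function(m) paste(m[, 1], m[, 2])
  excl <- unique(rbind(p12, p13))
  p14 <- p14[!(key(p14) %in% key(excl)), , drop = FALSE]
  list(excl12_13 = excl, pairs14 = p14)
}
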