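## Internal-coordinate <-> Cartesian conversion for a loop region.
##
## Convention: for loop residue i,
##   phi(i)   = C(i-1) - N(i) - CA(i) - C(i)
##   psi(i)   = N(i) - CA(i) - C(i) - N(i+1)
##   omega(i) = CA(i-1) - C(i-1) - N(i) - CA(i)   (the bond preceding i)
## The peptide attachment atoms N(start), H(start), C(end) and O(end)
## belong to the framework: they are never rebuilt, and the closure targets
## are derived from them (plus the anchor residue backbones) alone.  As a
## consequence psi(end) is determined by closure rather than free.

#' Measure loop torsion angles from coordinates
#'
#' @param structure a "protein" object with topology built.
#' @param loop a \code{\link{loop_definition}}.
#' @return object of class "torsion_state": per-residue phi, psi, omega
#'   (degrees), a list of side-chain chi vectors, and the fixed anchor
#'   torsions used for rebuilding.
#' @export
torsions_from_coords <- function(structure, loop) {
  validate_loop(structure, loop)
  ch <- loop$chain
  rs <- loop_resnos(loop)
  xyz <- get_xyz(structure)
  p <- function(resno, nm) {
    i <- atom_index(structure, ch, resno, nm)
    if (is.na(i)) stop(sprintf("missing atom %s in residue %d", nm, resno))
    xyz[i, ]
  }
  n <- length(rs)
  phi <- psi <- omega <- numeric(n)
  chi <- vector("list", n)
  for (k in seq_len(n)) {
    i <- rs[k]
    phi[k] <- dihedral_angle(p(i - 1, "C"), p(i, "N"), p(i, "CA"), p(i, "C"))
    psi[k] <- dihedral_angle(p(i, "N"), p(i, "CA"), p(i, "C"), p(i + 1, "N"))
    omega[k] <- dihedral_angle(p(i - 1, "CA"), p(i - 1, "C"), p(i, "N"), p(i, "CA"))
    rn <- structure$residues$resname[structure$residues$chain == ch &
                                       structure$residues$resno == i]
    chi[[k]] <- measure_chis(structure, ch, i, rn)
  }
  structure(list(resnos = rs, phi = phi, psi = psi, omega = omega, chi = chi),
            class = "torsion_state")
}

measure_chis <- function(prot, ch, resno, resname) {
  defs <- CHI_ATOMS[[resname]]
  if (is.null(defs)) return(numeric(0))
  xyz <- get_xyz(prot)
  vapply(defs, function(d) {
    idx <- atom_indices(prot, ch, resno, d)
    if (anyNA(idx)) return(NA_real_)
    dihedral_angle(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ])
  }, numeric(1))
}

## Geometry provider: ideal constants or values measured from a structure.
## Returns a function(kind, resno) -> numeric.
loop_geometry <- function(structure = NULL, loop = NULL, ideal = TRUE) {
  if (ideal) {
    return(function(kind, resno) {
      switch(kind,
             b_NCA = BB$b_NCA, b_CAC = BB$b_CAC, b_CN = BB$b_CN,
             b_CO = BB$b_CO, a_CNCA = BB$a_CNCA, a_NCAC = BB$a_NCAC,
             a_CACN = BB$a_CACN, a_OCCA = BB$a_OCCA,
             stop("unknown geometry key ", kind))
    })
  }
  ch <- loop$chain
  xyz <- get_xyz(structure)
  p <- function(resno, nm) xyz[atom_index(structure, ch, resno, nm), ]
  function(kind, resno) {
    switch(kind,
           b_NCA = vnorm(p(resno, "CA") - p(resno, "N")),
           b_CAC = vnorm(p(resno, "C") - p(resno, "CA")),
           b_CN = vnorm(p(resno + 1, "N") - p(resno, "C")),
           b_CO = vnorm(p(resno, "O") - p(resno, "C")),
           a_CNCA = bond_angle(p(resno - 1, "C"), p(resno, "N"), p(resno, "CA")),
           a_NCAC = bond_angle(p(resno, "N"), p(resno, "CA"), p(resno, "C")),
           a_CACN = bond_angle(p(resno, "CA"), p(resno, "C"), p(resno + 1, "N")),
           a_OCCA = bond_angle(p(resno, "O"), p(resno, "C"), p(resno, "CA")),
           stop("unknown geometry key ", kind))
  }
}

#' Rebuild loop coordinates from torsion angles
#'
#' Sequential internal-coordinate chain extension from the N-side anchor.
#' Environment atoms are untouched; the C-side anchor is generally not
#' matched (closure is a separate step).
#'
#' @param structure a "protein" object with topology built.
#' @param loop a \code{\link{loop_definition}}.
#' @param torsions a "torsion_state".
#' @param geometry "ideal" (default) for ideal bond lengths/angles, or
#'   "structure" to take them from \code{structure}.
#' @return the structure with loop atoms rebuilt.
#' @export
coords_from_torsions <- function(structure, loop, torsions,
                                 geometry = c("ideal", "structure"),
                                 sidechains = TRUE) {
  geometry <- match.arg(geometry)
  g <- loop_geometry(structure, loop, ideal = geometry == "ideal")
  ch <- loop$chain
  rs <- loop_resnos(loop)
  prot <- structure
  xyz <- get_xyz(prot)
  idx <- function(resno, nm) atom_index(prot, ch, resno, nm)
  ## previous-residue backbone (anchor to start with)
  prevN <- xyz[idx(loop$start - 1, "N"), ]
  prevCA <- xyz[idx(loop$start - 1, "CA"), ]
  prevC <- xyz[idx(loop$start - 1, "C"), ]
  for (k in seq_along(rs)) {
    i <- rs[k]
    rn <- prot$residues$resname[prot$residues$chain == ch &
                                  prot$residues$resno == i]
    if (k == 1) {
      N <- xyz[idx(i, "N"), ]          # framework-owned attachment atom
    } else {
      N <- place_atom(prevN, prevCA, prevC, g("b_CN", i - 1),
                      g("a_CACN", i - 1), torsions$psi[k - 1])
      xyz[idx(i, "N"), ] <- N
      hi <- idx(i, "H")
      if (!is.na(hi))
        xyz[hi, ] <- place_atom(prevCA, prevC, N, BB$b_NH, BB$a_HNC, 0)
    }
    CA <- place_atom(prevCA, prevC, N, g("b_NCA", i), g("a_CNCA", i),
                     torsions$omega[k])
    C <- place_atom(prevC, N, CA, g("b_CAC", i), g("a_NCAC", i),
                    torsions$phi[k])
    xyz[idx(i, "CA"), ] <- CA
    if (k < length(rs)) {
      O <- place_atom(N, CA, C, g("b_CO", i), g("a_OCCA", i),
                      wrap_angle(torsions$psi[k] + 180))
      xyz[idx(i, "C"), ] <- C; xyz[idx(i, "O"), ] <- O
    } else {
      ## C(end)/O(end) are framework-owned; still write the built C so that
      ## unclosed intermediates carry their strain into the junction terms
      xyz[idx(i, "C"), ] <- C
      xyz[idx(i, "O"), ] <- place_atom(N, CA, C, g("b_CO", i),
                                       g("a_OCCA", i),
                                       wrap_angle(torsions$psi[k] + 180))
    }
    if (sidechains)
      xyz <- rebuild_sidechain(prot, xyz, ch, i, rn, torsions$chi[[k]])
    prevN <- N; prevCA <- CA; prevC <- C
  }
  set_xyz(prot, xyz)
}

## Rebuild the side chain of one residue from its z-matrix at given chis.
rebuild_sidechain <- function(prot, xyz, ch, resno, resname, chis) {
  sc <- SIDECHAIN_ZMAT[[resname]]
  if (is.null(sc) || nrow(sc) == 0) return(xyz)
  nchi <- N_CHI[[resname]]
  if (nchi > 0) {
    base <- COMMON_ROTAMER[[resname]] %||% rep(180, nchi)
    if (length(chis) >= nchi && !anyNA(chis[seq_len(nchi)]))
      base <- chis[seq_len(nchi)]
    chis <- base
  }
  pos <- list(N = xyz[atom_index(prot, ch, resno, "N"), ],
              CA = xyz[atom_index(prot, ch, resno, "CA"), ],
              C = xyz[atom_index(prot, ch, resno, "C"), ])
  for (j in seq_len(nrow(sc))) {
    tors <- sc$tors[j]
    if (!is.na(sc$chi[j])) tors <- wrap_angle(chis[sc$chi[j]] + tors)
    p <- place_atom(pos[[sc$a[j]]], pos[[sc$b[j]]], pos[[sc$c[j]]],
                    sc$bond[j], sc$angle[j], tors)
    pos[[sc$name[j]]] <- p
    ai <- atom_index(prot, ch, resno, sc$name[j])
    if (!is.na(ai)) xyz[ai, ] <- p
  }
  xyz
}

## Set side-chain chi angles of an arbitrary residue in place.
set_sidechain_chis <- function(prot, ch, resno, chis) {
  rn <- prot$residues$resname[prot$residues$chain == ch &
                                prot$residues$resno == resno]
  xyz <- rebuild_sidechain(prot, get_xyz(prot), ch, resno, rn, chis)
  set_xyz(prot, xyz)
}

## Backward chain extension from the C-side anchor through residues with
## fixed torsions, down to pivot residue p3.  Returns the closure targets:
## positions of CA(p3), C(p3) and N(p3+1).  The targets derive only from
## framework-owned atoms: C(end), O(end), and the anchor residue backbone.
c_anchor_targets <- function(structure, loop, torsions, p3,
                             geometry = c("ideal", "structure")) {
  geometry <- match.arg(geometry)
  g <- loop_geometry(structure, loop, ideal = geometry == "ideal")
  ch <- loop$chain
  xyz <- get_xyz(structure)
  idx <- function(resno, nm) atom_index(structure, ch, resno, nm)
  post <- loop$end + 1
  Npost <- xyz[idx(post, "N"), ]
  C_i <- xyz[idx(loop$end, "C"), ]
  O_i <- xyz[idx(loop$end, "O"), ]
  ## CA(end) from sp2 planarity at the fixed carbonyl
  CA_i <- place_atom(Npost, O_i, C_i, g("b_CAC", loop$end),
                     g("a_OCCA", loop$end), 180)
  Nnext <- Npost
  i <- loop$end
  while (i > p3) {
    k <- match(i, torsions$resnos)
    N_i <- place_atom(Nnext, C_i, CA_i, g("b_NCA", i), g("a_NCAC", i),
                      torsions$psi[k])
    C_im1 <- place_atom(C_i, CA_i, N_i, g("b_CN", i - 1), g("a_CNCA", i),
                        torsions$phi[k])
    CA_im1 <- place_atom(CA_i, N_i, C_im1, g("b_CAC", i - 1),
                         g("a_CACN", i - 1), torsions$omega[k])
    Nnext <- N_i
    C_i <- C_im1
    CA_i <- CA_im1
    i <- i - 1
  }
  list(CA3 = CA_i, C3 = C_i, Npost = Nnext)
}

#' @export
print.torsion_state <- function(x, ...) {
  cat(sprintf("<torsion_state> %d residues (%d-%d)\n", length(x$resnos),
              min(x$resnos), max(x$resnos)))
  invisible(x)
}
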