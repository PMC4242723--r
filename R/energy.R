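## The hybrid energy: physics-based terms (bonded, Lennard-Jones, Coulomb,
## generalized-Born / surface-area solvation) plus knowledge-based terms
## (phi/psi and chi statistics, orientation-dependent hydrogen bonds,
## distance-binned atom-pair potential).
##
## E_total = E_bonded + E_vdW
##         + w_el (E_Coulomb + E_GB) + w_sa E_SA
##         + w_phipsi E_phipsi + w_chi E_chi
##         + w_hbond E_hbond + w_atompair E_atompair
##
## Terms are summed over loop-loop and loop-environment interactions only;
## environment-environment contributions are constant while the loop is
## sampled and are dropped.

COULOMB_KCAL <- 332.06   # (e^2/Angstrom) -> kcal/mol
EPS_SOLVENT <- 78.5
BORN_OFFSET <- 0.09      # Angstrom, intrinsic radius reduction
KBOND <- 300             # kcal/mol/A^2
KANGLE <- 50             # kcal/mol/rad^2
V3_CHI <- 0.3            # kcal/mol, 3-fold side-chain torsion barrier

#' Energy weights of the hybrid function
#'
#' Defaults are the trained weight vector
#' (w_electrostatics, w_sa, w_phipsi, w_chi, w_hbond, w_atompair) =
#' (0.16, 0.05, 1.2, 1.0, 4.0, 12.0).
#'
#' @param w_electrostatics,w_sa,w_phipsi,w_chi,w_hbond,w_atompair
#'   non-negative dimensionless multipliers.
#' @return object of class "energy_weights".
#' @export
energy_weights <- function(w_electrostatics = 0.16, w_sa = 0.05,
                           w_phipsi = 1.2, w_chi = 1.0, w_hbond = 4.0,
                           w_atompair = 12.0) {
  w <- c(w_electrostatics = w_electrostatics, w_sa = w_sa,
         w_phipsi = w_phipsi, w_chi = w_chi, w_hbond = w_hbond,
         w_atompair = w_atompair)
  if (any(w < 0)) stop("energy weights must be non-negative")
  structure(as.list(w), class = "energy_weights")
}

#' Construct an energy model
#'
#' Bundles the weight vector, knowledge tables and numerical options.  A
#' \code{custom} function (signature \code{function(torsions, xyz, ctx)})
#' replaces the physical energy entirely, which is used for analytic test
#' landscapes.
#'
#' @param weights an \code{\link{energy_weights}} object.
#' @param phipsi_table,chi_table,pair_table knowledge tables (defaults
#'   built in).
#' @param options list of numerical options (cutoffs, well parameters).
#' @param custom optional custom energy function.
#' @param custom_grad optional gradient of \code{custom} with signature
#'   \code{function(state, tmap)} returning one derivative (kcal/mol/degree)
#'   per torsion-map entry; used by the torsion-space minimizer.
#' @return object of class "energy_model".
#' @export
energy_model <- function(weights = energy_weights(),
                         phipsi_table = default_phipsi_table(),
                         chi_table = default_chi_table(),
                         pair_table = default_pair_potential(),
                         options = list(), custom = NULL,
                         custom_grad = NULL) {
  opt <- list(r_on = 8, r_off = 10, scale14 = 0.5, cap_frac = 0.6,
              vdw_scale = 1, eps_in = 1, sasa_points = 192, probe = 1.4,
              hb = list(d0 = 1.95, dw = 0.65, th0 = 180, thw = 70,
                        ps0 = 120, psw = 60, e_d = 1.0, e_th = 0.5,
                        e_ps = 0.5))
  opt[names(options)] <- options
  structure(list(weights = weights, phipsi = phipsi_table, chi = chi_table,
                 pair = pair_table, options = opt, custom = custom,
                 custom_grad = custom_grad),
            class = "energy_model")
}

## ---------------------------------------------------------------------------
## Template residue geometry (equilibrium bond lengths / angles measured
## from an ideal-geometry residue build)

template_geometry <- function(resname) {
  key <- paste0("tmpl_", resname)
  if (!is.null(.loopcsa_env[[key]])) return(.loopcsa_env[[key]])
  ## build one residue with ideal backbone and common-rotamer side chain
  N <- c(0, 0, 0); CA <- c(BB$b_NCA, 0, 0)
  C <- place_atom(c(-0.5, 1, 0), N, CA, BB$b_CAC, BB$a_NCAC, -60)
  O <- place_atom(N, CA, C, BB$b_CO, BB$a_OCCA, 120)
  pos <- list(N = N, CA = CA, C = C, O = O)
  pos$H <- place_atom(C, CA, N, BB$b_NH, 118, 180)
  sc <- SIDECHAIN_ZMAT[[resname]]
  nchi <- N_CHI[[resname]]
  chis <- if (nchi > 0) COMMON_ROTAMER[[resname]] %||% rep(180, nchi) else NULL
  if (nrow(sc) > 0) for (j in seq_len(nrow(sc))) {
    tors <- sc$tors[j]
    if (!is.na(sc$chi[j])) tors <- wrap_angle(chis[sc$chi[j]] + tors)
    pos[[sc$name[j]]] <- place_atom(pos[[sc$a[j]]], pos[[sc$b[j]]],
                                    pos[[sc$c[j]]], sc$bond[j], sc$angle[j],
                                    tors)
  }
  .loopcsa_env[[key]] <- pos
  pos
}

## equilibrium bond length between two named atoms of one residue
template_bond <- function(resname, n1, n2) {
  pos <- template_geometry(resname)
  if (is.null(pos[[n1]]) || is.null(pos[[n2]])) return(NA_real_)
  vnorm(pos[[n1]] - pos[[n2]])
}

template_angle <- function(resname, n1, n2, n3) {
  pos <- template_geometry(resname)
  if (is.null(pos[[n1]]) || is.null(pos[[n2]]) || is.null(pos[[n3]]))
    return(NA_real_)
  bond_angle(pos[[n1]], pos[[n2]], pos[[n3]])
}

## ---------------------------------------------------------------------------
## Energy context: static pair lists and parameters for one (structure, loop)

#' Precompute the evaluation context for a loop energy
#'
#' @param structure "protein" with topology built.
#' @param loop a \code{\link{loop_definition}}.
#' @param model an \code{\link{energy_model}}.
#' @return an opaque context used by \code{\link{total_energy}} and the
#'   optimizer.
#' @export
energy_context <- function(structure, loop, model = energy_model()) {
  prot <- structure
  at <- prot$atoms
  n <- nrow(at)
  rs <- loop_resnos(loop)
  in_loop <- at$chain == loop$chain & at$resno %in% rs
  loop_rows <- which(in_loop)
  nl <- length(loop_rows)

  sep <- bond_separation(prot)
  scale <- matrix(1, nl, n)
  li <- match(seq_len(n), loop_rows)       # global -> loop-local (NA if not)
  put <- function(pairs, value) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!is.na(li[i])) scale[li[i], j] <<- value
      if (!is.na(li[j])) scale[li[j], i] <<- value
    }
  }
  put(sep$excl12_13, 0)
  put(sep$pairs14, model$options$scale14)
  scale[cbind(seq_len(nl), loop_rows)] <- 0          # self
  ## avoid double counting loop-loop pairs: keep only j > i (global order)
  jj <- matrix(seq_len(n), nl, n, byrow = TRUE)
  ii <- matrix(loop_rows, nl, n)
  dup <- (jj %in% loop_rows) & (jj < ii)
  pairmask <- matrix(1, nl, n)
  pairmask[matrix(dup, nl, n)] <- 0

  ## atom-pair potential bookkeeping (heavy atoms, sequence separation >= 2)
  heavy <- at$element != "H"
  cls_idx <- match(at$class, model$pair$classes)
  sepres <- abs(outer(at$resno[loop_rows], at$resno, "-"))
  samechain <- outer(at$chain[loop_rows], at$chain, "==")
  ap_ok <- (!samechain | sepres >= 2) &
    matrix(heavy[loop_rows], nl, n) & matrix(heavy, nl, n, byrow = TRUE)
  ap_ok <- ap_ok & pairmask > 0 &
    !(matrix(seq_len(n), nl, n, byrow = TRUE) == matrix(loop_rows, nl, n))

  ## hydrogen-bond donors/acceptors
  don <- list(); acc <- list()
  for (k in seq_len(nrow(prot$residues))) {
    ch <- prot$residues$chain[k]; i <- prot$residues$resno[k]
    rn <- prot$residues$resname[k]
    for (d in c(HB_DONORS$backbone, HB_DONORS[[rn]] %||% list())) {
      hi <- atom_index(prot, ch, i, d[1]); di <- atom_index(prot, ch, i, d[2])
      if (!is.na(hi) && !is.na(di))
        don[[length(don) + 1]] <- c(hi, di, k)
    }
    for (a in c(HB_ACCEPTORS$backbone, HB_ACCEPTORS[[rn]] %||% list())) {
      ai <- atom_index(prot, ch, i, a[1]); bi <- atom_index(prot, ch, i, a[2])
      if (!is.na(ai) && !is.na(bi))
        acc[[length(acc) + 1]] <- c(ai, bi, k)
    }
  }
  don <- do.call(rbind, don); acc <- do.call(rbind, acc)
  ## candidate pairs with >= 1 loop atom, different residues, not bonded
  exkey <- c(paste(sep$excl12_13[, 1], sep$excl12_13[, 2]),
             paste(sep$pairs14[, 1], sep$pairs14[, 2]))
  hb_pairs <- NULL
  if (!is.null(don) && !is.null(acc)) {
    cand <- expand.grid(d = seq_len(nrow(don)), a = seq_len(nrow(acc)))
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      dd <- don[cand$d[r], ]; aa <- acc[cand$a[r], ]
      if (dd[3] == aa[3]) next                       # same residue
      if (!(in_loop[dd[1]] || in_loop[aa[1]])) next  # needs a loop atom
      i <- min(dd[1], aa[1]); j <- max(dd[1], aa[1])
      if (paste(i, j) %in% exkey) next
      keep[r] <- TRUE
    }
    cand <- cand[keep, , drop = FALSE]
    hb_pairs <- cbind(H = don[cand$d, 1], D = don[cand$d, 2],
                      A = acc[cand$a, 1], B = acc[cand$a, 2])
  }

  ## bonded terms touching the loop
  bonds <- prot$bonds
  touch <- in_loop[bonds[, 1]] | in_loop[bonds[, 2]]
  bsel <- bonds[touch, , drop = FALSE]
  b0 <- numeric(nrow(bsel))
  for (r in seq_len(nrow(bsel))) {
    i <- bsel[r, 1]; j <- bsel[r, 2]
    if (at$resno[i] == at$resno[j] && at$chain[i] == at$chain[j]) {
      b0[r] <- template_bond(at$resname[i], at$name[i], at$name[j])
    } else b0[r] <- BB$b_CN
  }
  ## angles: bond pairs sharing an atom, any member touching the loop
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  angles <- list()
  for (jc in seq_len(n)) {
    nb <- adj[[jc]]
    if (length(nb) < 2) next
    for (x in seq_len(length(nb) - 1)) for (y in (x + 1):length(nb)) {
      i <- nb[x]; k <- nb[y]
      if (!(in_loop[i] || in_loop[jc] || in_loop[k])) next
      angles[[length(angles) + 1]] <- c(i, jc, k)
    }
  }
  angles <- do.call(rbind, angles)
  a0 <- numeric(nrow(angles))
  for (r in seq_len(nrow(angles))) {
    i <- angles[r, 1]; jc <- angles[r, 2]; k <- angles[r, 3]
    same <- at$resno[i] == at$resno[jc] && at$resno[jc] == at$resno[k]
    a0[r] <- if (same)
      template_angle(at$resname[jc], at$name[i], at$name[jc], at$name[k])
    else {
      nm <- paste(at$name[i], at$name[jc], at$name[k])
      if (nm %in% c("CA C N", "N C CA")) BB$a_CACN
      else if (nm %in% c("C N CA", "CA N C")) BB$a_CNCA
      else if (nm %in% c("O C N", "N C O")) 123.0
      else if (nm %in% c("C N H", "H N C")) BB$a_HNC
      else if (nm %in% c("C N CD", "CD N C")) 125.0
      else 120.0
    }
  }
  ok <- !is.na(a0)
  angles <- angles[ok, , drop = FALSE]; a0 <- a0[ok]
  okb <- !is.na(b0)
  bsel <- bsel[okb, , drop = FALSE]; b0 <- b0[okb]

  ## 3-fold torsions on rotatable side-chain bonds of loop residues
  tors <- list()
  for (k in which(prot$residues$chain == loop$chain &
                    prot$residues$resno %in% rs)) {
    rn <- prot$residues$resname[k]
    defs <- CHI_ATOMS[[rn]]
    if (is.null(defs)) next
    for (d in defs) {
      idx <- atom_indices(prot, prot$residues$chain[k],
                          prot$residues$resno[k], d)
      if (!anyNA(idx)) tors[[length(tors) + 1]] <- idx
    }
  }
  tors <- if (length(tors)) do.call(rbind, tors) else
    matrix(integer(0), 0, 4)

  ## phi/psi measurement indices per loop residue
  ch <- loop$chain
  ppidx <- lapply(rs, function(i) {
    c(atom_index(prot, ch, i - 1, "C"), atom_index(prot, ch, i, "N"),
      atom_index(prot, ch, i, "CA"), atom_index(prot, ch, i, "C"),
      atom_index(prot, ch, i + 1, "N"))
  })
  resnames <- vapply(rs, function(i)
    prot$residues$resname[prot$residues$chain == ch &
                            prot$residues$resno == i], character(1))
  chi_idx <- lapply(seq_along(rs), function(k) {
    defs <- CHI_ATOMS[[resnames[k]]]
    if (is.null(defs)) return(matrix(integer(0), 0, 4))
    do.call(rbind, lapply(defs, function(d)
      atom_indices(prot, ch, rs[k], d)))
  })

  list(prot = prot, loop = loop, model = model, n = n,
       loop_rows = loop_rows, scale = scale * pairmask, ap_ok = ap_ok,
       cls_idx = cls_idx, heavy = heavy,
       q = at$charge, radius = at$radius, epsilon = at$epsilon,
       gamma = at$gamma, hct = at$hct_scale,
       hb_pairs = hb_pairs, bonds = bsel, b0 = b0,
       angles = angles, a0 = a0, tors = tors,
       ppidx = ppidx, chi_idx = chi_idx, resnames = resnames,
       frame_atoms = sasa_frame_atoms(prot),
       sphere = fibonacci_sphere(model$options$sasa_points))
}

## two reference atoms per atom (bonded neighbors, or neighbor-of-neighbor
## for terminal atoms) defining the local sphere-point frame
sasa_frame_atoms <- function(prot) {
  n <- nrow(prot$atoms)
  adj <- vector("list", n)
  for (r in seq_len(nrow(prot$bonds))) {
    i <- prot$bonds[r, 1]; j <- prot$bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  out <- matrix(1L, n, 2)
  for (i in seq_len(n)) {
    nb <- sort(adj[[i]])
    f1 <- nb[1]
    f2 <- if (length(nb) >= 2) nb[2] else {
      nn <- sort(setdiff(adj[[f1]], i))
      if (length(nn)) nn[1] else (i %% n) + 1L
    }
    out[i, ] <- c(f1, f2)
  }
  out
}

fibonacci_sphere <- function(npts) {
  k <- seq_len(npts) - 0.5
  phi <- acos(1 - 2 * k / npts)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## pairwise loop x all distance matrix
loop_dist <- function(ctx, xyz) {
  xl <- xyz[ctx$loop_rows, , drop = FALSE]
  d2 <- outer(rowSums(xl^2), rowSums(xyz^2), "+") - 2 * xl %*% t(xyz)
  sqrt(pmax(d2, 1e-12))
}

## CHARMM-style switching function and derivative wrt r
switch_fn <- function(r, ron, roff) {
  x <- r^2
  c3 <- (roff^2 - ron^2)^3
  s <- ifelse(r <= ron, 1,
              ifelse(r >= roff, 0,
                     (roff^2 - x)^2 * (roff^2 + 2 * x - 3 * ron^2) / c3))
  ds <- ifelse(r <= ron | r >= roff, 0,
               2 * r * 6 * (roff^2 - x) * (ron^2 - x) / c3)
  list(s = s, ds = ds)
}
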