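## Structure data model and PDB I/O.
##
## A "protein" object is a list with:
##   atoms    data.frame: chain, resno, resname, name, element, class,
##            charge, radius, epsilon, gamma, hct_scale, occ, x, y, z
##   residues data.frame: chain, resno, resname, cispro
##   bonds    2-column integer matrix of atom row indices
##   topology logical, TRUE after build_polar_hydrogen_topology()
##   breaks   data.frame of recorded chain breaks (chain, resno = i where
##            C(i)-N(i+1) exceeds the peptide-bond threshold)
##   source   provenance string
## Residue numbering is 1-based and ranges are inclusive throughout.

PEPTIDE_BREAK_DIST <- 2.5  # Angstrom; C(i)-N(i+1) beyond this is a break
CIS_OMEGA_TOL <- 30        # degrees; |omega| < 30 flags cis

new_protein <- function(atoms, source = "loopcsa", topology = FALSE) {
  atoms$key <- paste(atoms$chain, atoms$resno, atoms$name)
  res <- unique(atoms[, c("chain", "resno", "resname")])
  res <- res[order(match(res$chain, unique(atoms$chain)), res$resno), ]
  rownames(res) <- NULL
  res$cispro <- FALSE
  p <- structure(list(atoms = atoms, residues = res,
                      bonds = matrix(integer(0), 0, 2),
                      topology = topology, breaks = NULL, source = source),
                 class = "protein")
  p <- detect_breaks(p)
  detect_cispro(p)
}

get_xyz <- function(prot) {
  as.matrix(prot$atoms[, c("x", "y", "z")])
}

set_xyz <- function(prot, xyz) {
  prot$atoms$x <- xyz[, 1]; prot$atoms$y <- xyz[, 2]; prot$atoms$z <- xyz[, 3]
  prot
}

## Row index of one atom; NA if absent.
atom_index <- function(prot, chain, resno, name) {
  match(paste(chain, resno, name), prot$atoms$key)
}

## Row indices of several atoms of one residue (NA for missing).
atom_indices <- function(prot, chain, resno, names) {
  match(paste(chain, resno, names), prot$atoms$key)
}

atom_xyz <- function(prot, chain, resno, name) {
  i <- atom_index(prot, chain, resno, name)
  if (is.na(i)) stop(sprintf("atom %s %d %s not found", chain, resno, name))
  c(prot$atoms$x[i], prot$atoms$y[i], prot$atoms$z[i])
}

residue_rows <- function(prot, chain, resno) {
  which(prot$atoms$chain == chain & prot$atoms$resno %in% resno)
}

detect_breaks <- function(prot) {
  br <- list()
  for (ch in unique(prot$residues$chain)) {
    res <- prot$residues[prot$residues$chain == ch, ]
    rn <- sort(res$resno)
    for (k in seq_len(length(rn) - 1)) {
      i <- rn[k]; j <- rn[k + 1]
      if (j != i + 1) { br[[length(br) + 1]] <- data.frame(chain = ch, resno = i); next }
      ci <- atom_index(prot, ch, i, "C")
      nj <- atom_index(prot, ch, j, "N")
      if (is.na(ci) || is.na(nj)) next
      d <- vnorm(c(prot$atoms$x[ci] - prot$atoms$x[nj],
                   prot$atoms$y[ci] - prot$atoms$y[nj],
                   prot$atoms$z[ci] - prot$atoms$z[nj]))
      if (d > PEPTIDE_BREAK_DIST)
        br[[length(br) + 1]] <- data.frame(chain = ch, resno = i)
    }
  }
  prot$breaks <- if (length(br)) do.call(rbind, br) else
    data.frame(chain = character(0), resno = integer(0))
  prot
}

detect_cispro <- function(prot) {
  pro <- which(prot$residues$resname == "PRO")
  for (k in pro) {
    ch <- prot$residues$chain[k]; i <- prot$residues$resno[k]
    idx <- c(atom_index(prot, ch, i - 1, "CA"), atom_index(prot, ch, i - 1, "C"),
             atom_index(prot, ch, i, "N"), atom_index(prot, ch, i, "CA"))
    if (anyNA(idx)) next
    xyz <- get_xyz(prot)
    om <- dihedral_angle(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ])
    if (abs(om) < CIS_OMEGA_TOL) prot$residues$cispro[k] <- TRUE
  }
  prot
}

is_break_after <- function(prot, chain, resno) {
  nrow(prot$breaks) > 0 &&
    any(prot$breaks$chain == chain & prot$breaks$resno == resno)
}

#' Define a loop to be modeled
#'
#' @param chain chain identifier.
#' @param start,end first and last loop residue (1-based, inclusive).
#' @return object of class "loop_definition".
#' @export
loop_definition <- function(chain, start, end) {
  n <- end - start + 1
  if (n < 3 || n > 20) stop("loop length must be between 3 and 20 residues")
  structure(list(chain = chain, start = start, end = end, n_residues = n),
            class = "loop_definition")
}

#' Parse a loop spec string "CHAIN:START-END" into a loop definition
#'
#' @param spec string such as "A:10-17" (1-based, inclusive).
#' @return a \code{\link{loop_definition}}.
#' @export
parse_loop_spec <- function(spec) {
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)$", spec))[[1]]
  if (length(m) != 4) stop("loop spec must look like CHAIN:START-END")
  loop_definition(m[2], as.integer(m[3]), as.integer(m[4]))
}

validate_loop <- function(prot, loop) {
  res <- prot$residues
  need <- (loop$start - 1):(loop$end + 1)
  have <- res$resno[res$chain == loop$chain]
  if (!all(need %in% have))
    stop(sprintf("loop %s:%d-%d needs anchor residues %d and %d in the structure",
                 loop$chain, loop$start, loop$end, loop$start - 1, loop$end + 1))
  for (i in (loop$start - 1):loop$end)
    if (is_break_after(prot, loop$chain, i))
      stop("loop may not span a chain break")
  invisible(TRUE)
}

loop_resnos <- function(loop) loop$start:loop$end

#' Read a PDB file
#'
#' Parses ATOM records (via bio3d), keeping the requested model.  Alternate
#' locations are resolved to the highest occupancy (ties broken by altLoc
#' letter order); heteroatoms, waters and nucleic acids are skipped.
#'
#' @param path PDB file path.
#' @param model_index 1-based model number for multi-model files.
#' @return a "protein" object.
#' @export
read_pdb <- function(path, model_index = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = model_index > 1, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  if (model_index > 1) {
    if (nrow(pdb$xyz) < model_index) stop("model_index beyond models in file")
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  at <- at[at$type == "ATOM" & at$resid %in% AA3, , drop = FALSE]
  if (nrow(at) == 0) stop("no standard protein ATOM records in ", path)
  if (any(!is.na(at$insert) & at$insert != ""))
    warning("insertion codes present; those residues are skipped")
  at <- at[is.na(at$insert) | at$insert == "", , drop = FALSE]
  ## altLoc resolution: highest occupancy, ties by letter order
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$elety)
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[duplicated(key)])) {
    rows <- which(key == k)
    ord <- rows[order(-at$o[rows], at$alt[rows])]
    keep[setdiff(rows, ord[1])] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  atoms <- data.frame(chain = as.character(at$chain), resno = at$resno,
                      resname = at$resid, name = at$elety,
                      element = ifelse(is.na(at$elesy) | at$elesy == "",
                                       substr(at$elety, 1, 1), at$elesy),
                      class = NA_character_, charge = NA_real_,
                      radius = NA_real_, epsilon = NA_real_,
                      gamma = NA_real_, hct_scale = NA_real_,
                      occ = at$o, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  p <- new_protein(atoms, source = path)
  check_backbone(p)
  p
}

check_backbone <- function(prot) {
  for (k in seq_len(nrow(prot$residues))) {
    ch <- prot$residues$chain[k]; i <- prot$residues$resno[k]
    for (nm in c("N", "CA", "C", "O")) {
      if (is.na(atom_index(prot, ch, i, nm)))
        stop(sprintf("residue %s %d (%s) is missing backbone atom %s",
                     ch, i, prot$residues$resname[k], nm))
    }
  }
  invisible(TRUE)
}

#' Write a structure to a PDB file
#'
#' Emits standard ATOM records (TER between chains); coordinates keep the
#' PDB field precision of 0.001 Angstrom.
#'
#' @param structure a "protein" object.
#' @param path output file path.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  if (nrow(at) == 0) stop("cannot write an empty structure")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(get_xyz(structure))),
                   resno = at$resno, resid = at$resname, chain = at$chain,
                   eleno = seq_len(nrow(at)), elety = at$name,
                   elesy = at$element,
                   o = ifelse(is.na(at$occ), 1, at$occ),
                   b = rep(0, nrow(at)),
                   chainter = TRUE, verbose = FALSE)
  invisible(path)
}

#' Write a set of structures as a multi-MODEL PDB file
#'
#' @param structures list of "protein" objects with identical atom tables.
#' @param path output file path.
#' @export
write_pdb_models <- function(structures, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (m in seq_along(structures)) {
    writeLines(sprintf("MODEL %8d", m), con)
    write_pdb(structures[[m]], tmp)
    lines <- readLines(tmp)
    writeLines(lines[!grepl("^END$", lines)], con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
print.protein <- function(x, ...) {
  cat(sprintf("<protein> %d atoms, %d residues, %d chain(s)%s\n",
              nrow(x$atoms), nrow(x$residues),
              length(unique(x$residues$chain)),
              if (x$topology) ", polar-H topology" else ""))
  invisible(x)
}
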