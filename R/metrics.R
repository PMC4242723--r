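## Benchmark evaluation metrics: main-chain loop RMSD, all-atom RMSD under
## symmetric side-chain flipping, environment selection, and the environment
## RMSD (E-RMSD) that quantifies framework inaccuracy.

MAINCHAIN_ATOMS <- c("N", "CA", "C", "O")

#' Select the environment residues of a loop
#'
#' All residues outside the loop having at least one atom within
#' \code{cutoff} of any loop C-beta atom (C-alpha is used for loop
#' glycines).  The interval is closed: a distance exactly equal to the
#' cutoff is included.
#'
#' @param structure a "protein" object.
#' @param loop a \code{\link{loop_definition}}.
#' @param cutoff distance cutoff in Angstrom (default 10).
#' @return data.frame with columns chain, resno, ordered deterministically.
#' @export
environment_residues <- function(structure, loop, cutoff = 10) {
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- get_xyz(structure)
  rs <- loop_resnos(loop)
  cb <- integer(0)
  for (i in rs) {
    j <- atom_index(structure, loop$chain, i, "CB")
    if (is.na(j)) j <- atom_index(structure, loop$chain, i, "CA")
    if (is.na(j)) stop("loop residue ", i, " has neither CB nor CA")
    cb <- c(cb, j)
  }
  cbxyz <- xyz[cb, , drop = FALSE]
  res <- structure$residues
  keep <- logical(nrow(res))
  for (k in seq_len(nrow(res))) {
    if (res$chain[k] == loop$chain && res$resno[k] %in% rs) next
    rows <- residue_rows(structure, res$chain[k], res$resno[k])
    d2 <- outer(rowSums(xyz[rows, , drop = FALSE]^2), rowSums(cbxyz^2), "+") -
      2 * xyz[rows, , drop = FALSE] %*% t(cbxyz)
    keep[k] <- min(d2) <= cutoff^2 + 1e-9
  }
  out <- res[keep, c("chain", "resno")]
  rownames(out) <- NULL
  out
}

## Matched heavy-atom (or all-atom) coordinate pairs for a residue set.
matched_atoms <- function(model, reference, residues, include_hydrogens = FALSE) {
  keys <- character(0)
  for (k in seq_len(nrow(residues))) {
    rows <- residue_rows(reference, residues$chain[k], residues$resno[k])
    nm <- reference$atoms$name[rows]
    el <- reference$atoms$element[rows]
    if (!include_hydrogens) nm <- nm[el != "H"]
    keys <- c(keys, paste(residues$chain[k], residues$resno[k], nm))
  }
  im <- match(keys, model$atoms$key)
  ir <- match(keys, reference$atoms$key)
  ok <- !is.na(im) & !is.na(ir)
  list(model = im[ok], reference = ir[ok], keys = keys[ok])
}

#' Main-chain RMSD of a loop
#'
#' RMSD over N, CA, C, O atoms of the loop residues.  With
#' \code{presuperpose_on = "environment"} the transform that superposes the
#' model's environment atoms onto the reference is applied first, so that
#' environmental error propagates into the reported value, matching the
#' benchmark convention for inaccurate frameworks.
#'
#' @param model,reference "protein" objects with matching loop sequences.
#' @param loop a \code{\link{loop_definition}}.
#' @param presuperpose_on "environment" or "none".
#' @param cutoff environment cutoff (Angstrom) for the superposition set.
#' @return RMSD in Angstrom.
#' @export
loop_mainchain_rmsd <- function(model, reference, loop,
                                presuperpose_on = c("environment", "none"),
                                cutoff = 10) {
  presuperpose_on <- match.arg(presuperpose_on)
  rs <- loop_resnos(loop)
  seq_m <- model$residues$resname[model$residues$chain == loop$chain &
                                    model$residues$resno %in% rs]
  seq_r <- reference$residues$resname[reference$residues$chain == loop$chain &
                                        reference$residues$resno %in% rs]
  if (!identical(seq_m, seq_r)) stop("loop sequence mismatch")
  sel <- data.frame(chain = loop$chain, resno = rs)
  keys <- as.vector(t(outer(paste(loop$chain, rs), MAINCHAIN_ATOMS, paste)))
  im <- match(keys, model$atoms$key); ir <- match(keys, reference$atoms$key)
  if (anyNA(im) || anyNA(ir)) stop("incomplete loop main chain")
  xm <- get_xyz(model)[im, , drop = FALSE]
  xr <- get_xyz(reference)[ir, , drop = FALSE]
  if (presuperpose_on == "environment") {
    env <- environment_residues(reference, loop, cutoff)
    if (nrow(env) == 0) stop("empty environment")
    ma <- matched_atoms(model, reference, env)
    fit <- kabsch_superpose(get_xyz(model)[ma$model, , drop = FALSE],
                            get_xyz(reference)[ma$reference, , drop = FALSE])
    xm <- fit$transform(xm)
  }
  rmsd_direct(xm, xr)
}

#' All-atom RMSD minimized over symmetric side-chain flips
#'
#' Two-fold symmetric side chains (ASP, GLU, PHE, TYR, ARG, LEU, VAL)
#' produce chemically equivalent structures under relabeling; the flip is
#' chosen independently per residue, which is exact since residues
#' contribute independent sums.  Hydrogens are excluded by default.
#'
#' @param model,reference "protein" objects.
#' @param residues data.frame with columns chain, resno.
#' @param include_hydrogens include hydrogens in the sum.
#' @return RMSD in Angstrom over the matched atoms.
#' @export
symmetric_flip_rmsd <- function(model, reference, residues,
                                include_hydrogens = FALSE) {
  xm <- get_xyz(model); xr <- get_xyz(reference)
  ssd <- 0; nat <- 0
  for (k in seq_len(nrow(residues))) {
    ch <- residues$chain[k]; i <- residues$resno[k]
    rows <- residue_rows(reference, ch, i)
    rn <- reference$atoms$resname[rows[1]]
    nm <- reference$atoms$name[rows]
    if (!include_hydrogens)
      nm <- nm[reference$atoms$element[rows] != "H"]
    ir <- atom_indices(reference, ch, i, nm)
    im <- atom_indices(model, ch, i, nm)
    ok <- !is.na(ir) & !is.na(im)
    nm <- nm[ok]; ir <- ir[ok]; im <- im[ok]
    if (!length(nm)) next
    s_id <- sum((xm[im, , drop = FALSE] - xr[ir, , drop = FALSE])^2)
    s_best <- s_id
    pairs <- FLIP_PAIRS[[rn]]
    if (!is.null(pairs)) {
      nm_fl <- nm
      for (pr in pairs) {
        nm_fl[nm == pr[1]] <- pr[2]
        nm_fl[nm == pr[2]] <- pr[1]
      }
      im_fl <- atom_indices(model, ch, i, nm_fl)
      if (!anyNA(im_fl)) {
        s_fl <- sum((xm[im_fl, , drop = FALSE] - xr[ir, , drop = FALSE])^2)
        s_best <- min(s_best, s_fl)
      }
    }
    ssd <- ssd + s_best; nat <- nat + length(nm)
  }
  if (nat == 0) stop("no matched atoms")
  sqrt(ssd / nat)
}

#' Environment RMSD (E-RMSD)
#'
#' All-atom RMSD of the environment residues (any atom within \code{cutoff}
#' of a loop C-beta) after superposing the model's environment onto the
#' reference, with symmetric side-chain flips.  Measures framework
#' inaccuracy independently of the loop.
#'
#' @param model,reference "protein" objects (the reference must contain the
#'   loop; environment selection uses the reference coordinates).
#' @param loop a \code{\link{loop_definition}}.
#' @param cutoff environment cutoff in Angstrom (default 10).
#' @return E-RMSD in Angstrom.
#' @export
e_rmsd <- function(model, reference, loop, cutoff = 10) {
  env <- environment_residues(reference, loop, cutoff)
  if (nrow(env) == 0) stop("empty environment")
  ma <- matched_atoms(model, reference, env)
  if (length(ma$model) < 3) stop("too few matched environment atoms")
  fit <- kabsch_superpose(get_xyz(model)[ma$model, , drop = FALSE],
                          get_xyz(reference)[ma$reference, , drop = FALSE])
  moved <- model
  moved <- set_xyz(moved, fit$transform(get_xyz(model)))
  symmetric_flip_rmsd(moved, reference, env)
}

#' Full RMSD report for a modeled loop
#'
#' @param model,reference "protein" objects.
#' @param loop a \code{\link{loop_definition}}.
#' @param cutoff environment cutoff in Angstrom.
#' @return object of class "rmsd_report" with loop main-chain RMSD, loop
#'   all-atom (flip-minimized) RMSD, E-RMSD, environment size and the
#'   environment superposition rms.
#' @export
rmsd_report <- function(model, reference, loop, cutoff = 10) {
  env <- environment_residues(reference, loop, cutoff)
  if (nrow(env) == 0) stop("empty environment")
  ma <- matched_atoms(model, reference, env)
  fit <- kabsch_superpose(get_xyz(model)[ma$model, , drop = FALSE],
                          get_xyz(reference)[ma$reference, , drop = FALSE])
  moved <- set_xyz(model, fit$transform(get_xyz(model)))
  loopsel <- data.frame(chain = loop$chain, resno = loop_resnos(loop))
  structure(list(
    loop_mainchain_rmsd = loop_mainchain_rmsd(model, reference, loop,
                                              "environment", cutoff),
    loop_allatom_rmsd = symmetric_flip_rmsd(moved, reference, loopsel),
    e_rmsd = symmetric_flip_rmsd(moved, reference, env),
    n_env_residues = nrow(env),
    superposition_rms = fit$rms), class = "rmsd_report")
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat(sprintf(paste0("loop main-chain RMSD: %.3f A\n",
                     "loop all-atom RMSD:   %.3f A (flip-minimized)\n",
                     "E-RMSD:               %.3f A over %d residues\n"),
              x$loop_mainchain_rmsd, x$loop_allatom_rmsd, x$e_rmsd,
              x$n_env_residues))
  invisible(x)
}
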