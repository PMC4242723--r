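## Front-door fitting interface: loop_model() runs the full protocol and
## returns a classed object with the usual methods.

#' Model a protein loop by conformational space annealing
#'
#' Runs the full protocol: fragment-assembly generation of an initial bank
#' of closed conformations, conformational space annealing against the
#' hybrid energy, and selection of the bank energy minimum as the final
#' model.
#'
#' @param structure a "protein" object (see \code{\link{read_pdb}}), or a
#'   path to a PDB file.  The polar-hydrogen topology is built if absent.
#' @param loop a \code{\link{loop_definition}} or a spec string
#'   "CHAIN:START-END" (1-based, inclusive).
#' @param model an \code{\link{energy_model}}; defaults to the packaged
#'   weights (0.16, 0.05, 1.2, 1.0, 4.0, 12.0) and tables.
#' @param config a \code{\link{csa_config}}; defaults follow loop length
#'   ((M, N) = (10, 30) below 12 residues, (20, 50) otherwise).
#' @param library optional \code{\link{fragment_library}} override.
#' @param reference optional reference "protein" for RMSD reporting.
#' @return object of class "loop_model" with components
#'   \code{final_model}, \code{bank}, \code{trace}, \code{config},
#'   \code{energy}, and (when a reference is given) \code{rmsd}.
#' @seealso \code{\link{run_csa}} for the bare optimizer,
#'   \code{\link{rmsd_report}} for evaluation against a reference.
#' @examples
#' \donttest{
#' sc <- make_scaffold(scaffold_spec(rng_seed = 1, loop_length = 6))
#' fw <- delete_loop(sc$structure, sc$loop)
#' fit <- loop_model(fw, sc$loop, model = planted_energy_model(sc),
#'                   config = csa_config(6, n_iterations = 2,
#'                                       trials_per_seed = 1),
#'                   reference = sc$structure)
#' print(fit)
#' }
#' @export
loop_model <- function(structure, loop, model = energy_model(),
                       config = NULL, library = NULL, reference = NULL) {
  if (is.character(structure)) structure <- read_pdb(structure)
  if (!isTRUE(structure$topology))
    structure <- build_polar_hydrogen_topology(structure)
  if (is.character(loop)) loop <- parse_loop_spec(loop)
  validate_loop(structure, loop)
  if (is.null(config)) config <- csa_config(loop$n_residues)
  res <- run_csa(structure, loop, model, config, library)
  es <- vapply(res$bank, function(m) m$etotal, numeric(1))
  best <- which.min(es)
  out <- list(final_model = res$final_model, bank = res$bank,
              trace = res$trace, config = config, loop = loop,
              model = model,
              energy = res$bank[[best]]$energy,
              bank_energies = es)
  if (!is.null(reference))
    out$rmsd <- rmsd_report(res$final_model, reference, loop)
  structure(out, class = "loop_model")
}

#' @export
print.loop_model <- function(x, ...) {
  cat(sprintf("Loop model %s:%d-%d (%d residues)\n", x$loop$chain,
              x$loop$start, x$loop$end, x$loop$n_residues))
  cat(sprintf("  CSA bank: N = %d, final energy minimum %.2f kcal/mol\n",
              length(x$bank), min(x$bank_energies)))
  cat(sprintf("  iterations run: %d (of %d), final D_cut %.2f A\n",
              length(x$trace), x$config$n_iterations,
              x$trace[[length(x$trace)]]$d_cut))
  if (!is.null(x$rmsd))
    cat(sprintf("  loop main-chain RMSD vs reference: %.2f A\n",
                x$rmsd$loop_mainchain_rmsd))
  invisible(x)
}

#' @export
summary.loop_model <- function(object, ...) {
  tr <- do.call(rbind, lapply(object$trace, as.data.frame))
  br <- object$energy
  out <- list(loop = object$loop, trace = tr,
              energy_terms = data.frame(
                term = c("bonded", "vdw", "coulomb", "gb", "sa", "phipsi",
                         "chi", "hbond", "atompair", "total"),
                kcal_mol = c(br$e_bonded, br$e_vdw, br$e_coulomb, br$e_gb,
                             br$e_sa, br$e_phipsi, br$e_chi, br$e_hbond,
                             br$e_atompair, br$e_total)),
              bank_energies = sort(object$bank_energies),
              rmsd = object$rmsd)
  class(out) <- "summary.loop_model"
  out
}

#' @export
print.summary.loop_model <- function(x, ...) {
  cat(sprintf("Loop %s:%d-%d\n", x$loop$chain, x$loop$start, x$loop$end))
  cat("\nEnergy breakdown of the final model (kcal/mol):\n")
  print(x$energy_terms, row.names = FALSE)
  cat("\nAnnealing trace:\n")
  print(x$trace, row.names = FALSE)
  if (!is.null(x$rmsd)) {
    cat("\n")
    print(x$rmsd)
  }
  invisible(x)
}

#' Plot the annealing trace of a loop model
#'
#' Shows the bank minimum and mean energy per iteration together with the
#' shrinking diversity radius D_cut.
#'
#' @param x a "loop_model".
#' @param ... ignored.
#' @export
plot.loop_model <- function(x, ...) {
  tr <- do.call(rbind, lapply(x$trace, as.data.frame))
  op <- par(mar = c(4, 4, 2, 4))
  on.exit(par(op))
  plot(tr$iteration, tr$e_mean, type = "l", lty = 2,
       ylim = range(c(tr$e_min, tr$e_mean)),
       xlab = "CSA iteration", ylab = "bank energy (kcal/mol)",
       main = "Conformational space annealing")
  lines(tr$iteration, tr$e_min, lwd = 2)
  par(new = TRUE)
  plot(tr$iteration, tr$d_cut, type = "l", col = "grey50", axes = FALSE,
       xlab = "", ylab = "")
  axis(4, col = "grey50", col.axis = "grey50")
  mtext("D_cut (A)", side = 4, line = 2.5, col = "grey50")
  legend("topright", c("bank min", "bank mean", "D_cut"),
         lty = c(1, 2, 1), lwd = c(2, 1, 1),
         col = c("black", "black", "grey50"), bty = "n")
  invisible(x)
}
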