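## Fragment assembly with loop closure (FALC): draw backbone torsions from
## the statistics-derived fragment library, pick three pivot residues, close
## the chain analytically, and keep the closure root with the fewest steric
## clashes (ties broken by least total torsion change).

CLASH_FACTOR <- 0.7     # heavy-atom clash if r < 0.7 (r_i + r_j)

## valid pivot triples: at least one residue between consecutive pivots
pivot_triples <- function(resnos) {
  n <- length(resnos)
  gap <- if (n >= 5) 2 else 1
  out <- list()
  for (i in seq_len(n - 2 * gap))
    for (j in seq(i + gap, n - gap))
      for (k in seq(j + gap, n))
        out[[length(out) + 1]] <- resnos[c(i, j, k)]
  out
}

## heavy-atom clash count of the loop against itself and the environment
count_clashes <- function(prot, loop, xyz = get_xyz(prot)) {
  at <- prot$atoms
  rs <- loop_resnos(loop)
  lrows <- which(at$chain == loop$chain & at$resno %in% rs &
                   at$element != "H")
  others <- which(at$element != "H")
  d2 <- outer(rowSums(xyz[lrows, , drop = FALSE]^2),
              rowSums(xyz[others, , drop = FALSE]^2), "+") -
    2 * xyz[lrows, , drop = FALSE] %*% t(xyz[others, , drop = FALSE])
  lim <- CLASH_FACTOR * outer(at$radius[lrows], at$radius[others], "+")
  close_pair <- d2 < lim^2
  ## discard self, bonded neighbours and double counts via residue adjacency
  samei <- outer(at$resno[lrows], at$resno[others],
                 function(a, b) abs(a - b) <= 1)
  dup <- outer(lrows, others, function(i, j) j %in% lrows & j <= i)
  sum(close_pair & !samei & !dup)
}

## draw a full torsion state from the library (chi at common rotamer plus
## discrete-state randomization)
draw_torsions <- function(base, library, cispro, randomize_chi = TRUE) {
  ts <- base
  n <- length(ts$resnos)
  for (k in seq_len(n)) {
    fr <- sample_fragment(library, k)
    ts$phi[k] <- fr["phi"]; ts$psi[k] <- fr["psi"]
    ts$omega[k] <- if (cispro[k]) 0 else 180
    rn <- library$resnames[k]
    nchi <- N_CHI[[rn]]
    if (nchi > 0) {
      chi <- COMMON_ROTAMER[[rn]] %||% rep(180, nchi)
      if (randomize_chi) {
        chi[1] <- sample(CHI1_STATES, 1, prob = c(0.5, 0.32, 0.18))
        if (nchi >= 2)
          chi[2] <- if (rn %in% c("PHE", "TYR", "TRP", "HIS"))
            sample(CHI_RING_STATES, 1) else
              sample(CHI1_STATES, 1, prob = c(0.35, 0.45, 0.2))
        chi <- wrap_angle(chi + rnorm(nchi, 0, 8))
      }
      ts$chi[[k]] <- chi
    }
  }
  ts
}

#' Generate closed loop conformations by fragment assembly
#'
#' @param structure "protein" with topology built (the framework; loop
#'   coordinates need not be meaningful).
#' @param loop a \code{\link{loop_definition}}.
#' @param library a \code{\link{fragment_library}} for the loop sequence.
#' @param n_samples number of closed conformations to generate.
#' @param rng_seed integer seed; output is deterministic given it.
#' @param max_retries closure attempts per sample before it is skipped.
#' @param randomize_chi randomize side-chain rotamer states (default TRUE).
#' @return list of closed "torsion_state" objects; attribute "log" records
#'   skipped samples.
#' @export
falc_sample <- function(structure, loop, library, n_samples, rng_seed = 1,
                        max_retries = 50, randomize_chi = TRUE) {
  stopifnot(n_samples >= 1)
  set.seed(rng_seed)
  base <- torsions_from_coords(structure, loop)
  rs <- loop_resnos(loop)
  cis <- vapply(rs, function(i) {
    k <- which(structure$residues$chain == loop$chain &
                 structure$residues$resno == i)
    isTRUE(structure$residues$cispro[k])
  }, logical(1))
  triples <- pivot_triples(rs)
  out <- list()
  skipped <- 0
  for (s in seq_len(n_samples)) {
    got <- NULL
    for (try in seq_len(max_retries)) {
      ts <- draw_torsions(base, library, cis, randomize_chi)
      piv <- triples[[sample.int(length(triples), 1)]]
      prb <- closure_problem(structure, loop, ts, piv)
      sols <- tlc_solve(prb)
      if (!length(sols)) next
      ## rank closure roots: fewest clashes, then least torsion change
      kp <- match(piv, ts$resnos)
      ref <- c(ts$phi[kp], ts$psi[kp])
      scored <- lapply(sols, function(sol) {
        cand <- tlc_apply(ts, sol)
        built <- coords_from_torsions(structure, loop, cand)
        list(state = cand, clashes = count_clashes(built, loop),
             dtors = sum(abs(wrap_angle(c(sol$phi, sol$psi) - ref))))
      })
      ncl <- vapply(scored, function(x) x$clashes, numeric(1))
      dts <- vapply(scored, function(x) x$dtors, numeric(1))
      got <- scored[[order(ncl, dts)[1]]]$state
      break
    }
    if (is.null(got)) { skipped <- skipped + 1; next }
    out[[length(out) + 1]] <- got
  }
  if (!length(out)) stop("all FALC samples failed closure")
  attr(out, "log") <- list(skipped = skipped, requested = n_samples)
  out
}
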