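## Knowledge-based tables: backbone phi/psi statistics, side-chain chi
## statistics, and the distance-binned atom-pair potential of mean force
## with an ideal-gas r^alpha reference state.
##
## Table values are -ln of density relative to uniform, so a uniform table
## is identically zero and exp(-value) averages to 1 over each table's
## domain (the normalization invariant).

RT_KCAL <- 0.5917          # kcal/mol at 298 K
PHIPSI_BIN <- 10           # degrees
PHIPSI_CLASSES <- c("GEN", "GLY", "PRO")

phipsi_class <- function(resname) {
  ifelse(resname == "GLY", "GLY", ifelse(resname == "PRO", "PRO", "GEN"))
}

## tables may be sequence-dependent: when a grid exists for the residue
## type itself, it takes precedence over the coarse class
phipsi_class_for <- function(table, resnames) {
  ifelse(resnames %in% names(table$grid), resnames, phipsi_class(resnames))
}

phipsi_centers <- function() seq(-180 + PHIPSI_BIN / 2, 180 - PHIPSI_BIN / 2,
                                 by = PHIPSI_BIN)

## normalize a positive grid so that mean(exp(-v)) == 1
normalize_neglog <- function(dens) {
  dens <- dens / mean(dens)
  -log(dens)
}

wrapped_gauss2 <- function(phi, psi, mu, sigma) {
  d1 <- wrap_angle(phi - mu[1]); d2 <- wrap_angle(psi - mu[2])
  exp(-0.5 * (d1 / sigma[1])^2 - 0.5 * (d2 / sigma[2])^2)
}

#' Default backbone torsion-statistics table
#'
#' An analytic Ramachandran-basin mixture (alpha, beta, left-handed alpha;
#' glycine- and proline-specific variants), binned on a 36 x 36 grid of 10
#' degree bins and stored as -ln relative density.
#'
#' @return object of class "phipsi_table".
#' @export
default_phipsi_table <- function() {
  ctr <- phipsi_centers()
  gr <- expand.grid(phi = ctr, psi = ctr)
  basins <- list(
    GEN = list(list(c(-63, -43), c(25, 25), 0.42),
               list(c(-120, 135), c(35, 35), 0.40),
               list(c(60, 45), c(20, 20), 0.13),
               list(c(-100, 0), c(30, 35), 0.05)),
    GLY = list(list(c(-80, 0), c(35, 40), 0.25),
               list(c(80, 0), c(35, 40), 0.25),
               list(c(-120, 150), c(40, 35), 0.25),
               list(c(120, -150), c(40, 35), 0.25)),
    PRO = list(list(c(-65, -30), c(15, 25), 0.5),
               list(c(-65, 150), c(15, 25), 0.5)))
  grids <- lapply(basins, function(bs) {
    dens <- rep(1e-4, nrow(gr))
    for (b in bs)
      dens <- dens + b[[3]] * wrapped_gauss2(gr$phi, gr$psi, b[[1]], b[[2]])
    matrix(normalize_neglog(dens), length(ctr), length(ctr))
  })
  structure(list(classes = names(grids), centers = ctr, grid = grids),
            class = "phipsi_table")
}

#' Default side-chain torsion-statistics table
#'
#' Periodic -ln density profiles per residue type and chi index, built from
#' rotamer-state mixtures (gauche-/trans/gauche+ for sp3 torsions, +-90 for
#' aromatic ring torsions, broad profiles for amide/carboxylate torsions).
#'
#' @return object of class "chi_table".
#' @export
default_chi_table <- function() {
  ctr <- phipsi_centers()
  gprof <- function(mus, ws, sigma = 15) {
    dens <- rep(1e-4, length(ctr))
    for (k in seq_along(mus))
      dens <- dens + ws[k] * exp(-0.5 * (wrap_angle(ctr - mus[k]) / sigma)^2)
    normalize_neglog(dens)
  }
  sp3 <- gprof(c(-60, 180, 60), c(0.5, 0.32, 0.18))
  ring <- gprof(c(90, -90), c(0.5, 0.5), 25)
  flat <- gprof(c(-30, 30, 90, -90, 150, -150), rep(1 / 6, 6), 35)
  prof <- list()
  for (rn in names(CHI_ATOMS)) {
    np <- length(CHI_ATOMS[[rn]])
    prof[[rn]] <- lapply(seq_len(np), function(k) {
      if (k == 2 && rn %in% c("PHE", "TYR", "TRP", "HIS")) ring
      else if (k == N_CHI[[rn]] && rn %in% c("ASN", "ASP", "GLN", "GLU")) flat
      else sp3
    })
  }
  structure(list(centers = ctr, profiles = prof), class = "chi_table")
}

## periodic bilinear interpolation on a 2D grid
interp2_periodic <- function(grid, centers, phi, psi) {
  nb <- length(centers)
  step <- 360 / nb
  ix <- (phi - centers[1]) / step
  iy <- (psi - centers[1]) / step
  i0 <- floor(ix); j0 <- floor(iy)
  fx <- ix - i0; fy <- iy - j0
  w <- function(i) (i %% nb) + 1
  grid[w(i0), w(j0)] * (1 - fx) * (1 - fy) +
    grid[w(i0 + 1), w(j0)] * fx * (1 - fy) +
    grid[w(i0), w(j0 + 1)] * (1 - fx) * fy +
    grid[w(i0 + 1), w(j0 + 1)] * fx * fy
}

interp1_periodic <- function(prof, centers, x) {
  nb <- length(centers)
  step <- 360 / nb
  ix <- (x - centers[1]) / step
  i0 <- floor(ix); fx <- ix - i0
  w <- function(i) (i %% nb) + 1
  prof[w(i0)] * (1 - fx) + prof[w(i0 + 1)] * fx
}

## analytic derivative of the 1D interpolation (per degree)
interp1_periodic_deriv <- function(prof, centers, x) {
  nb <- length(centers)
  step <- 360 / nb
  ix <- (x - centers[1]) / step
  i0 <- floor(ix)
  w <- function(i) (i %% nb) + 1
  (prof[w(i0 + 1)] - prof[w(i0)]) / step
}

#' Backbone torsion-statistics energy of a loop
#'
#' Sum of interpolated -ln relative densities at each loop residue's
#' (phi, psi), in units of kcal/mol (RT-scaled).
#'
#' @param torsions a "torsion_state".
#' @param table a "phipsi_table".
#' @param resnames 3-letter codes of the loop residues.
#' @return energy in kcal/mol.
#' @export
e_phipsi <- function(torsions, table, resnames) {
  cl <- phipsi_class_for(table, resnames)
  v <- 0
  for (k in seq_along(torsions$resnos)) {
    g <- table$grid[[cl[k]]]
    v <- v + interp2_periodic(g, table$centers, torsions$phi[k],
                              torsions$psi[k])
  }
  RT_KCAL * v
}

#' Side-chain torsion-statistics energy
#'
#' @param torsions a "torsion_state" (loop side chains); additional chi sets
#'   may be supplied via \code{extra} as a list of (resname, chis) pairs.
#' @param table a "chi_table".
#' @param resnames 3-letter codes of the loop residues.
#' @param extra optional list of list(resname=, chi=) for environment side
#'   chains included in the score.
#' @return energy in kcal/mol.
#' @export
e_chi <- function(torsions, table, resnames, extra = NULL) {
  v <- 0
  score1 <- function(rn, chis) {
    prof <- table$profiles[[rn]]
    if (is.null(prof)) return(0)
    s <- 0
    for (k in seq_along(prof))
      if (k <= length(chis) && !is.na(chis[k]))
        s <- s + interp1_periodic(prof[[k]], table$centers, chis[k])
    s
  }
  for (k in seq_along(torsions$resnos))
    v <- v + score1(resnames[k], torsions$chi[[k]])
  for (ex in extra %||% list())
    v <- v + score1(ex$resname, ex$chi)
  RT_KCAL * v
}

## ---------------------------------------------------------------------------
## Atom-pair potential of mean force

PAIR_BIN_WIDTH <- 0.5
PAIR_R_CUT <- 15

#' Derive a distance-binned atom-pair potential
#'
#' Counts heavy-atom pairs (sequence separation >= 2 residues) in distance
#' bins and converts them to a potential of mean force against a
#' distance-scaled ideal-gas reference: u(i,j,r) =
#' -RT ln[N(i,j,r) / ((r/r_cut)^alpha N(i,j,r_cut))], with pseudocount 1 per
#' bin.  The last bin is the reference state and is exactly zero.
#'
#' @param training list of "protein" objects, or a data.frame with columns
#'   class, resno, x, y, z (one row per heavy atom).
#' @param alpha reference-state exponent (default 1.61).
#' @param bin_width bin width in Angstrom (default 0.5).
#' @param r_cut maximum distance in Angstrom (default 15).
#' @param min_sep minimum residue sequence separation (default 2).
#' @return object of class "pair_potential_table".
#' @export
derive_pair_potential <- function(training, alpha = 1.61,
                                  bin_width = PAIR_BIN_WIDTH,
                                  r_cut = PAIR_R_CUT, min_sep = 2) {
  if (inherits(training, "protein") || is.data.frame(training))
    training <- list(training)
  tabs <- lapply(training, function(p) {
    if (is.data.frame(p)) return(p)
    at <- p$atoms
    keep <- at$element != "H"
    data.frame(class = at$class[keep], resno = at$resno[keep],
               x = at$x[keep], y = at$y[keep], z = at$z[keep],
               stringsAsFactors = FALSE)
  })
  classes <- atom_class_table()$class
  classes <- classes[classes != "H"]
  nb <- as.integer(round(r_cut / bin_width))
  nc <- length(classes)
  counts <- array(0, c(nc, nc, nb))
  for (tb in tabs) {
    ci <- match(tb$class, classes)
    if (anyNA(ci)) stop("unknown atom class in training data")
    xyz <- as.matrix(tb[, c("x", "y", "z")])
    n <- nrow(xyz)
    ## chunked pair accumulation
    chunk <- max(1, floor(2e6 / n))
    for (a0 in seq(1, n, by = chunk)) {
      a1 <- min(n, a0 + chunk - 1)
      rows <- a0:a1
      d2 <- outer(rowSums(xyz[rows, , drop = FALSE]^2), rowSums(xyz^2), "+") -
        2 * xyz[rows, , drop = FALSE] %*% t(xyz)
      sep <- abs(outer(tb$resno[rows], tb$resno, "-"))
      sel <- which(d2 < r_cut^2 & sep >= min_sep &
                     outer(rows, seq_len(n), "<"), arr.ind = TRUE)
      if (!nrow(sel)) next
      bi <- pmin(nb, 1 + floor(sqrt(pmax(d2[sel], 0)) / bin_width))
      i1 <- ci[rows[sel[, 1]]]; i2 <- ci[sel[, 2]]
      lo <- pmin(i1, i2); hi <- pmax(i1, i2)
      lin <- lo + (hi - 1L) * nc + (bi - 1L) * nc * nc
      tab <- tabulate(lin, nbins = nc * nc * nb)
      counts <- counts + array(tab, c(nc, nc, nb))
    }
  }
  centers <- (seq_len(nb) - 0.5) * bin_width
  ref <- (centers / centers[nb])^alpha
  values <- array(0, c(nc, nc, nb))
  empty <- character(0)
  for (i in seq_len(nc)) for (j in i:nc) {
    ncount <- counts[i, j, ] + 1
    if (sum(counts[i, j, ]) == 0) {
      empty <- c(empty, paste0(classes[i], "-", classes[j]))
      next
    }
    u <- -RT_KCAL * log(ncount / (ref * ncount[nb]))
    u[nb] <- 0
    values[i, j, ] <- u
    values[j, i, ] <- u
  }
  if (length(empty) && length(empty) < nc * (nc + 1) / 2)
    warning("no pair counts for ", length(empty),
            " class pair(s) (rows set to 0): ",
            paste(utils::head(empty, 5), collapse = ", "),
            if (length(empty) > 5) ", ..." else "")
  structure(list(classes = classes, bin_width = bin_width, r_cut = r_cut,
                 alpha = alpha, centers = centers, values = values,
                 counts = counts),
            class = "pair_potential_table")
}

#' Default atom-pair potential
#'
#' A smooth, self-contained stand-in built from generic physical shape:
#' short-range repulsion, a shallow contact well at van der Waals contact,
#' zero at the reference distance.  Used when no trained table is supplied.
#'
#' @return object of class "pair_potential_table".
#' @export
default_pair_potential <- function() {
  cls <- atom_class_table()
  classes <- cls$class[cls$class != "H"]
  nb <- as.integer(round(PAIR_R_CUT / PAIR_BIN_WIDTH))
  centers <- (seq_len(nb) - 0.5) * PAIR_BIN_WIDTH
  nc <- length(classes)
  values <- array(0, c(nc, nc, nb))
  rad <- cls$radius[match(classes, cls$class)]
  for (i in seq_len(nc)) for (j in i:nc) {
    contact <- rad[i] + rad[j]
    depth <- 0.3
    u <- ifelse(centers < 0.8 * contact,
                2.0 * (0.8 * contact - centers),
                -depth * exp(-0.5 * ((centers - 1.1 * contact) / 1.0)^2))
    u[nb] <- 0
    values[i, j, ] <- u
    values[j, i, ] <- u
  }
  structure(list(classes = classes, bin_width = PAIR_BIN_WIDTH,
                 r_cut = PAIR_R_CUT, alpha = 1.61, centers = centers,
                 values = values, counts = NULL),
            class = "pair_potential_table")
}

#' Derive torsion-statistics tables from training structures
#'
#' Bins backbone (phi, psi) by residue class (general/glycine/proline) and
#' side-chain chi by residue type, with pseudocounts, normalized per class.
#'
#' @param training list of "protein" objects.
#' @param pseudocount added per bin before normalization.
#' @return list with elements \code{phipsi} ("phipsi_table") and \code{chi}
#'   ("chi_table").
#' @export
derive_torsion_tables <- function(training, pseudocount = 0.5) {
  if (inherits(training, "protein")) training <- list(training)
  ctr <- phipsi_centers()
  nb <- length(ctr)
  cnt2 <- lapply(PHIPSI_CLASSES, function(cl) matrix(0, nb, nb))
  names(cnt2) <- PHIPSI_CLASSES
  cnt1 <- list()
  binof <- function(x) pmin(nb, pmax(1, 1 + floor((x + 180) / PHIPSI_BIN)))
  for (p in training) {
    res <- p$residues
    for (ch in unique(res$chain)) {
      rn <- sort(res$resno[res$chain == ch])
      for (i in rn[-c(1, length(rn))]) {
        k <- which(res$chain == ch & res$resno == i)
        loopi <- tryCatch(torsions_from_coords(p, structure(
          list(chain = ch, start = i, end = i, n_residues = 1),
          class = "loop_definition")), error = function(e) NULL)
        if (is.null(loopi)) next
        cl <- phipsi_class(res$resname[k])
        cnt2[[cl]][binof(loopi$phi), binof(loopi$psi)] <-
          cnt2[[cl]][binof(loopi$phi), binof(loopi$psi)] + 1
        chis <- loopi$chi[[1]]
        rname <- res$resname[k]
        if (length(chis)) {
          if (is.null(cnt1[[rname]]))
            cnt1[[rname]] <- lapply(seq_along(chis), function(.) rep(0, nb))
          for (q in seq_along(chis)) if (!is.na(chis[q]))
            cnt1[[rname]][[q]][binof(chis[q])] <-
              cnt1[[rname]][[q]][binof(chis[q])] + 1
        }
      }
    }
  }
  grids <- lapply(cnt2, function(m) {
    matrix(normalize_neglog(as.numeric(m) + pseudocount), nb, nb)
  })
  chi_default <- default_chi_table()
  profs <- chi_default$profiles
  for (rn in names(cnt1))
    profs[[rn]] <- lapply(cnt1[[rn]], function(v)
      normalize_neglog(v + pseudocount))
  list(phipsi = structure(list(classes = names(grids), centers = ctr,
                               grid = grids), class = "phipsi_table"),
       chi = structure(list(centers = ctr, profiles = profs),
                       class = "chi_table"))
}

## validity check used by tests: mean(exp(-v)) == 1 per class
phipsi_table_normalized <- function(table, tol = 1e-6) {
  all(vapply(table$grid, function(g) abs(mean(exp(-g)) - 1) < tol, logical(1)))
}

## ---------------------------------------------------------------------------
## Fragment library (per-position (phi, psi, omega) triplets with weights)

#' Build a fragment library for a loop from a torsion-statistics table
#'
#' Per loop position, the (phi, psi) bins of the residue's class with their
#' statistical weights; omega is trans (180) except flagged cis-prolines.
#'
#' @param table a "phipsi_table".
#' @param resnames 3-letter codes of the loop residues.
#' @param top_mass keep the smallest set of bins covering this probability
#'   mass per position (default 0.98).
#' @return object of class "fragment_library".
#' @export
fragment_library <- function(table, resnames, top_mass = 0.98) {
  cls <- phipsi_class_for(table, resnames)
  positions <- lapply(cls, function(rn) {
    g <- table$grid[[rn]]
    dens <- exp(-g)
    dens <- dens / sum(dens)
    ord <- order(dens, decreasing = TRUE)
    keep <- ord[cumsum(dens[ord]) <= top_mass]
    if (!length(keep)) keep <- ord[1]
    ij <- arrayInd(keep, dim(g))
    data.frame(phi = table$centers[ij[, 1]], psi = table$centers[ij[, 2]],
               weight = dens[keep] / sum(dens[keep]))
  })
  structure(list(resnames = resnames, positions = positions),
            class = "fragment_library")
}

## draw one (phi, psi) for position k (uniform jitter within the bin)
sample_fragment <- function(library, k) {
  pos <- library$positions[[k]]
  i <- sample.int(nrow(pos), 1, prob = pos$weight)
  c(phi = wrap_angle(pos$phi[i] + runif(1, -PHIPSI_BIN / 2, PHIPSI_BIN / 2)),
    psi = wrap_angle(pos$psi[i] + runif(1, -PHIPSI_BIN / 2, PHIPSI_BIN / 2)))
}

## ---------------------------------------------------------------------------
## Text serialization (documented formats)

#' Write / read a phi/psi table as a text file
#'
#' Format: comment header, then rows "class phi_center psi_center value".
#' @param table a "phipsi_table".
#' @param path file path.
#' @export
write_phipsi_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# phi/psi torsion-statistics table: class phi psi value", con)
  for (cl in names(table$grid)) {
    g <- table$grid[[cl]]
    for (i in seq_along(table$centers)) for (j in seq_along(table$centers))
      writeLines(sprintf("%s\t%g\t%g\t%.8g", cl, table$centers[i],
                         table$centers[j], g[i, j]), con)
  }
  invisible(path)
}

#' @rdname write_phipsi_table
#' @export
read_phipsi_table <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("class", "phi", "psi", "value"))
  ctr <- sort(unique(df$phi))
  grids <- lapply(split(df, df$class), function(d) {
    g <- matrix(0, length(ctr), length(ctr))
    g[cbind(match(d$phi, ctr), match(d$psi, ctr))] <- d$value
    g
  })
  structure(list(classes = names(grids), centers = ctr, grid = grids),
            class = "phipsi_table")
}

#' Write / read an atom-pair potential as a text file
#'
#' Format: comment header, then rows "class_i class_j bin_center value".
#' @param table a "pair_potential_table".
#' @param path file path.
#' @export
write_pair_potential <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# atom-pair potential: bin_width %g r_cut %g alpha %g",
                     table$bin_width, table$r_cut, table$alpha), con)
  nc <- length(table$classes)
  for (i in seq_len(nc)) for (j in i:nc)
    for (b in seq_along(table$centers))
      writeLines(sprintf("%s\t%s\t%g\t%.8g", table$classes[i],
                         table$classes[j], table$centers[b],
                         table$values[i, j, b]), con)
  invisible(path)
}

#' @rdname write_pair_potential
#' @export
read_pair_potential <- function(path) {
  hdr <- readLines(path, n = 1)
  nums <- as.numeric(regmatches(hdr, gregexpr("[0-9.]+", hdr))[[1]])
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("ci", "cj", "center", "value"))
  classes <- sort(unique(c(df$ci, df$cj)))
  centers <- sort(unique(df$center))
  values <- array(0, c(length(classes), length(classes), length(centers)))
  i <- match(df$ci, classes); j <- match(df$cj, classes)
  b <- match(df$center, centers)
  values[cbind(i, j, b)] <- df$value
  values[cbind(j, i, b)] <- df$value
  structure(list(classes = classes, bin_width = nums[1], r_cut = nums[2],
                 alpha = nums[3], centers = centers, values = values,
                 counts = NULL),
            class = "pair_potential_table")
}

#' Write / read a fragment library as a text table
#'
#' Format: rows "position resname phi psi weight".
#' @param library a "fragment_library".
#' @param path file path.
#' @export
write_fragment_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fragment library: position resname phi psi weight", con)
  for (k in seq_along(library$positions)) {
    pos <- library$positions[[k]]
    for (r in seq_len(nrow(pos)))
      writeLines(sprintf("%d\t%s\t%g\t%g\t%.8g", k, library$resnames[k],
                         pos$phi[r], pos$psi[r], pos$weight[r]), con)
  }
  invisible(path)
}

#' @rdname write_fragment_library
#' @export
read_fragment_library <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("pos", "resname", "phi", "psi", "weight"))
  ks <- sort(unique(df$pos))
  positions <- lapply(ks, function(k) {
    d <- df[df$pos == k, ]
    data.frame(phi = d$phi, psi = d$psi, weight = d$weight / sum(d$weight))
  })
  structure(list(resnames = vapply(ks, function(k)
    df$resname[df$pos == k][1], character(1)), positions = positions),
    class = "fragment_library")
}
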