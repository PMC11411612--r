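#' @include AllClasses.R obmol.R descriptors2d.R
NULL

#' Ensemble size from the rotatable bond count
#'
#' Piecewise rule for how many conformers to request: 50 for up to 7
#' rotatable bonds, 200 for 8-12, 300 above 12.
#'
#' @param rotatableBonds non-negative integer vector
#' @return integer vector of requested ensemble sizes
#' @examples
#' conformerCountRule(c(0, 7, 8, 12, 13))  # 50 50 200 200 300
#' @export
conformerCountRule <- function(rotatableBonds) {
  rb <- as.integer(rotatableBonds)
  if (any(is.na(rb)) || any(rb < 0L)) {
    stop("rotatable bond counts must be non-negative integers")
  }
  ifelse(rb <= 7L, 50L, ifelse(rb <= 12L, 200L, 300L))
}

# Parse a (possibly multi-record) V2000 SDF into element symbols and a
# list of coordinate matrices. All records must share one connection
# table (conformers of the same molecule).
.readConformerSDF <- function(path) {
  lines <- readLines(path)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) stop("no SDF records in ", path)
  starts <- c(1L, head(ends, -1L) + 1L)
  coords <- vector("list", length(ends))
  elements <- NULL
  template <- NULL
  for (r in seq_along(ends)) {
    rec <- lines[starts[r]:ends[r]]
    counts <- rec[4]
    natoms <- as.integer(substr(counts, 1, 3))
    atomLines <- rec[5:(4 + natoms)]
    xyz <- matrix(NA_real_, natoms, 3)
    el <- character(natoms)
    for (i in seq_len(natoms)) {
      ln <- atomLines[i]
      xyz[i, ] <- as.numeric(c(substr(ln, 1, 10), substr(ln, 11, 20),
                               substr(ln, 21, 30)))
      el[i] <- trimws(substr(ln, 32, 34))
    }
    coords[[r]] <- xyz
    if (is.null(elements)) {
      elements <- el
      template <- rec
    }
  }
  list(elements = elements, coords = coords, template = template)
}

# Rewrite the template SDF record with new coordinates, one record per
# conformer.
.writeConformerSDF <- function(template, elements, coords, path) {
  natoms <- length(elements)
  out <- character(0)
  for (m in coords) {
    rec <- template
    for (i in seq_len(natoms)) {
      ln <- rec[4L + i]
      rec[4L + i] <- paste0(
        sprintf("%10.4f%10.4f%10.4f", m[i, 1], m[i, 2], m[i, 3]),
        substr(ln, 31, nchar(ln))
      )
    }
    out <- c(out, rec)
  }
  writeLines(out, path)
  invisible(path)
}

#' Generate a conformer ensemble
#'
#' Embeds a seed-reproducible 3D structure (deterministic 2D layout with
#' explicit hydrogens, seeded random out-of-plane displacements, then a
#' deep MMFF94 relaxation), and runs a systematic diverse torsion search
#' (Confab) with an RMS diversity threshold and energy window,
#' requesting the ensemble size given by [conformerCountRule()]. MMFF94
#' energies (kcal/mol) are attached per conformer. The protocol is fully
#' deterministic given (molecule, seed): the only random element is the
#' initial out-of-plane displacement, drawn from an RNG seeded by the
#' global seed plus a stable hash of the canonical SMILES, so adding
#' compounds to a run never reshuffles the ensembles of others. Ring
#' torsions are not enumerated, so macrocycles contribute a single ring
#' conformation.
#'
#' Molecules that cannot be embedded or parameterised raise a classed
#' error (`drugspace_descriptor_failure`) that pipeline callers can catch
#' and record as a per-compound failure.
#'
#' @param smiles a single valid SMILES string
#' @param id compound identifier carried into the ensemble
#' @param seed integer; combined with a stable per-molecule hash and
#'   recorded in the ensemble metadata
#' @param rmsThreshold minimum heavy-atom RMS (Angstrom) between kept
#'   conformers, default 0.1
#' @param energyWindow conformers above this MMFF94 energy above the
#'   minimum are discarded during the search (kcal/mol)
#' @param nConf override the rotatable-bond rule with a fixed request
#' @return a [ConformerEnsemble]
#' @export
generateEnsemble <- function(smiles, id = smiles, seed = 1L,
                             rmsThreshold = 0.1, energyWindow = 50,
                             nConf = NULL) {
  stopifnot(length(smiles) == 1L)
  can <- canonicalSmiles(smiles)
  if (is.na(can)) {
    stop(descriptorFailure(paste0("SMILES failed to parse: ", smiles), id))
  }
  mols <- obMolecules(can)
  rb <- smartsCount(mols, .SMARTS$rotor_loose) -
    smartsCount(mols, .SMARTS$amide_bond)
  nreq <- if (is.null(nConf)) conformerCountRule(rb) else as.integer(nConf)
  molSeed <- (as.integer(seed) + stableStringHash(can)) %% .Machine$integer.max

  dir <- tempfile("ens")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  smiFile <- file.path(dir, "in.smi")
  flatFile <- file.path(dir, "flat.sdf")
  pertFile <- file.path(dir, "pert.sdf")
  baseFile <- file.path(dir, "base.sdf")
  confFile <- file.path(dir, "confs.sdf")
  writeLines(can, smiFile)

  # deterministic 2D layout with explicit hydrogens
  runObabel(c("-ismi", shQuote(smiFile), "-O", shQuote(flatFile),
              "--gen2D", "-h"))
  if (!file.exists(flatFile) || !any(grepl("^\\$\\$\\$\\$",
                                           readLines(flatFile)))) {
    stop(descriptorFailure(paste0("structure layout failed for ", id), id))
  }
  flat <- .readConformerSDF(flatFile)
  # seeded out-of-plane displacement breaks planarity before relaxation
  xyz <- flat$coords[[1]]
  xyz[, 3] <- xyz[, 3] + withSeed(molSeed, stats::runif(nrow(xyz), -0.5, 0.5))
  .writeConformerSDF(flat$template, flat$elements, list(xyz), pertFile)
  # deep relaxation to a genuine 3D minimum
  runObabel(c(shQuote(pertFile), "-O", shQuote(baseFile), "--minimize",
              "--ff", "MMFF94", "--steps", 1500L, "--crit", "1e-7"))
  baseEnergy <- tryCatch(mmff94Energies(baseFile), error = function(e) NA)
  if (anyNA(baseEnergy) || !all(is.finite(baseEnergy)) ||
      baseEnergy[1] > 1e6) {
    stop(descriptorFailure(paste0("3D embedding failed for ", id), id))
  }
  runObabel(c(shQuote(baseFile), "-O", shQuote(confFile), "--confab",
              "--conf", nreq, "--rcutoff", rmsThreshold,
              "--ecutoff", energyWindow, "--original"))
  parsed <- .readConformerSDF(confFile)
  energies <- tryCatch(mmff94Energies(confFile), error = function(e) NULL)
  if (is.null(energies) || length(energies) != length(parsed$coords)) {
    stop(descriptorFailure(paste0("MMFF94 setup failed for ", id), id))
  }
  keep <- seq_len(min(length(parsed$coords), nreq))
  new("ConformerEnsemble", id = as.character(id), smiles = can,
      elements = parsed$elements, coords = parsed$coords[keep],
      energies = energies[keep], seed = as.integer(molSeed),
      nRequested = as.integer(nreq), sdfTemplate = parsed$template,
      meta = list(forceField = "MMFF94", rmsThreshold = rmsThreshold,
                  energyWindow = energyWindow, optimised = FALSE,
                  builder = "obabel gen3d fast + confab"))
}

#' Optimise a conformer ensemble with MMFF94
#'
#' Relaxes every conformer with the MMFF94 force field (conjugate
#' gradients), recomputes energies, and re-prunes the relaxed ensemble so
#' that all pairs remain separated by more than the RMS threshold
#' (lowest-energy conformers have priority). Per-conformer energies never
#' increase beyond convergence tolerance.
#'
#' @param ensemble a [ConformerEnsemble]
#' @param steps maximum optimisation iterations per conformer
#' @param crit convergence criterion on the energy change
#' @return the optimised [ConformerEnsemble]; pre-optimisation energies
#'   are kept in `meta$energiesBefore`
#' @export
optimiseEnsemble <- function(ensemble, steps = 200L, crit = 1e-6) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  dir <- tempfile("opt")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  inFile <- file.path(dir, "in.sdf")
  outFile <- file.path(dir, "out.sdf")
  .writeConformerSDF(ensemble@sdfTemplate, ensemble@elements,
                     ensemble@coords, inFile)
  runObabel(c(shQuote(inFile), "-O", shQuote(outFile), "--minimize",
              "--ff", "MMFF94", "--steps", as.integer(steps),
              "--crit", format(crit, scientific = FALSE)))
  parsed <- .readConformerSDF(outFile)
  energies <- mmff94Energies(outFile)
  if (length(energies) != length(parsed$coords)) {
    stop("optimisation lost conformers for ", ensemble@id)
  }
  heavy <- ensemble@elements != "H"
  ord <- order(energies)
  keptIdx <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in keptIdx) {
      r <- kabschRMSD(parsed$coords[[i]][heavy, , drop = FALSE],
                      parsed$coords[[j]][heavy, , drop = FALSE])
      if (r <= ensemble@meta$rmsThreshold) { ok <- FALSE; break }
    }
    if (ok) keptIdx <- c(keptIdx, i)
  }
  keptIdx <- sort(keptIdx)
  meta <- ensemble@meta
  meta$optimised <- TRUE
  meta$energiesBefore <- ensemble@energies
  meta$optimSteps <- as.integer(steps)
  meta$optimCrit <- crit
  new("ConformerEnsemble", id = ensemble@id, smiles = ensemble@smiles,
      elements = ensemble@elements, coords = parsed$coords[keptIdx],
      energies = energies[keptIdx], seed = ensemble@seed,
      nRequested = ensemble@nRequested, sdfTemplate = ensemble@sdfTemplate,
      meta = meta)
}

#' Minimum pairwise heavy-atom RMSD of an ensemble
#'
#' Post-hoc check of the pruning invariant: the smallest least-squares
#' heavy-atom RMSD over all conformer pairs.
#'
#' @param ensemble a [ConformerEnsemble] with at least 2 conformers
#' @return numeric (Angstrom); `Inf` for a single conformer
#' @export
minPairwiseRMSD <- function(ensemble) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  n <- nConformers(ensemble)
  if (n < 2L) return(Inf)
  heavy <- ensemble@elements != "H"
  best <- Inf
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- kabschRMSD(ensemble@coords[[i]][heavy, , drop = FALSE],
                      ensemble@coords[[j]][heavy, , drop = FALSE])
      best <- min(best, r)
    }
  }
  best
}
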