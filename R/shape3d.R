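#' @include conformer3d.R utils.R
NULL

# Boltzmann constant in kcal mol^-1 K^-1, matching MMFF94 energy units.
.KB_KCALMOL <- 0.0019872041

#' Principal moments of inertia
#'
#' Eigenvalues of the mass-weighted inertia tensor about the centre of
#' mass, sorted ascending (I1 <= I2 <= I3), in amu A^2. Each moment is
#' the sum over atoms of mass times squared perpendicular distance from
#' the corresponding principal axis; the result is invariant to rigid
#' rotation and translation of the coordinates.
#'
#' @param coords nAtom x 3 matrix of coordinates (Angstrom)
#' @param masses atomic masses (amu), one per atom
#' @return numeric c(i1, i2, i3)
#' @examples
#' # two unit masses on the x axis: moments (0, 2, 2)
#' momentsOfInertia(rbind(c(1, 0, 0), c(-1, 0, 0)), c(1, 1))
#' @export
momentsOfInertia <- function(coords, masses) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 1L,
            length(masses) == nrow(coords), all(is.finite(coords)),
            all(is.finite(masses)), all(masses >= 0))
  if (sum(masses) <= 0) stop("total mass must be positive")
  com <- colSums(coords * masses) / sum(masses)
  r <- sweep(coords, 2, com)
  r2 <- rowSums(r^2)
  tensor <- diag(c(sum(masses * r2), sum(masses * r2), sum(masses * r2))) -
    crossprod(r * sqrt(masses))
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  sort(pmax(ev, 0))
}

#' Normalised principal moment ratios
#'
#' NPR1 = I1/I3 and NPR2 = I2/I3 map a molecule into the shape triangle
#' with vertices rod (0, 1), disc (0.5, 0.5) and sphere (1, 1).
#'
#' @param moments numeric c(i1, i2, i3), sorted ascending, i3 > 0
#' @return numeric c(npr1, npr2)
#' @examples
#' nprRatios(c(0, 2, 2))   # 0 1   (linear)
#' nprRatios(c(4, 4, 8))   # 0.5 0.5 (disc)
#' @export
nprRatios <- function(moments) {
  stopifnot(length(moments) == 3L, all(is.finite(moments)))
  if (is.unsorted(moments)) stop("moments must be sorted ascending")
  if (moments[3] <= 0) {
    stop("NPR undefined: largest moment is zero (single atom or point mass)")
  }
  c(npr1 = moments[1] / moments[3], npr2 = moments[2] / moments[3])
}

#' Boltzmann weights for a conformer ensemble
#'
#' Weight of conformer i is exp(-Ei / kB T) normalised over the ensemble,
#' with energies shifted by their minimum before exponentiation for
#' numerical stability. kB is expressed in kcal/(mol K) to match MMFF94
#' energies. At `temperature = 0` all weight collapses onto the
#' minimum-energy conformer(s); at `temperature = Inf` weights are
#' uniform.
#'
#' @param energies numeric, kcal/mol
#' @param temperature Kelvin, default 300
#' @return numeric weights summing to 1, non-increasing in energy
#' @export
boltzmannWeights <- function(energies, temperature = 300) {
  stopifnot(length(energies) >= 1L, all(is.finite(energies)),
            temperature >= 0)
  if (temperature == 0) {
    w <- as.numeric(energies == min(energies))
    return(w / sum(w))
  }
  if (is.infinite(temperature)) {
    return(rep(1 / length(energies), length(energies)))
  }
  shifted <- energies - min(energies)
  w <- exp(-shifted / (.KB_KCALMOL * temperature))
  w / sum(w)
}

#' Boltzmann-averaged property
#'
#' Ensemble average of a per-conformer property A: sum of wi * Ai with
#' Boltzmann weights at the given temperature. The result is bounded by
#' the range of the input values.
#'
#' @param values per-conformer property values
#' @param energies MMFF94 energies, kcal/mol, same length
#' @param temperature Kelvin, default 300
#' @return numeric scalar
#' @examples
#' boltzmannAverage(c(1, 3), c(2, 2))  # equal energies -> plain mean, 2
#' @export
boltzmannAverage <- function(values, energies, temperature = 300) {
  if (length(values) == 0L) stop("empty ensemble")
  if (length(values) != length(energies)) {
    stop("values and energies must have the same length")
  }
  sum(boltzmannWeights(energies, temperature) * values)
}

#' Per-conformer shape descriptors
#'
#' Principal moments and NPR values for every conformer of an ensemble,
#' using isotope-averaged atomic masses (hydrogens are explicit in the
#' ensemble coordinates). With `unitMasses = TRUE` every atom gets unit
#' weight instead, for comparison with geometry-only shape conventions.
#'
#' @param ensemble a [ConformerEnsemble]
#' @param unitMasses logical, default FALSE
#' @return a [S4Vectors::DataFrame]: conformer, i1, i2, i3, npr1, npr2,
#'   energy
#' @export
conformerShapes <- function(ensemble, unitMasses = FALSE) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  masses <- if (unitMasses) rep(1, length(ensemble@elements))
            else atomicMasses(ensemble@elements)
  rows <- lapply(seq_len(nConformers(ensemble)), function(k) {
    m <- momentsOfInertia(ensemble@coords[[k]], masses)
    npr <- nprRatios(m)
    data.frame(conformer = k, i1 = m[1], i2 = m[2], i3 = m[3],
               npr1 = npr[1], npr2 = npr[2],
               energy = ensemble@energies[k])
  })
  DataFrame(do.call(rbind, rows))
}

#' Boltzmann-averaged shape summary of an ensemble
#'
#' NPR values are computed per conformer and averaged with Boltzmann
#' weights at the requested temperature (average of ratios, not ratio of
#' averaged moments). The lowest-energy conformer's NPRs are reported
#' alongside, since either convention is used for shape-triangle plots.
#'
#' @param ensemble a [ConformerEnsemble]
#' @param temperature Kelvin, default 300
#' @param unitMasses passed to [conformerShapes()]
#' @return a one-row [S4Vectors::DataFrame]: id, npr1_boltz, npr2_boltz,
#'   npr1_min, npr2_min, n_conformers, min_energy
#' @export
shapeDescriptors <- function(ensemble, temperature = 300,
                             unitMasses = FALSE) {
  per <- conformerShapes(ensemble, unitMasses = unitMasses)
  en <- per$energy
  lowest <- which.min(en)
  DataFrame(
    id = ensemble@id,
    npr1_boltz = boltzmannAverage(per$npr1, en, temperature),
    npr2_boltz = boltzmannAverage(per$npr2, en, temperature),
    npr1_min = per$npr1[lowest], npr2_min = per$npr2[lowest],
    n_conformers = nrow(per), min_energy = en[lowest],
    temperature = temperature
  )
}
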