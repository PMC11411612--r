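#' @include utils.R
NULL

.INDICATIONS <- c("cancer", "nervous system", "infection", "GI/metabolism",
                  "cardiovascular", "respiratory/inflammation", "other")

.EXCLUSION_REASONS <- c("not-absorbed-GI", "combination-of-older-drugs",
                        "descriptor-failure")

#' DrugSet: a table of drug approval records
#'
#' Container for parsed compound records (one row per approval): compound
#' identifier, name, input and canonical SMILES, approval year, major
#' indication class and exclusion flags. Created by [parseDataset()] or
#' [generateLibrary()].
#'
#' @slot records a [S4Vectors::DataFrame] with columns `id`, `name`,
#'   `smiles`, `canonical_smiles`, `approval_year`, `indication`,
#'   `excluded`, `exclusion_reason`, `fragment_stripped`
#' @slot provenance list describing the source (path or generator spec)
#'   and exclusion counts
#' @export
setClass("DrugSet", slots = c(records = "DataFrame", provenance = "list"))

setValidity("DrugSet", function(object) {
  rec <- object@records
  need <- c("id", "name", "smiles", "canonical_smiles", "approval_year",
            "indication", "excluded", "exclusion_reason", "fragment_stripped")
  missing <- setdiff(need, colnames(rec))
  if (length(missing)) {
    return(paste("missing record columns:", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(rec$id)) return("compound ids must be unique")
  bad <- !rec$excluded & is.na(rec$canonical_smiles)
  if (any(bad)) {
    return("records with unparseable SMILES must be excluded with reason 'descriptor-failure'")
  }
  TRUE
})

#' AnalysisSet: the exclusion-filtered compound set
#'
#' A [DrugSet] from which every flagged record has been removed (see
#' [applyExclusions()]); all remaining SMILES are valid.
#'
#' @export
setClass("AnalysisSet", contains = "DrugSet")

setValidity("AnalysisSet", function(object) {
  if (any(object@records$excluded)) {
    return("an AnalysisSet must not contain excluded records")
  }
  TRUE
})

#' ConformerEnsemble: 3D conformers of one molecule with MMFF94 energies
#'
#' Produced by [generateEnsemble()] and refined by [optimiseEnsemble()].
#' Coordinates are in Angstrom with explicit hydrogens; energies are
#' MMFF94 total energies in kcal/mol.
#'
#' @slot id compound identifier
#' @slot smiles the (canonical) SMILES the ensemble was built from
#' @slot elements element symbol per atom
#' @slot coords list of nAtom x 3 coordinate matrices (Angstrom)
#' @slot energies numeric, kcal/mol, one per conformer
#' @slot seed integer seed recorded for provenance
#' @slot nRequested ensemble size requested from the rotatable-bond rule
#' @slot sdfTemplate character lines of one SDF record, used to rewrite
#'   conformers for force-field tools
#' @slot meta list: force field, prune threshold, optimisation state
#' @export
setClass("ConformerEnsemble", slots = c(
  id = "character", smiles = "character", elements = "character",
  coords = "list", energies = "numeric", seed = "integer",
  nRequested = "integer", sdfTemplate = "character", meta = "list"
))

setValidity("ConformerEnsemble", function(object) {
  n <- length(object@coords)
  if (n == 0L) return("ensemble must contain at least one conformer")
  if (length(object@energies) != n) {
    return("one energy per conformer required")
  }
  if (!all(is.finite(object@energies))) return("energies must be finite")
  nat <- length(object@elements)
  okdim <- vapply(object@coords, function(m) {
    is.matrix(m) && nrow(m) == nat && ncol(m) == 3L && all(is.finite(m))
  }, logical(1))
  if (!all(okdim)) return("each conformer needs a finite nAtom x 3 matrix")
  if (n > object@nRequested) {
    return("kept more conformers than requested")
  }
  TRUE
})
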