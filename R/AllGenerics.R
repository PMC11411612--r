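#' @include AllClasses.R
NULL

#' Access the record table of a DrugSet
#' @param x a [DrugSet] or [AnalysisSet]
#' @return a [S4Vectors::DataFrame] of compound records
#' @export
setGeneric("drugRecords", function(x) standardGeneric("drugRecords"))

#' @rdname drugRecords
#' @export
setMethod("drugRecords", "DrugSet", function(x) x@records)

#' Provenance of a compound set
#' @param x a [DrugSet]
#' @return list with source information and exclusion counts
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
#' @export
setMethod("provenance", "DrugSet", function(x) x@provenance)

#' Number of compounds in a set
#' @param x a [DrugSet]
#' @return integer count
#' @export
setGeneric("nCompounds", function(x) standardGeneric("nCompounds"))

#' @rdname nCompounds
#' @export
setMethod("nCompounds", "DrugSet", function(x) nrow(x@records))

#' Conformer count of an ensemble
#' @param x a [ConformerEnsemble]
#' @return integer number of kept conformers
#' @export
setGeneric("nConformers", function(x) standardGeneric("nConformers"))

#' @rdname nConformers
#' @export
setMethod("nConformers", "ConformerEnsemble", function(x) length(x@coords))

#' MMFF94 energies of an ensemble
#' @param x a [ConformerEnsemble]
#' @return numeric vector, kcal/mol
#' @export
setGeneric("conformerEnergies", function(x) standardGeneric("conformerEnergies"))

#' @rdname conformerEnergies
#' @export
setMethod("conformerEnergies", "ConformerEnsemble", function(x) x@energies)

#' Conformer coordinates
#' @param x a [ConformerEnsemble]
#' @return list of nAtom x 3 matrices (Angstrom)
#' @export
setGeneric("conformerCoords", function(x) standardGeneric("conformerCoords"))

#' @rdname conformerCoords
#' @export
setMethod("conformerCoords", "ConformerEnsemble", function(x) x@coords)

setMethod("show", "DrugSet", function(object) {
  rec <- object@records
  cat(class(object), "with", nrow(rec), "compounds\n")
  if (nrow(rec)) {
    cat("  years:", min(rec$approval_year), "-", max(rec$approval_year), "\n")
    cat("  excluded:", sum(rec$excluded), "\n")
  }
  src <- object@provenance$source
  if (!is.null(src)) cat("  source:", src, "\n")
})

setMethod("show", "ConformerEnsemble", function(object) {
  cat("ConformerEnsemble for", object@id, "\n")
  cat("  atoms:", length(object@elements),
      " conformers:", length(object@coords),
      "(requested", paste0(object@nRequested, ")"), "\n")
  cat("  energy range:", sprintf("%.3f .. %.3f kcal/mol",
      min(object@energies), max(object@energies)), "\n")
  cat("  optimised:", isTRUE(object@meta$optimised), "\n")
})
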