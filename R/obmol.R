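# Thin interface to the OpenBabel layer (ChemmineOB in-process, obabel /
# obenergy CLI for 3D work). Everything downstream works with either raw
# SMILES vectors or the molecular graphs produced here.

#' Canonicalise SMILES
#'
#' Returns the OpenBabel canonical SMILES for each input, or `NA` for
#' strings that do not parse to a valid molecule.
#'
#' @param smiles character vector of SMILES strings
#' @return character vector, `NA` where parsing failed
#' @export
canonicalSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- suppressWarnings(
      tryCatch(ChemmineOB::convertFormat("SMI", "CAN", source = s),
               error = function(e) "")
    )
    out <- sub("[\t\n ].*$", "", out)
    if (nzchar(out)) out else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# List of OBMol references for *valid* SMILES (caller must pre-validate;
# OpenBabel silently drops unparseable entries which would misalign a
# batch).
obMolecules <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  if (length(mols) != length(smiles)) {
    stop("OpenBabel dropped ", length(smiles) - length(mols),
         " unparseable SMILES; validate with canonicalSmiles() first")
  }
  mols
}

# Count of unique SMARTS matches per molecule (deduplicated by matched
# atom set). `mols` is the result of obMolecules().
smartsCount <- function(mols, smarts) {
  ChemmineOB::smartsSearch_OB(mols, smarts, uniqueMatches = TRUE)
}

# OpenBabel whole-molecule properties (MW, logP, HBD, HBA1, TPSA, ...)
# as a data.frame with one row per molecule.
obProperties <- function(mols) {
  rows <- lapply(mols, ChemmineOB::prop_OB)
  do.call(rbind, rows)
}

# Heavy-atom molecular graph from OpenBabel MOL2 output: element symbols,
# bond table with aromatic flags, and (optionally) explicit hydrogens.
# No R package reads MOL2, so the two fixed-format TRIPOS blocks are
# parsed here directly.
molecularGraph <- function(smiles, addHydrogens = FALSE) {
  txt <- suppressWarnings(tryCatch({
    if (addHydrogens) {
      ChemmineOB::convertFormat("SMI", "MOL2", source = smiles,
                                options = data.frame(names = "h",
                                                     args = ""))
    } else {
      ChemmineOB::convertFormat("SMI", "MOL2", source = smiles)
    }
  }, error = function(e) ""))
  if (!nzchar(txt)) stop(descriptorFailure(paste0("SMILES failed to parse: ", smiles)))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  aStart <- grep("^@<TRIPOS>ATOM", lines)[1]
  bStart <- grep("^@<TRIPOS>BOND", lines)[1]
  ends <- c(grep("^@<TRIPOS>", lines), length(lines) + 1L)
  aEnd <- min(ends[ends > aStart]) - 1L
  bEnd <- min(ends[ends > bStart]) - 1L
  atomLines <- lines[(aStart + 1L):aEnd]
  atomLines <- atomLines[nzchar(trimws(atomLines))]
  atomFields <- strsplit(trimws(atomLines), "[[:space:]]+")
  type <- vapply(atomFields, `[`, character(1), 6L)
  element <- sub("\\..*$", "", type)
  bonds <- if (bEnd > bStart) {
    bl <- lines[(bStart + 1L):bEnd]
    bl <- bl[nzchar(trimws(bl))]
    bf <- strsplit(trimws(bl), "[[:space:]]+")
    data.frame(
      a1 = as.integer(vapply(bf, `[`, character(1), 2L)),
      a2 = as.integer(vapply(bf, `[`, character(1), 3L)),
      type = vapply(bf, `[`, character(1), 4L)
    )
  } else {
    data.frame(a1 = integer(), a2 = integer(), type = character())
  }
  bonds$aromatic <- bonds$type == "ar"
  list(elements = element, bonds = bonds, nAtoms = length(element))
}

# system2 wrapper for obabel with error capture.
runObabel <- function(args) {
  .checkTool("obabel")
  out <- suppressWarnings(
    system2("obabel", args = args, stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("obabel failed (exit ", status, "): ",
         paste(utils::tail(out, 3), collapse = " | "))
  }
  invisible(out)
}

# MMFF94 total energies (kcal/mol) for every record of an SDF file.
mmff94Energies <- function(sdfPath) {
  .checkTool("obenergy")
  out <- suppressWarnings(
    system2("obenergy", args = c("-ff", "MMFF94", shQuote(sdfPath)),
            stdout = TRUE, stderr = FALSE)
  )
  en <- grep("TOTAL ENERGY", out, value = TRUE)
  if (!length(en)) {
    stop("MMFF94 could not be set up for ", sdfPath,
         " (missing parameters)")
  }
  vals <- as.numeric(sub(".*=\\s*([-0-9.eE+]+)\\s*kcal/mol.*", "\\1", en))
  if (anyNA(vals)) stop("could not parse MMFF94 energies from obenergy output")
  vals
}
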