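#' @include AllGenerics.R obmol.R
NULL

.defaultColumns <- function() {
  list(id = "id", name = "name", smiles = "smiles",
       approval_year = "approval_year", indication = "indication",
       excluded = "excluded", exclusion_reason = "exclusion_reason")
}

# Keep the largest carbon-containing fragment of a multi-component
# (salt/solvate) SMILES. Returns list(smiles=, stripped=).
.largestOrganicFragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) <= 1L) return(list(smiles = smiles, stripped = FALSE))
  can <- canonicalSmiles(frags)
  if (anyNA(can)) return(list(smiles = smiles, stripped = FALSE))
  mols <- obMolecules(frags)
  heavy <- smartsCount(mols, "[!#1]")
  carbon <- smartsCount(mols, "[#6]")
  cand <- if (any(carbon > 0)) which(carbon > 0) else seq_along(frags)
  pick <- cand[which.max(heavy[cand])]
  list(smiles = frags[pick], stripped = TRUE)
}

#' Read a compound approval table from CSV
#'
#' Parses a CSV of drug approvals into a [DrugSet]. Each row must carry an
#' identifier, a SMILES string and an approval year; name, indication and
#' exclusion flags are optional. SMILES are validated and canonicalised
#' with OpenBabel; rows that fail to parse are kept but flagged as
#' excluded with reason `"descriptor-failure"` rather than dropped.
#' Multi-component SMILES (salts/solvates) are reduced to their largest
#' carbon-containing fragment before canonicalisation, and the reduction
#' is recorded per compound in the `fragment_stripped` column.
#'
#' @param path path to a UTF-8 CSV file with a header row
#' @param columns named list mapping the logical column roles
#'   (`id`, `name`, `smiles`, `approval_year`, `indication`, `excluded`,
#'   `exclusion_reason`) to the file's column names; defaults assume the
#'   roles are used verbatim as column names
#' @param yearRange two integers; rows outside this approval-year window
#'   raise an error
#' @return a [DrugSet]
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = c("d1", "d2"), smiles = c("CCO", "c1ccccc1"),
#'                      approval_year = c(2004L, 2015L)), tf, row.names = FALSE)
#' ds <- parseDataset(tf)
#' nCompounds(ds)
#' @export
parseDataset <- function(path, columns = .defaultColumns(),
                         yearRange = c(2000L, 2022L)) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  columns <- utils::modifyList(.defaultColumns(), as.list(columns))
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty dataset: ", path)
  need <- c("id", "smiles", "approval_year")
  for (role in need) {
    if (!columns[[role]] %in% colnames(raw)) {
      stop("required column '", columns[[role]], "' (role ", role,
           ") missing from ", path)
    }
  }
  pull <- function(role, default) {
    col <- columns[[role]]
    if (col %in% colnames(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  id <- as.character(raw[[columns$id]])
  smiles <- as.character(raw[[columns$smiles]])
  year <- as.integer(raw[[columns$approval_year]])
  name <- as.character(pull("name", NA_character_))
  indication <- as.character(pull("indication", "other"))
  excluded <- as.logical(pull("excluded", FALSE))
  excluded[is.na(excluded)] <- FALSE
  reason <- as.character(pull("exclusion_reason", NA_character_))
  reason[!excluded] <- NA_character_

  bad_year <- which(is.na(year) | year < yearRange[1] | year > yearRange[2])
  if (length(bad_year)) {
    stop("approval_year outside [", yearRange[1], ", ", yearRange[2],
         "] for id(s): ", paste(id[bad_year], collapse = ", "))
  }

  stripped <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    fr <- .largestOrganicFragment(smiles[i])
    if (fr$stripped) {
      smiles[i] <- fr$smiles
      stripped[i] <- TRUE
    }
  }
  can <- canonicalSmiles(smiles)
  failed <- is.na(can)
  if (any(failed)) {
    excluded[failed] <- TRUE
    reason[failed] <- "descriptor-failure"
  }

  rec <- DataFrame(
    id = id, name = name, smiles = as.character(raw[[columns$smiles]]),
    canonical_smiles = can, approval_year = year, indication = indication,
    excluded = excluded, exclusion_reason = reason,
    fragment_stripped = stripped
  )
  new("DrugSet", records = rec,
      provenance = list(source = path, n_parsed = nrow(rec),
                        n_smiles_failures = sum(failed)))
}

#' Apply exclusion flags to produce the analysis set
#'
#' Removes every record flagged `excluded` (gastrointestinal-acting
#' non-absorbed compounds, combinations of older drugs, and compounds
#' whose structures failed to parse), preserving the input order. The
#' counts per exclusion reason are recorded in the result's provenance.
#'
#' @param x a [DrugSet]
#' @return an [AnalysisSet]
#' @export
applyExclusions <- function(x) {
  stopifnot(is(x, "DrugSet"))
  rec <- drugRecords(x)
  keep <- !rec$excluded
  counts <- table(rec$exclusion_reason[!keep], useNA = "no")
  out <- rec[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("all records were excluded; the analysis set is empty")
  }
  prov <- c(provenance(x),
            list(n_excluded = sum(!keep),
                 exclusion_counts = as.list(counts)))
  new("AnalysisSet", records = out, provenance = prov)
}

#' Write an analysis set as an SDF structure file
#'
#' Emits one V2000 SDF record per compound (2D coordinates from the
#' structure generator) carrying `id`, `name` and `approval_year` as data
#' fields, so the set round-trips through any SDF reader.
#'
#' @param x an [AnalysisSet] (all SMILES valid)
#' @param path output file path
#' @return the path, invisibly
#' @export
writeStructures <- function(x, path) {
  stopifnot(is(x, "AnalysisSet"))
  rec <- drugRecords(x)
  if (nrow(rec) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  sdf <- ChemmineR::smiles2sdf(setNames(rec$canonical_smiles, rec$id))
  ChemmineR::datablock(sdf) <- data.frame(
    id = rec$id,
    name = ifelse(is.na(rec$name), "", rec$name),
    approval_year = rec$approval_year,
    stringsAsFactors = FALSE
  )
  ChemmineR::write.SDF(sdf, path)
  invisible(path)
}
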