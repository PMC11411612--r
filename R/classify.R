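#' @include descriptors2d.R
NULL

#' Default acidic group SMARTS patterns
#'
#' Carboxylic, sulfonic, sulfinic and phosphonic acids, acyl
#' sulfonamides and NH-tetrazoles. Each pattern is written so that one
#' ionisable group yields exactly one unique match, and the patterns are
#' mutually exclusive, so group counts can be summed across patterns.
#'
#' @return named character vector of SMARTS
#' @export
defaultAcidPatterns <- function() {
  c(
    carboxylic_acid = "[CX3](=[OX1])[OX2H1]",
    sulfonic_acid   = "[SX4](=[OX1])(=[OX1])[OX2H1]",
    sulfinic_acid   = "[SX3](=[OX1])[OX2H1]",
    phosphonic_acid = "[PX4](=[OX1])([OX2H1])[OX2H1]",
    acyl_sulfonamide = "[CX3](=[OX1])[NX3H1][SX4](=[OX1])=[OX1]",
    tetrazole       = "c1nnn[nH]1"
  )
}

#' Default basic group SMARTS patterns
#'
#' Aliphatic primary, secondary and tertiary amines (excluding amides,
#' thioamides, sulfonamides, anilines and amidine/guanidine nitrogens,
#' which are matched by their own group patterns or are non-basic),
#' amidines and guanidines. Patterns are mutually exclusive.
#'
#' @return named character vector of SMARTS
#' @export
defaultBasePatterns <- function() {
  excl <- paste0("!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[SX1]);",
                 "!$([NX3][CX3]=[NX2]);!$([NX3][SX4]);!$([NX3][a])")
  c(
    amine_primary   = sprintf("[NX3;H2;%s]", excl),
    amine_secondary = sprintf("[NX3;H1;%s]", excl),
    amine_tertiary  = sprintf("[NX3;H0;%s;!$([NX3+])]", excl),
    amidine   = "[CX3;!$([CX3](=[NX2])([NX3])[NX3])](=[NX2])[NX3]",
    guanidine = "[CX3](=[NX2])([NX3])[NX3]"
  )
}

#' Lipinski rule-of-5 assessment
#'
#' Flags each compound against the four rule-of-5 limits with strict
#' inequalities (MWt > 500 Da, clogP > 5, HBD > 5, HBA > 10); a compound
#' *fails* when two or more limits are exceeded. Boundary values (e.g.
#' MWt exactly 500) do not violate.
#'
#' @param descriptors output of [computeDescriptors()], or any data frame
#'   with columns `mwt`, `clogp`, `hbd`, `hba`
#' @return a [S4Vectors::DataFrame] with per-rule flags,
#'   `violation_count` (0-4) and `fails`
#' @export
lipinskiAssess <- function(descriptors) {
  d <- as.data.frame(descriptors)
  need <- c("mwt", "clogp", "hbd", "hba")
  stopifnot(all(need %in% colnames(d)))
  over_mwt <- d$mwt > 500
  over_clogp <- d$clogp > 5
  over_hbd <- d$hbd > 5
  over_hba <- d$hba > 10
  vc <- over_mwt + over_clogp + over_hbd + over_hba
  out <- DataFrame(over_mwt = over_mwt, over_clogp = over_clogp,
                   over_hbd = over_hbd, over_hba = over_hba,
                   violation_count = as.integer(vc), fails = vc >= 2)
  if ("id" %in% colnames(d)) out <- DataFrame(id = d$id, out)
  out
}

# Largest "smallest ring through a bond" in a heavy-atom graph: for each
# non-bridge edge, the shortest cycle containing it is 1 + the shortest
# path between its endpoints with the edge removed. This reproduces the
# smallest-ring semantics of ring-size SMARTS without depending on
# extended dialect support, and is immune to perimeter artefacts in
# fused systems (naphthalene's 10-atom perimeter is not a smallest ring).
maxSmallestRingSize <- function(edges, nAtoms) {
  if (nrow(edges) == 0L) return(0L)
  g <- igraph::make_graph(as.vector(t(edges[, 1:2, drop = FALSE])),
                          n = nAtoms, directed = FALSE)
  best <- 0L
  for (k in seq_len(nrow(edges))) {
    g2 <- igraph::delete_edges(g, k)
    d <- igraph::distances(g2, v = edges[k, 1], to = edges[k, 2])[1, 1]
    if (is.finite(d)) best <- max(best, as.integer(d) + 1L)
  }
  best
}

#' Macrocycle detection
#'
#' A molecule is macrocyclic when it contains a ring of 12 or more atoms,
#' judged on smallest rings (the 10-atom perimeter of naphthalene is not
#' a ring in this sense).
#'
#' @param smiles character vector of valid SMILES
#' @return logical vector
#' @examples
#' isMacrocycle(c("C1CCCCCCCCCCC1", "C1CCCCC1"))  # TRUE FALSE
#' @export
isMacrocycle <- function(smiles) {
  vapply(smiles, function(s) {
    g <- molecularGraph(s)
    maxSmallestRingSize(as.matrix(g$bonds[, c("a1", "a2")]), g$nAtoms) >= 12L
  }, logical(1), USE.NAMES = FALSE)
}

#' Ionisation class from acidic and basic group counts
#'
#' Counts acidic and basic groups by SMARTS matching and assigns each
#' compound a net-charge class: one net negative group is a monoacid, one
#' net positive a monobase, no ionisable groups neutral, balanced groups
#' zwitterion/other, and two or more net charges polyacid/polybase. The
#' shipped pattern sets are editable; matches are deduplicated by matched
#' atom set within a pattern and the patterns are constructed to be
#' mutually exclusive across groups.
#'
#' @param smiles character vector of valid SMILES (or a [DrugSet], whose
#'   canonical SMILES are used)
#' @param acidPatterns,basePatterns named SMARTS vectors; see
#'   [defaultAcidPatterns()] and [defaultBasePatterns()]
#' @return a [S4Vectors::DataFrame] with `acid_groups`, `base_groups`,
#'   `net_charge` and `net_class`
#' @examples
#' ionisationClass(c("CC(=O)O", "CCN", "CCO"))$net_class
#' @export
ionisationClass <- function(smiles, acidPatterns = defaultAcidPatterns(),
                            basePatterns = defaultBasePatterns()) {
  if (is(smiles, "DrugSet")) smiles <- drugRecords(smiles)$canonical_smiles
  stopifnot(length(acidPatterns) >= 1L, length(basePatterns) >= 1L)
  mols <- obMolecules(smiles)
  countAll <- function(patterns) {
    m <- vapply(patterns, function(p) smartsCount(mols, p),
                numeric(length(smiles)))
    if (length(smiles) == 1L) m <- matrix(m, nrow = 1L)
    as.integer(rowSums(m))
  }
  acids <- countAll(acidPatterns)
  bases <- countAll(basePatterns)
  net <- bases - acids
  cls <- ifelse(acids == 0L & bases == 0L, "neutral",
         ifelse(net == 0L, "zwitterion",
         ifelse(net == -1L, "monoacid",
         ifelse(net == 1L, "monobase",
         ifelse(net < 0L, "polyacid", "polybase")))))
  DataFrame(acid_groups = acids, base_groups = bases,
            net_charge = as.integer(net),
            net_class = factor(cls, levels = c("monoacid", "monobase",
              "neutral", "zwitterion", "polyacid", "polybase")))
}

#' Percentile-derived property rules
#'
#' Re-derives rule-of-5-style limits from a dataset as the order
#' statistic of each descriptor at a chosen percentile (the original
#' limits were set near the 90th percentile of then-known oral drugs).
#'
#' @param descriptors output of [computeDescriptors()] (needs `mwt`,
#'   `clogp`, `hbd`, `hba`) with at least 2 compounds
#' @param percentile percentile in (0, 100), default 90
#' @param quantileType quantile rule passed to [stats::quantile()];
#'   the default 6 is the (n+1)p empirical quantile
#' @return a data.frame with the raw threshold and the value rounded to
#'   reporting precision (MWt and counts to integers, clogP to 1 decimal)
#' @export
derivePercentileRules <- function(descriptors, percentile = 90,
                                  quantileType = 6) {
  d <- as.data.frame(descriptors)
  need <- c("mwt", "clogp", "hbd", "hba")
  stopifnot(all(need %in% colnames(d)))
  d <- d[stats::complete.cases(d[, need]), need, drop = FALSE]
  if (nrow(d) < 2L) stop("at least 2 compounds with complete descriptors required")
  stopifnot(percentile > 0, percentile < 100)
  thr <- vapply(need, function(col) {
    unname(quantile(d[[col]], percentile / 100, type = quantileType))
  }, numeric(1))
  digits <- c(mwt = 0, clogp = 1, hbd = 0, hba = 0)
  data.frame(descriptor = need, threshold = unname(thr),
             printed = unname(round(thr, digits[need])),
             percentile = percentile, row.names = NULL)
}
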