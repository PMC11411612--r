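#' @include obmol.R AllGenerics.R
NULL

# SMARTS used for the count descriptors. Donors/acceptors follow the
# rule-of-5 convention (donor = N or O bearing at least one H, acceptor =
# any N or O); the pharmacophoric alternative is taken from OpenBabel's
# own HBD/HBA1 typing. The "loose" rotor is any single acyclic bond
# between non-terminal, non-triple-bonded heavy atoms; "strict"
# additionally excludes amide C-N bonds.
.SMARTS <- list(
  donor      = "[#7,#8;!H0]",
  acceptor   = "[#7,#8]",
  rotor_loose = "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]",
  amide_bond = "[NX3;!D1]-&!@[CX3;!D1]=[OX1]",
  carbon_sp3 = "[CX4]",
  carbon     = "[#6]",
  sp3_heavy  = "[^3]",
  aromatic   = "[a]",
  non_carbon = "[!#6;!#1]",
  heavy      = "[!#1]"
)

#' Descriptor convention configuration
#'
#' Pins the conventions that change the numerical value of the 2D
#' descriptors, so they can be recorded alongside results.
#'
#' @param hbond `"lipinski"` (donors = N/O atoms bearing H, acceptors =
#'   all N + O atoms; the convention the rule-of-5 thresholds were derived
#'   under) or `"pharmacophore"` (OpenBabel's pharmacophoric typing)
#' @param rotor `"strict"` (amide C-N bonds not rotatable) or `"loose"`
#' @param fsp3Denominator `"carbon"` (the standard Lovering definition,
#'   sp3 carbons / carbons) or `"heavy"` (sp3 heavy atoms / heavy atoms)
#' @return a named list of class `drugspace_conventions`
#' @export
descriptorConventions <- function(hbond = c("lipinski", "pharmacophore"),
                                  rotor = c("strict", "loose"),
                                  fsp3Denominator = c("carbon", "heavy")) {
  out <- list(hbond = match.arg(hbond), rotor = match.arg(rotor),
              fsp3Denominator = match.arg(fsp3Denominator),
              clogp = "openbabel-atom-contribution")
  class(out) <- "drugspace_conventions"
  out
}

# Ring counts from the heavy-atom graph. The total ring count is the
# circuit rank (bonds - atoms + components), which equals the size of a
# smallest set of smallest rings; the aromatic ring count is the circuit
# rank of the aromatic-bond subgraph.
.ringCounts <- function(graph) {
  b <- graph$bonds
  n <- graph$nAtoms
  if (nrow(b) == 0L) return(c(ring_count = 0L, aromatic_rings = 0L))
  g <- igraph::make_graph(as.vector(rbind(b$a1, b$a2)), n = n,
                          directed = FALSE)
  ring <- as.integer(nrow(b) - n + igraph::components(g)$no)
  ar <- b[b$aromatic, , drop = FALSE]
  if (nrow(ar) == 0L) return(c(ring_count = ring, aromatic_rings = 0L))
  arv <- unique(c(ar$a1, ar$a2))
  ga <- igraph::make_graph(as.vector(rbind(match(ar$a1, arv),
                                           match(ar$a2, arv))),
                           n = length(arv), directed = FALSE)
  arRing <- as.integer(nrow(ar) - length(arv) + igraph::components(ga)$no)
  c(ring_count = ring, aromatic_rings = arRing)
}

# Constitutional stereocentre estimate: tetra-coordinated carbons whose
# four branches are pairwise distinct under Weisfeiler-Lehman colour
# refinement of the hydrogen-explicit graph. Counts atoms where chirality
# is possible by connectivity, whether or not it is assigned; stereocentres
# that depend on the configuration of other centres (meso cases) are not
# resolved.
.stereocentreCount <- function(smiles) {
  g <- molecularGraph(smiles, addHydrogens = TRUE)
  n <- g$nAtoms
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg <- lengths(adj)
  col <- match(paste(g$elements, deg), unique(paste(g$elements, deg)))
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      paste(col[i], paste(sort(col[adj[[i]]]), collapse = ","))
    }, character(1))
    newcol <- match(sig, unique(sig))
    if (length(unique(newcol)) == length(unique(col))) break
    col <- newcol
  }
  cand <- which(g$elements == "C" & deg == 4L)
  sum(vapply(cand, function(i) {
    anyDuplicated(col[adj[[i]]]) == 0L
  }, logical(1)))
}

#' Fraction of sp3 carbons
#'
#' Fsp3 of a molecule: sp3-hybridised carbons over all carbons by
#' default, or sp3 heavy atoms over all heavy atoms with
#' `denominator = "heavy"`.
#'
#' @param smiles character vector of valid SMILES
#' @param denominator `"carbon"` or `"heavy"`
#' @return numeric vector in \[0, 1\]
#' @examples
#' fsp3(c("C1CCCCC1", "c1ccccc1", "CCc1ccccc1"))  # 1, 0, 0.25
#' @export
fsp3 <- function(smiles, denominator = c("carbon", "heavy")) {
  denominator <- match.arg(denominator)
  mols <- obMolecules(smiles)
  if (denominator == "carbon") {
    num <- smartsCount(mols, .SMARTS$carbon_sp3)
    den <- smartsCount(mols, .SMARTS$carbon)
    if (any(den == 0)) {
      stop("Fsp3 is undefined for molecules with no carbon atoms: ",
           paste(smiles[den == 0], collapse = ", "))
    }
  } else {
    num <- smartsCount(mols, .SMARTS$sp3_heavy)
    den <- smartsCount(mols, .SMARTS$heavy)
  }
  num / den
}

#' Compute the 2D descriptor table
#'
#' One row per compound: molecular weight (Da), calculated logP
#' (atom-contribution estimate), hydrogen-bond donor and acceptor counts,
#' rotatable bonds, aromatic ring count, Fsp3, constitutional
#' stereocentres, ring count, non-carbon and aromatic heavy-atom counts.
#' Deterministic for a fixed molecule and convention configuration; the
#' conventions used are stored in `metadata()$conventions`.
#'
#' Compounds whose SMILES cannot be processed get an all-`NA` row with
#' `descriptor_failure = TRUE` rather than aborting the table.
#'
#' @param x an [AnalysisSet], [DrugSet], or character vector of SMILES
#' @param conventions a [descriptorConventions()] object
#' @return a [S4Vectors::DataFrame] with one row per compound
#' @examples
#' d <- computeDescriptors(c(ethanol = "CCO", benzene = "c1ccccc1"))
#' d$hbd   # 1 0
#' @export
computeDescriptors <- function(x, conventions = descriptorConventions()) {
  if (is(x, "DrugSet")) {
    rec <- drugRecords(x)
    smiles <- rec$canonical_smiles
    ids <- rec$id
  } else {
    smiles <- canonicalSmiles(as.character(x))
    ids <- if (!is.null(names(x))) names(x) else
      paste0("mol", seq_along(smiles))
  }
  n <- length(smiles)
  if (n == 0L) stop("no compounds to compute descriptors for")
  ok <- !is.na(smiles)

  cols <- c("mwt", "clogp", "hbd", "hba", "rotatable_bonds",
            "aromatic_rings", "fsp3", "stereocentres", "ring_count",
            "non_carbon_atoms", "aromatic_atoms", "heavy_atoms")
  out <- as.data.frame(matrix(NA_real_, n, length(cols),
                              dimnames = list(NULL, cols)))

  if (any(ok)) {
    sm <- smiles[ok]
    mols <- obMolecules(sm)
    props <- obProperties(mols)
    loose <- smartsCount(mols, .SMARTS$rotor_loose)
    rb <- if (conventions$rotor == "strict") {
      loose - smartsCount(mols, .SMARTS$amide_bond)
    } else loose
    if (conventions$hbond == "lipinski") {
      hbd <- smartsCount(mols, .SMARTS$donor)
      hba <- smartsCount(mols, .SMARTS$acceptor)
    } else {
      hbd <- props$HBD
      hba <- props$HBA1
    }
    carbons <- smartsCount(mols, .SMARTS$carbon)
    f3 <- if (conventions$fsp3Denominator == "carbon") {
      ifelse(carbons > 0, smartsCount(mols, .SMARTS$carbon_sp3) / carbons, NA)
    } else {
      smartsCount(mols, .SMARTS$sp3_heavy) /
        smartsCount(mols, .SMARTS$heavy)
    }
    rings <- t(vapply(sm, function(s) .ringCounts(molecularGraph(s)),
                      c(ring_count = 0L, aromatic_rings = 0L)))
    stereo <- vapply(sm, .stereocentreCount, integer(1))
    out[ok, ] <- data.frame(
      mwt = props$MW, clogp = props$logP, hbd = hbd, hba = hba,
      rotatable_bonds = rb, aromatic_rings = rings[, "aromatic_rings"],
      fsp3 = f3, stereocentres = stereo, ring_count = rings[, "ring_count"],
      non_carbon_atoms = smartsCount(mols, .SMARTS$non_carbon),
      aromatic_atoms = smartsCount(mols, .SMARTS$aromatic),
      heavy_atoms = smartsCount(mols, .SMARTS$heavy)
    )
  }
  res <- DataFrame(id = ids, out, descriptor_failure = !ok)
  metadata(res) <- list(conventions = conventions)
  res
}
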