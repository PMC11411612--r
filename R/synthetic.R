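#' @include classify.R dataset-io.R
NULL

# Fragment grammar. Ring labels A/B are rewritten to unique %nn ring
# closure numbers at assembly time so fragments can nest arbitrarily;
# "({})" marks substitution slots (unused slots are deleted). Masses are
# rough fragment contributions used only to steer assembly towards a
# target molecular weight; the realised weight is always recomputed.
.GRAMMAR <- list(
  scaffolds = data.frame(
    smiles = c("c~cc({})cc({})c~", "c~ccnc({})c~", "c~cnc({})nc~",
               "c~cc({})cs~", "C~CC({})CC({})C~", "C~CCOC({})C~",
               "c~ccc&cc({})ccc&c~", "C~CC(=O)NC({})C~"),
    mw = c(76, 77, 78, 82, 82, 84, 126, 97),
    logp = c(1.7, 1.2, 0.7, 1.8, 2.3, 1.1, 3.1, -0.3),
    stringsAsFactors = FALSE
  ),
  macrocycles = data.frame(
    smiles = c("C~CCC({})CCCCCCCC~", "O~C(=O)CCCCC({})CCCC~",
               "C~CCC({})CCNC(=O)CCCC~"),
    mw = c(166, 184, 195),
    logp = c(4.5, 3.0, 2.2),
    stringsAsFactors = FALSE
  ),
  linkers = data.frame(
    smiles = c("", "C", "CC", "O", "OC", "C(=O)N", "S(=O)(=O)N", "C#C",
               "C(=O)NCC(=O)N"),
    mw = c(0, 14, 28, 16, 30, 43, 79, 24, 114),
    logp = c(0, 0.5, 1.0, -0.2, 0.2, -0.6, -1.0, 0.3, -1.8),
    stringsAsFactors = FALSE
  ),
  polar = data.frame(
    smiles = c("O", "OC", "OCC", "C(N)=O", "NC(C)=O", "C#N",
               "S(C)(=O)=O", "F", "CO", "NC(N)=O", "S(N)(=O)=O",
               "C(=O)NC", "OCCO"),
    mw = c(17, 31, 45, 44, 58, 26, 79, 19, 31, 59, 80, 57, 61),
    logp = c(-0.4, 0, 0.4, -0.9, -0.7, -0.2, -1.3, 0.2, -0.6, -1.1,
             -1.2, -0.7, -0.8),
    stringsAsFactors = FALSE
  ),
  lipophilic = data.frame(
    smiles = c("Cl", "Br", "C(F)(F)F", "C", "CC", "C(C)C", "CCC",
               "-c~ccccc~", "OC(F)(F)F"),
    mw = c(35, 80, 69, 15, 29, 43, 43, 77, 85),
    logp = c(0.7, 0.9, 1.0, 0.5, 1.0, 1.4, 1.5, 1.9, 1.0),
    stringsAsFactors = FALSE
  ),
  acids = data.frame(
    smiles = c("C(=O)O", "CC(=O)O", "OCC(=O)O", "S(=O)(=O)O",
               "-c~nnn[nH]~"),
    mw = c(45, 59, 75, 81, 68),
    logp = c(-0.1, -0.2, -0.4, -1.5, -0.5),
    stringsAsFactors = FALSE
  ),
  bases = data.frame(
    smiles = c("CN", "CCN", "CN(C)C", "N~CCNCC~"),
    mw = c(30, 44, 58, 85),
    logp = c(-0.3, 0.1, 0.2, -0.5),
    stringsAsFactors = FALSE
  )
)

#' Specification for the synthetic compound library generator
#'
#' Defines the study conditions the generator emulates: library size,
#' target descriptor means/SDs, the macrocycle fraction, the ionisation
#' class mix, the approval-year window and the per-period rule-of-5 fail
#' rates. Defaults describe a 371-compound oral-drug-like library (mean
#' MWt 432, SD 159; clogP 3.4; ~3% macrocyclic; period fail rates
#' 12/20/18%).
#'
#' @param n library size
#' @param seed integer RNG seed; the same spec always yields the same
#'   SMILES list
#' @param mwtMean,mwtSD,clogpMean,clogpSD,hbdMean,hbdSD,hbaMean,hbaSD,rbMean,rbSD
#'   target descriptor moments
#' @param fractionMacrocyclic fraction of compounds with a >= 12-membered
#'   ring
#' @param ionisationFractions named fractions for monoacid, monobase,
#'   neutral and zwitterion classes; must sum to 1
#' @param yearRange approval-year window
#' @param binWeights sampling weight of each approval period
#' @param binFailRates target Lipinski fail rate per period
#' @param tolerance relative tolerance on realised vs target moments
#'   (checked for MWt; realised moments are recorded in provenance)
#' @return a list of class `drugspace_generator_spec`
#' @export
generatorSpec <- function(n = 371L, seed = 1L,
                          mwtMean = 432, mwtSD = 159,
                          clogpMean = 3.4, clogpSD = 2.1,
                          hbdMean = 1.9, hbdSD = 1.3,
                          hbaMean = 5.8, hbaSD = 2.7,
                          rbMean = 6, rbSD = 4,
                          fractionMacrocyclic = 10 / 371,
                          ionisationFractions = c(monoacid = 0.15,
                            monobase = 0.30, neutral = 0.50,
                            zwitterion = 0.05),
                          yearRange = c(2000L, 2022L),
                          binWeights = c(`2000-2009` = 0.29,
                            `2010-2019` = 0.51, `2020-2022` = 0.20),
                          binFailRates = c(`2000-2009` = 0.12,
                            `2010-2019` = 0.20, `2020-2022` = 0.18),
                          tolerance = 0.10) {
  spec <- as.list(environment())
  if (n < 1L) stop("n must be at least 1")
  fr <- ionisationFractions
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-8) {
    stop("ionisationFractions must lie in [0,1] and sum to 1")
  }
  if (fractionMacrocyclic < 0 || fractionMacrocyclic > 1) {
    stop("fractionMacrocyclic must lie in [0,1]")
  }
  if (any(binFailRates < 0) || any(binFailRates > 1)) {
    stop("binFailRates must lie in [0,1]")
  }
  # crude feasibility screen: the grammar cannot build molecules much
  # below ~180 Da, nor satisfy a heteroatom load incompatible with the
  # mass budget
  if (mwtMean < 180 || mwtMean < 25 * hbaMean) {
    stop("infeasible generator spec: MWt target too small for the ",
         "requested composition")
  }
  class(spec) <- "drugspace_generator_spec"
  spec
}

# Instantiate a fragment: assign fresh %nn ring-closure labels.
.instantiate <- function(tmpl, counter) {
  for (L in c("~", "&")) {
    if (grepl(L, tmpl, fixed = TRUE)) {
      lab <- sprintf("%%%d", counter$i)
      counter$i <- counter$i + 1L
      if (counter$i > 98L) counter$i <- 10L
      tmpl <- gsub(L, lab, tmpl, fixed = TRUE)
    }
  }
  tmpl
}

.fillSlot <- function(mol, frag) {
  sub("({})", paste0("(", frag, ")"), mol, fixed = TRUE)
}

.nSlots <- function(mol) {
  lengths(regmatches(mol, gregexpr("({})", mol, fixed = TRUE)))
}

.pickRow <- function(df) df[sample.int(nrow(df), 1L), , drop = FALSE]

# Assemble one candidate SMILES for the planted labels. Returns a string
# that still needs validation. A crude per-fragment logP tally steers
# substituent choice towards the per-molecule lipophilicity target.
.assembleCandidate <- function(targetMW, targetLogP, fail, macro, ionClass) {
  counter <- new.env()
  counter$i <- 10L
  g <- .GRAMMAR
  first <- if (macro) .pickRow(g$macrocycles) else .pickRow(g$scaffolds)
  # (scaffold/linker pools for the chain are set below once `fail` is known)
  mol <- .instantiate(first$smiles, counter)
  mw <- first$mw
  lp <- first$logp
  nUnits <- 1L
  linkerPool <- if (fail) g$linkers else {
    rbind(g$linkers[g$linkers$smiles != "C(=O)NCC(=O)N", ],
          g$linkers[g$linkers$smiles %in%
            c("C(=O)N", "O", "OC", "S(=O)(=O)N"), ])
  }
  scaffoldPool <- if (fail) g$scaffolds else {
    rbind(g$scaffolds, g$scaffolds[g$scaffolds$logp <= 1.2, ])
  }
  while (mw < targetMW - 140 && nUnits < 7L && .nSlots(mol) > 0L) {
    lk <- .pickRow(linkerPool)
    sc <- .pickRow(scaffoldPool)
    mol <- .fillSlot(mol, paste0(lk$smiles, .instantiate(sc$smiles, counter)))
    mw <- mw + lk$mw + sc$mw
    lp <- lp + lk$logp + sc$logp
    nUnits <- nUnits + 1L
  }
  groups <- switch(ionClass,
    monoacid = list(g$acids), monobase = list(g$bases),
    zwitterion = list(g$acids, g$bases), neutral = list())
  for (pool in groups) {
    if (.nSlots(mol) == 0L) return(NA_character_)
    pick <- .pickRow(pool)
    mol <- .fillSlot(mol, .instantiate(pick$smiles, counter))
    mw <- mw + pick$mw
    lp <- lp + pick$logp
  }
  while (.nSlots(mol) > 0L && mw < targetMW - 20) {
    pool <- if (lp < targetLogP) g$lipophilic else g$polar
    pick <- .pickRow(pool)
    mol <- .fillSlot(mol, .instantiate(pick$smiles, counter))
    mw <- mw + pick$mw
    lp <- lp + pick$logp
  }
  gsub("({})", "", mol, fixed = TRUE)
}

# Fast rule-of-5 check used by the rejection loop.
.quickRo5 <- function(smiles) {
  mols <- obMolecules(smiles)
  props <- obProperties(mols)
  data.frame(
    mwt = props$MW, clogp = props$logP,
    hbd = smartsCount(mols, .SMARTS$donor),
    hba = smartsCount(mols, .SMARTS$acceptor)
  )
}

#' Generate a synthetic compound library with planted ground truth
#'
#' Assembles `spec$n` chemically valid, unique molecules from a curated
#' fragment grammar (ring scaffolds x linkers x substituents, with
#' optional macrocyclisation), planting per compound: the approval
#' period and year, the Lipinski verdict (sampled at the period's target
#' fail rate and enforced by rejection against the real descriptor
#' pipeline), macrocyclic character, and ionisation class. The planted
#' labels are returned in the provenance so recovery can be tested
#' against pipeline output.
#'
#' @param spec a [generatorSpec()]
#' @return a [DrugSet]; `provenance(x)$planted` holds the planted labels
#'   and `provenance(x)$realised` the realised descriptor means
#' @export
generateLibrary <- function(spec = generatorSpec()) {
  stopifnot(inherits(spec, "drugspace_generator_spec"))
  withSeed(spec$seed, {
    n <- spec$n
    binNames <- names(spec$binWeights)
    binRanges <- list(c(2000L, 2009L), c(2010L, 2019L), c(2020L, 2022L))
    binRanges <- lapply(binRanges, function(r) {
      c(max(r[1], spec$yearRange[1]), min(r[2], spec$yearRange[2]))
    })
    usable <- vapply(binRanges, function(r) r[1] <= r[2], logical(1))
    if (!any(usable)) stop("yearRange overlaps no approval period")
    w <- spec$binWeights * usable
    bin <- sample.int(length(binNames), n, replace = TRUE, prob = w)
    year <- vapply(bin, function(b) {
      r <- binRanges[[b]]
      as.integer(sample(seq(r[1], r[2]), 1L))
    }, integer(1))
    fail <- stats::runif(n) < spec$binFailRates[bin]
    macro <- stats::runif(n) < spec$fractionMacrocyclic
    ion <- sample(names(spec$ionisationFractions), n, replace = TRUE,
                  prob = spec$ionisationFractions)

    smiles <- character(n)
    seen <- character(0)
    for (i in seq_len(n)) {
      done <- FALSE
      for (try in seq_len(200L)) {
        targetMW <- if (fail[i]) {
          max(530, stats::rnorm(1, 660, 140))
        } else {
          min(500, max(210, stats::rnorm(1, 420, 125)))
        }
        if (macro[i]) targetMW <- max(targetMW, 450)
        targetLogP <- if (fail[i]) {
          max(5.3, stats::rnorm(1, 6.0, 0.8))
        } else {
          min(4.6, max(-0.5, stats::rnorm(1, spec$clogpMean - 0.8,
                                          spec$clogpSD)))
        }
        cand <- .assembleCandidate(targetMW, targetLogP, fail[i],
                                   macro[i], ion[i])
        if (is.na(cand)) next
        can <- canonicalSmiles(cand)
        if (is.na(can) || can %in% seen) next
        d <- .quickRo5(can)
        verdict <- (d$mwt > 500) + (d$clogp > 5) + (d$hbd > 5) +
          (d$hba > 10) >= 2
        if (verdict != fail[i]) next
        # keep realised lipophilicity near the per-molecule draw so the
        # library-wide clogP distribution tracks the spec targets
        if (!fail[i] && abs(d$clogp - targetLogP) > 1.0) next
        if (fail[i] && d$clogp > 9) next
        if (isMacrocycle(can) != macro[i]) next
        if (as.character(ionisationClass(can)$net_class) != ion[i]) next
        smiles[i] <- can
        seen <- c(seen, can)
        done <- TRUE
        break
      }
      if (!done) {
        stop("infeasible generator spec: could not realise compound ", i,
             " (fail=", fail[i], ", macro=", macro[i], ", class=", ion[i],
             ") after 200 attempts")
      }
    }

    rec <- DataFrame(
      id = sprintf("SYN%04d", seq_len(n)),
      name = sprintf("synthetic-%04d", seq_len(n)),
      smiles = smiles, canonical_smiles = smiles,
      approval_year = year,
      indication = sample(.INDICATIONS, n, replace = TRUE),
      excluded = rep(FALSE, n),
      exclusion_reason = rep(NA_character_, n),
      fragment_stripped = rep(FALSE, n)
    )
    realised <- .quickRo5(smiles)
    relErr <- abs(mean(realised$mwt) - spec$mwtMean) / spec$mwtMean
    if (relErr > spec$tolerance) {
      warning(sprintf(
        "realised mean MWt %.0f deviates more than %.0f%% from target %.0f",
        mean(realised$mwt), 100 * spec$tolerance, spec$mwtMean))
    }
    planted <- data.frame(id = rec$id, period = binNames[bin],
                          fail = fail, macrocycle = macro,
                          ionisation = ion, stringsAsFactors = FALSE)
    new("DrugSet", records = rec,
        provenance = list(source = "synthetic fragment grammar",
                          spec = unclass(spec), planted = planted,
                          realised = colMeans(realised)))
  })
}

#' Hand-verified fixture molecules
#'
#' Small molecules whose descriptor values were derived by hand (atomic
#' mass sums, donor/acceptor counts, ring sizes) and are used as oracles
#' throughout the test suite.
#'
#' @return named list; each element has `smiles` and an `expect` list of
#'   hand-computed values
#' @export
fixtureMolecules <- function() {
  list(
    ethanol = list(smiles = "CCO", expect = list(
      mwt = 46.07, hbd = 1, hba = 1, rotatable_bonds = 0,
      aromatic_rings = 0, fsp3 = 1.0)),
    benzene = list(smiles = "c1ccccc1", expect = list(
      hbd = 0, hba = 0, aromatic_rings = 1, fsp3 = 0,
      aromatic_atoms = 6)),
    aspirin = list(smiles = "CC(=O)Oc1ccccc1C(=O)O", expect = list(
      hbd = 1, mwt = 180.16, hba = 4, aromatic_rings = 1)),
    cyclohexane = list(smiles = "C1CCCCC1", expect = list(
      fsp3 = 1.0, macrocycle = FALSE)),
    cyclododecane = list(smiles = "C1CCCCCCCCCCC1", expect = list(
      macrocycle = TRUE)),
    naphthalene = list(smiles = "c1ccc2ccccc2c1", expect = list(
      macrocycle = FALSE, aromatic_rings = 2, aromatic_atoms = 10)),
    acetic_acid = list(smiles = "CC(=O)O", expect = list(
      acid_groups = 1, base_groups = 0, net_class = "monoacid")),
    ethylamine = list(smiles = "CCN", expect = list(
      acid_groups = 0, base_groups = 1, net_class = "monobase")),
    ethylbenzene = list(smiles = "CCc1ccccc1", expect = list(
      fsp3 = 0.25))
  )
}
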