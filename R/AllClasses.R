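#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- isConstant
#' @importFrom IRanges IRanges CharacterList
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Ligand binding kinetics
#'
#' Holds the kinetic and concentration parameters of a reversible
#' protein--ligand equilibrium: association rate \eqn{k_{on}}
#' (M\eqn{^{-1}} min\eqn{^{-1}}), dissociation rate \eqn{k_{off}}
#' (min\eqn{^{-1}}), dissociation constant \eqn{K_D = k_{off}/k_{on}} (M),
#' and the ligand/protein concentrations (M) used in the exchange reaction.
#' Any parameter may be left `NA` when unknown; when all of `kOn`, `kOff`
#' and `KD` are given they must be mutually consistent.
#'
#' @slot kOn association rate constant, per molar per minute
#' @slot kOff dissociation rate constant, per minute
#' @slot KD equilibrium dissociation constant, molar
#' @slot ligandConc total ligand concentration, molar
#' @slot proteinConc total protein concentration, molar
#'
#' @seealso [bindingKinetics()], [observedExchangeRate()], [saturationCheck()]
#' @name BindingKinetics-class
#' @rdname BindingKinetics
#' @exportClass BindingKinetics
setClass("BindingKinetics",
  representation(
    kOn = "numeric", kOff = "numeric", KD = "numeric",
    ligandConc = "numeric", proteinConc = "numeric"
  ),
  prototype(
    kOn = NA_real_, kOff = NA_real_, KD = NA_real_,
    ligandConc = NA_real_, proteinConc = NA_real_
  )
)

setValidity("BindingKinetics", function(object) {
  msgs <- character()
  for (nm in c("kOn", "kOff", "KD", "ligandConc", "proteinConc")) {
    v <- slot(object, nm)
    if (length(v) != 1L)
      msgs <- c(msgs, sprintf("'%s' must have length 1", nm))
    else if (!is.na(v) && v < 0)
      msgs <- c(msgs, sprintf("'%s' must be non-negative, got %g", nm, v))
  }
  # rates and concentrations, when supplied, must be strictly positive
  # (zero ligand is expressed through ligandConc = 0, which is allowed)
  for (nm in c("kOn", "kOff", "KD")) {
    v <- slot(object, nm)
    if (length(v) == 1L && !is.na(v) && v == 0 && nm != "KD")
      msgs <- c(msgs, sprintf("'%s' must be strictly positive when supplied", nm))
  }
  if (!is.na(object@kOn) && !is.na(object@kOff) && !is.na(object@KD) &&
      object@KD > 0) {
    rel <- abs(object@KD - object@kOff / object@kOn) / object@KD
    if (rel >= 1e-9)
      msgs <- c(msgs, sprintf(
        "KD (%g) inconsistent with kOff/kOn (%g): relative error %.3g",
        object@KD, object@kOff / object@kOn, rel))
  }
  if (length(msgs)) msgs else TRUE
})

#' A mixing design for the deuterium-exchange reaction
#'
#' Describes the components pipetted into one exchange reaction: per
#' component a volume (uL), a solute concentration (any unit, carried
#' through linearly), a D2O fraction in \[0, 1\] and a solute name so
#' that distinct solutes are averaged independently.
#'
#' @slot volume component volumes in microlitres
#' @slot soluteConc per-component solute concentration
#' @slot d2oFraction per-component D2O fraction in \[0, 1\]
#' @slot solute per-component solute name ("" for pure diluent)
#' @seealso [mixDesign()], [mixConcentrations()]
#' @name MixDesign-class
#' @rdname MixDesign
#' @exportClass MixDesign
setClass("MixDesign",
  representation(
    volume = "numeric", soluteConc = "numeric",
    d2oFraction = "numeric", solute = "character"
  )
)

setValidity("MixDesign", function(object) {
  n <- length(object@volume)
  msgs <- character()
  if (length(object@soluteConc) != n || length(object@d2oFraction) != n ||
      length(object@solute) != n)
    msgs <- c(msgs, "all component vectors must have equal length")
  if (any(object@volume < 0)) msgs <- c(msgs, "volumes must be >= 0")
  if (any(object@soluteConc < 0)) msgs <- c(msgs, "concentrations must be >= 0")
  if (any(object@d2oFraction < 0 | object@d2oFraction > 1))
    msgs <- c(msgs, "D2O fractions must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' An exchange-competent amide site
#'
#' One backbone amide with its intrinsic exchange rate and its response to
#' ligand binding: `occluded` sites exchange at the observed rate of the
#' two-state binding model in the bound state; sites with
#' `allostericFactor != 1` have their intrinsic rate multiplied by that
#' factor in the bound state (conformational modulation without direct
#' ligand contact). A site cannot be both.
#'
#' @slot residueIndex 1-based position in the protein sequence
#' @slot kex intrinsic exchange rate, per minute
#' @slot occluded logical; shielded by bound ligand
#' @slot allostericFactor multiplicative modulation of `kex` in the bound
#'   conformation (1 = no effect)
#' @seealso [exchangeSite()], [simulateSiteUptake()]
#' @name ExchangeSite-class
#' @rdname ExchangeSite
#' @exportClass ExchangeSite
setClass("ExchangeSite",
  representation(
    residueIndex = "integer", kex = "numeric",
    occluded = "logical", allostericFactor = "numeric"
  ),
  prototype(occluded = FALSE, allostericFactor = 1)
)

setValidity("ExchangeSite", function(object) {
  msgs <- character()
  if (object@residueIndex < 1L) msgs <- c(msgs, "residueIndex must be >= 1")
  if (!(object@kex > 0)) msgs <- c(msgs, "kex must be > 0")
  if (!(object@allostericFactor > 0))
    msgs <- c(msgs, "allostericFactor must be > 0")
  if (object@occluded && object@allostericFactor != 1)
    msgs <- c(msgs,
      "a site cannot be both occluded and allosterically modulated")
  if (length(msgs)) msgs else TRUE
})

#' A set of proteolytic peptides with residue spans
#'
#' Wraps an [IRanges::IRanges] of 1-based inclusive residue spans whose
#' metadata columns carry the peptide sequence and the number of
#' exchange-observable backbone amides (see [exchangeableAmides()]).
#' Range names are the stable peptide identifiers.
#'
#' @slot ranges an `IRanges` with names (peptide ids) and mcols
#'   `sequence`, `nExchangeable`
#' @seealso [peptideSet()], [computeRDU()]
#' @name HDXPeptideSet-class
#' @rdname HDXPeptideSet
#' @exportClass HDXPeptideSet
setClass("HDXPeptideSet", representation(ranges = "IRanges"))

setValidity("HDXPeptideSet", function(object) {
  r <- object@ranges
  msgs <- character()
  if (is.null(names(r)) || anyDuplicated(names(r)))
    msgs <- c(msgs, "peptide ids (range names) must be present and unique")
  mc <- S4Vectors::mcols(r)
  if (is.null(mc) || !all(c("sequence", "nExchangeable") %in% colnames(mc)))
    return(c(msgs, "mcols must contain 'sequence' and 'nExchangeable'"))
  if (any(IRanges::start(r) < 1L)) msgs <- c(msgs, "peptide start must be >= 1")
  bad <- nchar(mc$sequence) != IRanges::width(r)
  if (any(bad))
    msgs <- c(msgs, sprintf(
      "sequence length must equal residue span width (peptides: %s)",
      paste(names(r)[bad], collapse = ", ")))
  if (any(mc$nExchangeable < 0L)) msgs <- c(msgs, "nExchangeable must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' A peptide-level deuterium uptake experiment
#'
#' Container pairing an [HDXPeptideSet] with a long-format table of
#' centroid uptake measurements: one row per (peptide, state, exposure)
#' with the uptake in Daltons and a replicate standard deviation.
#'
#' @slot peptides an [HDXPeptideSet]
#' @slot records a `DataFrame` with columns `peptide_id`, `state`,
#'   `exposure_min`, `uptake_da`, `sd_da`
#' @slot d2oFraction D2O fraction of the labelling buffer (used for the
#'   uptake ceiling check), default 0.9
#' @slot tolerance slack (Da per amide) allowed above the theoretical
#'   uptake ceiling before validity fails
#' @seealso [uptakeExperiment()], [readUptakeTable()], [differenceProfile()]
#' @name UptakeExperiment-class
#' @rdname UptakeExperiment
#' @exportClass UptakeExperiment
setClass("UptakeExperiment",
  representation(
    peptides = "HDXPeptideSet", records = "DataFrame",
    d2oFraction = "numeric", tolerance = "numeric"
  ),
  prototype(d2oFraction = 0.9, tolerance = 0.1)
)

setValidity("UptakeExperiment", function(object) {
  req <- c("peptide_id", "state", "exposure_min", "uptake_da", "sd_da")
  rec <- object@records
  msgs <- character()
  if (!all(req %in% colnames(rec)))
    return(sprintf("records must contain columns: %s",
                   paste(setdiff(req, colnames(rec)), collapse = ", ")))
  unknown <- setdiff(unique(rec$peptide_id), peptideIds(object@peptides))
  if (length(unknown))
    msgs <- c(msgs, sprintf("records reference unknown peptide ids: %s",
                            paste(unknown, collapse = ", ")))
  if (any(rec$exposure_min < 0)) msgs <- c(msgs, "exposure_min must be >= 0")
  if (any(rec$uptake_da < 0)) msgs <- c(msgs, "uptake_da must be >= 0")
  if (any(rec$sd_da < 0)) msgs <- c(msgs, "sd_da must be >= 0")
  if (!(object@d2oFraction > 0 && object@d2oFraction <= 1))
    msgs <- c(msgs, "d2oFraction must lie in (0, 1]")
  if (length(unknown) == 0L && nrow(rec) > 0L) {
    nex <- nExchangeable(object@peptides)[rec$peptide_id]
    ceiling_da <- nex * object@d2oFraction + object@tolerance * pmax(nex, 1)
    over <- rec$uptake_da > ceiling_da
    if (any(over))
      msgs <- c(msgs, sprintf(
        "uptake exceeds n_exchangeable x D2O fraction (+tolerance) for: %s",
        paste(unique(rec$peptide_id[over]), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' An apo-vs-bound difference profile
#'
#' Per (peptide, exposure) differences in centroid uptake,
#' \eqn{\Delta = apo - bound} (positive = protection, i.e. decreased
#' exchange in the bound state), together with the per-peptide
#' significance call under a fixed Dalton threshold.
#'
#' @slot states character(2): the apo and bound state labels compared
#' @slot deltas `DataFrame` with `peptide_id`, `exposure_min`,
#'   `delta_da` and `zscore` (delta over the pooled replicate SD; a
#'   diagnostic, not used for the significance call)
#' @slot peptideCalls `DataFrame` with one row per peptide: `peptide_id`,
#'   `start`, `end`, `significant`, `direction`, `maxAbsDelta`,
#'   `nExceeding`, `maxAbsZ`
#' @slot thresholdDa significance threshold in Daltons
#' @slot minTimepoints exposures required beyond threshold
#' @seealso [differenceProfile()], [mergeRegions()]
#' @name DifferenceProfile-class
#' @rdname DifferenceProfile
#' @exportClass DifferenceProfile
setClass("DifferenceProfile",
  representation(
    states = "character", deltas = "DataFrame", peptideCalls = "DataFrame",
    thresholdDa = "numeric", minTimepoints = "integer"
  )
)

#' A set of merged response regions
#'
#' Residue intervals of ligand response, with per-exposure maximum
#' absolute uptake differences, member peptides, and (after
#' classification) an orthosteric/allosteric label with supporting
#' contact residues. [mergeRegions()] output is always pairwise
#' non-overlapping; sets built directly from a published catalogue may
#' contain overlapping intervals as printed.
#'
#' @slot regions an `IRanges`; mcols: `direction`
#'   (protection/deprotection/mixed), `maxDelta` (Da, max over exposures),
#'   `peptideIds` (`CharacterList`), `label`
#'   (orthosteric/allosteric/`NA`), `contactResidues` (`IntegerList`)
#' @slot deltaByExposure numeric matrix, regions x exposures, of maximum
#'   absolute uptake difference (Da)
#' @slot thresholdDa the significance threshold the regions derive from
#' @seealso [mergeRegions()], [classifyRegions()]
#' @name ResponseRegionSet-class
#' @rdname ResponseRegionSet
#' @exportClass ResponseRegionSet
setClass("ResponseRegionSet",
  representation(
    regions = "IRanges", deltaByExposure = "matrix", thresholdDa = "numeric"
  )
)

setValidity("ResponseRegionSet", function(object) {
  r <- object@regions
  msgs <- character()
  need <- c("direction", "maxDelta", "peptideIds", "label")
  if (!all(need %in% colnames(S4Vectors::mcols(r))))
    return(sprintf("regions mcols must contain: %s",
                   paste(need, collapse = ", ")))
  # NOTE: intervals are NOT required to be pairwise disjoint here:
  # published region catalogues can overlap (e.g. a narrow region
  # printed inside a wider one). mergeRegions() guarantees disjoint
  # output; that is a postcondition of merging, not of the container.
  if (nrow(object@deltaByExposure) != length(r))
    msgs <- c(msgs, "deltaByExposure must have one row per region")
  if (length(msgs)) msgs else TRUE
})

#' Ligand-contact residues of a structure
#'
#' Residues of the protein with at least one (heavy) atom within
#' `cutoffA` Angstroms of any ligand atom, with the per-residue minimum
#' protein-atom-to-ligand-atom distance. A distance exactly equal to the
#' cutoff counts as a contact (the distal definition is strictly
#' greater-than).
#'
#' @slot cutoffA distance cutoff in Angstroms (default 4.0)
#' @slot table `DataFrame` with `residue` (sequence coordinate, offset
#'   applied), `resid` (three-letter residue name) and `minDistanceA`
#'   for contact residues only, ordered by residue
#' @seealso [contactResidues()], [classifyRegions()]
#' @name ContactSet-class
#' @rdname ContactSet
#' @exportClass ContactSet
setClass("ContactSet",
  representation(cutoffA = "numeric", table = "DataFrame")
)

setValidity("ContactSet", function(object) {
  msgs <- character()
  if (!(object@cutoffA > 0)) msgs <- c(msgs, "cutoffA must be > 0")
  if (!all(c("residue", "minDistanceA") %in% colnames(object@table)))
    return(c(msgs, "table must contain 'residue' and 'minDistanceA'"))
  if (nrow(object@table) &&
      any(object@table$minDistanceA > object@cutoffA + 1e-9))
    msgs <- c(msgs, "all member residues must have minDistanceA <= cutoffA")
  if (length(msgs)) msgs else TRUE
})

#' A protein structure partitioned into protein and ligand atoms
#'
#' Heavy-atom coordinates of a ligand-bound structure split into the
#' protein partition (ATOM records) and one selected HETATM ligand
#' group; waters and unselected heteroatoms belong to neither.
#'
#' @slot protein data.frame: `resno`, `resid`, `elety`, `x`, `y`, `z`
#' @slot ligand data.frame with the same columns for the ligand group
#' @slot offset integer added to author residue numbers to reach the
#'   HDX sequence coordinate
#' @slot source path or label of the structure source
#' @seealso [loadStructure()], [contactResidues()]
#' @name StructureModel-class
#' @rdname StructureModel
#' @exportClass StructureModel
setClass("StructureModel",
  representation(
    protein = "data.frame", ligand = "data.frame",
    offset = "integer", source = "character"
  ),
  prototype(offset = 0L, source = NA_character_)
)

setValidity("StructureModel", function(object) {
  msgs <- character()
  need <- c("resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% colnames(object@protein)) ||
      !all(need %in% colnames(object@ligand)))
    return("protein and ligand tables need columns resno, resid, elety, x, y, z")
  if (nrow(object@ligand) == 0L)
    msgs <- c(msgs, "ligand atom set must be non-empty")
  xyz <- c(object@protein$x, object@protein$y, object@protein$z,
           object@ligand$x, object@ligand$y, object@ligand$z)
  if (!all(is.finite(xyz))) msgs <- c(msgs, "coordinates must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Simulation specification for a synthetic HDX-MS experiment
#'
#' Everything needed to generate an apo/bound pair of uptake tables under
#' the two-state exchange model: per-residue intrinsic rates drawn
#' log-uniformly, a set of orthosteric (ligand-occluded) residues that
#' exchange at the observed rate of the binding model when bound, a
#' disjoint set of allosteric residues whose intrinsic rate is scaled by
#' `allostericFactor` when bound, a peptide tiling, an exposure grid and
#' Gaussian centroid noise.
#'
#' @slot proteinLength number of residues
#' @slot sequence one-letter protein sequence (generated if empty)
#' @slot kexBounds log-uniform bounds for intrinsic rates, per minute
#' @slot kinetics a [BindingKinetics]
#' @slot orthostericResidues integer residue set occluded by ligand
#' @slot allostericResidues integer residue set modulated allosterically
#' @slot allostericFactor kex multiplier at allosteric residues when bound
#' @slot peptideLength,peptideStep tiling of simulated pepsin peptides
#' @slot exposures labelling times in minutes, strictly increasing
#' @slot d2oFraction labelling D2O fraction
#' @slot noiseSd Gaussian SD on peptide centroids, Daltons
#' @slot seed RNG seed; fixed seed gives bit-identical output
#' @seealso [simulationSpec()], [simulateExperiment()]
#' @name SimulationSpec-class
#' @rdname SimulationSpec
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  representation(
    proteinLength = "integer", sequence = "character", kexBounds = "numeric",
    kinetics = "BindingKinetics", orthostericResidues = "integer",
    allostericResidues = "integer", allostericFactor = "numeric",
    peptideLength = "integer", peptideStep = "integer",
    exposures = "numeric", d2oFraction = "numeric", noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationSpec", function(object) {
  msgs <- character()
  if (object@proteinLength < 2L) msgs <- c(msgs, "proteinLength must be >= 2")
  if (length(intersect(object@orthostericResidues,
                       object@allostericResidues)))
    msgs <- c(msgs, "orthosteric and allosteric residue sets must be disjoint")
  if (any(object@orthostericResidues < 1L |
          object@orthostericResidues > object@proteinLength) ||
      any(object@allostericResidues < 1L |
          object@allostericResidues > object@proteinLength))
    msgs <- c(msgs, "residue sets must lie within the protein")
  if (length(object@exposures) == 0L || any(object@exposures <= 0) ||
      is.unsorted(object@exposures, strictly = TRUE))
    msgs <- c(msgs, "exposures must be strictly increasing and > 0")
  if (!(length(object@kexBounds) == 2L && all(object@kexBounds > 0) &&
        object@kexBounds[1] <= object@kexBounds[2]))
    msgs <- c(msgs, "kexBounds must be two positive ascending numbers")
  if (!(object@allostericFactor > 0))
    msgs <- c(msgs, "allostericFactor must be > 0")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (nchar(object@sequence) &&
      nchar(object@sequence) != object@proteinLength)
    msgs <- c(msgs, "sequence length must equal proteinLength")
  if (object@peptideLength < 2L)
    msgs <- c(msgs, "peptideLength must be >= 2")
  if (object@peptideStep < 1L) msgs <- c(msgs, "peptideStep must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Per-ligand response report
#'
#' A ligand's classified response regions with summary scores: total
#' region count, orthosteric/allosteric counts, and a total magnitude
#' score (sum over regions of the maximum-over-exposures absolute
#' uptake difference, Da).
#'
#' @slot ligand ligand name
#' @slot regions a classified [ResponseRegionSet]
#' @slot magnitudeStat how the per-region magnitude was computed
#'   ("max" over exposures, "sum", or "earliest")
#' @seealso [ligandReport()], [rankLigands()], [compareLigands()]
#' @name LigandReport-class
#' @rdname LigandReport
#' @exportClass LigandReport
setClass("LigandReport",
  representation(
    ligand = "character", regions = "ResponseRegionSet",
    magnitudeStat = "character"
  ),
  prototype(magnitudeStat = "max")
)

setValidity("LigandReport", function(object) {
  lab <- S4Vectors::mcols(object@regions@regions)$label
  if (length(lab) && any(is.na(lab)))
    "all regions in a LigandReport must be classified"
  else TRUE
})
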