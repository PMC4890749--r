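#' @include AllClasses.R
NULL

# ---- generics ------------------------------------------------------------

#' @rdname HDXPeptideSet
#' @param x an object with peptide identifiers
#' @export
setGeneric("peptideIds", function(x) standardGeneric("peptideIds"))

#' @rdname HDXPeptideSet
#' @export
setGeneric("nExchangeable", function(x) standardGeneric("nExchangeable"))

#' @rdname HDXPeptideSet
#' @export
setGeneric("peptideRanges", function(x) standardGeneric("peptideRanges"))

#' @rdname UptakeExperiment
#' @param x an `UptakeExperiment`
#' @export
setGeneric("uptakeRecords", function(x) standardGeneric("uptakeRecords"))

#' @rdname UptakeExperiment
#' @export
setGeneric("hdxStates", function(x) standardGeneric("hdxStates"))

#' @rdname UptakeExperiment
#' @export
setGeneric("exposures", function(x) standardGeneric("exposures"))

#' @rdname UptakeExperiment
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname ContactSet
#' @param x a `ContactSet`
#' @export
setGeneric("contactTable", function(x) standardGeneric("contactTable"))

#' @rdname ContactSet
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname ResponseRegionSet
#' @param x a `ResponseRegionSet`
#' @export
setGeneric("regionRanges", function(x) standardGeneric("regionRanges"))

#' @rdname ResponseRegionSet
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname DifferenceProfile
#' @param x a `DifferenceProfile`
#' @export
setGeneric("deltaTable", function(x) standardGeneric("deltaTable"))

#' @rdname DifferenceProfile
#' @export
setGeneric("peptideCalls", function(x) standardGeneric("peptideCalls"))

#' @rdname DifferenceProfile
#' @export
setGeneric("significantPeptides",
           function(x) standardGeneric("significantPeptides"))

#' @rdname LigandReport
#' @param x a `LigandReport`
#' @export
setGeneric("ligandScores", function(x) standardGeneric("ligandScores"))

# ---- HDXPeptideSet -------------------------------------------------------

#' @rdname HDXPeptideSet
setMethod("peptideIds", "HDXPeptideSet", function(x) names(x@ranges))

#' @rdname HDXPeptideSet
setMethod("nExchangeable", "HDXPeptideSet", function(x) {
  n <- S4Vectors::mcols(x@ranges)$nExchangeable
  names(n) <- names(x@ranges)
  n
})

#' @rdname HDXPeptideSet
setMethod("peptideRanges", "HDXPeptideSet", function(x) x@ranges)

#' @rdname HDXPeptideSet
setMethod("length", "HDXPeptideSet", function(x) length(x@ranges))

#' @rdname HDXPeptideSet
#' @param i peptide ids or indices
#' @param j,drop,... ignored
setMethod("[", "HDXPeptideSet", function(x, i, j, ..., drop = TRUE) {
  initialize(x, ranges = x@ranges[i])
})

setMethod("show", "HDXPeptideSet", function(object) {
  r <- object@ranges
  cat(sprintf("HDXPeptideSet with %d peptides spanning residues %d-%d\n",
              length(r),
              if (length(r)) min(IRanges::start(r)) else NA_integer_,
              if (length(r)) max(IRanges::end(r)) else NA_integer_))
  if (length(r)) {
    head_n <- min(5L, length(r))
    df <- data.frame(
      id = names(r)[seq_len(head_n)],
      start = IRanges::start(r)[seq_len(head_n)],
      end = IRanges::end(r)[seq_len(head_n)],
      nExchangeable = S4Vectors::mcols(r)$nExchangeable[seq_len(head_n)]
    )
    print(df, row.names = FALSE)
    if (length(r) > head_n) cat(sprintf("... and %d more\n", length(r) - head_n))
  }
  invisible(NULL)
})

# ---- UptakeExperiment ----------------------------------------------------

#' @rdname UptakeExperiment
setMethod("uptakeRecords", "UptakeExperiment", function(x) x@records)

#' @rdname UptakeExperiment
setMethod("peptides", "UptakeExperiment", function(x) x@peptides)

#' @rdname UptakeExperiment
setMethod("hdxStates", "UptakeExperiment",
          function(x) sort(unique(x@records$state)))

#' @rdname UptakeExperiment
setMethod("exposures", "UptakeExperiment",
          function(x) sort(unique(x@records$exposure_min)))

setMethod("show", "UptakeExperiment", function(object) {
  cat(sprintf(
    "UptakeExperiment: %d peptides, %d records, states: %s\n",
    length(object@peptides), nrow(object@records),
    paste(hdxStates(object), collapse = ", ")))
  cat(sprintf("exposures (min): %s; D2O fraction %.2f\n",
              paste(exposures(object), collapse = ", "),
              object@d2oFraction))
  invisible(NULL)
})

# ---- DifferenceProfile ---------------------------------------------------

#' @rdname DifferenceProfile
setMethod("deltaTable", "DifferenceProfile", function(x) x@deltas)

#' @rdname DifferenceProfile
setMethod("peptideCalls", "DifferenceProfile", function(x) x@peptideCalls)

#' @rdname DifferenceProfile
setMethod("significantPeptides", "DifferenceProfile", function(x) {
  x@peptideCalls[x@peptideCalls$significant, , drop = FALSE]
})

setMethod("show", "DifferenceProfile", function(object) {
  sig <- sum(object@peptideCalls$significant)
  cat(sprintf(
    "DifferenceProfile %s - %s: %d peptides, %d significant (|delta| > %.2f Da at >= %d exposure%s)\n",
    object@states[1], object@states[2], nrow(object@peptideCalls), sig,
    object@thresholdDa, object@minTimepoints,
    if (object@minTimepoints > 1L) "s" else ""))
  invisible(NULL)
})

# ---- ResponseRegionSet ---------------------------------------------------

#' @rdname ResponseRegionSet
setMethod("regionRanges", "ResponseRegionSet", function(x) x@regions)

#' @rdname ResponseRegionSet
setMethod("length", "ResponseRegionSet", function(x) length(x@regions))

#' @rdname ResponseRegionSet
setMethod("regionTable", "ResponseRegionSet", function(x) {
  r <- x@regions
  mc <- S4Vectors::mcols(r)
  data.frame(
    name = if (is.null(names(r))) rep(NA_character_, length(r)) else names(r),
    start = IRanges::start(r), end = IRanges::end(r),
    direction = mc$direction, label = mc$label,
    maxDelta = mc$maxDelta,
    nContacts = lengths(mc$contactResidues),
    peptides = vapply(mc$peptideIds, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
})

setMethod("show", "ResponseRegionSet", function(object) {
  cat(sprintf("ResponseRegionSet with %d region%s (threshold %.2f Da)\n",
              length(object), if (length(object) == 1L) "" else "s",
              object@thresholdDa))
  if (length(object)) print(regionTable(object), row.names = FALSE)
  invisible(NULL)
})

# ---- ContactSet ----------------------------------------------------------

#' @rdname ContactSet
setMethod("contactTable", "ContactSet", function(x) x@table)

#' @rdname ContactSet
setMethod("residues", "ContactSet", function(x) as.integer(x@table$residue))

#' @rdname ContactSet
setMethod("length", "ContactSet", function(x) nrow(x@table))

setMethod("show", "ContactSet", function(object) {
  cat(sprintf("ContactSet: %d residues within %.2f A of the ligand\n",
              nrow(object@table), object@cutoffA))
  if (nrow(object@table))
    cat(" ", paste(object@table$residue, collapse = ", "), "\n")
  invisible(NULL)
})

# ---- BindingKinetics / others -------------------------------------------

setMethod("show", "BindingKinetics", function(object) {
  fmt <- function(v) if (is.na(v)) "NA" else format(v, digits = 4)
  cat("BindingKinetics\n")
  cat(sprintf("  kOn  : %s /M/min\n  kOff : %s /min\n  KD   : %s M\n",
              fmt(object@kOn), fmt(object@kOff), fmt(object@KD)))
  cat(sprintf("  [L]  : %s M\n  [P]  : %s M\n",
              fmt(object@ligandConc), fmt(object@proteinConc)))
  invisible(NULL)
})

setMethod("show", "StructureModel", function(object) {
  cat(sprintf(
    "StructureModel: %d protein atoms over %d residues; ligand %s with %d atoms\n",
    nrow(object@protein), length(unique(object@protein$resno)),
    if (nrow(object@ligand)) object@ligand$resid[1] else "?",
    nrow(object@ligand)))
  if (object@offset != 0L)
    cat(sprintf("  residue numbering offset: %+d\n", object@offset))
  invisible(NULL)
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(
    "SimulationSpec: %d residues, %d orthosteric, %d allosteric (factor %.3g)\n",
    object@proteinLength, length(object@orthostericResidues),
    length(object@allostericResidues), object@allostericFactor))
  cat(sprintf("  exposures: %s min; noise SD %.3g Da; seed %d\n",
              paste(object@exposures, collapse = ", "),
              object@noiseSd, object@seed))
  invisible(NULL)
})

#' @rdname LigandReport
setMethod("ligandScores", "LigandReport", function(x) {
  lab <- S4Vectors::mcols(x@regions@regions)$label
  md <- S4Vectors::mcols(x@regions@regions)$maxDelta
  data.frame(
    ligand = x@ligand,
    nRegions = length(lab),
    nOrthosteric = sum(lab == "orthosteric"),
    nAllosteric = sum(lab == "allosteric"),
    totalMagnitude = if (length(md)) sum(md) else 0,
    stringsAsFactors = FALSE
  )
})

setMethod("show", "LigandReport", function(object) {
  s <- ligandScores(object)
  cat(sprintf(
    "LigandReport '%s': %d regions (%d orthosteric, %d allosteric), total magnitude %.2f Da\n",
    s$ligand, s$nRegions, s$nOrthosteric, s$nAllosteric, s$totalMagnitude))
  invisible(NULL)
})
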