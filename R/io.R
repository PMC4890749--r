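#' @include AllClasses.R accessors.R uptake.R
NULL

#' Read a peptide-level uptake table
#'
#' Reads the package's CSV dialect (header required): `protein`,
#' `peptide_id`, `start`, `end`, `sequence`, `state`, `exposure_min`,
#' `uptake_da`, `sd_da`. Peptide definitions must be consistent across
#' rows sharing an id.
#'
#' @param file CSV path
#' @param nFastTermini N-terminal residues discounted when counting
#'   exchangeable amides (default 1)
#' @param d2oFraction labelling D2O fraction for the validity ceiling
#'   (default 0.9)
#' @param tolerance validity slack (default 0.1)
#' @return an [UptakeExperiment-class]
#' @seealso [writeUptakeTable()]
#' @export
readUptakeTable <- function(file, nFastTermini = 1, d2oFraction = 0.9,
                            tolerance = 0.1) {
  req <- c("peptide_id", "start", "end", "sequence", "state",
           "exposure_min", "uptake_da", "sd_da")
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  miss <- setdiff(req, colnames(tab))
  if (length(miss))
    stop("readUptakeTable: missing columns in ", file, ": ",
         paste(miss, collapse = ", "))
  key <- !duplicated(tab$peptide_id)
  defs <- tab[key, c("peptide_id", "start", "end", "sequence")]
  chk <- merge(tab[, c("peptide_id", "start", "end", "sequence")], defs,
               by = "peptide_id")
  bad <- chk$start.x != chk$start.y | chk$end.x != chk$end.y |
    chk$sequence.x != chk$sequence.y
  if (any(bad))
    stop("readUptakeTable: inconsistent span/sequence for peptide ids: ",
         paste(unique(chk$peptide_id[bad]), collapse = ", "))
  peps <- peptideSet(defs$peptide_id, defs$start, defs$end, defs$sequence,
                     nFastTermini = nFastTermini)
  uptakeExperiment(peps, tab[, req[!req %in% c("start", "end", "sequence")]],
                   d2oFraction = d2oFraction, tolerance = tolerance)
}

#' Write a peptide-level uptake table
#'
#' Emits the same CSV dialect that [readUptakeTable()] reads.
#'
#' @param x an [UptakeExperiment-class]
#' @param file output CSV path
#' @param protein protein name written in the `protein` column
#' @return the file path, invisibly
#' @export
writeUptakeTable <- function(x, file, protein = "protein") {
  stopifnot(is(x, "UptakeExperiment"))
  r <- peptideRanges(x@peptides)
  rec <- as.data.frame(x@records)
  idx <- match(rec$peptide_id, names(r))
  out <- data.frame(
    protein = protein,
    peptide_id = rec$peptide_id,
    start = IRanges::start(r)[idx],
    end = IRanges::end(r)[idx],
    sequence = S4Vectors::mcols(r)$sequence[idx],
    state = rec$state,
    exposure_min = rec$exposure_min,
    uptake_da = rec$uptake_da,
    sd_da = rec$sd_da,
    stringsAsFactors = FALSE)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a response-region table as TSV
#'
#' One row per region: interval, direction, label, member peptides and
#' the per-exposure maximum absolute uptake difference.
#'
#' @param regions a [ResponseRegionSet-class]
#' @param file output path
#' @return the file path, invisibly
#' @export
writeRegionTable <- function(regions, file) {
  stopifnot(is(regions, "ResponseRegionSet"))
  tab <- regionTable(regions)
  dbe <- regions@deltaByExposure
  if (ncol(dbe))
    colnames(dbe) <- paste0("maxAbsDelta_t", colnames(dbe), "min")
  out <- cbind(tab, as.data.frame(dbe))
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a per-ligand JSON report
#'
#' @param report a [LigandReport-class]
#' @param file output path
#' @return the file path, invisibly
#' @export
writeLigandReport <- function(report, file) {
  stopifnot(is(report, "LigandReport"))
  tab <- regionTable(report@regions)
  tab$magnitude <- regionMagnitudes(report)
  payload <- list(
    ligand = report@ligand,
    scores = as.list(ligandScores(report)),
    magnitudeStat = report@magnitudeStat,
    regions = tab)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
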