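#' @include AllClasses.R accessors.R regions.R structure.R
NULL

#' Classify response regions as orthosteric or allosteric
#'
#' A region is orthosteric if and only if it contains at least one
#' ligand-contact residue; otherwise it is allosteric (a long-range
#' conformational response with no direct ligand contact). Direction of
#' the uptake change is carried through but does not influence the
#' label. Regions are named `O1..On` (orthosteric) and `A1..Am`
#' (allosteric) by ascending start.
#'
#' @param regions a [ResponseRegionSet-class]
#' @param contacts a [ContactSet-class]
#' @return the region set with `label`, `contactResidues` and names
#'   filled in
#' @examples
#' cat <- responseRegions(start = c(89, 2), end = c(119, 16))
#' ct <- new("ContactSet", cutoffA = 4,
#'           table = S4Vectors::DataFrame(residue = c(93L, 96L),
#'                                        minDistanceA = c(2.9, 3.4)))
#' regionTable(classifyRegions(cat, ct))
#' @export
classifyRegions <- function(regions, contacts) {
  stopifnot(is(regions, "ResponseRegionSet"), is(contacts, "ContactSet"))
  r <- regions@regions
  if (length(r) == 0L) return(regions)
  support <- lapply(seq_along(r), function(i) {
    peptideContactOverlap(IRanges::start(r)[i], IRanges::end(r)[i], contacts)
  })
  label <- ifelse(lengths(support) > 0L, "orthosteric", "allosteric")
  mc <- S4Vectors::mcols(r)
  mc$label <- label
  mc$contactResidues <- IRanges::IntegerList(support)
  S4Vectors::mcols(r) <- mc
  nm <- character(length(r))
  for (lab in c("orthosteric", "allosteric")) {
    idx <- which(label == lab)
    idx <- idx[order(IRanges::start(r)[idx])]
    nm[idx] <- paste0(substr(toupper(lab), 1, 1), seq_along(idx))
  }
  names(r) <- nm
  initialize(regions, regions = r)
}

#' Build a per-ligand response report
#'
#' @param ligand ligand name
#' @param regions a classified [ResponseRegionSet-class] (all labels
#'   assigned, e.g. by [classifyRegions()])
#' @param magnitudeStat how the per-region magnitude is summarised over
#'   exposures: `"max"` (default), `"sum"`, or `"earliest"`
#' @return a [LigandReport-class]
#' @export
ligandReport <- function(ligand, regions, magnitudeStat = c("max", "sum",
                                                            "earliest")) {
  magnitudeStat <- match.arg(magnitudeStat)
  new("LigandReport", ligand = as.character(ligand), regions = regions,
      magnitudeStat = magnitudeStat)
}

#' Per-region magnitudes of a ligand report
#'
#' @param report a [LigandReport-class]
#' @return numeric vector of per-region magnitudes (Da) under the
#'   report's `magnitudeStat`
#' @export
regionMagnitudes <- function(report) {
  stopifnot(is(report, "LigandReport"))
  rs <- report@regions
  md <- S4Vectors::mcols(rs@regions)$maxDelta
  if (report@magnitudeStat == "max" || ncol(rs@deltaByExposure) == 0L)
    return(md)
  switch(report@magnitudeStat,
    sum = rowSums(rs@deltaByExposure, na.rm = TRUE),
    earliest = rs@deltaByExposure[, 1L])
}

#' Compare response regions across ligands
#'
#' Regions are matched across ligands by interval overlap of at least
#' one residue: the union of all ligands' region intervals is reduced
#' into non-overlapping comparison intervals, and each ligand is marked
#' present on an interval when one of its regions overlaps it. The
#' result is invariant to the order of the reports (columns follow the
#' input order; rows are always sorted by start).
#'
#' @param reports list of [LigandReport-class] objects on the same
#'   protein coordinate system (at least 2)
#' @return data.frame with one row per comparison interval: `start`,
#'   `end`, `label` (orthosteric if any overlapping region is),
#'   `sharedBy` (count), plus `present.<ligand>` and
#'   `magnitude.<ligand>` columns
#' @export
compareLigands <- function(reports) {
  stopifnot(length(reports) >= 2L,
            all(vapply(reports, is, logical(1), "LigandReport")))
  ligands <- vapply(reports, function(r) r@ligand, character(1))
  if (anyDuplicated(ligands))
    stop("compareLigands: duplicated ligand names")
  all_r <- lapply(reports, function(r) r@regions@regions)
  pooled <- do.call(c, unname(lapply(all_r,
                                     function(r) { names(r) <- NULL; r })))
  if (length(pooled) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0), sharedBy = integer(0)))
  comp <- IRanges::reduce(pooled, min.gapwidth = 0L)  # already start-sorted
  out <- data.frame(start = IRanges::start(comp), end = IRanges::end(comp),
                    label = NA_character_,
                    sharedBy = 0L, stringsAsFactors = FALSE)
  labels <- rep(NA_character_, length(comp))
  for (k in seq_along(reports)) {
    rk <- all_r[[k]]
    hits <- IRanges::findOverlaps(comp, rk)
    present <- logical(length(comp)); mag <- rep(NA_real_, length(comp))
    mags_k <- regionMagnitudes(reports[[k]])
    labs_k <- S4Vectors::mcols(rk)$label
    for (i in seq_along(comp)) {
      j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
      if (length(j)) {
        present[i] <- TRUE
        mag[i] <- max(mags_k[j])
        if ("orthosteric" %in% labs_k[j]) labels[i] <- "orthosteric"
        else if (is.na(labels[i])) labels[i] <- "allosteric"
      }
    }
    out[[paste0("present.", ligands[k])]] <- present
    out[[paste0("magnitude.", ligands[k])]] <- mag
  }
  out$label <- labels
  out$sharedBy <- rowSums(as.matrix(
    out[, paste0("present.", ligands), drop = FALSE]))
  out
}

#' Rank ligands by response-region count and magnitude
#'
#' Primary key: number of response regions (descending); secondary:
#' total magnitude, the sum over regions of the per-region magnitude
#' (descending); tertiary: ligand name (ascending), for determinism.
#' Ligands equal on both scoring keys are flagged as tied.
#'
#' @param reports list of [LigandReport-class] objects (at least 1)
#' @return data.frame ordered by rank with columns `rank`, `ligand`,
#'   `nRegions`, `nOrthosteric`, `nAllosteric`, `totalMagnitude`, `tied`
#' @export
rankLigands <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, is, logical(1), "LigandReport")))
  scores <- do.call(rbind, lapply(reports, function(r) {
    s <- ligandScores(r)
    s$totalMagnitude <- sum(regionMagnitudes(r))
    if (s$nRegions == 0L) s$totalMagnitude <- 0
    s
  }))
  o <- order(-scores$nRegions, -scores$totalMagnitude, scores$ligand)
  scores <- scores[o, , drop = FALSE]
  key <- paste(scores$nRegions, signif(scores$totalMagnitude, 12))
  scores$tied <- key %in% key[duplicated(key)]
  scores$rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores[, c("rank", "ligand", "nRegions", "nOrthosteric", "nAllosteric",
             "totalMagnitude", "tied")]
}

#' Markdown summary of a cross-ligand comparison
#'
#' @param comparison output of [compareLigands()]
#' @return character vector of Markdown table lines
#' @export
comparisonMarkdown <- function(comparison) {
  ligs <- sub("^present\\.", "",
              grep("^present\\.", colnames(comparison), value = TRUE))
  hdr <- c("region", "label", ligs)
  rows <- apply(comparison, 1, function(row) {
    cells <- c(sprintf("%s-%s", trimws(row[["start"]]), trimws(row[["end"]])),
               row[["label"]],
               vapply(ligs, function(l)
                 if (as.logical(row[[paste0("present.", l)]])) "x" else "",
                 character(1)))
    paste0("| ", paste(cells, collapse = " | "), " |")
  })
  c(paste0("| ", paste(hdr, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
    rows)
}
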