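#' @include AllClasses.R accessors.R
NULL

.isHydrogen <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  ety <- toupper(trimws(ifelse(is.na(elety), "", elety)))
  el == "H" | (el == "" & grepl("^[0-9]*H", ety))
}

#' Load a ligand-bound structure and partition protein/ligand atoms
#'
#' Reads a PDB file (via [bio3d::read.pdb]) and splits it into the
#' protein partition (ATOM records) and one ligand HETATM group selected
#' by residue name. Waters (HOH/DOD/WAT) are excluded by default, as are
#' hydrogens and alternate locations other than the first; heteroatoms
#' other than the selected ligand belong to neither partition. Only the
#' first model of a multi-model file is used (with a warning).
#'
#' @param pdbSource path to a PDB file
#' @param ligandSelector HETATM residue name of the ligand (e.g.
#'   `"RDC"`); if `NULL` and exactly one non-water heteroatom group is
#'   present, that group is used
#' @param offset integer added to author residue numbers to reach the
#'   HDX sequence coordinate (default 0)
#' @param keepHydrogens include hydrogen atoms (default FALSE)
#' @param keepWaters include waters in the ligand candidate set
#'   (default FALSE)
#' @return a [StructureModel-class]
#' @seealso [contactResidues()]
#' @export
loadStructure <- function(pdbSource, ligandSelector = NULL, offset = 0L,
                          keepHydrogens = FALSE, keepWaters = FALSE) {
  if (!file.exists(pdbSource))
    stop("loadStructure: file not found: ", pdbSource)
  n_models <- sum(grepl("^MODEL", readLines(pdbSource, warn = FALSE)))
  if (n_models > 1L)
    warning("loadStructure: ", n_models,
            " models present; using the first model only")
  pdb <- suppressWarnings(bio3d::read.pdb(pdbSource, multi = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  # first altloc only, for deterministic output
  at <- at[is.na(at$alt) | at$alt %in% c("", "A", "1"), , drop = FALSE]
  if (!keepHydrogens)
    at <- at[!.isHydrogen(at$elesy, at$elety), , drop = FALSE]
  waters <- c("HOH", "DOD", "WAT")
  prot <- at[at$type == "ATOM", , drop = FALSE]
  het <- at[at$type == "HETATM", , drop = FALSE]
  if (!keepWaters) het <- het[!het$resid %in% waters, , drop = FALSE]
  available <- unique(het$resid)
  if (is.null(ligandSelector)) {
    if (length(available) != 1L)
      stop("loadStructure: ligandSelector required; HETATM groups present: ",
           if (length(available)) paste(available, collapse = ", ")
           else "(none)")
    ligandSelector <- available
  }
  lig <- het[het$resid == ligandSelector, , drop = FALSE]
  if (nrow(lig) == 0L)
    stop("loadStructure: no HETATM group '", ligandSelector,
         "'; available groups: ",
         if (length(available)) paste(available, collapse = ", ")
         else "(none)")
  cols <- c("resno", "resid", "elety", "x", "y", "z")
  new("StructureModel",
      protein = prot[, cols], ligand = lig[, cols],
      offset = as.integer(offset), source = as.character(pdbSource))
}

#' Residues in contact with the bound ligand
#'
#' A residue is a contact if the minimum Euclidean distance between any
#' of its (heavy) atoms and any ligand atom is less than or equal to
#' `cutoffA`. The boundary is inclusive: a pair at exactly the cutoff
#' counts as contact, because distal sites are defined by strictly
#' greater distances. Residue numbers in the result are in the HDX
#' sequence coordinate (author numbering plus the model's offset).
#'
#' @param model a [StructureModel-class]
#' @param cutoffA distance cutoff in Angstroms (default 4.0, an
#'   H-bonding-scale radius)
#' @return a [ContactSet-class]
#' @examples
#' \dontrun{
#' model <- loadStructure("complex.pdb", ligandSelector = "RDC")
#' residues(contactResidues(model))
#' }
#' @export
contactResidues <- function(model, cutoffA = 4.0) {
  stopifnot(is(model, "StructureModel"))
  if (!(cutoffA > 0)) stop("contactResidues: cutoffA must be > 0")
  if (nrow(model@ligand) == 0L)
    stop("contactResidues: empty ligand atom set")
  p <- model@protein
  lx <- model@ligand$x; ly <- model@ligand$y; lz <- model@ligand$z
  # squared distance of every protein atom to its nearest ligand atom
  d2min <- vapply(seq_len(nrow(p)), function(i) {
    min((p$x[i] - lx)^2 + (p$y[i] - ly)^2 + (p$z[i] - lz)^2)
  }, numeric(1))
  dmin_res <- tapply(d2min, p$resno, min)
  resno <- as.integer(names(dmin_res))
  dmin <- sqrt(as.numeric(dmin_res))
  keep <- dmin <= cutoffA
  resid_first <- p$resid[match(resno, p$resno)]
  tab <- S4Vectors::DataFrame(
    residue = resno[keep] + model@offset,
    resid = resid_first[keep],
    minDistanceA = dmin[keep])
  tab <- tab[order(tab$residue), , drop = FALSE]
  new("ContactSet", cutoffA = cutoffA, table = tab)
}

#' Contact residues overlapped by a peptide span
#'
#' @param start,end 1-based inclusive residue span of the peptide (in
#'   the same coordinate system as the contact set); alternatively
#'   `start` may be an [HDXPeptideSet-class] of length one, in which
#'   case `end` is ignored
#' @param contacts a [ContactSet-class]
#' @return sorted integer vector of contact residues inside the span
#' @examples
#' \dontrun{peptideContactOverlap(45, 70, contacts)}
#' @export
peptideContactOverlap <- function(start, end = NULL, contacts) {
  if (is(start, "HDXPeptideSet")) {
    stopifnot(length(start) == 1L)
    r <- peptideRanges(start)
    end <- IRanges::end(r); start <- IRanges::start(r)
  }
  stopifnot(is(contacts, "ContactSet"))
  res <- residues(contacts)
  sort(res[res >= start & res <= end])
}

#' Write a contact list as TSV
#'
#' @param contacts a [ContactSet-class]
#' @param file output path
#' @return the file path, invisibly
#' @export
writeContactTable <- function(contacts, file) {
  stopifnot(is(contacts, "ContactSet"))
  utils::write.table(as.data.frame(contacts@table), file = file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a residue attribute file for structure-viewer coloring
#'
#' Emits one `residue<TAB>label` row per residue of each classified
#' region (orthosteric/allosteric/unclassified), suitable for mapping
#' response regions onto a structure in a viewer.
#'
#' @param regions a [ResponseRegionSet-class]
#' @param file output path
#' @param attribute attribute name written in the header line
#' @return the file path, invisibly
#' @export
writeAttributeFile <- function(regions, file, attribute = "hdxResponse") {
  stopifnot(is(regions, "ResponseRegionSet"))
  r <- regions@regions
  lab <- S4Vectors::mcols(r)$label
  lab[is.na(lab)] <- "unclassified"
  rows <- unlist(lapply(seq_along(r), function(i) {
    paste(seq(IRanges::start(r)[i], IRanges::end(r)[i]), lab[i], sep = "\t")
  }))
  writeLines(c(paste0("#attribute\t", attribute), rows), con = file)
  invisible(file)
}
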