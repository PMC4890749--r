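#' @include AllClasses.R accessors.R uptake.R regions.R structure.R
#' @include classify.R io.R fixture.R
NULL

#' Default pipeline configuration
#'
#' Collects the thresholds of the analysis: 0.5 Da significance
#' threshold on uptake differences, reporter factor 0.5 of the maximum
#' short-time RDU, 4.0 A contact cutoff, zero merge gap and one
#' required exposure beyond threshold.
#'
#' @return named list of defaults, overridable in [runPipeline()]
#' @export
defaultRunConfig <- function() {
  list(
    uptake = NULL,            # CSV path (all states) or UptakeExperiment
    structure = NULL,         # PDB path (NULL = skip classification)
    ligandSelector = NULL,
    structureOffset = 0L,
    apoState = "apo",
    ligandStates = NULL,      # default: every non-apo state
    thresholdDa = 0.5,
    reporterFactor = 0.5,
    contactCutoffA = 4.0,
    maxGap = 0L,
    minTimepoints = 1L,
    shortTimes = NULL,        # default: earliest exposure
    magnitudeStat = "max",
    seed = 1L,
    outDir = NULL)
}

.configHash <- function(config) {
  plain <- config[vapply(config, function(v) !isS4(v) && !is.function(v),
                         logical(1))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(plain[order(names(plain))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full orthosteric/allosteric mapping pipeline
#'
#' Orchestrates ingest, relative-uptake reporters, apo-versus-bound
#' difference profiles, region merging, structure-contact overlay,
#' orthosteric/allosteric classification, cross-ligand comparison and
#' ranking as one reproducible run. With an output directory set, the
#' per-stage results are written as TSV/JSON plus a provenance record
#' (package version, configuration hash, seed); identical configuration
#' and inputs give identical outputs.
#'
#' @param config a named list overriding [defaultRunConfig()], or a
#'   path to a JSON file of such overrides
#' @return invisibly, a list with `experiment`, `rdu`, `reporters`,
#'   `contacts` (or `NULL`), and per-ligand `profiles`, `regions`,
#'   `reports`, plus `comparison`, `ranking`, `outputs` (paths) and
#'   `provenance`
#' @examples
#' fx <- makeHsp90Fixture()
#' res <- runPipeline(list(uptake = fx$experiment,
#'                         structure = fx$pdbLines,
#'                         shortTimes = 10))
#' res$ranking
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(defaultRunConfig(), as.list(config))
  for (nm in c("thresholdDa", "reporterFactor", "contactCutoffA"))
    if (!(cfg[[nm]] > 0)) stop("runPipeline: '", nm, "' must be positive")

  # -- ingest --------------------------------------------------------------
  ue <- cfg$uptake
  if (is.null(ue)) stop("runPipeline: 'uptake' input required")
  if (is.character(ue)) {
    if (!file.exists(ue)) stop("runPipeline: uptake table not found: ", ue)
    ue <- readUptakeTable(ue)
  }
  stopifnot(is(ue, "UptakeExperiment"))
  states <- hdxStates(ue)
  if (!cfg$apoState %in% states)
    stop("runPipeline: apo state '", cfg$apoState, "' absent; states: ",
         paste(states, collapse = ", "))
  ligand_states <- cfg$ligandStates
  if (is.null(ligand_states)) ligand_states <- setdiff(states, cfg$apoState)

  # -- structure contacts --------------------------------------------------
  contacts <- NULL
  if (!is.null(cfg$structure)) {
    structure_path <- cfg$structure
    if (length(structure_path) > 1L) {      # PDB text lines
      structure_path <- tempfile(fileext = ".pdb")
      writeLines(cfg$structure, structure_path)
    } else if (!file.exists(structure_path)) {
      stop("runPipeline: structure file not found: ", structure_path)
    }
    model <- loadStructure(structure_path,
                           ligandSelector = cfg$ligandSelector,
                           offset = cfg$structureOffset)
    contacts <- contactResidues(model, cutoffA = cfg$contactCutoffA)
  } else {
    warning("runPipeline: no structure given; regions will be reported ",
            "unclassified and ranking skipped")
  }

  # -- reporters from apo relative uptake ----------------------------------
  rdu <- computeRDU(ue)
  rdu_apo <- rdu[rdu$state == cfg$apoState, , drop = FALSE]
  short_times <- cfg$shortTimes
  if (is.null(short_times)) short_times <- min(exposures(ue))
  reporters <- reporterRegions(rdu_apo, shortTimes = short_times,
                               factor = cfg$reporterFactor)

  # -- per-ligand difference -> regions -> classification ------------------
  profiles <- list(); regions <- list(); reports <- list()
  for (lig in ligand_states) {
    prof <- differenceProfile(ue, apoState = cfg$apoState, boundState = lig,
                              thresholdDa = cfg$thresholdDa,
                              minTimepoints = cfg$minTimepoints)
    reg <- mergeRegions(prof, maxGap = cfg$maxGap)
    if (!is.null(contacts)) {
      reg <- classifyRegions(reg, contacts)
      reports[[lig]] <- ligandReport(lig, reg,
                                     magnitudeStat = cfg$magnitudeStat)
    }
    profiles[[lig]] <- prof
    regions[[lig]] <- reg
  }
  n_merged <- vapply(regions, length, integer(1))
  n_classified <- if (length(reports))
    vapply(reports, function(r) length(r@regions), integer(1))
  else integer(0)
  if (length(reports) && sum(n_merged) != sum(n_classified))
    stop("runPipeline: classified region count does not match merged count")

  comparison <- if (length(reports) >= 2L) compareLigands(reports) else NULL
  ranking <- if (length(reports) >= 1L) rankLigands(reports) else NULL

  provenance <- list(
    package = "AlloHDX",
    version = as.character(utils::packageVersion("AlloHDX")),
    configHash = .configHash(
      cfg[!names(cfg) %in% c("uptake", "structure", "outDir")]),
    seed = cfg$seed,
    apoState = cfg$apoState, ligandStates = ligand_states,
    thresholdDa = cfg$thresholdDa, contactCutoffA = cfg$contactCutoffA,
    nPeptides = length(peptides(ue)),
    nRecords = nrow(uptakeRecords(ue)),
    reporterThreshold = reporters$threshold,
    regionsPerLigand = as.list(n_merged))

  # -- reports -------------------------------------------------------------
  outputs <- character(0)
  if (!is.null(cfg$outDir)) {
    if (!dir.exists(cfg$outDir)) dir.create(cfg$outDir, recursive = TRUE)
    od <- cfg$outDir
    for (lig in ligand_states) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", lig)
      f <- file.path(od, paste0("regions_", safe, ".tsv"))
      writeRegionTable(regions[[lig]], f); outputs <- c(outputs, f)
      if (!is.null(contacts)) {
        f <- file.path(od, paste0("report_", safe, ".json"))
        writeLigandReport(reports[[lig]], f); outputs <- c(outputs, f)
        f <- file.path(od, paste0("attributes_", safe, ".txt"))
        writeAttributeFile(regions[[lig]], f); outputs <- c(outputs, f)
      }
    }
    if (!is.null(contacts)) {
      f <- file.path(od, "contacts.tsv")
      writeContactTable(contacts, f); outputs <- c(outputs, f)
    }
    if (!is.null(comparison)) {
      f <- file.path(od, "comparison.tsv")
      utils::write.table(comparison, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs <- c(outputs, f)
      f <- file.path(od, "comparison.md")
      writeLines(comparisonMarkdown(comparison), f)
      outputs <- c(outputs, f)
    }
    if (!is.null(ranking)) {
      f <- file.path(od, "ranking.tsv")
      utils::write.table(ranking, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs <- c(outputs, f)
    }
    f <- file.path(od, "provenance.json")
    jsonlite::write_json(provenance, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    outputs <- c(outputs, f)
  }

  invisible(list(
    experiment = ue, rdu = rdu, reporters = reporters, contacts = contacts,
    profiles = profiles, regions = regions, reports = reports,
    comparison = comparison, ranking = ranking,
    provenance = provenance, outputs = outputs))
}
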