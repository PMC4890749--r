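#' @include AllClasses.R accessors.R kinetics.R uptake.R simulate.R
NULL

#' The published Hsp90 N-domain response-region catalogue
#'
#' Residue intervals of the orthosteric (O1--O4) and allosteric
#' (A1--A5) response regions reported for the Hsp90 N-terminal ATPase
#' domain, with the per-ligand presence table: all four ligands respond
#' at O1--O4, A1 and A2; A3 and A4 respond to radicicol and fragment 1
#' only; A5 responds to fragment 1 only. Note that, as published, A2
#' (62--90) overlaps O1 and contains A3 (77--90); the intervals are kept
#' as printed.
#'
#' @return list with `regions` (data.frame: `name`, `label`, `start`,
#'   `end`), `presence` (logical matrix, regions x ligands),
#'   `contacts` (17 ligand-contact residues) and `proteinLength`
#' @export
hsp90RegionCatalogue <- function() {
  regions <- data.frame(
    name = c("O1", "O2", "O3", "O4", "A1", "A2", "A3", "A4", "A5"),
    label = rep(c("orthosteric", "allosteric"), c(4, 5)),
    start = c(45L, 89L, 131L, 171L, 2L, 62L, 77L, 120L, 201L),
    end = c(70L, 119L, 138L, 197L, 16L, 90L, 90L, 127L, 213L),
    stringsAsFactors = FALSE)
  ligands <- c("radicicol", "17-AAG", "fragment1", "fragment2")
  presence <- matrix(FALSE, nrow(regions), length(ligands),
                     dimnames = list(regions$name, ligands))
  presence[c("O1", "O2", "O3", "O4", "A1", "A2"), ] <- TRUE
  presence[c("A3", "A4"), c("radicicol", "fragment1")] <- TRUE
  presence["A5", "fragment1"] <- TRUE
  list(regions = regions, presence = presence,
       contacts = c(48L, 51L, 54L, 55L, 58L, 91L, 93L, 96L, 97L, 98L,
                    106L, 107L, 112L, 135L, 138L, 184L, 186L),
       proteinLength = 236L)
}

#' Hsp90 ligand kinetic parameters
#'
#' Dissociation constants and exchange-reaction concentrations of the
#' four ligands (two high-affinity inhibitors used at 20 uM, 6:1 over
#' protein; two phenolic fragments used at 5 mM, ~1500:1). No
#' association rates were reported for these ligands, so a single
#' diffusion-limited-scale `kOn` is assumed for all (configurable).
#'
#' @param kOn assumed association rate, per molar per minute
#'   (default 1e6)
#' @param proteinConc protein concentration, molar (default 3.3e-6)
#' @return data.frame: `ligand`, `KD_M`, `ligandConc_M`, `kOn`,
#'   `proteinConc_M`
#' @export
hsp90LigandTable <- function(kOn = 1e6, proteinConc = 3.3e-6) {
  data.frame(
    ligand = c("radicicol", "17-AAG", "fragment1", "fragment2"),
    KD_M = c(19e-9, 33e-9, 490e-6, 570e-6),
    ligandConc_M = c(20e-6, 20e-6, 5e-3, 5e-3),
    kOn = kOn, proteinConc_M = proteinConc,
    stringsAsFactors = FALSE)
}

# Peptide map used by the fixture: region peptides tiled inside each
# catalogued interval plus background peptides in the unaffected
# stretches. Spans are chosen so that every catalogued region contains
# at least one peptide lying entirely inside it.
.hsp90PeptideMap <- function() {
  data.frame(
    id = c("bg017", "bg030", "bg139", "bg152", "bg155", "bg214", "bg223",
           "a1a", "o1a", "o1b", "a2a", "a2b", "a3a", "o2a", "o2b",
           "a4a", "o3a", "o4a", "o4b", "a5a"),
    start = c(17L, 30L, 139L, 152L, 155L, 214L, 223L,
              2L, 45L, 55L, 62L, 74L, 77L, 89L, 102L,
              120L, 131L, 171L, 182L, 201L),
    end = c(31L, 44L, 153L, 166L, 170L, 228L, 236L,
            16L, 58L, 70L, 75L, 90L, 90L, 103L, 119L,
            127L, 138L, 185L, 197L, 213L),
    stringsAsFactors = FALSE)
}

# Residue sets carrying each ligand's bound-state effect. The A2
# response is localised at 62-76 and the A3 response at 77-90: as
# published the A3 interval is contained in A2, and only a residue-level
# split of this kind can make a peptide spanning 62-90 respond for every
# ligand while the 77-90 peptide responds only to radicicol/fragment 1.
.hsp90EffectSites <- function() {
  list(A1 = 2:16, A2 = 62:76, A3 = 77:90, A4 = 120:127, A5 = 201:213)
}

.hsp90AllostericSets <- function() {
  list(
    "radicicol" = c("A1", "A2", "A3", "A4"),
    "17-AAG" = c("A1", "A2"),
    "fragment1" = c("A1", "A2", "A3", "A4", "A5"),
    "fragment2" = c("A1", "A2"))
}

#' Generate the synthetic Hsp90 validation fixture
#'
#' Builds a deterministic, fully synthetic dataset that reproduces the
#' published per-ligand response pattern of the Hsp90 N-terminal
#' domain: an apo state plus four ligand-bound states (radicicol,
#' 17-AAG, fragment 1, fragment 2) simulated under the two-state
#' exchange model at the 17 ligand-contact residues and allosteric rate
#' modulation at the catalogued distal regions, together with a
#' synthetic ligand-bound structure whose 4 A contact set is exactly
#' the published contact-residue list. The protein sequence and peptide
#' map are synthetic (the real pepsin map is not public); intrinsic
#' rates are chosen so the binding-pocket region O2 shows its largest
#' differences at early exposures and the allosteric regions at later
#' ones.
#'
#' @param dir optional output directory; when given, writes
#'   `uptake.csv`, `structure_synthetic.pdb` and `manifest.json`
#' @param noiseSd Gaussian centroid noise, Da (default 0: bit-stable
#'   fixture)
#' @param seed RNG seed for the synthetic sequence and background
#'   intrinsic rates (default 421)
#' @param kOn assumed association rate for all ligands, per molar per
#'   minute (default 1e6)
#' @param allostericFactor bound-state kex multiplier at allosteric
#'   residues (default 0.2)
#' @param exposures labelling times, minutes (default 0.5, 2, 5, 10)
#' @return list with `experiment` (an [UptakeExperiment-class] with
#'   states apo + 4 ligands), `structureFile`-ready `pdbLines`,
#'   `catalogue` (see [hsp90RegionCatalogue()]), `ligands`
#'   (see [hsp90LigandTable()]), `kex` and `files` (paths, when `dir`
#'   was given)
#' @export
makeHsp90Fixture <- function(dir = NULL, noiseSd = 0, seed = 421L,
                             kOn = 1e6, allostericFactor = 0.2,
                             exposures = c(0.5, 2, 5, 10)) {
  cat_ <- hsp90RegionCatalogue()
  ligtab <- hsp90LigandTable(kOn = kOn)
  len <- cat_$proteinLength
  d2o <- 0.9
  set.seed(as.integer(seed))
  seqStr <- .randomSequence(len)
  seqChars <- strsplit(seqStr, "")[[1]]
  kex <- exp(stats::runif(len, log(0.05), log(5)))
  # deterministic rates at effect sites: fast at the H-bonding core of
  # the pocket (early-time differences), moderate elsewhere in the
  # pocket, slow at allosteric sites (late-time differences)
  o2core <- c(91L, 93L, 96L, 97L, 98L, 106L, 107L, 112L)
  kex[cat_$contacts] <- 1
  kex[o2core] <- 3
  effect <- .hsp90EffectSites()
  kex[unlist(effect)] <- 0.8
  kex[cat_$contacts] <- ifelse(cat_$contacts %in% o2core, 3, 1)

  pepmap <- .hsp90PeptideMap()
  seqs <- vapply(seq_len(nrow(pepmap)), function(i)
    substr(seqStr, pepmap$start[i], pepmap$end[i]), character(1))
  peps <- peptideSet(pepmap$id, pepmap$start, pepmap$end, seqs)

  allo_sets <- .hsp90AllostericSets()
  states <- c("apo", ligtab$ligand)
  rates_by_state <- list(apo = kex)
  for (i in seq_len(nrow(ligtab))) {
    lig <- ligtab$ligand[i]
    kin <- bindingKinetics(kOn = ligtab$kOn[i], KD = ligtab$KD_M[i],
                           ligandConc = ligtab$ligandConc_M[i],
                           proteinConc = ligtab$proteinConc_M[i])
    allo_res <- unlist(effect[allo_sets[[lig]]], use.names = FALSE)
    rates_by_state[[lig]] <- .boundRates(kex, cat_$contacts, allo_res,
                                         allostericFactor, kin)
  }
  grid <- expand.grid(pep = seq_len(nrow(pepmap)), exposure = exposures,
                      state = states, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  expected <- vapply(seq_len(nrow(grid)), function(i) {
    .peptideExpectedUptake(pepmap[grid$pep[i], ], seqChars,
                           rates_by_state[[grid$state[i]]],
                           grid$exposure[i], d2o)
  }, numeric(1))
  noise <- if (noiseSd > 0) stats::rnorm(nrow(grid), 0, noiseSd) else 0
  rec <- data.frame(
    peptide_id = pepmap$id[grid$pep], state = grid$state,
    exposure_min = grid$exposure,
    uptake_da = pmax(expected + noise, 0),
    sd_da = if (noiseSd > 0) noiseSd else 0.05,
    stringsAsFactors = FALSE)
  experiment <- uptakeExperiment(peps, rec, d2oFraction = d2o,
                                 tolerance = max(0.1, 4 * noiseSd))
  pdbLines <- makeSyntheticStructure(cat_$contacts, proteinLength = len)

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    uptake_csv <- file.path(dir, "uptake.csv")
    writeUptakeTable(experiment, uptake_csv, protein = "Hsp90N_synthetic")
    pdb_file <- file.path(dir, "structure_synthetic.pdb")
    writeLines(pdbLines, pdb_file)
    manifest <- list(
      description = paste("Synthetic Hsp90 N-domain HDX-MS fixture:",
                          "sequence, peptide map and structure are",
                          "synthetic; region catalogue, contact residues",
                          "and ligand parameters follow the published",
                          "response pattern"),
      proteinLength = len, d2oFraction = d2o, exposures = exposures,
      seed = seed, noiseSd = noiseSd,
      ligands = ligtab, regions = cat_$regions,
      presence = as.data.frame(cat_$presence),
      contacts = cat_$contacts,
      peptides = pepmap)
    manifest_file <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(uptake = uptake_csv, structure = pdb_file,
               manifest = manifest_file)
  }
  list(experiment = experiment, pdbLines = pdbLines, catalogue = cat_,
       ligands = ligtab, kex = kex, sequence = seqStr, files = files)
}

#' Presence of catalogued regions in a difference profile
#'
#' A catalogued region counts as present when at least one significant
#' peptide lies entirely inside its interval. Containment (rather than
#' mere overlap) is required because published region intervals may
#' overlap each other (the Hsp90 A3 interval is contained in A2):
#' a peptide reporting the wider region must not count as evidence for
#' the narrower one.
#'
#' @param profile a [DifferenceProfile-class]
#' @param catalogue a region catalogue as returned by
#'   [hsp90RegionCatalogue()], or any data.frame with `name`, `start`,
#'   `end`
#' @return named logical vector, one element per catalogued region
#' @export
regionPresence <- function(profile, catalogue = hsp90RegionCatalogue()) {
  stopifnot(is(profile, "DifferenceProfile"))
  regions <- if (is.data.frame(catalogue)) catalogue else catalogue$regions
  sig <- as.data.frame(significantPeptides(profile))
  out <- vapply(seq_len(nrow(regions)), function(i) {
    any(sig$start >= regions$start[i] & sig$end <= regions$end[i])
  }, logical(1))
  names(out) <- regions$name
  out
}
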