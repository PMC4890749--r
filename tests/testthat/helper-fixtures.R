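# Small in-code fixtures shared across test files.

toyPeptides <- function() {
  peptideSet(id = c("p1", "p2", "p3"),
             start = c(1, 10, 30), end = c(6, 21, 41),
             sequence = c("GGGGGG", "AAAAAAAAAAAA", "LLLLLLLLLLLL"))
}

toyExperiment <- function(boundShift = c(p1 = 0, p2 = 1.2, p3 = 0),
                          exposures = c(0.5, 2, 10)) {
  peps <- toyPeptides()
  grid <- expand.grid(peptide_id = peptideIds(peps),
                      exposure_min = exposures,
                      state = c("apo", "bound"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- c(p1 = 3.0, p2 = 6.0, p3 = 5.0)
  grid$uptake_da <- base[grid$peptide_id] *
    (1 - exp(-0.5 * grid$exposure_min))
  shift <- ifelse(grid$state == "bound",
                  boundShift[grid$peptide_id], 0)
  grid$uptake_da <- pmax(grid$uptake_da - shift, 0)
  grid$sd_da <- 0.05
  uptakeExperiment(peps, grid)
}

# A StructureModel built directly from coordinate tables.
toyStructure <- function(protXYZ, ligXYZ, offset = 0L) {
  prot <- data.frame(resno = protXYZ$resno, resid = "ALA", elety = "CA",
                     x = protXYZ$x, y = protXYZ$y, z = protXYZ$z)
  lig <- data.frame(resno = 1L, resid = "LIG",
                    elety = paste0("C", seq_len(nrow(ligXYZ))),
                    x = ligXYZ$x, y = ligXYZ$y, z = ligXYZ$z)
  new("StructureModel", protein = prot, ligand = lig,
      offset = as.integer(offset), source = "toy")
}

# Specification generator for recovery tests: one orthosteric and one
# allosteric 5-residue block, separated widely enough that recovered
# regions cannot bridge; effect sizes guaranteed above threshold + 3*SD
# at the 10-minute exposure for intrinsic rates in [0.8, 1.2].
recoverySpec <- function(seed) {
  set.seed(seed)
  orthoStart <- sample(5:15, 1)
  alloStart <- orthoStart + 30 + sample(0:10, 1)
  simulationSpec(
    proteinLength = 80L,
    kinetics = bindingKinetics(kOn = 1e6, KD = 1e-8,
                               ligandConc = 2e-5, proteinConc = 3e-6),
    orthostericResidues = orthoStart:(orthoStart + 4L),
    allostericResidues = alloStart:(alloStart + 4L),
    allostericFactor = 0.02,
    kexBounds = c(0.8, 1.2),
    peptideLength = 10L, peptideStep = 4L,
    noiseSd = 0.05, seed = seed)
}

# Closed-form expected span of significant peptides around an effect
# block: the union of tiled peptides whose amide range (start+1..end)
# intersects the block.
expectedBlockSpan <- function(block, len, peptideLength, peptideStep) {
  starts <- seq(1L, len - peptideLength + 1L, by = peptideStep)
  ends <- starts + peptideLength - 1L
  if (max(ends) < len) {
    starts <- c(starts, len - peptideLength + 1L)
    ends <- c(ends, len)
  }
  hit <- (starts + 1L) <= max(block) & ends >= min(block)
  c(min(starts[hit]), max(ends[hit]))
}
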