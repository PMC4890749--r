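test_that("single-site deuteration follows first-order labelling kinetics", {
  kin <- bindingKinetics(kOn = 1e6, kOff = 0.02, ligandConc = 2e-5)
  site <- exchangeSite(10, kex = 1, occluded = TRUE)
  expect_equal(simulateSiteUptake(site, "apo", kin, t = 0), 0)
  expect_equal(simulateSiteUptake(site, "apo", kin, t = 1e6), 0.9)
  expect_equal(simulateSiteUptake(site, "bound", kin, t = 1e6), 0.9,
               tolerance = 1e-6)
  # occlusion slows exchange whenever reassociation beats exchange
  t <- c(0.5, 2, 5, 10)
  expect_true(all(simulateSiteUptake(site, "bound", kin, t) <
                  simulateSiteUptake(site, "apo", kin, t)))
  # allosteric modulation scales the rate
  allo <- exchangeSite(11, kex = 1, allostericFactor = 0.2)
  expect_equal(simulateSiteUptake(allo, "bound", t = 2),
               0.9 * (1 - exp(-0.2 * 2)))
  expect_error(exchangeSite(1, kex = 1, occluded = TRUE,
                            allostericFactor = 2), "both")
})

test_that("simulated experiments are deterministic and null without sites", {
  spec0 <- simulationSpec(40L, noiseSd = 0, seed = 5L)
  sim <- simulateExperiment(spec0)
  rec <- as.data.frame(uptakeRecords(sim$experiment))
  apo <- rec[rec$state == "apo", ]; bnd <- rec[rec$state == "bound", ]
  key <- function(d) paste(d$peptide_id, d$exposure_min)
  bnd <- bnd[match(key(apo), key(bnd)), ]
  expect_equal(apo$uptake_da, bnd$uptake_da)

  specN <- recoverySpec(3L)
  r1 <- as.data.frame(uptakeRecords(simulateExperiment(specN)$experiment))
  r2 <- as.data.frame(uptakeRecords(simulateExperiment(specN)$experiment))
  expect_identical(r1, r2)

  expect_error(simulateExperiment(simulationSpec(10L, peptideLength = 11L)),
               "zero peptides")
})

test_that("a forced orthosteric block is recovered as one protected region", {
  kin <- bindingKinetics(kOn = 1e6, KD = 1e-8, ligandConc = 2e-5,
                         proteinConc = 3e-6)
  spec <- simulationSpec(60L, kinetics = kin,
                         orthostericResidues = 25:29,
                         kexBounds = c(0.8, 1.2), noiseSd = 0,
                         peptideLength = 10L, peptideStep = 5L,
                         seed = 9L)
  sim <- simulateExperiment(spec)
  prof <- differenceProfile(sim$experiment, "apo", "bound")
  regs <- regionTable(mergeRegions(prof))
  expect_equal(nrow(regs), 1)
  expect_identical(regs$direction, "protection")
  expect_true(regs$start <= 25 && regs$end >= 29)
  span <- expectedBlockSpan(25:29, 60L, 10L, 5L)
  expect_equal(c(regs$start, regs$end), span)
})

test_that("raising ligand concentration never increases occluded uptake", {
  concs <- c(1e-6, 5e-6, 2e-5, 1e-4, 1e-3)
  prev <- NULL
  for (L in concs) {
    kin <- bindingKinetics(kOn = 1e6, KD = 1e-6, ligandConc = L,
                           proteinConc = 1e-6)
    spec <- simulationSpec(30L, kinetics = kin,
                           orthostericResidues = 10:14, noiseSd = 0,
                           peptideLength = 10L, peptideStep = 10L,
                           seed = 13L)
    rec <- as.data.frame(uptakeRecords(simulateExperiment(spec)$experiment))
    bound <- rec[rec$state == "bound" & rec$peptide_id == "pep002", ]
    u <- sum(bound$uptake_da)
    if (!is.null(prev)) expect_lte(u, prev + 1e-9)
    prev <- u
  }
})

test_that("synthetic structures realise exactly the designated contacts", {
  f <- tempfile(fileext = ".pdb")
  makeSyntheticStructure(10L, proteinLength = 20L, file = f)
  cs <- contactResidues(loadStructure(f, "LIG"), 4.0)
  expect_identical(residues(cs), 10L)

  spec <- recoverySpec(2L)
  f2 <- tempfile(fileext = ".pdb")
  makeSyntheticStructure(spec, file = f2)
  cs2 <- contactResidues(loadStructure(f2, "LIG"), 4.0)
  expect_identical(residues(cs2), spec@orthostericResidues)

  expect_error(makeSyntheticStructure(integer(0), proteinLength = 10L),
               "non-empty")
  expect_error(makeSyntheticStructure(5L, proteinLength = 10L,
                                      spacing = 1.5), "infeasible")
})

test_that("generated PDB lines satisfy strict column conventions", {
  lines <- makeSyntheticStructure(c(3L, 7L), proteinLength = 8L)
  atoms <- grep("^(ATOM|HETATM)", lines, value = TRUE)
  for (ln in atoms) {
    expect_gte(nchar(ln), 66)
    expect_false(is.na(as.integer(substr(ln, 7, 11))))   # serial
    expect_match(substr(ln, 18, 20), "^[A-Z]{3}$")       # resName
    expect_match(substr(ln, 22, 22), "^[A-Z]$")          # chain
    expect_false(is.na(as.integer(substr(ln, 23, 26))))  # resSeq
    for (cols in list(c(31, 38), c(39, 46), c(47, 54)))  # x, y, z
      expect_false(is.na(as.numeric(substr(ln, cols[1], cols[2]))))
  }
  # parses under an independent reader with matching coordinates
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  pdb <- bio3d::read.pdb(f, verbose = FALSE)
  expect_equal(sum(pdb$atom$type == "ATOM"), 8)
  expect_equal(sum(pdb$atom$type == "HETATM"), 2)
  expect_equal(pdb$atom$x[1], 8.0)
})

test_that("single-exponential fits recover noiseless parameters", {
  t <- c(0.5, 1, 2, 5, 10, 20)
  u <- 4.2 * (1 - exp(-0.3 * t))
  fit <- fitSingleExponential(t, u)
  expect_equal(fit$k, 0.3, tolerance = 1e-6)
  expect_equal(fit$A, 4.2, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-8)
  expect_error(fitSingleExponential(t, rep(0, 6)), "degenerate")
  expect_error(fitSingleExponential(c(1, 2), c(0.1, 0.2)), "at least 3")
})

test_that("a two-site series fits to a rate between the true rates", {
  t <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32)
  u <- (1 - exp(-0.1 * t)) + (1 - exp(-1.0 * t))
  fit <- fitSingleExponential(t, u)
  expect_gt(fit$k, 0.1)
  expect_lt(fit$k, 1.0)
  # dense grid-search oracle over k with the optimal amplitude profiled out
  ks <- exp(seq(log(0.01), log(5), length.out = 2000))
  sse <- vapply(ks, function(k) {
    f <- 1 - exp(-k * t)
    A <- sum(u * f) / sum(f * f)
    sum((u - A * f)^2)
  }, numeric(1))
  kbest <- ks[which.min(sse)]
  expect_equal(fit$k, kbest, tolerance = 1e-2)
})

test_that("fitted rates are robust to centroid noise", {
  t <- c(0.5, 1, 2, 5, 10, 20)
  set.seed(77)
  relerr <- vapply(1:200, function(i) {
    u <- pmax(5 * (1 - exp(-0.3 * t)) + rnorm(6, 0, 0.05), 0)
    abs(fitSingleExponential(t, u)$k - 0.3) / 0.3
  }, numeric(1))
  expect_lt(median(relerr), 0.20)
})
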