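test_that("exchangeable amide counting follows the stated convention", {
  expect_equal(exchangeableAmides("GGGGG"), 4L)
  expect_equal(exchangeableAmides("GPGPG"), 2L)
  expect_equal(exchangeableAmides("P"), 0L)
  # proline inside the exempted N-terminal stretch is not double-counted
  expect_equal(exchangeableAmides("PGGG", nFastTermini = 1), 3L)
  expect_equal(exchangeableAmides("GGGGG", nFastTermini = 2), 3L)
  expect_equal(exchangeableAmides(c("GGGGG", "GPGPG")), c(4L, 2L))
  expect_error(exchangeableAmides("GGXGG"), "position 3")
  expect_error(exchangeableAmides(""), "non-empty")
})

test_that("relative uptake is the uptake per exchangeable amide", {
  peps <- peptideSet("p1", 1, 6, "GGGGGG")   # 5 exchangeable
  ue <- uptakeExperiment(peps, data.frame(
    peptide_id = "p1", state = "apo", exposure_min = c(0, 10),
    uptake_da = c(0, 3.35), sd_da = 0))
  tab <- computeRDU(ue)
  expect_equal(tab$rdu, c(0, 0.67))
  # optional D2O correction rescales by the labelling fraction
  expect_equal(computeRDU(ue, correctD2O = TRUE)$rdu[2], 0.67 / 0.9)
})

test_that("relative uptake validation and exclusions", {
  peps <- peptideSet(c("ok", "none"), c(1, 10), c(5, 11),
                     c("GGGGG", "GP"))   # "none" has 0 exchangeable
  ue <- uptakeExperiment(peps, data.frame(
    peptide_id = c("ok", "none"), state = "apo", exposure_min = 10,
    uptake_da = c(1, 0), sd_da = 0))
  expect_warning(tab <- computeRDU(ue), "no exchangeable")
  expect_identical(unique(tab$peptide_id), "ok")

  # uptake beyond the amide capacity is rejected at construction
  expect_error(uptakeExperiment(peptideSet("p", 1, 5, "GGGGG"),
    data.frame(peptide_id = "p", state = "apo", exposure_min = 10,
               uptake_da = 5.0, sd_da = 0)), "exceeds")
  # and an over-unity RDU is rejected by the computation
  ue2 <- uptakeExperiment(peptideSet("p", 1, 5, "GGGGG"),
    data.frame(peptide_id = "p", state = "apo", exposure_min = 10,
               uptake_da = 4.2, sd_da = 0), d2oFraction = 1,
    tolerance = 0.2)
  expect_error(computeRDU(ue2, tolerance = 0.01), "RDU exceeds")

  # unknown ids are caught by the container's validity
  expect_error(uptakeExperiment(peps, data.frame(
    peptide_id = "ghost", state = "apo", exposure_min = 1,
    uptake_da = 0.1, sd_da = 0)), "unknown peptide ids")
})

test_that("doubling uptake doubles RDU until the validity cap trips", {
  peps <- peptideSet("p", 1, 11, "GGGGGGGGGGG")  # 10 exchangeable
  mk <- function(u) uptakeExperiment(peps, data.frame(
    peptide_id = "p", state = "apo", exposure_min = 1,
    uptake_da = u, sd_da = 0), d2oFraction = 1)
  expect_equal(computeRDU(mk(4))$rdu, 2 * computeRDU(mk(2))$rdu)
  expect_silent(computeRDU(mk(8)))
  expect_error(uptakeExperiment(peps, data.frame(
    peptide_id = "p", state = "apo", exposure_min = 1,
    uptake_da = 2 * 6, sd_da = 0), d2oFraction = 1), "exceeds")
})

test_that("reporter threshold is half the maximum short-time RDU", {
  tab <- data.frame(peptide_id = c("a", "b", "c"),
                    exposure_min = c(10, 10, 10),
                    rdu = c(0.67, 0.40, 0.20))
  rep <- reporterRegions(tab, shortTimes = 10)
  expect_equal(rep$threshold, 0.335)
  expect_equal(rep$maxRDU, 0.67)
  expect_setequal(rep$reporters, c("a", "b"))

  # identical non-zero values: everyone exceeds half the maximum
  same <- data.frame(peptide_id = letters[1:4], exposure_min = 1,
                     rdu = 0.4)
  expect_setequal(reporterRegions(same, 1)$reporters, letters[1:4])

  # a single peptide with positive RDU is always its own reporter
  one <- data.frame(peptide_id = "solo", exposure_min = 1, rdu = 0.1)
  expect_identical(reporterRegions(one, 1)$reporters, "solo")

  expect_error(reporterRegions(tab[0, ], 10), "empty")
  expect_error(reporterRegions(tab, 99), "absent")
  expect_error(reporterRegions(tab, 10, factor = 1), "factor")
})

test_that("reporter factor limits select all / only the maximum", {
  set.seed(5)
  tab <- data.frame(peptide_id = sprintf("p%02d", 1:20),
                    exposure_min = 0.5,
                    rdu = round(runif(20, 0.05, 0.8), 3))
  lo <- reporterRegions(tab, 0.5, factor = 1e-9)
  expect_setequal(lo$reporters, tab$peptide_id[tab$rdu > 0])
  hi <- reporterRegions(tab, 0.5, factor = 1 - 1e-9)
  expect_identical(hi$reporters, tab$peptide_id[which.max(tab$rdu)])
})

test_that("difference profile applies the Dalton threshold per peptide", {
  ue <- toyExperiment(boundShift = c(p1 = 0, p2 = 1.0, p3 = 0.4))
  prof <- differenceProfile(ue, "apo", "bound", thresholdDa = 0.5)
  calls <- as.data.frame(peptideCalls(prof))
  # p2 protected by 1.0 Da, p3's 0.4 Da stays below 0.5, p1 unchanged
  expect_identical(calls$significant[calls$peptide_id == "p2"], TRUE)
  expect_identical(calls$direction[calls$peptide_id == "p2"], "protection")
  expect_identical(calls$significant[calls$peptide_id == "p3"], FALSE)
  expect_identical(calls$significant[calls$peptide_id == "p1"], FALSE)
  d <- as.data.frame(deltaTable(prof))
  expect_equal(d$delta_da[d$peptide_id == "p1"], rep(0, 3))
  # the auxiliary z-score is delta over the pooled replicate SD and
  # has no influence on the significance flags
  expect_equal(d$zscore, d$delta_da / sqrt(2 * 0.05^2))
  expect_equal(calls$maxAbsZ[calls$peptide_id == "p2"],
               1.0 / sqrt(2 * 0.05^2))
})

test_that("swapping apo and bound negates deltas, keeps significance", {
  ue <- toyExperiment(boundShift = c(p1 = -0.8, p2 = 1.3, p3 = 0))
  fwd <- differenceProfile(ue, "apo", "bound")
  rev <- differenceProfile(ue, "bound", "apo")
  df <- as.data.frame(deltaTable(fwd))
  dr <- as.data.frame(deltaTable(rev))
  key <- function(d) paste(d$peptide_id, d$exposure_min)
  dr <- dr[match(key(df), key(dr)), ]
  expect_equal(dr$delta_da, -df$delta_da)
  cf <- as.data.frame(peptideCalls(fwd)); cr <- as.data.frame(peptideCalls(rev))
  cr <- cr[match(cf$peptide_id, cr$peptide_id), ]
  expect_identical(cr$significant, cf$significant)
  # directions flip with the sign convention
  expect_identical(cr$direction[cf$direction %in% "protection"],
                   rep("deprotection", sum(cf$direction %in% "protection",
                                           na.rm = TRUE)))
})

test_that("mismatched exposure grids error unless intersection requested", {
  ue <- toyExperiment()
  rec <- as.data.frame(uptakeRecords(ue))
  rec <- rec[!(rec$state == "bound" & rec$exposure_min == 10), ]
  ue2 <- uptakeExperiment(peptides(ue), rec)
  expect_error(differenceProfile(ue2, "apo", "bound"), "missing in 'bound'")
  prof <- differenceProfile(ue2, "apo", "bound", strict = FALSE)
  expect_setequal(unique(as.data.frame(deltaTable(prof))$exposure_min),
                  c(0.5, 2))
})

test_that("minimum-timepoint stringency is honoured", {
  peps <- peptideSet("p", 1, 13, "AAAAAAAAAAAAA")
  t <- c(0.5, 2, 10)
  rec <- rbind(
    data.frame(peptide_id = "p", state = "apo", exposure_min = t,
               uptake_da = c(2.0, 4.0, 6.0), sd_da = 0),
    data.frame(peptide_id = "p", state = "bound", exposure_min = t,
               uptake_da = c(1.7, 3.4, 5.0), sd_da = 0))
  ue <- uptakeExperiment(peps, rec)
  # deltas are 0.3, 0.6, 1.0: two exposures exceed the 0.5 Da threshold
  p1 <- differenceProfile(ue, "apo", "bound", minTimepoints = 1)
  p2 <- differenceProfile(ue, "apo", "bound", minTimepoints = 2)
  p3 <- differenceProfile(ue, "apo", "bound", minTimepoints = 3)
  expect_true(as.data.frame(peptideCalls(p1))$significant)
  expect_true(as.data.frame(peptideCalls(p2))$significant)
  expect_equal(nrow(significantPeptides(p3)), 0)
  expect_equal(as.data.frame(peptideCalls(p2))$nExceeding, 2)
})

test_that("overlapping same-direction peptides merge into one region", {
  df <- data.frame(peptide_id = c("a", "b"), start = c(45, 55),
                   end = c(58, 70), direction = "protection")
  reg <- regionTable(mergeRegions(df))
  expect_equal(nrow(reg), 1)
  expect_equal(c(reg$start, reg$end), c(45, 70))
  expect_identical(reg$direction, "protection")
  expect_setequal(strsplit(reg$peptides, ";")[[1]], c("a", "b"))

  two <- mergeRegions(data.frame(start = c(2, 45), end = c(16, 70),
                                 direction = "protection"))
  expect_equal(length(two), 2)
})

test_that("region merging is idempotent and gap-aware", {
  df <- data.frame(peptide_id = letters[1:3], start = c(10, 22, 40),
                   end = c(20, 30, 50), direction = "protection")
  m1 <- mergeRegions(df, maxGap = 1)       # 20->22 gap of 1 bridges
  expect_equal(regionTable(m1)$start, c(10, 40))
  m0 <- mergeRegions(df, maxGap = 0)
  expect_equal(regionTable(m0)$start, c(10, 22, 40))
  # adjacency (gap 0) merges at the default
  adj <- mergeRegions(data.frame(start = c(1, 6), end = c(5, 9),
                                 direction = "protection"))
  expect_equal(nrow(regionTable(adj)), 1)

  m2 <- mergeRegions(m1)
  expect_equal(regionTable(m2)[, c("start", "end", "direction")],
               regionTable(m1)[, c("start", "end", "direction")])
})

test_that("merged regions cover exactly the union of input spans", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(1:12, 1)
    start <- sample(1:150, n, replace = TRUE)
    end <- start + sample(5:20, n, replace = TRUE)
    df <- data.frame(peptide_id = as.character(seq_len(n)),
                     start = start, end = end, direction = "protection")
    got <- regionTable(mergeRegions(df, maxGap = 0))
    want <- unionRuns(start, end)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("opposite-direction overlap collapses to a mixed region", {
  df <- data.frame(peptide_id = c("up", "down"), start = c(10, 15),
                   end = c(20, 25),
                   direction = c("protection", "deprotection"))
  expect_warning(reg <- mergeRegions(df), "mixed")
  tab <- regionTable(reg)
  expect_equal(nrow(tab), 1)
  expect_identical(tab$direction, "mixed")
  expect_equal(c(tab$start, tab$end), c(10, 25))

  # disjoint opposite directions stay separate, no warning
  df2 <- data.frame(peptide_id = c("up", "down"), start = c(10, 40),
                    end = c(20, 50),
                    direction = c("protection", "deprotection"))
  expect_no_warning(reg2 <- mergeRegions(df2))
  expect_equal(length(reg2), 2)
})
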