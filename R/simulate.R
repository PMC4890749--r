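#' @include AllClasses.R accessors.R kinetics.R uptake.R
NULL

#' Construct a SimulationSpec
#'
#' @param proteinLength number of residues
#' @param kinetics a [BindingKinetics-class] governing the bound state
#' @param orthostericResidues residues occluded by the bound ligand
#' @param allostericResidues residues whose intrinsic rate is modulated
#'   in the bound state (disjoint from the orthosteric set)
#' @param allostericFactor kex multiplier at allosteric residues when
#'   bound (< 1 = protection, > 1 = deprotection); default 0.2
#' @param kexBounds log-uniform bounds for intrinsic exchange rates,
#'   per minute (default 0.05--5)
#' @param peptideLength,peptideStep peptide tiling (default 12-mers
#'   every 8 residues, a pepsin-like overlapping map)
#' @param exposures labelling times in minutes (default 0.5, 2, 5, 10)
#' @param d2oFraction labelling D2O fraction (default 0.9)
#' @param noiseSd Gaussian SD on peptide centroids, Da (default 0.05)
#' @param seed RNG seed (fixed seed gives bit-identical output)
#' @param sequence optional one-letter sequence; generated
#'   (proline-free) from the seed when omitted
#' @return a [SimulationSpec-class]
#' @export
simulationSpec <- function(proteinLength,
                           kinetics = bindingKinetics(),
                           orthostericResidues = integer(0),
                           allostericResidues = integer(0),
                           allostericFactor = 0.2,
                           kexBounds = c(0.05, 5),
                           peptideLength = 12L, peptideStep = 8L,
                           exposures = c(0.5, 2, 5, 10),
                           d2oFraction = 0.9, noiseSd = 0.05,
                           seed = 1L, sequence = "") {
  new("SimulationSpec",
      proteinLength = as.integer(proteinLength), sequence = sequence,
      kexBounds = as.numeric(kexBounds), kinetics = kinetics,
      orthostericResidues = as.integer(sort(unique(orthostericResidues))),
      allostericResidues = as.integer(sort(unique(allostericResidues))),
      allostericFactor = as.numeric(allostericFactor),
      peptideLength = as.integer(peptideLength),
      peptideStep = as.integer(peptideStep),
      exposures = as.numeric(exposures),
      d2oFraction = as.numeric(d2oFraction),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Expected deuteration of a single amide site
#'
#' First-order labelling kinetics,
#' \eqn{D(t) = d_{2o} (1 - e^{-k t})}, where the rate depends on state:
#' the intrinsic rate `kex` in the apo state; the observed rate of the
#' two-state binding model at an occluded site in the bound state; and
#' `kex * allostericFactor` at an allosterically modulated site in the
#' bound state.
#'
#' @param site an [ExchangeSite-class]
#' @param state `"apo"` or `"bound"`
#' @param kin a [BindingKinetics-class] (required for occluded sites in
#'   the bound state)
#' @param t exposure time(s), minutes
#' @param d2o labelling D2O fraction (default 0.9)
#' @return expected deuteration in \[0, d2o\], vectorised over `t`
#' @examples
#' kin <- bindingKinetics(kOn = 1e6, kOff = 0.02, ligandConc = 2e-5)
#' s <- exchangeSite(10, kex = 1, occluded = TRUE)
#' simulateSiteUptake(s, "bound", kin, t = c(0.5, 2, 5, 10))
#' @export
simulateSiteUptake <- function(site, state = c("apo", "bound"), kin = NULL,
                               t, d2o = 0.9) {
  stopifnot(is(site, "ExchangeSite"))
  state <- match.arg(state)
  if (any(t < 0)) stop("simulateSiteUptake: t must be >= 0")
  rate <- if (state == "apo") site@kex
  else if (site@occluded) {
    if (is.null(kin)) stop("simulateSiteUptake: occluded site needs kinetics")
    observedExchangeRate(kin, site@kex)
  } else site@kex * site@allostericFactor
  d2o * (1 - exp(-rate * t))
}

.tilePeptides <- function(len, peptideLength, peptideStep) {
  if (peptideLength > len)
    stop("simulateExperiment: peptide tiling leaves zero peptides ",
         "(peptideLength > proteinLength)")
  starts <- seq(1L, len - peptideLength + 1L, by = peptideStep)
  ends <- starts + peptideLength - 1L
  if (max(ends) < len) {           # terminal peptide to complete coverage
    starts <- c(starts, len - peptideLength + 1L)
    ends <- c(ends, len)
  }
  keep <- !duplicated(paste(starts, ends))
  data.frame(start = starts[keep], end = ends[keep])
}

.randomSequence <- function(len) {
  # proline-free so every non-terminal amide is exchange-competent
  paste(sample(setdiff(.AA, "P"), len, replace = TRUE), collapse = "")
}

.boundRates <- function(kex, orthosteric, allosteric, factor, kin) {
  rates <- kex
  if (length(orthosteric))
    rates[orthosteric] <- observedExchangeRate(kin, kex[orthosteric])
  if (length(allosteric))
    rates[allosteric] <- kex[allosteric] * factor
  rates
}

.peptideExpectedUptake <- function(pep, seqChars, rates, t, d2o,
                                   nFastTermini = 1L) {
  pos <- seq(pep$start + nFastTermini, pep$end)
  pos <- pos[seqChars[pos] != "P"]
  sum(d2o * (1 - exp(-rates[pos] * t)))
}

#' Simulate a peptide-level apo/bound exchange experiment
#'
#' Draws per-residue intrinsic rates log-uniformly from the spec's
#' bounds, tiles peptides across the protein, and computes peptide
#' centroid uptake as the sum of the per-amide first-order deuteration
#' curves, with the bound state applying the two-state observed rate at
#' orthosteric residues and the allosteric rate modulation at allosteric
#' residues. Gaussian noise (SD `noiseSd`) is added to each centroid and
#' floored at zero. Output is deterministic for a fixed seed.
#'
#' @param spec a [SimulationSpec-class]
#' @return list with `experiment` (an [UptakeExperiment-class] with
#'   states `"apo"` and `"bound"`), `truth` (list of the orthosteric
#'   and allosteric residue sets), `kex` (per-residue intrinsic rates)
#'   and `boundRates`
#' @export
simulateExperiment <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  set.seed(spec@seed)
  len <- spec@proteinLength
  seqStr <- if (nchar(spec@sequence)) spec@sequence else .randomSequence(len)
  seqChars <- strsplit(seqStr, "")[[1]]
  kex <- exp(stats::runif(len, log(spec@kexBounds[1]),
                          log(spec@kexBounds[2])))
  tiles <- .tilePeptides(len, spec@peptideLength, spec@peptideStep)
  ids <- sprintf("pep%03d", seq_len(nrow(tiles)))
  seqs <- vapply(seq_len(nrow(tiles)), function(i)
    substr(seqStr, tiles$start[i], tiles$end[i]), character(1))
  peps <- peptideSet(ids, tiles$start, tiles$end, seqs)
  bound <- .boundRates(kex, spec@orthostericResidues,
                       spec@allostericResidues, spec@allostericFactor,
                       spec@kinetics)
  grid <- expand.grid(peptide = seq_len(nrow(tiles)),
                      exposure = spec@exposures,
                      state = c("apo", "bound"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expected <- vapply(seq_len(nrow(grid)), function(i) {
    rates <- if (grid$state[i] == "apo") kex else bound
    .peptideExpectedUptake(tiles[grid$peptide[i], ], seqChars, rates,
                           grid$exposure[i], spec@d2oFraction)
  }, numeric(1))
  noise <- if (spec@noiseSd > 0)
    stats::rnorm(nrow(grid), 0, spec@noiseSd) else 0
  rec <- data.frame(
    peptide_id = ids[grid$peptide], state = grid$state,
    exposure_min = grid$exposure,
    uptake_da = pmax(expected + noise, 0),
    sd_da = spec@noiseSd, stringsAsFactors = FALSE)
  list(
    experiment = uptakeExperiment(peps, rec,
                                  d2oFraction = spec@d2oFraction,
                                  tolerance = max(0.1, 4 * spec@noiseSd)),
    truth = list(orthosteric = spec@orthostericResidues,
                 allosteric = spec@allostericResidues),
    kex = kex, boundRates = bound)
}

#' Write a minimal synthetic ligand-bound structure
#'
#' Places one C-alpha per residue on a straight, widely spaced line and
#' a ligand heavy atom `contactDistance` Angstroms from the C-alpha of
#' each designated contact residue, so that the 4 A contact set of the
#' generated structure is exactly the designated set. The geometry is
#' deliberately synthetic (the file is for exercising contact mapping,
#' not for visualisation of a real fold).
#'
#' @param x a [SimulationSpec-class] (contacts = its orthosteric set) or
#'   an integer vector of contact residues
#' @param proteinLength protein length (taken from the spec when `x` is
#'   one)
#' @param file optional output path; when given, the text is written
#' @param spacing C-alpha spacing along the line, Angstroms (default 8)
#' @param contactDistance ligand-atom to contact-C-alpha distance,
#'   Angstroms (default 3.5; must be <= 4)
#' @param cutoffA the contact cutoff the geometry must satisfy
#'   (default 4)
#' @param ligandName HETATM residue name (default "LIG")
#' @return character vector of PDB lines, invisibly when `file` is given
#' @export
makeSyntheticStructure <- function(x, proteinLength = NULL, file = NULL,
                                   spacing = 8, contactDistance = 3.5,
                                   cutoffA = 4, ligandName = "LIG") {
  if (is(x, "SimulationSpec")) {
    contacts <- x@orthostericResidues
    proteinLength <- x@proteinLength
  } else {
    contacts <- as.integer(x)
    if (is.null(proteinLength)) proteinLength <- max(contacts)
  }
  if (length(contacts) == 0L)
    stop("makeSyntheticStructure: contact (orthosteric) set must be non-empty")
  if (any(contacts < 1L | contacts > proteinLength))
    stop("makeSyntheticStructure: contacts outside the protein")
  if (contactDistance > cutoffA)
    stop("makeSyntheticStructure: contactDistance must be <= cutoffA")
  if (sqrt(spacing^2 + contactDistance^2) <= cutoffA)
    stop("makeSyntheticStructure: geometric placement infeasible: ",
         "neighbouring residues would fall inside the cutoff; ",
         "increase 'spacing' or reduce 'contactDistance'")
  atom_line <- function(type, serial, name, resid, chain, resno, x, y, z,
                        element) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, "", resid, chain, resno, "",
            x, y, z, 1.00, 0.00, element)
  }
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(proteinLength)) {
    serial <- serial + 1L
    lines <- c(lines, atom_line("ATOM", serial, " CA", "ALA", "A", i,
                                spacing * i, 0, 0, "C"))
  }
  lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                            serial + 1L, "ALA", "A",
                            as.integer(proteinLength)))
  serial <- serial + 1L
  for (j in seq_along(contacts)) {
    serial <- serial + 1L
    lines <- c(lines, atom_line("HETATM", serial, sprintf(" C%d", j),
                                ligandName, "L", 1L,
                                spacing * contacts[j], contactDistance, 0,
                                "C"))
  }
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Fit a single-exponential uptake curve
#'
#' Least-squares fit of \eqn{u(t) = A (1 - e^{-k t})} to one peptide's
#' uptake time course, useful for characterising the apparent exchange
#' rate of a peptide and for parameter-recovery checks of the
#' simulator.
#'
#' @param time exposure times, minutes (or a data.frame with
#'   `exposure_min` and `uptake_da`)
#' @param uptake centroid uptake, Da (ignored when `time` is a
#'   data.frame)
#' @return list with `k` (per minute), `A` (Da) and `residual` (the
#'   residual norm)
#' @examples
#' t <- c(0.5, 1, 2, 5, 10, 20)
#' u <- 4 * (1 - exp(-0.3 * t))
#' fitSingleExponential(t, u)$k
#' @export
fitSingleExponential <- function(time, uptake = NULL) {
  if (is.data.frame(time) || is(time, "DataFrame")) {
    uptake <- time$uptake_da
    time <- time$exposure_min
  }
  ok <- is.finite(time) & is.finite(uptake)
  time <- time[ok]; uptake <- uptake[ok]
  if (length(time) < 3L)
    stop("fitSingleExponential: need at least 3 exposures")
  if (all(uptake <= 0))
    stop("fitSingleExponential: degenerate (all-zero) uptake series")
  A0 <- max(uptake) * 1.05
  frac <- pmin(pmax(uptake / A0, 1e-6), 1 - 1e-6)
  k0 <- stats::median(-log(1 - frac) / time)
  k0 <- min(max(k0, 1e-6), 1e4)
  df <- data.frame(t = time, u = uptake)
  fit <- tryCatch(
    stats::nls(u ~ A * (1 - exp(-k * t)), data = df,
               start = list(A = A0, k = k0),
               lower = c(A = 1e-12, k = 1e-12), algorithm = "port",
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- minpack.lm::nlsLM(u ~ A * (1 - exp(-k * t)), data = df,
                             start = list(A = A0, k = k0),
                             lower = c(1e-12, 1e-12),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))
  co <- stats::coef(fit)
  list(k = unname(co["k"]), A = unname(co["A"]),
       residual = sqrt(sum(stats::resid(fit)^2)))
}
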