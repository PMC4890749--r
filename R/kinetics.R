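#' @include AllClasses.R
NULL

#' Construct a BindingKinetics object
#'
#' Missing members of the triplet (`kOn`, `kOff`, `KD`) are filled in from
#' the identity \eqn{K_D = k_{off}/k_{on}} when the other two are given.
#'
#' @param kOn association rate constant, per molar per minute
#' @param kOff dissociation rate constant, per minute
#' @param KD equilibrium dissociation constant, molar
#' @param ligandConc total ligand concentration, molar
#' @param proteinConc total protein concentration, molar
#' @return a [BindingKinetics-class] object
#' @examples
#' bindingKinetics(kOn = 1e6, KD = 19e-9, ligandConc = 20e-6,
#'                 proteinConc = 3.3e-6)
#' @export
bindingKinetics <- function(kOn = NA_real_, kOff = NA_real_, KD = NA_real_,
                            ligandConc = NA_real_, proteinConc = NA_real_) {
  kOn <- as.numeric(kOn); kOff <- as.numeric(kOff); KD <- as.numeric(KD)
  if (is.na(KD) && !is.na(kOn) && !is.na(kOff)) KD <- kOff / kOn
  if (is.na(kOff) && !is.na(kOn) && !is.na(KD)) kOff <- KD * kOn
  if (is.na(kOn) && !is.na(kOff) && !is.na(KD) && KD > 0) kOn <- kOff / KD
  new("BindingKinetics", kOn = kOn, kOff = kOff, KD = KD,
      ligandConc = as.numeric(ligandConc),
      proteinConc = as.numeric(proteinConc))
}

#' Construct an ExchangeSite
#'
#' @param residueIndex 1-based residue position
#' @param kex intrinsic exchange rate, per minute
#' @param occluded logical; is the amide shielded by bound ligand
#' @param allostericFactor kex multiplier in the bound conformation
#' @return an [ExchangeSite-class] object
#' @export
exchangeSite <- function(residueIndex, kex, occluded = FALSE,
                         allostericFactor = 1) {
  new("ExchangeSite", residueIndex = as.integer(residueIndex),
      kex = as.numeric(kex), occluded = isTRUE(occluded),
      allostericFactor = as.numeric(allostericFactor))
}

#' Construct a MixDesign
#'
#' @param volume component volumes, microlitres
#' @param soluteConc per-component solute concentrations (any linear unit)
#' @param d2oFraction per-component D2O fractions in \[0, 1\]
#' @param solute per-component solute names; "" marks a pure diluent
#' @return a [MixDesign-class] object
#' @examples
#' # 1 uL of 100 uM protein + 27 uL of 99.9% D2O buffer + 2 uL DMSO
#' mixDesign(volume = c(1, 27, 2), soluteConc = c(100, 0, 0),
#'           d2oFraction = c(0, 0.999, 0),
#'           solute = c("protein", "", ""))
#' @export
mixDesign <- function(volume, soluteConc = 0, d2oFraction = 0, solute = "") {
  n <- length(volume)
  new("MixDesign",
      volume = as.numeric(volume),
      soluteConc = rep_len(as.numeric(soluteConc), n),
      d2oFraction = rep_len(as.numeric(d2oFraction), n),
      solute = rep_len(as.character(solute), n))
}

#' Observed exchange rate at a ligand-occluded amide
#'
#' The two-state model of exchange at a binding-site amide under
#' reversible ligand binding:
#' \deqn{k_{obs} = \frac{k_{off}\,k_{ex}}{k_{on}[L] + k_{ex}}}
#' The observed rate is bounded above by \eqn{k_{off}} and decreases
#' monotonically with ligand concentration: the complex must open
#' (dissociate) before the amide can exchange, and reassociation
#' competes with exchange.
#'
#' @param kin a [BindingKinetics-class] with `kOff`, `kOn` and `ligandConc`
#' @param kex intrinsic exchange rate(s), per minute (vectorised)
#' @return observed exchange rate(s), per minute
#' @examples
#' kin <- bindingKinetics(kOn = 1e6, kOff = 0.3, ligandConc = 2e-5)
#' observedExchangeRate(kin, kex = 1)   # 0.3 / 21
#' @seealso [limitingRate()] for the saturating-ligand limit
#' @export
observedExchangeRate <- function(kin, kex) {
  stopifnot(is(kin, "BindingKinetics"))
  if (is.na(kin@kOff) || kin@kOff <= 0)
    stop("observedExchangeRate: 'kOff' must be a positive rate, got ",
         kin@kOff)
  if (any(is.na(kex)) || any(kex <= 0))
    stop("observedExchangeRate: 'kex' must be a positive rate")
  konL <- if (is.na(kin@kOn) || is.na(kin@ligandConc)) 0
          else kin@kOn * kin@ligandConc
  if (konL < 0)
    stop("observedExchangeRate: 'kOn' and 'ligandConc' must be >= 0")
  kin@kOff * kex / (konL + kex)
}

#' Exchange rate in the saturating-ligand limit
#'
#' When ligand is in vast excess (\eqn{k_{on}[L] \gg k_{ex}}) the
#' two-state observed rate reduces to
#' \deqn{k_{obs} = \frac{K_D\,k_{ex}}{[L]}}
#'
#' @param KD dissociation constant, molar (vectorised)
#' @param kex intrinsic exchange rate, per minute
#' @param ligandConc ligand concentration, molar; must be > 0
#' @return limiting observed rate(s), per minute
#' @examples
#' limitingRate(KD = 19e-9, kex = 1, ligandConc = 20e-6)  # 9.5e-4
#' @export
limitingRate <- function(KD, kex, ligandConc) {
  if (any(is.na(ligandConc)) || any(ligandConc <= 0))
    stop("limitingRate: 'ligandConc' must be > 0")
  if (any(is.na(kex)) || any(kex <= 0))
    stop("limitingRate: 'kex' must be > 0")
  if (any(is.na(KD)) || any(KD < 0))
    stop("limitingRate: 'KD' must be >= 0")
  KD * kex / ligandConc
}

#' Fractional occupancy of the protein by ligand
#'
#' Exact equilibrium occupancy \eqn{[PL]/[P]_{tot}} using total (not
#' free) ligand: the complex concentration is the smaller root of
#' \eqn{x^2 - x(P + L + K_D) + P L = 0}, evaluated in the numerically
#' stable form \eqn{x = 2PL / (b + \sqrt{b^2 - 4PL})} with
#' \eqn{b = P + L + K_D}. Ligand depletion is therefore handled exactly,
#' which matters when ligand is not in large excess over protein.
#'
#' @param KD dissociation constant, molar
#' @param proteinConc total protein concentration, molar; must be > 0
#' @param ligandConc total ligand concentration, molar
#' @return occupancy in \[0, 1\] (vectorised over any argument)
#' @examples
#' fractionalOccupancy(KD = 19e-9, proteinConc = 3.3e-6,
#'                     ligandConc = 20e-6)
#' @export
fractionalOccupancy <- function(KD, proteinConc, ligandConc) {
  n <- max(length(KD), length(proteinConc), length(ligandConc))
  KD <- rep_len(as.numeric(KD), n)
  P <- rep_len(as.numeric(proteinConc), n)
  L <- rep_len(as.numeric(ligandConc), n)
  if (any(is.na(c(KD, P, L))) || any(c(KD, L) < 0) || any(P <= 0))
    stop("fractionalOccupancy: need KD >= 0, ligandConc >= 0, proteinConc > 0")
  b <- P + L + KD
  disc <- pmax(b * b - 4 * P * L, 0)
  x <- ifelse(P * L == 0, 0, 2 * P * L / (b + sqrt(disc)))
  pmin(pmax(x / P, 0), 1)
}

#' Final concentrations of a mixing design
#'
#' Volume-weighted averaging of each solute's concentration and of the
#' D2O fraction over all components.
#'
#' @param design a [MixDesign-class]
#' @param signif number of significant figures for the `summary`
#'   renderings (default 2, matching common reporting practice)
#' @return a list with `concentrations` (named, exact), `d2oFraction`
#'   (exact), `totalVolume`, and `summary`, a data.frame of the same
#'   quantities rounded to `signif` significant figures
#' @examples
#' d <- mixDesign(volume = c(1, 27, 2), soluteConc = c(100, 0, 0),
#'                d2oFraction = c(0, 0.999, 0),
#'                solute = c("protein", "", ""))
#' mixConcentrations(d)$summary   # protein 3.3, D2O 0.90
#' @export
mixConcentrations <- function(design, signif = 2) {
  stopifnot(is(design, "MixDesign"))
  total <- sum(design@volume)
  if (total <= 0)
    stop("mixConcentrations: total volume must be > 0")
  solutes <- unique(design@solute[design@solute != ""])
  conc <- vapply(solutes, function(s) {
    sel <- design@solute == s
    sum(design@volume[sel] * design@soluteConc[sel]) / total
  }, numeric(1))
  d2o <- sum(design@volume * design@d2oFraction) / total
  list(
    concentrations = conc,
    d2oFraction = d2o,
    totalVolume = total,
    summary = data.frame(
      quantity = c(solutes, "D2O fraction"),
      value = base::signif(c(conc, d2o), signif),
      stringsAsFactors = FALSE
    )
  )
}

#' Ligand-to-protein concentration ratio
#'
#' @param ligandConc ligand concentration
#' @param proteinConc protein concentration (same unit); must be > 0
#' @param signif significant figures for the rendered label (default 2)
#' @return list with `ratio` (exact) and `label` such as `"6:1"` or
#'   `"1500:1"` (ratio rounded to `signif` significant figures)
#' @examples
#' ligandProteinRatio(20, 10 / 3)$label   # "6:1"
#' ligandProteinRatio(5000, 10 / 3)$label # "1500:1"
#' @export
ligandProteinRatio <- function(ligandConc, proteinConc, signif = 2) {
  if (any(is.na(proteinConc)) || any(proteinConc <= 0))
    stop("ligandProteinRatio: 'proteinConc' must be > 0")
  ratio <- ligandConc / proteinConc
  r2 <- base::signif(ratio, signif)
  list(ratio = ratio,
       label = paste0(format(r2, scientific = FALSE, trim = TRUE), ":1"))
}

#' Check whether exchange conditions saturate the binding site
#'
#' Classifies an experimental design into the three kinetic scenarios of
#' the two-state exchange model: (1) "slow-off" -- dissociation so slow
#' that the complex would not open during the exchange time course;
#' (2) "intermediate" -- the full observed-rate expression is needed;
#' (3) "saturating" -- ligand in vast excess
#' (\eqn{k_{on}[L] \ge factor \times k_{ex}}), where the limiting form
#' applies and the complex reassociates before an exchange event.
#' Also reports the exact fractional occupancy.
#'
#' @param kin a [BindingKinetics-class] with full kinetics and
#'   concentrations
#' @param kex intrinsic exchange rate to compare against, per minute
#' @param saturationFactor the multiple of `kex` that `kOn*[L]` must
#'   reach to count as "vast excess" (default 10)
#' @param slowOffRate dissociation rate below which the complex is
#'   considered non-dissociating on the experimental timescale
#'   (default 1e-2 per minute)
#' @return a list with `occupancy`, `saturationRatio` (`kOn*[L]/kex`),
#'   `saturated` (logical), `scenario` (one of `"no-binding"`,
#'   `"slow-off"`, `"intermediate"`, `"saturating"`) and `message`
#' @examples
#' kin <- bindingKinetics(kOn = 1e6, KD = 19e-9, ligandConc = 20e-6,
#'                        proteinConc = 3.3e-6)
#' saturationCheck(kin, kex = 0.1)
#' @export
saturationCheck <- function(kin, kex, saturationFactor = 10,
                            slowOffRate = 1e-2) {
  stopifnot(is(kin, "BindingKinetics"))
  if (is.na(kin@ligandConc))
    stop("saturationCheck: 'ligandConc' must be supplied")
  if (kin@ligandConc == 0) {
    return(list(occupancy = 0, saturationRatio = 0, saturated = FALSE,
                scenario = "no-binding",
                message = "no ligand present; no binding expected"))
  }
  if (is.na(kin@KD) || is.na(kin@proteinConc) || is.na(kin@kOn) ||
      is.na(kin@kOff))
    stop("saturationCheck: full kinetics (kOn, kOff, KD, proteinConc) required")
  occ <- fractionalOccupancy(kin@KD, kin@proteinConc, kin@ligandConc)
  satRatio <- kin@kOn * kin@ligandConc / kex
  saturated <- satRatio >= saturationFactor
  scenario <-
    if (kin@kOff < slowOffRate) "slow-off"
    else if (saturated) "saturating"
    else "intermediate"
  msg <- switch(scenario,
    "slow-off" = sprintf(
      "slow-off: kOff = %.3g /min; the complex would not dissociate during the time course",
      kin@kOff),
    "saturating" = sprintf(
      "saturating: kOn*[L] = %.3g x kex; limiting-rate form valid; occupancy %.3f",
      satRatio, occ),
    "intermediate" = sprintf(
      "intermediate: kOn*[L] = %.3g x kex (< %g x); full observed-rate expression needed",
      satRatio, saturationFactor))
  list(occupancy = occ, saturationRatio = satRatio, saturated = saturated,
       scenario = scenario, message = msg)
}

#' Parse a concentration with a molar-unit suffix
#'
#' Accepts strings such as `"20uM"`, `"19 nM"`, `"5mM"`, `"3.3e-6"`
#' (plain numbers are taken as molar) and returns molar values.
#'
#' @param x character or numeric vector
#' @return numeric vector, molar
#' @examples
#' parseConcentration(c("20uM", "19nM", "5mM", "1M"))
#' @export
parseConcentration <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
  vapply(as.character(x), function(s) {
    s <- gsub("[[:space:]]", "", s)
    s <- sub("µ", "u", s)  # micro sign
    m <- regmatches(s, regexec("^([0-9.eE+-]+)(pM|nM|uM|mM|M)?$", s))[[1]]
    if (length(m) == 0L || m[2] == "")
      stop("parseConcentration: cannot parse '", s, "'")
    val <- as.numeric(m[2])
    unit <- if (m[3] == "") "M" else m[3]
    val * scale[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
}
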