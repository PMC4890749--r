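#' @include AllClasses.R accessors.R
NULL

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Count exchange-observable backbone amides of a peptide
#'
#' HDX-MS does not observe every backbone amide of a proteolytic
#' peptide: the first `nFastTermini` residues are discounted because
#' their amides back-exchange too fast to retain label, and proline has
#' no backbone amide hydrogen. The count is
#' `(length - nFastTermini) - (prolines after the exempted positions)`,
#' floored at zero.
#'
#' @param sequence one-letter amino-acid string(s); vectorised
#' @param nFastTermini number of N-terminal residues discounted
#'   (default 1; a common back-exchange convention uses 2)
#' @return integer count(s) of exchangeable amides
#' @examples
#' exchangeableAmides("GGGGG")            # 4
#' exchangeableAmides("GPGPG")            # 2
#' exchangeableAmides("P")                # 0
#' @export
exchangeableAmides <- function(sequence, nFastTermini = 1) {
  nFastTermini <- as.integer(nFastTermini)
  vapply(as.character(sequence), function(s) {
    if (is.na(s) || nchar(s) == 0L)
      stop("exchangeableAmides: sequence must be non-empty")
    chars <- strsplit(toupper(s), "")[[1]]
    bad <- which(!chars %in% .AA)
    if (length(bad))
      stop(sprintf(
        "exchangeableAmides: invalid residue '%s' at position %d",
        chars[bad[1]], bad[1]))
    tail_chars <- chars[seq_along(chars) > nFastTermini]
    max(length(tail_chars) - sum(tail_chars == "P"), 0L)
  }, integer(1), USE.NAMES = FALSE)
}

#' Construct an HDXPeptideSet
#'
#' @param id unique peptide identifiers
#' @param start,end 1-based inclusive residue spans
#' @param sequence one-letter sequences of length `end - start + 1`
#' @param nFastTermini N-terminal residues discounted when counting
#'   exchangeable amides (see [exchangeableAmides()])
#' @return an [HDXPeptideSet-class]
#' @export
peptideSet <- function(id, start, end, sequence, nFastTermini = 1) {
  r <- IRanges::IRanges(start = as.integer(start), end = as.integer(end),
                        names = as.character(id))
  S4Vectors::mcols(r) <- S4Vectors::DataFrame(
    sequence = as.character(sequence),
    nExchangeable = exchangeableAmides(sequence, nFastTermini))
  new("HDXPeptideSet", ranges = r)
}

#' Construct an UptakeExperiment
#'
#' @param peptides an [HDXPeptideSet-class]
#' @param records a data.frame/DataFrame with columns `peptide_id`,
#'   `state`, `exposure_min`, `uptake_da`, `sd_da`
#' @param d2oFraction labelling D2O fraction (default 0.9)
#' @param tolerance slack above the theoretical uptake ceiling per
#'   amide before validation fails (default 0.1)
#' @return an [UptakeExperiment-class]
#' @export
uptakeExperiment <- function(peptides, records, d2oFraction = 0.9,
                             tolerance = 0.1) {
  new("UptakeExperiment", peptides = peptides,
      records = S4Vectors::DataFrame(as.data.frame(records)),
      d2oFraction = d2oFraction, tolerance = tolerance)
}

#' Relative deuterium uptake per peptide and exposure
#'
#' RDU is the ratio of deuterons exchanged to exchangeable amides,
#' `uptake_da / nExchangeable` (optionally divided further by the
#' labelling D2O fraction). Peptides with no exchangeable amides are
#' excluded with a warning. Values outside `[0, 1 + tolerance]` are a
#' validation error.
#'
#' @param x an [UptakeExperiment-class]
#' @param correctD2O divide by the D2O fraction as well (default FALSE,
#'   so the theoretical maximum RDU equals the D2O fraction)
#' @param tolerance slack above 1 before validation fails (default 0.1)
#' @return a `DataFrame` with `peptide_id`, `state`, `exposure_min`, `rdu`
#' @examples
#' peps <- peptideSet("p1", 1, 6, "GGGGGG")  # 5 exchangeable amides
#' ue <- uptakeExperiment(peps, data.frame(
#'   peptide_id = "p1", state = "apo", exposure_min = 10,
#'   uptake_da = 3.35, sd_da = 0))
#' computeRDU(ue)$rdu   # 0.67
#' @export
computeRDU <- function(x, correctD2O = FALSE, tolerance = 0.1) {
  stopifnot(is(x, "UptakeExperiment"))
  rec <- x@records
  nex <- nExchangeable(x@peptides)
  unknown <- setdiff(unique(rec$peptide_id), names(nex))
  if (length(unknown))
    stop("computeRDU: unknown peptide ids: ", paste(unknown, collapse = ", "))
  zero <- names(nex)[nex == 0L]
  if (length(zero) && any(rec$peptide_id %in% zero)) {
    warning("computeRDU: excluding peptides with no exchangeable amides: ",
            paste(intersect(zero, unique(rec$peptide_id)), collapse = ", "))
    rec <- rec[!rec$peptide_id %in% zero, , drop = FALSE]
  }
  denom <- nex[rec$peptide_id]
  if (correctD2O) denom <- denom * x@d2oFraction
  rdu <- unname(rec$uptake_da / denom)
  bad <- rdu > 1 + tolerance
  if (any(bad))
    stop("computeRDU: RDU exceeds 1 + tolerance for peptides: ",
         paste(unique(rec$peptide_id[bad]), collapse = ", "))
  S4Vectors::DataFrame(peptide_id = rec$peptide_id, state = rec$state,
                       exposure_min = rec$exposure_min, rdu = rdu)
}

#' Identify reporter peptides from short-time relative uptake
#'
#' A peptide is a reporter if its RDU at any short labelling time
#' exceeds `factor` times the maximum RDU observed over all peptides at
#' the short times:
#' \deqn{RDU > factor \times \max RDU\ (short\ labeling\ times)}
#' Reporters are the dynamic regions best suited to monitoring ligand
#' interactions.
#'
#' @param rdu the table returned by [computeRDU()] (or any data.frame
#'   with `peptide_id`, `exposure_min`, `rdu`)
#' @param shortTimes exposures (minutes) counted as "short labelling
#'   times"; must be present in the table
#' @param factor fraction of the maximum (default 0.5); in (0, 1)
#' @return list with `threshold`, `maxRDU`, `reporters` (peptide ids)
#'   and `table` (the short-time rows with a `reporter` flag)
#' @examples
#' tab <- data.frame(peptide_id = c("a", "b"), exposure_min = 10,
#'                   rdu = c(0.67, 0.30))
#' reporterRegions(tab, shortTimes = 10)$threshold  # 0.335
#' @export
reporterRegions <- function(rdu, shortTimes, factor = 0.5) {
  rdu <- as.data.frame(rdu)
  if (nrow(rdu) == 0L)
    stop("reporterRegions: empty RDU table")
  if (!(factor > 0 && factor < 1))
    stop("reporterRegions: 'factor' must lie in (0, 1)")
  if (length(shortTimes) == 0L)
    stop("reporterRegions: 'shortTimes' must be non-empty")
  missing_t <- setdiff(shortTimes, unique(rdu$exposure_min))
  if (length(missing_t))
    stop("reporterRegions: short times absent from table: ",
         paste(missing_t, collapse = ", "))
  short <- rdu[rdu$exposure_min %in% shortTimes, , drop = FALSE]
  maxRDU <- max(short$rdu)
  threshold <- factor * maxRDU
  short$reporter <- short$rdu > threshold
  reporters <- sort(unique(short$peptide_id[short$reporter]))
  list(threshold = threshold, maxRDU = maxRDU, reporters = reporters,
       table = short)
}

#' Apo-versus-bound uptake difference profile
#'
#' Computes \eqn{\Delta = uptake_{apo} - uptake_{bound}} per (peptide,
#' exposure); positive differences mean protection (decreased exchange
#' in the bound state). A peptide is significant when
#' \eqn{|\Delta| >} `thresholdDa` at at least `minTimepoints`
#' exposures; its direction is taken from the sign of the exceeding
#' differences ("mixed" when both signs exceed).
#'
#' @param x an [UptakeExperiment-class] containing both states
#' @param apoState,boundState state labels to compare
#' @param thresholdDa significance threshold in Daltons (default 0.5)
#' @param minTimepoints minimum exposures beyond threshold (default 1)
#' @param strict if TRUE (default) the two states must share an
#'   identical (peptide, exposure) grid, otherwise an error lists the
#'   missing pairs; if FALSE the intersection is used
#' @return a [DifferenceProfile-class]
#' @export
differenceProfile <- function(x, apoState = "apo", boundState,
                              thresholdDa = 0.5, minTimepoints = 1L,
                              strict = TRUE) {
  stopifnot(is(x, "UptakeExperiment"))
  if (!(thresholdDa > 0)) stop("differenceProfile: thresholdDa must be > 0")
  rec <- as.data.frame(x@records)
  a <- rec[rec$state == apoState, , drop = FALSE]
  b <- rec[rec$state == boundState, , drop = FALSE]
  if (nrow(a) == 0L) stop("differenceProfile: no records for state '",
                          apoState, "'")
  if (nrow(b) == 0L) stop("differenceProfile: no records for state '",
                          boundState, "'")
  keyA <- paste(a$peptide_id, a$exposure_min)
  keyB <- paste(b$peptide_id, b$exposure_min)
  if (anyDuplicated(keyA) || anyDuplicated(keyB))
    stop("differenceProfile: duplicated (peptide, exposure) rows; ",
         "aggregate replicates first")
  onlyA <- setdiff(keyA, keyB); onlyB <- setdiff(keyB, keyA)
  if (length(onlyA) || length(onlyB)) {
    if (strict)
      stop("differenceProfile: exposure grids differ between states.\n",
           if (length(onlyA)) paste0("  missing in '", boundState, "': ",
                paste(utils::head(onlyA, 10), collapse = "; "), "\n") else "",
           if (length(onlyB)) paste0("  missing in '", apoState, "': ",
                paste(utils::head(onlyB, 10), collapse = "; "), "\n") else "",
           "  (use strict = FALSE to analyse the intersection)")
    shared <- intersect(keyA, keyB)
    a <- a[keyA %in% shared, , drop = FALSE]
    b <- b[keyB %in% shared, , drop = FALSE]
    keyA <- paste(a$peptide_id, a$exposure_min)
    keyB <- paste(b$peptide_id, b$exposure_min)
  }
  b <- b[match(keyA, keyB), , drop = FALSE]
  delta <- a$uptake_da - b$uptake_da
  # auxiliary replicate-SD z-score; a diagnostic only, never used for
  # the significance call (which is the fixed Dalton threshold)
  sdpool <- sqrt(a$sd_da^2 + b$sd_da^2)
  zscore <- ifelse(sdpool > 0, delta / sdpool, NA_real_)
  deltas <- S4Vectors::DataFrame(
    peptide_id = a$peptide_id, exposure_min = a$exposure_min,
    delta_da = delta, zscore = zscore)
  r <- peptideRanges(x@peptides)
  ids <- unique(a$peptide_id)
  calls <- do.call(rbind, lapply(ids, function(pid) {
    d <- delta[a$peptide_id == pid]
    exceed <- abs(d) > thresholdDa
    nex <- sum(exceed)
    sig <- nex >= minTimepoints
    dir <- if (!sig) NA_character_
    else {
      signs <- unique(sign(d[exceed]))
      if (length(signs) > 1L) "mixed"
      else if (signs > 0) "protection" else "deprotection"
    }
    z <- zscore[a$peptide_id == pid]
    data.frame(peptide_id = pid,
               start = IRanges::start(r[pid]), end = IRanges::end(r[pid]),
               significant = sig, direction = dir,
               maxAbsDelta = max(abs(d)), nExceeding = nex,
               maxAbsZ = if (all(is.na(z))) NA_real_
                         else max(abs(z), na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  new("DifferenceProfile",
      states = c(apoState, boundState),
      deltas = deltas,
      peptideCalls = S4Vectors::DataFrame(calls),
      thresholdDa = thresholdDa,
      minTimepoints = as.integer(minTimepoints))
}
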