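#' @include AllClasses.R accessors.R uptake.R
NULL

.emptyRegionIRanges <- function() {
  r <- IRanges::IRanges()
  S4Vectors::mcols(r) <- S4Vectors::DataFrame(
    direction = character(0), maxDelta = numeric(0),
    peptideIds = IRanges::CharacterList(),
    label = character(0),
    contactResidues = IRanges::IntegerList())
  r
}

#' Construct a ResponseRegionSet directly from intervals
#'
#' Mainly useful for feeding a published region catalogue straight into
#' [classifyRegions()] without re-deriving the regions from peptide
#' data. Intervals must be pairwise non-overlapping.
#'
#' @param start,end 1-based inclusive residue intervals
#' @param direction per-region direction (default "protection")
#' @param maxDelta per-region magnitude in Da (default `NA`)
#' @param peptideIds optional list of member peptide ids per region
#' @param names optional region names
#' @param thresholdDa the significance threshold the regions correspond
#'   to (default 0.5 Da)
#' @return a [ResponseRegionSet-class]
#' @export
responseRegions <- function(start, end, direction = "protection",
                            maxDelta = NA_real_, peptideIds = NULL,
                            names = NULL, thresholdDa = 0.5) {
  n <- length(start)
  r <- IRanges::IRanges(start = as.integer(start), end = as.integer(end),
                        names = names)
  if (is.null(peptideIds)) peptideIds <- rep(list(character(0)), n)
  S4Vectors::mcols(r) <- S4Vectors::DataFrame(
    direction = rep_len(as.character(direction), n),
    maxDelta = rep_len(as.numeric(maxDelta), n),
    peptideIds = IRanges::CharacterList(peptideIds),
    label = rep(NA_character_, n),
    contactResidues = IRanges::IntegerList(rep(list(integer(0)), n)))
  new("ResponseRegionSet", regions = r,
      deltaByExposure = matrix(numeric(0), nrow = n, ncol = 0),
      thresholdDa = thresholdDa)
}

#' Merge significant peptides into response regions
#'
#' Significant peptides of like direction whose residue spans overlap or
#' lie within `maxGap` residues of one another are unioned into a single
#' response region. Opposite-direction peptides are never merged
#' directly; where a protection region and a deprotection region end up
#' overlapping, they are combined into one region of direction
#' `"mixed"` with a warning, so that the output intervals are always
#' pairwise non-overlapping. The operation is idempotent and the output
#' is sorted by start.
#'
#' @param x a [DifferenceProfile-class], or a data.frame with columns
#'   `start`, `end` and optionally `direction`, `peptide_id`,
#'   `maxAbsDelta`
#' @param maxGap maximum residue gap bridged when merging (default 0:
#'   overlapping or directly adjacent spans merge)
#' @return a [ResponseRegionSet-class]
#' @examples
#' df <- data.frame(peptide_id = c("a", "b"), start = c(45, 55),
#'                  end = c(58, 70), direction = "protection")
#' regionTable(mergeRegions(df))   # one region 45-70
#' @export
setGeneric("mergeRegions", function(x, maxGap = 0L) {
  standardGeneric("mergeRegions")
})

.mergePeptideTable <- function(sig, maxGap, deltas = NULL,
                               thresholdDa = 0.5) {
  exposure_grid <- if (!is.null(deltas)) sort(unique(deltas$exposure_min))
                   else numeric(0)
  if (nrow(sig) == 0L) {
    return(new("ResponseRegionSet", regions = .emptyRegionIRanges(),
               deltaByExposure = matrix(numeric(0), 0, length(exposure_grid),
                 dimnames = list(NULL, as.character(exposure_grid))),
               thresholdDa = thresholdDa))
  }
  if (is.null(sig$direction)) sig$direction <- "protection"
  if (is.null(sig$peptide_id)) sig$peptide_id <- as.character(seq_len(nrow(sig)))
  pepR <- IRanges::IRanges(start = as.integer(sig$start),
                           end = as.integer(sig$end),
                           names = sig$peptide_id)

  # per-direction union of overlapping-or-near spans
  dirRegions <- list()
  for (d in unique(sig$direction)) {
    sel <- sig$direction == d
    red <- IRanges::reduce(pepR[sel], min.gapwidth = as.integer(maxGap) + 1L)
    S4Vectors::mcols(red) <- S4Vectors::DataFrame(
      direction = rep(d, length(red)))
    dirRegions[[d]] <- red
  }
  all_r <- do.call(c, unname(dirRegions))

  # collapse cross-direction overlaps into "mixed" regions
  super <- IRanges::reduce(all_r, min.gapwidth = 0L)
  hits <- IRanges::findOverlaps(all_r, super)
  final_start <- integer(0); final_end <- integer(0); final_dir <- character(0)
  for (i in seq_along(super)) {
    members <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]
    dirs <- unique(S4Vectors::mcols(all_r)$direction[members])
    if (length(dirs) > 1L) {
      warning("mergeRegions: residues covered by both protection and ",
              "deprotection peptides; reporting a single 'mixed' region ",
              sprintf("%d-%d", IRanges::start(super)[i],
                      IRanges::end(super)[i]))
      final_start <- c(final_start, IRanges::start(super)[i])
      final_end <- c(final_end, IRanges::end(super)[i])
      final_dir <- c(final_dir, "mixed")
    } else {
      for (m in members) {
        final_start <- c(final_start, IRanges::start(all_r)[m])
        final_end <- c(final_end, IRanges::end(all_r)[m])
        final_dir <- c(final_dir, dirs)
      }
    }
  }
  o <- order(final_start, final_end)
  out <- IRanges::IRanges(start = final_start[o], end = final_end[o])
  dir_out <- final_dir[o]

  memb <- IRanges::findOverlaps(pepR, out)
  pid_list <- lapply(seq_along(out), function(i) {
    sort(unique(names(pepR)[S4Vectors::queryHits(memb)[
      S4Vectors::subjectHits(memb) == i]]))
  })
  dbe <- matrix(NA_real_, nrow = length(out), ncol = length(exposure_grid),
                dimnames = list(NULL, as.character(exposure_grid)))
  maxDelta <- rep(NA_real_, length(out))
  if (!is.null(deltas)) {
    for (i in seq_along(out)) {
      d <- deltas[deltas$peptide_id %in% pid_list[[i]], , drop = FALSE]
      if (nrow(d)) {
        agg <- tapply(abs(d$delta_da), d$exposure_min, max)
        dbe[i, names(agg)] <- as.numeric(agg)
        maxDelta[i] <- max(abs(d$delta_da))
      }
    }
  } else if (!is.null(sig$maxAbsDelta)) {
    for (i in seq_along(out))
      maxDelta[i] <- max(sig$maxAbsDelta[sig$peptide_id %in% pid_list[[i]]])
  }
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    direction = dir_out, maxDelta = maxDelta,
    peptideIds = IRanges::CharacterList(pid_list),
    label = rep(NA_character_, length(out)),
    contactResidues = IRanges::IntegerList(
      rep(list(integer(0)), length(out))))
  new("ResponseRegionSet", regions = out, deltaByExposure = dbe,
      thresholdDa = thresholdDa)
}

#' @rdname mergeRegions
setMethod("mergeRegions", "DifferenceProfile", function(x, maxGap = 0L) {
  sig <- as.data.frame(significantPeptides(x))
  .mergePeptideTable(sig, maxGap, deltas = as.data.frame(x@deltas),
                     thresholdDa = x@thresholdDa)
})

#' @rdname mergeRegions
setMethod("mergeRegions", "data.frame", function(x, maxGap = 0L) {
  .mergePeptideTable(x, maxGap)
})

#' @rdname mergeRegions
setMethod("mergeRegions", "ResponseRegionSet", function(x, maxGap = 0L) {
  tab <- regionTable(x)
  tab$peptide_id <- paste0("region", seq_len(nrow(tab)))
  tab$maxAbsDelta <- tab$maxDelta
  .mergePeptideTable(tab, maxGap, thresholdDa = x@thresholdDa)
})
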