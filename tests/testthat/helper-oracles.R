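# Independent oracles used across the suite. These deliberately use
# naive formulations (bisection, explicit loops, per-residue sets) so
# they share no code path with the package implementation.

# Equilibrium complex concentration by bisection on
# (P - x)(L - x) = KD * x, root in [0, min(P, L)].
bisectOccupancy <- function(KD, P, L, iter = 200) {
  f <- function(x) (P - x) * (L - x) - KD * x
  lo <- 0; hi <- min(P, L)
  if (hi == 0) return(0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / P
}

# All-pairs distance scan with explicit loops.
bruteContacts <- function(protein, ligand, cutoff) {
  hits <- integer(0)
  for (rn in unique(protein$resno)) {
    atoms <- protein[protein$resno == rn, , drop = FALSE]
    found <- FALSE
    for (i in seq_len(nrow(atoms))) {
      for (j in seq_len(nrow(ligand))) {
        d <- sqrt((atoms$x[i] - ligand$x[j])^2 +
                  (atoms$y[i] - ligand$y[j])^2 +
                  (atoms$z[i] - ligand$z[j])^2)
        if (d <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hits <- c(hits, rn)
  }
  sort(hits)
}

# Residue-set union of intervals, re-segmented into maximal runs.
unionRuns <- function(start, end) {
  res <- sort(unique(unlist(mapply(seq, start, end, SIMPLIFY = FALSE))))
  if (length(res) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  brk <- c(0L, which(diff(res) > 1L), length(res))
  data.frame(
    start = res[brk[-length(brk)] + 1L],
    end = res[brk[-1L]])
}

# Random rigid-body transform applied to a coordinate table.
applyRigid <- function(df, R, t) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  df$x <- xyz[, 1] + t[1]; df$y <- xyz[, 2] + t[2]; df$z <- xyz[, 3] + t[3]
  df
}

randomRotation <- function() {
  a <- stats::runif(3, 0, 2 * pi)
  Rz <- matrix(c(cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0,
                 -sin(a[2]), 0, cos(a[2])), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(a[3]), -sin(a[3]),
                 0, sin(a[3]), cos(a[3])), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}
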