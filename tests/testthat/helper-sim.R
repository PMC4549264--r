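# Shared fixtures, built once per test run.  The "default" objects use the
# generator's default configuration (2 x 1 Mb, ~10,800 nucleosomes, 600,000
# fragments) and back the parameter-recovery and acceptance checks; the
# "small" configuration keeps unit tests fast.

.fixtures <- new.env(parent = emptyenv())

.memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

defaultSim <- function() .memo("sim", function() {
  suppressWarnings(simulateDataset(simConfig()))
})

defaultNosRaw <- function() .memo("nosRaw", function() {
  suppressWarnings(computeNOS(deduplicateFragments(defaultSim()$fragments)))
})

defaultNos <- function() .memo("nos", function() {
  normalizeTracks(defaultNosRaw())
})

defaultCalls <- function() .memo("calls", function() {
  suppressWarnings(callNucleosomes(defaultNos()))
})

# two independent half-depth fragment samples of the same truth
replicateTracks <- function() .memo("reps", function() {
  sim <- defaultSim()
  half <- sim$config@nFragments %/% 2L
  lapply(c(1001L, 2002L), function(s) {
    fr <- sampleFragments(sim$nucleosomes, simConfig(seed = s, nFragments = half))
    normalizeTracks(suppressWarnings(computeNOS(deduplicateFragments(fr))))
  })
})

smallConfig <- function(...) {
  args <- list(genomeLength = 2e5, nChroms = 1L, nGenes = 20L,
               nFragments = 40000L, nEnhancers = 4L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simConfig, args)
}

# distance from each position in `truth` to the nearest element of `called`
nearestDist <- function(truth, called) {
  vapply(truth, function(x) min(abs(called - x)), numeric(1))
}

# per-chromosome recovery of true positioned dyads by called dyads
dyadRecovery <- function(truthGr, calls, tol = 20) {
  ch <- as.character(GenomicRanges::seqnames(truthGr))
  cch <- as.character(GenomicRanges::seqnames(calls))
  hits <- unlist(lapply(unique(ch), function(cc) {
    nearestDist(GenomicRanges::start(truthGr)[ch == cc],
                calls$dyad[cch == cc]) <= tol
  }))
  mean(hits)
}

# single-base spike track for caller toys
spikeTrack <- function(pos, height, len = max(pos) + 500L) {
  v <- numeric(len)
  v[pos] <- height
  GenomeTrack(list(chr1 = v))
}

# exhaustive oracle: best legal dyad subset among single-base candidates,
# either maximizing summed height or the lexicographic (priority) order of
# descending heights; legal = all pairwise distances >= minSpacing
exhaustiveCaller <- function(pos, height, minSpacing = 150L,
                             objective = c("lex", "sum")) {
  objective <- match.arg(objective)
  n <- length(pos)
  best <- integer(0); bestKey <- NULL
  keyOf <- function(idx) {
    if (!length(idx)) return(numeric(0))
    sort(height[idx], decreasing = TRUE)
  }
  better <- function(a, b) {           # is key a better than key b?
    if (is.null(b)) return(TRUE)
    if (objective == "sum") return(sum(a) > sum(b))
    la <- length(a); lb <- length(b)
    for (i in seq_len(min(la, lb))) {
      if (a[i] != b[i]) return(a[i] > b[i])
    }
    la > lb
  }
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) > 1) {
      d <- pos[idx]
      if (min(diff(sort(d))) < minSpacing) next
    }
    key <- keyOf(idx)
    if (better(key, bestKey)) { bestKey <- key; best <- idx }
  }
  sort(pos[best])
}

# exact two-sided Mann-Whitney p by complete enumeration of labelings
exactMWW <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  mu <- nx * length(y) / 2
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  labelings <- utils::combn(length(pooled), nx)
  u <- apply(labelings, 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  mean(abs(u - mu) >= abs(obs - mu) - 1e-9)
}
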