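# Methylation-dyad geometry: site assignment, occupancy stratification
# with rank tests, distance histograms, in-core periodicity, and the
# high-occupancy subset.

.nuc <- function(dyads, chrom = "c1", summit = NULL, meanNos = NULL) {
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(dyads - 73L, dyads + 73L), dyad = as.integer(dyads))
  if (!is.null(summit)) gr$summitNos <- summit
  if (!is.null(meanNos)) gr$meanNos <- meanNos
  names(gr) <- paste0("nuc", seq_along(gr))
  gr
}

test_that("sites are assigned to cores by half-open interval membership", {
  # core [101, 248) in BED terms: 0-based positions 101..247
  nucs <- readNucleosomesBed(local({
    f <- tempfile()
    writeLines("c1\t101\t248\tnuc1\t5\t.\t174\t3.2", f)
    f
  }))
  mk <- function(pos0) data.frame(chrom = "c1", pos = pos0 + 1,
                                  context = "mCG")
  expect_equal(sum(assignSitesToNucleosomes(mk(150), nucs)), 1)
  expect_equal(sum(assignSitesToNucleosomes(mk(300), nucs)), 0)
  expect_equal(sum(assignSitesToNucleosomes(mk(101), nucs)), 1)  # at start
  expect_equal(sum(assignSitesToNucleosomes(mk(248), nucs)), 0)  # at end
  # linker site between two adjacent cores counts for neither
  two <- .nuc(c(1000, 1300))
  linker <- data.frame(chrom = "c1", pos = 1150, context = "mCHH")
  expect_true(all(assignSitesToNucleosomes(linker, two) == 0))
  # per-context columns
  ss <- data.frame(chrom = "c1", pos = c(1000, 1010, 1300),
                   context = c("mCG", "mCHH", "mCG"))
  ct <- assignSitesToNucleosomes(ss, two)
  expect_equal(ct[1, "mCG"], 1L)
  expect_equal(ct[1, "mCHH"], 1L)
  expect_equal(ct[2, "mCG"], 1L)
})

test_that("occupancy stratification reproduces exact rank statistics", {
  # Mann-Whitney {1,2} vs {3,4}: exact two-sided p = 1/3
  expect_equal(wilcox.test(c(1, 2), c(3, 4))$p.value, 1 / 3)
  # package pairwise tests match the enumeration oracle for small groups
  set.seed(77)
  for (rep in 1:8) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(seq(1, 1000), nx); y <- sample(seq(1, 1000), ny)
    expect_equal(wilcox.test(x, y, alternative = "two.sided")$p.value,
                 exactMWW(x, y))
  }
  # Bonferroni is raw * m capped at 1
  nucs <- .nuc(seq(1000, 10000, by = 300),
               meanNos = c(rep(1:5, each = 6), 6))
  counts <- matrix(c(rep(0:4, each = 6), 4L), ncol = 1,
                   dimnames = list(names(nucs), "mCG"))
  st <- occupancyByCount(nucs, counts, "mCG")
  expect_equal(st$pairwise$bonferroniP,
               pmin(1, st$pairwise$rawP * nrow(st$pairwise)))
  expect_equal(nrow(st$pairwise), choose(5, 2))
  expect_equal(st$groups$label, c("0", "1", "2", "3", "4+"))
  expect_true(all(st$pairwise$rawP >= 0 & st$pairwise$rawP <= 1))
  # single non-empty bucket errors
  c0 <- matrix(0L, length(nucs), 1, dimnames = list(names(nucs), "mCG"))
  expect_error(occupancyByCount(nucs, c0, "mCG"), "degenerate")
})

test_that("planted weight-coupled methylation gives monotone occupancy", {
  sim <- defaultSim()
  nucs <- defaultCalls()
  counts <- assignSitesToNucleosomes(sim$methylation, nucs)
  st <- occupancyByCount(nucs, counts, "mCG")
  expect_true(all(diff(st$groups$meanNos) > 0))
  expect_lt(st$kwP, 1e-10)
  expect_true(all(st$pairwise$bonferroniP[
    st$pairwise$groupA == "0" & st$pairwise$groupB == "4+"] < 1e-6))
})

test_that("distance-to-dyad histograms follow the signed convention", {
  dy <- data.frame(chrom = "c1", pos = c(1000, 1300))
  # site at a dyad: distance 0
  h0 <- distanceToNearestDyad(data.frame(chrom = "c1", pos = 1000,
                                         context = "mCG"), dy)
  expect_equal(h0$count[h0$offset == 0], 1)
  # dyads {1000, 1300}, site 1060: +60 to the nearest (1000)
  h <- distanceToNearestDyad(data.frame(chrom = "c1", pos = 1060,
                                        context = "mCG"), dy)
  expect_equal(h$count[h$offset == 60], 1)
  # equidistant site 1150: resolves to the downstream dyad (-150), which
  # is outside the core view but still counted in nTotal
  h2 <- distanceToNearestDyad(data.frame(chrom = "c1", pos = 1150,
                                         context = "mCG"), dy)
  expect_equal(attr(h2, "nSites"), 0)
  expect_equal(attr(h2, "nTotal"), 1)
  # percentages sum to 100
  ss <- data.frame(chrom = "c1", pos = c(990, 1000, 1010, 1330),
                   context = "mCG")
  h3 <- distanceToNearestDyad(ss, dy)
  expect_equal(sum(h3$frequencyPercent), 100, tolerance = 1e-8)
  expect_error(distanceToNearestDyad(ss, data.frame(chrom = character(0),
                                                    pos = integer(0))),
               "no dyads")
})

test_that("in-core methylation periodicity round-trips through the FFT", {
  p <- -73:73
  mkProfiles <- function(P) {
    prof <- defaultMethProfiles()
    w <- 1 + cos(2 * pi * p / P)
    prof$mCG <- w / sum(w)
    prof
  }
  for (P in c(8, 10)) {
    cfg <- smallConfig(methDyadProfile = mkProfiles(P),
                       methDensityByContext = c(mCG = 0.05, mCHG = 0.002,
                                                mCHH = 0.005, hmC = 0.001),
                       methCoreFraction = c(mCG = 1, mCHG = 0.75,
                                            mCHH = 0.2, hmC = 0.5))
    gg <- generateGenome(cfg)
    meth <- generateMethylation(gg$nucleosomes, cfg)
    h <- distanceToNearestDyad(meth, gg$nucleosomes, context = "mCG")
    est <- dominantPeriod(methylationPeriodogram(h))
    expect_lt(abs(est - P), 0.5)
  }
  # uniform placement: no dominant period
  prof <- defaultMethProfiles()
  prof$mCG <- rep(1 / 147, 147)
  cfgU <- smallConfig(methDyadProfile = prof,
                      methCoreFraction = c(mCG = 1, mCHG = 0.75,
                                           mCHH = 0.2, hmC = 0.5))
  ggU <- generateGenome(cfgU)
  mU <- generateMethylation(ggU$nucleosomes, cfgU)
  hU <- distanceToNearestDyad(mU, ggU$nucleosomes, context = "mCG")
  pgU <- methylationPeriodogram(hU, minPeakRatio = 12)
  expect_true(is.na(dominantPeriod(pgU)))
})

test_that("methylation-centred NOS reflects core vs linker placement", {
  sim <- defaultSim()
  nn <- defaultNos()
  prCG <- methylationCenteredNOS(nn, sim$methylation, "mCG")
  off <- as.integer(names(prCG))
  # core-planted mCG: occupancy maximum at the site
  expect_true(abs(off[which.max(prCG)]) <= 15)
  # linker-planted mCHH: local occupancy minimum at the site
  prHH <- methylationCenteredNOS(nn, sim$methylation, "mCHH")
  expect_lt(prHH[as.character(0)], mean(prHH[abs(off) > 150]))
  # the linker dip at the site is far below the core-planted mCG peak
  expect_lt(prHH[as.character(0)], prCG[as.character(0)])
  # slice identity and linearity
  v <- seq_len(3000)
  tr <- GenomeTrack(list(c1 = v))
  one <- methylationCenteredNOS(tr, data.frame(chrom = "c1", pos = 1500,
                                               context = "mCG"), "mCG",
                                flank = 100)
  expect_equal(unname(one), v[1400:1600], ignore_attr = TRUE)
  tr2 <- GenomeTrack(list(c1 = 2 * v))
  expect_equal(unname(methylationCenteredNOS(tr2,
    data.frame(chrom = "c1", pos = 1500, context = "mCG"), "mCG",
    flank = 100)), 2 * unname(one), ignore_attr = TRUE)
})

test_that("high-occupancy subset thresholds at the mean summit", {
  nucs <- .nuc(c(1000, 1300, 1600), summit = c(100, 200, 300))
  ss <- data.frame(chrom = "c1", pos = c(1010, 1310, 1590, 1660),
                   context = "mCG")
  h <- highOccupancySubset(ss, nucs)
  expect_equal(attr(h, "threshold"), 200)
  # only sites in the 300-summit nucleosome (strictly above the mean)
  expect_equal(attr(h, "nSites"), 2)
  expect_equal(h$count[h$offset == -10], 1)
  expect_equal(h$count[h$offset == 60], 1)
  expect_error(highOccupancySubset(ss, nucs, threshold = 500),
               "above the occupancy threshold")
  # planted geometry: high-occupancy mCGs are more dyad-proximal
  sim <- defaultSim()
  calls <- defaultCalls()
  hAll <- distanceToNearestDyad(sim$methylation, calls, context = "mCG")
  hHigh <- highOccupancySubset(sim$methylation, calls)
  massNear <- function(hh) {
    sum(hh$frequencyPercent[abs(hh$offset) <= 20])
  }
  expect_gt(massNear(hHigh), massNear(hAll))
})

test_that("mCG records that are hydroxymethylated are dropped on ingest", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("c1\t100\tmCG", "c1\t100\thmC", "c1\t200\tmCG",
               "c1\t300\tmCHH"), f)
  gr <- readMethylationTsv(f)
  expect_equal(sum(gr$context == "mCG"), 1)
  expect_equal(GenomicRanges::start(gr[gr$context == "mCG"]), 201)
  expect_equal(length(gr), 3)
})
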