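# The ground-truth generator: genome composition, landscape geometry,
# fragment sampling noise model, annotations, and methylation placement.

test_that("configuration validation rejects inconsistent parameters", {
  expect_error(simConfig(coreWidth = 146L), "odd")
  expect_error(simConfig(gcBackground = 1.4), "fractions")
  expect_error(simConfig(nGenes = 4L, nProfileClasses = 10L),
               "nProfileClasses")
  badProf <- defaultMethProfiles()
  badProf$mCG <- badProf$mCG * 2
  expect_error(simConfig(methDyadProfile = badProf), "summing to 1")
  expect_error(generateGenome(simConfig(genomeLength = 2e4, nChroms = 1L,
                                        nGenes = 10L)),
               "too small")
})

test_that("true nucleosome landscape respects spacing and bounds", {
  sim <- defaultSim()
  tru <- sim$nucleosomes
  ch <- as.character(GenomicRanges::seqnames(tru))
  for (cc in unique(ch)) {
    d <- GenomicRanges::start(tru)[ch == cc]
    expect_true(all(diff(d) >= 150))
    expect_true(all(d >= 1 & d <= sim$config@genomeLength))
  }
  expect_setequal(unique(tru$class), c("positioned", "fuzzy"))
  expect_true(all(tru$occupancyWeight > 0))
})

test_that("generator output is reproducible bit-exactly for a fixed seed", {
  cfg <- smallConfig()
  a <- generateGenome(cfg)
  b <- generateGenome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(GenomicRanges::start(a$nucleosomes),
                   GenomicRanges::start(b$nucleosomes))
  frA <- sampleFragments(a$nucleosomes, cfg)
  frB <- sampleFragments(b$nucleosomes, cfg)
  expect_identical(GenomicRanges::start(frA), GenomicRanges::start(frB))
})

test_that("base composition degenerate cases force the sequence", {
  # gc = 1 with no boost: only forced AA/TT motifs contain A or T
  cfg <- smallConfig(gcBackground = 1, gcCoreBoost = 0)
  gg <- generateGenome(cfg)
  seqStr <- as.character(gg$genome[[1]])
  at <- sum(Biostrings::alphabetFrequency(gg$genome[[1]])[c("A", "T")])
  # every A/T must come from a planted AA or TT dinucleotide
  expect_true(at > 0)
  runs <- gregexpr("[AT]+", seqStr)[[1]]
  expect_true(all(attr(runs, "match.length") %% 2 == 0))
  # amplitude 0: AA frequency profile over cores is flat up to noise
  cfg0 <- smallConfig(periodicAmplitude = 0)
  gg0 <- generateGenome(cfg0)
  prof <- dyadRelativeFrequency(gg0$genome, gg0$nucleosomes, k = 2)
  aa <- prof["AA", ]
  n <- attr(prof, "nSites")
  p <- mean(aa)
  expect_lt(sd(aa), 2 * sqrt(p * (1 - p) / n))
})

test_that("periodic AA/TT placement produces ~10 bp spaced maxima", {
  sim <- defaultSim()
  set.seed(7)
  d <- sim$nucleosomes[sample(length(sim$nucleosomes), 5000)]
  prof <- dyadRelativeFrequency(sim$genome, d, k = 2)
  aa <- prof["AA", ]
  sm <- as.numeric(stats::filter(aa, rep(1 / 3, 3), sides = 2))
  peaks <- which(diff(sign(diff(sm))) == -2) + 1
  spacing <- diff(peaks)
  expect_gt(mean(abs(spacing - 10) <= 2), 0.7)
})

test_that("fragment sampling matches the configured noise model", {
  sim <- defaultSim()
  cfg <- sim$config
  w <- Biostrings::width(sim$fragments)
  expect_true(all(w >= cfg@fragLenRange[1] & w <= cfg@fragLenRange[2]))
  expect_lt(abs(mean(w) - cfg@fragLenMean), 1)
  # duplicate fraction: each record gains a Bernoulli(dup) copy, so the
  # duplicate share is dup / (1 + dup)
  cfgD <- smallConfig(dupRate = 0.5)
  gg <- generateGenome(cfgD)
  fr <- sampleFragments(gg$nucleosomes, cfgD)
  key <- paste(GenomicRanges::seqnames(fr), GenomicRanges::start(fr),
               GenomicRanges::end(fr))
  dupFrac <- 1 - length(unique(key)) / length(key)
  expect_lt(abs(dupFrac - 1 / 3), 0.02)
  # all fragments inside chromosome bounds
  expect_true(all(GenomicRanges::start(fr) >= 1))
  expect_true(all(GenomicRanges::end(fr) <= cfgD@genomeLength))
})

test_that("zero-noise fragments reproduce true dyads exactly", {
  # uniform-weight truth: every nucleosome is sampled and every midpoint
  # is exactly its source dyad
  tru <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(500, 99500, by = 500), width = 1),
    class = "positioned", occupancyWeight = 1,
    seqlengths = c(chr1 = 100000L))
  cfg <- simConfig(jitterSdPositioned = 0, jitterSdFuzzy = 0,
                   fragLenSd = 0, dupRate = 0, nFragments = 20000L)
  fr <- sampleFragments(tru, cfg)
  mid <- (GenomicRanges::start(fr) - 1 +
            GenomicRanges::end(fr) - 1) %/% 2 + 1
  expect_setequal(unique(mid), GenomicRanges::start(tru))
  expect_true(all(Biostrings::width(fr) == round(cfg@fragLenMean)))
})

test_that("annotations are consistent with expression tiers", {
  sim <- defaultSim()
  genes <- sim$genes
  expect_false(anyDuplicated(genes$tss) > 0)
  rna <- buildRnaSignal(sim$rnaPlus, sim$rnaMinus)
  expr <- totalExpression(genes, rna)
  # silent tier emits exactly zero signal over the gene body
  expect_true(all(expr[genes$tier == 0] == 0))
  expect_true(all(expr[genes$tier > 0] > 0))
  # genes in the same class share identical TSS-relative dyad offsets
  tru <- sim$nucleosomes
  geneRoles <- c("major", "minor", "ndrFiller", "array")
  offsetsOf <- function(gi) {
    sel <- !is.na(tru$geneIndex) & tru$geneIndex == gi &
      as.character(GenomicRanges::seqnames(tru)) ==
        as.character(GenomicRanges::seqnames(genes))[gi] &
      tru$role %in% geneRoles
    g <- genes[gi]
    s <- if (as.character(GenomicRanges::strand(g)) == "+") 1 else -1
    sort(s * (GenomicRanges::start(tru)[sel] - g$tss))
  }
  cls <- genes$class
  # compare two same-chromosome, same-class genes (restrict to promoter
  # offsets, which are class-determined; distal array extent can differ
  # when landscape assembly drops a boundary nucleosome)
  ch <- as.character(GenomicRanges::seqnames(genes))
  found <- FALSE
  for (k in unique(cls)) {
    idx <- which(cls == k & ch == ch[1])
    if (length(idx) >= 2) {
      o1 <- offsetsOf(idx[1]); o2 <- offsetsOf(idx[2])
      o1 <- o1[abs(o1) <= 600]; o2 <- o2[abs(o2) <= 600]
      expect_identical(o1, o2)
      found <- TRUE
      break
    }
  }
  expect_true(found)
  # truth bundle bookkeeping
  expect_equal(length(sim$truth$enhancerSites), sim$config@nEnhancers)
  expect_identical(sim$truth$geneTiers, setNames(genes$tier, genes$name))
})

test_that("methylation placement follows the configured dyad geometry", {
  sim <- defaultSim()
  meth <- sim$methylation
  expect_true(all(meth$context %in% c("mCG", "mCHG", "mCHH", "hmC")))
  # zero density removes a context entirely
  cfg0 <- smallConfig(methDensityByContext = c(mCG = 0.01, mCHG = 0.002,
                                               mCHH = 0.005, hmC = 0))
  gg <- generateGenome(cfg0)
  m0 <- generateMethylation(gg$nucleosomes, cfg0)
  expect_false("hmC" %in% m0$context)
  # uniform profile + full core fraction: flat in-core histogram
  prof <- defaultMethProfiles()
  prof$mCHG <- rep(1 / 147, 147)
  cfgU <- smallConfig(methDyadProfile = prof,
                      methCoreFraction = c(mCG = 0.85, mCHG = 1,
                                           mCHH = 0.2, hmC = 0.5),
                      methDensityByContext = c(mCG = 0.01, mCHG = 0.02,
                                               mCHH = 0.005, hmC = 0.001))
  ggU <- generateGenome(cfgU)
  mU <- generateMethylation(ggU$nucleosomes, cfgU)
  h <- distanceToNearestDyad(mU, ggU$nucleosomes, context = "mCHG")
  inner <- h$count[abs(h$offset) <= 60]
  expect_lt(sd(inner) / mean(inner), 0.3)
  # missing profile for a requested context errors
  cfgBad <- smallConfig()
  cfgBad@methDyadProfile$mCHH <- NULL
  expect_error(generateMethylation(gg$nucleosomes, cfgBad), "mCHH")
})

test_that("truth placements match the configured density (TV < 0.05)", {
  prof <- defaultMethProfiles()
  cfg <- simConfig(methCoreFraction = c(mCG = 0.85, mCHG = 1, mCHH = 0.2,
                                        hmC = 0.5),
                   methDensityByContext = c(mCG = 0.01, mCHG = 0.012,
                                            mCHH = 0.005, hmC = 0.001))
  gg <- generateGenome(cfg)
  meth <- generateMethylation(gg$nucleosomes, cfg)
  h <- distanceToNearestDyad(meth, gg$nucleosomes, context = "mCHG")
  expect_gte(attr(h, "nSites"), 20000)
  emp <- h$count / sum(h$count)
  tv <- 0.5 * sum(abs(emp - prof$mCHG))
  expect_lt(tv, 0.05)
})
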