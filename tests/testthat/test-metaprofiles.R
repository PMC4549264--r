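# RNA-Signal construction, expression stratification, feature-centred
# aggregation, clustering of TSS architectures, +1 shifts, and the active
# site filter.

test_that("RNA-Signal combines strands after equal-total normalization", {
  plus <- GenomeTrack(list(c1 = c(1, 0)))
  minus <- GenomeTrack(list(c1 = c(0, 3)))
  comb <- buildRnaSignal(plus, minus)
  v <- trackValues(comb, "c1")
  expect_equal(v[1], v[2])              # equalized strand totals
  expect_equal(sum(v), 1 + 3)           # total signal preserved
  # zero minus strand: combined equals the plus strand unchanged
  z <- GenomeTrack(list(c1 = c(0, 0)))
  expect_equal(trackValues(buildRnaSignal(plus, z), "c1"), c(1, 0))
  # plus == minus: combined is twice each
  expect_equal(trackValues(buildRnaSignal(plus, plus), "c1"), c(2, 0))
  expect_error(buildRnaSignal(plus, GenomeTrack(list(c2 = c(1, 0)))),
               "chromosome sets")
})

test_that("expression totals and quartiles follow rank arithmetic", {
  genes <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    c(1, 11, 21, 31, 41, 51, 61, 71), width = 10),
    name = paste0("g", 1:8))
  rna <- GenomeTrack(list(c1 = rep(0:7, each = 10)))
  expr <- totalExpression(genes, rna)
  expect_equal(unname(expr), (0:7) * 10)
  q <- quartileSplit(expr)
  expect_equal(as.character(q), rep(paste0("Q", 1:4), each = 2))
  # all-equal values: stable-order split into equal quarters
  qt <- quartileSplit(rep(5, 8))
  expect_equal(as.character(qt), rep(paste0("Q", 1:4), each = 2))
  expect_error(quartileSplit(1:3), "at least 4")
  # silent gene lands in Q1
  expr2 <- c(0, expr[-1])
  expect_equal(as.character(quartileSplit(expr2))[1], "Q1")
})

test_that("silent-gene classification uses the flanked mean against eps", {
  genes <- GenomicRanges::GRanges("c1", IRanges::IRanges(600, 699),
                                  name = "g1")
  z <- GenomeTrack(list(c1 = numeric(2000)))
  expect_true(classifySilent(genes, z)[["g1"]])
  # one base of signal inside the 500 bp flank: not silent at eps = 0
  v <- numeric(2000); v[150] <- 1
  expect_false(classifySilent(genes, GenomeTrack(list(c1 = v)))[["g1"]])
  # mean 0.05 <= eps 0.1 -> silent
  v2 <- numeric(2000); v2[601:700] <- 0.55
  tr2 <- GenomeTrack(list(c1 = v2))
  m <- sum(v2[100:1199]) / 1100
  expect_true(m <= 0.1)
  expect_true(classifySilent(genes, tr2, eps = 0.1)[["g1"]])
  expect_false(classifySilent(genes, tr2, eps = 0)[["g1"]])
})

test_that("profile aggregation is strand-aware, boundary-safe and linear", {
  v <- seq_len(5000)
  tr <- GenomeTrack(list(c1 = v))
  # single + feature: identity slice
  fplus <- data.frame(chrom = "c1", pos = 1000, strand = "+")
  pr <- aggregateProfile(tr, fplus, flank = 100)
  expect_equal(unname(pr), v[900:1100], ignore_attr = TRUE)
  # single - feature: reversed, so +10 reads track[pos - 10]
  fminus <- data.frame(chrom = "c1", pos = 1000, strand = "-")
  prm <- aggregateProfile(tr, fminus, flank = 100)
  expect_equal(unname(prm[as.character(10)]), v[990])
  expect_equal(unname(prm[as.character(-25)]), v[1025])
  # two + features: elementwise mean
  f2 <- data.frame(chrom = "c1", pos = c(1000, 2000), strand = "+")
  pr2 <- aggregateProfile(tr, f2, flank = 50)
  expect_equal(unname(pr2), (v[950:1050] + v[1950:2050]) / 2,
               ignore_attr = TRUE)
  # features too close to a boundary are dropped and counted
  f3 <- data.frame(chrom = "c1", pos = c(30, 1000), strand = "+")
  m3 <- profileMatrix(tr, f3, flank = 100)
  expect_equal(nrow(m3), 1)
  expect_equal(attr(m3, "nDropped"), 1)
  expect_error(profileMatrix(tr, data.frame(chrom = "c1", pos = 5,
                                            strand = "+"), flank = 100),
               "no usable")
  # linearity: aggregate(alpha * T) == alpha * aggregate(T)
  tr3 <- GenomeTrack(list(c1 = 3 * v))
  expect_equal(unname(aggregateProfile(tr3, fplus, flank = 100)),
               3 * unname(pr), ignore_attr = TRUE)
})

test_that("reference normalization applies the pseudocount ratio per gene", {
  offs <- as.character(-2:2)
  A <- matrix(1, 2, 5, dimnames = list(c("g1", "g2"), offs))
  REF <- matrix(1, 2, 5, dimnames = list(c("g1", "g2"), offs))
  expect_equal(unname(normalizeByReference(A, REF)), rep(1, 5))
  # REF = 0, pseudo = 1, A = 1 -> ratio 2
  REF0 <- matrix(0, 2, 5, dimnames = list(c("g1", "g2"), offs))
  expect_equal(unname(normalizeByReference(A, REF0)), rep(2, 5))
  # monotone in A
  expect_true(all(normalizeByReference(2 * A, REF) >
                    normalizeByReference(A, REF)))
  # unmatched genes are dropped with a warning
  REFg1 <- REF[1, , drop = FALSE]
  expect_warning(r <- normalizeByReference(A, REFg1), "dropped")
  expect_equal(unname(r), rep(1, 5))
})

test_that("k-means on scaled profiles recovers planted architectures", {
  # k = 1: centroid equals column means of max-scaled rows
  m <- matrix(c(1, 2, 4, 2, 4, 8, 3, 6, 9), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("r", 1:3), as.character(-1:1)))
  k1 <- kmeansProfiles(m, k = 1, nInit = 2, seed = 1)
  expect_equal(unname(k1$centroids[1, ]),
               unname(colMeans(m / apply(m, 1, max))))
  # two well-separated synthetic classes: perfect recovery
  set.seed(5)
  offs <- -300:300
  mk <- function(center, n) t(vapply(seq_len(n), function(i) {
    exp(-0.5 * ((offs - center) / 40)^2) * runif(1, 5, 15) +
      runif(length(offs), 0, 0.5)
  }, numeric(length(offs))))
  mat <- rbind(mk(-150, 15), mk(150, 15))
  dimnames(mat) <- list(paste0("g", 1:30), as.character(offs))
  km <- kmeansProfiles(mat, k = 2, nInit = 5, seed = 2)
  truth <- rep(1:2, each = 15)
  expect_equal(mclust::adjustedRandIndex(km$assignments, truth), 1)
  # per-cluster centroid maxima sit at the planted peaks
  expect_true(all(abs(abs(km$maxNosLocation) - 150) <= 10))
  # all-zero rows are dropped with a warning
  matz <- rbind(mat, g31 = numeric(length(offs)))
  expect_warning(kmeansProfiles(matz, k = 2, nInit = 2, seed = 1),
                 "all-zero")
  expect_error(kmeansProfiles(mat[1:3, ], k = 5), "fewer usable rows")
})

test_that("+1 shift measures the first downstream local maximum", {
  offs <- -500:500
  mk <- function(peak) {
    pr <- exp(-0.5 * ((offs - peak) / 50)^2) +
      0.8 * exp(-0.5 * ((offs + 200) / 50)^2)
    names(pr) <- offs
    pr
  }
  a <- mk(50)
  expect_equal(plusOneShift(a, a)$shift, 0)
  # translated profile: shift equals the translation
  b <- mk(58)
  expect_equal(plusOneShift(a, b)$shift, 8)
  res <- plusOneShift(mk(50), mk(60))
  expect_equal(res$shift, 10)
  expect_equal(res$locationA, 50)
  expect_equal(res$locationB, 60)
  # no local maximum in the window errors
  flat <- setNames(rep(1, length(offs)), offs)
  expect_error(plusOneShift(flat, flat), "no local maximum")
})

test_that("active-site filter applies inclusive quantile thresholds", {
  sites <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    c(101, 201, 301, 401), width = 50))
  stepTrack <- function(vals) {
    v <- numeric(600)
    for (i in seq_along(vals)) v[(i * 100 + 1):(i * 100 + 50)] <- vals[i]
    GenomeTrack(list(c1 = v))
  }
  dnase <- stepTrack(c(1, 2, 3, 4))
  nos <- stepTrack(c(4, 3, 2, 1))
  act <- activeSiteFilter(sites, dnase, nos)
  expect_equal(length(act), 1)
  expect_equal(GenomicRanges::start(act), 401)
  expect_equal(act$accessMean, 4)
  expect_equal(act$nosMean, 1)
  # single site: its own value meets both inclusive thresholds
  one <- activeSiteFilter(sites[1], dnase, nos)
  expect_equal(length(one), 1)
  # all-equal tracks: every site is active
  eq <- stepTrack(c(2, 2, 2, 2))
  expect_equal(length(activeSiteFilter(sites, eq, eq)), 4)
  # empty input
  expect_equal(length(activeSiteFilter(sites[0], dnase, nos)), 0)
})

test_that("generator tiers shape quartile profiles as expected", {
  sim <- defaultSim()
  nn <- defaultNos()
  mat <- profileMatrix(nn, sim$genes, flank = 1000L)
  off <- as.integer(colnames(mat))
  p1 <- apply(mat[, off > 87 & off <= 400], 1, max)
  ndr <- apply(mat[, abs(off) <= 87], 1, min)
  rna <- buildRnaSignal(sim$rnaPlus, sim$rnaMinus)
  expr <- totalExpression(sim$genes, rna)
  q <- quartileSplit(expr)[match(rownames(mat), sim$genes$name)]
  # NDR empties and the +1 peak grows with expression
  expect_true(all(diff(tapply(ndr, q, mean)) < 0))
  expect_true(all(diff(tapply(p1, q, mean)) > 0))
})

test_that("silent-gene profiles from independent replicates agree (r > 0.95)", {
  sim <- defaultSim()
  reps <- replicateTracks()
  rna <- buildRnaSignal(sim$rnaPlus, sim$rnaMinus)
  sil <- classifySilent(sim$genes, rna)
  expect_gt(sum(sil), 10)
  pA <- aggregateProfile(reps[[1]], sim$genes[sil], flank = 1000L)
  pB <- aggregateProfile(reps[[2]], sim$genes[sil], flank = 1000L)
  expect_gt(cor(pA, pB), 0.95)
})
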