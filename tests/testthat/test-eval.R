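# Ground-truth accounting and the six evaluation metrics.

randAbund <- function(keys) {
  x <- stats::runif(length(keys))
  stats::setNames(x / sum(x), keys)
}

test_that("covered nucleotides follow 1-based inclusive interval overlap", {
  genes <- data.frame(genome_id = "G", gene_id = "g1",
                      start = 101, end = 200, group_id = "K1")
  one <- function(s, e) data.frame(read_id = "r", genome_id = "G",
                                   start = s, end = e)
  expect_equal(coveredNucleotides(one(151, 250), genes), c(g1 = 50))
  expect_equal(coveredNucleotides(one(201, 300), genes), c(g1 = 0))
  two <- rbind(one(151, 250), one(151, 250))
  expect_equal(coveredNucleotides(two, genes), c(g1 = 100))
  expect_warning(
    cov <- coveredNucleotides(data.frame(read_id = "r", genome_id = "ZZ",
                                         start = 1, end = 50), genes),
    "unknown genome")
  expect_equal(cov, c(g1 = 0))
})

test_that("covered nucleotides agree with a naive interval loop on random
           tables", {
  set.seed(103)
  for (rep in 1:5) {
    genes <- data.frame(
      genome_id = sample(c("G1", "G2"), 12, replace = TRUE),
      gene_id = sprintf("g%02d", 1:12),
      start = sample(1:900, 12), group_id = "K")
    genes$end <- genes$start + sample(20:150, 12)
    maps <- data.frame(
      read_id = sprintf("r%03d", 1:120),
      genome_id = sample(c("G1", "G2"), 120, replace = TRUE),
      start = sample(1:950, 120, replace = TRUE))
    maps$end <- maps$start + 49
    got <- coveredNucleotides(maps, genes)
    for (j in seq_len(nrow(genes))) {
      m <- maps[maps$genome_id == genes$genome_id[j], ]
      ov <- pmin(m$end, genes$end[j]) - pmax(m$start, genes$start[j]) + 1
      expect_equal(unname(got[genes$gene_id[j]]), sum(ov[ov > 0]))
    }
  }
})

test_that("ground truth normalizes group coverage with multi-group genes", {
  truth <- buildGroundTruth(
    c(g1 = 100, g2 = 300),
    data.frame(gene_id = c("g1", "g2"), group_id = c("K1", "K2")))
  expect_equal(abundances(truth), c(K1 = 0.25, K2 = 0.75))
  expect_equal(coveredNt(truth), c(K1 = 100, K2 = 300))

  # a gene in two groups contributes its coverage to each
  truth2 <- buildGroundTruth(
    c(g1 = 100, g2 = 100),
    data.frame(gene_id = c("g1", "g1", "g2"),
               group_id = c("K1", "K2", "K2")))
  expect_equal(coveredNt(truth2), c(K1 = 100, K2 = 200))

  # zero-coverage groups are omitted; orphan genes dropped with a message
  expect_message(
    truth3 <- buildGroundTruth(
      c(g1 = 50, g2 = 0, orphan = 10),
      data.frame(gene_id = c("g1", "g2"), group_id = c("K1", "K2"))),
    "without a group")
  expect_identical(groupIds(truth3), "K1")
})

test_that("purity is precision over detected groups", {
  expect_equal(purity(c("A", "B"), c("A", "B", "C")), 1.0)
  expect_equal(purity(c("A", "D"), c("A", "B", "C")), 0.5)
  expect_equal(purity(c("A", "B", "C"), c("A", "B", "C")), 1.0)
  expect_error(purity(character(0), "A"), "empty")
})

test_that("completeness honors the top-fraction prefix rule", {
  truth <- c(A = 0.6, B = 0.3, C = 0.06, D = 0.04)
  expect_equal(completeness(c("A", "B"), truth, topFraction = 0.95), 2 / 3)
  expect_equal(completeness(c("A", "B"), truth), 0.5)
  expect_equal(completeness(names(truth), truth), 1.0)
  expect_equal(completeness(c("X", "Y"), truth), 0.0)
  # q = 1 keeps the whole truth set
  expect_equal(completeness(c("A", "C"), truth, topFraction = 1),
               completeness(c("A", "C"), truth))
  # ties broken by group id: B and C tie at 0.2; prefix must take B first
  tied <- c(A = 0.6, C = 0.2, B = 0.2)
  expect_equal(completeness("B", tied, topFraction = 0.8), 0.5)
})

test_that("weighted Jaccard and Bray-Curtis match hand-computed examples", {
  x <- c(A = 0.6, B = 0.4)
  y <- c(A = 0.5, B = 0.3, C = 0.2)
  expect_equal(weightedJaccard(x, y), 0.8 / 1.2)
  expect_equal(brayCurtis(x, y), 0.2)
  expect_equal(weightedJaccard(x, x), 1.0)
  expect_equal(brayCurtis(x, x), 0.0)
  expect_equal(weightedJaccard(c(A = 1), c(B = 1)), 0.0)
  expect_equal(brayCurtis(c(A = 1), c(B = 1)), 1.0)
})

test_that("Bray-Curtis agrees with vegan and Pearson with the closed form", {
  set.seed(107)
  for (rep in 1:5) {
    keys <- sprintf("K%02d", 1:12)
    x <- randAbund(keys)
    y <- randAbund(sample(keys, 8))
    keysU <- union(names(x), names(y))
    xv <- stats::setNames(numeric(length(keysU)), keysU)
    yv <- xv
    xv[names(x)] <- x
    yv[names(y)] <- y
    expect_equal(brayCurtis(x, y),
                 as.numeric(vegan::vegdist(rbind(xv, yv), method = "bray")))
    r <- sum((xv - mean(xv)) * (yv - mean(yv))) /
      sqrt(sum((xv - mean(xv))^2) * sum((yv - mean(yv))^2))
    expect_equal(pearsonAbundance(x, y), r)
  }
  expect_error(pearsonAbundance(c(A = 0.5, B = 0.5), c(A = 0.3, B = 0.7)),
               "constant")
})

test_that("metrics ignore key order and zero-abundance padding", {
  set.seed(109)
  keys <- sprintf("K%02d", 1:10)
  x <- randAbund(keys[1:7])
  y <- randAbund(keys[3:10])
  shuffled <- sample(x)
  padded <- c(x, stats::setNames(0, "K99"))
  for (f in list(weightedJaccard, brayCurtis, pearsonAbundance)) {
    expect_equal(f(x, y), f(shuffled, y))
    expect_equal(f(x, y), f(padded, y))
  }
  expect_equal(purity(padded, y), purity(x, y))
  expect_equal(completeness(x, c(y, stats::setNames(0, "K99")),
                            topFraction = 0.9),
               completeness(x, y, topFraction = 0.9))
  expect_equal(weightedJaccard(x, y), weightedJaccard(y, x))
  expect_equal(brayCurtis(x, y), brayCurtis(y, x))
})

test_that("1 - weighted Jaccard and Bray-Curtis move together under
           perturbation", {
  set.seed(113)
  keys <- sprintf("K%02d", 1:8)
  for (rep in 1:20) {
    x <- randAbund(keys)
    y <- randAbund(keys)
    y2 <- y
    j <- sample(length(y), 1)
    y2[j] <- y2[j] * stats::runif(1, 0.2, 3)
    dwj <- (1 - weightedJaccard(x, y2)) - (1 - weightedJaccard(x, y))
    dbc <- brayCurtis(x, y2) - brayCurtis(x, y)
    expect_true(sign(dwj) == sign(dbc) || dwj == 0 || dbc == 0)
  }
})

test_that("evaluateProfile assembles all six metrics", {
  x <- c(A = 0.6, B = 0.4)
  rep0 <- evaluateProfile(x, x)
  expect_equal(unname(metricsAsVector(rep0)), c(1, 1, 1, 1, 1, 0))
  expect_error(evaluateProfile(stats::setNames(numeric(0), character(0)),
                               x), "empty")

  # independent scripted recomputation of the whole panel
  set.seed(127)
  keys <- sprintf("K%02d", 1:15)
  prof <- randAbund(sample(keys, 9))
  truth <- randAbund(sample(keys, 12))
  got <- metricsAsVector(evaluateProfile(prof, truth, topFraction = 0.95))
  p <- names(prof)
  g <- names(truth)
  ord <- order(-truth, names(truth))
  gq <- names(truth)[ord][seq_len(which(cumsum(truth[ord]) >= 0.95)[1])]
  keysU <- union(p, g)
  xv <- stats::setNames(numeric(length(keysU)), keysU)
  yv <- xv
  xv[p] <- prof
  yv[g] <- truth
  want <- c(length(intersect(p, g)) / length(p),
            length(intersect(p, g)) / length(g),
            length(intersect(p, gq)) / length(gq),
            sum(pmin(xv, yv)) / sum(pmax(xv, yv)),
            stats::cor(xv, yv),
            sum(abs(xv - yv)) / sum(xv + yv))
  expect_equal(unname(got), want)
})

test_that("reports serialize to JSON and TSV", {
  repx <- evaluateProfile(c(A = 0.7, B = 0.3), c(A = 0.6, B = 0.4))
  j <- tempfile(fileext = ".json")
  writeMetricsReport(repx, j)
  doc <- jsonlite::fromJSON(j)
  expect_equal(doc$purity, 1)
  expect_equal(doc$bray_curtis, 0.1)
  t <- tempfile(fileext = ".tsv")
  writeMetricsReport(repx, t)
  tab <- utils::read.table(t, header = TRUE, sep = "\t")
  expect_true("bray_curtis" %in% tab$metric)
})

test_that("BED-style coordinates convert to 1-based inclusive", {
  expect_equal(bedToOneBased(0, 100), data.frame(start = 1, end = 100))
})
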