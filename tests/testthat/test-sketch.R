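# Core sketching: translation, k-mer extraction, hashing, sketch
# construction, containment and weighted overlap.

test_that("six-frame translation matches hand-translated examples", {
  expect_setequal(translateSixFrames("ATGAAA"), c("MK", "E", "FH", "F", "S"))
  # +1 frame of TAA is a lone stop; only the reverse -1 frame has a codon
  expect_identical(translateSixFrames("TAA"), "L")
  expect_identical(translateSixFrames(""), character(0))
})

test_that("ambiguous bases become X and propagate into fragments", {
  frags <- translateSixFrames("ATGNAA")
  expect_true("MX" %in% frags)
  # non-IUPAC characters are treated as N
  expect_identical(sort(translateSixFrames("ATG.AA")),
                   sort(translateSixFrames("ATGNAA")))
})

test_that("six-frame translation agrees with a naive per-codon oracle", {
  set.seed(101)
  for (len in c(7L, 50L, 300L)) {
    for (rep in 1:8) {
      read <- randRead(len)
      expect_identical(sort(translateSixFrames(read)),
                       sort(naiveSixFrames(read)),
                       info = read)
    }
  }
})

test_that("k-mer extraction follows the multiset definition with X-drop", {
  expect_identical(extractKmers("MKVL", 2), c("MK", "KV", "VL"))
  expect_identical(extractKmers("AAAA", 2), c("AA", "AA", "AA"))
  expect_identical(extractKmers("MXKL", 2), "KL")
  expect_identical(extractKmers("MK", 3), character(0))
})

test_that("hashing is deterministic and matches frozen MurmurHash3 vectors", {
  km <- randKmers(5, 11)
  expect_identical(hashKmer(km), hashKmer(km))
  expect_false(identical(hashKmer(km, seed = 42L), hashKmer(km, seed = 1L)))
  # frozen from an independent MurmurHash3 x64_128 implementation (h1 of
  # the 128-bit digest, seed 42)
  expect_identical(hashKmer("MKVLAAGIRER"), "17030163374140391045")
  expect_identical(hashKmer("AAAAAAAAAAA"), "7773142420371383521")
  expect_identical(hashKmer("KVLYNNHQRSP"), "14719563718131807653")
  expect_identical(hashKmer("AC"), "15356153750468641786")
  expect_identical(hashKmer("protein"), "4802962628225237992")
})

test_that("hash values are uniform: retention rate near 1/scaled", {
  set.seed(7)
  n <- 1e5
  km <- randKmers(n, 9)
  frac <- mean(u64LessEq(hashKmer(km), scaledThreshold(1000)))
  ci <- 2.576 * sqrt(0.001 * 0.999 / n)
  expect_lt(abs(frac - 0.001), ci)
})

test_that("buildSketch keeps everything at scaled = 1 and honors counts", {
  p <- SketchParams(k = 2, scaled = 1)
  s <- buildSketch(extractKmers("AAAA", 2), p, "t")
  expect_identical(nHashes(s), 1L)
  expect_identical(weightedSize(s), 3)
  km <- randKmers(50, 11)
  s2 <- buildSketch(km, SketchParams(scaled = 1))
  expect_identical(nHashes(s2), 50L)
  expect_true(all(hashAbundance(s2) == 1))
  # explicit multiplicities behave like repeated entries
  s3 <- buildSketch(c("MK", "KV"), p, counts = c(3, 1))
  s4 <- buildSketch(c("MK", "MK", "MK", "KV"), p)
  expect_identical(sketchHashes(s3), sketchHashes(s4))
  expect_identical(hashAbundance(s3), hashAbundance(s4))
  empty <- buildSketch(character(0), p)
  expect_identical(nHashes(empty), 0L)
  expect_identical(weightedSize(empty), 0)
})

test_that("buildSketch equals the brute-force threshold filter", {
  set.seed(13)
  for (scaled in c(10, 100)) {
    km <- sample(c(randKmers(5000, 11), randKmers(1000, 11)), 6500,
                 replace = TRUE)
    s <- buildSketch(km, SketchParams(scaled = scaled))
    oracle <- bruteSketch(km, scaled)
    expect_identical(sketchHashes(s), oracle$hashes)
    expect_identical(unname(hashAbundance(s)), oracle$abundance)
  }
})

test_that("merging sketches is a homomorphism of multiset union", {
  set.seed(17)
  p <- SketchParams(scaled = 20)
  a <- sample(randKmers(3000, 11), 4000, replace = TRUE)
  b <- sample(randKmers(3000, 11), 4000, replace = TRUE)
  merged <- mergeSketches(buildSketch(a, p, "a"), buildSketch(b, p, "b"))
  direct <- buildSketch(c(a, b), p)
  expect_identical(sketchHashes(merged), sketchHashes(direct))
  expect_identical(unname(hashAbundance(merged)),
                   unname(hashAbundance(direct)))
})

test_that("downsampling to a coarser scaled equals sketching there", {
  set.seed(19)
  km <- randKmers(20000, 11)
  fine <- buildSketch(km, SketchParams(scaled = 1000))
  coarse <- buildSketch(km, SketchParams(scaled = 2000))
  down <- downsampleSketch(fine, 2000)
  expect_identical(sketchHashes(down), sketchHashes(coarse))
  expect_identical(sketchParams(down)@scaled, 2000L)
  expect_error(downsampleSketch(fine, 10), "finer")
})

test_that("containment is exact at scaled = 1 and guarded", {
  p <- SketchParams(scaled = 1)
  set.seed(23)
  km <- randKmers(1000, 11)
  query <- buildSketch(km, p, "q")
  ref <- buildSketch(c(km[1:300], randKmers(500, 11)), p, "r")
  expect_equal(containment(query, ref), 0.30)
  expect_equal(containment(query, query), 1.0)
  disjoint <- buildSketch(randKmers(200, 11), p)
  expect_equal(containment(buildSketch(km[1:50], p), disjoint), 0)
  expect_error(containment(buildSketch(character(0), p), ref), "empty")
  expect_error(containment(query, buildSketch(km, SketchParams(scaled = 2))),
               "not comparable")
})

test_that("weighted overlap uses the query's abundances", {
  p <- SketchParams(k = 3, scaled = 1)
  q <- buildSketch(c(rep("AAA", 3), rep("CCC", 5)), p)
  r1 <- buildSketch("AAA", p)
  expect_identical(weightedOverlap(q, r1),
                   list(hashCount = 1L, weightedCount = 3))
  expect_identical(weightedOverlap(q, q),
                   list(hashCount = 2L, weightedCount = 8))
  set.seed(29)
  km <- randKmers(400, 11)
  qs <- buildSketch(sample(km, 1000, replace = TRUE), p)
  rs <- buildSketch(sample(km, 300), p)
  # brute-force loop oracle
  shared <- intersect(sketchHashes(qs), sketchHashes(rs))
  expect_identical(weightedOverlap(qs, rs),
                   list(hashCount = length(shared),
                        weightedCount = sum(hashAbundance(qs)[shared])))
})

test_that("file sketching counts k-mers, merges across files, and is
           strand-symmetric", {
  p7 <- SketchParams(k = 7, scaled = 1)
  fa <- writeFasta(c(g1 = "MKVLMKVL"))
  s <- sketchSequences(fa, p7, mode = "protein")
  expect_identical(nHashes(s), 2L)

  # one file vs the same records split across two files then merged
  seqs <- c(a = "MKVLYAAGIRERPL", b = "WWHQNNSTVMKKL", c = "PLMKVLYAAGIR")
  whole <- sketchSequences(writeFasta(seqs), p7, mode = "protein")
  part <- mergeSketches(
    sketchSequences(writeFasta(seqs[1:2]), p7, mode = "protein"),
    sketchSequences(writeFasta(seqs[3]), p7, mode = "protein"))
  expect_identical(sketchHashes(whole), sketchHashes(part))
  expect_identical(unname(hashAbundance(whole)),
                   unname(hashAbundance(part)))

  # six-frame symmetry: a read and its reverse complement sketch identically
  p5 <- SketchParams(k = 5, scaled = 1)
  set.seed(31)
  for (i in 1:5) {
    read <- randRead(200)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(read)))
    s1 <- sketchSequences(Biostrings::DNAStringSet(read), p5)
    s2 <- sketchSequences(Biostrings::DNAStringSet(rc), p5)
    expect_identical(sketchHashes(s1), sketchHashes(s2))
    expect_identical(unname(hashAbundance(s1)), unname(hashAbundance(s2)))
  }
})

test_that("FASTQ and gzip input are transparent; malformed input names the
           record", {
  p <- SketchParams(k = 5, scaled = 1)
  read <- "ATGGCTAAAGTTCTGGAAGCTCCG"
  fq <- tempfile(fileext = ".fq.gz")
  con <- gzfile(fq, "wt")
  writeLines(c("@r1", read, "+", strrep("I", nchar(read))), con)
  close(con)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">r1", read), fa)
  sq <- sketchSequences(fq, p)
  sa <- sketchSequences(fa, p)
  expect_identical(sketchHashes(sq), sketchHashes(sa))

  bad <- tempfile(fileext = ".fq")
  writeLines(c("@r1", read, "oops"), bad)
  expect_error(sketchSequences(bad, p), "malformed FASTQ")

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_identical(nHashes(sketchSequences(empty, p)), 0L)
})

test_that("sketch JSON round-trips", {
  set.seed(37)
  s <- buildSketch(sample(randKmers(500, 11), 800, replace = TRUE),
                   SketchParams(scaled = 5), "roundtrip")
  path <- tempfile(fileext = ".sig.json")
  saveSketch(s, path)
  s2 <- loadSketch(path)
  expect_identical(sketchHashes(s2), sketchHashes(s))
  expect_identical(unname(hashAbundance(s2)), unname(hashAbundance(s)))
  expect_identical(sketchName(s2), "roundtrip")
  expect_true(paramsCompatible(sketchParams(s2), sketchParams(s)))
})
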