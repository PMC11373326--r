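# Core FracMinHash sketching: six-frame translation, k-mer extraction,
# hashing, sketch construction, containment and weighted overlap.

#' Construct sketching parameters
#'
#' @param k k-mer length in amino acids (default 11, the primary profiling
#'   length; 7 and 15 are the other conventional choices).
#' @param scaled downsampling denominator; the sketch keeps k-mers whose
#'   64-bit hash is at most \code{floor((2^64 - 1) / scaled)}, i.e. an
#'   expected fraction \code{1/scaled} of distinct k-mers (default 1000).
#' @param seed hash seed (default 42, the seed conventionally used for
#'   MurmurHash3 in k-mer sketching tools).
#' @param alphabet \code{"protein"} or \code{"nucleotide-translated"}; both
#'   denote amino-acid k-mer space and are mutually comparable.
#' @return A \linkS4class{SketchParams}.
#' @examples
#' SketchParams(k = 11, scaled = 1000)
#' @export
SketchParams <- function(k = 11L, scaled = 1000L, seed = 42L,
                         alphabet = c("protein", "nucleotide-translated")) {
  alphabet <- match.arg(alphabet)
  new("SketchParams", k = as.integer(k), scaled = as.integer(scaled),
      seed = as.integer(seed), alphabet = alphabet)
}

#' Hash-space constants
#'
#' \code{hashSpaceMax} returns H = 2^64 - 1, the maximum value of the 64-bit
#' hash space, and \code{scaledThreshold} the retention threshold
#' \code{floor(H / scaled)}, both as decimal strings (they exceed R's exact
#' integer range).
#'
#' @param scaled downsampling denominator.
#' @return character(1) decimal string.
#' @examples
#' hashSpaceMax()
#' scaledThreshold(1000)
#' @export
hashSpaceMax <- function() .u64_threshold_cpp(1)

#' @rdname hashSpaceMax
#' @export
scaledThreshold <- function(scaled) .u64_threshold_cpp(as.double(scaled))

#' @noRd
paramsIdentical <- function(a, b) {
  a@k == b@k && a@scaled == b@scaled && a@seed == b@seed &&
    a@alphabet == b@alphabet
}

#' Are two parameter sets comparable?
#'
#' Sketches are comparable when k, scaled and seed agree; the two alphabet
#' tags both denote amino-acid k-mers, so a translated-read sketch is
#' comparable with a protein reference sketch.
#'
#' @param a,b \linkS4class{SketchParams}.
#' @return logical(1).
#' @export
paramsCompatible <- function(a, b) {
  a@k == b@k && a@scaled == b@scaled && a@seed == b@seed
}

.stopIfIncompatible <- function(a, b) {
  if (!paramsCompatible(a, b))
    stop("sketches are not comparable: params differ (k ", a@k, "/", b@k,
         ", scaled ", a@scaled, "/", b@scaled, ", seed ", a@seed, "/", b@seed,
         ")", call. = FALSE)
  invisible(TRUE)
}

# internal constructor from the C++ (hashes, abundance) lists
.newSketch <- function(params, name, hl) {
  new("FracMinHashSketch", params = params, name = as.character(name),
      hashes = as.character(hl$hashes), abundance = as.numeric(hl$abundance))
}

#' Translate a read in all six reading frames
#'
#' Translates a nucleotide read in the three forward and three
#' reverse-complement frames with the standard genetic code, splits each
#' frame's translation at stop codons, and returns all fragments of length
#' >= 1. Codons containing an ambiguous or non-ACGT base translate to
#' \code{"X"}, which propagates into the fragments (k-mers containing X are
#' later dropped at sketching time); trailing partial codons are ignored.
#'
#' @param read character(1) nucleotide sequence (case-insensitive;
#'   characters outside A/C/G/T are treated as N).
#' @return character vector of peptide fragments (possibly empty).
#' @examples
#' sort(translateSixFrames("ATGAAA"))  # "E" "F" "FH" "MK" "S"
#' translateSixFrames("TAA")
#' @export
translateSixFrames <- function(read) {
  stopifnot(is.character(read), length(read) == 1L)
  if (is.na(read) || nchar(read) == 0L) return(character(0))
  frames <- .sixFrameStrings(toupper(read))
  frags <- unlist(strsplit(frames, "*", fixed = TRUE), use.names = FALSE)
  frags[nzchar(frags)]
}

# six frame translations (with '*' stop characters) of one sequence string
.sixFrameStrings <- function(seq) {
  seq <- gsub("[^ACGT]", "N", seq)
  x <- Biostrings::DNAStringSet(c(seq, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))))
  .sixFrameStringsSet(x[1], x[2])
}

# vectorized: fwd and rev are DNAStringSet of equal length (rev = revcomp);
# returns character vector of up to 6*n frame translations ('*' kept)
.sixFrameStringsSet <- function(fwd, rev) {
  out <- vector("list", 6L)
  i <- 1L
  for (strand in list(fwd, rev)) {
    w <- Biostrings::width(strand)
    for (off in 0:2) {
      cod <- (w - off) %/% 3L
      keep <- which(cod >= 1L)
      if (!length(keep)) { i <- i + 1L; next }
      sub <- Biostrings::subseq(strand[keep], start = off + 1L,
                                width = 3L * cod[keep])
      out[[i]] <- as.character(Biostrings::translate(
        sub, if.fuzzy.codon = "X", no.init.codon = TRUE))
      i <- i + 1L
    }
  }
  unlist(out, use.names = FALSE)
}

#' Extract amino-acid k-mers
#'
#' All substrings of length \code{k}, with multiplicity, in order of
#' occurrence. K-mers containing the undefined residue \code{X} are dropped;
#' protein k-mers are not canonicalized (there is no strand).
#'
#' @param peptide character(1) amino-acid string.
#' @param k k-mer length.
#' @return character vector (a multiset; possibly with repeats). Peptides
#'   shorter than \code{k} yield \code{character(0)}.
#' @examples
#' extractKmers("MKVL", 2)  # "MK" "KV" "VL"
#' extractKmers("AAAA", 2)  # "AA" "AA" "AA"
#' extractKmers("MXKL", 2)  # "KL"
#' @export
extractKmers <- function(peptide, k) {
  stopifnot(is.character(peptide), length(peptide) == 1L, k >= 1)
  k <- as.integer(k)
  n <- nchar(peptide)
  if (is.na(peptide) || n < k) return(character(0))
  km <- substring(peptide, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  km[!grepl("X", km, fixed = TRUE)]
}

#' Hash a k-mer
#'
#' Deterministic 64-bit hash of a k-mer string: the low 64 bits of
#' MurmurHash3 x64_128. Returned as a decimal string because the value can
#' exceed R's exact integer range.
#'
#' @param kmer character vector of nonempty k-mer strings.
#' @param seed integer hash seed (default 42).
#' @return character vector of decimal 64-bit values.
#' @examples
#' hashKmer("MKVLAAGIRER")
#' @export
hashKmer <- function(kmer, seed = 42L) {
  stopifnot(is.character(kmer), all(nzchar(kmer)))
  .hash_kmers_cpp(kmer, as.integer(seed))
}

#' Build a sketch from a k-mer multiset
#'
#' Hashes every k-mer and retains exactly those with hash at most
#' \code{floor((2^64 - 1) / scaled)}; the abundance of a retained hash is
#' the total multiplicity of the k-mers mapping to it.
#'
#' @param kmers character vector of k-mers (repeats allowed).
#' @param params a \linkS4class{SketchParams}.
#' @param name sketch identifier.
#' @param counts optional numeric vector of per-entry multiplicities
#'   (default: each entry counts once).
#' @return A \linkS4class{FracMinHashSketch}.
#' @examples
#' p <- SketchParams(k = 2, scaled = 1)
#' buildSketch(extractKmers("AAAA", 2), p, "toy")
#' @export
buildSketch <- function(kmers, params, name = "", counts = numeric(0)) {
  stopifnot(is(params, "SketchParams"))
  if (length(counts) && length(counts) != length(kmers))
    stop("'counts' must be parallel to 'kmers'")
  hl <- .sketch_kmers_cpp(as.character(kmers), as.numeric(counts),
                          as.double(params@scaled), params@seed)
  .newSketch(params, name, hl)
}

# ---- sequence input ----

.detectFormat <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!length(first)) return("empty")
  c1 <- substr(first, 1L, 1L)
  if (c1 == ">") "fasta" else if (c1 == "@") "fastq"
  else stop("cannot detect FASTA/FASTQ format of '", path,
            "': first record starts with '", c1, "'", call. = FALSE)
}

.readChunk <- function(path, format, type, skip, nrec) {
  reader <- if (type == "AA") Biostrings::readAAStringSet
            else Biostrings::readDNAStringSet
  tryCatch(
    reader(path, format = format, nrec = nrec, skip = skip),
    error = function(e)
      stop("malformed ", toupper(format), " in '", path, "' near record ",
           skip + 1L, ": ", conditionMessage(e), call. = FALSE))
}

#' Sketch a FASTA/FASTQ file (or sequence set)
#'
#' Builds one merged FracMinHash sketch over all records of a sequence
#' source. In \code{mode = "protein"} records are amino-acid sequences and
#' are k-merized directly; in \code{mode = "nucleotide"} every record is
#' translated in all six reading frames first (stop-spanning and
#' X-containing k-mers are dropped). Files are read in chunks so memory is
#' governed by the sketch, not the file; gzip input is transparent; FASTQ
#' qualities are ignored.
#'
#' @param source path to a FASTA or FASTQ file (optionally gzipped), or a
#'   \link[Biostrings]{XStringSet} already in memory.
#' @param params a \linkS4class{SketchParams}.
#' @param mode \code{"protein"} or \code{"nucleotide"}.
#' @param name sketch identifier (defaults to the file name).
#' @param chunkSize records per read chunk.
#' @return A \linkS4class{FracMinHashSketch}. Records shorter than one
#'   k-mer (after translation) contribute nothing; an empty source yields
#'   an empty sketch.
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">g1", "MKVLMKVL"), fa)
#' sketchSequences(fa, SketchParams(k = 7, scaled = 1), mode = "protein")
#' @export
sketchSequences <- function(source, params,
                            mode = c("nucleotide", "protein"),
                            name = NULL, chunkSize = 25000L) {
  mode <- match.arg(mode)
  stopifnot(is(params, "SketchParams"))
  if (is(source, "XStringSet")) {
    if (is.null(name)) name <- "sequences"
    return(.sketchRecords(source, params, mode, name))
  }
  stopifnot(is.character(source), length(source) == 1L)
  if (!file.exists(source)) stop("no such file: '", source, "'")
  if (is.null(name)) name <- basename(source)
  format <- .detectFormat(source)
  empty <- .newSketch(params, name, list(hashes = character(0),
                                         abundance = numeric(0)))
  if (format == "empty") return(empty)
  type <- if (mode == "protein") "AA" else "DNA"
  parts <- list()
  skip <- 0L
  repeat {
    recs <- .readChunk(source, format, type, skip, chunkSize)
    if (!length(recs)) break
    parts[[length(parts) + 1L]] <- .sketchRecords(recs, params, mode, name)
    skip <- skip + length(recs)
    if (length(recs) < chunkSize) break
  }
  if (!length(parts)) return(empty)
  if (length(parts) == 1L) parts[[1L]]
  else do.call(mergeSketches, c(parts, list(name = name)))
}

.sketchRecords <- function(recs, params, mode, name) {
  if (mode == "protein") {
    peptides <- as.character(recs)
  } else {
    if (!is(recs, "DNAStringSet")) recs <- Biostrings::DNAStringSet(recs)
    # normalize non-ACGT to N so translation yields X in those codons
    if (any(Biostrings::alphabetFrequency(recs, baseOnly = TRUE)[, "other"] > 0)) {
      chr <- toupper(as.character(recs))
      recs <- Biostrings::DNAStringSet(gsub("[^ACGT]", "N", chr))
    }
    peptides <- .sixFrameStringsSet(recs, Biostrings::reverseComplement(recs))
  }
  hl <- .sketch_peptides_cpp(peptides, params@k, as.double(params@scaled),
                             params@seed)
  .newSketch(params, name, hl)
}

# ---- comparisons ----

#' Containment of one sketch in another
#'
#' The containment index C(query, ref) = |hashes(query) n hashes(ref)| /
#' |hashes(query)|: the fraction of the query's retained hashes also present
#' in the reference. Asymmetric, unlike Jaccard.
#'
#' @param query,ref \linkS4class{FracMinHashSketch} objects with comparable
#'   parameters; the query must be nonempty.
#' @return numeric(1) in [0, 1].
#' @examples
#' p <- SketchParams(k = 2, scaled = 1)
#' a <- buildSketch(c("MK", "KV", "VL"), p)
#' b <- buildSketch(c("MK", "KV"), p)
#' containment(b, a)
#' @rdname containment
#' @export
setMethod("containment", signature("FracMinHashSketch", "FracMinHashSketch"),
  function(query, ref) {
    .stopIfIncompatible(query@params, ref@params)
    if (length(query@hashes) == 0L)
      stop("containment is undefined for an empty query sketch")
    sum(query@hashes %in% ref@hashes) / length(query@hashes)
  })

#' Overlap between two sketches
#'
#' \code{hashCount} is the number of intersecting hashes;
#' \code{weightedCount} weights each intersecting hash by the \emph{query's}
#' abundance, so overlaps scale with the query's sequencing depth.
#'
#' @param query,ref \linkS4class{FracMinHashSketch} objects with comparable
#'   parameters.
#' @return list with elements \code{hashCount} and \code{weightedCount}.
#' @examples
#' p <- SketchParams(k = 2, scaled = 1)
#' q <- buildSketch(c("MK", "MK", "MK", "KV"), p)
#' r <- buildSketch("MK", p)
#' weightedOverlap(q, r)  # hashCount 1, weightedCount 3
#' @rdname weightedOverlap
#' @export
setMethod("weightedOverlap", signature("FracMinHashSketch", "FracMinHashSketch"),
  function(query, ref) {
    .stopIfIncompatible(query@params, ref@params)
    hit <- query@hashes %in% ref@hashes
    list(hashCount = sum(hit),
         weightedCount = sum(query@abundance[hit]))
  })

#' Merge sketches
#'
#' Union of the hash sets with abundances added; all sketches must share
#' identical parameters. Merging the sketches of two sequence sets equals
#' sketching their concatenation (merge homomorphism).
#'
#' @param x a \linkS4class{FracMinHashSketch}.
#' @param ... further sketches.
#' @param name identifier of the merged sketch (default: \code{x}'s name).
#' @return A \linkS4class{FracMinHashSketch}.
#' @rdname mergeSketches
#' @export
setMethod("mergeSketches", "FracMinHashSketch", function(x, ..., name = NULL) {
  rest <- list(...)
  rest <- rest[vapply(rest, is, logical(1), "FracMinHashSketch")]
  for (s in rest) {
    if (!paramsIdentical(x@params, s@params))
      stop("cannot merge sketches with differing params")
  }
  all <- c(list(x), rest)
  hl <- .combine_hashes_cpp(
    unlist(lapply(all, slot, "hashes"), use.names = FALSE),
    unlist(lapply(all, slot, "abundance"), use.names = FALSE),
    as.double(x@params@scaled))
  .newSketch(x@params, if (is.null(name)) x@name else name, hl)
})

#' Downsample a sketch to a coarser scaled
#'
#' Re-filters the retained hashes with the threshold of a larger
#' \code{scaled}. The result is identical to having sketched the original
#' input at that \code{scaled} (downsampling consistency).
#'
#' @param x a \linkS4class{FracMinHashSketch}.
#' @param scaled new downsampling denominator, >= the sketch's current one.
#' @return A \linkS4class{FracMinHashSketch}.
#' @rdname downsampleSketch
#' @export
setMethod("downsampleSketch", "FracMinHashSketch", function(x, scaled) {
  scaled <- as.integer(scaled)
  if (scaled < x@params@scaled)
    stop("cannot downsample to a finer scaled (", scaled, " < ",
         x@params@scaled, ")")
  p <- x@params
  p@scaled <- scaled
  hl <- .combine_hashes_cpp(x@hashes, x@abundance, as.double(scaled))
  .newSketch(p, x@name, hl)
})

# ---- accessors & show ----

#' @rdname accessors
#' @export
setMethod("sketchParams", "FracMinHashSketch", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("sketchParams", "ReferenceCollection", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("sketchParams", "FunctionalProfile", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("sketchHashes", "FracMinHashSketch", function(x) x@hashes)
#' @rdname accessors
#' @export
setMethod("hashAbundance", "FracMinHashSketch", function(x) {
  a <- x@abundance
  names(a) <- x@hashes
  a
})
#' @rdname accessors
#' @export
setMethod("sketchName", "FracMinHashSketch", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("nHashes", "FracMinHashSketch", function(x) length(x@hashes))
#' @rdname accessors
#' @export
setMethod("weightedSize", "FracMinHashSketch", function(x) sum(x@abundance))

setMethod("show", "SketchParams", function(object) {
  cat("SketchParams: k=", object@k, " scaled=", object@scaled,
      " seed=", object@seed, " alphabet=", object@alphabet, "\n", sep = "")
})

setMethod("show", "FracMinHashSketch", function(object) {
  cat("FracMinHashSketch \"", object@name, "\": ", length(object@hashes),
      " hashes (weighted ", sum(object@abundance), "), k=", object@params@k,
      ", scaled=", object@params@scaled, "\n", sep = "")
})
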