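#' @import methods
NULL

#' Sketching parameters
#'
#' Parameters governing a FracMinHash sketch: the amino-acid k-mer length
#' \code{k}, the downsampling factor \code{scaled} (the sketch retains k-mers
#' whose 64-bit hash is at most \code{floor((2^64 - 1) / scaled)}, i.e. a
#' fraction \code{1/scaled} of the hash space), the hash seed, and the
#' alphabet tag. Two sketches may be compared only when their parameters
#' describe the same k-mer space (see \code{\link{paramsCompatible}}).
#'
#' @slot k integer(1), k-mer length in amino acids.
#' @slot scaled integer(1), downsampling denominator; \code{scaled = 1} keeps
#'   every distinct k-mer.
#' @slot seed integer(1), seed of the MurmurHash3 x64_128 hash function.
#' @slot alphabet character(1), \code{"protein"} for sketches built from
#'   protein sequence, \code{"nucleotide-translated"} for sketches built from
#'   six-frame-translated nucleotide reads. Both describe amino-acid k-mers
#'   and are mutually comparable.
#'
#' @seealso \code{\link{SketchParams}} for the constructor,
#'   \code{\link{hashSpaceMax}} and \code{\link{scaledThreshold}}.
#' @name SketchParams-class
#' @aliases SketchParams-class
#' @exportClass SketchParams
setClass("SketchParams",
  representation(
    k = "integer",
    scaled = "integer",
    seed = "integer",
    alphabet = "character"
  )
)

setValidity("SketchParams", function(object) {
  msg <- character(0)
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "'k' must be a single integer >= 1")
  if (length(object@scaled) != 1L || is.na(object@scaled) || object@scaled < 1L)
    msg <- c(msg, "'scaled' must be a single integer >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(object@alphabet) != 1L ||
      !object@alphabet %in% c("protein", "nucleotide-translated"))
    msg <- c(msg, "'alphabet' must be \"protein\" or \"nucleotide-translated\"")
  if (length(msg)) msg else TRUE
})

#' FracMinHash sketch of a sequence set
#'
#' The retained bottom fraction of hashed k-mers of a sequence set, with a
#' per-hash abundance (total multiplicity of the k-mers mapping to that
#' hash). Hashes are 64-bit unsigned values carried as decimal strings
#' (R has no native unsigned 64-bit integer type); they are stored sorted
#' ascending and each is at most \code{scaledThreshold(scaled)}.
#'
#' @slot params a \linkS4class{SketchParams}.
#' @slot name character(1) free-text identifier.
#' @slot hashes character vector of decimal 64-bit hash values, strictly
#'   increasing in numeric order.
#' @slot abundance numeric vector parallel to \code{hashes}; every entry a
#'   whole number >= 1.
#'
#' @seealso \code{\link{buildSketch}}, \code{\link{sketchSequences}},
#'   \code{\link{containment}}, \code{\link{weightedOverlap}}.
#' @name FracMinHashSketch-class
#' @aliases FracMinHashSketch-class
#' @exportClass FracMinHashSketch
setClass("FracMinHashSketch",
  representation(
    params = "SketchParams",
    name = "character",
    hashes = "character",
    abundance = "numeric"
  )
)

setValidity("FracMinHashSketch", function(object) {
  msg <- character(0)
  n <- length(object@hashes)
  if (length(object@abundance) != n)
    msg <- c(msg, "'hashes' and 'abundance' must be parallel")
  if (length(object@name) != 1L)
    msg <- c(msg, "'name' must be a single string")
  if (n > 0L) {
    if (anyNA(object@abundance) || any(object@abundance < 1) ||
        any(object@abundance != round(object@abundance)))
      msg <- c(msg, "abundances must be whole numbers >= 1")
    ord <- .u64_sort_order_cpp(object@hashes)
    if (!identical(ord, seq_len(n)) || anyDuplicated(object@hashes))
      msg <- c(msg, "hashes must be unique and sorted ascending")
    if (!all(.u64_below_threshold_cpp(object@hashes,
                                      as.double(object@params@scaled))))
      msg <- c(msg, "all hashes must be <= floor((2^64 - 1) / scaled)")
  }
  if (length(msg)) msg else TRUE
})

#' Collection of per-group reference sketches
#'
#' One \linkS4class{FracMinHashSketch} per ortholog group, all sharing the
#' same \linkS4class{SketchParams}. This is the reference database the
#' profiler searches with \code{\link{prefetchOverlaps}}.
#'
#' @slot params the shared \linkS4class{SketchParams}.
#' @slot sketches named list of \linkS4class{FracMinHashSketch}, one per
#'   group; names are the group identifiers.
#' @slot groupMeta named character vector of optional free-text group
#'   descriptions (possibly empty).
#'
#' @seealso \code{\link{buildReference}}, \code{\link{saveCollection}}.
#' @name ReferenceCollection-class
#' @aliases ReferenceCollection-class
#' @exportClass ReferenceCollection
setClass("ReferenceCollection",
  representation(
    params = "SketchParams",
    sketches = "list",
    groupMeta = "character"
  )
)

setValidity("ReferenceCollection", function(object) {
  msg <- character(0)
  ids <- names(object@sketches)
  if (length(object@sketches)) {
    if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
      msg <- c(msg, "group ids must be unique and nonempty")
    ok <- vapply(object@sketches, function(s)
      is(s, "FracMinHashSketch") && paramsIdentical(s@params, object@params),
      logical(1))
    if (!all(ok))
      msg <- c(msg, "all member sketches must share the collection's params")
  }
  if (length(object@groupMeta) &&
      !all(names(object@groupMeta) %in% ids))
    msg <- c(msg, "groupMeta names must be group ids")
  if (length(msg)) msg else TRUE
})

#' Relative-abundance functional profile
#'
#' Relative abundances of the ortholog groups detected in a metagenome,
#' normalized over the detected groups (abundances sum to 1 when nonempty).
#'
#' @slot abundances named numeric vector, group id -> relative abundance in
#'   (0, 1].
#' @slot params the \linkS4class{SketchParams} the profile was computed under.
#' @slot provenance list of free-form provenance fields (query name,
#'   overlap threshold, ...).
#'
#' @seealso \code{\link{computeProfile}}, \code{\link{evaluateProfile}}.
#' @name FunctionalProfile-class
#' @aliases FunctionalProfile-class
#' @exportClass FunctionalProfile
setClass("FunctionalProfile",
  representation(
    abundances = "numeric",
    params = "SketchParams",
    provenance = "list"
  )
)

.checkAbundanceMap <- function(x, what) {
  msg <- character(0)
  if (length(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))) || anyDuplicated(names(x)))
      msg <- c(msg, sprintf("%s must be named by unique group ids", what))
    if (anyNA(x) || any(x <= 0))
      msg <- c(msg, sprintf("%s must be positive", what))
    if (abs(sum(x) - 1) > 1e-9)
      msg <- c(msg, sprintf("%s must sum to 1 (within 1e-9)", what))
  }
  msg
}

setValidity("FunctionalProfile", function(object) {
  msg <- .checkAbundanceMap(object@abundances, "abundances")
  if (length(msg)) msg else TRUE
})

#' Ground-truth group abundances
#'
#' The true per-group relative abundances of a (simulated) metagenome,
#' derived from the number of read nucleotides covering annotated genes,
#' summed into groups through the gene-to-group mapping.
#'
#' @slot abundances named numeric, group id -> relative abundance, summing
#'   to 1 when nonempty.
#' @slot coveredNt named numeric parallel to \code{abundances}: total read
#'   nucleotides covering each group's genes.
#'
#' @seealso \code{\link{buildGroundTruth}}, \code{\link{coveredNucleotides}}.
#' @name GroundTruth-class
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    abundances = "numeric",
    coveredNt = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- .checkAbundanceMap(object@abundances, "abundances")
  if (!identical(names(object@abundances), names(object@coveredNt)))
    msg <- c(msg, "'abundances' and 'coveredNt' must share names")
  if (length(object@coveredNt) && any(object@coveredNt <= 0))
    msg <- c(msg, "coveredNt must be positive")
  if (length(msg)) msg else TRUE
})

#' Profile evaluation metrics
#'
#' The six metrics scoring a functional profile against a ground truth:
#' purity (precision of the detected group set), completeness (recall),
#' completeness restricted to the top fraction of truth abundance,
#' weighted Jaccard similarity, Pearson correlation, and Bray-Curtis
#' dissimilarity of the abundance vectors.
#'
#' @slot purity,completeness,completenessTop,weightedJaccard numeric(1)
#'   in [0, 1].
#' @slot pearson numeric(1) in [-1, 1].
#' @slot brayCurtis numeric(1) in [0, 1].
#' @slot topFraction numeric(1), the truth-abundance quantile used for
#'   \code{completenessTop} (default 0.95).
#'
#' @seealso \code{\link{evaluateProfile}}.
#' @name MetricsReport-class
#' @aliases MetricsReport-class
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    purity = "numeric",
    completeness = "numeric",
    completenessTop = "numeric",
    weightedJaccard = "numeric",
    pearson = "numeric",
    brayCurtis = "numeric",
    topFraction = "numeric"
  )
)

setValidity("MetricsReport", function(object) {
  unit <- c(purity = object@purity, completeness = object@completeness,
            completenessTop = object@completenessTop,
            weightedJaccard = object@weightedJaccard,
            brayCurtis = object@brayCurtis)
  msg <- character(0)
  if (any(unit < -1e-12 | unit > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "unit-interval metrics must lie in [0, 1]")
  if (!is.na(object@pearson) && abs(object@pearson) > 1 + 1e-12)
    msg <- c(msg, "pearson must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic benchmark configuration
#'
#' Parameters of the synthetic benchmark generator: an artificial database
#' of protein families, genomes assembled from family-member genes,
#' lognormally distributed genome abundances, and error-prone single-end
#' reads with Gaussian fragment lengths.
#'
#' @slot nFamilies,genesPerFamily integer(1): database size.
#' @slot geneLenRange integer(2): min/max gene length in nucleotides.
#' @slot withinFamilyDivergence numeric(1): per-residue substitution
#'   probability between a family member and the family's ancestral protein.
#' @slot nGenomes,genesPerGenome integer(1): community size; genes are drawn
#'   from the family pool without replacement within each genome.
#' @slot intergenicLenRange integer(2): min/max spacer length between genes.
#' @slot abundanceLogMu,abundanceLogSigma numeric(1): parameters of the
#'   underlying normal in log space for the lognormal genome abundances
#'   (defaults 1 and 2).
#' @slot totalBases numeric(1): approximate total sequenced bases.
#' @slot fragmentMean,fragmentSd numeric(1): Gaussian fragment-length model
#'   (defaults 270 and 27 nt).
#' @slot readLen integer(1): read length in nt.
#' @slot errorRate numeric(1): per-base substitution probability.
#' @slot seed integer(1): master seed; every generator stage derives its
#'   RNG state from it.
#'
#' @seealso \code{\link{synthConfig}}, \code{\link{makeBenchmark}}.
#' @name SynthConfig-class
#' @aliases SynthConfig-class
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(
    nFamilies = "integer",
    genesPerFamily = "integer",
    geneLenRange = "integer",
    withinFamilyDivergence = "numeric",
    nGenomes = "integer",
    genesPerGenome = "integer",
    intergenicLenRange = "integer",
    abundanceLogMu = "numeric",
    abundanceLogSigma = "numeric",
    totalBases = "numeric",
    fragmentMean = "numeric",
    fragmentSd = "numeric",
    readLen = "integer",
    errorRate = "numeric",
    seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character(0)
  pos <- c(nFamilies = object@nFamilies, genesPerFamily = object@genesPerFamily,
           nGenomes = object@nGenomes, genesPerGenome = object@genesPerGenome,
           totalBases = object@totalBases, fragmentMean = object@fragmentMean,
           readLen = object@readLen)
  if (any(pos < 1))
    msg <- c(msg, "counts and sizes must be positive")
  if (object@fragmentSd < 0)
    msg <- c(msg, "'fragmentSd' must be >= 0")
  for (p in c("withinFamilyDivergence", "errorRate")) {
    v <- slot(object, p)
    if (v < 0 || v >= 1)
      msg <- c(msg, sprintf("'%s' must lie in [0, 1)", p))
  }
  for (p in c("geneLenRange", "intergenicLenRange")) {
    v <- slot(object, p)
    if (length(v) != 2L || v[1] > v[2] || v[1] < 0)
      msg <- c(msg, sprintf("'%s' must be an increasing pair", p))
  }
  if (object@geneLenRange[1] < 3L)
    msg <- c(msg, "genes must be at least one codon long")
  if (object@abundanceLogSigma < 0)
    msg <- c(msg, "'abundanceLogSigma' must be >= 0")
  if (length(msg)) msg else TRUE
})
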