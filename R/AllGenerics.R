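#' @rdname containment
#' @export
setGeneric("containment", function(query, ref) standardGeneric("containment"))

#' @rdname weightedOverlap
#' @export
setGeneric("weightedOverlap", function(query, ref)
  standardGeneric("weightedOverlap"))

#' @rdname mergeSketches
#' @export
setGeneric("mergeSketches", function(x, ...) standardGeneric("mergeSketches"))

#' @rdname downsampleSketch
#' @export
setGeneric("downsampleSketch", function(x, scaled)
  standardGeneric("downsampleSketch"))

#' Accessors for sketches, collections, profiles and truths
#'
#' \code{sketchParams} returns the \linkS4class{SketchParams} of an object;
#' \code{sketchHashes} and \code{hashAbundance} the retained hash values
#' (decimal strings) and their abundances; \code{sketchName} the sketch
#' identifier; \code{nHashes} the unweighted sketch size and
#' \code{weightedSize} the abundance-weighted size; \code{groupIds} the
#' group identifiers of a \linkS4class{ReferenceCollection}, a
#' \linkS4class{FunctionalProfile} or a \linkS4class{GroundTruth};
#' \code{getSketch} one member sketch of a collection; \code{abundances}
#' the named relative-abundance vector of a profile or truth.
#'
#' @param x the object.
#' @param id character(1) group identifier.
#' @return See above; accessors return base vectors or member objects.
#' @examples
#' p <- SketchParams(k = 3, scaled = 1)
#' s <- buildSketch(c("MKV", "KVL"), p, name = "toy")
#' nHashes(s)
#' weightedSize(s)
#' sketchParams(s)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sketchParams", function(x) standardGeneric("sketchParams"))

#' @rdname accessors
#' @export
setGeneric("sketchHashes", function(x) standardGeneric("sketchHashes"))

#' @rdname accessors
#' @export
setGeneric("hashAbundance", function(x) standardGeneric("hashAbundance"))

#' @rdname accessors
#' @export
setGeneric("sketchName", function(x) standardGeneric("sketchName"))

#' @rdname accessors
#' @export
setGeneric("nHashes", function(x) standardGeneric("nHashes"))

#' @rdname accessors
#' @export
setGeneric("weightedSize", function(x) standardGeneric("weightedSize"))

#' @rdname accessors
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' @rdname accessors
#' @export
setGeneric("getSketch", function(x, id) standardGeneric("getSketch"))

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
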