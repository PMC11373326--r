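# Reference database: one sketch per ortholog group, JSON-lines on disk.

.FORMAT_NAME <- "orthosketch-refdb"
.FORMAT_VERSION <- 1L

# one sketch -> canonical single-line JSON (hashes as decimal strings: JSON
# numbers cannot carry full 64-bit integers exactly)
.sketchToJson <- function(s, description = NULL) {
  doc <- list(name = s@name, k = s@params@k, scaled = s@params@scaled,
              seed = s@params@seed, alphabet = s@params@alphabet,
              hashes = s@hashes, abundances = as.integer(s@abundance))
  if (!is.null(description) && !is.na(description))
    doc$description <- description
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
}

.sketchFromJson <- function(doc, params = NULL) {
  for (f in c("name", "k", "scaled", "seed", "alphabet", "hashes",
              "abundances"))
    if (is.null(doc[[f]]))
      stop("sketch record is missing field '", f, "'")
  p <- SketchParams(k = doc$k, scaled = doc$scaled, seed = doc$seed,
                    alphabet = doc$alphabet)
  if (!is.null(params) && !paramsIdentical(p, params))
    stop("sketch '", doc$name, "' params disagree with the collection manifest")
  .newSketch(p, doc$name,
             list(hashes = as.character(doc$hashes),
                  abundance = as.numeric(doc$abundances)))
}

#' Save / load a single sketch as JSON
#'
#' The JSON document stores the hash values sorted ascending as decimal
#' strings (exact 64-bit values do not fit JSON's double-precision
#' numbers), making files byte-reproducible.
#'
#' @param x a \linkS4class{FracMinHashSketch}.
#' @param path file path.
#' @return \code{loadSketch} returns the sketch; \code{saveSketch} its path,
#'   invisibly.
#' @export
saveSketch <- function(x, path) {
  stopifnot(is(x, "FracMinHashSketch"))
  writeLines(.sketchToJson(x), path)
  invisible(path)
}

#' @rdname saveSketch
#' @export
loadSketch <- function(path) {
  .sketchFromJson(jsonlite::fromJSON(readLines(path, warn = FALSE)))
}

#' Build a reference collection from grouped protein sequences
#'
#' Reads protein FASTA record(s), assigns each gene to its ortholog
#' group(s) through the gene-to-group mapping, and builds one merged
#' FracMinHash sketch per group. A gene mapped to several groups
#' contributes its k-mers to each. Genes present in the FASTA but absent
#' from the mapping are skipped (their count is reported); groups in the
#' mapping with no available sequence are omitted with a warning. Groups
#' whose sketch retains no hash are kept: they exist in the database but
#' can never be detected.
#'
#' @param proteins path(s) to protein FASTA file(s), or an
#'   \link[Biostrings]{AAStringSet}. Record ids are the first
#'   whitespace-delimited word of the header; duplicated ids are an error.
#' @param geneToGroup data.frame with columns \code{gene_id} and
#'   \code{group_id} (see \code{\link{readGeneToGroup}}).
#' @param params a \linkS4class{SketchParams}.
#' @param groupMeta optional named character vector of group descriptions.
#' @return A \linkS4class{ReferenceCollection}; groups are stored in
#'   lexicographic id order, so construction is independent of record
#'   order.
#' @examples
#' p <- SketchParams(k = 3, scaled = 1)
#' aa <- Biostrings::AAStringSet(c(g1 = "MKVLY", g2 = "MKVAA"))
#' m <- data.frame(gene_id = c("g1", "g2"), group_id = c("K1", "K1"))
#' buildReference(aa, m, p)
#' @export
buildReference <- function(proteins, geneToGroup, params,
                           groupMeta = character(0)) {
  stopifnot(is(params, "SketchParams"))
  if (!all(c("gene_id", "group_id") %in% names(geneToGroup)))
    stop("'geneToGroup' needs columns gene_id and group_id")
  if (is(proteins, "AAStringSet")) {
    seqs <- proteins
  } else {
    seqs <- do.call(c, lapply(proteins, Biostrings::readAAStringSet))
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))

  geneToGroup <- unique(geneToGroup[, c("gene_id", "group_id")])
  allGroups <- unique(geneToGroup$group_id)
  unmapped <- setdiff(names(seqs), geneToGroup$gene_id)
  if (length(unmapped))
    message(length(unmapped), " gene(s) without a group mapping were skipped")
  present <- geneToGroup$gene_id %in% names(seqs)
  missing <- unique(geneToGroup$gene_id[!present])
  if (length(missing))
    message(length(missing), " mapped gene(s) missing from the FASTA were ",
            "skipped")
  geneToGroup <- geneToGroup[present, , drop = FALSE]
  groups <- sort(unique(geneToGroup$group_id))
  omitted <- setdiff(allGroups, groups)
  if (length(omitted))
    warning(length(omitted), " group(s) with no available sequence were ",
            "omitted: ", paste(utils::head(omitted, 5L), collapse = ", "),
            if (length(omitted) > 5L) ", ...")
  byGroup <- split(geneToGroup$gene_id, geneToGroup$group_id)
  if (!length(byGroup))
    warning("no group has any sequence; collection is empty")
  sketches <- lapply(groups, function(g) {
    .sketchRecords(seqs[byGroup[[g]]], params, "protein", g)
  })
  names(sketches) <- groups
  if (length(groupMeta))
    groupMeta <- groupMeta[names(groupMeta) %in% groups]
  new("ReferenceCollection", params = params, sketches = sketches,
      groupMeta = groupMeta)
}

#' Save / load a reference collection
#'
#' JSON-lines format: the first line is a manifest (format name, version,
#' shared parameters, group count); each following line is one group sketch
#' in group-id order. \code{load(save(x))} reproduces the collection
#' exactly, and re-serialization is byte-identical.
#'
#' @param rc a \linkS4class{ReferenceCollection}.
#' @param path file path (conventionally \code{*.sig.jsonl}).
#' @return \code{loadCollection} returns the collection; \code{saveCollection}
#'   the path, invisibly.
#' @export
saveCollection <- function(rc, path) {
  stopifnot(is(rc, "ReferenceCollection"))
  ids <- sort(names(rc@sketches))
  manifest <- jsonlite::toJSON(
    list(format = .FORMAT_NAME, version = .FORMAT_VERSION,
         k = rc@params@k, scaled = rc@params@scaled, seed = rc@params@seed,
         alphabet = rc@params@alphabet, n_groups = length(ids)),
    auto_unbox = TRUE, digits = NA)
  lines <- vapply(ids, function(g)
    as.character(.sketchToJson(rc@sketches[[g]],
                               description = rc@groupMeta[g])),
    character(1))
  writeLines(c(manifest, lines), path)
  invisible(path)
}

#' @rdname saveCollection
#' @export
loadCollection <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("'", path, "' is empty")
  manifest <- jsonlite::fromJSON(lines[1L])
  for (f in c("format", "version", "k", "scaled", "seed", "alphabet",
              "n_groups"))
    if (is.null(manifest[[f]]))
      stop("collection manifest is missing field '", f, "'")
  if (!identical(manifest$format, .FORMAT_NAME))
    stop("'", path, "' is not a ", .FORMAT_NAME, " file (field 'format')")
  if (manifest$version > .FORMAT_VERSION)
    stop("unsupported collection version (field 'version'): ",
         manifest$version)
  params <- SketchParams(k = manifest$k, scaled = manifest$scaled,
                         seed = manifest$seed, alphabet = manifest$alphabet)
  body <- lines[-1L]
  if (length(body) != manifest$n_groups)
    stop("collection has ", length(body), " sketch lines but the manifest ",
         "declares ", manifest$n_groups, " (field 'n_groups')")
  sketches <- vector("list", length(body))
  meta <- character(0)
  for (i in seq_along(body)) {
    doc <- jsonlite::fromJSON(body[i])
    sketches[[i]] <- .sketchFromJson(doc, params)
    if (!is.null(doc$description)) meta[doc$name] <- doc$description
  }
  names(sketches) <- vapply(sketches, slot, character(1), "name")
  new("ReferenceCollection", params = params, sketches = sketches,
      groupMeta = meta)
}

#' @rdname accessors
#' @export
setMethod("groupIds", "ReferenceCollection", function(x) names(x@sketches))
#' @rdname accessors
#' @export
setMethod("getSketch", "ReferenceCollection", function(x, id) {
  if (!id %in% names(x@sketches)) stop("no group '", id, "' in collection")
  x@sketches[[id]]
})
#' @rdname accessors
#' @export
setMethod("nHashes", "ReferenceCollection", function(x)
  vapply(x@sketches, function(s) length(s@hashes), integer(1)))

setMethod("show", "ReferenceCollection", function(object) {
  cat("ReferenceCollection: ", length(object@sketches), " group(s), k=",
      object@params@k, ", scaled=", object@params@scaled, "\n", sep = "")
  if (length(object@sketches)) {
    sz <- nHashes(object)
    cat("  hashes per group: min ", min(sz), ", median ",
        stats::median(sz), ", max ", max(sz), "\n", sep = "")
  }
})
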