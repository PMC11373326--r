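# Prefetch-style overlap search and relative-abundance profiling.

#' Find reference groups overlapping a metagenome sketch
#'
#' Reports, independently for every reference group, the overlap between
#' the query sketch and the group's sketch, keeping groups whose hash
#' overlap reaches the threshold \code{ceiling(thresholdBp / scaled)}
#' (the minimum overlap expressed in base-pair equivalents; at the default
#' \code{thresholdBp = 1000} and \code{scaled = 1000} this is one hash).
#' Hashes shared between groups count toward every group: there is no
#' assignment of shared content.
#'
#' @param query a \linkS4class{FracMinHashSketch} of the metagenome.
#' @param rc a \linkS4class{ReferenceCollection} with comparable parameters.
#' @param thresholdBp minimum overlap in base-pair equivalents (default
#'   1000).
#' @return A \link[S4Vectors]{DataFrame} with one row per reported group:
#'   \code{group_id}, \code{hash_overlap}, \code{weighted_overlap} (query
#'   abundances summed over the intersection), \code{containment_of_ref}
#'   (fraction of the reference sketch covered), and \code{est_overlap_bp}
#'   (\code{hash_overlap * scaled}). Rows are sorted by
#'   \code{weighted_overlap} descending, ties by \code{group_id}.
#' @examples
#' p <- SketchParams(k = 3, scaled = 1)
#' aa <- Biostrings::AAStringSet(c(g1 = "MKVLY", g2 = "AAAWWW"))
#' m <- data.frame(gene_id = c("g1", "g2"), group_id = c("K1", "K2"))
#' rc <- buildReference(aa, m, p)
#' q <- buildSketch(extractKmers("MKVLY", 3), p, "sample")
#' prefetchOverlaps(q, rc, thresholdBp = 1)
#' @export
prefetchOverlaps <- function(query, rc, thresholdBp = 1000L) {
  stopifnot(is(query, "FracMinHashSketch"), is(rc, "ReferenceCollection"),
            thresholdBp >= 0)
  .stopIfIncompatible(query@params, rc@params)
  minHashes <- as.integer(ceiling(thresholdBp / query@params@scaled))
  ids <- names(rc@sketches)
  if (length(query@hashes) == 0L) {
    warning("query sketch is empty; no overlaps to report")
    ids <- character(0)
  }
  rows <- vector("list", length(ids))
  qh <- query@hashes
  qa <- query@abundance
  for (i in seq_along(ids)) {
    ref <- rc@sketches[[ids[i]]]
    pos <- match(ref@hashes, qh)
    hit <- !is.na(pos)
    ho <- sum(hit)
    if (ho < minHashes) next
    rows[[i]] <- data.frame(
      group_id = ids[i],
      hash_overlap = ho,
      weighted_overlap = if (ho) sum(qa[pos[hit]]) else 0,
      containment_of_ref = if (length(ref@hashes)) ho / length(ref@hashes)
                           else 0,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(group_id = character(0), hash_overlap = integer(0),
                         weighted_overlap = numeric(0),
                         containment_of_ref = numeric(0))
  out$est_overlap_bp <- out$hash_overlap * as.numeric(query@params@scaled)
  out <- out[order(-out$weighted_overlap, out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  S4Vectors::DataFrame(out)
}

#' Convert overlap records to a relative-abundance profile
#'
#' Each reported group's abundance is its weighted overlap divided by the
#' total weighted overlap across reported groups. A query hash shared by
#' several groups contributes to each group's numerator, so homologous
#' groups can be mildly inflated. Records with zero weighted overlap are
#' dropped (abundances lie in (0, 1]).
#'
#' @param overlaps output of \code{\link{prefetchOverlaps}} (a DataFrame or
#'   data.frame with \code{group_id} and \code{weighted_overlap}).
#' @param params optional \linkS4class{SketchParams} to record.
#' @param provenance optional list of provenance fields.
#' @return A \linkS4class{FunctionalProfile}; empty input yields an empty
#'   profile.
#' @examples
#' ov <- data.frame(group_id = c("K1", "K2"),
#'                  weighted_overlap = c(30, 10))
#' abundances(computeProfile(ov))  # 0.75, 0.25
#' @export
computeProfile <- function(overlaps, params = SketchParams(),
                           provenance = list()) {
  overlaps <- as.data.frame(overlaps)
  keep <- overlaps$weighted_overlap > 0
  overlaps <- overlaps[keep, , drop = FALSE]
  if (nrow(overlaps)) {
    ab <- overlaps$weighted_overlap / sum(overlaps$weighted_overlap)
    names(ab) <- overlaps$group_id
  } else {
    ab <- stats::setNames(numeric(0), character(0))
  }
  new("FunctionalProfile", abundances = ab, params = params,
      provenance = provenance)
}

#' Run the whole profiling pipeline on a read file
#'
#' Sketches the reads (six-frame translation for nucleotide input), finds
#' overlapping reference groups, converts them to relative abundances, and
#' optionally writes a TSV report. Deterministic: identical inputs give
#' byte-identical output.
#'
#' @param reads path to a FASTA/FASTQ file of reads (gzip transparent).
#' @param refdb path to a saved reference collection
#'   (\code{\link{saveCollection}}) or a \linkS4class{ReferenceCollection}.
#' @param thresholdBp minimum overlap in base-pair equivalents.
#' @param out optional output TSV path.
#' @param mode \code{"nucleotide"} (default) or \code{"protein"} reads.
#' @return Invisibly, a list with \code{profile}
#'   (\linkS4class{FunctionalProfile}) and \code{overlaps} (the record
#'   table with a \code{relative_abundance} column appended).
#' @export
runProfile <- function(reads, refdb, thresholdBp = 1000L, out = NULL,
                       mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  rc <- if (is(refdb, "ReferenceCollection")) refdb else loadCollection(refdb)
  query <- sketchSequences(reads, rc@params, mode = mode)
  if (nHashes(query) == 0L)
    warning("no k-mers were retained from '",
            if (is.character(reads)) reads else "reads",
            "'; profile is empty")
  ov <- if (nHashes(query)) prefetchOverlaps(query, rc, thresholdBp)
        else S4Vectors::DataFrame(group_id = character(0),
                                  hash_overlap = integer(0),
                                  weighted_overlap = numeric(0),
                                  containment_of_ref = numeric(0),
                                  est_overlap_bp = numeric(0))
  prof <- computeProfile(ov, params = rc@params,
                         provenance = list(reads = if (is.character(reads))
                                             basename(reads) else "reads",
                                           threshold_bp = thresholdBp))
  tab <- as.data.frame(ov)
  tab$relative_abundance <- abundances(prof)[tab$group_id]
  tab$relative_abundance[is.na(tab$relative_abundance)] <- 0
  if (!is.null(out)) writeProfileTsv(tab, out)
  invisible(list(profile = prof, overlaps = tab))
}

#' Write / read a profile TSV
#'
#' Columns: \code{group_id}, \code{hash_overlap}, \code{weighted_overlap},
#' \code{containment_of_ref}, \code{relative_abundance}; fractions are
#' printed with 6 significant digits.
#'
#' @param tab overlap table from \code{\link{runProfile}}.
#' @param path file path.
#' @return \code{writeProfileTsv} returns the path invisibly;
#'   \code{readProfileTsv} a \linkS4class{FunctionalProfile} rebuilt from
#'   the \code{weighted_overlap} column.
#' @export
writeProfileTsv <- function(tab, path) {
  tab <- as.data.frame(tab)
  out <- data.frame(
    group_id = tab$group_id,
    hash_overlap = tab$hash_overlap,
    weighted_overlap = tab$weighted_overlap,
    containment_of_ref = sprintf("%.6g", tab$containment_of_ref),
    relative_abundance = sprintf("%.6g", tab$relative_abundance),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileTsv
#' @export
readProfileTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  computeProfile(tab, provenance = list(source = basename(path)))
}

#' @rdname accessors
#' @export
setMethod("abundances", "FunctionalProfile", function(x) x@abundances)
#' @rdname accessors
#' @export
setMethod("groupIds", "FunctionalProfile", function(x) names(x@abundances))

setMethod("show", "FunctionalProfile", function(object) {
  cat("FunctionalProfile: ", length(object@abundances),
      " group(s)\n", sep = "")
  if (length(object@abundances)) {
    top <- utils::head(sort(object@abundances, decreasing = TRUE), 5L)
    for (g in names(top))
      cat(sprintf("  %-12s %.4g\n", g, top[g]))
    if (length(object@abundances) > 5L) cat("  ...\n")
  }
})
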