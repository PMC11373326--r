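# Ground-truth construction from read mappings + gene coordinates, and the
# six-metric evaluation of a profile against that truth.

#' Read the gene-to-group mapping table
#'
#' Two-column TSV \code{gene_id<TAB>group_id}; a gene may appear on several
#' rows (multi-group membership).
#'
#' @param path TSV path (a header line naming the two columns is optional).
#' @return data.frame with columns \code{gene_id}, \code{group_id}.
#' @export
readGeneToGroup <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("gene_id", "group_id"))
  if (nrow(tab) && identical(unlist(tab[1, ], use.names = FALSE),
                             c("gene_id", "group_id")))
    tab <- tab[-1, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Read gene annotations / read mappings
#'
#' \code{readGeneAnnotations}: TSV with columns \code{genome_id, gene_id,
#' start, end, group_id} (1-based inclusive nucleotide coordinates).
#' \code{readReadMappings}: TSV with columns \code{read_id, genome_id,
#' start, end}.
#'
#' @param path TSV path with a header line.
#' @return data.frame.
#' @export
readGeneAnnotations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("genome_id", "gene_id", "start", "end", "group_id")
  if (!all(need %in% names(tab)))
    stop("gene annotation table needs columns: ",
         paste(need, collapse = ", "))
  tab
}

#' @rdname readGeneAnnotations
#' @export
readReadMappings <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("read_id", "genome_id", "start", "end")
  if (!all(need %in% names(tab)))
    stop("read mapping table needs columns: ", paste(need, collapse = ", "))
  tab
}

#' Convert 0-based half-open (BED) coordinates to 1-based inclusive
#'
#' All coordinates in this package are 1-based inclusive; use this at the
#' boundary when importing BED-style intervals.
#'
#' @param start,end numeric vectors of 0-based half-open coordinates.
#' @return data.frame with 1-based inclusive \code{start}, \code{end}.
#' @examples
#' bedToOneBased(0, 100)  # start 1, end 100
#' @export
bedToOneBased <- function(start, end) {
  data.frame(start = start + 1L, end = end)
}

#' Nucleotides of each gene covered by mapped reads
#'
#' For every gene, the sum over reads of the length of the intersection of
#' the read's aligned span with the gene's span (1-based inclusive, same
#' genome). Overlaps are summed with multiplicity -- two identical reads
#' each overlapping a gene by 50 nt contribute 100 -- so coverage reflects
#' sequencing depth, not positional footprint.
#'
#' @param mappings data.frame of read mappings
#'   (\code{\link{readReadMappings}}).
#' @param genes data.frame of gene annotations
#'   (\code{\link{readGeneAnnotations}}).
#' @return named numeric vector, gene_id -> covered nucleotides (all
#'   annotated genes present, zeros included). Mappings to genomes absent
#'   from the annotation are counted as zero with a warning.
#' @examples
#' genes <- data.frame(genome_id = "G", gene_id = "g1",
#'                     start = 101, end = 200, group_id = "K1")
#' maps <- data.frame(read_id = "r1", genome_id = "G",
#'                    start = 151, end = 250)
#' coveredNucleotides(maps, genes)  # g1: 50
#' @export
coveredNucleotides <- function(mappings, genes) {
  stopifnot(all(genes$start >= 1), all(genes$start <= genes$end),
            all(mappings$start >= 1), all(mappings$start <= mappings$end))
  cov <- stats::setNames(numeric(length(unique(genes$gene_id))),
                         unique(genes$gene_id))
  unknown <- setdiff(unique(mappings$genome_id), unique(genes$genome_id))
  if (length(unknown))
    warning("mappings to unknown genome(s) counted as zero coverage: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  for (gm in intersect(unique(genes$genome_id), unique(mappings$genome_id))) {
    g <- genes[genes$genome_id == gm, , drop = FALSE]
    m <- mappings[mappings$genome_id == gm, , drop = FALSE]
    gi <- IRanges::IRanges(start = g$start, end = g$end)
    mi <- IRanges::IRanges(start = m$start, end = m$end)
    hits <- IRanges::findOverlaps(gi, mi)
    if (!length(hits)) next
    ints <- IRanges::pintersect(gi[S4Vectors::queryHits(hits)],
                                mi[S4Vectors::subjectHits(hits)])
    per <- tapply(IRanges::width(ints),
                  g$gene_id[S4Vectors::queryHits(hits)], sum)
    cov[names(per)] <- cov[names(per)] + as.numeric(per)
  }
  cov
}

#' Build the ground-truth group abundances
#'
#' Sums per-gene covered nucleotides into groups through the gene-to-group
#' mapping (a gene in several groups contributes its full coverage to
#' each), drops groups with zero coverage, and normalizes to relative
#' abundances.
#'
#' @param geneCov named numeric vector from
#'   \code{\link{coveredNucleotides}}.
#' @param geneToGroup data.frame with \code{gene_id}, \code{group_id}.
#' @return A \linkS4class{GroundTruth}. Covered genes without any group
#'   are dropped (their count is reported).
#' @examples
#' truth <- buildGroundTruth(
#'   c(g1 = 100, g2 = 300),
#'   data.frame(gene_id = c("g1", "g2"), group_id = c("K1", "K2")))
#' abundances(truth)  # K1 0.25, K2 0.75
#' @export
buildGroundTruth <- function(geneCov, geneToGroup) {
  geneCov <- geneCov[geneCov > 0]
  geneToGroup <- unique(geneToGroup[, c("gene_id", "group_id")])
  orphan <- setdiff(names(geneCov), geneToGroup$gene_id)
  if (length(orphan))
    message(length(orphan), " covered gene(s) without a group were dropped")
  hit <- geneToGroup[geneToGroup$gene_id %in% names(geneCov), , drop = FALSE]
  if (!nrow(hit))
    return(new("GroundTruth", abundances = stats::setNames(numeric(0),
                                                           character(0)),
               coveredNt = stats::setNames(numeric(0), character(0))))
  per <- tapply(geneCov[hit$gene_id], hit$group_id, sum)
  per <- per[order(names(per))]
  covered <- stats::setNames(as.numeric(per), names(per))
  new("GroundTruth", abundances = covered / sum(covered),
      coveredNt = covered)
}

#' @rdname accessors
#' @export
setMethod("abundances", "GroundTruth", function(x) x@abundances)
#' @rdname accessors
#' @export
setMethod("groupIds", "GroundTruth", function(x) names(x@abundances))

#' Covered nucleotides per group
#'
#' @param x a \linkS4class{GroundTruth}.
#' @return named numeric vector, group id -> covered nucleotides.
#' @export
coveredNt <- function(x) {
  stopifnot(is(x, "GroundTruth"))
  x@coveredNt
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth: ", length(object@abundances), " group(s), ",
      format(sum(object@coveredNt), big.mark = ","),
      " covered nt\n", sep = "")
})

# ---- metric primitives ----

.keysOf <- function(x) {
  if (is(x, "FunctionalProfile") || is(x, "GroundTruth")) groupIds(x)
  else if (is.character(x)) x
  else if (is.numeric(x) && !is.null(names(x))) names(x)[x > 0]
  else stop("cannot interpret group keys from a ", class(x)[1])
}

.abundanceOf <- function(x) {
  if (is(x, "FunctionalProfile") || is(x, "GroundTruth")) abundances(x)
  else if (is.numeric(x) && !is.null(names(x))) x
  else stop("an abundance map (named numeric) is required, got a ",
            class(x)[1])
}

# align two abundance maps on the union of positively supported keys,
# missing = 0 (keys at zero in both maps carry no information and would
# perturb the Pearson estimate)
.alignUnion <- function(x, y) {
  x <- .abundanceOf(x)
  y <- .abundanceOf(y)
  keys <- union(names(x)[x > 0], names(y)[y > 0])
  xv <- stats::setNames(numeric(length(keys)), keys)
  yv <- xv
  kx <- intersect(names(x), keys)
  ky <- intersect(names(y), keys)
  xv[kx] <- x[kx]
  yv[ky] <- y[ky]
  list(x = xv, y = yv)
}

#' Purity of a detected group set
#'
#' The precision |P n G| / |P| of the detected groups P against the truth
#' groups G.
#'
#' @param profileKeys detected groups: a character vector, a named
#'   abundance vector, or a \linkS4class{FunctionalProfile}.
#' @param truthKeys truth groups, same conventions (or a
#'   \linkS4class{GroundTruth}).
#' @return numeric(1) in [0, 1]; empty P is an error.
#' @examples
#' purity(c("A", "D"), c("A", "B", "C"))  # 0.5
#' @export
purity <- function(profileKeys, truthKeys) {
  p <- .keysOf(profileKeys)
  g <- .keysOf(truthKeys)
  if (!length(p)) stop("purity is undefined for an empty profile")
  length(intersect(p, g)) / length(p)
}

#' Completeness of a detected group set
#'
#' The recall |P n G| / |G| of the detected groups against the truth
#' groups. With \code{topFraction = q}, the truth is first reduced to the
#' minimal prefix of groups -- sorted by truth abundance descending, ties
#' broken by group id -- whose cumulative abundance reaches at least
#' \code{q} ("top-q completeness"): this discounts the very lowly abundant
#' groups a downsampling sketch cannot be expected to see.
#'
#' @param profileKeys detected groups (character vector, named abundance
#'   vector, or \linkS4class{FunctionalProfile}).
#' @param truth truth groups; must carry abundances (named numeric or
#'   \linkS4class{GroundTruth}) when \code{topFraction} is given.
#' @param topFraction optional quantile q in (0, 1].
#' @return numeric(1) in [0, 1].
#' @examples
#' truth <- c(A = 0.6, B = 0.3, C = 0.06, D = 0.04)
#' completeness(c("A", "B"), truth, topFraction = 0.95)  # 2/3
#' @export
completeness <- function(profileKeys, truth, topFraction = NULL) {
  p <- .keysOf(profileKeys)
  if (is.null(topFraction)) {
    g <- .keysOf(truth)
  } else {
    stopifnot(topFraction > 0, topFraction <= 1)
    ab <- .abundanceOf(truth)
    ord <- order(-ab, names(ab))
    cum <- cumsum(ab[ord])
    ncut <- which(cum >= topFraction - 1e-12)[1]
    if (is.na(ncut)) ncut <- length(ab)
    g <- names(ab)[ord][seq_len(ncut)]
  }
  if (!length(g)) stop("completeness is undefined for an empty truth set")
  length(intersect(p, g)) / length(g)
}

#' Weighted Jaccard similarity of two abundance maps
#'
#' sum(min(x, y)) / sum(max(x, y)) over the union of keys (missing = 0).
#'
#' @param x,y named abundance vectors, \linkS4class{FunctionalProfile} or
#'   \linkS4class{GroundTruth}.
#' @return numeric(1) in [0, 1].
#' @examples
#' weightedJaccard(c(A = 0.6, B = 0.4),
#'                 c(A = 0.5, B = 0.3, C = 0.2))  # 0.8 / 1.2
#' @export
weightedJaccard <- function(x, y) {
  al <- .alignUnion(x, y)
  sum(pmin(al$x, al$y)) / sum(pmax(al$x, al$y))
}

#' Bray-Curtis dissimilarity of two abundance maps
#'
#' sum(|x - y|) / sum(x + y) over the union of keys (missing = 0); 0 for
#' identical maps, 1 for disjoint supports.
#'
#' @inheritParams weightedJaccard
#' @return numeric(1) in [0, 1].
#' @examples
#' brayCurtis(c(A = 0.6, B = 0.4), c(A = 0.5, B = 0.3, C = 0.2))  # 0.2
#' @export
brayCurtis <- function(x, y) {
  al <- .alignUnion(x, y)
  sum(abs(al$x - al$y)) / sum(al$x + al$y)
}

#' Pearson correlation of two abundance maps
#'
#' Sample correlation of the two abundance vectors laid out over the union
#' of keys (missing = 0). Undefined (an error) when either vector is
#' constant.
#'
#' @inheritParams weightedJaccard
#' @return numeric(1) in [-1, 1].
#' @export
pearsonAbundance <- function(x, y) {
  al <- .alignUnion(x, y)
  if (length(al$x) < 2L || stats::sd(al$x) == 0 || stats::sd(al$y) == 0)
    stop("Pearson correlation is undefined for constant abundance vectors")
  stats::cor(al$x, al$y)
}

#' Score a profile against the ground truth
#'
#' Assembles the six evaluation metrics: purity and completeness of the
#' detected group set, completeness restricted to the top
#' \code{topFraction} of truth abundance, and weighted Jaccard, Pearson and
#' Bray-Curtis over the abundance vectors.
#'
#' @param profile a \linkS4class{FunctionalProfile} (or named abundance
#'   vector).
#' @param truth a \linkS4class{GroundTruth} (or named abundance vector).
#' @param topFraction truth-abundance quantile for the restricted
#'   completeness (default 0.95).
#' @return A \linkS4class{MetricsReport}.
#' @examples
#' x <- c(A = 0.6, B = 0.4)
#' evaluateProfile(x, x)  # all similarities 1, Bray-Curtis 0
#' @export
evaluateProfile <- function(profile, truth, topFraction = 0.95) {
  new("MetricsReport",
      purity = purity(profile, truth),
      completeness = completeness(profile, truth),
      completenessTop = completeness(profile, truth,
                                     topFraction = topFraction),
      weightedJaccard = weightedJaccard(profile, truth),
      pearson = pearsonAbundance(profile, truth),
      brayCurtis = brayCurtis(profile, truth),
      topFraction = topFraction)
}

#' @describeIn evaluateProfile flatten a report to a named numeric vector.
#' @param report a \linkS4class{MetricsReport}.
#' @export
metricsAsVector <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  c(purity = report@purity,
    completeness = report@completeness,
    completeness_top = report@completenessTop,
    weighted_jaccard = report@weightedJaccard,
    pearson = report@pearson,
    bray_curtis = report@brayCurtis)
}

#' Write a metrics report
#'
#' @param report a \linkS4class{MetricsReport}.
#' @param path output path; format follows the extension (\code{.json} or
#'   TSV otherwise).
#' @return the path, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  v <- metricsAsVector(report)
  if (grepl("\\.json$", path)) {
    doc <- c(as.list(v), list(top_fraction = report@topFraction))
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  } else {
    utils::write.table(
      data.frame(metric = c(names(v), "top_fraction"),
                 value = sprintf("%.6g", c(v, report@topFraction))),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

setMethod("show", "MetricsReport", function(object) {
  v <- metricsAsVector(object)
  cat("MetricsReport (top fraction ", object@topFraction, "):\n", sep = "")
  for (m in names(v)) cat(sprintf("  %-18s %.4f\n", m, v[m]))
})
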