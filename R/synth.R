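# Self-contained synthetic benchmark: an artificial ortholog database,
# genomes assembled from family-member genes, a lognormal community, and
# error-prone single-end reads with the matching mapping/annotation tables.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.BASES <- c("A", "C", "G", "T")

# codon table (sense codons only) as a padded matrix for vectorized
# uniform synonymous reverse translation
.codonTable <- local({
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  byAA <- split(names(sense), sense)
  n <- max(lengths(byAA))
  mat <- matrix(NA_character_, nrow = length(byAA), ncol = n,
                dimnames = list(names(byAA), NULL))
  for (a in names(byAA)) mat[a, seq_along(byAA[[a]])] <- byAA[[a]]
  list(mat = mat, n = lengths(byAA)[rownames(mat)])
})

#' Create a synthetic benchmark configuration
#'
#' Defaults describe the desk-scale benchmark used throughout the package:
#' 200 protein families of 64 members each at 15% within-family residue
#' divergence, 16 genomes of 200 genes drawn from the family pool with a
#' Zipf-like family frequency spectrum, lognormal genome abundances with
#' log-space mean 1 and standard deviation 2, and single-end reads with a
#' Gaussian fragment-length model (mean 270 nt, sd 27 nt).
#'
#' @param nFamilies,genesPerFamily database size (defaults 200, 64).
#' @param geneLenRange gene length range in nt (default 1200--2400;
#'   lengths are whole codons).
#' @param withinFamilyDivergence per-residue substitution probability
#'   between a member and the family ancestor (default 0.15; orthologous
#'   proteins routinely diverge this far and further).
#' @param nGenomes,genesPerGenome community size (defaults 16, 200).
#' @param intergenicLenRange spacer length range in nt (default 50--300).
#' @param abundanceLogMu,abundanceLogSigma lognormal parameters, as the
#'   mean and sd of the underlying normal in log space (defaults 1, 2).
#' @param totalBases approximate total sequenced bases (default 2e7).
#' @param fragmentMean,fragmentSd fragment length model in nt (defaults
#'   270, 27).
#' @param readLen read length in nt (default 100).
#' @param errorRate per-base substitution probability (default 0).
#' @param seed master seed for all generator stages.
#' @return A \linkS4class{SynthConfig}.
#' @examples
#' synthConfig(nFamilies = 5, genesPerFamily = 3, nGenomes = 2,
#'             genesPerGenome = 4, totalBases = 1e4)
#' @export
synthConfig <- function(nFamilies = 200L, genesPerFamily = 64L,
                        geneLenRange = c(1200L, 2400L),
                        withinFamilyDivergence = 0.15,
                        nGenomes = 16L, genesPerGenome = 200L,
                        intergenicLenRange = c(50L, 300L),
                        abundanceLogMu = 1, abundanceLogSigma = 2,
                        totalBases = 2e7, fragmentMean = 270,
                        fragmentSd = 27, readLen = 100L, errorRate = 0,
                        seed = 1L) {
  new("SynthConfig",
      nFamilies = as.integer(nFamilies),
      genesPerFamily = as.integer(genesPerFamily),
      geneLenRange = as.integer(geneLenRange),
      withinFamilyDivergence = as.numeric(withinFamilyDivergence),
      nGenomes = as.integer(nGenomes),
      genesPerGenome = as.integer(genesPerGenome),
      intergenicLenRange = as.integer(intergenicLenRange),
      abundanceLogMu = as.numeric(abundanceLogMu),
      abundanceLogSigma = as.numeric(abundanceLogSigma),
      totalBases = as.numeric(totalBases),
      fragmentMean = as.numeric(fragmentMean),
      fragmentSd = as.numeric(fragmentSd),
      readLen = as.integer(readLen),
      errorRate = as.numeric(errorRate),
      seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig: ", object@nFamilies, " families x ",
      object@genesPerFamily, " genes; ", object@nGenomes, " genomes x ",
      object@genesPerGenome, " genes; ",
      format(object@totalBases, big.mark = ","), " bases of ",
      object@readLen, " nt reads (error ", object@errorRate, "); seed ",
      object@seed, "\n", sep = "")
})

# each generator stage derives its own RNG stream from the master seed so
# stages are individually reproducible
.stageSeed <- function(cfg, stage) {
  set.seed((cfg@seed * 7L + stage) %% .Machine$integer.max)
}

# uniform substitution to one of the 19 other residues
.mutateProtein <- function(aas, p) {
  hit <- which(stats::runif(length(aas)) < p)
  if (length(hit)) {
    old <- match(aas[hit], .AA20)
    aas[hit] <- .AA20[(old + sample.int(19L, length(hit),
                                        replace = TRUE) - 1L) %% 20L + 1L]
  }
  aas
}

# uniform synonymous codon choice per residue
.reverseTranslate <- function(aas) {
  idx <- match(aas, rownames(.codonTable$mat))
  pick <- floor(stats::runif(length(aas)) * .codonTable$n[idx]) + 1L
  paste(.codonTable$mat[cbind(idx, pick)], collapse = "")
}

#' Generate the artificial protein-family database
#'
#' Each family is seeded by a random ancestral protein (uniform residues,
#' whole-codon length drawn from \code{geneLenRange}); members are copies
#' of the ancestor with i.i.d. substitutions at
#' \code{withinFamilyDivergence}, and each member is reverse-translated
#' into a nucleotide gene with uniform synonymous codon choice.
#'
#' @param cfg a \linkS4class{SynthConfig}.
#' @return list with \code{proteins} (\link[Biostrings]{AAStringSet}),
#'   \code{genes} (\link[Biostrings]{DNAStringSet}, same names), and
#'   \code{geneToGroup} (data.frame \code{gene_id}, \code{group_id}).
#'   Deterministic given \code{cfg@seed}.
#' @export
generateFamilies <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  .stageSeed(cfg, 1L)
  aaMin <- max(1L, cfg@geneLenRange[1] %/% 3L)
  aaMax <- max(aaMin, cfg@geneLenRange[2] %/% 3L)
  prot <- character(cfg@nFamilies * cfg@genesPerFamily)
  nt <- character(length(prot))
  gid <- character(length(prot))
  grp <- character(length(prot))
  r <- 0L
  for (f in seq_len(cfg@nFamilies)) {
    fam <- sprintf("OG%04d", f)
    aaLen <- if (aaMax > aaMin) aaMin + sample.int(aaMax - aaMin + 1L, 1L) - 1L
             else aaMin
    anc <- sample(.AA20, aaLen, replace = TRUE)
    for (j in seq_len(cfg@genesPerFamily)) {
      r <- r + 1L
      member <- .mutateProtein(anc, cfg@withinFamilyDivergence)
      prot[r] <- paste(member, collapse = "")
      nt[r] <- .reverseTranslate(member)
      gid[r] <- sprintf("%s_g%02d", fam, j)
      grp[r] <- fam
    }
  }
  proteins <- Biostrings::AAStringSet(prot)
  names(proteins) <- gid
  genes <- Biostrings::DNAStringSet(nt)
  names(genes) <- gid
  list(proteins = proteins, genes = genes,
       geneToGroup = data.frame(gene_id = gid, group_id = grp,
                                stringsAsFactors = FALSE))
}

#' Assemble genomes from family-member genes
#'
#' Each genome alternates random intergenic spacers with
#' \code{genesPerGenome} genes drawn from the family pool without
#' replacement (within that genome); gene coordinates are recorded 1-based
#' inclusive and verified by extraction.
#'
#' @param cfg a \linkS4class{SynthConfig}.
#' @param families output of \code{\link{generateFamilies}}.
#' @return list with \code{genomes} (\link[Biostrings]{DNAStringSet}) and
#'   \code{annotations} (data.frame \code{genome_id, gene_id, start, end,
#'   group_id}). Deterministic given \code{cfg@seed}.
#' @export
generateGenomes <- function(cfg, families) {
  stopifnot(is(cfg, "SynthConfig"))
  .stageSeed(cfg, 2L)
  pool <- names(families$genes)
  if (cfg@genesPerGenome > length(pool))
    stop("genesPerGenome (", cfg@genesPerGenome, ") exceeds the ",
         length(pool), " available genes")
  grpOf <- stats::setNames(families$geneToGroup$group_id,
                           families$geneToGroup$gene_id)
  geneStr <- as.character(families$genes)
  # family frequency spectrum: genes are drawn with weight proportional to
  # 1 / family rank (Zipf-like), so a few "housekeeping" families recur in
  # most genomes while high-rank families are rare -- mirroring the heavy
  # tail of ortholog-group frequencies in real communities
  famRank <- match(grpOf[pool], sort(unique(grpOf)))
  geneWeight <- 1 / famRank
  genomeSeq <- character(cfg@nGenomes)
  ann <- vector("list", cfg@nGenomes)
  for (i in seq_len(cfg@nGenomes)) {
    gm <- sprintf("G%02d", i)
    chosen <- sample(pool, cfg@genesPerGenome, prob = geneWeight)
    spLen <- sample(seq(cfg@intergenicLenRange[1], cfg@intergenicLenRange[2]),
                    cfg@genesPerGenome + 1L, replace = TRUE)
    spacers <- vapply(spLen, function(l)
      paste(sample(.BASES, l, replace = TRUE), collapse = ""), character(1))
    pieces <- character(2L * cfg@genesPerGenome + 1L)
    pieces[seq(1L, length(pieces), by = 2L)] <- spacers
    pieces[seq(2L, length(pieces), by = 2L)] <- geneStr[chosen]
    genomeSeq[i] <- paste(pieces, collapse = "")
    lens <- nchar(pieces)
    ends <- cumsum(lens)
    gidx <- seq(2L, length(pieces), by = 2L)
    ann[[i]] <- data.frame(
      genome_id = gm, gene_id = chosen,
      start = ends[gidx] - lens[gidx] + 1L, end = ends[gidx],
      group_id = unname(grpOf[chosen]), stringsAsFactors = FALSE)
  }
  genomes <- Biostrings::DNAStringSet(genomeSeq)
  names(genomes) <- sprintf("G%02d", seq_len(cfg@nGenomes))
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  # coordinate round-trip guard: [start, end] must return the gene exactly
  chk <- sample.int(nrow(annotations), min(nrow(annotations), 25L))
  for (j in chk) {
    a <- annotations[j, ]
    stopifnot(identical(substr(genomeSeq[match(a$genome_id, names(genomes))],
                               a$start, a$end),
                        geneStr[[a$gene_id]]))
  }
  list(genomes = genomes, annotations = annotations)
}

#' Draw lognormal community abundances
#'
#' One lognormal draw per genome (parameters are the mean and sd of the
#' underlying normal in log space), normalized to sum to 1.
#'
#' @param cfg a \linkS4class{SynthConfig}.
#' @param genomeIds character vector of genome names.
#' @return named numeric vector summing to 1. With
#'   \code{abundanceLogSigma = 0} all genomes are equally abundant.
#' @export
sampleAbundances <- function(cfg, genomeIds) {
  stopifnot(is(cfg, "SynthConfig"))
  .stageSeed(cfg, 3L)
  x <- stats::rlnorm(length(genomeIds), meanlog = cfg@abundanceLogMu,
                     sdlog = cfg@abundanceLogSigma)
  stats::setNames(x / sum(x), genomeIds)
}

# substitute bases at i.i.d. error positions (always to a different base)
.addReadErrors <- function(reads, errorRate) {
  if (errorRate <= 0) return(reads)
  nerr <- stats::rbinom(length(reads), nchar(reads), errorRate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(length(chars), nerr[i])
    old <- match(chars[pos], .BASES)
    old[is.na(old)] <- sample.int(4L, sum(is.na(old)), replace = TRUE)
    chars[pos] <- .BASES[(old + sample.int(3L, length(pos),
                                           replace = TRUE) - 1L) %% 4L + 1L]
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate single-end reads with known mappings
#'
#' Reads are assigned to genomes proportionally to abundance times genome
#' length; each read comes from a fragment of Gaussian length (truncated
#' to at least \code{readLen} and the genome bounds) starting at a uniform
#' position, takes the first \code{readLen} bases of the fragment on a
#' uniformly chosen strand, and accumulates i.i.d. substitution errors at
#' \code{errorRate}. The mapping table records each read's true 1-based
#' span on the forward strand.
#'
#' @param cfg a \linkS4class{SynthConfig}.
#' @param genomes \link[Biostrings]{DNAStringSet} of genome sequences.
#' @param abund named abundance vector over the genomes (summing to 1).
#' @return list with \code{reads} (character vector of read sequences),
#'   \code{readIds}, and \code{mappings} (data.frame \code{read_id,
#'   genome_id, start, end}). Genomes shorter than \code{readLen} are
#'   skipped with a warning. Deterministic given \code{cfg@seed}.
#' @export
simulateReads <- function(cfg, genomes, abund) {
  stopifnot(is(cfg, "SynthConfig"))
  .stageSeed(cfg, 4L)
  glen <- stats::setNames(Biostrings::width(genomes), names(genomes))
  usable <- names(glen)[glen >= cfg@readLen]
  if (length(usable) < length(glen))
    warning(length(glen) - length(usable),
            " genome(s) shorter than readLen were skipped")
  if (!length(usable)) stop("no genome is long enough to sequence")
  ab <- abund[usable]
  w <- ab * glen[usable]
  nReads <- as.integer(ceiling(cfg@totalBases / cfg@readLen))
  gm <- sample(usable, nReads, replace = TRUE, prob = w / sum(w))
  gm <- gm[order(match(gm, usable))]   # group reads per genome
  L <- glen[gm]
  fragLen <- pmin(pmax(round(stats::rnorm(nReads, cfg@fragmentMean,
                                          cfg@fragmentSd)),
                       cfg@readLen), L)
  fragStart <- 1L + floor(stats::runif(nReads) * (L - fragLen + 1))
  minus <- stats::runif(nReads) < 0.5
  start <- ifelse(minus, fragStart + fragLen - cfg@readLen, fragStart)
  end <- start + cfg@readLen - 1L
  genomeStr <- stats::setNames(as.character(genomes), names(genomes))
  reads <- substring(genomeStr[gm], start, end)
  if (any(minus))
    reads[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[minus])))
  reads <- .addReadErrors(reads, cfg@errorRate)
  ids <- sprintf("read_%07d", seq_len(nReads))
  list(reads = unname(reads), readIds = ids,
       mappings = data.frame(read_id = ids, genome_id = unname(gm),
                             start = as.integer(start),
                             end = as.integer(end),
                             stringsAsFactors = FALSE))
}

# generator-side truth accounting: naive per-gene sum of read/gene interval
# intersections (an independent route from eval's IRanges-based
# coveredNucleotides, compared exactly in the tests)
.naiveGeneCoverage <- function(mappings, annotations) {
  cov <- stats::setNames(numeric(length(unique(annotations$gene_id))),
                         unique(annotations$gene_id))
  for (gm in unique(annotations$genome_id)) {
    a <- annotations[annotations$genome_id == gm, , drop = FALSE]
    m <- mappings[mappings$genome_id == gm, , drop = FALSE]
    if (!nrow(m)) next
    for (j in seq_len(nrow(a))) {
      ov <- pmin(m$end, a$end[j]) - pmax(m$start, a$start[j]) + 1L
      cov[a$gene_id[j]] <- cov[a$gene_id[j]] + sum(ov[ov > 0])
    }
  }
  cov
}

#' Generate a complete benchmark bundle
#'
#' Runs all generator stages and writes every file the profiler and the
#' evaluator need: \code{reference.faa} (family protein sequences),
#' \code{gene2group.tsv}, \code{genomes.fna}, \code{genes.tsv} (gene
#' coordinates and groups), \code{reads.fq}, \code{mappings.tsv},
#' \code{truth.tsv} (per-group covered nucleotides and relative
#' abundances, from the generator's own accounting), and
#' \code{manifest.json} (the full configuration). Re-running with the same
#' configuration reproduces every file byte-identically.
#'
#' @param cfg a \linkS4class{SynthConfig}.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the written \code{paths}, the \code{cfg},
#'   the in-memory stage outputs (\code{families}, \code{genomes},
#'   \code{abundances}, \code{reads}), the per-gene coverage
#'   (\code{geneCov}) and the \code{truth} (\linkS4class{GroundTruth}).
#' @export
makeBenchmark <- function(cfg, outdir) {
  stopifnot(is(cfg, "SynthConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fam <- generateFamilies(cfg)
  gen <- generateGenomes(cfg, fam)
  ab <- sampleAbundances(cfg, names(gen$genomes))
  rd <- simulateReads(cfg, gen$genomes, ab)
  geneCov <- .naiveGeneCoverage(rd$mappings, gen$annotations)
  truth <- buildGroundTruth(geneCov, fam$geneToGroup)

  paths <- list(
    reference = file.path(outdir, "reference.faa"),
    geneToGroup = file.path(outdir, "gene2group.tsv"),
    genomes = file.path(outdir, "genomes.fna"),
    genes = file.path(outdir, "genes.tsv"),
    reads = file.path(outdir, "reads.fq"),
    mappings = file.path(outdir, "mappings.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    manifest = file.path(outdir, "manifest.json"))

  Biostrings::writeXStringSet(fam$proteins, paths$reference)
  utils::write.table(fam$geneToGroup, paths$geneToGroup, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  Biostrings::writeXStringSet(gen$genomes, paths$genomes)
  utils::write.table(gen$annotations, paths$genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  qual <- strrep("I", cfg@readLen)
  fq <- character(4L * length(rd$reads))
  fq[seq(1L, length(fq), by = 4L)] <- paste0("@", rd$readIds)
  fq[seq(2L, length(fq), by = 4L)] <- rd$reads
  fq[seq(3L, length(fq), by = 4L)] <- "+"
  fq[seq(4L, length(fq), by = 4L)] <- qual
  writeLines(fq, paths$reads)
  utils::write.table(rd$mappings, paths$mappings, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truthTab <- data.frame(group_id = groupIds(truth),
                         covered_nt = sprintf("%.0f", coveredNt(truth)),
                         relative_abundance = sprintf("%.10g",
                                                      abundances(truth)),
                         stringsAsFactors = FALSE)
  utils::write.table(truthTab, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    generator = "orthosketch-synth", version = 1L,
    config = list(
      n_families = cfg@nFamilies, genes_per_family = cfg@genesPerFamily,
      gene_len_range = cfg@geneLenRange,
      within_family_divergence = cfg@withinFamilyDivergence,
      n_genomes = cfg@nGenomes, genes_per_genome = cfg@genesPerGenome,
      intergenic_len_range = cfg@intergenicLenRange,
      abundance_lognormal_mu = cfg@abundanceLogMu,
      abundance_lognormal_sigma = cfg@abundanceLogSigma,
      total_bases = cfg@totalBases, fragment_mean = cfg@fragmentMean,
      fragment_sd = cfg@fragmentSd, read_len = cfg@readLen,
      error_rate = cfg@errorRate, seed = cfg@seed),
    n_reads = length(rd$reads), n_truth_groups = length(groupIds(truth)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             paths$manifest)

  invisible(list(paths = paths, cfg = cfg, families = fam, genomes = gen,
                 abundances = ab, reads = rd, geneCov = geneCov,
                 truth = truth))
}

#' Load a ground-truth table written by \code{\link{makeBenchmark}}
#'
#' @param path path to \code{truth.tsv}.
#' @return A \linkS4class{GroundTruth}.
#' @export
loadGroundTruth <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  cov <- stats::setNames(as.numeric(tab$covered_nt), tab$group_id)
  new("GroundTruth", abundances = cov / sum(cov), coveredNt = cov)
}
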