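# Shared fixtures and independent oracles used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# numeric comparison of decimal uint64 strings (no leading zeros)
u64LessEq <- function(a, b) {
  na <- nchar(a)
  nb <- nchar(b)
  ifelse(na != nb, na < nb, a <= b)
}

u64Order <- function(x) order(nchar(x), x)

# n distinct random amino-acid k-mers (sliding windows over long random
# strings; fast enough for 10^6-scale fixtures)
randKmers <- function(n, k) {
  out <- character(0)
  while (length(out) < n) {
    m <- n - length(out) + 100L
    s <- paste(sample(AA20, m + k - 1L, replace = TRUE), collapse = "")
    out <- unique(c(out, substring(s, seq_len(m), seq_len(m) + k - 1L)))
  }
  out[seq_len(n)]
}

randRead <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# brute-force FracMinHash oracle: hash every k-mer, filter at the scaled
# threshold, aggregate multiplicities, sort numerically ascending
bruteSketch <- function(kmers, scaled, seed = 42L) {
  hs <- hashKmer(kmers, seed)
  keep <- u64LessEq(hs, scaledThreshold(scaled))
  hs <- hs[keep]
  if (!length(hs))
    return(list(hashes = character(0), abundance = numeric(0)))
  tab <- table(hs)
  ord <- u64Order(names(tab))
  list(hashes = names(tab)[ord], abundance = as.numeric(tab)[ord])
}

# naive per-codon six-frame translator (independent of Biostrings translate)
naiveSixFrames <- function(read) {
  code <- as.list(Biostrings::GENETIC_CODE)
  revcomp <- function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  read <- gsub("[^ACGT]", "N", toupper(read))
  frames <- character(0)
  for (s in c(read, revcomp(read))) {
    for (off in 0:2) {
      chars <- strsplit(substr(s, off + 1L, nchar(s)), "")[[1]]
      ncod <- length(chars) %/% 3L
      if (ncod < 1L) next
      aa <- vapply(seq_len(ncod), function(i) {
        cod <- paste(chars[(3 * i - 2):(3 * i)], collapse = "")
        if (grepl("N", cod)) "X" else code[[cod]]
      }, character(1))
      frames <- c(frames, paste(aa, collapse = ""))
    }
  }
  frags <- unlist(strsplit(frames, "*", fixed = TRUE), use.names = FALSE)
  frags[nzchar(frags)]
}

# small protein FASTA on disk; returns the path
writeFasta <- function(seqs, path = tempfile(fileext = ".faa")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

smallSynthConfig <- function(seed = 11L, ...) {
  args <- list(nFamilies = 8L, genesPerFamily = 4L,
               geneLenRange = c(150L, 300L), nGenomes = 3L,
               genesPerGenome = 10L, totalBases = 3e4, readLen = 60L,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthConfig, args)
}
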