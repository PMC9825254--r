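# shared in-code fixtures

# small HaplotypeMatrix from a plain integer matrix
hm <- function(m, pos = seq_len(ncol(m)), class = "autosome", ids = NULL) {
  HaplotypeMatrix(m, pos, chromClass = class, sampleIds = ids)
}

# write a minimal phased VCF with the given GT token matrix (sites x samples)
writeToyVcf <- function(path, pos, gts, ref = "A", alt = "T",
                        chrom = "2R", samples = NULL) {
  ns <- ncol(gts)
  if (is.null(samples)) samples <- paste0("S", seq_len(ns))
  ref <- rep_len(ref, length(pos))
  alt <- rep_len(alt, length(pos))
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom, pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  path
}

# symmetric IBD matrix from an id vector and a list of (i, j, value) triples
ibdMatrix <- function(ids, pairs = list(), base = 0.01) {
  n <- length(ids)
  m <- matrix(base, n, n, dimnames = list(ids, ids))
  for (p in pairs) {
    m[p[[1]], p[[2]]] <- p[[3]]
    m[p[[2]], p[[1]]] <- p[[3]]
  }
  diag(m) <- 1
  m
}

# brute-force homozygosity oracle: expand a spectrum of class counts into
# labelled haplotypes and count matching ordered pairs drawn with replacement
bruteForceHStats <- function(counts) {
  n <- sum(counts)
  labels <- rep(seq_along(counts), counts)
  match1 <- outer(labels, labels, "==")
  h1 <- sum(match1) / n^2
  ord <- order(counts, decreasing = TRUE)
  # H12: merge the two most frequent classes into one label
  lab12 <- labels
  if (length(counts) > 1) lab12[labels == ord[2]] <- ord[1]
  h12 <- sum(outer(lab12, lab12, "==")) / n^2
  p1 <- max(counts) / n
  h2 <- h1 - p1^2
  list(h1 = h1, h2 = h2, h12 = h12, h2h1 = if (h1 > 0) h2 / h1 else 0)
}

# random spectrum of class counts for n haplotypes
randomSpectrumCounts <- function(n = 50, maxClasses = 12) {
  k <- sample.int(maxClasses, 1)
  as.numeric(table(sample.int(k, n, replace = TRUE)))
}
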