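#' Read phased haplotypes from a VCF file
#'
#' Reads a VCF 4.x file with phased diploid GT fields and emits two
#' haplotypes per sample, in sample order with the left allele of each GT
#' first.  Only biallelic SNP records are used; other records are skipped
#' and counted in a message.  Missing ("./.") and half-calls ("1|.") become
#' \code{NA} at the affected haplotype.
#'
#' @param path VCF file (plain or bgzipped)
#' @param chromClass "autosome" or "X"
#' @param forcePhase treat "/"-separated genotypes as phased instead of
#'   raising an error
#' @return a \code{\link{HaplotypeMatrix}}
#' @export
readPhasedVcf <- function(path, chromClass = c("autosome", "X"),
                          forcePhase = FALSE) {
  chromClass <- match.arg(chromClass)
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  nskip <- sum(!snp)
  if (nskip > 0) message(nskip, " non-biallelic-SNP record(s) skipped")
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  pos <- as.numeric(fix[snp, "POS"])
  chrom <- fix[snp, "CHROM"][1]
  samples <- colnames(gt)

  if (any(grepl("/", gt, fixed = TRUE), na.rm = TRUE) && !forcePhase) {
    stop("unphased genotypes present; set forcePhase = TRUE to read anyway")
  }
  parseAllele <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out[!a %in% c("0", "1")] <- NA_integer_
    out
  }
  m <- length(pos)
  n <- 2L * length(samples)
  hap <- matrix(NA_integer_, nrow = n, ncol = m)
  for (j in seq_along(samples)) {
    g <- gt[, j]
    g[is.na(g)] <- ".|."
    tok <- strsplit(gsub("/", "|", g, fixed = TRUE), "|", fixed = TRUE)
    a1 <- parseAllele(vapply(tok, function(t) if (length(t) >= 1) t[1] else ".", ""))
    a2 <- parseAllele(vapply(tok, function(t) if (length(t) >= 2) t[2] else ".", ""))
    hap[2L * j - 1L, ] <- a1
    hap[2L * j, ] <- a2
  }
  keep <- colSums(!is.na(hap)) > 0
  if (!all(keep)) {
    hap <- hap[, keep, drop = FALSE]
    pos <- pos[keep]
  }
  if (ncol(hap) == 0) stop("no callable biallelic SNPs in ", path)
  HaplotypeMatrix(hap, pos,
    chromLabel = chrom, chromClass = chromClass,
    sampleIds = paste0(rep(samples, each = 2), c("_1", "_2"))
  )
}

#' Write a HaplotypeMatrix as a phased VCF
#'
#' Haplotypes are paired in order (1,2), (3,4), ... into diploid samples
#' with "|"-phased GT fields; \code{NA} becomes ".".  Alleles are written as
#' A (REF) / T (ALT).  Round-trips with \code{\link{readPhasedVcf}}.
#'
#' @param x a HaplotypeMatrix with an even number of haplotypes
#' @param path output file
#' @export
writePhasedVcf <- function(x, path) {
  h <- x@haplotypes
  if (nrow(h) %% 2 != 0) stop("need an even number of haplotypes to pair into diploids")
  ns <- nrow(h) / 2
  sm <- sub("_1$", "", x@sampleIds[seq(1, nrow(h), by = 2)])
  if (anyDuplicated(sm)) sm <- paste0("S", seq_len(ns))
  tok <- matrix("", nrow = ns, ncol = ncol(h))
  for (i in seq_len(ns)) {
    a1 <- as.character(h[2 * i - 1, ])
    a2 <- as.character(h[2 * i, ])
    a1[is.na(a1)] <- "."
    a2[is.na(a2)] <- "."
    tok[i, ] <- paste0(a1, "|", a2)
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", x@chromLabel),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sm), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(h)), function(j) {
    paste(c(x@chromLabel, format(x@positions[j], scientific = FALSE), ".",
            "A", "T", ".", "PASS", ".", "GT", tok[, j]), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Remove strains with high identity-by-descent
#'
#' Removes every sample whose maximum pairwise genome-wide IBD fraction with
#' any other sample exceeds \code{threshold}.  Removal is simultaneous,
#' computed on the original table, not iterative.
#'
#' @param ibd symmetric numeric matrix of pairwise IBD fractions in [0,1],
#'   with sample ids as dimnames; the diagonal is ignored
#' @param threshold remove samples with max pairwise IBD above this (default
#'   0.20)
#' @return character vector of retained sample ids
#' @export
ibdFilter <- function(ibd, threshold = 0.20) {
  if (!is.matrix(ibd) || nrow(ibd) == 0) stop("empty IBD table")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  ids <- rownames(ibd)
  if (is.null(ids)) stop("IBD table must carry sample ids as dimnames")
  d <- ibd
  diag(d) <- -Inf
  keep <- apply(d, 1, max) <= threshold
  ids[keep]
}

#' Drop sites with low call rate
#'
#' Removes every site called (non-missing) in fewer than
#' \code{minCallFraction} of the haplotypes.
#'
#' @param x a HaplotypeMatrix
#' @param minCallFraction minimum non-missing fraction per site (default 0.5)
#' @return the filtered HaplotypeMatrix
#' @export
siteCallFilter <- function(x, minCallFraction = 0.5) {
  if (minCallFraction <= 0 || minCallFraction > 1)
    stop("minCallFraction must be in (0, 1]")
  h <- x@haplotypes
  frac <- colMeans(!is.na(h))
  keep <- frac >= minCallFraction
  if (!any(keep)) stop("all sites removed by the call-rate filter")
  subsetHaplotypeMatrix(x, cols = which(keep))
}

#' Down-sample to the most complete diploid samples
#'
#' Keeps the k diploid samples (consecutive haplotype pairs) with the
#' smallest missing-data fraction; ties are broken by lexicographic sample
#' id.
#'
#' @param x a HaplotypeMatrix whose haplotypes pair into diploids
#' @param k number of diploid samples to keep
#' @return the subset HaplotypeMatrix (2k haplotypes)
#' @export
topCompleteSubsample <- function(x, k) {
  h <- x@haplotypes
  if (nrow(h) %% 2 != 0) stop("haplotypes must pair into diploid samples")
  ns <- nrow(h) / 2
  if (k > ns) stop("k exceeds the number of available samples")
  sid <- sub("_[12]$", "", x@sampleIds[seq(1, nrow(h), by = 2)])
  miss <- vapply(seq_len(ns), function(i) {
    mean(is.na(h[c(2 * i - 1, 2 * i), ]))
  }, 0.0)
  ord <- order(miss, sid)
  pick <- sort(ord[seq_len(k)])
  rows <- as.vector(rbind(2 * pick - 1, 2 * pick))
  subsetHaplotypeMatrix(x, rows = rows)
}

#' Read / write a recombination map
#'
#' Four-column tab-separated text (chrom, start, end, rate), BED-like
#' half-open coordinates, rate in cM/bp.
#'
#' @param path file path
#' @return a \code{\link{RecombinationMap}}
#' @export
readRecombinationMap <- function(path) {
  d <- utils::read.table(path,
    header = FALSE, sep = "\t",
    col.names = c("chrom", "start", "end", "rate"),
    colClasses = c("character", "numeric", "numeric", "numeric")
  )
  RecombinationMap(d$chrom, d$start, d$end, d$rate)
}

#' @rdname readRecombinationMap
#' @param x a RecombinationMap
#' @export
writeRecombinationMap <- function(x, path) {
  iv <- x@intervals
  utils::write.table(iv, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Strains excluded from the DGRP/DPGP3 panels by the IBD filter
#'
#' The published lists of inbred strains whose genome-wide IBD with at least
#' one other strain exceeds 20\%: 27 Raleigh (RAL) strains of the 205-strain
#' DGRP panel and 8 Zambia (ZI) strains of the 197-strain DPGP3 panel.
#' Removing them leaves 178 RAL and 189 ZI strains.
#'
#' @return list with character vectors \code{ral} and \code{zi}
#' @export
dgrpExcludedStrains <- function() {
  list(
    ral = c(
      "RAL-385", "RAL-358", "RAL-712", "RAL-399", "RAL-879", "RAL-355",
      "RAL-810", "RAL-350", "RAL-832", "RAL-882", "RAL-306", "RAL-799",
      "RAL-801", "RAL-859", "RAL-907", "RAL-790", "RAL-748", "RAL-336",
      "RAL-850", "RAL-365", "RAL-786", "RAL-730", "RAL-861", "RAL-59",
      "RAL-646", "RAL-812", "RAL-787"
    ),
    zi = c(
      "ZI397N", "ZI530", "ZI269", "ZI240", "ZI218", "ZI207", "ZI523", "ZI86"
    )
  )
}
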