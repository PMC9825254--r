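# round half up (R's round() is banker's rounding); the epsilon guards
# binary-representation error at exact halves (e.g. 0.01*401/0.02)
roundHalfUp <- function(x) floor(x + 0.5 + 1e-9)

# subset a HaplotypeMatrix by haplotype rows and/or site columns
subsetHaplotypeMatrix <- function(x, rows = NULL, cols = NULL) {
  h <- x@haplotypes
  ids <- x@sampleIds
  p <- x@positions
  if (!is.null(rows)) {
    h <- h[rows, , drop = FALSE]
    ids <- ids[rows]
  }
  if (!is.null(cols)) {
    h <- h[, cols, drop = FALSE]
    p <- p[cols]
  }
  new("HaplotypeMatrix",
    haplotypes = h, positions = p, chromLabel = x@chromLabel,
    chromClass = x@chromClass, sampleIds = ids
  )
}
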