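`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical unordered-edge key; protein IDs are TSV fields so they can never
# contain a tab, making "\t" a collision-free separator
edgeKeys <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "\t")
}

# sample() on a length-1 character vector is safe (no 1:n surprise), but keep
# one choke point for set sampling anyway
sampleSet <- function(x, size) {
  if (size <= 0L) return(character(0))
  x[sample.int(length(x), size)]
}
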