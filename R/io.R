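# Shared file dialect: UTF-8, tab-separated, '#' starts a comment line.
# Protein IDs are opaque case-sensitive strings; no ID mapping is attempted.

readDataLines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a protein interaction network from a tab-separated edge list
#'
#' Each non-comment line holds two tab-separated protein IDs. Self-loops and
#' repeated interactions (in either orientation) are removed, mirroring the
#' standard cleanup applied to interaction databases; the counts of dropped
#' records are reported via [message()].
#'
#' @param path path to the edge-list file.
#' @return A [ProteinNetwork-class].
#' @export
readNetwork <- function(path) {
  dl <- readDataLines(path)
  if (length(dl$lines) == 0L) stop("no edges in ", path)
  parts <- strsplit(dl$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("malformed network line ", dl$lineno[bad[1L]], " in ", path)
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  nSelf <- sum(a == b)
  lo <- pmin(a, b)[a != b]
  hi <- pmax(a, b)[a != b]
  nDup <- sum(duplicated(edgeKeys(lo, hi)))
  net <- proteinNetwork(cbind(a, b))
  if (numEdges(net) == 0L) stop("no valid edges in ", path)
  message(
    "readNetwork: ", numProteins(net), " proteins, ", numEdges(net),
    " interactions (dropped ", nSelf, " self-loops, ", nDup, " duplicates)"
  )
  net
}

#' Write a network as a canonical tab-separated edge list
#'
#' @param net a [ProteinNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path) {
  em <- net@edges
  writeLines(paste(em[, 1L], em[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Read a gene-expression matrix
#'
#' Expects a header row of time-point labels followed by one row per protein:
#' the protein ID and T numeric expression values. Rows containing
#' non-numeric cells are dropped with a message; inconsistent row lengths or
#' duplicated protein IDs are hard errors.
#'
#' @param path path to the tab-separated matrix.
#' @return numeric matrix with protein IDs as row names and one column per
#'   time point (T >= 2).
#' @export
readExpression <- function(path) {
  dl <- readDataLines(path)
  if (length(dl$lines) < 2L) stop("empty expression data section in ", path)
  header <- strsplit(dl$lines[1L], "\t", fixed = TRUE)[[1L]]
  rows <- strsplit(dl$lines[-1L], "\t", fixed = TRUE)
  width <- lengths(rows)
  if (length(unique(width)) != 1L) {
    stop("inconsistent expression row length at line ",
         dl$lineno[-1L][which(width != width[1L])[1L]])
  }
  tp <- width[1L] - 1L
  if (tp < 2L) stop("expression matrix needs at least 2 time points")
  labels <- if (length(header) == tp + 1L) header[-1L] else header
  if (length(labels) != tp) {
    stop("header has ", length(labels), " labels for ", tp, " time points")
  }
  ids <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate protein ID in expression matrix: ",
         ids[duplicated(ids)][1L])
  }
  vals <- suppressWarnings(
    t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(tp)))
  )
  bad <- apply(is.na(vals), 1L, any)
  if (any(bad)) {
    message("readExpression: dropped ", sum(bad), " non-numeric rows")
  }
  if (all(bad)) stop("empty expression data section in ", path)
  mat <- vals[!bad, , drop = FALSE]
  dimnames(mat) <- list(ids[!bad], labels)
  mat
}

#' @rdname readExpression
#' @param mat numeric matrix with protein row names.
#' @export
writeExpression <- function(mat, path) {
  header <- paste(c("protein", colnames(mat)), collapse = "\t")
  body <- paste(
    rownames(mat),
    apply(mat, 1L, function(r) paste(format(r, digits = 15), collapse = "\t")),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read subcellular localization records
#'
#' Two tab-separated columns: protein ID and location label. Repeated
#' protein-location pairs are collapsed; a protein may carry several
#' locations.
#'
#' @param path path to the record file.
#' @return data frame with character columns `protein` and `location`.
#' @export
readSubcellular <- function(path) {
  dl <- readDataLines(path)
  if (length(dl$lines) == 0L) stop("no subcellular records in ", path)
  parts <- strsplit(dl$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("malformed subcellular line ", dl$lineno[bad[1L]], " in ", path)
  }
  rec <- data.frame(
    protein = vapply(parts, `[[`, "", 1L),
    location = vapply(parts, `[[`, "", 2L),
    stringsAsFactors = FALSE
  )
  rec[!duplicated(rec), , drop = FALSE]
}

#' @rdname readSubcellular
#' @param records data frame with `protein` and `location` columns.
#' @export
writeSubcellular <- function(records, path) {
  writeLines(paste(records$protein, records$location, sep = "\t"), path)
  invisible(path)
}

#' Read a protein-complex catalog
#'
#' One complex per line, tab-separated member IDs. Member duplicates within a
#' line and complexes with identical member sets are removed (the same rule
#' used when merging published complex collections).
#'
#' @param path path to the catalog file.
#' @return list of character vectors, one per distinct complex.
#' @export
readComplexes <- function(path) {
  dl <- readDataLines(path)
  if (length(dl$lines) == 0L) stop("no complexes in ", path)
  cx <- lapply(strsplit(dl$lines, "\t", fixed = TRUE), unique)
  if (any(vapply(cx, function(m) any(!nzchar(m)), TRUE))) {
    stop("empty member ID in complex file ", path)
  }
  keySet <- vapply(cx, function(m) paste(sort(m), collapse = "\t"), "")
  cx[!duplicated(keySet)]
}

#' @rdname readComplexes
#' @param complexes list of character vectors.
#' @export
writeComplexes <- function(complexes, path) {
  writeLines(vapply(complexes, paste, "", collapse = "\t"), path)
  invisible(path)
}

#' Read / write a known-essential-protein list (one ID per line)
#'
#' @param path path to the list file.
#' @return character vector of unique protein IDs.
#' @export
readEssential <- function(path) {
  dl <- readDataLines(path)
  ids <- unique(trimws(dl$lines))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L) stop("no essential proteins in ", path)
  ids
}

#' @rdname readEssential
#' @param ids character vector of protein IDs.
#' @export
writeEssential <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Read / write a ranked-protein table
#'
#' Tab-separated with a header and columns `rank`, `protein`, `score`.
#'
#' @param path path to the ranking file.
#' @return data frame with columns `rank`, `protein`, `score`.
#' @export
readRanking <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("rank", "protein", "score") %in% names(df))) {
    stop("ranking file needs columns rank, protein, score: ", path)
  }
  df[order(df$rank), c("rank", "protein", "score")]
}

#' @rdname readRanking
#' @param ranking data frame with columns `rank`, `protein`, `score`.
#' @export
writeRanking <- function(ranking, path) {
  utils::write.table(
    ranking, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
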