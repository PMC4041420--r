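## tRNA gene tables and the organisms x species presence/absence matrix.

#' PresenceMatrix: binary organisms x tRNA-species matrix
#'
#' The central object of the pipeline: a binary matrix with one row per
#' organism and one column per tRNA species (anticodon), where 1 means the
#' genome carries at least one gene copy of the species.
#'
#' @slot presence integer matrix with values in {0,1}; rownames are organism
#'   ids, colnames are anticodons.
#' @export
setClass("PresenceMatrix", representation(presence = "matrix"))

setValidity("PresenceMatrix", function(object) {
  m <- object@presence
  msg <- character(0)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "presence matrix must have organism and species names")
  if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicated organism ids")
  if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicated species ids")
  if (!all(m %in% c(0L, 1L))) msg <- c(msg, "values must be 0/1")
  if (length(msg)) msg else TRUE
})

#' @describeIn PresenceMatrix construct from a binary matrix
#' @param presence binary matrix, organisms in rows, species in columns.
#' @export
PresenceMatrix <- function(presence) {
  storage.mode(presence) <- "integer"
  methods::new("PresenceMatrix", presence = presence)
}

#' @export
setGeneric("organisms", function(x) standardGeneric("organisms"))

#' @describeIn PresenceMatrix organism ids (row labels)
#' @param x a PresenceMatrix.
#' @export
setMethod("organisms", "PresenceMatrix", function(x) rownames(x@presence))

#' @export
setGeneric("trnaSpecies", function(x) standardGeneric("trnaSpecies"))

#' @describeIn PresenceMatrix tRNA species (column labels)
#' @export
setMethod("trnaSpecies", "PresenceMatrix", function(x) colnames(x@presence))

#' @describeIn PresenceMatrix underlying binary matrix
#' @export
setMethod("as.matrix", "PresenceMatrix", function(x) x@presence)

#' @describeIn PresenceMatrix subset organisms (i) and/or species (j)
#' @param i,j,drop row/column indices (drop is ignored).
#' @export
setMethod("[", "PresenceMatrix", function(x, i, j, ..., drop = FALSE) {
  PresenceMatrix(x@presence[i, j, drop = FALSE])
})

setMethod("show", "PresenceMatrix", function(object) {
  m <- object@presence
  cat("PresenceMatrix:", nrow(m), "organisms x", ncol(m), "tRNA species\n")
  cat("  species:", paste(utils::head(colnames(m), 8), collapse = " "),
      if (ncol(m) > 8) "...\n" else "\n")
  cat("  occupancy:", round(mean(m), 3), "\n")
})

#' @describeIn PresenceMatrix dimensions
#' @export
setMethod("dim", "PresenceMatrix", function(x) dim(x@presence))

.is_trnascan_header <- function(lines) {
  any(grepl("tRNA\\s*#", lines)) || grepl("^Sequence", lines[1])
}

#' Parse a tRNA gene table
#'
#' Reads either tRNAscan-SE tabular output (header lines skipped; columns:
#' sequence name, tRNA number, begin, end, type, anticodon, intron bounds,
#' score, and an optional note column whose "pseudo" flag is honoured) or a
#' simple TSV with a header containing at least \code{organism_id} and
#' \code{anticodon}, optionally \code{gene_id}, \code{sequence} and
#' \code{pseudo}.
#'
#' Rows flagged pseudo, with undetermined anticodons (containing N), or
#' annotated as selenocysteine are dropped. Anticodons are normalized to the
#' RNA alphabet; rows whose anticodon reverse-complements to a stop codon
#' are dropped with a warning.
#'
#' @param path path to the table.
#' @return data.frame with columns \code{organism}, \code{geneId},
#'   \code{anticodon}, \code{sequence} (NA when absent).
#' @export
parseTrnaTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty tRNA table: ", path)
  if (.is_trnascan_header(lines)) {
    out <- .parse_trnascan(lines)
  } else {
    out <- .parse_simple_tsv(lines)
  }
  .clean_gene_rows(out)
}

.parse_trnascan <- function(lines) {
  ## header block: first lines up to the "----" ruler (or the two title rows)
  body <- grep("^-+\\s", lines)
  start <- if (length(body)) body[1] + 1L else 3L
  rows <- lines[start:length(lines)]
  fields <- strsplit(rows, "\t")
  parsed <- lapply(seq_along(fields), function(i) {
    f <- trimws(fields[[i]])
    if (length(f) < 6)
      stop("malformed tRNAscan-SE row at line ", start + i - 1L,
           ": expected >= 6 tab-separated fields")
    note <- if (length(f) >= 10) f[10] else if (length(f) >= 9) f[9] else ""
    data.frame(organism = f[1],
               geneId = paste0(f[1], ".trna", f[2]),
               type = f[5],
               anticodon = f[6],
               sequence = NA_character_,
               pseudo = grepl("pseudo", note, ignore.case = TRUE) ||
                 grepl("pseudo", f[5], ignore.case = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parsed)
}

.parse_simple_tsv <- function(lines) {
  header <- strsplit(lines[1], "\t")[[1]]
  need <- c("organism_id", "anticodon")
  if (!all(need %in% header))
    stop("simple TSV must have header columns organism_id and anticodon")
  fields <- strsplit(lines[-1], "\t")
  n <- length(header)
  parsed <- lapply(seq_along(fields), function(i) {
    f <- trimws(fields[[i]])
    if (length(f) < length(need))
      stop("malformed row at line ", i + 1L)
    length(f) <- n
    stats::setNames(as.list(f), header)
  })
  df <- do.call(rbind, lapply(parsed, function(p)
    as.data.frame(p, stringsAsFactors = FALSE)))
  data.frame(
    organism = df$organism_id,
    geneId = if ("gene_id" %in% header) df$gene_id else
      paste0(df$organism_id, ".trna", seq_len(nrow(df))),
    type = NA_character_,
    anticodon = df$anticodon,
    sequence = if ("sequence" %in% header) df$sequence else NA_character_,
    pseudo = if ("pseudo" %in% header)
      grepl("pseudo|true|1|yes", df$pseudo, ignore.case = TRUE) else FALSE,
    stringsAsFactors = FALSE
  )
}

.clean_gene_rows <- function(df) {
  drop <- df$pseudo
  drop <- drop | grepl("N", toupper(df$anticodon))
  drop <- drop | grepl("^sec$|selenocysteine|^sec\\b", df$type,
                       ignore.case = TRUE)
  df <- df[!drop, , drop = FALSE]
  ac <- rnaNormalize(df$anticodon)
  sup <- .revcomp(ac) %in% .stop_codons
  if (any(sup)) {
    warning(sum(sup), " gene(s) with suppressor anticodon (",
            paste(unique(ac[sup]), collapse = ", "),
            ") dropped: reverse complement is a stop codon")
    df <- df[!sup, , drop = FALSE]
    ac <- ac[!sup]
  }
  out <- data.frame(organism = df$organism, geneId = df$geneId,
                    anticodon = ac,
                    sequence = ifelse(is.na(df$sequence), NA_character_,
                                      rnaNormalize(df$sequence)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-organism species copy numbers
#'
#' @param genes gene table as returned by [parseTrnaTable()].
#' @return named list (by organism) of anticodon copy-number tables.
#' @export
speciesCopyNumber <- function(genes) {
  lapply(split(genes$anticodon, genes$organism), table)
}

#' Filter genomes by size and repertoire richness
#'
#' Removes organisms with severely reduced genomes (< 1e6 bp) or fewer than
#' 31 distinct tRNA species, the hallmark of endosymbionts whose repertoires
#' would distort the comparative analysis.
#'
#' @param genes gene table as returned by [parseTrnaTable()].
#' @param genomeSizes named numeric vector of genome sizes in bp.
#' @param minSize minimum genome size (bp).
#' @param minSpecies minimum number of distinct tRNA species (inclusive).
#' @return filtered gene table; the removal log is attached as attribute
#'   \code{"removed"} (data.frame organism/reason).
#' @export
filterGenomes <- function(genes, genomeSizes, minSize = 1e6,
                          minSpecies = 31L) {
  orgs <- unique(genes$organism)
  missing <- setdiff(orgs, names(genomeSizes))
  if (length(missing))
    stop("missing genome size for organism(s): ",
         paste(missing, collapse = ", "))
  nsp <- vapply(split(genes$anticodon, genes$organism),
                function(a) length(unique(a)), integer(1))
  removed <- data.frame(organism = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (o in orgs) {
    reasons <- character(0)
    if (genomeSizes[[o]] < minSize)
      reasons <- c(reasons, sprintf("genome %.3g bp < %.3g bp",
                                    genomeSizes[[o]], minSize))
    if (nsp[[o]] < minSpecies)
      reasons <- c(reasons, sprintf("%d tRNA species < %d", nsp[[o]],
                                    minSpecies))
    if (length(reasons))
      removed <- rbind(removed, data.frame(
        organism = o, reason = paste(reasons, collapse = "; "),
        stringsAsFactors = FALSE))
  }
  if (nrow(removed))
    message("filterGenomes: removed ", nrow(removed), " organism(s): ",
            paste(removed$organism, collapse = ", "))
  out <- genes[!(genes$organism %in% removed$organism), , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Build the presence/absence matrix
#'
#' @param genes gene table as returned by [parseTrnaTable()] (or any
#'   data.frame with \code{organism} and \code{anticodon} columns).
#' @return a [PresenceMatrix-class]: organisms in input order, species
#'   (anticodons observed in at least one organism) alphabetically.
#' @export
buildPresenceMatrix <- function(genes) {
  stopifnot(nrow(genes) > 0)
  orgs <- unique(genes$organism)
  sp <- sort(unique(genes$anticodon))
  m <- matrix(0L, length(orgs), length(sp), dimnames = list(orgs, sp))
  m[cbind(match(genes$organism, orgs), match(genes$anticodon, sp))] <- 1L
  PresenceMatrix(m)
}

#' Write / read a PresenceMatrix as TSV
#'
#' Organisms in rows, species in columns, first column \code{organism}.
#' @param x a PresenceMatrix.
#' @param path output path.
#' @export
writePresenceMatrix <- function(x, path) {
  m <- as.matrix(x)
  df <- data.frame(organism = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePresenceMatrix
#' @export
readPresenceMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  PresenceMatrix(m)
}
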