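## Genetic code tables and wobble decoding rules.
##
## Anticodons are written 5'->3' over the RNA alphabet and labelled by tRNA
## positions 34-35-36; position 34 is the wobble position and pairs the third
## codon position. The cognate (Watson-Crick) codon of an anticodon is its
## reverse complement.

.RNA_BASES <- c("A", "C", "G", "U")

.rna_complement <- c(A = "U", C = "G", G = "C", U = "A")

#' Reverse-complement a short RNA string
#' @param x character vector of RNA strings (A/C/G/U).
#' @return character vector of reverse complements.
#' @keywords internal
.revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b) {
    paste(rev(unname(.rna_complement[b])), collapse = "")
  }, character(1))
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Accepts DNA or RNA input in either case and returns an upper-case RNA
#' string (T converted to U).
#'
#' @param x character vector.
#' @return character vector over A/C/G/U (other letters left untouched).
#' @export
rnaNormalize <- function(x) {
  chartr("t", "u", chartr("T", "U", toupper(x)))
}

## Standard sense-codon table. The bacterial code (translation table 11)
## assigns the same amino acids to the same 61 sense codons as the standard
## code; only initiation contexts differ, which play no role here.
.sense_codon_table <- local({
  bases <- c("U", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[chartr("U", "T", codons)])
  keep <- aa != "*"
  codons <- codons[keep]
  aa <- aa[keep]
  quartet <- substr(codons, 1, 2)
  boxDeg <- vapply(seq_along(codons), function(i) {
    sum(aa[quartet == quartet[i]] == aa[i])
  }, integer(1))
  data.frame(codon = codons, aminoAcid = aa, quartet = quartet,
             boxDegeneracy = boxDeg, stringsAsFactors = FALSE)
})

.stop_codons <- c("UAA", "UAG", "UGA")

#' Sense codon table
#'
#' The 61 sense codons of the standard bacterial genetic code with their
#' amino acids and box degeneracy (number of codons in the codon quartet --
#' the four codons sharing the first two positions -- that code for the same
#' amino acid).
#'
#' @return A data.frame with columns \code{codon}, \code{aminoAcid},
#'   \code{quartet}, \code{boxDegeneracy}.
#' @export
senseCodons <- function() .sense_codon_table

#' Wobble interaction rule set
#'
#' Edges from the wobble base (anticodon position 34) to the codon third
#' positions it can read, with the interaction class. A34 is assumed to be
#' deaminated to inosine, which reads codons ending U, C and A; U34 reads
#' A (Watson-Crick) and G (modification-dependent wobble), and additionally
#' U and C by superwobbling; G34 reads C (Watson-Crick) and U (G:U wobble);
#' C34 reads only G.
#'
#' @return A data.frame with columns \code{n34}, \code{codon3},
#'   \code{interactionClass}.
#' @export
wobbleRules <- function() {
  data.frame(
    n34 = c("A", "A", "A", "A",
            "C",
            "G", "G",
            "U", "U", "U", "U"),
    codon3 = c("U", "U", "C", "A",
               "G",
               "C", "U",
               "A", "G", "U", "C"),
    interactionClass = c("watson_crick", "inosine", "inosine", "inosine",
                         "watson_crick",
                         "watson_crick", "wobble",
                         "watson_crick", "wobble", "superwobble",
                         "superwobble"),
    stringsAsFactors = FALSE
  )
}

#' Validate an anticodon
#'
#' An anticodon is valid when its reverse complement is a sense codon; the
#' three anticodons whose cognate codon is a stop (UUA, CUA, UCA -- the
#' suppressor anticodons) are rejected.
#'
#' @param anticodon character vector (DNA or RNA alphabet accepted).
#' @return normalized RNA anticodon(s); error if invalid.
#' @export
checkAnticodon <- function(anticodon) {
  ac <- rnaNormalize(anticodon)
  bad <- nchar(ac) != 3L | !vapply(strsplit(ac, ""), function(b)
    all(b %in% .RNA_BASES), logical(1))
  if (any(bad))
    stop("not a 3-letter anticodon over A/C/G/U: ",
         paste(anticodon[bad], collapse = ", "))
  codon <- .revcomp(ac)
  sup <- codon %in% .stop_codons
  if (any(sup))
    stop("suppressor anticodon (reverse complement is a stop codon): ",
         paste(ac[sup], collapse = ", "))
  ac
}

#' All 61 valid anticodon species
#'
#' @return character vector of the 61 anticodons whose cognate codon is a
#'   sense codon, alphabetically sorted.
#' @export
allAnticodons <- function() {
  sort(.revcomp(.sense_codon_table$codon))
}

.anticodon_info <- function(anticodon) {
  ac <- checkAnticodon(anticodon)
  codon <- .revcomp(ac)
  i <- match(codon, .sense_codon_table$codon)
  list(anticodon = ac, codon = codon,
       aminoAcid = .sense_codon_table$aminoAcid[i],
       quartet = .sense_codon_table$quartet[i],
       boxDegeneracy = .sense_codon_table$boxDegeneracy[i])
}

#' Codons decoded by an anticodon under the wobble rules
#'
#' Builds the set of codons reachable from an anticodon: the first two codon
#' positions are the complements of anticodon positions 36 and 35, and the
#' third position ranges over the bases reachable from the wobble base under
#' \code{rules}. A34 is treated as inosine-modified (reads U, C, A) unless
#' \code{inosine = FALSE}. Superwobble edges (U34 reading U3/C3) are only
#' applied inside 4-fold family boxes when \code{superwobbleFamilyOnly} is
#' \code{TRUE} (the default), and only when \code{superwobble = TRUE}.
#' Reachable codons that are stops or that code for a different amino acid
#' than the anticodon's cognate codon (the Met codon read by the Ile
#' U34A35U36, whose lysidine-modified form is out of scope) are dropped.
#'
#' @param anticodon a single anticodon (DNA or RNA alphabet).
#' @param rules a rule set as returned by [wobbleRules()].
#' @param superwobble include superwobble edges at all.
#' @param superwobbleFamilyOnly restrict superwobble to 4-fold family boxes.
#' @param inosine treat A34 as inosine-modified.
#' @return data.frame with columns \code{codon}, \code{interactionClass}.
#' @examples
#' decodedCodons("GAA")  # Phe: UUC (Watson-Crick) + UUU (wobble)
#' decodedCodons("ACG")  # Arg, I34: CGU, CGC, CGA
#' @export
decodedCodons <- function(anticodon, rules = wobbleRules(),
                          superwobble = TRUE, superwobbleFamilyOnly = TRUE,
                          inosine = TRUE) {
  info <- .anticodon_info(anticodon)
  stopifnot(length(info$anticodon) == 1L)
  n34 <- substr(info$anticodon, 1, 1)
  edges <- rules[rules$n34 == n34, , drop = FALSE]
  if (n34 == "A") {
    ## The encoded A34 Watson-Crick-pairs U3; deamination to inosine extends
    ## the range to C3 and A3. The U3 edge keeps its Watson-Crick label.
    if (!inosine)
      edges <- edges[edges$interactionClass == "watson_crick", , drop = FALSE]
  }
  if (!superwobble)
    edges <- edges[edges$interactionClass != "superwobble", , drop = FALSE]
  if (superwobbleFamilyOnly && info$boxDegeneracy != 4L)
    edges <- edges[edges$interactionClass != "superwobble", , drop = FALSE]
  prefix <- substr(info$codon, 1, 2)
  codons <- paste0(prefix, edges$codon3)
  keep <- !(codons %in% .stop_codons)
  codons <- codons[keep]
  cls <- edges$interactionClass[keep]
  aa <- .sense_codon_table$aminoAcid[match(codons, .sense_codon_table$codon)]
  keep2 <- aa == info$aminoAcid
  out <- data.frame(codon = codons[keep2], interactionClass = cls[keep2],
                    stringsAsFactors = FALSE)
  out[!duplicated(out$codon), , drop = FALSE]
}

#' Classify a tRNA species as mandatory, auxiliary, avoided or special
#'
#' Encodes the decoding logic implied by the near-absence of A34 tRNAs in
#' bacteria: with inosine-modified A34 tRNAs avoided, U34 species are needed
#' for A-ending codons and G34 species for pyrimidine-ending codons of 2- and
#' 3-fold boxes, so these are mandatory, as are the sole decoders of Met
#' (C34A35U36) and Trp (C34C35A36). G34 species in 4-fold family boxes can be
#' replaced by the superwobbling U34 species and are auxiliary, as are the
#' remaining C34 species (their G-ending codons are covered by U34 wobble).
#' The Arg box is the exception: A34C35G36 is in regular use (mandatory),
#' I34 does not read CGG, so U34C35G36 / C34C35G36 are mandatory only as a
#' pair and are classified auxiliary with an Arg-box flag (as is G34C35G36).
#' U34A35U36 (Ile) is special: the unmodified form would misread Met.
#'
#' @param anticodon character vector of anticodons.
#' @return character vector of statuses in
#'   \code{c("mandatory","auxiliary","avoided","special")}.
#' @export
classifySpecies <- function(anticodon) {
  ac <- checkAnticodon(anticodon)
  vapply(ac, function(a) {
    info <- .anticodon_info(a)
    n34 <- substr(a, 1, 1)
    if (n34 == "U") {
      if (a == "UAU") return("special")
      if (a == "UCG") return("auxiliary")
      return("mandatory")
    }
    if (n34 == "G") {
      if (info$boxDegeneracy == 4L) return("auxiliary")
      return("mandatory")
    }
    if (n34 == "C") {
      if (a %in% c("CAU", "CCA")) return("mandatory")
      return("auxiliary")
    }
    ## A34: all avoided except the Arg I34 decoder, which most bacteria use
    if (a == "ACG") return("mandatory")
    "avoided"
  }, character(1), USE.NAMES = FALSE)
}

#' Table of all 61 anticodon species
#'
#' @return data.frame with one row per valid anticodon: \code{anticodon},
#'   \code{aminoAcid}, \code{boxDegeneracy}, \code{n34}, \code{status}, and
#'   \code{argBox} flagging the context-dependent Arg-box species
#'   (G/U/C)34C35G36.
#' @export
anticodonTable <- function() {
  ac <- allAnticodons()
  info <- lapply(ac, .anticodon_info)
  data.frame(
    anticodon = ac,
    aminoAcid = vapply(info, `[[`, character(1), "aminoAcid"),
    boxDegeneracy = vapply(info, `[[`, integer(1), "boxDegeneracy"),
    n34 = substr(ac, 1, 1),
    status = classifySpecies(ac),
    argBox = ac %in% c("GCG", "UCG", "CCG"),
    stringsAsFactors = FALSE
  )
}

#' Report sense codons not decodable by a repertoire
#'
#' Lists the sense codons that cannot be read by any of the given tRNA
#' species under the wobble rules.
#'
#' @param species character vector of anticodons present in a genome.
#' @param rules rule set, see [wobbleRules()].
#' @param ... passed to [decodedCodons()].
#' @return character vector of uncovered sense codons (empty when decoding
#'   is complete).
#' @export
checkDecodingCompleteness <- function(species, rules = wobbleRules(), ...) {
  species <- unique(checkAnticodon(species))
  covered <- unique(unlist(lapply(species, function(a)
    decodedCodons(a, rules = rules, ...)$codon)))
  setdiff(.sense_codon_table$codon, covered)
}
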