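test_that("the 61 anticodon species partition into decoding classes", {
  tab <- anticodonTable()
  expect_equal(nrow(tab), 61)
  expect_setequal(unique(tab$status),
                  c("mandatory", "auxiliary", "avoided", "special"))
  counts <- table(tab$status)
  expect_equal(unname(counts[["special"]]), 1)   # U34A35U36-Ile
  expect_equal(unname(counts[["avoided"]]), 15)  # A34 species bar ACG
  ## the two single-codon decoders are mandatory by the sole-decoder rule
  singles <- tab[tab$boxDegeneracy == 1, ]
  expect_setequal(singles$anticodon, c("CAU", "CCA"))
  expect_true(all(singles$status == "mandatory"))
  ## Arg-box context-dependent species flagged
  expect_setequal(tab$anticodon[tab$argBox], c("GCG", "UCG", "CCG"))
})

test_that("classification matches the decoding logic case by case", {
  expect_equal(classifySpecies("CAU"), "mandatory")  # sole Met decoder
  expect_equal(classifySpecies("CCA"), "mandatory")  # sole Trp decoder
  expect_equal(classifySpecies("UAU"), "special")    # Ile, rarely seen
  expect_equal(classifySpecies("GGC"), "auxiliary")  # G34, Ala family box
  expect_equal(classifySpecies("GAA"), "mandatory")  # G34, Phe split box
  expect_equal(classifySpecies("UCG"), "auxiliary")  # Arg box U34
  expect_equal(classifySpecies("AAA"), "avoided")    # A34
  expect_equal(classifySpecies("ACG"), "mandatory")  # the used I34 species
  ## DNA alphabet accepted
  expect_equal(classifySpecies("cat"), "mandatory")
})

test_that("decoded codons follow the wobble rules", {
  gaa <- decodedCodons("GAA")
  expect_setequal(gaa$codon, c("UUC", "UUU"))
  expect_equal(gaa$interactionClass[gaa$codon == "UUC"], "watson_crick")
  expect_equal(gaa$interactionClass[gaa$codon == "UUU"], "wobble")
  ## C34 pairs only G3
  expect_equal(decodedCodons("CCA")$codon, "UGG")
  ## inosine-modified A34 reads U, C, A
  expect_setequal(decodedCodons("ACG")$codon, c("CGU", "CGC", "CGA"))
  expect_equal(decodedCodons("ACG", inosine = FALSE)$codon, "CGU")
  ## superwobble only inside family boxes by default
  expect_setequal(decodedCodons("UGC")$codon,
                  c("GCA", "GCG", "GCU", "GCC"))        # Ala family box
  expect_setequal(decodedCodons("UUC")$codon, c("GAA", "GAG"))  # Glu
  ## U34A35U36 must not cover the Met codon
  expect_false("AUG" %in% decodedCodons("UAU")$codon)
})

test_that("decoded codons of all species cover the sense codons with a
           Watson-Crick edge each", {
  dec <- do.call(rbind, lapply(allAnticodons(), decodedCodons))
  expect_setequal(unique(dec$codon), senseCodons()$codon)
  wc <- unique(dec$codon[dec$interactionClass == "watson_crick"])
  expect_setequal(wc, senseCodons()$codon)
})

test_that("suppressor anticodons are rejected", {
  expect_error(checkAnticodon("UCA"), "stop codon")
  expect_error(checkAnticodon("UUA"), "stop codon")
  expect_error(checkAnticodon("CUA"), "stop codon")
  expect_error(checkAnticodon("GA"), "3-letter")
  expect_equal(checkAnticodon("tGC"), "UGC")
})

test_that("decoding completeness reports uncovered codons", {
  expect_length(checkDecodingCompleteness(allAnticodons()), 0)
  ## no decoder for the Arg quartet at all
  noArg <- setdiff(allAnticodons(),
                   c("ACG", "GCG", "UCG", "CCG"))
  expect_true(all(c("CGU", "CGC", "CGA", "CGG") %in%
                    checkDecodingCompleteness(noArg)))
  ## I34 alone cannot read CGG
  expect_true("CGG" %in% checkDecodingCompleteness("ACG"))
  expect_false("CGU" %in% checkDecodingCompleteness("ACG"))
})

test_that("tRNA tables parse in both dialects and drop flagged rows", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "organism_id\tgene_id\tanticodon\tsequence\tpseudo",
    "O1\tg1\tGAA\tACGU\tno",
    "O1\tg2\tTTC\tACGU\tno",     # DNA alphabet normalized
    "O2\tg3\tGAA\t\tpseudo",     # dropped: pseudo
    "O2\tg4\tNNN\t\tno",         # dropped: undetermined
    "O2\tg5\tCAU\t\tno"
  ), tsv)
  genes <- parseTrnaTable(tsv)
  expect_equal(nrow(genes), 3)
  expect_setequal(genes$anticodon, c("GAA", "UUC", "CAU"))

  scan <- tempfile(fileext = ".out")
  writeLines(c(
    "Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\tCove",
    "Name    \ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
    "--------\t------\t-----\t---\t----\t-----\t-----\t---\t-----",
    "O1\t1\t100\t175\tPhe\tGAA\t0\t0\t55.1",
    "O1\t2\t300\t375\tSer\tNNN\t0\t0\t20.0",
    "O2\t1\t10\t85\tMet\tCAT\t0\t0\t60.0",
    "O2\t2\t90\t160\tUndet\tTTC\t0\t0\t30.0\t\tpseudo"
  ), scan)
  genes2 <- parseTrnaTable(scan)
  expect_equal(nrow(genes2), 3)
  expect_true("CAU" %in% genes2$anticodon)
  expect_equal(genes2$geneId[1], "O1.trna1")

  ## suppressor anticodon dropped with a warning
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c("organism_id\tanticodon", "O1\tGAA", "O1\tUCA"), tsv2)
  expect_warning(g3 <- parseTrnaTable(tsv2), "stop codon")
  expect_equal(nrow(g3), 1)

  ## malformed row errors with its line number
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("organism_id\tanticodon", "O1\tGAA", "justonefield"), bad)
  expect_error(parseTrnaTable(bad), "line 3")
})

test_that("genome filtering enforces the size and richness thresholds", {
  sp31 <- allAnticodons()[1:31]
  genes <- rbind(
    data.frame(organism = "small", geneId = paste0("s", 1:45),
               anticodon = rep(allAnticodons()[1:45], length.out = 45),
               sequence = NA, stringsAsFactors = FALSE),
    data.frame(organism = "poor", geneId = paste0("p", 1:30),
               anticodon = allAnticodons()[1:30], sequence = NA,
               stringsAsFactors = FALSE),
    data.frame(organism = "ok", geneId = paste0("k", 1:31),
               anticodon = sp31, sequence = NA, stringsAsFactors = FALSE)
  )
  sizes <- c(small = 9e5, poor = 5e6, ok = 2e6)
  out <- suppressMessages(filterGenomes(genes, sizes))
  expect_setequal(unique(out$organism), "ok")   # 31 species inclusive
  removed <- attr(out, "removed")
  expect_setequal(removed$organism, c("small", "poor"))
  expect_error(filterGenomes(genes, sizes[-1]), "small")
})

test_that("presence matrix construction binarizes and orders
           deterministically", {
  genes <- toy_gene_table()
  pm <- buildPresenceMatrix(genes)
  m <- as.matrix(pm)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(colnames(m), sort(c("GAA", "CAU", "UUC")))
  expect_equal(m["O1", "GAA"], 1L)   # two copies -> 1
  expect_equal(m["O1", "CAU"], 0L)
  ## row shuffling of the input leaves the matrix (up to row order) alone
  set.seed(1)
  pm2 <- buildPresenceMatrix(genes[sample(nrow(genes)), ])
  expect_equal(as.matrix(pm2)[rownames(m), colnames(m)], m)
  ## species never observed are absent: only observed anticodons appear
  expect_false("AAA" %in% trnaSpecies(pm))
})

test_that("PresenceMatrix validity, accessors and TSV round-trip", {
  m <- matrix(c(1L, 0L, 1L, 1L), 2, 2,
              dimnames = list(c("A", "B"), c("GAA", "CAU")))
  pm <- PresenceMatrix(m)
  expect_equal(organisms(pm), c("A", "B"))
  expect_equal(trnaSpecies(pm), c("GAA", "CAU"))
  expect_equal(dim(pm), c(2L, 2L))
  expect_error(PresenceMatrix(matrix(2L, 1, 1,
                                     dimnames = list("A", "X"))), "0/1")
  sub <- pm["A", "GAA"]
  expect_equal(as.matrix(sub)[1, 1], 1L)
  f <- tempfile(fileext = ".tsv")
  writePresenceMatrix(pm, f)
  expect_equal(as.matrix(readPresenceMatrix(f)), m)
})

test_that("per-organism copy numbers reflect the gene table", {
  cn <- speciesCopyNumber(toy_gene_table())
  expect_equal(unname(cn$O1[["GAA"]]), 2L)
  expect_equal(unname(cn$O2[["CAU"]]), 1L)
})
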