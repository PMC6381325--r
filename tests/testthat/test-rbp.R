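test_that("IUPAC expansion enumerates the degeneracy product", {
  expect_equal(iupacExpand("ACG"), "ACG")
  expect_setequal(iupacExpand("RY"), c("AC", "AT", "GC", "GT"))
  expect_setequal(iupacExpand("ACGU"), "ACGT")
  deg <- c(A = 1, C = 1, G = 1, T = 1, U = 1, R = 2, Y = 2, S = 2, W = 2,
           K = 2, M = 2, B = 3, D = 3, H = 3, V = 3, N = 4)
  set.seed(401)
  for (i in 1:10) {
    motif <- paste(sample(names(deg), sample(3:6, 1), replace = TRUE),
                   collapse = "")
    expanded <- iupacExpand(motif)
    expect_length(expanded, prod(deg[strsplit(gsub("U", "T", motif),
                                              "")[[1]]]))
    expect_false(anyDuplicated(expanded) > 0)
  }
  expect_error(iupacExpand("ACX"), "invalid IUPAC")
})

test_that("motif tables are filtered to human and normalized to DNA", {
  f <- tempfile(fileext = ".tsv")
  write_motif_table(f)
  sets <- parseMotifTable(f)
  expect_setequal(names(sets), c("RBP1", "RBP2", "RBP3"))  # mouse dropped
  # ACGUA and ACGTA collapse to one expanded sequence
  expect_identical(sets$RBP1$expanded, "ACGTA")
  expect_true(all(grepl("^[ACGT]+$",
                        unlist(lapply(sets, `[[`, "expanded")))))
  # dedup count across the set
  expect_equal(attr(sets, "n_unique"),
               length(unique(unlist(lapply(sets, `[[`, "expanded")))))
  # empty table
  empty <- tempfile(fileext = ".tsv")
  writeLines("species\trbp_id\tmotif", empty)
  expect_length(parseMotifTable(empty), 0)
  # invalid motif names the row
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("species\trbp_id\tmotif", "Homo_sapiens\tR1\tACGZ"), bad)
  expect_error(parseMotifTable(bad), "row 1")
})

test_that("hit counting is non-overlapping, additive and order-invariant", {
  expect_equal(countMotifHits("", "AA"), 0)
  expect_equal(countMotifHits("AAAA", "AA"), 2)
  expect_equal(countMotifHits("AAAA", "AA", overlapping = TRUE), 3)
  expect_equal(countMotifHits("ACGT", c("AC", "GT")), 2)
  expect_equal(countMotifHits("ACGT", c("GT", "AC")), 2)
  expect_equal(countMotifHits("ANGT", c("AC", "GT")), 1)  # N never matches
})

test_that("UTR extraction slices and orients by hand-checkable fixtures", {
  utr5 <- "AAATTT"; cds <- "ATGCCCTAA"; utr3 <- "GGGCGCGC"
  seq_plus <- paste0(utr5, cds, utr3)
  # minus-strand gene: genomic sequence is the reverse complement
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  seq_minus <- rc(seq_plus)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrP", seq_plus, ">chrM", seq_minus), fa)
  n <- nchar(seq_plus)
  gtf <- tempfile(fileext = ".gtf")
  at <- function(chr, type, s, e, strand, g, t) sprintf(
    "%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    chr, type, s, e, strand, g, t)
  writeLines(c(
    at("chrP", "exon", 1, n, "+", "gP", "tP"),
    at("chrP", "five_prime_utr", 1, 6, "+", "gP", "tP"),
    at("chrP", "CDS", 7, 15, "+", "gP", "tP"),
    at("chrP", "three_prime_utr", 16, n, "+", "gP", "tP"),
    # minus strand: 5' UTR occupies the end of the plus-strand coordinates
    at("chrM", "exon", 1, n, "-", "gM", "tM"),
    at("chrM", "three_prime_utr", 1, 8, "-", "gM", "tM"),
    at("chrM", "CDS", 9, 17, "-", "gM", "tM"),
    at("chrM", "five_prime_utr", 18, n, "-", "gM", "tM"),
    # generic UTR features classified relative to the CDS
    at("chrP", "exon", 1, n, "+", "gU", "tU"),
    at("chrP", "UTR", 1, 6, "+", "gU", "tU"),
    at("chrP", "CDS", 7, 15, "+", "gU", "tU"),
    at("chrP", "UTR", 16, n, "+", "gU", "tU")), gtf)
  recs <- extractUTRs(fa, gtf)
  get <- function(t, s) recs$sequence[recs$transcript_id == t &
                                        recs$side == s]
  expect_equal(get("tP", "five_prime"), utr5)
  expect_equal(get("tP", "three_prime"), utr3)
  expect_equal(get("tM", "five_prime"), utr5)
  expect_equal(get("tM", "three_prime"), utr3)
  expect_equal(get("tU", "five_prime"), utr5)
  expect_equal(get("tU", "three_prime"), utr3)
  # restriction to a gene set
  only <- extractUTRs(fa, gtf, genes = "gP")
  expect_setequal(only$gene_id, "gP")
})

test_that("coverage gate keeps 5' >= 3 and 3' >= 5 reads", {
  recs <- data.frame(
    transcript_id = paste0("t", 1:4),
    side = c("three_prime", "three_prime", "five_prime", "five_prime"),
    read_count = c(4, 5, 2, 3), stringsAsFactors = FALSE)
  out <- utrCoverageFilter(recs)
  expect_setequal(out$transcript_id, c("t2", "t4"))
  expect_identical(utrCoverageFilter(recs, 0, 0), recs)
})

test_that("gene-level aggregation sums transcripts order-invariantly", {
  sets <- list(list(rbp_id = "R", iupac_motifs = "AC", expanded = "AC"))
  recs <- data.frame(gene_id = c("g1", "g1", "g2"),
                     transcript_id = c("t1", "t2", "t3"),
                     side = "three_prime",
                     sequence = c("ACAC", "ACTT", "TTTT"),
                     stringsAsFactors = FALSE)
  out <- aggregateGeneLevel(recs, sets)
  expect_equal(out$hits[out$gene_id == "g1"], 3)  # 2 + 1
  expect_equal(out$hits[out$gene_id == "g2"], 0)
  out_rev <- aggregateGeneLevel(recs[c(3, 1, 2), ], sets)
  expect_equal(out_rev[order(out_rev$gene_id), "hits"],
               out[order(out$gene_id), "hits"])
  # single transcript is the identity
  one <- aggregateGeneLevel(recs[1, ], sets)
  expect_equal(one$hits, 2)
})

test_that("RBP expression filter keeps only universe members", {
  expect_identical(rbpExpressionFilter(c("A", "B"), c("A", "B", "C")),
                   c("A", "B"))
  expect_identical(rbpExpressionFilter(c("A", "Z"), c("A", "B")), "A")
  expect_warning(
    out <- rbpExpressionFilter(c("A", "B"), c("GA"),
                               id_map = c(A = "GA", B = NA)),
    "not mappable")
  expect_identical(out, "A")
})

test_that("tropism means match hand arithmetic", {
  hits <- data.frame(gene_id = c("g1", "g2", "g3", "g1"),
                     rbp_id = c("R", "R", "R", "R"),
                     side = c("three_prime", "three_prime", "three_prime",
                              "five_prime"),
                     hits = c(2, 4, 6, 1), stringsAsFactors = FALSE)
  out <- tropismSummary(hits)
  expect_equal(out$mean_3p, mean(c(2, 4, 6)))
  expect_equal(out$mean_5p, 1)
  only3 <- tropismSummary(hits[1:3, ])
  expect_equal(only3$mean_5p, 0)
  expect_true(all(out$mean_5p >= 0 & out$mean_3p >= 0))
})

test_that("site/logFC correlation finds planted and affine relations", {
  # affine relation: r = 1
  hits <- data.frame(gene_id = paste0("g", 1:10), rbp_id = "R",
                     side = "three_prime", hits = 1:10,
                     stringsAsFactors = FALSE)
  lf <- setNames(2 * (1:10) + 3, paste0("g", 1:10))
  out <- correlateSitesLogFC(hits, lf)
  expect_equal(out$r, 1, tolerance = 1e-12)
  # planted linear relation with noise
  set.seed(431)
  n <- 200
  lf2 <- setNames(rnorm(n), paste0("g", 1:n))
  planted_r <- 0.8
  noise <- rnorm(n)
  site <- round(5 + 3 * (planted_r * scale(lf2)[, 1] +
                           sqrt(1 - planted_r^2) * scale(noise)[, 1]))
  hits2 <- rbind(
    data.frame(gene_id = names(lf2), rbp_id = "HIT", side = "three_prime",
               hits = pmax(site, 0), stringsAsFactors = FALSE),
    data.frame(gene_id = names(lf2), rbp_id = "NULL1", side = "three_prime",
               hits = rpois(n, 5), stringsAsFactors = FALSE))
  out2 <- correlateSitesLogFC(hits2, lf2)
  r_hit <- out2$r[out2$rbp_id == "HIT"]
  expect_lt(abs(r_hit - planted_r), 0.1)
  expect_lt(out2$FDR[out2$rbp_id == "HIT"], 0.01)
  expect_gt(abs(r_hit), abs(out2$r[out2$rbp_id == "NULL1"]))
})
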