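write_genbank_fixture <- function(path, seq, cds_lines) {
  lines <- c(
    "LOCUS       TESTPHAGE        400 bp    DNA     linear   PHG",
    "VERSION     TESTPHAGE.1",
    "FEATURES             Location/Qualifiers",
    "     source          1..400",
    "                     /host=\"Escherichia coli\"",
    cds_lines,
    "ORIGIN")
  chunks <- substring(seq, seq(1, nchar(seq), 60), pmin(seq(60, nchar(seq) + 59, 60), nchar(seq)))
  for (k in seq_along(chunks)) {
    lines <- c(lines, sprintf("%9d %s", (k - 1) * 60 + 1, chunks[k]))
  }
  writeLines(c(lines, "//"), path)
  path
}

test_that("GenBank coordinates convert to 0-based half-open and host is read", {
  set.seed(1)
  seq <- random_genome <- paste(sample(c("A","C","G","T"), 600, TRUE), collapse = "")
  f <- withr::local_tempfile(fileext = ".gbk")
  write_genbank_fixture(f, substr(seq, 1, 600), c(
    "     CDS             1..462",
    "                     /gene=\"rz\"",
    "     CDS             complement(464..529)",
    "                     /gene=\"rev\""))
  g <- read_genome(f, format = "genbank")
  expect_s3_class(g, "genome_record")
  expect_equal(g$id, "TESTPHAGE.1")
  expect_equal(g$host, "Escherichia coli")
  expect_equal(g$features$start, c(0L, 463L))
  expect_equal(g$features$end, c(462L, 529L))
  expect_equal(g$features$strand, c("+", "-"))
  expect_equal(g$features$label, c("rz", "rev"))
})

test_that("FASTA input yields a record with no features", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">phageX some description", "ACGTACGTACGTAACCGGTT"), f)
  g <- read_genome(f)
  expect_equal(g$id, "phageX")
  expect_equal(g$length, 20L)
  expect_equal(nrow(g$features), 0L)
})

test_that("spliced CDS features are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".gbk")
  write_genbank_fixture(f, strrep("ACGT", 150), c(
    "     CDS             join(1..30,61..90)",
    "                     /gene=\"spliced\"",
    "     CDS             101..160",
    "                     /gene=\"plain\""))
  expect_warning(g <- read_genome(f, format = "genbank"), "unsupported")
  expect_equal(nrow(g$features), 1L)
  expect_equal(g$features$label, "plain")
})

test_that("non-IUPAC characters are rejected with their position", {
  expect_error(genome_record("x", "ACGTZACGT"), "position 5")
  # IUPAC ambiguity codes are tolerated and collapsed to N
  g <- genome_record("x", "ACGTRYACGT")
  expect_equal(g$sequence, "ACGTNNACGT")
})

test_that("scan_orfs matches a brute-force six-frame enumeration", {
  set.seed(42)
  for (rep in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
    g <- genome_record(sprintf("r%d", rep), seq)
    got <- scan_orfs(g, min_aa = 15L)
    want <- oracle_scan_orfs(seq, 15L)
    expect_equal(got[, c("start", "end", "strand", "aa_seq")], want,
                 ignore_attr = TRUE)
  }
})

test_that("candidate translation round-trips and strand symmetry holds", {
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  g <- genome_record("rt", seq)
  cands <- scan_orfs(g, min_aa = 12L)
  expect_gt(nrow(cands), 0L)
  for (i in seq_len(nrow(cands))) {
    nt <- substr(seq, cands$start[i] + 1L, cands$end[i])
    if (cands$strand[i] == "-") {
      nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    }
    # literal translation: GTG/TTG-initiated ORFs keep V/L, by convention
    expect_equal(as.character(Biostrings::translate(
      Biostrings::DNAString(nt), no.init.codon = TRUE)), cands$aa_seq[i])
  }
  # reverse-complementing the genome reflects all candidates
  rc <- genome_record("rc", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq))))
  cands_rc <- scan_orfs(rc, min_aa = 12L)
  L <- nchar(seq)
  reflected <- data.frame(start = L - cands$end, end = L - cands$start,
                          strand = ifelse(cands$strand == "+", "-", "+"),
                          aa_seq = cands$aa_seq, stringsAsFactors = FALSE)
  ord <- function(d) d[order(d$start, d$end, d$strand), ]
  expect_equal(ord(reflected)$aa_seq,
               ord(cands_rc[, c("start", "end", "strand", "aa_seq")])$aa_seq)
})

test_that("multiple admissible starts in one segment are all reported", {
  # 100-codon ORF with ATG at codon 1 and GTG at codon 10: both candidates
  # share the stop
  body <- paste(rep("GAA", 100), collapse = "")
  nt <- paste0("TAA", "ATG", paste(rep("GAA", 8), collapse = ""), "GTG",
               paste(rep("GAA", 90), collapse = ""), "TAA", strrep("T", 20))
  g <- genome_record("s", nt)
  cands <- scan_orfs(g, min_aa = 50L)
  fw <- cands[cands$strand == "+" & cands$start >= 3L, ]
  expect_equal(nrow(fw), 2L)
  expect_equal(unique(fw$end), max(fw$end))
  expect_setequal(fw$start_codon, c("ATG", "GTG"))
})

test_that("ORFs nested inside annotated genes are recovered and marked", {
  sim <- simulate_genome(sim_spec(n_embedded = 1, n_overlapped = 0,
                                  n_separated = 0, n_unimolecular = 0,
                                  n_decoys = 0, seed = 11))
  g <- sim$genome
  o_row <- sim$truth[sim$truth$role == "o", ]
  cands <- scan_orfs(g, min_aa = 40L)
  hit <- cands[cands$strand == o_row$strand &
                 abs(cands$start - o_row$start) <= 3L &
                 abs(cands$end - o_row$end) <= 3L, ]
  expect_gt(nrow(hit), 0L)
  expect_true(any(!is.na(hit$nested_in)))
})

test_that("stop-codon-saturated sequence yields no candidates", {
  g <- genome_record("e", strrep("TAATAG", 60))
  expect_equal(nrow(scan_orfs(g, min_aa = 10L)), 0L)
})

test_that("Shine-Dalgarno scoring finds the best ungapped consensus match", {
  mk <- function(upstream) {
    genome_record("t", paste0(strrep("T", 30), upstream,
                              "ATGAAACCCGGGTTTTAA", strrep("T", 10)))
  }
  g <- mk(paste0("AGGAGG", "CAACTAT"))          # perfect site, spacer 7
  orf <- list(start = 43L, end = 58L, strand = "+")
  sd <- score_sd(g, orf)
  expect_equal(sd$motif, "AGGAGG")
  expect_equal(sd$spacer, 7L)
  expect_equal(sd$score, 6L)

  g2 <- genome_record("t", paste0(strrep("T", 30), "GGAG", strrep("C", 9),
                                  "ATGAAACCCGGGTTTTAA"))
  sd2 <- score_sd(g2, list(start = 43L, end = 58L, strand = "+"))
  expect_equal(sd2$motif, "GGAG")
  expect_equal(sd2$spacer, 9L)
  expect_equal(sd2$score, 4L)

  g3 <- genome_record("t", paste0(strrep("T", 43), "ATGAAACCCGGGTTTTAA"))
  expect_null(score_sd(g3, list(start = 43L, end = 58L, strand = "+")))

  # an ORF too close to the genome edge on its strand scores none
  g4 <- genome_record("t", paste0(strrep("A", 10), "ATGAAACCCGGGTTTTAA"))
  expect_null(score_sd(g4, list(start = 10L, end = 25L, strand = "+")))
})

test_that("start refinement prefers signal-valid starts with SD evidence", {
  sib <- data.frame(start = c(0L, 30L, 60L), end = 300L, strand = "+",
                    frame = 0L,
                    aa_seq = c(strrep("Q", 100), strrep("K", 90),
                               strrep("E", 80)),
                    start_codon = "ATG",
                    sd_motif = c(NA, "AGGAGG", "GGAG"),
                    sd_spacer = c(NA, 7L, 8L),
                    sd_score = c(NA, 6L, 4L),
                    nested_in = NA_character_,
                    stringsAsFactors = FALSE)
  # validator admits the two shorter ones; the SD score decides
  val <- function(aa) nchar(aa) <= 90
  best <- refine_start(sib[1, ], sib, val)
  expect_equal(best$start, 30L)
  expect_equal(best$confidence, "high")
  # nothing validates: longest wins, flagged low-confidence
  best2 <- refine_start(sib[1, ], sib, function(aa) FALSE)
  expect_equal(best2$start, 0L)
  expect_equal(best2$confidence, "low")
  # empty sibling set: unchanged
  best3 <- refine_start(sib[2, ], sib[0, ], val)
  expect_equal(best3$start, 30L)
})

test_that("candidate GFF3 output is well-formed 1-based inclusive", {
  set.seed(3)
  seq <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  g <- genome_record("gff", seq)
  cands <- scan_orfs(g, min_aa = 12L)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_candidates_gff3(cands, g, f)
  ln <- readLines(f)
  expect_equal(ln[1], "##gff-version 3")
  body <- ln[!grepl("^#", ln)]
  expect_equal(length(body), nrow(cands))
  fields <- strsplit(body[1], "\t")[[1]]
  expect_equal(length(fields), 9L)
  expect_equal(fields[3], "CDS")
  a <- as.integer(fields[4]); b <- as.integer(fields[5])
  expect_true(a >= 1L && b <= nchar(seq) && (b - a + 1L) %% 3L == 0L)
})
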