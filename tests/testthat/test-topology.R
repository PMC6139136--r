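test_that("hydropathy profile equals direct window means", {
  expect_equal(hydropathy_profile(strrep("L", 19), 19)[10], 3.8)
  expect_equal(hydropathy_profile(strrep("S", 19), 19)[10], -0.8)
  p <- hydropathy_profile("LLLLSSSS", 3)
  expect_equal(p, oracle_profile("LLLLSSSS", 3))
  set.seed(5)
  for (k in 1:10) {
    aa <- random_protein(sample(25:120, 1))
    w <- sample(c(7L, 11L, 19L), 1)
    expect_equal(hydropathy_profile(aa, w), oracle_profile(aa, w))
  }
  # unknown residues contribute 0
  p2 <- hydropathy_profile(paste0(strrep("L", 9), "X", strrep("L", 9)), 19)
  expect_equal(p2[10], (18 * 3.8) / 19)
})

test_that("TMD detection equals thresholding of the hydropathy profile", {
  mk <- function(blocks) paste(blocks, collapse = "")
  one <- mk(c(strrep("S", 5), strrep("L", 21), strrep("S", 40)))
  tm <- find_tmds(one)
  expect_equal(nrow(tm), 1L)
  # the run must sit on the Leu block
  expect_true(tm$start[1] >= 0 && tm$end[1] <= 5 + 21 + 19)
  expect_gte(tm$mean_hydropathy[1], 1.6)

  expect_equal(nrow(find_tmds(strrep("S", 80))), 0L)

  two <- mk(c(strrep("S", 5), strrep("L", 21), strrep("S", 40),
              strrep("L", 21), strrep("S", 10)))
  expect_equal(nrow(find_tmds(two)), 2L)

  # oracle identity: every reported interval is a thresholded run of the
  # directly recomputed profile (up to the 30-residue trim)
  set.seed(9)
  for (k in 1:15) {
    aa <- paste0(random_protein(sample(5:30, 1)), strrep("L", 21),
                 random_protein(sample(20:60, 1)))
    prof <- oracle_profile(aa, 19)
    tm <- find_tmds(aa)
    for (r in seq_len(nrow(tm))) {
      run <- (tm$start[r] + 1L):tm$end[r]
      expect_true(all(prof[run] >= 1.6))
      expect_gte(length(run), 15L)
      expect_lte(length(run), 30L)
    }
  }
})

test_that("strict lipobox acceptance set is exactly the 45 consensus boxes", {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  accepted <- character(0)
  for (a in aas) for (b in aas) for (d in aas) {
    tri <- paste0(a, b, d)
    hit <- find_lipobox(lipobox_scaffold(tri), mode = "strict")
    if (!is.null(hit) && hit$motif == paste0(tri, "C")) {
      accepted <- c(accepted, tri)
    }
  }
  want <- as.vector(outer(outer(c("L", "V", "I"), c("A", "S", "T", "V", "I"),
                                paste0), c("G", "A", "S"), paste0))
  expect_setequal(accepted, want)
  expect_equal(length(accepted), 45L)
})

test_that("AWAC is accepted only in relaxed mode and AWAS never", {
  awac <- lipobox_scaffold("AWA")
  expect_null(find_lipobox(awac, mode = "strict"))
  hit <- find_lipobox(awac, mode = "relaxed")
  expect_equal(hit$motif, "AWAC")
  expect_equal(hit$mode, "relaxed")
  # LSGC matches the consensus even when searched in relaxed mode
  hit2 <- find_lipobox(lipobox_scaffold("LSG"), mode = "relaxed")
  expect_equal(hit2$mode, "strict")
  # no cysteine, no lipobox
  awas <- paste0("MAK", strrep("F", 8), "WH", "AWA", "S", strrep("Q", 30))
  expect_null(find_lipobox(awas, mode = "strict"))
  expect_null(find_lipobox(awas, mode = "relaxed"))
})

test_that("lipobox requires the signal-peptide context, not just the motif", {
  # no K/R near the N terminus
  expect_null(find_lipobox(paste0("MAQ", strrep("F", 8), "WH", "LSG", "C",
                                  strrep("Q", 30))))
  # no hydrophobic stretch before the box
  expect_null(find_lipobox(paste0("MAK", strrep("Q", 10), "LSG", "C",
                                  strrep("Q", 30))))
  # charged residue between the stretch and the Cys
  expect_null(find_lipobox(paste0("MAK", strrep("F", 8), "EH", "LSG", "C",
                                  strrep("Q", 30))))
})

test_that("topology classification follows the U > O > I order", {
  i_like <- paste0("MKRS", strrep("L", 21), strrep("Q", 90))
  o_like <- paste0("MAKN", strrep("L", 8), "SA", "LSGC", strrep("P", 45))
  u_like <- paste0("MAKN", strrep("L", 8), "SA", "LSGC", strrep("Q", 40),
                   strrep("L", 21), "K")
  expect_equal(classify_topology(i_like)$type, "I_CAND")
  expect_equal(classify_topology(o_like)$type, "O_CAND")
  expect_equal(classify_topology(u_like)$type, "U_CAND")
  expect_equal(classify_topology(strrep("Q", 100))$type, "NONE")
  # length gate
  short <- classify_topology(strrep("L", 30))
  expect_equal(short$type, "NONE")
  expect_equal(short$evidence, "length")
  expect_equal(classify_topology(random_protein(400))$type, "NONE")
})

test_that("the classifier is total: exactly one type per sequence", {
  set.seed(21)
  for (k in 1:50) {
    aa <- random_protein(sample(35:360, 1))
    type <- classify_topology(aa)$type
    expect_true(type %in% c("I_CAND", "O_CAND", "U_CAND", "NONE"))
  }
})

test_that("planted signals are recovered with full accuracy", {
  set.seed(33)
  n_each <- 67
  for (k in seq_len(n_each)) {
    i <- make_spanin_gene("i")
    o <- make_spanin_gene("o", list(lipobox = sample(c("LSGC", "LAGC",
                                                       "AWAC"), 1)))
    u <- make_spanin_gene("u", list(lipobox = sample(c("LSGC", "AWAC"), 1)))
    expect_equal(classify_topology(i$protein)$type, "I_CAND")
    expect_equal(classify_topology(o$protein)$type, "O_CAND")
    expect_equal(classify_topology(u$protein)$type, "U_CAND")
  }
})

test_that("periplasmic domains are delimited per topology type", {
  # o-spanin: lipoylated Cys excluded; 60 aa with Cys at residue 21 leaves
  # a 39 aa mature periplasmic domain
  o_like <- paste0("MAKN", strrep("L", 8), "SAHGS", "LSGC", strrep("P", 39))
  expect_equal(nchar(o_like), 60L)
  call <- classify_topology(o_like)
  expect_equal(call$type, "O_CAND")
  expect_equal(call$lipobox$cys_index, 20L)   # residue 21, 0-based 20
  pd <- periplasmic_domain(call, o_like)
  expect_equal(pd$interval, c(21L, 60L))
  expect_equal(nchar(pd$seq), 39L)
  expect_equal(pd$seq, strrep("P", 39))

  # i-spanin: everything after the TMD
  i_like <- paste0("MKRS", strrep("L", 21), strrep("Q", 100))
  ic <- classify_topology(i_like)
  pd_i <- periplasmic_domain(ic, i_like)
  expect_equal(pd_i$interval[2], nchar(i_like))
  expect_equal(pd_i$interval[1], ic$tmds$end[1])
  # the detected TMD boundary sits near the end of the planted block
  expect_lt(abs(pd_i$interval[1] - 25L), 6L)
  expect_true(grepl("Q$", pd_i$seq))
  expect_true(grepl("^L*Q+$", pd_i$seq))

  # u-spanin by definition: between the Cys and the anchor TMD
  fake_u <- structure(list(type = "U_CAND",
                           tmds = data.frame(start = 99L, end = 121L,
                                             mean_hydropathy = 3),
                           lipobox = list(cys_index = 21L, motif = "LSGC",
                                          mode = "strict"),
                           periplasmic = c(22L, 99L), evidence = ""),
                      class = "topology_call")
  aa <- random_protein(130)
  pd_u <- periplasmic_domain(fake_u, aa)
  expect_equal(pd_u$interval, c(22L, 99L))
  expect_equal(pd_u$seq, substr(aa, 23, 99))

  # degenerate interval errors
  bad <- fake_u; bad$periplasmic <- c(50L, 50L)
  expect_error(periplasmic_domain(bad, aa), "empty")
})

test_that("external topology override tables convert coordinates on read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\ttmd_start\ttmd_end\tcys_index",
               "p1\t6\t26\tNA",
               "p2\tNA\tNA\t19",
               "p3\t90\t110\t19"), f)
  ov <- read_topology_overrides(f)
  expect_equal(names(ov), c("p1", "p2", "p3"))
  expect_equal(ov$p1$tmds$start, 5L)     # 1-based file -> 0-based internal
  expect_equal(ov$p1$tmds$end, 26L)
  expect_true(is.na(ov$p1$cys_index))
  expect_equal(ov$p2$cys_index, 18L)
  expect_equal(nrow(ov$p2$tmds), 0L)
  expect_equal(ov$p3$cys_index, 18L)
  expect_error(read_topology_overrides({
    g <- withr::local_tempfile(fileext = ".tsv")
    writeLines("protein_id\tfoo", g); g
  }), "lacks column")
})
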