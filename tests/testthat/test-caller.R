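test_that("architecture classification reproduces the canonical cases", {
  # fully embedded (lambda-like)
  a <- classify_architecture(c(100, 700), c(300, 600))
  expect_equal(a, list(label = "embedded", overlap_bp = 300L, gap_bp = 0L))
  # 70 bp overlap (T5-like)
  b <- classify_architecture(c(100, 400), c(330, 520))
  expect_equal(b$label, "overlapped")
  expect_equal(b$overlap_bp, 70L)
  # an 8 bp overlap still counts as separated
  d <- classify_architecture(c(100, 400), c(392, 600), sep_threshold = 10)
  expect_equal(d$label, "separated")
  expect_equal(d$overlap_bp, 8L)
  expect_equal(d$gap_bp, 0L)
  # widely separated with a 700 bp gap
  e <- classify_architecture(c(100, 400), c(1100, 1300))
  expect_equal(e$label, "separated")
  expect_equal(e$gap_bp, 700L)
  # o upstream of i is an orientation error
  expect_error(classify_architecture(c(1000, 1300), c(100, 400)),
               "orientation")
})

test_that("architecture labels partition pairings and respect invariants", {
  set.seed(13)
  for (k in 1:200) {
    is <- sample(0:2000, 1); ilen <- sample(150:900, 1)
    os <- is + sample(0:1500, 1); olen <- sample(120:600, 1)
    a <- classify_architecture(c(is, is + ilen), c(os, os + olen))
    expect_true(a$label %in% c("embedded", "overlapped", "separated"))
    if (a$label == "separated") expect_lte(a$overlap_bp, 10L)
    if (a$label == "overlapped") expect_gt(a$overlap_bp, 10L)
    if (a$label == "embedded") {
      rel <- relative_position(c(is, is + ilen), c(os, os + olen))
      expect_lte(rel$end_frac, 1)
    }
    # invariance under joint translation
    sh <- sample(1:5000, 1)
    a2 <- classify_architecture(c(is, is + ilen) + sh,
                                c(os, os + olen) + sh)
    expect_equal(a, a2)
  }
})

test_that("frame offsets follow (o_start - i_start) mod 3", {
  expect_equal(frame_offset(100, 272), 1L)
  expect_equal(frame_offset(100, 273), -1L)
  expect_error(frame_offset(100, 274), "same-frame")
})

test_that("relative o-gene position is expressed in units of L", {
  r <- relative_position(c(0, 600), c(270, 570))
  expect_equal(r$start_frac, 0.45)
  expect_equal(r$end_frac, 0.95)
  r2 <- relative_position(c(50, 650), c(50, 650))
  expect_equal(unlist(r2), c(start_frac = 0, end_frac = 1))
  r3 <- relative_position(c(0, 300), c(1000, 1200))
  expect_gt(r3$start_frac, 1)
})

test_that("pairing is greedy by gap with deterministic tie handling", {
  i_tab <- data.frame(id = c("i1", "i2"), rd_start = c(0L, 2000L),
                      rd_end = c(300L, 2300L), strand = "+",
                      stringsAsFactors = FALSE)
  o_tab <- data.frame(id = "o1", rd_start = 350L, rd_end = 550L,
                      strand = "+", stringsAsFactors = FALSE)
  p <- pair_components(i_tab, o_tab)
  expect_equal(nrow(p), 1L)
  expect_equal(p$i_id, "i1")
  expect_equal(p$gap, 50L)
  expect_false(p$ambiguous)

  # exact distance tie between two i candidates: flagged ambiguous
  i_tie <- data.frame(id = c("iA", "iB"), rd_start = c(0L, 100L),
                      rd_end = c(300L, 400L), strand = "+",
                      stringsAsFactors = FALSE)
  o_mid <- data.frame(id = "o1", rd_start = 450L, rd_end = 600L,
                      strand = "+", stringsAsFactors = FALSE)
  # distances: gap to iA = 150, to iB = 50 -> iB; then make a true tie
  p2 <- pair_components(i_tie, o_mid)
  expect_equal(p2$i_id, "iB")
  i_tie2 <- data.frame(id = c("iA", "iB"), rd_start = c(0L, 100L),
                       rd_end = c(400L, 400L), strand = "+",
                       stringsAsFactors = FALSE)
  p3 <- pair_components(i_tie2, o_mid)
  expect_equal(nrow(p3), 1L)
  expect_true(p3$ambiguous)
  expect_equal(p3$i_id, "iB")   # nearest upstream start on a tie

  # out-of-reach lipoprotein stays unpaired
  o_far <- data.frame(id = "o1", rd_start = 5000L, rd_end = 5200L,
                      strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(pair_components(i_tab[1, ], o_far)), 0L)

  # overlapping same-frame combinations are not eligible
  o_same <- data.frame(id = "o1", rd_start = 150L, rd_end = 450L,
                       strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(pair_components(i_tab[1, ], o_same)), 0L)
  o_shift <- data.frame(id = "o1", rd_start = 151L, rd_end = 451L,
                        strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(pair_components(i_tab[1, ], o_shift)), 1L)
})

test_that("the full caller round-trips planted systems of each architecture", {
  sim <- simulate_genome(sim_spec(seed = 101))
  rep <- call_spanins(sim$genome)
  ev <- evaluate_calls(rep, sim$truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$architecture_accuracy, 1)
  expect_equal(ev$frame_accuracy, 1)
  expect_equal(rep$verdict, "spanins_found")
  # the planted lone lipoprotein surfaces as an unpaired lipoprotein
  expect_gte(length(rep$lipoproteins_without_partner), 1L)
})

test_that("a genome with only a u-spanin yields one unimolecular system", {
  sim <- simulate_genome(sim_spec(n_embedded = 0, n_overlapped = 0,
                                  n_separated = 0, n_unimolecular = 1,
                                  n_decoys = 0, seed = 5))
  rep <- call_spanins(sim$genome)
  expect_equal(length(rep$systems), 1L)
  expect_equal(rep$systems[[1]]$architecture, "unimolecular")
  expect_null(rep$systems[[1]]$i)
})

test_that("random non-coding sequence yields a no-spanins verdict", {
  set.seed(17)
  g <- genome_record("noise",
                     paste(sample(c("A", "C", "G", "T"), 4000, TRUE),
                           collapse = ""))
  rep <- call_spanins(g)
  expect_equal(rep$verdict, "no_spanins")
  expect_equal(length(rep$systems), 0L)
})

test_that("the report flattens to the spanin-table schema", {
  sim <- simulate_genome(sim_spec(seed = 23))
  rep <- call_spanins(sim$genome)
  df <- as.data.frame(rep, host = "Escherichia coli")
  expect_true(all(c("phage_name", "architecture", "component_role",
                    "gene_start", "gene_end", "strand", "sd_sequence",
                    "primary_structure", "periplasmic_sequence",
                    "length_aa", "periplasmic_cys_count", "lipobox",
                    "frame_offset", "overlap_bp", "rel_start_frac",
                    "rel_end_frac", "confidence") %in% names(df)))
  expect_equal(sum(df$component_role == "i"), sum(df$component_role == "o"))
  # coordinates are 1-based inclusive and frame-consistent
  expect_true(all((df$gene_end - df$gene_start + 1L) %% 3L == 0L))
  expect_true(all(df$gene_start >= 1L & df$gene_end <= sim$genome$length))
  # o/u rows carry a lipobox, i rows do not
  expect_true(all(!is.na(df$lipobox[df$component_role %in% c("o", "u")])))
  expect_true(all(is.na(df$lipobox[df$component_role == "i"])))
})

test_that("the all-frame lipoprotein scan certifies presence and absence", {
  # an embedded o gene is invisible to annotation but found by the scan
  sim <- simulate_genome(sim_spec(n_embedded = 1, n_overlapped = 0,
                                  n_separated = 0, n_unimolecular = 0,
                                  n_decoys = 0, seed = 31))
  hits <- all_frame_lipoprotein_scan(sim$genome)
  o_row <- sim$truth[sim$truth$role == "o", ]
  expect_true(any(hits$strand == o_row$strand &
                    abs(hits$start - o_row$start) <= 3L &
                    abs(hits$end - o_row$end) <= 3L))

  # a lipoprotein-free genome scans empty
  set.seed(47)
  g0 <- genome_record("clean",
                      paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                            collapse = ""))
  expect_equal(nrow(all_frame_lipoprotein_scan(g0)), 0L)

  # genomes over 50 kb are refused without force
  big <- genome_record("big", strrep("ACGT", 15001))
  expect_error(all_frame_lipoprotein_scan(big), "50 kb")
})
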