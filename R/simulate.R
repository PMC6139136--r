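# Synthetic phage genomes with planted spanin systems and truth tables.
# The generator emulates the genomic situations the search protocol must
# handle: o-spanin genes embedded in the +1/-1 frame of the i-spanin
# (reconciled through synonymous-codon space so both frames encode valid
# signals), partial overlaps, separated pairs, unimolecular spanins, decoy
# genes, deliberately missing annotation for embedded o genes, and
# perturbed start codons.

SYN_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

rev_translate <- function(aa) {
  res <- strsplit(aa, "")[[1]]
  paste(vapply(res, function(a) {
    syn <- SYN_CODONS[[a]]
    syn[sample.int(length(syn), 1L)]
  }, ""), collapse = "")
}

sample_aa <- function(n, alphabet, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# residue pools: hydrophilic (periplasmic tails), transmembrane blocks,
# proline/serine-rich o-spanin tails. None contain C or start-codon-capable
# residues (M/V/L) outside the transmembrane blocks, which keeps truncated
# in-frame siblings from mimicking a membrane signal.
POOL_HYDROPHILIC <- c("S", "T", "N", "Q", "E", "D", "K", "R", "G", "A", "P")
POOL_TMD <- c("L", "I", "V", "A", "F")
POOL_TMD_W <- c(0.4, 0.2, 0.2, 0.1, 0.1)
POOL_OTAIL <- c("P", "S", "Q", "N", "T", "G", "A", "E", "K", "D")
POOL_OTAIL_W <- c(0.2, 0.2, 0.1, 0.1, 0.1, 0.1, 0.05, 0.05, 0.05, 0.05)

SD_SPACER <- "CAACTAT"                 # 7 nt, no start codon, no stop
SD_CASSETTE <- paste0("AGGAGG", SD_SPACER)  # planted ribosome-binding site

plant_cys <- function(tail, positions) {
  if (!length(positions)) return(tail)
  res <- strsplit(tail, "")[[1]]
  if (any(positions < 1L | positions > length(res))) {
    stop("infeasible cysteine plan: position outside tail", call. = FALSE)
  }
  res[positions] <- "C"
  paste(res, collapse = "")
}

random_tail <- function(n, alphabet, prob = NULL, max_try = 50L) {
  for (k in seq_len(max_try)) {
    t <- sample_aa(n, alphabet, prob)
    # no hydrophobic run that could read as an h-region or TMD fragment
    if (!grepl("[ACFILMV]{5}", t)) return(t)
  }
  gsub("(....)A", "\\1S", t)  # last resort: break runs
}

signal_peptide <- function(lipobox) {
  stopifnot(nchar(lipobox) == 4L, substr(lipobox, 4L, 4L) == "C")
  # residue 2 is drawn from amino acids with G-initial codons so that the
  # -1 reading frame across the start codon (T-G-x) can avoid stops and
  # cysteines when the gene is reconciled into an i-spanin frame
  paste0("M", sample_aa(1L, c("A", "G", "E", "D")), "K",
         sample_aa(1L, c("K", "R", "N", "S")),
         sample_aa(9L, POOL_TMD, POOL_TMD_W), "SA", lipobox)
}

#' Build one synthetic spanin (or decoy) protein and gene
#'
#' i-spanin: Met + charged N-tail + 21-residue hydrophobic block +
#' hydrophilic periplasmic tail with planted cysteines. o-spanin:
#' lipoprotein signal (charged n-region, hydrophobic core, chosen lipobox)
#' + Pro/Ser-rich periplasmic tail with planted cysteines. u-spanin: the
#' o-spanin signal plus a cysteine-free periplasmic tail and a C-terminal
#' hydrophobic block. Codons are drawn uniformly among synonyms.
#'
#' @param role "i", "o" or "u".
#' @param params list: `tail_len` (periplasmic tail length, aa), `cys`
#'   (integer vector of planted Cys positions within the periplasmic tail;
#'   must be empty for "u"), `lipobox` (motif for o/u, default "LSGC"),
#'   `min_abs_cys` for i-spanins: planted Cys are kept at or beyond this
#'   absolute residue (default 41, outside the lipobox search window).
#' @return list with `nt` (coding sequence including stop codon), `protein`,
#'   `role`, `cys` (periplasmic positions), `lipobox`, `peri_len` and the
#'   signal/anchor geometry.
#' @export
make_spanin_gene <- function(role = c("i", "o", "u"), params = list()) {
  role <- match.arg(role)
  for (try in seq_len(60L)) {
    g <- make_spanin_gene_once(role, params)
    if (validate_planted(g, role)) return(g)
  }
  stop("could not construct a ", role, "-spanin gene that classifies to ",
       "its planted type", call. = FALSE)
}

make_spanin_gene_once <- function(role, params = list()) {
  p <- utils::modifyList(list(tail_len = NULL, cys = integer(0),
                              lipobox = "LSGC", min_abs_cys = 41L), params)
  if (!is.null(p$tail_len) && p$tail_len < 1L) {
    stop("spec error: zero-length periplasmic tail", call. = FALSE)
  }
  if (length(p$cys) && !is.null(p$tail_len) &&
      length(p$cys) > p$tail_len) {
    stop("spec error: more cysteines than tail residues", call. = FALSE)
  }
  if (role == "i") {
    tail_len <- if (is.null(p$tail_len)) sample(70:110, 1L) else p$tail_len
    head <- paste0("M", "K", sample_aa(3L, c("S", "R", "N", "T")),
                   sample_aa(21L, POOL_TMD, POOL_TMD_W))
    head_len <- nchar(head)           # 26
    cys_pos <- p$cys
    if (length(cys_pos)) {
      lo <- max(1L, p$min_abs_cys - head_len)
      if (any(cys_pos < lo)) cys_pos <- lo + (cys_pos - min(cys_pos))
      cys_pos <- pmin(cys_pos, tail_len)
    }
    tail <- plant_cys(random_tail(tail_len, POOL_HYDROPHILIC), cys_pos)
    protein <- paste0(head, tail)
    out <- list(role = role, protein = protein, cys = sort(unique(cys_pos)),
                lipobox = NA_character_, head_len = head_len,
                peri_len = tail_len)
  } else if (role == "o") {
    tail_len <- if (is.null(p$tail_len)) sample(40:65, 1L) else p$tail_len
    if (length(p$cys) > tail_len) {
      stop("spec error: more cysteines than tail residues", call. = FALSE)
    }
    sig <- signal_peptide(p$lipobox)  # 19 aa, Cys at 19
    tail <- plant_cys(random_tail(tail_len, POOL_OTAIL, POOL_OTAIL_W), p$cys)
    protein <- paste0(sig, tail)
    out <- list(role = role, protein = protein, cys = sort(unique(p$cys)),
                lipobox = p$lipobox, head_len = nchar(sig),
                peri_len = tail_len)
  } else {
    tail_len <- if (is.null(p$tail_len)) sample(35:60, 1L) else p$tail_len
    if (length(p$cys)) {
      stop("spec error: u-spanins carry no periplasmic cysteines",
           call. = FALSE)
    }
    sig <- signal_peptide(p$lipobox)
    tail <- random_tail(tail_len, POOL_HYDROPHILIC)
    anchor <- paste0(sample_aa(21L, POOL_TMD, POOL_TMD_W), "K")
    protein <- paste0(sig, tail, anchor)
    out <- list(role = role, protein = protein, cys = integer(0),
                lipobox = p$lipobox, head_len = nchar(sig),
                peri_len = tail_len)
  }
  out$nt <- paste0(rev_translate(out$protein), "TAA")
  out
}

# --- embedded / overlapped reconciliation -------------------------------

derived_prefix_len <- function(frame) if (frame == 1L) 13L else 14L

# assemble the nt that the i-spanin reading frame must read through:
# [pad][SD][spacer][o gene incl stop]
derived_nt <- function(o_nt, frame, pad_base = "C") {
  paste0(if (frame == -1L) pad_base else "", SD_CASSETTE, o_nt)
}

i_frame_violations <- function(aa_vec, upto = length(aa_vec),
                               forbid_cys = TRUE) {
  idx <- seq_len(upto)
  bad <- aa_vec[idx] == "*"
  if (forbid_cys) bad <- bad | aa_vec[idx] == "C"
  r <- rle(aa_vec[idx] %in% HYDROPHOBIC_SET)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= 5L)) {
    bad[starts[k]:ends[k]] <- TRUE
  }
  which(bad)
}

# resample the o-gene codons that overlap given nt positions of `derived`
resample_covering <- function(o_codons, o_aa, nt_positions, o_offset,
                              frozen = integer(0)) {
  touched <- unique(((nt_positions - o_offset - 1L) %/% 3L) + 1L)
  touched <- touched[touched >= 1L & touched <= length(o_codons)]
  touched <- setdiff(touched, frozen)
  for (j in touched) {
    syn <- SYN_CODONS[[o_aa[j]]]
    o_codons[j] <- syn[sample.int(length(syn), 1L)]
  }
  o_codons
}

# Reconcile an o gene into the i reading frame: resample synonymous o
# codons until the i-frame translation of [SD][o gene] has no stop, no Cys
# and no hydrophobic run of 5+, over the first `upto_nt` nucleotides.
reconcile_frames <- function(o_gene, frame, upto_nt = NULL,
                             frozen = integer(0), stop_at = NULL,
                             max_iter = 400L) {
  o_aa <- strsplit(paste0(o_gene$protein, "*"), "")[[1]]
  n_cod <- length(o_aa)
  o_codons <- substring(o_gene$nt, seq(1L, 3L * n_cod - 2L, 3L),
                        seq(3L, 3L * n_cod, 3L))
  off <- derived_prefix_len(frame)
  for (it in seq_len(max_iter)) {
    d <- derived_nt(paste(o_codons, collapse = ""), frame)
    n3 <- (nchar(d) %/% 3L) * 3L
    aa <- strsplit(translate_nt(substr(d, 1L, n3)), "")[[1]]
    upto <- if (is.null(upto_nt)) length(aa) else min(length(aa), upto_nt %/% 3L)
    viol <- i_frame_violations(aa, upto)
    if (!is.null(stop_at)) viol <- setdiff(viol, stop_at)
    if (!length(viol)) {
      return(list(o_codons = o_codons, derived = d, ok = TRUE))
    }
    nt_pos <- as.vector(outer((viol - 1L) * 3L + 1L, 0:2, `+`))
    o_codons <- resample_covering(o_codons, o_aa, nt_pos, off, frozen)
  }
  list(ok = FALSE)
}

# force the i-frame codon at index t of `derived` to be a stop by
# re-choosing synonyms of the o codons it overlaps (o protein unchanged)
force_i_stop <- function(o_gene, frame, t) {
  o_aa <- strsplit(paste0(o_gene$protein, "*"), "")[[1]]
  n_cod <- length(o_aa)
  o_codons <- substring(o_gene$nt, seq(1L, 3L * n_cod - 2L, 3L),
                        seq(3L, 3L * n_cod, 3L))
  off <- derived_prefix_len(frame)
  nt_pos <- (t - 1L) * 3L + 1:3
  js <- unique(((nt_pos - off - 1L) %/% 3L) + 1L)
  js <- js[js >= 1L & js <= n_cod]
  if (!length(js)) return(NULL)
  syn_sets <- lapply(js, function(j) SYN_CODONS[[o_aa[j]]])
  combos <- expand.grid(syn_sets, stringsAsFactors = FALSE)
  combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
  for (r in seq_len(nrow(combos))) {
    trial <- o_codons
    trial[js] <- unlist(combos[r, ])
    d <- derived_nt(paste(trial, collapse = ""), frame)
    cod <- substr(d, nt_pos[1], nt_pos[3])
    if (cod %in% STOP_CODONS) {
      g <- o_gene
      g$nt <- paste(trial, collapse = "")
      return(list(gene = g, frozen = js))
    }
  }
  NULL
}

build_embedded <- function(frame, i_cys, o_cys, lipobox, max_outer = 25L) {
  for (try in seq_len(max_outer)) {
    o <- make_spanin_gene("o", list(tail_len = sample(39:49, 1L),
                                    cys = o_cys, lipobox = lipobox))
    head_aa <- sample(52:62, 1L)
    free_a <- head_aa - 26L
    i_stub <- make_spanin_gene("i", list(tail_len = free_a, cys = i_cys))
    head_nt <- substr(i_stub$nt, 1L, 3L * head_aa)  # no stop
    if (grepl("AGGAGG", head_nt, fixed = TRUE)) next
    rec <- reconcile_frames(o, frame)
    if (!rec$ok) next
    dl <- nchar(rec$derived)
    pad2 <- strrep("C", (3L - dl %% 3L) %% 3L)
    free_c_aa <- sample(9:13, 1L)
    free_c <- rev_translate(random_tail(free_c_aa, POOL_HYDROPHILIC))
    i_nt <- paste0(head_nt, rec$derived, pad2, free_c, "TAA")
    i_protein <- translate_nt(substr(i_nt, 1L, nchar(i_nt) - 3L))
    if (grepl("\\*", i_protein)) next
    i_gene <- list(role = "i", protein = i_protein, nt = i_nt,
                   cys = i_stub$cys, lipobox = NA_character_,
                   head_len = 26L, peri_len = nchar(i_protein) - 26L)
    # planted cysteine count must survive assembly (frame reconciliation
    # and codon-boundary padding must not mint extra Cys)
    if (count_cys(substr(i_protein, 27L, nchar(i_protein))) !=
        length(i_gene$cys)) next
    o_gene <- o
    o_gene$nt <- substr(rec$derived, derived_prefix_len(frame) + 1L,
                        nchar(rec$derived))
    o_start <- 3L * head_aa + derived_prefix_len(frame)
    if (!validate_planted(i_gene, "i") ||
        !validate_planted(o_gene, "o")) next
    return(list(i = i_gene, o = o_gene, o_rel_start = o_start,
                i_len = nchar(i_nt)))
  }
  stop("embedded construction failed after ", max_outer, " attempts",
       call. = FALSE)
}

build_overlapped <- function(frame, i_cys, o_cys, lipobox, max_outer = 40L) {
  off <- derived_prefix_len(frame)
  for (try in seq_len(max_outer)) {
    o <- make_spanin_gene("o", list(tail_len = sample(45:65, 1L),
                                    cys = o_cys, lipobox = lipobox))
    o_nt_len <- nchar(o$nt)
    # candidate i-frame codon indices t with overlap v = 3t - off in
    # [30, 200] and the o gene extending at least 30 nt beyond the i stop
    t_lo <- as.integer(ceiling((30L + off) / 3))
    t_hi <- (min(200L, o_nt_len - 30L) + off) %/% 3L
    if (t_hi < t_lo) next
    ts <- seq.int(t_lo, t_hi)
    forced <- NULL
    for (t in sample(ts)) {
      forced <- force_i_stop(o, frame, t)
      if (!is.null(forced)) { t_stop <- t; break }
    }
    if (is.null(forced)) next
    rec <- reconcile_frames(forced$gene, frame,
                            upto_nt = 3L * t_stop,
                            frozen = forced$frozen, stop_at = t_stop)
    if (!rec$ok) next
    # re-check the forced stop survived
    cod <- substr(rec$derived, 3L * (t_stop - 1L) + 1L, 3L * t_stop)
    if (!(cod %in% STOP_CODONS)) next
    head_aa <- sample(52:62, 1L)
    free_a <- head_aa - 26L
    i_stub <- make_spanin_gene("i", list(tail_len = free_a, cys = i_cys))
    head_nt <- substr(i_stub$nt, 1L, 3L * head_aa)
    if (grepl("AGGAGG", head_nt, fixed = TRUE)) next
    i_nt <- paste0(head_nt, substr(rec$derived, 1L, 3L * t_stop))
    i_protein <- translate_nt(substr(i_nt, 1L, nchar(i_nt) - 3L))
    if (grepl("\\*", i_protein)) next
    i_gene <- list(role = "i", protein = i_protein, nt = i_nt,
                   cys = i_stub$cys, lipobox = NA_character_,
                   head_len = 26L, peri_len = nchar(i_protein) - 26L)
    if (count_cys(substr(i_protein, 27L, nchar(i_protein))) !=
        length(i_gene$cys)) next
    o_gene <- forced$gene
    o_gene$nt <- substr(rec$derived, off + 1L, off + o_nt_len)
    if (!validate_planted(i_gene, "i") ||
        !validate_planted(o_gene, "o")) next
    return(list(i = i_gene, o = o_gene, o_rel_start = 3L * head_aa + off,
                i_len = nchar(i_nt), overlap = 3L * t_stop - off))
  }
  stop("overlapped construction failed after ", max_outer, " attempts",
       call. = FALSE)
}

validate_planted <- function(gene, role,
                             params = topology_params()) {
  type <- classify_topology(gene$protein, params)$type
  switch(role,
         i = type == "I_CAND",
         o = type == "O_CAND",
         u = type == "U_CAND")
}

#' Simulation specification
#'
#' The synthetic study conditions: how many systems of each architecture to
#' plant, the +1/-1 frame mix among overlapping systems, the lipobox motif
#' mix (mostly consensus boxes with a minority of AWAC-class boxes, as in
#' the surveyed databases), and the per-system cysteine plan.
#'
#' @param n_embedded,n_overlapped,n_separated,n_unimolecular,n_decoys
#'   system/decoy counts per genome.
#' @param frame_mix fraction of +1 frames among overlapping systems.
#' @param lipobox_mix named weights over lipobox motifs.
#' @param cys_plan `NULL` (sampled: i-spanin 0-3 Cys, o-spanin 0-2, with
#'   the (0,2) combination most common) or a 2-column matrix of
#'   (i_count, o_count) rows recycled over two-component systems.
#' @param seed integer seed; the generator is deterministic for a fixed
#'   [sim_spec()].
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_embedded = 1L, n_overlapped = 1L, n_separated = 1L,
                     n_unimolecular = 1L, n_decoys = 5L, frame_mix = 0.5,
                     lipobox_mix = c(LSGC = 0.6, LAGC = 0.2, AWAC = 0.2),
                     cys_plan = NULL, seed = 1L) {
  stopifnot(n_embedded >= 0, n_overlapped >= 0, n_separated >= 0,
            n_unimolecular >= 0, n_decoys >= 0,
            frame_mix >= 0, frame_mix <= 1,
            abs(sum(lipobox_mix) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_spec")
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sample_lipobox <- function(mix) {
  names(mix)[sample.int(length(mix), 1L, prob = mix)]
}

draw_cys_counts <- function(spec, k) {
  if (!is.null(spec$cys_plan)) {
    m <- spec$cys_plan
    return(m[((k - 1L) %% nrow(m)) + 1L, ])
  }
  c(sample(0:3, 1L, prob = c(0.35, 0.3, 0.25, 0.1)),
    sample(0:2, 1L, prob = c(0.2, 0.3, 0.5)))
}

#' Simulate a phage genome with planted spanin systems
#'
#' Lays out the requested systems and decoys with random spacers, places
#' each cassette on a random strand, plants a Shine-Dalgarno site before
#' every gene (including, for embedded and overlapped o genes, inside the
#' i-spanin coding sequence), annotates everything except embedded o genes,
#' and perturbs 20% of annotated start codons to an alternative in-frame
#' start to exercise start-site recovery. Deterministic for a fixed spec.
#'
#' @param spec a [sim_spec()].
#' @return list with `genome` (a [genome_record()]) and `truth` (data frame
#'   of truth records: architecture, forward gene intervals including the
#'   stop codon, strand, frame offset, lipobox, planted periplasmic
#'   cysteine counts and periplasmic lengths, plus the planted proteins).
#' @export
simulate_genome <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(spec$seed)

  cassettes <- list()
  add <- function(x) cassettes[[length(cassettes) + 1L]] <<- x

  # decoy mix: one unpaired lipoprotein (placed first), then alternating
  # soluble and polytopic membrane decoys
  if (spec$n_decoys >= 1L) add(decoy_cassette("lipoprotein"))
  if (spec$n_decoys >= 2L) {
    kinds <- rep(c("soluble", "membrane"), length.out = spec$n_decoys - 1L)
    for (k in kinds) add(decoy_cassette(k))
  }
  arch_list <- c(rep("embedded", spec$n_embedded),
                 rep("overlapped", spec$n_overlapped),
                 rep("separated", spec$n_separated),
                 rep("unimolecular", spec$n_unimolecular))
  sysno <- 0L
  for (arch in arch_list) {
    sysno <- sysno + 1L
    add(system_cassette(arch, spec, sysno))
  }
  # keep the unpaired lipoprotein first; shuffle the rest
  if (length(cassettes) > 1L) {
    first_lipo <- spec$n_decoys >= 1L
    rest <- if (first_lipo) cassettes[-1L] else cassettes
    rest <- rest[sample.int(length(rest))]
    cassettes <- if (first_lipo) c(cassettes[1L], rest) else rest
  }

  seq_parts <- list(random_nt(sample(100:200, 1L)))
  pos <- nchar(seq_parts[[1L]])
  feats <- empty_features()
  truth <- list()
  for (cs in cassettes) {
    strand <- if (cs$force_plus) "+" else sample(c("+", "-"), 1L)
    nt <- cs$nt
    n <- nchar(nt)
    if (strand == "-") nt <- reverse_complement(nt)
    # genes: local reading-direction intervals within the cassette
    for (g in cs$genes) {
      if (strand == "+") {
        fs <- pos + g$start; fe <- pos + g$end
      } else {
        fs <- pos + n - g$end; fe <- pos + n - g$start
      }
      if (g$annotate) {
        feats <- rbind(feats, data.frame(
          start = fs, end = fe, strand = strand, kind = "CDS",
          label = g$label, stringsAsFactors = FALSE))
      }
      if (!is.null(g$truth_row)) {
        tr <- g$truth_row
        tr$strand <- strand
        tr$start <- fs; tr$end <- fe
        truth[[length(truth) + 1L]] <- tr
      }
    }
    seq_parts[[length(seq_parts) + 1L]] <- nt
    pos <- pos + n
    sp <- random_nt(sample(120:350, 1L))
    seq_parts[[length(seq_parts) + 1L]] <- sp
    pos <- pos + nchar(sp)
  }
  seq_parts[[length(seq_parts) + 1L]] <- random_nt(sample(100:200, 1L))
  genome_seq <- paste(unlist(seq_parts), collapse = "")

  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  truth_df <- make_truth_df(truth)

  # perturb 20% of annotated start codons to an in-frame alternative
  if (nrow(feats)) {
    idx <- which(stats::runif(nrow(feats)) < 0.2)
    for (i in idx) {
      feats[i, ] <- perturb_start(feats[i, ], genome_seq)
    }
  }
  genome <- genome_record(sprintf("SIMPHAGE_%06d", spec$seed), genome_seq,
                          feats, host = "synthetic")
  list(genome = genome, truth = truth_df)
}

make_truth_df <- function(truth) {
  if (is.null(truth)) {
    return(data.frame(system_id = integer(0), architecture = character(0),
                      role = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame_offset = integer(0), lipobox = character(0),
                      cys_count = integer(0), peri_len = integer(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  rownames(truth) <- NULL
  truth
}

truth_row <- function(system_id, architecture, role, frame_offset, gene) {
  data.frame(system_id = system_id, architecture = architecture,
             role = role, start = NA_integer_, end = NA_integer_,
             strand = NA_character_,
             frame_offset = frame_offset,
             lipobox = gene$lipobox,
             cys_count = length(gene$cys),
             peri_len = gene$peri_len,
             protein = gene$protein,
             stringsAsFactors = FALSE)
}

# a cassette is reading-direction nt plus gene descriptors with local
# 0-based half-open intervals (stop codon included)
gene_entry <- function(start, end, label, annotate, truth = NULL) {
  list(start = start, end = end, label = label, annotate = annotate,
       truth_row = truth)
}

decoy_cassette <- function(kind) {
  if (kind == "lipoprotein") {
    g <- make_spanin_gene("o", list(tail_len = sample(40:60, 1L),
                                    cys = integer(0), lipobox = "LSGC"))
    label <- "decoy_lipoprotein"
  } else if (kind == "soluble") {
    repeat {
      protein <- paste0("M", random_tail(sample(60:120, 1L),
                                         POOL_HYDROPHILIC))
      if (classify_topology(protein)$type == "NONE") break
    }
    g <- list(protein = protein, nt = paste0(rev_translate(protein), "TAA"))
    label <- "decoy_soluble"
  } else {
    repeat {
      protein <- paste0("M", "KR",
                        sample_aa(21L, POOL_TMD, POOL_TMD_W),
                        random_tail(30L, POOL_HYDROPHILIC),
                        sample_aa(21L, POOL_TMD, POOL_TMD_W),
                        random_tail(15L, POOL_HYDROPHILIC))
      if (classify_topology(protein)$type == "NONE") break
    }
    g <- list(protein = protein, nt = paste0(rev_translate(protein), "TAA"))
    label <- "decoy_membrane"
  }
  pre <- paste0("TAATT", SD_CASSETTE)   # in-frame stop, SD, spacer
  nt <- paste0(pre, g$nt)
  list(nt = nt, force_plus = kind == "lipoprotein",
       genes = list(gene_entry(nchar(pre), nchar(nt), label,
                               annotate = TRUE)))
}

system_cassette <- function(arch, spec, sysno) {
  pre <- paste0("TAATT", SD_CASSETTE)
  if (arch == "unimolecular") {
    u <- make_spanin_gene("u", list(lipobox = sample_lipobox(spec$lipobox_mix)))
    nt <- paste0(pre, u$nt)
    return(list(nt = nt, force_plus = FALSE, genes = list(
      gene_entry(nchar(pre), nchar(nt), sprintf("usp%02d", sysno),
                 annotate = TRUE,
                 truth = truth_row(sysno, "unimolecular", "u",
                                   NA_integer_, u)))))
  }
  cc <- draw_cys_counts(spec, sysno)
  i_cys <- if (cc[1] > 0L) sort(sample(20:60, cc[1])) else integer(0)
  o_cys <- if (cc[2] > 0L) sort(sample(3:35, cc[2])) else integer(0)
  lipobox <- sample_lipobox(spec$lipobox_mix)
  if (arch == "separated") {
    i <- make_spanin_gene("i", list(cys = i_cys))
    o <- make_spanin_gene("o", list(cys = o_cys, lipobox = lipobox))
    gap <- sample(20:880, 1L)
    mid <- paste0(random_nt(gap - 13L), SD_CASSETTE)
    nt <- paste0(pre, i$nt, mid, o$nt)
    i_iv <- c(nchar(pre), nchar(pre) + nchar(i$nt))
    o_iv <- c(i_iv[2] + gap, i_iv[2] + gap + nchar(o$nt))
    return(list(nt = nt, force_plus = FALSE, genes = list(
      gene_entry(i_iv[1], i_iv[2], sprintf("isp%02d", sysno), TRUE,
                 truth_row(sysno, arch, "i", NA_integer_, i)),
      gene_entry(o_iv[1], o_iv[2], sprintf("osp%02d", sysno), TRUE,
                 truth_row(sysno, arch, "o", NA_integer_, o)))))
  }
  frame <- if (stats::runif(1) < spec$frame_mix) 1L else -1L
  if (arch == "embedded") {
    b <- build_embedded(frame, i_cys, o_cys, lipobox)
  } else {
    b <- build_overlapped(frame, i_cys, o_cys, lipobox)
  }
  nt <- paste0(pre, b$i$nt)
  if (arch == "overlapped") {
    # append the part of the o gene that extends beyond the i stop
    nt <- paste0(nt, substr(b$o$nt, b$overlap + 1L, nchar(b$o$nt)))
  }
  i_iv <- c(nchar(pre), nchar(pre) + nchar(b$i$nt))
  o_iv <- c(nchar(pre) + b$o_rel_start,
            nchar(pre) + b$o_rel_start + nchar(b$o$nt))
  list(nt = nt, force_plus = FALSE, genes = list(
    gene_entry(i_iv[1], i_iv[2], sprintf("isp%02d", sysno), TRUE,
               truth_row(sysno, arch, "i", frame, b$i)),
    gene_entry(o_iv[1], o_iv[2], sprintf("osp%02d", sysno),
               annotate = arch == "overlapped",
               truth = truth_row(sysno, arch, "o", frame, b$o))))
}

perturb_start <- function(feat, genome_seq) {
  L <- nchar(genome_seq)
  if (feat$strand == "+") {
    nt <- substr(genome_seq, feat$start + 1L, feat$end)
  } else {
    nt <- reverse_complement(substr(genome_seq, feat$start + 1L, feat$end))
  }
  n <- nchar(nt)
  if (n < 64L) return(feat)
  cand <- seq(4L, n - 60L, by = 3L)
  codons <- substring(nt, cand, cand + 2L)
  ok <- which(codons %in% c("ATG", "GTG", "TTG"))
  if (!length(ok)) return(feat)
  shift <- cand[ok[1]] - 1L
  if (feat$strand == "+") feat$start <- feat$start + shift
  else feat$end <- feat$end - shift
  feat
}

#' Score a search report against the planted truth
#'
#' A called system matches a truth record when each component's gene
#' interval overlaps the corresponding truth interval by at least 90%
#' reciprocally, on the same strand.
#'
#' @param report a `spanin_report` from [call_spanins()].
#' @param truth truth data frame from [simulate_genome()].
#' @return list with `recall`, `precision`, `architecture_accuracy`,
#'   `frame_accuracy` (all in `[0, 1]`; vacuous ratios are 1) and the
#'   underlying counts.
#' @export
evaluate_calls <- function(report, truth) {
  truth_sys <- split(truth, truth$system_id)
  called <- report$systems
  reciprocal_ok <- function(a1, a2, b1, b2) {
    ov <- max(0L, min(a2, b2) - max(a1, b1))
    ov >= 0.9 * (a2 - a1) && ov >= 0.9 * (b2 - b1)
  }
  comp_match <- function(comp, row) {
    iv <- fwd_gene_interval(comp$orf)
    comp$orf$strand == row$strand && reciprocal_ok(iv[1], iv[2],
                                                   row$start, row$end)
  }
  n_truth <- length(truth_sys)
  matched_truth <- logical(n_truth)
  matched_called <- logical(length(called))
  arch_ok <- 0L; frame_eval <- 0L; frame_ok <- 0L
  for (ci in seq_along(called)) {
    s <- called[[ci]]
    for (ti in seq_len(n_truth)) {
      if (matched_truth[ti]) next
      tr <- truth_sys[[ti]]
      if (tr$architecture[1] == "unimolecular") {
        hit <- !is.null(s$u) && comp_match(s$u, tr[tr$role == "u", ])
      } else {
        hit <- !is.null(s$i) && !is.null(s$o) &&
          comp_match(s$i, tr[tr$role == "i", ]) &&
          comp_match(s$o, tr[tr$role == "o", ])
      }
      if (hit) {
        matched_truth[ti] <- TRUE
        matched_called[ci] <- TRUE
        if (s$architecture == tr$architecture[1]) arch_ok <- arch_ok + 1L
        tf <- tr$frame_offset[1]
        if (!is.na(tf)) {
          frame_eval <- frame_eval + 1L
          if (!is.na(s$frame_offset) && s$frame_offset == tf) {
            frame_ok <- frame_ok + 1L
          }
        }
        break
      }
    }
  }
  n_matched <- sum(matched_truth)
  ratio <- function(num, den) if (den == 0L) 1 else num / den
  list(recall = ratio(n_matched, n_truth),
       precision = ratio(sum(matched_called), length(called)),
       architecture_accuracy = ratio(arch_ok, n_matched),
       frame_accuracy = ratio(frame_ok, frame_eval),
       n_truth = n_truth, n_called = length(called),
       n_matched = n_matched, n_arch_correct = arch_ok,
       n_frame_eval = frame_eval, n_frame_correct = frame_ok)
}
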