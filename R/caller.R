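# Spanin calling: pairing of i/o candidates, architecture / reading-frame /
# relative-position classification, u-spanin calling, and the per-genome
# search report. All base-pair arithmetic is done in reading-direction
# coordinates; minus-strand systems are reflected before any comparison.

#' Classify the genetic architecture of a spanin gene pair
#'
#' Gene intervals are 0-based half-open in reading-direction coordinates,
#' stop codon included, with the i gene upstream. The o gene is `embedded`
#' when fully inside the i gene (alternate reading frame), `overlapped`
#' when the shared stretch exceeds `sep_threshold`, and `separated`
#' otherwise (small start/stop-codon overlaps up to the threshold still
#' count as separated, as in pairs sharing only 8 bp).
#'
#' @param i_interval,o_interval numeric length-2 vectors `c(start, end)`.
#' @param sep_threshold overlap (bp) at or below which a pair is still
#'   called separated; default 10.
#' @return list with `label`, `overlap_bp`, `gap_bp`.
#' @export
classify_architecture <- function(i_interval, o_interval,
                                  sep_threshold = 10L) {
  is <- i_interval[1]; ie <- i_interval[2]
  os <- o_interval[1]; oe <- o_interval[2]
  stopifnot(is < ie, os < oe)
  if (oe <= is || os < is) {
    stop("o gene upstream of i gene: orientation error", call. = FALSE)
  }
  overlap <- max(0L, min(ie, oe) - max(is, os))
  if (os >= is && oe <= ie) {
    return(list(label = "embedded", overlap_bp = oe - os, gap_bp = 0L))
  }
  if (overlap > sep_threshold) {
    return(list(label = "overlapped", overlap_bp = overlap, gap_bp = 0L))
  }
  list(label = "separated", overlap_bp = overlap,
       gap_bp = max(0L, os - ie))
}

#' Reading-frame offset of an overlapping o gene
#'
#' For genes that share DNA, `(o_start - i_start) mod 3` is 1 for the +1
#' frame and 2 for the -1 frame. A same-frame nested start is not a
#' distinct overlapping gene and raises an error.
#'
#' @param i_start,o_start gene starts in reading-direction coordinates.
#' @return `+1` or `-1` (integer).
#' @export
frame_offset <- function(i_start, o_start) {
  d <- (o_start - i_start) %% 3L
  if (d == 0L) {
    stop("same-frame overlap: not a distinct overlapping gene",
         call. = FALSE)
  }
  if (d == 1L) 1L else -1L
}

#' Position of the o gene relative to the i gene
#'
#' Expressed in units of L, the i gene length: embedded o-spanins
#' characteristically start at ~0.4-0.5 L and end at 0.9-1 L.
#'
#' @param i_interval,o_interval reading-direction intervals.
#' @return list with `start_frac`, `end_frac` (may exceed 1 for overlapped
#'   or separated pairs).
#' @export
relative_position <- function(i_interval, o_interval) {
  L <- i_interval[2] - i_interval[1]
  list(start_frac = (o_interval[1] - i_interval[1]) / L,
       end_frac = (o_interval[2] - i_interval[1]) / L)
}

#' Pair o-spanin candidates with i-spanin candidates
#'
#' Each o candidate is paired with the nearest same-strand i candidate that
#' starts at or before it (reading direction) and either overlaps it or
#' lies within `max_gap` bp. Pairing is greedy by ascending gap, ties by
#' ascending o start; each candidate is consumed by at most one pairing.
#' Overlapping same-frame combinations are not eligible. Exact distance
#' ties between two i candidates are resolved to the nearest upstream start
#' and flagged ambiguous.
#'
#' @param i_cands,o_cands data frames with reading-direction gene columns
#'   `rd_start`, `rd_end`, plus `strand` and an `id` column.
#' @param max_gap maximum intergenic distance (default 1000 bp, from the
#'   most extreme separated system known, at ~1 kb).
#' @return data frame of pairings: `i_id`, `o_id`, `gap`, `overlap`,
#'   `ambiguous`.
#' @export
pair_components <- function(i_cands, o_cands, max_gap = 1000L) {
  empty <- data.frame(i_id = character(0), o_id = character(0),
                      gap = integer(0), overlap = integer(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE)
  if (!nrow(i_cands) || !nrow(o_cands)) return(empty)
  edges <- list()
  for (oi in seq_len(nrow(o_cands))) {
    for (ii in seq_len(nrow(i_cands))) {
      if (o_cands$strand[oi] != i_cands$strand[ii]) next
      os <- o_cands$rd_start[oi]; oe <- o_cands$rd_end[oi]
      is <- i_cands$rd_start[ii]; ie <- i_cands$rd_end[ii]
      if (os < is) next
      overlap <- max(0L, min(ie, oe) - max(is, os))
      gap <- max(0L, os - ie)
      if (overlap == 0L && gap > max_gap) next
      if (overlap > 0L && (os - is) %% 3L == 0L) next  # same frame
      edges[[length(edges) + 1L]] <- data.frame(
        oi = oi, ii = ii, gap = gap, overlap = overlap,
        o_start = os, i_start = is, stringsAsFactors = FALSE)
    }
  }
  if (!length(edges)) return(empty)
  edges <- do.call(rbind, edges)
  edges <- edges[order(edges$gap, edges$o_start, -edges$i_start), ]
  used_o <- logical(nrow(o_cands)); used_i <- logical(nrow(i_cands))
  out <- empty
  for (k in seq_len(nrow(edges))) {
    e <- edges[k, ]
    if (used_o[e$oi] || used_i[e$ii]) next
    tie <- sum(edges$oi == e$oi & edges$gap == e$gap & !used_i[edges$ii]) > 1L
    used_o[e$oi] <- TRUE; used_i[e$ii] <- TRUE
    out <- rbind(out, data.frame(i_id = i_cands$id[e$ii],
                                 o_id = o_cands$id[e$oi],
                                 gap = e$gap, overlap = e$overlap,
                                 ambiguous = tie, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Caller configuration
#'
#' @param min_aa minimum ORF length (codons) for the recovery scan.
#' @param start_codons admissible start codons.
#' @param sep_threshold see [classify_architecture()].
#' @param max_gap see [pair_components()].
#' @param require_sd require Shine-Dalgarno evidence for candidates that
#'   are not backed by an annotated CDS (recovered purely from the
#'   six-frame scan). Annotation itself counts as evidence, so annotated
#'   genes are exempt.
#' @param topology list from [topology_params()].
#' @return list of configuration values.
#' @export
spanin_config <- function(min_aa = 40L,
                          start_codons = c("ATG", "GTG", "TTG"),
                          sep_threshold = 10L, max_gap = 1000L,
                          require_sd = TRUE,
                          topology = topology_params()) {
  as.list(environment())
}

# reading-direction gene interval (stop codon included) for a candidate
rd_gene_interval <- function(cand, genome_len) {
  if (cand$strand == "+") {
    c(cand$start, cand$end + 3L)
  } else {
    c(genome_len - cand$end, genome_len - cand$start + 3L)
  }
}

# forward-coordinate gene interval (stop codon included)
fwd_gene_interval <- function(cand) {
  if (cand$strand == "+") c(cand$start, cand$end + 3L)
  else c(cand$start - 3L, cand$end)
}

#' Search one genome for spanin systems
#'
#' Runs the full protocol: six-frame ORF enumeration (recovering genes that
#' annotation missed, including o-spanins embedded in alternate reading
#' frames of the i-spanin), per-segment start refinement guided by
#' membrane-signal validity and Shine-Dalgarno evidence, topology typing,
#' unimolecular-spanin calling, i/o pairing, and architecture / frame /
#' relative-position classification. Deterministic for a fixed
#' configuration.
#'
#' @param genome a [genome_record()].
#' @param config list from [spanin_config()].
#' @return object of class `spanin_report`: list with `genome_id`,
#'   `systems` (list of `spanin_system`), `lipoproteins_without_partner`,
#'   `candidates`, and `verdict` ("spanins_found" or "no_spanins").
#' @export
call_spanins <- function(genome, config = spanin_config()) {
  L <- genome$length
  cands <- scan_orfs(genome, min_aa = config$min_aa,
                     start_codons = config$start_codons)
  comp <- list()
  if (nrow(cands)) {
    # group candidates into stop-to-stop segments: same strand + same stop
    stop_key <- ifelse(cands$strand == "+",
                       paste0("+", cands$end), paste0("-", cands$start))
    cds <- genome$features[genome$features$kind == "CDS", , drop = FALSE]
    annotated_keys <- character(0)
    if (nrow(cds)) {
      annotated_keys <- ifelse(cds$strand == "+",
                               paste0("+", cds$end - 3L),
                               paste0("-", cds$start + 3L))
    }
    validator <- function(aa) {
      classify_topology(aa, config$topology)$type != "NONE"
    }
    for (key in unique(stop_key)) {
      sibs <- cands[stop_key == key, , drop = FALSE]
      best <- refine_start(sibs[1, ], sibs, validator)
      call <- classify_topology(best$aa_seq, config$topology)
      if (call$type == "NONE") next
      annotated <- key %in% annotated_keys
      if (!annotated && config$require_sd && is.na(best$sd_score)) next
      peri <- periplasmic_domain(call, best$aa_seq)
      comp[[length(comp) + 1L]] <- list(
        orf = best, topology = call, periplasmic_seq = peri$seq,
        annotated = annotated,
        role = switch(call$type, I_CAND = "i", O_CAND = "o", U_CAND = "u"))
    }
  }
  roles <- vapply(comp, `[[`, "", "role")
  ids <- sprintf("%s_cand%02d", genome$id, seq_along(comp))
  cand_table <- function(which) {
    idx <- which(roles == which)
    if (!length(idx)) {
      return(data.frame(id = character(0), rd_start = integer(0),
                        rd_end = integer(0), strand = character(0),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(idx, function(i) {
      iv <- rd_gene_interval(comp[[i]]$orf, L)
      data.frame(id = ids[i], rd_start = iv[1], rd_end = iv[2],
                 strand = comp[[i]]$orf$strand, stringsAsFactors = FALSE)
    }))
  }
  i_tab <- cand_table("i"); o_tab <- cand_table("o")
  pairs <- pair_components(i_tab, o_tab, config$max_gap)

  systems <- list()
  for (k in seq_len(nrow(pairs))) {
    ic <- comp[[match(pairs$i_id[k], ids)]]
    oc <- comp[[match(pairs$o_id[k], ids)]]
    i_iv <- rd_gene_interval(ic$orf, L)
    o_iv <- rd_gene_interval(oc$orf, L)
    arch <- classify_architecture(i_iv, o_iv, config$sep_threshold)
    fo <- if (arch$overlap_bp > 0L) frame_offset(i_iv[1], o_iv[1]) else NA_integer_
    rel <- relative_position(i_iv, o_iv)
    conf <- if (pairs$ambiguous[k] || ic$orf$confidence == "low" ||
                oc$orf$confidence == "low") "low" else "high"
    systems[[length(systems) + 1L]] <- structure(
      list(i = ic, o = oc, u = NULL, architecture = arch$label,
           overlap_bp = arch$overlap_bp, gap_bp = arch$gap_bp,
           frame_offset = fo, rel_start_frac = rel$start_frac,
           rel_end_frac = rel$end_frac, confidence = conf),
      class = "spanin_system")
  }
  for (i in which(roles == "u")) {
    systems[[length(systems) + 1L]] <- structure(
      list(i = NULL, o = NULL, u = comp[[i]], architecture = "unimolecular",
           overlap_bp = 0L, gap_bp = 0L, frame_offset = NA_integer_,
           rel_start_frac = NA_real_, rel_end_frac = NA_real_,
           confidence = if (comp[[i]]$orf$confidence == "low") "low"
                        else "high"),
      class = "spanin_system")
  }
  unpaired <- comp[which(roles == "o" & !(ids %in% pairs$o_id))]
  structure(list(genome_id = genome$id, systems = systems,
                 lipoproteins_without_partner = unpaired,
                 candidates = comp,
                 verdict = if (length(systems)) "spanins_found"
                           else "no_spanins"),
            class = "spanin_report")
}

#' @export
print.spanin_report <- function(x, ...) {
  cat("<spanin_report> ", x$genome_id, ": ", length(x$systems),
      " system(s), verdict ", x$verdict, "\n", sep = "")
  for (s in x$systems) {
    if (s$architecture == "unimolecular") {
      cat("  u-spanin, ", nchar(s$u$orf$aa_seq), " aa, lipobox ",
          s$u$topology$lipobox$motif, "\n", sep = "")
    } else {
      cat("  ", s$architecture, " 2CS: overlap ", s$overlap_bp,
          " bp, gap ", s$gap_bp, " bp, frame ",
          if (is.na(s$frame_offset)) "n/a" else sprintf("%+d", s$frame_offset),
          "\n", sep = "")
    }
  }
  if (length(x$lipoproteins_without_partner)) {
    cat("  ", length(x$lipoproteins_without_partner),
        " lipoprotein(s) without an i-spanin partner\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.spanin_report <- function(object, ...) {
  archs <- vapply(object$systems, `[[`, "", "architecture")
  out <- list(genome_id = object$genome_id, verdict = object$verdict,
              architecture_counts = table(archs),
              unpaired_lipoproteins =
                length(object$lipoproteins_without_partner))
  class(out) <- "summary.spanin_report"
  out
}

#' @export
print.summary.spanin_report <- function(x, ...) {
  cat("Genome:", x$genome_id, "-", x$verdict, "\n")
  print(x$architecture_counts)
  cat("Unpaired lipoproteins:", x$unpaired_lipoproteins, "\n")
  invisible(x)
}

#' Flatten a search report to the spanin-table schema
#'
#' One row per component, with 1-based inclusive gene coordinates, the
#' Shine-Dalgarno evidence, full and periplasmic sequences, periplasmic
#' cysteine count, lipobox (o/u only) and the system-level architecture,
#' frame and relative-position fields.
#'
#' @param x a `spanin_report`.
#' @param phage_name,host optional metadata columns.
#' @param ... unused.
#' @return data frame in the spanin-table schema.
#' @export
as.data.frame.spanin_report <- function(x, ..., phage_name = x$genome_id,
                                        host = NA_character_) {
  rows <- list()
  sys_id <- 0L
  for (s in x$systems) {
    sys_id <- sys_id + 1L
    comps <- Filter(Negate(is.null), list(i = s$i, o = s$o, u = s$u))
    for (role in names(comps)) {
      c0 <- comps[[role]]
      iv <- fwd_gene_interval(c0$orf)
      rows[[length(rows) + 1L]] <- data.frame(
        phage_name = phage_name, accession_version = x$genome_id,
        system_id = sys_id, architecture = s$architecture, host = host,
        component_role = role,
        gene_start = iv[1] + 1L, gene_end = iv[2],
        strand = c0$orf$strand,
        sd_sequence = c0$orf$sd_motif,
        primary_structure = c0$orf$aa_seq,
        periplasmic_sequence = c0$periplasmic_seq,
        length_aa = nchar(c0$orf$aa_seq),
        periplasmic_cys_count =
          count_cys(c0$periplasmic_seq),
        lipobox = if (role %in% c("o", "u"))
          c0$topology$lipobox$motif else NA_character_,
        frame_offset = s$frame_offset,
        overlap_bp = s$overlap_bp,
        rel_start_frac = s$rel_start_frac,
        rel_end_frac = s$rel_end_frac,
        confidence = s$confidence,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(phage_name = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

count_cys <- function(aa) {
  lengths(regmatches(aa, gregexpr("C", aa, fixed = TRUE)))
}

#' Scan every reading frame for lipoprotein genes
#'
#' The certification step for "no spanin found": enumerates ORFs in all six
#' frames with a permissive length floor (40 codons) irrespective of the
#' annotated gene structure, and keeps those whose translation carries a
#' relaxed-mode lipobox with a valid signal peptide. An empty result
#' certifies that no o-spanin or u-spanin gene can hide in any frame.
#' Genomes over 50 kb are refused unless `force = TRUE` (frame-exhaustive
#' scanning of large genomes is impractical; 50 kb is the conventional
#' limit).
#'
#' @param genome a [genome_record()].
#' @param force scan even if the genome exceeds 50 kb.
#' @param params topology parameters (lipobox settings are used).
#' @return data frame of lipoprotein-bearing ORF candidates (one per
#'   stop-to-stop segment, start refined for lipobox validity) with
#'   `lipobox` and `lipobox_mode` columns.
#' @export
all_frame_lipoprotein_scan <- function(genome, force = FALSE,
                                       params = topology_params()) {
  if (genome$length > 50000L && !force) {
    stop("genome is ", genome$length, " bp (> 50 kb); frame-exhaustive ",
         "lipoprotein scan refused without force = TRUE", call. = FALSE)
  }
  cands <- scan_orfs(genome, min_aa = 40L)
  if (!nrow(cands)) return(cbind(cands, lipobox = character(0),
                                 lipobox_mode = character(0)))
  stop_key <- ifelse(cands$strand == "+",
                     paste0("+", cands$end), paste0("-", cands$start))
  validator <- function(aa) {
    !is.null(find_lipobox(aa, params$min_cys, params$max_cys, "relaxed"))
  }
  out <- list()
  for (key in unique(stop_key)) {
    sibs <- cands[stop_key == key, , drop = FALSE]
    best <- refine_start(sibs[1, ], sibs, validator)
    hit <- find_lipobox(best$aa_seq, params$min_cys, params$max_cys,
                        "relaxed")
    if (is.null(hit)) next
    best$lipobox <- hit$motif
    best$lipobox_mode <- hit$mode
    out[[length(out) + 1L]] <- best
  }
  if (!length(out)) {
    res <- cands[0, , drop = FALSE]
    res$lipobox <- character(0); res$lipobox_mode <- character(0)
    res$confidence <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  res[order(res$start), ]
}
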