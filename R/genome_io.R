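# Genome input and six-frame ORF enumeration.
#
# Internal coordinate convention: 0-based half-open intervals on the forward
# strand. GenBank/GFF3 input (1-based inclusive) is converted on read.
# OrfCandidate intervals exclude the stop codon, so that translating
# sequence[start, end) on the candidate strand reproduces aa_seq exactly.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a genome record
#'
#' Container for a nucleotide sequence plus annotated gene features, the
#' substrate searched for spanin genes.
#'
#' @param id accession or sequence identifier.
#' @param sequence nucleotide string over A, C, G, T, N (other IUPAC
#'   ambiguity codes are mapped to N; anything else is rejected).
#' @param features data frame with columns `start`, `end` (0-based
#'   half-open), `strand` ("+"/"-"), `kind` ("CDS" or "other"), `label`.
#' @param host optional host organism string.
#' @return object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, features = empty_features(),
                          host = NA_character_) {
  sequence <- toupper(sequence)
  bad <- gregexpr("[^ACGTURYSWKMBDHVN]", sequence)[[1]]
  if (bad[1] != -1L) {
    stop("non-IUPAC character '", substr(sequence, bad[1], bad[1]),
         "' at position ", bad[1], call. = FALSE)
  }
  # collapse ambiguity codes (incl. U) to N; keep the unambiguous alphabet
  sequence <- gsub("[^ACGTN]", "N", sequence)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  stopifnot(all(c("start", "end", "strand", "kind", "label") %in%
                  names(features)))
  n <- nchar(sequence)
  if (nrow(features)) {
    if (any(features$start >= features$end)) {
      stop("feature with start >= end", call. = FALSE)
    }
    if (any(features$start < 0L | features$end > n)) {
      stop("feature interval outside [0, ", n, ")", call. = FALSE)
    }
    cds <- features$kind == "CDS"
    if (any((features$end[cds] - features$start[cds]) %% 3L != 0L)) {
      stop("CDS feature length not divisible by 3", call. = FALSE)
    }
  }
  structure(list(id = id, sequence = sequence, features = features,
                 host = host, length = n),
            class = "genome_record")
}

empty_features <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             kind = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$id, ": ", x$length, " bp, ",
      sum(x$features$kind == "CDS"), " annotated CDS",
      if (!is.na(x$host)) paste0(", host ", x$host), "\n", sep = "")
  invisible(x)
}

#' Read a phage genome with optional annotation
#'
#' Reads a GenBank flat file (sequence + CDS features) or a FASTA file,
#' optionally combined with a GFF3 annotation. Coordinates are converted
#' from the 1-based inclusive file convention to internal 0-based half-open
#' intervals on the forward strand. Spliced (`join(...)`) CDS features are
#' not supported and are skipped with a warning.
#'
#' @param path input file.
#' @param format "auto" (by extension), "genbank" or "fasta".
#' @param gff3 optional GFF3 annotation file used with FASTA input.
#' @return a [genome_record()].
#' @export
read_genome <- function(path, format = c("auto", "genbank", "fasta"),
                        gff3 = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  if (format == "genbank") {
    rec <- parse_genbank(path)
  } else {
    ss <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("cannot read FASTA '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
    if (!length(ss)) stop("no records in FASTA '", path, "'", call. = FALSE)
    id <- strsplit(names(ss)[1], "\\s+")[[1]][1]
    rec <- genome_record(id, as.character(ss[[1]]))
  }
  if (!is.null(gff3)) {
    rec$features <- rbind(rec$features, read_gff3_features(gff3, rec$length))
    rec <- genome_record(rec$id, rec$sequence, rec$features, rec$host)
  }
  rec
}

# Minimal GenBank flat-file parser: LOCUS/ACCESSION/VERSION, FEATURES
# (CDS + source/host), ORIGIN. Phage records are single-locus and unspliced;
# join() locations are skipped with a warning.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    stop("'", path, "' does not look like a GenBank flat file (no LOCUS line)",
         call. = FALSE)
  }
  id <- sub("^LOCUS\\s+(\\S+).*", "\\1", lines[1])
  ver <- grep("^VERSION", lines, value = TRUE)
  if (length(ver)) id <- sub("^VERSION\\s+(\\S+).*", "\\1", ver[1])

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank record ", id, ": no ORIGIN section",
                         call. = FALSE)
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))

  feats <- empty_features()
  host <- NA_character_
  fstart <- grep("^FEATURES", lines)
  if (length(fstart)) {
    flines <- lines[(fstart[1] + 1L):(ori[1] - 1L)]
    # a new feature starts with a key at column 6; continuation lines at 22
    is_key <- grepl("^ {5}\\S", flines)
    key_idx <- which(is_key)
    for (k in seq_along(key_idx)) {
      i0 <- key_idx[k]
      i1 <- if (k < length(key_idx)) key_idx[k + 1] - 1L else length(flines)
      block <- flines[i0:i1]
      key <- sub("^\\s+(\\S+).*", "\\1", block[1])
      loc <- sub("^\\s+\\S+\\s+", "", block[1])
      # location may continue on following lines until the first qualifier
      qual_at <- grep("^\\s+/", block)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
      if (loc_end > 1L) {
        loc <- paste0(loc, paste(trimws(block[2:loc_end]), collapse = ""))
      }
      quals <- paste(block, collapse = " ")
      if (key == "source") {
        if (grepl("/host=\"", quals)) {
          host <- sub('.*?/host="([^"]*)".*', "\\1", quals)
        }
        next
      }
      if (key != "CDS") next
      if (grepl("join|order", loc)) {
        warning("GenBank record ", id,
                ": spliced CDS location '", loc, "' unsupported; skipped")
        next
      }
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) < 2L) {
        warning("GenBank record ", id, ": cannot parse CDS location '",
                loc, "'; skipped")
        next
      }
      a <- as.integer(nums[1]); b <- as.integer(nums[2])
      label <- NA_character_
      for (q in c("gene", "locus_tag", "product")) {
        pat <- paste0('/', q, '="([^"]*)"')
        if (grepl(pat, quals)) { label <- sub(paste0(".*?", pat, ".*"), "\\1", quals); break }
      }
      feats <- rbind(feats, data.frame(start = a - 1L, end = b,
                                       strand = strand, kind = "CDS",
                                       label = label,
                                       stringsAsFactors = FALSE))
    }
  }
  genome_record(id, sequence, feats, host)
}

read_gff3_features <- function(path, genome_len) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    lab <- if ("Name" %in% names(S4Vectors::mcols(gr))) gr$Name else gr$ID
    if (is.null(lab)) lab <- rep(NA_character_, length(gr))
    data.frame(start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr),
               strand = as.character(BiocGenerics::strand(gr)),
               kind = "CDS", label = as.character(lab),
               stringsAsFactors = FALSE)
  } else {
    ln <- readLines(path, warn = FALSE)
    ln <- ln[!grepl("^#", ln) & nzchar(ln)]
    f <- do.call(rbind, strsplit(ln, "\t"))
    keep <- f[, 3] == "CDS"
    f <- f[keep, , drop = FALSE]
    lab <- sub(".*(?:Name|ID)=([^;]*).*", "\\1", f[, 9])
    data.frame(start = as.integer(f[, 4]) - 1L, end = as.integer(f[, 5]),
               strand = f[, 7], kind = "CDS", label = lab,
               stringsAsFactors = FALSE)
  }
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# fast table-driven translation (codons with ambiguity translate to X)
GC_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

translate_nt <- function(nt) {
  n3 <- (nchar(nt) %/% 3L) * 3L
  if (!n3) return("")
  cod <- substring(nt, seq(1L, n3 - 2L, 3L), seq(3L, n3, 3L))
  aa <- GC_TABLE[cod]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Enumerate ORF candidates in all six frames
#'
#' Every maximal stop-to-stop segment on both strands yields one candidate
#' per admissible start codon whose ORF is at least `min_aa` codons long.
#' Candidates overlapping annotated CDS features are retained and marked in
#' `nested_in` (overlapping genes are exactly what standard gene callers
#' miss, and exactly where o-spanins live). ORFs whose translation is more
#' than 10% X (from N runs) are dropped as likely sequencing artifacts.
#' Each candidate carries the best upstream Shine-Dalgarno evidence from
#' [score_sd()].
#'
#' @param genome a [genome_record()].
#' @param min_aa minimum ORF length in codons (start codon included, stop
#'   excluded); must be >= 10.
#' @param start_codons admissible start codons.
#' @return data frame of candidates sorted by forward start: columns
#'   `start`, `end` (0-based half-open, stop codon excluded), `strand`,
#'   `frame` (0-5), `aa_seq`, `start_codon`, `sd_motif`, `sd_spacer`,
#'   `sd_score`, `nested_in`.
#' @export
scan_orfs <- function(genome, min_aa = 40L,
                      start_codons = c("ATG", "GTG", "TTG")) {
  stopifnot(inherits(genome, "genome_record"), min_aa >= 10L)
  L <- genome$length
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$sequence else
      reverse_complement(genome$sequence)
    for (f in 0:2) {
      n3 <- ((nchar(s) - f) %/% 3L) * 3L
      if (n3 < 3L * (min_aa + 1L)) next
      sub <- substr(s, f + 1L, f + n3)
      codons <- substring(sub, seq(1L, n3 - 2L, 3L), seq(3L, n3, 3L))
      aa <- strsplit(translate_nt(sub), "")[[1]]
      stops <- which(codons %in% STOP_CODONS)
      if (!length(stops)) next
      prev <- c(0L, stops[-length(stops)])
      for (j in seq_along(stops)) {
        st <- stops[j]
        if (st - prev[j] - 1L < min_aa) next
        seg <- (prev[j] + 1L):(st - 1L)
        starts <- seg[codons[seg] %in% start_codons]
        starts <- starts[st - starts >= min_aa]
        for (idx in starts) {
          aa_seq <- paste(aa[idx:(st - 1L)], collapse = "")
          if (mean(strsplit(aa_seq, "")[[1]] == "X") > 0.10) next
          s0 <- f + (idx - 1L) * 3L        # on current strand, 0-based
          e0 <- f + (st - 1L) * 3L
          if (strand == "+") {
            fs <- s0; fe <- e0
          } else {
            fs <- L - e0; fe <- L - s0
          }
          out[[length(out) + 1L]] <- data.frame(
            start = fs, end = fe, strand = strand,
            frame = if (strand == "+") f else 3L + f,
            aa_seq = aa_seq, start_codon = codons[idx],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    cands <- data.frame(start = integer(0), end = integer(0),
                        strand = character(0), frame = integer(0),
                        aa_seq = character(0), start_codon = character(0),
                        stringsAsFactors = FALSE)
  } else {
    cands <- do.call(rbind, out)
    cands <- cands[order(cands$start, cands$end, cands$strand), ]
    rownames(cands) <- NULL
  }
  sd <- lapply(seq_len(nrow(cands)), function(i) score_sd(genome, cands[i, ]))
  cands$sd_motif <- vapply(sd, function(x) if (is.null(x)) NA_character_ else x$motif, "")
  cands$sd_spacer <- vapply(sd, function(x) if (is.null(x)) NA_integer_ else x$spacer, 1L)
  cands$sd_score <- vapply(sd, function(x) if (is.null(x)) NA_integer_ else x$score, 1L)
  cands$nested_in <- nested_labels(cands, genome$features)
  cands
}

nested_labels <- function(cands, features) {
  if (!nrow(cands)) return(character(0))
  cds <- features[features$kind == "CDS", , drop = FALSE]
  vapply(seq_len(nrow(cands)), function(i) {
    if (!nrow(cds)) return(NA_character_)
    ov <- pmin(cds$end, cands$end[i]) - pmax(cds$start, cands$start[i])
    # a candidate is not "nested in" the gene whose own reading frame it is:
    # same strand and same stop-to-stop segment (gene end matches ORF end
    # plus the stop codon in reading direction)
    own <- cds$strand == cands$strand[i] &
      ((cands$strand[i] == "+" & cds$end == cands$end[i] + 3L) |
         (cands$strand[i] == "-" & cds$start == cands$start[i] - 3L))
    hit <- which(ov > 0L & !own)
    if (!length(hit)) return(NA_character_)
    lab <- cds$label[hit[1]]
    if (is.na(lab)) paste0("CDS:", cds$start[hit[1]] + 1L, "..",
                           cds$end[hit[1]]) else lab
  }, "")
}

SD_CONSENSUS <- "AGGAGG"

#' Score a Shine-Dalgarno site upstream of an ORF
#'
#' Finds the best ungapped match of at least 4 consecutive bases of the
#' anti-Shine-Dalgarno consensus AGGAGG in the window 4-14 nt upstream of
#' the start codon, on the coding strand. Ties are broken toward the longer
#' match, then the smaller spacer. A heuristic: the survey records a
#' predicted SD for each spanin but states no model.
#'
#' @param genome a [genome_record()].
#' @param orf one candidate row from [scan_orfs()] (or a list with `start`,
#'   `end`, `strand`).
#' @param min_match minimum match length (default 4).
#' @return `NULL`, or a list with `motif`, `spacer` (nt between motif end
#'   and start codon) and `score` (matched bases).
#' @export
score_sd <- function(genome, orf, min_match = 4L) {
  L <- genome$length
  need <- 14L + 6L  # max spacer + full motif
  if (orf$strand == "+") {
    if (orf$start < 20L) return(NULL)
    ctx <- substr(genome$sequence, orf$start - need + 1L, orf$start)
  } else {
    if (orf$end + 20L > L) return(NULL)
    ctx <- reverse_complement(substr(genome$sequence, orf$end + 1L,
                                     orf$end + need))
  }
  nc <- nchar(ctx)
  for (ml in seq(nchar(SD_CONSENSUS), min_match)) {
    subs <- unique(substring(SD_CONSENSUS, seq_len(nchar(SD_CONSENSUS) - ml + 1L),
                             seq_len(nchar(SD_CONSENSUS) - ml + 1L) + ml - 1L))
    for (sp in 4:14) {
      a <- nc - sp - ml + 1L
      if (a < 1L) next
      piece <- substr(ctx, a, nc - sp)
      if (piece %in% subs) {
        return(list(motif = piece, spacer = sp, score = ml))
      }
    }
  }
  NULL
}

#' Refine the start codon of an ORF among its siblings
#'
#' Misidentified start codons are the main obstacle to automated spanin
#' annotation, because membrane-localization signals live at the N terminus.
#' Among sibling candidates sharing the same stop codon, the starts whose
#' translation satisfies `signal_validator` are ranked by Shine-Dalgarno
#' score (then by length); if no start validates, the longest ORF is
#' returned flagged `confidence = "low"`.
#'
#' @param orf candidate row (from [scan_orfs()]).
#' @param siblings data frame of candidates sharing `orf`'s stop (may
#'   include `orf` itself; it is added if absent).
#' @param signal_validator predicate on an amino-acid string.
#' @return a single candidate row with a `confidence` column.
#' @export
refine_start <- function(orf, siblings, signal_validator) {
  orf <- as.data.frame(orf, stringsAsFactors = FALSE)
  if (is.null(siblings) || !nrow(siblings)) {
    orf$confidence <- "high"
    return(orf)
  }
  all <- unique(rbind(orf[names(siblings)], siblings))
  valid <- vapply(all$aa_seq, function(a) isTRUE(signal_validator(a)), TRUE)
  if (any(valid)) {
    cand <- all[valid, , drop = FALSE]
    sc <- ifelse(is.na(cand$sd_score), -1L, cand$sd_score)
    len <- nchar(cand$aa_seq)
    # best SD first; longer match already encoded in score; then spacer,
    # then longer ORF
    sp <- ifelse(is.na(cand$sd_spacer), 99L, cand$sd_spacer)
    best <- cand[order(-sc, sp, -len), , drop = FALSE][1, ]
    best$confidence <- "high"
  } else {
    best <- all[which.max(nchar(all$aa_seq)), , drop = FALSE]
    best$confidence <- "low"
  }
  rownames(best) <- NULL
  best
}

#' Write ORF candidates as GFF3
#'
#' @param cands candidate data frame from [scan_orfs()].
#' @param genome the [genome_record()] the candidates came from.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidates_gff3 <- function(cands, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(paste0("##sequence-region ", genome$id, " 1 ", genome$length), con)
  for (i in seq_len(nrow(cands))) {
    # gene interval includes the stop codon, per annotation convention
    if (cands$strand[i] == "+") {
      a <- cands$start[i] + 1L; b <- cands$end[i] + 3L
    } else {
      a <- cands$start[i] - 2L; b <- cands$end[i]
    }
    attrs <- paste0("ID=orf", i, ";start_codon=", cands$start_codon[i])
    if (!is.na(cands$nested_in[i])) {
      attrs <- paste0(attrs, ";nested_in=", cands$nested_in[i])
    }
    writeLines(paste(genome$id, "spaninscan", "CDS", a, b, ".",
                     cands$strand[i], "0", attrs, sep = "\t"), con)
  }
  invisible(path)
}
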