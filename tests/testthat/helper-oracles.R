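# Independent oracles used to check the implementation paths.

# Brute-force six-frame ORF enumeration: walk every position, check the
# start codon, read codon by codon to the first stop. Independent of
# scan_orfs (no segment logic, Biostrings translation).
oracle_scan_orfs <- function(seq, min_aa, starts = c("ATG", "GTG", "TTG")) {
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    gc_tab <- Biostrings::GENETIC_CODE
    for (p in seq_len(L - 2L)) {
      if (!(substr(s, p, p + 2L) %in% starts)) next
      q <- p
      aa <- character(0)
      found <- FALSE
      while (q + 2L <= L) {
        cod <- substr(s, q, q + 2L)
        if (cod %in% c("TAA", "TAG", "TGA")) { found <- TRUE; break }
        res <- unname(gc_tab[cod])
        aa <- c(aa, if (is.na(res)) "X" else res)
        q <- q + 3L
      }
      if (!found || length(aa) < min_aa) next
      if (mean(aa == "X") > 0.10) next
      s0 <- p - 1L; e0 <- q - 1L
      if (strand == "-") { t <- s0; s0 <- L - e0; e0 <- L - t }
      out[[length(out) + 1L]] <- data.frame(
        start = s0, end = e0, strand = strand,
        aa_seq = paste(aa, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), aa_seq = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$strand), c("start", "end", "strand",
                                               "aa_seq")]
}

# Direct truncated-window mean oracle for the hydropathy profile.
oracle_profile <- function(aa, window) {
  kd <- spaninscan::KD_SCALE
  v <- unname(kd[strsplit(aa, "")[[1]]])
  v[is.na(v)] <- 0
  h <- (window - 1L) %/% 2L
  vapply(seq_along(v), function(i) {
    mean(v[max(1L, i - h):min(length(v), i + h)])
  }, 0)
}

# Tiny affine-gap Smith-Waterman (BLOSUM62, open 11, extend 1) for small
# sequences; returns best score, identity over aligned columns and the
# aligned fraction of each input.
oracle_local_align <- function(a, b, open = 11, ext = 1) {
  B <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)      # best ending in a match/mismatch
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in y (x aligned to gap)
  Iy <- matrix(NEG, n + 1, m + 1)
  ptr <- array("", c(n + 1, m + 1, 3))
  best <- 0; bi <- 0; bj <- 0; bk <- 1
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- B[x[i - 1], y[j - 1]]
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1], 0)
      k <- which.max(prev)
      M[i, j] <- prev[k] + s
      ptr[i, j, 1] <- c("M", "X", "Y", "0")[k]
      gx <- c(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      kx <- which.max(gx); Ix[i, j] <- gx[kx]
      ptr[i, j, 2] <- c("M", "X")[kx]
      gy <- c(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      ky <- which.max(gy); Iy[i, j] <- gy[ky]
      ptr[i, j, 3] <- c("M", "Y")[ky]
      if (M[i, j] > best) { best <- M[i, j]; bi <- i; bj <- j; bk <- 1 }
    }
  }
  if (best <= 0) return(list(score = 0, identity_pct = 0, cov_a = 0,
                             cov_b = 0))
  # traceback
  i <- bi; j <- bj; state <- "M"
  cols <- 0L; matches <- 0L; used_a <- 0L; used_b <- 0L
  while (i > 1 && j > 1) {
    if (state == "M") {
      if (M[i, j] <= 0 && cols > 0L) break
      cols <- cols + 1L
      if (x[i - 1] == y[j - 1]) matches <- matches + 1L
      used_a <- used_a + 1L; used_b <- used_b + 1L
      nxt <- ptr[i, j, 1]
      i <- i - 1L; j <- j - 1L
      if (nxt == "0") break
      state <- c(M = "M", X = "X", Y = "Y")[[nxt]]
    } else if (state == "X") {
      cols <- cols + 1L; used_a <- used_a + 1L
      nxt <- ptr[i, j, 2]; i <- i - 1L
      state <- if (nxt == "M") "M" else "X"
    } else {
      cols <- cols + 1L; used_b <- used_b + 1L
      nxt <- ptr[i, j, 3]; j <- j - 1L
      state <- if (nxt == "M") "M" else "Y"
    }
  }
  list(score = best, identity_pct = 100 * matches / cols,
       cov_a = used_a / nchar(a), cov_b = used_b / nchar(b))
}

# Breadth-first connected components over an explicit edge predicate;
# returns a canonical partition (list of sorted member vectors, sorted).
oracle_components <- function(ids, edge) {
  n <- length(ids)
  seen <- logical(n)
  comps <- list()
  adj <- lapply(seq_len(n), function(i) {
    which(vapply(seq_len(n), function(j) i != j && edge(i, j), TRUE))
  })
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(ids[comp])
  }
  comps[order(vapply(comps, `[`, "", 1))]
}

canonical_partition <- function(families) {
  comps <- unname(lapply(families, function(f) sort(f$members)))
  comps[order(vapply(comps, `[`, "", 1))]
}

# random protein helper
random_protein <- function(n, alphabet = strsplit("ARNDCQEGHILKMFPSTWYV",
                                                  "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# scaffold that places a candidate lipobox tripeptide before a Cys inside
# a valid signal-peptide context; F/W/H flanks ensure no stray upstream
# residue can complete an alternative box
lipobox_scaffold <- function(tri) {
  paste0("MAK", strrep("F", 8), "WH", tri, "C", strrep("Q", 30))
}

# lightweight two-component system for the statistics layer
mini_system <- function(i_peri, o_peri) {
  structure(list(i = list(periplasmic_seq = i_peri,
                          length_aa = nchar(i_peri) + 30L),
                 o = list(periplasmic_seq = o_peri,
                          length_aa = nchar(o_peri) + 19L),
                 u = NULL, architecture = "separated",
                 overlap_bp = 0L, gap_bp = 100L, frame_offset = NA_integer_,
                 rel_start_frac = 1.2, rel_end_frac = 1.5,
                 confidence = "high"),
            class = "spanin_system")
}

# place cysteines at given 1-based positions of a sequence (test-side
# implementation, independent of the generator's)
plant_c <- function(seq, positions) {
  res <- strsplit(seq, "")[[1]]
  res[positions] <- "C"
  paste(res, collapse = "")
}
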