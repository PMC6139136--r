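# Membrane-topology signals: Kyte-Doolittle transmembrane segments and
# lipoprotein signal / lipobox detection, and the candidate typing that
# follows from them (i-spanin / o-spanin / u-spanin).

#' Kyte-Doolittle hydropathy index
#' @format named numeric vector over the 20 amino acids.
#' @export
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

# residues counted as hydrophobic when requiring a signal-peptide h-region
HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V")

#' Sliding-window Kyte-Doolittle hydropathy profile
#'
#' Position i holds the mean hydropathy of the window centred at i; at the
#' termini the window is truncated to the residues available. Unknown
#' residues (X) contribute 0.
#'
#' @param aa_seq protein string.
#' @param window odd window size (default 19, the classic
#'   transmembrane-scan width).
#' @return numeric vector of length `nchar(aa_seq)`.
#' @export
hydropathy_profile <- function(aa_seq, window = 19L) {
  stopifnot(window %% 2L == 1L, nchar(aa_seq) >= window)
  res <- strsplit(aa_seq, "")[[1]]
  v <- unname(KD_SCALE[res])
  v[is.na(v)] <- 0
  n <- length(v)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect transmembrane segments by hydropathy thresholding
#'
#' Maximal runs of positions whose window mean is at or above `threshold`
#' are taken as transmembrane segments; runs separated by fewer than 3
#' positions are merged, runs shorter than `min_len` are dropped, and runs
#' longer than 30 residues are trimmed to the best-scoring 30-residue
#' window (a membrane-spanning helix cannot be much longer).
#'
#' @param aa_seq protein string.
#' @param window,threshold,min_len scan parameters.
#' @return data frame with columns `start`, `end` (0-based half-open
#'   residue indices) and `mean_hydropathy`.
#' @export
find_tmds <- function(aa_seq, window = 19L, threshold = 1.6, min_len = 15L) {
  n <- nchar(aa_seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_hydropathy = numeric(0))
  if (n < window) return(empty)
  prof <- hydropathy_profile(aa_seq, window)
  hit <- prof >= threshold
  if (!any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by fewer than 3 positions
  if (nrow(runs) > 1L) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if (runs[i, 1] - merged[nrow(merged), 2] - 1L < 3L) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  keep <- (runs[, 2] - runs[, 1] + 1L) >= min_len
  runs <- runs[keep, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  out <- lapply(seq_len(nrow(runs)), function(i) {
    a <- runs[i, 1]; b <- runs[i, 2]
    if (b - a + 1L > 30L) {
      win_means <- vapply(a:(b - 29L),
                          function(s) mean(prof[s:(s + 29L)]), 0)
      a <- (a:(b - 29L))[which.max(win_means)]
      b <- a + 29L
    }
    data.frame(start = a - 1L, end = b, mean_hydropathy = mean(prof[a:b]))
  })
  do.call(rbind, out)
}

STRICT_LIPOBOX <- "^[LVI][ASTVI][GAS]$"
RELAXED_LIPOBOX_SET <- c("A", "L", "V", "I", "F", "G", "S", "T", "W", "M")

#' Find a lipoprotein lipobox in a protein sequence
#'
#' Looks for a lipoylatable Cys whose residue number (1-based) lies within
#' `[min_cys, max_cys]`, preceded by a lipobox tripeptide. In strict mode
#' the tripeptide must match the consensus `[LVI][ASTVI][GAS]`; relaxed mode
#' additionally accepts tripeptides whose every residue is drawn from
#' {A,L,V,I,F,G,S,T,W,M}, which admits unusual but functional boxes such as
#' AWAC, LNGC or FVGC. In both modes the sequence upstream must look like a
#' lipoprotein signal peptide: at least one K/R in the first 7 residues
#' (n-region), a hydrophobic stretch of >= 6 residues (h-region) ending
#' within 6 residues of the lipobox, and no charged residue (D/E/K/R)
#' between the start of that stretch and the Cys (c-region).
#'
#' @param aa_seq protein string.
#' @param min_cys,max_cys Cys window bounds (1-based residue numbers).
#' @param mode "strict" or "relaxed".
#' @return `NULL` if no hit, else a list with `cys_index` (0-based residue
#'   index of the Cys), `motif` (4-residue string ending in C) and `mode`
#'   ("strict" if the consensus matched, otherwise "relaxed").
#' @export
find_lipobox <- function(aa_seq, min_cys = 12L, max_cys = 40L,
                         mode = c("relaxed", "strict")) {
  mode <- match.arg(mode)
  res <- strsplit(aa_seq, "")[[1]]
  n <- length(res)
  if (n < min_cys + 1L) return(NULL)
  # n-region: positive charge near the N terminus
  if (!any(res[seq_len(min(7L, n))] %in% c("K", "R"))) return(NULL)
  hydro <- res %in% HYDROPHOBIC_SET
  charged <- res %in% c("D", "E", "K", "R")
  upper <- min(max_cys, n)
  for (p in seq(max(min_cys, 4L), upper)) {
    if (res[p] != "C") next
    tri <- paste(res[(p - 3L):(p - 1L)], collapse = "")
    strict_ok <- grepl(STRICT_LIPOBOX, tri)
    relaxed_ok <- all(res[(p - 3L):(p - 1L)] %in% RELAXED_LIPOBOX_SET)
    if (!(strict_ok || (mode == "relaxed" && relaxed_ok))) next
    # h-region: hydrophobic run of >= 6 ending within 6 residues of the box
    r <- rle(hydro[seq_len(p - 1L)])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok_run <- r$values & r$lengths >= 6L & ends >= (p - 3L) - 6L &
      starts > 1L
    if (!any(ok_run)) next
    run_start <- starts[ok_run][1]
    # c-region (and h-region) free of charged residues up to the Cys
    if (any(charged[run_start:(p - 1L)])) next
    return(list(cys_index = p - 1L,
                motif = paste(res[(p - 3L):p], collapse = ""),
                mode = if (strict_ok) "strict" else "relaxed"))
  }
  NULL
}

#' Default topology-typing parameters
#'
#' @param window,threshold,min_len transmembrane scan settings
#'   (see [find_tmds()]).
#' @param min_cys,max_cys lipobox Cys window (see [find_lipobox()]).
#' @param lipobox_mode "relaxed" (default; admits AWAC-class boxes) or
#'   "strict".
#' @param min_len_aa,max_len_aa protein length gate; sequences outside are
#'   typed NONE. Brackets the observed spanin range (lambda Rz1 at 60 aa up
#'   to the largest separated systems).
#' @param cterm_tmd_window a u-spanin's anchor TMD must lie wholly within
#'   this many C-terminal residues.
#' @param nterm_tmd_start an i-spanin's TMD must start within this many
#'   N-terminal residues.
#' @param max_peri_hydropathy maximum mean Kyte-Doolittle index of the
#'   periplasmic domain; the domain spans an aqueous compartment and must
#'   be soluble, which rejects the hydrophobic junk ORFs that shifted
#'   reading frames of transmembrane segments produce.
#' @return list of parameters.
#' @export
topology_params <- function(window = 19L, threshold = 1.6, min_len = 15L,
                            min_cys = 12L, max_cys = 40L,
                            lipobox_mode = "relaxed",
                            min_len_aa = 40L, max_len_aa = 350L,
                            cterm_tmd_window = 35L, nterm_tmd_start = 30L,
                            max_peri_hydropathy = 0.5) {
  as.list(environment())
}

kd_mean <- function(aa) {
  v <- KD_SCALE[strsplit(aa, "")[[1]]]
  v[is.na(v)] <- 0
  mean(v)
}

#' Type a protein as i-, o-, or u-spanin candidate
#'
#' Applies the membrane-topology eligibility rules in the order
#' U_CAND, O_CAND, I_CAND (lipobox checks precede TMD-only checks so that
#' lipoproteins carrying a C-terminal TMD are not mistyped as inner-membrane
#' proteins):
#' \itemize{
#' \item U_CAND: lipobox plus a TMD wholly within the last
#'   `cterm_tmd_window` residues (the unimolecular topology: lipoylated N
#'   terminus in the outer membrane, C-terminal anchor in the inner).
#' \item O_CAND: lipobox and no TMD starting downstream of the Cys.
#' \item I_CAND: no lipobox, exactly one TMD, starting within the first
#'   `nterm_tmd_start` residues (class II, N-in C-out).
#' }
#'
#' @param aa_seq protein string.
#' @param params list from [topology_params()].
#' @return object of class `topology_call`: list with `type` (one of
#'   "I_CAND", "O_CAND", "U_CAND", "NONE"), `tmds`, `lipobox`,
#'   `periplasmic` (0-based half-open residue interval or NULL), `evidence`.
#' @export
classify_topology <- function(aa_seq, params = topology_params()) {
  n <- nchar(aa_seq)
  mk <- function(type, tmds, lipobox, peri, evidence) {
    structure(list(type = type, tmds = tmds, lipobox = lipobox,
                   periplasmic = peri, evidence = evidence),
              class = "topology_call")
  }
  if (n < params$min_len_aa || n > params$max_len_aa) {
    return(mk("NONE", NULL, NULL, NULL, "length"))
  }
  tmds <- find_tmds(aa_seq, params$window, params$threshold, params$min_len)
  lipo <- find_lipobox(aa_seq, params$min_cys, params$max_cys,
                       params$lipobox_mode)
  # a spanin's periplasmic domain spans an aqueous compartment and must be
  # soluble; this rejects the hydrophobic junk ORFs that shifted reading
  # frames of transmembrane segments produce
  soluble <- function(iv) {
    kd_mean(substr(aa_seq, iv[1] + 1L, iv[2])) <= params$max_peri_hydropathy
  }
  if (!is.null(lipo)) {
    cterm <- tmds[tmds$start >= n - params$cterm_tmd_window, , drop = FALSE]
    if (nrow(cterm)) {
      anchor <- cterm[nrow(cterm), ]
      peri <- c(lipo$cys_index + 1L, anchor$start)
      if (peri[2] <= peri[1]) {
        return(mk("NONE", tmds, lipo, NULL, "degenerate u topology"))
      }
      if (!soluble(peri)) {
        return(mk("NONE", tmds, lipo, NULL,
                  "hydrophobic periplasmic domain"))
      }
      return(mk("U_CAND", tmds, lipo, peri,
                paste0("lipobox ", lipo$motif, " (", lipo$mode,
                       ") + C-terminal TMD")))
    }
    if (!any(tmds$start >= lipo$cys_index)) {
      peri <- c(lipo$cys_index + 1L, n)
      if (!soluble(peri)) {
        return(mk("NONE", tmds, lipo, NULL,
                  "hydrophobic periplasmic domain"))
      }
      return(mk("O_CAND", tmds, lipo, peri,
                paste0("lipobox ", lipo$motif, " (", lipo$mode,
                       "), no downstream TMD")))
    }
    return(mk("NONE", tmds, lipo, NULL, "lipobox with internal TMD"))
  }
  if (nrow(tmds) == 1L && tmds$start[1] < params$nterm_tmd_start) {
    peri <- c(tmds$end[1], n)
    if (peri[2] <= peri[1]) {
      return(mk("NONE", tmds, NULL, NULL, "degenerate i topology"))
    }
    if (!soluble(peri)) {
      return(mk("NONE", tmds, NULL, NULL, "hydrophobic periplasmic domain"))
    }
    return(mk("I_CAND", tmds, NULL, peri, "single N-terminal TMD"))
  }
  mk("NONE", tmds, NULL, NULL,
     if (nrow(tmds)) paste0(nrow(tmds), " TMD(s), not N-terminal single")
     else "no membrane signal")
}

#' @export
print.topology_call <- function(x, ...) {
  cat("<topology_call> ", x$type, " - ", x$evidence, "\n", sep = "")
  invisible(x)
}

#' Extract the periplasmic domain of a typed protein
#'
#' i-spanin: everything C-terminal of the TMD. o-spanin: everything after
#' the lipoylated Cys (the Cys itself anchors the outer membrane and is
#' excluded). u-spanin: between the lipoylated Cys and the C-terminal TMD.
#'
#' @param call a `topology_call`.
#' @param aa_seq the protein it was computed from.
#' @return list with `interval` (0-based half-open) and `seq`.
#' @export
periplasmic_domain <- function(call, aa_seq) {
  if (is.null(call$periplasmic)) {
    stop("degenerate or untyped topology call: no periplasmic domain",
         call. = FALSE)
  }
  iv <- call$periplasmic
  if (iv[2] <= iv[1]) stop("empty periplasmic interval", call. = FALSE)
  list(interval = iv, seq = substr(aa_seq, iv[1] + 1L, iv[2]))
}

#' Read an external TMD/lipobox override table
#'
#' Users who prefer externally computed membrane-topology calls (e.g. from
#' a dedicated transmembrane or lipoprotein predictor) can supply them as a
#' TSV with columns `protein_id`, `tmd_start`, `tmd_end`, `cys_index`
#' (1-based residue numbers in the file; empty/NA where not applicable).
#' Coordinates are converted to the package's 0-based half-open convention
#' on read.
#'
#' @param path TSV file.
#' @return named list (by protein id) of overrides, each with `tmds` (data
#'   frame, possibly empty) and `cys_index` (0-based, or NA).
#' @export
read_topology_overrides <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "tmd_start", "tmd_end", "cys_index")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("override table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (id in unique(df$protein_id)) {
    rows <- df[df$protein_id == id, , drop = FALSE]
    has_tmd <- !is.na(rows$tmd_start) & !is.na(rows$tmd_end)
    tmds <- data.frame(start = rows$tmd_start[has_tmd] - 1L,
                       end = rows$tmd_end[has_tmd],
                       mean_hydropathy = rep(NA_real_, sum(has_tmd)))
    cys <- rows$cys_index[!is.na(rows$cys_index)]
    out[[id]] <- list(tmds = tmds,
                      cys_index = if (length(cys)) cys[1] - 1L
                                  else NA_integer_)
  }
  out
}
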