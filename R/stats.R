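# Database-level analyses: periplasmic cysteine counts and normalized
# positions, lipobox position-frequency matrices, and architecture /
# frame / length summaries.

peri_seq <- function(comp) {
  if (is.null(comp)) return(NULL)
  comp$periplasmic_seq
}

is_two_component <- function(system) {
  !is.null(system$i) && !is.null(system$o)
}

#' Periplasmic cysteine counts of a two-component system
#'
#' Counts cysteines strictly within each periplasmic domain. The
#' lipoylated Cys of the o-spanin anchors the outer membrane and is outside
#' the periplasmic domain by definition, so it is never counted.
#'
#' @param system a `spanin_system` (two-component).
#' @return list with `i_count`, `o_count`, `total`, and `cys_free`
#'   (`TRUE` for the rare systems with no periplasmic cysteine at all).
#' @export
cysteine_counts <- function(system) {
  if (!is_two_component(system)) {
    stop("unimolecular system: cysteine_counts applies to two-component ",
         "systems (u-spanins carry no periplasmic cysteines)", call. = FALSE)
  }
  ic <- count_cys(peri_seq(system$i))
  oc <- count_cys(peri_seq(system$o))
  list(i_count = ic, o_count = oc, total = ic + oc, cys_free = ic + oc == 0L)
}

cys_positions <- function(aa) {
  which(strsplit(aa, "")[[1]] == "C")
}

#' Normalized cysteine positions of a spanin complex
#'
#' The complex periplasmic coordinate runs from the inner membrane to the
#' outer membrane: the i-spanin periplasmic domain (IM end first) followed
#' by the reversed o-spanin periplasmic domain (OM end last). Distances of
#' the closest cysteine to each membrane are reported as percent of the
#' complex length; per component, distances to the membrane anchor and to
#' the C-terminal interaction interface are percent of that component's
#' periplasmic length. A cysteine at a boundary has distance 0.
#'
#' @param system a two-component `spanin_system`.
#' @return list of class `cysteine_profile` with counts, the six percent
#'   positions (NA where the relevant count is 0) and `single_cys`.
#' @export
cysteine_positions <- function(system) {
  cc <- cysteine_counts(system)
  i_peri <- peri_seq(system$i); o_peri <- peri_seq(system$o)
  li <- nchar(i_peri); lo <- nchar(o_peri)
  ip <- cys_positions(i_peri); op <- cys_positions(o_peri)
  total_len <- li + lo
  # complex coordinate: i positions as-is; o position p maps to
  # li + (lo - p + 1) because the o domain enters reversed (OM end last)
  cxp <- c(ip, if (length(op)) li + (lo - op + 1L))
  pct <- function(x) 100 * x
  out <- list(
    i_count = cc$i_count, o_count = cc$o_count, total = cc$total,
    pos_closest_IM_pct = if (length(cxp)) pct(min(cxp - 1L) / total_len)
                         else NA_real_,
    pos_closest_OM_pct = if (length(cxp)) pct(min(total_len - cxp) / total_len)
                         else NA_real_,
    i_closest_IM_pct = if (length(ip)) pct(min(ip - 1L) / li) else NA_real_,
    i_closest_interface_pct = if (length(ip)) pct(min(li - ip) / li)
                              else NA_real_,
    o_closest_OM_pct = if (length(op)) pct(min(op - 1L) / lo) else NA_real_,
    o_closest_interface_pct = if (length(op)) pct(min(lo - op) / lo)
                              else NA_real_,
    single_cys = cc$total == 1L)
  class(out) <- "cysteine_profile"
  out
}

#' @export
print.cysteine_profile <- function(x, ...) {
  cat("<cysteine_profile> i:", x$i_count, " o:", x$o_count,
      " total:", x$total, "\n")
  if (x$total > 0L) {
    cat(sprintf("  closest Cys: %.1f%% from IM, %.1f%% from OM (complex)\n",
                x$pos_closest_IM_pct, x$pos_closest_OM_pct))
  }
  invisible(x)
}

#' Cysteine-count histograms over a spanin database
#'
#' @param db list of two-component `spanin_system` objects (unimolecular
#'   entries are ignored; u-spanins carry no periplasmic cysteines).
#' @return list with `total`, `i`, `o` count histograms (named integer
#'   tables) and the `joint` (i_count x o_count) contingency table.
#' @export
db_cysteine_tables <- function(db) {
  db <- Filter(is_two_component, db)
  if (!length(db)) {
    e <- table(integer(0))
    return(list(total = e, i = e, o = e,
                joint = table(integer(0), integer(0))))
  }
  cc <- lapply(db, cysteine_counts)
  i <- vapply(cc, `[[`, 0L, "i_count")
  o <- vapply(cc, `[[`, 0L, "o_count")
  list(total = table(i + o), i = table(i), o = table(o),
       joint = table(i_count = i, o_count = o))
}

#' Lipobox position-frequency matrix
#'
#' Counts residues at the three positions before the lipoylation cysteine
#' plus the cysteine itself, across all components with a lipobox hit
#' (members without one are skipped). This matrix is the numeric form of a
#' sequence logo.
#'
#' @param motifs 4-residue lipobox strings (ending in C), or a list of
#'   spanin components carrying `topology$lipobox$motif`.
#' @return list with `counts` (20 x 4 matrix) and `n`.
#' @export
lipobox_pfm <- function(motifs) {
  if (is.list(motifs) && !is.null(motifs[[1]]$topology)) {
    motifs <- vapply(motifs, function(m) {
      lb <- m$topology$lipobox
      if (is.null(lb)) NA_character_ else lb$motif
    }, "")
  }
  motifs <- motifs[!is.na(motifs)]
  counts <- matrix(0L, nrow = length(AA20), ncol = 4L,
                   dimnames = list(AA20, c("-3", "-2", "-1", "C")))
  for (m in motifs) {
    stopifnot(nchar(m) == 4L, substr(m, 4L, 4L) == "C")
    res <- strsplit(m, "")[[1]]
    for (j in 1:4) counts[res[j], j] <- counts[res[j], j] + 1L
  }
  list(counts = counts, n = length(motifs))
}

comp_len <- function(comp) {
  if (!is.null(comp$length_aa)) comp$length_aa else nchar(comp$orf$aa_seq)
}

#' Summary statistics over a spanin database
#'
#' Architecture and reading-frame counts, how often the i-spanin is the
#' longer component, the extremes of the combined periplasmic length, the
#' cysteine histograms, and the o-gene relative-start histogram in 0.1 L
#' bins.
#'
#' @param db list of `spanin_system` objects; names, if present, identify
#'   the phage/genome of each entry.
#' @return object of class `spanin_db_summary`.
#' @export
db_summary <- function(db) {
  if (is.null(names(db)) && length(db)) {
    names(db) <- sprintf("system%03d", seq_along(db))
  }
  two <- Filter(is_two_component, db)
  archs <- vapply(db, `[[`, "", "architecture")
  fo <- vapply(two, `[[`, 1L, "frame_offset")
  fo <- fo[!is.na(fo)]
  longer <- vapply(two, function(s) comp_len(s$i) > comp_len(s$o), TRUE)
  peri_len <- vapply(two, function(s) {
    nchar(peri_seq(s$i)) + nchar(peri_seq(s$o))
  }, 0L)
  rel <- vapply(two, `[[`, 0, "rel_start_frac")
  rel_hist <- if (length(rel)) {
    table(cut(rel, breaks = seq(0, max(1, ceiling(max(rel) * 10) / 10), 0.1),
              right = FALSE))
  } else table(numeric(0))
  out <- list(
    n_systems = length(db),
    n_two_component = length(two),
    architecture_counts = table(archs),
    frame_counts = table(factor(ifelse(fo > 0, "+1", "-1"),
                                levels = c("+1", "-1"))),
    i_longer_than_o_count = sum(longer),
    periplasmic_length_min =
      if (length(peri_len)) unname(min(peri_len)) else NA_integer_,
    periplasmic_length_min_id =
      if (length(peri_len)) names(two)[which.min(peri_len)] else NA_character_,
    periplasmic_length_max =
      if (length(peri_len)) unname(max(peri_len)) else NA_integer_,
    periplasmic_length_max_id =
      if (length(peri_len)) names(two)[which.max(peri_len)] else NA_character_,
    cys_histograms = db_cysteine_tables(two),
    rel_position_histogram = rel_hist)
  class(out) <- "spanin_db_summary"
  out
}

#' @export
print.spanin_db_summary <- function(x, ...) {
  cat("<spanin_db_summary> ", x$n_systems, " systems (",
      x$n_two_component, " two-component)\n", sep = "")
  print(x$architecture_counts)
  cat("frame offsets: "); print(x$frame_counts)
  cat("i-spanin longer than o-spanin in", x$i_longer_than_o_count, "of",
      x$n_two_component, "systems\n")
  if (!is.na(x$periplasmic_length_min)) {
    cat("combined periplasmic length: min ", x$periplasmic_length_min,
        " (", x$periplasmic_length_min_id, "), max ",
        x$periplasmic_length_max, " (", x$periplasmic_length_max_id,
        ")\n", sep = "")
  }
  invisible(x)
}

#' Read a spanin table and rebuild lightweight systems
#'
#' Accepts the TSV written by [as.data.frame.spanin_report()] (or the same
#' column layout exported from a spreadsheet). Rows are grouped into
#' systems by phage and system id; each system carries the component
#' periplasmic sequences, lengths, architecture, frame offset, relative
#' position and lipobox, which is everything the statistics layer needs.
#'
#' @param path TSV file.
#' @return named list of lightweight `spanin_system` objects.
#' @export
read_spanin_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  systems_from_table(df)
}

#' @rdname read_spanin_table
#' @param df a data frame in the spanin-table schema.
#' @export
systems_from_table <- function(df) {
  need <- c("phage_name", "architecture", "component_role",
            "periplasmic_sequence", "length_aa")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("spanin table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$system_id)) df$system_id <- 1L
  key <- paste(df$phage_name, df$system_id, sep = "#")
  out <- list()
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    mkcomp <- function(role) {
      r <- rows[rows$component_role == role, , drop = FALSE]
      if (!nrow(r)) return(NULL)
      list(periplasmic_seq = r$periplasmic_sequence[1],
           length_aa = r$length_aa[1],
           lipobox = if ("lipobox" %in% names(r)) r$lipobox[1]
                     else NA_character_)
    }
    s <- structure(list(
      i = mkcomp("i"), o = mkcomp("o"), u = mkcomp("u"),
      architecture = rows$architecture[1],
      overlap_bp = if ("overlap_bp" %in% names(rows)) rows$overlap_bp[1]
                   else NA_integer_,
      gap_bp = NA_integer_,
      frame_offset = if ("frame_offset" %in% names(rows))
        rows$frame_offset[1] else NA_integer_,
      rel_start_frac = if ("rel_start_frac" %in% names(rows))
        rows$rel_start_frac[1] else NA_real_,
      rel_end_frac = if ("rel_end_frac" %in% names(rows))
        rows$rel_end_frac[1] else NA_real_,
      confidence = NA_character_), class = "spanin_system")
    out[[k]] <- s
  }
  # prefer bare phage names when they are unique across systems
  phs <- sub("#.*$", "", names(out))
  if (!anyDuplicated(phs)) names(out) <- phs
  out
}
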