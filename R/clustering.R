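# Family clustering of periplasmic domains: BLOSUM62 local alignment,
# identity/coverage edges, single-linkage (connected-component) families.
# Emulates the clustering regime of the classic BLAST-based clustering
# tools at >=40% identity over >=40% length.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

check_protein <- function(x, what = "sequence") {
  bad <- regexpr(paste0("[^", paste(AA20, collapse = ""), "]"), x)
  if (bad != -1L) {
    stop(what, " contains non-amino-acid character '",
         substr(x, bad, bad), "' at position ", bad, call. = FALSE)
  }
  invisible(x)
}

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Local alignment identity and coverage of two proteins
#'
#' Best Smith-Waterman local alignment under BLOSUM62 with gap open 11 and
#' gap extension 1 (the scoring regime of the emulated clustering tool).
#' Identity is matches over aligned columns (gaps included); coverage is
#' the aligned fraction of each sequence's length. A best local score at or
#' below 0 is a no-hit sentinel (`score <= 0`, identity and coverages 0).
#'
#' @param a,b protein strings (20 standard residues).
#' @return list with `identity_pct`, `cov_a`, `cov_b`, `score`.
#' @export
pairwise_local_identity <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  check_protein(a, "sequence a"); check_protein(b, "sequence b")
  # co-optimal local alignments can differ by traceback; canonicalize the
  # argument order so that results are exactly symmetric under swap
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    al <- pairwise_local_identity(b, a)
    return(list(identity_pct = al$identity_pct, cov_a = al$cov_b,
                cov_b = al$cov_a, score = al$score))
  }
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = blosum62(),
                                       gapOpening = 11, gapExtension = 1)
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    return(list(identity_pct = 0, cov_a = 0, cov_b = 0, score = sc))
  }
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(pat)
  matches <- sum(strsplit(pat, "")[[1]] == strsplit(sub, "")[[1]])
  list(identity_pct = 100 * matches / cols,
       cov_a = nchar(gsub("-", "", pat)) / nchar(a),
       cov_b = nchar(gsub("-", "", sub)) / nchar(b),
       score = sc)
}

#' Clustering parameters
#'
#' @param id_threshold minimum percent identity for an edge (default 40).
#' @param cov_threshold minimum aligned length fraction (default 0.4).
#' @param cov_rule which sequence(s) the coverage requirement applies to:
#'   "both" (default, each sequence), "either", or "shorter".
#' @param short_len sequences shorter than this (aa) are routed to
#'   [assign_short_sequences()] rather than clustered directly (default 50;
#'   deep scoring matrices need long alignments).
#' @return list of parameters.
#' @export
cluster_params <- function(id_threshold = 40, cov_threshold = 0.4,
                           cov_rule = c("both", "either", "shorter"),
                           short_len = 50L) {
  cov_rule <- match.arg(cov_rule)
  stopifnot(id_threshold >= 0, id_threshold <= 100,
            cov_threshold >= 0, cov_threshold <= 1)
  list(id_threshold = id_threshold, cov_threshold = cov_threshold,
       cov_rule = cov_rule, short_len = short_len)
}

edge_ok <- function(al, a, b, params) {
  if (al$score <= 0) return(FALSE)
  if (al$identity_pct < params$id_threshold) return(FALSE)
  t <- params$cov_threshold
  switch(params$cov_rule,
         both = al$cov_a >= t && al$cov_b >= t,
         either = al$cov_a >= t || al$cov_b >= t,
         shorter = (if (nchar(a) <= nchar(b)) al$cov_a else al$cov_b) >= t)
}

make_family <- function(members, lengths) {
  members <- sort(members)
  list(members = members,
       representative = choose_representative(members, lengths),
       singleton = length(members) == 1L)
}

#' Cluster periplasmic domains into single-linkage families
#'
#' Builds the graph whose edges join sequence pairs meeting the identity
#' and coverage thresholds, and returns its connected components (single
#' linkage, matching the behaviour of the emulated clustering tool).
#' Families are ordered by representative id.
#'
#' @param seqs named character vector (id to periplasmic sequence). All
#'   sequences must be at least `params$short_len` long; route shorter ones
#'   through [assign_short_sequences()].
#' @param params list from [cluster_params()].
#' @return list of families, each a list with `members`, `representative`,
#'   `singleton`.
#' @export
family_clusters <- function(seqs, params = cluster_params()) {
  seqs <- unlist(seqs)
  if (!length(seqs)) return(list())
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("seqs must be uniquely named", call. = FALSE)
  }
  if (any(nchar(seqs) < params$short_len)) {
    stop("sequences shorter than short_len (", params$short_len,
         " aa) must go through assign_short_sequences()", call. = FALSE)
  }
  ids <- names(seqs)
  n <- length(ids)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  edges <- integer(0)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        al <- pairwise_local_identity(seqs[[i]], seqs[[j]])
        if (edge_ok(al, seqs[[i]], seqs[[j]], params)) {
          edges <- c(edges, i, j)
        }
      }
    }
  }
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  lens <- nchar(seqs)
  fams <- unname(lapply(split(ids, memb), make_family, lengths = lens))
  fams[order(vapply(fams, `[[`, "", "representative"))]
}

#' Group full-length sequences that are strictly identical
#'
#' The identical-set analysis: 100% identity over 100% of the length,
#' signal sequences included. Equivalent to clustering at id 100 and
#' coverage 1, but implemented by exact string grouping.
#'
#' @param full_seqs named character vector of full-length sequences.
#' @return list of families as in [family_clusters()].
#' @export
identical_sets <- function(full_seqs) {
  full_seqs <- unlist(full_seqs)
  if (!length(full_seqs)) return(list())
  lens <- nchar(full_seqs)
  fams <- lapply(split(names(full_seqs), full_seqs), make_family,
                 lengths = lens)
  names(fams) <- NULL
  fams[order(vapply(fams, `[[`, "", "representative"))]
}

#' Attach short sequences to existing families
#'
#' Sequences shorter than `short_len` align too briefly for a deep scoring
#' matrix, so they are assigned by end-gap-free global identity instead:
#' each short sequence joins the family of its best-scoring partner if that
#' pairing meets the identity/coverage rule, and otherwise becomes a new
#' singleton family. Ties are broken by higher identity, then by
#' lexicographic family representative, and flagged.
#'
#' @param families list from [family_clusters()].
#' @param shorts named character vector of short sequences.
#' @param long_seqs named character vector of the sequences behind
#'   `families` (alignment partners).
#' @param params list from [cluster_params()].
#' @return updated list of families (new singletons appended), re-sorted by
#'   representative.
#' @export
assign_short_sequences <- function(families, shorts, long_seqs,
                                   params = cluster_params()) {
  shorts <- unlist(shorts); long_seqs <- unlist(long_seqs)
  if (!length(shorts)) return(families)
  fam_of <- stats::setNames(
    rep(seq_along(families), lengths(lapply(families, `[[`, "members"))),
    unlist(lapply(families, `[[`, "members")))
  all_len <- c(nchar(long_seqs), nchar(shorts))
  names(all_len) <- c(names(long_seqs), names(shorts))
  for (sid in names(shorts)) {
    best <- NULL
    for (pid in names(long_seqs)) {
      aln <- Biostrings::pairwiseAlignment(shorts[[sid]], long_seqs[[pid]],
                                           type = "overlap",
                                           substitutionMatrix = blosum62(),
                                           gapOpening = 11, gapExtension = 1)
      pat <- as.character(Biostrings::alignedPattern(aln))
      sub <- as.character(Biostrings::alignedSubject(aln))
      cols <- nchar(pat)
      if (!cols) next
      idpct <- 100 * sum(strsplit(pat, "")[[1]] ==
                           strsplit(sub, "")[[1]]) / cols
      al <- list(identity_pct = idpct,
                 cov_a = nchar(gsub("-", "", pat)) / nchar(shorts[[sid]]),
                 cov_b = nchar(gsub("-", "", sub)) / nchar(long_seqs[[pid]]),
                 score = Biostrings::score(aln))
      if (!edge_ok(al, shorts[[sid]], long_seqs[[pid]], params)) next
      rep_id <- families[[fam_of[[pid]]]]$representative
      if (is.null(best) || idpct > best$idpct ||
          (idpct == best$idpct && rep_id < best$rep_id)) {
        tie <- !is.null(best) && idpct == best$idpct
        best <- list(fam = fam_of[[pid]], idpct = idpct, rep_id = rep_id,
                     tie = tie)
      } else if (idpct == best$idpct) {
        best$tie <- TRUE
      }
    }
    if (is.null(best)) {
      families[[length(families) + 1L]] <- make_family(sid, all_len)
    } else {
      fam <- families[[best$fam]]
      fam$members <- sort(c(fam$members, sid))
      fam$representative <- choose_representative(fam$members, all_len)
      fam$singleton <- FALSE
      if (isTRUE(best$tie)) fam$tied_assignment <- TRUE
      families[[best$fam]] <- fam
    }
  }
  families[order(vapply(families, `[[`, "", "representative"))]
}

#' Pick a family representative
#'
#' The member with the longest (periplasmic) sequence; ties go to the
#' lexicographically first id.
#'
#' @param members character vector of member ids.
#' @param lengths named lengths (aa) covering all members.
#' @return a single id.
#' @export
choose_representative <- function(members, lengths) {
  members <- sort(members)
  members[which.max(lengths[members])]
}

#' Tabulate families
#'
#' @param families list from [family_clusters()] and friends.
#' @return data frame with columns `family_id`, `representative`, `member`,
#'   `member_count`, `singleton`.
#' @export
family_table <- function(families) {
  if (!length(families)) {
    return(data.frame(family_id = integer(0), representative = character(0),
                      member = character(0), member_count = integer(0),
                      singleton = logical(0)))
  }
  do.call(rbind, lapply(seq_along(families), function(i) {
    f <- families[[i]]
    data.frame(family_id = i, representative = f$representative,
               member = f$members, member_count = length(f$members),
               singleton = f$singleton, stringsAsFactors = FALSE)
  }))
}
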