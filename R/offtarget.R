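#' Decompose a sequence into overlapping k-mers
#'
#' Slides a window of width `k` along the sequence in steps of `step` nt
#' (default 1, i.e. consecutive 21-mers overlap by 20 nt). Windows containing
#' characters outside A/C/G/T are emitted but flagged non-matchable; the
#' screen never matches them.
#'
#' @param sequence Nucleotide string (A/C/G/T/N; lower case accepted).
#' @param k Window width in nt (default 21).
#' @param step Step between window starts in nt.
#' @return Data frame with columns `offset` (0-based window start), `kmer`
#'   and `matchable`. Empty (with a warning) if the sequence is shorter
#'   than `k`.
#' @export
kmerize <- function(sequence, k = 21L, step = 1L) {
  if (k < 1L || step < 1L) stop("`k` and `step` must be positive", call. = FALSE)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < k) {
    warning("sequence shorter than k = ", k, "; no k-mers emitted")
    return(data.frame(offset = integer(0), kmer = character(0),
                      matchable = logical(0)))
  }
  starts <- seq.int(1L, L - k + 1L, by = step)
  kmers <- substring(sequence, starts, starts + k - 1L)
  data.frame(
    offset = starts - 1L,
    kmer = kmers,
    matchable = !grepl("[^ACGT]", kmers)
  )
}

#' Reverse complement of a nucleotide string
#'
#' @param sequence String over A/C/G/T/N (lower case accepted); N maps to N.
#' @return The reverse complement, uppercase.
#' @export
reverse_complement <- function(sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside A/C/G/T/N", call. = FALSE)
  }
  paste(rev(strsplit(chartr("ACGT", "TGCA", sequence), "")[[1]]), collapse = "")
}

#' Screen dsRNA candidates for exact k-mer matches in reference panels
#'
#' Decomposes every dsRNA into its overlapping k-mers (default 21-mers in 1-nt
#' steps) and reports every exact occurrence in each reference sequence, on
#' the forward and (optionally) reverse strand. Only exact matching is
#' supported. Overlapping occurrences are each counted; reverse-strand hits
#' are reported at the forward-strand coordinate of the matched window
#' (1-based, inclusive). K-mers containing non-A/C/G/T characters never match.
#'
#' @param dsrnas Named character vector of dsRNA candidate sequences.
#' @param references Named character vector of reference sequences (a panel).
#' @param k Match length in nt (default 21).
#' @param max_mismatches Must be 0; any other value is an error (the screen
#'   counts exact matches only).
#' @param both_strands Search the reverse strand as well (default `TRUE`).
#' @return Object of class `match_report`: a list with `hits` (one row per
#'   occurrence: `dsrna_id`, `ref_id`, `kmer`, `position`, `strand`) and
#'   `summary` (rows for every dsRNA x reference pair with `n_matches`,
#'   including zeros).
#' @export
screen <- function(dsrnas, references, k = 21L, max_mismatches = 0L,
                   both_strands = TRUE) {
  if (max_mismatches != 0L) {
    stop("only exact matching (max_mismatches = 0) is implemented", call. = FALSE)
  }
  empty_hits <- data.frame(dsrna_id = character(0), ref_id = character(0),
                           kmer = character(0), position = integer(0),
                           strand = character(0))
  if (length(references) == 0L) {
    warning("empty reference panel; empty report returned")
    return(structure(list(hits = empty_hits,
                          summary = data.frame(dsrna_id = character(0),
                                               ref_id = character(0),
                                               n_matches = integer(0))),
                     class = "match_report"))
  }
  if (is.null(names(dsrnas)) || is.null(names(references))) {
    stop("dsRNA and reference vectors must be named", call. = FALSE)
  }
  dsrnas <- toupper(dsrnas)
  references <- toupper(references)
  # one pass of window extraction per reference, reused across dsRNAs
  ref_windows <- lapply(references, function(s) {
    L <- nchar(s)
    if (L < k) character(0) else substring(s, 1:(L - k + 1L), k:L)
  })
  rows <- list()
  for (did in names(dsrnas)) {
    km <- kmerize(dsrnas[[did]], k = k)
    km <- km[km$matchable, , drop = FALSE]
    km <- km[!duplicated(km$kmer), , drop = FALSE]
    for (rid in names(references)) {
      win <- ref_windows[[rid]]
      if (length(win) == 0L) next
      for (kmer in km$kmer) {
        fwd <- which(win == kmer)
        if (length(fwd)) {
          rows[[length(rows) + 1L]] <- data.frame(
            dsrna_id = did, ref_id = rid, kmer = kmer,
            position = fwd, strand = "+"
          )
        }
        if (both_strands) {
          rev_hits <- which(win == reverse_complement(kmer))
          if (length(rev_hits)) {
            rows[[length(rows) + 1L]] <- data.frame(
              dsrna_id = did, ref_id = rid, kmer = kmer,
              position = rev_hits, strand = "-"
            )
          }
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits
  hits <- hits[order(hits$dsrna_id, hits$ref_id, hits$position, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  summary <- expand.grid(dsrna_id = names(dsrnas), ref_id = names(references),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  summary$n_matches <- vapply(seq_len(nrow(summary)), function(i) {
    sum(hits$dsrna_id == summary$dsrna_id[i] & hits$ref_id == summary$ref_id[i])
  }, integer(1))
  summary <- summary[order(summary$dsrna_id, summary$ref_id), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(hits = hits, summary = summary), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("Off-target screen report:", nrow(x$hits), "exact match(es) across",
      nrow(x$summary), "dsRNA x reference pair(s)\n")
  if (nrow(x$hits)) print(utils::head(x$hits, 10L))
  invisible(x)
}
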