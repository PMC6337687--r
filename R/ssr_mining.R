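#' Mining configuration for microsatellite detection
#'
#' Thresholds follow the widely distributed defaults of MISA-style
#' miners: a mononucleotide tract needs at least 10 repeats, a
#' dinucleotide 6, and tri- to hexanucleotides 5; two tracts separated
#' by at most `max_interrupt` bp are merged into one compound locus.
#'
#' @param min_repeats integer vector of length 6: minimum repeat count
#'   per unit length 1..6 (each >= 2).
#' @param max_interrupt maximum gap (bp, >= 0) between two tracts merged
#'   as a compound locus.
#' @return object of class `mining_config`.
#' @export
mining_config <- function(min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L),
                          max_interrupt = 100L) {
  min_repeats <- as.integer(min_repeats)
  if (length(min_repeats) != 6L || anyNA(min_repeats))
    stop("min_repeats must be six integers (unit lengths 1..6)")
  if (any(min_repeats < 2L))
    stop("every min_repeats threshold must be >= 2")
  max_interrupt <- as.integer(max_interrupt)
  if (is.na(max_interrupt) || max_interrupt < 0L)
    stop("max_interrupt must be >= 0")
  structure(list(min_repeats = min_repeats,
                 max_interrupt = max_interrupt),
            class = "mining_config")
}

## A motif that is a whole-number repetition of a shorter unit
## (e.g. "ATAT" = ("AT")2) is never reported as its own repeat unit.
.is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (length(motif) == 0L) return(logical(0))
  out <- rep(TRUE, length(motif))
  kk <- k[1L]  # callers pass uniform unit length
  if (kk > 1L) {
    for (d in seq_len(kk - 1L)) {
      if (kk %% d != 0L) next
      rep_d <- strrep(substring(motif, 1L, d), kk %/% d)
      out <- out & (rep_d != motif)
    }
  }
  out
}

## empty loci table with the canonical column set
.empty_loci <- function() {
  data.frame(seq_id = character(0), ssr_type = character(0),
             motif = character(0), repeat_count = integer(0),
             tract_length = integer(0), start = integer(0),
             end = integer(0), annotation = character(0),
             stringsAsFactors = FALSE)
}

## core scan over one residue string; returns perfect tracts only
.find_tracts <- function(seq, seq_id, config) {
  res <- list()
  for (k in 1:6) {
    m <- config$min_repeats[k]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, m - 1L)
    g <- gregexpr(pat, seq, perl = TRUE)[[1L]]
    if (g[1L] == -1L) next
    starts <- as.integer(g)
    lens <- attr(g, "match.length")
    count <- lens %/% k
    motif <- substring(seq, starts, starts + k - 1L)
    keep <- .is_primitive_motif(motif)
    if (!any(keep)) next
    res[[k]] <- data.frame(
      seq_id = seq_id, ssr_type = paste0("p", k), motif = motif[keep],
      repeat_count = count[keep], tract_length = count[keep] * k,
      start = starts[keep], end = starts[keep] + count[keep] * k - 1L,
      annotation = "", stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) return(.empty_loci())
  loci <- do.call(rbind, res)
  ## shorter-unit runs win: suppress a longer-unit tract wholly
  ## contained in a shorter-unit tract's span
  if (nrow(loci) > 1L) {
    unit <- nchar(loci$motif)
    drop <- logical(nrow(loci))
    for (i in seq_len(nrow(loci))) {
      inside <- unit < unit[i] & loci$start <= loci$start[i] &
        loci$end >= loci$end[i]
      if (any(inside)) drop[i] <- TRUE
    }
    loci <- loci[!drop, , drop = FALSE]
  }
  loci <- loci[order(loci$start, nchar(loci$motif)), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Detect perfect microsatellite tracts in one record
#'
#' Finds every maximal perfect tandem run of a primitive 1-6 bp unit
#' meeting the per-unit-length repeat threshold. Tracts never span an N;
#' the motif is reported as first encountered at the tract start (no
#' reverse-complement collapsing); a unit that is itself a repetition of
#' a shorter unit is never reported, and a longer-unit tract wholly
#' inside a shorter-unit tract's span is suppressed.
#'
#' @param record one sequence record (single row of a record set, or a
#'   list with `id` and `residues`).
#' @param config a [mining_config()].
#' @return data.frame of loci (columns seq_id, ssr_type, motif,
#'   repeat_count, tract_length, start, end, annotation), 1-based
#'   inclusive coordinates, sorted by start.
#' @export
find_perfect_ssrs <- function(record, config = mining_config()) {
  record <- .as_record(record)
  .find_tracts(record$residues, record$id, config)
}

#' Merge nearby perfect tracts into compound loci
#'
#' Maximal chains of perfect tracts whose pairwise gaps are each at most
#' `max_interrupt` bp are replaced by one compound locus (type `c`,
#' spanning from the first tract's start to the last tract's end, with
#' the constituent motifs recorded in the annotation column). Isolated
#' tracts pass through unchanged.
#'
#' @param loci data.frame of perfect tracts on one sequence, sorted by
#'   start.
#' @param max_interrupt maximum inter-tract gap in bp.
#' @return data.frame of loci sorted by start.
#' @export
merge_compound <- function(loci, max_interrupt = 100L) {
  if (is.null(loci) || nrow(loci) == 0L) return(.empty_loci())
  if (any(loci$ssr_type == "c"))
    stop("merge_compound expects perfect tracts only")
  if (length(unique(loci$seq_id)) > 1L)
    stop("merge_compound expects tracts from a single sequence")
  if (is.unsorted(loci$start))
    stop("merge_compound expects tracts sorted by start")
  n <- nrow(loci)
  ## chain id: new chain when gap to the running end exceeds the limit
  chain <- integer(n)
  chain[1L] <- 1L
  run_end <- loci$end[1L]
  for (i in seq_len(n)[-1L]) {
    gap <- loci$start[i] - run_end - 1L
    if (gap <= max_interrupt) {
      chain[i] <- chain[i - 1L]
      run_end <- max(run_end, loci$end[i])
    } else {
      chain[i] <- chain[i - 1L] + 1L
      run_end <- loci$end[i]
    }
  }
  pieces <- lapply(split(seq_len(n), chain), function(idx) {
    if (length(idx) == 1L) return(loci[idx, , drop = FALSE])
    sub <- loci[idx, , drop = FALSE]
    s <- min(sub$start); e <- max(sub$end)
    data.frame(seq_id = sub$seq_id[1L], ssr_type = "c",
               motif = NA_character_, repeat_count = NA_integer_,
               tract_length = e - s + 1L, start = s, end = e,
               annotation = paste0("(", sub$motif, ")", sub$repeat_count,
                                   collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine microsatellite loci across a set of records
#'
#' Per-record driver over [find_perfect_ssrs()] and [merge_compound()].
#' Locus ids are `seq_id` plus a per-sequence ordinal.
#'
#' @param records sequence-record set.
#' @param config a [mining_config()].
#' @param compound merge nearby tracts into compound loci (default TRUE).
#' @return data.frame of loci with a leading `locus_id` column; record
#'   order, then start order.
#' @export
mine_genome <- function(records, config = mining_config(),
                        compound = TRUE) {
  if (is.null(records) || nrow(records) == 0L)
    stop("mine_genome needs at least one record")
  pieces <- lapply(seq_len(nrow(records)), function(i) {
    loci <- .find_tracts(records$residues[i], records$id[i], config)
    if (compound) loci <- merge_compound(loci, config$max_interrupt)
    loci
  })
  loci <- do.call(rbind, pieces)
  if (nrow(loci) == 0L) {
    out <- cbind(locus_id = character(0), .empty_loci())
    return(out)
  }
  ordinal <- stats::ave(seq_len(nrow(loci)), loci$seq_id,
                        FUN = seq_along)
  loci <- cbind(locus_id = paste0(loci$seq_id, "_", ordinal), loci,
                stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  loci
}

#' Write a mined-loci table to TSV
#'
#' Columns: locus_id, seq_id, ssr_type, motif, repeat_count,
#' tract_length, start, end (1-based inclusive), annotation.
#'
#' @param loci data.frame from [mine_genome()].
#' @param path output path.
#' @export
write_loci <- function(loci, path) write_tsv(loci, path)

#' Read a mined-loci TSV
#' @param path path written by [write_loci()].
#' @export
read_loci <- function(path) read_tsv(path)
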