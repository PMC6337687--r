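#' In-silico PCR parameters
#'
#' Default stringency is exact matching (no mismatches), appropriate for
#' same-species re-sequencing data; mismatch tolerance with an exact
#' 3'-terminal seed is available for heterologous (transferability) use.
#'
#' @param max_mismatch mismatches tolerated per primer (0-3).
#' @param three_prime_seed bases at the primer 3' end that must match
#'   exactly.
#' @param max_product largest reported product (bp).
#' @param min_product smallest reported product (bp); default (`NULL`)
#'   is the sum of the two primer lengths.
#' @return object of class `epcr_params`.
#' @export
epcr_params <- function(max_mismatch = 0L, three_prime_seed = 5L,
                        max_product = 5000L, min_product = NULL) {
  max_mismatch <- as.integer(max_mismatch)
  if (is.na(max_mismatch) || max_mismatch < 0L || max_mismatch > 3L)
    stop("max_mismatch must be between 0 and 3")
  three_prime_seed <- as.integer(three_prime_seed)
  if (is.na(three_prime_seed) || three_prime_seed < 0L)
    stop("three_prime_seed must be >= 0")
  max_product <- as.integer(max_product)
  if (!is.null(min_product)) {
    min_product <- as.integer(min_product)
    if (min_product > max_product)
      stop("min_product must be <= max_product")
  }
  structure(list(max_mismatch = max_mismatch,
                 three_prime_seed = three_prime_seed,
                 max_product = max_product, min_product = min_product),
            class = "epcr_params")
}

.check_primer_seq <- function(primer) {
  if (length(primer) != 1L || is.na(primer) || !nzchar(primer))
    stop("primer sequence must be a non-empty string")
  if (grepl("[^ACGT]", primer))
    stop("primer contains residues outside {A,C,G,T}: ", primer)
  primer
}

## match a pattern (already oriented to the plus strand) against a
## DNAString subject; returns starts and per-hit mismatch counts, with
## the exact-seed rule applied at the pattern positions in `seed_pos`.
## fixed = TRUE comparison: an N in the subject never matches a base.
.match_oriented <- function(pattern, subject, mm, seed_pos) {
  hits <- Biostrings::matchPattern(pattern, subject, max.mismatch = mm,
                                   with.indels = FALSE, fixed = TRUE)
  starts <- BiocGenerics::start(hits)
  if (length(starts) == 0L)
    return(list(start = integer(0), mismatches = integer(0)))
  if (mm == 0L)
    return(list(start = starts, mismatches = integer(length(starts))))
  pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  views <- as.character(hits)
  n_mm <- integer(length(starts))
  ok <- logical(length(starts))
  for (i in seq_along(starts)) {
    v <- strsplit(views[i], "", fixed = TRUE)[[1L]]
    diff <- v != pat
    n_mm[i] <- sum(diff)
    ok[i] <- n_mm[i] <= mm && !any(diff[seed_pos])
  }
  list(start = starts[ok], mismatches = n_mm[ok])
}

#' Find primer binding sites on a record
#'
#' Reports every position, on both strands, where the primer anneals
#' with at most `max_mismatch` mismatches and no mismatch within the
#' 3'-terminal `three_prime_seed` bases. N in the template never
#' matches. Footprint coordinates are 1-based inclusive on the plus
#' strand.
#'
#' @param primer primer sequence, 5' to 3'.
#' @param record the template sequence record.
#' @param params an [epcr_params()].
#' @return data.frame: seq_id, start, end, strand (+/-), mismatches;
#'   sorted by start.
#' @export
find_matches <- function(primer, record, params = epcr_params()) {
  primer <- .check_primer_seq(primer)
  record <- .as_record(record)
  if (nchar(primer) < params$three_prime_seed)
    stop("primer shorter than three_prime_seed")
  subject <- Biostrings::DNAString(record$residues)
  m <- nchar(primer)
  seed <- params$three_prime_seed
  ## plus strand: primer as-is; 3' seed = last `seed` pattern positions
  seed_plus <- if (seed > 0L) (m - seed + 1L):m else integer(0)
  plus <- .match_oriented(primer, subject, params$max_mismatch,
                          seed_plus)
  ## minus strand: the primer anneals to the minus strand where its
  ## reverse complement occurs on the plus strand; the primer 3' end
  ## maps to the leftmost footprint position
  seed_minus <- if (seed > 0L) 1L:seed else integer(0)
  minus <- .match_oriented(reverse_complement(primer), subject,
                           params$max_mismatch, seed_minus)
  n_all <- length(plus$start) + length(minus$start)
  out <- data.frame(
    seq_id = rep(record$id, n_all),
    start = c(plus$start, minus$start),
    end = c(plus$start, minus$start) + m - 1L,
    strand = c(rep("+", length(plus$start)),
               rep("-", length(minus$start))),
    mismatches = c(plus$mismatches, minus$mismatches),
    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_hits <- function() {
  data.frame(seq_id = character(0), start = integer(0),
             end = integer(0), size = integer(0),
             orientation = character(0), mismatches_f = integer(0),
             mismatches_r = integer(0), stringsAsFactors = FALSE)
}

## core per-record amplicon enumeration from precomputed match sets.
## fwd_plus / rev_rc: forward primer on plus strand, revcomp(reverse)
## occurrences (reverse primer annealing the minus strand); the mirror
## orientation swaps the roles.
.pair_hits <- function(seq_id, left, right, left_len, right_len,
                       min_product, max_product, orientation) {
  if (length(left$start) == 0L || length(right$start) == 0L)
    return(.empty_hits())
  grid <- expand.grid(i = seq_along(left$start),
                      j = seq_along(right$start))
  a <- left$start[grid$i]
  b <- right$start[grid$j] + right_len - 1L
  size <- b - a + 1L
  ## primer footprints sit at the two extremities and must not overlap
  keep <- right$start[grid$j] > a + left_len - 1L &
    size >= min_product & size <= max_product
  if (!any(keep)) return(.empty_hits())
  grid <- grid[keep, , drop = FALSE]
  data.frame(seq_id = seq_id, start = a[keep], end = b[keep],
             size = size[keep], orientation = orientation,
             mismatches_f = if (orientation == "plus")
               left$mismatches[grid$i] else right$mismatches[grid$j],
             mismatches_r = if (orientation == "plus")
               right$mismatches[grid$j] else left$mismatches[grid$i],
             stringsAsFactors = FALSE)
}

## all four oriented match sets for one pair on one DNAString subject
.pair_matches <- function(forward, reverse, subject, params) {
  mf <- nchar(forward); mr <- nchar(reverse)
  seed <- params$three_prime_seed
  mm <- params$max_mismatch
  seed_end <- function(m) if (seed > 0L) (m - seed + 1L):m else integer(0)
  seed_beg <- if (seed > 0L) 1L:seed else integer(0)
  list(
    f_plus = .match_oriented(forward, subject, mm, seed_end(mf)),
    r_rc   = .match_oriented(reverse_complement(reverse), subject, mm,
                             seed_beg),
    r_plus = .match_oriented(reverse, subject, mm, seed_end(mr)),
    f_rc   = .match_oriented(reverse_complement(forward), subject, mm,
                             seed_beg))
}

## amplicons for one pair on one record, given precomputed matches
.epcr_record <- function(seq_id, mset, mf, mr, min_product,
                         max_product) {
  plus <- .pair_hits(seq_id, mset$f_plus, mset$r_rc, mf, mr,
                     min_product, max_product, "plus")
  minus <- .pair_hits(seq_id, mset$r_plus, mset$f_rc, mr, mf,
                      min_product, max_product, "minus")
  hits <- rbind(plus, minus)
  if (nrow(hits) > 1L) {
    ## identical coordinates found by both orientation searches
    ## (palindromic primers) are reported once
    key <- paste(hits$seq_id, hits$start, hits$end)
    hits <- hits[!duplicated(key), , drop = FALSE]
  }
  hits
}

#' Run in-silico PCR for one primer pair
#'
#' Locates all forward/reverse binding-site combinations on each record
#' (both the plus orientation and its mirror on the minus strand),
#' keeps products within the size bounds with non-overlapping primer
#' footprints, deduplicates identical coordinates, and reports amplicon
#' coordinates and sizes.
#'
#' @param pair list or one-row data.frame with `forward` and `reverse`
#'   primer sequences (5' to 3').
#' @param records sequence-record set to amplify from.
#' @param params an [epcr_params()].
#' @return data.frame: seq_id, start, end, size, orientation
#'   (plus/minus), mismatches_f, mismatches_r; sorted by (seq_id,
#'   start).
#' @export
epcr <- function(pair, records, params = epcr_params()) {
  if (is.data.frame(pair)) pair <- as.list(pair[1L, ])
  forward <- .check_primer_seq(pair$forward)
  reverse <- .check_primer_seq(pair$reverse)
  min_product <- if (is.null(params$min_product))
    nchar(forward) + nchar(reverse) else params$min_product
  out <- lapply(seq_len(nrow(records)), function(i) {
    subject <- Biostrings::DNAString(records$residues[i])
    mset <- .pair_matches(forward, reverse, subject, params)
    .epcr_record(records$id[i], mset, nchar(forward), nchar(reverse),
                 min_product, params$max_product)
  })
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$seq_id, hits$start, hits$end), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Construct a genotype set
#'
#' @param genotype_id non-empty genotype label.
#' @param records sequence-record set for this genotype.
#' @return object of class `genotype_set`.
#' @export
genotype_set <- function(genotype_id, records) {
  genotype_id <- as.character(genotype_id)
  if (length(genotype_id) != 1L || !nzchar(genotype_id))
    stop("genotype_id must be a non-empty string")
  if (anyDuplicated(records$id))
    stop("duplicate record ids within genotype ", genotype_id)
  structure(list(genotype_id = genotype_id, records = records),
            class = "genotype_set")
}

#' Batch e-PCR over primer pairs and genotypes
#'
#' Fills the complete (locus, genotype) cross product: each cell holds
#' the amplicon hits (possibly none) plus an asymmetric flag that is
#' TRUE when exactly one of the two primers has a binding site anywhere
#' in the genotype.
#'
#' @param pairs data.frame with columns locus_id, forward, reverse
#'   (unique locus_ids).
#' @param genotypes list of [genotype_set()] objects.
#' @param params an [epcr_params()].
#' @return object of class `amplicon_table`: list with `hits`
#'   (data.frame locus_id, genotype_id, seq_id, start, end, size,
#'   orientation, mismatches_f, mismatches_r) and `cells` (data.frame
#'   locus_id, genotype_id, n_hits, f_matched, r_matched, asymmetric).
#' @export
epcr_batch <- function(pairs, genotypes, params = epcr_params()) {
  if (nrow(pairs) == 0L) stop("no primer pairs supplied")
  if (anyDuplicated(pairs$locus_id))
    stop("duplicate locus_id in primer pairs")
  if (length(genotypes) == 0L) stop("no genotypes supplied")
  if (inherits(genotypes, "genotype_set")) genotypes <- list(genotypes)
  gids <- vapply(genotypes, function(g) g$genotype_id, character(1L))
  if (anyDuplicated(gids)) stop("duplicate genotype ids")
  hit_rows <- list()
  cell_rows <- list()
  for (g in genotypes) {
    subjects <- lapply(g$records$residues, Biostrings::DNAString)
    for (p in seq_len(nrow(pairs))) {
      forward <- .check_primer_seq(pairs$forward[p])
      reverse <- .check_primer_seq(pairs$reverse[p])
      min_product <- if (is.null(params$min_product))
        nchar(forward) + nchar(reverse) else params$min_product
      f_any <- FALSE; r_any <- FALSE
      hits <- list()
      for (i in seq_along(subjects)) {
        mset <- .pair_matches(forward, reverse, subjects[[i]], params)
        f_any <- f_any || length(mset$f_plus$start) > 0L ||
          length(mset$f_rc$start) > 0L
        r_any <- r_any || length(mset$r_rc$start) > 0L ||
          length(mset$r_plus$start) > 0L
        h <- .epcr_record(g$records$id[i], mset, nchar(forward),
                          nchar(reverse), min_product,
                          params$max_product)
        if (nrow(h) > 0L) hits[[length(hits) + 1L]] <- h
      }
      h <- if (length(hits)) do.call(rbind, hits) else .empty_hits()
      if (nrow(h) > 0L) {
        h <- cbind(locus_id = pairs$locus_id[p],
                   genotype_id = g$genotype_id, h,
                   stringsAsFactors = FALSE)
        hit_rows[[length(hit_rows) + 1L]] <- h
      }
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        locus_id = pairs$locus_id[p], genotype_id = g$genotype_id,
        n_hits = nrow(h), f_matched = f_any, r_matched = r_any,
        asymmetric = xor(f_any, r_any), stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    cbind(data.frame(locus_id = character(0),
                     genotype_id = character(0),
                     stringsAsFactors = FALSE), .empty_hits())
  hits <- hits[order(match(hits$locus_id, pairs$locus_id),
                     match(hits$genotype_id, gids), hits$seq_id,
                     hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  cells <- do.call(rbind, cell_rows)
  rownames(cells) <- NULL
  structure(list(hits = hits, cells = cells,
                 locus_ids = pairs$locus_id, genotype_ids = gids),
            class = "amplicon_table")
}

#' @export
print.amplicon_table <- function(x, ...) {
  cat("Amplicon table:", length(x$locus_ids), "loci x",
      length(x$genotype_ids), "genotypes;", nrow(x$hits),
      "amplicon(s)\n")
  invisible(x)
}

#' Write an amplicon table's hits and cell flags to TSV
#'
#' @param table an [epcr_batch()] result.
#' @param path output path for the hit table; the asymmetric flag per
#'   cell is merged in (rows with no product carry NA coordinates).
#' @export
write_amplicons <- function(table, path) {
  cells <- table$cells
  hits <- table$hits
  key_h <- paste(hits$locus_id, hits$genotype_id)
  key_c <- paste(cells$locus_id, cells$genotype_id)
  hits$asymmetric_flag <- cells$asymmetric[match(key_h, key_c)]
  empty <- cells[cells$n_hits == 0L, , drop = FALSE]
  if (nrow(empty) > 0L) {
    pad <- data.frame(locus_id = empty$locus_id,
                      genotype_id = empty$genotype_id,
                      seq_id = NA_character_, start = NA_integer_,
                      end = NA_integer_, size = NA_integer_,
                      orientation = NA_character_,
                      mismatches_f = NA_integer_,
                      mismatches_r = NA_integer_,
                      asymmetric_flag = empty$asymmetric,
                      stringsAsFactors = FALSE)
    hits <- rbind(hits, pad)
  }
  hits <- hits[order(match(hits$locus_id, table$locus_ids),
                     match(hits$genotype_id, table$genotype_ids)), ,
               drop = FALSE]
  write_tsv(hits, path)
}
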