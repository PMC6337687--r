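#' Primer-design parameters
#'
#' Defaults approximate Primer3-style bulk design for uniform-Tm SSR
#' genotyping panels: 500 bp flanks, up to five ranked pairs per locus,
#' primer length 18/20/24 (min/opt/max), Tm 57/60/63 degrees C under the
#' salt-adjusted GC formula at 50 mM Na+, GC fraction 0.20-0.80, product
#' size 100-300 bp, mononucleotide runs capped at 4, and 3'-anchored
#' self-complementarity capped at 3 bp.
#'
#' @param flank_len flank length in bp extracted on each side of a locus.
#' @param n_pairs maximum number of ranked pairs returned per locus.
#' @param len_min,len_opt,len_max primer length bounds/optimum (bp).
#' @param tm_min,tm_opt,tm_max melting-temperature bounds/optimum (deg C).
#' @param gc_min,gc_max GC-content bounds (fraction of length).
#' @param product_min,product_max PCR product size bounds (bp).
#' @param max_polyx longest tolerated mononucleotide run (bp).
#' @param max_3prime_selfcomp longest tolerated 3'-anchored
#'   self-complementary run (bp).
#' @param na_conc monovalent cation concentration (molar) for the Tm
#'   model.
#' @param tm_method `"gc"` (salt-adjusted GC formula, default) or
#'   `"wallace"` (2(A+T) + 4(G+C) rule).
#' @return object of class `primer_params`.
#' @export
primer_params <- function(flank_len = 500L, n_pairs = 5L,
                          len_min = 18L, len_opt = 20L, len_max = 24L,
                          tm_min = 57, tm_opt = 60, tm_max = 63,
                          gc_min = 0.20, gc_max = 0.80,
                          product_min = 100L, product_max = 300L,
                          max_polyx = 4L, max_3prime_selfcomp = 3L,
                          na_conc = 0.05, tm_method = c("gc", "wallace")) {
  tm_method <- match.arg(tm_method)
  p <- list(flank_len = as.integer(flank_len),
            n_pairs = as.integer(n_pairs),
            len_min = as.integer(len_min), len_opt = as.integer(len_opt),
            len_max = as.integer(len_max),
            tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
            gc_min = gc_min, gc_max = gc_max,
            product_min = as.integer(product_min),
            product_max = as.integer(product_max),
            max_polyx = as.integer(max_polyx),
            max_3prime_selfcomp = as.integer(max_3prime_selfcomp),
            na_conc = na_conc, tm_method = tm_method)
  if (p$n_pairs < 1L) stop("n_pairs must be >= 1")
  if (!(p$len_min <= p$len_opt && p$len_opt <= p$len_max))
    stop("primer length bounds must satisfy min <= opt <= max")
  if (!(p$tm_min <= p$tm_opt && p$tm_opt <= p$tm_max))
    stop("Tm bounds must satisfy min <= opt <= max")
  if (p$product_min < 2L * p$len_min)
    stop("product_min must be >= 2 * len_min")
  if (p$flank_len < p$len_min) stop("flank_len too short for primers")
  structure(p, class = "primer_params")
}

#' Extract flanking sequence around a locus
#'
#' Takes up to `flank_len` bp immediately upstream and downstream of the
#' tract (clipped, never padded, at sequence boundaries) and the
#' template spanning upstream + tract + downstream.
#'
#' @param record the source sequence record.
#' @param locus one locus row (needs start, end; 1-based inclusive).
#' @param flank_len flank length in bp.
#' @return object of class `flanked_locus`: list with `locus`,
#'   `upstream`, `downstream`, `template`, and `template_start` (the
#'   record coordinate of template position 1).
#' @export
extract_flanks <- function(record, locus, flank_len = 500L) {
  record <- .as_record(record)
  s <- as.integer(locus$start); e <- as.integer(locus$end)
  if (is.na(s) || is.na(e) || s < 1L || e > record$length || s > e)
    stop("locus coordinates outside record bounds")
  up_from <- max(1L, s - as.integer(flank_len))
  down_to <- min(record$length, e + as.integer(flank_len))
  upstream <- if (s > 1L) substring(record$residues, up_from, s - 1L) else ""
  downstream <- if (e < record$length)
    substring(record$residues, e + 1L, down_to) else ""
  tract <- substring(record$residues, s, e)
  structure(list(locus = locus, upstream = upstream,
                 downstream = downstream,
                 template = paste0(upstream, tract, downstream),
                 template_start = up_from,
                 tract_length = e - s + 1L,
                 seq_id = record$id),
            class = "flanked_locus")
}

#' GC content of a sequence
#'
#' Fraction (#G + #C) / length; N counts in the denominator only.
#' Vectorized.
#'
#' @param seq character vector of non-empty sequences.
#' @return numeric vector in [0, 1].
#' @export
gc_content <- function(seq) {
  n <- nchar(seq)
  if (any(n == 0L)) stop("gc_content of an empty sequence is undefined")
  gc <- nchar(gsub("[^GC]", "", seq))
  gc / n
}

#' Primer melting temperature
#'
#' Default model is the salt-adjusted GC formula
#' `Tm = 81.5 + 16.6 log10([Na+]) + 0.41 (%GC) - 600 / length`,
#' reported to 0.1 degrees C. The Wallace rule `2(A+T) + 4(G+C)` is
#' available as a cross-check for short oligos. Vectorized.
#'
#' @param seq character vector over \{A,C,G,T\}, each at least 8 bp.
#' @param na_conc monovalent cation concentration (molar).
#' @param method `"gc"` or `"wallace"`.
#' @return numeric vector of temperatures in degrees C.
#' @export
melting_temperature <- function(seq, na_conc = 0.05,
                                method = c("gc", "wallace")) {
  method <- match.arg(method)
  if (any(grepl("N", seq, fixed = TRUE)))
    stop("melting temperature undefined for sequences containing N")
  len <- nchar(seq)
  if (any(len < 8L)) stop("sequence too short for Tm (need >= 8 bp)")
  if (method == "wallace") {
    gc <- nchar(gsub("[^GC]", "", seq))
    return(2 * (len - gc) + 4 * gc)
  }
  round(81.5 + 16.6 * log10(na_conc) + 0.41 * (100 * gc_content(seq)) -
          600 / len, 1L)
}

## longest k such that the reverse complement of the 3'-terminal k-mer
## occurs anywhere in the primer. The reverse complement of the
## 3'-suffix of length k is the length-k prefix of the primer's full
## reverse complement, so one precomputed rc string serves all k
## (monotone in k: scan upward).
.selfcomp_3prime <- function(seq, rc = reverse_complement(seq)) {
  n <- nchar(seq)
  k <- 0L
  while (k < n) {
    if (!grepl(substr(rc, 1L, k + 1L), seq, fixed = TRUE)) break
    k <- k + 1L
  }
  k
}

## vectorized hard filters; returns character reason ("" = accept)
.candidate_reason <- function(seq, params) {
  reason <- character(length(seq))
  len <- nchar(seq)
  hasN <- grepl("N", seq, fixed = TRUE)
  reason[hasN] <- "ambiguous_base"
  bad_len <- reason == "" & (len < params$len_min | len > params$len_max)
  reason[bad_len] <- "length"
  polyx <- grepl(sprintf("([ACGT])\\1{%d,}", params$max_polyx), seq,
                 perl = TRUE)
  reason[reason == "" & polyx] <- "poly_x"
  ok <- reason == ""
  if (any(ok)) {
    gc <- gc_content(seq[ok])
    r <- character(sum(ok))
    r[gc < params$gc_min | gc > params$gc_max] <- "gc"
    tm_ok <- r == ""
    if (any(tm_ok)) {
      tm <- melting_temperature(seq[ok][tm_ok], params$na_conc,
                                params$tm_method)
      r[tm_ok][tm < params$tm_min | tm > params$tm_max] <- "tm"
    }
    reason[ok] <- r
  }
  ok <- reason == ""
  if (any(ok)) {
    rc <- reverse_complement(seq[ok])
    sc <- mapply(.selfcomp_3prime, seq[ok], rc, USE.NAMES = FALSE)
    reason[ok][sc > params$max_3prime_selfcomp] <- "self_complementarity_3prime"
  }
  reason
}

#' Check one primer candidate against the hard filters
#'
#' Rejects on: N content, length outside bounds, mononucleotide run
#' longer than `max_polyx`, GC outside bounds, Tm outside bounds, or a
#' 3'-anchored self-complementary run longer than
#' `max_3prime_selfcomp`.
#'
#' @param seq one candidate sequence (5' to 3').
#' @param params a [primer_params()].
#' @return list with `ok` (logical) and `reason` (character, `""` when
#'   accepted).
#' @export
candidate_ok <- function(seq, params = primer_params()) {
  reason <- .candidate_reason(seq, params)[1L]
  list(ok = reason == "", reason = reason)
}

## enumerate accepted candidate windows on one flank strand.
## `starts`/`lens` are template coordinates of the window.
.enum_candidates <- function(template, start_lo, start_hi, params,
                             as_reverse = FALSE) {
  if (start_hi < start_lo) {
    return(data.frame(start = integer(0), len = integer(0),
                      seq = character(0), tm = numeric(0),
                      gc = numeric(0), stringsAsFactors = FALSE))
  }
  grid <- expand.grid(start = start_lo:start_hi,
                      len = params$len_min:params$len_max)
  keep <- grid$start + grid$len - 1L <= nchar(template)
  grid <- grid[keep, , drop = FALSE]
  win <- substring(template, grid$start, grid$start + grid$len - 1L)
  primer <- if (as_reverse) reverse_complement(win) else win
  reason <- .candidate_reason(primer, params)
  ok <- reason == ""
  if (!any(ok)) {
    return(data.frame(start = integer(0), len = integer(0),
                      seq = character(0), tm = numeric(0),
                      gc = numeric(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(start = grid$start[ok], len = grid$len[ok],
                    seq = primer[ok], stringsAsFactors = FALSE)
  out$tm <- melting_temperature(out$seq, params$na_conc, params$tm_method)
  out$gc <- gc_content(out$seq)
  out
}

#' Design ranked primer pairs for a flanked locus
#'
#' Enumerates every accepted forward candidate wholly inside the
#' upstream flank and every accepted reverse candidate (as the reverse
#' complement of a downstream window), keeps pairs whose product size is
#' within bounds and whose Tm difference is at most 5 degrees C, scores
#' them with `penalty = |tm_f - tm_opt| + |tm_r - tm_opt| +
#' 0.5 (|len_f - len_opt| + |len_r - len_opt|) + |tm_f - tm_r|`, and
#' returns the `n_pairs` lowest-penalty pairs with pairwise distinct
#' forward 5' positions (ties broken by penalty, forward start, reverse
#' start). The repeat tract is always fully contained in the product.
#'
#' @param flanked a [extract_flanks()] result.
#' @param params a [primer_params()].
#' @param locus_id identifier used in the output table.
#' @return object of class `primer_set`: list with `locus_id`, `pairs`
#'   (data.frame, possibly empty) and `reason` (design-failure reason,
#'   `""` on success).
#' @export
design_primers <- function(flanked, params = primer_params(),
                           locus_id = NULL) {
  stopifnot(inherits(flanked, "flanked_locus"))
  if (is.null(locus_id))
    locus_id <- if (!is.null(flanked$locus$locus_id))
      as.character(flanked$locus$locus_id) else flanked$seq_id
  U <- nchar(flanked$upstream)
  Tn <- flanked$tract_length
  L <- nchar(flanked$template)
  fail <- function(reason) {
    structure(list(locus_id = locus_id, pairs = .empty_pairs(),
                   reason = reason), class = "primer_set")
  }
  if (U < params$len_min || (L - U - Tn) < params$len_min)
    return(fail("flank_too_short"))
  ## forward windows: wholly in upstream (end <= U); prune starts whose
  ## smallest reachable product already exceeds product_max
  f_lo <- max(1L, U + Tn + params$len_min - params$product_max + 1L)
  f_hi <- U - params$len_min + 1L
  fw <- .enum_candidates(flanked$template, f_lo, f_hi, params,
                         as_reverse = FALSE)
  fw <- fw[fw$start + fw$len - 1L <= U, , drop = FALSE]
  ## reverse windows: wholly in downstream (start >= U+Tn+1)
  r_lo <- U + Tn + 1L
  r_hi <- min(L, f_hi + params$len_min - 1L + params$product_max) -
    params$len_min + 1L
  rv <- .enum_candidates(flanked$template, r_lo, r_hi, params,
                         as_reverse = TRUE)
  if (nrow(fw) == 0L || nrow(rv) == 0L)
    return(fail("no_acceptable_candidate"))
  cross <- expand.grid(f = seq_len(nrow(fw)), r = seq_len(nrow(rv)))
  size <- rv$start[cross$r] + rv$len[cross$r] - fw$start[cross$f]
  tmd <- abs(fw$tm[cross$f] - rv$tm[cross$r])
  keep <- size >= params$product_min & size <= params$product_max &
    tmd <= 5
  if (!any(keep)) return(fail("no_acceptable_pair"))
  cross <- cross[keep, , drop = FALSE]
  size <- size[keep]; tmd <- tmd[keep]
  pen <- abs(fw$tm[cross$f] - params$tm_opt) +
    abs(rv$tm[cross$r] - params$tm_opt) +
    0.5 * (abs(fw$len[cross$f] - params$len_opt) +
             abs(rv$len[cross$r] - params$len_opt)) + tmd
  ord <- order(pen, fw$start[cross$f], rv$start[cross$r])
  cross <- cross[ord, , drop = FALSE]
  size <- size[ord]; pen <- pen[ord]
  ## pair-diversity rule: distinct forward 5' positions
  first <- !duplicated(fw$start[cross$f])
  take <- which(first)[seq_len(min(params$n_pairs, sum(first)))]
  f <- cross$f[take]; r <- cross$r[take]
  pairs <- data.frame(
    locus_id = locus_id, rank = seq_along(take),
    forward = fw$seq[f], reverse = rv$seq[r],
    tm_f = fw$tm[f], tm_r = rv$tm[r],
    gc_f = round(fw$gc[f], 4L), gc_r = round(rv$gc[r], 4L),
    product_size = size[take], penalty = round(pen[take], 4L),
    f_start = fw$start[f], f_len = fw$len[f],
    r_start = rv$start[r], r_len = rv$len[r],
    stringsAsFactors = FALSE)
  structure(list(locus_id = locus_id, pairs = pairs, reason = ""),
            class = "primer_set")
}

.empty_pairs <- function() {
  data.frame(locus_id = character(0), rank = integer(0),
             forward = character(0), reverse = character(0),
             tm_f = numeric(0), tm_r = numeric(0), gc_f = numeric(0),
             gc_r = numeric(0), product_size = integer(0),
             penalty = numeric(0), f_start = integer(0),
             f_len = integer(0), r_start = integer(0),
             r_len = integer(0), stringsAsFactors = FALSE)
}

#' @export
print.primer_set <- function(x, ...) {
  cat("Primer set for locus", x$locus_id, "-", nrow(x$pairs), "pair(s)")
  if (x$reason != "") cat(" [", x$reason, "]", sep = "")
  cat("\n")
  if (nrow(x$pairs) > 0L)
    print(x$pairs[, c("rank", "forward", "reverse", "tm_f", "tm_r",
                      "product_size", "penalty")], ...)
  invisible(x)
}

#' Design primers for every mined locus of a genome
#'
#' Driver over [extract_flanks()] and [design_primers()].
#'
#' @param records sequence-record set the loci were mined from.
#' @param loci data.frame from [mine_genome()].
#' @param params a [primer_params()].
#' @return list with `pairs` (data.frame over all loci, ranked within
#'   locus) and `failures` (data.frame locus_id, reason).
#' @export
design_for_loci <- function(records, loci, params = primer_params()) {
  pairs <- list(); fails <- list()
  for (i in seq_len(nrow(loci))) {
    rec <- records[records$id == loci$seq_id[i], , drop = FALSE]
    if (nrow(rec) != 1L)
      stop("locus ", loci$locus_id[i], " references unknown sequence ",
           loci$seq_id[i])
    fl <- extract_flanks(rec, loci[i, ], params$flank_len)
    ps <- design_primers(fl, params, locus_id = loci$locus_id[i])
    if (nrow(ps$pairs) > 0L) pairs[[length(pairs) + 1L]] <- ps$pairs
    else fails[[length(fails) + 1L]] <-
        data.frame(locus_id = ps$locus_id, reason = ps$reason,
                   stringsAsFactors = FALSE)
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else
         .empty_pairs(),
       failures = if (length(fails)) do.call(rbind, fails) else
         data.frame(locus_id = character(0), reason = character(0),
                    stringsAsFactors = FALSE))
}

#' Write a primer table to TSV
#'
#' The same dialect (columns locus_id, forward, reverse at minimum) is
#' accepted back as "external primer" input by the e-PCR stage.
#'
#' @param pairs data.frame of primer pairs.
#' @param path output path.
#' @export
write_primers <- function(pairs, path) {
  cols <- intersect(c("locus_id", "rank", "forward", "reverse", "tm_f",
                      "tm_r", "gc_f", "gc_r", "product_size", "penalty"),
                    names(pairs))
  write_tsv(pairs[, cols, drop = FALSE], path)
}

#' Read a primer TSV (external-primer dialect)
#'
#' Requires columns locus_id, forward, reverse; extra columns are kept.
#'
#' @param path path to a TSV.
#' @export
read_primers <- function(path) {
  df <- read_tsv(path)
  need <- c("locus_id", "forward", "reverse")
  if (!all(need %in% names(df)))
    stop("primer table needs columns: ", paste(need, collapse = ", "))
  df$forward <- normalize_residues(df$forward)
  df$reverse <- normalize_residues(df$reverse)
  if (anyDuplicated(df$locus_id))
    stop("duplicate locus_id in primer table")
  df
}
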