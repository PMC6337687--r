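## Independent oracles and fixture builders shared across tests.
## The oracles deliberately use different algorithms from the package
## (shift-equality run decomposition for repeat mining; naive
## sliding-window scans for primer matching).

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
        collapse = "")
}

rc_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "", fixed = TRUE)[[1]]]),
        collapse = "")
}

oracle_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    if (strrep(substr(motif, 1L, d), k %/% d) == motif) return(FALSE)
  }
  TRUE
}

## maximal-tandem-run enumerator built on period-k shift equality:
## eq[i] <- s[i] == s[i+k] decomposes the sequence into maximal
## periodic regions; tracts are taken left to right within each
## region, never overlapping a previously taken same-period tract.
oracle_find_ssrs <- function(seq, config = mining_config()) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  rows <- list()
  for (k in 1:6) {
    m <- config$min_repeats[k]
    if (n < (m) * k) next
    eq <- ch[seq_len(n - k)] == ch[(k + 1):n] &
      ch[seq_len(n - k)] != "N"
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    done <- 0L  # end of the last reported tract of this period
    for (ri in seq_along(r$lengths)) {
      if (!r$values[ri]) next
      a <- pos[ri]                      # region start
      b <- pos[ri] + r$lengths[ri] - 1L + k  # region end (sequence)
      s <- max(a, done + 1L)
      count <- (b - s + 1L) %/% k
      if (count < m) next
      e <- s + count * k - 1L
      motif <- paste(ch[s:(s + k - 1L)], collapse = "")
      done <- e
      rows[[length(rows) + 1L]] <-
        data.frame(start = s, end = e, motif = motif,
                   repeat_count = count, unit = k,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), repeat_count = integer(0),
                      unit = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[vapply(out$motif, oracle_primitive, logical(1)), ,
             drop = FALSE]
  ## shorter-unit tract spans suppress contained longer-unit tracts
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    inside <- out$unit < out$unit[i] & out$start <= out$start[i] &
      out$end >= out$end[i]
    if (any(inside)) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## naive sliding-window primer matcher: per-offset mismatch totals via
## shifted vector comparisons; N never matches; exact 3' seed.
oracle_matches <- function(primer, seq, mm = 0L, seed = 5L) {
  p <- strsplit(primer, "", fixed = TRUE)[[1]]
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- length(p); n <- length(ch)
  if (n < m) return(integer(0))
  total <- integer(n - m + 1L)
  seed_bad <- integer(n - m + 1L)
  seed_pos <- if (seed > 0L) (m - seed + 1L):m else integer(0)
  for (j in seq_len(m)) {
    neq <- ch[j:(n - m + j)] != p[j]
    total <- total + neq
    if (j %in% seed_pos) seed_bad <- seed_bad + neq
  }
  which(total <= mm & seed_bad == 0L)
}

## naive e-PCR: all combinations in both orientations, size filter,
## non-overlapping footprints, coordinate dedup
oracle_epcr <- function(forward, reverse, seq,
                        params = epcr_params()) {
  mm <- params$max_mismatch; seed <- params$three_prime_seed
  mf <- nchar(forward); mr <- nchar(reverse)
  min_p <- if (is.null(params$min_product)) mf + mr else
    params$min_product
  hits <- list()
  add <- function(s, e, ori) {
    size <- e - s + 1L
    if (size >= min_p && size <= params$max_product)
      hits[[length(hits) + 1L]] <<-
        data.frame(start = s, end = e, size = size, orientation = ori,
                   stringsAsFactors = FALSE)
  }
  fp <- oracle_matches(forward, seq, mm, seed)
  ## revcomp occurrences: seed sits at the footprint's left end
  rrc <- oracle_matches_rc(reverse, seq, mm, seed)
  for (a in fp) for (b in rrc)
    if (b > a + mf - 1L) add(a, b + mr - 1L, "plus")
  rp <- oracle_matches(reverse, seq, mm, seed)
  frc <- oracle_matches_rc(forward, seq, mm, seed)
  for (a in rp) for (b in frc)
    if (b > a + mr - 1L) add(a, b + mf - 1L, "minus")
  if (length(hits) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      size = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[!duplicated(paste(out$start, out$end)), , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## occurrences of revcomp(primer) with the exact-seed positions mapped
## to the primer 3' end (= leftmost footprint bases)
oracle_matches_rc <- function(primer, seq, mm = 0L, seed = 5L) {
  p <- strsplit(rc_chars(primer), "", fixed = TRUE)[[1]]
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- length(p); n <- length(ch)
  if (n < m) return(integer(0))
  total <- integer(n - m + 1L)
  seed_bad <- integer(n - m + 1L)
  seed_pos <- if (seed > 0L) seq_len(seed) else integer(0)
  for (j in seq_len(m)) {
    neq <- ch[j:(n - m + j)] != p[j]
    total <- total + neq
    if (j %in% seed_pos) seed_bad <- seed_bad + neq
  }
  which(total <= mm & seed_bad == 0L)
}

## published rice HvSSR primer pairs used for validation
table1_primers <- function() {
  data.frame(
    locus_id = c("HvSSR03-37", "HvSSR04-27", "HvSSR07-51",
                 "HvSSR08-14"),
    forward = c("GGAAATCGTCAAGAACGTC", "ATGGATTTAGGCTTGTTTGA",
                "CGAGCATGTCTGTCAAGTAA", "TCCACTTTACATCGTCACAA"),
    reverse = c("TAATTGTATACCACTCCGCC", "ATACTGCGAAGGTGAAGAGA",
                "GTTCGAATGTAATGTTGGCT", "CTACCTCTTAACCGCACATT"),
    stringsAsFactors = FALSE)
}

## published in-silico allele-size profiles for those four loci
table1_sizes <- function() {
  matrix(c(337, 351, 305, 338,
           292, 292, 293, 296,
           286, 281, 282, 293,
           257, 258, 266, 257),
         nrow = 4, byrow = TRUE,
         dimnames = list(table1_primers()$locus_id,
                         c("Cauvery", "Co36", "Co39", "Dubraj")))
}

## amplifiable cassette: forward + spacer + revcomp(reverse), with the
## spacer chosen so the product has exactly `size` bp
make_cassette <- function(forward, reverse, size) {
  spacer_len <- size - nchar(forward) - nchar(reverse)
  stopifnot(spacer_len >= 0)
  paste0(forward, rand_seq(spacer_len), rc_chars(reverse))
}

## genotype genomes carrying one cassette per Table-1 locus, embedded
## in shared random padding so only repeat-count differences vary
make_table1_genotypes <- function() {
  primers <- table1_primers()
  sizes <- table1_sizes()
  lapply(colnames(sizes), function(g) {
    parts <- character(0)
    for (i in seq_len(nrow(primers))) {
      parts <- c(parts, rand_seq(200),
                 make_cassette(primers$forward[i], primers$reverse[i],
                               sizes[i, g]))
    }
    parts <- c(parts, rand_seq(200))
    genotype_set(g, sequence_records("chr1", paste(parts,
                                                   collapse = "")))
  })
}
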