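## Seeded synthetic references, genotypes, and truth tables: a
## download-free test surface emulating re-sequenced genotype panels.

## evaluate expr with a temporary RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.DEFAULT_MOTIFS <- c("AC", "AG", "AT", "AAG", "AAT", "ATC", "ACG",
                     "AAAT", "AAAC")

## break every threshold-meeting tandem run in a background character
## vector by single-base substitutions, iterating to convergence
.scrub_background <- function(bg, config, protect = integer(0)) {
  for (iter in 1:30) {
    tr <- .find_tracts(paste(bg, collapse = ""), "bg", config)
    if (length(protect) && nrow(tr) > 0L) {
      inside <- tr$start %in% protect
      tr <- tr[!inside, , drop = FALSE]
    }
    if (nrow(tr) == 0L) return(bg)
    for (i in seq_len(nrow(tr))) {
      mid <- (tr$start[i] + tr$end[i]) %/% 2L
      bg[mid] <- setdiff(.BASES, bg[mid])[1L]
    }
  }
  stop("background scrub did not converge")
}

## pick a base different from every base in `avoid`
.other_base <- function(avoid) setdiff(.BASES, avoid)[1L]

#' Generate a synthetic reference genome with planted SSR loci
#'
#' Builds a random A/C/G/T background scrubbed of incidental
#' threshold-meeting tandem runs, then plants `n_loci` perfect repeat
#' tracts (motifs drawn from `motif_pool`, repeat counts from
#' `repeat_range`) in unique flanking context with at least ~1 kb
#' spacing. Optionally copies the first `n_duplicated` loci together
#' with their 500 bp flanks to a second location (paralogy material).
#' Boundary bases are forced, and a verify-and-repair mining pass run,
#' so that the planted loci are exactly the genome's mineable locus
#' set. Deterministic under `seed`.
#'
#' @param n_loci number of planted loci.
#' @param genome_len genome length in bp (needs roughly 1.3 kb per
#'   planted locus plus per duplicate).
#' @param motif_pool primitive repeat units (1-6 bp) to draw from.
#' @param repeat_range integer range of reference repeat counts.
#' @param seed integer seed; all randomness flows from it.
#' @param config a [mining_config()].
#' @param n_duplicated how many loci to duplicate (taken from the
#'   first loci).
#' @return list with `records` (single-chromosome record set) and
#'   `truth` (object of class `synthetic_truth`: planted locus table
#'   with coordinates, motifs, repeat counts, duplication links).
#' @export
generate_reference <- function(n_loci, genome_len = 100000L,
                               motif_pool = .DEFAULT_MOTIFS,
                               repeat_range = c(8L, 15L), seed = 1L,
                               config = mining_config(),
                               n_duplicated = 0L) {
  .with_seed(seed, {
    n_loci <- as.integer(n_loci)
    genome_len <- as.integer(genome_len)
    n_blocks <- n_loci + as.integer(n_duplicated)
    if (n_duplicated > n_loci)
      stop("n_duplicated cannot exceed n_loci")
    if (n_blocks > 0L) {
      block <- genome_len %/% n_blocks
      if (block < 1300L)
        stop("genome_len too small to place ", n_blocks,
             " loci with 500 bp flanks and 1 kb spacing")
    }
    bg <- sample(.BASES, genome_len, replace = TRUE)
    bg <- .scrub_background(bg, config)
    if (n_loci == 0L) {
      truth <- structure(list(
        loci = data.frame(truth_id = character(0), seq_id = character(0),
                          start = integer(0), end = integer(0),
                          motif = character(0), unit_len = integer(0),
                          repeat_count = integer(0),
                          duplicate_of = character(0),
                          stringsAsFactors = FALSE),
        config = config, seed = seed, genome_len = genome_len),
        class = "synthetic_truth")
      return(list(records = sequence_records("chr1",
                                             paste(bg, collapse = "")),
                  truth = truth))
    }
    rows <- vector("list", n_blocks)
    for (i in seq_len(n_loci)) {
      motif <- sample(motif_pool, 1L)
      k <- nchar(motif)
      thr <- config$min_repeats[k]
      count <- sample(max(repeat_range[1L], thr):repeat_range[2L], 1L)
      tl <- count * k
      off <- sample(551L:(block - 550L - tl), 1L)
      s <- (i - 1L) * block + off
      e <- s + tl - 1L
      bg[s:e] <- strsplit(strrep(motif, count), "", fixed = TRUE)[[1L]]
      ## forbid one-unit or rotated-phase extension across boundaries
      bg[s - 1L] <- .other_base(c(substr(motif, k, k), bg[s - 2L]))
      bg[e + 1L] <- .other_base(c(substr(motif, 1L, 1L), bg[e + 2L]))
      rows[[i]] <- data.frame(
        truth_id = sprintf("L%02d", i), seq_id = "chr1", start = s,
        end = e, motif = motif, unit_len = k, repeat_count = count,
        duplicate_of = NA_character_, stringsAsFactors = FALSE)
    }
    for (j in seq_len(as.integer(n_duplicated))) {
      src <- rows[[j]]
      cassette <- bg[(src$start - 500L):(src$end + 500L)]
      tl <- src$end - src$start + 1L
      blk <- n_loci + j
      off <- sample(551L:(block - 550L - tl), 1L)
      s <- (blk - 1L) * block + off
      pos0 <- s - 500L
      bg[pos0:(pos0 + length(cassette) - 1L)] <- cassette
      rows[[n_loci + j]] <- data.frame(
        truth_id = sprintf("L%02d_dup", j), seq_id = "chr1",
        start = s, end = s + tl - 1L, motif = src$motif,
        unit_len = src$unit_len, repeat_count = src$repeat_count,
        duplicate_of = src$truth_id, stringsAsFactors = FALSE)
    }
    loci <- do.call(rbind, rows)
    loci <- loci[order(loci$start), , drop = FALSE]
    rownames(loci) <- NULL
    ## verify-and-repair: the mineable tract set must equal the truth
    for (iter in 1:10) {
      mined <- .find_tracts(paste(bg, collapse = ""), "chr1", config)
      key_m <- paste(mined$start, mined$end, mined$motif)
      key_t <- paste(loci$start, loci$end, loci$motif)
      if (setequal(key_m, key_t) && nrow(mined) == nrow(loci)) break
      if (any(!(key_t %in% key_m)))
        stop("fixture generation damaged a planted locus")
      extra <- mined[!(key_m %in% key_t), , drop = FALSE]
      for (i in seq_len(nrow(extra))) {
        overlaps <- any(extra$start[i] <= loci$end &
                          extra$end[i] >= loci$start)
        if (overlaps)
          stop("fixture generation produced a tract overlapping a ",
               "planted locus")
        mid <- (extra$start[i] + extra$end[i]) %/% 2L
        bg[mid] <- .other_base(c(bg[mid], bg[mid - 1L], bg[mid + 1L]))
      }
      if (iter == 10L) stop("fixture repair did not converge")
    }
    truth <- structure(list(loci = loci, config = config, seed = seed,
                            genome_len = genome_len),
                       class = "synthetic_truth")
    list(records = sequence_records("chr1", paste(bg, collapse = "")),
         truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:", nrow(x$loci), "planted loci")
  nd <- sum(!is.na(x$loci$duplicate_of))
  if (nd > 0L) cat(" (", nd, " duplicated)", sep = "")
  if (!is.null(x$deltas))
    cat(";", ncol(x$deltas), "genotypes")
  cat("\n")
  invisible(x)
}

## design the rank-1 primer pair for every truth locus; returns a
## data.frame with reference-coordinate 3' positions of both primers
.truth_primers <- function(reference, truth, params) {
  loci <- truth$loci
  rows <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    fl <- extract_flanks(reference, loci[i, ], params$flank_len)
    ps <- design_primers(fl, params, locus_id = loci$truth_id[i])
    if (nrow(ps$pairs) == 0L) {
      rows[[i]] <- data.frame(
        truth_id = loci$truth_id[i], designed = FALSE,
        forward = NA_character_, reverse = NA_character_,
        product_size = NA_integer_, f_3p = NA_integer_,
        r_3p = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    p1 <- ps$pairs[1L, ]
    rows[[i]] <- data.frame(
      truth_id = loci$truth_id[i], designed = TRUE,
      forward = p1$forward, reverse = p1$reverse,
      product_size = p1$product_size,
      ## forward primer 3' end = rightmost footprint base;
      ## reverse primer 3' end = leftmost plus-strand footprint base
      f_3p = fl$template_start + p1$f_start + p1$f_len - 2L,
      r_3p = fl$template_start + p1$r_start - 1L,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Derive genotype genomes from a synthetic reference
#'
#' Each genotype is the reference with every planted tract resized by a
#' per-locus signed repeat-count delta (drawn uniformly from
#' `delta_range`, truncated so the count stays at or above the mining
#' threshold). With probability `null_rate` a (non-duplicated) locus is
#' turned into a null allele in a genotype by a single substitution at
#' the 3'-terminal base of one of its rank-1 primer binding sites.
#' Background SNPs (substitutions) are placed only outside the planted
#' 500 bp flank windows. Deterministic under `seed`.
#'
#' @param reference record set from [generate_reference()].
#' @param truth the matching `synthetic_truth`.
#' @param n_genotypes number of derived genotypes.
#' @param delta_range integer range of repeat-count deltas.
#' @param null_rate per-cell null-allele probability.
#' @param snp_rate per-base substitution rate outside flank windows.
#' @param seed integer seed.
#' @param params [primer_params()] used to locate primer sites (and
#'   reused by downstream recovery checks).
#' @return list with `genotypes` (list of [genotype_set()]) and
#'   `truth` (updated: `$deltas` locus-by-genotype matrix, `$nulls`
#'   data.frame, `$primers` rank-1 primer table).
#' @export
generate_genotypes <- function(reference, truth, n_genotypes = 4L,
                               delta_range = c(-3L, 3L),
                               null_rate = 0, snp_rate = 0, seed = 1L,
                               params = primer_params()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  loci <- truth$loci
  primers <- .truth_primers(reference, truth, params)
  .with_seed(seed + 1L, {
    gids <- paste0("geno", seq_len(n_genotypes))
    nl <- nrow(loci)
    deltas <- matrix(0L, nrow = nl, ncol = n_genotypes,
                     dimnames = list(loci$truth_id, gids))
    for (i in seq_len(nl)) {
      thr <- truth$config$min_repeats[loci$unit_len[i]]
      lo <- max(delta_range[1L], thr - loci$repeat_count[i])
      hi <- delta_range[2L]
      deltas[i, ] <- sample(lo:hi, n_genotypes, replace = TRUE)
    }
    ## null alleles only at single-copy loci with designed primers
    dup_ids <- unique(c(loci$truth_id[!is.na(loci$duplicate_of)],
                        loci$duplicate_of[!is.na(loci$duplicate_of)]))
    nullable <- !(loci$truth_id %in% dup_ids) &
      primers$designed[match(loci$truth_id, primers$truth_id)]
    nulls <- list()
    if (null_rate > 0) {
      for (i in which(nullable)) for (g in seq_len(n_genotypes)) {
        if (stats::runif(1L) < null_rate) {
          side <- sample(c("forward", "reverse"), 1L)
          pr <- primers[primers$truth_id == loci$truth_id[i], ]
          nulls[[length(nulls) + 1L]] <- data.frame(
            truth_id = loci$truth_id[i], genotype_id = gids[g],
            primer = side,
            ref_pos = if (side == "forward") pr$f_3p else pr$r_3p,
            stringsAsFactors = FALSE)
        }
      }
    }
    nulls <- if (length(nulls)) do.call(rbind, nulls) else
      data.frame(truth_id = character(0), genotype_id = character(0),
                 primer = character(0), ref_pos = integer(0),
                 stringsAsFactors = FALSE)
    ref_chars <- strsplit(reference$residues[1L], "", fixed = TRUE)[[1L]]
    ## flank-window mask for SNP placement
    allowed <- NULL
    if (snp_rate > 0) {
      mask <- rep(TRUE, length(ref_chars))
      for (i in seq_len(nl)) {
        a <- max(1L, loci$start[i] - params$flank_len)
        b <- min(length(ref_chars), loci$end[i] + params$flank_len)
        mask[a:b] <- FALSE
      }
      allowed <- which(mask)
    }
    genotypes <- vector("list", n_genotypes)
    ord <- order(loci$start)
    for (g in seq_len(n_genotypes)) {
      chars <- ref_chars
      gn <- nulls[nulls$genotype_id == gids[g], , drop = FALSE]
      for (r in seq_len(nrow(gn)))
        chars[gn$ref_pos[r]] <-
          sample(setdiff(.BASES, chars[gn$ref_pos[r]]), 1L)
      if (!is.null(allowed) && length(allowed) > 0L) {
        n_snp <- stats::rbinom(1L, length(allowed), snp_rate)
        if (n_snp > 0L) {
          pos <- sample(allowed, n_snp)
          for (p in pos)
            chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
        }
      }
      ## splice resized tracts in one left-to-right pass
      parts <- character(0)
      prev <- 1L
      for (i in ord) {
        cnt <- loci$repeat_count[i] + deltas[loci$truth_id[i], g]
        parts <- c(parts,
                   paste(chars[prev:(loci$start[i] - 1L)],
                         collapse = ""),
                   strrep(loci$motif[i], cnt))
        prev <- loci$end[i] + 1L
      }
      parts <- c(parts, paste(chars[prev:length(chars)], collapse = ""))
      genotypes[[g]] <- genotype_set(
        gids[g],
        sequence_records(reference$id[1L],
                         paste(parts, collapse = "")))
    }
    truth$deltas <- deltas
    truth$nulls <- nulls
    truth$primers <- primers
    truth$genotype_ids <- gids
    list(genotypes = genotypes, truth = truth)
  })
}

#' Expected locus calls implied by a synthetic truth table
#'
#' Computes, by arithmetic on the truth table alone (no sequence
#' matching), the allele sizes and status each planted locus should
#' produce when the pipeline is run with the reference included as
#' genotype zero: per genotype, each copy of a locus's cassette yields
#' `rank-1 product size + unit length x delta` unless nulled; the
#' status rules are those of [call_locus()].
#'
#' @param truth a `synthetic_truth` updated by [generate_genotypes()].
#' @param include_reference include the reference as first genotype.
#' @return data.frame: truth_id, status, and one expected-label column
#'   per genotype (size, "NA", or "MULTI:a;b"); loci without designed
#'   primers are omitted.
#' @export
truth_expected_calls <- function(truth, include_reference = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"),
            !is.null(truth$deltas))
  loci <- truth$loci
  primers <- truth$primers
  gids <- truth$genotype_ids
  all_g <- c(if (include_reference) "reference", gids)
  ## cassette group: a locus plus its duplicates share primer sites
  group_key <- ifelse(is.na(loci$duplicate_of), loci$truth_id,
                      loci$duplicate_of)
  out <- list()
  for (i in seq_len(nrow(loci))) {
    pr <- primers[primers$truth_id == loci$truth_id[i], ]
    if (!pr$designed) next
    members <- which(group_key == group_key[i])
    labels <- character(length(all_g))
    sizes_by_g <- vector("list", length(all_g))
    for (gi in seq_along(all_g)) {
      g <- all_g[gi]
      sizes <- integer(0)
      for (m in members) {
        if (g == "reference") {
          sizes <- c(sizes, pr$product_size)
        } else {
          nulled <- nrow(truth$nulls) > 0L &&
            any(truth$nulls$truth_id == loci$truth_id[m] &
                  truth$nulls$genotype_id == g)
          if (nulled) next
          sizes <- c(sizes, pr$product_size + loci$unit_len[m] *
                       truth$deltas[loci$truth_id[m], g])
        }
      }
      sizes_by_g[[gi]] <- sizes
    }
    names(sizes_by_g) <- all_g
    cl <- call_locus(loci$truth_id[i], sizes_by_g)
    row <- data.frame(truth_id = loci$truth_id[i], status = cl$status,
                      stringsAsFactors = FALSE)
    for (gi in seq_along(all_g)) row[[all_g[gi]]] <- cl$allele_label[gi]
    out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}

#' Compare a pipeline result against the planted truth
#'
#' Maps mined loci to planted truth loci by exact coordinates, derives
#' the expected per-genotype allele labels and statuses from the truth
#' table with [truth_expected_calls()], and counts agreements with the
#' observed polymorphism report.
#'
#' @param result a [run_polymorphism_pipeline()] result (run with the
#'   reference included).
#' @param truth the `synthetic_truth` updated by
#'   [generate_genotypes()].
#' @return list of counts: `n_truth`, `n_mined_matched` (mined loci
#'   with exact truth coordinates), `n_evaluated` (loci with designed
#'   primers compared), `status_matches`, `cell_matches`, `n_cells`,
#'   plus `status_concordance` and `cell_concordance` fractions.
#' @export
compare_to_truth <- function(result, truth) {
  stopifnot(inherits(truth, "synthetic_truth"),
            !is.null(result$report))
  loci <- result$loci
  tl <- truth$loci
  key_m <- paste(loci$seq_id, loci$start, loci$end, loci$motif)
  key_t <- paste(tl$seq_id, tl$start, tl$end, tl$motif)
  map <- match(key_m, key_t)
  expected <- truth_expected_calls(truth)
  obs_mat <- result$report$matrix
  obs_calls <- result$report$calls
  gcols <- names(expected)[-(1:2)]
  n_eval <- 0L; status_ok <- 0L; cell_ok <- 0L; n_cells <- 0L
  for (i in seq_len(nrow(loci))) {
    if (is.na(map[i])) next
    tid <- tl$truth_id[map[i]]
    e <- expected[expected$truth_id == tid, , drop = FALSE]
    if (nrow(e) == 0L) next  # no designed primers for this locus
    o_status <- obs_calls$status[obs_calls$locus_id == loci$locus_id[i]]
    if (length(o_status) == 0L) next
    n_eval <- n_eval + 1L
    if (o_status == e$status) status_ok <- status_ok + 1L
    o_row <- obs_mat[obs_mat$locus_id == loci$locus_id[i], , drop = FALSE]
    for (j in seq_along(gcols)) {
      n_cells <- n_cells + 1L
      ## expected columns are reference + genoK in generation order;
      ## the observed matrix carries the same genotypes in the same
      ## order (possibly under different labels)
      if (o_row[[j + 1L]] == e[[gcols[j]]]) cell_ok <- cell_ok + 1L
    }
  }
  list(n_truth = nrow(tl), n_mined_matched = sum(!is.na(map)),
       n_evaluated = n_eval, status_matches = status_ok,
       cell_matches = cell_ok, n_cells = n_cells,
       status_concordance = if (n_eval > 0L) status_ok / n_eval else
         NA_real_,
       cell_concordance = if (n_cells > 0L) cell_ok / n_cells else
         NA_real_)
}

#' Write fixture files
#'
#' Writes `reference.fasta`, `genotype_<k>.fasta` and `truth.tsv`
#' (planted locus table with per-genotype deltas and null flags) to a
#' directory.
#'
#' @param reference record set from [generate_reference()].
#' @param genotypes list of genotype sets.
#' @param truth the updated `synthetic_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(reference, genotypes, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(reference, file.path(dir, "reference.fasta"))
  for (k in seq_along(genotypes))
    write_fasta(genotypes[[k]]$records,
                file.path(dir, sprintf("genotype_%d.fasta", k)))
  tab <- truth$loci
  if (!is.null(truth$deltas)) {
    for (g in colnames(truth$deltas))
      tab[[paste0("delta_", g)]] <- truth$deltas[tab$truth_id, g]
    if (nrow(truth$nulls) > 0L) {
      key <- paste(truth$nulls$truth_id, truth$nulls$genotype_id)
      for (g in truth$genotype_ids)
        tab[[paste0("null_", g)]] <-
          paste(tab$truth_id, g) %in% key
    }
  }
  write_tsv(tab, file.path(dir, "truth.tsv"))
  invisible(dir)
}
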