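#' Call one locus from per-genotype amplicon sizes
#'
#' A genotype's allele is its single product size; no product is
#' MISSING, two or more products is MULTI. The locus is PARALOGOUS as
#' soon as any genotype is MULTI (multi-locus amplification makes
#' length genotyping unreliable); otherwise it is POLYMORPHIC when at
#' least two single-product genotypes show at least two distinct sizes,
#' MONOMORPHIC when at least two single-product genotypes all agree,
#' and INSUFFICIENT when fewer than two genotypes have a single
#' product. Missing genotypes are reported but never make a locus
#' polymorphic.
#'
#' @param locus_id locus identifier.
#' @param sizes_by_genotype named list; one integer vector of product
#'   sizes per genotype (length 0 = no product). Genotype order is
#'   preserved.
#' @return object of class `locus_call`: list with `locus_id`,
#'   `alleles` (named list of sizes / `NA` for missing), `allele_label`
#'   (named character: size, "NA", or "MULTI:a;b"), `status`,
#'   `distinct_allele_sizes`.
#' @export
call_locus <- function(locus_id, sizes_by_genotype) {
  if (is.null(names(sizes_by_genotype)) ||
      any(!nzchar(names(sizes_by_genotype))))
    stop("sizes_by_genotype must be a named list (one entry/genotype)")
  n_hits <- lengths(sizes_by_genotype)
  label <- vapply(sizes_by_genotype, function(s) {
    if (length(s) == 0L) "NA"
    else if (length(s) == 1L) as.character(s)
    else paste0("MULTI:", paste(sort(s), collapse = ";"))
  }, character(1L))
  singles <- unlist(sizes_by_genotype[n_hits == 1L], use.names = FALSE)
  status <- if (any(n_hits >= 2L)) "PARALOGOUS"
  else if (length(singles) < 2L) "INSUFFICIENT"
  else if (length(unique(singles)) >= 2L) "POLYMORPHIC"
  else "MONOMORPHIC"
  structure(list(locus_id = locus_id,
                 alleles = sizes_by_genotype,
                 allele_label = label,
                 status = status,
                 distinct_allele_sizes = sort(unique(singles))),
            class = "locus_call")
}

#' @export
print.locus_call <- function(x, ...) {
  cat(x$locus_id, ": ", x$status, " [",
      paste(names(x$allele_label), x$allele_label, sep = "=",
            collapse = ", "), "]\n", sep = "")
  invisible(x)
}

.STATUSES <- c("POLYMORPHIC", "MONOMORPHIC", "INSUFFICIENT",
               "PARALOGOUS")

#' Detect allele-length polymorphism from an amplicon table
#'
#' Applies [call_locus()] to every locus of a complete amplicon table
#' and assembles the locus-by-genotype allele-size matrix plus summary
#' counts per status.
#'
#' @param table an [epcr_batch()] result.
#' @return object of class `polymorphism_report`: list with `calls`
#'   (data.frame locus_id, status, n_alleles, allele_sizes, note),
#'   `matrix` (data.frame: locus_id plus one character column per
#'   genotype, entries a size, "NA" or "MULTI:a;b"), `summary` (named
#'   integer counts per status) and `genotype_ids`.
#' @export
detect_polymorphism <- function(table) {
  stopifnot(inherits(table, "amplicon_table"))
  gids <- table$genotype_ids
  calls <- vector("list", length(table$locus_ids))
  mat <- matrix("NA", nrow = length(table$locus_ids),
                ncol = length(gids),
                dimnames = list(table$locus_ids, gids))
  for (li in seq_along(table$locus_ids)) {
    lid <- table$locus_ids[li]
    h <- table$hits[table$hits$locus_id == lid, , drop = FALSE]
    sizes <- lapply(gids, function(g)
      h$size[h$genotype_id == g])
    names(sizes) <- gids
    cl <- call_locus(lid, sizes)
    mat[li, ] <- cl$allele_label
    calls[[li]] <- data.frame(
      locus_id = lid, status = cl$status,
      n_alleles = length(cl$distinct_allele_sizes),
      allele_sizes = paste(cl$distinct_allele_sizes, collapse = ";"),
      note = if (cl$status == "PARALOGOUS")
        "multi-product genotype" else "",
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  counts <- table(factor(calls$status, levels = .STATUSES))
  summary <- stats::setNames(as.integer(counts), .STATUSES)
  stopifnot(sum(summary) == nrow(calls))
  matrix_df <- cbind(data.frame(locus_id = table$locus_ids,
                                stringsAsFactors = FALSE),
                     as.data.frame(mat, stringsAsFactors = FALSE,
                                   row.names = NULL))
  rownames(matrix_df) <- NULL
  structure(list(calls = calls, matrix = matrix_df, summary = summary,
                 genotype_ids = gids),
            class = "polymorphism_report")
}

#' @export
print.polymorphism_report <- function(x, ...) {
  cat("Polymorphism report:", nrow(x$calls), "loci x",
      length(x$genotype_ids), "genotypes\n")
  for (s in names(x$summary))
    if (x$summary[[s]] > 0L) cat(" ", s, ":", x$summary[[s]], "\n")
  invisible(x)
}

#' @method summary polymorphism_report
#' @export
summary.polymorphism_report <- function(object, ...) {
  object$summary
}

#' Write the two polymorphism report TSVs
#'
#' @param report a [detect_polymorphism()] result.
#' @param matrix_path path for the locus-by-genotype allele matrix.
#' @param calls_path path for the per-locus status table.
#' @export
write_polymorphism <- function(report, matrix_path, calls_path) {
  write_tsv(report$matrix, matrix_path)
  write_tsv(report$calls, calls_path)
  invisible(NULL)
}

#' Evaluate cross-species marker transferability
#'
#' Runs e-PCR of each pair against a heterologous host genome and
#' classifies each locus: TRANSFERABLE (a product of at most
#' `size_cutoff` bp with both primers matched), FILTERED_SIZE (products
#' only above the cutoff), FILTERED_ASYMMETRIC (exactly one primer has
#' a binding site), or ABSENT.
#'
#' @param pairs data.frame with locus_id, forward, reverse.
#' @param host a [genotype_set()] of the host species' records.
#' @param size_cutoff amplicon size filter in bp (default 500).
#' @param params an [epcr_params()]; mismatch tolerance is typically
#'   raised for heterologous templates.
#' @return object of class `transferability_report`: data.frame
#'   `table` (locus_id, disposition, size, note) plus
#'   `count_transferable`.
#' @export
evaluate_transferability <- function(pairs, host, size_cutoff = 500L,
                                     params = epcr_params()) {
  stopifnot(inherits(host, "genotype_set"))
  tab <- epcr_batch(pairs, list(host), params)
  rows <- lapply(seq_len(nrow(pairs)), function(p) {
    lid <- pairs$locus_id[p]
    cell <- tab$cells[tab$cells$locus_id == lid, , drop = FALSE]
    sizes <- tab$hits$size[tab$hits$locus_id == lid]
    if (length(sizes) > 0L) {
      if (any(sizes <= size_cutoff)) {
        data.frame(locus_id = lid, disposition = "TRANSFERABLE",
                   size = min(sizes[sizes <= size_cutoff]), note = "",
                   stringsAsFactors = FALSE)
      } else {
        data.frame(locus_id = lid, disposition = "FILTERED_SIZE",
                   size = min(sizes), note = "", stringsAsFactors = FALSE)
      }
    } else if (cell$asymmetric) {
      data.frame(locus_id = lid, disposition = "FILTERED_ASYMMETRIC",
                 size = NA_integer_, note = "", stringsAsFactors = FALSE)
    } else {
      data.frame(locus_id = lid, disposition = "ABSENT",
                 size = NA_integer_,
                 note = if (cell$f_matched && cell$r_matched)
                   "both primers matched, no valid product" else "",
                 stringsAsFactors = FALSE)
    }
  })
  table <- do.call(rbind, rows)
  structure(list(table = table,
                 count_transferable =
                   sum(table$disposition == "TRANSFERABLE"),
                 size_cutoff = size_cutoff),
            class = "transferability_report")
}

#' @export
print.transferability_report <- function(x, ...) {
  cat("Transferability:", x$count_transferable, "of", nrow(x$table),
      "loci transferable (size cutoff", x$size_cutoff, "bp)\n")
  invisible(x)
}

#' Screen genic (transcript-designed) primers against a genome
#'
#' Primers designed on transcript templates can fail on genomic DNA
#' when the amplicon contains an intron or a primer spans an exon-exon
#' junction. For each pair, the expected size is its product on the
#' transcript set; the genomic products are then compared: OK when a
#' genomic product matches the expected size; INTRON_CONTAINING (with
#' the size excess) when a genomic product is larger; JUNCTION_PRIMER
#' when at least one primer has no genomic binding site;
#' NO_GENOMIC_PRODUCT_OVERSIZE when both primers bind but no product
#' falls within `max_product` (oversized intron).
#'
#' @param pairs data.frame with locus_id, forward, reverse.
#' @param transcripts sequence-record set of transcript templates.
#' @param genome a [genotype_set()] of the genomic records.
#' @param params an [epcr_params()].
#' @return data.frame: locus_id, expected_size, genomic_sizes
#'   (semicolon-joined), verdict, delta_bp, note.
#' @export
evaluate_genic_primers <- function(pairs, transcripts, genome,
                                   params = epcr_params()) {
  stopifnot(inherits(genome, "genotype_set"))
  tx <- genotype_set("transcripts", transcripts)
  tx_tab <- epcr_batch(pairs, list(tx), params)
  g_tab <- epcr_batch(pairs, list(genome), params)
  rows <- lapply(seq_len(nrow(pairs)), function(p) {
    lid <- pairs$locus_id[p]
    tx_sizes <- tx_tab$hits$size[tx_tab$hits$locus_id == lid]
    g_sizes <- g_tab$hits$size[g_tab$hits$locus_id == lid]
    cell <- g_tab$cells[g_tab$cells$locus_id == lid, , drop = FALSE]
    if (length(tx_sizes) == 0L) {
      return(data.frame(locus_id = lid, expected_size = NA_integer_,
                        genomic_sizes = "", verdict = "INPUT_ERROR",
                        delta_bp = NA_integer_,
                        note = "no transcript product for this pair",
                        stringsAsFactors = FALSE))
    }
    expected <- tx_sizes[1L]
    note <- if (length(tx_sizes) > 1L)
      "multiple transcript products; first used" else ""
    if (length(g_sizes) == 0L) {
      verdict <- if (cell$f_matched && cell$r_matched)
        "NO_GENOMIC_PRODUCT_OVERSIZE" else "JUNCTION_PRIMER"
      delta <- NA_integer_
    } else if (any(g_sizes > expected)) {
      verdict <- "INTRON_CONTAINING"
      delta <- max(g_sizes) - expected
    } else {
      verdict <- "OK"
      delta <- 0L
      if (all(g_sizes < expected))
        note <- paste0(note, if (nzchar(note)) "; ",
                       "genomic product smaller than transcript product")
    }
    data.frame(locus_id = lid, expected_size = expected,
               genomic_sizes = paste(sort(g_sizes), collapse = ";"),
               verdict = verdict, delta_bp = delta, note = note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
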