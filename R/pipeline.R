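#' Run the self-designed-primer polymorphism pipeline
#'
#' Mines SSR loci from the reference, designs primers (the rank-1 pair
#' per locus is used for genotyping), runs batch e-PCR over the
#' reference (as genotype zero, unless disabled) and every genotype,
#' and calls per-locus polymorphism status.
#'
#' @param reference sequence-record set of the reference
#'   genome/transcriptome.
#' @param genotypes list of [genotype_set()] objects.
#' @param mining a [mining_config()].
#' @param primers a [primer_params()].
#' @param pcr an [epcr_params()].
#' @param include_reference include the reference as genotype
#'   `"reference"` in the comparison (default TRUE).
#' @return list with `loci`, `primer_pairs` (all ranks),
#'   `design_failures`, `table` (amplicon table) and `report`
#'   (polymorphism report). `NULL` table/report when no locus yields
#'   primers.
#' @export
run_polymorphism_pipeline <- function(reference, genotypes,
                                      mining = mining_config(),
                                      primers = primer_params(),
                                      pcr = epcr_params(),
                                      include_reference = TRUE) {
  loci <- mine_genome(reference, mining)
  design <- design_for_loci(reference, loci, primers)
  rank1 <- design$pairs[design$pairs$rank == 1L, , drop = FALSE]
  gsets <- genotypes
  if (include_reference)
    gsets <- c(list(genotype_set("reference", reference)), gsets)
  if (nrow(rank1) == 0L) {
    return(list(loci = loci, primer_pairs = design$pairs,
                design_failures = design$failures, table = NULL,
                report = NULL))
  }
  table <- epcr_batch(rank1, gsets, pcr)
  report <- detect_polymorphism(table)
  list(loci = loci, primer_pairs = design$pairs,
       design_failures = design$failures, table = table,
       report = report)
}
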