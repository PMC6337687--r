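test_that("the generator is deterministic and the truth is the complete locus set", {
  g1 <- generate_reference(8, 40000, seed = 9)
  g2 <- generate_reference(8, 40000, seed = 9)
  expect_identical(g1$records$residues, g2$records$residues)
  expect_identical(g1$truth$loci, g2$truth$loci)
  g3 <- generate_reference(8, 40000, seed = 10)
  expect_false(identical(g1$records$residues, g3$records$residues))

  loci <- mine_genome(g1$records)
  expect_equal(nrow(loci), 8L)
  expect_equal(loci$start, g1$truth$loci$start)
  expect_equal(loci$end, g1$truth$loci$end)

  ## a zero-locus genome is pure scrubbed background: nothing to mine,
  ## and the miner agrees with the independent oracle on it
  g0 <- generate_reference(0, 20000, seed = 4)
  expect_equal(nrow(mine_genome(g0$records)), 0L)
  expect_equal(nrow(oracle_find_ssrs(g0$records$residues)), 0L)
})

test_that("genotype derivation applies exact repeat-count deltas", {
  gen <- generate_reference(6, 30000, seed = 13)
  out <- generate_genotypes(gen$records, gen$truth, n_genotypes = 2,
                            delta_range = c(-2L, 3L), seed = 13)
  truth <- out$truth
  expect_equal(dim(truth$deltas), c(6L, 2L))
  ## per-genotype tract lengths change by delta x unit length
  for (gi in 1:2) {
    gt <- out$genotypes[[gi]]
    expect_equal(gt$records$length - gen$records$length,
                 sum(truth$deltas[, gi] * truth$loci$unit_len))
    mined <- mine_genome(gt$records)
    expect_equal(sort(mined$repeat_count),
                 sort(unname(truth$loci$repeat_count +
                               truth$deltas[truth$loci$truth_id, gi])))
  }
  ## delta bounded below by the mining threshold
  thr <- truth$config$min_repeats[truth$loci$unit_len]
  expect_true(all(truth$loci$repeat_count + truth$deltas >= thr))
})

test_that("zero deltas and zero SNPs reproduce the reference byte-for-byte", {
  gen <- generate_reference(4, 20000, seed = 17)
  out <- generate_genotypes(gen$records, gen$truth, n_genotypes = 2,
                            delta_range = c(0L, 0L), seed = 17)
  for (g in out$genotypes)
    expect_identical(g$records$residues, gen$records$residues)
})

test_that("null alleles knock out single cells; expected calls mark them MISSING", {
  gen <- generate_reference(5, 25000, seed = 19)
  out <- generate_genotypes(gen$records, gen$truth, n_genotypes = 1,
                            delta_range = c(0L, 0L), null_rate = 1,
                            seed = 19)
  truth <- out$truth
  expect_equal(nrow(truth$nulls), 5L)  # every designable cell nulled
  pairs <- data.frame(locus_id = truth$primers$truth_id,
                      forward = truth$primers$forward,
                      reverse = truth$primers$reverse,
                      stringsAsFactors = FALSE)
  tab <- epcr_batch(pairs, out$genotypes)
  expect_true(all(tab$cells$n_hits == 0L))
  expect_true(all(tab$cells$asymmetric))
  ## and on the unmutated reference all cells amplify
  tab_ref <- epcr_batch(pairs,
                        list(genotype_set("reference", gen$records)))
  expect_true(all(tab_ref$cells$n_hits == 1L))
  expect_equal(
    tab_ref$hits$size[match(pairs$locus_id, tab_ref$hits$locus_id)],
    truth$primers$product_size)
  exp <- truth_expected_calls(truth)
  expect_true(all(exp$geno1 == "NA"))
  expect_true(all(exp$status == "INSUFFICIENT"))
})

test_that("SNPs land outside flank windows only", {
  gen <- generate_reference(3, 20000, seed = 23)
  out <- generate_genotypes(gen$records, gen$truth, n_genotypes = 1,
                            delta_range = c(0L, 0L), snp_rate = 0.01,
                            seed = 23)
  ref <- strsplit(gen$records$residues, "")[[1]]
  alt <- strsplit(out$genotypes[[1]]$records$residues, "")[[1]]
  changed <- which(ref != alt)
  expect_gt(length(changed), 0L)
  loci <- gen$truth$loci
  for (i in seq_len(nrow(loci)))
    expect_false(any(changed >= loci$start[i] - 500 &
                       changed <= loci$end[i] + 500))
})

test_that("duplicated loci carry identical cassettes and become paralogous", {
  gen <- generate_reference(6, 35000, seed = 29, n_duplicated = 1)
  truth <- gen$truth$loci
  dup <- truth[!is.na(truth$duplicate_of), ]
  expect_equal(nrow(dup), 1L)
  src <- truth[truth$truth_id == dup$duplicate_of, ]
  expect_equal(dup$motif, src$motif)
  expect_equal(dup$repeat_count, src$repeat_count)
  ## identical 500 bp cassette context
  g <- gen$records$residues
  expect_equal(substring(g, dup$start - 500, dup$end + 500),
               substring(g, src$start - 500, src$end + 500))
  out <- generate_genotypes(gen$records, gen$truth, n_genotypes = 2,
                            seed = 29)
  exp <- truth_expected_calls(out$truth)
  expect_equal(sort(exp$status[exp$truth_id %in%
                                 c(dup$truth_id, src$truth_id)]),
               c("PARALOGOUS", "PARALOGOUS"))
})

test_that("fixture files round-trip through the standard formats", {
  dir <- withr::local_tempdir()
  gen <- generate_reference(3, 15000, seed = 31)
  out <- generate_genotypes(gen$records, gen$truth, n_genotypes = 2,
                            null_rate = 0.2, seed = 31)
  write_fixtures(gen$records, out$genotypes, out$truth, dir)
  expect_true(file.exists(file.path(dir, "reference.fasta")))
  expect_true(file.exists(file.path(dir, "genotype_1.fasta")))
  expect_true(file.exists(file.path(dir, "genotype_2.fasta")))
  back <- read_fasta(file.path(dir, "reference.fasta"))
  expect_equal(back$residues, gen$records$residues)
  truth_tab <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth_tab), 3L)
  expect_true(all(c("delta_geno1", "delta_geno2") %in%
                    names(truth_tab)))
})

test_that("infeasible placements are rejected up front", {
  expect_error(generate_reference(50, 10000, seed = 1), "too small")
  expect_error(generate_reference(3, 30000, seed = 1,
                                  n_duplicated = 4), "n_duplicated")
})
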