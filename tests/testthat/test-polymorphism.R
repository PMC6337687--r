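sizes_list <- function(...) {
  x <- list(...)
  lapply(x, function(v) if (length(v) == 1L && is.na(v)) integer(0)
         else as.integer(v))
}

test_that("locus calling reproduces the published rice allelic profiles", {
  sz <- table1_sizes()
  for (i in seq_len(nrow(sz))) {
    cl <- call_locus(rownames(sz)[i],
                     as.list(setNames(sz[i, ], colnames(sz))))
    expect_equal(cl$status, "POLYMORPHIC")
  }
  cl <- call_locus("HvSSR03-37",
                   as.list(setNames(sz["HvSSR03-37", ], colnames(sz))))
  expect_equal(cl$distinct_allele_sizes, c(305, 337, 338, 351))
  cl <- call_locus("HvSSR04-27",
                   as.list(setNames(sz["HvSSR04-27", ], colnames(sz))))
  expect_equal(length(cl$distinct_allele_sizes), 3L)
})

test_that("status decision rules cover every branch", {
  expect_equal(call_locus("l", sizes_list(a = 100, b = 100,
                                          c = 100))$status,
               "MONOMORPHIC")
  expect_equal(call_locus("l", sizes_list(a = NA, b = NA,
                                          c = 200))$status,
               "INSUFFICIENT")
  expect_equal(call_locus("l", sizes_list(a = c(150, 300),
                                          b = 150))$status,
               "PARALOGOUS")
  ## paralogy takes precedence over observed size differences
  expect_equal(call_locus("l", sizes_list(a = c(150, 300), b = 150,
                                          c = 170))$status,
               "PARALOGOUS")
  ## a missing genotype never makes a locus polymorphic
  expect_equal(call_locus("l", sizes_list(a = NA, b = 120,
                                          c = 120))$status,
               "MONOMORPHIC")
  cl <- call_locus("l", sizes_list(a = c(150, 300), b = NA, c = 170))
  expect_equal(cl$allele_label,
               c(a = "MULTI:150;300", b = "NA", c = "170"))
})

test_that("polymorphism reports are complete and internally consistent", {
  set.seed(61)
  genotypes <- make_table1_genotypes()
  tab <- epcr_batch(table1_primers(), genotypes)
  rep <- detect_polymorphism(tab)
  expect_equal(unname(rep$summary["POLYMORPHIC"]), 4L)
  expect_equal(sum(rep$summary), nrow(rep$calls))
  ## the allele matrix reproduces the constructed sizes
  sz <- table1_sizes()
  for (g in colnames(sz))
    expect_equal(rep$matrix[[g]],
                 as.character(sz[rep$matrix$locus_id, g]))
  ## every locus gets exactly one status
  expect_true(all(rep$calls$status %in%
                    c("POLYMORPHIC", "MONOMORPHIC", "INSUFFICIENT",
                      "PARALOGOUS")))
})

test_that("transferability dispositions follow the size and asymmetry filters", {
  set.seed(67)
  prs <- table1_primers()
  host_seq <- paste0(
    rand_seq(100),
    make_cassette(prs$forward[1], prs$reverse[1], 120),  # transferable
    rand_seq(100),
    make_cassette(prs$forward[2], prs$reverse[2], 620),  # oversize
    rand_seq(100),
    prs$forward[3],                                      # asymmetric
    rand_seq(100))
  host <- genotype_set("peach", sequence_records("c1", host_seq))
  rep <- evaluate_transferability(prs, host, size_cutoff = 500)
  d <- setNames(rep$table$disposition, rep$table$locus_id)
  expect_equal(unname(d["HvSSR03-37"]), "TRANSFERABLE")
  expect_equal(unname(d["HvSSR04-27"]), "FILTERED_SIZE")
  expect_equal(unname(d["HvSSR07-51"]), "FILTERED_ASYMMETRIC")
  expect_equal(unname(d["HvSSR08-14"]), "ABSENT")
  expect_equal(rep$count_transferable, 1L)
  expect_equal(rep$table$size[rep$table$locus_id == "HvSSR03-37"], 120L)
  ## raising the cutoff never decreases the transferable count
  counts <- vapply(c(100, 300, 500, 700, 1000), function(cut)
    evaluate_transferability(prs, host, size_cutoff = cut)$count_transferable,
    integer(1))
  expect_false(is.unsorted(counts))
  expect_equal(counts[length(counts)], 2L)
})

test_that("genic screening detects introns, junction primers, oversized products", {
  set.seed(71)
  prs <- table1_primers()[1:4, ]
  cass <- function(i, size) make_cassette(prs$forward[i],
                                          prs$reverse[i], size)
  tx_seq <- paste0(rand_seq(60), cass(1, 200), rand_seq(60),
                   cass(2, 200), rand_seq(60), cass(3, 200),
                   rand_seq(60), cass(4, 200), rand_seq(60))
  transcripts <- sequence_records("tx1", tx_seq)
  ## genome: locus 1 intact with a 550 bp intron inside the amplicon;
  ## locus 2 exact; locus 3 forward primer split by an intron (no
  ## binding site); locus 4 with both primers but 6 kb apart
  genome_seq <- paste0(
    rand_seq(80), cass(1, 750), rand_seq(80), cass(2, 200),
    rand_seq(80), substr(prs$forward[3], 1, 10), rand_seq(300),
    substr(prs$forward[3], 11, 20), rand_seq(40),
    rc_chars(prs$reverse[3]),
    rand_seq(80), prs$forward[4], rand_seq(6000),
    rc_chars(prs$reverse[4]), rand_seq(80))
  genome <- genotype_set("genome", sequence_records("chr1", genome_seq))
  out <- evaluate_genic_primers(prs, transcripts, genome)
  v <- setNames(out$verdict, out$locus_id)
  expect_equal(unname(v["HvSSR03-37"]), "INTRON_CONTAINING")
  expect_equal(out$delta_bp[out$locus_id == "HvSSR03-37"], 550L)
  expect_equal(unname(v["HvSSR04-27"]), "OK")
  expect_equal(unname(v["HvSSR07-51"]), "JUNCTION_PRIMER")
  expect_equal(unname(v["HvSSR08-14"]), "NO_GENOMIC_PRODUCT_OVERSIZE")
  expect_equal(out$expected_size, rep(200L, 4))
  ## a pair with no transcript product is an input error, per locus
  bad <- rbind(prs, data.frame(locus_id = "novel",
                               forward = "GATCGGCAGCCAGGCTGCAC",
                               reverse = "GGCAGGCTGCAGCCGGGTGC"))
  out2 <- evaluate_genic_primers(bad, transcripts, genome)
  expect_equal(out2$verdict[out2$locus_id == "novel"], "INPUT_ERROR")
})
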