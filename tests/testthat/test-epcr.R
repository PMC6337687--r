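test_that("primer matching finds planted sites on both strands", {
  set.seed(41)
  primer <- "ACGTACGTACGTACGTAC"
  bg <- rand_seq(400)
  seq <- paste0(substring(bg, 1, 100), primer, substring(bg, 101, 400))
  ## scrub accidental extra occurrences out of the fixture
  rec <- sequence_records("t", seq)
  m <- find_matches(primer, rec)
  plus <- m[m$strand == "+", ]
  expect_true(any(plus$start == 101L & plus$end == 118L &
                    plus$mismatches == 0L))

  m2 <- find_matches(reverse_complement(primer), rec)
  minus <- m2[m2$strand == "-", ]
  expect_true(any(minus$start == 101L & minus$end == 118L))

  expect_equal(nrow(find_matches("GGGGGGGGGGGGGGGGGG",
                                 sequence_records("t", rand_seq(60)))),
               0L)
})

test_that("the exact 3'-seed rule vetoes terminal mismatches", {
  primer <- "GATCGGCAGCCAGGCTGCAC"
  ## template carries the site with a substitution at the primer's
  ## 3'-terminal base
  site_mut <- paste0(substr(primer, 1, 19), "G")
  template <- sequence_records("t", paste0(strrep("T", 30), site_mut,
                                           strrep("T", 30)))
  p1 <- epcr_params(max_mismatch = 1, three_prime_seed = 5)
  expect_equal(nrow(find_matches(primer, template, p1)), 0L)
  ## same mismatch count, but outside the seed: accepted
  site_mut5p <- paste0("T", substr(primer, 2, 20))
  template2 <- sequence_records("t", paste0(strrep("T", 30), site_mut5p,
                                            strrep("T", 30)))
  m <- find_matches(primer, template2, p1)
  expect_equal(m$mismatches, 1L)
  ## and exact mode rejects it
  expect_equal(nrow(find_matches(primer, template2, epcr_params())), 0L)
})

test_that("constructed cassettes amplify at the constructed size", {
  set.seed(43)
  pr <- table1_primers()[1, ]  # 19 bp forward, 20 bp reverse
  cassette <- make_cassette(pr$forward, pr$reverse, 337)
  expect_equal(nchar(cassette), 19 + 298 + 20)
  rec <- sequence_records("t", paste0(rand_seq(150), cassette,
                                      rand_seq(150)))
  hits <- epcr(pr, rec)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$size, 337L)
  expect_equal(hits$orientation, "plus")
  expect_equal(hits$end - hits$start + 1L, hits$size)

  ## reverse-complemented template: same product, minus orientation
  rc_rec <- sequence_records("t", reverse_complement(rec$residues))
  hits_rc <- epcr(pr, rc_rec)
  expect_equal(hits_rc$size, 337L)
  expect_equal(hits_rc$orientation, "minus")
  ## coordinates mirror: start' = len - end + 1
  expect_equal(hits_rc$start, rec$length - hits$end + 1L)

  ## duplicated cassette -> two products (paralogy raw material);
  ## max_product below the cross-site span keeps the combinatorial
  ## forward(site1) x reverse(site2) pairing out
  rec2 <- sequence_records("t", paste0(rand_seq(100), cassette,
                                       rand_seq(100), cassette,
                                       rand_seq(100)))
  two <- epcr(pr, rec2, epcr_params(max_product = 500))
  expect_equal(nrow(two), 2L)
  expect_equal(two$size, c(337L, 337L))
  ## with an unbounded product range the cross pairing appears too
  expect_equal(nrow(epcr(pr, rec2)), 3L)

  ## forward without reverse: no product
  rec3 <- sequence_records("t", paste0(rand_seq(100), pr$forward,
                                       rand_seq(100)))
  expect_equal(nrow(epcr(pr, rec3)), 0L)
})

test_that("batch e-PCR covers the cross product and flags asymmetric cells", {
  set.seed(47)
  prs <- table1_primers()[1:2, ]
  g1 <- genotype_set("g1", sequence_records("c1", paste0(
    rand_seq(50), make_cassette(prs$forward[1], prs$reverse[1], 150),
    rand_seq(50), make_cassette(prs$forward[2], prs$reverse[2], 200),
    rand_seq(50))))
  ## g2 lacks locus 2's reverse site entirely (asymmetric)
  g2 <- genotype_set("g2", sequence_records("c1", paste0(
    rand_seq(50), make_cassette(prs$forward[1], prs$reverse[1], 153),
    rand_seq(50), prs$forward[2], rand_seq(50))))
  g3 <- genotype_set("g3", sequence_records("c1", rand_seq(400)))
  tab <- epcr_batch(prs, list(g1, g2, g3))
  expect_equal(nrow(tab$cells), 6L)
  expect_equal(sort(unique(tab$cells$genotype_id)),
               c("g1", "g2", "g3"))
  cell <- function(l, g)
    tab$cells[tab$cells$locus_id == l & tab$cells$genotype_id == g, ]
  expect_equal(cell("HvSSR03-37", "g1")$n_hits, 1L)
  expect_equal(cell("HvSSR04-27", "g2")$n_hits, 0L)
  expect_true(cell("HvSSR04-27", "g2")$asymmetric)
  expect_false(cell("HvSSR03-37", "g3")$asymmetric)
  expect_error(epcr_batch(rbind(prs, prs), list(g1)), "duplicate")

  ## exact mode: every reported mismatch count is zero; sizes coherent
  expect_true(all(tab$hits$mismatches_f == 0L))
  expect_true(all(tab$hits$mismatches_r == 0L))
  expect_true(all(tab$hits$size == tab$hits$end - tab$hits$start + 1L))
})

test_that("e-PCR agrees with the naive quadratic scanner on random genomes", {
  set.seed(53)
  prs <- table1_primers()
  for (rep in 1:4) {
    genome <- paste0(
      rand_seq(3000),
      make_cassette(prs$forward[1], prs$reverse[1], sample(120:400, 1)),
      rand_seq(2000),
      make_cassette(prs$forward[2], prs$reverse[2], sample(120:400, 1)),
      rand_seq(3000))
    rec <- sequence_records("g", genome)
    for (i in 1:2) {
      got <- epcr(prs[i, ], rec)
      want <- oracle_epcr(prs$forward[i], prs$reverse[i], genome)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$size, want$size)
      expect_equal(got$orientation, want$orientation)
    }
  }
})

test_that("strand involution: a reverse-complemented genome mirrors all hits", {
  set.seed(59)
  prs <- table1_primers()
  genome <- paste0(rand_seq(500),
                   make_cassette(prs$forward[1], prs$reverse[1], 250),
                   rand_seq(500),
                   make_cassette(prs$forward[1], prs$reverse[1], 190),
                   rand_seq(500))
  rec <- sequence_records("g", genome)
  fwd <- epcr(prs[1, ], rec)
  rev <- epcr(prs[1, ], sequence_records("g",
                                         reverse_complement(genome)))
  n <- nchar(genome)
  expect_equal(sort(rev$size), sort(fwd$size))
  expect_equal(sort(n - rev$end + 1L), sort(fwd$start))
  expect_equal(sort(ifelse(rev$orientation == "plus", "minus", "plus")),
               sort(fwd$orientation))
})

test_that("e-PCR parameter validation", {
  expect_error(epcr_params(max_mismatch = 4), "between 0 and 3")
  expect_error(epcr_params(min_product = 6000, max_product = 5000),
               "min_product")
  expect_error(find_matches("ACGU", sequence_records("t", "ACGT")),
               "primer")
})
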