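test_that("allele matching: exact, near, ambiguous, unknown locus", {
  loci <- toy_loci()
  db <- toy_reference(loci, n = 4L, seed = 71)
  a1 <- db$alleles$sequence[1]
  expect_equal(match_allele(a1, db, "AAX"), db$alleles$label[1])
  expect_error(match_allele(a1, db, "ZZZ"), "unknown locus")

  # one substitution away from allele 01 and far from the rest:
  # brute-force identity over all stored alleles confirms the winner
  near <- a1
  substr(near, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substr(a1, 10, 10))[1]
  at <- db$alleles[db$alleles$locus == "AAX", ]
  ident <- vapply(at$sequence, function(s) {
    mean(strsplit(near, "")[[1]] == strsplit(s, "")[[1]])
  }, numeric(1))
  expect_equal(at$label[which.max(ident)], "01")
  expect_true(sort(ident, decreasing = TRUE)[2] < 0.98)
  expect_equal(match_allele(near, db, "AAX", min_identity = 0.98), "01")
  expect_equal(match_allele(rnd_dna(170), db, "AAX"), "NOMATCH")

  # equidistant from two alleles -> AMBIGUOUS
  base <- strrep("A", 170)
  two <- data.frame(locus = "AAX", label = c("x1", "x2"),
                    sequence = c(paste0("C", substr(base, 2, 170)),
                                 paste0("G", substr(base, 2, 170))))
  db2 <- mhc_reference(loci, two)
  expect_equal(match_allele(base, db2, "AAX", min_identity = 0.9),
               "AMBIGUOUS")
})

test_that("tallying books matched and unmatched reads separately", {
  loci <- toy_loci()
  db <- toy_reference(loci, n = 2L, seed = 72)
  a1 <- db$alleles$sequence[db$alleles$locus == "AAX"][1]
  lab1 <- db$alleles$label[db$alleles$locus == "AAX"][1]
  unk <- rnd_dna(170)
  merged <- tibble::tibble(
    individual = "k1", locus = "AAX",
    sequence = c(rep(a1, 60), rep(unk, 40))
  )
  t <- tally_reads(merged, db)
  expect_equal(sum(t$count), 100L)
  expect_equal(t$count[!is.na(t$allele) & t$allele == lab1], 60L)
  expect_equal(t$count[is.na(t$allele)], 40L)
  expect_equal(t$sequence[is.na(t$allele)], unk)

  # all one allele
  t2 <- tally_reads(merged[1:60, ], db)
  expect_equal(nrow(t2), 1L)
  expect_equal(t2$count, 60L)

  # empty input
  expect_equal(nrow(tally_reads(merged[0, ], db)), 0L)
})

test_that("calling uses a strictly-greater-than threshold", {
  loci <- toy_loci()
  mk_tally <- function(counts) {
    tibble::tibble(individual = "k1", locus = "AAX",
                   allele = names(counts), sequence = NA_character_,
                   count = as.integer(counts))
  }
  # 85/10/5: the 10% allele is excluded (strict inequality)
  p <- call_alleles(mk_tally(c(a = 85, b = 10, c = 5)), loci)
  expect_equal(p$alleles[p$locus == "AAX"], "a")
  # 50/50
  p <- call_alleles(mk_tally(c(a = 50, b = 50)), loci)
  expect_equal(p$alleles[p$locus == "AAX"], "a;b")
  # 11/89
  p <- call_alleles(mk_tally(c(a = 11, b = 89)), loci)
  expect_equal(p$alleles[p$locus == "AAX"], "a;b")
  # locus with no reads is NO_DATA, not an empty call
  expect_equal(p$status[p$locus == "BBX"], "NO_DATA")
  # calling is scale invariant
  p10 <- call_alleles(mk_tally(c(a = 110, b = 890)), loci)
  expect_equal(p10$alleles, p$alleles)
})

test_that("six alleles each above threshold are all called at a
           three-copy locus", {
  loci <- toy_loci()
  t <- tibble::tibble(individual = "k1", locus = "BBX",
                      allele = sprintf("%02d", 1:6),
                      sequence = NA_character_, count = rep(100L, 6))
  p <- call_alleles(t, loci)
  expect_equal(p$n_alleles[p$locus == "BBX"], 6L)
  # a seventh would exceed the copy-number bound and warn
  t7 <- tibble::tibble(individual = "k1", locus = "BBX",
                       allele = sprintf("%02d", 1:7),
                       sequence = NA_character_, count = rep(100L, 7))
  expect_warning(call_alleles(t7, loci), "copy-number")
})

test_that("novel detection keeps duplicated sequences above threshold", {
  loci <- toy_loci()
  db <- toy_reference(loci, n = 2L, seed = 73)
  a1 <- db$alleles$sequence[db$alleles$locus == "AAX"][1]
  unk <- rnd_dna(170)
  mk <- function(n_known, n_unk, unk_seqs = unk) {
    tibble::tibble(individual = "k1", locus = "AAX",
                   sequence = c(rep(a1, n_known),
                                rep(unk_seqs, each = n_unk)))
  }
  t <- tally_reads(mk(60, 40), db)
  found <- detect_novel(t, db, min_copies = 10)
  expect_equal(nrow(found$candidates), 1L)
  expect_equal(found$candidates$sequence, unk)
  expect_equal(found$candidates$label, "novel-001")

  # two rare unmatched sequences (5 and 4 copies of 100 reads): noise
  t2 <- tally_reads(
    tibble::tibble(individual = "k1", locus = "AAX",
                   sequence = c(rep(a1, 91), rep(rnd_dna(170), 5),
                                rep(rnd_dna(170), 4))), db)
  found2 <- detect_novel(t2, db, min_copies = 3)
  expect_equal(nrow(found2$candidates), 0L)
})

test_that("genotyping recovers simulated truth and held-out alleles", {
  cfg <- sim_config(n_founders = 4, n_trios = 1, n_pairs = 1,
                    depth = 300, seed = 91)
  truth <- simulate_pedigree(cfg)
  reads <- simulate_reads(truth)
  run <- run_pipeline(reads, truth_reference(truth), cfg$loci)
  m <- dplyr::inner_join(truth$expected, run$profiles,
                         by = c("individual", "locus"),
                         suffix = c("_true", "_called"))
  expect_equal(m$alleles_called, m$alleles_true)

  # hold out one carried single-copy allele: recovered verbatim as novel
  carried <- truth$genotypes$allele[truth$genotypes$locus == "DCB"][1]
  ref2 <- truth_reference(truth, withhold = paste0("DCB*", carried))
  run2 <- run_pipeline(reads, ref2, cfg$loci)
  held <- truth$alleles$sequence[truth$alleles$locus == "DCB" &
                                   truth$alleles$label == carried]
  expect_true(held %in% run2$genotypes$novel$sequence)
})

test_that("read counts are conserved through tallying", {
  cfg <- sim_config(n_founders = 2, n_trios = 0, n_pairs = 0,
                    depth = 60, seed = 92)
  ds <- simulate_dataset(cfg)
  r <- ds$reads[ds$reads$individual == "F001", ]
  res <- process_read_pairs(r, cfg$loci)
  res$merged$individual <- "F001"
  t <- tally_reads(res$merged, ds$reference)
  expect_equal(sum(t$count), nrow(res$merged))
  tot <- dplyr::count(t, locus, wt = count)
  expect_equal(tot$n, rep(cfg$depth, 6))
})
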