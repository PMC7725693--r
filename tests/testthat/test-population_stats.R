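mk_profiles <- function(sets, locus = "L1") {
  tibble::tibble(
    individual = names(sets), locus = locus,
    alleles = vapply(sets, paste, character(1), collapse = ";"),
    status = "OK"
  )
}

test_that("presence matrix encodes carrier status deterministically", {
  p <- mk_profiles(list(k1 = "A", k2 = c("A", "B")))
  m <- build_presence_matrix(p)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m["k1", ]), c(1L, 0L))
  expect_equal(unname(m["k2", ]), c(1L, 1L))
  # identical profiles give identical rows
  p2 <- mk_profiles(list(k1 = c("A", "B"), k2 = c("A", "B")))
  m2 <- build_presence_matrix(p2)
  expect_equal(unname(m2[1, ]), unname(m2[2, ]))
  expect_error(build_presence_matrix(p[0, ]), "no profiles")
  # packaged tables: 37 distinct alleles across the six loci
  m3 <- build_presence_matrix(koala_family_profiles())
  expect_equal(ncol(m3), 37L)
  counts <- table(sub("\\*.*$", "", colnames(m3)))
  expect_equal(as.integer(counts[c("UA", "UC", "DAB", "DBB", "DCB",
                                   "DMB")]),
               c(7L, 5L, 10L, 8L, 3L, 4L))
})

test_that("Gower on binary profiles is simple matching distance", {
  m <- rbind(a = c(1, 0, 1, 0), b = c(1, 1, 1, 1), c = c(1, 0, 1, 0),
             d = c(0, 1, 0, 1))
  d <- as.matrix(gower_dissimilarity(m))
  expect_equal(d["a", "c"], 0)       # identical rows
  expect_equal(d["a", "d"], 1)       # complementary rows
  expect_equal(d["a", "b"], 0.5)     # 2 mismatches of 4
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
})

test_that("Gower agrees with daisy and satisfies the triangle inequality", {
  skip_if_not_installed("cluster")
  set.seed(121)
  for (k in 1:10) {
    m <- matrix(rbinom(8 * 12, 1, 0.5), nrow = 8,
                dimnames = list(paste0("i", 1:8), NULL))
    ours <- as.matrix(gower_dissimilarity(m))
    ref <- as.matrix(cluster::daisy(as.data.frame(m), metric = "gower"))
    expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
    for (a in 1:8) for (b in 1:8) for (cc in 1:8) {
      expect_lte(ours[a, b], ours[a, cc] + ours[cc, b] + 1e-12)
    }
  }
})

test_that("complete linkage merges by maximum distance with fixed ties", {
  D <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3)
  h <- complete_linkage(D)
  expect_equal(h$height, c(0.1, 0.9))
  expect_equal(sort(h$merge[1, ]), c(-2L, -1L))
  # all-equal distances: deterministic despite full tie
  De <- matrix(0.5, 4, 4); diag(De) <- 0
  h1 <- complete_linkage(De)
  h2 <- complete_linkage(De)
  expect_identical(h1$merge, h2$merge)
  expect_equal(h1$height, rep(0.5, 3))
  expect_error(complete_linkage(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})

test_that("complete linkage equals the naive oracle and hclust", {
  set.seed(131)
  for (k in 1:30) {
    n <- 6
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- round(runif(n * (n - 1) / 2), 3)
    D <- D + t(D)
    h <- complete_linkage(D)
    o <- oracle_complete_linkage(D)
    expect_equal(h$height, o$heights)
    expect_equal(hclust_members(h), o$members)
  }
  # reference implementation agrees when distances are tie-free (under
  # ties, complete linkage admits several valid dendrograms)
  for (k in 1:20) {
    D <- matrix(0, 6, 6)
    D[upper.tri(D)] <- runif(15)
    D <- D + t(D)
    expect_equal(sort(complete_linkage(D)$height),
                 sort(hclust(as.dist(D), method = "complete")$height))
  }
})

test_that("complete linkage heights are invariant under permutation", {
  set.seed(141)
  D <- matrix(0, 7, 7)
  D[upper.tri(D)] <- runif(21)
  D <- D + t(D)
  h1 <- complete_linkage(D)
  p <- sample(7)
  h2 <- complete_linkage(D[p, p])
  expect_equal(sort(h1$height), sort(h2$height))
  # no ties in a continuous draw: member sets agree up to relabeling
  expect_setequal(lapply(hclust_members(h2), function(x) sort(p[x])),
                  hclust_members(h1))
})

test_that("Fisher exact reproduces the published association and the
           enumeration oracle", {
  t <- matrix(c(5, 3, 0, 6), 2, 2, byrow = TRUE)
  expect_equal(round(fisher_exact_2x2(t), 3), 0.031)
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2, 2)), 1.0)
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 1), 2, 2)),
               "non-negative")
  set.seed(151)
  for (k in 1:50) {
    tt <- matrix(rpois(4, 3), 2, 2)
    if (any(rowSums(tt) == 0) || any(colSums(tt) == 0)) next
    expect_equal(fisher_exact_2x2(tt), oracle_fisher(tt),
                 tolerance = 1e-10)
  }
})

test_that("chi-squared test matches the direct summation oracle", {
  # table equal to its expected counts -> statistic 0, p 1
  t0 <- outer(c(10, 20), c(3, 7)) / 10
  r0 <- chi_squared_test(t0)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  # 30 x 2 table -> df 29
  set.seed(161)
  t30 <- matrix(rpois(60, 5) + 1, 30, 2)
  expect_equal(chi_squared_test(t30)$df, 29)
  # random 3 x 4 vs direct Pearson summation
  t34 <- matrix(rpois(12, 6) + 1, 3, 4)
  E <- outer(rowSums(t34), colSums(t34)) / sum(t34)
  expect_equal(chi_squared_test(t34)$statistic, sum((t34 - E)^2 / E))
  expect_error(chi_squared_test(matrix(c(1, 0, 2, 0), 2, 2)), "margin")
})

test_that("allele association reproduces carrier prevalences and p", {
  sets <- c(lapply(1:5, function(i) c("03", "05")),
            lapply(6:8, function(i) "05"),
            lapply(9:14, function(i) c("01", "02")))
  names(sets) <- sprintf("k%02d", 1:14)
  profiles <- mk_profiles(sets, locus = "DBB")
  outcomes <- tibble::tibble(
    individual = names(sets),
    outcome = rep(c("cancer", "natural"), c(8, 6))
  )
  a <- allele_association(profiles, outcomes, "DBB", "03")
  expect_equal(round(a$p_value, 3), 0.031)
  pv <- a$prevalence
  expect_equal(pv$prevalence_pct[pv$outcome == "cancer"], 63)
  expect_equal(pv$prevalence_pct[pv$outcome == "natural"], 0)
  expect_equal(glance(a)$p_value, a$p_value)
  expect_error(allele_association(profiles, outcomes, "DBB", "99"),
               "not observed")
  # degenerate: everyone carries the allele
  all_c <- mk_profiles(lapply(stats::setNames(1:6, paste0("x", 1:6)),
                              function(i) "03"), locus = "DBB")
  out6 <- tibble::tibble(individual = paste0("x", 1:6),
                         outcome = rep(c("a", "b"), 3))
  expect_equal(allele_association(all_c, out6, "DBB", "03")$p_value, 1.0)
})

test_that("association p is calibrated under label permutation", {
  set.seed(171)
  sets <- lapply(1:20, function(i)
    unique(sample(sprintf("%02d", 1:6), sample(1:3, 1), replace = TRUE)))
  names(sets) <- sprintf("k%02d", 1:20)
  profiles <- mk_profiles(sets, locus = "DBB")
  allele <- "01"
  outcomes <- tibble::tibble(individual = names(sets),
                             outcome = rep(c("a", "b"), each = 10))
  obs <- allele_association(profiles, outcomes, "DBB", allele)$p_value
  # observed p reproduced exactly on unpermuted labels
  expect_equal(allele_association(profiles, outcomes, "DBB",
                                  allele)$p_value, obs)
  ps <- replicate(200, {
    perm <- outcomes
    perm$outcome <- sample(perm$outcome)
    allele_association(profiles, perm, "DBB", allele)$p_value
  })
  # discrete exact p-values are super-uniform: P(p <= x) <= x
  for (x in c(0.05, 0.25, 0.5)) {
    expect_lte(mean(ps <= x), x + 3 * sqrt(x * (1 - x) / 200) + 0.02)
  }
})

test_that("dendrogram export produces Newick and a merge table", {
  skip_if_not_installed("ape")
  m <- build_presence_matrix(koala_family_profiles())
  h <- complete_linkage(gower_dissimilarity(m))
  nwk <- as_newick(h)
  expect_match(nwk, "^\\(")
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, gsub("[ ']", "_", rownames(m)))
  tsv <- tempfile(fileext = ".tsv")
  write_merge_table(h, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), nrow(m) - 1L)
  expect_true(all(diff(tab$height) >= -1e-12))
})
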