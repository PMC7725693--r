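# Population-level analyses of multi-locus MHC profiles: binary
# allele-presence encoding, Gower dissimilarity with complete-linkage
# clustering, and allele/haplotype association tests against phenotype
# labels (Fisher exact, Pearson chi-squared).

#' Build a binary allele-presence matrix
#'
#' Rows are individuals (sorted), columns the sorted union of observed
#' `LOCUS*allele` pairs; cells indicate carrier status. Loci with
#' `NO_DATA` contribute no columns for that individual.
#'
#' @param profiles Long profile tibble (`individual, locus, alleles`).
#' @return An integer 0/1 matrix with dimnames.
#' @export
build_presence_matrix <- function(profiles) {
  if (is.null(profiles) || nrow(profiles) == 0L) {
    stop("no profiles supplied")
  }
  long <- tidyr::unnest(
    tibble::tibble(individual = profiles$individual,
                   locus = profiles$locus,
                   allele = split_alleles(profiles$alleles)),
    "allele"
  )
  if (nrow(long) == 0L) stop("profiles contain no alleles")
  inds <- sort(unique(profiles$individual))
  cols <- sort(unique(paste0(long$locus, "*", long$allele)))
  m <- matrix(0L, nrow = length(inds), ncol = length(cols),
              dimnames = list(inds, cols))
  m[cbind(match(long$individual, inds),
          match(paste0(long$locus, "*", long$allele), cols))] <- 1L
  empty <- rowSums(m) == 0L
  if (any(empty)) {
    stop("individual(s) with no alleles at any locus: ",
         paste(inds[empty], collapse = ", "))
  }
  m
}

#' Gower dissimilarity for binary presence profiles
#'
#' For symmetric binary attributes with equal weights Gower's coefficient
#' reduces to simple matching: d(i, j) is the proportion of columns where
#' the two rows differ. Values lie in `[0, 1]` with `d(i, i) = 0`.
#'
#' @param m Binary matrix from [build_presence_matrix()].
#' @return A `dist` object.
#' @export
gower_dissimilarity <- function(m) {
  if (nrow(m) < 2L) stop("need at least 2 individuals")
  stats::dist(m, method = "manhattan") / ncol(m)
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise dissimilarity of their members. Deterministic
#' tie-breaking: at each step the closest pair with the lowest pair index
#' (first, then second, in current cluster order; merged clusters are
#' appended) is merged. The result is `hclust`-compatible.
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @return An object of classes `mhc_hclust` and `hclust` with `merge`,
#'   `height`, `order` and `labels`.
#' @export
complete_linkage <- function(d) {
  D <- unname(as.matrix(d))
  if (!isSymmetric(D)) stop("dissimilarity matrix must be symmetric")
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 items")
  labels <- rownames(as.matrix(d))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  ids <- -seq_len(n)
  cur <- D
  for (k in seq_len(n - 1L)) {
    v <- cur
    v[lower.tri(v, diag = TRUE)] <- Inf
    hit <- which(v == min(v), arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]
    j <- hit[1L, 2L]
    height[k] <- cur[i, j]
    pair <- sort(c(ids[i], ids[j]))
    merge[k, ] <- pair
    newd <- pmax(cur[i, ], cur[j, ])[-c(i, j)]
    cur <- cur[-c(i, j), -c(i, j), drop = FALSE]
    cur <- rbind(cbind(cur, newd), c(newd, 0))
    ids <- c(ids[-c(i, j)], k)
  }
  ord_of <- function(x) {
    if (x < 0L) return(-x)
    c(ord_of(merge[x, 1L]), ord_of(merge[x, 2L]))
  }
  structure(
    list(merge = merge, height = height,
         order = if (n > 1L) ord_of(n - 1L) else 1L,
         labels = labels, method = "complete",
         dist.method = "gower", call = match.call()),
    class = c("mhc_hclust", "hclust")
  )
}

#' Export a dendrogram
#'
#' `as_newick()` renders the tree in Newick format (branch lengths derived
#' from merge heights via `ape`); `write_merge_table()` writes the merge
#' list with heights as TSV.
#'
#' @param h An `hclust`-like object, e.g. from [complete_linkage()].
#' @return A Newick string, or (for `write_merge_table`) `path` invisibly.
#' @export
as_newick <- function(h) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the ape package is required for Newick export")
  }
  h <- stats::as.hclust(h)
  # Newick-safe tip labels (spaces/quotes break downstream parsers)
  h$labels <- gsub("[ ']", "_", h$labels)
  ape::write.tree(ape::as.phylo(h))
}

#' @rdname as_newick
#' @param path Output TSV path.
#' @export
write_merge_table <- function(h, path) {
  utils::write.table(
    data.frame(step = seq_along(h$height), left = h$merge[, 1L],
               right = h$merge[, 2L], height = h$height),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the
#' probability of the observed table (within a relative tolerance of
#' about 1e-7).
#'
#' @param t A 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == 2L)) stop("table must be 2x2")
  if (any(t < 0) || any(t != round(t))) {
    stop("cells must be non-negative integers")
  }
  stats::fisher.test(t)$p.value
}

#' Pearson chi-squared test of independence
#'
#' @param t An r x c matrix of counts with positive row and column sums.
#' @return A tibble with `statistic`, `df` and `p_value`.
#' @export
chi_squared_test <- function(t) {
  t <- as.matrix(t)
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    stop("table has a zero margin; drop empty rows/columns first")
  }
  fit <- suppressWarnings(stats::chisq.test(t, correct = FALSE))
  tibble::tibble(statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = fit$p.value)
}

#' Allele carrier-status association with a binary outcome
#'
#' Cross-tabulates carrier status of one allele against a two-level
#' outcome and applies the two-sided Fisher exact test; carrier
#' prevalence is reported per group (percentages rounded to nearest
#' integer). Raw p-values are reported without multiple-testing
#' correction.
#'
#' @param profiles Long profile tibble.
#' @param outcomes Tibble `individual, outcome` with exactly two distinct
#'   outcome values among the tested individuals.
#' @param locus,allele The allele whose carriage is tested; must be
#'   observed at that locus in `profiles`.
#' @return An object of class `mhc_association`: list with `table`
#'   (2x2: outcome x carrier), `p_value`, `prevalence` tibble, `locus`,
#'   `allele`.
#' @export
allele_association <- function(profiles, outcomes, locus, allele) {
  at <- profiles[profiles$locus == locus, , drop = FALSE]
  seen <- unique(unlist(split_alleles(at$alleles)))
  if (!allele %in% seen) {
    stop("allele ", allele, " not observed at locus ", locus)
  }
  missing <- setdiff(outcomes$individual, at$individual)
  if (length(missing) > 0L) {
    stop("no profile for labelled individual(s): ",
         paste(missing, collapse = ", "))
  }
  groups <- sort(unique(outcomes$outcome))
  if (length(groups) != 2L) stop("outcome must have exactly two levels")
  carrier <- vapply(
    split_alleles(at$alleles[match(outcomes$individual, at$individual)]),
    function(x) allele %in% x, logical(1)
  )
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(groups, c("carrier", "non_carrier")))
  for (g in seq_along(groups)) {
    in_g <- outcomes$outcome == groups[g]
    tab[g, ] <- c(sum(carrier & in_g), sum(!carrier & in_g))
  }
  prevalence <- tibble::tibble(
    outcome = groups,
    carriers = unname(tab[, "carrier"]),
    n = unname(rowSums(tab)),
    prevalence_pct = round_pct(
      unname(100 * tab[, "carrier"] / rowSums(tab)))
  )
  structure(
    list(table = tab, p_value = fisher_exact_2x2(tab),
         prevalence = prevalence, locus = locus, allele = allele),
    class = "mhc_association"
  )
}

#' @export
print.mhc_association <- function(x, ...) {
  cat("<mhc_association> ", x$locus, "*", x$allele,
      "  Fisher exact p = ", signif(x$p_value, 3), "\n", sep = "")
  print(x$prevalence, ...)
  invisible(x)
}

#' Cut a dendrogram into haplotype groups
#'
#' @param h An `hclust`-like object.
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
haplotype_groups <- function(h, k) {
  stats::cutree(stats::as.hclust(h), k = k)
}
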