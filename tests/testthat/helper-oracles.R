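# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive re-derivation of the quantity it
# checks, sharing no code with the package implementation.

rnd_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
}

# Exhaustive-offset merge oracle: enumerates every offset, applies the
# longest-overlap / fewest-mismatch / smallest-offset rule and builds the
# consensus base by base.
oracle_merge <- function(fwd_seq, rev_seq, fwd_qual, rev_qual,
                         min_overlap = 10L, max_density = 0.25) {
  a <- strsplit(fwd_seq, "")[[1]]
  b <- strsplit(oracle_revcomp(rev_seq), "")[[1]]
  qa <- utf8ToInt(fwd_qual) - 33L
  qb <- rev(utf8ToInt(rev_qual)) - 33L
  n1 <- length(a)
  n2 <- length(b)
  cand <- data.frame(d = integer(), o = integer(), mm = integer())
  for (d in seq(-(n2 - min_overlap), n1 - min_overlap)) {
    s <- max(0L, d)
    e <- min(n1, d + n2)
    o <- e - s
    if (o < min_overlap) next
    mm <- sum(a[(s + 1):e] != b[(s + 1):e - d])
    if (mm <= o * max_density) {
      cand <- rbind(cand, data.frame(d = d, o = o, mm = mm))
    }
  }
  if (nrow(cand) == 0L) return(NULL)
  cand <- cand[order(-cand$o, cand$mm, cand$d), ]
  d <- cand$d[1]
  lo <- min(0L, d)
  hi <- max(n1, d + n2)
  seq <- character(hi - lo)
  qual <- integer(hi - lo)
  for (p in seq_len(hi - lo)) {
    ia <- p + lo            # 1-based position in a
    ib <- p + lo - d        # 1-based position in b
    ina <- ia >= 1L && ia <= n1
    inb <- ib >= 1L && ib <= n2
    if (ina && inb) {
      if (a[ia] == b[ib]) {
        seq[p] <- a[ia]
        qual[p] <- max(qa[ia], qb[ib])
      } else if (qb[ib] > qa[ia]) {
        seq[p] <- b[ib]
        qual[p] <- qb[ib]
      } else {
        seq[p] <- a[ia]
        qual[p] <- qa[ia]
      }
    } else if (ina) {
      seq[p] <- a[ia]
      qual[p] <- qa[ia]
    } else {
      seq[p] <- b[ib]
      qual[p] <- qb[ib]
    }
  }
  list(sequence = paste(seq, collapse = ""),
       support = intToUtf8(pmin(qual, 60L) + 33L))
}

# Brute-force two-sided Fisher p: enumerate every table with the observed
# margins and sum the hypergeometric probabilities not exceeding the
# observed one.
oracle_fisher <- function(t) {
  a <- t[1, 1]
  r1 <- sum(t[1, ])
  r2 <- sum(t[2, ])
  c1 <- sum(t[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  pobs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Naive complete-linkage oracle: clusters kept as explicit member sets,
# inter-cluster distance recomputed from the original matrix at every
# step (max over all member pairs); same deterministic tie rule.
oracle_complete_linkage <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        dij <- max(D[clusters[[i]], clusters[[j]]])
        if (is.null(best) || dij < best$d) {
          best <- list(i = i, j = j, d = dij)
        }
      }
    }
    heights <- c(heights, best$d)
    merges <- c(merges, list(sort(c(clusters[[best$i]],
                                    clusters[[best$j]]))))
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(heights = heights, members = merges)
}

# Member sets at each merge of an hclust-style object.
hclust_members <- function(h) {
  mem <- list()
  for (k in seq_along(h$height)) {
    get <- function(x) if (x < 0) -x else mem[[x]]
    mem[[k]] <- sort(c(get(h$merge[k, 1]), get(h$merge[k, 2])))
  }
  mem
}

# Small two-locus configuration with short primers for unit tests.
toy_loci <- function() {
  tab <- tempfile(fileext = ".tsv")
  writeLines(c(
    "locus\tclass\tfwd_primer\trev_primer\tamplicon_bp\tgenome_copies",
    "AAX\tII\tACGTACGTAA\tTTGGCCAATT\t190\t1",
    "BBX\tII\tGGGTTTCCCA\tAACCGGTTAA\t200\t3"
  ), tab)
  read_locus_table(tab)
}

# Reference with n random alleles per locus (interior-length sequences).
toy_reference <- function(loci, n = 3L, seed = 7L) {
  set.seed(seed)
  alleles <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    data.frame(locus = loci$locus[i],
               label = sprintf("%02d", seq_len(n)),
               sequence = vapply(seq_len(n), function(k)
                 rnd_dna(loci$interior_bp[i]), character(1)))
  }))
  mhc_reference(loci, alleles)
}

# Error-free read pair covering an amplicon built from a reference allele.
toy_pair <- function(loci, locus, interior, read_len = 160L,
                     id = "r1", qual_char = "D") {
  i <- match(locus, loci$locus)
  amp <- paste0(loci$fwd_primer[i], interior,
                oracle_revcomp(loci$rev_primer[i]))
  pad <- strrep("G", read_len)
  tibble::tibble(
    read_id = id,
    fwd_seq = substr(paste0(amp, pad), 1L, read_len),
    rev_seq = substr(paste0(oracle_revcomp(amp), pad), 1L, read_len),
    fwd_qual = strrep(qual_char, read_len),
    rev_qual = strrep(qual_char, read_len)
  )
}
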