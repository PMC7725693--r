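# Merged reads -> per-individual allele profiles.
#
# Reads are matched against the reference database (exact sequence match
# first, then end-free pairwise alignment); per (individual, locus) the
# matched read counts are tallied and every reference allele holding
# strictly more than 10% of that target's reads is called present.
# Highly duplicated unmatched sequences above the same threshold are
# registered as provisional novel alleles and the tally is repeated with
# the augmented database until no new candidate appears.

#' Match one sequence against the reference alleles of a locus
#'
#' Exact sequence equality wins immediately. Otherwise each stored allele
#' is compared by global end-free (overlap) alignment; identity is the
#' number of matching bases divided by the longer sequence length. The
#' best allele is returned if its identity reaches `min_identity`; an
#' exact tie between two alleles yields `"AMBIGUOUS"`, a best identity
#' below the cutoff yields `"NOMATCH"`.
#'
#' @param seq A merged, primer-trimmed read sequence.
#' @param db An [mhc_reference()].
#' @param locus Locus label (must exist in `db`).
#' @param min_identity Minimum identity for a non-exact match.
#' @return The allele label, `"AMBIGUOUS"`, or `"NOMATCH"`.
#' @export
match_allele <- function(seq, db, locus, min_identity = 0.98) {
  if (!locus %in% db$loci$locus) stop("unknown locus: ", locus)
  match_alleles(seq, db, locus, min_identity)
}

# unit-score substitution matrix so alignment score == match count
.sub_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = 0)
    }
    m
  }
})

#' @noRd
seq_identity <- function(seq, ref) {
  if (nchar(seq) == nchar(ref)) {
    return((nchar(seq) - hamming(seq, ref)) / nchar(seq))
  }
  aln <- Biostrings::pairwiseAlignment(
    seq, ref, type = "overlap", substitutionMatrix = .sub_matrix(),
    gapOpening = 4, gapExtension = 1
  )
  Biostrings::nmatch(aln) / max(nchar(seq), nchar(ref))
}

# Vectorised matcher over many sequences at one locus. Equal-length
# comparisons use Hamming distance (exact for substitution-only
# divergence); unequal lengths fall back to end-free alignment.
#' @noRd
match_alleles <- function(seqs, db, locus, min_identity = 0.98) {
  at <- db_alleles(db, locus)
  out <- rep("NOMATCH", length(seqs))
  if (nrow(at) == 0L) return(out)
  exact <- match(seqs, at$sequence)
  out[!is.na(exact)] <- at$label[exact[!is.na(exact)]]
  todo <- which(is.na(exact))
  for (i in todo) {
    L <- nchar(seqs[i])
    mm <- cpp_hamming_many(seqs[i], at$sequence)
    ident <- (L - mm) / L
    diff_len <- is.na(ident)
    if (any(diff_len)) {
      ident[diff_len] <- vapply(at$sequence[diff_len], seq_identity,
                                numeric(1), seq = seqs[i],
                                USE.NAMES = FALSE)
    }
    best <- max(ident)
    if (best < min_identity) next
    hits <- which(abs(ident - best) < 1e-12)
    out[i] <- if (length(hits) > 1L) "AMBIGUOUS" else at$label[hits]
  }
  out
}

#' Tally merged reads per individual and locus
#'
#' Each merged read is matched against the reference alleles of its locus;
#' matched reads increment the allele's count, while `NOMATCH` and
#' `AMBIGUOUS` reads accumulate per exact sequence in the unmatched pool
#' (ambiguous reads never increment allele counts, so near-identical
#' alleles are not double counted).
#'
#' @param merged Tibble of merged reads with columns `individual`,
#'   `locus`, `sequence`.
#' @inheritParams match_allele
#' @return A tidy tally: one row per (individual, locus, allele) or
#'   (individual, locus, unmatched sequence) with columns `individual`,
#'   `locus`, `allele` (`NA` for unmatched), `sequence` (`NA` for
#'   matched), `count`.
#' @export
tally_reads <- function(merged, db, min_identity = 0.98) {
  empty <- tibble::tibble(individual = character(), locus = character(),
                          allele = character(), sequence = character(),
                          count = integer())
  if (nrow(merged) == 0L) return(empty)
  if (!"individual" %in% names(merged)) {
    stop("merged reads need an `individual` column")
  }
  out <- vector("list", 0)
  for (loc in intersect(db$loci$locus, unique(merged$locus))) {
    m <- merged[merged$locus == loc, ]
    useq <- unique(m$sequence)
    lab <- match_alleles(useq, db, loc, min_identity)
    hit <- lab[match(m$sequence, useq)]
    matched <- !(hit %in% c("NOMATCH", "AMBIGUOUS"))
    t1 <- dplyr::count(
      tibble::tibble(individual = m$individual[matched],
                     locus = loc, allele = hit[matched],
                     sequence = NA_character_),
      .data$individual, .data$locus, .data$allele, .data$sequence,
      name = "count"
    )
    t2 <- dplyr::count(
      tibble::tibble(individual = m$individual[!matched],
                     locus = loc, allele = NA_character_,
                     sequence = m$sequence[!matched]),
      .data$individual, .data$locus, .data$allele, .data$sequence,
      name = "count"
    )
    out[[length(out) + 1L]] <- dplyr::bind_rows(t1, t2)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(empty)
  dplyr::arrange(res, .data$individual, .data$locus, .data$allele)
}

#' Call alleles from a read tally
#'
#' An allele is considered present when its reads make up strictly more
#' than `threshold` of the total reads for that gene target in that
#' individual (a fraction of exactly 10% is excluded). Loci with reads
#' but no allele above threshold are reported as `NO_CALL`; loci of the
#' configuration with no reads at all as `NO_DATA`. A warning is emitted
#' when a call set exceeds the locus's copy-number bound.
#'
#' @param tally Output of [tally_reads()].
#' @param loci Locus tibble (defines the full locus grid and the
#'   per-locus allele bound).
#' @param threshold Read-fraction calling threshold.
#' @return Profile tibble: `individual`, `locus`, `alleles`
#'   (semicolon-joined, sorted lexicographically), `n_alleles`, `status`.
#' @export
call_alleles <- function(tally, loci, threshold = 0.10) {
  inds <- unique(tally$individual)
  grid <- tidyr::expand_grid(individual = inds, locus = loci$locus)
  groups <- dplyr::group_by(tally, .data$individual, .data$locus)
  calls <- dplyr::summarise(
    groups,
    alleles = {
      tot <- sum(.data$count)
      ok <- !is.na(.data$allele) & .data$count / tot > threshold
      join_alleles(.data$allele[ok])
    },
    .groups = "drop"
  )
  out <- dplyr::left_join(grid, calls, by = c("individual", "locus"))
  out$n_alleles <- lengths(split_alleles(dplyr::coalesce(out$alleles, "")))
  out$status <- dplyr::case_when(
    is.na(out$alleles) ~ "NO_DATA",
    out$n_alleles == 0L ~ "NO_CALL",
    TRUE ~ "OK"
  )
  out$alleles <- dplyr::coalesce(out$alleles, "")
  over <- out$n_alleles >
    loci$max_alleles[match(out$locus, loci$locus)]
  if (any(over)) {
    warning("call set exceeds copy-number bound for: ",
            paste(out$individual[over], out$locus[over], collapse = ", "))
  }
  dplyr::arrange(out, .data$individual, .data$locus)
}

#' Detect candidate novel alleles
#'
#' Exact-duplicate clusters in the unmatched pool whose read fraction is
#' strictly above `threshold` in at least one individual (and with at
#' least `min_copies` supporting reads) are registered into the database
#' as provisional novel alleles; smaller clusters are treated as noise.
#'
#' @inheritParams call_alleles
#' @param db An [mhc_reference()].
#' @param min_copies Minimum supporting read count per candidate.
#' @return A list with `db` (augmented reference) and `candidates`
#'   (tibble `locus, label, sequence`).
#' @export
detect_novel <- function(tally, db, threshold = 0.10, min_copies = 10L) {
  totals <- dplyr::summarise(
    dplyr::group_by(tally, .data$individual, .data$locus),
    total = sum(.data$count), .groups = "drop"
  )
  un <- tally[is.na(tally$allele), , drop = FALSE]
  un <- dplyr::left_join(un, totals, by = c("individual", "locus"))
  keep <- un$count / un$total > threshold & un$count >= min_copies
  cand <- dplyr::distinct(un[keep, , drop = FALSE],
                          .data$locus, .data$sequence)
  out <- tibble::tibble(locus = character(), label = character(),
                        sequence = character())
  for (i in seq_len(nrow(cand))) {
    already <- db_alleles(db, cand$locus[i])
    if (cand$sequence[i] %in% already$sequence) next
    db <- register_novel(db, cand$locus[i], cand$sequence[i])
    out <- dplyr::bind_rows(out, tibble::tibble(
      locus = cand$locus[i], label = attr(db, "label"),
      sequence = cand$sequence[i]
    ))
  }
  list(db = db, candidates = out)
}

#' Genotype a cohort of individuals from merged reads
#'
#' Orchestrates tallying, novel-allele discovery, re-tallying with the
#' augmented reference and final calling. Iteration stops when a round
#' discovers no new candidate (at most `max_rounds` tally rounds); each
#' round is deterministic given the read multiset.
#'
#' @inheritParams tally_reads
#' @inheritParams call_alleles
#' @inheritParams detect_novel
#' @param max_rounds Cap on tally/discovery rounds.
#' @return An object of class `mhc_genotypes`: a list with `profiles`
#'   (see [call_alleles()]), `tally`, `novel` (discovered candidates) and
#'   `reference` (the augmented database).
#' @export
genotype_cohort <- function(merged, db, threshold = 0.10,
                            min_identity = 0.98, min_copies = 10L,
                            max_rounds = 3L) {
  novel <- tibble::tibble(locus = character(), label = character(),
                          sequence = character())
  tally <- NULL
  for (round in seq_len(max_rounds)) {
    tally <- tally_reads(merged, db, min_identity)
    found <- detect_novel(tally, db, threshold, min_copies)
    if (nrow(found$candidates) == 0L) break
    db <- found$db
    novel <- dplyr::bind_rows(novel, found$candidates)
    if (round == max_rounds) tally <- tally_reads(merged, db, min_identity)
  }
  structure(
    list(profiles = call_alleles(tally, db$loci, threshold),
         tally = tally, novel = novel, reference = db),
    class = "mhc_genotypes"
  )
}

#' Genotype a single individual
#'
#' Convenience wrapper around [genotype_cohort()] for merged reads that
#' lack an `individual` column.
#'
#' @param merged Merged-read tibble for one individual (`locus`,
#'   `sequence`).
#' @param individual Identifier to assign.
#' @inheritParams genotype_cohort
#' @return An `mhc_genotypes` object.
#' @export
genotype_individual <- function(merged, db, individual = "individual",
                                ...) {
  merged$individual <- individual
  genotype_cohort(merged, db, ...)
}

#' @export
print.mhc_genotypes <- function(x, ...) {
  cat("<mhc_genotypes> ", length(unique(x$profiles$individual)),
      " individuals, ", nrow(x$novel), " novel allele(s)\n", sep = "")
  print(x$profiles, ...)
  invisible(x)
}

#' Write and read genotype profile tables
#'
#' Wide TSV layout: one row per individual, one column per locus, alleles
#' semicolon-joined and sorted lexicographically; loci without reads are
#' written as `NO_DATA`.
#'
#' @param profiles Long profile tibble (`individual, locus, alleles,
#'   status`).
#' @param path Output TSV path.
#' @param loci Locus tibble giving the column order.
#' @return `path` invisibly; [read_profiles()] returns the long tibble.
#' @export
write_profiles <- function(profiles, path, loci = koala_loci()) {
  cell <- ifelse(profiles$status == "NO_DATA", "NO_DATA", profiles$alleles)
  wide <- tidyr::pivot_wider(
    tibble::tibble(individual = profiles$individual,
                   locus = profiles$locus, cell = cell),
    names_from = "locus", values_from = "cell"
  )
  wide <- wide[c("individual", intersect(loci$locus, names(wide)))]
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path, loci = koala_loci()) {
  wide <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character", na.strings = NULL)
  long <- tidyr::pivot_longer(wide, -"individual", names_to = "locus",
                              values_to = "alleles")
  long$status <- ifelse(long$alleles == "NO_DATA", "NO_DATA",
                        ifelse(nzchar(long$alleles), "OK", "NO_CALL"))
  long$alleles[long$status == "NO_DATA"] <- ""
  long$n_alleles <- lengths(split_alleles(long$alleles))
  tibble::as_tibble(long[c("individual", "locus", "alleles",
                           "n_alleles", "status")])
}
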