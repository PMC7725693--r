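# Raw paired reads -> per-locus merged amplicon interiors.
#
# The stages mirror the wet-lab design: each read pair carries the PCR
# primers of exactly one gene target at the 5' ends of its mates, so the
# primer pair identifies the locus; primers (and any 3' read-through past
# the amplicon) are trimmed; mates shorter than 150 bp are culled; the
# overlapping mates are merged into the full amplicon interior.

#' Read one paired FASTQ into a read-pair table
#'
#' @param fwd_path,rev_path Paths to the R1/R2 FASTQ files (optionally
#'   gzipped). Mates are paired by position.
#' @return A tibble with columns `read_id`, `fwd_seq`, `rev_seq`,
#'   `fwd_qual`, `rev_qual` (qualities as Phred+33 strings).
#' @export
read_fastq_pair <- function(fwd_path, rev_path) {
  # harmless metadata-column drop when FASTQ descriptions are present
  f <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(fwd_path))
  r <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(rev_path))
  if (length(f) != length(r)) {
    stop("mate files differ in read count: ", fwd_path, " vs ", rev_path)
  }
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(f)),
    fwd_seq = unname(as.character(f)),
    rev_seq = unname(as.character(r)),
    fwd_qual = unname(as.character(Biostrings::quality(f))),
    rev_qual = unname(as.character(Biostrings::quality(r)))
  )
}

#' Assign read pairs to gene targets by primer match
#'
#' A pair is assigned to the unique locus whose forward primer matches a
#' prefix of the forward mate and whose reverse primer matches a prefix of
#' the reverse mate, each with at most `max_mismatches` substitutions
#' (IUPAC-aware, no indels). Pairs matching no locus, or more than one,
#' are `UNASSIGNED`.
#'
#' @param pairs Read-pair tibble (see [read_fastq_pair()]).
#' @param loci Locus tibble from [read_locus_table()].
#' @param max_mismatches Maximum substitutions tolerated per primer.
#' @return `pairs` with a `locus` column added.
#' @export
assign_locus <- function(pairs, loci, max_mismatches = 2L) {
  n <- nrow(pairs)
  hits <- matrix(FALSE, nrow = n, ncol = nrow(loci))
  for (i in seq_len(nrow(loci))) {
    mf <- prefix_mismatches(pairs$fwd_seq, loci$fwd_primer[i])
    mr <- prefix_mismatches(pairs$rev_seq, loci$rev_primer[i])
    hits[, i] <- !is.na(mf) & !is.na(mr) &
      mf <= max_mismatches & mr <= max_mismatches
  }
  nhit <- rowSums(hits)
  locus <- rep("UNASSIGNED", n)
  one <- which(nhit == 1L)
  locus[one] <- loci$locus[max.col(hits[one, , drop = FALSE])]
  dplyr::mutate(pairs, locus = locus)
}

# Earliest admissible occurrence (full or 3'-partial) of an IUPAC pattern
# in each sequence; returns the kept length (bases before the occurrence).
# Mirrors 3'-adapter trimming: tolerated mismatch count is
# floor(overlap * max_err_rate), overlaps shorter than min_overlap are
# ignored.
#' @noRd
readthrough_keep <- function(seqs, pattern, max_err_rate = 0.1,
                             min_overlap = 3L) {
  keep <- nchar(seqs)
  pb <- seq_bits(pattern)
  plen <- length(pb)
  for (n in unique(keep)) {
    idx <- which(nchar(seqs) == n)
    m <- matrix(.iupac_bits[utf8ToInt(paste(seqs[idx], collapse = ""))],
                nrow = n)
    kl <- rep(n, length(idx))
    for (p in seq(n, 1L)) {
      o <- min(n - p + 1L, plen)
      if (o < min_overlap) next
      z <- bitwAnd(m[p:(p + o - 1L), , drop = FALSE], pb[seq_len(o)]) == 0L
      dim(z) <- c(o, ncol(m))
      mm <- colSums(z)
      kl[mm <= floor(o * max_err_rate)] <- p - 1L
    }
    keep[idx] <- kl
  }
  keep
}

#' Trim primers and cull short reads
#'
#' Removes each mate's own primer from its 5' end and any 3' read-through
#' into (or past) the reverse complement of the opposite primer, so that
#' trimmed mates carry amplicon interior only and are directly comparable
#' to the primer-trimmed reference alleles. Pairs where either trimmed
#' mate is shorter than `min_len` are culled (strictly shorter-than; a
#' mate of exactly `min_len` is kept).
#'
#' @param pairs Read-pair tibble with a `locus` column
#'   (see [assign_locus()]); `UNASSIGNED` rows are dropped.
#' @param loci Locus tibble.
#' @param min_len Minimum trimmed mate length in bp.
#' @return The trimmed pairs tibble with a logical `culled` column.
#' @export
trim_reads <- function(pairs, loci, min_len = 150L) {
  pairs <- pairs[pairs$locus %in% loci$locus, , drop = FALSE]
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    p <- pairs[pairs$locus == loci$locus[i], , drop = FALSE]
    if (nrow(p) == 0L) next
    fl <- nchar(loci$fwd_primer[i])
    rl <- nchar(loci$rev_primer[i])
    p$fwd_seq <- substr(p$fwd_seq, fl + 1L, nchar(p$fwd_seq))
    p$fwd_qual <- substr(p$fwd_qual, fl + 1L, nchar(p$fwd_qual))
    p$rev_seq <- substr(p$rev_seq, rl + 1L, nchar(p$rev_seq))
    p$rev_qual <- substr(p$rev_qual, rl + 1L, nchar(p$rev_qual))
    kf <- readthrough_keep(p$fwd_seq, revcomp(loci$rev_primer[i]))
    kr <- readthrough_keep(p$rev_seq, revcomp(loci$fwd_primer[i]))
    p$fwd_seq <- substr(p$fwd_seq, 1L, kf)
    p$fwd_qual <- substr(p$fwd_qual, 1L, kf)
    p$rev_seq <- substr(p$rev_seq, 1L, kr)
    p$rev_qual <- substr(p$rev_qual, 1L, kr)
    p$culled <- kf < min_len | kr < min_len
    out[[i]] <- p
  }
  dplyr::bind_rows(out)
}

#' Merge one trimmed read pair
#'
#' The reverse mate is reverse-complemented, then the overlap offset is
#' chosen among all offsets with overlap of at least `min_overlap` and a
#' mismatch fraction of at most `max_mismatch_density`: longest admissible
#' overlap wins, ties go to the lowest mismatch count and then to the
#' smallest offset. The consensus takes the higher-quality base at each
#' conflicting position (quality tie: forward base); the merged interior
#' is reported on the forward-primer strand.
#'
#' @param fwd_seq,rev_seq Trimmed mate sequences.
#' @param fwd_qual,rev_qual Phred+33 quality strings (same lengths).
#' @param min_overlap Minimum admissible overlap in bp.
#' @param max_mismatch_density Maximum mismatch fraction in the overlap.
#' @return A list with `sequence` and `support` (consensus Phred+33
#'   string), or `NULL` when no admissible overlap exists.
#' @export
merge_pair <- function(fwd_seq, rev_seq, fwd_qual, rev_qual,
                       min_overlap = 10L, max_mismatch_density = 0.25) {
  res <- cpp_merge_pair(
    fwd_seq, revcomp(rev_seq),
    utf8ToInt(fwd_qual) - 33L,
    rev(utf8ToInt(rev_qual)) - 33L,
    as.integer(min_overlap), max_mismatch_density
  )
  res
}

#' Merge a table of trimmed read pairs
#'
#' Vectorised wrapper around [merge_pair()]; identical pairs are merged
#' once and the result reused.
#'
#' @param trimmed Output of [trim_reads()] (culled rows are ignored).
#' @inheritParams merge_pair
#' @return A tibble `read_id, locus, sequence, support, merged` where
#'   `merged` is `FALSE` for pairs with no admissible overlap.
#' @export
merge_pairs <- function(trimmed, min_overlap = 10L,
                        max_mismatch_density = 0.25) {
  trimmed <- trimmed[!trimmed$culled, , drop = FALSE]
  if (nrow(trimmed) == 0L) {
    return(tibble::tibble(read_id = character(), locus = character(),
                          sequence = character(), support = character(),
                          merged = logical()))
  }
  key <- paste(trimmed$fwd_seq, trimmed$rev_seq,
               trimmed$fwd_qual, trimmed$rev_qual, sep = "\r")
  uniq <- which(!duplicated(key))
  res <- lapply(uniq, function(i) {
    merge_pair(trimmed$fwd_seq[i], trimmed$rev_seq[i],
               trimmed$fwd_qual[i], trimmed$rev_qual[i],
               min_overlap, max_mismatch_density)
  })
  idx <- match(key, key[uniq])
  seqs <- vapply(res, function(x) if (is.null(x)) NA_character_
                 else x$sequence, character(1))
  sup <- vapply(res, function(x) if (is.null(x)) NA_character_
                else x$support, character(1))
  tibble::tibble(
    read_id = trimmed$read_id,
    locus = trimmed$locus,
    sequence = seqs[idx],
    support = sup[idx],
    merged = !is.na(seqs[idx])
  )
}

#' Run the full read-processing stage for one individual
#'
#' Locus assignment, primer trimming with length cull, and pair merging,
#' with a per-read status log.
#'
#' @inheritParams assign_locus
#' @inheritParams trim_reads
#' @inheritParams merge_pair
#' @return A list with `merged` (tibble `read_id, locus, sequence,
#'   support`) and `log` (tibble `read_id, locus, status`, status one of
#'   `merged`, `culled`, `unassigned`, `unmerged`).
#' @export
process_read_pairs <- function(pairs, loci, max_mismatches = 2L,
                               min_len = 150L, min_overlap = 10L,
                               max_mismatch_density = 0.25) {
  assigned <- assign_locus(pairs, loci, max_mismatches)
  trimmed <- trim_reads(assigned, loci, min_len)
  merged <- merge_pairs(trimmed, min_overlap, max_mismatch_density)
  log <- tibble::tibble(
    read_id = assigned$read_id,
    locus = assigned$locus,
    status = "unassigned"
  )
  log$status[match(trimmed$read_id[trimmed$culled], log$read_id)] <- "culled"
  log$status[match(merged$read_id[!merged$merged], log$read_id)] <- "unmerged"
  log$status[match(merged$read_id[merged$merged], log$read_id)] <- "merged"
  list(
    merged = merged[merged$merged,
                    c("read_id", "locus", "sequence", "support")],
    log = log
  )
}

#' Write merged reads as per-locus FASTA
#'
#' @param merged Merged-read tibble (`read_id, locus, sequence`).
#' @param dir Output directory; one `<locus>.fasta` per locus present.
#' @return The paths written, invisibly.
#' @export
write_merged_fasta <- function(merged, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (loc in unique(merged$locus)) {
    m <- merged[merged$locus == loc, ]
    x <- Biostrings::DNAStringSet(m$sequence)
    names(x) <- m$read_id
    path <- file.path(dir, paste0(loc, ".fasta"))
    Biostrings::writeXStringSet(x, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
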