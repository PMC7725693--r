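# End-to-end orchestration: FASTQ directory (or in-memory read pairs)
# -> per-locus merged reads -> genotype profiles -> optional pedigree
# congruence report, with per-individual per-stage counts.

#' Find paired FASTQ files in a directory
#'
#' Expects one `<individual>_R1.fastq[.gz]` / `_R2.fastq[.gz]` pair per
#' individual.
#'
#' @param dir Directory to scan.
#' @return Tibble `individual, fwd, rev`.
#' @export
find_read_pairs <- function(dir) {
  f1 <- sort(list.files(dir, pattern = "_R1\\.fastq(\\.gz)?$",
                        full.names = TRUE))
  if (length(f1) == 0L) stop("no *_R1.fastq[.gz] files in ", dir)
  f2 <- sub("_R1\\.fastq", "_R2.fastq", f1)
  missing <- !file.exists(f2)
  if (any(missing)) {
    stop("missing mate file(s): ", paste(f2[missing], collapse = ", "))
  }
  tibble::tibble(
    individual = sub("_R1\\.fastq(\\.gz)?$", "", basename(f1)),
    fwd = f1, rev = f2
  )
}

#' Run the full genotyping pipeline
#'
#' Per individual: locus assignment, primer trimming and culling, pair
#' merging; then cohort genotyping with novel-allele discovery; then,
#' when a pedigree is supplied, Mendelian congruence checking. Identical
#' inputs and parameters give identical outputs.
#'
#' @param reads Either a directory of paired FASTQ files (see
#'   [find_read_pairs()]) or a read-pair tibble with an `individual`
#'   column.
#' @param reference An [mhc_reference()], or a FASTA path.
#' @param loci Locus tibble (defaults to the packaged koala targets).
#' @param pedigree Optional pedigree tibble or TSV path.
#' @param threshold Read-fraction calling threshold.
#' @param min_identity Reference-match identity cutoff.
#' @param max_mismatches Primer-match substitution tolerance.
#' @param min_len Post-trim length cull.
#' @param min_overlap,max_mismatch_density Merge parameters.
#' @param min_copies Minimum duplicate count for novel candidates.
#' @return An object of class `mhc_run`: list with `genotypes`
#'   (an `mhc_genotypes`), `profiles`, `stage_counts` (tibble
#'   `individual, reads_in, merged, culled, unassigned, unmerged`),
#'   `congruence` (`mhc_congruence` or `NULL`) and the parameters used.
#' @export
run_pipeline <- function(reads, reference, loci = koala_loci(),
                         pedigree = NULL, threshold = 0.10,
                         min_identity = 0.98, max_mismatches = 2L,
                         min_len = 150L, min_overlap = 10L,
                         max_mismatch_density = 0.25,
                         min_copies = 10L) {
  if (is.character(reference)) {
    reference <- read_reference(reference, loci)
  }
  if (is.character(reads)) {
    files <- find_read_pairs(reads)
    reads <- dplyr::bind_rows(lapply(seq_len(nrow(files)), function(i) {
      dplyr::mutate(read_fastq_pair(files$fwd[i], files$rev[i]),
                    individual = files$individual[i], .before = 1L)
    }))
  }
  if (!"individual" %in% names(reads)) {
    stop("read pairs need an `individual` column")
  }
  merged <- vector("list", 0)
  counts <- vector("list", 0)
  for (ind in unique(reads$individual)) {
    r <- reads[reads$individual == ind, ]
    res <- process_read_pairs(r, loci, max_mismatches, min_len,
                              min_overlap, max_mismatch_density)
    res$merged$individual <- ind
    merged[[length(merged) + 1L]] <- res$merged
    counts[[length(counts) + 1L]] <- tibble::tibble(
      individual = ind,
      reads_in = nrow(r),
      merged = sum(res$log$status == "merged"),
      culled = sum(res$log$status == "culled"),
      unassigned = sum(res$log$status == "unassigned"),
      unmerged = sum(res$log$status == "unmerged")
    )
  }
  merged <- dplyr::bind_rows(merged)
  genotypes <- genotype_cohort(merged, reference, threshold,
                               min_identity, min_copies)
  congruence <- NULL
  if (!is.null(pedigree)) {
    if (is.character(pedigree)) pedigree <- read_pedigree(pedigree)
    congruence <- check_pedigree(genotypes$profiles, pedigree)
  }
  structure(
    list(genotypes = genotypes, profiles = genotypes$profiles,
         stage_counts = dplyr::bind_rows(counts),
         congruence = congruence,
         params = list(threshold = threshold,
                       min_identity = min_identity,
                       max_mismatches = max_mismatches,
                       min_len = min_len, min_overlap = min_overlap,
                       max_mismatch_density = max_mismatch_density,
                       min_copies = min_copies)),
    class = "mhc_run"
  )
}

#' @export
print.mhc_run <- function(x, ...) {
  cat("<mhc_run> ", nrow(x$stage_counts), " individuals\n", sep = "")
  print(x$stage_counts, ...)
  if (!is.null(x$congruence)) print(x$congruence, ...)
  invisible(x)
}
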