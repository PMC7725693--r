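# Locus configuration and reference allele database. Every other module is
# written against these two containers: a locus table (one row per PCR
# target) and an `mhc_reference` (locus table + named, primer-trimmed
# exon-2 allele sequences).

.iupac_alphabet <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                     "B", "D", "H", "V", "N")

#' Read a locus configuration table
#'
#' Loads the per-target PCR configuration: primers, amplicon size and the
#' number of gene copies the primer pair amplifies. The packaged default
#' ([koala_loci()]) describes the six koala MHC targets: class I UA
#' (which co-amplifies the paralogous UB gene) and UC, and class II DAB,
#' DBB, DCB and DMB. DAB and DBB are present as three gene copies in the
#' koala genome; the remaining targets are single copy.
#'
#' @param path Path to a tab-separated table with columns
#'   `locus,class,fwd_primer,rev_primer,amplicon_bp,genome_copies` and an
#'   optional `coamplified_paralog` column.
#' @return A tibble with one row per locus and derived columns
#'   `interior_bp` (amplicon minus both primers) and
#'   `max_alleles` (2 distinct alleles per amplified gene copy; the pooled
#'   UA+UB target allows 4).
#' @export
read_locus_table <- function(path) {
  if (!file.exists(path)) stop("locus table not found: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (nrow(raw) == 0L) stop("no loci in ", path)
  needed <- c("locus", "class", "fwd_primer", "rev_primer",
              "amplicon_bp", "genome_copies")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("locus table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"coamplified_paralog" %in% names(raw)) raw$coamplified_paralog <- ""
  loci <- tibble::tibble(
    locus = raw$locus,
    mhc_class = raw$class,
    fwd_primer = toupper(raw$fwd_primer),
    rev_primer = toupper(raw$rev_primer),
    amplicon_bp = suppressWarnings(as.integer(raw$amplicon_bp)),
    genome_copies = suppressWarnings(as.integer(raw$genome_copies)),
    coamplified_paralog = ifelse(nzchar(raw$coamplified_paralog),
                                 raw$coamplified_paralog, NA_character_)
  )
  bad <- which(!nzchar(loci$locus) | is.na(loci$amplicon_bp) |
                 is.na(loci$genome_copies) | !nzchar(loci$fwd_primer) |
                 !nzchar(loci$rev_primer))
  if (length(bad) > 0L) {
    stop("malformed locus table row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  }
  validate_loci(loci)
}

#' @noRd
validate_loci <- function(loci) {
  dup <- loci$locus[duplicated(loci$locus)]
  if (length(dup) > 0L) {
    stop("duplicate locus name(s): ", paste(unique(dup), collapse = ", "))
  }
  for (p in c(loci$fwd_primer, loci$rev_primer)) {
    extra <- setdiff(strsplit(p, "")[[1]], .iupac_alphabet)
    if (length(extra) > 0L) {
      stop("primer ", p, " contains non-IUPAC character(s): ",
           paste(extra, collapse = ""))
    }
  }
  if (!all(loci$genome_copies %in% c(1L, 3L))) {
    stop("genome_copies must be 1 or 3")
  }
  plen <- nchar(loci$fwd_primer) + nchar(loci$rev_primer)
  if (any(loci$amplicon_bp <= plen)) {
    stop("amplicon_bp must exceed the combined primer length")
  }
  loci$interior_bp <- loci$amplicon_bp - plen
  # 2 alleles per amplified gene copy; co-amplified paralogs add one gene.
  n_genes <- loci$genome_copies + !is.na(loci$coamplified_paralog)
  loci$max_alleles <- 2L * n_genes
  loci
}

#' Packaged koala MHC locus configuration
#'
#' The six-target table shipped with the package (class I UA, UC; class II
#' DAB, DBB, DCB, DMB with amplicons of 313, 397, 271, 282, 200 and 266 bp).
#'
#' @return A locus tibble, see [read_locus_table()].
#' @export
koala_loci <- function() {
  read_locus_table(
    system.file("extdata", "koala_loci.tsv", package = "koalamhc",
                mustWork = TRUE)
  )
}

#' Construct a reference allele database
#'
#' @param loci Locus tibble from [read_locus_table()].
#' @param alleles Tibble with columns `locus`, `label`, `sequence` and
#'   optionally `provenance` (`"reference"` or `"novel"`). Sequences are
#'   primer-trimmed amplicon interiors (uppercase ACGT, at least 150 bp).
#' @return An object of class `mhc_reference`.
#' @export
mhc_reference <- function(loci, alleles = NULL) {
  if (is.null(alleles)) {
    alleles <- tibble::tibble(locus = character(), label = character(),
                              sequence = character(),
                              provenance = character())
  }
  alleles <- tibble::as_tibble(alleles)
  if (!"provenance" %in% names(alleles)) alleles$provenance <- "reference"
  bad_locus <- setdiff(alleles$locus, loci$locus)
  if (length(bad_locus) > 0L) {
    stop("allele(s) reference unknown locus: ",
         paste(unique(bad_locus), collapse = ", "))
  }
  bad_seq <- grepl("[^ACGT]", alleles$sequence)
  if (any(bad_seq)) {
    stop("non-ACGT characters in sequence of: ",
         paste(alleles$label[bad_seq], collapse = ", "))
  }
  if (any(nchar(alleles$sequence) < 150L)) {
    stop("allele sequences must be at least 150 bp")
  }
  key <- paste(alleles$locus, alleles$label)
  if (anyDuplicated(key)) {
    stop("duplicate (locus, label): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  skey <- paste(alleles$locus, alleles$sequence)
  if (anyDuplicated(skey)) {
    d <- alleles$label[duplicated(skey) | duplicated(skey, fromLast = TRUE)]
    stop("duplicate (locus, sequence) among: ", paste(d, collapse = ", "))
  }
  structure(list(loci = loci, alleles = alleles), class = "mhc_reference")
}

#' @export
print.mhc_reference <- function(x, ...) {
  n <- table(factor(x$alleles$locus, levels = x$loci$locus))
  cat("<mhc_reference> ", nrow(x$alleles), " alleles over ",
      nrow(x$loci), " loci\n", sep = "")
  cat(paste0("  ", names(n), ": ", as.integer(n), collapse = "\n"), "\n")
  invisible(x)
}

#' Load reference alleles from FASTA
#'
#' FASTA headers follow the `>LOCUS*LABEL` dialect used for koala MHC
#' allele names (e.g. `>DBB*03`, `>UC*01:01`); anything after the first
#' whitespace is ignored. Records whose locus is not configured are
#' rejected and reported via the `rejected` attribute (and a message).
#'
#' @param fasta Path to a FASTA of primer-trimmed allele sequences.
#' @inheritParams mhc_reference
#' @return An `mhc_reference`.
#' @export
read_reference <- function(fasta, loci) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  headers <- sub("\\s.*$", "", names(seqs))
  star <- regexpr("*", headers, fixed = TRUE)
  if (any(star < 0L)) {
    stop("FASTA header(s) without LOCUS*LABEL form: ",
         paste(headers[star < 0L], collapse = ", "))
  }
  alleles <- tibble::tibble(
    locus = substr(headers, 1L, star - 1L),
    label = substr(headers, star + 1L, nchar(headers)),
    sequence = unname(as.character(seqs)),
    provenance = "reference"
  )
  rejected <- alleles[!alleles$locus %in% loci$locus, ]
  kept <- alleles[alleles$locus %in% loci$locus, ]
  if (nrow(rejected) > 0L) {
    message("rejected ", nrow(rejected),
            " record(s) with unconfigured locus: ",
            paste(unique(rejected$locus), collapse = ", "))
  }
  db <- mhc_reference(loci, kept)
  attr(db, "rejected") <- rejected
  db
}

#' Write a reference database to FASTA
#'
#' Inverse of [read_reference()]; headers are `LOCUS*LABEL`.
#'
#' @param db An `mhc_reference`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(db, path) {
  x <- Biostrings::DNAStringSet(db$alleles$sequence)
  names(x) <- paste0(db$alleles$locus, "*", db$alleles$label)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Register a novel allele
#'
#' Adds a newly discovered sequence to the database under a provisional
#' label `LOCUS*novel-NNN` (zero-padded counter per locus, starting at
#' 001). The `novel-` namespace keeps provisional labels disjoint from
#' published allele names.
#'
#' @param db An `mhc_reference`.
#' @param locus Locus label.
#' @param sequence Uppercase ACGT interior sequence not yet in the
#'   database at that locus.
#' @return The updated `mhc_reference`; the new label is available as
#'   `attr(db, "label")`.
#' @export
register_novel <- function(db, locus, sequence) {
  if (!locus %in% db$loci$locus) stop("unknown locus: ", locus)
  at <- db$alleles[db$alleles$locus == locus, ]
  hit <- at$label[at$sequence == sequence]
  if (length(hit) > 0L) {
    stop("sequence already present at ", locus, " as ", hit[1])
  }
  n_prev <- sum(startsWith(at$label, "novel-"))
  label <- sprintf("novel-%03d", n_prev + 1L)
  db$alleles <- dplyr::bind_rows(
    db$alleles,
    tibble::tibble(locus = locus, label = label, sequence = sequence,
                   provenance = "novel")
  )
  out <- mhc_reference(db$loci, db$alleles)
  attr(out, "label") <- label
  out
}

#' @noRd
db_alleles <- function(db, locus) {
  db$alleles[db$alleles$locus == locus, ]
}
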