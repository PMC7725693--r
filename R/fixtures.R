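# Packaged data: the captive-population family genotype tables re-typed
# as TSV, the pedigree they imply, and the set of family x locus cells
# flagged as Mendelian discrepancies in the published tables.
#
# Transcription notes: allele labels in the class II columns are bare
# two-digit numbers, class I labels carry a colon suffix. Two typesetting
# artifacts in the printed family 6 row are normalised: a colon used as a
# separator in the UA cell, and a UC label printed as "5:02" (first field
# zero-padded to two digits).

#' @noRd
fixture_path <- function(file) {
  system.file("extdata", file, package = "koalamhc", mustWork = TRUE)
}

#' Packaged family genotype profiles
#'
#' The 36 captive family units (18 dam-sire-joey trios, 18 single-parent
#' pairs; 90 table rows over 58 distinct koalas). Individuals appearing
#' in several families are verified to have identical profiles before
#' deduplication.
#'
#' @param dedupe Return one row per distinct individual (long profile
#'   tibble) rather than the raw per-family rows.
#' @return With `dedupe = TRUE` (default) a long profile tibble
#'   (`individual, locus, alleles, n_alleles, status`); otherwise the raw
#'   table (`family_id, relationship, name`, one column per locus).
#' @export
koala_family_profiles <- function(dedupe = TRUE) {
  raw <- tibble::as_tibble(utils::read.delim(
    fixture_path("koala_family_profiles.tsv"),
    check.names = FALSE, colClasses = "character", na.strings = NULL
  ))
  raw$family_id <- as.integer(raw$family_id)
  loci <- c("UA", "UC", "DAB", "DBB", "DCB", "DMB")
  key <- apply(raw[loci], 1L, paste, collapse = "|")
  bad <- names(which(tapply(key, raw$name,
                            function(x) length(unique(x)) > 1L)))
  if (length(bad) > 0L) {
    stop("inconsistent repeated profile(s) for: ",
         paste(bad, collapse = ", "))
  }
  if (!dedupe) return(raw)
  u <- raw[!duplicated(raw$name), c("name", loci)]
  long <- tidyr::pivot_longer(u, -"name", names_to = "locus",
                              values_to = "alleles")
  long$alleles <- vapply(split_alleles(long$alleles), join_alleles,
                         character(1))
  tibble::tibble(
    individual = long$name, locus = long$locus, alleles = long$alleles,
    n_alleles = lengths(split_alleles(long$alleles)), status = "OK"
  )
}

#' Packaged pedigree of the captive family units
#'
#' @return Pedigree tibble (`family_id, joey, dam, sire, kind`); see
#'   [read_pedigree()].
#' @export
koala_pedigree <- function() {
  read_pedigree(fixture_path("koala_pedigree.tsv"))
}

#' Packaged expected Mendelian discrepancies
#'
#' The family x locus cells italicised in the published family tables,
#' with their discrepancy class.
#'
#' @return Tibble `family_id, locus, discrepancy`.
#' @export
koala_expected_discrepancies <- function() {
  out <- tibble::as_tibble(utils::read.delim(
    fixture_path("koala_expected_discrepancies.tsv"),
    check.names = FALSE
  ))
  out$family_id <- as.integer(out$family_id)
  out
}

#' Load all packaged fixture tables
#'
#' @return List with `loci`, `profiles` (deduplicated long tibble),
#'   `pedigree` and `expected_discrepancies`.
#' @export
load_fixture_tables <- function() {
  list(
    loci = koala_loci(),
    profiles = koala_family_profiles(),
    pedigree = koala_pedigree(),
    expected_discrepancies = koala_expected_discrepancies()
  )
}
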