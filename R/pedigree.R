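# Mendelian congruence checking of genotype profiles within family units.
#
# A joey must inherit an allele from each parent, and every joey allele
# must be present in at least one parent. With both parents genotyped
# (trio) the full rule applies; with a single genotyped parent (pair)
# only allele sharing with that parent can be required, since alleles the
# parent lacks may come from the unknown parent.

#' Check one family at one locus
#'
#' Trio rule: congruent iff the joey's alleles are a subset of the
#' parents' union and the joey shares at least one allele with each
#' parent. Discrepancy classification (one class per family-locus, in
#' precedence order): shares with neither parent -> `NEITHER_PARENT`;
#' shares with only one -> `MISSING_PARENTAL`; subset violation only ->
#' `EXTRA_ALLELE`. Pair rule: congruent iff the joey shares an allele
#' with the genotyped parent (incongruent pairs are `MISSING_PARENTAL`).
#'
#' @param joey Character vector of the joey's alleles at the locus.
#' @param dam,sire Parent allele vectors; `NULL` for an ungenotyped
#'   parent (at most one may be `NULL`).
#' @return A list with `status` (`"CONGRUENT"`/`"INCONGRUENT"`) and
#'   `discrepancy` (`"NONE"`, `"MISSING_PARENTAL"`, `"EXTRA_ALLELE"`,
#'   `"NEITHER_PARENT"`).
#' @export
check_family_locus <- function(joey, dam = NULL, sire = NULL) {
  if (length(joey) == 0L) stop("joey allele set is empty")
  if (is.null(dam) && is.null(sire)) stop("at least one parent required")
  if (!is.null(dam) && !is.null(sire)) {
    share_dam <- length(intersect(joey, dam)) > 0L
    share_sire <- length(intersect(joey, sire)) > 0L
    subset_ok <- all(joey %in% union(dam, sire))
    if (share_dam && share_sire && subset_ok) {
      return(list(status = "CONGRUENT", discrepancy = "NONE"))
    }
    disc <- if (!share_dam && !share_sire) {
      "NEITHER_PARENT"
    } else if (!share_dam || !share_sire) {
      "MISSING_PARENTAL"
    } else {
      "EXTRA_ALLELE"
    }
    return(list(status = "INCONGRUENT", discrepancy = disc))
  }
  parent <- if (is.null(dam)) sire else dam
  if (length(intersect(joey, parent)) > 0L) {
    list(status = "CONGRUENT", discrepancy = "NONE")
  } else {
    list(status = "INCONGRUENT", discrepancy = "MISSING_PARENTAL")
  }
}

#' Check a pedigree against genotype profiles
#'
#' Applies [check_family_locus()] to every family x locus combination.
#' Comparisons where any family member is `NO_DATA` at the locus are
#' `SKIPPED` and excluded from the congruence denominators.
#'
#' @param profiles Long profile tibble (`individual, locus, alleles,
#'   status`), e.g. from [genotype_cohort()] or [read_profiles()].
#' @param pedigree Tibble `family_id, joey, dam, sire`; empty or `NA`
#'   cells mark an ungenotyped parent.
#' @return An object of class `mhc_congruence`: list with `results`
#'   (per family x locus), `by_locus` (congruent/total and percentage,
#'   rounded to nearest integer), and `overall` counts.
#' @export
check_pedigree <- function(profiles, pedigree) {
  loci <- unique(profiles$locus)
  sets <- stats::setNames(
    split_alleles(profiles$alleles),
    paste(profiles$individual, profiles$locus, sep = "\r")
  )
  status_of <- stats::setNames(
    profiles$status, paste(profiles$individual, profiles$locus, sep = "\r"))
  get_set <- function(ind, loc) {
    if (is.na(ind) || !nzchar(ind)) return(NULL)
    key <- paste(ind, loc, sep = "\r")
    if (!key %in% names(sets)) stop("missing profile for ", ind)
    if (status_of[[key]] == "NO_DATA") return(NA)
    sets[[key]]
  }
  rows <- vector("list", nrow(pedigree) * length(loci))
  k <- 0L
  for (i in seq_len(nrow(pedigree))) {
    fam <- pedigree[i, ]
    for (loc in loci) {
      k <- k + 1L
      joey <- get_set(fam$joey, loc)
      dam <- get_set(fam$dam, loc)
      sire <- get_set(fam$sire, loc)
      members <- list(joey, dam, sire)
      if (any(vapply(members, function(x)
        length(x) == 1L && !is.null(x) && all(is.na(x)), logical(1)))) {
        res <- list(status = "SKIPPED", discrepancy = "NONE")
      } else {
        res <- check_family_locus(joey, dam, sire)
      }
      rows[[k]] <- tibble::tibble(
        family_id = fam$family_id, locus = loc,
        kind = if (is.null(dam) || is.null(sire)) "PAIR" else "TRIO",
        status = res$status, discrepancy = res$discrepancy
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  done <- results[results$status != "SKIPPED", ]
  by_locus <- dplyr::summarise(
    dplyr::group_by(done, .data$locus),
    congruent = sum(.data$status == "CONGRUENT"),
    total = dplyr::n(),
    pct = round_pct(100 * .data$congruent / .data$total),
    .groups = "drop"
  )
  overall <- tibble::tibble(
    congruent = sum(done$status == "CONGRUENT"),
    total = nrow(done),
    pct = round_pct(100 * sum(done$status == "CONGRUENT") / nrow(done))
  )
  structure(list(results = results, by_locus = by_locus,
                 overall = overall),
            class = "mhc_congruence")
}

#' @export
print.mhc_congruence <- function(x, ...) {
  cat("<mhc_congruence> ", x$overall$congruent, "/", x$overall$total,
      " comparisons congruent (", x$overall$pct, "%)\n", sep = "")
  print(x$by_locus, ...)
  inc <- x$results[x$results$status == "INCONGRUENT", ]
  if (nrow(inc) > 0L) {
    cat("incongruent family x locus cases:\n")
    print(inc[c("family_id", "locus", "kind", "discrepancy")], ...)
  }
  invisible(x)
}

#' Congruence summary report
#'
#' Tabulates a fitted [check_pedigree()] object: per-locus congruence,
#' discrepancy tallies by class and locus, and the itemised incongruent
#' cases.
#'
#' @param x An `mhc_congruence`.
#' @return A list with `by_locus`, `overall`, `by_class`
#'   (discrepancy class x locus counts) and `incongruent`.
#' @export
congruence_summary <- function(x) {
  stopifnot(inherits(x, "mhc_congruence"))
  inc <- x$results[x$results$status == "INCONGRUENT", ]
  by_class <- dplyr::count(inc, .data$discrepancy, .data$locus,
                           name = "cases")
  list(by_locus = x$by_locus, overall = x$overall, by_class = by_class,
       incongruent = inc[c("family_id", "locus", "kind", "discrepancy")])
}

#' Read a pedigree table
#'
#' @param path TSV with columns `family_id, joey, dam, sire` (empty cells
#'   for unknown parents).
#' @return A tibble with `NA` for unknown parents and a `kind` column
#'   (`TRIO`/`PAIR`).
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  ped <- tibble::tibble(
    family_id = as.integer(raw$family_id),
    joey = raw$joey,
    dam = ifelse(nzchar(raw$dam), raw$dam, NA_character_),
    sire = ifelse(nzchar(raw$sire), raw$sire, NA_character_)
  )
  if (any(!nzchar(ped$joey))) stop("pedigree rows must name a joey")
  if (any(is.na(ped$dam) & is.na(ped$sire))) {
    stop("pedigree rows must name at least one parent")
  }
  ped$kind <- ifelse(!is.na(ped$dam) & !is.na(ped$sire), "TRIO", "PAIR")
  ped
}
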