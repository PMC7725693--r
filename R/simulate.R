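# Ground-truth simulator: allele pools, diploid multi-gene genotypes over
# a founder pedigree, and 2x250 bp overlapping paired amplicon reads with
# per-base substitution errors. The defaults emulate the captive study
# design: 36 family units (18 trios + 18 single-parent pairs) on top of a
# founder population, six gene targets with amplicons of 200-397 bp, and
# per-locus allele pool sizes matching the observed diversity (7 UA
# incl. the co-amplified UB paralog, 5 UC, 10 DAB, 8 DBB, 3 DCB, 4 DMB).

.fwd_adaptor <- "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG"
.rev_adaptor <- "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG"

#' Simulation configuration
#'
#' @param loci Locus tibble (defaults to the packaged koala targets).
#' @param alleles_per_locus Pool size per locus; a single integer or a
#'   named vector over loci. Defaults to the per-locus allele counts
#'   observed in the captive population.
#' @param n_founders,n_trios,n_pairs Founder count and number of trio /
#'   single-parent family units (each unit contributes one joey; parents
#'   are drawn from the founders).
#' @param depth Reads simulated per individual per gene target.
#' @param read_length Read length in bp (2 x 250 paired-end design).
#' @param error_rate Per-base substitution error rate (must be < 0.1).
#' @param allele_freqs Optional named list of per-locus allele frequency
#'   vectors (uniform when `NULL`).
#' @param seed Integer seed; all downstream simulation stages derive
#'   their randomness from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(loci = koala_loci(),
                       alleles_per_locus = c(UA = 7L, UC = 5L, DAB = 10L,
                                             DBB = 8L, DCB = 3L, DMB = 4L),
                       n_founders = 46L, n_trios = 18L, n_pairs = 18L,
                       depth = 500L, read_length = 250L,
                       error_rate = 0.002, allele_freqs = NULL,
                       seed = 1L) {
  if (length(alleles_per_locus) == 1L) {
    alleles_per_locus <- stats::setNames(
      rep(as.integer(alleles_per_locus), nrow(loci)), loci$locus)
  }
  stopifnot(all(loci$locus %in% names(alleles_per_locus)),
            depth >= 1L, error_rate >= 0, error_rate < 0.1,
            n_founders >= 2L)
  if (!is.null(allele_freqs)) {
    for (loc in names(allele_freqs)) {
      f <- allele_freqs[[loc]]
      if (abs(sum(f) - 1) > 1e-8) {
        stop("allele frequencies for ", loc, " must sum to 1")
      }
    }
  }
  if (any(loci$interior_bp < 150L)) {
    stop("amplicon interior shorter than 150 bp; reads would be culled")
  }
  if (any(read_length < nchar(loci$fwd_primer) + 10L)) {
    stop("read_length too short to cover primer plus overlap")
  }
  structure(
    list(loci = loci,
         alleles_per_locus = alleles_per_locus[loci$locus],
         n_founders = as.integer(n_founders),
         n_trios = as.integer(n_trios), n_pairs = as.integer(n_pairs),
         depth = as.integer(depth),
         read_length = as.integer(read_length),
         error_rate = error_rate, allele_freqs = allele_freqs,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate per-locus allele pools
#'
#' Random interior sequences of the exact per-locus interior length,
#' kept pairwise at Hamming distance of at least 5 within a locus by
#' rejection sampling. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return Tibble `locus, label, sequence`.
#' @export
simulate_alleles <- function(config) {
  set.seed(config$seed)
  out <- vector("list", nrow(config$loci))
  for (i in seq_len(nrow(config$loci))) {
    loc <- config$loci$locus[i]
    len <- config$loci$interior_bp[i]
    n <- config$alleles_per_locus[[loc]]
    pool <- character(0)
    tries <- 0L
    while (length(pool) < n) {
      cand <- random_dna(1L, len)
      if (all(vapply(pool, hamming, integer(1), a = cand) >= 5L)) {
        pool <- c(pool, cand)
      }
      tries <- tries + 1L
      if (tries > 100L * n) {
        stop("cannot satisfy Hamming distance constraint at ", loc)
      }
    }
    out[[i]] <- tibble::tibble(locus = loc,
                               label = sprintf("%02d", seq_len(n)),
                               sequence = pool)
  }
  dplyr::bind_rows(out)
}

# Draw one chromosome-pair allele assignment for a founder.
#' @noRd
.draw_founder <- function(config, locus, n_genes) {
  labels <- sprintf("%02d", seq_len(config$alleles_per_locus[[locus]]))
  freqs <- config$allele_freqs[[locus]]
  if (is.null(freqs)) freqs <- rep(1 / length(labels), length(labels))
  sample(labels, 2L * n_genes, replace = TRUE, prob = freqs)
}

#' Simulate a pedigree with ground-truth genotypes
#'
#' Founders draw alleles per chromosome per gene copy from the configured
#' frequencies; each joey inherits, independently per gene copy, one
#' uniformly chosen chromosome from each parent. The co-amplified UA
#' paralog is simulated as a second single-copy gene whose reads share the
#' UA locus label. Single-parent units hide one parent in the pedigree
#' output but both exist in the truth.
#'
#' @param config A [sim_config()].
#' @return An object of class `mhc_truth`: list with `alleles` (pools),
#'   `genotypes` (`individual, locus, gene, chrom, allele`), `pedigree`
#'   (visible table, hidden parents `NA`), `parents` (true parentage),
#'   `expected` (per individual x locus distinct-label call sets) and
#'   `config`.
#' @export
simulate_pedigree <- function(config) {
  pools <- simulate_alleles(config)
  set.seed(config$seed + 1L)
  loci <- config$loci
  n_genes <- loci$genome_copies + !is.na(loci$coamplified_paralog)
  founders <- sprintf("F%03d", seq_len(config$n_founders))
  geno <- list()
  for (ind in founders) {
    for (i in seq_len(nrow(loci))) {
      a <- .draw_founder(config, loci$locus[i], n_genes[i])
      geno[[length(geno) + 1L]] <- tibble::tibble(
        individual = ind, locus = loci$locus[i],
        gene = rep(seq_len(n_genes[i]), each = 2L),
        chrom = rep(1:2, n_genes[i]), allele = a
      )
    }
  }
  genotypes <- dplyr::bind_rows(geno)
  n_fam <- config$n_trios + config$n_pairs
  ped <- vector("list", n_fam)
  parents <- vector("list", n_fam)
  for (f in seq_len(n_fam)) {
    pair <- sample(founders, 2L)
    dam <- pair[1L]
    sire <- pair[2L]
    joey <- sprintf("J%03d", f)
    jg <- list()
    for (i in seq_len(nrow(loci))) {
      for (g in seq_len(n_genes[i])) {
        dal <- genotypes$allele[genotypes$individual == dam &
                                  genotypes$locus == loci$locus[i] &
                                  genotypes$gene == g]
        sal <- genotypes$allele[genotypes$individual == sire &
                                  genotypes$locus == loci$locus[i] &
                                  genotypes$gene == g]
        jg[[length(jg) + 1L]] <- tibble::tibble(
          individual = joey, locus = loci$locus[i], gene = g,
          chrom = 1:2,
          allele = c(sample(dal, 1L), sample(sal, 1L))
        )
      }
    }
    genotypes <- dplyr::bind_rows(genotypes, dplyr::bind_rows(jg))
    is_trio <- f <= config$n_trios
    hide <- if (is_trio) "none" else if (f %% 2L == 0L) "sire" else "dam"
    ped[[f]] <- tibble::tibble(
      family_id = f, joey = joey,
      dam = if (hide == "dam") NA_character_ else dam,
      sire = if (hide == "sire") NA_character_ else sire,
      kind = if (is_trio) "TRIO" else "PAIR"
    )
    parents[[f]] <- tibble::tibble(family_id = f, joey = joey,
                                   dam = dam, sire = sire)
  }
  expected <- dplyr::summarise(
    dplyr::group_by(genotypes, .data$individual, .data$locus),
    alleles = join_alleles(.data$allele), .groups = "drop"
  )
  structure(
    list(alleles = pools, genotypes = genotypes,
         pedigree = dplyr::bind_rows(ped),
         parents = dplyr::bind_rows(parents),
         expected = expected, config = config),
    class = "mhc_truth"
  )
}

# Substitute random wrong bases at a per-base rate.
#' @noRd
inject_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  L <- nchar(reads)
  nerr <- stats::rbinom(length(reads), L, rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(L[i], nerr[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                               old), 1L)
    }
  }
  reads
}

#' Simulate paired amplicon reads from a truth set
#'
#' Per individual and gene target, `depth` reads are allocated uniformly
#' over the individual's chromosome copies; each pair consists of the
#' amplicon 5' forward read (primer included) and the 3' reverse-
#' complement read, with sequencing adaptors appearing as 3' read-through
#' on amplicons shorter than the read length. Qualities are fixed at Q35;
#' substitution errors are injected per base at the configured rate.
#' Byte-identical output for identical config and seed.
#'
#' @param truth An [simulate_pedigree()] truth set.
#' @param individuals Subset of individuals (default: all).
#' @return Tibble of read pairs (`individual, read_id, fwd_seq, rev_seq,
#'   fwd_qual, rev_qual, true_locus, true_allele`), all loci interleaved
#'   per individual.
#' @export
simulate_reads <- function(truth, individuals = NULL) {
  config <- truth$config
  set.seed(config$seed + 2L)
  loci <- config$loci
  rl <- config$read_length
  qual <- strrep(rawToChar(as.raw(35L + 33L)), rl)
  pools <- truth$alleles
  if (is.null(individuals)) {
    individuals <- unique(truth$genotypes$individual)
  }
  out <- vector("list", 0)
  for (ind in individuals) {
    for (i in seq_len(nrow(loci))) {
      loc <- loci$locus[i]
      slots <- truth$genotypes$allele[
        truth$genotypes$individual == ind & truth$genotypes$locus == loc]
      draw <- slots[sample.int(length(slots), config$depth,
                               replace = TRUE)]
      interior <- pools$sequence[match(paste(loc, draw),
                                       paste(pools$locus, pools$label))]
      amp <- paste0(loci$fwd_primer[i], interior,
                    revcomp(loci$rev_primer[i]))
      pad <- strrep("G", rl)
      fwd <- substr(paste0(amp, revcomp(.rev_adaptor), pad), 1L, rl)
      rev <- substr(paste0(revcomp(amp), revcomp(.fwd_adaptor), pad),
                    1L, rl)
      out[[length(out) + 1L]] <- tibble::tibble(
        individual = ind,
        read_id = sprintf("%s:%s:%04d", ind, loc,
                          seq_len(config$depth)),
        fwd_seq = inject_errors(fwd, config$error_rate),
        rev_seq = inject_errors(rev, config$error_rate),
        fwd_qual = qual, rev_qual = qual,
        true_locus = loc, true_allele = draw
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Reference database from a truth set
#'
#' @param truth An `mhc_truth`.
#' @param withhold Character vector of `LOCUS*label` allele names to
#'   leave out (for novel-allele discovery experiments).
#' @return An [mhc_reference()].
#' @export
truth_reference <- function(truth, withhold = character()) {
  alleles <- truth$alleles
  keep <- !paste0(alleles$locus, "*", alleles$label) %in% withhold
  mhc_reference(truth$config$loci, alleles[keep, , drop = FALSE])
}

#' Write simulated reads as per-individual FASTQ pairs
#'
#' @param reads Output of [simulate_reads()].
#' @param dir Output directory; files are `<individual>_R1.fastq.gz` /
#'   `_R2.fastq.gz` (uncompressed when `gzip = FALSE`).
#' @param gzip Compress output.
#' @return Tibble of the individuals and file paths, invisibly.
#' @export
write_sim_fastq <- function(reads, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  inds <- unique(reads$individual)
  paths <- vector("list", length(inds))
  for (k in seq_along(inds)) {
    r <- reads[reads$individual == inds[k], ]
    p1 <- file.path(dir, paste0(inds[k], "_R1", ext))
    p2 <- file.path(dir, paste0(inds[k], "_R2", ext))
    for (side in 1:2) {
      x <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(
          if (side == 1L) r$fwd_seq else r$rev_seq),
        Biostrings::PhredQuality(
          if (side == 1L) r$fwd_qual else r$rev_qual)
      )
      names(x) <- r$read_id
      suppressWarnings(Biostrings::writeQualityScaledXStringSet(
        x, if (side == 1L) p1 else p2, compress = gzip))
    }
    paths[[k]] <- tibble::tibble(individual = inds[k], fwd = p1, rev = p2)
  }
  invisible(dplyr::bind_rows(paths))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: truth set, reads and (optionally withheld)
#' reference in one call.
#'
#' @inheritParams simulate_reads
#' @param config A [sim_config()].
#' @param withhold Allele names (`LOCUS*label`) to omit from the
#'   reference.
#' @param dir Optional directory to also write FASTQ files to.
#' @return List with `truth`, `reads`, `reference`.
#' @export
simulate_dataset <- function(config, withhold = character(), dir = NULL) {
  truth <- simulate_pedigree(config)
  reads <- simulate_reads(truth)
  if (!is.null(dir)) write_sim_fastq(reads, dir)
  list(truth = truth, reads = reads,
       reference = truth_reference(truth, withhold))
}
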