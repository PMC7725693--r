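# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a congruence report
#'
#' @param x An `mhc_congruence` from [check_pedigree()].
#' @param ... Unused.
#' @return One row per family x locus comparison.
#' @export
tidy.mhc_congruence <- function(x, ...) {
  tibble::as_tibble(x$results)
}

#' @rdname tidy.mhc_congruence
#' @return `glance()`: a one-row summary (comparisons, congruent count,
#'   percentage, discrepancy class totals).
#' @export
glance.mhc_congruence <- function(x, ...) {
  inc <- x$results[x$results$status == "INCONGRUENT", ]
  tibble::tibble(
    comparisons = x$overall$total,
    congruent = x$overall$congruent,
    pct_congruent = x$overall$pct,
    missing_parental = sum(inc$discrepancy == "MISSING_PARENTAL"),
    extra_allele = sum(inc$discrepancy == "EXTRA_ALLELE"),
    neither_parent = sum(inc$discrepancy == "NEITHER_PARENT")
  )
}

#' Tidy an allele association result
#'
#' @param x An `mhc_association` from [allele_association()].
#' @param ... Unused.
#' @return One row per outcome group with carrier counts and prevalence.
#' @export
tidy.mhc_association <- function(x, ...) {
  dplyr::mutate(x$prevalence, locus = x$locus, allele = x$allele)
}

#' @rdname tidy.mhc_association
#' @export
glance.mhc_association <- function(x, ...) {
  tibble::tibble(locus = x$locus, allele = x$allele,
                 p_value = x$p_value)
}

#' Tidy genotype calls
#'
#' @param x An `mhc_genotypes` from [genotype_cohort()].
#' @param ... Unused.
#' @return The long profile tibble.
#' @export
tidy.mhc_genotypes <- function(x, ...) {
  tibble::as_tibble(x$profiles)
}

#' Plot per-locus congruence
#'
#' @param object An `mhc_congruence`.
#' @param ... Unused.
#' @return A ggplot barchart of percent congruent per locus.
#' @export
autoplot.mhc_congruence <- function(object, ...) {
  d <- object$by_locus
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locus, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$overall$pct,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "% congruent family units",
                  title = sprintf("Overall congruence %d%% (%d/%d)",
                                  object$overall$pct,
                                  object$overall$congruent,
                                  object$overall$total)) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot a clustering dendrogram
#'
#' @param object An `mhc_hclust` from [complete_linkage()].
#' @param ... Unused.
#' @return A ggplot dendrogram (segments drawn from the merge table).
#' @export
autoplot.mhc_hclust <- function(object, ...) {
  n <- length(object$order)
  x_leaf <- numeric(n)
  x_leaf[object$order] <- seq_len(n)
  xs <- numeric(n - 1L)
  segs <- vector("list", n - 1L)
  pos <- function(k) {
    if (k < 0L) c(x_leaf[-k], 0) else c(xs[k], object$height[k])
  }
  for (k in seq_len(n - 1L)) {
    a <- pos(object$merge[k, 1L])
    b <- pos(object$merge[k, 2L])
    h <- object$height[k]
    xs[k] <- (a[1L] + b[1L]) / 2
    segs[[k]] <- tibble::tibble(
      x = c(a[1L], a[1L], b[1L]), xend = c(a[1L], b[1L], b[1L]),
      y = c(a[2L], h, h), yend = c(h, h, b[2L])
    )
  }
  leaves <- tibble::tibble(
    x = seq_len(n),
    label = if (is.null(object$labels)) as.character(object$order)
            else object$labels[object$order]
  )
  ggplot2::ggplot(dplyr::bind_rows(segs)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leaves$x,
                                labels = leaves$label) +
    ggplot2::labs(x = NULL, y = "Gower dissimilarity (complete linkage)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}
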