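# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a criteria report
#'
#' One row per acceptance check with its measured value, threshold and
#' verdict.
#'
#' @param x A `criteria_report`.
#' @param ... Unused.
#' @export
tidy.criteria_report <- function(x, ...) {
  out <- x$checks
  out$primer <- x$primer
  out$orientation <- x$orientation
  dplyr::relocate(out, "primer", "orientation")
}

#' @rdname tidy.criteria_report
#' @export
glance.criteria_report <- function(x, ...) {
  tibble::tibble(
    primer = x$primer,
    orientation = x$orientation,
    n_target = x$n_target,
    n_nontarget = x$n_nontarget,
    n_pass = sum(x$checks$verdict == "PASS"),
    n_warn = sum(x$checks$verdict == "WARN"),
    n_fail = sum(x$checks$verdict == "FAIL"),
    passes = all(x$checks$verdict != "FAIL")
  )
}

#' Tidy a primer design result
#'
#' Drops the list-columns, leaving one plain row per candidate primer.
#'
#' @param x A `primer_design` tibble from [design_primers()].
#' @param ... Unused.
#' @export
tidy.primer_design <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$excluded_rare_phyla <- vapply(out$excluded_rare_phyla, paste,
                                    character(1), collapse = ",")
  dplyr::select(out, -"report")
}

#' @rdname tidy.primer_design
#' @export
glance.primer_design <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_pass = sum(x$tier == "pass"),
    n_near_miss = sum(x$tier == "near_miss"),
    n_windows = nrow(attr(x, "windows"))
  )
}

#' Tidy a novelty summary
#'
#' @param x A `novelty_summary`.
#' @param ... Unused.
#' @return The per-query calls tibble.
#' @export
tidy.novelty_summary <- function(x, ...) x$calls

#' @rdname tidy.novelty_summary
#' @export
glance.novelty_summary <- function(x, ...) {
  tibble::tibble(
    n_classified = nrow(x$calls),
    n_skipped = length(x$skipped),
    n_novel = sum(x$calls$novelty_rank != "none"),
    median_identity = stats::median(x$calls$identity)
  )
}

#' Identity-distribution plot for a novelty summary
#'
#' Histogram of best-hit identities with dashed lines at the ladder
#' thresholds delineating the novelty ranks.
#'
#' @param object A `novelty_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.novelty_summary <- function(object, ...) {
  ladder <- tibble::tibble(rank = names(object$ladder),
                           threshold = as.numeric(object$ladder))
  ggplot2::ggplot(object$calls, ggplot2::aes(x = .data$identity)) +
    ggplot2::geom_histogram(binwidth = 0.005, boundary = 0,
                            fill = "grey35") +
    ggplot2::geom_vline(data = ladder,
                        ggplot2::aes(xintercept = .data$threshold),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = "best-hit identity",
                  y = "OTUs",
                  title = "Best-hit identity distribution",
                  subtitle = "dashed lines: novelty thresholds") +
    ggplot2::theme_minimal()
}

#' Coverage plot for a coverage table
#'
#' @param object A `coverage_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_table <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[object$taxon != "TOTAL", ],
    dplyr::all_of(c("coverage_0mm", "coverage_1mm")),
    names_to = "allowance", values_to = "coverage"
  )
  df$allowance <- ifelse(df$allowance == "coverage_0mm",
                         "0 mismatches", "≤ 1 mismatch")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon, y = .data$coverage,
                                   fill = .data$allowance)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction amplified",
                  title = "In-silico coverage by taxon") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Candidate-primer map along the alignment
#'
#' @param object A `primer_design`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.primer_design <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start_column,
                                   xend = .data$end_column,
                                   y = .data$coverage_total,
                                   yend = .data$coverage_total,
                                   colour = .data$tier)) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::facet_wrap(~orientation, ncol = 1) +
    ggplot2::labs(x = "alignment column", y = "target coverage (< 2 mismatches)",
                  title = "Candidate primers") +
    ggplot2::theme_minimal()
}
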