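# Cohort-level arithmetic on detection reports: expression normalization,
# generic/discriminative neoepitope categorization, and RPKM.

#' Cohort categorization configuration
#'
#' @param generic_prevalence_min Targets present in strictly more than this
#'   fraction of each group are candidates for the generic label (0.20).
#' @param generic_expression_min Mean normalized expression both groups must
#'   strictly exceed for the generic label (0.1).
#' @param discriminative_fold Fold change in mean normalized expression
#'   required between groups (2).
#' @param discriminative_min_individuals Minimum individuals of the enriched
#'   group the target must be detected in (3).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(generic_prevalence_min = 0.20,
                          generic_expression_min = 0.1,
                          discriminative_fold = 2.0,
                          discriminative_min_individuals = 3L) {
  cfg <- list(generic_prevalence_min = generic_prevalence_min,
              generic_expression_min = generic_expression_min,
              discriminative_fold = discriminative_fold,
              discriminative_min_individuals = discriminative_min_individuals)
  if (any(unlist(cfg) <= 0)) {
    abort("cohort thresholds must be positive", class = "neonull_config_error")
  }
  structure(cfg, class = "cohort_config")
}

#' Library-size normalized expression
#'
#' `log10(1 + 1e6 * mapped_reads / total_reads)` — reads scaled to counts
#' per million then log10 with a pseudocount of one, so zero coverage maps
#' to zero and the generic-expression threshold of 0.1 is meaningful.
#'
#' @param mapped_reads Reads mapped to the target in a sample.
#' @param total_reads Total reads in that sample's library.
#' @return Numeric vector.
#' @export
normalized_expression <- function(mapped_reads, total_reads) {
  stopifnot(all(total_reads > 0))
  log10(1 + 1e6 * mapped_reads / total_reads)
}

#' Reads per kilobase per million mapped reads
#'
#' `(mapped_reads / (total_reads / 1e6)) / effective_length`.
#'
#' @param mapped_reads Reads mapped to the element.
#' @param total_reads Total reads in the sample.
#' @param effective_length Effective element length in nucleotides.
#' @return Numeric vector.
#' @export
rpkm <- function(mapped_reads, total_reads, effective_length) {
  stopifnot(all(total_reads > 0), all(effective_length > 0))
  (mapped_reads / (total_reads / 1e6)) / effective_length
}

# Per-target cohort statistics from a long detection table + sample sheet.
cohort_stats <- function(detections, samples) {
  need <- c("sample_id", "group", "total_reads")
  if (!all(need %in% names(samples))) {
    abort(sprintf("sample sheet lacks column(s): %s",
                  paste(setdiff(need, names(samples)), collapse = ", ")),
          class = "neonull_format_error")
  }
  if (!all(samples$group %in% c("case", "control"))) {
    abort("sample sheet `group` must be 'case' or 'control'",
          class = "neonull_format_error")
  }
  grid <- tidyr::crossing(target_id = unique(detections$target_id),
                          sample_id = samples$sample_id)
  long <- grid %>%
    left_join(detections %>% select("sample_id", "target_id", "mapped_reads"),
              by = c("sample_id", "target_id")) %>%
    mutate(mapped_reads = dplyr::coalesce(.data$mapped_reads, 0L)) %>%
    left_join(samples, by = "sample_id") %>%
    mutate(expr = normalized_expression(.data$mapped_reads, .data$total_reads),
           present = .data$mapped_reads >= 1L)
  long %>%
    group_by(.data$target_id, .data$group) %>%
    summarise(n = dplyr::n(), n_present = sum(.data$present),
              prevalence = mean(.data$present),
              mean_expr = mean(.data$expr), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("n", "n_present", "prevalence",
                                       "mean_expr"),
                       values_fill = list(n = 0L, n_present = 0L,
                                          prevalence = 0, mean_expr = 0))
}

#' Generic-target rule
#'
#' A target is generic (ubiquitous background, removed from analyses) when
#' its prevalence exceeds 20% in cases AND in controls, and its mean
#' normalized expression exceeds 0.1 in both groups.
#'
#' @param stats Per-target stats tibble with `prevalence_case`,
#'   `prevalence_control`, `mean_expr_case`, `mean_expr_control`.
#' @param cfg A [cohort_config()].
#' @return Logical vector.
#' @export
flag_generic <- function(stats, cfg = cohort_config()) {
  stats$prevalence_case > cfg$generic_prevalence_min &
    stats$prevalence_control > cfg$generic_prevalence_min &
    stats$mean_expr_case > cfg$generic_expression_min &
    stats$mean_expr_control > cfg$generic_expression_min
}

#' Discriminative-target rule
#'
#' A (non-generic) target is case-enriched when its mean normalized
#' expression in cases is at least twice that in controls and it is
#' detected in at least 3 case individuals; control-enriched vice versa.
#'
#' @param stats Per-target stats tibble (see [flag_generic()]) with
#'   `n_present_case` / `n_present_control`.
#' @param cfg A [cohort_config()].
#' @return Character vector: `"case-enriched"`, `"control-enriched"` or
#'   `"none"`.
#' @export
flag_discriminative <- function(stats, cfg = cohort_config()) {
  fold <- cfg$discriminative_fold
  nmin <- cfg$discriminative_min_individuals
  case_up <- stats$mean_expr_case >= fold * stats$mean_expr_control &
    stats$n_present_case >= nmin
  ctrl_up <- stats$mean_expr_control >= fold * stats$mean_expr_case &
    stats$n_present_control >= nmin
  dplyr::case_when(case_up ~ "case-enriched",
                   ctrl_up ~ "control-enriched",
                   TRUE ~ "none")
}

#' Summarise a cohort of detection reports
#'
#' Builds the per-target cohort table: prevalence, mean normalized
#' expression and detection counts per group, the generic flag, and the
#' discriminative category (computed only for non-generic targets).
#'
#' @param detections Long tibble of per-sample detections: `sample_id`,
#'   `target_id`, `mapped_reads` (e.g. stacked pass-filtered coverage rows).
#' @param samples Sample sheet: `sample_id`, `group` (`case`/`control`),
#'   `total_reads`.
#' @param cfg A [cohort_config()].
#' @return A tibble of class `neonull_cohort`, one row per target.
#' @export
cohort_summary <- function(detections, samples, cfg = cohort_config()) {
  stats <- cohort_stats(as_tibble(detections), as_tibble(samples))
  stats <- stats %>%
    mutate(generic = flag_generic(stats, cfg),
           discriminative = dplyr::if_else(
             .data$generic, "none", flag_discriminative(stats, cfg))) %>%
    arrange(.data$target_id)
  class(stats) <- c("neonull_cohort", class(stats))
  stats
}

#' Plot cohort mean expression by group
#'
#' Scatter of per-target mean normalized expression in cases versus
#' controls, coloured by category; the identity and fold-change lines are
#' drawn for orientation.
#'
#' @param object A [cohort_summary()] result.
#' @param cfg A [cohort_config()] (for the fold lines).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neonull_cohort <- function(object, cfg = cohort_config(), ...) {
  cat_col <- dplyr::case_when(object$generic ~ "generic",
                              TRUE ~ object$discriminative)
  df <- mutate(as_tibble(object), category = cat_col)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_expr_control,
                                   y = .data$mean_expr_case,
                                   colour = .data$category)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = cfg$discriminative_fold, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_abline(slope = 1 / cfg$discriminative_fold, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean normalized expression (controls)",
                  y = "mean normalized expression (cases)") +
    ggplot2::theme_minimal()
}
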