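#' Plot the prioritization funnel
#'
#' Cohort-wide survivor counts after each cascade criterion, the standard
#' way to audit how many exome variants each filter removes.
#'
#' @param object an `fsgs_cascade`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fsgs_cascade
#' @export
autoplot.fsgs_cascade <- function(object, ...) {
  totals <- object$trace %>%
    group_by(.data$criterion) %>%
    summarise(n_in = sum(.data$n_in), n_out = sum(.data$n_out),
              .groups = "drop") %>%
    mutate(criterion = factor(.data$criterion,
                              levels = c("I", "II", "III", "IV", "V")))
  start <- tibble(criterion = "input", n_out = sum(totals$n_in[totals$criterion == "I"]))
  df <- bind_rows(start, totals %>% select("criterion", "n_out")) %>%
    mutate(criterion = factor(.data$criterion,
                              levels = c("input", "I", "II", "III", "IV", "V")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$criterion, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4, size = 3) +
    ggplot2::labs(x = "after criterion", y = "surviving variants",
                  title = "Variant prioritization funnel") +
    ggplot2::theme_minimal()
}

#' Plot subgroup diagnostic yields
#'
#' @param object an `fsgs_report`.
#' @param ... unused.
#' @return a ggplot of detection rate by subgroup, annotated with
#'   numerator/denominator.
#' @method autoplot fsgs_report
#' @export
autoplot.fsgs_report <- function(object, ...) {
  df <- object$rates %>%
    filter(!is.na(.data$rate)) %>%
    mutate(subgroup = factor(.data$subgroup, levels = rev(.data$subgroup)),
           lab = paste0(.data$n_solved, "/", .data$n_total))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate_pct, y = .data$subgroup)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::geom_text(ggplot2::aes(label = .data$lab), hjust = -0.15, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.15))) +
    ggplot2::labs(x = "detection rate (%)", y = NULL,
                  title = "Diagnostic yield by subgroup") +
    ggplot2::theme_minimal()
}
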