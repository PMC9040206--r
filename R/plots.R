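#' Scatter of Gail against PRS 5-year absolute risk
#'
#' @param prs_risk,gail_risk aligned risks in \[0, 1\].
#' @param threshold threshold drawn as reference lines (default 0.013).
#' @return A ggplot object.
#' @export
plot_risk_comparison <- function(prs_risk, gail_risk, threshold = 0.013) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_risk_comparison requires ggplot2")
  df <- data.frame(prs = 100 * prs_risk, gail = 100 * gail_risk)
  ggplot2::ggplot(df, ggplot2::aes(x = prs, y = gail)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_vline(xintercept = 100 * threshold, linetype = 2) +
    ggplot2::geom_hline(yintercept = 100 * threshold, linetype = 2) +
    ggplot2::labs(x = "5-year absolute risk by PRS (%)",
                  y = "5-year absolute risk by Gail model (%)")
}

#' Incremental high-risk proportions by age group
#'
#' Step-area view of [incremental_by_age()]: one line per criterion prefix.
#'
#' @param age_table result of [incremental_by_age()].
#' @return A ggplot object.
#' @export
plot_incremental_age <- function(age_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_incremental_age requires ggplot2")
  cols <- grep("^upto_", names(age_table), value = TRUE)
  long <- do.call(rbind, lapply(cols, function(cl)
    data.frame(age_group = age_table$age_group,
               prefix = sub("^upto_", "+", cl),
               proportion = age_table[[cl]])))
  long$prefix <- factor(long$prefix, levels = sub("^upto_", "+", cols))
  ggplot2::ggplot(long, ggplot2::aes(x = age_group, y = proportion,
                                     group = prefix, colour = prefix)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "age group", y = "proportion identified high risk",
                  colour = "criteria added")
}
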