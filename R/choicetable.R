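#' Daily choice proportions from labelled flights
#'
#' Pools flights within each day and computes the per-day proportion of
#' upwind flights (upwind count over total, both channels pooled: flow is
#' upwind in each channel for one direction of travel) and of
#' right-channel flights. Days with no flights are dropped with a
#' warning.
#'
#' @param flights data.frame with one row per flight and columns
#'   \code{day}, \code{heading} (\code{"upwind"}/\code{"downwind"}) and
#'   \code{channel} (\code{"left"}/\code{"right"}).
#' @return a \code{"choice_table"} (see [simulate_choice_sessions()])
#'   with attributes \code{grand_mean_upwind}, \code{grand_sd_upwind},
#'   \code{grand_mean_right}, \code{grand_sd_right}.
#' @export
daily_proportions <- function(flights) {
  need <- c("day", "heading", "channel")
  miss <- setdiff(need, names(flights))
  if (length(miss)) {
    stop("`flights` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  days <- sort(unique(flights$day))
  rows <- lapply(days, function(d) {
    f <- flights[flights$day == d, ]
    data.frame(day = d, n_total = nrow(f),
               n_upwind = sum(f$heading == "upwind"),
               n_right = sum(f$channel == "right"))
  })
  tab <- do.call(rbind, rows)
  if (any(tab$n_total == 0L)) {
    warning(sprintf("dropping %d day(s) with no flights",
                    sum(tab$n_total == 0L)))
    tab <- tab[tab$n_total > 0L, , drop = FALSE]
  }
  tab <- as_choice_table(tab)
  attr(tab, "grand_mean_upwind") <- mean(tab$p_upwind_day)
  attr(tab, "grand_sd_upwind") <- sd(tab$p_upwind_day)
  attr(tab, "grand_mean_right") <- mean(tab$p_right_day)
  attr(tab, "grand_sd_right") <- sd(tab$p_right_day)
  tab
}

#' Run the choice-preference analysis on a choice table
#'
#' One-sided signed-rank tests of whether the daily upwind (and,
#' separately, right-channel) proportions exceed 0.5, plus per-day
#' two-sided binomial tests of each day's counts against 0.5.
#'
#' @param table a \code{"choice_table"}.
#' @return list with elements \code{upwind} and \code{right_channel}
#'   (each a \code{"test_result"}), \code{per_day} (data.frame of
#'   binomial p-values) and \code{summary} (grand means/SDs).
#' @export
choice_preference_tests <- function(table) {
  up <- wilcoxon_signed_rank(table$p_upwind_day, 0.5, "greater")
  ri <- wilcoxon_signed_rank(table$p_right_day, 0.5, "greater")
  per_day <- data.frame(
    day = table$day,
    p_upwind = vapply(seq_len(nrow(table)), function(i) {
      binomial_test(table$n_upwind[i], table$n_total[i])$p.value
    }, 1),
    p_right = vapply(seq_len(nrow(table)), function(i) {
      binomial_test(table$n_right[i], table$n_total[i])$p.value
    }, 1)
  )
  list(upwind = up, right_channel = ri, per_day = per_day,
       summary = list(
         mean_p_upwind = mean(table$p_upwind_day),
         sd_p_upwind = sd(table$p_upwind_day),
         mean_p_right = mean(table$p_right_day),
         sd_p_right = sd(table$p_right_day)))
}
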