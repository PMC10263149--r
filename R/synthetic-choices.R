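#' Parameters for synthetic two-choice sessions
#'
#' Describes a multi-day two-choice experiment in which each recorded
#' flight is independently upwind with probability \code{p_upwind} and in
#' the right channel with probability \code{p_right}. Defaults reproduce
#' the study conditions the package targets: 12 daily sessions averaging
#' 244 flights, an upwind preference of 0.644 and no channel preference
#' beyond 0.525.
#'
#' @param p_upwind probability that a flight is upwind.
#' @param p_right probability that a flight uses the right channel.
#' @param n_days number of daily sessions.
#' @param flights_per_day scalar or length-\code{n_days} vector of flight
#'   counts per day.
#' @param seed integer seed.
#' @return an object of class \code{"choice_model_params"}.
#' @export
choice_model_params <- function(p_upwind = 0.644, p_right = 0.525,
                                n_days = 12L, flights_per_day = 244L,
                                seed = 1L) {
  for (p in c(p_upwind, p_right)) {
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
      stop("choice probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  n_days <- as.integer(n_days)
  if (n_days < 1L) stop("`n_days` must be >= 1", call. = FALSE)
  if (length(flights_per_day) == 1L) {
    flights_per_day <- rep.int(as.integer(flights_per_day), n_days)
  } else if (length(flights_per_day) != n_days) {
    stop("`flights_per_day` must have length 1 or `n_days`", call. = FALSE)
  }
  flights_per_day <- as.integer(flights_per_day)
  if (any(flights_per_day < 0L)) {
    stop("`flights_per_day` must be non-negative", call. = FALSE)
  }
  structure(list(p_upwind = p_upwind, p_right = p_right, n_days = n_days,
                 flights_per_day = flights_per_day,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "choice_model_params")
}

#' Simulate per-day two-choice outcome tables
#'
#' Each day's upwind count is Binomial(\code{n_day}, \code{p_upwind}) and
#' its right-channel count is Binomial(\code{n_day}, \code{p_right}),
#' independent across days and of each other (every flight is classified
#' on both axes: a flight is upwind in either channel for one direction
#' of travel).
#'
#' @param cp a [choice_model_params()] object.
#' @return a \code{data.frame} of class \code{"choice_table"} with columns
#'   \code{day, n_total, n_upwind, n_right, p_upwind_day, p_right_day}.
#' @examples
#' ct <- simulate_choice_sessions(choice_model_params(seed = 42))
#' mean(ct$p_upwind_day)
#' @export
simulate_choice_sessions <- function(cp) {
  if (!inherits(cp, "choice_model_params")) {
    stop("`cp` must be created by choice_model_params()", call. = FALSE)
  }
  n <- cp$flights_per_day
  with_seed(cp$seed, {
    up <- rbinom(cp$n_days, n, cp$p_upwind)
    right <- rbinom(cp$n_days, n, cp$p_right)
  })
  as_choice_table(data.frame(
    day = seq_len(cp$n_days), n_total = n, n_upwind = up, n_right = right
  ))
}

# Attach derived proportions and the class label to a per-day count table.
as_choice_table <- function(df) {
  df$p_upwind_day <- ifelse(df$n_total > 0, df$n_upwind / df$n_total, NA_real_)
  df$p_right_day <- ifelse(df$n_total > 0, df$n_right / df$n_total, NA_real_)
  class(df) <- c("choice_table", "data.frame")
  df
}

#' @export
print.choice_table <- function(x, ...) {
  cat(sprintf("Two-choice table: %d day(s), %d flights\n", nrow(x),
              sum(x$n_total)))
  cat(sprintf("  mean daily upwind proportion %.3f (SD %.3f)\n",
              mean(x$p_upwind_day, na.rm = TRUE),
              sd(x$p_upwind_day, na.rm = TRUE)))
  cat(sprintf("  mean daily right-channel proportion %.3f (SD %.3f)\n",
              mean(x$p_right_day, na.rm = TRUE),
              sd(x$p_right_day, na.rm = TRUE)))
  print.data.frame(x, ...)
  invisible(x)
}
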