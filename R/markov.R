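#' @title Markov cohort engine
#' @description Minimal discrete-time Markov state-transition engine for
#'   post-delivery follow-up of mother and child. The engine is generic:
#'   states, transition probabilities, per-cycle costs, cycle length and
#'   discount rate are all configuration-driven, with defaults of 1-year
#'   cycles, a 20-cycle horizon, and a 0% discount rate.
#' @name markov_engine
NULL

#' Construct a Markov cohort model
#'
#' @param states character vector of state names (order fixes the
#'   transition-matrix layout).
#' @param transition square matrix of per-cycle transition probabilities;
#'   row `i`, column `j` is P(state `j` next cycle | state `i` now). Every
#'   row must sum to 1 within 1e-9 and all entries must lie in `[0, 1]`.
#' @param cycle_cost per-state USD cost accrued per cycle spent in the
#'   state (defaults to zero).
#' @param cycle_length free-text time unit of one cycle (default
#'   `"year"`).
#' @param discount_rate per-cycle discount rate as a proportion `>= 0`
#'   (default 0).
#' @return an object of class `markov_model`.
#' @export
#' @examples
#' m <- markov_model(c("healthy", "diabetic"),
#'                   rbind(c(0.96, 0.04), c(0, 1)))
markov_model <- function(states, transition, cycle_cost = NULL,
                         cycle_length = "year", discount_rate = 0) {
  stopifnot(is.character(states), length(states) >= 1L,
            is.matrix(transition),
            nrow(transition) == length(states),
            ncol(transition) == length(states),
            is.numeric(discount_rate), length(discount_rate) == 1L,
            discount_rate >= 0)
  if (is.null(cycle_cost)) cycle_cost <- rep(0, length(states))
  stopifnot(is.numeric(cycle_cost), length(cycle_cost) == length(states))
  validate_transition(transition, states)
  dimnames(transition) <- list(states, states)
  structure(list(states = states, transition = transition,
                 cycle_cost = stats::setNames(as.numeric(cycle_cost), states),
                 cycle_length = cycle_length,
                 discount_rate = as.numeric(discount_rate)),
            class = "markov_model")
}

validate_transition <- function(transition, states) {
  if (any(!is.finite(transition)) || any(transition < 0) ||
      any(transition > 1)) {
    stop("transition matrix entries must lie in [0, 1]", call. = FALSE)
  }
  sums <- rowSums(transition)
  bad <- which(abs(sums - 1) > PROB_TOL)
  if (length(bad) > 0L) {
    stop(sprintf("transition row(s) do not sum to 1: %s",
                 paste(sprintf("'%s' (sum %.12g)", states[bad], sums[bad]),
                       collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Run a Markov cohort simulation
#'
#' Propagates a cohort through the chain: `occupancy[t] = initial %*%
#' transition^t` for `t = 0, ..., n_cycles`, and accumulates discounted
#' costs over the `n_cycles` cycles lived, `sum_{t=0}^{n_cycles-1}
#' occupancy[t] . cycle_cost / (1 + discount_rate)^t`. State membership is
#' costed at the start of each cycle; an optional half-cycle correction
#' (off by default) instead weights the first and last occupancy rows by
#' one half.
#'
#' @param model a `markov_model`.
#' @param initial initial state-occupancy proportions (must sum to 1
#'   within 1e-9).
#' @param n_cycles number of cycles to simulate (`>= 0`).
#' @param half_cycle apply the half-cycle correction (default `FALSE`).
#' @return an object of class `cohort_trace`: list with `occupancy`
#'   (matrix of `n_cycles + 1` rows, one per time point, states as
#'   columns), `cycle_cost`, `discount_rate`, `half_cycle`, and
#'   `cumulative_cost` (discounted USD).
#' @export
#' @examples
#' m <- markov_model(c("healthy", "diabetic"),
#'                   rbind(c(0.96, 0.04), c(0, 1)))
#' tr <- run_cohort(m, c(1, 0), 17)
#' tr$occupancy[18, "healthy"]  # 0.96^17
run_cohort <- function(model, initial, n_cycles, half_cycle = FALSE) {
  stopifnot(inherits(model, "markov_model"),
            is.numeric(initial), length(initial) == length(model$states),
            length(n_cycles) == 1L, n_cycles >= 0,
            n_cycles == as.integer(n_cycles))
  if (any(initial < 0) || abs(sum(initial) - 1) > PROB_TOL) {
    stop("initial occupancy must be non-negative and sum to 1", call. = FALSE)
  }
  validate_transition(model$transition, model$states)
  n_cycles <- as.integer(n_cycles)
  k <- length(model$states)
  occupancy <- matrix(NA_real_, nrow = n_cycles + 1L, ncol = k,
                      dimnames = list(cycle = 0:n_cycles, state = model$states))
  occupancy[1L, ] <- initial
  state <- matrix(initial, nrow = 1L)
  if (n_cycles > 0L) {
    for (t in seq_len(n_cycles)) {
      state <- state %*% model$transition
      occupancy[t + 1L, ] <- state
    }
  }
  trace <- structure(list(occupancy = occupancy,
                          cycle_cost = model$cycle_cost,
                          discount_rate = model$discount_rate,
                          half_cycle = half_cycle,
                          cumulative_cost = NA_real_),
                     class = "cohort_trace")
  trace$cumulative_cost <- compute_trace_cost(trace)
  trace
}

compute_trace_cost <- function(trace) {
  n_cycles <- nrow(trace$occupancy) - 1L
  if (n_cycles == 0L) return(0)
  per_point <- as.numeric(trace$occupancy %*% trace$cycle_cost)
  if (trace$half_cycle) {
    w <- c(0.5, rep(1, n_cycles - 1L), 0.5)
    t_idx <- 0:n_cycles
  } else {
    w <- rep(1, n_cycles)
    t_idx <- 0:(n_cycles - 1L)
  }
  sum(w * per_point[t_idx + 1L] / (1 + trace$discount_rate)^t_idx)
}

#' Discounted cumulative cost of a cohort trace
#'
#' Recomputes the discounted cost sum from the trace's occupancy rows and
#' per-state cycle costs; with a zero discount rate this is the plain
#' undiscounted sum.
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @return discounted cumulative cost in USD.
#' @export
cumulative_cost <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  compute_trace_cost(trace)
}

#' Export a cohort trace as a data frame
#'
#' @param x a `cohort_trace`.
#' @param ... unused.
#' @return data.frame with a `cycle` column and one column per state.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = 0:(nrow(x$occupancy) - 1L), x$occupancy,
             check.names = FALSE, row.names = NULL)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %d cycle(s), %d state(s), cumulative cost %s (discount %.1f%%/cycle)\n",
              nrow(x$occupancy) - 1L, ncol(x$occupancy),
              fmt_usd(x$cumulative_cost), 100 * x$discount_rate))
  invisible(x)
}
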