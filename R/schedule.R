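#' Piecewise-linear rate schedule
#'
#' A schedule maps simulation year to a rate (stem-volume increment in
#' m3 ha-1 yr-1, or peat carbon flux in t C ha-1 yr-1) by linear
#' interpolation between breakpoints, with constant extrapolation beyond
#' the last breakpoint.  Years must start at 0 and increase strictly.
#'
#' @param year Numeric vector of breakpoint years, starting at 0.
#' @param rate Numeric vector of rates at the breakpoints.
#' @return A tibble of class `peat_schedule` with columns `year`, `rate`.
#' @examples
#' ramp <- schedule(year = c(0, 20, 50), rate = c(0, 0, 4))
#' schedule_rate(ramp, c(10, 35, 100))
#' @export
schedule <- function(year, rate) {
  stopifnot(length(year) == length(rate), length(year) >= 1,
            all(is.finite(year)), all(is.finite(rate)))
  if (year[1] != 0) abort("schedule must start at year 0")
  if (length(year) > 1 && any(diff(year) <= 0)) {
    abort("schedule years must be strictly increasing")
  }
  tibble::new_tibble(list(year = as.numeric(year), rate = as.numeric(rate)),
                     class = "peat_schedule")
}

#' Evaluate a schedule
#'
#' @param sched A [schedule()].
#' @param t Numeric vector of query years (>= 0).
#' @return Rates at `t`, linearly interpolated between breakpoints and
#'   constant after the last one.
#' @export
schedule_rate <- function(sched, t) {
  stopifnot(inherits(sched, "peat_schedule"), all(t >= 0))
  if (nrow(sched) == 1) return(rep(sched$rate, length(t)))
  approx(sched$year, sched$rate, xout = t, rule = 2)$y
}

# compiled evaluator for hot loops
schedule_fun <- function(sched) {
  if (nrow(sched) == 1) {
    r <- sched$rate
    function(t) r
  } else {
    stats::approxfun(sched$year, sched$rate, rule = 2)
  }
}
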