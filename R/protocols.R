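#' Parse a distraction-protocol label
#'
#' Grammar of the rate-varying protocol family: `"control"` is the constant
#' low-rate protocol (1 mm/day in two 0.5 mm actions, 15 days);
#' `"L<a>H<b>"` runs `a` low-rate days then `b` high-rate days (2 mm/day in
#' two 1 mm actions); `"H<a>L<b>"` is the reverse. All protocols must
#' distract exactly 15 mm in total -- labels that do not are rejected. Four
#' latency days precede distraction; the two daily actions are 12 h apart.
#'
#' @param label Protocol label, e.g. `"control"`, `"L11H2"`, `"H4L7"`.
#' @param total_length Required total distracted length in mm.
#' @param latency_days Latency phase duration in days.
#' @return An object of class `do_protocol`: a `schedule` data.frame (one
#'   row per distraction day: `day` since surgery, `rate` mm/day,
#'   `increment` mm per action), plus `latency_days`, `distraction_days`,
#'   `total_length` and the `label`.
#' @examples
#' parse_protocol("L11H2")   # 11 * 1 + 2 * 2 = 15 mm over 13 days
#' parse_protocol("control")
#' @export
parse_protocol <- function(label, total_length = 15, latency_days = 4) {
  rates <- if (identical(label, "control")) {
    rep(1, 15)
  } else if (grepl("^[LH][0-9]+[LH][0-9]+$", label)) {
    m <- regmatches(label, regexec("^([LH])([0-9]+)([LH])([0-9]+)$", label))[[1]]
    r1 <- if (m[2] == "L") 1 else 2
    r2 <- if (m[4] == "L") 1 else 2
    a <- as.integer(m[3]); b <- as.integer(m[5])
    if (m[2] == m[4]) stop("protocol '", label, "' repeats the same rate; ",
                           "use 'control' for constant low rate")
    if (a < 1 || b < 1) stop("both phases need at least one day")
    c(rep(r1, a), rep(r2, b))
  } else stop("unrecognised protocol label '", label,
              "' (expected control, L<a>H<b> or H<a>L<b>)")
  tot <- sum(rates)
  if (abs(tot - total_length) > 1e-9)
    stop("protocol '", label, "' distracts ", tot, " mm, not the required ",
         total_length, " mm")
  sched <- data.frame(day = latency_days + seq_along(rates),
                      rate = rates, increment = rates / 2)
  structure(list(label = label, schedule = sched,
                 latency_days = latency_days,
                 distraction_days = length(rates),
                 total_length = tot),
            class = "do_protocol")
}

#' @export
print.do_protocol <- function(x, ...) {
  cat(sprintf("Protocol %s: %d latency days, %d distraction days, %.3g mm total\n",
              x$label, x$latency_days, x$distraction_days, x$total_length))
  r <- rle(x$schedule$rate)
  cat("  rates:", paste(sprintf("%d d @ %g mm/day", r$lengths, r$values),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Export a protocol schedule as CSV
#'
#' One row per distraction action: day since surgery, action time in hours
#' (two actions 12 h apart) and the increment in mm.
#'
#' @param protocol A [parse_protocol()] result.
#' @param path Output CSV path.
#' @export
write_protocol_csv <- function(protocol, path) {
  stopifnot(inherits(protocol, "do_protocol"))
  s <- protocol$schedule
  d <- data.frame(day = rep(s$day, each = 2),
                  action_time_h = rep(c(0, 12), nrow(s)),
                  increment_mm = rep(s$increment, each = 2))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Effective distraction strain
#'
#' The per-day strain imposed on the gap tissue: distraction rate divided by
#' the present gap length. The design heuristic for rate-varying protocols:
#' keep this quantity inside the favourable mechanical window as the gap
#' grows.
#'
#' @param l Gap length in mm.
#' @param r Distraction rate in mm/day.
#' @return Effective strain per day (dimensionless).
#' @examples
#' effective_strain(15, 1)  # late low-rate distraction: 0.067/day
#' @export
effective_strain <- function(l, r) {
  if (any(l <= 0)) stop("gap length must be positive")
  if (any(r < 0)) stop("negative distraction rate")
  r / l
}

#' Distraction rate achieving a target effective strain
#'
#' Inverse of [effective_strain()]: the rate that imposes `target_strain`
#' per day on a gap of length `l`.
#'
#' @param l Gap length in mm.
#' @param target_strain Desired effective strain per day.
#' @return Rate in mm/day.
#' @export
design_rate <- function(l, target_strain) {
  if (any(l <= 0)) stop("gap length must be positive")
  if (any(target_strain <= 0)) stop("target_strain must be positive")
  l * target_strain
}

#' Daily effective-strain report for a protocol
#'
#' For each distraction day, the gap length at the start of the day (initial
#' osteotomy gap plus cumulative distraction through the previous day), the
#' day's rate, the effective strain, and whether it sits inside the
#' favourable window.
#'
#' @param protocol A [parse_protocol()] result.
#' @param initial_gap Osteotomy gap in mm.
#' @param window Favourable effective-strain window (per day), used only
#'   for the report's `favorable` flag. The default brackets the favourable
#'   dilatational window of the regulation model under free lateral
#'   contraction.
#' @return A data.frame with one row per distraction day.
#' @export
protocol_strain_report <- function(protocol, initial_gap = 1,
                                   window = c(0.00025, 0.085)) {
  stopifnot(inherits(protocol, "do_protocol"))
  s <- protocol$schedule
  gap_start <- initial_gap + cumsum(c(0, s$rate))[seq_len(nrow(s))]
  eff <- effective_strain(gap_start, s$rate)
  data.frame(day = s$day, gap_mm = gap_start, rate_mm_day = s$rate,
             effective_strain = eff,
             favorable = eff > window[1] & eff < window[2])
}
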