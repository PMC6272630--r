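#' License policy for job dispatch
#'
#' Dispatch of docking jobs is constrained by commercial licenses: each
#' licensed program is confined to its own "traffic lane" whose width (the
#' number of jobs of that program that may run simultaneously) equals the
#' number of licenses held, while all license-free programs share the
#' leftover cores.
#'
#' @param licenses named integer vector, program -> license count (programs
#'   absent from the vector are unlicensed). May be empty.
#' @param total_cores total cores available, >= 1.
#' @return object of class `license_policy`.
#' @examples
#' license_policy(c(GLIDE = 1, GOLD = 1, MOE = 1), total_cores = 8)
#' @export
license_policy <- function(licenses = integer(0), total_cores) {
  if (length(licenses)) {
    stopifnot(!is.null(names(licenses)), all(nzchar(names(licenses))))
    if (any(licenses < 1)) stop("license counts must be >= 1", call. = FALSE)
  }
  if (!is.numeric(total_cores) || total_cores < 1)
    stop("total_cores must be >= 1", call. = FALSE)
  structure(list(licenses = as.integer(round(licenses)) |>
                   stats::setNames(names(licenses)),
                 total_cores = as.integer(total_cores)),
            class = "license_policy")
}

#' Build the lane layout from a license policy
#'
#' One lane per licensed program, of width equal to its license count;
#' those widths are subtracted from the total cores and the remainder
#' becomes the shared lane for unlicensed jobs. The unlicensed lane must
#' keep at least one core, so license counts summing to the core count (or
#' beyond) are a capacity error.
#'
#' @param policy a [license_policy()].
#' @return object of class `lane_layout`: data.frame with columns `lane`
#'   (program name, or "unlicensed") and `width`.
#' @examples
#' build_lanes(license_policy(c(GLIDE = 1, GOLD = 1, MOE = 1), 8))
#' @export
build_lanes <- function(policy) {
  stopifnot(inherits(policy, "license_policy"))
  reserved <- sum(policy$licenses)
  leftover <- policy$total_cores - reserved
  if (leftover < 1L)
    stop("capacity error: ", reserved, " licensed core(s) leave no room ",
         "for the unlicensed lane on ", policy$total_cores, " cores",
         call. = FALSE)
  layout <- data.frame(
    lane = c(names(policy$licenses), "unlicensed"),
    width = c(unname(policy$licenses), leftover),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(layout$width) == policy$total_cores)
  structure(layout, class = c("lane_layout", "data.frame"))
}

#' Simulate license-aware job dispatch
#'
#' Discrete-event simulation of the lane model: jobs arrive in input order
#' at time zero, each is routed to its program's lane (or to the shared
#' unlicensed lane) and starts as soon as one of the lane's slots frees,
#' FIFO within the lane. Idle slots of a licensed lane are never lent to
#' unlicensed jobs — licensed lanes are reserved. The simulation is
#' deterministic given the job order.
#'
#' @param jobs data.frame with columns `id`, `program`, `duration`
#'   (simulated seconds, > 0).
#' @param layout a [lane_layout()].
#' @return object of class `schedule_result`: list with `schedule`
#'   (data.frame: id, program, lane, start, end), `makespan`, and
#'   `peak_concurrency` (named vector, per lane).
#' @export
simulate_schedule <- function(jobs, layout) {
  stopifnot(is.data.frame(jobs),
            all(c("id", "program", "duration") %in% names(jobs)),
            inherits(layout, "lane_layout"))
  if (any(jobs$duration <= 0))
    stop("job durations must be positive", call. = FALSE)
  lane_of <- function(p) if (p %in% layout$lane) p else "unlicensed"
  lanes <- vapply(jobs$program, lane_of, character(1))
  slots <- lapply(stats::setNames(layout$width, layout$lane), numeric)
  start <- end <- numeric(nrow(jobs))
  for (i in seq_len(nrow(jobs))) {
    ln <- lanes[i]
    k <- which.min(slots[[ln]])
    start[i] <- slots[[ln]][k]
    end[i] <- start[i] + jobs$duration[i]
    slots[[ln]][k] <- end[i]
  }
  sched <- data.frame(id = jobs$id, program = jobs$program, lane = lanes,
                      start = start, end = end, stringsAsFactors = FALSE)
  peak <- vapply(layout$lane, function(ln) {
    s <- sched[sched$lane == ln, , drop = FALSE]
    if (nrow(s) == 0L) return(0L)
    # concurrency right after each start event
    max(vapply(seq_len(nrow(s)), function(j)
      sum(s$start <= s$start[j] & s$end > s$start[j]), integer(1)))
  }, integer(1))
  structure(list(schedule = sched,
                 makespan = if (nrow(sched)) max(sched$end) else 0,
                 peak_concurrency = stats::setNames(peak, layout$lane)),
            class = "schedule_result")
}

#' @export
print.schedule_result <- function(x, ...) {
  cat("<schedule_result> ", nrow(x$schedule), " jobs, makespan ",
      x$makespan, " s\n", sep = "")
  print(x$peak_concurrency)
  invisible(x)
}

#' Per-lane utilisation of a simulated schedule
#'
#' Busy core-seconds of each lane divided by its capacity over the whole
#' schedule (lane width times the schedule makespan); in `[0, 1]`, 1 for a
#' fully packed lane.
#'
#' @param result a `schedule_result`.
#' @param layout the [lane_layout()] used for the simulation.
#' @return named numeric vector of busy fractions, one per lane.
#' @export
lane_utilisation <- function(result, layout) {
  stopifnot(inherits(result, "schedule_result"),
            inherits(layout, "lane_layout"))
  if (result$makespan == 0) return(stats::setNames(rep(0, nrow(layout)),
                                                   layout$lane))
  busy <- vapply(layout$lane, function(ln) {
    s <- result$schedule[result$schedule$lane == ln, , drop = FALSE]
    sum(s$end - s$start)
  }, numeric(1))
  stats::setNames(busy / (layout$width * result$makespan), layout$lane)
}
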