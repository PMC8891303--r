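# Release-pause schedules: construction, summaries, random generation, CSV IO.
# A schedule always starts and ends with a release phase, so N release
# phases are separated by exactly N - 1 pauses.

new_schedule <- function(kind, duration) {
  structure(list(kind = kind, duration = duration), class = "release_schedule")
}

#' Construct a release-pause schedule
#'
#' Builds the alternating sequence R, P, R, ..., R from the release and
#' pause durations. The first and last phases are always release phases:
#' a leading or trailing pause would leave no trace on the released mass.
#'
#' @param release_durations Numeric vector of release (contact) durations in
#'   seconds, all strictly positive. Its length is the number of contacts N.
#' @param pause_durations Numeric vector of pause durations in seconds,
#'   length N - 1, all strictly positive.
#' @return An object of class `release_schedule` with components `kind`
#'   (character, `"R"`/`"P"`) and `duration` (seconds).
#' @examples
#' s <- make_schedule(c(100, 300), 200)
#' mean_release_time(s)    # 200 s
#' pause_release_ratio(s)  # 1
#' @export
make_schedule <- function(release_durations, pause_durations = numeric(0)) {
  n <- length(release_durations)
  if (n < 1L) {
    stop("at least one release phase is required", call. = FALSE)
  }
  if (length(pause_durations) != n - 1L) {
    stop(sprintf(
      "with %d release phase(s) there must be exactly %d pause(s), got %d",
      n, n - 1L, length(pause_durations)
    ), call. = FALSE)
  }
  bad <- which(!is.finite(release_durations) | release_durations <= 0)
  if (length(bad)) {
    stop(sprintf("release duration at index %d is not strictly positive", bad[1L]),
         call. = FALSE)
  }
  bad <- which(!is.finite(pause_durations) | pause_durations <= 0)
  if (length(bad)) {
    stop(sprintf("pause duration at index %d is not strictly positive", bad[1L]),
         call. = FALSE)
  }
  m <- 2L * n - 1L
  kind <- rep(c("R", "P"), length.out = m)
  duration <- numeric(m)
  duration[kind == "R"] <- release_durations
  duration[kind == "P"] <- pause_durations
  new_schedule(kind, duration)
}

validate_schedule <- function(s) {
  if (!inherits(s, "release_schedule")) {
    stop("not a 'release_schedule' object", call. = FALSE)
  }
  k <- s$kind
  if (k[1L] != "R" || k[length(k)] != "R") {
    stop("schedule must begin and end with a release phase", call. = FALSE)
  }
  if (length(k) > 1L && any(k[-1L] == k[-length(k)])) {
    stop("release and pause phases must alternate strictly", call. = FALSE)
  }
  if (any(!is.finite(s$duration) | s$duration <= 0)) {
    stop("all phase durations must be strictly positive", call. = FALSE)
  }
  invisible(s)
}

#' Schedule summaries
#'
#' `n_releases` counts the release phases N, `total_time` returns the total
#' elapsed time t_tot, `total_release_time` the cumulative contact time
#' t_R_tot, and `mean_release_time` the mean contact duration
#' (1/N) * sum of release durations.
#'
#' @param s A `release_schedule`.
#' @return A single number (seconds, except `n_releases`).
#' @export
n_releases <- function(s) {
  validate_schedule(s)
  sum(s$kind == "R")
}

#' @rdname n_releases
#' @export
total_time <- function(s) {
  validate_schedule(s)
  sum(s$duration)
}

#' @rdname n_releases
#' @export
total_release_time <- function(s) {
  validate_schedule(s)
  sum(s$duration[s$kind == "R"])
}

#' @rdname n_releases
#' @export
mean_release_time <- function(s) {
  total_release_time(s) / n_releases(s)
}

#' Pause/release duration ratio z
#'
#' The dimensionless ratio between the mean pause duration and the mean
#' release duration, z = (t_tot - N * tau_bar) / ((N - 1) * tau_bar). It is
#' the single schedule descriptor entering the empirical envelope [f_of_z()].
#' Defined only for N >= 2; callers handling single-contact scenarios must
#' branch before evaluating it (see [approx_released_mass()]).
#'
#' @param s A `release_schedule` with at least two release phases.
#' @return Dimensionless ratio, >= 0.
#' @export
pause_release_ratio <- function(s) {
  n <- n_releases(s)
  if (n < 2L) {
    stop("pause/release ratio is undefined for a single release phase",
         call. = FALSE)
  }
  tau_bar <- mean_release_time(s)
  (total_time(s) - n * tau_bar) / ((n - 1) * tau_bar)
}

# Uniform draw on the simplex {d_i > 0, sum d_i = total}: normalized i.i.d.
# exponentials (flat Dirichlet), the maximum-ignorance choice for durations
# with a fixed sum.
runif_simplex <- function(n, total) {
  if (n == 1L) return(total)
  w <- stats::rexp(n)
  w / sum(w) * total
}

#' Generate a random release-pause schedule
#'
#' Two sampling modes emulate the two ensemble protocols used throughout
#' the package. Mode A (default, `t_R_tot = NULL`): all 2N - 1 durations are
#' drawn jointly uniform on the simplex summing to `t_tot` — the protocol of
#' the violation-statistics ensembles. Mode B (`t_R_tot` given): release
#' durations are uniform on the simplex summing to `t_R_tot` and pause
#' durations independently on the simplex summing to `t_tot - t_R_tot` —
#' the calibration protocol, where the total contact time is held fixed.
#'
#' @param N Number of release phases (contacts), >= 1.
#' @param t_tot Total elapsed time in seconds.
#' @param t_R_tot Optional total contact time in seconds (mode B); must lie
#'   strictly between 0 and `t_tot` when N >= 2.
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return A `release_schedule`.
#' @export
random_schedule <- function(N, t_tot, t_R_tot = NULL, seed = NULL) {
  if (N < 1L) stop("N must be >= 1", call. = FALSE)
  if (!is.finite(t_tot) || t_tot <= 0) stop("t_tot must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(t_R_tot)) {
    if (N == 1L) return(make_schedule(t_tot))
    d <- runif_simplex(2L * N - 1L, t_tot)
    idx <- seq_len(2L * N - 1L)
    make_schedule(d[idx %% 2L == 1L], d[idx %% 2L == 0L])
  } else {
    if (N == 1L) {
      if (abs(t_R_tot - t_tot) > 1e-9 * t_tot) {
        stop("with N = 1 there are no pauses: t_R_tot must equal t_tot",
             call. = FALSE)
      }
      return(make_schedule(t_tot))
    }
    if (!(t_R_tot > 0 && t_R_tot < t_tot)) {
      stop("t_R_tot must lie strictly between 0 and t_tot", call. = FALSE)
    }
    make_schedule(runif_simplex(N, t_R_tot),
                  runif_simplex(N - 1L, t_tot - t_R_tot))
  }
}

#' @export
as.data.frame.release_schedule <- function(x, ...) {
  data.frame(kind = x$kind, duration_s = x$duration, stringsAsFactors = FALSE)
}

#' @export
print.release_schedule <- function(x, ...) {
  n <- sum(x$kind == "R")
  cat(sprintf("Release-pause schedule: %d release phase(s), %d pause(s)\n",
              n, sum(x$kind == "P")))
  cat(sprintf("  t_tot = %.6g s, t_R_tot = %.6g s, tau_bar = %.6g s\n",
              sum(x$duration), sum(x$duration[x$kind == "R"]),
              mean(x$duration[x$kind == "R"])))
  if (n >= 2L) cat(sprintf("  z = %.4g\n", pause_release_ratio(x)))
  invisible(x)
}

#' Read / write schedule CSV files
#'
#' The on-disk dialect is fixed: a header line, a `kind` column with literal
#' `"R"` or `"P"`, and a `duration_s` column with positive decimal seconds,
#' one row per phase in time order. The reader rejects malformed files with
#' an error naming the offending data line.
#'
#' @param path File path.
#' @return `read_schedule_csv` returns a `release_schedule`;
#'   `write_schedule_csv` invisibly returns `path`.
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("kind", "duration_s") %in% names(df))) {
    stop("schedule CSV must have columns 'kind' and 'duration_s'", call. = FALSE)
  }
  if (nrow(df) == 0L) stop("schedule CSV contains no phases", call. = FALSE)
  # +1 for the header so reported numbers match file line numbers
  bad <- which(!df$kind %in% c("R", "P"))
  if (length(bad)) {
    stop(sprintf("line %d: kind must be 'R' or 'P'", bad[1L] + 1L), call. = FALSE)
  }
  bad <- which(!is.finite(df$duration_s) | df$duration_s <= 0)
  if (length(bad)) {
    stop(sprintf("line %d: duration_s must be strictly positive", bad[1L] + 1L),
         call. = FALSE)
  }
  if (df$kind[1L] != "R") stop("line 2: schedule must start with 'R'", call. = FALSE)
  if (df$kind[nrow(df)] != "R") {
    stop(sprintf("line %d: schedule must end with 'R'", nrow(df) + 1L),
         call. = FALSE)
  }
  if (nrow(df) > 1L) {
    bad <- which(df$kind[-1L] == df$kind[-nrow(df)])
    if (length(bad)) {
      stop(sprintf("line %d: phases must alternate R/P", bad[1L] + 2L),
           call. = FALSE)
    }
  }
  make_schedule(df$duration_s[df$kind == "R"], df$duration_s[df$kind == "P"])
}

#' @rdname read_schedule_csv
#' @param s A `release_schedule` to write.
#' @export
write_schedule_csv <- function(s, path) {
  validate_schedule(s)
  df <- as.data.frame(s)
  # %.17g round-trips doubles exactly through the text format
  df$duration_s <- sprintf("%.17g", df$duration_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
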