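# Shared helpers: classed conditions, angle arithmetic, measure registry.

et_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "exploretrace_error")))
}

et_warn <- function(msg, class = "exploretrace_warning") {
  warning(warningCondition(msg, class = c(class, "exploretrace_warning")))
}

# wrap to [-pi, pi); reversals of exactly pi map to -pi, which keeps
# |turn| = pi and is what the turnaround counters rely on
wrap_pi <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

#' The thirteen exploration measures
#'
#' Canonical column order used by feature tables throughout the package.
#'
#' @return character vector of length 13.
#' @export
measure_names <- function() {
  c("path_length", "pausing", "area_covered", "roaming_entropy",
    "landmark_visits", "fractal_dimension", "sinuosity",
    "landmark_revisits", "revisiting", "turnarounds", "flight_turnarounds",
    "area_efficiency", "landmark_efficiency")
}

#' Measures inverted so that higher values mean more exploration
#'
#' Four measures quantify the *absence* of exploration (time standing still,
#' going back to known places, reversing direction); their z-scores are
#' negated before clustering and compounding.
#'
#' @return character vector of length 4.
#' @export
inverted_measures <- function() {
  c("pausing", "revisiting", "landmark_revisits", "flight_turnarounds")
}

#' Reference cluster membership of the thirteen measures
#'
#' The canonical three-dimension partition: exploratory activity (extent and
#' breadth), shape of exploration (trajectory complexity), and exploratory
#' efficiency (coverage per distance with little redundancy).
#'
#' @return named list of three character vectors.
#' @export
reference_clusters <- function() {
  list(
    activity   = c("path_length", "pausing", "area_covered",
                   "roaming_entropy", "landmark_visits"),
    shape      = c("fractal_dimension", "sinuosity"),
    efficiency = c("landmark_revisits", "revisiting", "turnarounds",
                   "flight_turnarounds", "area_efficiency",
                   "landmark_efficiency")
  )
}
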