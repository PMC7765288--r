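#' The 48-variable sleep registry
#'
#' Builds the canonical registry of the 48 infant sleep variables used
#' throughout the pipeline. Each entry carries:
#' \describe{
#'   \item{id}{variable id, 1..48 (stable numbering used in all outputs)}
#'   \item{name}{variable name}
#'   \item{units}{reporting units}
#'   \item{family}{screening family: one of `"clock_time"`, `"partial_day"`,
#'     `"entire_day"`, `"movement_count"`, or `"variability"` for cross-day
#'     standard deviations (whose per-day validity follows their base
#'     variable's family)}
#'   \item{is_variability}{TRUE for the 22 cross-day standard-deviation
#'     variables ("Standard deviation of X across recording days"). Note
#'     that *Variability of Activity level* (27) is a within-night SD and is
#'     not a variability variable in this sense.}
#'   \item{base_id}{for variability entries, the id of the base variable}
#'   \item{day_window}{the window the base quantity is computed over:
#'     `"night"`, `"day"` (sleep offset to next sleep onset), `"24h"`,
#'     `"7am-7pm"`, or `"7pm-7am"`}
#' }
#'
#' @return a `data.frame` with 48 rows, one per variable.
#' @export
variable_registry <- function() {
  if (!is.null(.registry_cache$reg)) return(.registry_cache$reg)
  e <- function(id, name, units, family, window, base = NA_integer_) {
    data.frame(id = id, name = name, units = units, family = family,
               is_variability = family == "variability",
               base_id = base, day_window = window,
               stringsAsFactors = FALSE)
  }
  v <- function(id, base_name, base, window) {
    e(id, paste("Variability of", base_name), "SD", "variability", window, base)
  }
  reg <- rbind(
    e(1L,  "Bedtime",                         "clock time in min", "clock_time",     "night"),
    v(2L,  "Bedtime",                         1L,                  "night"),
    e(3L,  "Get up Time",                     "clock time in min", "clock_time",     "night"),
    v(4L,  "Get up Time",                     3L,                  "night"),
    e(5L,  "Sleep Onset",                     "clock time in min", "clock_time",     "night"),
    v(6L,  "Sleep Onset",                     5L,                  "night"),
    e(7L,  "Sleep Latency",                   "min",               "partial_day",    "night"),
    v(8L,  "Sleep Latency",                   7L,                  "night"),
    e(9L,  "Sleep Offset",                    "clock time in min", "clock_time",     "night"),
    v(10L, "Sleep Offset",                    9L,                  "night"),
    e(11L, "Midsleep",                        "clock time in min", "clock_time",     "night"),
    v(12L, "Midsleep",                        11L,                 "night"),
    e(13L, "Sleep Opportunity",               "min",               "partial_day",    "night"),
    v(14L, "Sleep Opportunity",               13L,                 "night"),
    e(15L, "Sleep Period",                    "min",               "partial_day",    "night"),
    v(16L, "Sleep Period",                    15L,                 "night"),
    e(17L, "Total Sleep Time",                "min",               "partial_day",    "night"),
    v(18L, "Total Sleep Time",                17L,                 "night"),
    e(19L, "Sleep Efficiency",                "%",                 "entire_day",     "night"),
    v(20L, "Sleep Efficiency",                19L,                 "night"),
    e(21L, "Wake after Sleep Onset",          "min",               "partial_day",    "night"),
    v(22L, "Wake after Sleep Onset",          21L,                 "night"),
    e(23L, "Longest Nocturnal Wake",          "min",               "partial_day",    "night"),
    v(24L, "Longest Nocturnal Wake",          23L,                 "night"),
    e(25L, "Nocturnal Wake Frequency per Hour", "wakings/hour",    "partial_day",    "night"),
    v(26L, "Nocturnal Wake Frequency per Hour", 25L,               "night"),
    e(27L, "Variability of Activity level",   "SD of counts",      "movement_count", "night"),
    e(28L, "Percent Active Epochs",           "ratio",             "movement_count", "night"),
    v(29L, "Percent Active Epochs",           28L,                 "night"),
    e(30L, "Longest Sleep",                   "min",               "partial_day",    "night"),
    v(31L, "Longest Sleep",                   30L,                 "night"),
    e(32L, "Longest Wake",                    "min",               "partial_day",    "day"),
    v(33L, "Longest Wake",                    32L,                 "day"),
    e(34L, "Nap Counter",                     "count",             "partial_day",    "day"),
    v(35L, "Nap Counter",                     34L,                 "day"),
    e(36L, "Sleep after Wake Onset",          "min",               "partial_day",    "day"),
    v(37L, "Sleep after Wake Onset",          36L,                 "day"),
    e(38L, "Sleep Duration 24 h",             "min",               "entire_day",     "24h"),
    v(39L, "Sleep Duration 24 h",             38L,                 "24h"),
    e(40L, "Sleep Duration Day",              "min",               "entire_day",     "7am-7pm"),
    v(41L, "Sleep Duration Day",              40L,                 "7am-7pm"),
    e(42L, "Sleep Duration Night",            "min",               "entire_day",     "7pm-7am"),
    v(43L, "Sleep Duration Night",            42L,                 "7pm-7am"),
    e(44L, "% Sleep Duration Night",          "ratio",             "entire_day",     "24h"),
    v(45L, "% Sleep Duration Night",          44L,                 "24h"),
    e(46L, "Sleep Regularity Index Whole Day", "ratio",            "entire_day",     "24h"),
    e(47L, "Sleep Regularity Index Day",      "ratio",             "entire_day",     "7am-7pm"),
    e(48L, "Sleep Regularity Index Night",    "ratio",             "entire_day",     "7pm-7am")
  )
  rownames(reg) <- NULL
  stopifnot(nrow(reg) == 48L, identical(reg$id, 1:48))
  .registry_cache$reg <- reg
  reg
}

.registry_cache <- new.env(parent = emptyenv())

#' Screening family of a variable, resolving variability entries to their base
#' @param registry registry from [variable_registry()].
#' @return character vector of length 48 over the four screening families.
#' @export
screening_family <- function(registry = variable_registry()) {
  if (!is.null(.registry_cache$fam)) return(.registry_cache$fam)
  fam <- registry$family
  idx <- which(fam == "variability")
  fam[idx] <- registry$family[match(registry$base_id[idx], registry$id)]
  .registry_cache$fam <- fam
  fam
}
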