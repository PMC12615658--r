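# Desk-scale simulator of the field robot's sensor-decision and movement
# logic: soil-moisture categorization from an analog moisture level, and
# single-character app commands mapped to motor directions.

#' Classify soil moisture into a monotone category scale
#'
#' Maps a raw analog soil-moisture level (0-1023) to one of four
#' categories using three ascending cut points: below `t1` is `dry`,
#' `[t1, t2)` `almost_dry`, `[t2, t3)` `almost_wet`, and `>= t3` `wet`.
#' Higher moisture never maps to a drier category. A narrative string in
#' the field-log phrasing ("Soil is dry, temperature 28 °C, humidity 98")
#' accompanies each category.
#'
#' @param moisture numeric vector of raw levels in [0, 1023].
#' @param temperature,humidity optional scalars or vectors used in the
#'   narrative.
#' @param thresholds three strictly ascending cut points within [0, 1023];
#'   the defaults (500, 640, 790) reproduce the internally consistent rows
#'   of the reference sensor log.
#' @return data.frame with columns `moisture_raw`, `category` (ordered
#'   factor dry < almost_dry < almost_wet < wet) and `narrative`.
#' @examples
#' classifyMoisture(c(450, 590, 800), temperature = 28, humidity = 98)
#' @export
classifyMoisture <- function(moisture, temperature = NA, humidity = NA,
                             thresholds = c(500, 640, 790)) {
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0))
    stop("thresholds must be three strictly ascending cut points")
  if (any(thresholds < 0) || any(thresholds > 1023))
    stop("thresholds must lie within [0, 1023]")
  if (any(moisture < 0 | moisture > 1023))
    stop("moisture levels must lie within [0, 1023]")
  lev <- c("dry", "almost_dry", "almost_wet", "wet")
  idx <- findInterval(moisture, thresholds) + 1L
  category <- factor(lev[idx], levels = lev, ordered = TRUE)
  narrative <- sprintf("Soil is %s, temperature %s °C, humidity %s",
                       gsub("_", " ", lev[idx]), temperature, humidity)
  data.frame(moisture_raw = moisture, category = category,
             narrative = narrative, stringsAsFactors = FALSE)
}

#' Interpret a single-character movement command
#'
#' `F`, `B`, `L`, `R` (case-insensitive) map to forward, backward, left and
#' right at the requested speed, clamped to `speedThreshold`. Any other
#' input — including arbitrary bytes — degrades to `STOP` (speed 0) with a
#' warning: the interpreter is total and fail-safe over every single-byte
#' input. Bytes are compared directly so invalid-encoding characters are
#' handled like any other unknown command.
#'
#' @param raw a length-1 character string (normally a single character).
#' @param speed requested speed level (non-negative).
#' @param speedThreshold maximum permitted speed.
#' @return list with `code` (one of `"L" "R" "F" "B" "STOP"`) and `speed`.
#' @examples
#' interpretCommand("F", speed = 200, speedThreshold = 150)
#' @export
interpretCommand <- function(raw, speed = 100, speedThreshold = 150) {
  if (!is.character(raw) || length(raw) != 1L)
    stop("raw must be a length-1 character string")
  if (speed < 0) stop("speed must be non-negative")
  bytes <- charToRaw(raw)
  known <- as.raw(utf8ToInt("F") + c(0L, 32L))  # F/f
  known <- c(known, as.raw(utf8ToInt("B") + c(0L, 32L)),
             as.raw(utf8ToInt("L") + c(0L, 32L)),
             as.raw(utf8ToInt("R") + c(0L, 32L)))
  if (length(bytes) != 1L || !bytes %in% known) {
    warning("unknown command (byte ",
            if (length(bytes)) paste(as.integer(bytes), collapse = ",")
            else "<empty>", "): stopping", call. = FALSE)
    return(list(code = "STOP", speed = 0))
  }
  code <- toupper(rawToChar(bytes))
  list(code = code, speed = min(speed, speedThreshold))
}

#' Simulate a stream of sensor readings with soil decisions
#'
#' Generates `n` readings as a seeded random walk of temperature (degrees
#' Celsius), relative humidity (percent, clipped to [0, 100]) and raw soil
#' moisture (clipped to [0, 1023]) with non-decreasing integer timestamps,
#' and attaches the [classifyMoisture()] decision to every reading.
#'
#' @param n number of readings (>= 1).
#' @param seed integer RNG seed.
#' @param start named numeric vector with elements `temperature`,
#'   `humidity`, `moisture`.
#' @param stepSd random-walk step standard deviations in the same order
#'   (use 0 for a constant signal).
#' @param thresholds moisture cut points, see [classifyMoisture()].
#' @return data.frame with columns `timestamp`, `temperature`, `humidity`,
#'   `moisture_raw`, `category`, `narrative`.
#' @examples
#' streamReadings(3, seed = 1)[, 1:4]
#' @export
streamReadings <- function(n, seed = 1,
                           start = c(temperature = 28, humidity = 96,
                                     moisture = 600),
                           stepSd = c(0.3, 1, 60),
                           thresholds = c(500, 640, 790)) {
  if (n < 1) stop("n must be >= 1")
  withSeed(seed, {
    temp <- cumsum(c(start[["temperature"]], rnorm(n - 1L, sd = stepSd[1])))
    hum <- pmin(pmax(
      cumsum(c(start[["humidity"]], rnorm(n - 1L, sd = stepSd[2]))), 0), 100)
    moist <- pmin(pmax(
      cumsum(c(start[["moisture"]], rnorm(n - 1L, sd = stepSd[3]))), 0), 1023)
    moist <- round(moist)
    dec <- classifyMoisture(moist, temperature = round(temp),
                            humidity = round(hum), thresholds = thresholds)
    data.frame(timestamp = seq_len(n), temperature = temp, humidity = hum,
               moisture_raw = moist, category = dec$category,
               narrative = dec$narrative, stringsAsFactors = FALSE)
  })
}

#' Write a telemetry log to a delimited text file
#'
#' @param log data.frame from [streamReadings()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeTelemetryLog <- function(log, path) {
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}
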