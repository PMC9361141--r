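#' Clock times as minutes since midnight
#'
#' Sleep diaries record clock times only ("HH:MM"), with no date attached to
#' either end of the night, so all interval arithmetic has to be done on the
#' 24 h circle. A clock time is represented as an integer number of minutes
#' since midnight in `[0, 1440)`; values are always reduced modulo 1440.
#'
#' @param x A character vector of `"HH:MM"` strings, or a numeric vector of
#'   minutes (reduced modulo 1440).
#' @return An integer vector of minutes since midnight in `[0, 1440)`.
#' @examples
#' clock_time("23:30")
#' clock_time(1440 + 90)  # wraps to 01:30
#' format_clock(clock_time("06:45") + 15)
#' @export
clock_time <- function(x) {
  if (is.character(x)) {
    ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x) | is.na(x)
    if (!all(ok)) {
      stop("invalid clock time(s): ", paste(x[!ok], collapse = ", "),
           " (expected \"HH:MM\")", call. = FALSE)
    }
    hm <- matrix(as.integer(unlist(strsplit(x, ":", fixed = TRUE))),
                 ncol = 2, byrow = TRUE)
    out <- hm[, 1] * 60L + hm[, 2]
  } else if (is.numeric(x)) {
    if (any(x != floor(x), na.rm = TRUE)) {
      stop("clock times must be whole minutes", call. = FALSE)
    }
    out <- as.integer(x %% 1440)
  } else {
    stop("cannot interpret ", class(x)[1], " as a clock time", call. = FALSE)
  }
  out %% 1440L
}

#' @rdname clock_time
#' @export
format_clock <- function(x) {
  x <- clock_time(x)
  sprintf("%02d:%02d", x %/% 60L, x %% 60L)
}

#' Elapsed minutes between two clock times
#'
#' Forward difference on the 24 h circle: the number of minutes from `from`
#' to the next occurrence of `to`. When `to` falls at or before `from` on the
#' clock face the interval wraps midnight (1440 is added), so a bedtime of
#' 23:30 and an arising time of 07:00 give 450 minutes. A zero-length
#' interval maps to 0, which callers treat as invalid where it would divide.
#'
#' @param from,to Clock times (anything `clock_time()` accepts).
#' @return Integer minutes in `[0, 1440)`.
#' @export
clock_diff <- function(from, to) {
  (clock_time(to) - clock_time(from)) %% 1440L
}
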