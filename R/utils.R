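#' @keywords internal
"_PACKAGE"

# Internal validation helpers ------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_field(field, "must be a probability in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != as.integer(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    stop_field(field, if (positive) "must be a positive integer" else "must be a nonnegative integer")
  }
  invisible(as.integer(x))
}

as_date_strict <- function(x, field) {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1L || is.na(d)) stop_field(field, "must be a calendar date")
  d
}

#' Monday on or before a date
#'
#' Weeks are taken to start on a Monday throughout the package, matching the
#' week-resolution dates of birth carried by linked demographic registers.
#'
#' @param date a `Date` vector.
#' @return the `Date` of the Monday on or before each element.
#' @export
week_monday <- function(date) {
  date <- as.Date(date)
  # day 0 (1970-01-01) was a Thursday, so (day + 3) mod 7 counts days past Monday
  date - (as.integer(date) + 3L) %% 7L
}

is_monday <- function(date) (as.integer(as.Date(date)) + 3L) %% 7L == 0L

# add k whole years to a Date (calendar arithmetic, Feb 29 clamped to Feb 28);
# computed on unique values only, since callers pass long vectors with few
# distinct dates
add_years <- function(date, k) {
  date <- as.Date(date)
  u <- unique(date)
  lt <- as.POSIXlt(u)
  lt$year <- lt$year + k
  shifted <- as.Date(lt)
  bad <- is.na(shifted) & !is.na(u)
  if (any(bad)) {
    lt2 <- as.POSIXlt(u[bad])
    lt2$year <- lt2$year + k
    lt2$mday <- 28L
    shifted[bad] <- as.Date(lt2)
  }
  shifted[match(as.integer(date), as.integer(u))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
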