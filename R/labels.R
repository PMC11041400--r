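#' Activity label vocabulary
#'
#' The six activity classes recognized by the pipeline, in the fixed
#' alphabetical order used everywhere for class indices and
#' confusion-matrix axes: `dws` (downstairs), `jog` (jogging), `sit`
#' (sitting), `std` (standing), `ups` (upstairs), `wlk` (walking).
#'
#' @return Character vector of the 6 class codes, in canonical order.
#' @export
#' @examples
#' activity_codes()
activity_codes <- function() {
  c("dws", "jog", "sit", "std", "ups", "wlk")
}

#' @rdname activity_codes
#' @return `activity_labels()`: a data.frame with columns `code` and
#'   `display_name`, one row per class, in canonical order.
#' @export
activity_labels <- function() {
  data.frame(
    code = activity_codes(),
    display_name = c("downstairs", "jogging", "sitting", "standing",
                     "upstairs", "walking"),
    stringsAsFactors = FALSE
  )
}

#' Coerce and validate activity codes
#'
#' @param x character vector of class codes.
#' @return `x`, validated.
#' @keywords internal
as_activity_code <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), activity_codes())
  if (length(bad) > 0) {
    stop("unknown activity code(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(activity_codes(), collapse = ", "), ")",
         call. = FALSE)
  }
  x
}

#' Activity factor with canonical level order
#' @param x character vector of codes.
#' @keywords internal
activity_factor <- function(x) {
  factor(as_activity_code(x), levels = activity_codes())
}

#' The default 6-channel IMU channel set
#'
#' Channels are ordered accelerometer first (x, y, z; m/s^2), then
#' gyroscope rotation rates (roll, pitch, yaw; rad/s). Sensor groups are
#' contiguous in the ordering. A `channel_set` is a data.frame with
#' columns `name`, `unit`, `sensor_group`.
#'
#' @return A `channel_set` data.frame with 6 rows.
#' @export
#' @examples
#' default_channels()
default_channels <- function() {
  cs <- data.frame(
    name = c("acc_x", "acc_y", "acc_z", "rot_roll", "rot_pitch", "rot_yaw"),
    unit = c(rep("m/s^2", 3), rep("rad/s", 3)),
    sensor_group = c(rep("accelerometer", 3), rep("gyroscope", 3)),
    stringsAsFactors = FALSE
  )
  class(cs) <- c("channel_set", "data.frame")
  cs
}

#' Validate a channel set
#' @param cs a channel_set data.frame.
#' @keywords internal
validate_channel_set <- function(cs) {
  stopifnot(is.data.frame(cs),
            all(c("name", "unit", "sensor_group") %in% names(cs)))
  if (anyDuplicated(cs$name)) stop("channel names must be unique", call. = FALSE)
  groups <- c("accelerometer", "gyroscope", "magnetometer")
  if (!all(cs$sensor_group %in% groups)) {
    stop("sensor_group must be one of: ", paste(groups, collapse = ", "),
         call. = FALSE)
  }
  # groups must be contiguous in the channel ordering
  r <- rle(cs$sensor_group)
  if (anyDuplicated(r$values)) {
    stop("sensor groups must be contiguous in the channel ordering",
         call. = FALSE)
  }
  invisible(cs)
}

#' Sensor groups present in a channel set
#' @param cs a channel_set.
#' @keywords internal
channel_groups <- function(cs) unique(cs$sensor_group)
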