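#' Direction vocabulary for memory-guided movement tasks
#'
#' Eight peripheral targets spaced 45 degrees apart plus a CENTER label.
#' CENTER is never a cue; it can only arise as a multicoder prediction when
#' both component classifiers vote for their middle class. The angle
#' convention is R = 0 degrees, counterclockwise positive (screen-up = 90).
#'
#' @format `peripheral_directions()` returns the eight labels in canonical
#'   order (counterclockwise from R); `direction_angle()` maps labels to
#'   degrees (NA for CENTER).
#' @name directions
NULL

.DIRECTIONS <- c("R", "UR", "U", "UL", "L", "DL", "D", "DR")
.DIRECTION_ANGLES <- c(R = 0, UR = 45, U = 90, UL = 135,
                       L = 180, DL = 225, D = 270, DR = 315)

# fixed class orders used for deterministic tie-breaking in the decoders
.VERTICAL_LEVELS <- c("UP", "MID", "DOWN")
.HORIZONTAL_LEVELS <- c("LEFT", "MID", "RIGHT")

.DECOMPOSE <- list(
  R  = c(vertical = "MID",  horizontal = "RIGHT"),
  UR = c(vertical = "UP",   horizontal = "RIGHT"),
  U  = c(vertical = "UP",   horizontal = "MID"),
  UL = c(vertical = "UP",   horizontal = "LEFT"),
  L  = c(vertical = "MID",  horizontal = "LEFT"),
  DL = c(vertical = "DOWN", horizontal = "LEFT"),
  D  = c(vertical = "DOWN", horizontal = "MID"),
  DR = c(vertical = "DOWN", horizontal = "RIGHT")
)

#' @rdname directions
#' @export
peripheral_directions <- function() .DIRECTIONS

#' @rdname directions
#' @param direction character vector of direction labels.
#' @return `direction_angle()`: numeric vector of angles in degrees
#'   (NA for CENTER).
#' @export
direction_angle <- function(direction) {
  stopifnot(is.character(direction))
  bad <- setdiff(direction, c(.DIRECTIONS, "CENTER"))
  if (length(bad) > 0) {
    stop("unknown direction label(s): ", paste(bad, collapse = ", "))
  }
  unname(.DIRECTION_ANGLES[direction])
}

#' Decompose peripheral directions into vertical and horizontal components
#'
#' The eight-direction multicoder predicts the vertical (UP/MID/DOWN) and
#' horizontal (LEFT/MID/RIGHT) components of the intended movement with two
#' independent three-class models; this maps each peripheral direction to its
#' unique component pair. CENTER is rejected because it is never a cue.
#'
#' @param direction character vector of peripheral direction labels.
#' @return A tibble with columns `direction`, `vertical`, `horizontal`.
#' @seealso [combine_components()]
#' @examples
#' decompose_direction(c("UR", "L", "D"))
#' @export
decompose_direction <- function(direction) {
  stopifnot(is.character(direction))
  if (any(direction == "CENTER")) {
    stop("CENTER is not a cue direction and has no component decomposition")
  }
  bad <- setdiff(direction, .DIRECTIONS)
  if (length(bad) > 0) {
    stop("unknown direction label(s): ", paste(bad, collapse = ", "))
  }
  comp <- .DECOMPOSE[direction]
  tibble::tibble(
    direction = direction,
    vertical = unname(vapply(comp, `[[`, character(1), "vertical")),
    horizontal = unname(vapply(comp, `[[`, character(1), "horizontal"))
  )
}

#' Combine vertical and horizontal component predictions into a direction
#'
#' The inverse of [decompose_direction()] on the eight peripheral pairs;
#' the (MID, MID) pair maps to CENTER, a possible multicoder output that is
#' never among the cued targets.
#'
#' @param vertical character vector in {UP, MID, DOWN}.
#' @param horizontal character vector in {LEFT, MID, RIGHT}.
#' @return Character vector of direction labels (possibly CENTER).
#' @examples
#' combine_components("UP", "RIGHT")   # "UR"
#' combine_components("MID", "MID")    # "CENTER"
#' @export
combine_components <- function(vertical, horizontal) {
  stopifnot(is.character(vertical), is.character(horizontal),
            length(vertical) == length(horizontal))
  if (!all(vertical %in% .VERTICAL_LEVELS)) {
    stop("vertical labels must be in {UP, MID, DOWN}")
  }
  if (!all(horizontal %in% .HORIZONTAL_LEVELS)) {
    stop("horizontal labels must be in {LEFT, MID, RIGHT}")
  }
  key <- paste(vertical, horizontal, sep = "/")
  lut <- c("MID/RIGHT" = "R", "UP/RIGHT" = "UR", "UP/MID" = "U",
           "UP/LEFT" = "UL", "MID/LEFT" = "L", "DOWN/LEFT" = "DL",
           "DOWN/MID" = "D", "DOWN/RIGHT" = "DR", "MID/MID" = "CENTER")
  unname(lut[key])
}

#' Absolute angular error between cued and predicted directions
#'
#' Minimal absolute angle between the two labels, one of
#' {0, 45, 90, 135, 180} degrees. A CENTER prediction scores 180 degrees
#' (the conservative convention: a CENTER prediction is always maximally
#' wrong). The cue must be peripheral.
#'
#' @param cue character vector of peripheral cue labels.
#' @param prediction character vector of predicted labels (may include CENTER).
#' @return Numeric vector of absolute angular errors in degrees.
#' @examples
#' angular_error("U", c("U", "UR", "D"))  # 0 45 180
#' @export
angular_error <- function(cue, prediction) {
  stopifnot(is.character(cue), is.character(prediction))
  n <- max(length(cue), length(prediction))
  cue <- rep_len(cue, n)
  prediction <- rep_len(prediction, n)
  if (any(cue == "CENTER")) stop("cue must be a peripheral direction")
  a_cue <- direction_angle(cue)
  a_pred <- direction_angle(prediction)
  err <- abs(((a_cue - a_pred + 180) %% 360) - 180)
  err[prediction == "CENTER"] <- 180
  err
}
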