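# Gesture taxonomy. Eight specific propulsion gestures (PGs) arise from the
# bilateral combination of two basic per-arm strokes (forward, backward);
# everything else -- including fake propulsions (FPGs), which mimic a PG
# kinematically but never touch the hand rim -- counts as dance.

#' Propulsion gesture labels
#'
#' The eight specific propulsion gestures recognized by the pipeline, in
#' their canonical numbering order (ids 1-8; "dance" is id 9).
#'
#' @return Character vector of the eight propulsion gesture labels.
#' @export
#' @examples
#' propulsion_gestures()
propulsion_gestures <- function() {
  c("left-forward", "left-backward", "right-forward", "right-backward",
    "forward", "backward", "clockwise", "anticlockwise")
}

# id lookup, 1-8 for PGs, 9 for dance
gesture_id_table <- function() {
  stats::setNames(seq_len(9L), c(propulsion_gestures(), "dance"))
}

#' Numeric id of a gesture label
#'
#' @param label Gesture label ("left-forward", ..., "anticlockwise", "dance").
#' @return Integer id in 1..9 (9 = dance).
#' @export
gesture_id <- function(label) {
  tab <- gesture_id_table()
  bad <- setdiff(label, names(tab))
  if (length(bad) > 0) {
    stop("unknown gesture label(s): ", paste(bad, collapse = ", "))
  }
  unname(tab[label])
}

#' Basic per-side classifier labels
#'
#' @return The three-class label set used by each side classifier.
#' @export
basic_labels <- function() c("forward", "backward", "dance")

# Which arms a gesture engages. FPG variants ("fpg-<base>") engage the same
# arms as their base gesture but without rim contact.
gesture_sides <- function(label) {
  base <- sub("^fpg-", "", label)
  switch(base,
    "left-forward" = ,
    "left-backward" = "left",
    "right-forward" = ,
    "right-backward" = "right",
    "forward" = ,
    "backward" = ,
    "clockwise" = ,
    "anticlockwise" = c("left", "right"),
    "dance" = character(0),
    stop("unknown gesture label: ", label)
  )
}

# Basic stroke performed by one arm during a gesture. During a clockwise
# turn the left wheel is pushed forward and the right wheel backward;
# anticlockwise is the mirror image.
side_basic_label <- function(label, side) {
  side <- match.arg(side, c("left", "right"))
  base <- sub("^fpg-", "", label)
  if (!side %in% gesture_sides(base)) {
    return("dance")
  }
  if (base %in% c("forward", "left-forward", "right-forward")) {
    return("forward")
  }
  if (base %in% c("backward", "left-backward", "right-backward")) {
    return("backward")
  }
  if (base == "clockwise") {
    return(if (side == "left") "forward" else "backward")
  }
  if (base == "anticlockwise") {
    return(if (side == "left") "backward" else "forward")
  }
  "dance"
}
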