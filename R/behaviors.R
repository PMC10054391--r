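#' The behavior catalogue (ethogram)
#'
#' Twelve dog behaviors, each assigned to the `active` or `static`
#' category. The order of `behavior_labels()` is the canonical order of
#' probability columns (`p_barking` ... `p_idle`) in behavior logs.
#'
#' @return `behavior_labels()`: character vector of the 12 labels.
#'   `behavior_categories()`: named character vector mapping each label
#'   to `"active"` or `"static"`.
#' @export
behavior_labels <- function() {
  c("barking", "door_biting", "door_scratching", "engaging_toy",
    "grooming", "wall_bouncing", "shaking_off", "standing_up", "walking",
    "sleeping", "lying_down", "idle")
}

#' @rdname behavior_labels
#' @export
behavior_categories <- function() {
  c(barking = "active", door_biting = "active", door_scratching = "active",
    engaging_toy = "active", grooming = "active", wall_bouncing = "active",
    shaking_off = "active", standing_up = "active", walking = "active",
    sleeping = "static", lying_down = "static", idle = "static")
}

prob_cols <- function() paste0("p_", behavior_labels())
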