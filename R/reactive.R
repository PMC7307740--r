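#' Reward-seeking Braitenberg behavior
#'
#' Crossed excitatory / direct inhibitory wiring between one pair of reward
#' sensors and the wheels, on top of a forward speed constant `f`:
#' `m_left = f + s_right - s_left`, `m_right = f + s_left - s_right`. The
#' wheel opposite the stronger sensor speeds up, turning the agent toward
#' the stimulus; with no stimulus the agent drives straight at speed `f`.
#'
#' @param s_left,s_right Sensor activations in `[0, 1]`.
#' @param f Forward speed constant (default 0.3).
#' @return Named numeric `c(m_left, m_right)`.
#' @export
#' @examples
#' reward_seeking(0, 0.5) # turn toward the right-side spot
reward_seeking <- function(s_left, s_right, f = 0.3) {
  c(m_left = f + s_right - s_left, m_right = f + s_left - s_right)
}

#' Collision-avoidance Braitenberg behavior
#'
#' Direct excitatory / crossed inhibitory wiring from the agent-proximity
#' sensors: `m_left = f + sA_left - sA_right`,
#' `m_right = f + sA_right - sA_left`. The wheel on the same side as the
#' stronger sensor speeds up, turning the agent away from the partner.
#'
#' @param sA_left,sA_right Agent-proximity activations in `[0, 1]`.
#' @param f Forward speed constant (default 0.3).
#' @return Named numeric `c(m_left, m_right)`.
#' @export
#' @examples
#' collision_avoidance(0.5, 0) # veer away from the left
collision_avoidance <- function(sA_left, sA_right, f = 0.3) {
  c(m_left = f + sA_left - sA_right, m_right = f + sA_right - sA_left)
}

#' Inhibition mask implied by an adaptive-layer action
#'
#' The inhibitor function is the top-down interface between the layers:
#' committing to the high spot shuts down the low-reward-seeking behavior
#' and vice versa; the `none` action leaves every reactive behavior active.
#' Collision avoidance is never inhibited.
#'
#' @param action One of `"go_high"`, `"go_low"`, `"none"`.
#' @return A list with logical fields `high_seek_active`, `low_seek_active`.
#' @export
#' @examples
#' inhibition_for("go_high")
inhibition_for <- function(action) {
  action <- match.arg(action, crl_actions())
  switch(action,
         go_high = list(high_seek_active = TRUE, low_seek_active = FALSE),
         go_low = list(high_seek_active = FALSE, low_seek_active = TRUE),
         none = list(high_seek_active = TRUE, low_seek_active = TRUE))
}

#' Combine the reactive behaviors under an inhibition mask
#'
#' Active behaviors superpose additively: each contributes its differential
#' wheel term while the forward constant `f` enters once. Inhibited
#' attractors contribute nothing; avoidance is always active. The summed
#' command is clamped to `[m_min, m_max]`.
#'
#' @param sensors Named vector from [read_sensors()].
#' @param mask Mask from [inhibition_for()].
#' @param f Forward speed constant.
#' @param m_min,m_max Clamp bounds.
#' @return Named numeric `c(m_left, m_right)`.
#' @export
#' @examples
#' s <- c(sH_left = 0, sH_right = 0.5, sL_left = 0, sL_right = 0,
#'        sA_left = 0.2, sA_right = 0)
#' combine_behaviors(s, inhibition_for("none"))
combine_behaviors <- function(sensors, mask, f = 0.3, m_min = -1, m_max = 1) {
  dl <- sensors[["sA_left"]] - sensors[["sA_right"]]
  if (mask$high_seek_active)
    dl <- dl + sensors[["sH_right"]] - sensors[["sH_left"]]
  if (mask$low_seek_active)
    dl <- dl + sensors[["sL_right"]] - sensors[["sL_left"]]
  c(m_left = min(max(f + dl, m_min), m_max),
    m_right = min(max(f - dl, m_min), m_max))
}
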