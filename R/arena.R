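#' Arena configuration for the embodied game
#'
#' Builds the configuration of the continuous 2D arena in which two
#' differential-drive agents compete for two reward spots. The geometry is
#' mirror-symmetric about the vertical midline of the arena: the two spot
#' positions and the two start poses are reflections of each other, so
#' neither agent is favoured by construction.
#'
#' Reward spots are sensed at long range, the bigger high-reward spot from
#' farther than the small one (`sensor_range_high` vs `sensor_range_low`),
#' while the partner agent is sensed by short-range proximity sensors
#' (`sensor_range_agent`), matching the collision-avoidance role of that
#' signal. Wheel commands are
#' perturbed each step by zero-mean Gaussian noise (`motor_noise_sd`) before
#' clamping to `[m_min, m_max]`; this breaks the exact mirror symmetry of a
#' dyad so that the spot each agent commits to is stochastic round by round.
#'
#' @param width,height Arena size in length units.
#' @param agent_radius Body radius of each agent.
#' @param spot_positions List of two `c(x, y)` points, mirror images about
#'   the vertical midline `x = width / 2`.
#' @param agent_start_poses List of two `c(x, y, heading)` start poses,
#'   mirror images about the vertical midline (headings reflected too).
#' @param tie_radius Radius of the tie circle around each spot; a round in
#'   which the loser sits inside the winner's circle is a tie.
#' @param spot_reach_radius Distance at which a spot counts as reached.
#' @param sensor_range_high,sensor_range_low Linear-falloff sensing
#'   ranges of the high- and the low-reward spot. The high spot is the
#'   physically bigger target (Battle-of-the-Exes arenas draw it bigger),
#'   so it is detectable from farther away; the contrast between the two
#'   ranges is what lets an uncommitted agent be captured by the big spot
#'   unless the small one is competitive from where it stands.
#' @param sensor_range_agent Range of the agent-proximity sensors.
#' @param sensor_halfangle Angular offset of the left/right sensor axes from
#'   the heading, radians.
#' @param dt Integration step, seconds.
#' @param speed_scale Length per second produced by a unit wheel command.
#' @param wheelbase Distance between the two wheels.
#' @param max_steps Steps after which a round times out.
#' @param motor_noise_sd Standard deviation of the per-step wheel noise.
#' @param heading_jitter Half-width (radians) of the uniform perturbation
#'   added to each agent's nominal start heading at the beginning of every
#'   round: agents do not line up perfectly between rounds, and which spot
#'   an uncommitted agent locks onto is decided by this initial gaze.
#' @param m_min,m_max Clamp bounds for wheel commands.
#'
#' @return An object of class `crl_arena` (a named list).
#' @export
#' @examples
#' cfg <- arena_config()
#' cfg$spot_positions
arena_config <- function(width = 20, height = 20, agent_radius = 0.5,
                         spot_positions = list(c(7, 14), c(13, 14)),
                         agent_start_poses = list(c(8, 2, pi / 2),
                                                  c(12, 2, pi / 2)),
                         tie_radius = 2.4, spot_reach_radius = 1,
                         sensor_range_high = 17.8, sensor_range_low = 13,
                         sensor_range_agent = 0.8,
                         sensor_halfangle = pi / 4,
                         dt = 0.1, speed_scale = 1,
                         wheelbase = 2 * agent_radius, max_steps = 600,
                         motor_noise_sd = 0.2, heading_jitter = 0.5,
                         m_min = -1, m_max = 1) {
  cfg <- list(width = width, height = height, agent_radius = agent_radius,
              spot_positions = spot_positions,
              agent_start_poses = agent_start_poses,
              tie_radius = tie_radius, spot_reach_radius = spot_reach_radius,
              sensor_range_high = sensor_range_high,
              sensor_range_low = sensor_range_low,
              sensor_range_agent = sensor_range_agent,
              sensor_halfangle = sensor_halfangle,
              dt = dt, speed_scale = speed_scale, wheelbase = wheelbase,
              max_steps = as.integer(max_steps),
              motor_noise_sd = motor_noise_sd,
              heading_jitter = heading_jitter, m_min = m_min, m_max = m_max)
  validate_arena(cfg)
  structure(cfg, class = "crl_arena")
}

validate_arena <- function(cfg) {
  stopifnot(cfg$tie_radius > cfg$spot_reach_radius,
            cfg$spot_reach_radius > 0,
            cfg$max_steps >= 1L,
            cfg$sensor_range_high > 0, cfg$sensor_range_low > 0,
            cfg$sensor_range_agent > 0,
            cfg$dt > 0, cfg$wheelbase > 0,
            cfg$m_max > cfg$m_min, cfg$motor_noise_sd >= 0,
            cfg$heading_jitter >= 0, cfg$heading_jitter < pi)
  mid <- cfg$width / 2
  mirror_xy <- function(p) c(2 * mid - p[1], p[2])
  sp <- cfg$spot_positions
  if (max(abs(mirror_xy(sp[[1]]) - sp[[2]])) > 1e-9)
    stop("spot_positions must be mirror images about the arena midline",
         call. = FALSE)
  ap <- cfg$agent_start_poses
  if (max(abs(mirror_xy(ap[[1]][1:2]) - ap[[2]][1:2])) > 1e-9 ||
      abs(wrap_angle(pi - ap[[1]][3]) - wrap_angle(ap[[2]][3])) > 1e-9)
    stop("agent_start_poses must be mirror images about the arena midline",
         call. = FALSE)
  invisible(cfg)
}

#' Wrap an angle to (-pi, pi]
#' @param x Angle(s) in radians.
#' @return Wrapped angle(s).
#' @keywords internal
wrap_angle <- function(x) {
  w <- ((x - pi) %% (2 * pi)) - pi
  w[w <= -pi] <- pi
  w
}

# One left/right sensor pair for a single entity: linear distance falloff
# times rectified cosine angular tuning, sensor axes at heading +/- halfangle.
sensor_pair <- function(px, py, heading, tx, ty, range, half) {
  dx <- tx - px
  dy <- ty - py
  d <- sqrt(dx * dx + dy * dy)
  prox <- 1 - d / range
  if (prox <= 0) return(c(0, 0))
  beta <- if (d < 1e-12) 0 else wrap_angle(atan2(dy, dx) - heading)
  c(prox * max(0, cos(beta - half)), prox * max(0, cos(beta + half)))
}

#' Read the six proximity sensors of an agent
#'
#' Computes the left/right activations for the high-reward spot, the
#' low-reward spot and the other agent. Each activation is
#' `max(0, 1 - d/range) * max(0, cos(beta -/+ halfangle))` where `d` is the
#' centre distance and `beta` the bearing of the entity relative to the
#' heading (positive = left). Spots use their per-spot ranges, the partner
#' agent `cfg$sensor_range_agent`; `range_high`/`range_low` override the
#' per-spot ranges when supplied.
#'
#' @param pose_self,pose_other Numeric `c(x, y, heading)` poses.
#' @param spot_high,spot_low Numeric `c(x, y)` spot centres.
#' @param cfg An [arena_config()] object.
#' @param range_high,range_low Sensing ranges of the two spots.
#' @return Named numeric vector
#'   `c(sH_left, sH_right, sL_left, sL_right, sA_left, sA_right)`, all in
#'   `[0, 1]`.
#' @export
#' @examples
#' cfg <- arena_config()
#' read_sensors(c(10, 3, pi / 2), c(11, 3, pi / 2),
#'              c(7, 14), c(13, 14), cfg)
read_sensors <- function(pose_self, pose_other, spot_high, spot_low, cfg,
                         range_high = cfg$sensor_range_high,
                         range_low = cfg$sensor_range_low) {
  if (!all(is.finite(c(pose_self, pose_other))))
    stop("non-finite agent pose: corrupted simulation state", call. = FALSE)
  h <- sensor_pair(pose_self[1], pose_self[2], pose_self[3],
                   spot_high[1], spot_high[2],
                   range_high, cfg$sensor_halfangle)
  l <- sensor_pair(pose_self[1], pose_self[2], pose_self[3],
                   spot_low[1], spot_low[2],
                   range_low, cfg$sensor_halfangle)
  a <- sensor_pair(pose_self[1], pose_self[2], pose_self[3],
                   pose_other[1], pose_other[2],
                   cfg$sensor_range_agent, cfg$sensor_halfangle)
  c(sH_left = h[1], sH_right = h[2],
    sL_left = l[1], sL_right = l[2],
    sA_left = a[1], sA_right = a[2])
}

#' Advance a differential-drive agent by one Euler step
#'
#' Linear speed is `speed_scale * (m_left + m_right) / 2`, angular speed
#' `speed_scale * (m_right - m_left) / wheelbase`. The position is advanced
#' along the current heading for `dt` seconds, then clamped so the body
#' stays inside the arena; the heading is wrapped to `(-pi, pi]`.
#'
#' @param pose Numeric `c(x, y, heading)`.
#' @param cmd Numeric `c(m_left, m_right)` wheel commands (already clamped).
#' @param cfg An [arena_config()] object.
#' @return The new pose.
#' @export
#' @examples
#' step_kinematics(c(0.5, 0.5, 0), c(0.3, 0.3), arena_config())
step_kinematics <- function(pose, cmd, cfg) {
  if (!all(is.finite(cmd))) stop("non-finite motor command", call. = FALSE)
  v <- cfg$speed_scale * (cmd[1] + cmd[2]) / 2
  om <- cfg$speed_scale * (cmd[2] - cmd[1]) / cfg$wheelbase
  x <- pose[1] + v * cos(pose[3]) * cfg$dt
  y <- pose[2] + v * sin(pose[3]) * cfg$dt
  th <- wrap_angle(pose[3] + om * cfg$dt)
  r <- cfg$agent_radius
  c(min(max(x, r), cfg$width - r), min(max(y, r), cfg$height - r), th)
}

#' Check whether a round has ended
#'
#' A round ends when an agent comes within `spot_reach_radius` of a spot
#' (boundary inclusive) or when `steps` reaches `max_steps`.
#'
#' @param pose_a,pose_b Agent poses, `c(x, y, heading)`.
#' @param spot_high,spot_low Spot centres.
#' @param cfg An [arena_config()] object.
#' @param steps Steps elapsed so far in the round.
#' @return A list with `kind` (`"none"`, `"reached"` or `"timeout"`) and,
#'   when `kind == "reached"`, `reached`: a 2 x 2 logical matrix with rows
#'   `a`, `b` and columns `high`, `low` naming every agent-spot contact
#'   (both agents can reach in the same step; the game engine resolves
#'   that downstream).
#' @export
check_round_end <- function(pose_a, pose_b, spot_high, spot_low, cfg, steps) {
  stopifnot(steps <= cfg$max_steps)
  d2 <- function(p, s) sqrt(sum((p[1:2] - s)^2))
  m <- matrix(c(d2(pose_a, spot_high) <= cfg$spot_reach_radius,
                d2(pose_b, spot_high) <= cfg$spot_reach_radius,
                d2(pose_a, spot_low) <= cfg$spot_reach_radius,
                d2(pose_b, spot_low) <= cfg$spot_reach_radius),
              nrow = 2, dimnames = list(c("a", "b"), c("high", "low")))
  if (any(m)) return(list(kind = "reached", reached = m))
  if (steps >= cfg$max_steps) return(list(kind = "timeout"))
  list(kind = "none")
}
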