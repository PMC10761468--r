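#' Four-zone open-loop SMB configuration
#'
#' Stream flow rates and switching time of a four-zone open-loop simulated
#' moving bed with one column per zone. The raffinate flow follows from the
#' overall liquid mass balance (diluent + feed = extract + raffinate +
#' waste); give either `raffinate_flow` or leave it `NULL` to have it
#' solved.
#'
#' @param diluent_flow,extract_flow,feed_flow,waste_flow Stream flow rates
#'   in uL/min.
#' @param raffinate_flow Raffinate flow in uL/min, or `NULL` to solve from
#'   the balance.
#' @param switching_time Port switching interval in s.
#' @return An object of class `smb_config`.
#' @examples
#' smb_config(122, 44, 15, 63, switching_time = 120)
#' @export
smb_config <- function(diluent_flow, extract_flow, feed_flow, waste_flow,
                       raffinate_flow = NULL, switching_time = 120) {
  if (switching_time <= 0) stop("switching_time must be > 0", call. = FALSE)
  solved <- solve_raffinate_flow(diluent_flow, extract_flow, feed_flow,
                                 waste_flow)
  if (is.null(raffinate_flow)) {
    raffinate_flow <- solved
  } else if (abs(raffinate_flow - solved) > 1e-9) {
    stop("stream flows violate the overall balance: raffinate should be ",
         solved, " uL/min", call. = FALSE)
  }
  cfg <- structure(list(diluent_flow = diluent_flow,
                        extract_flow = extract_flow,
                        feed_flow = feed_flow,
                        raffinate_flow = raffinate_flow,
                        waste_flow = waste_flow,
                        switching_time = switching_time,
                        n_zones = 4L, columns_per_zone = 1L,
                        open_loop = TRUE),
                   class = "smb_config")
  zone_flows(cfg)  # validates zone feasibility
  cfg
}

#' Raffinate flow from the overall liquid mass balance
#'
#' In the hyphenated setup the raffinate outlet feeds the ESI source
#' directly and cannot be pressure-controlled; its flow is whatever the
#' overall balance leaves: diluent + feed - extract - waste.
#'
#' @param diluent,extract,feed,waste Stream flow rates in uL/min (>= 0).
#' @return Raffinate flow rate in uL/min.
#' @examples
#' solve_raffinate_flow(122, 44, 15, 63)  # 30
#' @export
solve_raffinate_flow <- function(diluent, extract, feed, waste) {
  v <- c(diluent, extract, feed, waste)
  if (any(!is.finite(v)) || any(v < 0))
    stop("stream flows must be nonnegative", call. = FALSE)
  r <- diluent + feed - extract - waste
  if (r < 0)
    stop("infeasible flows: overall balance gives negative raffinate (",
         r, " uL/min)", call. = FALSE)
  r
}

#' Zone flow rates from the node balances
#'
#' Q1 = diluent; Q2 = Q1 - extract; Q3 = Q2 + feed; Q4 = Q3 - raffinate,
#' and Q4 must equal the waste flow. All zone flows must be positive.
#'
#' @param cfg An [smb_config()].
#' @return Named numeric vector `c(Q1, Q2, Q3, Q4)` in uL/min.
#' @examples
#' zone_flows(smb_config(122, 44, 15, 63))
#' @export
zone_flows <- function(cfg) {
  stopifnot(inherits(cfg, "smb_config"))
  q1 <- cfg$diluent_flow
  q2 <- q1 - cfg$extract_flow
  q3 <- q2 + cfg$feed_flow
  q4 <- q3 - cfg$raffinate_flow
  if (abs(q4 - cfg$waste_flow) > 1e-9)
    stop("inconsistent configuration: zone 4 flow (", q4,
         ") does not match the waste flow (", cfg$waste_flow, ")",
         call. = FALSE)
  q <- c(Q1 = q1, Q2 = q2, Q3 = q3, Q4 = q4)
  if (any(q <= 0))
    stop("infeasible configuration: zone flow(s) ",
         paste(names(q)[q <= 0], collapse = ", "), " nonpositive",
         call. = FALSE)
  q
}

#' Flow-rate ratio m_j of triangle theory
#'
#' m = (Q t_switch - V eps_int) / (V (1 - eps_int)): net fluid volume moved
#' per switch relative to the solid-phase-equivalent volume. For linear
#' (SEC) systems the separation constraints are inequalities on the m_j
#' against the species' pore-phase capacities H_i = eps_p K_d,i.
#'
#' @param Q Zone flow rate in uL/min.
#' @param t_switch Switching time in s.
#' @param col A [column_params()] object.
#' @return Dimensionless flow-rate ratio.
#' @examples
#' flow_ratio(93, 120, column_params())  # ~0.237
#' @export
flow_ratio <- function(Q, t_switch, col) {
  stopifnot(inherits(col, "column_params"))
  V <- column_volume(col)
  eps <- col$interstitial_porosity
  (Q / 60 * t_switch - V * eps) / (V * (1 - eps))
}

# Inverse of flow_ratio: zone flow (uL/min) giving ratio m.
flow_from_ratio <- function(m, t_switch, col) {
  V <- column_volume(col)
  eps <- col$interstitial_porosity
  (m * V * (1 - eps) + V * eps) / t_switch * 60
}

#' Triangle-theory operating point for SEC desalting
#'
#' Places the four flow-rate ratios for a linear (size-exclusion) system
#' with pore-phase capacities H_i = eps_p K_d,i. Zone 1 must move fluid
#' faster than the retained species (m1 > H_strong) and zones 2/3 bracket
#' the separation region: m2 and m3 are placed symmetrically inside
#' (H_weak, H_strong), shrunk by the safety margin, which maximizes the
#' feed flow m3 - m2 under that margin. When a fixed raffinate flow is
#' requested (the open-loop fourth zone decouples it from zone 3), zone 4
#' is set to the largest flow that still retains the weak species
#' (m4 <= H_weak, shrunk by the margin) and zone 3 follows from
#' Q3 = Q4 + raffinate; the symmetric m3 is used when it is smaller.
#'
#' @param col A [column_params()] object.
#' @param weak A [species_params()] for the raffinate (less retained)
#'   species, here the protein.
#' @param strong A [species_params()] for the extract (more retained)
#'   species, here the buffer salt.
#' @param t_switch Switching time in s.
#' @param raffinate_target Fixed raffinate flow in uL/min, or `NULL` to use
#'   the symmetric design throughout.
#' @param safety Fractional safety margin in \[0, 0.5).
#' @return An object of class `operating_point`: list with `m` (m1..m4),
#'   `zone_flows` (Q1..Q4, uL/min), and `config` (an [smb_config()]).
#' @examples
#' mb <- species_params("mb", 17566, pore_access = 0)
#' tris <- species_params("tris", 121.14, pore_access = 1)
#' triangle_design(column_params(), mb, tris, t_switch = 120,
#'                 raffinate_target = 30, safety = 0.2)
#' @export
triangle_design <- function(col, weak, strong, t_switch,
                            raffinate_target = NULL, safety = 0.1) {
  stopifnot(inherits(col, "column_params"),
            inherits(weak, "species_params"),
            inherits(strong, "species_params"))
  if (safety < 0 || safety >= 0.5)
    stop("safety must lie in [0, 0.5)", call. = FALSE)
  epsp <- col$particle_porosity
  h_w <- epsp * weak$pore_access
  h_s <- epsp * strong$pore_access
  if (h_w >= h_s)
    stop("no separation region: H_weak (", h_w, ") >= H_strong (", h_s, ")",
         call. = FALSE)
  dh <- h_s - h_w
  m1 <- h_s * (1 + safety)
  # fully excluded weak species (H = 0): the relative margin degenerates,
  # so take the margin on the separation interval instead
  m4 <- if (h_w > 0) h_w * (1 - safety) else -safety * dh
  m2 <- h_w + safety * dh
  m3 <- h_s - safety * dh

  q1 <- flow_from_ratio(m1, t_switch, col)
  q2 <- flow_from_ratio(m2, t_switch, col)
  if (!is.null(raffinate_target)) {
    q4_cap <- flow_from_ratio(m4, t_switch, col)
    q3_cap <- q4_cap + raffinate_target
    m3_cap <- flow_ratio(q3_cap, t_switch, col)
    if (m3_cap <= m2)
      stop("infeasible design: raffinate target forces m3 (", round(m3_cap, 4),
           ") below m2 (", round(m2, 4), ")", call. = FALSE)
    m3 <- min(m3, m3_cap)
  }
  q3 <- flow_from_ratio(m3, t_switch, col)
  q4 <- if (is.null(raffinate_target)) flow_from_ratio(m4, t_switch, col)
        else q3 - raffinate_target
  m4 <- flow_ratio(q4, t_switch, col)

  flows <- c(diluent = q1, extract = q1 - q2, feed = q3 - q2,
             raffinate = q3 - q4, waste = q4)
  if (any(flows <= 0))
    stop("infeasible design: stream flow(s) ",
         paste(names(flows)[flows <= 0], collapse = ", "), " nonpositive",
         call. = FALSE)
  cfg <- smb_config(flows[["diluent"]], flows[["extract"]], flows[["feed"]],
                    flows[["waste"]], raffinate_flow = flows[["raffinate"]],
                    switching_time = t_switch)
  structure(list(m = c(m1 = m1, m2 = m2, m3 = m3, m4 = m4),
                 H = c(weak = h_w, strong = h_s),
                 zone_flows = zone_flows(cfg),
                 stream_flows = flows,
                 config = cfg),
            class = "operating_point")
}

#' Named operating-point presets
#'
#' `"reference"` is the experimentally optimized desalting point used
#' throughout the package's worked examples: diluent 122, extract 44, feed
#' 15, raffinate 30, waste 63 uL/min, switching time 120 s.
#'
#' @param name Preset name (currently `"reference"`).
#' @return An [smb_config()].
#' @export
smb_preset <- function(name = "reference") {
  switch(match.arg(name, "reference"),
         reference = smb_config(diluent_flow = 122, extract_flow = 44,
                                feed_flow = 15, waste_flow = 63,
                                raffinate_flow = 30, switching_time = 120))
}
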