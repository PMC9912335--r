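# Telegraph-state kinetic model of a NEOtrap recording.
#
# The current trace visits discrete levels: the open pore (I0), an optional
# attempted-docking level, the docked level (origami sphere on the pore), and
# the protein-trapped level (a second, deeper current drop). Transitions are
# Poissonian, so the state sequence is a continuous-time Markov chain and all
# dwell times are exponential.

.STATE_OPEN    <- 1L
.STATE_ATTEMPT <- 2L
.STATE_DOCKED  <- 3L
.STATE_TRAPPED <- 4L
.STATE_NAMES   <- c("open", "attempt", "docked", "trapped")

#' Kinetic scheme for trace synthesis
#'
#' Defines the current levels and Poisson rates of the open / docked /
#' trapped telegraph process. Levels are fractions of the open-pore current
#' `i0_pA`; the trapped level is a fraction of the docked level (the trapped
#' protein deepens the blockade).
#'
#' @param i0_pA Open-pore current at the reference bias (pA).
#' @param docked_frac Docked level I_d as a fraction of I0 (0, 1].
#' @param attempt_frac Optional attempted-docking level I_a as a fraction of
#'   I0, or NULL for a scheme without a distinct attempt state.
#' @param trapped_frac Trapped level as a fraction of the docked level (< 1).
#' @param dock_rate Docking rate, open -> docked (or -> attempt), 1/s.
#' @param undock_rate Undocking rate at positive bias, 1/s (0 for a
#'   cholesterol-locked sphere).
#' @param undock_rate_neg Undocking rate while the bias is negative, 1/s
#'   (large for a bare sphere that is ejected on voltage inversion, 0 for a
#'   cholesterol-anchored one).
#' @param lock_rate attempt -> docked locking rate, 1/s (only with an attempt
#'   state).
#' @param capture_rate Protein capture rate k_c, docked -> trapped, 1/s.
#' @param escape_rate Protein escape rate k_e, trapped -> docked, 1/s.
#' @param v_ref_mV Reference bias at which `i0_pA` is defined (mV).
#' @return Object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(i0_pA = 1500,
                           docked_frac = 0.83,
                           attempt_frac = NULL,
                           trapped_frac = 0.8,
                           dock_rate = 0,
                           undock_rate = 0,
                           undock_rate_neg = 0,
                           lock_rate = 0,
                           capture_rate = 0,
                           escape_rate = 0,
                           v_ref_mV = 100) {
  stopifnot(i0_pA > 0, docked_frac > 0, docked_frac <= 1,
            trapped_frac > 0, trapped_frac < 1,
            dock_rate >= 0, undock_rate >= 0, undock_rate_neg >= 0,
            lock_rate >= 0, capture_rate >= 0, escape_rate >= 0)
  if (!is.null(attempt_frac)) stopifnot(attempt_frac > 0, attempt_frac <= 1)
  structure(list(i0_pA = i0_pA, docked_frac = docked_frac,
                 attempt_frac = attempt_frac, trapped_frac = trapped_frac,
                 dock_rate = dock_rate, undock_rate = undock_rate,
                 undock_rate_neg = undock_rate_neg, lock_rate = lock_rate,
                 capture_rate = capture_rate, escape_rate = escape_rate,
                 v_ref_mV = v_ref_mV),
            class = "kinetic_scheme")
}

# level of each state as a fraction of I0 at the reference bias
state_level_frac <- function(scheme) {
  c(1,
    if (is.null(scheme$attempt_frac)) NA_real_ else scheme$attempt_frac,
    scheme$docked_frac,
    scheme$docked_frac * scheme$trapped_frac)
}

# transition rate matrix rows = from-state, given the sign of the bias
scheme_rates <- function(scheme, positive_bias = TRUE) {
  q <- matrix(0, 4, 4)
  has_attempt <- !is.null(scheme$attempt_frac)
  if (positive_bias) {
    q[.STATE_OPEN, if (has_attempt) .STATE_ATTEMPT else .STATE_DOCKED] <- scheme$dock_rate
    if (has_attempt) {
      q[.STATE_ATTEMPT, .STATE_OPEN]   <- scheme$undock_rate
      q[.STATE_ATTEMPT, .STATE_DOCKED] <- scheme$lock_rate
    }
    q[.STATE_DOCKED, .STATE_OPEN]    <- scheme$undock_rate
    q[.STATE_DOCKED, .STATE_TRAPPED] <- scheme$capture_rate
    q[.STATE_TRAPPED, .STATE_DOCKED] <- scheme$escape_rate
  } else {
    # negative bias: no docking or capture; a bare sphere is ejected
    if (has_attempt) q[.STATE_ATTEMPT, .STATE_OPEN] <- max(scheme$undock_rate_neg,
                                                           scheme$undock_rate)
    q[.STATE_DOCKED, .STATE_OPEN]    <- scheme$undock_rate_neg
    q[.STATE_TRAPPED, .STATE_DOCKED] <- scheme$escape_rate
  }
  q
}

#' Simulate the telegraph state path of a NEOtrap recording
#'
#' Exact (Gillespie-style) stochastic simulation of the continuous-time Markov
#' chain defined by a kinetic scheme: in each state the waiting time to the
#' next transition is exponential with the total outgoing rate, and the
#' destination is drawn with probability proportional to the individual rates.
#' If a voltage protocol is supplied, rates switch at segment boundaries
#' according to the bias sign (the exponential clock is memoryless, so
#' redrawing at boundaries is exact).
#'
#' @param scheme A `kinetic_scheme`.
#' @param duration Total simulated time (s). Ignored if `protocol` is given
#'   (its total duration is used).
#' @param seed Integer RNG seed; identical inputs and seed give identical paths.
#' @param protocol Optional `voltage_protocol`; default is a constant positive
#'   bias at the scheme reference voltage.
#' @param initial_state One of "open", "docked", "trapped".
#' @return data.frame of class `state_path` with columns `t_start`, `t_end`,
#'   `state` (integer), `state_name`; attributes `scheme`, `duration`.
#' @export
simulate_state_path <- function(scheme, duration, seed,
                                protocol = NULL, initial_state = "docked") {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (is.null(protocol)) {
    stopifnot(duration > 0)
    protocol <- voltage_protocol(duration, scheme$v_ref_mV)
  }
  seg_end <- cumsum(protocol$duration_s)
  seg_start <- c(0, seg_end[-length(seg_end)])
  duration <- seg_end[length(seg_end)]

  initial_state <- match.arg(initial_state, c("open", "docked", "trapped"))
  state <- c(open = .STATE_OPEN, docked = .STATE_DOCKED,
             trapped = .STATE_TRAPPED)[[initial_state]]

  set.seed(as.integer(seed %% .Machine$integer.max))
  qs <- list(pos = scheme_rates(scheme, TRUE), neg = scheme_rates(scheme, FALSE))

  t_now <- 0
  ts_cap <- 1024L
  t_start_v <- numeric(ts_cap); state_v <- integer(ts_cap); nrec <- 0L
  push <- function(t0, s) {
    nrec <<- nrec + 1L
    if (nrec > ts_cap) {
      ts_cap <<- ts_cap * 2L
      length(t_start_v) <<- ts_cap; length(state_v) <<- ts_cap
    }
    t_start_v[nrec] <<- t0; state_v[nrec] <<- s
  }
  push(0, state)

  seg <- 1L
  while (t_now < duration) {
    q <- if (protocol$voltage_mV[seg] >= 0) qs$pos else qs$neg
    rates <- q[state, ]
    rtot <- sum(rates)
    t_seg_end <- seg_end[seg]
    if (rtot <= 0) {
      t_now <- t_seg_end
    } else {
      wait <- stats::rexp(1, rtot)
      if (t_now + wait >= t_seg_end) {
        t_now <- t_seg_end
      } else {
        t_now <- t_now + wait
        state <- sample.int(4L, 1L, prob = rates)
        push(t_now, state)
      }
    }
    if (t_now >= t_seg_end && seg < length(seg_end)) seg <- seg + 1L
  }

  t_start <- t_start_v[seq_len(nrec)]
  st <- state_v[seq_len(nrec)]
  out <- data.frame(t_start = t_start,
                    t_end = c(t_start[-1], duration),
                    state = st,
                    state_name = .STATE_NAMES[st])
  attr(out, "scheme") <- scheme
  attr(out, "duration") <- duration
  attr(out, "protocol") <- protocol
  class(out) <- c("state_path", "data.frame")
  out
}

#' Dwell times of a state in a simulated path
#'
#' @param path A `state_path`.
#' @param state State name ("trapped" by default).
#' @param drop_truncated Drop sojourns cut off by the path start/end.
#' @return Numeric vector of dwell times (s).
#' @export
state_dwells <- function(path, state = "trapped", drop_truncated = TRUE) {
  idx <- which(path$state_name == state)
  if (!length(idx)) return(numeric(0))
  d <- path$t_end[idx] - path$t_start[idx]
  if (drop_truncated) {
    dur <- attr(path, "duration")
    keep <- path$t_start[idx] > 0 & path$t_end[idx] < dur
    d <- d[keep]
  }
  d
}
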