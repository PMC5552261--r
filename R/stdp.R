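#' STDP parameter set
#'
#' Parameters of the exponential spike-timing-dependent plasticity rule
#' with "mixed" weight dependence: multiplicative long-term potentiation
#' (LTP, soft ceiling at `w_max`) and additive long-term depression (LTD,
#' hard floor at 0 nA).
#'
#' Defaults follow the cortical projections of the full auditory model:
#' `tau_p = 15` ms, `tau_d = 25` ms, `alpha_p = 0.005`,
#' `alpha_d = -0.015`, `w_max = 60` nA. The reduced two-stage model uses
#' `alpha_d = -0.033`.
#'
#' @param tau_p,tau_d LTP / LTD time constants (ms), both `> 0`.
#' @param alpha_p LTP magnitude, `> 0`.
#' @param alpha_d LTD magnitude, `< 0`.
#' @param w_max Weight ceiling (nA), `> 0`.
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(tau_p = 15, tau_d = 25, alpha_p = 0.005,
                        alpha_d = -0.015, w_max = 60) {
  stopifnot(tau_p > 0, tau_d > 0, alpha_p > 0, alpha_d < 0, w_max > 0)
  structure(list(tau_p = tau_p, tau_d = tau_d, alpha_p = alpha_p,
                 alpha_d = alpha_d, w_max = w_max),
            class = "stdp_params")
}

#' @export
print.stdp_params <- function(x, ...) {
  cat(sprintf(
    "STDP (mixed, nearest-only): tau_p=%g ms tau_d=%g ms alpha_p=%g alpha_d=%g w_max=%g nA\n",
    x$tau_p, x$tau_d, x$alpha_p, x$alpha_d, x$w_max))
  invisible(x)
}

#' Exponential STDP scale factor
#'
#' Computes the signed scale factor `f(s)` for a post-minus-pre timing
#' difference `s` (ms), where pre times are delayed arrival times:
#' `f(s) = alpha_p exp(-s / tau_p)` for `s > 0` (LTP) and
#' `f(s) = alpha_d exp(s / tau_d)` for `s < 0` (LTD). `s = 0` (exact tie
#' at step resolution) is a no-op and returns 0.
#'
#' @param s Signed timing differences in ms (vectorised).
#' @param params An [stdp_params()] object.
#' @return Scale factors, same sign convention as `alpha_p`/`alpha_d`.
#' @examples
#' stdp_scale(15, stdp_params())   # 0.005 * exp(-1)
#' stdp_scale(-25, stdp_params())  # -0.015 * exp(-1)
#' @export
stdp_scale <- function(s, params = stdp_params()) {
  stopifnot(all(is.finite(s)))
  out <- numeric(length(s))
  ltp <- s > 0
  ltd <- s < 0
  out[ltp] <- params$alpha_p * exp(-s[ltp] / params$tau_p)
  out[ltd] <- params$alpha_d * exp(s[ltd] / params$tau_d)
  out
}

#' Mixed additive/multiplicative weight update
#'
#' Applies a scale factor from [stdp_scale()] to a weight: LTP is
#' multiplicative in the headroom, `w' = w + (w_max - w) * scale`; LTD is
#' additive, `w' = max(0, w + w_max * scale)`. The result always lies in
#' `[0, w_max]`.
#'
#' @param w Current weights (nA), each in `[0, w_max]`.
#' @param scale Signed scale factors (vectorised with `w`).
#' @param params An [stdp_params()] object.
#' @return Updated weights.
#' @export
stdp_apply <- function(w, scale, params = stdp_params()) {
  if (any(w < 0 | w > params$w_max))
    stop("weight outside [0, w_max]: upstream invariant breach")
  ltp <- scale > 0
  ltd <- scale < 0
  w2 <- w
  w2[ltp] <- w[ltp] + (params$w_max - w[ltp]) * scale[ltp]
  w2[ltd] <- pmax(0, w[ltd] + params$w_max * scale[ltd])
  w2
}

#' Nearest-only spike pairing with conduction delays
#'
#' Reference implementation of the pairing bookkeeping used online by the
#' simulation engine, exposed for testing and analysis. Pre-synaptic spike
#' times are converted to arrival times (`emission + delay`); each post
#' spike pairs for LTP with the most recent unused arrival per synapse,
#' and each arrival pairs for LTD with the most recent preceding post
#' spike. Each arrival is usable for at most one LTP pairing, and any
#' further pre-synaptic spike arriving within the STDP window of the last
#' counted arrival on the same synapse is ignored entirely (first-spike-only
#' rule).
#'
#' @param pre_times List of numeric vectors: per-synapse pre-synaptic
#'   emission times (ms), each sorted ascending.
#' @param post_times Sorted numeric vector of post-synaptic spike times (ms).
#' @param delays Numeric vector of per-synapse conduction delays (ms, >= 0).
#' @param params An [stdp_params()] object.
#' @param window Pairings with `|s|` beyond this many ms are skipped
#'   (negligible scale); default `7 * max(tau_p, tau_d)`.
#' @param blank First-spike-only window (ms): a further spike of the same
#'   cell arriving within `blank` of the previous counted arrival is
#'   ignored. Default `max(tau_p, tau_d)`, the STDP time-constant scale.
#' @return A data.frame with columns `synapse`, `time` (ms, when the update
#'   is applied), `s` (ms) and `scale`, ordered by application time.
#' @export
stdp_pair <- function(pre_times, post_times, delays,
                      params = stdp_params(),
                      window = 7 * max(params$tau_p, params$tau_d),
                      blank = max(params$tau_p, params$tau_d)) {
  stopifnot(length(pre_times) == length(delays), all(delays >= 0))
  if (is.unsorted(post_times)) stop("post_times must be sorted")
  events <- list()
  for (k in seq_along(pre_times)) {
    pt <- pre_times[[k]]
    if (length(pt) == 0) next
    if (is.unsorted(pt)) stop("pre_times[[", k, "]] must be sorted")
    arr <- pt + delays[k]
    last_seen <- -Inf
    pending <- NA_real_
    used <- TRUE
    # merge arrival and post events in time order; post processed after
    # arrivals at the same instant (an exact tie is s = 0, a no-op)
    for (t in sort(unique(c(arr, post_times)))) {
      if (any(abs(arr - t) < 1e-12)) {
        post_before <- post_times[post_times < t]
        last_post <- if (length(post_before)) max(post_before) else -Inf
        # first-spike-only: ignore further spikes of the cell within
        # `blank` of the previous counted arrival; a counted arrival is
        # the nearest LTP candidate and pairs for LTD with the last post
        first <- last_seen <= last_post || t - last_seen > blank
        if (first) {
          last_seen <- t
          pending <- t
          used <- FALSE
          if (is.finite(last_post)) {
            s <- last_post - t
            if (-s <= window)
              events[[length(events) + 1L]] <-
                data.frame(synapse = k, time = t, s = s,
                           scale = stdp_scale(s, params))
          }
        }
      }
      if (any(abs(post_times - t) < 1e-12)) {
        if (!used && !is.na(pending) && t > pending && t - pending <= window) {
          s <- t - pending
          used <- TRUE
          events[[length(events) + 1L]] <-
            data.frame(synapse = k, time = t, s = s,
                       scale = stdp_scale(s, params))
        }
      }
    }
  }
  if (length(events) == 0)
    return(data.frame(synapse = integer(), time = numeric(),
                      s = numeric(), scale = numeric()))
  out <- do.call(rbind, events)
  out[order(out$time, out$synapse), , drop = FALSE]
}
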