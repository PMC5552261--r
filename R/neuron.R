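#' Izhikevich neuron parameter presets
#'
#' Returns the constants of the Izhikevich point-neuron model for one of the
#' three cell classes used throughout the network: spike-frequency-adapting
#' excitatory cortical cells, Class-1 (integrator) excitatory subcortical
#' cells, and phasic-bursting inhibitory interneurons. All presets share a
#' 30 mV spike cutoff.
#'
#' @param name One of `"excitatory_cortical"`, `"excitatory_subcortical"`,
#'   `"inhibitory"`.
#' @return An object of class `izh_params`: a list with elements `a`
#'   (recovery time scale), `b` (recovery sensitivity), `c` (after-spike
#'   membrane reset, mV), `d` (after-spike recovery increment) and
#'   `threshold` (spike cutoff, mV).
#' @examples
#' izh_preset("excitatory_subcortical")
#' @export
izh_preset <- function(name = c("excitatory_cortical",
                                "excitatory_subcortical",
                                "inhibitory")) {
  name <- match.arg(name)
  p <- switch(name,
    excitatory_cortical    = list(a = 0.01, b = 0.2,  c = -65, d = 8),
    excitatory_subcortical = list(a = 0.02, b = -0.1, c = -55, d = 6),
    inhibitory             = list(a = 0.02, b = 0.25, c = -55, d = 0.05))
  p$threshold <- 30
  p$name <- name
  structure(p, class = "izh_params")
}

#' @export
print.izh_params <- function(x, ...) {
  cat(sprintf("Izhikevich parameters (%s): a=%g b=%g c=%g d=%g threshold=%g mV\n",
              x$name %||% "custom", x$a, x$b, x$c, x$d, x$threshold))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct custom Izhikevich parameters
#'
#' @param a,b,c,d Model constants (see [izh_preset()]).
#' @param threshold Spike cutoff in mV (30 by default).
#' @return An `izh_params` object.
#' @export
izh_params <- function(a, b, c, d, threshold = 30) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c), is.finite(d),
            is.finite(threshold))
  structure(list(a = a, b = b, c = c, d = d, threshold = threshold,
                 name = "custom"),
            class = "izh_params")
}

#' Resting state of an Izhikevich neuron
#'
#' Solves for the quiescent equilibrium of the membrane equation at zero
#' input: the stable root of `0.04 v^2 + (5 - b) v + 140 = 0` with
#' `u = b v`. Used to initialise neuron state at presentation onset.
#'
#' @param params An `izh_params` object.
#' @return A list with elements `v` (mV) and `u`.
#' @export
izh_rest <- function(params) {
  b <- params$b
  disc <- (5 - b)^2 - 4 * 0.04 * 140
  if (disc < 0)
    stop("no real rest point for these parameters (b = ", b, ")")
  roots <- (-(5 - b) + c(-1, 1) * sqrt(disc)) / (2 * 0.04)
  # stable root: d(dv/dt)/dv = 0.08 v + 5 - b < 0
  v <- roots[0.08 * roots + 5 - b < 0]
  if (length(v) == 0) v <- min(roots)
  v <- v[1]
  list(v = v, u = b * v)
}

#' Advance Izhikevich neurons by one Euler step
#'
#' One explicit forward-Euler step of the membrane and recovery equations
#' `dv/dt = 0.04 v^2 + 5 v + 140 - u + I`, `du/dt = a (b v - u)`, followed
#' by threshold detection and after-spike reset (`v <- c`, `u <- u + d`).
#' Vectorised over neurons; all neurons share `params`.
#'
#' @param v,u Membrane potential (mV) and recovery variable; numeric
#'   vectors of equal length.
#' @param params An `izh_params` object.
#' @param I Injected current for this step (same length as `v`, or scalar).
#' @param dt Time step in ms (default 0.1).
#' @return A list with updated `v`, `u` and a logical vector `spiked`.
#'   Where `spiked` is `TRUE` the returned `v` equals `params$c`.
#' @examples
#' r <- izh_rest(izh_preset("excitatory_cortical"))
#' izh_step(r$v, r$u, izh_preset("excitatory_cortical"), I = 0)
#' @export
izh_step <- function(v, u, params, I = 0, dt = 0.1) {
  stopifnot(length(v) == length(u), dt > 0)
  if (!all(is.finite(v)) || !all(is.finite(u)) || !all(is.finite(I)))
    stop("non-finite neuron state or current: integration blow-up")
  v1 <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  u1 <- u + dt * (params$a * (params$b * v - u))
  if (!all(is.finite(v1)))
    stop("non-finite membrane potential after update: integration blow-up")
  spiked <- v1 >= params$threshold
  v1[spiked] <- params$c
  u1[spiked] <- u1[spiked] + params$d
  list(v = v1, u = u1, spiked = spiked)
}
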