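#' Weight change for a single pre/post spike pairing
#'
#' Soft-bounded additive STDP rule: a post-after-pre pairing potentiates
#' by `lam * (w_max - w) * exp(-(t_post - t_pre)/tau_plus)`; a
#' pre-after-post pairing depresses by
#' `-lam * w * exp(-(t_pre - t_post)/tau_minus)`.  Exactly coincident
#' spikes contribute zero by convention.
#'
#' @param w current weight in `[0, w_max]`, nS.
#' @param t_pre,t_post pre- and postsynaptic spike times, ms.
#' @param params an [stdp_params()].
#' @return The weight change `dw` (nS, signed).
#' @export
#' @examples
#' p <- stdp_params(w0 = 1, w_max = 2)
#' stdp_delta_w(1, 0, 20, p)   #  0.1 * exp(-1)
#' stdp_delta_w(1, 20, 0, p)   # -0.1 * exp(-1)
stdp_delta_w <- function(w, t_pre, t_post, params) {
  stopifnot(inherits(params, "stdp_params"), w >= 0, w <= params$w_max)
  dt <- t_post - t_pre
  if (dt > 0) {
    params$lam * (params$w_max - w) * exp(-dt / params$tau_plus)
  } else if (dt < 0) {
    -params$lam * w * exp(dt / params$tau_minus)
  } else {
    0
  }
}

#' Apply the STDP rule online to full spike trains
#'
#' All-to-all pairing implemented with exponential pre/post traces
#' processed in chronological order: at each postsynaptic spike the
#' weight potentiates in proportion to the accumulated presynaptic
#' trace (the sum of `exp(-dt/tau_plus)` over all earlier presynaptic
#' spikes), and at each presynaptic spike it depresses in proportion to
#' the accumulated postsynaptic trace.  Events are processed exactly
#' (no grid), and the weight is confined to `[0, w_max]`.  Coincident
#' pre/post spikes see each other's trace *before* its increment, so an
#' exactly simultaneous pair contributes zero.
#'
#' `pairing = "nearest"` restricts each spike to pair only with the most
#' recent opposite spike (the nearest-neighbour variant): the opposite
#' trace is reset to 1 instead of incremented.
#'
#' @param pre_spikes,post_spikes sorted spike times, ms.
#' @param params an [stdp_params()].
#' @param pairing `"all"` (default) or `"nearest"`.
#' @return A list with `w_final` and `w_trajectory`, a data frame of the
#'   weight after each spike event (columns `t`, `w`).
#' @export
#' @examples
#' p <- stdp_params(w0 = 1, w_max = 2)
#' apply_stdp_online(0, 10, p)$w_final  # w0 + one potentiation step
apply_stdp_online <- function(pre_spikes, post_spikes, params,
                              pairing = c("all", "nearest")) {
  stopifnot(inherits(params, "stdp_params"))
  pairing <- match.arg(pairing)
  if (is.unsorted(pre_spikes) || is.unsorted(post_spikes))
    stop("spike time lists must be sorted")
  ev_t <- c(pre_spikes, post_spikes)
  ev_is_pre <- c(rep(TRUE, length(pre_spikes)),
                 rep(FALSE, length(post_spikes)))
  o <- order(ev_t)
  ev_t <- ev_t[o]
  ev_is_pre <- ev_is_pre[o]

  w <- params$w0
  a_pre <- 0
  a_post <- 0
  t_last <- if (length(ev_t)) ev_t[1] else 0
  wt <- numeric(length(ev_t))
  i <- 1
  while (i <= length(ev_t)) {
    # decay traces exactly to this event time
    gap <- ev_t[i] - t_last
    a_pre <- a_pre * exp(-gap / params$tau_plus)
    a_post <- a_post * exp(-gap / params$tau_minus)
    t_last <- ev_t[i]
    # all events at this exact time share the pre-increment traces
    j <- i
    while (j <= length(ev_t) && ev_t[j] == ev_t[i]) j <- j + 1
    a_pre0 <- a_pre
    a_post0 <- a_post
    for (k in i:(j - 1)) {
      if (ev_is_pre[k]) {
        w <- w - params$lam * w * a_post0
        a_pre <- if (pairing == "all") a_pre + 1 else 1
      } else {
        w <- w + params$lam * (params$w_max - w) * a_pre0
        a_post <- if (pairing == "all") a_post + 1 else 1
      }
      w <- min(max(w, 0), params$w_max)
      wt[k] <- w
    }
    i <- j
  }
  list(w_final = w,
       w_trajectory = data.frame(t = ev_t, w = wt))
}
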