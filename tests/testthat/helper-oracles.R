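# Independent oracles used across the suite.  These deliberately do not
# call the package's update functions: they re-derive the same quantities
# from the closed-form solutions so that implementation and oracle are
# separate routes to the same number.

# Two-spike TPM recursion: released fractions and the voltage-clamp PPR
# (including the residual conductance from pulse 1) for an inter-spike
# interval `isi`, derived by hand from the inter-spike exponentials.
oracle_two_spike <- function(U, tau_in, tau_rec, tau_f, isi,
                             tau_syn = 3) {
  u1 <- U                      # facilitation jump from u0 = 0
  rel1 <- u1 * 1               # x0 = 1 at the first spike
  # inter-spike decay of the released fraction through the recovery chain
  x1 <- rel1 * exp(-isi / tau_in)
  if (abs(tau_in - tau_rec) < 1e-12) {
    x2 <- rel1 * (isi / tau_in) * exp(-isi / tau_rec)
  } else {
    A <- rel1 * tau_rec / (tau_in - tau_rec)
    x2 <- A * (exp(-isi / tau_in) - exp(-isi / tau_rec))
  }
  x0 <- 1 - x1 - x2
  u_pre <- u1 * exp(-isi / tau_f)
  u2 <- u_pre + U * (1 - u_pre)
  rel2 <- u2 * x0
  ppr_clamp <- (rel1 * exp(-isi / tau_syn) + rel2) / rel1
  list(rel1 = rel1, rel2 = rel2, ppr_release = rel2 / rel1,
       ppr_clamp = ppr_clamp)
}

# Closed-form LIF latency to first spike from rest under constant current
# I (pA), with the package's default constants unless overridden.
oracle_lif_latency <- function(I, Rm = 100, Cm = 150, EL = -65,
                               Vthre = -50) {
  tau <- Rm * Cm / 1000
  IR <- I * Rm / 1000  # mV
  if (IR <= Vthre - EL) return(Inf)
  tau * log(IR / (IR - (Vthre - EL)))
}

# Brute-force all-pairs STDP: processes spikes chronologically; at each
# spike the kernel sum over all earlier opposite spikes is applied as one
# soft-bounded update (coincident spikes contribute zero).
oracle_stdp_allpairs <- function(pre, post, params) {
  ev <- rbind(data.frame(t = pre, pre = TRUE),
              data.frame(t = post, pre = FALSE))
  ev <- ev[order(ev$t), , drop = FALSE]
  w <- params$w0
  for (i in seq_len(nrow(ev))) {
    t_i <- ev$t[i]
    if (ev$pre[i]) {
      earlier <- post[post < t_i]
      s <- sum(exp(-(t_i - earlier) / params$tau_minus))
      w <- w - params$lam * w * s
    } else {
      earlier <- pre[pre < t_i]
      s <- sum(exp(-(t_i - earlier) / params$tau_plus))
      w <- w + params$lam * (params$w_max - w) * s
    }
    w <- min(max(w, 0), params$w_max)
  }
  w
}

# One-tailed F tail probability computed directly from the distribution
# function (the oracle route for variance_f_test).
oracle_f_tail <- function(F, df1, df2) stats::pf(F, df1, df2,
                                                 lower.tail = FALSE)
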