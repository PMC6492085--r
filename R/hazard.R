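# Risk-set bookkeeping and the Breslow baseline-hazard estimator.  The
# baseline hazard is nonparametric: increments at observed event times only,
# one set per stratum when the hazard is stratified by study.

# Precomputes, per stratum: subject indices, descending-time order, unique
# event times (ascending), tie counts d_r, risk-set boundary positions in the
# sorted order, and each subject's interval position for cumulative-hazard
# lookups.  Reused across all M-step Newton iterations.
make_riskset <- function(Tsurv, delta, strata) {
  out <- lapply(sort(unique(strata)), function(s) {
    idx <- which(strata == s)
    Ts <- Tsurv[idx]
    ds <- delta[idx]
    ord <- order(Ts, decreasing = TRUE)
    ue <- sort(unique(Ts[ds == 1]))
    dr <- if (length(ue)) as.numeric(table(factor(Ts[ds == 1], levels = ue)))
          else numeric(0)
    # number of subjects with T >= ue[r] (risk-set size boundary)
    Tdesc <- Ts[ord]
    pos <- if (length(ue)) findInterval(-ue, -Tdesc) else integer(0)
    # event-time index of each subject's own time (events only)
    ev_at <- match(Ts, ue)                      # NA if not an event time
    # interval position for cumulative hazard: count of ue <= T_i
    cumpos <- if (length(ue)) findInterval(Ts, ue) else rep(0L, length(Ts))
    list(idx = idx, ord = ord, ue = ue, dr = dr, pos = pos,
         ev_at = ev_at, cumpos = cumpos, n_event = sum(ds))
  })
  out
}

# Breslow increments d_r / S0_r given per-subject expected risk scores
# (E[exp(eta)]); returns the hazard per stratum plus per-subject cumulative
# hazard H0(T_i) and log increment at the subject's own event time.
breslow_baseline <- function(rs, riskexp, delta) {
  n <- length(riskexp)
  H0 <- numeric(n)
  logh0 <- numeric(n)
  haz <- vector("list", length(rs))
  for (s in seq_along(rs)) {
    r <- rs[[s]]
    if (!length(r$ue)) {
      haz[[s]] <- list(time = numeric(0), haz = numeric(0))
      next
    }
    cum <- cumsum(riskexp[r$idx][r$ord])
    S0 <- cum[r$pos]
    lam <- r$dr / S0
    haz[[s]] <- list(time = r$ue, haz = lam)
    ch <- cumsum(lam)
    H0[r$idx] <- ifelse(r$cumpos > 0, ch[pmax(r$cumpos, 1L)], 0)
    ev <- which(delta[r$idx] == 1)
    logh0[r$idx][ev] <- log(lam[r$ev_at[ev]])
  }
  list(haz = haz, H0 = H0, logh0 = logh0)
}
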