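# Independent oracles for the closed-form PK solution.

# Random mixed bolus/infusion schedule over ~48 h.
random_schedule <- function() {
  doses <- dose_events()
  if (runif(1) < 0.8) {
    nb <- sample(1:6, 1)
    doses <- rbind(doses,
                   dose_events(drug = rep("levetiracetam", nb),
                               time_h = sort(runif(nb, 0, 40)),
                               route = rep("bolus", nb),
                               amount = runif(nb, 1, 15)))
  }
  if (runif(1) < 0.6) {
    t0 <- runif(1, 0, 30)
    doses <- rbind(doses, doses_infusion("levetiracetam", runif(1, 0.1, 2),
                                         t0, t0 + runif(1, 2, 20)))
  }
  if (!nrow(doses))
    doses <- dose_events("levetiracetam", 1, "bolus", 5)
  doses <- doses[order(doses$time_h), , drop = FALSE]
  class(doses) <- c("dose_events", "data.frame")
  doses
}

# Numeric integration of dC/dt = input(t)/V - k_e C with boluses as add
# events; the independent check of the superposition closed form.
ode_oracle <- function(doses, pk, times) {
  testthat::skip_if_not_installed("deSolve")
  st <- doses[doses$route == "infusion_start", , drop = FALSE]
  sp <- doses$time_h[doses$route == "infusion_stop"]
  rate_fn <- function(t) {
    r <- 0
    if (nrow(st)) for (i in seq_len(nrow(st))) {
      stop_t <- c(sp[sp > st$time_h[i]], max(times))[1]
      if (t >= st$time_h[i] && t < stop_t) r <- r + st$amount[i]
    }
    r
  }
  bol <- doses[doses$route == "bolus", , drop = FALSE]
  ev <- NULL
  if (nrow(bol)) {
    # the closed form is right-continuous at a bolus (C(t0) includes the
    # dose); apply the add-event an instant early so grid values compare
    # the post-dose state
    ev <- list(data = data.frame(var = "C", time = bol$time_h - 1e-9,
                                 value = bol$amount / pk$V, method = "add"))
  }
  tt <- sort(unique(c(times, bol$time_h - 1e-9, st$time_h, sp)))
  sol <- deSolve::ode(c(C = 0), tt,
                      function(t, y, p) list(rate_fn(t) / pk$V - pk$k_e * y["C"]),
                      parms = NULL, events = ev, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  sol[match(times, sol[, "time"]), "C"]
}
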