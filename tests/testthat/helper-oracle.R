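# Exhaustive Markov-chain oracle for single-vHPC necrosis-trigger times,
# shared by the unit and acceptance suites.

# Single-vHPC Markov oracle: the distribution of necrosis-trigger times
# under a scripted NAPQI arrival schedule (mitigation off) is computed by
# exhaustive enumeration over the (removal, amplification) chain and
# compared with the simulated histogram.

# Exact forward enumeration.  State: (napqi n, gsh g, mitoD m); each cycle
# arrivals are added, then each NAPQI is independently removed with
# probability p_rm; removals consume GSH first, and each post-depletion
# removal adds a burst of size uniform on {amp_min+1, ..., amp_max+1}
# (all MitoD here, p_mito = 1).  The trigger fires at the end of the cycle
# in which mitoD exceeds the necrosis threshold.
necrosis_trigger_oracle <- function(schedule, gsh0, mech, t_max = 60L) {
  p_rm <- mech$napqi_removal_prob
  amp <- (mech$amplification_range[1]:mech$amplification_range[2]) + 1L
  thr <- mech$necrosis_threshold
  m_cap <- thr + max(amp) * 8L
  arr <- integer(t_max + 1L)
  arr[schedule$cycle + 1L] <- schedule$n_arrivals
  # burst-sum pmf for b bursts (b small)
  burst_pmf <- list(stats::setNames(1, "0"))
  for (b in seq_len(8L)) {
    prev <- burst_pmf[[b]]
    nxt <- new.env()
    for (nm in names(prev)) for (a in amp) {
      key <- as.character(min(as.integer(nm) + a, m_cap))
      assign(key, (if (exists(key, nxt)) get(key, nxt) else 0) +
               prev[[nm]] / length(amp), nxt)
    }
    burst_pmf[[b + 1L]] <- unlist(as.list(nxt))
  }
  # state probabilities keyed "n.g.m" over non-triggered states
  states <- stats::setNames(1, paste(0L, gsh0, 0L, sep = "."))
  trig <- numeric(t_max + 1L)
  for (t in 0:t_max) {
    # arrivals
    if (arr[t + 1L] > 0L) {
      parts <- do.call(rbind, strsplit(names(states), ".", fixed = TRUE))
      nn <- as.integer(parts[, 1]) + arr[t + 1L]
      names(states) <- paste(nn, parts[, 2], parts[, 3], sep = ".")
    }
    nxt <- new.env()
    addp <- function(key, p) assign(key, (if (exists(key, nxt)) get(key, nxt) else 0) + p, nxt)
    for (key in names(states)) {
      p0 <- states[[key]]
      s <- as.integer(strsplit(key, ".", fixed = TRUE)[[1]])
      n <- s[1]; g <- s[2]; m <- s[3]
      for (r in 0:n) {
        pr <- stats::dbinom(r, n, p_rm) * p0
        if (pr < 1e-15) next
        g2 <- max(0L, g - r)
        b <- max(0L, r - g)                 # bursts this cycle
        if (b == 0L) {
          addp(paste(n - r, g2, m, sep = "."), pr)
        } else {
          pmf <- burst_pmf[[b + 1L]]
          for (nm in names(pmf)) {
            m2 <- min(m + as.integer(nm), m_cap)
            addp(paste(n - r, g2, m2, sep = "."), pr * pmf[[nm]])
          }
        }
      }
    }
    states <- unlist(as.list(nxt))
    if (is.null(states) || !length(states)) break   # residual mass underflow
    # split off triggered states
    parts <- do.call(rbind, strsplit(names(states), ".", fixed = TRUE))
    m_now <- as.integer(parts[, 3])
    trig[t + 1L] <- sum(states[m_now > thr])
    states <- states[m_now <= thr]
    if (!length(states)) break
  }
  trig / sum(trig)   # conditional on eventually triggering
}

simulate_trigger_times <- function(schedule, gsh0, mech, grads, n_rep,
                                   t_max = 60L) {
  vapply(seq_len(n_rep), function(i) {
    h <- hepatocyte_state(zone = 1, grads)
    h$gsh_counter <- gsh0
    for (t in 0:t_max) {
      hit <- schedule$cycle == t
      if (any(hit)) h$napqi <- h$napqi + sum(schedule$n_arrivals[hit])
      h <- napqi_removal_step(h, mech, grads)
      h <- necrosis_step(h, mech, t)
      if (h$necrosis_triggered) return(t)
    }
    NA_integer_
  }, integer(1))
}

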