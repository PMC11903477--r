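# Independent brute-force enumeration over all integer 2x2x2 tables with
# fixed tap/DESH margins: nested loops over the five free cells, checking
# every rule metric directly. Deliberately naive -- this is the oracle the
# reconstruction solver is tested against.
brute_force_tables <- function(n, tap_pos, desh_pos, targets, sens, tol = 0.005) {
  sols <- list()
  metric <- function(k) if (sens) k / n else (n - k) / n
  for (a in 0:min(tap_pos, desh_pos)) {          # tap+ desh+ ca+
    for (b in 0:(min(tap_pos, desh_pos) - a)) {  # tap+ desh+ ca-
      for (cc in 0:(tap_pos - a - b)) {          # tap+ desh- ca+
        d <- tap_pos - a - b - cc
        for (e in 0:(desh_pos - a - b)) {        # tap- desh+ ca+
          f <- desh_pos - a - b - e
          rest <- n - tap_pos - e - f
          if (rest < 0) next
          for (g in 0:rest) {                    # tap- desh- ca+
            h <- rest - g
            ca_k <- a + cc + e + g
            utd <- tap_pos + e + f
            utc <- tap_pos + e + g
            maj <- a + b + cc + e
            dev <- max(abs(metric(ca_k) - targets$ca),
                       abs(metric(utd) - targets$tap_desh),
                       abs(metric(utc) - targets$tap_ca),
                       abs(metric(maj) - targets$majority))
            if (dev < tol) {
              sols[[length(sols) + 1]] <- c(n111 = a, n110 = b, n101 = cc,
                                            n100 = d, n011 = e, n010 = f,
                                            n001 = g, n000 = h, dev = dev)
            }
          }
        }
      }
    }
  }
  if (length(sols) == 0) return(NULL)
  as.data.frame(do.call(rbind, sols))
}

group_targets <- function(targets, which) {
  key <- if (which == "responders") "sensitivity" else "specificity"
  t4 <- targets$table4
  list(ca = t4$ca[[key]], tap_desh = t4$tap_desh[[key]],
       tap_ca = t4$tap_ca[[key]], majority = t4$majority[[key]])
}

tiny_cohort <- function(n = 6, seed = 99) {
  cfg <- simulation_config(n_responders = max(2, n %/% 2),
                           n_non_responders = max(2, n - n %/% 2))
  simulate_cohort(cfg, seed = seed)
}
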