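# Shared builders for small, fully determined fixtures.

# a two-pair choice table with known structure:
# pair 1: a = (300, 600, 900), b = (450, 500, 550)  -> min_adv = b, ev_adv = a
# pair 2: a = (200, 500, 800), b = (100, 700, 900)  -> min_adv = a, ev_adv = b
tiny_choices <- function(choice = c("a", "b"), rt = c(2, 3),
                         condition = "Self") {
  data.frame(trial_id = 1:2, condition = condition,
             a_low = c(300, 200), a_mid = c(600, 500), a_high = c(900, 800),
             b_low = c(450, 100), b_mid = c(500, 700), b_high = c(550, 900),
             choice = choice, rt_s = rt, stringsAsFactors = FALSE)
}

# choices of a synthetic agent on a fresh conflict-structured set
agent_choices <- function(alpha, lam, n_pairs = 36, reps = 1,
                          condition = "Self") {
  pairs <- generate_lottery_set(design_config(n_pairs = n_pairs))
  out <- do.call(rbind, replicate(reps, simulate_choices(
    pairs, alpha, lam, condition = condition), simplify = FALSE))
  out$trial_id <- seq_len(nrow(out))
  out
}

# uniform 500 Hz samples from piecewise segments:
# segs is a list of c(duration_s, x, y) for stationary parts and
# list(dur, from_xy, to_xy) for raised-cosine moves
stationary_trace <- function(dur, x = 0, y = 0, rate = 500) {
  n <- round(dur * rate)
  data.frame(t_s = (seq_len(n) - 1) / rate, x_deg = rep(x, n),
             y_deg = rep(y, n), valid = TRUE)
}

# one left-right-left trace with known event boundaries (no jitter)
three_fix_trace <- function(fix_dur = 0.4, sac_dur = 0.04, rate = 500,
                            x_left = -6, x_right = 6) {
  nf <- round(fix_dur * rate)
  ns <- round(sac_dur * rate) - 1
  move <- function(from, to)
    from + (to - from) * (1 - cos(pi * seq_len(ns) / (ns + 1))) / 2
  x <- c(rep(x_left, nf), move(x_left, x_right), rep(x_right, nf),
         move(x_right, x_left), rep(x_left, nf))
  data.frame(t_s = (seq_along(x) - 1) / rate, x_deg = x,
             y_deg = 0, valid = TRUE)
}
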