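# Independent oracles used across the suite.  These deliberately avoid
# the package's own grid-based code paths.

# Exact centre of mass of a trapezoid (a,b,c,d) clipped at level alpha,
# by piecewise-polynomial integration of the three linear segments.
exact_clipped_centroid <- function(p, alpha = 1) {
  if (length(p) == 3L) p <- c(p[1], p[2], p[2], p[3])
  a <- p[1]; b <- p[2]; c <- p[3]; d <- p[4]
  x1 <- if (b > a) a + alpha * (b - a) else a
  x2 <- if (d > c) d - alpha * (d - c) else d
  area <- 0; moment <- 0
  if (b > a) { # rising flank: mu = (x - a) / (b - a) on [a, x1]
    area <- area + (x1 - a)^2 / (2 * (b - a))
    moment <- moment +
      ((x1^3 / 3 - a * x1^2 / 2) - (a^3 / 3 - a^3 / 2)) / (b - a)
  }
  area <- area + alpha * (x2 - x1) # plateau at alpha
  moment <- moment + alpha * (x2^2 - x1^2) / 2
  if (d > c) { # falling flank: mu = (d - x) / (d - c) on [x2, d]
    area <- area + (d - x2)^2 / (2 * (d - c))
    moment <- moment +
      ((d^3 / 2 - d^3 / 3) - (d * x2^2 / 2 - x2^3 / 3)) / (d - c)
  }
  moment / area
}

# Brute-force AUC: count concordant positive-negative pairs, ties 1/2.
brute_force_auc <- function(predictor, outcome) {
  pos <- predictor[outcome == 1]
  neg <- predictor[outcome == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Fresh trapezoid membership evaluation, written independently of the
# package (explicit branch per segment, scalar).
naive_trap_membership <- function(p, x) {
  if (length(p) == 3L) p <- c(p[1], p[2], p[2], p[3])
  a <- p[1]; b <- p[2]; c <- p[3]; d <- p[4]
  vapply(x, function(xi) {
    if (xi < a || xi > d) return(0)
    if (xi >= b && xi <= c) return(1)
    if (xi < b) return((xi - a) / (b - a))
    (d - xi) / (d - c)
  }, numeric(1))
}

# A complete random daily series for plumbing tests.
random_series <- function(n = 60, seed = 1) {
  set.seed(seed)
  data.frame(
    date = seq(as.Date("2012-01-01"), by = "day", length.out = n),
    pm10 = runif(n, 5, 140),
    no2 = runif(n, 5, 120),
    temperature = runif(n, 12, 40),
    wind = runif(n, 1, 4),
    hospitalizations = rpois(n, 1.6)
  )
}
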