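# Internal helpers shared across modules.

# Signal errors carry a condition class so callers/tests can discriminate
# failure modes (invalid cutoff vs. malformed file vs. degenerate input).
abort_iba <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "iba_error")))
}

nyquist <- function(x) 1 / (2 * x$dt)

# Butterworth design in second-order sections. The direct transfer-function
# (b, a) form of a narrow low-pass (2.5 Hz at 1 kHz) is numerically fragile:
# its recursion amplifies per-sample rounding by roughly (1 - pole radius)
# to the minus filter order, i.e. ~1e8 for an order-4 design. Factoring the
# design into biquads keeps the amplification at the per-section level and
# makes the chain accurate to ~1e-12. Poles are taken from the designed
# denominator; zeros are known analytically per response type; the gain is
# matched to the original design at a pass-band reference frequency.
butter_sos <- function(order, w, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  flt <- signal::butter(order, w, type = type)
  a <- as.numeric(flt$a)
  b <- as.numeric(flt$b) / a[1]
  a <- a / a[1]
  poles <- polyroot(rev(a))
  tol <- 1e-8
  pairs <- lapply(poles[Im(poles) > tol], function(p) c(p, Conj(p)))
  re_p <- poles[abs(Im(poles)) <= tol]
  re_p <- re_p[order(-Mod(re_p))]
  while (length(re_p) >= 2L) {
    pairs[[length(pairs) + 1L]] <- re_p[1:2]
    re_p <- re_p[-(1:2)]
  }
  if (length(re_p) == 1L) {
    abort_iba("odd filter order not supported in section form",
              "iba_validation")
  }
  biquad <- function(r) c(1, -Re(r[1] + r[2]), Re(r[1] * r[2]))
  zsec <- switch(type,
                 low = c(-1, -1),
                 high = c(1, 1),
                 pass = c(1, -1))
  secs <- lapply(pairs, function(p) list(b = biquad(zsec), a = biquad(p)))
  # pass-band reference: DC for low, Nyquist for high, geometric band centre
  # for pass
  zref <- switch(type,
                 low = 1 + 0i,
                 high = -1 + 0i,
                 pass = exp(1i * pi * sqrt(prod(w))))
  resp <- function(bb, aa) {
    zz <- zref^-(seq_along(bb) - 1)
    sum(bb * zz) / sum(aa * zz)
  }
  # Butterworth gain at the low/high reference is exactly 1 by design;
  # evaluating the (b, a) form there would reintroduce its cancellation
  # error, so only the band-pass matches the designed response numerically.
  target <- if (type == "pass") resp(b, a) else 1 + 0i
  g <- Re(target /
            prod(vapply(secs, function(s) resp(s$b, s$a), complex(1))))
  gs <- g^(1 / length(secs))
  lapply(secs, function(s) list(b = s$b * gs, a = s$a))
}

# Zero-phase IIR filtering through cascaded second-order sections.
# `signal::filtfilt` assumes the signal is zero outside its support, which
# leaves long edge transients for envelopes that start away from zero; here
# the signal is extended by odd reflection at both ends and every section
# pass is initialised at the steady state for its first sample, so a
# constant passes through unchanged and edges stay clean.
zero_phase_filter <- function(sos, x) {
  n <- length(x)
  npad <- min(6L * length(sos) + 3L, n - 1L)
  one_pass <- function(z) {
    for (s in sos) {
      g <- sum(s$b) / sum(s$a)
      z <- as.numeric(signal::filter(s$b, s$a, z,
                                     init.x = rep(z[1], length(s$b) - 1L),
                                     init.y = rep(z[1] * g,
                                                  length(s$a) - 1L)))
    }
    z
  }
  if (npad > 0) {
    xe <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  } else {
    xe <- x
  }
  y <- rev(one_pass(rev(one_pass(xe))))
  y[(npad + 1):(npad + n)]
}

# Evaluate a set of reproducible draws without disturbing the caller's RNG
# stream: generator outputs must be pure functions of (spec, seed).
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Centred moving average with edge replication; used to stabilise the
# angular-rate estimate before thresholding.
smooth_ma <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < width) return(x)
  half <- (width - 1L) %/% 2L
  xe <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xe, rep(1 / width, width), sides = 2))[
    (half + 1):(half + length(x))]
}

check_dt <- function(dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort_iba("`dt` must be a single positive number (seconds)",
              "iba_validation")
  }
  as.numeric(dt)
}

resolve_segment <- function(segment, n) {
  if (is.null(segment)) return(c(1L, n))
  segment <- as.integer(segment)
  if (length(segment) != 2L || anyNA(segment) ||
      segment[1] < 1L || segment[2] > n || segment[1] > segment[2]) {
    abort_iba(sprintf("segment must be c(start, end) within 1..%d", n),
              "iba_validation")
  }
  segment
}
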