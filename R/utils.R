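# Internal numerical helpers shared across modules.

# Linear interpolation with constant extrapolation at the edges.
interp_lin <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", rule = 2)$y
}

# Nearest-neighbour lookup (used for resampling the X-ray status channel).
interp_nn <- function(x, y, xout) {
  idx <- findInterval(xout, x, all.inside = TRUE)
  right <- idx + 1L
  use_right <- (xout - x[idx]) > (x[right] - xout)
  y[ifelse(use_right, right, idx)]
}

# Centered moving average; window in samples (odd), edges use shrunken windows.
moving_average <- function(y, k) {
  if (k <= 1) return(y)
  if (k %% 2 == 0) k <- k + 1L
  n <- length(y)
  cs <- cumsum(c(0, y))
  half <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Vertex of the parabola through three equally spaced points (y1, y2, y3)
# around x2; returns c(x, y) of the vertex, falling back to the centre
# sample when the points are collinear.
parabola_vertex <- function(x2, h, y1, y2, y3) {
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < .Machine$double.eps * max(1, abs(y2)))
    return(c(x2, y2))
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(min(delta, 1), -1)  # stay within one grid step
  c(x2 + delta * h, y2 - 0.25 * (y1 - y3) * delta)
}

# All local extrema of a sampled signal with plateau handling: a plateau of
# equal values is resolved to its centre sample (ties toward the earlier
# sample). Returns a data.frame(index, type) with type "peak"/"valley".
local_extrema <- function(amp) {
  s <- sign(diff(amp))
  idx <- which(s != 0)
  out_i <- integer(0)
  out_ty <- character(0)
  if (length(idx) >= 2) {
    for (j in seq_len(length(idx) - 1L)) {
      a <- idx[j]; b <- idx[j + 1L]
      if (s[a] == s[b]) next
      centre <- (a + 1L + b) %/% 2L
      out_i <- c(out_i, centre)
      out_ty <- c(out_ty, if (s[a] > 0) "peak" else "valley")
    }
  }
  data.frame(index = out_i, type = out_ty, stringsAsFactors = FALSE)
}

# Alternating extrema after removing oscillations smaller than `min_prom`
# (absolute amplitude units). Classic turning-point simplification: the
# adjacent extrema pair with the smallest amplitude difference below the
# threshold is removed until all remaining swings are significant.
significant_extrema <- function(amp, min_prom) {
  ext <- local_extrema(amp)
  if (nrow(ext) == 0) return(ext)
  # enforce alternation up-front (plateaus can yield repeated types)
  keep <- rep(TRUE, nrow(ext))
  last <- 1L
  for (j in seq_len(nrow(ext))[-1]) {
    if (ext$type[j] == ext$type[last]) {
      better_new <- if (ext$type[j] == "peak")
        amp[ext$index[j]] > amp[ext$index[last]]
      else amp[ext$index[j]] < amp[ext$index[last]]
      if (better_new) { keep[last] <- FALSE; last <- j } else keep[j] <- FALSE
    } else last <- j
  }
  ext <- ext[keep, , drop = FALSE]
  repeat {
    if (nrow(ext) < 2) break
    dif <- abs(diff(amp[ext$index]))
    small <- which(dif < min_prom)
    if (length(small) == 0) break
    j <- small[which.min(dif[small])]
    # removing the adjacent pair preserves alternation; at the boundary it
    # simply trims the edge oscillation
    ext <- ext[-c(j, j + 1L), , drop = FALSE]
  }
  row.names(ext) <- NULL
  ext
}

# Quadratic sub-sample refinement of an extremum at sample index i.
# Returns c(time, value).
refine_extremum <- function(t, amp, i) {
  n <- length(amp)
  if (i <= 1 || i >= n) return(c(t[i], amp[i]))
  parabola_vertex(t[i], t[i + 1] - t[i], amp[i - 1], amp[i], amp[i + 1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. A NULL seed leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
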