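# Independent brute-force oracles used to cross-check package results.

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
enumerate_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_stat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  }
  obs <- u_stat(seq_len(n1))
  us <- apply(combn(n1 + n2, n1), 2, u_stat)
  p_lo <- mean(us <= obs)
  p_hi <- mean(us >= obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Minimum-total-distance one-to-one matching under a distance cap,
# maximizing the number of pairs first: exhaustive over all injections.
brute_force_matching <- function(ax, ay, bx, by, max_dist) {
  nA <- length(ax); nB <- length(bx)
  d <- sqrt(outer(ax, bx, `-`)^2 + outer(ay, by, `-`)^2)
  best <- list(count = 0, total = Inf)
  swap <- nA > nB
  if (swap) { d <- t(d); tmp <- nA; nA <- nB; nB <- tmp }
  # assign each of the nA rows to a distinct column or to nothing
  recurse <- function(row, used, count, total) {
    if (row > nA) {
      if (count > best$count ||
          (count == best$count && total < best$total)) {
        best <<- list(count = count, total = total)
      }
      return(invisible())
    }
    recurse(row + 1, used, count, total)  # leave row unmatched
    for (col in seq_len(nB)) {
      if (!used[col] && d[row, col] <= max_dist) {
        used[col] <- TRUE
        recurse(row + 1, used, count + 1, total + d[row, col])
        used[col] <- FALSE
      }
    }
  }
  recurse(1, logical(nB), 0, 0)
  best
}

# Pooled-variance two-sample t-test, closed form.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = n1 + n2 - 2, p = 2 * pt(-abs(tval), n1 + n2 - 2))
}

# Direct convolution argmax of the LoG response on a small image.
direct_log_argmax <- function(m, sigma) {
  r <- ceiling(4 * sigma)
  ax <- -r:r
  d2 <- outer(ax^2, ax^2, `+`)
  k <- (d2 - 2 * sigma^2) / sigma^4 * exp(-d2 / (2 * sigma^2))
  k <- -(k - mean(k))
  resp <- matrix(-Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      ii <- (i - r):(i + r); jj <- (j - r):(j + r)
      ok <- ii >= 1 & ii <= nrow(m)
      ok2 <- jj >= 1 & jj <= ncol(m)
      if (all(ok) && all(ok2)) {
        resp[i, j] <- sum(k * m[ii, jj])
      }
    }
  }
  which(resp == max(resp), arr.ind = TRUE)[1, ]
}

# A tiny noise-free field with Gaussian spots at known centers.
make_spot_field <- function(centers, shape = c(64, 64), sigma = 1.5,
                            amplitude = 100, background = 0, noise_sd = 0,
                            seed = 1) {
  set.seed(seed)
  m <- matrix(background, shape[1], shape[2])
  for (k in seq_len(nrow(centers))) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    for (i in seq_len(shape[1])) {
      d2 <- (i - cx)^2 + (seq_len(shape[2]) - cy)^2
      m[i, ] <- m[i, ] + amplitude * exp(-d2 / (2 * sigma^2))
    }
  }
  if (noise_sd > 0) m <- m + matrix(rnorm(length(m), 0, noise_sd),
                                    shape[1], shape[2])
  image_stack(list(FISH = pmax(m, 0)))
}
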