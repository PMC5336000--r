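# Naive, loop-based scalar re-implementations of the six quality indices,
# written directly from their defining formulas with explicit sums. They
# deliberately share no code with the package internals so they can act as
# independent oracles on small instances.

oracle_sam <- function(ref, fus) {
  d <- dim(ref)
  total <- 0
  count <- 0
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      a <- ref[i, j, ]
      b <- fus[i, j, ]
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na > 0 && nb > 0) {
        cosv <- sum(a * b) / (na * nb)
        cosv <- min(max(cosv, -1), 1)
        total <- total + acos(cosv)
        count <- count + 1
      }
    }
  }
  total / count * 180 / pi
}

oracle_ergas_spectral <- function(ref, fus, h_over_l) {
  nb <- dim(ref)[3]
  acc <- 0
  for (k in seq_len(nb)) {
    rmse <- sqrt(mean((ref[, , k] - fus[, , k])^2))
    acc <- acc + (rmse / mean(ref[, , k]))^2
  }
  100 * h_over_l * sqrt(acc / nb)
}

oracle_moment_match <- function(src, ref) {
  (src - mean(src)) * (sd(as.vector(ref)) / sd(as.vector(src))) + mean(ref)
}

oracle_ergas_spatial <- function(pan, fus, h_over_l, matched = TRUE) {
  nb <- dim(fus)[3]
  acc <- 0
  for (k in seq_len(nb)) {
    pk <- if (matched) oracle_moment_match(pan, fus[, , k]) else pan
    rmse <- sqrt(mean((fus[, , k] - pk)^2))
    acc <- acc + (rmse / mean(pk))^2
  }
  100 * h_over_l * sqrt(acc / nb)
}

oracle_dct_block <- function(m) {
  # direct DCT-II double sum, orthonormal scaling
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (u in 0:(n - 1)) {
    for (v in 0:(n - 1)) {
      s <- 0
      for (x in 0:(n - 1)) {
        for (y in 0:(n - 1)) {
          s <- s + m[x + 1, y + 1] *
            cos(pi * (2 * x + 1) * u / (2 * n)) *
            cos(pi * (2 * y + 1) * v / (2 * n))
        }
      }
      au <- if (u == 0) sqrt(1 / n) else sqrt(2 / n)
      av <- if (v == 0) sqrt(1 / n) else sqrt(2 / n)
      out[u + 1, v + 1] <- au * av * s
    }
  }
  out
}

oracle_fc <- function(pan, fus, block) {
  # image dims must be multiples of `block` (no padding in the oracle)
  nb <- dim(fus)[3]
  d <- dim(pan)
  ac_of <- function(m) {
    acs <- c()
    for (bi in seq_len(d[1] / block)) {
      for (bj in seq_len(d[2] / block)) {
        rows <- ((bi - 1) * block + 1):(bi * block)
        cols <- ((bj - 1) * block + 1):(bj * block)
        coef <- oracle_dct_block(m[rows, cols])
        acs <- c(acs, as.vector(coef)[-1])
      }
    }
    acs
  }
  pan_ac <- ac_of(pan)
  vals <- numeric(nb)
  for (k in seq_len(nb)) vals[k] <- cor(pan_ac, ac_of(fus[, , k]))
  mean(vals)
}

oracle_reflect <- function(q, n) {
  while (q < 0 || q > n - 1) {
    if (q < 0) q <- -1 - q
    if (q > n - 1) q <- 2 * n - 1 - q
  }
  q
}

oracle_laplacian <- function(m) {
  d <- dim(m)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      acc <- 8 * m[i, j]
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- oracle_reflect(i - 1 + di, d[1]) + 1
          jj <- oracle_reflect(j - 1 + dj, d[2]) + 1
          acc <- acc - m[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

oracle_zhou <- function(pan, fus) {
  nb <- dim(fus)[3]
  ph <- oracle_laplacian(pan)
  vals <- numeric(nb)
  for (k in seq_len(nb)) {
    vals[k] <- cor(as.vector(ph), as.vector(oracle_laplacian(fus[, , k])))
  }
  mean(vals)
}

oracle_q <- function(ref, fus) {
  nb <- dim(ref)[3]
  vals <- numeric(nb)
  for (k in seq_len(nb)) {
    x <- as.vector(ref[, , k]); y <- as.vector(fus[, , k])
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    vals[k] <- 4 * cxy * mx * my / ((vx + vy) * (mx^2 + my^2))
  }
  mean(vals)
}

# random strictly positive test image pair
random_pair <- function(h, w, nb, seed) {
  set.seed(seed)
  ref <- array(runif(h * w * nb) + 0.5, c(h, w, nb))
  fus <- ref + array(rnorm(h * w * nb, sd = 0.1), c(h, w, nb))
  fus[fus <= 0] <- 0.01
  list(ref = ref, fus = fus)
}

# constant-band scene where the PAN equals the band mean: the zero-detail
# case in which every fusion algorithm must return its input
zero_detail_scene <- function(h = 32, w = 32, values = c(10, 20, 30)) {
  pix <- array(rep(values, each = h * w), c(h, w, length(values)))
  ms <- ms_image(pix, bands = wv2_bands()[seq_along(values), ])
  pan <- rowMeans(pix, dims = 2)
  list(ms = ms, pan = pan)
}
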