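# Independent brute-force oracles: every one is a direct loop transcription
# of the defining formula, kept free of the vectorized implementation paths
# it checks.

rand_img <- function(h, w = h, seed = 1) {
  withr::with_seed(seed, matrix(runif(h * w), h, w))
}

# per-pixel neighborhood extremum over a flat structuring element,
# out-of-frame neighbors ignored
morph_oracle <- function(img, mask, fun) {
  r <- (nrow(mask) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      if (!mask[di + r + 1L, dj + r + 1L]) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
        vals <- c(vals, img[ii, jj])
    }
    out[i, j] <- fun(vals)
  }
  out
}

# scalar-loop softmax across a list of maps
softmax_oracle <- function(acts) {
  h <- nrow(acts[[1]]); w <- ncol(acts[[1]])
  out <- lapply(acts, function(a) matrix(0, h, w))
  for (i in seq_len(h)) for (j in seq_len(w)) {
    e <- exp(vapply(acts, function(a) a[i, j], numeric(1)))
    for (z in seq_along(acts)) out[[z]][i, j] <- e[z] / sum(e)
  }
  out
}

# explicit scatter-add transposed convolution: each input pixel scatters
# through the kernel onto a stride-S grid; P border pixels cropped
tconv_oracle <- function(img, kernel, S = 1L, P = 1L) {
  K <- nrow(kernel)
  h <- nrow(img); w <- ncol(img)
  full <- matrix(0, (h - 1L) * S + K, (w - 1L) * S + K)
  for (i in seq_len(h)) for (j in seq_len(w))
    for (ki in seq_len(K)) for (kj in seq_len(K)) {
      r <- (i - 1L) * S + ki
      c <- (j - 1L) * S + kj
      full[r, c] <- full[r, c] + img[i, j] * kernel[ki, kj]
    }
  full[(P + 1L):(nrow(full) - P), (P + 1L):(ncol(full) - P), drop = FALSE]
}

# all-pairs dominance filter over objective points (minimize-recast)
front_oracle <- function(points) {
  mins <- lapply(points, function(p)
    ifelse(p$directions == "maximize", -p$objectives, p$objectives))
  n <- length(points)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(mins[[j]] <= mins[[i]]) && any(mins[[j]] < mins[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  points[keep]
}

# second, independent SSIM: same standard formula, computed per window
# position with explicit weighted moments
ssim_oracle <- function(a, b, K1 = 0.01, K2 = 0.03, L = 1) {
  half <- 5L
  g <- exp(-(seq(-half, half)^2) / (2 * 1.5^2))
  w <- outer(g, g); w <- w / sum(w)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  vals <- c()
  for (i in seq_len(nrow(a) - 10L)) for (j in seq_len(ncol(a) - 10L)) {
    pa <- a[i:(i + 10L), j:(j + 10L)]
    pb <- b[i:(i + 10L), j:(j + 10L)]
    mu_a <- sum(w * pa); mu_b <- sum(w * pb)
    va <- sum(w * pa^2) - mu_a^2
    vb <- sum(w * pb^2) - mu_b^2
    vab <- sum(w * pa * pb) - mu_a * mu_b
    vals <- c(vals, ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
                    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2)))
  }
  mean(vals)
}

rand_points <- function(n, m, seed, directions = "minimize") {
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    objective_point(list(id = i), round(runif(m), 2), directions)))
}
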