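# Shared fixtures and independent oracles, built in code at test time.

# a recording with strictly increasing 4 ms steps and given points
make_recording <- function(xy, valid = rep(TRUE, nrow(xy)),
                           screen = c(1280, 1024), rate = 250) {
  gaze_recording(data.frame(t = (seq_len(nrow(xy)) - 1) * (1000 / rate),
                            x = xy[, 1], y = xy[, 2], valid = valid),
                 screen = screen, sampling_rate = rate)
}

# random valid recording: n samples uniform on the screen
random_recording <- function(n, screen = c(1280, 1024)) {
  make_recording(cbind(runif(n, 0, screen[1]), runif(n, 0, screen[2])),
                 screen = screen)
}

random_segment <- function(n = 50, screen = c(1280, 1024)) {
  segment_scanpath(random_recording(n, screen), max_points = n)[[1]]
}

# brute-force AUC: fraction of concordant positive/negative pairs, ties 1/2
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# brute-force velocity: pairwise Euclidean distance over time step, loop form
brute_force_speeds <- function(recording) {
  s <- recording$samples
  out <- c()
  for (i in seq_len(nrow(s) - 1)) {
    if (s$valid[i] && s$valid[i + 1]) {
      d <- sqrt((s$x[i + 1] - s$x[i])^2 + (s$y[i + 1] - s$y[i])^2)
      out <- c(out, d / (s$t[i + 1] - s$t[i]))
    }
  }
  out
}

# exhaustive MIC at small n: maximise normalised mutual information over all
# axis partitions (every subset of midpoint cuts) with nx * ny <= n^0.6
brute_force_mic <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- max(n^alpha, 4)
  mids <- function(v) {
    u <- sort(unique(v))
    if (length(u) < 2) numeric(0) else (utils::head(u, -1) + utils::tail(u, -1)) / 2
  }
  cx <- mids(x); cy <- mids(y)
  best <- 0
  for (nx in 2:floor(B / 2)) {
    if (nx - 1 > length(cx)) break
    nymax <- floor(B / nx)
    if (nymax < 2) break
    gx <- utils::combn(cx, nx - 1, simplify = FALSE)
    for (ny in 2:min(nymax, length(cy) + 1)) {
      gy <- utils::combn(cy, ny - 1, simplify = FALSE)
      denom <- log(min(nx, ny))
      for (a in gx) {
        xb <- findInterval(x, a)
        for (b in gy) {
          yb <- findInterval(y, b)
          tab <- tabulate(xb * (ny + 1) + yb + 1, (nx + 1) * (ny + 1)) / n
          tab <- matrix(tab, ncol = ny + 1, byrow = TRUE)
          tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
          px <- rowSums(tab); py <- colSums(tab)
          e <- outer(px, py)
          mi <- sum(ifelse(tab > 0, tab * log(tab / e), 0))
          v <- mi / denom
          if (v > best) best <- v
        }
      }
    }
  }
  best
}

# exhaustive best 2x2 grid score (tractable at any n): lower bound on MIC
brute_force_mic_2x2 <- function(x, y) {
  n <- length(x)
  mids <- function(v) {
    u <- sort(unique(v))
    (utils::head(u, -1) + utils::tail(u, -1)) / 2
  }
  best <- 0
  for (a in mids(x)) {
    xb <- x > a
    for (b in mids(y)) {
      yb <- y > b
      p <- c(sum(xb & yb), sum(xb & !yb), sum(!xb & yb), sum(!xb & !yb)) / n
      px <- c(p[1] + p[2], p[3] + p[4])
      py <- c(p[1] + p[3], p[2] + p[4])
      e <- c(px[1] * py[1], px[1] * py[2], px[2] * py[1], px[2] * py[2])
      mi <- sum(ifelse(p > 0, p * log(p / e), 0))
      if (mi / log(2) > best) best <- mi / log(2)
    }
  }
  best
}

# flat synthetic image with a lit block, for bookkeeping-style tests
block_image <- function(dims = c(16L, 16L), participant_id = "p0",
                        value = 0.5) {
  px <- matrix(0, dims[2], dims[1])
  px[4:10, 4:10] <- value
  scanpath_image(px, list(participant_id = participant_id,
                          stimulus_id = "s0", segment_index = 0L))
}
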