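# Fixture builders and independent oracles shared across the suite.

# construct a CohortPanel directly from a complete values array
makePanel <- function(values, mask = NULL, biomarkerIndex = integer(0),
                      surveyFlags = NULL) {
  d <- dim(values)
  if (is.null(dimnames(values)[[3]]))
    dimnames(values) <- list(NULL, NULL, paste0("f", seq_len(d[3])))
  fn <- dimnames(values)[[3]]
  if (is.null(mask)) mask <- array(TRUE, d)
  if (is.null(surveyFlags)) surveyFlags <- array(FALSE, c(d[1], d[2], 3))
  obs <- values
  obs[!mask] <- NA_real_
  new("CohortPanel", participantIds = sprintf("P%04d", seq_len(d[1])),
      values = obs, mask = mask, completeValues = values,
      featureNames = fn, biomarkerIndex = biomarkerIndex,
      surveyFlags = surveyFlags, metadata = list())
}

# smooth sinusoidal panel with MCAR masking; returns panel + truth + mask
makeSinusoidalPanel <- function(n = 100, T = 7, d = 4, missRate = 0.3,
                                noiseSd = 0.05, seed = 1) {
  set.seed(seed)
  vals <- array(0, c(n, T, d))
  for (i in seq_len(n))
    for (j in seq_len(d))
      vals[i, , j] <- sin(2 * pi * (seq_len(T) / T + i / n + j / d)) +
        rnorm(T, sd = noiseSd)
  mask <- array(runif(n * T * d) > missRate, c(n, T, d))
  list(panel = makePanel(vals, mask), truth = vals, mask = mask)
}

# plain-R forward pass of the multilayer recurrent classifier, one
# participant at a time (independent of the C++ batched implementation)
rnnForwardOracle <- function(weights, x, cell, H, L) {
  n <- dim(x)[1]; T <- dim(x)[2]
  sig <- function(v) 1 / (1 + exp(-v))
  probs <- numeric(n)
  for (i in seq_len(n)) {
    h <- replicate(L, rep(0, H), simplify = FALSE)
    cc <- replicate(L, rep(0, H), simplify = FALSE)
    for (t in seq_len(T)) {
      a <- x[i, t, ]
      for (l in seq_len(L)) {
        Wx <- weights[[paste0("Wx", l)]]
        Wh <- weights[[paste0("Wh", l)]]
        b <- as.numeric(weights[[paste0("b", l)]])
        pre <- as.numeric(a %*% Wx) + b
        hh <- as.numeric(h[[l]] %*% Wh)
        if (cell == "rnn") {
          h[[l]] <- tanh(pre + hh)
        } else if (cell == "gru") {
          r <- sig(pre[1:H] + hh[1:H])
          z <- sig(pre[(H + 1):(2 * H)] + hh[(H + 1):(2 * H)])
          nn <- tanh(pre[(2 * H + 1):(3 * H)] + r * hh[(2 * H + 1):(3 * H)])
          h[[l]] <- (1 - z) * nn + z * h[[l]]
        } else {
          p2 <- pre + hh
          i_ <- sig(p2[1:H]); f_ <- sig(p2[(H + 1):(2 * H)])
          g_ <- tanh(p2[(2 * H + 1):(3 * H)]); o_ <- sig(p2[(3 * H + 1):(4 * H)])
          cc[[l]] <- f_ * cc[[l]] + i_ * g_
          h[[l]] <- o_ * tanh(cc[[l]])
        }
        a <- h[[l]]
      }
    }
    probs[i] <- sig(sum(h[[L]] * weights$w_out) + weights$b_out[1, 1])
  }
  probs
}

# O(n^2) all-pairs concordance AUC with half credit for ties
aucPairwiseOracle <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# quick labeled dataset for trainer tests: class separated on feature 1
makeSeparableTask <- function(n = 200, T = 3, d = 4, gap = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  x <- array(rnorm(n * T * d), c(n, T, d))
  x[, , 1] <- x[, , 1] + gap * y
  list(x = x, y = y)
}

# independent window-enumeration oracles, written as naive loops
expandingOracle <- function(N, n) {
  out <- list()
  for (i in seq_len(N - n))
    out[[i]] <- list(input_steps = 1:(i + n - 1), label_step = i + n)
  out
}
rollingOracle <- function(N, n) {
  out <- list()
  for (i in seq_len(N - n))
    out[[i]] <- list(input_steps = i:(i + n - 1), label_step = i + n)
  out
}
skippingOracle <- function(N, w) {
  out <- list()
  for (i in seq_len(N - w - 2)) {
    steps <- c(); idx <- i + w + 1  # window end = last input step
    while (idx >= 1) { steps <- c(idx, steps); idx <- idx - (w + 1) }
    out[[i]] <- list(input_steps = steps, label_step = i + w + 2)
  }
  out
}
asPlain <- function(seqc) lapply(tasks(seqc), function(t)
  list(input_steps = as.integer(t$input_steps),
       label_step = as.integer(t$label_step)))
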