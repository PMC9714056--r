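# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive re-derivations (loops, pair counting, exhaustive
# search), kept free of the code paths they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_hexapeptides <- function(n, seed) {
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(AA20, 6, replace = TRUE), collapse = "")
  }, character(1)))
}

# Expensive shared objects, built once per test run.
.cache <- new.env()

fixture_train_fm <- function() {
  if (is.null(.cache$train_fm)) {
    ds <- gen_labelled_fixture(fixture_spec(100, seed = 3))
    .cache$train_ds <- ds
    .cache$train_fm <- extract_all(ds)
  }
  .cache$train_fm
}
fixture_train_ds <- function() { fixture_train_fm(); .cache$train_ds }

fixture_test_fm <- function() {
  if (is.null(.cache$test_fm)) {
    ds <- gen_labelled_fixture(fixture_spec(50, seed = 77))
    .cache$test_ds <- ds
    .cache$test_fm <- extract_all(ds)
  }
  .cache$test_fm
}
fixture_test_ds <- function() { fixture_test_fm(); .cache$test_ds }

# ---- oracles ---------------------------------------------------------------

# brute-force dipeptide-deviation over the length-1 windows of a sequence
oracle_dde <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  codons <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3,
              K = 2, L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6,
              T = 4, V = 4, W = 1, Y = 2)
  n_windows <- length(ch) - 1
  out <- numeric(0)
  for (a in AA20) {
    for (b in AA20) {
      dc <- 0
      for (k in seq_len(n_windows)) {
        if (ch[k] == a && ch[k + 1] == b) dc <- dc + 1
      }
      dc <- dc / n_windows
      tm <- (codons[[a]] / 61) * (codons[[b]] / 61)
      tv <- tm * (1 - tm) / n_windows
      out <- c(out, (dc - tm) / sqrt(tv))
    }
  }
  out
}

# brute-force pseudo amino-acid composition via an explicit double loop
oracle_paac <- function(sequence, lambda = 5, w = 0.05) {
  tb <- property_tables()
  ch <- strsplit(sequence, "")[[1]]
  len <- length(ch)
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    acc <- 0
    for (i in seq_len(len - j)) {
      s <- 0
      for (p in 1:3) {
        s <- s + (tb$paac_props[p, ch[i]] - tb$paac_props[p, ch[i + j]])^2
      }
      acc <- acc + s / 3
    }
    theta[j] <- acc / (len - j)
  }
  f <- vapply(AA20, function(a) sum(ch == a), numeric(1)) / len
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom)
}

# brute-force sequence-order coupling numbers
oracle_socnumber <- function(sequence, nlag = 5) {
  tb <- property_tables()
  ch <- strsplit(sequence, "")[[1]]
  len <- length(ch)
  tau <- function(dmat) {
    vapply(seq_len(nlag), function(d) {
      s <- 0
      for (i in seq_len(len - d)) s <- s + dmat[ch[i], ch[i + d]]^2
      s
    }, numeric(1))
  }
  c(tau(tb$physchem), tau(tb$grantham))
}

# brute-force autocorrelations from the standardised property table
oracle_autocorr <- function(sequence, kind, nlag = 5) {
  tb <- property_tables()
  ch <- strsplit(sequence, "")[[1]]
  len <- length(ch)
  out <- numeric(0)
  for (p in seq_len(nrow(tb$autocorr_props))) {
    x <- tb$autocorr_props[p, ch]
    xbar <- mean(x)
    for (d in seq_len(nlag)) {
      i <- seq_len(len - d)
      v <- switch(kind,
        NMBroto = sum(x[i] * x[i + d]) / (len - d),
        Moran = {
          den <- sum((x - xbar)^2) / len
          if (den < 1e-15) 0 else
            (sum((x[i] - xbar) * (x[i + d] - xbar)) / (len - d)) / den
        },
        Geary = {
          den <- sum((x - xbar)^2) / (len - 1)
          if (den < 1e-15) 0 else
            (sum((x[i] - x[i + d])^2) / (2 * (len - d))) / den
        })
      out <- c(out, v)
    }
  }
  out
}

# exhaustive weighted least-squares stump: best single split over all
# features and all midpoint thresholds
oracle_best_stump_sse <- function(X, y, w) {
  best_sse <- sum(w * (y - sum(w * y) / sum(w))^2)
  for (f in seq_len(ncol(X))) {
    xs <- sort(unique(X[, f]))
    if (length(xs) < 2) next
    thrs <- (xs[-1] + xs[-length(xs)]) / 2
    for (thr in thrs) {
      l <- X[, f] <= thr
      if (sum(w[l]) == 0 || sum(w[!l]) == 0) next
      ml <- sum(w[l] * y[l]) / sum(w[l])
      mr <- sum(w[!l] * y[!l]) / sum(w[!l])
      sse <- sum(w[l] * (y[l] - ml)^2) + sum(w[!l] * (y[!l] - mr)^2)
      if (sse < best_sse) best_sse <- sse
    }
  }
  best_sse
}

tree_sse <- function(tree, X, y, w) {
  sum(w * (y - predict_tree(tree, X))^2)
}

# AUC as the probability that a random positive outscores a random negative
# (ties one half), by explicit pair counting
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == "amyloid"]
  neg <- scores[labels == "non-amyloid"]
  total <- 0
  for (sp in pos) {
    for (sn in neg) {
      total <- total + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  total / (length(pos) * length(neg))
}
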