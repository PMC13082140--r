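## Independent oracles used by the test suite.  These deliberately avoid
## the package's own code paths.

## Brute-force one-vs-rest metrics from an explicitly built confusion
## matrix (nested loops, no vectorized counting).
oracle_metrics <- function(gold, pred) {
  classes <- c("negative", "neutral", "positive")
  cm <- matrix(0, 3, 3, dimnames = list(gold = classes, pred = classes))
  for (i in seq_along(gold))
    cm[gold[i], pred[i]] <- cm[gold[i], pred[i]] + 1
  per <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p = p, r = r, f = f)
  })
  m <- do.call(rbind, per)
  list(precision = m[, "p"], recall = m[, "r"], f1 = m[, "f"],
       macro = colMeans(m))
}

## Maximum-likelihood logistic fit through a generic optimizer (BFGS on the
## negative log-likelihood), independent of glm's IRLS.
oracle_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  gr <- function(b) {
    p <- plogis(as.numeric(X %*% b))
    as.numeric(t(X) %*% (p - y))
  }
  opt <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}

## Case-insensitive sentiment-substring search by brute force over all
## substrings of length 7/8 (the three class words).
oracle_sentiments_present <- function(x) {
  x <- tolower(x)
  found <- character(0)
  for (w in c("negative", "neutral", "positive")) {
    hit <- FALSE
    for (i in seq_len(max(nchar(x) - nchar(w) + 1, 0))) {
      if (substr(x, i, i + nchar(w) - 1) == w) {
        before_ok <- i == 1 || !grepl("[a-z]", substr(x, i - 1, i - 1))
        after <- substr(x, i + nchar(w), i + nchar(w))
        after_ok <- after == "" || !grepl("[a-z]", after)
        if (before_ok && after_ok) hit <- TRUE
      }
    }
    if (hit) found <- c(found, w)
  }
  found
}

## Random raw-output strings for parser totality fuzzing: a mix of random
## bytes, JSON fragments, and label-like text.
random_raw_strings <- function(n) {
  frags <- c("{", "}", "\"0\":", "\"negative\"", "neutral", "positive",
             "I cannot", "unable", "explanation:", "[1,2]", "null", ":",
             ",", "{\"0\"", "pt presents", "\\", "\"", "-", "/")
  vapply(seq_len(n), function(i) {
    k <- sample(0:6, 1)
    rand <- paste(sample(c(letters, LETTERS, 0:9, " ", ".", "!"),
                         sample(0:20, 1), replace = TRUE), collapse = "")
    paste(c(sample(frags, k, replace = TRUE), rand), collapse = " ")
  }, "")
}

## Tiny synthetic world reused across tests.
tiny_scenario <- function(n = 30, seed = 11) {
  scenario("table2", n_patients = n, seed = seed)
}
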