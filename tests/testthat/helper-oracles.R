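# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

random_seq <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Count overlapping occurrences of a pattern in a subject by direct scan.
naive_substring_count <- function(subject, pattern) {
  k <- nchar(pattern)
  L <- nchar(subject)
  if (L < k) return(0L)
  sum(vapply(1:(L - k + 1L),
             function(i) substr(subject, i, i + k - 1L) == pattern,
             logical(1)))
}

# Exhaustive O(L*W) sliding-window repeat scan: flag counts > thr, a window
# [i, i+W) is positive iff the flagged fraction >= comp (and > 0), union of
# positive windows is split into maximal runs, each run trimmed to its
# flagged span, ends extended by k-1.
naive_window_scan <- function(counts, W, thr, comp, k) {
  n <- length(counts)
  if (W > n) return(matrix(numeric(0), ncol = 2))
  flagged <- counts > thr
  covered <- rep(FALSE, n)
  for (i in 1:(n - W + 1L)) {
    frac <- mean(flagged[i:(i + W - 1L)])
    if (frac >= comp && frac > 0) covered[i:(i + W - 1L)] <- TRUE
  }
  if (!any(covered)) return(matrix(numeric(0), ncol = 2))
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- NULL
  for (j in which(r$values)) {
    lo <- starts[[j]]; hi <- ends[[j]]
    fl <- which(flagged[lo:hi])
    if (length(fl) > 0L) {
      lo2 <- lo + fl[[1L]] - 1L
      hi2 <- lo + fl[[length(fl)]] - 1L
    } else {
      lo2 <- lo; hi2 <- hi
    }
    out <- rbind(out, c(lo2 - 1L, hi2 - 1L + k))  # 0-based half-open bp
  }
  out
}

# Tiny Needleman/Smith-Waterman with traceback, match 2 / mismatch -6 /
# affine gaps open 5 extend 3 (costs), local mode. Independent of the
# package's Biostrings-based route; only for short strings.
naive_local_align <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)      # match/mismatch state
  X <- matrix(NEG, n + 1L, m + 1L)    # gap in b (deletion from a)
  Y <- matrix(NEG, n + 1L, m + 1L)    # gap in a
  ptr <- array(0L, c(n + 1L, m + 1L, 3L))
  best <- 0; bi <- 0L; bj <- 0L; bs <- 1L
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (A[[i]] == B[[j]]) 2 else -6
      cand <- c(M[i, j], X[i, j], Y[i, j], 0)
      w <- which.max(cand)
      if (cand[[w]] <= 0) w <- 4L  # local restart

      M[i + 1L, j + 1L] <- cand[[w]] + s
      ptr[i + 1L, j + 1L, 1L] <- w
      cx <- c(M[i, j + 1L] - 8, X[i, j + 1L] - 3)
      wx <- which.max(cx)
      X[i + 1L, j + 1L] <- cx[[wx]]
      ptr[i + 1L, j + 1L, 2L] <- wx
      cy <- c(M[i + 1L, j] - 8, Y[i + 1L, j] - 3)
      wy <- which.max(cy)
      Y[i + 1L, j + 1L] <- cy[[wy]]
      ptr[i + 1L, j + 1L, 3L] <- wy
      if (M[i + 1L, j + 1L] > best) {
        best <- M[i + 1L, j + 1L]; bi <- i + 1L; bj <- j + 1L; bs <- 1L
      }
    }
  }
  # traceback from (bi, bj) in state 1 until score source 0
  ra <- character(0); rb <- character(0)
  i <- bi; j <- bj; st <- bs
  while (i > 1L || j > 1L) {
    if (st == 1L) {
      src <- ptr[i, j, 1L]
      ra <- c(A[[i - 1L]], ra); rb <- c(B[[j - 1L]], rb)
      i <- i - 1L; j <- j - 1L
      if (src == 4L) break
      st <- src
    } else if (st == 2L) {
      src <- ptr[i, j, 2L]
      ra <- c(A[[i - 1L]], ra); rb <- c("-", rb)
      i <- i - 1L
      st <- if (src == 1L) 1L else 2L
    } else {
      src <- ptr[i, j, 3L]
      ra <- c("-", ra); rb <- c(B[[j - 1L]], rb)
      j <- j - 1L
      st <- if (src == 1L) 1L else 3L
    }
  }
  list(score = best, a_row = paste(ra, collapse = ""),
       b_row = paste(rb, collapse = ""))
}

# Exhaustive two-sided Fisher p by enumerating all tables with the observed
# margins.
naive_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, c1, n - c1, r1),
                  numeric(1))
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A 20-copy exact tandem fixture used by aligner tests.
exact_tandem_assembly <- function(monomer_len = 60L, copies = 20L,
                                  flank = 400L, seed = 42L) {
  set.seed(seed)
  monomer <- random_seq(monomer_len)
  genome_assembly(c(
    chrT = paste0(random_seq(flank), strrep(monomer, copies),
                  random_seq(flank))
  ))
}
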