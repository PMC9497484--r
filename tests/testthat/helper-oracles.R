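# Independent oracles used across the suite. These deliberately avoid the
# package's cumulative-moment code paths: sums are taken directly per
# threshold over pixels or bins.

# Brute-force class statistics by iterating over pixel values.
oracle_pixel_stats <- function(pixels, t) {
  x <- as.numeric(pixels)
  o <- x[x <= t]
  b <- x[x > t]
  n <- length(x)
  pv <- function(v) if (length(v) == 0) 0 else mean((v - mean(v))^2)
  mu_T <- mean(x)
  Po <- length(o) / n
  Pb <- length(b) / n
  mu_o <- if (length(o)) mean(o) else 0
  mu_b <- if (length(b)) mean(b) else 0
  list(
    Po = Po, Pb = Pb, mu_o = mu_o, mu_b = mu_b, mu_T = mu_T,
    var_o = pv(o), var_b = pv(b),
    var_between = Po * (mu_o - mu_T)^2 + Pb * (mu_b - mu_T)^2,
    var_within = Po * pv(o) + Pb * pv(b),
    var_total = pv(x)
  )
}

# Between-class variance curve by direct summation per threshold, with
# arbitrary bin values `vals` (vals = 0:(L-1) gives the Gaussian objective;
# vals = log(0:(L-1) + 1) gives the log-mapped objective).
oracle_between_curve <- function(p, vals = seq_along(p) - 1) {
  L <- length(p)
  mu_T <- sum(p * vals)
  sapply(seq_len(L), function(k) {
    Po <- sum(p[1:k])
    Pb <- if (k == L) 0 else sum(p[(k + 1):L])
    if (Po == 0 || Pb == 0) {
      return(0)
    }
    mu_o <- sum(p[1:k] * vals[1:k]) / Po
    mu_b <- sum(p[(k + 1):L] * vals[(k + 1):L]) / Pb
    Po * (mu_o - mu_T)^2 + Pb * (mu_b - mu_T)^2
  })
}

oracle_argmax <- function(v) which.max(v) - 1L

# Misclassification count at each threshold, for a pixel vector + truth.
oracle_misclass <- function(pixels, truth, L = 256) {
  x <- as.numeric(pixels)
  tr <- as.logical(truth)
  sapply(0:(L - 1), function(t) sum((x > t) != tr))
}

# Random histograms: a mix of sparse-spiky and smooth shapes under one seed.
rand_hist <- function(L = 256, n_pixels = NULL) {
  if (is.null(n_pixels)) {
    n_pixels <- sample(200:5000, 1)
  }
  shape <- sample(c("spiky", "smooth"), 1)
  w <- if (shape == "spiky") {
    rgamma(L, shape = 0.05) # most bins near-empty
  } else {
    rgamma(L, shape = 2)
  }
  counts <- as.vector(stats::rmultinom(1, n_pixels, prob = w / sum(w)))
  gray_histogram(counts, L = L)
}

# All ways of distributing n pixels over k bins (compositions); used for
# exhaustive small-L checks.
compositions <- function(n, k) {
  if (k == 1) {
    return(matrix(n, 1, 1))
  }
  do.call(rbind, lapply(0:n, function(j) {
    cbind(j, compositions(n - j, k - 1))
  }))
}

# Random small grayscale image.
rand_image <- function(nr = 16, nc = 16, L = 8) {
  matrix(sample(0:(L - 1), nr * nc, replace = TRUE), nr, nc)
}

# scikit-image's threshold_otsu computed from a histogram, via the python
# on PATH; used as the cross-implementation reference.
skimage_otsu <- function(counts) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(paste(counts, collapse = ","), f)
  code <- paste0(
    "import numpy as np; from skimage.filters import threshold_otsu; ",
    "c = np.loadtxt('", f, "', delimiter=','); ",
    "print(int(threshold_otsu(hist=(c, np.arange(c.size)))))"
  )
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  as.integer(out[length(out)])
}
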