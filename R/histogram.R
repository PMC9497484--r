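#' Gray-level histograms
#'
#' A gray-level histogram is the substrate of every thresholding objective in
#' this package. It is represented as a tibble with one row per intensity bin
#' and columns `bin` (0 to L-1), `count` (pixel count n_i) and `p` (bin
#' probability n_i / n), carrying the total pixel count `n` and the number of
#' gray levels `L` as attributes.
#'
#' @param counts Non-negative per-bin pixel counts, length `L`.
#' @param L Number of gray levels; defaults to `length(counts)`.
#' @return A `gray_histogram` tibble.
#' @export
gray_histogram <- function(counts, L = length(counts)) {
  counts <- as.numeric(counts)
  if (length(counts) != L) {
    abort("length(counts) must equal L")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != trunc(counts))) {
    abort("counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n <= 0) {
    abort("empty input")
  }
  out <- tibble(bin = 0:(L - 1L), count = counts, p = counts / n)
  structure(out,
    class = c("gray_histogram", class(out)),
    n = n, L = as.integer(L)
  )
}

#' Compute the intensity histogram of a grayscale image
#'
#' Tallies per-bin pixel counts `n_i` and probabilities `P_i = n_i / n` over
#' the `L` gray levels.
#'
#' @param image An integer matrix of gray levels in `[0, L-1]` (or anything
#'   accepted by [validate_gray_image()]).
#' @param L Number of gray levels (default 256).
#' @return A `gray_histogram` tibble with columns `bin`, `count`, `p`.
#' @examples
#' img <- matrix(c(0L, 0L, 0L, 0L), 2, 2)
#' compute_histogram(img)
#' @export
compute_histogram <- function(image, L = 256L) {
  image <- validate_gray_image(image, L = L)
  counts <- tabulate(as.integer(image) + 1L, nbins = L)
  gray_histogram(counts, L = L)
}

#' Number of pixels and gray levels of a histogram
#'
#' @param h A `gray_histogram`.
#' @return An integer scalar.
#' @export
hist_n <- function(h) attr(h, "n")

#' @rdname hist_n
#' @export
hist_L <- function(h) attr(h, "L")

#' Per-threshold class statistics of a histogram
#'
#' For each candidate threshold `t` the histogram is split into an object
#' class (bins `0..t`) and a background class (bins `t+1..L-1`). The function
#' returns the class probabilities, class means, class variances and the
#' between/within/total variance decomposition. For a threshold leaving one
#' class empty the empty class's mean and variance are defined as 0 and the
#' row is flagged `degenerate`; every objective in this package scores such
#' thresholds 0 so the argmax scan stays total over `[0, L-1]`.
#'
#' The identities `Po + Pb = 1`, `Po*mu_o + Pb*mu_b = mu_T` and
#' `var_between + var_within = var_total` hold (to floating-point tolerance)
#' whenever both classes are non-empty, and `var_total` does not depend on
#' `t`.
#'
#' @param h A `gray_histogram`.
#' @param t Integer thresholds in `[0, L-1]`; defaults to all of them.
#' @return A tibble with one row per `t` and columns `t`, `Po`, `Pb`, `mu_o`,
#'   `mu_b`, `mu_T`, `var_o`, `var_b`, `var_between`, `var_within`,
#'   `var_total`, `degenerate`.
#' @export
class_stats <- function(h, t = NULL) {
  stopifnot(inherits(h, "gray_histogram"))
  L <- hist_L(h)
  n <- hist_n(h)
  if (is.null(t)) {
    t <- 0:(L - 1L)
  }
  if (any(t < 0 | t > L - 1L | t != trunc(t))) {
    abort(sprintf("t must be an integer in [0, %d]", L - 1L))
  }
  counts <- h$count
  i <- 0:(L - 1L)
  # Cumulative moments on integer counts: class emptiness is detected
  # exactly, probabilities are formed once in double precision.
  C0 <- cumsum(counts)
  C1 <- cumsum(i * counts)
  C2 <- cumsum(i^2 * counts)
  mu_T <- C1[L] / n
  var_total <- C2[L] / n - mu_T^2

  idx <- t + 1L
  no <- C0[idx]
  nb <- n - no
  Po <- no / n
  Pb <- nb / n
  mu_o <- ifelse(no > 0, C1[idx] / no, 0)
  mu_b <- ifelse(nb > 0, (C1[L] - C1[idx]) / nb, 0)
  var_o <- ifelse(no > 0, pmax(C2[idx] / no - mu_o^2, 0), 0)
  var_b <- ifelse(nb > 0, pmax((C2[L] - C2[idx]) / nb - mu_b^2, 0), 0)
  var_between <- Po * (mu_o - mu_T)^2 + Pb * (mu_b - mu_T)^2
  var_within <- Po * var_o + Pb * var_b

  tibble(
    t = as.integer(t),
    Po = Po, Pb = Pb,
    mu_o = mu_o, mu_b = mu_b, mu_T = mu_T,
    var_o = var_o, var_b = var_b,
    var_between = var_between,
    var_within = var_within,
    var_total = var_total,
    degenerate = no == 0 | nb == 0
  )
}

#' Read and write histograms as CSV or JSON
#'
#' The CSV form has columns `bin,count`; the JSON form is
#' `{"counts": [...]}`.
#'
#' @param h A `gray_histogram`.
#' @param path File path.
#' @param L Number of gray levels assumed when reading CSV (bins absent from
#'   the file are zero).
#' @return The histogram (readers) or `path`, invisibly (writers).
#' @export
write_histogram_csv <- function(h, path) {
  stopifnot(inherits(h, "gray_histogram"))
  write.csv(data.frame(bin = h$bin, count = h$count), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path, L = 256L) {
  d <- read.csv(path)
  if (!all(c("bin", "count") %in% names(d))) {
    abort("histogram CSV must have columns bin,count")
  }
  counts <- numeric(L)
  counts[d$bin + 1L] <- d$count
  gray_histogram(counts, L = L)
}

#' @rdname write_histogram_csv
#' @export
write_histogram_json <- function(h, path) {
  stopifnot(inherits(h, "gray_histogram"))
  jsonlite::write_json(list(counts = h$count), path, digits = NA)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(d$counts)) {
    abort("histogram JSON must contain a \"counts\" array")
  }
  gray_histogram(d$counts)
}

#' @exportS3Method ggplot2::autoplot
autoplot.gray_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::labs(x = "gray level", y = "pixel count") +
    ggplot2::theme_minimal()
}
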