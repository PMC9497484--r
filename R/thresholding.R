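#' Log-intensity map
#'
#' The lognormal objectives replace the gray level `i` by a log-intensity
#' `lambda(i)`. The sum defining the class log-means starts at bin 0, where
#' `log(0)` is undefined, so two conventions are offered: `"shift1"` (the
#' default) uses `lambda(i) = log(i + 1)`, which is monotone and defined
#' everywhere; `"skip-zero"` uses `lambda(i) = log(i)` and excludes bin 0
#' from the log-mean sums (the lognormal model lives on `x > 0`).
#'
#' @param L Number of gray levels.
#' @param log_map `"shift1"` or `"skip-zero"`.
#' @return A numeric vector of length `L` of log-mapped bin values.
#' @keywords internal
log_intensity_map <- function(L, log_map = c("shift1", "skip-zero")) {
  log_map <- match.arg(log_map)
  if (log_map == "shift1") {
    log(seq_len(L))
  } else {
    c(0, log(seq_len(L - 1L)))
  }
}

# Class masses used by the lognormal objectives. Under "skip-zero" bin 0 is
# excluded from the lognormal model entirely, so the masses renormalise over
# bins >= 1; under "shift1" they are the ordinary class counts.
log_weights <- function(h, log_map) {
  w <- h$count
  if (log_map == "skip-zero") {
    w[1L] <- 0
  }
  w
}

#' Class log-means at candidate thresholds
#'
#' Computes the object, background and total means of the log-mapped
#' intensities: `mu_o_log(t)` is the `lambda(i)`-mean of bins `0..t` weighted
#' by their counts, `mu_b_log(t)` the complement, and `mu_T_log` the whole
#' histogram's log-mean. Empty classes yield 0 and are flagged `degenerate`.
#' The weighted decomposition `Po*mu_o_log + Pb*mu_b_log = mu_T_log` holds
#' whenever both classes are non-empty.
#'
#' @inheritParams class_stats
#' @inheritParams log_intensity_map
#' @return A tibble with columns `t`, `mu_o_log`, `mu_b_log`, `mu_T_log`,
#'   `degenerate`.
#' @export
log_means <- function(h, t = NULL, log_map = c("shift1", "skip-zero")) {
  stopifnot(inherits(h, "gray_histogram"))
  log_map <- match.arg(log_map)
  L <- hist_L(h)
  if (is.null(t)) {
    t <- 0:(L - 1L)
  }
  if (any(t < 0 | t > L - 1L | t != trunc(t))) {
    abort(sprintf("t must be an integer in [0, %d]", L - 1L))
  }
  lam <- log_intensity_map(L, log_map)
  w <- log_weights(h, log_map)
  Cw <- cumsum(w)
  Cl <- cumsum(w * lam)
  nw <- Cw[L]

  idx <- t + 1L
  no <- Cw[idx]
  nb <- nw - no
  mu_o_log <- ifelse(no > 0, Cl[idx] / no, 0)
  mu_b_log <- ifelse(nb > 0, (Cl[L] - Cl[idx]) / nb, 0)
  mu_T_log <- if (nw > 0) Cl[L] / nw else 0

  tibble(
    t = as.integer(t),
    mu_o_log = mu_o_log,
    mu_b_log = mu_b_log,
    mu_T_log = mu_T_log,
    degenerate = no == 0 | nb == 0
  )
}

new_threshold_curve <- function(values, method, log_map = NA_character_) {
  L <- length(values)
  out <- tibble(t = 0:(L - 1L), value = values)
  structure(out,
    class = c("threshold_curve", class(out)),
    method = method,
    log_map = log_map,
    t_star = which.max(values) - 1L,
    L = as.integer(L)
  )
}

#' Threshold objective curves
#'
#' Evaluates one of the three between-class variance objectives at every
#' candidate threshold `t` in `[0, L-1]` and records the argmax `t*` (ties
#' broken to the smallest `t`, matching an upward sequential scan).
#'
#' * `otsu_gaussian` — the classical Otsu objective. The production path is
#'   the rational form `(mu_T*Po - mu_cum)^2 / (Po*(1 - Po))` built from the
#'   cumulative moments; `form = "explicit"` instead evaluates the two-term
#'   between-class variance `Po*(mu_o - mu_T)^2 + Pb*(mu_b - mu_T)^2`. The
#'   two agree to floating-point tolerance.
#' * `otsu_modified` — the rational Otsu form with the class and total means
#'   replaced by the log-intensity means (the "mean of the lognormal" drop-in
#'   baseline).
#' * `otsu_lognormal` — the between-class variance computed entirely in
#'   log-intensity space:
#'   `Po*(mu_o_log - mu_T_log)^2 + Pb*(mu_b_log - mu_T_log)^2`.
#'
#' Thresholds that leave a class empty are scored 0, so the scan is total.
#'
#' @inheritParams log_means
#' @param method One of `"otsu_gaussian"`, `"otsu_modified"`,
#'   `"otsu_lognormal"`.
#' @param form For `otsu_gaussian` only: `"rational"` (default) or
#'   `"explicit"`.
#' @return A `threshold_curve` tibble with columns `t`, `value` and
#'   attributes `method`, `t_star`.
#' @export
otsu_curve <- function(h, method = OTSU_METHODS,
                       log_map = c("shift1", "skip-zero"),
                       form = c("rational", "explicit")) {
  stopifnot(inherits(h, "gray_histogram"))
  method <- match.arg(method)
  log_map <- match.arg(log_map)
  form <- match.arg(form)
  L <- hist_L(h)

  if (method == "otsu_gaussian") {
    if (form == "rational") {
      counts <- h$count
      n <- hist_n(h)
      i <- 0:(L - 1L)
      C0 <- cumsum(counts)
      Po <- C0 / n
      Pb <- (n - C0) / n
      mu_cum <- cumsum(i * counts) / n
      mu_T <- mu_cum[L]
      v <- ifelse(C0 > 0 & C0 < n,
        (mu_T * Po - mu_cum)^2 / (Po * Pb), 0
      )
    } else {
      cs <- class_stats(h)
      v <- ifelse(cs$degenerate, 0, cs$var_between)
    }
    return(new_threshold_curve(pmax(v, 0), method))
  }

  lam <- log_intensity_map(L, log_map)
  w <- log_weights(h, log_map)
  Cw <- cumsum(w)
  nw <- Cw[L]
  if (nw == 0) {
    # all mass at bin 0 under skip-zero: no lognormal model to fit
    return(new_threshold_curve(rep(0, L), method, log_map))
  }
  Po <- Cw / nw
  Pb <- (nw - Cw) / nw
  M_log <- cumsum(w * lam) / nw
  mu_T_log <- M_log[L]
  nondeg <- Cw > 0 & Cw < nw

  if (method == "otsu_modified") {
    v <- ifelse(nondeg, (mu_T_log * Po - M_log)^2 / (Po * Pb), 0)
  } else {
    mu_o_log <- ifelse(Cw > 0, M_log / Po, 0)
    mu_b_log <- ifelse(Cw < nw, (mu_T_log - M_log) / Pb, 0)
    v <- ifelse(nondeg,
      Po * (mu_o_log - mu_T_log)^2 + Pb * (mu_b_log - mu_T_log)^2, 0
    )
  }
  new_threshold_curve(pmax(v, 0), method, log_map)
}

#' @rdname otsu_curve
#' @export
otsu_gaussian_curve <- function(h, form = c("rational", "explicit")) {
  otsu_curve(h, "otsu_gaussian", form = match.arg(form))
}

#' @rdname otsu_curve
#' @export
otsu_modified_curve <- function(h, log_map = c("shift1", "skip-zero")) {
  otsu_curve(h, "otsu_modified", log_map = match.arg(log_map))
}

#' @rdname otsu_curve
#' @export
otsu_lognormal_curve <- function(h, log_map = c("shift1", "skip-zero")) {
  otsu_curve(h, "otsu_lognormal", log_map = match.arg(log_map))
}

#' Optimal threshold of a curve or thresholding result
#'
#' @param x A `threshold_curve` or `skewotsu_threshold`.
#' @return The integer threshold `t*`.
#' @export
t_star <- function(x) {
  if (inherits(x, "threshold_curve")) {
    return(attr(x, "t_star"))
  }
  if (inherits(x, "skewotsu_threshold")) {
    return(x$t_star)
  }
  abort("no threshold in this object")
}

#' Threshold an image with one of the three objectives
#'
#' Computes the image histogram, evaluates the selected objective over all
#' candidate thresholds, and binarizes the image at the argmax `t*`. Object
#' pixels are those with intensity strictly greater than `t*` (bright object
#' on dark background); `invert = TRUE` flips the polarity. A constant image
#' has no between-class structure: every objective is identically 0, `t*` is
#' 0, the mask is all-`FALSE` and the result is flagged degenerate (with a
#' warning).
#'
#' @param image An integer matrix of gray levels in `[0, L-1]`.
#' @param method One of `"otsu_gaussian"`, `"otsu_modified"`,
#'   `"otsu_lognormal"`.
#' @inheritParams log_intensity_map
#' @param invert Flip mask polarity (object = pixels `<= t*`).
#' @param L Number of gray levels (default 256).
#' @return A `skewotsu_threshold` object: a list with elements `t_star`,
#'   `method`, `mask` (logical matrix), `curve` (the `threshold_curve`),
#'   `degenerate` and `invert`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' img <- matrix(c(rep(50L, 8), rep(200L, 8)), 4, 4)
#' fit <- threshold_image(img, "otsu_lognormal")
#' fit$t_star
#' glance(fit)
#' @export
threshold_image <- function(image, method = OTSU_METHODS,
                            log_map = c("shift1", "skip-zero"),
                            invert = FALSE, L = 256L) {
  method <- match.arg(method)
  log_map <- match.arg(log_map)
  image <- validate_gray_image(image, L = L)
  h <- compute_histogram(image, L = L)
  curve <- otsu_curve(h, method, log_map = log_map)
  degenerate <- all(curve$value == 0)
  if (degenerate) {
    warn("degenerate image: no between-class variance at any threshold")
    ts <- 0L
    mask <- matrix(FALSE, nrow(image), ncol(image))
  } else {
    ts <- attr(curve, "t_star")
    mask <- image > ts
    if (invert) {
      mask <- !mask
    }
  }
  structure(
    list(
      t_star = ts, method = method, mask = mask, curve = curve,
      degenerate = degenerate, invert = invert, L = as.integer(L)
    ),
    class = "skewotsu_threshold"
  )
}

#' @export
print.skewotsu_threshold <- function(x, ...) {
  cat(sprintf(
    "<skewotsu_threshold> method = %s, t* = %d%s\n",
    x$method, x$t_star, if (x$degenerate) " (degenerate image)" else ""
  ))
  cat(sprintf(
    "  object pixels: %d of %d (%.1f%%)\n",
    sum(x$mask), length(x$mask), 100 * mean(x$mask)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.skewotsu_threshold <- function(x, ...) {
  dplyr::mutate(as_tibble(x$curve), method = x$method, .before = 1L)
}

#' @exportS3Method generics::glance
glance.skewotsu_threshold <- function(x, ...) {
  tibble(
    method = x$method,
    t_star = x$t_star,
    degenerate = x$degenerate,
    n_object = sum(x$mask),
    n_background = sum(!x$mask),
    prop_object = mean(x$mask)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.threshold_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(
      xintercept = attr(object, "t_star"),
      linetype = "dashed", color = "firebrick"
    ) +
    ggplot2::labs(
      x = "candidate threshold t",
      y = "between-class variance",
      title = attr(object, "method"),
      subtitle = sprintf("t* = %d", attr(object, "t_star"))
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.skewotsu_threshold <- function(object, ...) {
  autoplot(object$curve, ...)
}

#' Write a threshold curve as CSV
#'
#' @param curve A `threshold_curve`.
#' @param path Output path; columns `t,value`.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "threshold_curve"))
  write.csv(data.frame(t = curve$t, value = curve$value), path,
    row.names = FALSE
  )
  invisible(path)
}
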