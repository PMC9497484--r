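#' Lognormal probability density
#'
#' Density of the lognormal distribution,
#' `f(x) = 1 / (x * sigma * sqrt(2*pi)) * exp(-((log(x) - mu) / sigma)^2 / 2)`,
#' defined for `x > 0`. The distribution is right-skewed, increasingly so as
#' `sigma` grows; its mode sits at `exp(mu - sigma^2)` and its mean at
#' `exp(mu + sigma^2 / 2)`.
#'
#' @param x Positive intensities.
#' @param mu Log-scale location.
#' @param sigma Log-scale standard deviation (> 0).
#' @return Densities at `x`.
#' @export
lognormal_pdf <- function(x, mu, sigma) {
  if (sigma <= 0) {
    abort("sigma must be > 0")
  }
  if (any(x <= 0)) {
    abort("x must be > 0: the lognormal density is defined on (0, Inf)")
  }
  dlnorm(x, meanlog = mu, sdlog = sigma)
}

#' Specify a two-component lognormal mixture image
#'
#' A mixture spec describes a synthetic two-region image: object pixels
#' (inside the shape) draw their intensities from one lognormal component,
#' background pixels from the other. By convention the object is the
#' *brighter* component (larger lognormal mean `exp(mu + sigma^2/2)`),
#' matching the bright-tumor-on-dark-tissue geometry the bright-object mask
#' polarity assumes. Component weights are the exact pixel fractions of the
#' shape and so sum to 1.
#'
#' @param object,background Named numeric vectors `c(mu = , sigma = )`, the
#'   log-scale location and standard deviation of each component.
#' @param coverage Fraction of pixels inside the object shape, in (0, 1).
#' @param shape `"disk"` (centered disk), `"rect"` (centered square) or
#'   `"blobs"` (two disks).
#' @param size Image dimensions, default `c(256, 256)`.
#' @param seed RNG seed used by [generate_image()].
#' @param allow_identical Permit identical object/background components (for
#'   degenerate-case studies); otherwise the object must be strictly
#'   brighter.
#' @return A `mixture_spec` object.
#' @seealso [mixture_template()] for the two named study templates.
#' @export
mixture_spec <- function(object = c(mu = 5.0, sigma = 0.25),
                         background = c(mu = 3.5, sigma = 0.25),
                         coverage = 0.5,
                         shape = c("disk", "rect", "blobs"),
                         size = c(256L, 256L),
                         seed = NULL,
                         allow_identical = FALSE) {
  shape <- match.arg(shape)
  object <- unlist(object)
  background <- unlist(background)
  for (m in list(object, background)) {
    if (!all(c("mu", "sigma") %in% names(m)) || m[["sigma"]] <= 0) {
      abort("each mode needs mu and sigma > 0")
    }
  }
  if (coverage <= 0 || coverage >= 1) {
    abort("coverage must lie strictly between 0 and 1")
  }
  mean_o <- exp(object[["mu"]] + object[["sigma"]]^2 / 2)
  mean_b <- exp(background[["mu"]] + background[["sigma"]]^2 / 2)
  if (!allow_identical && mean_o <= mean_b) {
    abort(paste0(
      "object component must be brighter than the background ",
      "(lognormal mean ", signif(mean_o, 4), " vs ", signif(mean_b, 4), "); ",
      "set allow_identical = TRUE for degenerate studies"
    ))
  }
  structure(
    list(
      object = object, background = background,
      coverage = coverage, shape = shape,
      size = as.integer(size), seed = seed
    ),
    class = "mixture_spec"
  )
}

#' Named mixture templates used throughout the package
#'
#' * `"well_separated"` — object (mu 5.0, sigma 0.25), background (mu 3.5,
#'   sigma 0.25), coverage 0.5. Equal log-scale dispersion and equal class
#'   weights with a 6-sigma gap between log-means: the regime where the
#'   log-domain threshold tracks the misclassification-minimizing boundary.
#' * `"high_skew"` — object (mu 4.7, sigma 0.55), background (mu 3.5,
#'   sigma 0.55), coverage 0.40. Strongly right-skewed, overlapping modes:
#'   the failure regime of the Gaussian objective that the lognormal
#'   objective targets.
#'
#' @param name Template name.
#' @param seed Seed stored in the spec.
#' @param ... Overrides passed on to [mixture_spec()].
#' @return A `mixture_spec`.
#' @export
mixture_template <- function(name = c("well_separated", "high_skew"),
                             seed = NULL, ...) {
  name <- match.arg(name)
  args <- switch(name,
    well_separated = list(
      object = c(mu = 5.0, sigma = 0.25),
      background = c(mu = 3.5, sigma = 0.25),
      coverage = 0.5
    ),
    high_skew = list(
      object = c(mu = 4.7, sigma = 0.55),
      background = c(mu = 3.5, sigma = 0.55),
      coverage = 0.40
    )
  )
  args$seed <- seed
  do.call(mixture_spec, utils::modifyList(args, list(...)))
}

# Pixel membership of the object shape. Shapes are sized so the object
# covers (approximately, exactly up to pixelation) `coverage` of the image.
shape_mask <- function(spec) {
  w <- spec$size[1]
  h <- spec$size[2]
  xs <- matrix(seq_len(w), w, h)
  ys <- matrix(seq_len(h), w, h, byrow = TRUE)
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  area <- spec$coverage * w * h
  mask <- switch(spec$shape,
    disk = {
      r <- sqrt(area / pi)
      (xs - cx)^2 + (ys - cy)^2 <= r^2
    },
    rect = {
      half <- sqrt(area) / 2
      abs(xs - cx) <= half & abs(ys - cy) <= half
    },
    blobs = {
      r <- sqrt(area / (2 * pi))
      d1 <- (xs - w / 3)^2 + (ys - h / 3)^2 <= r^2
      d2 <- (xs - 2 * w / 3)^2 + (ys - 2 * h / 3)^2 <= r^2
      d1 | d2
    }
  )
  if (!any(mask) || all(mask)) {
    abort("degenerate shape: object or background region is empty")
  }
  mask
}

#' Generate one synthetic two-region image with ground truth
#'
#' Samples object-region intensities from the spec's object lognormal
#' component and background intensities from the background component,
#' rounds them to integers and clamps to `[1, 255]` (bin 0 is left empty:
#' the lognormal model lives on positive intensities). The fraction of
#' samples falling outside `[1, 255]` before clamping is reported as
#' `clamp_fraction`. Running the generator twice with the same spec (same
#' seed) reproduces the image exactly.
#'
#' @param spec A [mixture_spec()].
#' @return A list with `image` (integer matrix), `truth` (logical matrix,
#'   the exact object membership), `clamp_fraction` and `spec`.
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  truth <- shape_mask(spec)
  n_o <- sum(truth)
  n_b <- sum(!truth)
  draw <- function() {
    list(
      o = rlnorm(n_o, spec$object[["mu"]], spec$object[["sigma"]]),
      b = rlnorm(n_b, spec$background[["mu"]], spec$background[["sigma"]])
    )
  }
  raw <- if (is.null(spec$seed)) draw() else withr::with_seed(spec$seed, draw())
  all_r <- round(c(raw$o, raw$b))
  clamp_fraction <- mean(all_r < 1 | all_r > 255)
  img <- matrix(0L, spec$size[1], spec$size[2])
  img[truth] <- as.integer(pmin(pmax(round(raw$o), 1), 255))
  img[!truth] <- as.integer(pmin(pmax(round(raw$b), 1), 255))
  list(image = img, truth = truth, clamp_fraction = clamp_fraction, spec = spec)
}

#' Generate a seeded dataset of mixture images
#'
#' Produces `n` images from a template spec with per-image parameter jitter:
#' each class's log-location `mu` is perturbed independently, the log-scale
#' `sigma` of both classes is perturbed *jointly* (dispersion is treated as a
#' global acquisition property, so the two tissue classes keep their shared
#' multiplicative spread), and the object coverage is perturbed. All jitters
#' are uniform on `+/-` the stated half-widths. The same master seed
#' reproduces the dataset exactly.
#'
#' @param n Number of images.
#' @param template A `mixture_spec` or a template name for
#'   [mixture_template()].
#' @param seed Master RNG seed.
#' @param jitter Named list of uniform jitter half-widths:
#'   `mu`, `sigma`, `coverage`.
#' @return A tibble with one row per image: `id`, list-columns `image` and
#'   `truth`, the realized parameters, the per-image `seed` and the
#'   `clamp_fraction`. This tibble is the in-memory manifest;
#'   [write_dataset()] serializes it.
#' @export
generate_dataset <- function(n, template = "high_skew", seed = 1L,
                             jitter = list(mu = 0.1, sigma = 0.05,
                                           coverage = 0.05)) {
  if (n < 1) {
    abort("n must be >= 1")
  }
  base <- if (is.character(template)) mixture_template(template) else template
  stopifnot(inherits(base, "mixture_spec"))
  jit <- utils::modifyList(list(mu = 0, sigma = 0, coverage = 0), jitter)
  params <- withr::with_seed(seed, {
    tibble(
      mu_o = base$object[["mu"]] + stats::runif(n, -jit$mu, jit$mu),
      mu_b = base$background[["mu"]] + stats::runif(n, -jit$mu, jit$mu),
      dsigma = stats::runif(n, -jit$sigma, jit$sigma),
      coverage = pmin(pmax(
        base$coverage + stats::runif(n, -jit$coverage, jit$coverage),
        0.01
      ), 0.99),
      seed = sample.int(.Machine$integer.max, n)
    )
  })
  rows <- purrr::pmap(params, function(mu_o, mu_b, dsigma, coverage, seed) {
    spec <- mixture_spec(
      object = c(mu = mu_o, sigma = base$object[["sigma"]] + dsigma),
      background = c(mu = mu_b, sigma = base$background[["sigma"]] + dsigma),
      coverage = coverage, shape = base$shape, size = base$size, seed = seed
    )
    g <- generate_image(spec)
    tibble(
      image = list(g$image), truth = list(g$truth),
      mu_o = mu_o, sigma_o = spec$object[["sigma"]],
      mu_b = mu_b, sigma_b = spec$background[["sigma"]],
      coverage = coverage, shape = base$shape, seed = seed,
      clamp_fraction = g$clamp_fraction
    )
  })
  dplyr::bind_rows(rows, .id = NULL) |>
    dplyr::mutate(id = sprintf("img_%03d", seq_len(n)), .before = 1L)
}

#' Write and read a generated dataset
#'
#' `write_dataset()` writes each image and its ground-truth mask as 8-bit
#' PNGs plus a `manifest.json` recording every generation parameter;
#' `read_dataset()` reconstructs the dataset tibble from such a directory
#' (or from any directory of images, with masks matched by filename, when no
#' manifest is present).
#'
#' @param dataset A tibble from [generate_dataset()].
#' @param dir Output/input directory.
#' @return `dir`, invisibly, for the writer; a dataset tibble for the
#'   reader.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(nrow(dataset))) {
    id <- dataset$id[k]
    write_gray_png(dataset$image[[k]], file.path(dir, paste0(id, ".png")))
    write_mask_png(dataset$truth[[k]], file.path(dir, paste0(id, "_mask.png")))
  }
  manifest <- dataset |>
    dplyr::select(-dplyr::any_of(c("image", "truth")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    digits = NA, auto_unbox = FALSE
  )
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    manifest <- as_tibble(jsonlite::read_json(mf, simplifyVector = TRUE))
    ids <- manifest$id
  } else {
    files <- list.files(dir, pattern = "\\.(png|tif|tiff)$", full.names = FALSE)
    files <- files[!grepl("_mask\\.", files)]
    if (length(files) == 0L) {
      abort(paste0("no images found in ", dir))
    }
    ids <- tools::file_path_sans_ext(files)
    manifest <- tibble(id = ids)
  }
  imgs <- purrr::map(ids, function(id) {
    read_gray_image(find_image_file(dir, id))
  })
  truths <- purrr::map(ids, function(id) {
    f <- tryCatch(find_image_file(dir, paste0(id, "_mask")),
      error = function(e) NULL
    )
    if (is.null(f)) NULL else read_gray_image(f) > 0
  })
  dplyr::mutate(manifest,
    image = imgs, truth = truths,
    .after = "id"
  )
}

find_image_file <- function(dir, id) {
  for (ext in c(".png", ".tif", ".tiff")) {
    f <- file.path(dir, paste0(id, ext))
    if (file.exists(f)) {
      return(f)
    }
  }
  abort(paste0("no image file for ", id, " in ", dir))
}
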