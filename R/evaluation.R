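#' Pixelwise confusion counts between a mask and its ground truth
#'
#' Counts true positives (object in both), true negatives, false positives
#' (object in the mask only) and false negatives, with the mask as the
#' prediction and the truth as the reference. The four counts always sum to
#' the number of pixels.
#'
#' @param mask A logical matrix, or a `skewotsu_threshold` (its mask is
#'   used).
#' @param truth A logical matrix of the same dimensions.
#' @return A one-row tibble with integer columns `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(mask, truth) {
  mask <- as_mask(mask)
  truth <- as_mask(truth)
  if (!identical(dim(mask), dim(truth))) {
    abort("mask and truth dimensions differ")
  }
  tibble(
    TP = sum(mask & truth),
    TN = sum(!mask & !truth),
    FP = sum(mask & !truth),
    FN = sum(!mask & truth)
  )
}

as_mask <- function(x) {
  if (inherits(x, "skewotsu_threshold")) {
    return(x$mask)
  }
  if (is.matrix(x) && is.logical(x)) {
    return(x)
  }
  if (is.matrix(x) && is.numeric(x) && all(x %in% c(0, 1, 255))) {
    return(x > 0)
  }
  abort("expected a logical matrix or a skewotsu_threshold")
}

#' Supervised overlap scores from confusion counts
#'
#' Jaccard index `TP / (TP + FP + FN)`, F-score (harmonic mean of precision
#' `TP / (TP + FP)` and recall `TP / (TP + FN)`) and pixel accuracy
#' `(TP + TN) / n`. Any zero-denominator score is defined as 0 and the row is
#' flagged, so batch aggregation never propagates `NaN`. The Jaccard index
#' never exceeds the F-score (`J = F / (2 - F)`).
#'
#' @param counts A one-row data frame (or named list/vector) with
#'   non-negative `TP`, `TN`, `FP`, `FN`.
#' @return A one-row tibble with columns `jaccard`, `precision`, `recall`,
#'   `fscore`, `accuracy` and a `flags` string noting degeneracies.
#' @examples
#' supervised_scores(list(TP = 3, FP = 1, FN = 2, TN = 4))
#' @export
supervised_scores <- function(counts) {
  cn <- as.list(counts)
  TP <- as.numeric(cn$TP)
  TN <- as.numeric(cn$TN)
  FP <- as.numeric(cn$FP)
  FN <- as.numeric(cn$FN)
  if (anyNA(c(TP, TN, FP, FN)) || any(c(TP, TN, FP, FN) < 0)) {
    abort("confusion counts must be non-negative")
  }
  total <- TP + TN + FP + FN
  if (total == 0) {
    abort("empty comparison")
  }
  flags <- character()
  frac <- function(num, den, flag) {
    if (den == 0) {
      flags <<- c(flags, flag)
      0
    } else {
      num / den
    }
  }
  jaccard <- frac(TP, TP + FP + FN, "jaccard_zero_denominator")
  precision <- frac(TP, TP + FP, "precision_zero_denominator")
  recall <- frac(TP, TP + FN, "recall_zero_denominator")
  fscore <- frac(2 * precision * recall, precision + recall,
    "fscore_zero_denominator"
  )
  accuracy <- (TP + TN) / total
  tibble(
    jaccard = jaccard, precision = precision, recall = recall,
    fscore = fscore, accuracy = accuracy,
    flags = paste(unique(flags), collapse = ";")
  )
}

pop_var <- function(v) {
  if (length(v) == 0L) {
    return(0)
  }
  mean((v - mean(v))^2)
}

#' Image uniformity (unsupervised)
#'
#' `IU(t) = 1 - (s1^2 + s2^2) / Z`, where `s1^2` and `s2^2` are the
#' (population) intensity variances of the two thresholded regions and
#' `Z = (Imax - Imin)^2 / 2` normalizes by the image's intensity range, so
#' that the score lies in `[0, 1]` (1 = perfectly flat regions). By default
#' `Imax`/`Imin` are the observed extremes; `z_range = "nominal"` uses the
#' full `(L-1)^2 / 2` range instead. A constant image (`Z = 0`) is defined
#' to have uniformity 1 and is flagged.
#'
#' @param image An integer matrix of gray levels.
#' @param t Threshold; region 1 is `image > t`, region 2 is `image <= t`.
#' @param z_range `"observed"` (default) or `"nominal"`.
#' @param L Number of gray levels (used by `z_range = "nominal"`).
#' @return A numeric score in `[0, 1]` with attribute `flags` (character
#'   vector of degeneracy notes, possibly empty).
#' @export
image_uniformity <- function(image, t, z_range = c("observed", "nominal"),
                             L = 256L) {
  z_range <- match.arg(z_range)
  image <- validate_gray_image(image, L = L)
  x <- as.numeric(image)
  flags <- character()
  Z <- if (z_range == "observed") {
    (max(x) - min(x))^2 / 2
  } else {
    (L - 1)^2 / 2
  }
  if (Z == 0) {
    return(structure(1, flags = "constant_image"))
  }
  obj <- x > t
  if (!any(obj) || all(obj)) {
    flags <- c(flags, "empty_region")
  }
  iu <- 1 - (pop_var(x[obj]) + pop_var(x[!obj])) / Z
  structure(min(max(iu, 0), 1), flags = flags)
}

#' Region contrast (unsupervised)
#'
#' `RC(t) = |mu1 - mu2| / (mu1 + mu2)`, the normalized absolute difference
#' of the two thresholded regions' mean intensities: 0 for indistinguishable
#' regions, 1 for maximal contrast. An empty region, or two all-zero
#' regions, scores 0 with a flag.
#'
#' @inheritParams image_uniformity
#' @return A numeric score in `[0, 1]` with attribute `flags`.
#' @export
region_contrast <- function(image, t, L = 256L) {
  image <- validate_gray_image(image, L = L)
  x <- as.numeric(image)
  obj <- x > t
  if (!any(obj) || all(obj)) {
    return(structure(0, flags = "empty_region"))
  }
  m1 <- mean(x[obj])
  m2 <- mean(x[!obj])
  if (m1 + m2 == 0) {
    return(structure(0, flags = "zero_mean_regions"))
  }
  structure(abs(m1 - m2) / (m1 + m2), flags = character())
}

#' Evaluate one segmentation with both metric families
#'
#' Builds the per-image evaluation record: the unsupervised scores (image
#' uniformity, region contrast) computed from the original image and the
#' threshold, and the supervised scores (Jaccard, F-score, accuracy)
#' computed from the mask against the ground truth. The `supervised_mean`
#' and `unsupervised_mean` columns are the arithmetic means of each family's
#' scores.
#'
#' @param image The original grayscale image matrix.
#' @param fit A `skewotsu_threshold` from [threshold_image()], or an integer
#'   threshold `t` (the mask is then `image > t`).
#' @param truth Ground-truth logical matrix; required for the supervised
#'   family.
#' @param metrics Metric families to compute.
#' @inheritParams image_uniformity
#' @return A one-row tibble with columns `t_star`, `IU`, `RC`, `jaccard`,
#'   `fscore`, `accuracy`, `supervised_mean`, `unsupervised_mean`, `flags`
#'   (unselected families are `NA`).
#' @export
evaluate_segmentation <- function(image, fit, truth = NULL,
                                  metrics = c("supervised", "unsupervised"),
                                  z_range = c("observed", "nominal"),
                                  L = 256L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  z_range <- match.arg(z_range)
  if (inherits(fit, "skewotsu_threshold")) {
    t <- fit$t_star
    mask <- fit$mask
    flags <- if (fit$degenerate) "degenerate_image" else character()
  } else {
    t <- as.integer(fit)
    mask <- image > t
    flags <- character()
  }
  IU <- RC <- jaccard <- fscore <- accuracy <- NA_real_
  if ("unsupervised" %in% metrics) {
    iu <- image_uniformity(image, t, z_range = z_range, L = L)
    rc <- region_contrast(image, t, L = L)
    IU <- as.numeric(iu)
    RC <- as.numeric(rc)
    flags <- c(flags, attr(iu, "flags"), attr(rc, "flags"))
  }
  if ("supervised" %in% metrics) {
    if (is.null(truth)) {
      abort("ground truth required for supervised metrics")
    }
    sc <- supervised_scores(confusion(mask, truth))
    jaccard <- sc$jaccard
    fscore <- sc$fscore
    accuracy <- sc$accuracy
    if (nzchar(sc$flags)) {
      flags <- c(flags, strsplit(sc$flags, ";")[[1]])
    }
  }
  tibble(
    t_star = t,
    IU = IU, RC = RC,
    jaccard = jaccard, fscore = fscore, accuracy = accuracy,
    supervised_mean = mean(c(jaccard, fscore, accuracy)),
    unsupervised_mean = mean(c(IU, RC)),
    flags = paste(unique(flags), collapse = ";")
  )
}
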