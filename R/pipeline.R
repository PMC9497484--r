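#' Run the three-method segmentation comparison
#'
#' For every image, runs each selected thresholding objective, evaluates the
#' resulting segmentation with the selected metric families, and aggregates
#' per-method averages and relative increase rates against a baseline
#' method. Per-image results do not depend on the worker count; parallelism
#' is a throughput option only.
#'
#' @param data A dataset tibble with list-columns `image` (integer matrices)
#'   and optionally `truth` (logical matrices), as produced by
#'   [generate_dataset()] or [read_dataset()]; or a directory path readable
#'   by [read_dataset()]; or a single image matrix.
#' @param methods Subset of `"otsu_gaussian"`, `"otsu_modified"`,
#'   `"otsu_lognormal"`; at least one.
#' @param metrics Metric families: `"supervised"`, `"unsupervised"`.
#' @param baseline Method against which increase rates are computed
#'   (increase rate of the baseline itself is 0 by definition). Falls back
#'   to the first selected method if not among `methods`.
#' @inheritParams threshold_image
#' @inheritParams image_uniformity
#' @param workers Number of forked workers for the per-image loop.
#' @return A `skewotsu_comparison`: a list with tibbles `per_image` (one row
#'   per image and method), `per_method` (metric means), `increase_rate`
#'   (per method and metric family, in percent vs the baseline), and the run
#'   settings. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' ds <- generate_dataset(2, "well_separated", seed = 7)
#' cmp <- run_comparison(ds)
#' glance(cmp)
#' @export
run_comparison <- function(data,
                           methods = OTSU_METHODS,
                           metrics = c("supervised", "unsupervised"),
                           baseline = "otsu_gaussian",
                           log_map = c("shift1", "skip-zero"),
                           z_range = c("observed", "nominal"),
                           invert = FALSE,
                           workers = 1L,
                           L = 256L) {
  methods <- match.arg(methods, OTSU_METHODS, several.ok = TRUE)
  metrics <- match.arg(metrics, c("supervised", "unsupervised"),
    several.ok = TRUE
  )
  log_map <- match.arg(log_map)
  z_range <- match.arg(z_range)
  if (length(methods) < 1L || length(metrics) < 1L) {
    abort("select at least one method and one metric family")
  }
  if (!baseline %in% methods) {
    baseline <- methods[1]
  }
  data <- coerce_dataset(data)

  supervised <- "supervised" %in% metrics
  eval_one <- function(k) {
    image <- data$image[[k]]
    truth <- if ("truth" %in% names(data)) data$truth[[k]] else NULL
    if (supervised && is.null(truth)) {
      return(NULL)
    }
    purrr::map_dfr(methods, function(m) {
      fit <- withCallingHandlers(
        threshold_image(image, m, log_map = log_map, invert = invert, L = L),
        warning = function(w) invokeRestart("muffleWarning")
      )
      ev <- evaluate_segmentation(image, fit,
        truth = truth, metrics = metrics,
        z_range = z_range, L = L
      )
      dplyr::mutate(ev, id = data$id[k], method = m, .before = 1L)
    })
  }

  ks <- seq_len(nrow(data))
  res <- if (workers > 1L) {
    parallel::mclapply(ks, eval_one, mc.cores = workers)
  } else {
    lapply(ks, eval_one)
  }
  skipped <- data$id[vapply(res, is.null, logical(1))]
  if (length(skipped) > 0L) {
    warn(paste0(
      "skipped ", length(skipped),
      " image(s) without ground truth: ",
      paste(head(skipped, 5), collapse = ", ")
    ))
  }
  per_image <- dplyr::bind_rows(res)
  if (nrow(per_image) == 0L) {
    abort("no image could be evaluated")
  }

  metric_cols <- intersect(
    c(
      "IU", "RC", "jaccard", "fscore", "accuracy",
      "supervised_mean", "unsupervised_mean"
    ),
    names(per_image)
  )
  per_method <- per_image |>
    dplyr::group_by(method = factor(.data$method, levels = OTSU_METHODS)) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(metric_cols), mean),
      .groups = "drop"
    ) |>
    dplyr::mutate(method = as.character(.data$method))

  fam <- c(
    supervised = "supervised_mean",
    unsupervised = "unsupervised_mean"
  )[metrics]
  increase_rate <- purrr::map_dfr(names(fam), function(family) {
    col <- fam[[family]]
    avg <- setNames(per_method[[col]], per_method$method)
    tibble(
      method = per_method$method,
      family = family,
      average = unname(avg),
      increase_rate = 100 * (unname(avg) - avg[[baseline]]) / avg[[baseline]]
    )
  })

  structure(
    list(
      per_image = per_image,
      per_method = per_method,
      increase_rate = increase_rate,
      methods = methods,
      metrics = metrics,
      baseline = baseline,
      n_images = nrow(data) - length(skipped),
      skipped = skipped
    ),
    class = "skewotsu_comparison"
  )
}

coerce_dataset <- function(data) {
  if (is.matrix(data)) {
    return(tibble(id = "img_001", image = list(data)))
  }
  if (is.character(data) && length(data) == 1L) {
    return(read_dataset(data))
  }
  if (is.data.frame(data)) {
    if (!"image" %in% names(data)) {
      abort("dataset must have an `image` list-column")
    }
    if (!"id" %in% names(data)) {
      data$id <- sprintf("img_%03d", seq_len(nrow(data)))
    }
    return(data)
  }
  abort("data must be a dataset tibble, a directory path, or an image matrix")
}

#' Select the best-performing method of a comparison
#'
#' Ranks the selected methods by the mean of all computed metric scores
#' (both families pooled, equally weighted) and returns the winner. Ties go
#' to the earliest method in the canonical order (gaussian, modified,
#' lognormal).
#'
#' @param report A `skewotsu_comparison`.
#' @return A method name.
#' @export
best_method_select <- function(report) {
  stopifnot(inherits(report, "skewotsu_comparison"))
  cols <- intersect(
    c("IU", "RC", "jaccard", "fscore", "accuracy"),
    names(report$per_method)
  )
  scores <- report$per_method |>
    dplyr::mutate(score = rowMeans(dplyr::pick(dplyr::all_of(cols)),
      na.rm = TRUE
    )) |>
    dplyr::arrange(factor(.data$method, levels = OTSU_METHODS))
  scores$method[which.max(scores$score)]
}

#' @export
print.skewotsu_comparison <- function(x, ...) {
  cat(sprintf(
    "<skewotsu_comparison> %d image(s), methods: %s\n",
    x$n_images, paste(x$methods, collapse = ", ")
  ))
  print(x$per_method)
  cat(sprintf("increase rates vs %s (%%):\n", x$baseline))
  print(x$increase_rate)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.skewotsu_comparison <- function(x, ...) {
  x$per_image
}

#' @exportS3Method generics::glance
glance.skewotsu_comparison <- function(x, ...) {
  x$per_method
}

#' @exportS3Method ggplot2::autoplot
autoplot.skewotsu_comparison <- function(object, ...) {
  cols <- intersect(
    c("IU", "RC", "jaccard", "fscore", "accuracy"),
    names(object$per_image)
  )
  long <- tidyr::pivot_longer(object$per_image,
    dplyr::all_of(cols),
    names_to = "metric", values_to = "score"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = factor(.data$method, levels = OTSU_METHODS),
      y = .data$score, fill = .data$method
    )
  ) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Write comparison reports to a directory
#'
#' Emits the per-image table as CSV and the aggregate (per-method averages
#' and increase rates) as JSON and CSV.
#'
#' @param report A `skewotsu_comparison`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "skewotsu_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$per_image, file.path(dir, "per_image.csv"),
    row.names = FALSE
  )
  write.csv(report$per_method, file.path(dir, "per_method.csv"),
    row.names = FALSE
  )
  jsonlite::write_json(
    list(
      per_method = report$per_method,
      increase_rate = report$increase_rate,
      baseline = report$baseline,
      n_images = report$n_images
    ),
    file.path(dir, "aggregate.json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}
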