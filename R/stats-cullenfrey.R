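#' Moment-based sample skewness and kurtosis
#'
#' Central-moment estimators used throughout the Cullen-Frey analysis:
#' skewness `m3 / m2^(3/2)` and (non-excess) kurtosis `m4 / m2^2`, with
#' `m_k` the k-th central sample moment (1/n denominators). Any sample
#' satisfies `kurtosis >= skewness^2 + 1`.
#'
#' @param x Numeric vector (missing values dropped).
#' @return Numeric scalar.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  m2 <- mean((x - mean(x))^2)
  mean((x - mean(x))^3) / m2^1.5
}

#' @rdname sample_skewness
#' @export
sample_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  m2 <- mean((x - mean(x))^2)
  mean((x - mean(x))^4) / m2^2
}

#' Cullen-Frey bootstrap distribution-shape analysis
#'
#' Locates a pooled sample on the skewness-squared / kurtosis plane used to
#' suggest candidate distribution families (normal at (0, 3), log-normal
#' and gamma along curves, beta in a region). Sampling uncertainty of the
#' two shape statistics is visualized by a cloud of bootstrap replicates
#' obtained by resampling the sample with replacement. Pooling single-cell
#' values across patients of a group reveals shape differences -- e.g. a
#' heavier right tail of the modulus distribution in the pathological
#' group -- that group medians miss.
#'
#' @param values Numeric vector of pooled observations (>= 30 recommended).
#' @param n_boot Number of bootstrap replicates (>= 200).
#' @param seed Optional integer seed; identical seeds give identical clouds.
#' @return An object of class `cullen_frey`: list with `skewness_sq`,
#'   `kurtosis`, `n`, `n_boot`, and a `boot` tibble of replicate
#'   `(skewness_sq, kurtosis)` pairs. Has [autoplot()] and [tidy()]
#'   methods.
#' @export
#' @examples
#' cf <- cullen_frey(rlnorm(500, 0, 0.5), n_boot = 200, seed = 1)
#' tidy(cf)
cullen_frey <- function(values, n_boot = 500, seed = NULL) {
  x <- values[!is.na(values)]
  if (length(x) < 4)
    abort("need at least 4 observations", class = "rbcmech_insufficient_data")
  if (length(x) < 30)
    warn("fewer than 30 observations: shape statistics will be unstable")
  if (var(x) == 0)
    abort("degenerate data: zero variance", class = "rbcmech_degenerate_data")
  if (n_boot < 200) abort("n_boot must be at least 200")
  run <- function() {
    reps <- purrr::map(seq_len(n_boot), function(i) {
      xb <- sample(x, replace = TRUE)
      c(sk2 = sample_skewness(xb)^2, kr = sample_kurtosis(xb))
    })
    boot <- tibble::tibble(
      skewness_sq = purrr::map_dbl(reps, "sk2"),
      kurtosis = purrr::map_dbl(reps, "kr")
    )
    structure(list(
      skewness_sq = sample_skewness(x)^2,
      kurtosis = sample_kurtosis(x),
      n = length(x), n_boot = n_boot, boot = boot
    ), class = "cullen_frey")
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' @export
print.cullen_frey <- function(x, ...) {
  cat(sprintf("<cullen_frey> n = %d, %d bootstrap replicates\n", x$n, x$n_boot))
  cat(sprintf("  skewness^2 = %.3f, kurtosis = %.3f\n",
              x$skewness_sq, x$kurtosis))
  invisible(x)
}

#' @method tidy cullen_frey
#' @export
tidy.cullen_frey <- function(x, ...) {
  tibble::tibble(skewness_sq = x$skewness_sq, kurtosis = x$kurtosis,
                 n = x$n, n_boot = x$n_boot)
}

# theoretical (skewness^2, kurtosis) locus of the log-normal family as its
# log-scale SD varies
lognormal_locus <- function(sigma = seq(0.01, 1, length.out = 200)) {
  w <- exp(sigma^2)
  tibble::tibble(
    skewness_sq = ((w + 2) * sqrt(w - 1))^2,
    kurtosis = w^4 + 2 * w^3 + 3 * w^2 - 3
  )
}

# gamma family locus: skewness^2 = 4/shape, kurtosis = 3 + 6/shape
gamma_locus <- function(shape = exp(seq(log(0.5), log(200), length.out = 200))) {
  tibble::tibble(skewness_sq = 4 / shape, kurtosis = 3 + 6 / shape)
}

#' Cullen-Frey plot
#'
#' Kurtosis against squared skewness (kurtosis axis reversed, following the
#' usual convention) with the observed point, its bootstrap cloud, the
#' normal point, and the log-normal and gamma family curves.
#'
#' @param object A `cullen_frey` result (or a named list of them, drawn in
#'   different colours via [plot_cullen_frey()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cullen_frey
#' @export
autoplot.cullen_frey <- function(object, ...) {
  plot_cullen_frey(list(sample = object))
}

#' @rdname autoplot.cullen_frey
#' @param results Named list of `cullen_frey` objects (e.g. one per group).
#' @export
plot_cullen_frey <- function(results) {
  stopifnot(length(results) > 0, all(purrr::map_lgl(results, inherits,
                                                    "cullen_frey")))
  if (is.null(names(results))) names(results) <- paste0("sample_", seq_along(results))
  pts <- purrr::imap_dfr(results, function(r, nm)
    tibble::tibble(group = nm, skewness_sq = r$skewness_sq,
                   kurtosis = r$kurtosis))
  cloud <- purrr::imap_dfr(results, function(r, nm)
    dplyr::mutate(r$boot, group = nm))
  lims_x <- range(c(0, cloud$skewness_sq, pts$skewness_sq)) * c(1, 1.1)
  ln <- dplyr::filter(lognormal_locus(), .data$skewness_sq <= lims_x[2])
  gm <- dplyr::filter(gamma_locus(), .data$skewness_sq <= lims_x[2])
  ggplot2::ggplot(cloud, ggplot2::aes(x = .data$skewness_sq,
                                      y = .data$kurtosis,
                                      colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::geom_line(data = ln, ggplot2::aes(colour = NULL),
                       linetype = "dotted", colour = "grey30") +
    ggplot2::geom_line(data = gm, ggplot2::aes(colour = NULL),
                       linetype = "dashed", colour = "grey60") +
    ggplot2::annotate("point", x = 0, y = 3, shape = 8, size = 3) +
    ggplot2::geom_point(data = pts, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(skewness^2), y = "kurtosis",
                  title = "Cullen-Frey plane",
                  subtitle = "star: normal; dotted: log-normal; dashed: gamma") +
    ggplot2::theme_minimal()
}
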