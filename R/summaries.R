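#' Highest-density interval of a sample
#'
#' Returns the shortest contiguous interval containing `ceiling(mass * n)`
#' of the sorted samples, found by exhaustive search over all candidate
#' windows; ties in width are broken toward the lower interval. The HDI is
#' never wider than the equal-tailed interval and is the natural summary for
#' skewed posteriors.
#'
#' @param samples Numeric vector of draws (at least 2 finite values; 20 or
#'   more are needed for the interval to be statistically meaningful).
#' @param mass Probability mass to cover, in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  stopifnot(is.numeric(samples), mass > 0, mass < 1)
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2) stop("hdi() needs at least 2 finite samples, got ", n)
  m <- ceiling(mass * n)
  x <- sort(samples)
  widths <- x[m:n] - x[seq_len(n - m + 1L)]
  i <- which.min(widths)  # first minimum: ties break toward the lower window
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Inverse-variance-weighted grand mean of phylum draws
#'
#' The hierarchical model does not identify an overall mean directly, so the
#' grand estimate is formed from the phylum-level means weighted by the
#' inverse of their marginal posterior variances. Weights are computed once
#' per phylum; the weighted combination is then applied draw-wise so the
#' grand mean carries full posterior uncertainty.
#'
#' @param phylum_draws A draws-by-phylum matrix (see [phylum_draws()]).
#' @return A vector of grand-mean draws with the weights as an attribute.
#' @export
weighted_grand_mean <- function(phylum_draws) {
  phylum_draws <- as.matrix(phylum_draws)
  stopifnot(ncol(phylum_draws) >= 2)
  v <- apply(phylum_draws, 2, var)
  if (any(v == 0)) stop("degenerate phylum draws: zero posterior variance")
  w <- 1 / v
  g <- as.numeric(phylum_draws %*% w) / sum(w)
  attr(g, "weights") <- w / sum(w)
  g
}

#' Posterior medians and 95% HDIs per phylum plus the grand mean
#'
#' @param fit A `macro_fit`.
#' @param mass HDI mass.
#' @param grand Include the inverse-variance-weighted grand row (requires at
#'   least two phyla).
#' @return A tibble with `level` (`"phylum"`/`"grand"`), `name`, `median`,
#'   `hdi_low`, `hdi_high`, `n_obs`.
#' @export
phylum_summary <- function(fit, mass = 0.95, grand = TRUE) {
  ph <- phylum_draws(fit)
  rows <- lapply(seq_len(ncol(ph)), function(j) {
    h <- hdi(ph[, j], mass)
    tibble::tibble(level = "phylum", name = colnames(ph)[j],
                   median = median(ph[, j]), hdi_low = h[["lower"]],
                   hdi_high = h[["upper"]],
                   n_obs = as.integer(fit$n_obs$by_phylum[[colnames(ph)[j]]]))
  })
  out <- dplyr::bind_rows(rows)
  if (grand && ncol(ph) >= 2) {
    g <- weighted_grand_mean(ph)
    h <- hdi(g, mass)
    out <- dplyr::bind_rows(out, tibble::tibble(
      level = "grand", name = "Grand", median = median(g),
      hdi_low = h[["lower"]], hdi_high = h[["upper"]],
      n_obs = as.integer(fit$n_obs$total)
    ))
  }
  out
}

#' Pairwise phylum contrasts from posterior draws
#'
#' Differences between phylum-level means are formed draw-wise and
#' summarized by their median and 95% HDI; a pair is flagged significant
#' when the HDI of the difference excludes zero. No null-hypothesis tests or
#' multiplicity corrections are involved. The table contains both
#' orientations of each pair and is antisymmetric under swapping.
#'
#' @param fit A `macro_fit`, or a draws-by-phylum matrix.
#' @param mass HDI mass.
#' @return A tibble with `phylum_a`, `phylum_b`, difference summaries and a
#'   `significant` flag.
#' @export
pairwise_contrasts <- function(fit, mass = 0.95) {
  ph <- if (inherits(fit, "macro_fit")) phylum_draws(fit) else as.matrix(fit)
  stopifnot(ncol(ph) >= 2)
  nm <- colnames(ph)
  pairs <- expand.grid(a = seq_len(ncol(ph)), b = seq_len(ncol(ph)))
  pairs <- pairs[pairs$a != pairs$b, ]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$a[i]; b <- pairs$b[i]
    d <- ph[, a] - ph[, b]
    h <- hdi(d, mass)
    tibble::tibble(phylum_a = nm[a], phylum_b = nm[b],
                   median = median(d), hdi_low = h[["lower"]],
                   hdi_high = h[["upper"]],
                   significant = h[["lower"]] > 0 | h[["upper"]] < 0)
  })
  dplyr::bind_rows(rows)
}

#' Decompose total variance across taxonomic levels
#'
#' Splits the total response variance into the within-species (residual),
#' among-species-within-phyla, and among-phyla components, computed from the
#' posterior median of each standard deviation (the single-number summary
#' used in reporting). A draw-wise decomposition, propagating posterior
#' uncertainty, is returned alongside when `drawwise = TRUE`.
#'
#' @param fit A `macro_fit`, or a draws-by-3 matrix of SD draws.
#' @param drawwise Also return draw-wise percentage draws.
#' @return A tibble with `component` and `percent` (summing to 100); with
#'   `drawwise = TRUE`, a `drawwise` attribute holds the per-draw matrix.
#' @export
variance_decomposition <- function(fit, drawwise = FALSE) {
  sg <- if (inherits(fit, "macro_fit")) sigma_draws(fit) else as.matrix(fit)
  stopifnot(ncol(sg) == 3, all(sg >= 0))
  med <- apply(sg, 2, median)
  v <- med^2
  pct <- 100 * v / sum(v)
  out <- tibble::tibble(
    component = c("among_phyla", "among_species_within_phyla", "within_species"),
    percent = c(pct[1], pct[2], pct[3])
  )
  if (drawwise) {
    v_d <- sg^2
    attr(out, "drawwise") <- 100 * v_d / rowSums(v_d)
  }
  out
}

#' Summarize a log-scale ratio fit on the ratio scale
#'
#' Mass ratios are modeled on the natural-log scale; medians and HDIs are
#' computed on the log scale and exponentiated (the median commutes with
#' monotone transforms, and the back-transformed log-scale HDI is the
#' reported interval).
#'
#' @param fit A `macro_fit` of log-ratio observations.
#' @param mass HDI mass.
#' @param grand Include the weighted grand row.
#' @return A tibble in the layout of [phylum_summary()], on the ratio scale.
#' @export
summarize_ratios <- function(fit, mass = 0.95, grand = TRUE) {
  out <- phylum_summary(fit, mass = mass, grand = grand)
  out$median <- exp(out$median)
  out$hdi_low <- exp(out$hdi_low)
  out$hdi_high <- exp(out$hdi_high)
  out
}

#' Forest plot of phylum medians and credible intervals
#'
#' Medians (points) with 95% HDIs (horizontal lines) per phylum, with the
#' grand median and its interval as a vertical line and shaded band.
#' Ordering is fixed (alphabetical) so output is deterministic.
#'
#' @param summary A summary tibble from [phylum_summary()] or
#'   [summarize_ratios()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_phylum_medians <- function(summary, title = NULL) {
  ph <- summary[summary$level == "phylum", ]
  gr <- summary[summary$level == "grand", ]
  ph$name <- factor(ph$name, levels = rev(sort(unique(ph$name))))
  p <- ggplot2::ggplot(ph, ggplot2::aes(x = .data$median, y = .data$name))
  if (nrow(gr) == 1) {
    p <- p +
      ggplot2::annotate("rect", xmin = gr$hdi_low, xmax = gr$hdi_high,
                        ymin = -Inf, ymax = Inf, alpha = 0.15) +
      ggplot2::geom_vline(xintercept = gr$median, linewidth = 0.3)
  }
  p +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hdi_low, xmax = .data$hdi_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "median (95% HDI)", y = NULL, title = title) +
    ggplot2::theme_minimal()
}
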