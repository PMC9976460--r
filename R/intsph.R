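# Interaction-sphere (IntSph) partitioning: per-bead contact density at a
# physical radius, radius scans, sigmoid fitting of the scan, and the
# working-radius recommendation.

#' Per-bead contact density at an interaction-sphere radius
#'
#' For every bead, counts the other beads whose centres lie within the
#' closed ball of radius `r` (the bead itself excluded; genomic neighbours
#' included by default, since small spheres are naturally dominated by
#' local genomic contacts).
#'
#' @param conf n x 3 coordinate matrix, nm.
#' @param r sphere radius, nm.
#' @param exclude_adjacent exclude beads within this genomic offset of the
#'   centre (0 = count everything; 1 drops i±1, etc.). Sensitivity hook.
#' @param members if TRUE, also return the per-bead neighbour index sets.
#' @return an `intsph_profile`: list with `r`, `density` (integer per
#'   bead), and optionally `members` (list of 1-based bead indices).
#' @export
contact_density <- function(conf, r, exclude_adjacent = 0L, members = FALSE) {
  stopifnot(r > 0)
  n <- nrow(conf)
  d <- as.matrix(stats::dist(conf))
  inside <- d <= r
  diag(inside) <- FALSE
  if (exclude_adjacent > 0L) {
    off <- abs(row(inside) - col(inside)) <= exclude_adjacent
    inside[off] <- FALSE
    diag(inside) <- FALSE
  }
  out <- list(r = r, density = as.integer(rowSums(inside)),
              exclude_adjacent = as.integer(exclude_adjacent))
  if (members)
    out$members <- lapply(seq_len(n), function(i) which(inside[i, ]))
  structure(out, class = "intsph_profile")
}

#' Scan contact density over a range of sphere radii
#'
#' @param conf n x 3 coordinate matrix, nm.
#' @param radii ascending radii, nm.
#' @inheritParams contact_density
#' @return data.frame with `r`, `mean_density`, `median_density`; mean
#'   density is non-decreasing in `r`.
#' @export
radius_scan <- function(conf, radii, exclude_adjacent = 0L) {
  stopifnot(length(radii) >= 1L, !is.unsorted(radii))
  rows <- lapply(radii, function(r) {
    dens <- contact_density(conf, r, exclude_adjacent)$density
    data.frame(r = r, mean_density = mean(dens),
               median_density = stats::median(dens))
  })
  do.call(rbind, rows)
}

sigmoid4 <- function(r, bottom, top, x0, slope) {
  bottom + (top - bottom) / (1 + exp((x0 - r) / slope))
}

#' Fit a four-parameter logistic to a radius scan
#'
#' Least-squares fit of mean contact density against radius,
#' `y = bottom + (top - bottom) / (1 + exp((x0 - r) / slope))`, from
#' multiple quartile-based starting points (deterministic). The inflection
#' `x0` is the input to the working-radius rule. A fit whose inflection
#' falls outside the scanned range, whose asymptotes overshoot the data by
#' more than half its span, or whose residuals exceed 5% of the data
#' variance is flagged `poor_fit` — the scan did not resolve a sigmoidal
#' rise and plateau.
#'
#' @param scan data.frame from [radius_scan()] (columns `r`,
#'   `mean_density`), or any data.frame with those columns.
#' @return a `sigmoid_fit`: list with `bottom`, `top`, `x0`, `slope`,
#'   `rss`, `poor_fit`.
#' @export
fit_sigmoid <- function(scan) {
  x <- scan$r
  y <- scan$mean_density
  if (length(x) < 5L) stop_sc("need at least 5 scan points to fit a sigmoid")
  span <- diff(range(x))
  obj <- function(th) {
    pred <- sigmoid4(x, th[1], th[2], th[3], exp(th[4]))
    sum((y - pred)^2)
  }
  starts <- expand.grid(
    x0 = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
    lslope = log(span / c(20, 5, 2)))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    th0 <- c(min(y), max(y), starts$x0[k], starts$lslope[k])
    fit <- try(stats::optim(th0, obj, method = "BFGS",
                            control = list(maxit = 2000, reltol = 1e-14)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop_sc("sigmoid fit failed to converge from all %d starts", nrow(starts))
  # polish with nls when it cooperates; keep the optim solution otherwise
  th <- best$par
  pol <- try(suppressWarnings(stats::nls(
    y ~ bottom + (top - bottom) / (1 + exp((x0 - x) / slope)),
    start = list(bottom = th[1], top = th[2], x0 = th[3], slope = exp(th[4])),
    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    silent = TRUE)
  if (!inherits(pol, "try-error")) {
    cf <- stats::coef(pol)
    if (sum(stats::resid(pol)^2) <= best$value + 1e-12) {
      th <- c(cf[["bottom"]], cf[["top"]], cf[["x0"]], log(abs(cf[["slope"]])))
      best$value <- sum(stats::resid(pol)^2)
    }
  }
  bottom <- th[1]; top <- th[2]; x0 <- th[3]; slope <- exp(th[4])
  if (bottom > top) {  # canonical orientation
    tmp <- bottom; bottom <- top; top <- tmp
  }
  vary <- sum((y - mean(y))^2)
  poor <- x0 < min(x) || x0 > max(x) ||
    top > max(y) + 0.5 * diff(range(y)) ||
    bottom < min(y) - 0.5 * diff(range(y)) ||
    (vary > 0 && best$value / vary > 0.05)
  structure(list(bottom = bottom, top = top, x0 = x0, slope = slope,
                 rss = best$value, poor_fit = poor),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("logistic fit: bottom %.4g, top %.4g, inflection %.4g nm, slope %.4g (rss %.4g)%s\n",
              x$bottom, x$top, x$x0, x$slope, x$rss,
              if (x$poor_fit) " [poor fit]" else ""))
  invisible(x)
}

#' Recommend a working IntSph radius from a sigmoid fit
#'
#' The working radius is `fraction * x0` with `fraction` in the 0.5-1.0
#' band below the fitted inflection: small enough to stay in the
#' informative rise of the density curve, large enough to see beyond
#' nearest genomic neighbours.
#'
#' @param fit a [fit_sigmoid()] result.
#' @param fraction multiplier in `[0.5, 1.0]`.
#' @return radius in nm.
#' @export
recommend_radius <- function(fit, fraction = 0.5) {
  if (fraction < 0.5 || fraction > 1.0)
    stop_sc("fraction must lie in [0.5, 1.0], got %g", fraction)
  fraction * fit$x0
}
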