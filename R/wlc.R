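# Worm-like-chain statistics of fibril contours (2D convention throughout:
# transmission micrograph contours are planar projections). Persistence
# length is estimated three ways -- bond (tangent) correlation decay,
# mean-squared end-to-end distance, and mean-squared midpoint displacement
# -- and combined as their arithmetic mean. Lengths in nanometres.

.as_contour_list <- function(contours) {
  if (is.matrix(contours)) return(list(list(points = contours)))
  if (is.list(contours) && !is.null(contours$points)) return(list(contours))
  lapply(contours, function(ct) {
    if (is.matrix(ct)) list(points = ct) else ct
  })
}

#' Arc-length of a polyline contour
#'
#' @param contour an n x 2 point matrix (nm), or a contour list with a
#'   `points` element.
#' @return Contour length in nm.
#' @export
contour_length <- function(contour) {
  p <- if (is.matrix(contour)) contour else contour$points
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Resample a contour at uniform arc-length steps
#'
#' Linear interpolation along the polyline; total length is preserved to
#' well within 0.5% for step sizes small relative to contour features.
#'
#' @param points n x 2 matrix of ordered contour points (nm).
#' @param ds target spacing (nm).
#' @param width optional per-point width profile, interpolated alongside.
#' @return A contour list with elements `points`, `ds` and optionally
#'   `width`.
#' @export
resample_contour <- function(points, ds, width = NULL) {
  stopifnot(is.matrix(points), ncol(points) == 2, nrow(points) >= 2,
            ds > 0)
  seg <- sqrt(rowSums(diff(points)^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate (zero-length) contour", call. = FALSE)
  s_in <- c(0, cumsum(seg))
  n_out <- max(2L, round(L / ds) + 1L)
  s_out <- seq(0, L, length.out = n_out)
  px <- stats::approx(s_in, points[, 1], xout = s_out)$y
  py <- stats::approx(s_in, points[, 2], xout = s_out)$y
  out <- list(points = cbind(px, py), ds = L / (n_out - 1L))
  if (!is.null(width)) {
    out$width <- stats::approx(s_in, width, xout = s_out)$y
  }
  out
}

# tangent angles and actual step size of a contour
.contour_tangents <- function(p) {
  d <- diff(p)
  list(theta = atan2(d[, 2], d[, 1]),
       ds = mean(sqrt(rowSums(d^2))))
}

# pooled <cos theta(s)> over all contours and positions, per lag
.pooled_bcf <- function(cl, max_lag) {
  num <- numeric(max_lag); cnt <- numeric(max_lag)
  for (ct in cl) {
    th <- .contour_tangents(ct$points)$theta
    n <- length(th)
    for (m in seq_len(min(max_lag, n - 1))) {
      v <- cos(th[(1 + m):n] - th[1:(n - m)])
      num[m] <- num[m] + sum(v)
      cnt[m] <- cnt[m] + length(v)
    }
  }
  keep <- cnt > 0
  list(lag = which(keep), cos = num[keep] / cnt[keep], n = cnt[keep])
}

#' Persistence length from the bond correlation function
#'
#' Pools the tangent-angle correlation \eqn{\langle\cos\theta(s)\rangle}
#' over all contours and positions and fits the 2D worm-like-chain decay
#' \eqn{e^{-s/(2\lambda)}} by least squares over
#' \eqn{s \in [\Delta s, \min(2\hat\lambda_0, s_{max})]}, where
#' \eqn{\hat\lambda_0} comes from an initial log-linear fit. Ensembles with
#' no measurable decay are flagged rigid.
#'
#' @param contours a contour, matrix, or list of contours (see
#'   [generate_wlc_contours()]).
#' @param s_max largest separation used (nm); default the shortest contour
#'   length.
#' @return list with `lambda` (nm), `r_squared`, `rigid` flag, `converged`,
#'   and the pooled `curve` (s, cos).
#' @export
persistence_length_bcf <- function(contours, s_max = NULL) {
  cl <- .as_contour_list(contours)
  ds <- mean(vapply(cl, function(ct) .contour_tangents(ct$points)$ds,
                    numeric(1)))
  lens <- vapply(cl, contour_length, numeric(1))
  if (is.null(s_max)) s_max <- min(lens)
  max_lag <- max(2L, floor(s_max / ds))
  bc <- .pooled_bcf(cl, max_lag)
  if (length(bc$lag) < 2) stop("insufficient data for the requested s_max",
                               call. = FALSE)
  s <- bc$lag * ds
  y <- bc$cos
  if (all(y > 0.999)) {
    return(list(lambda = Inf, r_squared = NA_real_, rigid = TRUE,
                converged = FALSE,
                curve = data.frame(s = s, cos = y)))
  }
  pos <- y > 0.05
  lam0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(y[pos]) ~ 0 + s[pos]))[1]
    if (sl < 0) -1 / (2 * sl) else max(s)
  } else max(s) / 4
  win <- s <= min(2 * lam0, max(s))
  fit <- try(minpack.lm::nlsLM(
    cosv ~ exp(-sv / (2 * lambda)),
    data = data.frame(sv = s[win], cosv = y[win]),
    start = list(lambda = lam0),
    lower = 1e-6, control = minpack.lm::nls.lm.control(maxiter = 200)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(lambda = NA_real_, r_squared = NA_real_, rigid = FALSE,
                converged = FALSE, curve = data.frame(s = s, cos = y)))
  }
  lam <- unname(stats::coef(fit)[1])
  res <- y[win] - exp(-s[win] / (2 * lam))
  r2 <- 1 - sum(res^2) / sum((y[win] - mean(y[win]))^2)
  list(lambda = lam, r_squared = r2, rigid = FALSE, converged = TRUE,
       curve = data.frame(s = s, cos = y))
}

# pooled mean-squared end-to-end distance over internal segments
.pooled_msed <- function(cl, max_lag) {
  num <- numeric(max_lag); cnt <- numeric(max_lag)
  for (ct in cl) {
    p <- ct$points
    n <- nrow(p)
    for (m in seq_len(min(max_lag, n - 1))) {
      d <- p[(1 + m):n, , drop = FALSE] - p[1:(n - m), , drop = FALSE]
      v <- rowSums(d^2)
      num[m] <- num[m] + sum(v)
      cnt[m] <- cnt[m] + length(v)
    }
  }
  keep <- cnt > 0
  list(lag = which(keep), r2 = num[keep] / cnt[keep], n = cnt[keep])
}

#' Persistence length from the mean-squared end-to-end distance
#'
#' Fits the pooled internal-segment statistic to the 2D worm-like-chain
#' closed form
#' \eqn{\langle R^2(s)\rangle = 4\lambda\,[s - 2\lambda(1 - e^{-s/(2\lambda)})]}
#' by nonlinear least squares.
#'
#' @inheritParams persistence_length_bcf
#' @return list with `lambda`, `rigid`, `converged` and the pooled `curve`.
#' @export
persistence_length_msed <- function(contours, s_max = NULL) {
  cl <- .as_contour_list(contours)
  ds <- mean(vapply(cl, function(ct) .contour_tangents(ct$points)$ds,
                    numeric(1)))
  lens <- vapply(cl, contour_length, numeric(1))
  if (is.null(s_max)) s_max <- min(lens)
  max_lag <- max(2L, floor(s_max / ds))
  ms <- .pooled_msed(cl, max_lag)
  s <- ms$lag * ds
  y <- ms$r2
  if (all(y / s^2 > 0.999)) {
    return(list(lambda = Inf, rigid = TRUE, converged = FALSE,
                curve = data.frame(s = s, r2 = y)))
  }
  lam0 <- max(s) / 4
  fit <- try(minpack.lm::nlsLM(
    yv ~ 4 * lambda * (sv - 2 * lambda * (1 - exp(-sv / (2 * lambda)))),
    data = data.frame(sv = s, yv = y),
    start = list(lambda = lam0), lower = 1e-6,
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(lambda = NA_real_, rigid = FALSE, converged = FALSE,
                curve = data.frame(s = s, r2 = y)))
  }
  list(lambda = unname(stats::coef(fit)[1]), rigid = FALSE,
       converged = TRUE, curve = data.frame(s = s, r2 = y))
}

# mean-squared perpendicular deviation of segment midpoints from the
# straight secant joining the segment ends
.pooled_msmd <- function(cl, max_lag) {
  lags <- seq(2L, max_lag, by = 2L)
  num <- numeric(length(lags)); cnt <- numeric(length(lags))
  for (ct in cl) {
    p <- ct$points
    n <- nrow(p)
    for (li in seq_along(lags)) {
      m <- lags[li]
      if (m > n - 1) break
      a <- p[1:(n - m), , drop = FALSE]
      b <- p[(1 + m):n, , drop = FALSE]
      mid <- p[(1 + m / 2):(n - m / 2), , drop = FALSE]
      ab <- b - a
      am <- mid - a
      # perpendicular distance of mid from line (a, b)
      cross <- ab[, 1] * am[, 2] - ab[, 2] * am[, 1]
      u2 <- cross^2 / rowSums(ab^2)
      num[li] <- num[li] + sum(u2)
      cnt[li] <- cnt[li] + length(u2)
    }
  }
  keep <- cnt > 0
  list(lag = lags[keep], u2 = num[keep] / cnt[keep], n = cnt[keep])
}

#' Persistence length from the mean-squared midpoint displacement
#'
#' For each internal segment, the perpendicular deviation of its midpoint
#' from the straight secant joining its ends; in the weakly-bent 2D
#' worm-like-chain regime \eqn{\langle u^2(s)\rangle = s^3/(48\lambda)}.
#' The fit is restricted to \eqn{s \le \lambda/2} (iterating once on the
#' estimate).
#'
#' @inheritParams persistence_length_bcf
#' @return list with `lambda`, `rigid`, `converged` and the pooled `curve`.
#' @export
persistence_length_msmd <- function(contours, s_max = NULL) {
  cl <- .as_contour_list(contours)
  ds <- mean(vapply(cl, function(ct) .contour_tangents(ct$points)$ds,
                    numeric(1)))
  lens <- vapply(cl, contour_length, numeric(1))
  if (is.null(s_max)) s_max <- min(lens)
  max_lag <- max(2L, floor(s_max / ds))
  ms <- .pooled_msmd(cl, max_lag)
  s <- ms$lag * ds
  y <- ms$u2
  if (all(y < 1e-12 * max(s)^2)) {
    return(list(lambda = Inf, rigid = TRUE, converged = FALSE,
                curve = data.frame(s = s, u2 = y)))
  }
  est <- function(window) {
    sw <- s[window]; yw <- y[window]
    sum(yw * sw^3) / sum((sw^3 / 48) * sw^3) # LS slope of y ~ s^3/48
  }
  inv_lam <- est(rep(TRUE, length(s)))
  lam <- 1 / inv_lam
  win <- s <= lam / 2
  if (sum(win) < 2) win <- s <= stats::quantile(s, 0.25)
  if (sum(win) < 2) {
    return(list(lambda = NA_real_, rigid = FALSE, converged = FALSE,
                curve = data.frame(s = s, u2 = y)))
  }
  lam <- 1 / est(win)
  list(lambda = lam, rigid = FALSE, converged = TRUE,
       curve = data.frame(s = s, u2 = y))
}

#' Fit worm-like-chain statistics to a contour ensemble
#'
#' Runs the three persistence-length estimators (bond correlation,
#' mean-squared end-to-end distance, mean-squared midpoint displacement),
#' combines the converged estimates as their arithmetic mean, and collects
#' contour-length statistics. This is the package's summary estimator for
#' fibril ensembles.
#'
#' @param contours list of contours (see [generate_wlc_contours()] or
#'   [read_contours_csv()]).
#' @param s_max largest separation used in the fits (nm).
#' @return An object of class `wlc_fit` with per-estimator results, the
#'   combined estimate, and diagnostics.
#' @examples
#' cts <- generate_wlc_contours(lambda = 100, length = 400, ds = 5,
#'                              n = 40, seed = 1)
#' fit <- wlc_fit(cts)
#' coef(fit)
#' @export
wlc_fit <- function(contours, s_max = NULL) {
  cl <- .as_contour_list(contours)
  bcf <- persistence_length_bcf(cl, s_max)
  msed <- persistence_length_msed(cl, s_max)
  msmd <- persistence_length_msmd(cl, s_max)
  lams <- c(bcf = bcf$lambda, msed = msed$lambda, msmd = msmd$lambda)
  conv <- c(bcf = isTRUE(bcf$converged), msed = isTRUE(msed$converged),
            msmd = isTRUE(msmd$converged))
  if (!any(conv)) {
    if (any(c(bcf$rigid, msed$rigid, msmd$rigid))) {
      stop("contours are rigid at the sampled scale; ",
           "persistence length is not identifiable", call. = FALSE)
    }
    stop("no persistence-length estimator converged", call. = FALSE)
  }
  lens <- vapply(cl, contour_length, numeric(1))
  structure(list(
    lambda = mean(lams[conv]),
    lambda_bcf = bcf$lambda, lambda_msed = msed$lambda,
    lambda_msmd = msmd$lambda, converged = conv,
    contour_length_mean = mean(lens), contour_length_sd = stats::sd(lens),
    n_contours = length(cl),
    bcf = bcf, msed = msed, msmd = msmd),
    class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat("Worm-like-chain fit over", x$n_contours, "contours\n")
  cat(sprintf("  persistence length: %.1f nm (BCF %.1f, MSED %.1f, MSMD %.1f)\n",
              x$lambda, x$lambda_bcf, x$lambda_msed, x$lambda_msmd))
  cat(sprintf("  contour length: %.1f +/- %.1f nm\n",
              x$contour_length_mean, x$contour_length_sd))
  if (!all(x$converged)) {
    cat("  non-converged estimators:",
        paste(names(x$converged)[!x$converged], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.wlc_fit <- function(object, ...) {
  cat("Worm-like-chain persistence-length estimation (2D convention)\n\n")
  print(object)
  cat(sprintf("\n  BCF fit R^2: %.4f\n",
              if (is.na(object$bcf$r_squared)) NA else object$bcf$r_squared))
  invisible(object)
}

#' @export
coef.wlc_fit <- function(object, ...) {
  c(lambda = object$lambda, lambda_bcf = object$lambda_bcf,
    lambda_msed = object$lambda_msed, lambda_msmd = object$lambda_msmd,
    contour_length = object$contour_length_mean)
}

#' @export
plot.wlc_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  b <- x$bcf$curve
  graphics::plot(b$s, b$cos, xlab = "s (nm)",
                 ylab = expression(paste("<cos ", theta, "(s)>")),
                 main = "Bond correlation", pch = 16, cex = 0.5, ...)
  if (is.finite(x$lambda_bcf)) {
    graphics::curve(exp(-s / (2 * x$lambda_bcf)), xname = "s",
                    add = TRUE, col = 2)
  }
  m <- x$msed$curve
  graphics::plot(m$s, m$r2, xlab = "s (nm)", ylab = "<R2(s)> (nm2)",
                 main = "Mean-squared end-to-end", pch = 16, cex = 0.5, ...)
  if (is.finite(x$lambda_msed)) {
    lam <- x$lambda_msed
    graphics::curve(4 * lam * (s - 2 * lam * (1 - exp(-s / (2 * lam)))),
                    xname = "s", add = TRUE, col = 2)
  }
  invisible(x)
}

#' Fibril diameter statistics by random arc-length sampling
#'
#' Samples `n_samples` points uniformly along the pooled arc length of the
#' contours (seeded), interpolates the local width, and reports the sample
#' mean and standard deviation plus a Gaussian (normal) maximum-likelihood
#' fit of the sampled widths.
#'
#' @param contours contour list; each contour must carry a `width` profile.
#' @param n_samples number of sampled points (>= 2).
#' @param seed integer seed.
#' @return list with `mean`, `sd`, `fit` (Gaussian fit coefficients and
#'   standard errors) and the sampled `widths`.
#' @export
diameter_stats <- function(contours, n_samples = 100, seed = NULL) {
  cl <- .as_contour_list(contours)
  if (any(vapply(cl, function(ct) is.null(ct$width), logical(1)))) {
    stop("contours carry no width profile", call. = FALSE)
  }
  stopifnot(n_samples >= 2)
  lens <- vapply(cl, contour_length, numeric(1))
  .with_seed(seed, {
    tot <- sum(lens)
    pos <- runif(n_samples, 0, tot)
    cum <- c(0, cumsum(lens))
    widths <- numeric(n_samples)
    for (k in seq_len(n_samples)) {
      ci <- findInterval(pos[k], cum, rightmost.closed = TRUE)
      ci <- min(ci, length(cl))
      ct <- cl[[ci]]
      s_local <- pos[k] - cum[ci]
      seg <- sqrt(rowSums(diff(ct$points)^2))
      s_in <- c(0, cumsum(seg))
      widths[k] <- stats::approx(s_in, ct$width, xout = s_local,
                                 rule = 2)$y
    }
    fit <- MASS::fitdistr(widths, "normal")
    list(mean = mean(widths), sd = stats::sd(widths),
         fit = list(estimate = fit$estimate, sd_error = fit$sd),
         widths = widths)
  })
}
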