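#' One-site total binding model
#'
#' Equilibrium binding with a linear nonspecific component:
#' `Y = Bmax * X / (Kd + X) + NS * X + Background`.
#'
#' @param x Ligand concentration (same unit as `kd`; non-negative).
#' @param bmax Maximum specific binding.
#' @param kd Equilibrium dissociation constant (positive).
#' @param ns Slope of the nonspecific (linear) term.
#' @param background Signal at zero ligand.
#' @return Predicted response.
#' @export
total_binding_predict <- function(x, bmax, kd, ns, background) {
  stopifnot(kd > 0, all(x >= 0))
  bmax * x / (kd + x) + ns * x + background
}

#' Variable-slope (four-parameter logistic) dose-response model
#'
#' Inhibitor-versus-response with variable Hill slope, parameterized on
#' log10 concentration:
#' `Y = bottom + (top - bottom) / (1 + 10^((log10(ic50) - log10(x)) * hill))`.
#' At `x = ic50` the curve passes through `(top + bottom) / 2`.
#'
#' @param x Concentration (positive).
#' @param top,bottom Upper and lower plateaus.
#' @param ic50 Half-maximal concentration (positive, in the unit of `x`).
#' @param hill Hill slope (negative for inhibition curves read top-down in
#'   concentration).
#' @return Predicted response.
#' @export
dose_response_predict <- function(x, top, bottom, ic50, hill) {
  stopifnot(ic50 > 0, all(x > 0))
  bottom + (top - bottom) / (1 + 10^((log10(ic50) - log10(x)) * hill))
}

#' Serial dilution concentration series
#'
#' Descending geometric series `top, top/factor, ..., top/factor^(n-1)`, as
#' used to prepare a 1:1 (two-fold) dilution gradient for binding assays.
#' With the defaults (250 concentration units, 16 points) the floor is
#' `250 / 2^15`; a 15-point series bottoms at `250 / 2^14` (about 0.0153),
#' matching protocols that quote a floor near 0.015.
#'
#' @param top Highest concentration (positive).
#' @param factor Dilution factor per step (> 1; 2 means 1:1).
#' @param n_points Number of concentrations (>= 2).
#' @return Numeric vector of length `n_points`, descending.
#' @export
dilution_series <- function(top = 250, factor = 2, n_points = 16) {
  stopifnot(top > 0, factor > 1, n_points >= 2)
  top / factor^(seq_len(n_points) - 1)
}

#' Construct a binding curve
#'
#' @param concentration Ligand concentrations (non-negative; at most one
#'   zero point).
#' @param response Measured responses, same length.
#' @param replicate Optional replicate labels.
#' @return `data.frame` of class `binding_curve`, sorted by concentration.
#' @export
binding_curve <- function(concentration, response, replicate = NULL) {
  stopifnot(length(concentration) == length(response),
            all(concentration >= 0), sum(concentration == 0) <= 1 ||
              !is.null(replicate))
  d <- data.frame(concentration = concentration, response = response,
                  replicate = if (is.null(replicate)) NA
                              else as.character(replicate),
                  stringsAsFactors = FALSE)
  d <- d[order(d$concentration), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("binding_curve", "data.frame")
  d
}

#' Read a binding curve from CSV
#'
#' Expects columns `concentration` and `response` (and optionally
#' `replicate`).
#'
#' @param file Path to a CSV file.
#' @return A `binding_curve`.
#' @export
read_curve <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("concentration", "response") %in% names(d))) {
    stop("curve file needs 'concentration' and 'response' columns")
  }
  binding_curve(d$concentration, d$response,
                if ("replicate" %in% names(d)) d$replicate else NULL)
}

fit_converged <- function(fit) {
  ci <- fit$convInfo
  isTRUE(ci$isConv) || (is.numeric(ci$stopCode) && ci$stopCode %in% 1:4)
}

#' Fit the one-site total binding model
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt). Replicates are
#' fitted jointly over all points. Default initialization:
#' `background = min(Y)`, `bmax = max(Y) - min(Y)`, `kd` at the half-rise
#' concentration, `ns` from the terminal slope. Default bounds keep
#' `kd > 0` and `bmax >= 0`. A degenerate input (flat responses) is
#' returned with `converged = FALSE` rather than an error.
#'
#' @param curve A [binding_curve()].
#' @param init Optional named list overriding the starting values
#'   (`bmax`, `kd`, `ns`, `background`).
#' @param lower,upper Named bounds on the four parameters.
#' @return List of class `binding_model_fit` with `estimate`, `std_error`,
#'   `rss`, `converged`, and the underlying `nls` object.
#' @export
fit_total_binding <- function(curve, init = NULL,
                              lower = c(bmax = 0, kd = 1e-9, ns = -Inf,
                                        background = -Inf),
                              upper = c(bmax = Inf, kd = Inf, ns = Inf,
                                        background = Inf)) {
  x <- curve$concentration; y <- curve$response
  if (length(unique(x)) < 5) stop("need at least 5 distinct concentrations")
  if (stats::sd(y) < .Machine$double.eps^0.5 * max(1, abs(mean(y)))) {
    est <- c(bmax = 0, kd = NA_real_, ns = 0, background = mean(y))
    return(structure(list(estimate = est,
                          std_error = stats::setNames(rep(NA_real_, 4),
                                                      names(est)),
                          rss = sum((y - mean(y))^2), converged = FALSE,
                          fit = NULL, model = "one-site-total"),
                     class = "binding_model_fit"))
  }
  start <- list(background = min(y), bmax = max(y) - min(y),
                kd = half_rise_x(x, y), ns = terminal_slope(x, y))
  if (!is.null(init)) start[names(init)] <- init
  start$kd <- max(start$kd, lower[["kd"]] * 2)
  fit <- minpack.lm::nlsLM(
    response ~ bmax * concentration / (kd + concentration) +
      ns * concentration + background,
    data = data.frame(concentration = x, response = y),
    start = start[c("bmax", "kd", "ns", "background")],
    lower = lower[c("bmax", "kd", "ns", "background")],
    upper = upper[c("bmax", "kd", "ns", "background")],
    control = minpack.lm::nls.lm.control(maxiter = 500))
  summarize_fit(fit, c("bmax", "kd", "ns", "background"), "one-site-total")
}

half_rise_x <- function(x, y) {
  yr <- (y - min(y)) / max(max(y) - min(y), .Machine$double.eps)
  xs <- x[x > 0]
  if (length(xs) == 0) return(stats::median(x) + 1e-9)
  i <- which.min(abs(yr[x > 0] - 0.5))
  xs[i]
}

terminal_slope <- function(x, y) {
  top <- x >= stats::quantile(x, 0.75)
  if (sum(top) < 2) return(0)
  unname(stats::coef(stats::lm(y[top] ~ x[top]))[2])
}

summarize_fit <- function(fit, par_names, model_tag) {
  est <- stats::coef(fit)[par_names]
  se <- tryCatch(summary(fit)$coefficients[par_names, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_,
                                                         length(par_names)),
                                                     par_names))
  structure(list(estimate = est, std_error = se,
                 rss = sum(stats::residuals(fit)^2),
                 converged = fit_converged(fit), fit = fit,
                 model = model_tag),
            class = "binding_model_fit")
}

#' Fit the variable-slope dose-response model
#'
#' Four-parameter logistic on log10 concentration, unweighted least squares,
#' replicates fitted jointly. Initialization from the data quartiles: the
#' plateaus from the response extremes, IC50 at the concentration nearest
#' the half response, Hill slope sign from the observed trend. The fit is
#' canonicalized so `top >= bottom` (swapping plateaus and negating the
#' Hill slope is the identical curve). Zero-concentration points cannot sit
#' on a log axis and are dropped with a warning.
#'
#' @param curve A [binding_curve()].
#' @param init Optional named list overriding starting values
#'   (`top`, `bottom`, `ic50`, `hill`).
#' @return List of class `binding_model_fit` with `estimate` (`top`,
#'   `bottom`, `ic50`, `hill`), `std_error`, `rss`, `converged`.
#' @export
fit_dose_response <- function(curve, init = NULL) {
  keep <- curve$concentration > 0
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " zero-concentration point(s)")
  }
  x <- curve$concentration[keep]; y <- curve$response[keep]
  if (length(unique(x)) < 5) stop("need at least 5 distinct concentrations")
  half <- (max(y) + min(y)) / 2
  trend <- unname(stats::coef(stats::lm(y ~ log10(x)))[2])
  start <- list(top = max(y), bottom = min(y),
                ic50 = x[which.min(abs(y - half))],
                hill = if (trend >= 0) 1 else -1)
  if (!is.null(init)) start[names(init)] <- init
  fit <- minpack.lm::nlsLM(
    response ~ bottom + (top - bottom) /
      (1 + 10^((log10(ic50) - log10(concentration)) * hill)),
    data = data.frame(concentration = x, response = y),
    start = start[c("top", "bottom", "ic50", "hill")],
    lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-12, hill = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  out <- summarize_fit(fit, c("top", "bottom", "ic50", "hill"),
                       "dose-response-4pl")
  if (out$estimate[["top"]] < out$estimate[["bottom"]]) {
    est <- out$estimate; se <- out$std_error
    out$estimate[c("top", "bottom")] <- est[c("bottom", "top")]
    out$std_error[c("top", "bottom")] <- se[c("bottom", "top")]
    out$estimate[["hill"]] <- -est[["hill"]]
  }
  out
}

#' @export
print.binding_model_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s)\n", x$model,
              if (x$converged) "converged" else "NOT converged"))
  for (p in names(x$estimate)) {
    cat(sprintf("  %-10s %12.6g  (SE %.4g)\n", p, x$estimate[[p]],
                x$std_error[[p]]))
  }
  cat(sprintf("  RSS %.6g\n", x$rss))
  invisible(x)
}

#' Serialize a model fit to JSON
#'
#' @param fit A `binding_model_fit`.
#' @param file Optional output path.
#' @return JSON string (invisibly when written).
#' @export
fit_to_json <- function(fit, file = NULL) {
  x <- list(model = fit$model, estimate = as.list(fit$estimate),
            std_error = as.list(fit$std_error), rss = fit$rss,
            converged = fit$converged)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
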