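#' Peredox calibration model
#'
#' Bundles the parameters linking the normalized Peredox red/green
#' fluorescence ratio to the cytoplasmic NAD+/NADH redox ratio. The
#' fluorescence response to the lactate:pyruvate ratio `X` follows a
#' logistic (Hill) curve
#' \deqn{F(X) = 1 + A / (1 + (B/X)^{h})}
#' with the Hill coefficient `h` fixed at 1.7, and the lactate
#' dehydrogenase (LDH) equilibrium
#' \deqn{K = [Pyr][NADH][H^+] / ([Lac][NAD^+])}
#' converts `X` to NAD+/NADH at fixed pH.
#'
#' @param A Logistic amplitude (dynamic range above the lower asymptote);
#'   must be positive. Default 1.04, the mean of per-cell fits at the
#'   leading edge of a 24-h monolayer.
#' @param B Logistic midpoint in lactate:pyruvate ratio units; must be
#'   positive. Default 44.13.
#' @param hill Hill coefficient; fixed at 1.7 for the Peredox sensor.
#' @param K LDH equilibrium constant (molar). Default 1.1e-11.
#' @param pH Assumed cytoplasmic pH. Default 7.4, so `[H+] = 10^-7.4` M.
#'
#' @return An object of class `peredox_calibration`.
#' @examples
#' cal <- peredox_calibration()
#' fluorescence_to_redox(1 + 1.04 / 2, cal) # F at the midpoint maps to X = B
#' @export
peredox_calibration <- function(A = 1.04, B = 44.13, hill = 1.7,
                                K = 1.1e-11, pH = 7.4) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(B), length(B) == 1L, is.finite(B))
  if (A <= 0) stop("calibration amplitude 'A' must be positive")
  if (B <= 0) stop("calibration midpoint 'B' must be positive")
  if (hill <= 0) stop("'hill' must be positive")
  if (K <= 0) stop("LDH equilibrium constant 'K' must be positive")
  structure(
    list(A = A, B = B, hill = hill, K = K, pH = pH, H_plus = 10^(-pH)),
    class = "peredox_calibration"
  )
}

#' @export
print.peredox_calibration <- function(x, ...) {
  cat("Peredox calibration model\n")
  cat(sprintf("  F(X) = 1 + A / (1 + (B/X)^%.2f)\n", x$hill))
  cat(sprintf("  A = %.4g, B = %.4g (lactate:pyruvate units)\n", x$A, x$B))
  cat(sprintf("  LDH equilibrium: K = %.3g M, pH = %.2f\n", x$K, x$pH))
  invisible(x)
}

#' Logistic titration response
#'
#' Evaluates the normalized fluorescence ratio expected at a given
#' lactate:pyruvate ratio under a calibration model. This is the forward
#' curve fitted during titration calibration.
#'
#' @param X Lactate:pyruvate ratio(s), positive.
#' @param model A [peredox_calibration()] object.
#' @return Normalized fluorescence ratio(s) in `(1, 1 + A)`.
#' @export
titration_response <- function(X, model = peredox_calibration()) {
  stopifnot(inherits(model, "peredox_calibration"))
  if (any(X <= 0)) stop("lactate:pyruvate ratio 'X' must be positive")
  1 + model$A / (1 + (model$B / X)^model$hill)
}

#' Convert normalized fluorescence ratio to NAD+/NADH
#'
#' Inverts the logistic titration curve for the lactate:pyruvate ratio
#' `X` and applies the LDH equilibrium,
#' `NAD+/NADH = [H+] / (K * X)`. The transform is strictly decreasing in
#' `F_norm`: a brighter green (NADH-bound) sensor means a more reduced
#' cytoplasm. Values at or outside the asymptotes `(1, 1 + A)` cannot be
#' inverted; they are clipped to an epsilon-interior of the dynamic range
#' and flagged.
#'
#' @param F_norm Normalized fluorescence ratio(s).
#' @param model A [peredox_calibration()] object.
#' @param eps Clipping margin as a fraction of the dynamic range `A`.
#'   Default 1e-3.
#' @return A numeric vector of NAD+/NADH values with attribute
#'   `"clipped"`, a logical vector marking entries that fell outside the
#'   invertible range.
#' @seealso [redox_to_fluorescence()] for the exact inverse.
#' @export
fluorescence_to_redox <- function(F_norm, model = peredox_calibration(),
                                  eps = 1e-3) {
  stopifnot(inherits(model, "peredox_calibration"))
  lo <- 1 + eps * model$A
  hi <- 1 + (1 - eps) * model$A
  clipped <- !is.na(F_norm) & (F_norm <= lo | F_norm >= hi)
  Fc <- pmin(pmax(F_norm, lo), hi)
  X <- model$B / (model$A / (Fc - 1) - 1)^(1 / model$hill)
  redox <- model$H_plus / (model$K * X)
  attr(redox, "clipped") <- clipped
  redox
}

#' Convert NAD+/NADH to normalized fluorescence ratio
#'
#' Exact inverse of [fluorescence_to_redox()]: the LDH equilibrium gives
#' the lactate:pyruvate ratio `X = [H+] / (K * redox)` that would hold
#' the cytoplasm at the stated redox ratio, and the logistic curve gives
#' the sensor response at that `X`. Used by the synthetic renderer to
#' paint cells with a prescribed redox state.
#'
#' @param redox NAD+/NADH ratio(s), positive.
#' @inheritParams fluorescence_to_redox
#' @return Normalized fluorescence ratio(s) in the open interval
#'   `(1, 1 + A)`.
#' @export
redox_to_fluorescence <- function(redox, model = peredox_calibration()) {
  stopifnot(inherits(model, "peredox_calibration"))
  if (any(redox <= 0, na.rm = TRUE)) stop("'redox' must be positive")
  X <- model$H_plus / (model$K * redox)
  titration_response(X, model)
}

#' Per-cell two-channel intensity ratio
#'
#' Computes, for every labeled nucleus, the mean red (mCherry) and mean
#' green (T-Sapphire) intensity over the nucleus mask and their ratio
#' `F_raw = mean(red) / mean(green)`. The ratio of mean intensities is
#' used rather than the mean of pixel-wise ratios: it is robust to
#' low-count pixels and is invariant to a common scaling of both
#' channels, which is what makes the sensor insensitive to expression
#' level.
#'
#' @param red,green Numeric matrices, the two registered channels.
#' @param labels Integer matrix of the same shape; 0 = background,
#'   positive integers identify nuclei.
#' @param background_floor Cells whose mean green signal does not exceed
#'   this floor get `F_raw = NA` and `qc_flag = "low_green"`.
#' @return A data.frame with columns `label`, `mean_red`, `mean_green`,
#'   `F_raw`, `n_pixels`, `qc_flag`.
#' @export
per_cell_ratio <- function(red, green, labels, background_floor = 0) {
  if (!all(dim(red) == dim(green)) || !all(dim(red) == dim(labels)))
    stop("'red', 'green' and 'labels' must have identical dimensions")
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) {
    return(data.frame(label = integer(), mean_red = numeric(),
                      mean_green = numeric(), F_raw = numeric(),
                      n_pixels = integer(), qc_flag = character()))
  }
  f <- factor(labels[labels > 0], levels = ids)
  mr <- tapply(red[labels > 0], f, mean)
  mg <- tapply(green[labels > 0], f, mean)
  np <- as.integer(table(f))
  low <- mg <= background_floor
  data.frame(
    label = as.integer(ids),
    mean_red = as.numeric(mr),
    mean_green = as.numeric(mg),
    F_raw = ifelse(low, NA_real_, as.numeric(mr) / as.numeric(mg)),
    n_pixels = np,
    qc_flag = ifelse(low, "low_green", "ok"),
    row.names = NULL
  )
}

#' Normalize a titration series to its pyruvate-saturated anchor
#'
#' Divides every raw red/green ratio in a titration series by the ratio
#' measured at the lowest lactate:pyruvate step. At vanishing `X` the
#' sensor sits at its low-NADH state and the logistic response tends to
#' its lower asymptote, so the anchored series satisfies `F_norm -> 1`
#' as `X -> 0`, matching the fitted curve's convention.
#'
#' @param series A data.frame with columns `X` (lactate:pyruvate ratio,
#'   positive) and `F_raw` (raw red/green ratio).
#' @return The input with an `F_norm` column appended (or replaced).
#' @export
normalize_titration <- function(series) {
  if (!all(c("X", "F_raw") %in% names(series)))
    stop("'series' needs columns 'X' and 'F_raw'")
  if (any(series$X <= 0)) stop("titration steps require X > 0")
  i0 <- which.min(series$X)
  anchor <- series$F_raw[i0]
  if (!is.finite(anchor) || anchor <= 0)
    stop("low-X anchor step has a non-positive or missing ratio")
  series$F_norm <- series$F_raw / anchor
  series
}

#' Fit the logistic titration curve per cell
#'
#' Bounded nonlinear least squares of `F_norm ~ 1 + A/(1 + (B/X)^hill)`
#' with the Hill coefficient held fixed, run independently for each
#' cell's titration series. Cells that fail to converge are excluded and
#' counted rather than silently dropped.
#'
#' @param series_list A list of titration data.frames, each with columns
#'   `X` and `F_norm` (see [normalize_titration()]), one per cell.
#' @param hill Fixed Hill coefficient. Default 1.7.
#' @param lower,upper Bounds on `(A, B)` for the constrained fit.
#' @return A list with `fits` (data.frame: `cell`, `A`, `B`, `rss`,
#'   `converged`), `A_mean`, `A_sd`, `B_mean`, `B_sd` over converged
#'   cells, and `n_failed`.
#' @examples
#' cal <- peredox_calibration(A = 1.0, B = 40)
#' X <- c(0.5, 2, 10, 40, 120, 400)
#' ser <- data.frame(X = X, F_norm = titration_response(X, cal))
#' fit_calibration(list(ser))$fits[, c("A", "B")]
#' @export
fit_calibration <- function(series_list, hill = 1.7,
                            lower = c(A = 1e-3, B = 1e-3),
                            upper = c(A = 20, B = 1e4)) {
  if (is.data.frame(series_list)) series_list <- list(series_list)
  n <- length(series_list)
  out <- data.frame(cell = seq_len(n), A = NA_real_, B = NA_real_,
                    rss = NA_real_, converged = FALSE)
  for (i in seq_len(n)) {
    s <- series_list[[i]]
    if (!all(c("X", "F_norm") %in% names(s)))
      stop("each series needs columns 'X' and 'F_norm'")
    if (nrow(s) < 4L)
      stop("need at least 4 titration steps spanning the sigmoid")
    fit <- fit_one_titration(s$X, s$F_norm, hill, lower, upper)
    if (!is.null(fit)) {
      out$A[i] <- fit$A
      out$B[i] <- fit$B
      out$rss[i] <- fit$rss
      out$converged[i] <- TRUE
    }
  }
  ok <- out$converged
  list(
    fits = out,
    A_mean = mean(out$A[ok]), A_sd = stats::sd(out$A[ok]),
    B_mean = mean(out$B[ok]), B_sd = stats::sd(out$B[ok]),
    n_failed = sum(!ok)
  )
}

# Single-cell bounded logistic fit. nls("port") from a data-driven start,
# falling back to L-BFGS-B on the residual sum of squares if nls fails.
fit_one_titration <- function(X, F_norm, hill, lower, upper) {
  keep <- is.finite(X) & is.finite(F_norm)
  X <- X[keep]; F_norm <- F_norm[keep]
  if (length(X) < 4L) return(NULL)
  A0 <- max(max(F_norm) - 1, 0.1)
  # X at which the response crosses halfway up the observed range
  half <- 1 + A0 / 2
  B0 <- if (any(F_norm >= half)) X[which(F_norm >= half)[1]] else stats::median(X)
  B0 <- min(max(B0, lower[["B"]] * 2), upper[["B"]] / 2)
  df <- data.frame(X = X, F_norm = F_norm)
  fit <- tryCatch(
    stats::nls(F_norm ~ 1 + A / (1 + (B / X)^hill), data = df,
               start = list(A = A0, B = B0),
               lower = lower, upper = upper, algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    return(list(A = cf[["A"]], B = cf[["B"]],
                rss = sum(stats::resid(fit)^2)))
  }
  obj <- function(p) sum((F_norm - (1 + p[1] / (1 + (p[2] / X)^hill)))^2)
  op <- tryCatch(
    stats::optim(c(A0, B0), obj, method = "L-BFGS-B",
                 lower = lower, upper = upper),
    error = function(e) NULL
  )
  if (is.null(op) || op$convergence != 0) return(NULL)
  list(A = op$par[1], B = op$par[2], rss = op$value)
}

#' Propagate fluorescence dispersion to asymmetric redox error bars
#'
#' The fluorescence-to-redox transform is nonlinear, so a symmetric
#' spread in the fluorescence ratio maps to an asymmetric interval in
#' NAD+/NADH. Following the compositing convention, the standard
#' deviation is added to and subtracted from the mean fluorescence ratio
#' first, and each of the three ratios is then transformed.
#'
#' @param F_mean Mean normalized fluorescence ratio(s).
#' @param F_sd Standard deviation(s) of the fluorescence ratio.
#' @inheritParams fluorescence_to_redox
#' @return A data.frame with columns `redox`, `lower`, `upper`,
#'   `clipped`. Because the transform is decreasing, `F_mean + F_sd`
#'   yields the lower redox bound and `F_mean - F_sd` the upper.
#' @export
propagate_error <- function(F_mean, F_sd, model = peredox_calibration(),
                            eps = 1e-3) {
  if (any(F_sd < 0, na.rm = TRUE)) stop("'F_sd' must be non-negative")
  mid <- fluorescence_to_redox(F_mean, model, eps)
  lo <- fluorescence_to_redox(F_mean + F_sd, model, eps)  # decreasing map
  hi <- fluorescence_to_redox(F_mean - F_sd, model, eps)
  data.frame(
    redox = as.numeric(mid),
    lower = as.numeric(lo),
    upper = as.numeric(hi),
    clipped = attr(mid, "clipped") | attr(lo, "clipped") | attr(hi, "clipped")
  )
}

#' Simulate per-cell titration series
#'
#' Draws per-cell true logistic parameters from normal distributions
#' (truncated at small positive values), evaluates the titration curve
#' on a lactate:pyruvate grid, and applies multiplicative Gaussian
#' noise. This is the stated world for calibration-recovery checks:
#' population means 1.04 and 44.13 with between-cell standard deviations
#' 0.24 and 26.08, seven titration steps spanning 0.1-400, and 2%
#' multiplicative noise.
#'
#' @param n_cells Number of cells to simulate.
#' @param A_mean,A_sd,B_mean,B_sd Population mean and between-cell SD of
#'   the per-cell true parameters.
#' @param X Lactate:pyruvate grid; default 7 log-spaced steps 0.1-400.
#' @param noise_sd Multiplicative noise SD as a fraction of the signal.
#' @param hill Hill coefficient used in the forward curve.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A list with `series` (list of data.frames with `X`, `F_norm`)
#'   and `truth` (data.frame of per-cell true `A`, `B`).
#' @export
simulate_titration_series <- function(n_cells = 200,
                                      A_mean = 1.04, A_sd = 0.24,
                                      B_mean = 44.13, B_sd = 26.08,
                                      X = exp(seq(log(0.1), log(400),
                                                  length.out = 7)),
                                      noise_sd = 0.02, hill = 1.7,
                                      seed = 1L) {
  stopifnot(n_cells >= 1, all(X > 0))
  set.seed(seed)
  rtruncnorm <- function(n, mean, sd, lo) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= lo)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  A <- rtruncnorm(n_cells, A_mean, A_sd, 0.05)
  B <- rtruncnorm(n_cells, B_mean, B_sd, 0.5)
  series <- lapply(seq_len(n_cells), function(i) {
    m <- peredox_calibration(A = A[i], B = B[i], hill = hill)
    f <- titration_response(X, m) *
      (1 + stats::rnorm(length(X), 0, noise_sd))
    data.frame(X = X, F_norm = f)
  })
  list(series = series, truth = data.frame(cell = seq_len(n_cells), A = A, B = B))
}
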