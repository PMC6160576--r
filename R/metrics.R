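#' Potential-map error metrics
#'
#' The three standard scalar comparisons between a ground-truth body-surface
#' potential map `gt` and a simulated one `s`, evaluated per time frame:
#'
#' * RMS error \eqn{\bar{E}}: `norm(gt - s) / sqrt(n)` under the `"sqrt_n"`
#'   convention (the true root-mean-square, the default), or
#'   `norm(gt - s) / n` under the `"n"` convention (the form some reports
#'   print). Every summary names the convention used.
#' * Relative RMS error `rRMSE`: `norm(gt - s) / norm(gt)`.
#' * Correlation `rho`: the **uncentered** cosine similarity
#'   `sum(gt * s) / (norm(gt) * norm(s))` - not Pearson correlation. A
#'   mean-centred variant is available behind `centered = TRUE` for
#'   sensitivity checks only.
#'
#' @param gt,s numeric vectors of equal length (one frame of potentials).
#' @param convention RMS denominator convention, `"sqrt_n"` or `"n"`.
#' @param centered mean-centre both inputs before the cosine (default
#'   `FALSE`).
#' @return a scalar.
#' @name metrics
NULL

#' @rdname metrics
#' @export
rms_error <- function(gt, s, convention = c("sqrt_n", "n")) {
  convention <- match.arg(convention)
  if (length(gt) != length(s)) stop("length mismatch")
  n <- length(gt)
  if (n < 1L) stop("empty input")
  nrm <- sqrt(sum((gt - s)^2))
  if (convention == "sqrt_n") nrm / sqrt(n) else nrm / n
}

#' @rdname metrics
#' @export
rrmse <- function(gt, s) {
  if (length(gt) != length(s)) stop("length mismatch")
  ngt <- sqrt(sum(gt^2))
  if (ngt == 0) stop("rRMSE undefined: ground-truth frame has zero norm")
  sqrt(sum((gt - s)^2)) / ngt
}

#' @rdname metrics
#' @export
correlation <- function(gt, s, centered = FALSE) {
  if (length(gt) != length(s)) stop("length mismatch")
  if (centered) {
    gt <- gt - mean(gt)
    s <- s - mean(s)
  }
  ngt <- sqrt(sum(gt^2)); ns <- sqrt(sum(s^2))
  if (ngt == 0 || ns == 0)
    stop("correlation undefined: zero-norm frame")
  sum(gt * s) / (ngt * ns)
}

#' Per-frame error series between two frame sets
#'
#' Applies the three metrics frame by frame. Frames whose ground-truth norm
#' falls below `1e-9` of the window's maximum frame norm are flagged as
#' excluded (`rRMSE` and `rho` are undefined there) rather than silently
#' skipped; excluded frames carry `NA` and are dropped from summaries.
#'
#' @param gt,s [frame_set()] objects on the same mesh with equal frame
#'   counts.
#' @param convention RMS convention passed to [rms_error()].
#' @return an object of class `error_series`: fields `e_rms`, `rrmse`,
#'   `rho` (per-frame), `excluded` (logical), `n` (nodes per frame),
#'   `convention`.
#' @export
error_series <- function(gt, s, convention = c("sqrt_n", "n")) {
  convention <- match.arg(convention)
  if (!identical(gt$mesh_id, s$mesh_id))
    stop("frame sets are bound to different meshes")
  if (!all(dim(gt$values) == dim(s$values)))
    stop("frame sets differ in shape")
  nf <- ncol(gt$values)
  norms <- sqrt(colSums(gt$values^2))
  excluded <- norms < 1e-9 * max(norms)
  e_rms <- rr <- rho <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    g <- gt$values[, f]; x <- s$values[, f]
    e_rms[f] <- rms_error(g, x, convention)
    if (!excluded[f]) {
      rr[f] <- rrmse(g, x)
      sn <- sqrt(sum(x^2))
      rho[f] <- if (sn == 0) NA_real_ else correlation(g, x)
    }
  }
  structure(list(e_rms = e_rms, rrmse = rr, rho = rho,
                 excluded = excluded, n = nrow(gt$values),
                 convention = convention),
            class = "error_series")
}

#' @export
print.error_series <- function(x, ...) {
  s <- summarize_errors(x)
  cat(sprintf(paste0("error_series over %d frames (%d excluded): mean ",
                     "rRMSE %.4g, peak rRMSE %.4g, mean rho %.4g\n"),
              length(x$rrmse), sum(x$excluded), s$mean_rrmse, s$peak_rrmse,
              s$mean_rho))
  invisible(x)
}

#' Summaries of an error series over a frame window
#'
#' Mean and peak of each metric over the window; "peak" is the worst case:
#' the maximum for the RMS error and rRMSE and the minimum for rho.
#' Excluded frames are dropped and counted.
#'
#' @param series an [error_series()].
#' @param window integer vector of frame indices (default: all frames).
#' @return a one-row `data.frame` with columns `mean_e_rms`, `peak_e_rms`,
#'   `mean_rrmse`, `peak_rrmse`, `mean_rho`, `peak_rho`, `n_excluded`,
#'   `convention`.
#' @export
summarize_errors <- function(series, window = NULL) {
  nf <- length(series$e_rms)
  if (is.null(window)) window <- seq_len(nf)
  if (!length(window) || min(window) < 1 || max(window) > nf)
    stop("summary window must be a non-empty range within the series")
  keep <- window[!series$excluded[window]]
  if (!length(keep)) stop("all frames in the window are excluded")
  data.frame(mean_e_rms = mean(series$e_rms[window]),
             peak_e_rms = max(series$e_rms[window]),
             mean_rrmse = mean(series$rrmse[keep]),
             peak_rrmse = max(series$rrmse[keep]),
             mean_rho = mean(series$rho[keep]),
             peak_rho = min(series$rho[keep]),
             n_excluded = sum(series$excluded[window]),
             convention = series$convention,
             stringsAsFactors = FALSE)
}
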