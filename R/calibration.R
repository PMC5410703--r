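#' Thin reads to a target mean coverage
#'
#' Emulates shallow (~1x) sequencing by binomial thinning: each read is
#' retained independently with probability `target / current mean
#' coverage`, methylated and unmethylated reads thinned identically, so
#' the expected weighted methylation level is unchanged.
#'
#' @param records per-cytosine record table.
#' @param target_mean_coverage desired mean reads per cytosine (> 0).
#' @param seed RNG seed; the same seed reproduces the thinning exactly.
#' @return a thinned copy of `records`. If the target is at or above the
#'   current mean, the records are returned unchanged with a warning.
#' @export
downsample_records <- function(records, target_mean_coverage, seed = 1L) {
  if (target_mean_coverage <= 0) stop("target coverage must be > 0")
  cur <- mean(records$total_reads)
  if (is.na(cur) || cur == 0) stop("records carry no reads to thin")
  if (target_mean_coverage >= cur) {
    warning("target coverage (", target_mean_coverage,
            ") is not below the current mean (", signif(cur, 4L),
            "); records returned unchanged")
    return(copy(records))
  }
  r <- target_mean_coverage / cur
  set.seed(seed)
  out <- copy(records)
  keep_m <- stats::rbinom(nrow(out), out$meth_reads, r)
  keep_u <- stats::rbinom(nrow(out), out$total_reads - out$meth_reads, r)
  out[, `:=`(meth_reads = as.integer(keep_m),
             total_reads = as.integer(keep_m + keep_u))]
  out[]
}

#' Fit the deep-vs-shallow methylation calibration line
#'
#' Ordinary least squares of the shallow (~1x) methylation level (y) on
#' the deep-coverage level (x) across species, the relationship used to
#' extrapolate deep levels for species sequenced only at low coverage.
#'
#' @param pairs a data frame with columns `deep_level` (x) and
#'   `shallow_level` (y); at least 3 rows, x not all equal.
#' @param context optional context label carried through to outputs.
#' @return an object of class `calibration_model`: slope, intercept,
#'   residual standard deviation, and the data retained for
#'   prediction-band inversion.
#' @export
fit_calibration <- function(pairs, context = NA_character_) {
  pairs <- as.data.frame(pairs)
  if (!all(c("deep_level", "shallow_level") %in% names(pairs)))
    stop("pairs must have columns deep_level and shallow_level")
  x <- pairs$deep_level; y <- pairs$shallow_level
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0) stop("degenerate fit: deep levels are all equal")
  fit <- stats::lm(y ~ x)
  model <- list(slope = unname(stats::coef(fit)[2L]),
                intercept = unname(stats::coef(fit)[1L]),
                sigma = stats::sigma(fit),
                n_points = length(x),
                x = x, y = y,
                x_mean = mean(x),
                sxx = sum((x - mean(x))^2),
                df = length(x) - 2L,
                context = context)
  class(model) <- "calibration_model"
  model
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "calibration line (shallow ~ deep%s): y = %.4f x + %.4f\n",
    if (is.na(x$context)) "" else paste0(", ", x$context),
    x$slope, x$intercept))
  cat(sprintf("  n = %d, residual SD = %.4g\n", x$n_points, x$sigma))
  invisible(x)
}

#' Extrapolate a deep methylation level from a shallow observation
#'
#' Inverse prediction through the fitted calibration line: the point
#' estimate is `(y - intercept) / slope`, and the 95% interval is the set
#' of deep levels whose prediction band (for a new shallow observation)
#' covers y — the Fieller-type inversion standard for linear calibration —
#' truncated to [0, 1]. With zero residual scatter the interval collapses
#' to the exact inversion.
#'
#' @param model a [fit_calibration()] result with positive slope.
#' @param shallow_level observed shallow level(s) in [0, 1].
#' @param level confidence level (default 0.95).
#' @return a `data.table`: `shallow_level`, `estimate`, `lower`, `upper`,
#'   with `lower <= estimate <= upper`, all in [0, 1].
#' @export
extrapolate_level <- function(model, shallow_level, level = 0.95) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$slope <= 0)
    stop("calibration invalid: slope must be positive")
  if (any(shallow_level < 0 | shallow_level > 1))
    stop("shallow_level must lie in [0, 1]")
  a <- model$intercept; b <- model$slope
  tval <- stats::qt(1 - (1 - level) / 2, df = model$df)
  s2 <- model$sigma^2
  one <- function(y0) {
    xhat <- (y0 - a) / b
    if (s2 == 0) {
      xhat <- min(max(xhat, 0), 1)
      return(c(xhat, xhat, xhat))
    }
    # solve (y0 - a - b x)^2 = t^2 s^2 (1 + 1/n + (x - xbar)^2 / Sxx)
    c2 <- tval^2 * s2
    A <- b^2 - c2 / model$sxx
    B <- -2 * b * (y0 - a) + 2 * c2 * model$x_mean / model$sxx
    C <- (y0 - a)^2 - c2 * (1 + 1 / model$n_points) -
      c2 * model$x_mean^2 / model$sxx
    disc <- B^2 - 4 * A * C
    if (A <= 0 || disc < 0) {
      lo <- 0; hi <- 1  # band does not close: interval is the whole range
    } else {
      lo <- (-B - sqrt(disc)) / (2 * A)
      hi <- (-B + sqrt(disc)) / (2 * A)
    }
    lo <- min(max(lo, 0), 1); hi <- min(max(hi, 0), 1)
    est <- min(max(xhat, lo), hi)
    c(est, lo, hi)
  }
  res <- t(vapply(shallow_level, one, numeric(3L)))
  data.table(shallow_level = shallow_level, estimate = res[, 1L],
             lower = res[, 2L], upper = res[, 3L])
}

#' Serialise / restore a calibration model as plain text
#'
#' @param model a `calibration_model`.
#' @param path file path.
#' @return `write_calibration` the path invisibly; `read_calibration` the
#'   restored model.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  lines <- c(paste0("slope=", num(model$slope)),
             paste0("intercept=", num(model$intercept)),
             paste0("sigma=", num(model$sigma)),
             paste0("n_points=", model$n_points),
             paste0("context=", model$context),
             paste0("x=", num(model$x)),
             paste0("y=", num(model$y)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1L), 2L),
                          vapply(kv, `[`, character(1L), 1L))
  nums <- function(key) as.numeric(strsplit(vals[[key]], ",")[[1L]])
  fit_calibration(data.frame(deep_level = nums("x"),
                             shallow_level = nums("y")),
                  context = vals[["context"]])
}
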