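#' Melt-curve container
#'
#' A thermal denaturation dataset: strictly increasing Kelvin temperatures
#' paired with helicity-degree values `theta` (nominally in `[0, 1]`;
#' noisy points may fall slightly outside).
#'
#' @param temperature_K Strictly increasing Kelvin temperatures.
#' @param theta Helicity values, same length.
#' @param label Free-text provenance tag.
#' @return Data frame of class `melt_curve` with attribute `label`.
#' @export
melt_curve <- function(temperature_K, theta, label = "") {
  stopifnot(is.numeric(temperature_K), is.numeric(theta))
  if (length(temperature_K) != length(theta))
    stop("temperature_K and theta must have the same length")
  if (length(temperature_K) > 1 && any(diff(temperature_K) <= 0))
    stop("temperatures must be strictly increasing")
  structure(data.frame(temperature_K = temperature_K, theta = theta),
            class = c("melt_curve", "data.frame"), label = label)
}

#' Specification for a synthetic melt curve
#'
#' Defines the signal (a [lab_params()] set evaluated through the order
#' parameter) and the additive Gaussian noise of a simulated thermal
#' denaturation experiment.
#'
#' @param params A [lab_params()] object.
#' @param T_start,T_stop Kelvin range; `T_start > params$t0`.
#' @param n_points Grid size (`>= 2`), default 60 (comparable to a dense
#'   CD melt).
#' @param noise_sd Additive Gaussian standard deviation on `theta`
#'   (`>= 0`), default 0.
#' @param seed Integer RNG seed, default 0.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(params, T_start, T_stop, n_points = 60,
                           noise_sd = 0, seed = 0) {
  stopifnot(inherits(params, "lab_params"))
  if (T_start <= params$t0)
    stop(sprintf("T_start must exceed t0 = %g K", params$t0))
  if (T_stop <= T_start) stop("T_stop must exceed T_start")
  if (n_points < 2) stop("n_points must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(params = params, T_start = T_start, T_stop = T_stop,
                 n_points = n_points, noise_sd = noise_sd, seed = seed),
            class = "generator_spec")
}

# run code with a local, seeded RNG stream; caller's RNG state untouched
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic melt curve
#'
#' `theta_i = order_parameter(s_tilde_lab(T_i)) + eps_i` with
#' `eps_i ~ N(0, noise_sd^2)` on a uniform temperature grid. Noise is not
#' clipped to `[0, 1]`, matching the scatter of real normalized CD data.
#' The generating spec is attached as attribute `spec`, and the caller's
#' RNG state is left untouched.
#'
#' @param spec A [generator_spec()] object.
#' @param R Gas constant, default [R_GAS].
#' @return A [melt_curve()] with attribute `spec`.
#' @examples
#' p <- lab_params(t0 = 260.6, h = 2134, h_ps = 2141, Q = 233)
#' gen <- generate_melt_curve(generator_spec(p, 265, 330, noise_sd = 0.01))
#' @export
generate_melt_curve <- function(spec, R = R_GAS) {
  stopifnot(inherits(spec, "generator_spec"))
  grid <- seq(spec$T_start, spec$T_stop, length.out = spec$n_points)
  signal <- theta_curve(grid, spec$params, R)$theta
  eps <- if (spec$noise_sd > 0) {
    .with_seed(spec$seed, stats::rnorm(spec$n_points, 0, spec$noise_sd))
  } else rep(0, spec$n_points)
  mc <- melt_curve(grid, signal + eps,
                   label = sprintf("synthetic (noise_sd=%g, seed=%d)",
                                   spec$noise_sd, spec$seed))
  attr(mc, "spec") <- spec
  mc
}

# reference fit table: panel, color, estimates, percent errors, printed
# sigma and R^2 for the eleven published parameter rows
.table1 <- function() {
  df <- read.csv(text = "
panel,color,t0,h,h_ps,Q,t0_err,h_err,h_ps_err,Q_err,sigma_printed,r2_printed
a,darkgreen,251.0,5754,5701,299,4.8,16.1,15.9,4.3,0.003,0.997
a,lightgreen,235.2,5086,5049,275,2.2,4.7,4.66,0.8,0.004,0.999
a,yellowgreen,216.4,5761,5727,278,8.6,14.4,14.3,1.47,0.004,0.992
b,darkgreen,247.6,4018,3955,279,5.62,13.6,13.3,5.2,0.004,0.998
b,lightgreen,289.4,1973,1930,273,2.5,11.3,11.0,10.2,0.004,0.999
c,darkgreen,260.6,2134,2141,233,0.42,1.8,1.9,0.7,0.004,0.994
d,darkgreen,241.2,1954,2068,32,2.4,8.3,7.6,9.4,0.032,0.999
d,forestgreen,238.2,1792,1981,28,1.6,6.7,6.28,8.0,0.035,0.999
d,yellowgreen,245.3,1267,1476,19,1.0,5.7,5.5,6.5,0.052,0.999
d,lightgreen,215.9,1971,2428,29,1.6,8.2,6.7,11.8,0.034,0.997
d,limegreen,215.9,1771,2292,24,2.1,11.8,9.3,16.0,0.042,0.993
", stringsAsFactors = FALSE, strip.white = TRUE)
  df
}

#' Reference fitted parameter sets
#'
#' The eleven published parameter rows (four studies, panels a-d, keyed by
#' panel and curve color), as fixtures for simulation, phase analysis, and
#' recovery experiments. Called without `key`, returns the full table
#' including percent errors and the printed `sigma` and `R^2`; with a key
#' such as `"c:darkgreen"`, returns the corresponding [lab_params()]
#' (with `q = 16`).
#'
#' @param key Optional `"panel:color"` string, e.g. `"d:limegreen"`.
#' @return A data frame (no key) or a [lab_params()] object.
#' @examples
#' table1_params("c:darkgreen")
#' head(table1_params())
#' @export
table1_params <- function(key = NULL) {
  df <- .table1()
  if (is.null(key)) return(df)
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  hit <- which(df$panel == parts[1] & df$color == parts[2])
  if (length(parts) != 2 || length(hit) != 1)
    stop(sprintf("unknown fixture key '%s' (use e.g. 'c:darkgreen'; see table1_params())",
                 key))
  with(df[hit, ], lab_params(t0 = t0, h = h, h_ps = h_ps, Q = Q, q = 16))
}

#' Read a melt curve from delimited text
#'
#' Expects a header with columns `temperature_K` and `theta`; the
#' delimiter is auto-detected (comma or tab). Extra columns are ignored
#' with a warning; non-numeric cells or non-increasing temperatures are
#' rejected with the offending line number.
#'
#' @param path File path.
#' @return A [melt_curve()].
#' @export
read_melt_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("temperature_K", "theta")
  if (!all(need %in% names(df)))
    stop(sprintf("missing required column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  extra <- setdiff(names(df), need)
  if (length(extra))
    warning(sprintf("ignoring extra column(s): %s",
                    paste(extra, collapse = ", ")))
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric value in column '%s' at data line %d",
                   col, if (length(bad)) bad[1] else which(is.na(v))[1]))
    df[[col]] <- v
  }
  if (nrow(df) > 1) {
    drop <- which(diff(df$temperature_K) <= 0)
    if (length(drop))
      stop(sprintf("temperatures must be strictly increasing (violated at data line %d)",
                   drop[1] + 1))
  }
  melt_curve(df$temperature_K, df$theta, label = basename(path))
}

#' Write a melt curve to CSV
#'
#' Comma-delimited with header `temperature_K,theta`; full double
#' precision so that a write/read round trip is lossless.
#'
#' @param curve A [melt_curve()] (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_melt_csv <- function(curve, path) {
  stopifnot(is.data.frame(curve),
            all(c("temperature_K", "theta") %in% names(curve)))
  df <- data.frame(temperature_K = format(curve$temperature_K, digits = 17,
                                          trim = TRUE, scientific = FALSE),
                   theta = format(curve$theta, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
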