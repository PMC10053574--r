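#' Spiking-cortical-model parameters
#'
#' Defaults follow the published parameterization of the fusion scheme:
#' membrane attenuation `f = 0.8`, threshold attenuation `g = 0.7`,
#' absolute-refractory recharge `h = 20`, `k = 200` iterations, and the
#' 3 x 3 synaptic kernel with zero center (no self-linking). The linking
#' strength `beta` is a field-typical value exposed for tuning.
#'
#' @param f membrane potential attenuation constant, in (0, 1).
#' @param g threshold attenuation constant, in (0, 1).
#' @param h absolute-refractory recharge added to the threshold on firing.
#' @param beta linking strength of the neighborhood modulation.
#' @param W 3 x 3 synaptic weight kernel; center must be zero.
#' @param k number of iterations (spikes are totalled over all `k`).
#' @param theta0 initial dynamic threshold.
#' @return a list of class `scm_params`.
#' @export
scm_params <- function(f = 0.8, g = 0.7, h = 20, beta = 0.3,
                       W = matrix(c(0.1091, 0.1409, 0.1091,
                                    0.1409, 0,      0.1409,
                                    0.1091, 0.1409, 0.1091), 3, 3),
                       k = 200L, theta0 = 1) {
  stopifnot(is.numeric(f), length(f) == 1, is.numeric(g), length(g) == 1)
  if (f <= 0 || f >= 1) stop("scm f must lie in (0, 1)", call. = FALSE)
  if (g <= 0 || g >= 1) stop("scm g must lie in (0, 1)", call. = FALSE)
  if (h <= 0) stop("scm h must be positive", call. = FALSE)
  if (!is.matrix(W) || any(dim(W) != 3)) stop("scm W must be 3 x 3", call. = FALSE)
  if (W[2, 2] != 0) stop("scm W must have a zero center (no self-linking)", call. = FALSE)
  k <- as.integer(k)
  if (k < 1) stop("scm k must be >= 1", call. = FALSE)
  structure(list(f = f, g = g, h = h, beta = beta, W = W, k = k,
                 theta0 = theta0), class = "scm_params")
}

#' Enhancement-stage parameters
#'
#' Defaults follow the published step-3 settings: a 5 x 5 CLAHE tile grid
#' with normalized clip limit 0.00125 and 500 histogram bins; unsharp gain
#' damping `sharpen_alpha = 3`; sigmoid tone parameters
#' `lambda1 = 4.8`, `lambda2 = 0.49`.
#'
#' @param clahe_tiles integer (rows, cols) tile grid.
#' @param clahe_clip normalized clip limit in (0, 1).
#' @param clahe_bins histogram bin count.
#' @param sharpen_alpha divisor applied to the entropy-maximizing unsharp
#'   gain, guarding against over-sharpening.
#' @param sharpen_C_grid numeric (min, max, step) search grid for the gain.
#' @param lambda1,lambda2 sigmoid slope and midpoint of the tone curve.
#' @return a list of class `enhance_params`.
#' @export
enhance_params <- function(clahe_tiles = c(5L, 5L), clahe_clip = 0.00125,
                           clahe_bins = 500L, sharpen_alpha = 3,
                           sharpen_C_grid = c(0, 5, 0.05),
                           lambda1 = 4.8, lambda2 = 0.49) {
  clahe_tiles <- as.integer(clahe_tiles)
  if (length(clahe_tiles) != 2 || any(clahe_tiles < 1)) {
    stop("clahe_tiles must be two positive integers", call. = FALSE)
  }
  if (clahe_clip <= 0 || clahe_clip >= 1) {
    stop("clahe_clip must lie in (0, 1)", call. = FALSE)
  }
  if (clahe_bins < 2) stop("clahe_bins must be >= 2", call. = FALSE)
  if (sharpen_alpha <= 0) stop("sharpen_alpha must be > 0", call. = FALSE)
  if (length(sharpen_C_grid) != 3 || sharpen_C_grid[3] <= 0 ||
      sharpen_C_grid[2] < sharpen_C_grid[1]) {
    stop("sharpen_C_grid must be (min, max, step) with step > 0", call. = FALSE)
  }
  structure(list(clahe_tiles = clahe_tiles, clahe_clip = clahe_clip,
                 clahe_bins = as.integer(clahe_bins),
                 sharpen_alpha = sharpen_alpha,
                 sharpen_C_grid = as.numeric(sharpen_C_grid),
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "enhance_params")
}

#' Full fusion configuration
#'
#' Collects every tunable parameter of the three-step scheme. Defaults are
#' the published settings: 5 x 5 Wiener window; NSCT direction levels
#' (4, 4, 4, 4); low-frequency AC affinity `a = 0.55`; high-frequency blend
#' weights `(b, c, d) = (0.41, 0.29, 0.30)`; significance threshold
#' `Tth = 1`.
#'
#' @param wiener_window integer (rows, cols), both odd and >= 3.
#' @param nsct_levels integer vector `l_j`, directional levels per pyramid
#'   scale; scale 1 is the finest.
#' @param scm [scm_params()] list.
#' @param low_weight_a low-frequency selection weight in (0, 1); larger `a`
#'   pulls the fused image toward the AC channel.
#' @param high_weights_bcd blend weights (b, c, d) for the no-dominant-channel
#'   high-frequency case; must sum to 1.
#' @param high_threshold_Tth ignition-count margin above which one channel's
#'   activity is considered significantly larger than another's.
#' @param enhance [enhance_params()] list.
#' @param seed integer seed recorded with the run.
#' @return a list of class `fusion_config`.
#' @export
#' @examples
#' cfg <- fusion_config()
#' cfg$low_weight_a
fusion_config <- function(wiener_window = c(5L, 5L),
                          nsct_levels = c(4L, 4L, 4L, 4L),
                          scm = scm_params(),
                          low_weight_a = 0.55,
                          high_weights_bcd = c(0.41, 0.29, 0.30),
                          high_threshold_Tth = 1,
                          enhance = enhance_params(),
                          seed = 1L) {
  wiener_window <- as.integer(wiener_window)
  if (length(wiener_window) != 2 || any(wiener_window < 3) ||
      any(wiener_window %% 2 == 0)) {
    stop("wiener_window dimensions must be odd and >= 3", call. = FALSE)
  }
  nsct_levels <- as.integer(nsct_levels)
  if (length(nsct_levels) < 1 || any(nsct_levels < 1)) {
    stop("nsct_levels must be a non-empty vector of integers >= 1", call. = FALSE)
  }
  if (!inherits(scm, "scm_params")) scm <- do.call(scm_params, scm)
  if (low_weight_a <= 0 || low_weight_a >= 1) {
    stop("low_weight_a must lie in the open interval (0, 1)", call. = FALSE)
  }
  if (length(high_weights_bcd) != 3) {
    stop("high_weights_bcd must have three entries", call. = FALSE)
  }
  if (abs(sum(high_weights_bcd) - 1) > 1e-9) {
    stop("high_weights_bcd must sum to 1 (got ",
         format(sum(high_weights_bcd)), ")", call. = FALSE)
  }
  if (high_threshold_Tth < 0) stop("high_threshold_Tth must be >= 0", call. = FALSE)
  if (!inherits(enhance, "enhance_params")) enhance <- do.call(enhance_params, enhance)
  structure(list(wiener_window = wiener_window, nsct_levels = nsct_levels,
                 scm = scm, low_weight_a = low_weight_a,
                 high_weights_bcd = as.numeric(high_weights_bcd),
                 high_threshold_Tth = high_threshold_Tth,
                 enhance = enhance, seed = as.integer(seed)),
            class = "fusion_config")
}

#' Load a fusion configuration from a YAML file
#'
#' Absent file or absent keys fall back to the published defaults (see
#' [fusion_config()]). Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return a `fusion_config` list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(fusion_config())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(fusion_config())
  top <- c("wiener_window", "nsct_levels", "scm", "low_weight_a",
           "high_weights_bcd", "high_threshold_Tth", "enhance", "seed")
  bad <- setdiff(names(raw), top)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  check_sub <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stop("unknown keys in config section '", section, "': ",
                          paste(bad, collapse = ", "), call. = FALSE)
    x
  }
  if (!is.null(raw$scm)) {
    raw$scm <- check_sub(raw$scm,
      c("f", "g", "h", "beta", "W", "k", "theta0"), "scm")
    if (!is.null(raw$scm$W)) raw$scm$W <- matrix(unlist(raw$scm$W), 3, 3, byrow = TRUE)
    raw$scm <- do.call(scm_params, raw$scm)
  }
  if (!is.null(raw$enhance)) {
    raw$enhance <- check_sub(raw$enhance,
      c("clahe_tiles", "clahe_clip", "clahe_bins", "sharpen_alpha",
        "sharpen_C_grid", "lambda1", "lambda2"), "enhance")
    raw$enhance <- do.call(enhance_params, raw$enhance)
  }
  do.call(fusion_config, raw)
}

#' Serialize a run manifest
#'
#' Writes every parameter of a run (plus caller-supplied stage metadata) as
#' JSON, so any fused output can be traced back to its exact settings.
#'
#' @param config a `fusion_config`.
#' @param path output JSON path.
#' @param extra named list of additional fields (stage timings, hashes,
#'   input paths).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  stopifnot(inherits(config, "fusion_config"))
  payload <- c(list(
    package = "xgifuse",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass_deep(config)
  ), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (is.matrix(x)) return(apply(x, 1, as.numeric, simplify = FALSE))
  x
}
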