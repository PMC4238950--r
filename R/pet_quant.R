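#' Gumbel distribution functions
#'
#' Density, distribution function and random generation for the Gumbel
#' (type-I extreme value) distribution with location and scale parameters,
#' used to model the maxima of reference-region PET signal sub-samples.
#'
#' @param x,q numeric vector of quantiles.
#' @param n number of draws.
#' @param location location parameter.
#' @param scale scale parameter, > 0.
#' @param log logical; return log-density.
#' @return `dgumbel` the density, `pgumbel` the CDF
#'   `exp(-exp(-(q - location)/scale))`, `rgumbel` random draws.
#' @name gumbel
NULL

#' @rdname gumbel
#' @export
dgumbel <- function(x, location = 0, scale = 1, log = FALSE) {
  if (any(scale <= 0)) return(rep(NaN, length(x)))
  z <- (x - location) / scale
  ld <- -z - exp(-z) - base::log(scale)
  if (log) ld else exp(ld)
}

#' @rdname gumbel
#' @export
pgumbel <- function(q, location = 0, scale = 1) {
  if (any(scale <= 0)) return(rep(NaN, length(q)))
  exp(-exp(-(q - location) / scale))
}

#' @rdname gumbel
#' @export
rgumbel <- function(n, location = 0, scale = 1) {
  stopifnot(scale > 0)
  location - scale * base::log(-base::log(runif(n)))
}

#' Bootstrap extreme-value calibration of a reference region
#'
#' Draws `n_boot` sub-samples (with replacement) of size `subsample_size`
#' from the reference-region voxel values, records each sub-sample maximum,
#' and fits a Gumbel distribution to the maxima by maximum likelihood. The
#' fitted CDF converts any voxel signal into the probability of exceeding
#' the reference region's plausible maxima, i.e. a deposition probability.
#'
#' @param reference_values numeric vector of reference-region voxel signals.
#' @param n_boot number of bootstrap sub-samples (>= 100; default 40000).
#' @param subsample_size voxels per sub-sample (>= 2 in normal use; 1 is
#'   allowed and reproduces the parent distribution of the values).
#' @param rng_seed integer seed; the calibration is deterministic given it.
#' @return an `evd_calibration`: list with `location`, `scale`, `n_boot`,
#'   `subsample_size`, `rng_seed`.
#' @export
bootstrap_evd <- function(reference_values, n_boot = 40000L,
                          subsample_size = 100L, rng_seed = 1L) {
  if (length(reference_values) == 0) stop("reference values must be non-empty")
  if (!all(is.finite(reference_values))) stop("reference values must be finite")
  if (var(reference_values) == 0) stop("degenerate reference region: zero variance")
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (subsample_size < 1) stop("subsample_size must be >= 1")
  maxima <- with_rng_seed(rng_seed, {
    m <- matrix(sample(reference_values, n_boot * subsample_size,
                       replace = TRUE),
                nrow = n_boot, ncol = subsample_size)
    do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
  })
  scale0 <- sd(maxima) * sqrt(6) / pi
  if (scale0 <= 0) stop("degenerate bootstrap maxima: zero variance")
  loc0 <- mean(maxima) - 0.5772156649 * scale0
  fit <- fitdistrplus::fitdist(maxima, "gumbel",
                               start = list(location = loc0, scale = scale0))
  est <- fit$estimate
  structure(list(location = unname(est["location"]),
                 scale = unname(est["scale"]),
                 n_boot = as.integer(n_boot),
                 subsample_size = as.integer(subsample_size),
                 rng_seed = rng_seed),
            class = "evd_calibration")
}

#' @export
print.evd_calibration <- function(x, ...) {
  cat(sprintf("evd_calibration: Gumbel(location=%.4g, scale=%.4g), %d x %d bootstrap\n",
              x$location, x$scale, x$n_boot, x$subsample_size))
  invisible(x)
}

#' Voxel deposition probability
#'
#' Gumbel CDF of a voxel signal under the reference-region extreme-value
#' calibration: the probability that the signal equals or exceeds the
#' plausible maxima of the non-specific-binding reference region.
#'
#' @param value voxel signal intensities (vectorized).
#' @param calib an `evd_calibration`.
#' @return probabilities in (0, 1).
#' @export
voxel_probability <- function(value, calib) {
  stopifnot(inherits(calib, "evd_calibration"))
  pgumbel(value, calib$location, calib$scale)
}

#' Regional deposition pattern from a voxel table
#'
#' Aggregates voxel deposition probabilities within each labelled region:
#' by default the within-region mean of voxel CDF values; a max-based
#' alternative is available.
#'
#' @param voxels data.frame with columns `region_id` and `value` (one row
#'   per voxel).
#' @param calib an `evd_calibration`.
#' @param region_order character vector of region labels defining the order
#'   of the output; every label must be present in `voxels`.
#' @param aggregate `"mean"` (default) or `"max"`.
#' @return named numeric vector of regional deposition probabilities
#'   following `region_order`.
#' @export
regional_pattern <- function(voxels, calib, region_order,
                             aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(voxels), all(c("region_id", "value") %in% names(voxels)))
  missing <- setdiff(region_order, unique(voxels$region_id))
  if (length(missing) > 0) {
    stop("missing region label(s): ", paste(missing, collapse = ", "))
  }
  pr <- voxel_probability(voxels$value, calib)
  f <- if (aggregate == "mean") mean else max
  agg <- tapply(pr, voxels$region_id, f)
  out <- as.numeric(agg[region_order])
  names(out) <- region_order
  out
}

#' Read a voxel table from TSV
#'
#' @param path TSV file with header columns `region_id` and `value`.
#' @return data.frame with those columns.
#' @export
read_voxel_table <- function(path) {
  v <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("region_id", "value") %in% names(v))) {
    stop("voxel table must have columns region_id and value")
  }
  v
}
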