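#' Specification for synthetic connectomes, cohorts and voxel tables
#'
#' Defines the study conditions emulated by the generators: connectome
#' geometry and edge statistics, cohort size and parameter priors, and the
#' voxel-level signal model. Defaults: a geometric-random graph in a 120 mm
#' cube with edge density 0.4 and ACP uniform in (0.4, 0.95)
#' (sparse enough that outbreak fronts stay active across the simulated
#' decades); a 20-subject
#' cohort with production amplitude U(0.3, 0.9), clearance amplitude
#' U(0.1, 0.5) and snapshot days U(2000, 12000); a 2-region outbreak set
#' (as for the posterior + anterior cingulate outbreak); 500 voxels per
#' region with unit reference noise.
#'
#' @param n_regions number of regions.
#' @param rng_seed integer seed; every generator is deterministic given it.
#' @param geometry `"geometric"` (random geometric graph), `"chain"`,
#'   `"ring"` or `"hub_spoke"`.
#' @param edge_density fraction of possible connections kept (geometric
#'   geometry only), in (0, 1].
#' @param acp_range range of the uniform distribution for ACP edge weights.
#' @param length_scale_mm inter-region distance per index step for the
#'   regular geometries (chain/ring/hub_spoke), mm.
#' @param box_mm side of the cube in which geometric-random centroids are
#'   placed, mm.
#' @param cohort_size number of synthetic subjects.
#' @param beta0_range,delta0_range,snapshot_range per-subject priors for the
#'   production amplitude, clearance amplitude and snapshot day.
#' @param seeds outbreak region indices used for every subject.
#' @param sigma simulation noise level for cohort generation (0 =
#'   deterministic).
#' @param voxels_per_region voxels generated per region.
#' @param reference_noise_sd voxel signal standard deviation (arbitrary
#'   units); regional signal shift is `3 * reference_noise_sd * P`.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_regions = 10L, rng_seed = 1L,
                       geometry = c("geometric", "chain", "ring", "hub_spoke"),
                       edge_density = 0.4, acp_range = c(0.4, 0.95),
                       length_scale_mm = 40, box_mm = 120,
                       cohort_size = 20L, beta0_range = c(0.3, 0.9),
                       delta0_range = c(0.1, 0.5),
                       snapshot_range = c(2000, 12000),
                       seeds = c(1L, 2L), sigma = 0,
                       voxels_per_region = 500L, reference_noise_sd = 1) {
  geometry <- match.arg(geometry)
  stopifnot(n_regions >= 2, edge_density > 0, edge_density <= 1,
            length(acp_range) == 2, acp_range[1] > 0, acp_range[2] <= 1,
            length_scale_mm > 0, box_mm > 0, cohort_size >= 1,
            all(seeds >= 1), all(seeds <= n_regions),
            voxels_per_region >= 1, reference_noise_sd > 0, sigma >= 0)
  structure(list(n_regions = as.integer(n_regions),
                 rng_seed = as.integer(rng_seed), geometry = geometry,
                 edge_density = edge_density, acp_range = acp_range,
                 length_scale_mm = length_scale_mm, box_mm = box_mm,
                 cohort_size = as.integer(cohort_size),
                 beta0_range = beta0_range, delta0_range = delta0_range,
                 snapshot_range = snapshot_range,
                 seeds = as.integer(seeds), sigma = sigma,
                 voxels_per_region = as.integer(voxels_per_region),
                 reference_noise_sd = reference_noise_sd),
            class = "synth_spec")
}

#' Generate a synthetic connectome
#'
#' Produces a connected graph of the requested geometry with ACP weights
#' drawn uniformly from `acp_range`, unit self-connections, and fiber
#' lengths equal to Euclidean inter-centroid distance (geometric geometry)
#' or index distance times `length_scale_mm` (regular geometries). For the
#' geometric geometry, generation is retried (up to 50 times) until the
#' graph is connected.
#'
#' @param spec a [synth_spec()].
#' @return a validated [connectome()].
#' @export
make_connectome <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_regions
  with_rng_seed(spec$rng_seed, {
    if (spec$geometry == "geometric") {
      for (try in seq_len(50)) {
        coords <- matrix(runif(n * 3, 0, spec$box_mm), n, 3)
        adj <- matrix(FALSE, n, n)
        ut <- which(upper.tri(adj), arr.ind = TRUE)
        keep <- runif(nrow(ut)) < spec$edge_density
        adj[ut[keep, , drop = FALSE]] <- TRUE
        adj <- adj | t(adj)
        g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
        if (igraph::is_connected(g)) break
        if (try == 50) stop("edge density too low: could not generate a connected graph")
      }
      # order regions by centroid centrality so the conventional outbreak
      # set {1, 2} falls on central structures, as the cingulate outbreak
      # regions do anatomically
      centrality <- rowMeans(as.matrix(stats::dist(coords)))
      ord <- order(centrality)
      coords <- coords[ord, , drop = FALSE]
      adj <- adj[ord, ord]
      len <- as.matrix(stats::dist(coords))
    } else {
      coords <- NULL
      adj <- matrix(FALSE, n, n)
      if (spec$geometry == "chain") {
        for (i in seq_len(n - 1)) adj[i, i + 1] <- TRUE
      } else if (spec$geometry == "ring") {
        for (i in seq_len(n - 1)) adj[i, i + 1] <- TRUE
        adj[1, n] <- TRUE
      } else { # hub_spoke: region 1 is the hub
        adj[1, 2:n] <- TRUE
      }
      adj <- adj | t(adj)
      if (spec$geometry == "hub_spoke") {
        # radial spokes of similar physical length
        len <- matrix(0, n, n)
        radial <- spec$length_scale_mm * runif(n - 1, 0.8, 1.2)
        len[1, 2:n] <- radial
        len[2:n, 1] <- radial
      } else {
        idx <- abs(outer(seq_len(n), seq_len(n), "-"))
        len <- idx * spec$length_scale_mm
      }
    }
    acp <- matrix(0, n, n)
    sel <- upper.tri(acp) & adj
    acp[sel] <- runif(sum(sel), spec$acp_range[1], spec$acp_range[2])
    acp <- acp + t(acp)
    diag(acp) <- 1
    len[!adj] <- 0
    diag(len) <- 0
    connectome(acp, len, coords = coords)
  })
}

#' Generate a synthetic cohort of deposition patterns
#'
#' Per subject: draw (beta0, delta0, snapshot day) from the priors in
#' `spec`, simulate the ESM from `spec$seeds` (with noise level
#' `spec$sigma`), and take the deposition pattern at the drawn day. The
#' truth table of generating parameters is returned for recovery scoring.
#'
#' @param conn a `connectome`.
#' @param spec a [synth_spec()].
#' @return list with `patterns` (subjects x regions matrix) and `truth`
#'   (data.frame with `beta0`, `delta0`, `t_day`, `sigma`).
#' @export
make_cohort <- function(conn, spec) {
  stopifnot(inherits(conn, "connectome"), inherits(spec, "synth_spec"))
  n <- n_regions(conn)
  s <- spec$cohort_size
  draws <- with_rng_seed(spec$rng_seed, {
    data.frame(beta0 = runif(s, spec$beta0_range[1], spec$beta0_range[2]),
               delta0 = runif(s, spec$delta0_range[1], spec$delta0_range[2]),
               t_day = round(runif(s, spec$snapshot_range[1],
                                   spec$snapshot_range[2])),
               sigma = spec$sigma,
               noise_seed = sample.int(.Machine$integer.max, s))
  })
  horizon <- max(1, draws$t_day)
  patterns <- matrix(NA_real_, s, n)
  for (i in seq_len(s)) {
    params <- esm_params(beta0 = draws$beta0[i], delta0 = draws$delta0[i],
                         noise_sd = spec$sigma, horizon_days = horizon)
    traj <- simulate_esm(conn, params, spec$seeds,
                         rng_seed = if (spec$sigma > 0) draws$noise_seed[i]
                         else NULL)
    patterns[i, ] <- traj$p[which(traj$time_days == draws$t_day[i]), ]
  }
  colnames(patterns) <- conn$labels
  list(patterns = patterns,
       truth = draws[, c("beta0", "delta0", "t_day", "sigma")])
}

#' Generate a synthetic voxel table from a deposition pattern
#'
#' Emulates regional PET signals with a non-specific-binding reference
#' region: reference voxels are Normal(0, sd); region i voxels are
#' Normal(3 * sd * P_i, sd), so regional separability from the reference
#' scales linearly with deposition.
#'
#' @param pattern named numeric vector of regional deposition probabilities
#'   (names become region labels; unnamed patterns get `"R1".."RN"`).
#' @param spec a [synth_spec()].
#' @param reference_label label used for the reference region voxels.
#' @return data.frame with columns `region_id` and `value`.
#' @export
make_voxel_table <- function(pattern, spec, reference_label = "REF") {
  stopifnot(inherits(spec, "synth_spec"))
  labs <- names(pattern)
  if (is.null(labs)) labs <- paste0("R", seq_along(pattern))
  if (reference_label %in% labs) stop("reference label collides with a region label")
  v <- spec$voxels_per_region
  sdv <- spec$reference_noise_sd
  with_rng_seed(spec$rng_seed, {
    ref <- rnorm(v, 0, sdv)
    vals <- unlist(lapply(seq_along(pattern), function(i) {
      rnorm(v, 3 * sdv * pattern[i], sdv)
    }))
    data.frame(region_id = c(rep(reference_label, v), rep(labs, each = v)),
               value = c(ref, vals), stringsAsFactors = FALSE)
  })
}
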