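#' Fitting configuration
#'
#' Controls the per-subject parameter search. The trajectory-matching
#' objective has a known shallow valley along the amplitude-scaling
#' direction (c beta0, c delta0): scaling both amplitudes approximately
#' rescales time, which the optimal-day matching largely absorbs. The
#' search therefore combines a log-spaced grid, Nelder-Mead refinement from
#' several mutually distant grid starts, and a sweep of the scaling family
#' through the incumbent followed by re-refinement.
#'
#' @param grid_n grid points per axis (default 12).
#' @param grid_range range of the log-spaced grid for both amplitudes.
#' @param refine logical; run Nelder-Mead refinement (default TRUE).
#' @param n_starts target number of refinement starts; the log-grid is
#'   partitioned into ~sqrt(n_starts) x sqrt(n_starts) blocks and
#'   Nelder-Mead runs from the best point of each block (default 9).
#' @param sweep logical; sweep the amplitude-scaling family through the
#'   incumbent and re-refine (default TRUE; two rounds).
#' @param max_iter Nelder-Mead iteration cap per start.
#' @param tol relative convergence tolerance on the fit distance.
#' @param params template `esm_params` supplying everything except beta0 and
#'   delta0 (velocity, dt, horizon, seeds' initial probability, shape
#'   constants). Fitting always uses the deterministic skeleton (no noise).
#' @return a `fit_config` list.
#' @export
fit_config <- function(grid_n = 12L, grid_range = c(1e-3, 1), refine = TRUE,
                       n_starts = 9L, sweep = TRUE, max_iter = 300L,
                       tol = 1e-7,
                       params = esm_params(beta0 = 0.5, delta0 = 0.3)) {
  stopifnot(grid_n >= 2, length(grid_range) == 2, all(grid_range > 0),
            grid_range[1] < grid_range[2], n_starts >= 1,
            inherits(params, "esm_params"))
  structure(list(grid_n = as.integer(grid_n), grid_range = grid_range,
                 refine = isTRUE(refine), n_starts = as.integer(n_starts),
                 sweep = isTRUE(sweep), max_iter = as.integer(max_iter),
                 tol = tol, params = params),
            class = "fit_config")
}

sim_deterministic <- function(conn, cfg, beta0, delta0, seeds) {
  p <- cfg$params
  params <- esm_params(beta0 = beta0, delta0 = delta0,
                       noise_mean = p$noise_mean, # deterministic drift kept
                       noise_sd = 0, velocity = p$velocity, dt = p$dt,
                       horizon_days = p$horizon, p_seed_init = p$p_seed_init,
                       sigmoid_slope = p$sigmoid_slope,
                       sigmoid_mid = p$sigmoid_mid,
                       clearance_decay = p$clearance_decay)
  simulate_esm(conn, params, seeds, rng_seed = NULL)
}

#' Fit the ESM to one subject's deposition pattern
#'
#' Trajectory matching: for candidate amplitudes (beta0, delta0) the
#' deterministic model is simulated from the given seeds over the full
#' horizon, and the optimal day `t_opt` is the earliest day minimizing the
#' Euclidean distance between the simulated and observed deposition
#' patterns. The outer search over (beta0, delta0) is a coarse log-spaced
#' grid followed by Nelder-Mead refinement. The residual noise level sigma
#' is estimated as the standard deviation of the residuals at `t_opt`.
#'
#' @param pattern numeric vector of N observed deposition probabilities.
#' @param conn a `connectome`.
#' @param seeds outbreak region indices used for every candidate simulation.
#' @param cfg a [fit_config()].
#' @param age_years optional chronological age; if supplied, the onset age
#'   `age - t_opt / 365.25` is reported.
#' @return an `esm_fit`: list with `seeds`, `beta0`, `delta0`, `sigma`,
#'   `t_opt` (days), `fit_distance`, `beta_eff`, `delta_eff`, `onset_age`
#'   (or NA), `converged`.
#' @export
fit_subject <- function(pattern, conn, seeds, cfg = fit_config(),
                        age_years = NULL) {
  stopifnot(inherits(conn, "connectome"), inherits(cfg, "fit_config"))
  n <- n_regions(conn)
  pattern <- as.numeric(pattern)
  if (length(pattern) != n) stop("pattern length must equal region count")

  objective <- function(b, d) {
    traj <- sim_deterministic(conn, cfg, b, d, seeds)
    m <- traj_best_match_cpp(traj$p, pattern)
    list(dist = m$distance, t_index = m$t_index,
         t_opt = traj$time_days[m$t_index], traj = traj)
  }

  lo <- cfg$grid_range[1]
  hi <- cfg$grid_range[2]
  grid <- exp(seq(log(lo), log(hi), length.out = cfg$grid_n))
  cand <- expand.grid(b = grid, d = grid)
  cand$dist <- vapply(seq_len(nrow(cand)), function(k) {
    objective(cand$b[k], cand$d[k])$dist
  }, numeric(1))
  cand <- cand[order(cand$dist), ]

  best_bd <- c(cand$b[1], cand$d[1])
  best <- objective(best_bd[1], best_bd[2])
  converged <- TRUE

  if (cfg$refine) {
    fn <- function(lp) {
      bd <- pmin(pmax(exp(lp), lo), hi)
      objective(bd[1], bd[2])$dist
    }
    refine_from <- function(bd0) {
      opt <- optim(log(bd0), fn, method = "Nelder-Mead",
                   control = list(maxit = cfg$max_iter, reltol = cfg$tol))
      list(bd = pmin(pmax(exp(opt$par), lo), hi), conv = opt$convergence == 0)
    }
    # block-stratified starts: the objective's shallow scaling valley can
    # out-score the true basin on a coarse grid, so refinement starts from
    # the best point of every block of a coarse partition of the log-grid,
    # guaranteeing a start near each candidate basin
    nb <- max(1L, as.integer(round(sqrt(cfg$n_starts))))
    block_of <- function(v) {
      pmin(nb, 1L + floor(nb * (log(v) - log(lo)) / (log(hi) - log(lo) + 1e-12)))
    }
    cand$block <- paste(block_of(cand$b), block_of(cand$d))
    starts <- lapply(split(cand, cand$block), function(blk) {
      c(blk$b[1], blk$d[1]) # blocks inherit the global ascending sort
    })
    for (s in starts) {
      r <- refine_from(s)
      converged <- converged && r$conv
      o <- objective(r$bd[1], r$bd[2])
      if (o$dist < best$dist) {
        best <- o
        best_bd <- r$bd
      }
    }
    if (cfg$sweep) {
      # sweep the joint-rescaling family (the known shallow valley) around
      # the incumbent, plus full-range line searches along each amplitude
      # axis (escapes spurious minima where one amplitude is far off)
      cs <- exp(seq(log(0.05), log(3), length.out = 25))
      axis_grid <- exp(seq(log(lo), log(hi), length.out = 25))
      for (round in 1:2) {
        cand_pts <- c(
          lapply(cs, function(cc) best_bd * cc),
          lapply(axis_grid, function(g) c(g, best_bd[2])),
          lapply(axis_grid, function(g) c(best_bd[1], g)))
        for (bd in cand_pts) {
          if (any(bd > hi) || any(bd < lo)) next
          o <- objective(bd[1], bd[2])
          if (o$dist < best$dist) {
            best <- o
            best_bd <- bd
          }
        }
        r <- refine_from(best_bd)
        o <- objective(r$bd[1], r$bd[2])
        if (o$dist < best$dist) {
          best <- o
          best_bd <- r$bd
        }
      }
    }
    if (!converged) {
      warning("optimizer did not converge in every refinement; returning best-so-far")
    }
  }

  estimate <- best$traj$p[best$t_index, ]
  resid <- estimate - pattern
  mr <- marginal_rates(best$traj$params)
  structure(list(seeds = as.integer(seeds),
                 beta0 = best_bd[1], delta0 = best_bd[2],
                 sigma = sd(resid), t_opt = best$t_opt,
                 fit_distance = best$dist, estimate = estimate,
                 beta_eff = mr$beta_eff, delta_eff = mr$delta_eff,
                 onset_age = if (is.null(age_years)) NA_real_ else
                   age_years - best$t_opt / 365.25,
                 converged = converged),
            class = "esm_fit")
}

#' @export
print.esm_fit <- function(x, ...) {
  cat(sprintf(paste0("esm_fit: beta0=%.4g delta0=%.4g t_opt=%d days ",
                     "distance=%.4g sigma=%.3g\n"),
              x$beta0, x$delta0, as.integer(x$t_opt), x$fit_distance,
              x$sigma))
  invisible(x)
}

#' Exact number of candidate seed sets
#'
#' Binomial coefficient C(n_regions, k) by exact stepwise integer
#' arithmetic (every intermediate value is an integer binomial, so the
#' computation is exact well beyond the 78-region atlas). With
#' `cumulative = TRUE`, the number of non-empty sets of size up to k.
#'
#' @param n_regions number of regions.
#' @param k seed-set size (0 < k <= n_regions).
#' @param cumulative sum the counts for sizes 1..k.
#' @return exact count as a numeric (integer-valued).
#' @export
count_seed_sets <- function(n_regions, k, cumulative = FALSE) {
  stopifnot(n_regions >= 1, k >= 1, k <= n_regions)
  ch <- function(n, k) {
    res <- 1
    for (i in seq_len(k)) res <- round(res * (n - k + i) / i)
    res
  }
  if (cumulative) sum(vapply(seq_len(k), function(kk) ch(n_regions, kk),
                             numeric(1)))
  else ch(n_regions, k)
}

#' Search for the outbreak seed set across a cohort
#'
#' Scores every candidate seed set by the cohort-mean trajectory-matching
#' distance (mean over subjects of [fit_subject()] `fit_distance`).
#' Exhaustive mode enumerates all sets of size 1..max_k (guarded by a
#' budget on [count_seed_sets()]); greedy mode grows the set one region at
#' a time, keeping the best augmentation.
#'
#' @param patterns matrix (subjects x regions) of deposition patterns, or a
#'   list of pattern vectors.
#' @param conn a `connectome`.
#' @param max_k maximum seed-set size.
#' @param strategy `"exhaustive"` or `"greedy"`.
#' @param cfg a [fit_config()] used for every per-subject fit.
#' @param budget maximum number of candidate sets allowed in exhaustive
#'   mode.
#' @return data.frame with list-column `seeds` and column `score`, sorted
#'   ascending by score (best set first).
#' @export
seed_search <- function(patterns, conn, max_k = 2L,
                        strategy = c("exhaustive", "greedy"),
                        cfg = fit_config(), budget = 5000L) {
  strategy <- match.arg(strategy)
  if (is.list(patterns)) patterns <- do.call(rbind, patterns)
  patterns <- as.matrix(patterns)
  if (nrow(patterns) == 0) stop("patterns must be non-empty")
  n <- n_regions(conn)
  stopifnot(ncol(patterns) == n, max_k >= 1)

  score_set <- function(seeds) {
    mean(vapply(seq_len(nrow(patterns)), function(s) {
      fit_subject(patterns[s, ], conn, seeds, cfg)$fit_distance
    }, numeric(1)))
  }

  sets <- list()
  scores <- numeric(0)
  if (strategy == "exhaustive") {
    total <- count_seed_sets(n, min(max_k, n), cumulative = TRUE)
    if (total > budget) {
      stop(sprintf(paste0("exhaustive enumeration of %g sets exceeds budget %d; ",
                          "use strategy = 'greedy'"), total, budget))
    }
    for (k in seq_len(min(max_k, n))) {
      cand <- combn(n, k, simplify = FALSE)
      for (s in cand) {
        sets[[length(sets) + 1L]] <- s
        scores <- c(scores, score_set(s))
      }
    }
  } else {
    current <- integer(0)
    repeat {
      remaining <- setdiff(seq_len(n), current)
      if (length(remaining) == 0 || length(current) >= max_k) break
      aug_scores <- vapply(remaining, function(r) {
        score_set(sort(c(current, r)))
      }, numeric(1))
      for (i in seq_along(remaining)) {
        sets[[length(sets) + 1L]] <- sort(c(current, remaining[i]))
        scores <- c(scores, aug_scores[i])
      }
      current <- sort(c(current, remaining[which.min(aug_scores)]))
    }
  }
  ord <- order(scores)
  out <- data.frame(score = scores[ord])
  out$seeds <- sets[ord]
  out[, c("seeds", "score")]
}

#' Scan every region as a candidate propagation epicenter
#'
#' For each candidate region c, the Pearson correlation between the observed
#' deposition pattern and the effective anatomical distances to c, over the
#' remaining regions. The most negative correlation flags the likeliest
#' epicenter (deposition decays with connectional distance from the true
#' outbreak).
#'
#' @param pattern numeric vector of N deposition probabilities.
#' @param conn a `connectome` (N >= 3).
#' @param transform edge-length convention, see [acp_edge_length()].
#' @return numeric vector of N correlation coefficients (NaN with a warning
#'   for a constant pattern).
#' @export
epicenter_scan <- function(pattern, conn, transform = "log") {
  n <- n_regions(conn)
  stopifnot(n >= 3, length(pattern) == n)
  if (var(pattern) == 0) {
    warning("constant pattern: epicenter correlations undefined")
    return(rep(NaN, n))
  }
  vapply(seq_len(n), function(cand) {
    d <- effective_distance(conn, cand, transform = transform)
    keep <- setdiff(which(is.finite(d)), cand)
    if (length(keep) < 3 || var(pattern[keep]) == 0 || var(d[keep]) == 0) {
      return(NaN)
    }
    cor(pattern[keep], d[keep])
  }, numeric(1))
}

#' Write a list of fits to TSV and JSON
#'
#' @param fits list of `esm_fit` objects.
#' @param tsv_path,json_path destinations (either may be NULL).
#' @return invisibly, the fits as a data.frame.
#' @export
write_fits <- function(fits, tsv_path = NULL, json_path = NULL) {
  df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(seeds = paste(f$seeds, collapse = ","), beta0 = f$beta0,
               delta0 = f$delta0, sigma = f$sigma, t_opt = f$t_opt,
               fit_distance = f$fit_distance, beta_eff = f$beta_eff,
               delta_eff = f$delta_eff, onset_age = f$onset_age,
               converged = f$converged)
  }))
  if (!is.null(tsv_path)) {
    write.table(df, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(lapply(fits, unclass), json_path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(df)
}
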