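#' Regional arrival times at a deposition threshold
#'
#' First day each region's deposition probability reaches the threshold
#' (`Inf` if never reached within the horizon). Seeds are included.
#'
#' @param traj an `esm_trajectory`.
#' @param threshold deposition probability in (0, 1).
#' @return an `arrival_times`: list with `threshold` and `t_arrive` (vector
#'   of N day values or `Inf`).
#' @export
arrival_times <- function(traj, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  t_arrive <- apply(traj$p, 2, function(col) {
    hit <- which(col >= threshold)
    if (length(hit) == 0) Inf else traj$time_days[hit[1]]
  })
  structure(list(threshold = threshold, t_arrive = t_arrive),
            class = "arrival_times")
}

#' Regress arrival times on effective distances
#'
#' Ordinary least squares of arrival times on effective anatomical
#' distances; pairs with non-finite entries (regions never reached, or
#' disconnected) are excluded pairwise.
#'
#' @param dist numeric vector of effective distances.
#' @param times numeric vector of arrival times (may contain `Inf`).
#' @return list with `slope`, `intercept`, `r`, `p_value`, `n_used`.
#' @export
distance_time_regression <- function(dist, times) {
  stopifnot(length(dist) == length(times))
  keep <- is.finite(dist) & is.finite(times)
  if (sum(keep) < 3) stop("fewer than 3 finite (distance, time) pairs")
  d <- dist[keep]
  tt <- times[keep]
  fit <- lm(tt ~ d)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = cor(d, tt), p_value = sm$coefficients[2, 4],
       n_used = sum(keep))
}

#' Explained variance between two deposition patterns
#'
#' `100 * (Pearson r)^2`, the percentage of variance in the reference
#' pattern explained by the estimated one.
#'
#' @param estimated,reference numeric vectors of equal length >= 3.
#' @return percentage in \[0, 100\].
#' @export
explained_variance <- function(estimated, reference) {
  stopifnot(length(estimated) == length(reference), length(estimated) >= 3)
  if (var(estimated) == 0 || var(reference) == 0) {
    stop("zero-variance input: explained variance undefined")
  }
  100 * cor(estimated, reference)^2
}

cohort_mean_ev <- function(patterns, conn, seeds, cfg) {
  mean(vapply(seq_len(nrow(patterns)), function(s) {
    f <- fit_subject(patterns[s, ], conn, seeds, cfg)
    est <- f$estimate
    if (var(est) == 0 || var(patterns[s, ]) == 0) 0
    else explained_variance(est, patterns[s, ])
  }, numeric(1)))
}

#' Contrast model competence on the true vs randomized connectomes
#'
#' Fits the cohort on the original connectome and on `n_random`
#' weight/degree-preserving randomizations ([randomize_connectome()]); the
#' score of a connectome is the cohort-mean explained variance of the
#' per-subject fits. The empirical p-value uses the add-one permutation
#' convention `(1 + #\{null >= true\}) / (n_random + 1)`, so it is never
#' exactly zero.
#'
#' @param patterns matrix (subjects x regions) of deposition patterns.
#' @param conn a `connectome`.
#' @param seeds outbreak region indices used for every fit.
#' @param n_random number of randomized connectomes (>= 19).
#' @param rng_seed integer seed controlling the randomizations.
#' @param cfg a [fit_config()].
#' @return list with `true_score`, `null_scores`, `empirical_p`.
#' @export
null_model_contrast <- function(patterns, conn, seeds, n_random = 19L,
                                rng_seed = 1L, cfg = fit_config()) {
  stopifnot(n_random >= 19)
  patterns <- as.matrix(patterns)
  true_score <- cohort_mean_ev(patterns, conn, seeds, cfg)
  null_scores <- vapply(seq_len(n_random), function(k) {
    rc <- randomize_connectome(conn, rng_seed = rng_seed + k)
    cohort_mean_ev(patterns, rc, seeds, cfg)
  }, numeric(1))
  list(true_score = true_score, null_scores = null_scores,
       empirical_p = (1 + sum(null_scores >= true_score)) / (n_random + 1))
}

#' Split-half cross-validation of group-level model parameters
#'
#' Each split halves the cohort at random; group-level amplitudes are the
#' medians of the training-subject fits; the test score is the mean
#' explained variance of the group-parameter trajectory (matched at each
#' test subject's best day) against the test patterns.
#'
#' @param patterns matrix (subjects x regions), >= 4 subjects.
#' @param conn a `connectome`.
#' @param seeds outbreak region indices.
#' @param n_splits number of random splits (>= 2).
#' @param rng_seed integer seed for the splits.
#' @param cfg a [fit_config()].
#' @return numeric vector of test explained-variance percentages, one per
#'   split.
#' @export
split_half_cv <- function(patterns, conn, seeds, n_splits = 5L,
                          rng_seed = 1L, cfg = fit_config()) {
  patterns <- as.matrix(patterns)
  s <- nrow(patterns)
  stopifnot(s >= 4, n_splits >= 2)
  splits <- with_rng_seed(rng_seed, {
    lapply(seq_len(n_splits), function(k) sample(s, floor(s / 2)))
  })
  vapply(splits, function(train) {
    test <- setdiff(seq_len(s), train)
    fits <- lapply(train, function(i) {
      fit_subject(patterns[i, ], conn, seeds, cfg)
    })
    b <- stats::median(vapply(fits, `[[`, numeric(1), "beta0"))
    d <- stats::median(vapply(fits, `[[`, numeric(1), "delta0"))
    traj <- sim_deterministic(conn, cfg, b, d, seeds)
    mean(vapply(test, function(i) {
      m <- traj_best_match_cpp(traj$p, patterns[i, ])
      est <- traj$p[m$t_index, ]
      if (var(est) == 0 || var(patterns[i, ]) == 0) 0
      else explained_variance(est, patterns[i, ])
    }, numeric(1)))
  }, numeric(1))
}

#' Correlation between connectivity degree and arrival time
#'
#' Pearson correlation between weighted connectivity degree and finite
#' arrival times, with excluded regions (typically the seeds) removed.
#' Hubs arriving earlier show as a negative correlation.
#'
#' @param conn a `connectome`.
#' @param times an `arrival_times`.
#' @param exclude region indices to drop (e.g. the seeds).
#' @return list with `r` and `p_value`.
#' @export
degree_time_correlation <- function(conn, times, exclude = integer(0)) {
  stopifnot(inherits(times, "arrival_times"))
  deg <- weighted_degree(conn)
  keep <- setdiff(which(is.finite(times$t_arrive)), exclude)
  if (length(keep) < 3) stop("fewer than 3 finite, non-excluded regions")
  ct <- cor.test(deg[keep], times$t_arrive[keep])
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
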