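# Bio-inspired clusterers. Every agent encodes a flattened k x d centroid
# set; the shared fitness is the within-cluster sum of squares (q = 2), so
# all four methods are directly comparable with k-means on the same data.
# All four archive the best solution ever visited (elitism), so their
# best-fitness traces are monotone non-increasing.

flatten_centroids <- function(B) as.numeric(t(B))
unflatten_centroids <- function(v, k, d) matrix(v, nrow = k, ncol = d, byrow = TRUE)

centroid_fitness <- function(v, data, k, d) {
  clustering_objective(data, unflatten_centroids(v, k, d), q = 2)$objective
}

# Initial population: each agent is a random selection of k data points.
init_population <- function(X, n_agents, k, seed) {
  n <- nrow(X)
  with_seed(seed, {
    t(vapply(seq_len(n_agents),
             function(i) flatten_centroids(X[sample.int(n, k), , drop = FALSE]),
             numeric(k * ncol(X))))
  })
}

data_box <- function(X, k) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  list(lo = rep(lo, times = k), hi = rep(hi, times = k),
       range = rep(pmax(hi - lo, .Machine$double.eps), times = k),
       diag = sqrt(sum((hi - lo)^2)))
}

clamp_box <- function(v, box) pmin(pmax(v, box$lo), box$hi)

#' Heavy-tailed Levy-flight step (Mantegna construction)
#'
#' Draws a `dim`-vector whose components follow `scale * u / |v|^(1/beta)`
#' with `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)` and the Mantegna sigma for
#' stability exponent `beta`. Deterministic given `seed`; with `seed = NULL`
#' the current RNG stream is used (internal callers).
#'
#' @param dim step dimension.
#' @param beta stability exponent in (0, 2).
#' @param scale multiplicative step scale (possibly a vector of length `dim`).
#' @param seed integer seed or `NULL`.
#' @return numeric vector of length `dim`.
#' @export
levy_flight_step <- function(dim, beta = 1.5, scale = 1, seed = NULL) {
  assert_number(dim, "dim", lower = 1)
  if (beta <= 0 || beta >= 2) stop_validation("beta must be in (0, 2)")
  draw <- function() {
    sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                  (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
    u <- rnorm(dim, sd = sigma_u)
    v <- rnorm(dim)
    scale * u / abs(v)^(1 / beta)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Cuckoo-search parameters
#'
#' @param n_nests number of host nests (population size).
#' @param pa discovery probability in `[0, 1]`: the fraction of worst nests
#'   abandoned and rebuilt each generation.
#' @param levy_beta Levy stability exponent in (0, 2).
#' @param step_scale Levy step scale; the raw step is multiplied by the
#'   perturbed nest's coordinate-wise distance from the best nest (floored at
#'   1 percent of the data range), so steps anneal as the population
#'   converges.
#' @param iters number of generations.
#' @param seed integer seed (`NULL` falls back to the clustering config seed).
#' @return a list of class `cuckoo_params`.
#' @export
cuckoo_params <- function(n_nests = 15L, pa = 0.25, levy_beta = 1.5,
                          step_scale = 0.01, iters = 200L, seed = NULL) {
  assert_number(pa, "pa", lower = 0, upper = 1)
  if (levy_beta <= 0 || levy_beta >= 2) stop_validation("levy_beta must be in (0, 2)")
  assert_number(n_nests, "n_nests", lower = 2)
  assert_number(iters, "iters", lower = 1)
  assert_number(step_scale, "step_scale", lower = 0)
  structure(list(n_nests = as.integer(n_nests), pa = pa,
                 levy_beta = levy_beta, step_scale = step_scale,
                 iters = as.integer(iters), seed = seed),
            class = "cuckoo_params")
}

#' Cuckoo-search clustering
#'
#' Each nest encodes a flattened centroid set; fitness is the within-cluster
#' sum of squares. Per generation every nest is perturbed by a Levy flight
#' whose step length is proportional to the nest's distance from the best
#' nest (so exploration anneals into refinement), each candidate greedily
#' replacing its nest when fitter; a fraction `pa` of the worst nests (never
#' the best) is then abandoned and rebuilt by stochastic mixing of two
#' random nests, again keeping the better of old and new. The best solution
#' ever seen is archived.
#'
#' @param X numeric matrix (n x d) or vector.
#' @param cfg a [cluster_config()] (uses `k` and `seed`; fitness is q = 2).
#' @param params a [cuckoo_params()].
#' @return a `cluster_model`; `$extra$n_abandoned` counts nest rebuilds and
#'   `$trace` holds the best fitness per generation.
#' @export
cuckoo_cluster <- function(X, cfg, params = cuckoo_params()) {
  X <- as_matrix(X)
  stopifnot(inherits(cfg, "cluster_config"), inherits(params, "cuckoo_params"))
  n <- nrow(X); d <- ncol(X); k <- cfg$k
  if (k > n) stop_validation("k must not exceed the number of points")
  seed <- if (is.null(params$seed)) cfg$seed else params$seed
  box <- data_box(X, k)
  nests <- init_population(X, params$n_nests, k, derive_seed(seed, "init"))
  fit <- apply(nests, 1L, centroid_fitness, data = X, k = k, d = d)
  best_v <- nests[which.min(fit), ]
  best_f <- min(fit)
  trace <- numeric(params$iters)
  n_abandoned <- 0L
  n_ab <- floor(params$pa * params$n_nests)
  with_seed(derive_seed(seed, "search"), {
    for (g in seq_len(params$iters)) {
      for (j in seq_len(params$n_nests)) {
        # step length proportional to the distance from the best nest
        # (range-scaled floor keeps the best nest itself exploring locally)
        rel <- nests[j, ] - best_v
        if (all(rel == 0)) rel <- 0.1 * box$range
        step <- params$step_scale *
          levy_flight_step(k * d, params$levy_beta, scale = 1) * rel
        cand <- clamp_box(nests[j, ] + step, box)
        f_cand <- centroid_fitness(cand, X, k, d)
        if (f_cand < fit[j]) {
          nests[j, ] <- cand
          fit[j] <- f_cand
        }
      }
      if (n_ab > 0L) {
        worst <- order(fit, decreasing = TRUE)
        worst <- setdiff(worst, which.min(fit))[seq_len(n_ab)]
        pq <- matrix(sample.int(params$n_nests, 2L * n_ab, replace = TRUE),
                     ncol = 2L)
        for (wi in seq_along(worst)) {
          w <- worst[wi]
          cand <- clamp_box(
            nests[w, ] + runif(k * d) * (nests[pq[wi, 1L], ] - nests[pq[wi, 2L], ]),
            box)
          f_cand <- centroid_fitness(cand, X, k, d)
          n_abandoned <- n_abandoned + 1L
          if (f_cand < fit[w]) {
            nests[w, ] <- cand
            fit[w] <- f_cand
          }
        }
      }
      if (min(fit) < best_f) {
        best_f <- min(fit)
        best_v <- nests[which.min(fit), ]
      }
      trace[g] <- best_f
    }
  })
  new_cluster_model("cuckoo", X, unflatten_centroids(best_v, k, d), cfg, trace,
                    extra = list(n_abandoned = n_abandoned))
}

#' Dragonfly parameters
#'
#' Force weights for the swarm update: separation, alignment, cohesion,
#' food attraction, enemy repulsion, plus the step-retention (inertia)
#' weight. The neighbourhood radius shrinks linearly from
#' `radius_frac[1]` to `radius_frac[2]` of the search-space diagonal.
#'
#' @param w_sep,w_ali,w_coh,w_food,w_enemy nonnegative force weights.
#' @param inertia step-retention weight (decays linearly to half its value
#'   over the run).
#' @param radius_frac length-2 vector: initial and final neighbourhood radius
#'   as fractions of the data diagonal.
#' @param n_agents population size.
#' @param iters number of iterations.
#' @param seed integer seed (`NULL` falls back to the config seed).
#' @return a list of class `dragonfly_params`.
#' @export
dragonfly_params <- function(w_sep = 0.1, w_ali = 0.1, w_coh = 0.7,
                             w_food = 1, w_enemy = 0.1, inertia = 0.5,
                             radius_frac = c(0.25, 0.05), n_agents = 15L,
                             iters = 200L, seed = NULL) {
  for (nm in c("w_sep", "w_ali", "w_coh", "w_food", "w_enemy", "inertia"))
    assert_number(get(nm), nm, lower = 0)
  stopifnot(length(radius_frac) == 2L, all(radius_frac > 0))
  structure(list(w_sep = w_sep, w_ali = w_ali, w_coh = w_coh, w_food = w_food,
                 w_enemy = w_enemy, inertia = inertia,
                 radius_frac = radius_frac, n_agents = as.integer(n_agents),
                 iters = as.integer(iters), seed = seed),
            class = "dragonfly_params")
}

#' Dragonfly swarm forces for one agent
#'
#' Neighbours are the agents within `radius` of agent `idx` (excluding
#' itself); with `M` neighbours: separation `sum_l (He_idx - He_l)`,
#' alignment = mean neighbour velocity, cohesion = neighbour centroid minus
#' own position, food attraction = `food_pos - He_idx`, enemy repulsion =
#' `He_idx - enemy_pos`. With no neighbours, separation, alignment and
#' cohesion are zero.
#'
#' @param idx agent index (row of `positions`).
#' @param positions n_agents x dim matrix of agent positions.
#' @param velocities n_agents x dim matrix of previous step vectors.
#' @param food_pos,enemy_pos positions of the best and worst solutions.
#' @param radius neighbourhood radius (> 0).
#' @return list with vectors `sep`, `ali`, `coh`, `food`, `ene` and the
#'   neighbour count `m`.
#' @export
dragonfly_forces <- function(idx, positions, velocities, food_pos, enemy_pos,
                             radius) {
  assert_number(radius, "radius", lower = .Machine$double.xmin)
  he <- positions[idx, ]
  dvec <- sqrt(rowSums((positions - matrix(he, nrow(positions), length(he),
                                           byrow = TRUE))^2))
  nb <- which(dvec <= radius)
  nb <- setdiff(nb, idx)
  m <- length(nb)
  if (m == 0L) {
    zero <- numeric(length(he))
    sep <- ali <- coh <- zero
  } else {
    sep <- m * he - colSums(positions[nb, , drop = FALSE])
    ali <- colMeans(velocities[nb, , drop = FALSE])
    coh <- colMeans(positions[nb, , drop = FALSE]) - he
  }
  list(sep = sep, ali = ali, coh = coh,
       food = food_pos - he, ene = he - enemy_pos, m = m)
}

#' Dragonfly clustering
#'
#' Swarm search over flattened centroid sets: each agent's step is the
#' weighted sum of separation, alignment, cohesion, attraction to the best
#' solution found so far (food) and repulsion from the worst of the current
#' population (enemy), plus an inertia term retaining the previous step.
#' Positions are clamped to the data bounding box. The best solution is
#' archived.
#'
#' @inheritParams cuckoo_cluster
#' @param params a [dragonfly_params()].
#' @return a `cluster_model` with the best-fitness trace.
#' @export
dragonfly_cluster <- function(X, cfg, params = dragonfly_params()) {
  X <- as_matrix(X)
  stopifnot(inherits(cfg, "cluster_config"), inherits(params, "dragonfly_params"))
  n <- nrow(X); d <- ncol(X); k <- cfg$k
  if (k > n) stop_validation("k must not exceed the number of points")
  seed <- if (is.null(params$seed)) cfg$seed else params$seed
  box <- data_box(X, k)
  pos <- init_population(X, params$n_agents, k, derive_seed(seed, "init"))
  vel <- matrix(0, params$n_agents, k * d)
  fit <- apply(pos, 1L, centroid_fitness, data = X, k = k, d = d)
  best_v <- pos[which.min(fit), ]; best_f <- min(fit)
  trace <- numeric(params$iters)
  any_dyn <- params$w_sep + params$w_ali + params$w_coh + params$w_food +
    params$w_enemy + params$inertia > 0
  with_seed(derive_seed(seed, "search"), {
    for (g in seq_len(params$iters)) {
      prog <- (g - 1) / max(1L, params$iters - 1L)
      radius <- (params$radius_frac[1] +
                   (params$radius_frac[2] - params$radius_frac[1]) * prog) *
        box$diag
      inertia_g <- params$inertia * (1 - 0.5 * prog)  # decays to half
      enemy <- pos[which.max(fit), ]
      for (i in seq_len(params$n_agents)) {
        fr <- dragonfly_forces(i, pos, vel, best_v, enemy, radius)
        # uniform random multipliers on each force (standard swarm practice)
        # keep the population diverse instead of collapsing onto the food
        u <- runif(5)
        step <- u[1] * params$w_sep * fr$sep + u[2] * params$w_ali * fr$ali +
          u[3] * params$w_coh * fr$coh + u[4] * params$w_food * fr$food +
          u[5] * params$w_enemy * fr$ene + inertia_g * vel[i, ]
        # isolated agent with active dynamics: heavy-tailed local walk
        # (with every weight zero the update degenerates to no motion)
        if (fr$m == 0L && any_dyn)
          step <- step + levy_flight_step(k * d, scale = 0.01) * box$range
        vel[i, ] <- step
        pos[i, ] <- clamp_box(pos[i, ] + step, box)
      }
      fit <- apply(pos, 1L, centroid_fitness, data = X, k = k, d = d)
      if (min(fit) < best_f) { best_f <- min(fit); best_v <- pos[which.min(fit), ] }
      trace[g] <- best_f
    }
  })
  new_cluster_model("dragonfly", X, unflatten_centroids(best_v, k, d), cfg, trace)
}

#' Firefly parameters
#'
#' @param n_fireflies population size.
#' @param lam light absorption coefficient (>= 0), applied to the squared
#'   distance normalised by the search-space diagonal.
#' @param alpha randomisation parameter in `[0, 1]` (step scale of the random
#'   term, relative to the per-coordinate data range).
#' @param alpha_decay geometric per-iteration decay of `alpha`.
#' @param a0 attraction scale at distance zero (standard variant; 1 by
#'   convention).
#' @param iters number of iterations.
#' @param s_directions number of trial unit vectors for the brightest
#'   firefly's directed move (modified variant only).
#' @param b0_mode `"unit"` (attraction scale `a0`) or `"intensity_ratio"`
#'   (attraction scale = ratio of source intensities; modified variant).
#' @param seed integer seed (`NULL` falls back to the config seed).
#' @return a list of class `firefly_params`.
#' @export
firefly_params <- function(n_fireflies = 15L, lam = 1, alpha = 0.2,
                           alpha_decay = 0.97, a0 = 1, iters = 200L,
                           s_directions = 10L, b0_mode = c("unit", "intensity_ratio"),
                           seed = NULL) {
  assert_number(lam, "lam", lower = 0)
  assert_number(alpha, "alpha", lower = 0, upper = 1)
  assert_number(s_directions, "s_directions", lower = 1)
  b0_mode <- match.arg(b0_mode)
  structure(list(n_fireflies = as.integer(n_fireflies), lam = lam,
                 alpha = alpha, alpha_decay = alpha_decay, a0 = a0,
                 iters = as.integer(iters),
                 s_directions = as.integer(s_directions),
                 b0_mode = b0_mode, seed = seed),
            class = "firefly_params")
}

#' Distance-attenuated intensity / attractiveness kernel
#'
#' `value0 / (1 + lam * q_dist^2)`: the rational approximation of the
#' exponential attenuation of light intensity (and attractiveness) with
#' distance, strictly decreasing in `q_dist` for `lam > 0`.
#'
#' @param q_dist nonnegative distance.
#' @param value0 value at distance zero (source intensity `J0` or
#'   attractiveness `B0`).
#' @param lam absorption coefficient (>= 0).
#' @return the attenuated value.
#' @export
#' @examples
#' firefly_kernel(1, 1, 1)  # 0.5
firefly_kernel <- function(q_dist, value0, lam) {
  if (any(q_dist < 0)) stop_validation("q_dist must be nonnegative")
  assert_number(lam, "lam", lower = 0)
  value0 / (1 + lam * q_dist^2)
}

#' One firefly attraction move
#'
#' `y + a0 * exp(-lam * q^2) * (y_bright - y) + alpha * eps`, with `q` the
#' Euclidean distance between `y` and `y_bright` divided by `dist_scale`
#' (distance normalisation; see the methods vignette) and `eps` the
#' caller-supplied random vector.
#'
#' @param y position of the moving (dimmer) firefly.
#' @param y_bright position of the brighter firefly.
#' @param params a [firefly_params()] supplying `lam` and the default `a0`.
#' @param eps random vector (already scaled to the search space).
#' @param alpha current randomisation parameter (defaults to `params$alpha`).
#' @param a0 attraction scale override (`B0` in the modified variant).
#' @param dist_scale normalisation of the distance entering the attenuation.
#' @return the updated position.
#' @export
firefly_move <- function(y, y_bright, params, eps, alpha = params$alpha,
                         a0 = params$a0, dist_scale = 1) {
  stopifnot(length(y) == length(y_bright))
  q <- sqrt(sum((y - y_bright)^2)) / dist_scale
  y + a0 * exp(-params$lam * q^2) * (y_bright - y) + alpha * eps
}

firefly_engine <- function(X, cfg, params, modified) {
  X <- as_matrix(X)
  n <- nrow(X); d <- ncol(X); k <- cfg$k
  if (k > n) stop_validation("k must not exceed the number of points")
  seed <- if (is.null(params$seed)) cfg$seed else params$seed
  box <- data_box(X, k)
  pos <- init_population(X, params$n_fireflies, k, derive_seed(seed, "init"))
  fit <- apply(pos, 1L, centroid_fitness, data = X, k = k, d = d)
  best_v <- pos[which.min(fit), ]; best_f <- min(fit)
  trace <- numeric(params$iters)
  pop_best_trace <- numeric(params$iters)
  intensity <- function(f) 1 / (1 + f)   # lower objective = brighter
  with_seed(derive_seed(seed, "search"), {
    for (g in seq_len(params$iters)) {
      alpha_g <- params$alpha * params$alpha_decay^(g - 1)
      inten <- intensity(fit)
      if (any(inten == 0)) stop_validation("singular zero intensity encountered")
      order_bright <- order(fit)          # brightest first
      brightest <- order_bright[1L]
      for (i in seq_len(params$n_fireflies)) {
        if (i == brightest) next
        for (j in seq_len(params$n_fireflies)) {
          if (inten[j] <= inten[i]) next
          a0 <- if (modified && params$b0_mode == "intensity_ratio")
            inten[j] / inten[i] else params$a0
          eps <- runif(k * d, -0.5, 0.5) * box$range
          pos[i, ] <- clamp_box(
            firefly_move(pos[i, ], pos[j, ], params, eps, alpha = alpha_g,
                         a0 = a0, dist_scale = box$diag), box)
        }
        fit[i] <- centroid_fitness(pos[i, ], X, k, d)
        inten[i] <- intensity(fit[i])
      }
      if (modified) {
        # Brightest firefly: trial s random unit directions, move only along
        # a strictly improving one (best of the improving trials), else stay.
        step_len <- alpha_g * mean(box$range)
        best_cand <- NULL; best_cand_f <- fit[brightest]
        for (s in seq_len(params$s_directions)) {
          v <- rnorm(k * d); v <- v / sqrt(sum(v^2))
          cand <- clamp_box(pos[brightest, ] + step_len * v, box)
          f_cand <- centroid_fitness(cand, X, k, d)
          if (f_cand < best_cand_f) { best_cand <- cand; best_cand_f <- f_cand }
        }
        if (!is.null(best_cand)) {
          pos[brightest, ] <- best_cand
          fit[brightest] <- best_cand_f
        }
      } else {
        eps <- runif(k * d, -0.5, 0.5) * box$range
        pos[brightest, ] <- clamp_box(pos[brightest, ] + alpha_g * eps, box)
        fit[brightest] <- centroid_fitness(pos[brightest, ], X, k, d)
      }
      if (min(fit) < best_f) { best_f <- min(fit); best_v <- pos[which.min(fit), ] }
      trace[g] <- best_f
      pop_best_trace[g] <- min(fit)
    }
  })
  new_cluster_model(if (modified) "modified_firefly" else "firefly",
                    X, unflatten_centroids(best_v, k, d), cfg, trace,
                    extra = list(pop_best_trace = pop_best_trace))
}

#' Firefly clustering
#'
#' Every firefly moves toward each brighter firefly via [firefly_move()]
#' (attraction scale `a0`, brightness = `1 / (1 + objective)` so lower
#' objective means brighter); the brightest firefly moves randomly. The best
#' solution ever visited is archived.
#'
#' @inheritParams cuckoo_cluster
#' @param params a [firefly_params()] with `b0_mode = "unit"`.
#' @return a `cluster_model`; `$extra$pop_best_trace` records the current
#'   population's best objective per iteration.
#' @export
firefly_cluster <- function(X, cfg, params = firefly_params()) {
  stopifnot(inherits(cfg, "cluster_config"), inherits(params, "firefly_params"))
  firefly_engine(X, cfg, params, modified = FALSE)
}

#' Modified firefly clustering
#'
#' As [firefly_cluster()] with two changes: (a) the brightest firefly
#' evaluates `s_directions` random unit directions and moves a step
#' `alpha * V` only along a strictly brightness-improving direction (staying
#' put if none exists), so its brightness is non-decreasing at every
#' iteration; (b) the attraction scale toward a brighter firefly is the
#' intensity ratio `B0 = J0' / J0` of the two source intensities.
#'
#' @inheritParams cuckoo_cluster
#' @param params a [firefly_params()]; `b0_mode` is forced to
#'   `"intensity_ratio"`.
#' @return a `cluster_model`; `$extra$pop_best_trace` (the current-population
#'   best objective) is monotone non-increasing.
#' @export
modified_firefly_cluster <- function(X, cfg, params = firefly_params()) {
  stopifnot(inherits(cfg, "cluster_config"), inherits(params, "firefly_params"))
  params$b0_mode <- "intensity_ratio"
  firefly_engine(X, cfg, params, modified = TRUE)
}

# Registry used by the feature extractor and the pipeline.
CLUSTER_METHODS <- c("kmeans", "kmedian", "fcm", "cuckoo", "dragonfly",
                     "firefly", "modified_firefly")

#' Run any of the six clusterers by name
#'
#' Dispatch helper: `"kmeans"`, `"kmedian"` (k-means with q = 1), `"fcm"`,
#' `"cuckoo"`, `"dragonfly"`, `"firefly"`, `"modified_firefly"`.
#'
#' @param X numeric matrix or vector.
#' @param method method name.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param nstart restarts for the learning-based methods.
#' @param params optional metaheuristic parameter object matching the method.
#' @param p fuzziness index for `"fcm"`.
#' @return a `cluster_model`.
#' @export
cluster_eeg <- function(X, method, k, seed = 1L, nstart = 1L, params = NULL,
                        p = 2) {
  method <- match.arg(method, CLUSTER_METHODS)
  cfg <- cluster_config(k = k, q = if (method == "kmedian") 1 else 2,
                        seed = seed, nstart = nstart)
  switch(method,
    kmeans = kmeans_cluster(X, cfg),
    kmedian = kmeans_cluster(X, cfg),
    fcm = fcm_cluster(X, fcm_config(k = k, p = p, seed = seed)),
    cuckoo = cuckoo_cluster(X, cfg, params %||% cuckoo_params()),
    dragonfly = dragonfly_cluster(X, cfg, params %||% dragonfly_params()),
    firefly = firefly_cluster(X, cfg, params %||% firefly_params()),
    modified_firefly = modified_firefly_cluster(X, cfg, params %||% firefly_params()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
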