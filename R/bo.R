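#' Configuration for CAWarm-BO
#'
#' An "iteration" is one objective evaluation, for both the warmup cap and
#' the total budget (the budget is inclusive of the warmup phase).
#'
#' @param max_warmup_evals Cap on coordinate-ascent warmup evaluations
#'   (default 60).
#' @param total_evals Total evaluation budget including warmup
#'   (default 200).
#' @param seed Seed for the BO phase (the warmup is deterministic).
#' @param n_candidates Random candidates per acquisition maximization.
#' @param n_local Local perturbations of the incumbent added to the
#'   candidate set.
#' @param refit_every Re-optimize GP hyperparameters every this many BO
#'   evaluations (the GP itself is refit on the full trace every step).
#' @param halve_steps Halve a coordinate's warmup step (floored at 1 for
#'   integers) when neither probe direction improves during a pass that
#'   improved elsewhere.
#' @return A list of class `bo_config`.
#' @export
bo_config <- function(max_warmup_evals = 60, total_evals = 200, seed = 1,
                      n_candidates = 256, n_local = 64, refit_every = 10,
                      halve_steps = TRUE) {
  if (!(max_warmup_evals > 0 && max_warmup_evals < total_evals)) {
    abort("need 0 < max_warmup_evals < total_evals")
  }
  structure(
    list(max_warmup_evals = max_warmup_evals, total_evals = total_evals,
         seed = seed, n_candidates = n_candidates, n_local = n_local,
         refit_every = refit_every, halve_steps = halve_steps),
    class = "bo_config"
  )
}

#' Coordinate-ascent warmup
#'
#' Starts from the space defaults and cycles the coordinates in space
#' order. At each coordinate it probes one warmup step up and one down
#' (binary coordinates: a flip), greedily accepts the better
#' strictly-improving move, and keeps walking in that direction while the
#' loss keeps improving; probes are clipped into the search domain. The
#' warmup stops when a full pass over all coordinates yields no
#' improvement, or when the evaluation count reaches
#' `config$max_warmup_evals`. The warmup is fully deterministic.
#'
#' @param objective An `asm_objective`.
#' @param space A [param_space()].
#' @param domain A `search_domain` (defaults to [initial_domain()]).
#' @param config A [bo_config()].
#' @return A list with `theta_hat` (the incumbent), `trace` (a
#'   [bo_trace()] with phase `"warmup"`) and `stopped` (`"no_improvement"`
#'   or `"budget"`).
#' @export
ca_warmup <- function(objective, space, domain = initial_domain(space),
                      config = bo_config()) {
  steps <- setNames(space$warmup_step, space$name)
  theta <- default_vector(space)
  if (!validate_vector(space, theta, domain)) {
    abort("default vector is not valid in the given domain")
  }
  thetas <- list()
  ys <- numeric(0)
  evaluate <- function(th) {
    thetas[[length(thetas) + 1]] <<- th
    ys[length(ys) + 1] <<- objective(th)
    ys[length(ys)]
  }
  best_y <- evaluate(theta)
  stopped <- "budget"
  while (length(ys) < config$max_warmup_evals) {
    improved_pass <- FALSE
    failed_coords <- character(0)
    for (i in seq_len(nrow(space))) {
      if (length(ys) >= config$max_warmup_evals) break
      nm <- space$name[i]
      cands <- warmup_probes(theta, nm, steps[nm], space$kind[i], domain, i)
      if (length(cands) == 0) next
      cand_y <- numeric(0)
      for (cand in cands) {
        cand_y <- c(cand_y, evaluate(cand))
        if (length(ys) >= config$max_warmup_evals) break
      }
      tried <- cands[seq_along(cand_y)]
      j <- which.min(cand_y)
      if (length(cand_y) > 0 && cand_y[j] < best_y) {
        direction <- sign(tried[[j]][nm] - theta[nm])
        theta <- tried[[j]]
        best_y <- cand_y[j]
        improved_pass <- TRUE
        # keep walking this coordinate while it improves
        while (space$kind[i] != "binary" &&
               length(ys) < config$max_warmup_evals) {
          nxt <- theta
          nxt[nm] <- min(max(theta[nm] + direction * steps[nm],
                             domain$lo[i]), domain$hi[i])
          if (space$kind[i] == "integer") nxt[nm] <- round(nxt[nm])
          if (nxt[nm] == theta[nm]) break
          y_nxt <- evaluate(nxt)
          if (y_nxt < best_y) {
            theta <- nxt
            best_y <- y_nxt
          } else break
        }
      } else {
        failed_coords <- c(failed_coords, nm)
      }
    }
    if (length(ys) >= config$max_warmup_evals) break
    if (!improved_pass) {
      stopped <- "no_improvement"
      break
    }
    if (config$halve_steps && length(failed_coords) > 0) {
      int_coords <- space$name[space$kind == "integer"]
      steps[failed_coords] <- steps[failed_coords] / 2
      ints <- intersect(failed_coords, int_coords)
      steps[ints] <- pmax(1, round(steps[ints]))
    }
  }
  trace <- bo_trace(thetas, ys, phase = "warmup",
                    sample_id = attr(objective, "sample_id") %||% "sample",
                    space = space)
  best <- trace_best(trace)
  list(theta_hat = best$theta, trace = trace, stopped = stopped)
}

warmup_probes <- function(theta, nm, step, kind, domain, i) {
  if (kind == "binary") {
    cand <- theta
    cand[nm] <- 1 - cand[nm]
    return(list(cand))
  }
  up <- theta; down <- theta
  up[nm] <- min(theta[nm] + step, domain$hi[i])
  down[nm] <- max(theta[nm] - step, domain$lo[i])
  if (kind == "integer") {
    up[nm] <- round(up[nm]); down[nm] <- round(down[nm])
  }
  out <- list()
  if (up[nm] != theta[nm]) out <- c(out, list(up))
  if (down[nm] != theta[nm]) out <- c(out, list(down))
  out
}

#' Propose the next point by expected improvement
#'
#' Maximizes expected improvement over the incumbent by scoring a seeded
#' random candidate set (uniform over the domain, integers on the lattice)
#' plus local perturbations of the incumbent, all projected onto the mixed
#' structure of the space. Points already present in the trace are
#' excluded, and the proposal always lies in the domain.
#'
#' @param surrogate A fitted `gp_surrogate`.
#' @param domain The active `search_domain`.
#' @param trace The current [bo_trace()].
#' @param seed Seed for the candidate draw.
#' @param space The [param_space()].
#' @param n_candidates,n_local Candidate counts.
#' @return A named parameter vector.
#' @export
bo_step <- function(surrogate, domain, trace, seed = 1,
                    space = attr(trace, "space"),
                    n_candidates = 256, n_local = 64) {
  rng <- local_rng(seed)
  incumbent <- trace_best(trace)
  cands <- random_candidates(space, domain, n_candidates, rng)
  local_wide <- local_candidates(space, domain, incumbent$theta,
                                 ceiling(n_local / 2), rng, scale = 0.1)
  local_fine <- local_candidates(space, domain, incumbent$theta,
                                 floor(n_local / 2), rng, scale = 0.02)
  X <- rbind(cands, local_wide, local_fine)
  # drop exact duplicates of evaluated points
  seen <- apply(theta_matrix(trace, space), 1, paste, collapse = ",")
  keys <- apply(X, 1, paste, collapse = ",")
  X <- X[!keys %in% seen & !duplicated(keys), , drop = FALSE]
  if (nrow(X) == 0) {
    return(project_vector(space, random_candidates(space, domain, 1, rng)[1, ],
                          domain))
  }
  post <- gp_posterior(surrogate, X)
  ei <- expected_improvement(post$mean, post$sd, incumbent$y)
  setNames(X[which.max(ei), ], space$name)
}

expected_improvement <- function(mu, sd, y_best) {
  imp <- y_best - mu
  out <- ifelse(sd > 1e-12,
                imp * pnorm(imp / sd) + sd * dnorm(imp / sd),
                pmax(imp, 0))
  out
}

random_candidates <- function(space, domain, n, rng) {
  p <- nrow(space)
  X <- matrix(0, n, p, dimnames = list(NULL, space$name))
  for (j in seq_len(p)) {
    u <- rng(n, domain$lo[j], domain$hi[j])
    X[, j] <- switch(space$kind[j],
      binary = as.numeric(rng(n) < 0.5),
      integer = pmin(pmax(round(u), ceiling(domain$lo[j])),
                     floor(domain$hi[j])),
      u
    )
  }
  X
}

local_candidates <- function(space, domain, center, n, rng, scale = 0.1) {
  p <- nrow(space)
  X <- matrix(rep(center, each = n), n, p, dimnames = list(NULL, space$name))
  for (j in seq_len(p)) {
    if (space$kind[j] == "binary") {
      flip <- rng(n) < 0.2
      X[flip, j] <- 1 - X[flip, j]
    } else {
      range_j <- domain$hi[j] - domain$lo[j]
      # Box-Muller from the private uniform stream
      z <- sqrt(-2 * log(pmax(rng(n), 1e-12))) * cos(2 * pi * rng(n))
      X[, j] <- X[, j] + z * scale * range_j
      X[, j] <- pmin(pmax(X[, j], domain$lo[j]), domain$hi[j])
      if (space$kind[j] == "integer") {
        X[, j] <- pmin(pmax(round(X[, j]), ceiling(domain$lo[j])),
                       floor(domain$hi[j]))
      }
    }
  }
  X
}

#' Coordinate-ascent warmup followed by mixed-space GP-BO
#'
#' Runs [ca_warmup()] from the space defaults, re-centers the search
#' domain on the warmup incumbent (`[0, max(2 * theta_hat_i, U_i)]` per
#' non-binary coordinate), then runs GP Bayesian optimization with
#' expected improvement until the total evaluation budget — inclusive of
#' the warmup phase — is spent. The returned incumbent is the earliest
#' trace record attaining the smallest loss; since the defaults are
#' evaluated first, it is never worse than the default vector.
#'
#' @inheritParams ca_warmup
#' @return A list with `theta_hat`, `y_hat`, `trace` (warmup + BO records)
#'   and `domain` (the adjusted domain used by the BO phase).
#' @examples
#' sp <- param_space(data.frame(
#'   name = c("a", "b"), kind = "integer", default = c(10, 10)
#' ), "toy")
#' obj <- synthetic_objective(c(a = 14, b = 6), sp, seed = 1)
#' fit <- cawarm_bo(obj, sp, bo_config(max_warmup_evals = 8,
#'                                     total_evals = 20, seed = 1))
#' fit$theta_hat
#' @export
cawarm_bo <- function(objective, space, config = bo_config(),
                      domain = initial_domain(space)) {
  wu <- ca_warmup(objective, space, domain, config)
  domain_bo <- adjust_domain(domain, wu$theta_hat)
  thetas <- wu$trace$theta
  ys <- wu$trace$y
  phases <- wu$trace$phase
  sample_id <- attr(objective, "sample_id") %||% "sample"

  par_cache <- NULL
  n_bo <- 0
  while (length(ys) < config$total_evals) {
    trace <- bo_trace(thetas, ys, phase = phases,
                      sample_id = sample_id, space = space)
    optimize <- is.null(par_cache) || n_bo %% config$refit_every == 0
    surrogate <- tryCatch(
      fit_surrogate(trace, domain_bo, space,
                    optimize_hyperparams = optimize, par = par_cache),
      error = function(e) NULL
    )
    if (is.null(surrogate)) {
      rng <- local_rng(config$seed + length(ys))
      theta_next <- setNames(
        random_candidates(space, domain_bo, 1, rng)[1, ], space$name)
    } else {
      if (optimize) par_cache <- surrogate$par
      theta_next <- bo_step(surrogate, domain_bo, trace,
                            seed = config$seed + length(ys), space = space,
                            n_candidates = config$n_candidates,
                            n_local = config$n_local)
    }
    thetas[[length(thetas) + 1]] <- theta_next
    ys <- c(ys, objective(theta_next))
    phases <- c(phases, "bo")
    n_bo <- n_bo + 1
  }
  trace <- bo_trace(thetas, ys, phase = phases,
                    sample_id = sample_id, space = space)
  best <- trace_best(trace)
  list(theta_hat = best$theta, y_hat = best$y, trace = trace,
       domain = domain_bo)
}
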