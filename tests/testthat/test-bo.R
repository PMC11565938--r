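test_that("warmup stops after one unproductive sweep on a flat objective", {
  sp <- toy_space_mixed()
  const <- new_objective(function(th) -0.5, "const")
  wu <- ca_warmup(const, sp)
  # 1 (defaults) + 1 flip (binary) + 2 probes each for the two non-binary
  expect_equal(nrow(wu$trace), 6L)
  expect_equal(wu$stopped, "no_improvement")
  expect_theta_equal(wu$theta_hat, default_vector(sp))
})

test_that("warmup exhausts the cap on a strictly improving objective", {
  sp <- toy_space3()
  mono <- new_objective(function(th) -1 + exp(-1e-6 * sum(th)), "mono")
  wu <- ca_warmup(mono, sp)
  expect_equal(nrow(wu$trace), 60L)       # default cap
  expect_equal(wu$stopped, "budget")
  wu2 <- ca_warmup(mono, sp, config = bo_config(max_warmup_evals = 17,
                                                total_evals = 40))
  expect_equal(nrow(wu2$trace), 17L)
})

test_that("warmup solves a separable concave toy to the grid argmin", {
  sp <- toy_space2()    # integer steps of 1 (defaults 5)
  f <- function(th) ((th[["a"]] - 3)^2 + (th[["b"]] - 7)^2) / 5000 - 1
  obj <- new_objective(f, "sep")
  wu <- ca_warmup(obj, sp)
  grid <- expand.grid(a = 0:50, b = 0:50)
  vals <- apply(grid, 1, function(r) f(c(a = r[[1]], b = r[[2]])))
  expect_theta_equal(wu$theta_hat,
                     unlist(grid[which.min(vals), ]))
  # warmup is deterministic
  wu2 <- ca_warmup(obj, sp)
  expect_identical(wu$trace$y, wu2$trace$y)
})

test_that("surrogate interpolates noise-free training data", {
  sp <- toy_space2()
  opt <- c(a = 3, b = 7)
  f <- synthetic_objective(opt, sp, seed = 2)
  withr::with_seed(3, {
    th <- lapply(1:12, function(i) c(a = sample(0:20, 1),
                                     b = sample(0:20, 1)))
  })
  th <- th[!duplicated(vapply(th, paste, "", collapse = ","))]
  tr <- bo_trace(th, vapply(th, f, 0), space = sp)
  sur <- fit_surrogate(tr, initial_domain(sp), sp, noise = 1e-10)
  mu <- posterior_mean(sur, tr$theta)
  expect_lt(max(abs(mu - tr$y) / pmax(abs(tr$y), 1e-3)), 1e-6)

  # constant-loss trace: posterior mean constant
  trc <- bo_trace(th, rep(-0.4, length(th)), space = sp)
  surc <- fit_surrogate(trc, initial_domain(sp), sp, noise = 1e-10,
                        optimize_hyperparams = FALSE)
  muc <- posterior_mean(surc, list(c(a = 2, b = 2), c(a = 19, b = 5)))
  expect_equal(muc, c(-0.4, -0.4), tolerance = 1e-6)

  # degenerate trace
  trd <- bo_trace(list(c(a = 1, b = 1), c(a = 1, b = 1)), c(-0.1, -0.1),
                  space = sp)
  expect_error(fit_surrogate(trd, initial_domain(sp), sp), "degenerate")
})

test_that("two-point GP posterior mean matches the closed form", {
  sp <- param_space(data.frame(name = "a", kind = "float", default = 5),
                    "line")
  dom <- initial_domain(sp)     # [0, 50]
  tr <- bo_trace(list(c(a = 10), c(a = 40)), c(-0.2, -0.8), space = sp)
  par <- c(log(0.5), log(1))
  sur <- fit_surrogate(tr, dom, sp, noise = 1e-10,
                       optimize_hyperparams = FALSE, par = par)
  # independent closed form: Matern-5/2 on [0,1]-scaled inputs,
  # standardized y
  m52 <- function(r, ell) {
    r <- r / ell
    (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  }
  z <- c(10, 40) / 50
  ys <- (c(-0.2, -0.8) - mean(c(-0.2, -0.8))) / stats::sd(c(-0.2, -0.8))
  ell <- 0.5
  K <- outer(z, z, function(a, b) m52(abs(a - b), ell)) + diag(1e-10, 2)
  zq <- 25 / 50
  ks <- vapply(z, function(t) m52(abs(zq - t), ell), 0)
  mu_expected <- sum(ks * solve(K, ys)) * stats::sd(c(-0.2, -0.8)) +
    mean(c(-0.2, -0.8))
  mu <- posterior_mean(sur, c(a = 25))
  expect_equal(mu, mu_expected, tolerance = 1e-6)
  # posterior mean between the two observations for a midpoint query
  expect_gt(mu, -0.8); expect_lt(mu, -0.2)
})

test_that("acquisition proposal maximizes EI over a dense lattice", {
  sp <- param_space(data.frame(name = "a", kind = "integer", default = 3),
                    "lat")
  dom <- initial_domain(sp)     # integers in [0, 30]
  tr <- bo_trace(list(c(a = 5), c(a = 25), c(a = 14)),
                 c(-0.3, -0.6, -0.1), space = sp)
  par <- c(log(0.3), log(1))
  sur <- fit_surrogate(tr, dom, sp, noise = 1e-8,
                       optimize_hyperparams = FALSE, par = par)
  prop <- bo_step(sur, dom, tr, seed = 9, space = sp)
  expect_true(validate_vector(sp, prop, dom))
  # dense-lattice EI oracle via the closed-form normal EI formula
  lattice <- setdiff(0:30, c(5, 25, 14))
  post <- gp_posterior(sur, matrix(lattice, ncol = 1,
                                   dimnames = list(NULL, "a")))
  y_best <- min(tr$y)
  imp <- y_best - post$mean
  zz <- imp / post$sd
  ei <- imp * stats::pnorm(zz) + post$sd * stats::dnorm(zz)
  expect_equal(unname(prop["a"]), lattice[which.max(ei)])
  # deterministic on repeat
  expect_identical(prop, bo_step(sur, dom, tr, seed = 9, space = sp))
})

test_that("cawarm_bo keeps its budget accounting and incumbent invariants", {
  sp <- toy_space3()
  f <- synthetic_objective(c(a = 30, b = 55, c = 6), sp, seed = 8)
  cfg <- bo_config(max_warmup_evals = 12, total_evals = 36, seed = 2)
  fit <- cawarm_bo(f, sp, cfg)
  expect_equal(nrow(fit$trace), 36L)
  expect_lte(sum(fit$trace$phase == "warmup"), 12L)
  # best-so-far is monotone non-increasing
  expect_true(all(diff(cummin(fit$trace$y)) <= 0))
  # never worse than the default vector (evaluated first)
  expect_lte(fit$y_hat, fit$trace$y[1])
  # warmup points lie in the initial domain, BO points in the adjusted one
  dom0 <- initial_domain(sp)
  for (i in seq_len(nrow(fit$trace))) {
    d <- if (fit$trace$phase[i] == "warmup") dom0 else fit$domain
    expect_true(validate_vector(sp, fit$trace$theta[[i]], d))
  }
  # earliest-minimum tie-breaking
  expect_equal(fit$trace$eval[which.min(fit$trace$y)],
               trace_best(fit$trace)$eval)
})

test_that("small-budget run closes in on a planted optimum", {
  sp <- toy_space2()
  opt <- c(a = 17, b = 38)
  f <- synthetic_objective(opt, sp, seed = 3)
  fit <- cawarm_bo(f, sp, bo_config(max_warmup_evals = 25,
                                    total_evals = 70, seed = 5))
  expect_lt(fit$y_hat, -0.9)
})

test_that("trace persistence round-trips", {
  sp <- toy_space2()
  f <- synthetic_objective(c(a = 4, b = 9), sp, seed = 1)
  wu <- ca_warmup(f, sp, config = bo_config(max_warmup_evals = 8,
                                            total_evals = 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(wu$trace, path)
  back <- read_trace(path, space = sp)
  expect_equal(back$y, wu$trace$y)
  expect_equal(theta_matrix(back), theta_matrix(wu$trace))
  expect_equal(attr(back, "sample_id"), attr(wu$trace, "sample_id"))
  g <- glance(wu$trace)
  expect_equal(g$n_evals, nrow(wu$trace))
})
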