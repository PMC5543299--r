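test_that("the CAR full conditional is the neighbour average with variance 1/(tau*m)", {
  w <- build_weights(cbind(c(1, 1), c(2, 3)), 1:3)
  cc <- car_conditional(c(0, 0.2, 0.4), w, tau_v = 2, i = 1)
  expect_equal(unname(cc["mean"]), 0.3)
  expect_equal(unname(cc["variance"]), 0.25)
  # single neighbour
  cc2 <- car_conditional(c(0.7, 0, 0), w, tau_v = 1, i = 2)
  expect_equal(unname(cc2["mean"]), 0.7)
  wi <- build_weights(cbind(1, 2), 1:3)
  expect_error(car_conditional(c(0, 0, 0), wi, 1, 3), "island")
})

test_that("Gelman-Rubin matches hand evaluation and is consistent for one stream", {
  expect_equal(gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4))),
               sqrt(0.75))
  set.seed(8)
  z <- rnorm(20000)
  expect_equal(gelman_rubin(list(z[1:10000], z[10001:20000])), 1,
               tolerance = 0.01)
  expect_error(gelman_rubin(list(c(0, 0), c(0, 0))), "degenerate")
  expect_error(gelman_rubin(list(1:3)), "2 chains")
})

test_that("precision full conditionals match brute-force gamma log-densities", {
  set.seed(13)
  pr <- bym_priors()
  w <- build_weights(path_edges(6), 1:6)
  nbr <- neighbor_list(w)
  for (rep in 1:5) {
    u <- rnorm(6); v <- rnorm(6); v <- v - mean(v)
    taus <- rexp(4, 0.2)
    gu <- sirscan:::tau_u_conditional(u, pr)
    gv <- sirscan:::tau_v_conditional(v, nbr, k = 1, pr)
    # brute force: log prior + log of the normal/ICAR kernels, up to a
    # constant in tau
    lp_u <- function(t) (pr$a_u - 1) * log(t) - pr$b_u * t +
      sum(dnorm(u, 0, 1 / sqrt(t), log = TRUE))
    pairs <- cbind(1:5, 2:6)
    lp_v <- function(t) (pr$a_v - 1) * log(t) - pr$b_v * t +
      (6 - 1) / 2 * log(t) - t / 2 * sum((v[pairs[, 1]] - v[pairs[, 2]])^2)
    dg <- function(t, g) dgamma(t, g["shape"], rate = g["rate"], log = TRUE)
    expect_equal(diff(dg(taus[1:2], gu)), lp_u(taus[2]) - lp_u(taus[1]),
                 tolerance = 1e-10)
    expect_equal(diff(dg(taus[3:4], gv)), lp_v(taus[4]) - lp_v(taus[3]),
                 tolerance = 1e-10)
  }
})

test_that("with no spatial term and a single area the posterior matches the Gamma(O, E) closed form", {
  # flat alpha + N(0, 1/tau_u) u with tau_u integrated out leaves a flat
  # prior on log(theta): posterior is Gamma(O, E), mean O/E
  tab <- data.frame(id = 1, cases = 10, expected = 5)
  fit <- fit_bym(tab, build_weights(NULL, 1),
                 config = mcmc_config(8000, 1000, 2, seed = 3, thin = 1),
                 spatial = FALSE)
  th <- theta_draws(fit)
  expect_equal(mean(th), 10 / 5, tolerance = 0.05)
  expect_equal(sd(th), sqrt(10) / 5, tolerance = 0.1)
})

test_that("exchangeable areas get exchangeable risk estimates centred on O/E", {
  tab <- data.frame(id = 1:9, cases = 6, expected = 5)
  st <- simulate_lattice(simulation_spec(3, 3, seed = 1))
  w <- build_weights(st$edges, 1:9)
  fit <- fit_bym(tab, w, config = mcmc_config(4000, 1000, 2, seed = 5,
                                              thin = 1))
  sm <- summarize_posterior(fit)
  expect_true(all(sm$sir_bym > 0))
  expect_lt(diff(range(sm$sir_bym)), 0.12)     # symmetry within MC error
  expect_equal(mean(sm$sir_bym), 6 / 5, tolerance = 0.1)
})

test_that("spatial draws are centred and the fit records diagnostics", {
  st <- tiny_study(seed = 2, n_rows = 6, n_cols = 6, total_cases = 150)
  sir <- compute_expected(st$areas)
  w <- build_weights(st$edges, st$areas$id)
  fit <- fit_bym(sir, w, config = mcmc_config(1500, 500, 2, seed = 9,
                                              thin = 1))
  v <- sirscan:::pool_draws(fit, "v")
  expect_lt(max(abs(rowSums(v))), 1e-10)
  expect_true(all(c("alpha", "tau_u", "tau_v") %in% names(fit$rhat)))
  expect_true(all(fit$rhat > 0))
  expect_true(all(is.finite(unlist(fit$accept))))
  sm <- summarize_posterior(fit)
  expect_true(all(sm$sir_bym > 0))
  expect_true(all(sm$lower <= sm$sir_bym & sm$sir_bym <= sm$upper))
})

test_that("islands and bad expected counts are rejected", {
  tab <- data.frame(id = 1:3, cases = 1:3, expected = c(1, 1, 1))
  wi <- build_weights(cbind(1, 2), 1:3)
  expect_error(fit_bym(tab, wi, config = mcmc_config(100, 10, 2)), "island")
  tab$expected[1] <- 0
  expect_error(fit_bym(tab, build_weights(path_edges(3), 1:3),
                       config = mcmc_config(100, 10, 2)), "expected")
})

test_that("posterior medians follow quantile semantics", {
  fit <- list(chains = list(list(alpha = rep(0, 101),
                                 u = matrix(log(1:101), 101, 1),
                                 v = matrix(0, 101, 1),
                                 tau_u = rep(1, 101), tau_v = rep(1, 101))),
              area_ids = "a", O = 1, E = 1, spatial = TRUE)
  class(fit) <- "bym_fit"
  expect_equal(summarize_posterior(fit)$sir_bym, 51)
})
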