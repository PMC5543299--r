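#' Gamma hyperpriors for the BYM precision parameters
#'
#' Shape/rate gamma priors G(a, b) (mean a/b, variance a/b^2) for the
#' precision of the spatially structured effect (tau_v) and of the
#' unstructured effect (tau_u). Defaults follow the common disease-mapping
#' choice: G(0.5, 0.005) for tau_v (prior mean 100) and G(0.5, 0.5) for
#' tau_u (prior mean 1).
#'
#' @param a_v,b_v shape and rate for tau_v.
#' @param a_u,b_u shape and rate for tau_u.
#' @return list of class `bym_priors`.
#' @export
bym_priors <- function(a_v = 0.5, b_v = 0.005, a_u = 0.5, b_u = 0.5) {
  vals <- c(a_v = a_v, b_v = b_v, a_u = a_u, b_u = b_u)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all hyperparameters must be positive")
  structure(as.list(vals), class = "bym_priors")
}

#' MCMC configuration for the BYM sampler
#'
#' Defaults follow the common full-scale protocol: 100,000 iterations per
#' chain with the first 5,000 discarded as burn-in and 2 parallel chains
#' started from overdispersed initial values. `thin` subsamples the stored
#' draws (all iterations are still run); at full scale a thinning of 10
#' keeps the stored arrays small without affecting the posterior summaries
#' materially.
#'
#' @param n_iter total iterations per chain.
#' @param n_burn burn-in iterations (adaptation happens only here).
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param seed integer seed; chain c uses seed + c.
#' @param thin storage thinning interval.
#' @param adapt_batch iterations per step-size adaptation batch.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 100000L, n_burn = 5000L, n_chains = 2L,
                        seed = 1L, thin = 10L, adapt_batch = 50L) {
  if (n_burn >= n_iter) stop("n_burn must be smaller than n_iter")
  if (n_chains < 1L) stop("need at least one chain")
  if (thin < 1L || adapt_batch < 1L) stop("thin and adapt_batch must be >= 1")
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 thin = as.integer(thin), adapt_batch = as.integer(adapt_batch)),
            class = "mcmc_config")
}

# gamma full-conditional parameters of the precisions: tau_u sees the iid
# normal field, tau_v the ICAR pairwise kernel with rank deficiency k
tau_u_conditional <- function(u, priors) {
  c(shape = priors$a_u + length(u) / 2, rate = priors$b_u + sum(u^2) / 2)
}
tau_v_conditional <- function(v, nbr, k, priors) {
  pair_ss <- sum(vapply(seq_along(v), function(i)
    sum((v[i] - v[nbr[[i]]])^2), numeric(1))) / 2
  c(shape = priors$a_v + (length(v) - k) / 2, rate = priors$b_v + pair_ss / 2)
}

# connected components of the adjacency graph (BFS over the neighbour list)
graph_components <- function(nbr) {
  n <- length(nbr)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      i <- queue[[1L]]; queue <- queue[-1L]
      new <- nbr[[i]][comp[nbr[[i]]] == 0L]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  comp
}

# greedy vertex colouring; vertices in one colour class share no edge, so
# their CAR full conditionals are mutually independent and can be updated
# as one vectorized Metropolis block
greedy_coloring <- function(nbr) {
  n <- length(nbr)
  col <- integer(n)
  for (i in order(-lengths(nbr))) {
    used <- col[nbr[[i]]]
    c0 <- 1L
    while (c0 %in% used) c0 <- c0 + 1L
    col[i] <- c0
  }
  col
}

#' Full conditional of one intrinsic CAR spatial effect
#'
#' Under the intrinsic CAR prior with binary weights, the conditional
#' distribution of v_i given its neighbours is normal with mean equal to the
#' neighbour average and variance 1/(tau_v * m_i) where m_i is the number of
#' neighbours.
#'
#' @param v numeric vector of current spatial effects.
#' @param w a [build_weights()] object.
#' @param tau_v CAR precision (> 0).
#' @param i area index (1-based, in `area_ids` order).
#' @return named numeric vector `c(mean, variance)`.
#' @export
car_conditional <- function(v, w, tau_v, i) {
  stopifnot(inherits(w, "weights_matrix"))
  if (!is.numeric(tau_v) || tau_v <= 0) stop("tau_v must be positive")
  wi <- w$W[i, ]
  m <- sum(wi)
  if (m == 0) stop("area ", w$area_ids[i], " is an island: CAR undefined")
  c(mean = sum(wi * v) / m, variance = 1 / (tau_v * m))
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' R-hat for a scalar parameter sampled on several chains:
#' sqrt(((n-1)/n * W + B/n) / W) with W the mean within-chain sample
#' variance and B = n * variance of the chain means. Values near 1 indicate
#' that the chains have mixed.
#'
#' @param chains list of numeric vectors (one per chain, equal length) or a
#'   matrix with one column per chain.
#' @return the R-hat value.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2L) stop("need at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L || n < 2L) stop("chains must have equal length >= 2")
  W <- mean(vapply(chains, stats::var, numeric(1)))
  if (!is.finite(W) || W == 0) stop("degenerate chains: zero within-chain variance")
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the Besag-York-Mollie convolution model
#'
#' Poisson log-linear model O_i ~ Poisson(E_i * theta_i) with
#' log(theta_i) = alpha + u_i + v_i, where u_i are exchangeable N(0, 1/tau_u)
#' effects, v_i carry an intrinsic CAR prior over the contiguity graph, and
#' the precisions get gamma hyperpriors. Fitting is Metropolis-within-Gibbs:
#' alpha (flat prior) and the latent effects move by adaptive random-walk
#' Metropolis — all u_i as one conditionally independent block and the v_i
#' in graph-colouring blocks — while tau_u and tau_v are drawn from their
#' conjugate gamma full conditionals:
#' tau_u | u ~ G(a_u + I/2, b_u + sum(u^2)/2) and
#' tau_v | v ~ G(a_v + (I-k)/2, b_v + 0.5 * sum over adjacent pairs of
#' (v_i - v_j)^2), k the number of connected components. Each sweep the v
#' field is recentred to sum to zero (per component) with the removed mean
#' absorbed into alpha, fixing the intrinsic CAR level. Step sizes adapt
#' toward ~0.44 acceptance during burn-in only.
#'
#' @param sir_table output of [compute_expected()] (needs `cases`,
#'   `expected`; `id` used for labels).
#' @param w a [build_weights()] object over the same areas; islands are
#'   rejected when `spatial = TRUE`.
#' @param priors a [bym_priors()] object.
#' @param config an [mcmc_config()] object.
#' @param spatial set `FALSE` to fix v at zero (Poisson-lognormal model).
#' @param monitor_theta number of areas (deterministically subsampled) whose
#'   theta draws enter the R-hat table in addition to alpha and the
#'   precisions.
#' @return object of class `bym_fit`: per-chain draws of alpha, tau_u,
#'   tau_v and matrices of u, v; `rhat` table; `accept` rates; the inputs.
#' @export
fit_bym <- function(sir_table, w, priors = bym_priors(), config = mcmc_config(),
                    spatial = TRUE, monitor_theta = 10L) {
  stopifnot(inherits(w, "weights_matrix"), inherits(priors, "bym_priors"),
            inherits(config, "mcmc_config"))
  if (!all(c("cases", "expected") %in% names(sir_table)))
    stop("sir_table must carry cases and expected (run compute_expected first)")
  O <- sir_table$cases
  E <- sir_table$expected
  if (any(E <= 0)) stop("non-positive expected count")
  n <- length(O)
  if (n != length(w$area_ids)) stop("table and weights dimension mismatch")

  nbr <- neighbor_list(w)
  if (spatial && any(lengths(nbr) == 0L))
    stop("island area(s) present: ", paste(w$area_ids[lengths(nbr) == 0L],
                                           collapse = ", "),
         " (CAR prior undefined; drop them or use spatial = FALSE)")
  comp <- graph_components(nbr)
  k <- max(comp)
  col <- greedy_coloring(nbr)
  color_sets <- split(seq_len(n), col)
  mdeg <- lengths(nbr)
  Wsp <- w$W

  chains <- vector("list", config$n_chains)
  accepts <- vector("list", config$n_chains)
  n_keep <- length(seq(config$n_burn + 1L, config$n_iter, by = config$thin))

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    # overdispersed starting points
    alpha <- stats::rnorm(1, 0, 2)
    u <- stats::rnorm(n, 0, 2)
    v <- if (spatial) stats::rnorm(n, 0, 2) else numeric(n)
    if (spatial) for (cc in seq_len(k)) v[comp == cc] <- v[comp == cc] - mean(v[comp == cc])
    tau_u <- 1
    tau_v <- 100
    ls_a <- log(0.1); ls_u <- rep(log(0.5), n); ls_v <- rep(log(0.5), n)
    ls_s <- log(0.1); ls_su <- log(0.1)
    acc_a <- 0; acc_u <- numeric(n); acc_v <- numeric(n)
    acc_s <- 0; acc_su <- 0
    bat_a <- 0; bat_u <- numeric(n); bat_v <- numeric(n)
    bat_s <- 0; bat_su <- 0
    bat_n <- 0L

    a_draw <- tu_draw <- tv_draw <- numeric(n_keep)
    u_draw <- matrix(0, n_keep, n)
    v_draw <- matrix(0, n_keep, n)
    keep_i <- 0L
    sumO <- sum(O)

    for (it in seq_len(config$n_iter)) {
      eta_uv <- u + v
      # alpha | rest : flat prior random-walk Metropolis
      a_prop <- alpha + exp(ls_a) * stats::rnorm(1)
      lr <- sumO * (a_prop - alpha) -
        (exp(a_prop) - exp(alpha)) * sum(E * exp(eta_uv))
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        alpha <- a_prop; acc_a <- acc_a + 1; bat_a <- bat_a + 1
      }

      # u block: conditionally independent scalar updates, vectorized
      lam0 <- E * exp(alpha + v)
      u_prop <- u + exp(ls_u) * stats::rnorm(n)
      lr <- O * (u_prop - u) - lam0 * (exp(u_prop) - exp(u)) -
        tau_u / 2 * (u_prop^2 - u^2)
      ok <- log(stats::runif(n)) < lr
      ok[!is.finite(lr)] <- FALSE
      u[ok] <- u_prop[ok]
      acc_u <- acc_u + ok; bat_u <- bat_u + ok
      # joint ridge move (u, tau_u) -> (c*u, tau_u/c^2): travels along the
      # field-scale/precision ridge the single-site updates cross slowly.
      # Prior and Jacobian terms reduce to the gamma prior ratio times c^-2.
      cs <- exp(exp(ls_su) * stats::rnorm(1))
      tau_u_p <- tau_u / cs^2
      lr <- sum(O * (cs - 1) * u) - sum(lam0 * (exp(cs * u) - exp(u))) +
        priors$a_u * log(tau_u_p / tau_u) - priors$b_u * (tau_u_p - tau_u)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        u <- cs * u
        tau_u <- tau_u_p
        acc_su <- acc_su + 1; bat_su <- bat_su + 1
      }

      # v blocks by graph colouring
      if (spatial) {
        lam0 <- E * exp(alpha + u)
        for (S in color_sets) {
          s_nb <- as.numeric(Wsp[S, , drop = FALSE] %*% v)  # neighbour sums
          vS <- v[S]
          v_prop <- vS + exp(ls_v[S]) * stats::rnorm(length(S))
          lr <- O[S] * (v_prop - vS) - lam0[S] * (exp(v_prop) - exp(vS)) -
            tau_v / 2 * (mdeg[S] * (v_prop^2 - vS^2) - 2 * s_nb * (v_prop - vS))
          ok <- log(stats::runif(length(S))) < lr
          ok[!is.finite(lr)] <- FALSE
          vS[ok] <- v_prop[ok]
          v[S] <- vS
          acc_v[S] <- acc_v[S] + ok; bat_v[S] <- bat_v[S] + ok
        }
        # joint ridge move (v, tau_v) -> (c*v, tau_v/c^2), as for u above;
        # the ICAR kernel and its Jacobian cancel exactly on the
        # sum-to-zero subspace, leaving the gamma prior ratio times c^-2
        cs <- exp(exp(ls_s) * stats::rnorm(1))
        tau_v_p <- tau_v / cs^2
        lr <- sum(O * (cs - 1) * v) -
          sum(E * exp(alpha + u) * (exp(cs * v) - exp(v))) +
          priors$a_v * log(tau_v_p / tau_v) - priors$b_v * (tau_v_p - tau_v)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          v <- cs * v
          tau_v <- tau_v_p
          acc_s <- acc_s + 1; bat_s <- bat_s + 1
        }
        # recentre per component; absorb the (area-weighted) mean into alpha
        shift <- 0
        for (cc in seq_len(k)) {
          idx <- comp == cc
          mu <- mean(v[idx])
          v[idx] <- v[idx] - mu
          shift <- shift + mu * sum(idx)
        }
        alpha <- alpha + shift / n
      }

      # conjugate precision updates
      gu <- tau_u_conditional(u, priors)
      tau_u <- stats::rgamma(1, gu["shape"], rate = gu["rate"])
      if (spatial) {
        gv <- tau_v_conditional(v, nbr, k, priors)
        tau_v <- max(stats::rgamma(1, gv["shape"], rate = gv["rate"]), 1e-12)
      }

      lp <- sum(O * (alpha + u + v) - E * exp(alpha + u + v))
      if (!is.finite(lp))
        stop("divergent chain ", ch, " at iteration ", it,
             ": non-finite log-posterior")

      # step-size adaptation in burn-in batches (frozen afterwards)
      bat_n <- bat_n + 1L
      if (it <= config$n_burn && bat_n == config$adapt_batch) {
        delta <- min(0.25, 1 / sqrt(it / config$adapt_batch))
        ls_a <- ls_a + delta * sign(bat_a / bat_n - 0.44)
        ls_u <- ls_u + delta * sign(bat_u / bat_n - 0.44)
        ls_su <- ls_su + delta * sign(bat_su / bat_n - 0.44)
        if (spatial) {
          ls_v <- ls_v + delta * sign(bat_v / bat_n - 0.44)
          ls_s <- ls_s + delta * sign(bat_s / bat_n - 0.44)
        }
        bat_a <- 0; bat_u[] <- 0; bat_v[] <- 0; bat_s <- 0; bat_su <- 0
        bat_n <- 0L
      } else if (bat_n == config$adapt_batch) {
        bat_n <- 0L; bat_a <- 0; bat_u[] <- 0; bat_v[] <- 0
        bat_s <- 0; bat_su <- 0
      }

      if (it > config$n_burn && (it - config$n_burn - 1L) %% config$thin == 0L) {
        keep_i <- keep_i + 1L
        a_draw[keep_i] <- alpha
        tu_draw[keep_i] <- tau_u
        tv_draw[keep_i] <- tau_v
        u_draw[keep_i, ] <- u
        v_draw[keep_i, ] <- v
      }
    }
    chains[[ch]] <- list(alpha = a_draw, tau_u = tu_draw, tau_v = tv_draw,
                         u = u_draw, v = v_draw)
    accepts[[ch]] <- c(alpha = acc_a / config$n_iter,
                       u = mean(acc_u) / config$n_iter,
                       v = if (spatial) mean(acc_v) / config$n_iter else NA_real_,
                       v_scale = if (spatial) acc_s / config$n_iter else NA_real_)
  }

  rhat <- NULL
  if (config$n_chains >= 2L) {
    rh <- c(alpha = gelman_rubin(lapply(chains, `[[`, "alpha")),
            tau_u = gelman_rubin(lapply(chains, `[[`, "tau_u")))
    if (spatial)
      rh <- c(rh, tau_v = gelman_rubin(lapply(chains, `[[`, "tau_v")))
    mon <- unique(round(seq(1, n, length.out = min(monitor_theta, n))))
    th_rh <- vapply(mon, function(i) {
      gelman_rubin(lapply(chains, function(chn)
        exp(chn$alpha + chn$u[, i] + chn$v[, i])))
    }, numeric(1))
    names(th_rh) <- paste0("theta[", mon, "]")
    rhat <- c(rh, th_rh)
  }

  structure(list(chains = chains, rhat = rhat, accept = accepts,
                 area_ids = sir_table$id, O = O, E = E,
                 spatial = spatial, priors = priors, config = config,
                 n_components = k),
            class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  cat(sprintf("BYM fit: %d areas, %d chain(s) x %d stored draws\n",
              length(x$O), length(x$chains), length(x$chains[[1]]$alpha)))
  if (!is.null(x$rhat)) {
    cat("R-hat (alpha, precisions):\n")
    print(round(x$rhat[seq_len(min(3, length(x$rhat)))], 3))
  }
  invisible(x)
}

# pooled post-burn-in draws of a quantity across chains
pool_draws <- function(fit, what) {
  do.call(if (is.matrix(fit$chains[[1]][[what]])) rbind else c,
          lapply(fit$chains, `[[`, what))
}

#' Pooled draws of the relative-risk surface theta
#'
#' @param fit a [fit_bym()] object.
#' @return matrix, draws x areas, of theta = exp(alpha + u + v).
#' @export
theta_draws <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  a <- pool_draws(fit, "alpha")
  exp(a + pool_draws(fit, "u") + pool_draws(fit, "v"))
}

#' Posterior summaries of the BYM relative risks
#'
#' @param post a [fit_bym()] object with stored draws.
#' @param probs credible-interval probabilities (default central 95%).
#' @return data frame: `id`, `sir_bym` (posterior median of theta_i),
#'   `lower`, `upper`.
#' @export
summarize_posterior <- function(post, probs = c(0.025, 0.975)) {
  stopifnot(inherits(post, "bym_fit"))
  th <- theta_draws(post)
  if (nrow(th) == 0L) stop("no post-burn-in draws stored")
  qs <- apply(th, 2, stats::quantile, probs = probs)
  data.frame(id = post$area_ids,
             sir_bym = apply(th, 2, stats::median),
             lower = qs[1, ], upper = qs[2, ], row.names = NULL)
}
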