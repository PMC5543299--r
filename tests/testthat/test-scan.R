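test_that("window enumeration obeys the population bound, dedupe and nesting", {
  # 4 equal-population collinear areas: four singletons + three pairs
  ar <- compute_expected(area_table(
    data.frame(id = 1:4, x = 0:3, y = 0, pop = 1, cases = c(1, 2, 1, 0))))
  win <- enumerate_windows(ar, max_frac = 0.5)
  keys <- sort(vapply(win$members, function(m) paste(sort(m), collapse = ","),
                      character(1)))
  expect_equal(keys, sort(c("1", "2", "3", "4", "1,2", "2,3", "3,4")))

  # singleton-only regime
  win1 <- enumerate_windows(ar, max_frac = 0.26)
  expect_equal(length(win1$members), 4L)
  expect_true(all(win1$size == 1L))

  # nesting: dropping the farthest member of any window leaves another
  # emitted window (or the empty set)
  st <- tiny_study(seed = 3)
  sir <- compute_expected(st$areas)
  D <- pairwise_distances(sir)
  win <- enumerate_windows(sir, D, 0.15)
  keys <- new.env()
  for (m in win$members) assign(paste(sort(m), collapse = ","), TRUE, keys)
  ok <- TRUE
  for (k in seq_along(win$members)) {
    m <- win$members[[k]]
    if (length(m) == 1L) next
    ctr <- win$center[k]
    # drop the member added last under the (distance, id) growth order
    ord <- m[order(D[ctr, m], sir$id[m])]
    inner <- ord[-length(ord)]
    ok <- ok && exists(paste(sort(inner), collapse = ","), keys)
  }
  expect_true(ok)
  expect_error(enumerate_windows(sir[0, ], D, 0.1), "empty")
  expect_error(enumerate_windows(sir, D, 0.7), "max_frac")
})

test_that("the log likelihood ratio matches direct evaluation and edge cases", {
  expect_equal(poisson_llr(5, 5, 100)$llr, 0)
  r <- poisson_llr(217, 55.37, 3080)
  expect_equal(r$llr, 139.16, tolerance = 1e-4)
  expect_equal(r$direction, "high")
  r0 <- poisson_llr(0, 1, 10)
  expect_equal(r0$llr, 10 * log(10 / 9))
  expect_equal(r0$direction, "low")
  expect_error(poisson_llr(5, 0, 10), "E_c")
  expect_error(poisson_llr(5, 11, 10), "E_c")
})

test_that("llr is invariant to relabeling and joint rescaling", {
  set.seed(17)
  c_ <- rpois(8, 10); E_ <- runif(8, 5, 15); C <- 200
  a <- poisson_llr(c_, E_, C)
  s <- 3.5
  b <- poisson_llr(c_ * s, E_ * s, C * s)
  expect_equal(b$llr, s * a$llr)       # llr is extensive in counts
  perm <- sample(8)
  expect_equal(poisson_llr(c_[perm], E_[perm], C)$llr, a$llr[perm])
})

test_that("optimized scan equals exhaustive brute force on random instances", {
  set.seed(23)
  for (rep in 1:6) {
    n <- 15L
    ar <- compute_expected(area_table(data.frame(
      id = 1:n, x = runif(n), y = runif(n),
      pop = runif(n, 1, 4), cases = rpois(n, 4))))
    D <- pairwise_distances(ar)
    win <- enumerate_windows(ar, D, 0.5)
    obs <- poisson_llr(win$cases, win$expected, win$C)
    got <- c(high = suppressWarnings(max(obs$llr[obs$direction == "high"])),
             low = suppressWarnings(max(obs$llr[obs$direction == "low"])))
    want <- brute_scan_max(ar, D, 0.5)
    for (d in c("high", "low"))
      if (is.finite(want[d])) expect_equal(got[[d]], want[[d]])
  }
})

test_that("Monte Carlo p-values are bounded, deterministic under the seed, and attain 1/(R+1)", {
  st <- tiny_study(seed = 12, implants = list(list(center = 28L,
                                                   n_areas = 4L, rr = 6)))
  sir <- compute_expected(st$areas)
  win <- enumerate_windows(sir, max_frac = 0.2)
  mc1 <- scan_mc_pvalues(win, E_area = sir$expected, R = 99, seed = 7)
  mc2 <- scan_mc_pvalues(win, E_area = sir$expected, R = 99, seed = 7)
  expect_identical(mc1$p, mc2$p)
  expect_true(all(mc1$p >= 1 / 100 & mc1$p <= 1))
  # a strongly implanted cluster should reach the minimum attainable p
  expect_equal(min(mc1$p[mc1$direction == "high"]), 1 / 100)
  expect_error(scan_mc_pvalues(win, E_area = sir$expected, R = 0), "R")
})

test_that("cluster selection ranks by llr with greedy non-overlap", {
  ar <- compute_expected(area_table(data.frame(
    id = 1:6, x = c(0, 1, 10, 11, 20, 21), y = 0, pop = 1,
    cases = c(9, 7, 5, 4, 1, 1))))
  win <- enumerate_windows(ar, max_frac = 1 / 3)
  obs <- poisson_llr(win$cases, win$expected, win$C)
  cl <- select_clusters(win, obs$llr, obs$direction,
                        p = rep(0.01, length(obs$llr)), alpha = 0.05)
  hi <- cl[cl$direction == "high", ]
  # non-overlap within a direction, ranks follow llr order
  mem <- unlist(hi$members)
  expect_equal(anyDuplicated(mem), 0L)
  expect_true(all(diff(hi$llr) <= 0))
  expect_equal(hi$rank, seq_len(nrow(hi)))
  # alpha filter removes everything at alpha = 0
  cl0 <- select_clusters(win, obs$llr, obs$direction,
                         p = rep(0.2, length(obs$llr)), alpha = 0.05)
  expect_equal(nrow(cl0), 0L)
})

test_that("cluster report arithmetic reproduces O/E, RR and rates", {
  cl <- data.frame(cases = c(217, 27), expected = c(55.37, 118.50),
                   pop = c(58039, 124216))
  out <- cluster_table(cl, C = 3080, years = 3, digits = 2)
  expect_equal(out$oe, c(3.92, 0.23))
  expect_equal(out$rr, c(4.14, 0.22))
  # rr = 1 when inside and outside rates agree
  even <- cluster_table(data.frame(cases = 10, expected = 10, pop = 5),
                        C = 100, digits = NULL)
  expect_equal(even$rr, 1)
  expect_error(cluster_table(data.frame(cases = 50, expected = 10, pop = 1),
                             C = 50), "all cases")
})

test_that("the cluster Gini coefficient follows the Lorenz construction", {
  C <- 3080
  expect_equal(cluster_gini(0.5 * C, 0.1 * C, C), 0.4)
  expect_equal(cluster_gini(numeric(0), numeric(0), C), 0)
  # two clusters, hand trapezoid: (0,0)-(.1,.4)-(.3,.6)-(1,1)
  g <- cluster_gini(c(0.4, 0.2) * C, c(0.1, 0.2) * C, C)
  auc <- 0.1 * 0.2 + 0.2 * 0.5 + 0.7 * 0.8
  expect_equal(g, 2 * (auc - 0.5))
})

test_that("Gini selection prefers a maximum size near an implanted tight cluster", {
  st <- tiny_study(seed = 19, n_rows = 12, n_cols = 12, total_cases = 900,
                   implants = list(list(center = 67L, n_areas = 5L, rr = 4)))
  sir <- compute_expected(st$areas)
  share <- sum(sir$n[sir$id %in% st$truth[[1]]]) / sum(sir$n)
  gs <- gini_select(sir, candidate_fracs = c(0.02, 0.05, 0.10, 0.20, 0.35,
                                             0.50),
                    R = 199, seed = 31)
  expect_false(is.na(gs$optimal_frac))
  steps <- gs$profile$frac
  expect_lte(gs$optimal_frac,
             steps[min(which(steps >= share) + 1, length(steps))])
  expect_true(all(gs$profile$gini >= 0 & gs$profile$gini <= 1))
})
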