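test_that("lattice simulation produces queen adjacency and is deterministic", {
  s22 <- simulate_lattice(simulation_spec(2, 2, seed = 1))
  expect_equal(nrow(s22$areas), 4L)
  expect_equal(nrow(s22$edges), 6L)          # 2x2 queen = complete graph

  big <- simulate_lattice(simulation_spec(20, 19, seed = 2))
  expect_equal(nrow(big$areas), 380L)
  w <- build_weights(big$edges, big$areas$id)
  deg <- Matrix::rowSums(w$W)
  interior <- big$areas$x > 1 & big$areas$x < 19 &
    big$areas$y > 1 & big$areas$y < 20
  expect_true(all(deg[interior] == 8))
  expect_true(Matrix::isSymmetric(w$W))
  expect_equal(length(w$islands), 0L)

  a <- simulate_lattice(simulation_spec(5, 5, seed = 9))
  b <- simulate_lattice(simulation_spec(5, 5, seed = 9))
  expect_identical(a, b)
  expect_error(simulation_spec(1, 3), "at least 4")
})

test_that("BYM-generated counts hit the target total and carry spatial signal", {
  # near-degenerate precisions: theta ~ 1, Poisson concentration around total
  spec <- simulation_spec(10, 10, total_cases = 2000, tau_u = 1e6,
                          tau_v = 1e6, implants = NULL, seed = 4)
  ar <- simulate_bym_counts(simulate_lattice(spec), spec)
  expect_lt(abs(sum(ar$cases) - 2000), 3 * sqrt(2000))
  expect_true(all(abs(attr(ar, "theta") - 1) < 0.01))

  # spatially dominated risks show positive Moran's I of log-theta
  pos <- logical(20)
  for (s in 1:20) {
    spec <- simulation_spec(9, 9, tau_u = 100, tau_v = 2, implants = NULL,
                            seed = 100 + s)
    lat <- simulate_lattice(spec)
    ar <- simulate_bym_counts(lat, spec)
    w <- build_weights(lat$edges, ar$id)
    z <- log(attr(ar, "theta"))
    zc <- z - mean(z)
    pos[s] <- (as.numeric(zc %*% (w$W %*% zc)) > 0)
  }
  expect_gte(mean(pos), 0.9)

  spec <- simulation_spec(6, 6, seed = 11, implants = NULL)
  lat <- simulate_lattice(spec)
  expect_identical(simulate_bym_counts(lat, spec),
                   simulate_bym_counts(lat, spec))
})

test_that("implanted clusters scale means by rr and return ground truth", {
  spec <- simulation_spec(10, 10, total_cases = 1500, implants = NULL,
                          seed = 6)
  lat <- simulate_lattice(spec)
  base <- simulate_bym_counts(lat, spec)
  D <- pairwise_distances(base)

  # rr = 1 leaves the distribution unchanged under the same seed
  same <- implant_clusters(base, D, list(list(center = 45L, n_areas = 5L,
                                              rr = 1)), seed = 2)
  set.seed(2)
  expect_equal(same$cases, rpois(nrow(base), attr(base, "lambda")))

  # rr = 4: implanted means are 4x their baseline
  imp <- implant_clusters(base, D, list(list(center = 45L, n_areas = 5L,
                                             rr = 4)), seed = 2)
  tru <- imp$id %in% attr(imp, "truth")[[1]]
  expect_equal(attr(imp, "lambda")[tru], 4 * attr(base, "lambda")[tru])
  expect_equal(attr(imp, "lambda")[!tru], attr(base, "lambda")[!tru])
  # law of large numbers: observed counts track the inflated means
  tot <- replicate(50, {
    sum(implant_clusters(base, D, list(list(center = 45L, n_areas = 5L,
                                            rr = 4)),
                         seed = sample.int(1e6, 1))$cases[tru])
  })
  expect_equal(mean(tot), sum(attr(imp, "lambda")[tru]), tolerance = 0.1)

  expect_error(implant_clusters(base, D,
                                list(list(center = 45L, n_areas = 8L, rr = 2),
                                     list(center = 46L, n_areas = 8L, rr = 2)),
                                seed = 1), "overlap")
})

test_that("the default study profile emulates the intended scale", {
  st <- simulate_study(simulation_spec(seed = 5))
  expect_equal(nrow(st$areas), 374L)
  expect_lt(abs(sum(st$areas$cases) - 3080) / 3080, 0.25)
  expect_equal(length(st$truth), 2L)
  w <- build_weights(st$edges, st$areas$id)
  expect_equal(length(w$islands), 0L)
  # low-rate implant emulates a near-zero O/E regime
  low <- st$areas$id %in% st$truth[[2]]
  sir <- compute_raw_sir(compute_expected(st$areas))
  oe_low <- sum(sir$cases[low]) / sum(sir$expected[low])
  expect_lt(oe_low, 0.3)
})
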