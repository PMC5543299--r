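#' Enumerate circular scan windows
#'
#' For every area taken as a centre, windows grow outward over the
#' centroid-nearest areas (distance ties broken by ascending area id): each
#' cumulative set whose population at risk does not exceed
#' `max_frac * total population` is a candidate window. Windows with
#' identical member sets are emitted once.
#'
#' @param areas an [area_table()] with an `expected` column
#'   (see [compute_expected()]).
#' @param D centroid distance matrix from [pairwise_distances()] (computed
#'   from `areas` when `NULL`).
#' @param max_frac maximum window size as a fraction of the total population
#'   at risk, in (0, 0.5].
#' @return object of class `scan_windows`: parallel vectors `center`,
#'   `radius`, `size`, `pop`, `cases`, `expected`, a list `members` of area
#'   indices, a sparse window-by-area indicator matrix `M`, and the study
#'   totals.
#' @export
enumerate_windows <- function(areas, D = NULL, max_frac = 0.5) {
  if (nrow(areas) == 0L) stop("empty area set")
  if (!("expected" %in% names(areas))) stop("areas must carry expected counts")
  if (max_frac <= 0 || max_frac > 0.5)
    stop("max_frac must lie in (0, 0.5]")
  if (is.null(D)) D <- pairwise_distances(areas)
  n <- nrow(areas)
  thr <- max_frac * sum(areas$n)

  seen <- new.env(hash = TRUE, parent = emptyenv())
  center <- integer(0); radius <- numeric(0)
  members <- list()
  for (i in seq_len(n)) {
    ord <- order(D[i, ], areas$id)        # nearest first, id breaks ties
    cpop <- cumsum(areas$n[ord])
    L <- sum(cpop <= thr)
    if (L == 0L) next
    for (l in seq_len(L)) {
      mem <- ord[seq_len(l)]
      key <- paste(sort(mem), collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      members[[length(members) + 1L]] <- mem
      center <- c(center, i)
      radius <- c(radius, D[i, ord[l]])
    }
  }
  nw <- length(members)
  if (nw == 0L) stop("no window fits under max_frac = ", max_frac)
  M <- Matrix::sparseMatrix(i = rep.int(seq_len(nw), lengths(members)),
                            j = unlist(members), x = 1, dims = c(nw, n))
  structure(list(center = center, radius = radius, size = lengths(members),
                 members = members, M = M,
                 pop = as.numeric(M %*% areas$n),
                 cases = as.numeric(M %*% areas$cases),
                 expected = as.numeric(M %*% areas$expected),
                 C = sum(areas$cases), E_total = sum(areas$expected),
                 total_pop = sum(areas$n), area_ids = areas$id,
                 max_frac = max_frac),
            class = "scan_windows")
}

#' @export
print.scan_windows <- function(x, ...) {
  cat(sprintf("scan_windows: %d windows over %d areas (max_frac %.3g)\n",
              length(x$center), length(x$area_ids), x$max_frac))
  invisible(x)
}

#' Poisson scan log likelihood ratio of a window
#'
#' Log of the likelihood ratio comparing the rate inside a window with the
#' rate outside, for the conditional Poisson model:
#' llr = c log(c / E) + (C - c) log((C - c) / (C - E)), with 0 log 0 = 0.
#' Vectorized over windows.
#'
#' @param c observed cases inside the window(s).
#' @param E_c expected cases inside (0 < E_c < C).
#' @param C total cases in the study area.
#' @return data frame with `llr` (>= 0) and `direction` (`"high"` when
#'   c > E_c, else `"low"`).
#' @export
poisson_llr <- function(c, E_c, C) {
  if (any(E_c <= 0) || any(E_c >= C))
    stop("E_c must lie strictly between 0 and C")
  if (any(c < 0) || any(c > C)) stop("c must lie in [0, C]")
  xlogx <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
  llr <- xlogx(c, E_c) + xlogx(C - c, C - E_c)
  data.frame(llr = pmax(llr, 0), direction = ifelse(c > E_c, "high", "low"),
             stringsAsFactors = FALSE)
}

# replicate max-llr null distributions, one column per (population-fraction
# candidate), separately for high and low windows; conditional on C the
# null redistributes cases multinomially with probabilities E_i / sum(E)
scan_null_maxima <- function(windows, E_area, fracs, R, seed) {
  M <- windows$M
  C <- windows$C
  Ew <- windows$expected
  prob <- E_area / sum(E_area)
  sub <- lapply(fracs, function(f) windows$pop <= f * windows$total_pop)
  set.seed(as.integer(seed))
  max_h <- matrix(-Inf, R, length(fracs))
  max_l <- matrix(-Inf, R, length(fracs))
  for (r in seq_len(R)) {
    Orep <- as.numeric(stats::rmultinom(1, C, prob))
    crep <- as.numeric(M %*% Orep)
    lr <- poisson_llr(crep, Ew, C)
    hi <- lr$direction == "high"
    for (k in seq_along(fracs)) {
      sh <- sub[[k]] & hi
      sl <- sub[[k]] & !hi
      if (any(sh)) max_h[r, k] <- max(lr$llr[sh])
      if (any(sl)) max_l[r, k] <- max(lr$llr[sl])
    }
  }
  list(high = max_h, low = max_l, fracs = fracs, R = R)
}

#' Monte Carlo p-values for scan windows
#'
#' Conditional-on-total Monte Carlo inference: each of `R` replicates
#' redistributes the C cases multinomially over areas with probabilities
#' proportional to the expected counts, rescans the identical window set,
#' and records the replicate maximum llr separately for high- and low-rate
#' windows. A window's p-value is (R_beat + 1) / (R + 1) where R_beat
#' counts replicates whose maximum (in the window's direction) exceeds the
#' window's observed llr.
#'
#' @param windows a [enumerate_windows()] object.
#' @param E_area per-area expected counts (defaults are carried inside
#'   `windows` via the member matrix; pass explicitly to override).
#' @param R number of replicates (>= 1; 999 for publication-scale inference).
#' @param seed integer seed (same seed, windows and R give identical
#'   p-values).
#' @return list: `p` (per window), `llr`, `direction`, and the replicate
#'   maxima `max_high`, `max_low`.
#' @export
scan_mc_pvalues <- function(windows, E_area = NULL, R = 999L, seed = 1L) {
  stopifnot(inherits(windows, "scan_windows"))
  if (R < 1L) stop("R must be >= 1")
  if (is.null(E_area)) {
    # recover per-area E from singleton windows when present, else solve
    E_area <- rep(NA_real_, length(windows$area_ids))
    singles <- which(windows$size == 1L)
    E_area[unlist(windows$members[singles])] <- windows$expected[singles]
    if (anyNA(E_area))
      stop("supply E_area: not all areas appear as singleton windows")
  }
  obs <- poisson_llr(windows$cases, windows$expected, windows$C)
  nulls <- scan_null_maxima(windows, E_area, fracs = windows$max_frac,
                            R = R, seed = seed)
  p <- vapply(seq_along(obs$llr), function(i) {
    ref <- if (obs$direction[i] == "high") nulls$high[, 1] else nulls$low[, 1]
    (sum(ref > obs$llr[i]) + 1) / (R + 1)
  }, numeric(1))
  list(p = p, llr = obs$llr, direction = obs$direction,
       max_high = nulls$high[, 1], max_low = nulls$low[, 1], R = R)
}

#' Rank significant non-overlapping clusters
#'
#' Within each direction, windows are sorted by decreasing llr and kept
#' greedily when they share no area with an already-kept window; windows
#' with p >= alpha are dropped. Ranks 1 (most likely), 2 (secondary),
#' 3 (tertiary), ... are assigned per direction.
#'
#' @param windows a [enumerate_windows()] object.
#' @param llr,direction,p per-window statistics (e.g. from
#'   [scan_mc_pvalues()]).
#' @param alpha significance level (default 0.05).
#' @return data frame of class `scan_clusters`: `rank`, `direction`,
#'   `window` (index into `windows`), `center_id`, `radius`, `n_areas`,
#'   `pop`, `cases`, `expected`, `llr`, `p`, and a `members` list-column of
#'   area ids.
#' @export
select_clusters <- function(windows, llr, direction, p = NULL, alpha = 0.05) {
  stopifnot(inherits(windows, "scan_windows"))
  if (is.null(p)) p <- rep(0, length(llr))
  keep <- integer(0); rank <- integer(0); dirs <- character(0)
  for (d in c("high", "low")) {
    cand <- which(direction == d & p < alpha)
    cand <- cand[order(-llr[cand])]
    used <- logical(length(windows$area_ids))
    rk <- 0L
    for (wdx in cand) {
      mem <- windows$members[[wdx]]
      if (any(used[mem])) next
      used[mem] <- TRUE
      rk <- rk + 1L
      keep <- c(keep, wdx); rank <- c(rank, rk); dirs <- c(dirs, d)
    }
  }
  out <- data.frame(rank = rank, direction = dirs, window = keep,
                    center_id = windows$area_ids[windows$center[keep]],
                    radius = windows$radius[keep],
                    n_areas = windows$size[keep],
                    pop = windows$pop[keep],
                    cases = windows$cases[keep],
                    expected = windows$expected[keep],
                    llr = llr[keep], p = p[keep],
                    stringsAsFactors = FALSE)
  out$members <- lapply(windows$members[keep],
                        function(m) windows$area_ids[m])
  class(out) <- c("scan_clusters", "data.frame")
  out
}

#' Cluster report arithmetic
#'
#' Appends the observed-to-expected ratio, the relative risk comparing the
#' rate inside the cluster with the rate outside
#' (rr = (c/E) / ((C - c)/(C - E))), and the annual rate per 100,000 at
#' risk, rounded to a display precision.
#'
#' @param clusters a [select_clusters()] data frame (or any frame with
#'   `cases`, `expected`, `pop`).
#' @param C total cases in the study area.
#' @param years study duration in years (for the annual rate).
#' @param digits rounding for `oe`/`rr` (`NULL` keeps full precision); the
#'   annual rate rounds to one decimal.
#' @return the input with `oe`, `rr`, `annual_rate` appended.
#' @export
cluster_table <- function(clusters, C, years = 3, digits = 2) {
  c_ <- clusters$cases; E_ <- clusters$expected
  if (any(c_ >= C)) stop("cluster holds all cases: relative risk undefined")
  oe <- c_ / E_
  rr <- oe / ((C - c_) / (C - E_))
  rate <- c_ / (clusters$pop * years) * 1e5
  if (!is.null(digits)) {
    oe <- round(oe, digits); rr <- round(rr, digits); rate <- round(rate, 1)
  }
  clusters$oe <- oe
  clusters$rr <- rr
  clusters$annual_rate <- rate
  clusters
}

#' Gini coefficient of a cluster collection
#'
#' Concentration of observed versus expected cases across a set of
#' non-overlapping clusters: clusters are ordered by decreasing O/E, the
#' Lorenz-type curve accumulates expected-case fraction (x) against
#' observed-case fraction (y) with the non-cluster remainder as the final
#' segment, and the coefficient is twice the area between the curve and the
#' diagonal. Zero clusters give 0.
#'
#' @param cases,expected per-cluster observed and expected counts (possibly
#'   empty).
#' @param C,E_total study totals (E_total defaults to C, the internal-
#'   standardization identity).
#' @return Gini coefficient in \[0, 1\].
#' @export
cluster_gini <- function(cases, expected, C, E_total = C) {
  if (length(cases) == 0L) return(0)
  ord <- order(-(cases / expected))
  x <- c(0, cumsum(expected[ord]) / E_total, 1)
  y <- c(0, cumsum(cases[ord]) / C, 1)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  2 * (auc - 0.5)
}

#' Purely spatial Poisson scan at a fixed maximum window size
#'
#' End-to-end convenience: window enumeration, likelihood-ratio scoring,
#' conditional Monte Carlo inference, and greedy selection of significant
#' non-overlapping clusters in both directions, with report arithmetic.
#'
#' @param areas an [area_table()]; expected counts are computed when absent.
#' @param D optional distance matrix.
#' @inheritParams enumerate_windows
#' @inheritParams scan_mc_pvalues
#' @param alpha significance level for reported clusters.
#' @param years study duration for the annual-rate column.
#' @param digits report rounding (see [cluster_table()]).
#' @return list of class `scan_result`: `clusters` (report table),
#'   `windows`, `mc` (Monte Carlo output), `alpha`.
#' @export
scan_poisson <- function(areas, D = NULL, max_frac = 0.5, R = 999L,
                         seed = 1L, alpha = 0.05, years = 3, digits = 2) {
  if (!("expected" %in% names(areas))) areas <- compute_expected(areas)
  if (is.null(D)) D <- pairwise_distances(areas)
  win <- enumerate_windows(areas, D, max_frac)
  mc <- scan_mc_pvalues(win, E_area = areas$expected, R = R, seed = seed)
  cl <- select_clusters(win, mc$llr, mc$direction, mc$p, alpha)
  cl <- cluster_table(cl, C = win$C, years = years, digits = digits)
  structure(list(clusters = cl, windows = win, mc = mc, alpha = alpha),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d significant cluster(s) at alpha = %g\n",
              nrow(x$clusters), x$alpha))
  if (nrow(x$clusters))
    print(x$clusters[, c("rank", "direction", "n_areas", "pop", "cases",
                         "expected", "oe", "rr", "p")])
  invisible(x)
}

#' Gini-based selection of the maximum scan window size
#'
#' Runs the scan over a ladder of candidate maximum population fractions
#' sharing one set of Monte Carlo replicates (windows are enumerated once at
#' the largest candidate; each candidate restricts to windows within its
#' population bound). For every candidate, the significant non-overlapping
#' high-rate clusters are collected and their [cluster_gini()] computed; the
#' optimum is the candidate with maximal Gini, ties resolved toward the
#' smaller fraction. The default ladder is the conventional one:
#' 0.01-0.05 in steps of 0.01, then 0.06, 0.08, 0.10, 0.12, 0.15, 0.20,
#' 0.25, 0.30, 0.40, 0.50.
#'
#' @inheritParams scan_poisson
#' @param candidate_fracs increasing vector of candidate maximum fractions,
#'   each in (0, 0.5].
#' @return list of class `gini_profile`: `profile` (data frame: frac,
#'   n_clusters, gini), `optimal_frac`, `optimal_gini` (both `NA` when no
#'   candidate yields a significant high-rate cluster), `clusters` — the
#'   full two-direction report at the optimal fraction.
#' @export
gini_select <- function(areas, D = NULL,
                        candidate_fracs = c(0.01, 0.02, 0.03, 0.04, 0.05,
                                            0.06, 0.08, 0.10, 0.12, 0.15,
                                            0.20, 0.25, 0.30, 0.40, 0.50),
                        R = 999L, seed = 1L, alpha = 0.05, years = 3,
                        digits = 2) {
  if (length(candidate_fracs) == 0L ||
      any(candidate_fracs <= 0 | candidate_fracs > 0.5))
    stop("candidate_fracs must be nonempty, each in (0, 0.5]")
  candidate_fracs <- sort(unique(candidate_fracs))
  if (!("expected" %in% names(areas))) areas <- compute_expected(areas)
  if (is.null(D)) D <- pairwise_distances(areas)
  win <- enumerate_windows(areas, D, max(candidate_fracs))
  obs <- poisson_llr(win$cases, win$expected, win$C)
  nulls <- scan_null_maxima(win, areas$expected, candidate_fracs, R, seed)

  select_at <- function(k) {
    f <- candidate_fracs[k]
    sub <- win$pop <= f * win$total_pop
    p <- vapply(seq_along(obs$llr), function(i) {
      if (!sub[i]) return(1)
      ref <- if (obs$direction[i] == "high") nulls$high[, k] else nulls$low[, k]
      (sum(ref > obs$llr[i]) + 1) / (R + 1)
    }, numeric(1))
    llr_m <- ifelse(sub, obs$llr, -Inf)
    select_clusters(win, llr_m, obs$direction, p, alpha)
  }

  gini <- nclus <- numeric(length(candidate_fracs))
  for (k in seq_along(candidate_fracs)) {
    cl <- select_at(k)
    hi <- cl[cl$direction == "high", , drop = FALSE]
    nclus[k] <- nrow(hi)
    gini[k] <- cluster_gini(hi$cases, hi$expected, win$C, win$E_total)
  }
  profile <- data.frame(frac = candidate_fracs, n_clusters = nclus,
                        gini = gini)
  if (all(nclus == 0)) {
    opt_f <- NA_real_; opt_g <- NA_real_; cl_opt <- select_at(1L)
  } else {
    kopt <- which(gini == max(gini))[1L]        # ties: smaller fraction
    opt_f <- candidate_fracs[kopt]; opt_g <- gini[kopt]
    cl_opt <- select_at(kopt)
  }
  cl_opt <- cluster_table(cl_opt, C = win$C, years = years, digits = digits)
  structure(list(profile = profile, optimal_frac = opt_f,
                 optimal_gini = opt_g, clusters = cl_opt, alpha = alpha,
                 R = R),
            class = "gini_profile")
}

#' @export
print.gini_profile <- function(x, ...) {
  cat("Gini profile over candidate maximum cluster sizes:\n")
  print(x$profile)
  if (is.na(x$optimal_frac)) {
    cat("no significant high-rate cluster at any candidate size\n")
  } else {
    cat(sprintf("optimal maximum size: %.3g of population (Gini %.3f)\n",
                x$optimal_frac, x$optimal_gini))
  }
  invisible(x)
}
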