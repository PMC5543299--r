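#' Validate and normalize an area table
#'
#' The universal input of the pipeline: one row per small area with an
#' identifier, planar centroid, the female population at risk `n` and the
#' observed case count `cases`. When two census population columns
#' (`pop2006`, `pop2011`) are supplied the population at risk is their
#' arithmetic mean; a single `pop` column is used as-is. Areas with zero
#' population are dropped with a warning (their SIR is undefined).
#'
#' @param df data frame with columns `id`, `x`, `y`, `cases`, and one of:
#'   `pop`, the pair `pop2006`/`pop2011`, or an already-normalized `n`.
#' @return data frame of class `area_table` with columns
#'   `id, x, y, n, cases`.
#' @export
area_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("id", "x", "y", "cases")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("area table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate area id(s)")
  if ("pop" %in% names(df)) {
    n <- as.numeric(df$pop)
  } else if (all(c("pop2006", "pop2011") %in% names(df))) {
    n <- (as.numeric(df$pop2006) + as.numeric(df$pop2011)) / 2
  } else if ("n" %in% names(df)) {       # already-normalized table
    n <- as.numeric(df$n)
  } else {
    stop("area table missing column(s): pop (or pop2006 and pop2011)")
  }
  if (any(!is.finite(n)) || any(n < 0)) stop("invalid population values")
  cases <- as.numeric(df$cases)
  if (any(!is.finite(cases)) || any(cases < 0))
    stop("cases must be nonnegative")
  out <- data.frame(id = df$id, x = as.numeric(df$x), y = as.numeric(df$y),
                    n = n, cases = cases, stringsAsFactors = FALSE)
  if (any(n == 0)) {
    warning(sum(n == 0), " area(s) with zero population dropped")
    out <- out[n > 0, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("area_table", "data.frame")
  out
}

#' Expected counts by internal standardization
#'
#' E_i = n_i * (sum of observed cases / total population at risk), so the
#' study population is its own reference and sum(E) equals sum(O) by
#' construction.
#'
#' @param areas an [area_table()] (or data frame with `n` and `cases`).
#' @return the input with an `expected` column appended.
#' @export
compute_expected <- function(areas) {
  if (!all(c("n", "cases") %in% names(areas)))
    stop("areas must carry columns n and cases")
  if (any(areas$n <= 0)) stop("population at risk must be positive")
  total_n <- sum(areas$n)
  total_o <- sum(areas$cases)
  if (total_n <= 0) stop("zero total population")
  if (total_o <= 0) stop("no observed cases: crude rate undefined")
  areas$expected <- areas$n * (total_o / total_n)
  areas
}

#' Raw standardized incidence ratios
#'
#' SIR_i = O_i / E_i on the table produced by [compute_expected()].
#'
#' @param sir_table data frame with `cases` and `expected` columns.
#' @return the input with a `sir` column appended.
#' @export
compute_raw_sir <- function(sir_table) {
  if (!all(c("cases", "expected") %in% names(sir_table)))
    stop("table must carry columns cases and expected")
  if (any(sir_table$expected <= 0))
    stop("expected count must be positive for every analyzed area")
  sir_table$sir <- sir_table$cases / sir_table$expected
  sir_table
}

#' Moran's I with permutation inference
#'
#' Global spatial autocorrelation of `x` under the weights `w`:
#' I = (N/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2 with z = x - mean(x) and
#' S0 the sum of all weights. Inference is by random permutation of the
#' values over the areas; the two-sided p-value compares distances from the
#' closed-form null expectation E[I] = -1/(N-1).
#'
#' @param x numeric vector of per-area values (counts, rates or SIRs).
#' @param w a [build_weights()] object (binary weights by default).
#' @param n_perm number of permutations (conventional default 999).
#' @param seed integer seed for the permutation stream.
#' @param row_standardize divide each row of W by its row sum first.
#' @return list of class `moran_result`: `I`, `E_I`, `p_perm`, `n_perm`,
#'   `perm` (the permuted statistics).
#' @export
morans_i <- function(x, w, n_perm = 999L, seed = 1L, row_standardize = FALSE) {
  stopifnot(inherits(w, "weights_matrix"))
  n <- length(x)
  if (n != length(w$area_ids)) stop("length(x) must match the weights matrix")
  if (n < 3L) stop("need at least 3 areas")
  if (!is.finite(stats::var(x)) || stats::var(x) == 0)
    stop("x is constant: Moran's I undefined")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  W <- w$W
  if (row_standardize) {
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  s0 <- sum(W)
  if (s0 <= 0) stop("weights matrix has no links")
  stat <- function(z) {
    zc <- z - mean(z)
    (n / s0) * as.numeric(zc %*% (W %*% zc)) / sum(zc^2)
  }
  I_obs <- stat(x)
  E_I <- -1 / (n - 1)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(x)), numeric(1))
  p <- (sum(abs(perm - E_I) >= abs(I_obs - E_I)) + 1) / (n_perm + 1)
  structure(list(I = I_obs, E_I = E_I, p_perm = p,
                 n_perm = as.integer(n_perm), perm = perm),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), permutation p = %.4g (%d perms)\n",
              x$I, x$E_I, x$p_perm, x$n_perm))
  invisible(x)
}
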