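#' Binomial-product likelihood of a presence table
#'
#' Likelihood of observing the contingency counts given the presence
#' probabilities `pc` (control) and `pl` (lesion): the product of two
#' binomial probability mass functions,
#' \deqn{P(D \mid P_C, P_L) = \binom{CR}{CS} P_C^{CS} (1-P_C)^{CR-CS}
#'   \binom{LR}{LS} P_L^{LS} (1-P_L)^{LR-LS}.}
#' Evaluated in log space with the convention \eqn{0^0 = 1}, so the
#' boundary values `pc`/`pl` of 0 or 1 are exact. Vectorised over `pc`
#' and `pl` (recycled to a common length).
#'
#' @param table A [contingency_table()].
#' @param pc,pl Presence probabilities in `[0, 1]`.
#' @param log Return the log likelihood?
#' @return Numeric likelihood (or log likelihood) values.
#' @export
presence_likelihood <- function(table, pc, pl, log = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  if (any(pc < 0 | pc > 1) || any(pl < 0 | pl > 1))
    stop("pc and pl must lie in [0, 1]")
  ll <- log_binom_term(table$control_with, table$control_total, pc) +
    log_binom_term(table$lesion_with, table$lesion_total, pl)
  if (log) ll else exp(ll)
}

# log C(n, k) + k log p + (n - k) log(1 - p) with 0 log 0 = 0.
log_binom_term <- function(k, n, p) {
  t1 <- if (k == 0) 0 else k * log(p)
  t2 <- if (n - k == 0) 0 else (n - k) * log1p(-p)
  lchoose(n, k) + t1 + t2
}

#' Posterior over the two presence probabilities
#'
#' Posterior distribution of `(PC, PL)` under a uniform prior on the unit
#' square and the binomial-product likelihood, evaluated on a midpoint
#' grid and normalised to total mass 1 (the evidence is the normalising
#' constant). With a uniform prior the two marginals are conjugate Beta
#' distributions, which the grid approximation converges to as the
#' resolution grows.
#'
#' @param table A [contingency_table()].
#' @param resolution Grid points per axis (default 1001, midpoint rule).
#' @return An object of class `posterior_grid`: `p` (midpoint abscissae),
#'   `density` (resolution x resolution matrix of posterior mass, rows =
#'   PC, columns = PL), `resolution`, `log_normalizer` (log of the summed
#'   unnormalised mass; the evidence up to the grid cell area).
#' @export
presence_posterior <- function(table, resolution = 1001) {
  stopifnot(inherits(table, "contingency_table"), resolution >= 2)
  p <- (seq_len(resolution) - 0.5) / resolution
  la <- log_binom_term(table$control_with, table$control_total, p)
  lb <- log_binom_term(table$lesion_with, table$lesion_total, p)
  lm <- outer(la, lb, "+")
  mx <- max(lm)
  m <- exp(lm - mx)
  s <- sum(m)
  structure(list(p = p, density = m / s, resolution = resolution,
                 log_normalizer = mx + log(s)),
            class = "posterior_grid")
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat(sprintf("<posterior_grid: %d x %d midpoint grid over (PC, PL)>\n",
              x$resolution, x$resolution))
  invisible(x)
}

#' Posterior probability that PC exceeds a multiple of PL
#'
#' Sums posterior mass over the region `PC > k * PL`. Grid points lying
#' exactly on the boundary `PC = k * PL` contribute half their mass,
#' which removes resolution-parity artifacts (e.g. the diagonal at
#' `k = 1`).
#'
#' @param post A [presence_posterior()] result.
#' @param k Non-negative multiplier (default 1).
#' @return Probability in `[0, 1]`.
#' @export
prob_greater <- function(post, k = 1) {
  stopifnot(inherits(post, "posterior_grid"))
  if (k < 0) stop("k must be non-negative")
  d <- outer(post$p, k * post$p, "-")
  tol <- 1e-10
  ind <- (d > tol) + 0.5 * (abs(d) <= tol)
  sum(post$density * ind)
}

#' Wald statistic for a difference in proportions
#'
#' \eqn{(p_1 - p_2) / \sqrt{p_1(1-p_1)/CR + p_2(1-p_2)/LR}} with
#' \eqn{p_1 = CS/CR} and \eqn{p_2 = LS/LR}. Cells with zero variance
#' (a proportion of exactly 0 or 1) contribute 0 to the standard error;
#' when both proportions are degenerate and equal the statistic is 0 by
#' convention, and `Inf` (signed) when they are degenerate but unequal.
#'
#' @param table A [contingency_table()].
#' @return The Wald statistic, with attribute `diff_proportion`
#'   (`p1 - p2`).
#' @export
wald_statistic <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$control_total == 0 || table$lesion_total == 0)
    stop("both conditions need at least one recording")
  w <- wald_stat_num(table$control_with, table$control_total,
                     table$lesion_with, table$lesion_total)
  attr(w, "diff_proportion") <-
    table$control_with / table$control_total -
    table$lesion_with / table$lesion_total
  w
}

# Vectorised Wald statistic on raw counts.
wald_stat_num <- function(cs, cr, ls, lr) {
  p1 <- cs / cr
  p2 <- ls / lr
  d <- p1 - p2
  se <- sqrt(p1 * (1 - p1) / cr + p2 * (1 - p2) / lr)
  out <- d / se
  deg <- se == 0
  out[deg] <- ifelse(d[deg] == 0, 0, sign(d[deg]) * Inf)
  out
}

#' Barnard's unconditional exact test
#'
#' Two-sided unconditional exact test of equal presence probabilities in
#' the two conditions, ordering outcomes by the absolute Wald statistic.
#' Every possible table with the observed group sizes is enumerated; for
#' each value of the common nuisance proportion on a uniform open-interval
#' grid, the probability of all tables at least as extreme as the observed
#' one is accumulated, and the p value is the maximum over the nuisance
#' grid.
#'
#' @param table A [contingency_table()].
#' @param nuisance_grid Number of nuisance-proportion grid points
#'   (midpoints of `(0, 1)`, endpoints excluded; default 2001).
#' @return An object of class `barnard_result`: `wald`,
#'   `diff_proportion`, `p_two_sided`, `nuisance_at_max`.
#' @export
barnard_test <- function(table, nuisance_grid = 2001) {
  stopifnot(inherits(table, "contingency_table"))
  cr <- table$control_total
  lr <- table$lesion_total
  cs <- 0:cr
  ls <- 0:lr
  w <- outer(cs, ls, function(a, b) wald_stat_num(a, cr, b, lr))
  wobs <- w[table$control_with + 1L, table$lesion_with + 1L]
  extreme <- (abs(w) >= abs(wobs) - 1e-12) + 0
  pi_grid <- (seq_len(nuisance_grid) - 0.5) / nuisance_grid
  a <- outer(cs, pi_grid, function(k, p) stats::dbinom(k, cr, p))
  b <- outer(ls, pi_grid, function(k, p) stats::dbinom(k, lr, p))
  tail_p <- colSums(a * (extreme %*% b))
  structure(list(wald = wobs,
                 diff_proportion = table$control_with / cr -
                   table$lesion_with / lr,
                 p_two_sided = min(1, max(tail_p)),
                 nuisance_at_max = pi_grid[which.max(tail_p)]),
            class = "barnard_result")
}

#' @export
print.barnard_result <- function(x, ...) {
  cat(sprintf(paste0("<barnard: Wald %.3f, diff in proportion %.4f, ",
                     "two-sided p %.4g>\n"),
              x$wald, x$diff_proportion, x$p_two_sided))
  invisible(x)
}
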