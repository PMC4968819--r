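# Monte-Carlo validation of the analytic coverage model: simulate the
# circular-arc process directly and compare empirical gap-count frequencies
# with the series values.

#' Simulate gap counts under the circular coverage model
#'
#' Runs the coverage model forward: in each trial every one of the \eqn{R}
#' community reads lands on the target with probability \eqn{\alpha};
#' on-target reads become arcs of length \eqn{l} at uniform real-valued
#' start positions on a circle of circumference \eqn{L}, and \eqn{B} is the
#' number of maximal uncovered intervals after merging overlapping arcs
#' (wrap-around included; a zero-length gap where two arcs exactly touch
#' counts as covered). A trial with no on-target read has \eqn{B = 0}: a
#' null assembly has no gaps.
#'
#' @param query A [coverage_query()].
#' @param trials Number of Monte-Carlo trials.
#' @param seed Integer seed.
#' @return An object of class `"gap_count_sample"`: the `query`, `trials`,
#'   `seed`, and `counts`, a named integer vector mapping each observed gap
#'   count `k` to its number of occurrences.
#' @examples
#' s <- simulate_gap_counts(coverage_query(2, 60, 100, 1), 1e4, seed = 1)
#' s$counts / s$trials  # close to (0.2, 0.8)
#' @export
simulate_gap_counts <- function(query, trials, seed = NULL) {
  stopifnot(inherits(query, "coverage_query"))
  if (!is.finite(trials) || trials < 1 || trials != floor(trials))
    stop("trials must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  b <- .gap_count_trials(as.integer(query$reads), query$read_length,
                         query$genome_length, query$abundance,
                         as.integer(trials))
  counts <- table(factor(b, levels = 0:max(b)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(query = query, trials = as.integer(trials),
                 counts = counts, seed = seed),
            class = "gap_count_sample")
}

#' Count coverage gaps for explicit arc start positions
#'
#' Deterministic companion to [simulate_gap_counts()]: places arcs of length
#' `l` at the given start positions (reduced modulo `L` onto the circle) and
#' returns the number of maximal uncovered intervals. Rotation-invariant by
#' construction.
#'
#' @param starts Numeric vector of arc start positions.
#' @param l Arc length.
#' @param L Circle circumference.
#' @return Integer gap count.
#' @export
gap_count <- function(starts, l, L) {
  stopifnot(is.numeric(starts), l > 0, L > 0)
  .gap_count_starts(starts %% L, l, L)
}

#' Empirical gap-count frequencies
#'
#' @param sample A [simulate_gap_counts()] result.
#' @param k_max Report frequencies for `k = 0..k_max`.
#' @return Named numeric vector of empirical frequencies.
#' @export
empirical_gap_probs <- function(sample, k_max = NULL) {
  stopifnot(inherits(sample, "gap_count_sample"))
  if (is.null(k_max)) k_max <- max(as.integer(names(sample$counts)))
  freq <- stats::setNames(numeric(k_max + 1L), as.character(0:k_max))
  present <- intersect(names(sample$counts), names(freq))
  freq[present] <- sample$counts[present] / sample$trials
  freq
}

#' Validate the analytic series against the Monte-Carlo oracle
#'
#' Compares [gap_distribution()] with empirical gap-count frequencies over
#' a grid of design points. A cell/k combination passes when the analytic
#' probability lies within `sigma` binomial standard errors
#' \eqn{\sqrt{\hat p (1-\hat p)/\mathrm{trials}}} of the empirical
#' frequency.
#'
#' @param reads,phi,abundance Grid values (all combinations are tested).
#'   Defaults form the standard 45-cell validation grid.
#' @param genome_length Circle circumference used for the simulation (the
#'   model only depends on `phi`, so this is a scale choice).
#' @param trials Trials per grid cell.
#' @param k_max Largest gap count compared.
#' @param sigma Width of the agreement band in binomial standard errors.
#' @param seed Integer seed.
#' @return A data frame with one row per (cell, k): analytic and empirical
#'   probabilities, the tolerance, and a logical `pass`.
#' @export
mc_validate <- function(reads = c(1, 2, 3, 5, 10),
                        phi = c(0.3, 0.6, 0.9),
                        abundance = c(0.25, 0.5, 1.0),
                        genome_length = 1000, trials = 2e5, k_max = 3,
                        sigma = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(reads = reads, phi = phi, abundance = abundance,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    q <- coverage_query(g$reads, g$phi * genome_length, genome_length,
                        g$abundance)
    kk <- 0:min(k_max, g$reads)
    analytic <- vapply(kk, function(k) gap_probability(q, k), numeric(1))
    s <- simulate_gap_counts(q, trials)
    emp <- empirical_gap_probs(s, k_max = min(k_max, g$reads))
    # floor p-hat at one observed count so a true probability below the
    # Monte-Carlo resolution is not compared against a zero-width band
    p_floor <- 1 / trials
    tol <- sigma *
      sqrt(pmax(emp * (1 - emp), p_floor * (1 - p_floor)) / trials)
    rows[[i]] <- data.frame(
      reads = g$reads, phi = g$phi, abundance = g$abundance, k = kk,
      analytic = analytic, empirical = as.numeric(emp), tolerance = tol,
      pass = abs(analytic - as.numeric(emp)) <= tol)
  }
  do.call(rbind, rows)
}
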