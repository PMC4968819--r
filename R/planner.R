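# Iterative sequencing-run planner: keep adding runs until the rarest
# target genome reaches the requested full-coverage probability.

#' Plan the number of sequencing runs for a target coverage probability
#'
#' Given a sequencing profile (read count per run and mean read length) and
#' the rarest community member of interest (abundance and genome length),
#' evaluates the full-coverage probability after 1, 2, ... cumulative runs —
#' runs are additive in reads, so run \eqn{n} is evaluated at
#' \eqn{R = n \cdot \mathrm{reads\_per\_run}} — and stops at the first
#' \eqn{n} whose probability reaches `threshold`. At most 10 runs are
#' considered; if the threshold is still out of reach all 10 probabilities
#' are reported with `runs_needed = NA`.
#'
#' @param profile A [sequencing_profile()] supplying `reads_per_run` and
#'   `length_mean`, or `NULL` if `reads_per_run` and `read_length` are given
#'   directly.
#' @param abundance Relative abundance of the (rarest) target, in (0, 1].
#' @param genome_length Target genome length in bases.
#' @param threshold Required full-coverage probability, in (0, 1).
#'   Default 0.95.
#' @param reads_per_run,read_length Direct overrides used when no profile is
#'   supplied (e.g. from command-line flags).
#' @param max_runs Run cap (default 10).
#' @return An object of class `"run_plan"`: `per_run_probabilities` (length
#'   `runs_needed` when reached, `max_runs` when not), `runs_needed`
#'   (integer or `NA` when the threshold is not reached), plus the inputs.
#' @examples
#' p <- plan_runs(reads_per_run = 2, read_length = 60,
#'                genome_length = 100, abundance = 1, threshold = 0.15)
#' p$runs_needed  # 1 (P after one run = 0.2)
#' @export
plan_runs <- function(profile = NULL, abundance, genome_length,
                      threshold = 0.95, reads_per_run = NULL,
                      read_length = NULL, max_runs = 10L) {
  if (!is.null(profile)) {
    if (!inherits(profile, "sequencing_profile"))
      stop("profile must be a sequencing_profile (or NULL)")
    reads_per_run <- profile$reads_per_run
    read_length <- profile$length_mean
  }
  if (is.null(reads_per_run) || is.null(read_length))
    stop("either a profile or both reads_per_run and read_length are required")
  if (!is.finite(reads_per_run) || reads_per_run < 1 ||
      reads_per_run != floor(reads_per_run))
    stop("reads_per_run must be a positive integer")
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  if (!is.finite(abundance) || abundance <= 0 || abundance > 1)
    stop("abundance must lie in (0, 1]")

  probs <- numeric(0)
  runs_needed <- NA_integer_
  for (n in seq_len(max_runs)) {
    q <- coverage_query(n * reads_per_run, read_length, genome_length,
                        abundance)
    probs[n] <- full_coverage_probability(q)
    if (probs[n] >= threshold) {
      runs_needed <- n
      break
    }
  }
  structure(
    list(reads_per_run = reads_per_run, read_length = read_length,
         genome_length = genome_length, abundance = abundance,
         threshold = threshold, per_run_probabilities = probs,
         runs_needed = runs_needed),
    class = "run_plan")
}

#' @export
print.run_plan <- function(x, ...) {
  cat(sprintf(
    "Sequencing run plan: %g reads/run of %g nt, target genome %g nt at abundance %g\n",
    x$reads_per_run, x$read_length, x$genome_length, x$abundance))
  cat(sprintf("Required full-coverage probability: %g\n", x$threshold))
  for (i in seq_along(x$per_run_probabilities))
    cat(sprintf("  after %2d run%s: P(full coverage) = %.6f\n",
                i, if (i == 1) " " else "s", x$per_run_probabilities[i]))
  if (is.na(x$runs_needed)) {
    cat("Threshold not reached within 10 runs.\n")
  } else {
    cat(sprintf("Runs needed: %d\n", x$runs_needed))
  }
  invisible(x)
}

#' @export
as.data.frame.run_plan <- function(x, ...) {
  data.frame(run = seq_along(x$per_run_probabilities),
             cumulative_reads = seq_along(x$per_run_probabilities) *
               x$reads_per_run,
             full_coverage_probability = x$per_run_probabilities)
}
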