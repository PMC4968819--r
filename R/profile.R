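# Statistical sequencing profiles: read count, read-length mean/SD, and
# per-position error probabilities, inferred from FASTQ or supplied as
# editable platform presets.

#' Construct a sequencing profile
#'
#' A profile is a deliberately simple statistical summary of one sequencing
#' run: how many reads it yields, the mean and standard deviation of the
#' read lengths, and the mean error probability at every read position up
#' to the maximum observed length. It drives both the run planner (read
#' count and mean length) and the read simulator (lengths and errors).
#'
#' @param name Profile name.
#' @param reads_per_run Positive integer, reads produced by one run.
#' @param length_mean Positive real, mean read length (bases); must not
#'   exceed `max_length`.
#' @param length_sd Non-negative real, SD of read length (bases).
#' @param max_length Positive integer, maximum read length (bases).
#' @param per_position_error Numeric vector of length `max_length` with
#'   values in (0, 1]: error probability at each read position.
#' @return An object of class `"sequencing_profile"`.
#' @export
sequencing_profile <- function(name, reads_per_run, length_mean, length_sd,
                               max_length, per_position_error) {
  p <- structure(
    list(name = as.character(name),
         reads_per_run = as.numeric(reads_per_run),
         length_mean = as.numeric(length_mean),
         length_sd = as.numeric(length_sd),
         max_length = as.numeric(max_length),
         per_position_error = as.numeric(per_position_error)),
    class = "sequencing_profile")
  validate_profile(p)
}

validate_profile <- function(p, context = "sequencing profile") {
  fail <- function(field, why)
    stop(sprintf("invalid %s: field '%s' %s", context, field, why))
  if (length(p$name) != 1L || is.na(p$name) || !nzchar(p$name))
    fail("name", "must be a non-empty string")
  if (length(p$reads_per_run) != 1L || !is.finite(p$reads_per_run) ||
      p$reads_per_run < 1 || p$reads_per_run != floor(p$reads_per_run))
    fail("reads_per_run", "must be a positive integer")
  if (length(p$max_length) != 1L || !is.finite(p$max_length) ||
      p$max_length < 1 || p$max_length != floor(p$max_length))
    fail("max_length", "must be a positive integer")
  if (length(p$length_mean) != 1L || !is.finite(p$length_mean) ||
      p$length_mean <= 0 || p$length_mean > p$max_length)
    fail("length_mean", "must be positive and at most max_length")
  if (length(p$length_sd) != 1L || !is.finite(p$length_sd) || p$length_sd < 0)
    fail("length_sd", "must be non-negative")
  if (length(p$per_position_error) != p$max_length)
    fail("per_position_error", "must have length max_length")
  if (!all(is.finite(p$per_position_error)) ||
      any(p$per_position_error <= 0) || any(p$per_position_error > 1))
    fail("per_position_error", "values must lie in (0, 1]")
  p
}

#' @export
print.sequencing_profile <- function(x, ...) {
  cat(sprintf(
    "<sequencing_profile> %s: %g reads/run, length %.1f +/- %.1f nt (max %g), mean error %.2g\n",
    x$name, x$reads_per_run, x$length_mean, x$length_sd, x$max_length,
    mean(x$per_position_error)))
  invisible(x)
}

# Structural check of a 4-line-record FASTQ before it reaches the parser:
# the parser tolerates quality strings whose length disagrees with the
# sequence, which must instead be rejected.
validate_fastq_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  while (length(lines) > 0L && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: expected four-line records")
  if (length(lines) == 0L) return(invisible(TRUE))
  heads <- lines[seq(1L, length(lines), by = 4L)]
  seps <- lines[seq(3L, length(lines), by = 4L)]
  if (!all(startsWith(heads, "@")) || !all(startsWith(seps, "+")))
    stop("malformed FASTQ: record headers must start with '@' and '+'")
  seq_len_ <- nchar(lines[seq(2L, length(lines), by = 4L)])
  qual_len <- nchar(lines[seq(4L, length(lines), by = 4L)])
  if (any(seq_len_ != qual_len))
    stop("malformed FASTQ: quality string length differs from ",
         "sequence length for at least one read")
  invisible(TRUE)
}

# Parse one FASTQ quality string (Sanger, phred+33) into error probabilities.
phred_error_probs <- function(qual_string) {
  codes <- utf8ToInt(qual_string)
  if (any(codes < 33L) || any(codes > 126L))
    stop("quality string contains characters outside the Sanger phred+33 ",
         "range '!'..'~'")
  10^(-(codes - 33L) / 10)
}

#' Infer a sequencing profile from FASTQ data
#'
#' Summarises a FASTQ file (Sanger, phred+33) into a [sequencing_profile()]:
#' the read count, the sample mean and SD of the read lengths, and at each
#' position the mean phred-implied error probability
#' \eqn{10^{-Q/10}} over the reads long enough to reach that position.
#' Averaging probabilities (rather than quality codes) keeps the profile on
#' the scale the simulator consumes.
#'
#' Read order does not affect the result.
#'
#' @param fastq Path to a FASTQ file, or a character vector of FASTQ lines.
#' @param name Name for the resulting profile (default: the file name).
#' @return A [sequencing_profile()].
#' @export
infer_profile <- function(fastq, name = NULL) {
  if (length(fastq) == 1L && file.exists(fastq)) {
    path <- fastq
    if (is.null(name)) name <- sub("\\.(fastq|fq)$", "", basename(path))
  } else {
    path <- tempfile(fileext = ".fastq")
    on.exit(unlink(path), add = TRUE)
    writeLines(fastq, path)
    if (is.null(name)) name <- "inferred"
  }
  validate_fastq_structure(path)
  reads <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
  if (length(reads) == 0L)
    stop("cannot infer a profile from an empty FASTQ input")
  lens <- Biostrings::width(reads)
  quals <- as.character(S4Vectors::mcols(reads)$qualities)

  max_len <- max(lens)
  err_sum <- numeric(max_len)
  n_at <- numeric(max_len)
  for (i in seq_along(quals)) {
    p <- phred_error_probs(quals[[i]])
    idx <- seq_along(p)
    err_sum[idx] <- err_sum[idx] + p
    n_at[idx] <- n_at[idx] + 1
  }
  sequencing_profile(
    name = name,
    reads_per_run = length(reads),
    length_mean = mean(lens),
    length_sd = if (length(lens) > 1L) sd(lens) else 0,
    max_length = max_len,
    per_position_error = err_sum / n_at)
}

#' Save a sequencing profile to JSON
#'
#' Profiles are stored as flat, human-editable JSON; error probabilities are
#' written at full precision so that [load_profile()] reproduces every field
#' exactly.
#'
#' @param profile A [sequencing_profile()].
#' @param destination Path to write.
#' @return `destination`, invisibly.
#' @export
save_profile <- function(profile, destination) {
  validate_profile(profile)
  # %.17g guarantees binary-exact roundtrip of doubles, which jsonlite's
  # own numeric formatting (15 significant digits) does not
  num <- function(x)
    structure(if (length(x) == 1L) sprintf("%.17g", x)
              else paste0("[", paste(sprintf("%.17g", x), collapse = ","),
                          "]"),
              class = "json")
  obj <- list(name = profile$name,
              reads_per_run = num(profile$reads_per_run),
              length_mean = num(profile$length_mean),
              length_sd = num(profile$length_sd),
              max_length = num(profile$max_length),
              per_position_error = num(profile$per_position_error))
  jsonlite::write_json(obj, destination, auto_unbox = TRUE, pretty = TRUE,
                       json_verbatim = TRUE)
  invisible(destination)
}

#' Load a sequencing profile from JSON
#'
#' @param source Path to a JSON file written by [save_profile()] (or edited
#'   by hand).
#' @return A [sequencing_profile()]; malformed files raise a parse error
#'   naming the offending field.
#' @export
load_profile <- function(source) {
  raw <- tryCatch(jsonlite::read_json(source, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse profile file '", source, "': ",
                         conditionMessage(e)))
  required <- c("name", "reads_per_run", "length_mean", "length_sd",
                "max_length", "per_position_error")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L)
    stop("profile file '", source, "' is missing field(s): ",
         paste(missing, collapse = ", "))
  p <- structure(raw[required], class = "sequencing_profile")
  for (f in setdiff(required, "name")) p[[f]] <- as.numeric(p[[f]])
  validate_profile(p, context = paste0("profile file '", source, "'"))
}

# Log-spaced error ramp from `from` at the first cycle to `to` at the last;
# the usual shape of per-cycle substitution error on short-read platforms.
error_ramp <- function(n, from, to) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Built-in platform profiles
#'
#' Editable starting-point profiles for seven sequencing platforms:
#' IonTorrent, IonProton, Illumina MiSeq, Illumina HiSeq, Illumina NextSeq,
#' PacBio, and Oxford Nanopore. The numbers are representative of typical
#' runs (read counts, length distributions and error ramps of the right
#' order of magnitude), not measurements of any particular instrument; for
#' serious planning, infer a profile from your own data with
#' [infer_profile()], or export a preset with [save_profile()] and edit it.
#'
#' @return A named list of seven [sequencing_profile()] objects.
#' @examples
#' names(preset_profiles())
#' @export
preset_profiles <- function() {
  specs <- list(
    list("IonTorrent",      2.5e6, 199,   40,   400,  0.005, 0.02),
    list("IonProton",       1.5e7, 145,   30,   300,  0.005, 0.025),
    list("IlluminaMiSeq",   2.5e7, 250,   10,   301,  0.001, 0.01),
    list("IlluminaHiSeq",   3e8,   100,   5,    151,  0.001, 0.008),
    list("IlluminaNextSeq", 4e8,   150,   8,    151,  0.001, 0.012),
    list("PacBio",          5e5,   10000, 4000, 40000, 0.12, 0.08),
    list("OxfordNanopore",  1e5,   8000,  6000, 50000, 0.12, 0.10))
  out <- lapply(specs, function(s)
    sequencing_profile(
      name = s[[1]], reads_per_run = s[[2]], length_mean = s[[3]],
      length_sd = s[[4]], max_length = s[[5]],
      per_position_error = error_ramp(s[[5]], s[[6]], s[[7]])))
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}
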