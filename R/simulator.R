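# Metagenome read simulation: sample a community from a genome collection,
# draw reads under a sequencing profile, inject substitution errors marked
# in lowercase, and emit Sanger FASTQ plus a ground-truth key CSV.

#' Assemble a simulated community from a genome collection
#'
#' Samples `n_species` genomes without replacement and assigns abundance
#' weights: `uniform` gives every member weight \eqn{1/n}; `exponential`
#' gives member at rank \eqn{i = 0, \dots, n-1} (in sampled order) weight
#' proportional to \eqn{e^{-\mathrm{decay} \cdot i}}, normalised to sum
#' to 1. The exponential option mimics the steep rank-abundance curves
#' typical of viral communities.
#'
#' @param genomes Path to a (multi-)FASTA file, a `Biostrings::DNAStringSet`,
#'   or a named character vector of sequences.
#' @param n_species Number of community members to draw.
#' @param distribution `"uniform"` or `"exponential"`.
#' @param decay Positive rank-decay rate for the exponential distribution.
#' @param seed Optional integer seed for reproducible sampling.
#' @return An object of class `"community"`: a list of members, each with
#'   `genome_id`, `sequence` (uppercase character string) and `weight`.
#' @export
build_community <- function(genomes, n_species,
                            distribution = c("uniform", "exponential"),
                            decay = 0.5, seed = NULL) {
  distribution <- match.arg(distribution)
  seqs <- load_genomes(genomes)
  if (!is.finite(n_species) || n_species < 1 ||
      n_species != floor(n_species))
    stop("n_species must be a positive integer")
  if (length(seqs) < n_species)
    stop("genome collection holds ", length(seqs),
         " sequences but n_species = ", n_species)
  if (!is.finite(decay) || decay <= 0)
    stop("decay must be positive")
  if (!is.null(seed)) set.seed(seed)

  picked <- sample(seq_along(seqs), n_species)
  weights <- switch(distribution,
    uniform = rep(1 / n_species, n_species),
    exponential = {
      w <- exp(-decay * (seq_len(n_species) - 1))
      w / sum(w)
    })
  members <- lapply(seq_len(n_species), function(i)
    list(genome_id = names(seqs)[picked[i]],
         sequence = seqs[[picked[i]]],
         weight = weights[i]))
  structure(members, class = "community")
}

# Accept FASTA path, DNAStringSet, or named character vector; return an
# uppercase named character vector of sequences.
load_genomes <- function(genomes) {
  if (inherits(genomes, "DNAStringSet")) {
    seqs <- as.character(genomes)
  } else if (is.character(genomes) && length(genomes) == 1L &&
             file.exists(genomes)) {
    set <- Biostrings::readDNAStringSet(genomes)
    seqs <- as.character(set)
  } else if (is.character(genomes) && !is.null(names(genomes))) {
    seqs <- genomes
  } else {
    stop("genomes must be a FASTA path, a DNAStringSet, ",
         "or a named character vector")
  }
  if (length(seqs) == 0L) stop("genome collection is empty")
  if (any(!nzchar(seqs))) stop("genome collection contains empty sequences")
  # keep only the FASTA id (first whitespace-delimited token)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  toupper(seqs)
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("<community> %d members\n", length(x)))
  for (m in x)
    cat(sprintf("  %s: %d nt, weight %.5f\n", m$genome_id,
                nchar(m$sequence), m$weight))
  invisible(x)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

reverse_complement <- function(chars) rev(unname(COMPLEMENT[chars]))

#' Inject substitution errors into a read
#'
#' Each position is independently substituted with its per-position error
#' probability; an error replaces the base with a uniformly chosen
#' *different* base and marks it in lowercase. Error-free positions stay
#' uppercase and unchanged, so the lowercase positions of the output are
#' exactly the introduced errors.
#'
#' Uses the current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param bases Uppercase nucleotide string (A/C/G/T/N).
#' @param error_probs Numeric vector of per-position error probabilities, at
#'   least as long as `bases`.
#' @return A list with `bases` (errors in lowercase) and `n_errors`.
#' @export
inject_errors <- function(bases, error_probs) {
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (length(error_probs) < n)
    stop("error_probs shorter than the read (", length(error_probs),
         " < ", n, ")")
  hit <- runif(n) < error_probs[seq_len(n)]
  acgt <- c("A", "C", "G", "T")
  for (j in which(hit)) {
    alternatives <- setdiff(acgt, chars[j])
    chars[j] <- tolower(sample(alternatives, 1L))
  }
  list(bases = paste(chars, collapse = ""), n_errors = sum(hit))
}

#' Draw one simulated read from a community member
#'
#' The read length is drawn from Normal(`length_mean`, `length_sd`),
#' rounded, and truncated to `[1, min(max_length, genome length)]`. The
#' start is uniform over the genome (reads are placed on the linear
#' sequence, so coordinates never wrap), the strand is uniform, and the
#' extracted substring (reverse-complemented for `-`) is passed through
#' [inject_errors()]. Qualities encode the profile's per-position error
#' probabilities as phred scores clamped to `[2, 41]`.
#'
#' Uses the current RNG state; identical state gives identical output.
#'
#' @param member One element of a [build_community()] result.
#' @param profile A [sequencing_profile()].
#' @return A list with `read` (fields `bases`, `qualities`) and `key`
#'   (fields `genome_id`, `start`, `end`, `strand`, `n_errors`;
#'   0-based half-open genome coordinates).
#' @export
draw_read <- function(member, profile) {
  glen <- nchar(member$sequence)
  stopifnot(glen >= 1L)
  len <- round(rnorm(1L, profile$length_mean, profile$length_sd))
  len <- max(1L, min(len, profile$max_length, glen))
  start <- sample.int(glen - len + 1L, 1L) - 1L  # 0-based
  strand <- if (runif(1L) < 0.5) "+" else "-"
  template <- substr(member$sequence, start + 1L, start + len)
  if (strand == "-")
    template <- paste(reverse_complement(strsplit(template, "")[[1]]),
                      collapse = "")
  err <- inject_errors(template, profile$per_position_error)
  q <- round(-10 * log10(profile$per_position_error[seq_len(len)]))
  q <- pmin(pmax(q, 2L), 41L)
  list(read = list(bases = err$bases, qualities = as.integer(q)),
       key = list(genome_id = member$genome_id, start = start,
                  end = start + len, strand = strand,
                  n_errors = err$n_errors))
}

#' Simulate a sequencing run over a community
#'
#' Draws `n_reads` reads, assigning each read to a community member
#' multinomially by abundance weight, and optionally writes a Sanger FASTQ
#' file (errors in lowercase) and a comma-separated ground-truth key file
#' with one row per read
#' (`read_id,genome_id,start,end,strand,n_errors`; 0-based half-open
#' coordinates on the source genome).
#'
#' @param community A [build_community()] result.
#' @param profile A [sequencing_profile()].
#' @param n_reads Number of reads to simulate.
#' @param seed Integer seed; the same seed, community and profile give
#'   byte-identical outputs.
#' @param out_prefix If non-`NULL`, write `<out_prefix>.fastq` and
#'   `<out_prefix>_key.csv`.
#' @return Invisibly, a list with `reads` (list of `bases`/`qualities`),
#'   `key` (data frame), and the output paths (`NULL` when not written).
#' @export
simulate_run <- function(community, profile, n_reads, seed = NULL,
                         out_prefix = NULL) {
  stopifnot(inherits(community, "community"),
            inherits(profile, "sequencing_profile"))
  if (!is.finite(n_reads) || n_reads < 1 || n_reads != floor(n_reads))
    stop("n_reads must be a positive integer")
  if (!is.null(seed)) set.seed(seed)

  weights <- vapply(community, `[[`, numeric(1), "weight")
  origin <- sample(length(community), n_reads, replace = TRUE,
                   prob = weights)
  ids <- sprintf("read_%06d", seq_len(n_reads))
  reads <- vector("list", n_reads)
  keys <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    drawn <- draw_read(community[[origin[i]]], profile)
    reads[[i]] <- c(list(read_id = ids[i]), drawn$read)
    keys[[i]] <- c(list(read_id = ids[i]), drawn$key)
  }
  key <- data.frame(
    read_id = ids,
    genome_id = vapply(keys, `[[`, character(1), "genome_id"),
    start = vapply(keys, `[[`, numeric(1), "start"),
    end = vapply(keys, `[[`, numeric(1), "end"),
    strand = vapply(keys, `[[`, character(1), "strand"),
    n_errors = vapply(keys, `[[`, numeric(1), "n_errors"))

  fastq_path <- key_path <- NULL
  if (!is.null(out_prefix)) {
    fastq_path <- paste0(out_prefix, ".fastq")
    key_path <- paste0(out_prefix, "_key.csv")
    write_fastq(reads, fastq_path)
    write.csv(key, key_path, row.names = FALSE, quote = FALSE)
  }
  invisible(list(reads = reads, key = key,
                 fastq = fastq_path, key_file = key_path))
}

# Sanger FASTQ writer.  Written directly (not through DNAStringSet) because
# the simulator's lowercase error marks are part of the record and XString
# containers canonicalise case.
write_fastq <- function(reads, path) {
  lines <- character(4L * length(reads))
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    lines[4L * i - 3L] <- paste0("@", r$read_id)
    lines[4L * i - 2L] <- r$bases
    lines[4L * i - 1L] <- "+"
    lines[4L * i] <- intToUtf8(r$qualities + 33L)
  }
  con <- file(path, open = "wb")  # binary mode: LF endings on any platform
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
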