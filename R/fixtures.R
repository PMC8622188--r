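# Evaluate code under a temporary RNG state; the caller's stream is
# untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

#' Generate a synthetic nucleotide sequence
#'
#' Deterministic sequence generator for simulations and tests. `"random"`
#' draws each site independently: G/C with probability `gc_fraction` (then
#' uniformly G or C), A/T otherwise. The structured kinds ignore
#' `gc_fraction`. The generator uses R's Mersenne-Twister stream seeded with
#' `seed` and restores the caller's RNG state afterwards; identical
#' arguments give identical sequences.
#'
#' @param n Sequence length, >= 2.
#' @param gc_fraction Expected G+C proportion in `[0, 1]` (default 0.5).
#' @param seed Integer seed (required for the random kind's determinism).
#' @param kind One of `"random"`, `"homopolymer-A"`, `"homopolymer-G"`,
#'   `"alternating-AT"`, `"alternating-GC"`.
#' @return Character string of length-`n` over A/C/G/T, with attribute
#'   `spec` recording `n`, `gc_fraction`, `seed`, `kind` and the RNG
#'   identifier.
#' @export
#' @examples
#' random_sequence(12, gc_fraction = 0, seed = 1)  # A/T only
random_sequence <- function(n, gc_fraction = 0.5, seed = 1L,
                            kind = c("random", "homopolymer-A",
                                     "homopolymer-G", "alternating-AT",
                                     "alternating-GC")) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2", call. = FALSE)
  if (!is.finite(gc_fraction) || gc_fraction < 0 || gc_fraction > 1)
    stop("'gc_fraction' must lie in [0, 1]", call. = FALSE)
  bases <- switch(kind,
    "homopolymer-A"  = rep("A", n),
    "homopolymer-G"  = rep("G", n),
    "alternating-AT" = rep_len(c("A", "T"), n),
    "alternating-GC" = rep_len(c("G", "C"), n),
    "random" = with_seed(seed, {
      gc <- stats::runif(n) < gc_fraction
      ifelse(gc, sample(c("G", "C"), n, replace = TRUE),
                 sample(c("A", "T"), n, replace = TRUE))
    }))
  seq <- paste(bases, collapse = "")
  attr(seq, "spec") <- list(n = n, gc_fraction = gc_fraction,
                            seed = as.integer(seed), kind = kind,
                            rng = "Mersenne-Twister")
  seq
}

#' Named paper-scale sequence presets
#'
#' Synthetic stand-ins, at 50% GC and fixed seeds, for the two gene-scale
#' duplexes the model is typically run on: an interferon-alpha-17-like
#' length (n = 980) and a Drosophila-fragment-like length (n = 5000). The
#' real gene sequences are not bundled; these presets only reproduce the
#' lengths.
#'
#' @param name `"interferon-like"` or `"drosophila-like"`.
#' @return A sequence string as from [random_sequence()].
#' @export
preset_sequence <- function(name = c("interferon-like", "drosophila-like")) {
  name <- match.arg(name)
  switch(name,
    "interferon-like" = random_sequence(980, 0.5, seed = 17L),
    "drosophila-like" = random_sequence(5000, 0.5, seed = 28L))
}

#' Write a sequence to FASTA
#'
#' @param seq Sequence string over A/C/G/T.
#' @param path Output path.
#' @param id Record identifier (default `"synthetic"`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seq, path, id = "synthetic") {
  check_sequence(seq)
  set <- Biostrings::DNAStringSet(toupper(as.character(seq)))
  names(set) <- id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Synthetic damped cosine signal
#'
#' Closed-form test input for the envelope and damping analysis:
#' `offset + amplitude * exp(-gamma * t) * cos(omega * t)`.
#'
#' @param gamma Decay rate (s^-1), >= 0.
#' @param omega Angular frequency (s^-1).
#' @param amplitude Amplitude (rad).
#' @param offset Constant offset (rad).
#' @param times Increasing time grid (s).
#' @return An [observable_series()].
#' @export
damped_cosine_signal <- function(gamma, omega, amplitude = 1, offset = 0,
                                 times) {
  if (gamma < 0) stop("'gamma' must be >= 0", call. = FALSE)
  observable_series(times,
                    offset + amplitude * exp(-gamma * times) *
                      cos(omega * times),
                    label = sprintf("damped_cosine_gamma%g", gamma))
}
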