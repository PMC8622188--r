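#' Default per-base mechanical constants
#'
#' Returns the table of mechanical coefficients assigned to each nucleotide:
#' moment of inertia `I` (kg m^2), lever arm `R` (m, distance from the base's
#' centre of mass to the backbone), backbone torsional stiffness `K` (J),
#' hydrogen-bond pair stiffness `k12` (N/m) and dissipation coefficient
#' `beta` (J s). All values are stored in SI units; the conversion from the
#' customary publication units (I x 1e-44 kg m^2, R in Angstrom, K x 1e-18 J,
#' k12 x 1e-2 N/m, beta x 1e-34 J s) is applied once, here.
#'
#' The pair stiffness is a property of the base pair, not of a single base,
#' so `k12` is identical within a Watson-Crick pair (A = T, G = C).
#'
#' @return A data.frame with one row per base (A, T, G, C) and columns
#'   `base`, `I`, `R`, `K`, `k12`, `beta`.
#' @export
#' @examples
#' base_parameter_table()
base_parameter_table <- function() {
  data.frame(
    base = c("A", "T", "G", "C"),
    I    = c(7.61e-44, 4.86e-44, 8.22e-44, 4.11e-44),
    R    = c(5.80e-10, 4.80e-10, 5.70e-10, 4.70e-10),
    K    = c(2.35e-18, 1.61e-18, 2.27e-18, 1.54e-18),
    k12  = c(6.20e-2,  6.20e-2,  9.60e-2,  9.60e-2),
    beta = c(4.25e-34, 2.91e-34, 4.10e-34, 2.79e-34),
    stringsAsFactors = FALSE
  )
}

validate_parameter_table <- function(params) {
  required <- c("base", "I", "R", "K", "k12", "beta")
  if (!is.data.frame(params) || !all(required %in% names(params)))
    stop("parameter table must be a data.frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  if (!setequal(params$base, c("A", "C", "G", "T")))
    stop("parameter table must contain exactly the bases A, C, G, T",
         call. = FALSE)
  num <- as.matrix(params[, c("I", "R", "K", "k12", "beta")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all mechanical constants must be finite and strictly positive",
         call. = FALSE)
  rownames(params) <- params$base
  if (params["A", "k12"] != params["T", "k12"] ||
      params["G", "k12"] != params["C", "k12"])
    stop("pair stiffness k12 must be identical within a Watson-Crick pair",
         call. = FALSE)
  params
}

#' Mechanical parameters for a single base
#'
#' Looks up the row of the parameter table for one nucleotide. Lower-case
#' input is accepted; IUPAC ambiguity codes (N, R, Y, ...) are rejected
#' because no mechanical constants exist for them.
#'
#' @param base Single character, one of A, C, G, T (case-insensitive).
#' @param params Parameter table, defaults to [base_parameter_table()].
#' @return A list with elements `base`, `I`, `R`, `K`, `k12`, `beta`.
#' @export
#' @examples
#' base_parameters("A")$I   # 7.61e-44 kg m^2
base_parameters <- function(base, params = base_parameter_table()) {
  params <- validate_parameter_table(params)
  if (length(base) != 1L || !is.character(base) || nchar(base) != 1L)
    stop("'base' must be a single nucleotide symbol", call. = FALSE)
  b <- toupper(base)
  if (!b %in% params$base)
    stop(sprintf("unsupported nucleotide symbol '%s' (only A, C, G, T carry parameters)",
                 base), call. = FALSE)
  row <- params[params$base == b, , drop = FALSE]
  list(base = b, I = row$I, R = row$R, K = row$K, k12 = row$k12,
       beta = row$beta)
}

check_sequence <- function(seq) {
  if (length(seq) != 1L || !is.character(seq))
    stop("'seq' must be a single character string", call. = FALSE)
  if (nchar(seq) == 0L)
    stop("empty sequence", call. = FALSE)
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("unsupported nucleotide symbol '%s' at position %d",
                 bases[bad[1]], bad[1]), call. = FALSE)
  bases
}

#' Watson-Crick complement of a sequence
#'
#' Position-wise complement without reversal: site i of the returned strand
#' pairs with site i of the input. The model indexes base pairs along the
#' duplex, so 5'->3' orientation plays no role.
#'
#' @param seq Character string over A/C/G/T (case-insensitive).
#' @return Upper-case complementary sequence of the same length.
#' @export
#' @examples
#' complement_sequence("ACGT")  # "TGCA"
complement_sequence <- function(seq) {
  bases <- check_sequence(seq)
  paste(c(A = "T", T = "A", G = "C", C = "G")[bases], collapse = "")
}

#' Assemble the coupled-pendulum system for a duplex
#'
#' Builds per-site coefficient arrays for both strands of the duplex whose
#' first strand is `seq` and whose second strand is its position-wise
#' complement. Each strand's inertia, lever, backbone stiffness and
#' dissipation come from that strand's own base at the site; the pair
#' stiffness `k12` comes from the pair type (identical for both members).
#' The dimensionless viscosity scale `lambda` multiplies the dissipation
#' coefficients of both strands uniformly, so the effective damping used in
#' the equations of motion is `lambda * beta`.
#'
#' @param seq First-strand sequence (string over A/C/G/T) of length >= 2.
#' @param lambda Positive dimensionless viscosity scale (default 1).
#' @param params Per-base parameter table, defaults to
#'   [base_parameter_table()]; override for sensitivity studies.
#' @return An object of class `chain_system`: a list with `n`, `strand1`,
#'   `strand2`, coefficient vectors `I1`, `I2`, `R1`, `R2`, `K1`, `K2`,
#'   `beta1`, `beta2`, `k12`, and `lambda`.
#' @export
#' @examples
#' sys <- build_system("ATGC", lambda = 0.5)
#' sys$k12             # pair stiffness per site
#' effective_damping(sys)  # lambda * beta, both strands
build_system <- function(seq, lambda = 1, params = base_parameter_table()) {
  params <- validate_parameter_table(params)
  bases1 <- check_sequence(seq)
  n <- length(bases1)
  if (n < 2L)
    stop("sequence must have length >= 2 (a single pair cannot host both boundary equations)",
         call. = FALSE)
  if (length(lambda) != 1L || !is.finite(lambda) || lambda <= 0)
    stop("'lambda' must be a single positive number", call. = FALSE)
  bases2 <- c(A = "T", T = "A", G = "C", C = "G")[bases1]
  pick <- function(bases, col) unname(params[bases, col])
  sys <- list(
    n = n,
    strand1 = paste(bases1, collapse = ""),
    strand2 = paste(bases2, collapse = ""),
    I1 = pick(bases1, "I"),   I2 = pick(bases2, "I"),
    R1 = pick(bases1, "R"),   R2 = pick(bases2, "R"),
    K1 = pick(bases1, "K"),   K2 = pick(bases2, "K"),
    beta1 = pick(bases1, "beta"), beta2 = pick(bases2, "beta"),
    k12 = pick(bases1, "k12"),   # pair property: strand-2 lookup is identical
    lambda = lambda
  )
  class(sys) <- "chain_system"
  sys
}

#' Effective dissipation coefficients of a system
#'
#' The damping actually entering the equations of motion is the tabulated
#' `beta`, scaled by the system's viscosity factor `lambda`.
#'
#' @param system A `chain_system`.
#' @return List with vectors `strand1` and `strand2` (J s).
#' @export
effective_damping <- function(system) {
  stopifnot(inherits(system, "chain_system"))
  list(strand1 = system$lambda * system$beta1,
       strand2 = system$lambda * system$beta2)
}

#' @export
print.chain_system <- function(x, ...) {
  gc <- mean(strsplit(x$strand1, "")[[1]] %in% c("G", "C"))
  cat(sprintf("<chain_system> n = %d base pairs, lambda = %g, GC = %.1f%%\n",
              x$n, x$lambda, 100 * gc))
  cat(" strand1:", abbreviate_seq(x$strand1), "\n")
  cat(" strand2:", abbreviate_seq(x$strand2), "\n")
  invisible(x)
}

abbreviate_seq <- function(s) {
  if (nchar(s) <= 40) s else paste0(substr(s, 1, 37), "...")
}

#' Read a nucleotide sequence from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]: returns one record as
#' a plain upper-case string. By default the first record is used; a record
#' can be selected by its identifier.
#'
#' @param path Path to a FASTA file (single- or multi-record).
#' @param id Optional record identifier; matched against the first
#'   whitespace-delimited token of each header.
#' @return Character string of the selected record's sequence.
#' @export
read_sequence <- function(path, id = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  if (is.null(id)) {
    rec <- set[[1]]
  } else {
    tokens <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
    hit <- which(tokens == id)
    if (!length(hit)) stop("no FASTA record with id '", id, "'", call. = FALSE)
    rec <- set[[hit[1]]]
  }
  toupper(as.character(rec))
}

#' Load a parameter table from a config file
#'
#' Reads a JSON file mapping base symbols to named constants
#' (`I`, `R`, `K`, `k12`, `beta`, SI units) and returns a parameter table
#' usable wherever [base_parameter_table()] is. Bases absent from the file
#' keep their defaults.
#'
#' @param path Path to a JSON file, e.g.
#'   `{"A": {"I": 7.61e-44, "R": 5.8e-10, "K": 2.35e-18,
#'           "k12": 6.2e-2, "beta": 4.25e-34}}`.
#' @return A validated parameter table.
#' @export
read_parameter_table <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- base_parameter_table()
  rownames(params) <- params$base
  for (b in names(cfg)) {
    bb <- toupper(b)
    if (!bb %in% params$base)
      stop("unsupported base '", b, "' in parameter config", call. = FALSE)
    for (f in names(cfg[[b]])) {
      if (!f %in% c("I", "R", "K", "k12", "beta"))
        stop("unknown parameter field '", f, "' for base ", bb, call. = FALSE)
      params[bb, f] <- as.numeric(cfg[[b]][[f]])
    }
  }
  validate_parameter_table(params)
}
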