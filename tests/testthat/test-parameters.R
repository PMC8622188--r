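test_that("per-base constants match the reference table in SI units", {
  for (b in names(reference_constants)) {
    p <- base_parameters(b)
    ref <- reference_constants[[b]]
    for (f in names(ref))
      expect_identical(p[[f]], ref[[f]],
                       label = sprintf("%s[%s]", b, f))
  }
  # pair stiffness is a pair property
  expect_identical(base_parameters("A")$k12, base_parameters("T")$k12)
  expect_identical(base_parameters("G")$k12, base_parameters("C")$k12)
})

test_that("base lookup normalizes case and rejects ambiguity codes", {
  expect_identical(base_parameters("g"), base_parameters("G"))
  expect_error(base_parameters("N"), "N")
  expect_error(base_parameters("R"), "'R'")
  expect_error(base_parameters("AT"), "single nucleotide")
})

test_that("complement is position-wise, involutive, and validates input", {
  expect_identical(complement_sequence("ACGT"), "TGCA")
  expect_identical(complement_sequence("AAAA"), "TTTT")
  expect_identical(complement_sequence("acgt"), "TGCA")
  expect_error(complement_sequence(""), "empty")
  expect_error(complement_sequence("ACGNT"), "'N' at position 4")
  for (seed in 1:5) {
    s <- random_sequence(50, gc_fraction = 0.4, seed = seed)
    expect_identical(complement_sequence(complement_sequence(s)),
                     as.character(toupper(s)))
  }
})

test_that("build_system fills per-site arrays from each strand's own base", {
  sys <- build_system("AT", lambda = 1)
  expect_identical(sys$n, 2L)
  expect_identical(sys$strand2, "TA")
  expect_identical(sys$k12, c(6.20e-2, 6.20e-2))
  expect_identical(sys$I1, c(reference_constants$A[["I"]],
                             reference_constants$T[["I"]]))
  expect_identical(sys$I2, c(reference_constants$T[["I"]],
                             reference_constants$A[["I"]]))

  sys2 <- build_system("GC", lambda = 2)
  eff <- effective_damping(sys2)
  expect_identical(eff$strand1, 2 * c(4.10e-34, 2.79e-34))
  expect_identical(eff$strand2, 2 * c(2.79e-34, 4.10e-34))
})

test_that("build_system rejects degenerate input", {
  expect_error(build_system("A"), "length >= 2")
  expect_error(build_system("ATGC", lambda = 0), "positive")
  expect_error(build_system("ATGC", lambda = -1), "positive")
  expect_error(build_system("ATNC"), "'N' at position 3")
})

test_that("lambda scales only the effective dissipation", {
  s <- random_sequence(30, seed = 11)
  base <- build_system(s, lambda = 1)
  for (c_fac in c(0.1, 2, 3.5)) {
    scaled <- build_system(s, lambda = c_fac)
    expect_identical(scaled[setdiff(names(scaled), "lambda")],
                     base[setdiff(names(base), "lambda")])
    expect_equal(effective_damping(scaled)$strand1,
                 c_fac * effective_damping(base)$strand1, tolerance = 1e-15)
  }
  expect_identical(effective_damping(base)$strand1, base$beta1)
})

test_that("FASTA round trip and record selection work", {
  s1 <- random_sequence(40, seed = 1)
  f <- tempfile(fileext = ".fasta")
  write_fasta(s1, f, id = "recA")
  expect_identical(read_sequence(f), as.character(s1))
  # multi-record selection by id
  set <- Biostrings::DNAStringSet(c(recA = as.character(s1), recB = "ACGTACGT"))
  f2 <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(set, f2)
  expect_identical(read_sequence(f2, id = "recB"), "ACGTACGT")
  expect_identical(read_sequence(f2), as.character(s1))
  expect_error(read_sequence(f2, id = "nope"), "no FASTA record")
})

test_that("parameter table overrides load from JSON and are validated", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(A = list(K = 3e-18), T = list(K = 2e-18)), f,
                       auto_unbox = TRUE, digits = NA)
  tab <- read_parameter_table(f)
  expect_identical(tab["A", "K"], 3e-18)
  expect_identical(tab["G", "K"], 2.27e-18)  # untouched default
  sys <- build_system("AT", params = tab)
  expect_identical(sys$K1[1], 3e-18)

  jsonlite::write_json(list(A = list(k12 = 1e-2)), f, auto_unbox = TRUE,
                       digits = NA)
  expect_error(read_parameter_table(f), "Watson-Crick")
  jsonlite::write_json(list(A = list(I = -1)), f, auto_unbox = TRUE,
                       digits = NA)
  expect_error(read_parameter_table(f), "positive")
})
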