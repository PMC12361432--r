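test_that("motif location and N-terminal region match the printed CCL25 sequence", {
  ccl25 <- builtin_sequence("CCL25")
  expect_equal(length(ccl25), 127L)
  expect_identical(find_subsequence(ccl25, "QEVSGSCNLPA"), 29L)
  expect_identical(n_terminal_region(ccl25), 6L)
  # the engineered analog differs only in residues 1-4
  analog <- builtin_sequence("1P6-CCL25")
  expect_identical(substr(analog$residues, 5, 127),
                   substr(ccl25$residues, 5, 127))
  expect_identical(substr(analog$residues, 1, 4), "YQAS")
})

test_that("find_subsequence agrees with a brute-force scan on random pairs", {
  set.seed(42)
  scan_oracle <- function(s, m) {
    n <- nchar(s); k <- nchar(m)
    for (i in seq_len(n - k + 1))
      if (substr(s, i, i + k - 1) == m) return(i)
    NA_integer_
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep_i in 1:200) {
    s <- paste(sample(aa, 100, replace = TRUE), collapse = "")
    start <- sample(90, 1); len <- sample(3:8, 1)
    m <- substr(s, start, start + len - 1)
    rec <- sequence_record("r", s)
    expect_identical(suppressWarnings(find_subsequence(rec, m)),
                     scan_oracle(s, m))
  }
  expect_error(find_subsequence(sequence_record("r", "AAAA"), "W"),
               "not found")
})

test_that("edge behaviors of the sequence operations hold", {
  expect_identical(find_subsequence(sequence_record("x", "MKV"), "M"), 1L)
  expect_identical(n_terminal_region(sequence_record("x", "CAAA")), 0L)
  expect_error(n_terminal_region(sequence_record("x", "AAAA")),
               "no cysteine")
  # planted first cysteine recovered for random sequences
  set.seed(7)
  for (i in 1:50) {
    pos <- sample(1:40, 1)
    s <- paste(sample(c("A", "G", "V"), 40, replace = TRUE), collapse = "")
    substr(s, pos, pos) <- "C"
    expect_identical(n_terminal_region(sequence_record("x", s)), pos - 1L)
  }
  # numbering offset shifts results into mature numbering
  rec <- sequence_record("frag", "AAQEV", numbering_offset = 27L)
  expect_identical(find_subsequence(rec, "QEV"), 29L)
})

test_that("tabular round-trips are lossless, including unicode names", {
  df <- data.frame(cell_line = c("WT", "K40A", "ΔN-variant"),
                   ligand = "CCL25", concentration = 3e-7,
                   mfi = c(1000, 500, 700), autofluorescence_mfi = 100,
                   events = 10000L, experiment_id = "E1",
                   stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".csv")
  write_tables(flow_table(df), p)
  back <- read_tables(p, "flow_table")
  expect_equal(as.data.frame(back), df)
  # header-only file for empty record sets
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_tables(df[0, ], p2)
  expect_length(readLines(p2), 1L)
})

test_that("plate map invariants are enforced", {
  ok <- data.frame(well_id = c("A1", "A2"), variant = "WT",
                   ligand = c("CCL25", "buffer"), concentration = c(1e-9, 0),
                   role = c("agonist", "buffer"), replicate = 1L,
                   experiment_id = "E1")
  expect_s3_class(plate_map(ok), "plate_map")
  dup <- ok; dup$well_id <- c("A1", "A1")
  expect_error(plate_map(dup), "duplicated well_id")
  bad <- ok; bad$concentration <- c(0, 0)
  expect_error(plate_map(bad), "nonpositive concentration")
  nobuf <- ok[1, ]
  expect_error(plate_map(nobuf), "no buffer/vehicle")
})

test_that("kinetic traces round-trip through long-format CSV", {
  tr1 <- make_trace("W01", post = 250)
  tr2 <- make_bret_trace(1.1, "W02")
  p <- withr::local_tempfile(fileext = ".csv")
  write_traces(list(tr1, tr2), p)
  back <- read_traces(p)
  expect_equal(back[["W01"]]$channels$fluo, tr1$channels$fluo)
  expect_equal(back[["W02"]]$channels$em540, tr2$channels$em540)
  expect_equal(back[["W02"]]$injections, tr2$injections)
})

test_that("structure files round-trip through PDB and mmCIF", {
  at <- rbind(atom_row("A", 1, "N", 1.234, 2.345, 3.456, "N"),
              atom_row("A", 1, "CA", 2.001, 3.002, 4.003, "C"),
              atom_row("A", 2, "CA", 5.100, 6.200, 7.300, "C"))
  m <- make_model(at)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  write_structure(m, pdb)
  write_structure(m, cif)
  m_pdb <- read_structure(pdb, c(receptor = "A"))
  m_cif <- read_structure(cif, c(receptor = "A"))
  expect_equal(nrow(m_pdb$atoms), 3L)
  expect_equal(m_pdb$atoms[, c("x", "y", "z")], at[, c("x", "y", "z")],
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(m_cif$atoms[, c("x", "y", "z")],
               m_pdb$atoms[, c("x", "y", "z")], tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(m_pdb$atoms$conf, rep(90, 3))  # B column carries confidence
  expect_error(read_structure(pdb, c(receptor = "Z")), "chain")
})

test_that("full toy models survive a write/read cycle", {
  toy <- generate_toy_ensemble(n_models = 1, seed = 3)
  m <- toy$ensemble$models[[1]]
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, p)
  back <- read_structure(p, m$chain_roles)
  expect_equal(nrow(back$atoms), nrow(m$atoms))
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]), tolerance = 1e-3,
               ignore_attr = TRUE)
})
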