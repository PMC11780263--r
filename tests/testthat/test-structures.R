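test_that("read_structure converts Angstrom C-alpha records to nm beads", {
  p <- write_pdb_text(pdb_lines(1:3, c(0, 3.8, 7.6), 0, 0))
  s <- read_structure(p, chain = "A", label = "toy")
  expect_s3_class(s, "bead_structure")
  expect_equal(n_beads(s), 3)
  expect_equal(coords(s),
               matrix(c(0, 0.38, 0.76, 0, 0, 0, 0, 0, 0), ncol = 3),
               tolerance = 1e-9)
  expect_equal(s$beads$resid, 1:3)
  expect_equal(s$label, "toy")
})

test_that("altloc duplicates collapse to one bead by occupancy then altloc A", {
  # residue 2 has three altlocs: B with top occupancy must win
  lines <- c(pdb_lines(1, 0, 0, 0),
             pdb_lines(2, 3.8, 0, 0, alt = "A", occ = 0.4),
             pdb_lines(2, 3.9, 0, 0, alt = "B", occ = 0.6),
             pdb_lines(3, 7.6, 0, 0))
  s <- read_structure(write_pdb_text(lines), chain = "A")
  expect_equal(n_beads(s), 3)
  expect_equal(coords(s)[2, 1], 0.39, tolerance = 1e-9)
  # occupancy tie: altloc A wins
  lines2 <- c(pdb_lines(1, 0, 0, 0),
              pdb_lines(2, 3.9, 0, 0, alt = "B", occ = 0.5),
              pdb_lines(2, 3.8, 0, 0, alt = "A", occ = 0.5))
  s2 <- read_structure(write_pdb_text(lines2), chain = "A")
  expect_equal(coords(s2)[2, 1], 0.38, tolerance = 1e-9)
})

test_that("HETATM and non-CA atoms are ignored; missing chain is an error", {
  lines <- c(pdb_lines(1:2, c(0, 3.8), 0, 0),
             pdb_lines(9, 50, 0, 0, type = "HETATM", resname = "HOH",
                       elety = "O"),
             pdb_lines(3, 1.9, 1, 0, elety = "CB"))
  p <- write_pdb_text(lines)
  expect_equal(n_beads(read_structure(p, chain = "A")), 2)
  expect_error(read_structure(p, chain = "Q"), "chain 'Q'")
  expect_error(read_structure(tempfile(), chain = "A"), "no such file")
})

test_that("structure round-trips through PDB at coordinate precision", {
  fx <- make_two_state_bundle()
  p <- tempfile(fileext = ".pdb")
  write_structure(fx$state_a, p)
  back <- read_structure(p)  # all chains
  expect_equal(n_beads(back), n_beads(fx$state_a))
  expect_equal(back$beads$resid, fx$state_a$beads$resid)
  expect_lt(max(abs(coords(back) - coords(fx$state_a))), 0.001)
})

test_that("bead_structure enforces uniqueness and ordering invariants", {
  df <- data.frame(chain = "A", resid = c(1L, 1L), resname = "ALA",
                   x = 0:1, y = 0, z = 0)
  expect_error(bead_structure(df), "duplicate")
  df2 <- data.frame(chain = "A", resid = c(2L, 1L), resname = "ALA",
                    x = 0:1, y = 0, z = 0)
  expect_error(bead_structure(df2), "strictly increasing")
})

test_that("identity mapping of a structure onto itself is the full map", {
  fx <- make_two_state_bundle()
  m <- map_residues(fx$state_a, fx$state_a, mode = "identity")
  expect_equal(nrow(m$pairs), n_beads(fx$state_a))
  expect_equal(m$pairs$idx_a, m$pairs$idx_b)
  expect_equal(m$coverage_a, 1)
  expect_equal(m$coverage_b, 1)
})

test_that("alignment mode pairs residues across a deletion", {
  # "ACDEFG" vs "ACEFG": hand alignment pairs A,C,E,F,G and skips D
  aa3 <- function(s) vapply(strsplit(s, "")[[1]], function(a)
    bio3d::aa123(a), "")
  mk <- function(seq1) {
    n <- nchar(seq1)
    bead_structure(data.frame(chain = "A", resid = seq_len(n),
                              resname = aa3(seq1),
                              x = 0.38 * seq_len(n), y = 0, z = 0),
                   "s", "synthetic")
  }
  a <- mk("ACDEFG"); b <- mk("ACEFG")
  m <- expect_warning(map_residues(a, b, mode = "alignment"), NA)
  expect_equal(nrow(m$pairs), 5)
  expect_equal(m$pairs$resid_a, c(1, 2, 4, 5, 6))
  expect_equal(m$pairs$resid_b, 1:5)
  # symmetric up to side order
  m2 <- map_residues(b, a, mode = "alignment")
  expect_equal(m2$pairs$resid_a, m$pairs$resid_b)
  expect_equal(m2$pairs$resid_b, m$pairs$resid_a)
})

test_that("explicit mapping validates its pair table", {
  fx <- make_two_state_bundle()
  pairs <- data.frame(resid_a = 1:5, resid_b = 1:5,
                      chain_a = "A", chain_b = "B")
  m <- map_residues(fx$state_a, fx$state_b, mode = "explicit",
                    pairs = pairs, min_coverage = 0)
  expect_equal(nrow(m$pairs), 5)
  bad <- data.frame(resid_a = c(1, 999), resid_b = c(1, 2))
  expect_error(
    map_residues(fx$state_a, fx$state_b, mode = "explicit", pairs = bad),
    "absent")
})

test_that("low mapping coverage warns and empty maps are hard errors", {
  fx <- make_two_state_bundle()
  pairs <- data.frame(resid_a = 1:3, resid_b = 1:3)
  expect_warning(
    map_residues(fx$state_a, fx$state_b, mode = "explicit", pairs = pairs),
    "coverage")
})

test_that("segment configs load, validate spans, and reject duplicates", {
  fx <- make_two_state_bundle()
  p <- tempfile(fileext = ".yaml")
  write_segments(fx$segments, p)
  segs <- load_segments(p, fx$state_a)
  expect_length(segs, 2 * 6)
  expect_setequal(vapply(segs, function(s) s$side, ""),
                  c("in", "out"))

  # an 11-residue span must fail naming the segment
  bad <- fx$segments
  bad[[1]]$end <- bad[[1]]$start + 10L
  p2 <- tempfile(fileext = ".yaml")
  write_segments(bad, p2)
  expect_error(load_segments(p2, fx$state_a), "TM1/in")

  # residues absent from the structure
  bad2 <- fx$segments
  bad2[[2]]$start <- 100L; bad2[[2]]$end <- 109L
  p3 <- tempfile(fileext = ".yaml")
  write_segments(bad2, p3)
  expect_error(load_segments(p3, fx$state_a), "absent")

  # duplicate (tm, side)
  dup <- c(fx$segments, fx$segments[1])
  p4 <- tempfile(fileext = ".yaml")
  write_segments(dup, p4)
  expect_error(load_segments(p4, fx$state_a), "duplicate")
})
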