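test_that("multi-model PDB round trip preserves coordinates to PDB precision", {
  e <- random_ensemble(8, 4, seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "MODEL")), 4)
  back <- read_multimodel_pdb(path)
  expect_equal(n_frames(back), 4)
  expect_equal(n_atoms(back), 8)
  expect_lt(max(abs(back$coords - e$coords)), 1e-4 + 1e-12)
  expect_equal(back$atoms$resno, e$atoms$resno)
})

test_that("PDB unit conversion is Angstrom on disk, nm in memory", {
  atoms <- tibble::tibble(serial = 1L, name = "CA", element = "C",
    resname = "ALA", resno = 1L, chain = "A")
  e <- ensemble(matrix(c(1.0, 0.2, -0.3), 1), atoms)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e, path)
  atom_line <- grep("^ATOM", readLines(path), value = TRUE)[1]
  expect_equal(substr(atom_line, 31, 38), "  10.000")
  back <- read_multimodel_pdb(path)
  expect_equal(as.numeric(back$coords[1, 1, ]), c(1.0, 0.2, -0.3), tolerance = 1e-6)
})

test_that("a file without MODEL records is a single frame", {
  e <- random_ensemble(5, 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e, path)
  # strip MODEL/ENDMDL records entirely
  lines <- readLines(path)
  writeLines(lines[!startsWith(lines, "MODEL") & !startsWith(lines, "ENDMDL")], path)
  back <- read_multimodel_pdb(path)
  expect_equal(n_frames(back), 1)
  expect_equal(n_atoms(back), 5)
})

test_that("malformed PDB input fails loudly with location information", {
  e <- random_ensemble(4, 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e, path)
  lines <- readLines(path)
  # drop one ATOM line from the second model -> atom-count mismatch
  atom_idx <- which(startsWith(lines, "ATOM"))
  writeLines(lines[-atom_idx[6]], path)
  expect_error(read_multimodel_pdb(path), "MODEL #2")
  # corrupt a coordinate field
  writeLines(ifelse(seq_along(lines) == atom_idx[1],
    paste0(substr(lines[atom_idx[1]], 1, 30), "  xx.xxx", substr(lines[atom_idx[1]], 39, 80)),
    lines), path)
  expect_error(read_multimodel_pdb(path), "line")
  # insertion code
  l2 <- lines
  substr(l2[atom_idx[1]], 27, 27) <- "B"
  writeLines(l2, path)
  expect_error(read_multimodel_pdb(path), "insertion")
})

test_that("oversized coordinates are rejected by the writer", {
  atoms <- tibble::tibble(serial = 1L, name = "CA", element = "C",
    resname = "ALA", resno = 1L, chain = "A")
  e <- ensemble(matrix(c(1000.1, 0, 0), 1), atoms)
  expect_error(write_multimodel_pdb(e, withr::local_tempfile()), "fixed-width")
})

test_that("select_atoms reproduces the canonical region sizes", {
  regions <- alas2_regions("A")
  atoms <- tidyr::expand_grid(resno = 143:587, name = c("N", "CA", "C")) |>
    dplyr::mutate(serial = dplyr::row_number(), element = substr(name, 1, 1),
      resname = "ALA", chain = "A")
  nf <- nrow(atoms)
  e <- ensemble(array(rnorm(2 * nf * 3), c(2, nf, 3)), atoms)
  tail_ca <- select_atoms(e, regions, "c_tail", "CA")
  expect_length(tail_ca, 35)
  expect_equal(attr(tail_ca, "n_residues"), 35)
  loop_ca <- select_atoms(e, regions, "loop", "CA")
  expect_length(loop_ca, 15)
  bb <- select_atoms(e, regions, "loop")
  expect_length(bb, 45) # N, CA, C per residue
  # ordering: chain, residue, then N < CA < C
  expect_equal(e$atoms$name[bb[1:3]], c("N", "CA", "C"))
  expect_true(all(diff(e$atoms$resno[bb[seq(1, 45, 3)]]) == 1))
})

test_that("select_atoms errors on empty selections and missing atom names", {
  e <- random_ensemble(10, 2, seed = 4) # CA-only roster, residues 1..10
  regs <- region_set(outside = list(chain = "A", start = 100, end = 120),
    inside = list(chain = "A", start = 2, end = 5))
  expect_error(select_atoms(e, regs, "outside", "CA"), "no atoms")
  expect_error(select_atoms(e, regs, "inside", c("N", "CA", "C")), "missing in residue")
  expect_error(select_atoms(e, regs, "nope", "CA"), "not found")
})

test_that("selecting the union of disjoint regions equals re-sorted concatenation", {
  e <- random_ensemble(30, 2, seed = 5)
  regs <- region_set(
    a = list(chain = "A", start = 3, end = 7),
    b = list(chain = "A", start = 20, end = 24),
    both = list(list(chain = "A", start = 3, end = 7), list(chain = "A", start = 20, end = 24))
  )
  ia <- select_atoms(e, regs, "a", "CA")
  ib <- select_atoms(e, regs, "b", "CA")
  iu <- select_atoms(e, regs, "both", "CA")
  expect_equal(as.integer(iu), sort(c(as.integer(ia), as.integer(ib))))
  # idempotent / order-stable
  expect_equal(as.integer(select_atoms(e, regs, "a", "CA")), as.integer(ia))
})

test_that("time axis arithmetic matches the sampling convention", {
  expect_length(build_time_axis(100, 100), 1001)
  expect_equal(build_time_axis(1, 1000), c(0, 1000))
  expect_length(build_time_axis(5, 100), 51)
  expect_equal(build_time_axis(5, 100)[51], 5000)
  expect_error(build_time_axis(1, 300), "divide")
})

test_that("region sets validate their invariants", {
  expect_error(region_set(x = list(chain = "A", start = 10, end = 5)), "start > end")
  expect_error(
    region_set(x = list(list(chain = "A", start = 1, end = 10),
      list(chain = "A", start = 5, end = 20))),
    "overlap")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("regions:", "  c_tail:", "    - {chain: A, start: 553, end: 587}"), tmp)
  rs <- read_regions(tmp)
  expect_s3_class(rs, "region_set")
  expect_equal(nrow(region_residues(rs, "c_tail")), 35)
})
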