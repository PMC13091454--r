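test_that("PDB reading loads records, flags HETATM, and errors usefully", {
  p <- write_tiny_pdb()
  m <- read_structure(p)
  expect_s3_class(m, "fibril_model")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(length(chain_ids(m)), 1L)
  expect_equal(n_residues(m), 1L)
  expect_equal(m$atoms$name, c("N", "CA", "C"))
  expect_equal(m$atoms$res_seq, rep(1L, 3))

  het <- c(tiny_pdb_text[1:3],
           "HETATM    4 CL    CL A 901      10.000  10.000  10.000  1.00  0.00          CL",
           "END")
  ph <- tempfile(fileext = ".pdb"); writeLines(het, ph)
  mh <- read_structure(ph)
  expect_equal(sum(mh$atoms$is_hetero), 1L)
  expect_equal(mh$atoms$element[4], "CL")

  bad <- tempfile(fileext = ".pdb")
  writeLines(c(tiny_pdb_text[1], "ATOM      2  CA  ALA A   1     bad"), bad)
  expect_error(read_structure(bad), "line 2")
  empty <- tempfile(fileext = ".pdb"); writeLines("END", empty)
  expect_error(read_structure(empty), "empty model")
})

test_that("write/read roundtrip preserves content to format precision", {
  stack <- make_fibril(fibril_recipe("ARNDCQEGHILKMFPSTWYV", "c_shape",
                                     n_layers = 5))
  f <- tempfile(fileext = ".pdb")
  write_structure(stack, f)
  back <- read_structure(f)
  expect_equal(nrow(back$atoms), nrow(stack$atoms))
  expect_equal(back$atoms$name, stack$atoms$name)
  expect_equal(back$atoms$res_seq, stack$atoms$res_seq)
  expect_equal(back$atoms$res_name, stack$atoms$res_name)
  expect_lt(max(abs(coords(back) - coords(stack))), 1e-3)
})

test_that("mmCIF atom_site parsing agrees with the PDB reader", {
  cif <- c(
    "data_toy", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy",
    "ATOM 1 N N . ALA A 1 0.000 0.000 0.000 1.00",
    "ATOM 2 C CA . ALA A 1 1.458 0.000 0.000 1.00",
    "HETATM 3 CL CL . CL A 901 9.000 9.000 9.000 1.00",
    "#")
  p <- tempfile(fileext = ".cif"); writeLines(cif, p)
  m <- read_structure(p)
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(m$atoms$is_hetero, c(FALSE, FALSE, TRUE))
  expect_equal(m$atoms$x, c(0, 1.458, 9))
  # format auto-detection from content, not extension
  p2 <- tempfile(fileext = ".txt"); writeLines(cif, p2)
  expect_equal(nrow(read_structure(p2)$atoms), 3L)
  expect_error(read_structure(tempfile(fileext = ".cif")), "not found")
})

test_that("altloc resolution is deterministic and policy-driven", {
  base <- toy_atoms(rbind(c(0, 0, 0), c(0.5, 0, 0), c(1.4, 0, 0)),
                    name = c("CA", "CA", "CB"), res_seq = c(1, 1, 1))
  base$alt_loc <- c("A", "B", "")
  base$occupancy <- c(0.6, 0.4, 1)
  m <- fibril_model(base)
  r1 <- resolve_altlocs(m, "highest_occupancy")
  expect_equal(nrow(r1$atoms), 2L)
  expect_equal(r1$atoms$x[r1$atoms$name == "CA"], 0)
  r2 <- resolve_altlocs(m, "first_conformer")
  expect_equal(r2$atoms$x[r2$atoms$name == "CA"], 0)
  # flipped occupancies: policies now disagree
  base$occupancy <- c(0.4, 0.6, 1)
  m2 <- fibril_model(base)
  expect_equal(resolve_altlocs(m2, "highest_occupancy")$atoms$x[1], 0.5)
  expect_equal(resolve_altlocs(m2, "first_conformer")$atoms$x[1], 0)
  # no altlocs -> identity
  clean <- toy_model(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_identical(resolve_altlocs(clean), clean)
})

test_that("segment selection uses closed author-numbered intervals", {
  stand <- synthetic_standin("9o8e", n_layers = 3)
  ch <- central_chain_ids(stand)[1]
  seg <- select_segment(stand, ch, 391, 400, atom_filter = "CA")
  expect_equal(nrow(seg$atoms), 10L)
  expect_equal(range(seg$atoms$res_seq), c(391L, 400L))
  # full-span CA selection over the published core
  core <- select_segment(stand, ch, 341, 449, atom_filter = "CA")
  expect_equal(nrow(core$atoms), 109L)
  # idempotence on the same interval
  seg2 <- select_segment(seg, ch, 391, 400, atom_filter = "CA")
  expect_equal(seg2$atoms[, -1], seg$atoms[, -1], ignore_attr = TRUE)
  # "all" on a full chain is the identity on that chain
  whole <- select_segment(stand, ch, -10000, 10000, "all")
  expect_equal(nrow(whole$atoms), sum(stand$atoms$chain_id == ch))
  expect_error(select_segment(stand, "nope", 1, 2), "not present")
  expect_error(select_segment(stand, ch, 1, 5), "empty selection")
  expect_error(select_segment(stand, ch, 400, 391), "start_res")
})
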