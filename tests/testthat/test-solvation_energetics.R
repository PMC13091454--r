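test_that("the default ASP table loads and classifies all standard residues", {
  asp <- asp_table()
  expect_equal(unname(asp$sigma["apolar_C"]), 0.016)
  expect_equal(unname(asp$sigma["charged_N_plus"]), -0.050)
  # every heavy atom of a 20-residue chain classifies to exactly one class
  lay <- make_layer(fibril_recipe("ARNDCQEGHILKMFPSTWYV", "straight"))
  cls <- classify_atoms(lay$atoms$res_name, lay$atoms$name,
                        lay$atoms$element, asp)
  expect_true(all(cls %in% c("apolar_C", "polar_N_O", "carboxylate_O_minus",
                             "charged_N_plus", "sulfur")))
  pick <- function(rn, nm) cls[lay$atoms$res_name == rn & lay$atoms$name == nm]
  expect_equal(pick("LYS", "NZ"), "charged_N_plus")
  expect_equal(pick("ARG", "NH1"), "charged_N_plus")
  expect_equal(pick("ASP", "OD1"), "carboxylate_O_minus")
  expect_equal(pick("HIS", "ND1"), "polar_N_O")   # neutral-His default
  expect_equal(pick("MET", "SD"), "sulfur")
  expect_equal(pick("SER", "OG"), "polar_N_O")
  # charged-His variant flips only the imidazole nitrogens
  clsh <- classify_atoms(lay$atoms$res_name, lay$atoms$name,
                         lay$atoms$element, asp_table(his_charged = TRUE))
  flipped <- which(cls != clsh)
  expect_true(all(lay$atoms$res_name[flipped] == "HIS" &
                  lay$atoms$name[flipped] %in% c("ND1", "NE2")))
  expect_error(classify_atoms("ALA", "QQ", "Q", asp), "unclassifiable")
  expect_error(asp_table(sigma = c(apolar_C = 1)), "lacks classes")
  expect_error(asp_table(sigma = c(apolar_C = 1, polar_N_O = 1,
                                   carboxylate_O_minus = 1,
                                   charged_N_plus = 1, sulfur = 1)),
               "opposite signs")
})

test_that("residue energies follow -sigma x buried with the stated signs", {
  asp <- asp_table()
  ar <- data.frame(chain_id = "A", res_seq = c(1L, 1L, 2L),
                   res_name = c("ALA", "ALA", "LYS"),
                   name = c("CA", "CB", "NZ"), element = c("C", "C", "N"),
                   reference = c(20, 30, 25), assembly = c(10, 30, 5),
                   buried = c(10, 0, 20), stringsAsFactors = FALSE)
  prof <- residue_energies(ar, asp)
  # 10 A^2 of buried carbon at sigma +0.016 -> -0.16 kcal/mol
  expect_equal(prof$dG[prof$res_seq == 1], -0.16, tolerance = 1e-12)
  # buried charged nitrogen is a positive (destabilizing) contribution
  expect_equal(prof$dG[prof$res_seq == 2], 1.0, tolerance = 1e-12)
  # zero burial -> exactly zero everywhere
  ar0 <- ar; ar0$buried <- 0
  expect_true(all(residue_energies(ar0, asp)$dG == 0))
  # scale covariance: doubling sigma doubles every dG
  asp2 <- asp_table(sigma = asp$sigma * 2)
  expect_equal(residue_energies(ar, asp2)$dG, prof$dG * 2)
})

test_that("chain summaries are exact residue sums with the stated denominator", {
  ar <- data.frame(chain_id = "A", res_seq = c(1L, 2L),
                   res_name = c("LEU", "LYS"), name = c("CB", "NZ"),
                   element = c("C", "N"), reference = c(70, 40),
                   assembly = c(7.5, 30), buried = c(62.5, 10),
                   stringsAsFactors = FALSE)
  prof <- residue_energies(ar, asp_table())
  expect_equal(prof$dG, c(-1.0, 0.5))
  s <- chain_summary(prof, "A")
  expect_equal(s$dG_chain, -0.5)
  expect_equal(s$dG_residue, -0.25)
  expect_equal(s$n_ordered_residues, 2L)
  expect_error(chain_summary(prof, "Z"), "not present")
  # additivity on a real profile: chain total equals the residue sum exactly
  stack <- make_fibril(fibril_recipe("GAVLIKSTNQ", "c_shape", n_layers = 5))
  ch <- central_chain_ids(stack)
  areas <- buried_areas(stack, ch, n_sphere_points = default_standin_points)
  p <- residue_energies(areas)
  expect_equal(chain_summary(p, ch)$dG_chain, sum(p$dG), tolerance = 1e-12)
  # a mostly-apolar synthetic fibril chain is stabilized (dG < 0)
  expect_lt(chain_summary(p, ch)$dG_chain, 0)
})

test_that("compensation specs enforce residue types and imply 1/3/2 nitrogens", {
  expect_error(compensation_spec(data.frame(res_seq = 1, res_name = "ALA")),
               "only LYS/ARG/HIS")
  spec <- compensation_spec(data.frame(res_seq = c(1, 2, 3),
                                       res_name = c("LYS", "ARG", "HIS")))
  atoms <- compensation_atoms(spec)
  expect_equal(nrow(atoms), 1 + 3 + 2)
  expect_setequal(atoms$name[atoms$res_name == "ARG"], c("NE", "NH1", "NH2"))
  expect_setequal(atoms$name[atoms$res_name == "HIS"], c("ND1", "NE2"))
  expect_equal(atoms$name[atoms$res_name == "LYS"], "NZ")
})

test_that("builtin compensation specs match the published residue lists", {
  specs <- builtin_compensation_specs()
  expect_setequal(names(specs),
                  c("7sp1", "9o8e", "9o8h", "9o8e_proximity"))
  expect_equal(nrow(specs[["7sp1"]]$residues), 1L)
  expect_equal(specs[["7sp1"]]$residues$res_name, "ARG")
  expect_equal(nrow(compensation_atoms(specs[["7sp1"]])), 3L)
  expect_equal(nrow(specs[["9o8e"]]$residues), 8L)
  expect_setequal(specs[["9o8e"]]$residues$res_seq,
                  c(343, 347, 349, 370, 375, 379, 383, 385))
  expect_equal(nrow(specs[["9o8h"]]$residues), 5L)
  expect_equal(nrow(compensation_atoms(specs[["9o8h"]])), 3 * 1 + 2 * 2)
  # every builtin residue matches the construct sequence identity
  seqv <- tau40_sequence()
  aa3 <- c(K = "LYS", R = "ARG", H = "HIS")
  for (sp in specs) {
    expect_equal(unname(aa3[seqv[sp$residues$res_seq]]), sp$residues$res_name)
  }
})

test_that("charge compensation removes exactly the positive nitrogen terms", {
  fx <- make_energy_fixture()
  asp <- asp_table()
  plain <- residue_energies(fx$areas, asp)
  comp <- apply_charge_compensation(fx$areas, asp, fx$spec)
  d_chain <- chain_summary(comp, fx$chain)$dG_chain -
             chain_summary(plain, fx$chain)$dG_chain
  # bookkeeping identity against the fixture's independent re-summation
  expect_equal(d_chain, fx$expected_delta, tolerance = 1e-9)
  expect_lte(fx$expected_delta, 0)
  expect_equal(attr(comp, "removed_penalty"), -fx$expected_delta,
               tolerance = 1e-12)
  expect_true(all(comp$compensated[comp$res_name == "LYS"]))
  # empty spec is the identity
  empty <- compensation_spec(data.frame(res_seq = integer(),
                                        res_name = character()))
  same <- apply_charge_compensation(fx$areas, asp, empty)
  expect_equal(same$dG, plain$dG)
  # spec naming an absent residue or the wrong type errors with the entry
  expect_error(apply_charge_compensation(fx$areas, asp,
    compensation_spec(data.frame(res_seq = 999, res_name = "LYS"))),
    "LYS999")
  expect_error(apply_charge_compensation(fx$areas, asp,
    compensation_spec(data.frame(res_seq = fx$spec$residues$res_seq[1],
                                 res_name = "ARG"))),
    "model has")
})

test_that("compensation is monotone across random specs (property)", {
  stack <- make_fibril(fibril_recipe("KLKRLHKALK", "c_shape", n_layers = 5))
  ch <- central_chain_ids(stack)
  areas <- buried_areas(stack, ch, n_sphere_points = default_standin_points)
  asp <- asp_table()
  base <- chain_summary(residue_energies(areas, asp), ch)$dG_chain
  cand <- unique(areas[areas$res_name %in% c("LYS", "ARG", "HIS"),
                       c("res_seq", "res_name")])
  set.seed(11)
  for (i in 1:8) {
    pick <- cand[sample(nrow(cand), sample(nrow(cand), 1)), , drop = FALSE]
    spec <- compensation_spec(pick)
    dg <- chain_summary(apply_charge_compensation(areas, asp, spec), ch)$dG_chain
    expect_lte(dg, base + 1e-12)
  }
})

test_that("a buried lysine ladder is destabilizing relative to leucine, and compensation removes the NZ difference", {
  mk <- function(s) {
    st <- make_fibril(fibril_recipe(s, "straight", n_layers = 5))
    ch <- central_chain_ids(st)
    buried_areas(st, ch, n_sphere_points = default_standin_points)
  }
  asp <- asp_table()
  ak <- mk("ALKALKALKA")
  al <- mk("ALLALLALLA")
  dk <- chain_summary(residue_energies(ak, asp), "A_L2")$dG_chain
  dl <- chain_summary(residue_energies(al, asp), "A_L2")$dG_chain
  expect_gt(dk, dl)  # lysine variant less stable
  kres <- unique(ak[ak$res_name == "LYS", "res_seq"])
  spec <- compensation_spec(data.frame(res_seq = kres, res_name = "LYS"))
  comp <- chain_summary(apply_charge_compensation(ak, asp, spec), "A_L2")$dG_chain
  # compensated lysine chain recovers the part of the gap due to NZ penalties
  nz <- ak$res_name == "LYS" & ak$name == "NZ"
  nz_pen <- sum(pmax(0, 0.050 * ak$buried[nz]))
  expect_equal(dk - comp, nz_pen, tolerance = 1e-9)
})
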